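sim_metrics <- function(n, seed, shift_span = 0) {
  # synthetic individual-metric table (no inference involved)
  set.seed(seed)
  data.frame(
    individual_id = sprintf("s%03d", seq_len(n)),
    observed_steps = rep(10L, n),
    switching_cost = runif(n, 0, 0.3),
    visiting_cost = runif(n, 0, 0.3),
    absence_cost = runif(n, 0, 0.3),
    community_stay = runif(n, 1, 10),
    peer_count = runif(n, 0, 4),
    peer_coordination = runif(n),
    group_size = runif(n, 1, 8),
    group_homogeneity = runif(n),
    community_size = runif(n, 1, 8),
    community_span = runif(n, 1, 20) + shift_span,
    community_apparancy = runif(n)
  )
}

attrs_for <- function(im, species = "spA") {
  synthetic_attributes(im$individual_id, species, seed = 1L)
}

test_that("feature matrix has the seven documented columns", {
  im <- sim_metrics(10, 1)
  fm <- build_feature_matrix(im, attrs_for(im))
  expect_equal(dim(fm$x), c(10L, 7L))
  expect_equal(colnames(fm$x), feature_metrics)
  expect_equal(fm$labels$individual_id, im$individual_id)
  expect_error(build_feature_matrix(im, attrs_for(im)[-1, ]),
               "missing from attribute table: s001")
})

test_that("PCA is exact, sign-fixed and permutation invariant", {
  im <- sim_metrics(30, 2)
  fm <- build_feature_matrix(im, attrs_for(im))
  pca <- run_pca(fm)
  # reconstruction: scores %*% t(loadings) gives the processed matrix back
  xs <- scale(fm$x)
  recon <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(recon - xs)), 1e-8)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))
  expect_equal(sum(pca$variance_fraction), 1)
  # orthonormal loadings
  expect_equal(t(pca$loadings) %*% pca$loadings, diag(7),
               ignore_attr = TRUE)
  # sign convention
  for (j in 1:7)
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  # permutation invariance of the spectrum
  perm <- sample(nrow(fm$x))
  fm2 <- fm; fm2$x <- fm$x[perm, ]; fm2$labels <- fm$labels[perm, ]
  expect_equal(run_pca(fm2)$variance_fraction, pca$variance_fraction)
})

test_that("collinear data loads entirely on the first component", {
  im <- sim_metrics(10, 3)
  base <- seq(0, 1, length.out = 10)
  for (m in feature_metrics) im[[m]] <- base * which(feature_metrics == m)
  fm <- build_feature_matrix(im, attrs_for(im))
  pca <- run_pca(fm, standardize = TRUE)
  expect_equal(pca$variance_fraction[1], 1)
})

test_that("zero-variance columns are rejected under standardization", {
  im <- sim_metrics(10, 4)
  im$switching_cost <- 0
  fm <- build_feature_matrix(im, attrs_for(im))
  expect_error(run_pca(fm, standardize = TRUE), "switching_cost")
  expect_silent(run_pca(fm, standardize = FALSE))
})

test_that("a planted class shift separates on PC1", {
  # a 3-within-SD between-class shift in community span dominates the
  # unstandardized covariance, so PC1 aligns with it
  im_a <- sim_metrics(20, 5)
  im_b <- sim_metrics(20, 6, shift_span = 3 * sqrt(19^2 / 12))
  im_b$individual_id <- sprintf("t%03d", 1:20)
  im <- rbind(im_a, im_b)
  at <- rbind(synthetic_attributes(im_a$individual_id, "spA", 1L),
              synthetic_attributes(im_b$individual_id, "spB", 2L))
  fm <- build_feature_matrix(im, at)
  pca <- run_pca(fm, standardize = FALSE)
  tt <- group_ttest(pca$scores, fm$labels$species, 1L)
  expect_gt(abs(tt$statistic), 5)
})

test_that("Welch t-test on scores behaves", {
  scores <- cbind(c(1:10, 1:10), rnorm(20))
  labels <- rep(c("A", "B"), each = 10)
  tt <- group_ttest(scores, labels, 1L)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  # shifted classes: p below closed-form bound
  scores2 <- cbind(c(rnorm(20), rnorm(20) + 10), 0)
  labels2 <- rep(c("A", "B"), each = 20)
  tt2 <- group_ttest(scores2, labels2, 1L)
  expect_lt(tt2$p_value, 1e-6)
  # label swap flips the sign only
  tt3 <- group_ttest(scores2, rev(labels2), 1L)
  expect_equal(tt3$statistic, -tt2$statistic)
  expect_equal(tt3$p_value, tt2$p_value)
  expect_error(group_ttest(scores, rep("A", 20), 1L), "two label classes")
})

test_that("Fisher switching test matches hypergeometric enumeration", {
  # [[5,0],[0,5]]: only tables with x = 0 or 5 are as extreme;
  # p = 2 * dhyper(5, 5, 5, 5)
  im <- sim_metrics(10, 7)
  im$switching_cost <- rep(c(0, 0.2), each = 5)
  labels <- rep(c("A", "B"), each = 5)
  p <- fisher_switching(im, labels)
  enum <- sum(vapply(0:5, function(x) {
    px <- dhyper(x, 5, 5, 5)
    if (px <= dhyper(5, 5, 5, 5) + 1e-12) px else 0
  }, numeric(1)))
  expect_equal(p, enum)
  expect_equal(p, 2 / choose(10, 5))

  # balanced table [[3,3],[2,2]]: no association
  im$switching_cost <- c(0, 0, 0, 0.2, 0.2, 0, 0, 0, 0.2, 0.2)
  expect_equal(fisher_switching(im, rep(c("A", "B"), each = 5)), 1)

  # degenerate margin
  im$switching_cost <- 0.1
  expect_warning(p1 <- fisher_switching(im, labels), "degenerate")
  expect_equal(p1, 1)
})

test_that("Fisher p equals full enumeration for random tables", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    sw <- runif(n) < 0.5
    cl <- rep(c("A", "B"), length.out = n)[sample(n)]
    im <- sim_metrics(n, i)
    im$switching_cost <- ifelse(sw, 0.1, 0)
    tab <- table(factor(sw, c(FALSE, TRUE)), factor(cl, c("A", "B")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    m <- sum(tab[, 1]); nn <- sum(tab[, 2]); kk <- sum(tab[2, ])
    p_obs <- dhyper(tab[2, 1], m, nn, kk)
    enum <- sum(vapply(0:kk, function(x) {
      px <- dhyper(x, m, nn, kk)
      if (px <= p_obs * (1 + 1e-7)) px else 0
    }, numeric(1)))
    expect_equal(fisher_switching(im, cl), enum, tolerance = 1e-7)
  }
})

test_that("radial SVM holdout is deterministic and separates clean classes", {
  im_a <- sim_metrics(20, 9)
  im_b <- sim_metrics(20, 10, shift_span = 200)
  im_b$individual_id <- sprintf("t%03d", 1:20)
  im <- rbind(im_a, im_b)
  at <- rbind(synthetic_attributes(im_a$individual_id, "spA", 1L),
              synthetic_attributes(im_b$individual_id, "spB", 2L))
  fm <- build_feature_matrix(im, at)
  acc <- svm_cv(fm, fm$labels$species, n_sims = 20L, seed = 3L)
  expect_equal(acc, 1)
  expect_equal(svm_cv(fm, fm$labels$species, n_sims = 20L, seed = 3L), acc)
  expect_error(svm_cv(fm, fm$labels$species, holdout = 0.01),
               "rounds to zero")
})
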