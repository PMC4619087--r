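## Statistical stage over the individual feature space: the seven
## community-identity metrics per individual, linear PCA, Welch t-tests on
## component scores, Fisher exact test on ever-switching by class, and a
## radial-SVM repeated stratified holdout.

#' Build the individual feature matrix
#'
#' Rows are observed individuals, columns the seven feature metrics in the
#' fixed order of [feature_metrics]; class labels (species, sex,
#' reproductive status) are joined from the attribute table.
#'
#' @param im data.frame from [individual_metrics()].
#' @param attributes data.frame from [read_attributes()] covering every
#'   individual in `im`.
#' @return A list of class `feature_matrix` with `x` (numeric matrix,
#'   rownames = individual ids) and `labels` (data.frame).
#' @export
build_feature_matrix <- function(im, attributes) {
  missing <- setdiff(im$individual_id, attributes$individual_id)
  if (length(missing))
    stop("individuals missing from attribute table: ",
         paste(missing, collapse = ", "))
  x <- as.matrix(im[, feature_metrics])
  rownames(x) <- im$individual_id
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature matrix contains missing values")
  labels <- attributes[match(im$individual_id, attributes$individual_id), ]
  rownames(labels) <- NULL
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' Linear PCA of the feature matrix
#'
#' Columns are centered and, by default, scaled to unit variance (the seven
#' metrics have incommensurate units). The decomposition is deterministic up
#' to sign; signs are fixed so that each loading column's largest-magnitude
#' entry is positive.
#'
#' @param fm a `feature_matrix`.
#' @param standardize scale columns to unit variance before decomposition.
#' @return A list of class `pca_result` with `loadings` (metric x
#'   component), `scores` (individual x component), `variance_fraction`,
#'   and the centering/scaling used.
#' @export
run_pca <- function(fm, standardize = TRUE) {
  x <- fm$x
  if (nrow(x) < 3L) stop("PCA needs at least 3 rows")
  sds <- apply(x, 2L, stats::sd)
  if (standardize && any(sds == 0))
    stop("zero-variance column under standardization: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  p <- prcomp(x, center = TRUE, scale. = standardize)
  for (j in seq_len(ncol(p$rotation))) {
    lead <- which.max(abs(p$rotation[, j]))
    if (p$rotation[lead, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(loadings = p$rotation, scores = p$x,
                 variance_fraction = p$sdev^2 / sum(p$sdev^2),
                 center = p$center, scale = p$scale),
            class = "pca_result")
}

#' Welch two-sample t-test on component scores
#'
#' @param scores score matrix from [run_pca()] (or any numeric matrix).
#' @param labels vector with exactly two classes (each with >= 2 members).
#' @param component column to test (default 1).
#' @return A list with `statistic`, `p_value`, `classes`.
#' @export
group_ttest <- function(scores, labels, component = 1L) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("exactly two label classes required")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 members")
  s <- scores[, component]
  tt <- t.test(s[labels == levels(labels)[1L]],
               s[labels == levels(labels)[2L]], var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       classes = levels(labels))
}

#' Fisher exact test on ever-switching by class
#'
#' Dichotomizes individuals on any community switching (switch count > 0)
#' and tests association with a two-class label via the two-sided Fisher
#' exact test. A degenerate table (an empty margin) yields p = 1 with a
#' warning.
#'
#' @param im data.frame from [individual_metrics()].
#' @param labels class per individual, aligned with `im` rows.
#' @return The two-sided p-value.
#' @export
fisher_switching <- function(im, labels) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("exactly two label classes required")
  switched <- factor(im$switching_cost > 0, levels = c(FALSE, TRUE),
                     labels = c("never", "switched"))
  tab <- table(switched, labels)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate 2x2 table (empty margin); p = 1")
    return(1)
  }
  fisher.test(tab)$p.value
}

#' Radial-SVM repeated stratified holdout accuracy
#'
#' `n_sims` random splits reserving `holdout` of each class for testing; a
#' radial-basis SVM (kernel width from the median heuristic on the scaled
#' features, regularization cost 1) is trained on the remainder and scored
#' on the holdout. Deterministic given `seed`.
#'
#' @param fm a `feature_matrix`.
#' @param labels class per individual (>= 2 classes).
#' @param n_sims number of random splits (default 99).
#' @param holdout fraction of each class reserved for testing (default 0.1).
#' @param seed integer seed.
#' @return Mean test accuracy over the splits.
#' @export
svm_cv <- function(fm, labels, n_sims = 99L, holdout = 0.1, seed = 0L) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("need at least two classes")
  x <- fm$x
  counts <- table(labels)
  n_test <- round(as.numeric(counts) * holdout)
  if (any(n_test < 1L))
    stop("holdout rounds to zero for class: ",
         paste(names(counts)[n_test < 1L], collapse = ", "))
  xs <- scale(x)
  d2 <- as.numeric(dist(xs))^2
  gamma <- 1 / (2 * median(d2[d2 > 0]))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  acc <- vapply(seq_len(n_sims), function(sim) {
    test_idx <- unlist(lapply(seq_along(counts), function(k) {
      members <- which(labels == names(counts)[k])
      sample(members, n_test[k])
    }))
    fit <- e1071::svm(x[-test_idx, , drop = FALSE],
                      droplevels(labels[-test_idx]),
                      kernel = "radial", gamma = gamma, cost = 1,
                      scale = TRUE)
    pred <- stats::predict(fit, x[test_idx, , drop = FALSE])
    mean(as.character(pred) == as.character(labels[test_idx]))
  }, numeric(1))
  mean(acc)
}
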