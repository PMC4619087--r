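## Exhaustive small-instance oracle for the coloring optimization (the exact
## problem is NP-complete; the matching + DP pipeline is a heuristic, and
## this oracle provides ground truth on tiny instances).
##
## Group colorings are enumerated canonically (restricted-growth strings) up
## to color relabeling, restricted to "proper" colorings where no two groups
## at the same step share a color -- the one-group-per-community-per-step
## semantics; every coloring the heuristic can produce lies in this space.
## Given a fixed group coloring, the optimal individual assignment is exact:
## a batched DP over all colors plus one fresh color. Costs incurred outside
## an individual's observation window are zero and an optimal sequence never
## needs to switch there, so running the batched DP over all steps yields
## the window-restricted optimum.

#' Exhaustive optimum of the dynamic community coloring
#'
#' Brute-force global minimum of the switch/visit/absence cost over all
#' group colorings (up to relabeling, no color reuse within a step) and all
#' individual color sequences. Refuses instances beyond the stated limits.
#'
#' @param timeline a `grouping_timeline`.
#' @param costs a [cost_settings()].
#' @param limits list with `max_individuals` (default 5), `max_steps` (4)
#'   and `max_groups_per_step` (3).
#' @return A list with `cost` (the global optimum) and `structure` (one
#'   optimal `dynamic_communities` object).
#' @export
brute_force_oracle <- function(timeline, costs = cost_settings(),
                               limits = list()) {
  lim <- utils::modifyList(
    list(max_individuals = 5L, max_steps = 4L, max_groups_per_step = 3L),
    limits)
  T <- n_steps(timeline)
  if (length(timeline$individuals) > lim$max_individuals)
    stop("instance above limit: > ", lim$max_individuals, " individuals")
  if (T > lim$max_steps)
    stop("instance above limit: > ", lim$max_steps, " steps")
  if (max(lengths(timeline$groups)) > lim$max_groups_per_step)
    stop("instance above limit: > ", lim$max_groups_per_step,
         " groups per step")

  ids <- timeline$individuals
  n <- length(ids)
  group_step <- rep(seq_len(T), lengths(timeline$groups))
  group_ids <- unlist(lapply(timeline$groups, names), use.names = FALSE)
  G <- length(group_ids)
  C <- G + 1L  # enough colors for any canonical coloring plus a fresh one

  ## og_idx[i, t]: flat group index holding individual i at step t (0 = none)
  og_idx <- matrix(0L, nrow = n, ncol = T)
  flat <- 0L
  for (t in seq_len(T)) for (g in seq_along(timeline$groups[[t]])) {
    flat <- flat + 1L
    og_idx[match(timeline$groups[[t]][[g]], ids), t] <- flat
  }
  windows <- t(vapply(seq_len(n), function(i) {
    obs <- which(og_idx[i, ] > 0L)
    c(min(obs), max(obs))
  }, integer(2)))

  alpha <- costs$switch_cost; beta <- costs$visit_cost
  gamma <- costs$absence_cost

  eval_coloring <- function(col) {
    present <- matrix(FALSE, nrow = T, ncol = C)
    present[cbind(group_step, col)] <- TRUE
    f <- matrix(0, nrow = n, ncol = C)
    for (t in seq_len(T)) {
      if (t > 1L) {
        fmin <- apply(f, 1L, min)
        f <- pmin(f, fmin + alpha)
      }
      for (i in seq_len(n)) {
        if (t < windows[i, 1L] || t > windows[i, 2L]) next
        gi <- og_idx[i, t]
        if (gi > 0L) {
          e <- rep(beta, C); e[col[gi]] <- 0
        } else {
          e <- gamma * present[t, ]
        }
        f[i, ] <- f[i, ] + e
      }
    }
    sum(apply(f, 1L, min))
  }

  best_cost <- Inf
  best_col <- NULL
  col <- integer(G)
  recurse <- function(j, max_used) {
    if (j > G) {
      cost <- eval_coloring(col)
      if (cost < best_cost) {
        best_cost <<- cost
        best_col <<- col
      }
      return(invisible(NULL))
    }
    same_step <- which(group_step[seq_len(j - 1L)] == group_step[j])
    used_here <- col[same_step]
    for (c in seq_len(max_used + 1L)) {
      if (c %in% used_here) next
      col[j] <<- c
      recurse(j + 1L, max(max_used, c))
    }
    invisible(NULL)
  }
  if (G == 0L) stop("timeline has no groups")
  recurse(1L, 0L)

  group_colors <- data.frame(step = group_step, group_id = group_ids,
                             color = best_col)
  structure_out <- build_structure(timeline, group_colors, costs,
                                   candidate_mode = "all")
  list(cost = best_cost, structure = structure_out)
}
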