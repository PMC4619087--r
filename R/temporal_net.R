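## Temporal analogues of the static summaries, built on time-respecting
## paths: successive edges occur at non-decreasing time steps, and edges
## within one step may be chained in any order within that step (group
## cliques make within-step components coincide with groups).

#' Earliest-arrival latencies from one source
#'
#' Latency of v = (earliest step t >= start at which v is reachable from the
#' source by a time-respecting path) - start + 1; the source itself has
#' latency 0; unreachable nodes are `NA`. Latency counts elapsed sampling
#' occasions, not calendar days.
#'
#' @param snapshots list of per-step graphs from [build_snapshots()].
#' @param source individual id.
#' @param start first step the walk may use (default 1).
#' @return Named numeric vector of latencies over all individuals seen
#'   anywhere in the snapshots.
#' @export
earliest_arrival_distance <- function(snapshots, source, start = 1L) {
  all_ids <- sort(unique(unlist(lapply(snapshots, function(g)
    igraph::V(g)$name))))
  if (!source %in% all_ids) stop("unknown source id '", source, "'")
  if (start < 1L || start > length(snapshots)) stop("start outside timeline")
  latency <- setNames(rep(NA_real_, length(all_ids)), all_ids)
  latency[source] <- 0
  reached <- source
  for (t in seq(start, length(snapshots))) {
    g <- snapshots[[t]]
    if (igraph::vcount(g) == 0L) next
    comp <- igraph::components(g)
    mem <- setNames(comp$membership, igraph::V(g)$name)
    hit <- unique(mem[names(mem) %in% reached])
    if (length(hit)) {
      new_nodes <- names(mem)[mem %in% hit]
      new_nodes <- setdiff(new_nodes, reached)
      if (length(new_nodes)) {
        latency[new_nodes] <- t - start + 1
        reached <- c(reached, new_nodes)
      }
    }
  }
  latency
}

#' Temporal network summary
#'
#' Reports two documented density variants side by side -- the mean per-step
#' density among observed nodes and the temporal reachability density (the
#' fraction of ordered pairs (u, v) with v reachable from u by a
#' time-respecting path starting at step 1) -- together with the mean
#' earliest-arrival latency over reachable ordered pairs, the temporal
#' diameter (maximum latency) and the mean per-step clustering coefficient.
#'
#' @param snapshots list of per-step graphs from [build_snapshots()].
#' @return A list of class `temporal_summary` with fields
#'   `mean_snapshot_density`, `reachability_density`, `mean_latency`,
#'   `temporal_diameter`, `mean_snapshot_clustering`.
#' @export
temporal_summary <- function(snapshots) {
  stopifnot(length(snapshots) >= 1L)
  all_ids <- sort(unique(unlist(lapply(snapshots, function(g)
    igraph::V(g)$name))))
  n <- length(all_ids)
  snap_density <- vapply(snapshots, function(g) {
    if (igraph::vcount(g) < 2L) 0 else igraph::edge_density(g)
  }, numeric(1))
  snap_clust <- vapply(snapshots, function(g) {
    if (igraph::vcount(g) == 0L) return(0)
    cl <- igraph::transitivity(g, type = "local", isolates = "zero")
    cl[is.na(cl)] <- 0
    mean(cl)
  }, numeric(1))
  lat <- unlist(lapply(all_ids, function(u) {
    l <- earliest_arrival_distance(snapshots, u, start = 1L)
    l[names(l) != u]
  }))
  reachable <- lat[!is.na(lat)]
  structure(list(
    mean_snapshot_density = mean(snap_density),
    reachability_density = if (n < 2L) 0 else length(reachable) / (n * (n - 1)),
    mean_latency = if (length(reachable)) mean(reachable) else NA_real_,
    temporal_diameter = if (length(reachable)) max(reachable) else NA_real_,
    mean_snapshot_clustering = mean(snap_clust)
  ), class = "temporal_summary")
}
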