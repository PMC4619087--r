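## Static network summaries and Louvain community detection.

#' Summary measures of an aggregated static network
#'
#' Density, mean shortest path, diameter, mean local clustering and connected
#' components of the unweighted skeleton. Path measures are averaged over
#' reachable ordered pairs only (field association networks routinely have
#' several components, under which an all-pairs convention is infinite);
#' nodes of degree < 2 contribute local clustering 0.
#'
#' @param net an undirected igraph (e.g. from [aggregate_static()]).
#' @return A list of class `static_summary` with fields `density`,
#'   `mean_shortest_path`, `diameter`, `mean_clustering`, `n_components`,
#'   `component_sizes`. Path measures are `NA` when no pair is reachable.
#' @export
static_summary <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  density <- if (n < 2L) 0 else igraph::edge_density(net)
  d <- igraph::distances(net, weights = NA)
  finite <- d[is.finite(d) & d > 0]
  cl <- igraph::transitivity(net, type = "local", isolates = "zero")
  cl[is.na(cl)] <- 0
  comps <- igraph::components(net)
  structure(list(
    density = density,
    mean_shortest_path = if (length(finite)) mean(finite) else NA_real_,
    diameter = if (length(finite)) max(finite) else NA_real_,
    mean_clustering = mean(cl),
    n_components = comps$no,
    component_sizes = as.integer(comps$csize)
  ), class = "static_summary")
}

#' Louvain static communities
#'
#' Greedy multi-level modularity maximization on the weighted static network
#' (co-sighting counts as weights, resolution 1). Deterministic given `seed`.
#'
#' @param net undirected igraph; optional edge attribute `weight`.
#' @param seed integer seed controlling the (stochastic) level moves.
#' @return Named integer vector: community id per node. An edgeless network
#'   yields the all-singletons partition.
#' @export
detect_static_communities <- function(net, seed = 0L) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  if (igraph::ecount(net) == 0L) {
    return(setNames(seq_len(igraph::vcount(net)), igraph::V(net)$name))
  }
  w <- igraph::E(net)$weight
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cl <- igraph::cluster_louvain(net, weights = w)
  setNames(as.integer(igraph::membership(cl)), igraph::V(net)$name)
}

#' Weighted modularity of a node partition
#'
#' @param net undirected igraph with optional `weight` edge attribute.
#' @param membership named (or vertex-ordered) integer vector of community ids.
#' @return Modularity value.
#' @export
partition_modularity <- function(net, membership) {
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(net)$name]
  igraph::modularity(net, membership, weights = igraph::E(net)$weight)
}
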