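## Grouping timeline: the observational input. `groups[[t]]` is a named list
## of character vectors (group id -> member ids); groups within a step are
## disjoint and non-empty. Steps are consecutive sampling occasions 1..T;
## the original labels (e.g. calendar day numbers) are kept in `step_labels`.

#' Construct a grouping timeline
#'
#' A grouping timeline is an ordered sequence of sampling occasions (time
#' steps), each holding a set of pairwise-disjoint, non-empty groups of
#' individual ids. It is the sole observational input to dynamic community
#' inference: group co-membership at a step is the association ("gambit of
#' the group").
#'
#' @param groups list of length T; element t is a named list of character
#'   vectors, one per group observed at step t (names are group ids, scoped
#'   to that step). Unnamed lists receive ids `"G1"`, `"G2"`, ...
#' @param step_labels optional vector of original step labels (e.g. day
#'   numbers); defaults to `1:T`.
#' @return An object of class `grouping_timeline` with fields `steps`,
#'   `groups`, `individuals` and `step_labels`.
#' @export
grouping_timeline <- function(groups, step_labels = seq_along(groups)) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            length(step_labels) == length(groups))
  groups <- lapply(groups, function(gs) {
    gs <- lapply(gs, function(g) sort(as.character(g)))
    if (is.null(names(gs)) || any(!nzchar(names(gs)))) {
      names(gs) <- paste0("G", seq_along(gs))
    }
    gs[order(names(gs))]
  })
  for (t in seq_along(groups)) {
    gs <- groups[[t]]
    if (anyDuplicated(names(gs)))
      stop("duplicate group ids at step ", t)
    sizes <- lengths(gs)
    if (length(gs) && any(sizes == 0L))
      stop("empty group at step ", t)
    members <- unlist(gs, use.names = FALSE)
    if (anyDuplicated(members)) {
      dup <- members[duplicated(members)][1L]
      stop("individual '", dup, "' appears in two groups at step ", t)
    }
  }
  individuals <- sort(unique(unlist(groups, use.names = FALSE)))
  if (length(individuals) == 0L)
    stop("timeline contains no observed individuals")
  structure(
    list(steps = seq_along(groups), groups = groups,
         individuals = individuals, step_labels = step_labels),
    class = "grouping_timeline"
  )
}

#' @export
print.grouping_timeline <- function(x, ...) {
  cat("<grouping_timeline> ", length(x$individuals), " individuals, ",
      length(x$steps), " time steps, ",
      sum(lengths(x$groups)), " groups\n", sep = "")
  invisible(x)
}

n_steps <- function(timeline) length(timeline$steps)

#' Read group-sighting records
#'
#' Parses a sightings CSV with header `time_step,individual_id,group_id` into
#' a [grouping_timeline()]. Time steps are re-indexed to consecutive
#' `1..T` preserving order (sampling occasions, not calendar days); the
#' original labels are retained in `step_labels`. Group ids are scoped to a
#' time step: `G1` at step 1 and `G1` at step 2 are distinct groups, since
#' group identity across time is what the inference estimates.
#'
#' @param path path to the CSV file.
#' @return A `grouping_timeline`.
#' @export
parse_sightings <- function(path) {
  df <- read.csv(path, colClasses = "character")
  required <- c("time_step", "individual_id", "group_id")
  if (!all(required %in% names(df)))
    stop("sightings file must have columns ", paste(required, collapse = ", "))
  if (nrow(df) == 0L) stop("sightings file is empty")
  ts <- suppressWarnings(as.integer(df$time_step))
  if (anyNA(ts) || any(ts != as.numeric(df$time_step)) || any(ts <= 0L))
    stop("time_step must be a positive integer (offending value: '",
         df$time_step[which(is.na(ts) | ts <= 0L)[1L]], "')")
  key <- paste(ts, df$individual_id)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop("individual '", df$individual_id[bad],
         "' appears more than once at time step ", ts[bad])
  }
  labels <- sort(unique(ts))
  idx <- match(ts, labels)
  groups <- lapply(seq_along(labels), function(t) {
    sel <- idx == t
    split(df$individual_id[sel], df$group_id[sel])
  })
  grouping_timeline(groups, step_labels = labels)
}

#' Write a grouping timeline as a sightings CSV
#'
#' Inverse of [parse_sightings()] up to row order: the original time-step
#' labels are written back.
#'
#' @param timeline a `grouping_timeline`.
#' @param path output path.
#' @export
write_sightings <- function(timeline, path) {
  rows <- do.call(rbind, lapply(timeline$steps, function(t) {
    gs <- timeline$groups[[t]]
    if (length(gs) == 0L) return(NULL)
    data.frame(time_step = timeline$step_labels[t],
               individual_id = unlist(gs, use.names = FALSE),
               group_id = rep(names(gs), lengths(gs)))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an individual attribute table
#'
#' @param path CSV with columns `individual_id,species,sex,reproductive_status`.
#' @return A data.frame with one row per individual; ids must be unique.
#' @export
read_attributes <- function(path) {
  df <- read.csv(path, colClasses = "character")
  required <- c("individual_id", "species", "sex", "reproductive_status")
  if (!all(required %in% names(df)))
    stop("attribute file must have columns ", paste(required, collapse = ", "))
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual_id in attribute table: ",
         df$individual_id[duplicated(df$individual_id)][1L])
  df[required]
}

#' Per-step snapshot networks
#'
#' One undirected graph per time step: nodes are the individuals observed at
#' that step and each group of size k contributes its k(k-1)/2 clique edges,
#' so snapshot edges form disjoint cliques (one per group).
#'
#' @param timeline a `grouping_timeline`.
#' @return A list of igraph objects, one per step (graph attribute `step`).
#' @export
build_snapshots <- function(timeline) {
  lapply(timeline$steps, function(t) {
    gs <- timeline$groups[[t]]
    nodes <- unlist(gs, use.names = FALSE)
    edges <- unlist(lapply(gs, function(g) {
      if (length(g) < 2L) return(character(0))
      as.vector(utils::combn(g, 2L))
    }))
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    igraph::set_graph_attr(g, "step", t)
  })
}

#' Aggregate a timeline into a weighted static network
#'
#' Edge weight(u, v) = number of time steps at which u and v shared a group.
#' All individuals appear as nodes; individuals never co-grouped remain
#' isolated nodes. Distinct timelines can aggregate to identical static
#' networks -- the information the dynamic analysis recovers.
#'
#' @param timeline a `grouping_timeline`.
#' @return An undirected igraph with integer edge attribute `weight`.
#' @export
aggregate_static <- function(timeline) {
  pair_rows <- do.call(rbind, lapply(timeline$steps, function(t) {
    do.call(rbind, lapply(timeline$groups[[t]], function(g) {
      if (length(g) < 2L) return(NULL)
      t(utils::combn(g, 2L))
    }))
  }))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(timeline$individuals),
                            name = timeline$individuals)
  if (!is.null(pair_rows) && nrow(pair_rows)) {
    key <- paste(pair_rows[, 1L], pair_rows[, 2L], sep = "\r")
    counts <- table(key)
    uv <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(uv)),
                           weight = as.integer(counts))
  }
  g
}

#' Export the static network as GraphML
#'
#' @param net igraph static network from [aggregate_static()].
#' @param path output path.
#' @export
write_static_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Export snapshot networks as per-step edge lists
#'
#' Writes `snapshot_<t>.csv` (columns `from,to`) per step into `dir`.
#'
#' @param snapshots list of snapshot graphs from [build_snapshots()].
#' @param dir output directory (created if missing).
#' @export
write_snapshot_edgelists <- function(snapshots, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in snapshots) {
    t <- igraph::graph_attr(g, "step")
    el <- igraph::as_edgelist(g)
    df <- data.frame(from = el[, 1L], to = el[, 2L])
    write.csv(df, file.path(dir, sprintf("snapshot_%03d.csv", t)),
              row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
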