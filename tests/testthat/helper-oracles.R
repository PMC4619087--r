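# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive quantities by brute force / enumeration rather than
# calling the implementation under test.

# all set partitions of n items as membership vectors (restricted growth)
enum_partitions <- function(n) {
  out <- list()
  rec <- function(mem, max_used) {
    j <- length(mem) + 1L
    if (j > n) {
      out[[length(out) + 1L]] <<- mem
      return(invisible(NULL))
    }
    for (c in seq_len(max_used + 1L)) rec(c(mem, c), max(max_used, c))
  }
  rec(integer(0), 0L)
  out
}

# earliest-arrival latencies by explicit BFS over (node, time) states:
# bidirectional co-grouping edges within a step, directed waiting edges to
# the next step
bf_earliest_arrival <- function(timeline, source, start) {
  T <- length(timeline$steps)
  ids <- timeline$individuals
  node <- function(v, t) paste0(v, "|", t)
  edges <- character(0)
  for (t in seq_len(T)) {
    for (g in timeline$groups[[t]]) {
      if (length(g) >= 2L) {
        pr <- t(combn(g, 2L))
        for (r in seq_len(nrow(pr))) {
          edges <- c(edges, node(pr[r, 1], t), node(pr[r, 2], t),
                     node(pr[r, 2], t), node(pr[r, 1], t))
        }
      }
    }
    if (t < T) for (v in ids)
      edges <- c(edges, node(v, t), node(v, t + 1L))
  }
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(ids) * T,
                            name = as.vector(outer(ids, seq_len(T), node)))
  if (length(edges)) g <- igraph::add_edges(g, edges)
  reach <- igraph::subcomponent(g, node(source, start), mode = "out")$name
  lat <- setNames(rep(NA_real_, length(ids)), ids)
  lat[source] <- 0
  for (v in setdiff(ids, source)) {
    ts <- as.integer(sub("^.*\\|", "", grep(paste0("^", v, "\\|"), reach,
                                            value = TRUE)))
    ts <- ts[ts >= start]
    if (length(ts)) lat[v] <- min(ts) - start + 1
  }
  lat
}

# exhaustive minimum cost over all candidate color sequences for one
# individual, given fixed group colors
dp_enum <- function(individual, timeline, group_colors, costs,
                    candidates = NULL) {
  T <- length(timeline$steps)
  og <- vapply(seq_len(T), function(t) {
    gs <- timeline$groups[[t]]
    hit <- which(vapply(gs, function(g) individual %in% g, logical(1)))
    if (length(hit)) names(gs)[hit] else NA_character_
  }, character(1))
  obs <- which(!is.na(og))
  window <- min(obs):max(obs)
  gcol <- setNames(group_colors$color,
                   paste(group_colors$step, group_colors$group_id))
  obs_color <- ifelse(is.na(og), NA_integer_, gcol[paste(seq_len(T), og)])
  cand <- if (is.null(candidates))
    sort(unique(obs_color[!is.na(obs_color)])) else candidates
  present <- function(t, c) any(group_colors$color[group_colors$step == t] == c)
  seqs <- do.call(expand.grid, rep(list(cand), length(window)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    cs <- as.integer(seqs[r, ])
    cost <- costs$switch_cost * sum(diff(cs) != 0)
    for (w in seq_along(window)) {
      t <- window[w]
      if (!is.na(og[t])) {
        if (obs_color[t] != cs[w]) cost <- cost + costs$visit_cost
      } else if (present(t, cs[w])) cost <- cost + costs$absence_cost
    }
    best <- min(best, cost)
  }
  best
}

# random tiny instance within the exhaustive-oracle limits; total group
# count capped so full enumeration stays cheap
random_small_timeline <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  T <- sample(2:4, 1)
  ids <- letters[seq_len(n)]
  repeat {
    groups <- lapply(seq_len(T), function(t) {
      present <- ids[runif(n) < 0.8]
      if (length(present) == 0L) present <- sample(ids, 1)
      k <- min(sample(1:3, 1, prob = c(0.35, 0.45, 0.2)), length(present))
      cells <- sample(rep_len(seq_len(k), length(present)))
      unname(split(present, cells))
    })
    if (sum(lengths(groups)) <= 9L) break
  }
  grouping_timeline(groups)
}

# persistent two-community fixture: identical disjoint groups every step
persistent_timeline <- function(T = 4L) {
  grouping_timeline(rep(list(list(R = c("r1", "r2", "r3"),
                                  B = c("b1", "b2"))), T))
}

# five-individual fixture in which focal "f" rides the red chain for two
# steps and the blue chain for two steps; both chains persist throughout
red_blue_timeline <- function() {
  grouping_timeline(list(
    list(R = c("r1", "r2", "f"), B = c("b1", "b2")),
    list(R = c("r1", "r2", "f"), B = c("b1", "b2")),
    list(R = c("r1", "r2"), B = c("b1", "b2", "f")),
    list(R = c("r1", "r2"), B = c("b1", "b2", "f"))
  ))
}

write_tmp_sightings <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("time_step,individual_id,group_id", rows), path)
  path
}
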