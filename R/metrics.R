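## Dynamic community metrics at group, community and individual level,
## computed from an inferred (or oracle) structure.

#' Per-group metrics
#'
#' Size counts all occupants of the group (members and visitors; absents are
#' by definition not in the group). Homogeneity is the fraction of occupants
#' whose individual color equals the group color; a group occupied only by
#' visitors has homogeneity 0 (the metric lives in \[0, 1\]).
#'
#' @param structure a `dynamic_communities` object.
#' @return A data.frame with columns `step`, `group_id`, `color`, `size`,
#'   `homogeneity`.
#' @export
group_metrics <- function(structure) {
  ev <- structure$events
  occ <- ev[!is.na(ev$group_id), , drop = FALSE]
  key <- paste(occ$time_step, occ$group_id, sep = "\r")
  agg <- lapply(split(occ, key), function(d) {
    data.frame(step = d$time_step[1L], group_id = d$group_id[1L],
               color = d$group_color[1L], size = nrow(d),
               homogeneity = mean(d$individual_color == d$group_color))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$step, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-community metrics
#'
#' A community is the set of groups of one color over time. Presence steps
#' are steps with at least one group of that color; span is last presence
#' minus first presence plus one (inclusive, so that apparancy -- presence
#' count over span -- is a fraction in (0, 1\]); size is the mean over
#' presence steps of the number of affiliated individuals (members,
#' including absents, excluding visitors).
#'
#' @param structure a `dynamic_communities` object.
#' @return A data.frame with columns `color`, `first_step`, `last_step`,
#'   `span`, `n_present`, `apparancy`, `size`.
#' @export
community_metrics <- function(structure) {
  gc <- structure$group_colors
  ic <- structure$ind_colors
  out <- do.call(rbind, lapply(sort(unique(gc$color)), function(cc) {
    steps <- sort(unique(gc$step[gc$color == cc]))
    span <- max(steps) - min(steps) + 1L
    sizes <- vapply(steps, function(t)
      sum(ic[, t] == cc, na.rm = TRUE), numeric(1))
    data.frame(color = cc, first_step = min(steps), last_step = max(steps),
               span = span, n_present = length(steps),
               apparancy = length(steps) / span, size = mean(sizes))
  }))
  rownames(out) <- NULL
  out
}

## mean length of maximal constant runs in a vector
mean_run_length <- function(x) mean(rle(x)$lengths)

#' Per-individual metrics
#'
#' Switching, visiting and absence costs are event counts normalized by the
#' number of observed steps. Community stay is the mean length (in time
#' steps) of maximal constant-color runs within the observation window (set
#' `stay_normalized = TRUE` to divide by the observed-step count instead).
#' Peers at a step are same-group occupants sharing the individual's own
#' color; peer coordination at step t is the fraction of current peers that
#' were peers at t - 1, averaged over steps where the individual is observed,
#' was observed at t - 1 and has at least one current peer (steps with no
#' current peers are skipped, not counted as zero; individuals with no
#' qualifying step report 0). Community size / span / apparancy average the
#' community metrics over the distinct colors the individual ever holds
#' (`community_time_weighted = TRUE` weights colors by steps held).
#'
#' @param structure a `dynamic_communities` object.
#' @param stay_normalized divide community stay by observed steps.
#' @param community_time_weighted time-weight the community-level averages.
#' @return A data.frame, one row per observed individual.
#' @export
individual_metrics <- function(structure, stay_normalized = FALSE,
                               community_time_weighted = FALSE) {
  ev <- structure$events
  gm <- group_metrics(structure)
  cm <- community_metrics(structure)
  ledger <- structure$ledger
  ic <- structure$ind_colors
  gkey <- paste(gm$step, gm$group_id, sep = "\r")

  ## peer sets: per (step, group), occupant ids and colors
  occ <- ev[!is.na(ev$group_id), , drop = FALSE]
  occ_split <- split(occ, paste(occ$time_step, occ$group_id, sep = "\r"))

  out <- do.call(rbind, lapply(ledger$individual_id, function(id) {
    led <- ledger[ledger$individual_id == id, ]
    mine <- ev[ev$individual_id == id, , drop = FALSE]
    obs <- mine[!is.na(mine$group_id), , drop = FALSE]
    n_obs <- nrow(obs)
    window <- which(!is.na(ic[id, ]))
    colors_held <- ic[id, window]

    ## peers per observed step
    peers <- lapply(seq_len(nrow(mine)), function(t) {
      if (is.na(mine$group_id[t])) return(NULL)
      cell <- occ_split[[paste(mine$time_step[t], mine$group_id[t],
                               sep = "\r")]]
      others <- cell[cell$individual_id != id, , drop = FALSE]
      others$individual_id[others$individual_color ==
                             mine$individual_color[t]]
    })
    peer_counts <- vapply(which(!is.na(mine$group_id)), function(t)
      length(peers[[t]]), numeric(1))
    coord <- c()
    for (t in seq_len(nrow(mine))[-1]) {
      if (is.na(mine$group_id[t]) || is.na(mine$group_id[t - 1L])) next
      cur <- peers[[t]]
      if (length(cur) == 0L) next
      coord <- c(coord, length(intersect(cur, peers[[t - 1L]])) / length(cur))
    }

    gsub <- gm[match(paste(obs$time_step, obs$group_id, sep = "\r"), gkey), ]
    held <- if (community_time_weighted) colors_held else
      sort(unique(colors_held))
    csub <- cm[match(held, cm$color), , drop = FALSE]
    stay <- mean_run_length(colors_held)
    data.frame(
      individual_id = id,
      observed_steps = n_obs,
      switching_cost = led$switches / n_obs,
      visiting_cost = led$visits / n_obs,
      absence_cost = led$absences / n_obs,
      community_stay = if (stay_normalized) stay / n_obs else stay,
      peer_count = mean(peer_counts),
      peer_coordination = if (length(coord)) mean(coord) else 0,
      group_size = mean(gsub$size),
      group_homogeneity = mean(gsub$homogeneity),
      community_size = mean(csub$size, na.rm = TRUE),
      community_span = mean(csub$span, na.rm = TRUE),
      community_apparancy = mean(csub$apparancy, na.rm = TRUE)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Write the three metric tables
#'
#' Writes `group_metrics.csv`, `community_metrics.csv` and
#' `individual_metrics.csv` into `dir`; the individual table gains a
#' companion long-format column `feature` marking the seven metrics used in
#' the statistical feature space (see [feature_metrics]).
#'
#' @param structure a `dynamic_communities` object.
#' @param dir output directory (created if missing).
#' @param ... passed to [individual_metrics()].
#' @export
write_metrics <- function(structure, dir, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(group_metrics(structure), file.path(dir, "group_metrics.csv"),
            row.names = FALSE)
  write.csv(community_metrics(structure),
            file.path(dir, "community_metrics.csv"), row.names = FALSE)
  im <- individual_metrics(structure, ...)
  long <- do.call(rbind, lapply(
    setdiff(names(im), "individual_id"), function(mname)
      data.frame(individual_id = im$individual_id, metric = mname,
                 value = im[[mname]],
                 feature = mname %in% feature_metrics)))
  write.csv(long, file.path(dir, "individual_metrics.csv"),
            row.names = FALSE)
  invisible(dir)
}
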