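## Native-contact order parameters and refolding-landscape analysis.
##
## Q fractions use the conventional formed criterion dist < lambda * r0
## (lambda = 1.2 by default); for dual-basin contacts the basin-specific
## distance of the state whose Q is being computed must be supplied via
## the contact subset (state subsets are taken from the per-state
## single-basin maps, so each carries its own r0).

#' Fraction of native contacts formed in one frame
#'
#' @param frame n x 3 coordinates, nm.
#' @param contacts data.frame with columns `i`, `j`, `r0` (nm).
#' @param lambda formed-contact factor: a contact counts as formed when its
#'   distance is below `lambda * r0` (default 1.2).
#' @return fraction in `[0, 1]`.
#' @export
q_fraction <- function(frame, contacts, lambda = 1.2) {
  if (is.null(contacts) || nrow(contacts) == 0)
    stop("empty contact set: Q is undefined")
  frame <- as.matrix(frame)
  d <- sqrt(rowSums((frame[contacts$i, , drop = FALSE] -
                     frame[contacts$j, , drop = FALSE])^2))
  mean(d < lambda * contacts$r0)
}

#' Order-parameter definitions for a fold-switch system
#'
#' @param id ID (interdomain) contact subset, data.frame `i`,`j`,`r0`.
#' @param state_a,state_b native contact subsets of the two end states of
#'   the switching segment (e.g. the helical-hairpin and beta-barrel forms
#'   of KOW), each with its own `r0`.
#' @param anchor_idx,switch_idx atom indices of the anchored domain (NGN)
#'   and the switching segment (KOW).
#' @param ref_active_dist reference centre-of-geometry distance between the
#'   two domains in the active state, nm (subtracted to give Delta-d).
#' @param lambda formed-contact factor.
#' @param extra_groups optional named list of atom-index vectors; the
#'   switch-segment COG distance to each is reported as an extra column.
#' @return list of class `op_defs`.
#' @export
op_defs <- function(id, state_a, state_b, anchor_idx, switch_idx,
                    ref_active_dist, lambda = 1.2, extra_groups = list()) {
  stopifnot(length(anchor_idx) > 0, length(switch_idx) > 0)
  structure(list(id = id, state_a = state_a, state_b = state_b,
                 anchor_idx = anchor_idx, switch_idx = switch_idx,
                 ref_active_dist = ref_active_dist, lambda = lambda,
                 extra_groups = extra_groups),
            class = "op_defs")
}

cog_dist <- function(frame, ia, ib) {
  sqrt(sum((colMeans(frame[ia, , drop = FALSE]) -
            colMeans(frame[ib, , drop = FALSE]))^2))
}

#' Per-frame order parameters of a trajectory
#'
#' Computes Q_ID, Q of both end states (Q_a / Q_b, e.g. Q_KOW-alpha and
#' Q_KOW-beta), their difference Q_diff = Q_b - Q_a, and Delta-d (the
#' anchor-switch centre-of-geometry distance minus its active-state
#' reference value).
#'
#' @param traj an `sbm_trajectory` (or list with `frames`, `times`).
#' @param defs an [op_defs()] object.
#' @return data.frame of class `op_series` with columns `time`, `q_id`,
#'   `q_a`, `q_b`, `q_diff`, `delta_d` (+ one distance column per extra
#'   group).
#' @export
order_parameters <- function(traj, defs) {
  stopifnot(inherits(defs, "op_defs"))
  nf <- length(traj$times)
  natoms <- dim(traj$frames)[1]
  idx_max <- max(defs$anchor_idx, defs$switch_idx,
                 defs$id$i, defs$id$j, defs$state_a$i, defs$state_a$j,
                 defs$state_b$i, defs$state_b$j)
  if (idx_max > natoms) stop("order-parameter definitions reference atoms beyond the trajectory")
  out <- data.frame(time = traj$times, q_id = NA_real_, q_a = NA_real_,
                    q_b = NA_real_, q_diff = NA_real_, delta_d = NA_real_)
  for (g in names(defs$extra_groups)) out[[paste0("d_", g)]] <- NA_real_
  for (f in seq_len(nf)) {
    x <- traj$frames[, , f]
    out$q_id[f] <- q_fraction(x, defs$id, defs$lambda)
    out$q_a[f] <- q_fraction(x, defs$state_a, defs$lambda)
    out$q_b[f] <- q_fraction(x, defs$state_b, defs$lambda)
    out$delta_d[f] <- cog_dist(x, defs$anchor_idx, defs$switch_idx) -
      defs$ref_active_dist
    for (g in names(defs$extra_groups))
      out[[paste0("d_", g)]][f] <- cog_dist(x, defs$switch_idx,
                                            defs$extra_groups[[g]])
  }
  out$q_diff <- out$q_b - out$q_a
  class(out) <- c("op_series", "data.frame")
  out
}

#' 2D landscape histogram over order parameters
#'
#' Counts configurations over all supplied series; the grid sum equals the
#' total number of frames.
#'
#' @param series one `op_series` or a list of them.
#' @param x,y column names of the two projected parameters.
#' @param bins number of bins per axis (default 40).
#' @param xlim,ylim axis ranges (defaults: data range).
#' @return list of class `landscape`: `counts` matrix (x by y), bin
#'   `xbreaks`/`ybreaks`.
#' @export
landscape_histogram <- function(series, x = "q_id", y = "q_diff", bins = 40,
                                xlim = NULL, ylim = NULL) {
  if (inherits(series, "data.frame")) series <- list(series)
  if (!length(series)) stop("empty input")
  df <- do.call(rbind, lapply(series, function(s) s[, c(x, y)]))
  if (!nrow(df)) stop("empty input")
  if (is.null(xlim)) xlim <- range(df[[x]])
  if (is.null(ylim)) ylim <- range(df[[y]])
  eps <- 1e-9
  xb <- seq(xlim[1] - eps, xlim[2] + eps, length.out = bins + 1)
  yb <- seq(ylim[1] - eps, ylim[2] + eps, length.out = bins + 1)
  ix <- pmin(pmax(findInterval(df[[x]], xb), 1L), bins)
  iy <- pmin(pmax(findInterval(df[[y]], yb), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (r in seq_along(ix)) counts[ix[r], iy[r]] <- counts[ix[r], iy[r]] + 1L
  structure(list(counts = counts, xbreaks = xb, ybreaks = yb,
                 xname = x, yname = y),
            class = "landscape")
}

#' Rectangular state window in order-parameter space
#'
#' @param name label (e.g. `"I2"`).
#' @param x,y column names of the windowed parameters.
#' @param xlim,ylim inclusive bounds.
#' @return list of class `state_window`.
#' @export
state_window <- function(name, x, xlim, y, ylim) {
  structure(list(name = name, x = x, xlim = xlim, y = y, ylim = ylim),
            class = "state_window")
}

frames_in_window <- function(series, window) {
  which(series[[window$x]] >= window$xlim[1] & series[[window$x]] <= window$xlim[2] &
        series[[window$y]] >= window$ylim[1] & series[[window$y]] <= window$ylim[2])
}

#' Per-residue-pair contact formation probabilities within a state window
#'
#' For every residue pair carrying native contacts in a layer, the
#' probability (over frames assigned to the window) that any of its
#' atom-atom contacts is formed.
#'
#' @param traj an `sbm_trajectory`.
#' @param series the matching `op_series`.
#' @param window a [state_window()].
#' @param layers named list of contact subsets (each data.frame `i`, `j`,
#'   `r0` plus `res_i`, `res_j` residue labels; see
#'   [contact_residue_pairs()]).
#' @param lambda formed-contact factor.
#' @return named list of data.frames (`res_i`, `res_j`, `prob`).
#' @export
contact_probability_map <- function(traj, series, window, layers,
                                    lambda = 1.2) {
  fr <- frames_in_window(series, window)
  if (!length(fr)) stop("state window '", window$name, "' contains no frames")
  lapply(layers, function(ct) {
    stopifnot(all(c("res_i", "res_j") %in% names(ct)))
    pair <- paste(ct$res_i, ct$res_j)
    upair <- unique(pair)
    formed_any <- matrix(0, length(upair), length(fr))
    for (q in seq_along(fr)) {
      x <- traj$frames[, , fr[q]]
      d <- sqrt(rowSums((x[ct$i, , drop = FALSE] - x[ct$j, , drop = FALSE])^2))
      formed <- d < lambda * ct$r0
      formed_any[, q] <- as.numeric(tapply(formed, factor(pair, levels = upair), any))
    }
    first <- match(upair, pair)
    data.frame(res_i = ct$res_i[first], res_j = ct$res_j[first],
               prob = rowMeans(formed_any), stringsAsFactors = FALSE)
  })
}

#' Attach residue-pair labels to a contact subset
#'
#' @param contacts data.frame with `i`, `j`.
#' @param atoms atom metadata table (from a `contact_map` or topology).
#' @return `contacts` with `res_i`, `res_j` columns (`chain:resno`).
#' @export
contact_residue_pairs <- function(contacts, atoms) {
  contacts$res_i <- paste0(atoms$chain[contacts$i], ":", atoms$resno[contacts$i])
  contacts$res_j <- paste0(atoms$chain[contacts$j], ":", atoms$resno[contacts$j])
  contacts
}

#' First-passage event detection on a trajectory
#'
#' Reports, per event type, the first sampled time at which
#' (i) each formation subset's contact fraction reaches
#' `formation_threshold` (strand-pair formation / association events), and
#' (ii) Q_ID drops to `dissociation_threshold` or below (domain
#' dissociation). A threshold never crossed yields no row for that event.
#'
#' @param traj an `sbm_trajectory`.
#' @param formation named list of contact subsets (data.frames `i`,`j`,`r0`).
#' @param dissociation ID contact subset, or `NULL` to skip.
#' @param formation_threshold fraction in (0,1), default 0.75 (association
#'   convention: more than 75 percent of native contacts formed).
#' @param dissociation_threshold fraction in (0,1), default 0.30 (70
#'   percent of interdomain contacts broken).
#' @param lambda formed-contact factor.
#' @return data.frame `event`, `time`, `frame` (class `event_list`).
#' @export
detect_events <- function(traj, formation = list(), dissociation = NULL,
                          formation_threshold = 0.75,
                          dissociation_threshold = 0.30, lambda = 1.2) {
  stopifnot(formation_threshold > 0, formation_threshold < 1,
            dissociation_threshold > 0, dissociation_threshold < 1)
  nf <- length(traj$times)
  qmat <- function(ct) vapply(seq_len(nf), function(f)
    q_fraction(traj$frames[, , f], ct, lambda), numeric(1))
  rows <- list()
  for (nm in names(formation)) {
    qs <- qmat(formation[[nm]])
    hit <- which(qs >= formation_threshold)
    if (length(hit))
      rows[[length(rows) + 1]] <- data.frame(event = nm,
                                             time = traj$times[hit[1]],
                                             frame = hit[1])
  }
  if (!is.null(dissociation)) {
    qs <- qmat(dissociation)
    hit <- which(qs <= dissociation_threshold)
    if (length(hit))
      rows[[length(rows) + 1]] <- data.frame(event = "dissociation",
                                             time = traj$times[hit[1]],
                                             frame = hit[1])
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(event = character(0), time = numeric(0), frame = integer(0))
  class(out) <- c("event_list", "data.frame")
  out
}

#' Switching-order statistics over a set of trajectories
#'
#' For each replica: whether the run switched (terminated on the RMSD stop
#' criterion), whether Q_diff traverses from below `-traverse` to above
#' `+traverse`, the first time interdomain breakage reaches the
#' dissociation threshold, the first time the target-state Q reaches
#' `barrel_q`, and the minimum Q_ID seen before the committed zero
#' crossing of Q_diff (the last frame with Q_diff <= 0; transient
#' one-contact blips above zero do not count as the switch).
#'
#' @param series list of `op_series` (one per replica).
#' @param events list of `event_list`s from [detect_events()] (with a
#'   `"dissociation"` event type).
#' @param terminations character vector of per-replica termination reasons.
#' @param barrel_q target-state Q marking completion of the new fold
#'   (default 0.8).
#' @param traverse Q_diff excursion bound (default 0.5).
#' @return data.frame with one row per replica and the summary columns
#'   described above.
#' @export
switching_order_stats <- function(series, events, terminations,
                                  barrel_q = 0.8, traverse = 0.5) {
  stopifnot(length(series) == length(events),
            length(series) == length(terminations))
  rows <- lapply(seq_along(series), function(i) {
    s <- series[[i]]; e <- events[[i]]
    td <- e$time[e$event == "dissociation"]
    barrel <- which(s$q_b >= barrel_q)[1]
    t_barrel <- if (is.na(barrel)) NA_real_ else s$time[barrel]
    last0 <- max(which(s$q_diff <= 0))
    data.frame(
      replica = i,
      switched = terminations[i] == "stop_rmsd",
      traversed = min(s$q_diff) <= -traverse & max(s$q_diff) >= traverse,
      t_dissociation = if (length(td)) td[1] else NA_real_,
      t_barrel = t_barrel,
      dissociation_first = length(td) > 0 && !is.na(t_barrel) &&
        td[1] <= t_barrel,
      min_qid_before_commit = min(s$q_id[1:last0]))
  })
  do.call(rbind, rows)
}

#' Histogram of first-passage times
#'
#' @param events an `event_list` (or numeric vector of times).
#' @param breaks bin edges (tau); default 20 bins over the event range.
#' @param event optional event-name filter.
#' @return list `counts`, `breaks`, `mids`; counts sum to the number of
#'   events histogrammed.
#' @export
first_passage_histogram <- function(events, breaks = NULL, event = NULL) {
  times <- if (is.numeric(events)) events else {
    ev <- events
    if (!is.null(event)) ev <- ev[ev$event == event, , drop = FALSE]
    ev$time
  }
  if (is.null(breaks)) {
    if (!length(times)) breaks <- c(0, 1)
    else breaks <- seq(0, max(times) * 1.0001 + 1e-9, length.out = 21)
  }
  counts <- if (!length(times)) rep(0L, length(breaks) - 1) else {
    idx <- findInterval(times, breaks)
    idx <- idx[idx >= 1L & idx <= length(breaks) - 1L]  # drop out-of-range
    tabulate(idx, nbins = length(breaks) - 1L)
  }
  list(counts = counts, breaks = breaks,
       mids = (head(breaks, -1) + breaks[-1]) / 2)
}
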