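#' Trajectory quantification
#'
#' Turns simulated trajectories into the readouts used to describe
#' imaging data: baseline-normalized traces (F/F0), spike events with
#' width at half maximum, oscillation frequency, kymographs, integrated
#' activity and an automated spatiotemporal pattern class.
#'
#' @name quantify
NULL

#' Normalize a trace to its baseline (F/F0)
#'
#' The baseline `F0` is the 10th percentile of the series, a robust
#' stand-in for the inter-spike resting level that tolerates long active
#' episodes. A constant series maps to all ones; scaling the raw series
#' by any positive factor leaves the output unchanged.
#'
#' @param x Non-negative numeric series.
#' @return The normalized series.
#' @export
normalize_trace <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  if (any(x < 0)) stop("trace values must be non-negative", call. = FALSE)
  f0 <- stats::quantile(x, 0.10, names = FALSE)
  if (f0 <= 0) stop("degenerate baseline: F0 = 0", call. = FALSE)
  x / f0
}

#' Detect Ca2+ spike events in a single trace
#'
#' A spike is a maximal excursion of the normalized trace above
#' `threshold`; excursions separated by less than `min_separation`
#' seconds are merged into one event. Per event the peak time/amplitude
#' and the width at half maximum (width of the excursion above
#' `baseline + (peak - baseline)/2`, with baseline 1 after
#' normalization, measured by linear interpolation) are recorded.
#'
#' @param trace Raw (un-normalized) trace; normalization is applied
#'   internally, so detection is invariant to uniform scaling.
#' @param times Sample times, s (same length as `trace`).
#' @param threshold F/F0 detection threshold (> 1; default 1.5).
#' @param min_separation Merge distance between excursions, s
#'   (default 20).
#' @return A `data.frame` with columns
#'   `t_onset, t_peak, amplitude, whm_s` (zero rows if no event).
#' @examples
#' t <- seq(0, 600, by = 1)
#' y <- 1 + 2 * exp(-(t - 300)^2 / (2 * 15^2))
#' detect_spikes(y, t)
#' @export
detect_spikes <- function(trace, times, threshold = 1.5,
                          min_separation = 20) {
  if (threshold <= 1) stop("threshold must exceed 1", call. = FALSE)
  if (length(trace) != length(times))
    stop("trace and times lengths differ", call. = FALSE)
  f <- normalize_trace(trace)
  above <- f > threshold
  if (!any(above))
    return(data.frame(t_onset = numeric(0), t_peak = numeric(0),
                      amplitude = numeric(0), whm_s = numeric(0)))
  # maximal runs above threshold
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- cbind(starts[rl$values], ends[rl$values])
  # merge runs whose gap is below min_separation
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (k in 2:nrow(runs)) {
      gap <- times[runs[k, 1]] - times[merged[nrow(merged), 2]]
      if (gap < min_separation) {
        merged[nrow(merged), 2] <- runs[k, 2]
      } else merged <- rbind(merged, runs[k, ])
    }
    runs <- merged
  }
  ev <- lapply(seq_len(nrow(runs)), function(k) {
    a <- runs[k, 1]; b <- runs[k, 2]
    ipk <- a - 1L + which.max(f[a:b])
    peak <- f[ipk]
    half <- 1 + (peak - 1) / 2
    data.frame(t_onset = times[a], t_peak = times[ipk],
               amplitude = peak,
               whm_s = half_max_width(f, times, ipk, half))
  })
  do.call(rbind, ev)
}

# width of the excursion around peak index ipk above `level`,
# via linear interpolation at the two crossings
half_max_width <- function(f, times, ipk, level) {
  n <- length(f)
  i <- ipk
  while (i > 1 && f[i - 1] > level) i <- i - 1
  t_lo <- if (i == 1 || f[i] <= level) times[i] else {
    # crossing between i-1 (below) and i (above)
    t1 <- times[i - 1]; t2 <- times[i]
    t1 + (level - f[i - 1]) / (f[i] - f[i - 1]) * (t2 - t1)
  }
  j <- ipk
  while (j < n && f[j + 1] > level) j <- j + 1
  t_hi <- if (j == n || f[j] <= level) times[j] else {
    t1 <- times[j]; t2 <- times[j + 1]
    t1 + (level - f[j]) / (f[j + 1] - f[j]) * (t2 - t1)
  }
  t_hi - t_lo
}

#' Oscillation frequency, amplitude and width of a trace
#'
#' Frequency is the reciprocal mean peak-to-peak interval of detected
#' spike events; amplitude and width at half maximum are averaged over
#' events. With fewer than two events the frequency is reported as `NA`
#' (absent), never zero.
#'
#' @inheritParams detect_spikes
#' @return A list with `frequency` (1/s or `NA`), `amplitude`, `whm_s`,
#'   `n_events`.
#' @export
oscillation_metrics <- function(trace, times, threshold = 1.5,
                                min_separation = 20) {
  ev <- detect_spikes(trace, times, threshold, min_separation)
  list(frequency = if (nrow(ev) >= 2) 1 / mean(diff(ev$t_peak))
       else NA_real_,
       amplitude = if (nrow(ev)) mean(ev$amplitude) else NA_real_,
       whm_s = if (nrow(ev)) mean(ev$whm_s) else NA_real_,
       n_events = nrow(ev))
}

#' Kymograph along a line through the tissue
#'
#' Cells whose polygon intersects the segment are ordered by the
#' projection of their centroid onto it; the intensity matrix holds the
#' baseline-normalized Ca2+ of those cells at every sample.
#'
#' @param traj A `ca_trajectory`.
#' @param line 2x2 matrix: the two endpoints (rows) of the segment.
#' @return A `ca_kymograph`: `cells` (ordered ids), `positions`
#'   (projections along the line), `intensity` (cells x samples),
#'   `times`.
#' @export
make_kymograph <- function(traj, line) {
  tissue <- traj$tissue
  a <- as.numeric(line[1, ]); b <- as.numeric(line[2, ])
  hit <- which(vapply(tissue$polygons, segment_hits_polygon, TRUE,
                      a = a, b = b))
  if (!length(hit)) stop("line does not intersect any cell",
                         call. = FALSE)
  d <- b - a
  tt <- ((tissue$centroids[hit, 1] - a[1]) * d[1] +
           (tissue$centroids[hit, 2] - a[2]) * d[2]) / sum(d^2)
  ord <- order(tt)
  cells <- hit[ord]
  intensity <- t(apply(traj$c[, cells, drop = FALSE], 2,
                       normalize_trace))
  if (length(cells) == 1L) intensity <- matrix(intensity, nrow = 1)
  structure(list(cells = cells, positions = tt[ord],
                 intensity = intensity, times = traj$times,
                 line = rbind(a, b)),
            class = "ca_kymograph")
}

#' @export
print.ca_kymograph <- function(x, ...) {
  cat("Kymograph:", length(x$cells), "cells x", length(x$times),
      "samples\n")
  invisible(x)
}

segment_hits_polygon <- function(poly, a, b) {
  if (point_in_polygon(a, poly) || point_in_polygon(b, poly))
    return(TRUE)
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1L)
  for (k in seq_len(n)) {
    if (segments_cross(a, b, poly[k, ], poly[nxt[k], ])) return(TRUE)
  }
  FALSE
}

point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n; inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1]) inside <- !inside
    j <- i
  }
  inside
}

segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2) && (o3 != o4)
}

#' Classify the spatiotemporal pattern of a trajectory
#'
#' Automated rubric standing in for classification by eye. Per frame a
#' cell is active if its F/F0 exceeds `active_threshold`; activity is
#' grouped into events as connected components of the spatiotemporal
#' graph (active neighbours within a frame, the same active cell across
#' consecutive frames). Classes, in order of precedence:
#' \describe{
#'   \item{none}{no events at all;}
#'   \item{fluttering}{global synchronized activity: at least
#'     `flutter_fraction` of the tissue active in at least
#'     `flutter_time` of the frames, *or* some single frame with at
#'     least `flutter_fraction` of the tissue simultaneously active (a
#'     near-global flash — the model's fluttering state is periodic
#'     whole-tissue flashing whose duty cycle sits well below 50%, so
#'     sustained occupancy alone cannot recognise it, while propagating
#'     waves engage only about a third of the tissue at any instant);}
#'   \item{ICW}{some event reaches `icw_fraction` of the tissue *and*
#'     its per-frame active centroid travels more than
#'     `propagation_diameters` mean cell diameters (a propagating
#'     wave);}
#'   \item{ICT}{some event involves more than `spike_cells` cells;}
#'   \item{spikes}{all events confined to at most `spike_cells` cells.}
#' }
#'
#' @param traj A `ca_trajectory`.
#' @param tissue The tissue (defaults to the one in `traj`).
#' @param active_threshold F/F0 activity threshold (default 1.5).
#' @param spike_cells Maximum cells of a single-cell-scale event
#'   (default 3).
#' @param icw_fraction Tissue fraction an event must reach to qualify as
#'   a wave (default 0.1).
#' @param flutter_fraction,flutter_time Tissue and time fractions for
#'   the fluttering test (defaults 0.5, 0.5).
#' @param propagation_diameters Minimum active-centroid displacement of
#'   a wave, in mean cell diameters (default 2).
#' @return A list (class `ca_pattern`): `class` (factor level among
#'   `none, spikes, ICT, ICW, fluttering`), `n_events`, `events`
#'   (per-event cell counts, durations, displacements), and the active
#'   fraction time series.
#' @export
classify_pattern <- function(traj, tissue = traj$tissue,
                             active_threshold = 1.5, spike_cells = 3,
                             icw_fraction = 0.1, flutter_fraction = 0.5,
                             flutter_time = 0.5,
                             propagation_diameters = 2) {
  if (traj$times[length(traj$times)] < 600)
    stop("trajectory must cover at least 10 min", call. = FALSE)
  n <- tissue$n_cells
  nt <- nrow(traj$c)
  fmat <- apply(traj$c, 2, normalize_trace)        # nt x n
  active <- fmat > active_threshold
  frac <- rowMeans(active)
  cls <- function(label, events) {
    structure(list(class = label, n_events = nrow(events),
                   events = events, active_fraction = frac),
              class = "ca_pattern")
  }
  empty <- data.frame(cells = integer(0), frames = integer(0),
                      displacement = numeric(0))
  if (!any(active)) return(cls("none", empty))

  # connected components over (cell, frame) nodes
  node <- which(active)                            # column-major: t + nt*(i-1)
  id <- seq_along(node)
  lookup <- integer(nt * n); lookup[node] <- id
  edges_st <- NULL
  # same cell, consecutive frames
  tt <- (node - 1L) %% nt + 1L
  ci <- (node - 1L) %/% nt + 1L
  nxt <- ifelse(tt < nt, lookup[node + 1L], 0L)
  sel <- nxt > 0 & tt < nt
  e1 <- cbind(id[sel], nxt[sel])
  # adjacent cells, same frame
  e2 <- NULL
  if (nrow(tissue$edges)) {
    eA <- tissue$edges$i; eB <- tissue$edges$j
    # for each tissue edge, frames where both endpoints are active
    actA <- active[, eA, drop = FALSE]; actB <- active[, eB, drop = FALSE]
    both <- which(actA & actB)                     # nt x nEdges
    if (length(both)) {
      fr <- (both - 1L) %% nt + 1L
      ed <- (both - 1L) %/% nt + 1L
      na <- lookup[fr + nt * (eA[ed] - 1L)]
      nb <- lookup[fr + nt * (eB[ed] - 1L)]
      e2 <- cbind(na, nb)
    }
  }
  g <- igraph::graph_from_edgelist(rbind(e1, e2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(node) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(node)]

  diam <- mean_cell_diameter(tissue)
  events <- do.call(rbind, lapply(split(seq_along(node), comp),
                                  function(idx) {
    cells <- unique(ci[idx]); frames <- sort(unique(tt[idx]))
    # per-frame centroid of the event's active cells
    cen <- vapply(frames, function(fr) {
      cc <- ci[idx][tt[idx] == fr]
      colMeans(tissue$centroids[cc, , drop = FALSE])
    }, c(0, 0))
    disp <- if (length(frames) > 1) {
      max(dist(t(cen)))
    } else 0
    data.frame(cells = length(cells), frames = length(frames),
               displacement = disp)
  }))
  rownames(events) <- NULL

  flutter <- mean(frac >= flutter_fraction) >= flutter_time ||
    max(frac) >= flutter_fraction
  if (flutter) return(cls("fluttering", events))
  wave <- any(events$cells >= icw_fraction * n &
                events$displacement > propagation_diameters * diam)
  if (wave) return(cls("ICW", events))
  if (any(events$cells > spike_cells)) return(cls("ICT", events))
  cls("spikes", events)
}

#' @export
print.ca_pattern <- function(x, ...) {
  cat("Pattern class:", x$class, "(", x$n_events, "events )\n")
  invisible(x)
}

#' Integrated Ca2+ activity of a trajectory
#'
#' Time-tissue sum of the suprabasal normalized signal:
#' `sum_cells sum_samples max(F/F0 - 1, 0) * dt`.
#'
#' @param traj A `ca_trajectory`.
#' @return Non-negative scalar (units: s).
#' @export
integrated_activity <- function(traj) {
  dt <- diff(traj$times)
  dt <- c(dt, dt[length(dt)])
  fmat <- apply(traj$c, 2, normalize_trace)
  sum(pmax(fmat - 1, 0) * dt)
}

#' Full activity report for a trajectory
#'
#' Runs spike detection on every cell, classifies the pattern, and
#' aggregates tissue-level summaries.
#'
#' @param traj A `ca_trajectory`.
#' @param threshold,min_separation Passed to [detect_spikes].
#' @param ... Passed to [classify_pattern].
#' @return A `ca_report`: per-cell event table (`events`, with
#'   `cell_id`), `n_spikes`, `spikes_per_area`, `mean_frequency`,
#'   `mean_whm`, `integrated_activity`, `class`.
#' @export
activity_report <- function(traj, threshold = 1.5, min_separation = 20,
                            ...) {
  n <- ncol(traj$c)
  evs <- lapply(seq_len(n), function(i) {
    ev <- detect_spikes(traj$c[, i], traj$times, threshold,
                        min_separation)
    if (nrow(ev)) cbind(cell_id = i, ev) else NULL
  })
  events <- do.call(rbind, evs)
  if (is.null(events))
    events <- data.frame(cell_id = integer(0), t_onset = numeric(0),
                         t_peak = numeric(0), amplitude = numeric(0),
                         whm_s = numeric(0))
  freq <- vapply(seq_len(n), function(i) {
    pk <- events$t_peak[events$cell_id == i]
    if (length(pk) >= 2) 1 / mean(diff(pk)) else NA_real_
  }, 0)
  pat <- classify_pattern(traj, ...)
  rep <- list(events = events,
              n_spikes = nrow(events),
              spikes_per_area = nrow(events) / sum(traj$tissue$areas),
              mean_frequency = if (any(!is.na(freq)))
                mean(freq, na.rm = TRUE) else NA_real_,
              mean_whm = if (nrow(events)) mean(events$whm_s)
              else NA_real_,
              integrated_activity = integrated_activity(traj),
              class = pat$class, pattern = pat)
  class(rep) <- "ca_report"
  rep
}

#' @export
print.ca_report <- function(x, ...) {
  cat("Activity report\n")
  cat("  class:              ", x$class, "\n")
  cat("  spikes:             ", x$n_spikes, "\n")
  cat("  spikes per area:    ", signif(x$spikes_per_area, 4), "\n")
  cat("  mean frequency:     ",
      if (is.na(x$mean_frequency)) "NA" else
        paste(signif(x$mean_frequency, 4), "1/s"), "\n")
  cat("  mean WHM:           ",
      if (is.na(x$mean_whm)) "NA" else paste(signif(x$mean_whm, 4), "s"),
      "\n")
  cat("  integrated activity:", signif(x$integrated_activity, 5), "\n")
  invisible(x)
}

#' Spike count per unit pouch area
#'
#' @param report A `ca_report`.
#' @param tissue The tissue the report was computed on.
#' @return Spikes per unit area (mean-cell-diameter units squared).
#' @export
spikes_per_area <- function(report, tissue) {
  report$n_spikes / sum(tissue$areas)
}
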