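#' @title Proton-coupled electron transfer trajectory analysis
#' @name pcet_analysis
#' @description
#' Post-processing of excited- and ground-state trajectories: proton
#' transfer coordinates (donor-H and acceptor-H distances), persistent
#' transfer-event detection with hysteresis, dipole-based assignment of
#' locally excited vs charge-transfer character, torsion-window conformer
#' classification and ensemble statistics of transfer delays.
NULL

#' Define a proton-transfer coordinate
#'
#' @param label coordinate name (e.g. `"PT1"`)
#' @param donor_atom_index,hydrogen_atom_index,acceptor_atom_index distinct
#'   atom indices
#' @return object of class `pt_definition`
#' @export
pt_definition <- function(label, donor_atom_index, hydrogen_atom_index,
                          acceptor_atom_index) {
  idx <- c(donor_atom_index, hydrogen_atom_index, acceptor_atom_index)
  if (length(unique(idx)) != 3) stop("pt_definition: indices must be distinct")
  structure(list(label = label, donor = as.integer(donor_atom_index),
                 hydrogen = as.integer(hydrogen_atom_index),
                 acceptor = as.integer(acceptor_atom_index)),
            class = "pt_definition")
}

#' Proton-transfer coordinates along a trajectory
#'
#' @param frames list of `traj_frame`
#' @param defs list of `pt_definition`
#' @return named list (one entry per definition) of data frames with
#'   columns `time_fs`, `d_donor_h`, `d_acceptor_h` (Angstrom)
#' @export
pt_coordinates <- function(frames, defs) {
  if (inherits(defs, "pt_definition")) defs <- list(defs)
  nat <- nrow(frames[[1]]$coords)
  out <- list()
  for (d in defs) {
    if (max(d$donor, d$hydrogen, d$acceptor) > nat) {
      stop("pt_coordinates: atom index out of range")
    }
    t_fs <- vapply(frames, function(f) f$time_fs, 0)
    ddh <- vapply(frames, function(f) {
      bohr2ang(sqrt(sum((f$coords[d$donor, ] - f$coords[d$hydrogen, ])^2)))
    }, 0)
    dah <- vapply(frames, function(f) {
      bohr2ang(sqrt(sum((f$coords[d$acceptor, ] - f$coords[d$hydrogen, ])^2)))
    }, 0)
    out[[d$label]] <- data.frame(time_fs = t_fs, d_donor_h = ddh,
                                 d_acceptor_h = dah)
  }
  out
}

#' Detect persistent proton-transfer events
#'
#' A forward event is recorded at the first frame where
#' `d_donor_h - d_acceptor_h > hysteresis` and the condition persists for
#' `persistence_frames` consecutive frames; reverse events swap the roles.
#' Events alternate: no duplicate direction without an intervening
#' opposite event.
#'
#' @param series data frame from [pt_coordinates()] (one coordinate)
#' @param label coordinate label carried into the events
#' @param persistence_frames persistence window (frames, default 50)
#' @param hysteresis distance margin (Angstrom, default 0.1)
#' @return data frame with columns `pt_label`, `event_time` (fs),
#'   `direction` (`"forward"`/`"reverse"`), `frame_index`
#' @export
detect_pt_events <- function(series, label = "PT",
                             persistence_frames = 50, hysteresis = 0.1) {
  diffv <- series$d_donor_h - series$d_acceptor_h
  n <- length(diffv)
  events <- list()
  last_dir <- NA_character_
  i <- 1
  while (i + persistence_frames - 1 <= n) {
    win <- diffv[i:(i + persistence_frames - 1)]
    if (!identical(last_dir, "forward") && all(win > hysteresis)) {
      events[[length(events) + 1]] <- data.frame(
        pt_label = label, event_time = series$time_fs[i],
        direction = "forward", frame_index = as.integer(i))
      last_dir <- "forward"
      i <- i + 1
    } else if (!identical(last_dir, "reverse") && all(win < -hysteresis) &&
               length(events) > 0) {
      events[[length(events) + 1]] <- data.frame(
        pt_label = label, event_time = series$time_fs[i],
        direction = "reverse", frame_index = as.integer(i))
      last_dir <- "reverse"
      i <- i + 1
    } else {
      i <- i + 1
    }
  }
  if (length(events) == 0) {
    return(data.frame(pt_label = character(0), event_time = numeric(0),
                      direction = character(0), frame_index = integer(0)))
  }
  do.call(rbind, events)
}

#' Assign LE-like / CT-like character from the dipole moment
#'
#' A frame is CT-like when its median-filtered dipole magnitude exceeds
#' the threshold; the threshold is typically calibrated as the midpoint of
#' the ground- and CT-state dipole magnitudes of the system at hand.
#'
#' @param frames list of `traj_frame` (must carry dipole moments)
#' @param threshold dipole magnitude threshold (a.u.)
#' @param smooth_window odd median-filter window (frames, default 11)
#' @return data frame with `time_fs`, `dipole_norm` (smoothed), `state`
#'   (`"LE-like"`/`"CT-like"`)
#' @export
dipole_state_series <- function(frames, threshold, smooth_window = 11) {
  mu <- vapply(frames, function(f) {
    if (is.null(f$dipole_moment)) stop("dipole_state_series: missing dipole")
    sqrt(sum(f$dipole_moment^2))
  }, 0)
  t_fs <- vapply(frames, function(f) f$time_fs, 0)
  w <- min(smooth_window, length(mu))
  if (w %% 2 == 0) w <- w - 1
  sm <- if (w >= 3) as.numeric(stats::runmed(mu, w)) else mu
  data.frame(time_fs = t_fs, dipole_norm = sm,
             state = ifelse(sm > threshold, "CT-like", "LE-like"))
}

#' Onset time of charge-transfer character
#'
#' First frame assigned CT-like; `NA` if none.
#'
#' @param state_series data frame from [dipole_state_series()]
#' @return time (fs) or NA
#' @export
ct_onset_time <- function(state_series) {
  i <- which(state_series$state == "CT-like")[1]
  if (is.na(i)) NA_real_ else state_series$time_fs[i]
}

#' Signed dihedral of four atoms
#'
#' IUPAC convention, degrees in (-180, 180].
#'
#' @param coords n x 3 coordinates
#' @param idx four atom indices
#' @return dihedral in degrees
#' @export
dihedral_angle <- function(coords, idx) {
  b1 <- coords[idx[2], ] - coords[idx[1], ]
  b2 <- coords[idx[3], ] - coords[idx[2], ]
  b3 <- coords[idx[4], ] - coords[idx[3], ]
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("dihedral_angle: undefined dihedral (collinear atoms)")
  }
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2 / sqrt(sum(b2^2)))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Classify frames into torsion-window conformers
#'
#' @param frames list of `traj_frame`
#' @param torsion_spec list with `atoms` (four indices) and `windows`
#'   (named list of `c(lo, hi)` degree intervals, half-open `[lo, hi)`,
#'   non-overlapping)
#' @return character vector of per-frame labels (`"other"` for gaps)
#' @export
conformer_classify <- function(frames, torsion_spec) {
  wins <- torsion_spec$windows
  wm <- do.call(rbind, wins)
  ord <- order(wm[, 1])
  wm <- wm[ord, , drop = FALSE]
  if (nrow(wm) > 1) {
    for (i in 2:nrow(wm)) {
      if (wm[i, 1] < wm[i - 1, 2]) stop("conformer_classify: overlapping windows")
    }
  }
  labs <- names(wins)
  vapply(frames, function(f) {
    a <- dihedral_angle(f$coords, torsion_spec$atoms)
    av <- if (a == 180) -180 else a     # windows cover [-180, 180)
    for (k in seq_along(wins)) {
      if (av >= wins[[k]][1] && av < wins[[k]][2]) return(labs[k])
    }
    "other"
  }, "")
}

#' Full PCET analysis report for one or more trajectories
#'
#' Runs the proton-transfer and dipole diagnostics over a set of
#' trajectories and assembles the per-trajectory event tables, the
#' dipole-based charge-transfer onset times and the ensemble delay
#' statistics; this is the analysis surface the `diabat-md analyze`
#' command wraps.
#'
#' @param trajectories list of frame lists (each from [read_traj()] or
#'   [run_md()])
#' @param pt_defs list of `pt_definition`
#' @param ct_threshold dipole threshold for CT assignment (a.u.); NA skips
#'   the dipole diagnostics (reference times then default to 0)
#' @param persistence_frames,hysteresis passed to [detect_pt_events()]
#' @param report_path optional TSV file for the per-event table
#' @return list with `events` (one data frame per trajectory),
#'   `ct_onsets`, `summary` (from [ensemble_summary()])
#' @export
pcet_report <- function(trajectories, pt_defs, ct_threshold = NA,
                        persistence_frames = 50, hysteresis = 0.1,
                        report_path = NULL) {
  if (!is.null(trajectories$frames)) trajectories <- list(trajectories$frames)
  events <- list(); onsets <- numeric(0)
  for (k in seq_along(trajectories)) {
    fr <- trajectories[[k]]
    pc <- pt_coordinates(fr, pt_defs)
    ev <- do.call(rbind, lapply(names(pc), function(lb) {
      detect_pt_events(pc[[lb]], lb, persistence_frames, hysteresis)
    }))
    ev$trajectory <- if (nrow(ev)) k else integer(0)
    events[[k]] <- ev
    onsets[k] <- if (is.na(ct_threshold)) 0 else
      ct_onset_time(dipole_state_series(fr, ct_threshold))
  }
  summ <- ensemble_summary(events, onsets)
  if (!is.null(report_path)) {
    tab <- do.call(rbind, events)
    utils::write.table(tab, report_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  list(events = events, ct_onsets = onsets, summary = summ)
}

#' Ensemble statistics of transfer delays
#'
#' Delays of the first forward event of each PT label after a
#' per-trajectory reference time (e.g. the CT onset), plus the fraction of
#' trajectories showing a transfer.
#'
#' @param event_lists list (one per trajectory) of event data frames from
#'   [detect_pt_events()]
#' @param reference_times per-trajectory reference times (fs); `NA`
#'   entries count as non-transferring trajectories
#' @return list with `per_label` (data frame: `pt_label`, `n_events`,
#'   `mean_delay`, `median_delay`, `min_delay`, `max_delay`, all fs) and
#'   `transfer_fraction`
#' @export
ensemble_summary <- function(event_lists, reference_times = NULL) {
  stopifnot(length(event_lists) >= 1)
  if (is.null(reference_times)) reference_times <- rep(0, length(event_lists))
  labels <- unique(unlist(lapply(event_lists, function(e) e$pt_label)))
  rows <- list()
  transferred <- logical(length(event_lists))
  for (lb in labels) {
    delays <- c()
    for (k in seq_along(event_lists)) {
      if (is.na(reference_times[k])) next
      e <- event_lists[[k]]
      e <- e[e$pt_label == lb & e$direction == "forward" &
               e$event_time >= reference_times[k], , drop = FALSE]
      if (nrow(e) > 0) {
        delays <- c(delays, e$event_time[1] - reference_times[k])
        transferred[k] <- TRUE
      }
    }
    rows[[lb]] <- data.frame(
      pt_label = lb, n_events = length(delays),
      mean_delay = if (length(delays)) mean(delays) else NA_real_,
      median_delay = if (length(delays)) median(delays) else NA_real_,
      min_delay = if (length(delays)) min(delays) else NA_real_,
      max_delay = if (length(delays)) max(delays) else NA_real_)
  }
  per_label <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pt_label = character(0), n_events = integer(0),
               mean_delay = numeric(0), median_delay = numeric(0),
               min_delay = numeric(0), max_delay = numeric(0))
  rownames(per_label) <- NULL
  list(per_label = per_label,
       transfer_fraction = mean(transferred))
}
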