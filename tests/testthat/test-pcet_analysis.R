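scripted_crossing <- function(n_pre = 100, n_post = 201, dt = 0.5) {
  # proton migrates linearly from the donor to the acceptor
  sym <- c("X", "H", "X")
  co <- function(hx) matrix(c(0, 0, 0, hx, 0, 0, 5, 0, 0), 3, 3,
                            byrow = TRUE)
  tmax <- (n_pre + n_post - 1) * dt
  make_scripted_trajectory(list(
    times = c(0, (n_pre - 1) * dt, tmax),
    coords = list(co(1.2), co(1.2), co(4.2)),
    dipoles = rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
    symbols = sym), dt)
}

test_that("proton-transfer coordinates are Euclidean distances in Angstrom", {
  # H midway, 1.2 Angstrom from both partners
  d <- ang2bohr(1.2)
  g <- geometry(c("X", "H", "X"),
                matrix(c(0, 0, 0, d, 0, 0, 2 * d, 0, 0), 3, 3, byrow = TRUE),
                charges = c(1, 1, 1), masses = c(12, 1, 12))
  frames <- lapply(0:4, function(k) {
    traj_frame(k, 0.5, g, matrix(0, 3, 3), energy_total = 0, energy_qm = 0)
  })
  pd <- pt_definition("PT1", 1, 2, 3)
  pc <- pt_coordinates(frames, pd)[["PT1"]]
  expect_equal(pc$d_donor_h, rep(1.2, 5), tolerance = 1e-12)
  expect_equal(pc$d_acceptor_h, rep(1.2, 5), tolerance = 1e-12)
  expect_error(pt_coordinates(frames, pt_definition("x", 1, 2, 9)),
               "out of range")
  expect_error(pt_definition("x", 1, 1, 2), "distinct")
})

test_that("a scripted linear migration gives monotone coordinates", {
  fr <- scripted_crossing()
  pc <- pt_coordinates(fr, pt_definition("PT1", 1, 2, 3))[["PT1"]]
  mig <- 101:300
  expect_true(all(diff(pc$d_donor_h[mig]) > 0))
  expect_true(all(diff(pc$d_acceptor_h[mig]) < 0))
  # rotation invariance
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr_rot <- lapply(fr, function(f) { f$coords <- f$coords %*% R; f })
  pc2 <- pt_coordinates(fr_rot, pt_definition("PT1", 1, 2, 3))[["PT1"]]
  expect_equal(pc2$d_donor_h, pc$d_donor_h, tolerance = 1e-10)
})

test_that("event detection requires persistence and alternation", {
  fr <- scripted_crossing()
  pc <- pt_coordinates(fr, pt_definition("PT1", 1, 2, 3))[["PT1"]]
  ev <- detect_pt_events(pc, "PT1")
  expect_equal(nrow(ev), 1)
  expect_identical(ev$direction, "forward")
  # the crossing happens mid-migration; the event fires where the
  # difference first exceeds the hysteresis and persists
  diffv <- pc$d_donor_h - pc$d_acceptor_h
  expect_identical(ev$frame_index, which(diffv > 0.1)[1])

  # brief oscillating crossings shorter than the persistence: no events
  osc <- data.frame(time_fs = seq(0, 100, by = 0.5))
  osc$d_donor_h <- 1.5 + 0.6 * sin(osc$time_fs)       # crosses briefly
  osc$d_acceptor_h <- 1.5
  expect_equal(nrow(detect_pt_events(osc, "x", persistence_frames = 50)), 0)
})

test_that("two sequential transfers report the scripted 125 fs delay", {
  dt <- 0.5
  n <- 600
  t_fs <- (seq_len(n) - 1) * dt
  mk <- function(cross_frame) {
    d <- rep(-0.5, n)
    d[cross_frame:n] <- 0.5
    data.frame(time_fs = t_fs, d_donor_h = 1.5 + d, d_acceptor_h = 1.5 - d)
  }
  e1 <- detect_pt_events(mk(101), "PT1")
  e2 <- detect_pt_events(mk(351), "PT2")
  expect_equal(e2$event_time - e1$event_time, 250 * dt, tolerance = 1e-12)
  expect_equal(e2$event_time - e1$event_time, 125)
})

test_that("event detection is invariant under subsampling with rescaled persistence", {
  fr <- scripted_crossing()
  pc <- pt_coordinates(fr, pt_definition("PT1", 1, 2, 3))[["PT1"]]
  ev <- detect_pt_events(pc, "PT1", persistence_frames = 50)
  sub <- pc[seq(1, nrow(pc), by = 2), ]
  ev2 <- detect_pt_events(sub, "PT1", persistence_frames = 25)
  expect_equal(ev2$event_time, ev$event_time, tolerance = 1.0)
})

test_that("dipole-based state assignment thresholds and smooths", {
  g <- geometry(c("H", "H"), matrix(c(0, 0, 0, 0, 0, 2), 2, 3, byrow = TRUE))
  mk_frames <- function(mus) {
    lapply(seq_along(mus), function(k) {
      traj_frame(k - 1L, 0.5, g, matrix(0, 2, 3), energy_total = 0,
                 energy_qm = 0, dipole_moment = c(mus[k], 0, 0))
    })
  }
  const <- dipole_state_series(mk_frames(rep(0.5, 40)), threshold = 2)
  expect_true(all(const$state == "LE-like"))

  stepf <- dipole_state_series(mk_frames(c(rep(0.5, 50), rep(4, 50))),
                               threshold = 2)
  trans <- which(stepf$state == "CT-like")[1]
  expect_lt(abs(trans - 51), 6)       # within half the smoothing window
  expect_equal(ct_onset_time(stepf), stepf$time_fs[trans])

  no_dip <- mk_frames(rep(1, 5))
  no_dip[[2]]$dipole_moment <- NULL
  expect_error(dipole_state_series(no_dip, 2), "missing dipole")
})

test_that("torsion windows classify conformers and reject degeneracies", {
  mk <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    co <- matrix(c(1, 0, 1,
                   0, 0, 1,
                   0, 0, 0,
                   cos(phi), sin(phi), -1), 4, 3, byrow = TRUE)
    g <- geometry(rep("H", 4), co * 2)
    traj_frame(0L, 0.5, g, matrix(0, 4, 3), energy_total = 0, energy_qm = 0)
  }
  spec <- list(atoms = 1:4,
               windows = list(cis = c(-30, 30), trans = c(150, 180)))
  expect_identical(conformer_classify(list(mk(0)), spec), "cis")
  expect_identical(conformer_classify(list(mk(-170)), spec), "trans")
  expect_identical(conformer_classify(list(mk(90)), spec), "other")

  # scripted rotation switches the label exactly once at the boundary
  labs <- conformer_classify(lapply(seq(0, 60, by = 2), mk), spec)
  expect_identical(unique(labs), c("cis", "other"))
  expect_equal(sum(diff(labs == "cis") != 0), 1)

  bad <- list(atoms = 1:4, windows = list(a = c(-30, 30), b = c(20, 60)))
  expect_error(conformer_classify(list(mk(0)), bad), "overlap")

  lin <- geometry(rep("H", 4),
                  matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), 4, 3,
                         byrow = TRUE) * 2)
  fr_lin <- traj_frame(0L, 0.5, lin, matrix(0, 4, 3), energy_total = 0,
                       energy_qm = 0)
  expect_error(conformer_classify(list(fr_lin), spec), "undefined dihedral")
})

test_that("ensemble statistics follow their definitions", {
  ev <- function(t) data.frame(pt_label = "PT1", event_time = t,
                               direction = "forward", frame_index = 1L)
  none <- data.frame(pt_label = character(0), event_time = numeric(0),
                     direction = character(0), frame_index = integer(0))
  lists <- c(list(ev(80), ev(90)), replicate(8, none, simplify = FALSE))
  s <- ensemble_summary(lists, reference_times = rep(0, 10))
  row <- s$per_label[s$per_label$pt_label == "PT1", ]
  expect_equal(row$mean_delay, 85)
  expect_equal(row$n_events, 2)
  expect_equal(s$transfer_fraction, 0.2)

  one_in_ten <- c(list(ev(40)), replicate(9, none, simplify = FALSE))
  s2 <- ensemble_summary(one_in_ten)
  expect_equal(s2$transfer_fraction, 0.1)

  empty <- ensemble_summary(list(none))
  expect_equal(nrow(empty$per_label), 0)
  expect_equal(empty$transfer_fraction, 0)
})
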