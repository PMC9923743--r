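#' @title Geometries, environment sites, trajectories and run configuration
#' @name chem_io
#' @description
#' Readers and writers for the package's text formats.  External files use
#' Angstrom; everything returned to the caller is in atomic units (bohr).
#' All readers reject malformed input rather than silently repairing it, and
#' every writer/reader pair round-trips bit-identically on text it emitted.
NULL

.num_fmt <- "%.16e"

#' Construct a molecular geometry
#'
#' The QM region: element symbols, nuclear (core) charges and Cartesian
#' coordinates in bohr.  For model (PPP) systems the symbols may be "X"
#' placeholders and the charges are the model core charges.
#'
#' @param symbols character vector of element symbols
#' @param coords n x 3 numeric matrix, bohr
#' @param charges nuclear charges (e); defaults to the tabulated element charge
#' @param qm_charge net charge of the QM region (e)
#' @param multiplicity_hint integer >= 1
#' @param masses atomic masses (amu); defaults to tabulated values
#' @return object of class `geometry`
#' @export
geometry <- function(symbols, coords, charges = NULL, qm_charge = 0,
                     multiplicity_hint = 1, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(symbols)
  if (is.null(charges)) charges <- element_charge(symbols)
  if (is.null(masses)) masses <- element_mass(symbols)
  if (nrow(coords) != n || length(charges) != n) {
    stop("geometry: symbols, coords and charges must have matching lengths")
  }
  if (multiplicity_hint < 1) stop("geometry: multiplicity_hint must be >= 1")
  if (n > 1) {
    dmin <- min(dist(coords))
    if (dmin <= 1e-6) stop("geometry: coincident atoms (distance <= 1e-6 bohr)")
  }
  structure(list(symbols = symbols, charges = as.numeric(charges),
                 coords = coords, qm_charge = qm_charge,
                 multiplicity_hint = as.integer(multiplicity_hint),
                 masses = as.numeric(masses)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d atoms, charge %g, Z_tot %g>\n",
              length(x$symbols), x$qm_charge, sum(x$charges)))
  invisible(x)
}

#' Read a geometry from an XYZ file
#'
#' Standard XYZ: integer atom count, comment line, then `symbol x y z`
#' records in Angstrom.  Coordinates are converted to bohr.
#'
#' @param path file path
#' @param qm_charge,multiplicity_hint passed to [geometry()]
#' @return a `geometry`
#' @export
read_xyz <- function(path, qm_charge = 0, multiplicity_hint = 1) {
  if (!file.exists(path)) stop("read_xyz: no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 1 || !grepl("^\\s*[0-9]+\\s*$", lines[1])) {
    stop("read_xyz: malformed count line")
  }
  n <- as.integer(trimws(lines[1]))
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) stop("read_xyz: count mismatch (expected ", n,
                             " atom lines, found ", length(body), ")")
  toks <- strsplit(trimws(body[seq_len(n)]), "\\s+")
  if (any(vapply(toks, length, 1L) < 4)) stop("read_xyz: malformed atom line")
  symbols <- vapply(toks, `[`, "", 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("read_xyz: non-numeric coordinate")
  geometry(symbols, ang2bohr(xyz), qm_charge = qm_charge,
           multiplicity_hint = multiplicity_hint)
}

#' Write a geometry to an XYZ file
#' @param geom a `geometry`
#' @param path file path
#' @param comment comment-line text
#' @export
write_xyz <- function(geom, path, comment = "") {
  xyz <- bohr2ang(geom$coords)
  lines <- c(sprintf("%d", length(geom$symbols)), comment,
             sprintf(paste("%-3s", .num_fmt, .num_fmt, .num_fmt),
                     geom$symbols, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a trajectory frame
#'
#' Per-step record of a molecular dynamics run.  Energies in hartree,
#' coordinates/velocities in atomic units, dipole in e*bohr, time in fs.
#'
#' @param step_index integer step number (0-based)
#' @param dt_fs time step (fs)
#' @param geom the `geometry` at this step
#' @param velocities n x 3 matrix, bohr per atomic time unit
#' @param energy_total,energy_qm,energy_fixed_elec,energy_pol,kinetic_energy
#'   energies (hartree); `energy_total` is the conserved total
#'   (potential + kinetic)
#' @param dipole_moment length-3 QM dipole (a.u.)
#' @param state_label text tag, e.g. `"GS"` or `"CT"`
#' @param time_fs simulation time; defaults to `step_index * dt_fs`
#' @return object of class `traj_frame`
#' @export
traj_frame <- function(step_index, dt_fs, geom, velocities,
                       energy_total, energy_qm, energy_fixed_elec = 0,
                       energy_pol = 0, dipole_moment = c(0, 0, 0),
                       kinetic_energy = 0, state_label = "GS",
                       time_fs = step_index * dt_fs) {
  if (abs(time_fs - step_index * dt_fs) > 1e-9) {
    stop("traj_frame: time is not step_index * dt (invariant violated)")
  }
  structure(list(step_index = as.integer(step_index), time_fs = time_fs,
                 dt_fs = dt_fs, symbols = geom$symbols, coords = geom$coords,
                 velocities = matrix(as.numeric(velocities), ncol = 3),
                 energy_total = energy_total, energy_qm = energy_qm,
                 energy_fixed_elec = energy_fixed_elec,
                 energy_pol = energy_pol,
                 dipole_moment = as.numeric(dipole_moment),
                 kinetic_energy = kinetic_energy,
                 state_label = state_label),
            class = "traj_frame")
}

#' Append a trajectory frame to an extended-XYZ file
#'
#' The comment line carries `key=value` pairs (step, time_fs, dt_fs, the
#' energy decomposition, dipole components and state label); atom lines carry
#' positions (Angstrom) and velocities (bohr / atomic time unit).  Floats are
#' printed with 17 significant digits so that [read_traj()] recovers them to
#' full double precision.
#'
#' @param frame a `traj_frame`
#' @param path file to append to (created if absent)
#' @return `path`, invisibly
#' @export
write_traj_frame <- function(frame, path) {
  stopifnot(inherits(frame, "traj_frame"))
  if (abs(frame$time_fs - frame$step_index * frame$dt_fs) > 1e-9) {
    stop("write_traj_frame: frame fails the time invariant")
  }
  f <- function(x) sprintf(.num_fmt, x)
  comment <- paste0(
    "step=", frame$step_index,
    " time_fs=", f(frame$time_fs), " dt_fs=", f(frame$dt_fs),
    " E_total=", f(frame$energy_total), " E_qm=", f(frame$energy_qm),
    " E_fixed=", f(frame$energy_fixed_elec), " E_pol=", f(frame$energy_pol),
    " E_kin=", f(frame$kinetic_energy),
    " dipole_x=", f(frame$dipole_moment[1]),
    " dipole_y=", f(frame$dipole_moment[2]),
    " dipole_z=", f(frame$dipole_moment[3]),
    " state=", frame$state_label)
  xyz <- bohr2ang(frame$coords)
  v <- frame$velocities
  lines <- c(sprintf("%d", length(frame$symbols)), comment,
             sprintf(paste("%-3s", .num_fmt, .num_fmt, .num_fmt,
                           .num_fmt, .num_fmt, .num_fmt),
                     frame$symbols, xyz[, 1], xyz[, 2], xyz[, 3],
                     v[, 1], v[, 2], v[, 3]))
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read all frames from an extended-XYZ trajectory
#' @param path file written by [write_traj_frame()]
#' @return list of `traj_frame` objects
#' @export
read_traj <- function(path) {
  if (!file.exists(path)) stop("read_traj: no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("read_traj: malformed count line at line ", i)
    kv <- .parse_kv(lines[i + 1])
    body <- lines[i + 1 + seq_len(n)]
    toks <- strsplit(trimws(body), "\\s+")
    symbols <- vapply(toks, `[`, "", 1)
    mat <- t(vapply(toks, function(t) as.numeric(t[2:7]), numeric(6)))
    geom <- geometry(symbols, ang2bohr(mat[, 1:3, drop = FALSE]))
    frames[[length(frames) + 1]] <- traj_frame(
      step_index = as.integer(kv$step), dt_fs = as.numeric(kv$dt_fs),
      geom = geom, velocities = mat[, 4:6, drop = FALSE],
      energy_total = as.numeric(kv$E_total), energy_qm = as.numeric(kv$E_qm),
      energy_fixed_elec = as.numeric(kv$E_fixed),
      energy_pol = as.numeric(kv$E_pol),
      dipole_moment = as.numeric(c(kv$dipole_x, kv$dipole_y, kv$dipole_z)),
      kinetic_energy = as.numeric(kv$E_kin), state_label = kv$state,
      time_fs = as.numeric(kv$time_fs))
    i <- i + 2 + n
  }
  frames
}

.parse_kv <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) paste(p[-1], collapse = "="))
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Construct an environment-site set
#'
#' AMOEBA-style embedding sites: positions (bohr), permanent monopole,
#' dipole (e*bohr) and symmetric traceless Cartesian quadrupole (e*bohr^2),
#' isotropic polarizability (bohr^3), polarizable/frozen flags and a
#' polarization group id (induced interactions within a group are excluded).
#'
#' @param positions n x 3 matrix, bohr
#' @param charge monopoles (e)
#' @param dipole n x 3 permanent dipoles (e*bohr)
#' @param quadrupole n x 3 x 3 array of symmetric traceless quadrupoles
#'   (e*bohr^2), or NULL for all-zero
#' @param alpha isotropic polarizabilities (bohr^3); must be zero on
#'   non-polarizable sites
#' @param polarizable logical flags
#' @param frozen logical flags (frozen sites never move; far frozen sites are
#'   typically also depolarized)
#' @param group integer polarization-group ids
#' @return object of class `embedding_sites`
#' @export
embedding_sites <- function(positions, charge = NULL, dipole = NULL,
                            quadrupole = NULL, alpha = NULL,
                            polarizable = NULL, frozen = NULL, group = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  if (is.null(charge)) charge <- numeric(n)
  if (is.null(dipole)) dipole <- matrix(0, n, 3)
  if (is.null(quadrupole)) quadrupole <- array(0, c(n, 3, 3))
  if (is.null(alpha)) alpha <- numeric(n)
  if (is.null(polarizable)) polarizable <- alpha > 0
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  if (is.null(group)) group <- seq_len(n)
  dipole <- matrix(as.numeric(dipole), ncol = 3)
  for (i in seq_len(n)) {
    q <- quadrupole[i, , ]
    if (max(abs(q - t(q))) > 1e-10 || abs(sum(diag(q))) > 1e-10) {
      stop("embedding_sites: quadrupole on site ", i,
           " not symmetric traceless")
    }
  }
  if (any(alpha < 0)) stop("embedding_sites: negative polarizability")
  if (any(alpha[!polarizable] != 0)) {
    stop("embedding_sites: nonzero alpha on non-polarizable site")
  }
  structure(list(positions = positions, charge = as.numeric(charge),
                 dipole = dipole, quadrupole = quadrupole,
                 alpha = as.numeric(alpha),
                 polarizable = as.logical(polarizable),
                 frozen = as.logical(frozen), group = as.integer(group)),
            class = "embedding_sites")
}

#' @export
print.embedding_sites <- function(x, ...) {
  cat(sprintf("<embedding_sites: %d sites, %d polarizable, %d frozen>\n",
              length(x$charge), sum(x$polarizable), sum(x$frozen)))
  invisible(x)
}

#' Read environment sites from a columnar text file
#'
#' One site per line:
#' `id x y z q dx dy dz Qxx Qxy Qxz Qyy Qyz Qzz alpha polarizable frozen group`
#' with positions in Angstrom, dipoles in e*Angstrom, quadrupoles in
#' e*Angstrom^2 and polarizabilities in Angstrom^3; all are converted to
#' atomic units.  The quadrupole is symmetrized from its six upper-triangle
#' components and must be traceless to 1e-8 (input units).
#'
#' @param path file path
#' @return an `embedding_sites` object
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("read_sites: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  if (any(vapply(toks, length, 1L) != 18)) {
    stop("read_sites: every line must have 18 columns")
  }
  m <- t(vapply(toks, as.numeric, numeric(18)))
  if (anyNA(m)) stop("read_sites: non-numeric field")
  n <- nrow(m)
  quad <- array(0, c(n, 3, 3))
  b <- units_au$bohr_per_angstrom
  for (i in seq_len(n)) {
    q <- matrix(c(m[i, 9], m[i, 10], m[i, 11],
                  m[i, 10], m[i, 12], m[i, 13],
                  m[i, 11], m[i, 13], m[i, 14]), 3, 3)
    if (abs(sum(diag(q))) > 1e-8) {
      stop("read_sites: quadrupole on line ", i, " has |trace| > 1e-8")
    }
    q <- q - diag(3) * sum(diag(q)) / 3
    quad[i, , ] <- q * b^2
  }
  if (any(m[, 15] < 0)) stop("read_sites: negative polarizability")
  embedding_sites(positions = ang2bohr(m[, 2:4, drop = FALSE]),
                  charge = m[, 5],
                  dipole = m[, 6:8, drop = FALSE] * b,
                  quadrupole = quad,
                  alpha = m[, 15] * b^3,
                  polarizable = m[, 16] != 0,
                  frozen = m[, 17] != 0,
                  group = as.integer(m[, 18]))
}

#' Write environment sites in the columnar format read by [read_sites()]
#' @param sites an `embedding_sites` object
#' @param path file path
#' @export
write_sites <- function(sites, path) {
  b <- units_au$bohr_per_angstrom
  n <- length(sites$charge)
  lines <- character(n)
  for (i in seq_len(n)) {
    q <- sites$quadrupole[i, , ] / b^2
    lines[i] <- paste(c(
      i,
      sprintf(.num_fmt, c(bohr2ang(sites$positions[i, ]), sites$charge[i],
                          sites$dipole[i, ] / b,
                          q[1, 1], q[1, 2], q[1, 3], q[2, 2], q[2, 3], q[3, 3],
                          sites$alpha[i] / b^3)),
      as.integer(sites$polarizable[i]), as.integer(sites$frozen[i]),
      sites$group[i]), collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values are coerced
#' to logical (`true`/`false`), numeric where possible, and strings otherwise.
#' Dotted keys (e.g. `scf.tol_commutator`) are kept flat.
#'
#' @param path file path
#' @return named list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  out <- list()
  for (ln in lines) {
    p <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
    key <- trimws(p[1]); val <- trimws(p[2])
    if (tolower(val) %in% c("true", "false")) {
      out[[key]] <- as.logical(toupper(val))
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      out[[key]] <- as.numeric(val)
    } else {
      out[[key]] <- val
    }
  }
  out
}

# level-configurable structured logging: one line per SCF cycle / MD step
log_line <- function(level = "info", ...) {
  lv <- getOption("diabatmd.verbosity", 0)
  want <- switch(level, debug = 2, info = 1, warn = 0, 0)
  if (lv >= want) message(sprintf("[diabatmd %s] ", level), ...)
  invisible(NULL)
}
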