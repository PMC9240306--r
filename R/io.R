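# Readers/writers: GRO single frames, the package's multi-frame XYZ
# trajectory dialect, XVG-tolerant umbrella series, YAML configuration,
# TSV/JSON results.  All coordinates nm; energies kJ/mol internally,
# kcal/mol only at reporting boundaries.

# short deterministic hash of a config list for provenance headers
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 5381
  for (code in utf8ToInt(s)) h <- (h * 33 + code) %% 2147483647
  sprintf("%08x", h)
}

.provenanceHeader <- function(seed = NA, config = list()) {
  c(sprintf("# cgmelt %s", as.character(packageVersion("cgmelt"))),
    sprintf("# seed=%s config=%s", seed, .configHash(config)))
}

#' Read a GRO coordinate file
#'
#' Fixed-column GROMACS GRO parser (single frame, positions in nm;
#' velocity columns, if present, are ignored).
#'
#' @param path file path.
#' @return List with `title`, `atoms` (data.frame: `resid`, `resname`,
#'   `name`, `x`, `y`, `z`) and `box` (numeric, nm).
#' @export
readGRO <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO: fewer than 3 lines in ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1)
    stop("malformed GRO atom-count line 2: '", lines[2], "'")
  if (length(lines) < 2 + n + 1)
    stop(sprintf("malformed GRO: expected %d atom lines, found %d (line %d)",
                 n, length(lines) - 3, length(lines)))
  al <- lines[3:(2 + n)]
  num <- function(ss, what, from, to) {
    v <- suppressWarnings(as.numeric(substr(ss, from, to)))
    if (anyNA(v))
      stop(sprintf("malformed GRO %s at line %d", what, 2 + which(is.na(v))[1]))
    v
  }
  atoms <- data.frame(
    resid = as.integer(num(al, "residue id", 1, 5)),
    resname = trimws(substr(al, 6, 10)),
    name = trimws(substr(al, 11, 15)),
    x = num(al, "x coordinate", 21, 28),
    y = num(al, "y coordinate", 29, 36),
    z = num(al, "z coordinate", 37, 44))
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                              "\\s+")[[1]]))
  if (anyNA(box) || length(box) < 3)
    stop("malformed GRO box line ", 3 + n)
  list(title = lines[1], atoms = atoms, box = box[1:3])
}

#' Write a GRO coordinate file
#'
#' @param atoms data.frame with `resid`, `resname`, `name`, `x`, `y`, `z`
#'   (nm).
#' @param path output path.
#' @param box box lengths, nm.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
writeGRO <- function(atoms, path, box, title = "cgmelt coordinates") {
  n <- nrow(atoms)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     atoms$resid %% 100000, substr(atoms$resname, 1, 5),
                     substr(atoms$name, 1, 5), seq_len(n) %% 100000,
                     atoms$x, atoms$y, atoms$z),
             sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory in the multi-frame XYZ dialect
#'
#' Each frame is a bead-count line, a structured comment
#' `frame=<i> temperature=<K> time=<ps> box=<Lx>,<Ly>,<Lz>`, then one
#' `name resid x y z` line per bead (peptide beads `BB`, phosphates
#' `PO4`; nm).  Leading `#` lines carry provenance and are skipped by the
#' reader.  The full grammar is documented in the package README.
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  nf <- nFrames(traj); nr <- nResidues(traj); np <- nrow(traj@phosphates)
  phosLines <- sprintf("PO4 %d %.5f %.5f %.5f", seq_len(np),
                       traj@phosphates[, 1], traj@phosphates[, 2],
                       traj@phosphates[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(seed = traj@provenance$seed,
                               config = traj@provenance), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("%d", nr + np), con)
    writeLines(sprintf("frame=%d temperature=%g time=%g box=%g,%g,%g",
                       f - 1, traj@temperature, f - 1,
                       traj@box[1], traj@box[2], traj@box[3]), con)
    writeLines(sprintf("BB %d %.5f %.5f %.5f", traj@residueIds,
                       traj@peptide[f, , 1], traj@peptide[f, , 2],
                       traj@peptide[f, , 3]), con)
    writeLines(phosLines, con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file in the dialect written by [writeTrajectoryXYZ()].
#' @return A [Trajectory-class].
#' @export
readTrajectoryXYZ <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty trajectory file: ", path)
  pos <- 1L
  frames <- list(); temps <- numeric(); box <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat)) stop("malformed bead-count line ", pos, " in ", path)
    comment <- lines[pos + 1L]
    kv <- regmatches(comment, gregexpr("[a-z]+=[^ ]+", comment))[[1]]
    meta <- setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
    temps <- c(temps, as.numeric(meta[["temperature"]]))
    if (is.null(box) && "box" %in% names(meta))
      box <- as.numeric(strsplit(meta[["box"]], ",")[[1]])
    rows <- lines[(pos + 2L):(pos + 1L + nat)]
    parts <- strsplit(trimws(rows), "\\s+")
    if (any(lengths(parts) != 5))
      stop("malformed bead line near ", pos + 1L + which(lengths(parts) != 5)[1])
    m <- matrix(unlist(parts), ncol = 5, byrow = TRUE)
    frames[[length(frames) + 1L]] <-
      list(name = m[, 1], resid = as.integer(m[, 2]),
           xyz = matrix(as.numeric(m[, 3:5]), ncol = 3))
    pos <- pos + 2L + nat
  }
  f1 <- frames[[1]]
  isBB <- f1$name == "BB"
  nr <- sum(isBB)
  pept <- array(0, dim = c(length(frames), nr, 3))
  for (f in seq_along(frames)) {
    sel <- frames[[f]]$name == "BB"
    if (sum(sel) != nr) stop("inconsistent bead counts across frames")
    pept[f, , ] <- frames[[f]]$xyz[sel, ]
  }
  if (is.null(box)) box <- c(0, 0, 0)
  trajectory(pept, f1$xyz[!isBB, , drop = FALSE], f1$resid[isBB],
             temps[1], box, provenance = list(source = path))
}

#' Read a bead chain from a GRO file
#'
#' Interprets each atom of a single-frame GRO file as one backbone bead,
#' ordered as written, with residue ids taken from the residue column.
#'
#' @param path GRO file.
#' @param state conformational-state tag for the chain.
#' @return A [BeadChain-class].
#' @export
beadChainFromGRO <- function(path, state = c("helical", "extended")) {
  g <- readGRO(path)
  beadChain(cbind(g$atoms$x, g$atoms$y, g$atoms$z),
            residueIds = g$atoms$resid, state = match.arg(state))
}

#' Read an umbrella reaction-coordinate series
#'
#' Two-column text (time, xi in nm); lines starting with `#` or `@`
#' (XVG-style) are skipped.
#'
#' @param path file path.
#' @return List with `time` and `xi`.
#' @export
readUmbrellaSeries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("ragged row at line ", which(keep)[bad[1]], " in ", path,
         ": expected two numeric columns")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2,
              byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value at line ",
                     which(keep)[which(is.na(rowSums(m)))[1]], " in ", path)
  list(time = m[, 1], xi = m[, 2])
}

#' Write an umbrella reaction-coordinate series
#'
#' @param time,xi numeric vectors of equal length.
#' @param path output path.
#' @param comments extra comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
writeUmbrellaSeries <- function(time, xi, path, comments = character()) {
  stopifnot(length(time) == length(xi))
  writeLines(c(.provenanceHeader(), paste0("# ", comments),
               sprintf("%.6g %.10g", time, xi)), path)
  invisible(path)
}

#' Read an umbrella-window manifest
#'
#' YAML manifest with a `windows` list (`center`, `force_constant`,
#' `file`) and optional `temperature`; series files are resolved relative
#' to the manifest directory.
#'
#' @param path manifest path.
#' @return List of [UmbrellaWindow-class]; attribute `"temperature"` if
#'   stated.
#' @export
readUmbrellaManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$windows) || !length(y$windows))
    stop("manifest has no windows block: ", path)
  dir <- dirname(path)
  out <- lapply(y$windows, function(w) {
    for (fld in c("center", "force_constant", "file"))
      if (is.null(w[[fld]])) stop("window entry missing '", fld, "' in ", path)
    ser <- readUmbrellaSeries(file.path(dir, w$file))
    umbrellaWindow(as.numeric(w$center), ser$xi,
                   as.numeric(w$force_constant))
  })
  if (!is.null(y$temperature))
    attr(out, "temperature") <- as.numeric(y$temperature)
  out
}

.numField <- function(block, name, unit, min = -Inf, blockName = "config") {
  v <- block[[name]]
  if (is.null(v)) return(NULL)
  v <- suppressWarnings(as.numeric(v))
  if (is.na(v) || v < min)
    stop(sprintf("%s: '%s' must be a number >= %g (%s)", blockName, name,
                 min, unit))
  v
}

#' Read and validate a run configuration
#'
#' YAML with optional blocks `restraints` (state, K_angle, theta_min,
#' sigma_angle, K_dihedral, phi_min, sigma_dihedral), `simulator` (dt,
#' friction, temperature, n_steps, save_interval, seed, bond_k, bond_r0),
#' `membrane` (plane_z, well_depth, well_width, box), `analysis`
#' (threshold, segments, burn_in) and `wham` (temp, bin_width, tol,
#' plateau, bound).  Every numeric field is validated with a
#' unit-annotated message.
#'
#' @param path YAML path.
#' @return Named list: `restraints` ([RestraintParams-class] or NULL),
#'   `simulator` ([SimulationConfig-class] or NULL), `membrane`
#'   ([MembraneModel-class] or NULL), `analysis`, `wham`, `seed`, and the
#'   raw YAML under `raw`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  out <- list(raw = y, seed = if (!is.null(y$seed)) as.integer(y$seed) else 1L)
  if (!is.null(y$restraints)) {
    b <- y$restraints
    out$restraints <- restraintParams(
      state = if (is.null(b$state)) "helical" else b$state,
      Kangle = .numField(b, "K_angle", "kJ/mol", 0, "restraints") %||% 10,
      thetaMin = .numField(b, "theta_min", "degrees", 0, "restraints"),
      sigmaAngle = .numField(b, "sigma_angle", "degrees^2", 1e-12, "restraints") %||% 200,
      Kdihedral = .numField(b, "K_dihedral", "kJ/mol", 0, "restraints") %||% 10,
      phiMin = .numField(b, "phi_min", "degrees", -180, "restraints"),
      sigmaDihedral = .numField(b, "sigma_dihedral", "degrees^2", 1e-12, "restraints") %||% 200)
  }
  if (!is.null(y$simulator)) {
    b <- y$simulator
    out$simulator <- simulationConfig(
      dt = .numField(b, "dt", "ps", 1e-12, "simulator") %||% 0.01,
      friction = .numField(b, "friction", "1/ps", 1e-12, "simulator") %||% 1,
      temperature = .numField(b, "temperature", "K", 1e-12, "simulator") %||% 310,
      nSteps = .numField(b, "n_steps", "steps", 1, "simulator") %||% 10000,
      saveInterval = .numField(b, "save_interval", "steps", 1, "simulator") %||% 10,
      seed = if (!is.null(b$seed)) as.integer(b$seed) else out$seed,
      bondK = .numField(b, "bond_k", "kJ/mol/nm^2", 0, "simulator") %||% 2000,
      bondR0 = .numField(b, "bond_r0", "nm", 1e-12, "simulator") %||% 0.35)
  }
  if (!is.null(y$membrane)) {
    b <- y$membrane
    out$membrane <- membraneModel(
      planeZ = .numField(b, "plane_z", "nm", 0, "membrane") %||% 2,
      wellDepth = .numField(b, "well_depth", "kJ/mol", 0, "membrane") %||% 10,
      wellWidth = .numField(b, "well_width", "nm", 1e-12, "membrane") %||% 0.3,
      box = if (is.null(b$box)) c(6, 6, 10) else as.numeric(b$box))
  }
  if (!is.null(y$analysis)) {
    b <- y$analysis
    out$analysis <- list(
      threshold = .numField(b, "threshold", "nm", 1e-12, "analysis") %||% 1,
      segments = .numField(b, "segments", "count", 0, "analysis") %||% 3,
      burn_in = .numField(b, "burn_in", "fraction", 0, "analysis") %||% 0)
  }
  if (!is.null(y$wham)) {
    b <- y$wham
    out$wham <- list(
      temp = .numField(b, "temp", "K", 1e-12, "wham"),
      bin_width = .numField(b, "bin_width", "nm", 1e-12, "wham") %||% 0.02,
      tol = .numField(b, "tol", "kBT", 1e-15, "wham") %||% 1e-7,
      plateau = if (!is.null(b$plateau)) as.numeric(b$plateau) else NULL,
      bound = if (!is.null(b$bound)) as.numeric(b$bound) else NULL)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a contact profile as TSV
#'
#' Columns `residue`, `index`, `stderr` (between-segment standard error
#' when segment profiles are supplied), with a provenance header.
#'
#' @param profile a [ContactProfile-class].
#' @param path output path.
#' @param segments optional output of [segmentConvergence()] for the
#'   stderr column.
#' @param seed seed recorded in the header.
#' @return `path`, invisibly.
#' @export
writeContactTSV <- function(profile, path, segments = NULL, seed = NA) {
  stopifnot(is(profile, "ContactProfile"))
  se <- rep(NA_real_, length(profile@index))
  if (!is.null(segments)) {
    mat <- do.call(rbind, lapply(segments$profiles, slot, "index"))
    se <- apply(mat, 2, sd) / sqrt(nrow(mat))
  }
  df <- data.frame(residue = profile@residueIds, index = profile@index,
                   stderr = se)
  writeLines(.provenanceHeader(seed = seed,
                               config = list(temperature = profile@temperature)),
             path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Write a melting curve as TSV
#'
#' @param curve a [MeltingCurve-class].
#' @param path output path.
#' @param stderr optional per-temperature standard errors.
#' @param seed seed recorded in the header.
#' @return `path`, invisibly.
#' @export
writeMeltingTSV <- function(curve, path, stderr = NULL, seed = NA) {
  stopifnot(is(curve, "MeltingCurve"))
  df <- data.frame(temperature = curve@temperature, index = curve@index,
                   stderr = if (is.null(stderr)) NA_real_ else stderr)
  writeLines(.provenanceHeader(seed = seed, config = curve@fit), path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Write a PMF profile as TSV
#'
#' Columns `xi`, `G_kJ`, `G_kcal`, `counts`.
#'
#' @param pmf a [PMFProfile-class].
#' @param path output path.
#' @param seed seed recorded in the header.
#' @return `path`, invisibly.
#' @export
writePMFTSV <- function(pmf, path, seed = NA) {
  stopifnot(is(pmf, "PMFProfile"))
  df <- data.frame(xi = pmf@grid, G_kJ = pmf@freeEnergy,
                   G_kcal = freeEnergyKcal(pmf), counts = pmf@counts)
  writeLines(.provenanceHeader(seed = seed,
                               config = list(reference = pmf@reference,
                                             temperature = pmf@temperature)),
             path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}
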