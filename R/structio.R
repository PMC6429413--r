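# Structure/trajectory/table input and output. PDB parsing and writing are
# delegated to bio3d; this layer converts to the package's S4 containers,
# assigns masses from element symbols and enforces the contracts the
# downstream numerics rely on (stable atom order, matching frame sizes).

#' Construct a Structure
#'
#' @param atoms data.frame with columns `name`, `resid`, `resname`, `chain`
#'   and optionally `element` (inferred from atom names when absent).
#' @param coords N x 3 coordinate matrix (\enc{Å}{Angstrom}).
#' @param masses optional per-atom masses (amu); derived from the element
#'   symbols via [elementMass()] when omitted.
#' @return a [Structure-class]
#' @export
Structure <- function(atoms, coords, masses = NULL) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$element))
    atoms$element <- .guessElement(atoms$name, atoms$resname)
  if (is.null(masses)) masses <- elementMass(atoms$element)
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("Structure", atoms = atoms[, c("name", "element", "resid",
                                     "resname", "chain")],
      coords = coords, masses = as.numeric(masses))
}

#' Construct a Trajectory
#'
#' @param structure the [Structure-class] the frames refer to.
#' @param coords F x 3N frame matrix (bio3d xyz layout) or a list of N x 3
#'   matrices.
#' @param times frame times in ps (default 0, 1, 2, ...).
#' @return a [Trajectory-class]
#' @export
Trajectory <- function(structure, coords, times = NULL) {
  if (is.list(coords)) coords <- do.call(rbind, lapply(coords, .flatten))
  coords <- unclass(as.matrix(coords))   # bio3d returns class "xyz"
  if (is.null(times)) times <- seq_len(nrow(coords)) - 1
  new("Trajectory", structure = structure, coords = coords,
      times = as.numeric(times))
}

# Light syntactic validation so malformed coordinate records fail with the
# offending line number rather than propagating NA coordinates.
.checkPdbRecords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec))
    stop("no ATOM/HETATM records found in '", path, "' (empty or not a PDB file)")
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed PDB record at line ", i, ": unparsable coordinates")
  }
  invisible(TRUE)
}

#' Read a structure from a PDB file
#'
#' Atoms are returned in file order; hetero atoms are retained. Masses are
#' assigned from element symbols (the PDB element column when present,
#' otherwise inferred from atom names); an unknown element is an error.
#'
#' @param path path to a PDB file.
#' @param format only "pdb" is supported.
#' @return a [Structure-class]
#' @export
readStructure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: '", path, "'")
  .checkPdbRecords(path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  element <- a$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  if (any(missing_el))
    element[missing_el] <- .guessElement(a$elety[missing_el],
                                         a$resid[missing_el])
  chain <- a$chain
  chain[is.na(chain)] <- " "
  Structure(
    atoms = data.frame(name = a$elety, element = toupper(trimws(element)),
                       resid = a$resno, resname = a$resid, chain = chain),
    coords = cbind(a$x, a$y, a$z))
}

#' Write a structure to a PDB file
#'
#' @param structure a [Structure-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStructure <- function(structure, path) {
  a <- structure@atoms
  bio3d::write.pdb(file = path, xyz = .flatten(structure@coords),
                   elety = a$name, resid = a$resname, resno = a$resid,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Read a trajectory
#'
#' Multi-model PDB is the portable mandatory format; DCD is supported through
#' bio3d. Frame times come from `times`, or from `dt`/`startTime` when only a
#' frame interval is known.
#'
#' @param path path to a multi-model PDB or DCD file.
#' @param structure optional [Structure-class]; when given, every frame must
#'   match its atom count. For DCD input a structure is required.
#' @param format "pdb" or "dcd".
#' @param dt frame interval in ps (default 1).
#' @param startTime time of the first frame in ps (default 0).
#' @param times explicit frame times (overrides `dt`/`startTime`).
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(path, structure = NULL, format = c("pdb", "dcd"),
                           dt = 1, startTime = 0, times = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (format == "pdb") {
    .checkPdbRecords(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    if (is.null(structure)) {
      structure <- readStructure(path)
    }
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  } else {
    if (is.null(structure))
      stop("reading DCD requires the matching Structure")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  }
  n3 <- 3L * nAtoms(structure)
  if (ncol(xyz) != n3) {
    # locate the first offending frame for the error message
    stop(sprintf(
      "frame 1..%d: atom count mismatch (file has %d coordinates per frame, structure implies %d)",
      nrow(xyz), ncol(xyz), n3))
  }
  if (is.null(times)) times <- startTime + dt * (seq_len(nrow(xyz)) - 1)
  if (length(times) != nrow(xyz))
    stop("length of 'times' must equal the number of frames")
  Trajectory(structure, xyz, times)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTrajectory <- function(traj, path) {
  a <- traj@structure@atoms
  bio3d::write.pdb(file = path, xyz = traj@coords, elety = a$name,
                   resid = a$resname, resno = a$resid, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' Extract a time window from a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param start,end window bounds in ps.
#' @param closed if FALSE (default) the window is half-open, `[start, end)`;
#'   if TRUE it is closed, `[start, end]`. A duration D sampled at interval
#'   dt therefore yields `floor(D/dt)` frames half-open and `floor(D/dt)+1`
#'   closed.
#' @return a [Trajectory-class] restricted to the window.
#' @export
trajectoryWindow <- function(traj, start, end, closed = FALSE) {
  keep <- .framesInWindow(traj@times, c(start, end), closed = closed)
  if (!length(keep))
    stop(sprintf("no frames in window [%g, %g%s", start, end,
                 if (closed) "]" else ")"))
  Trajectory(traj@structure, traj@coords[keep, , drop = FALSE],
             traj@times[keep])
}

#' Thin a trajectory to regular snapshots
#'
#' Keeps frames whose time offset from the first frame is a multiple of
#' `interval`. Whether the first frame itself is kept is explicit because
#' both conventions occur in practice (a 120-ns trajectory thinned at 2 ns
#' yields 60 snapshots without the origin, 61 with it).
#'
#' @param traj a [Trajectory-class].
#' @param interval snapshot interval, ps.
#' @param includeOrigin keep the first frame (default FALSE).
#' @return a [Trajectory-class].
#' @export
snapshotTrajectory <- function(traj, interval, includeOrigin = FALSE) {
  stopifnot(interval > 0)
  off <- traj@times - traj@times[1]
  keep <- which(abs(off %% interval) < 1e-9 |
                  abs(off %% interval - interval) < 1e-9)
  if (!includeOrigin) keep <- setdiff(keep, 1L)
  if (!length(keep)) stop("no frames on the requested snapshot grid")
  Trajectory(traj@structure, traj@coords[keep, , drop = FALSE],
             traj@times[keep])
}

#' Write a rectangular table at full precision
#'
#' Writes a data.frame (or a [GeometrySeries-class]) as CSV/TSV with a header
#' row; doubles are written with 17 significant digits so a read-back
#' reproduces them exactly.
#'
#' @param x data.frame, matrix or GeometrySeries.
#' @param path output path.
#' @param format "csv" or "tsv" (default from the file extension).
#' @return invisibly, the path.
#' @export
writeTable <- function(x, path, format = NULL) {
  if (is(x, "GeometrySeries")) x <- as.data.frame(x)
  x <- as.data.frame(x)
  if (is.null(format))
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  format <- match.arg(format, c("csv", "tsv"))
  sep <- if (format == "csv") "," else "\t"
  y <- x
  for (j in seq_along(y))
    if (is.double(y[[j]])) y[[j]] <- sprintf("%.17g", y[[j]])
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot write '", path, "'"))
  on.exit(close(con))
  utils::write.table(y, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [writeTable()]
#'
#' @param path input path.
#' @param format "csv" or "tsv" (default from the file extension).
#' @return data.frame
#' @export
readTable <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  format <- match.arg(format, c("csv", "tsv"))
  utils::read.table(path, header = TRUE, sep = if (format == "csv") "," else "\t")
}
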