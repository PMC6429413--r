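# Essential dynamics: Cartesian covariance of a trajectory over an analysis
# atom set (after rigid-body fitting to the initial conformation of the
# window), its eigen-decomposition, variance spectra, projections, extreme
# frames and porcupine vector fields.

#' Cartesian covariance matrix of a trajectory
#'
#' Frames in the window are rigidly fitted to the reference (the first frame
#' of the window, removing overall translation and rotation), and the 3n x 3n
#' covariance \eqn{C_{ij} = \langle (x_i - \langle x_i\rangle)(x_j - \langle
#' x_j\rangle)\rangle} is accumulated over the analysis atoms with 1/F
#' (population) normalisation by default.
#'
#' @param traj a [Trajectory-class].
#' @param atomSet analysis atoms (e.g. `selectAtoms(s, "name CA")`).
#' @param window optional time window in ps, half-open unless `closed`.
#' @param align fit frames to the reference before accumulating (default
#'   TRUE; disable only for pre-aligned input).
#' @param normalization "population" (1/F, default) or "sample" (1/(F-1)).
#' @param closed use a closed time window.
#' @return list with `C` (3n x 3n), `mean` (n x 3), `refCoords` (n x 3
#'   alignment reference, 0 x 3 when `align = FALSE`), `nFrames`, `window`
#'   and `atomIndices`. Feed it to [pcaModes()].
#' @export
covarianceMatrix <- function(traj, atomSet, window = NULL, align = TRUE,
                             normalization = c("population", "sample"),
                             closed = FALSE) {
  normalization <- match.arg(normalization)
  idx <- .asIndexSet(atomSet, traj@structure)
  keep <- .framesInWindow(traj@times, window, closed = closed)
  if (length(keep) < 2)
    stop("covariance needs at least 2 frames in the window")
  xyz <- traj@coords[keep, , drop = FALSE]
  if (align) {
    ref <- .unflatten(xyz[1, .xyzIndices(idx)])
    X <- .alignedFrameBlock(xyz, idx, idx, ref)
  } else {
    ref <- matrix(numeric(0), 0, 3)
    X <- xyz[, .xyzIndices(idx), drop = FALSE]
  }
  f <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  denom <- if (normalization == "population") f else f - 1
  C <- crossprod(Xc) / denom
  win <- if (is.null(window)) c(NA_real_, NA_real_) else as.numeric(window)
  list(C = C, mean = .unflatten(mu), refCoords = ref, nFrames = f,
       window = win, atomIndices = as.integer(idx))
}

#' Principal component analysis of a covariance matrix
#'
#' Eigen-decomposition with eigenvalues in decreasing order. Each eigenvector
#' is a unit-norm collective displacement of the analysis atoms and its
#' eigenvalue is the variance (\enc{Å}{Angstrom}^2) of the motion along it.
#'
#' @param cov result of [covarianceMatrix()], or a bare symmetric matrix (in
#'   which case `mean` coordinates may be supplied separately).
#' @param mean optional n x 3 mean coordinates when `cov` is a bare matrix.
#' @return a [PCResult-class].
#' @export
pcaModes <- function(cov, mean = NULL) {
  if (is.matrix(cov))
    cov <- list(C = cov,
                mean = if (is.null(mean)) .unflatten(numeric(ncol(cov)))
                       else as.matrix(mean),
                refCoords = matrix(numeric(0), 0, 3),
                nFrames = NA_integer_, window = c(NA_real_, NA_real_),
                atomIndices = integer())
  C <- cov$C
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C), .Machine$double.eps))
    stop("covariance matrix must be symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (min(e$values) < -1e-8 * max(lmax, .Machine$double.eps))
    stop("matrix has significantly negative eigenvalues: not a covariance")
  values <- pmax(e$values, 0)
  new("PCResult", values = values,
      vectors = .normalizeSigns(e$vectors),
      meanCoords = cov$mean, refCoords = cov$refCoords,
      nFrames = as.integer(cov$nFrames), window = cov$window,
      atomIndices = as.integer(cov$atomIndices))
}

#' Variance spectrum of a PCA
#'
#' @param pc a [PCResult-class].
#' @param nComponents number of leading components to tabulate (default 25).
#' @return data.frame(component, eigenvalue, cumulative) where `cumulative`
#'   is the cumulative percentage of total variance.
#' @export
varianceSpectrum <- function(pc, nComponents = 25L) {
  stopifnot(is(pc, "PCResult"), nComponents >= 1,
            nComponents <= length(pc@values))
  tot <- sum(pc@values)
  k <- seq_len(nComponents)
  data.frame(component = k, eigenvalue = pc@values[k],
             cumulative = 100 * cumsum(pc@values[k]) / tot)
}

# Aligned, flattened analysis-atom coordinates of every frame, using the
# alignment stored in the PCResult (no-op if the PCA was built unaligned).
.pcFrameMatrix <- function(traj, pc) {
  idx <- pc@atomIndices
  if (!length(idx)) stop("PCResult carries no atom indices")
  if (nrow(pc@refCoords))
    .alignedFrameBlock(traj@coords, idx, idx, pc@refCoords)
  else traj@coords[, .xyzIndices(idx), drop = FALSE]
}

#' Project a trajectory onto a principal component
#'
#' Per-frame scalar \eqn{p(t) = (x(t) - \bar x)\cdot d_k} after applying the
#' same rigid-body fit used to build the covariance. The variance of the
#' projections reproduces the component's eigenvalue.
#'
#' @param traj a [Trajectory-class] (same structure the PCA was built from).
#' @param pc a [PCResult-class].
#' @param component component index (1-based).
#' @return a [GeometrySeries-class] of kind "projection".
#' @export
projectOnComponent <- function(traj, pc, component) {
  stopifnot(is(traj, "Trajectory"), is(pc, "PCResult"))
  if (component < 1 || component > length(pc@values))
    stop("component index out of range")
  X <- .pcFrameMatrix(traj, pc)
  p <- as.numeric(sweep(X, 2, .flatten(pc@meanCoords)) %*%
                    pc@vectors[, component])
  new("GeometrySeries", times = traj@times, values = p, kind = "projection")
}

#' Extreme conformations along a principal component
#'
#' Returns the actual trajectory frames attaining the minimum and maximum
#' projection on a component (no synthetic extrapolation).
#'
#' @param traj a [Trajectory-class].
#' @param pc a [PCResult-class].
#' @param component component index.
#' @return list with `min`/`max` ([Structure-class] at the extreme frames,
#'   full-structure original coordinates), `frames` (their indices) and
#'   `projections` (their projection values).
#' @export
extremeConformations <- function(traj, pc, component) {
  p <- projectOnComponent(traj, pc, component)
  imin <- which.min(p@values); imax <- which.max(p@values)
  asStructure <- function(i)
    methods::initialize(traj@structure, coords = frameCoords(traj, i))
  list(min = asStructure(imin), max = asStructure(imax),
       frames = c(min = imin, max = imax),
       projections = c(min = p@values[imin], max = p@values[imax]))
}

#' Porcupine vector field of a component
#'
#' One arrow per analysis atom, \eqn{scale \cdot \sqrt{\lambda_k} \cdot
#' d_{k,atom}}, anchored at the mean coordinates; optionally exported as an
#' NMD file for VMD's Normal Mode Wizard.
#'
#' @param pc a [PCResult-class].
#' @param component component index.
#' @param scale extra scale factor (default 1).
#' @param nmdPath optional path for an NMD export.
#' @param atoms optional atom metadata passed to [writeNmd()].
#' @return n x 3 matrix of arrow vectors (invisibly when `nmdPath` is set).
#' @export
porcupineField <- function(pc, component, scale = 1, nmdPath = NULL,
                           atoms = NULL) {
  stopifnot(is(pc, "PCResult"))
  if (component < 1 || component > length(pc@values))
    stop("component index out of range")
  arrows <- .unflatten(scale * sqrt(pc@values[component]) *
                         pc@vectors[, component])
  if (!is.null(nmdPath)) {
    writeNmd(nmdPath, coords = pc@meanCoords,
             modes = pc@vectors[, component, drop = FALSE],
             scales = scale * sqrt(pc@values[component]),
             atoms = atoms, title = "principal component",
             modeIndices = component)
    return(invisible(arrows))
  }
  arrows
}
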