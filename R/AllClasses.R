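#' @import methods
NULL

.checkMatrix <- function(x, nrow = NULL, ncol = NULL, what = "matrix") {
  msg <- character()
  if (!is.numeric(x)) msg <- c(msg, sprintf("%s must be numeric", what))
  if (!is.null(ncol) && ncol(x) != ncol)
    msg <- c(msg, sprintf("%s must have %d columns", what, ncol))
  if (!is.null(nrow) && nrow(x) != nrow)
    msg <- c(msg, sprintf("%s must have %d rows", what, nrow))
  if (length(x) && any(!is.finite(x)))
    msg <- c(msg, sprintf("%s contains non-finite values", what))
  msg
}

#' Molecular structure
#'
#' An ordered set of atoms with names, residue assignments, chain identifiers,
#' Cartesian coordinates (\enc{Å}{Angstrom}) and masses (amu). The atom order
#' is stable and defines the canonical index space for every matrix and vector
#' produced downstream (Hessians, modes, covariances, selections).
#'
#' @slot atoms data.frame with columns \code{name}, \code{element},
#'   \code{resid} (1-based residue number), \code{resname}, \code{chain}.
#' @slot coords N x 3 numeric matrix of coordinates in \enc{Å}{Angstrom}.
#' @slot masses numeric vector of atomic masses in amu, one per atom.
#' @export
setClass("Structure",
  representation(atoms = "data.frame", coords = "matrix", masses = "numeric"))

setValidity("Structure", function(object) {
  n <- nrow(object@atoms)
  msg <- character()
  need <- c("name", "element", "resid", "resname", "chain")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (n < 1) msg <- c(msg, "structure must contain at least one atom")
  msg <- c(msg, .checkMatrix(object@coords, nrow = n, ncol = 3, what = "coords"))
  if (length(object@masses) != n) msg <- c(msg, "one mass per atom required")
  if (length(object@masses) && any(!is.finite(object@masses) | object@masses <= 0))
    msg <- c(msg, "masses must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Coordinate trajectory bound to a Structure
#'
#' Frames are rows of a F x 3N matrix in the bio3d xyz layout
#' (x1, y1, z1, x2, ...); times are in picoseconds and non-decreasing.
#'
#' @slot structure the [Structure-class] the frames refer to.
#' @slot times numeric vector of frame times (ps).
#' @slot coords F x 3N numeric matrix of per-frame coordinates.
#' @export
setClass("Trajectory",
  representation(structure = "Structure", times = "numeric", coords = "matrix"))

setValidity("Trajectory", function(object) {
  msg <- character()
  n3 <- 3L * nrow(object@structure@atoms)
  if (ncol(object@coords) != n3)
    msg <- c(msg, sprintf("frames have %d coordinates but structure implies %d",
                          ncol(object@coords), n3))
  if (nrow(object@coords) != length(object@times))
    msg <- c(msg, "one time per frame required")
  if (length(object@times) && any(!is.finite(object@times)))
    msg <- c(msg, "times must be finite")
  if (length(object@times) > 1 && any(diff(object@times) < 0))
    msg <- c(msg, "times must be non-decreasing")
  if (length(object@coords) && any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Ordered atom selection
#'
#' An ordered, duplicate-free set of 1-based positions into the atom list of a
#' [Structure-class], carrying the selection expression that produced it.
#'
#' @slot .Data integer vector of atom indices.
#' @slot label free-text label (usually the selection expression).
#' @export
setClass("AtomIndexSet", contains = "integer",
  representation(label = "character"))

setValidity("AtomIndexSet", function(object) {
  idx <- object@.Data
  msg <- character()
  if (length(idx) < 1) msg <- c(msg, "empty atom selection")
  if (anyDuplicated(idx)) msg <- c(msg, "duplicate atom indices")
  if (length(idx) && any(idx < 1)) msg <- c(msg, "indices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Second-derivative (Hessian) model of a structure
#'
#' A dense, symmetric 3N x 3N matrix of second derivatives of the potential
#' energy, either built from an anisotropic elastic network or imported from
#' an external computation, together with the reference coordinates and, when
#' mass-weighted, the masses used.
#'
#' @slot matrix 3N x 3N symmetric numeric matrix.
#' @slot origin "enm" or "imported".
#' @slot refCoords N x 3 reference coordinates (\enc{Å}{Angstrom}).
#' @slot cutoff elastic-network distance cutoff (\enc{Å}{Angstrom}; NA when imported).
#' @slot forceConstant uniform spring constant (energy
#'   length^-2; NA when imported).
#' @slot massWeighted logical; TRUE after [massWeight()].
#' @slot masses per-atom masses (amu) used for weighting (length 0 otherwise).
#' @export
setClass("HessianModel",
  representation(matrix = "matrix", origin = "character", refCoords = "matrix",
                 cutoff = "numeric", forceConstant = "numeric",
                 massWeighted = "logical", masses = "numeric"))

setValidity("HessianModel", function(object) {
  msg <- character()
  n <- nrow(object@refCoords)
  if (nrow(object@matrix) != ncol(object@matrix))
    msg <- c(msg, "Hessian must be square")
  if (nrow(object@matrix) != 3L * n)
    msg <- c(msg, "Hessian must be 3N x 3N for the N reference atoms")
  if (!object@origin %in% c("enm", "imported"))
    msg <- c(msg, "origin must be 'enm' or 'imported'")
  scale <- max(abs(object@matrix))
  if (scale > 0) {
    asym <- max(abs(object@matrix - t(object@matrix))) / scale
    if (asym > 1e-8)
      msg <- c(msg, sprintf("Hessian asymmetric (relative asymmetry %.2e)", asym))
  }
  if (object@massWeighted && length(object@masses) != n)
    msg <- c(msg, "mass-weighted Hessian must carry one mass per atom")
  if (length(msg)) msg else TRUE
})

#' Normal-mode set
#'
#' Eigenvalues (ascending), unit-norm eigenvectors and derived frequencies of
#' a (usually mass-weighted) Hessian. The first \code{nTrivial} modes are the
#' rigid-body translations/rotations and are disregarded in analyses.
#'
#' @slot values eigenvalues in ascending order.
#' @slot vectors 3N x k matrix with unit-norm eigenvectors in columns.
#' @slot frequencies per-mode frequencies \eqn{\nu_i = \sqrt{\lambda_i}/2\pi}
#'   in native units (0 for modes with \eqn{\lambda_i \le 0}).
#' @slot massWeighted whether the decomposed Hessian was mass-weighted.
#' @slot nTrivial number of leading modes treated as trivial (default 6).
#' @slot masses per-atom masses (amu; length 0 when not mass-weighted).
#' @slot refCoords N x 3 reference coordinates.
#' @export
setClass("ModeSet",
  representation(values = "numeric", vectors = "matrix",
                 frequencies = "numeric", massWeighted = "logical",
                 nTrivial = "integer", masses = "numeric",
                 refCoords = "matrix"))

setValidity("ModeSet", function(object) {
  msg <- character()
  k <- length(object@values)
  if (ncol(object@vectors) != k) msg <- c(msg, "one eigenvector per eigenvalue")
  if (nrow(object@vectors) != 3L * nrow(object@refCoords))
    msg <- c(msg, "eigenvectors must have 3N components")
  if (k > 1 && any(diff(object@values) < -1e-9 * max(abs(object@values), 1)))
    msg <- c(msg, "eigenvalues must be ascending")
  if (k) {
    nrm <- sqrt(colSums(object@vectors^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "eigenvectors must be unit norm")
  }
  if (length(object@frequencies) != k)
    msg <- c(msg, "one frequency per mode")
  if (length(msg)) msg else TRUE
})

#' Principal components of a trajectory covariance
#'
#' Eigen-decomposition of a Cartesian covariance matrix over an analysis atom
#' set: descending eigenvalues (variances, \enc{Å}{Angstrom}^2) and unit-norm
#' eigenvectors, plus the mean coordinates and the alignment reference needed
#' to project frames consistently.
#'
#' @slot values eigenvalues in decreasing order (\enc{Å}{Angstrom}^2).
#' @slot vectors 3n x 3n matrix of unit-norm eigenvectors (columns).
#' @slot meanCoords n x 3 mean coordinates of the analysis atoms.
#' @slot refCoords n x 3 alignment reference (0 x 3 if frames were not fitted).
#' @slot nFrames number of frames used.
#' @slot window analysed time range, ps (c(NA, NA) if the full trajectory).
#' @slot atomIndices indices of the analysis atoms in the parent structure.
#' @export
setClass("PCResult",
  representation(values = "numeric", vectors = "matrix",
                 meanCoords = "matrix", refCoords = "matrix",
                 nFrames = "integer", window = "numeric",
                 atomIndices = "integer"))

setValidity("PCResult", function(object) {
  msg <- character()
  k <- length(object@values)
  if (ncol(object@vectors) != k) msg <- c(msg, "one eigenvector per eigenvalue")
  if (k > 1 && any(diff(object@values) > 1e-9 * max(abs(object@values), 1)))
    msg <- c(msg, "eigenvalues must be descending")
  if (k && min(object@values) < -1e-8 * max(object@values, 0))
    msg <- c(msg, "covariance eigenvalues must be non-negative (to tolerance)")
  if (nrow(object@vectors) != 3L * nrow(object@meanCoords))
    msg <- c(msg, "eigenvectors must have 3n components")
  if (length(msg)) msg else TRUE
})

#' Per-frame scalar series
#'
#' A time-stamped scalar observable measured on every frame of a trajectory:
#' a distance, an angle, an RMSD or a principal-component projection.
#'
#' @slot times frame times, ps.
#' @slot values one scalar per frame.
#' @slot kind one of "distance", "angle", "rmsd", "projection".
#' @export
setClass("GeometrySeries",
  representation(times = "numeric", values = "numeric", kind = "character"))

setValidity("GeometrySeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (!object@kind %in% c("distance", "angle", "rmsd", "projection"))
    msg <- c(msg, "kind must be distance, angle, rmsd or projection")
  if (length(msg)) msg else TRUE
})

#' Rigid-body superposition result
#'
#' @slot rotation 3 x 3 proper rotation matrix (applied to row vectors).
#' @slot translation length-3 translation (\enc{Å}{Angstrom}).
#' @slot rmsd post-fit root-mean-square deviation (\enc{Å}{Angstrom}).
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric", rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  msg <- character()
  if (!all(dim(object@rotation) == c(3, 3))) msg <- c(msg, "rotation must be 3x3")
  else if (abs(det(object@rotation) - 1) > 1e-6)
    msg <- c(msg, "rotation must be proper (det = +1)")
  if (length(object@translation) != 3) msg <- c(msg, "translation must be length 3")
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-residue mobility profile
#'
#' Root-mean-square fluctuations of selected atoms about their mean positions
#' over a time window, with optional high-mobility regions.
#'
#' @slot rmsf per-atom RMSF (\enc{Å}{Angstrom}).
#' @slot atoms data.frame describing the profiled atoms (name, resid, chain).
#' @slot window time range used, ps.
#' @slot regions data.frame of detected mobile regions
#'   (chain, startRes, endRes, label), non-overlapping and sorted.
#' @export
setClass("MobilityProfile",
  representation(rmsf = "numeric", atoms = "data.frame",
                 window = "numeric", regions = "data.frame"))

setValidity("MobilityProfile", function(object) {
  msg <- character()
  if (length(object@rmsf) != nrow(object@atoms))
    msg <- c(msg, "one RMSF value per profiled atom")
  if (length(object@rmsf) && any(object@rmsf < 0))
    msg <- c(msg, "RMSF must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Mode-overlap comparison matrix
#'
#' All-pairs absolute inner products between two sets of unit eigenvectors,
#' 1 meaning identical motions and 0 orthogonal ones.
#'
#' @slot values numeric matrix in \[0, 1\] with mode labels as dimnames.
#' @export
setClass("ComparisonMatrix", representation(values = "matrix"))

setValidity("ComparisonMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    msg <- c(msg, "inner products must lie in [0, 1]")
  if (is.null(dimnames(v)) || is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "comparison matrix must carry mode labels as dimnames")
  if (length(msg)) msg else TRUE
})

#' Active-site geometry definition
#'
#' Atom indices (into a Structure) for one inter-domain active site: the
#' closure marker pair (e.g. Mg2 in the L domain and the His N\eqn{\epsilon}2
#' in the K domain), the candidate nucleophile oxygens, the gamma-phosphorus
#' and the leaving (scissile-bond) oxygen.
#'
#' @slot label site label, e.g. "L2-K1".
#' @slot closurePair length-2 integer: the two closure marker atoms.
#' @slot nucleophileOxygens named integer vector (e.g. c(O1 = ..., O3 = ...)).
#' @slot gammaPhosphorus index of the attacked phosphorus.
#' @slot leavingOxygen index of the scissile P-O bridging oxygen.
#' @export
setClass("SiteDefinition",
  representation(label = "character", closurePair = "integer",
                 nucleophileOxygens = "integer", gammaPhosphorus = "integer",
                 leavingOxygen = "integer"))

setValidity("SiteDefinition", function(object) {
  msg <- character()
  if (length(object@closurePair) != 2) msg <- c(msg, "closurePair must have 2 atoms")
  if (length(object@nucleophileOxygens) < 1)
    msg <- c(msg, "at least one nucleophile oxygen required")
  if (is.null(names(object@nucleophileOxygens)) ||
      any(!nzchar(names(object@nucleophileOxygens))))
    msg <- c(msg, "nucleophile oxygens must be named (e.g. O1, O3)")
  if (length(object@gammaPhosphorus) != 1 || length(object@leavingOxygen) != 1)
    msg <- c(msg, "gammaPhosphorus and leavingOxygen must be single atoms")
  all_idx <- c(object@closurePair, object@nucleophileOxygens,
               object@gammaPhosphorus, object@leavingOxygen)
  if (any(all_idx < 1)) msg <- c(msg, "atom indices must be >= 1")
  if (anyDuplicated(all_idx)) msg <- c(msg, "site atom indices must be distinct")
  if (length(msg)) msg else TRUE
})

#' Synthetic-system recipe
#'
#' Deterministic description of a toy elongated dimer (four domains,
#' L2-K1-K2-L1, 575 residues per subunit by default) and of the trajectories
#' generated from it: planted collective modes, isotropic jitter, and
#' near-attack episodes during which a nucleophile oxygen is driven towards
#' the phosphorus in line with the scissile bond.
#'
#' @slot nResPerSubunit residues per subunit (default 575).
#' @slot nSubunits number of identical subunits (2).
#' @slot kDomainSize residues in the K domain; the rest form the L domain.
#' @slot domainSpacing distance between neighbouring domain centres
#'   (\enc{Å}{Angstrom}).
#' @slot cloudRadius radius of each uniform-density spherical domain cloud
#'   (\enc{Å}{Angstrom}).
#' @slot closureDistance initial closure-marker separation (\enc{Å}{Angstrom},
#'   default 14).
#' @slot withBackbone if TRUE, build N/CA/C/O main-chain atoms per residue.
#' @slot withLigands if TRUE, add one phosphorus/oxygen triad per site.
#' @slot plantedVariances variances (\enc{Å}{Angstrom}^2) of the planted
#'   collective modes; length 0 means solve them from \code{targetCumVar}.
#' @slot modeRatios relative sizes of the planted variances.
#' @slot targetCumVar target cumulative variance fraction of the planted
#'   modes over the analysis atom set (default 0.68).
#' @slot noiseSigma isotropic per-coordinate jitter (\enc{Å}{Angstrom}).
#' @slot nFrames number of trajectory frames.
#' @slot frameDt frame interval, ps.
#' @slot timeOrigin time of the first frame, ps.
#' @slot nacEpisodes data.frame(start, end, minDistance, maxAngle, oxygen)
#'   of near-attack episodes (times in ps).
#' @slot seed RNG seed; a fixed seed gives bit-identical output.
#' @export
setClass("SyntheticSpec",
  representation(nResPerSubunit = "integer", nSubunits = "integer",
                 kDomainSize = "integer", domainSpacing = "numeric",
                 cloudRadius = "numeric", closureDistance = "numeric",
                 withBackbone = "logical", withLigands = "logical",
                 plantedVariances = "numeric", modeRatios = "numeric",
                 targetCumVar = "numeric", noiseSigma = "numeric",
                 nFrames = "integer", frameDt = "numeric",
                 timeOrigin = "numeric", nacEpisodes = "data.frame",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nResPerSubunit < 8) msg <- c(msg, "need at least 8 residues per subunit")
  if (object@nSubunits != 2L) msg <- c(msg, "only 2-subunit dimers are supported")
  if (object@kDomainSize < 4 || object@kDomainSize >= object@nResPerSubunit)
    msg <- c(msg, "kDomainSize must lie strictly inside the subunit")
  if (any(object@plantedVariances <= 0) && length(object@plantedVariances))
    msg <- c(msg, "planted variances must be > 0")
  if (object@targetCumVar <= 0 || object@targetCumVar >= 1)
    msg <- c(msg, "targetCumVar must lie in (0, 1)")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@nFrames < 1 || object@frameDt <= 0)
    msg <- c(msg, "nFrames >= 1 and frameDt > 0 required")
  ep <- object@nacEpisodes
  need <- c("start", "end", "minDistance", "maxAngle", "oxygen")
  if (nrow(ep)) {
    if (!all(need %in% names(ep)))
      msg <- c(msg, paste("nacEpisodes needs columns:", paste(need, collapse = ", ")))
    else {
      if (any(ep$end <= ep$start)) msg <- c(msg, "episode end must exceed start")
      if (nrow(ep) > 1) {
        o <- order(ep$start)
        if (any(ep$start[o][-1] < ep$end[o][-nrow(ep)]))
          msg <- c(msg, "near-attack episodes must not overlap")
      }
      if (any(ep$maxAngle <= 0 | ep$maxAngle > 180))
        msg <- c(msg, "episode maxAngle must lie in (0, 180]")
      if (any(ep$minDistance <= 0)) msg <- c(msg, "episode minDistance must be > 0")
    }
  }
  if (length(msg)) msg else TRUE
})
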