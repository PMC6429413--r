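# Normal-mode stage: anisotropic elastic-network Hessians (or imported
# second-derivative matrices), mass-weighted eigenanalysis, frequencies,
# trivial-mode handling with a rigid-body diagnostic, and the two mode-based
# trajectory generators (harmonic oscillation and thermal ensemble).
#
# Units: coordinates Å, masses amu, force constants (energy) Å^-2 with
# energy in kJ/mol. With these units the Boltzmann constant is
# kB = 0.0083144621 kJ mol^-1 K^-1 and mass-weighted eigenvalues are in
# kJ mol^-1 Å^-2 amu^-1.

.KB_KJ_MOL <- 0.0083144621  # kJ mol^-1 K^-1 (CODATA)

#' Build an anisotropic elastic-network Hessian
#'
#' Standard anisotropic network model: every atom pair within `cutoff`
#' contributes a 3x3 superelement \eqn{-k\,\hat r \hat r^T} on the
#' off-diagonal, and diagonal blocks are the negative sums of the
#' off-diagonal blocks of their row, which makes the matrix exactly
#' translation invariant (zero row sums).
#'
#' @param structure a [Structure-class].
#' @param atomSet atoms forming the network (default: all atoms). The
#'   selected atoms define the model's reference coordinates and index space.
#' @param cutoff interaction cutoff in \enc{Å}{Angstrom} (default 13, a
#'   common choice for C-alpha networks).
#' @param k uniform spring force constant (default 1, energy
#'   \enc{Å}{Angstrom}^-2).
#' @return a [HessianModel-class] (not mass-weighted).
#' @details Atoms with no neighbour within the cutoff produce spurious zero
#'   modes; they trigger a warning listing the offending atoms.
#' @export
buildEnmHessian <- function(structure, atomSet = NULL, cutoff = 13, k = 1) {
  stopifnot(is(structure, "Structure"), cutoff > 0, k > 0)
  idx <- if (is.null(atomSet)) seq_len(nAtoms(structure))
         else .asIndexSet(atomSet, structure)
  xyz <- structure@coords[idx, , drop = FALSE]
  n <- nrow(xyz)
  if (n < 2) stop("elastic network needs at least 2 atoms")
  d <- as.matrix(stats::dist(xyz))
  contact <- d <= cutoff & upper.tri(d)
  pairs <- which(contact, arr.ind = TRUE)
  neighbours <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
  if (any(neighbours == 0))
    warning("atom(s) with no neighbour within the cutoff (spurious zero modes): ",
            paste(utils::head(which(neighbours == 0), 20), collapse = ", "))
  H <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    rij <- xyz[j, ] - xyz[i, ]
    rhat <- rij / sqrt(sum(rij^2))
    blk <- -k * tcrossprod(rhat)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  new("HessianModel", matrix = H, origin = "enm", refCoords = xyz,
      cutoff = cutoff, forceConstant = k, massWeighted = FALSE,
      masses = structure@masses[idx])
}

#' Mass-weight a Hessian
#'
#' Element-wise \eqn{H'_{ia,jb} = H_{ia,jb} / \sqrt{m_i m_j}}, the similarity
#' transform whose eigenvalues give vibrational frequencies.
#'
#' @param h a [HessianModel-class], not yet mass-weighted.
#' @param masses per-atom masses in amu (default: the masses stored with the
#'   model).
#' @return the mass-weighted [HessianModel-class].
#' @export
massWeight <- function(h, masses = NULL) {
  stopifnot(is(h, "HessianModel"))
  if (h@massWeighted) stop("Hessian is already mass-weighted")
  n <- nrow(h@refCoords)
  if (is.null(masses)) masses <- h@masses
  if (length(masses) != n) stop("need one mass per atom (", n, ")")
  if (any(masses <= 0)) stop("masses must be > 0")
  invsq <- 1 / sqrt(rep(masses, each = 3))
  Hw <- h@matrix * tcrossprod(invsq)
  methods::initialize(h, matrix = Hw, massWeighted = TRUE,
                      masses = as.numeric(masses))
}

#' Eigen-decompose a Hessian into a mode set
#'
#' Full symmetric eigen-decomposition with eigenvalues in ascending order and
#' unit-norm eigenvectors, signs fixed so the largest-magnitude component of
#' each mode is positive. Degenerate eigenvalues return an arbitrary
#' orthonormal basis of their eigenspace.
#'
#' @param h a [HessianModel-class] (mass-weighted for physical frequencies).
#' @return a [ModeSet-class] with `nTrivial = 6`.
#' @export
eigenModes <- function(h) {
  stopifnot(is(h, "HessianModel"))
  e <- eigen(h@matrix, symmetric = TRUE)
  ord <- rev(seq_along(e$values))      # eigen() returns descending
  values <- e$values[ord]
  vectors <- .normalizeSigns(e$vectors[, ord, drop = FALSE])
  freq <- if (h@massWeighted) sqrt(pmax(values, 0)) / (2 * pi)
          else rep(NA_real_, length(values))
  new("ModeSet", values = values, vectors = vectors, frequencies = freq,
      massWeighted = h@massWeighted, nTrivial = 6L,
      masses = h@masses, refCoords = h@refCoords)
}

#' Normal-mode frequencies
#'
#' \eqn{\nu_i = \sqrt{\lambda_i}/(2\pi)} from the mass-weighted eigenvalues.
#' In native units \eqn{\lambda} is in kJ mol\eqn{^{-1}}
#' \enc{Å}{Angstrom}\eqn{^{-2}} amu\eqn{^{-1}}; the wavenumber conversion
#' uses \eqn{\tilde\nu = \sqrt{\lambda} \cdot 10^{13} / (2\pi c)} with
#' \eqn{c = 2.99792458\times10^{10}} cm/s, because 1 kJ mol\eqn{^{-1}}
#' amu\eqn{^{-1}} = \eqn{10^6} m\eqn{^2} s\eqn{^{-2}} and 1
#' \enc{Å}{Angstrom} = \eqn{10^{-10}} m, giving
#' \eqn{\omega\,[\mathrm{s}^{-1}] = \sqrt{\lambda}\cdot 10^{13}}.
#'
#' @param ms a mass-weighted [ModeSet-class].
#' @param unit "native" or "cm-1".
#' @return numeric vector of per-mode frequencies.
#' @details Small negative eigenvalues (down to \eqn{-10^{-6}\lambda_{max}},
#'   numerical noise in the rigid-body nullspace) are clamped to zero; larger
#'   negative values indicate an unconverged minimisation and are an error.
#' @export
modeFrequencies <- function(ms, unit = c("native", "cm-1")) {
  unit <- match.arg(unit)
  stopifnot(is(ms, "ModeSet"))
  if (!ms@massWeighted)
    stop("frequencies require a mass-weighted mode set")
  lam <- ms@values
  lmax <- max(lam, 0)
  if (any(lam < -1e-6 * max(lmax, .Machine$double.eps)))
    stop("large negative eigenvalue(s): Hessian is not at a minimum")
  lam <- pmax(lam, 0)
  nu <- sqrt(lam) / (2 * pi)
  if (unit == "native") return(nu)
  sqrt(lam) * 1e13 / (2 * pi * 2.99792458e10)
}

.subsetModes <- function(ms, cols, nTrivial = 0L) {
  new("ModeSet", values = ms@values[cols],
      vectors = ms@vectors[, cols, drop = FALSE],
      frequencies = ms@frequencies[cols], massWeighted = ms@massWeighted,
      nTrivial = as.integer(nTrivial), masses = ms@masses,
      refCoords = ms@refCoords)
}

#' Split trivial (rigid-body) modes from a mode set
#'
#' Removes the `nTrivial` lowest-frequency modes (the six zero-frequency
#' rigid-body translations and rotations of a connected structure) and, as a
#' diagnostic, reports the overlap of each removed mode with the exact
#' rigid-body basis constructed from the reference coordinates, rather than
#' trusting the count silently.
#'
#' @param ms a [ModeSet-class] holding the full spectrum.
#' @param nTrivial number of leading modes to remove (default 6).
#' @return list with elements `trivial` (a ModeSet), `nontrivial` (a ModeSet
#'   whose `nTrivial` is 0) and `rigidOverlap` (per removed mode, the norm of
#'   its projection onto the 6-dimensional rigid-body space; near 1 for true
#'   rigid-body modes).
#' @export
splitTrivial <- function(ms, nTrivial = 6L) {
  stopifnot(is(ms, "ModeSet"), nTrivial >= 0,
            nTrivial <= length(ms@values))
  nTrivial <- as.integer(nTrivial)
  triv_cols <- seq_len(nTrivial)
  basis <- .rigidBodyBasis(ms@refCoords,
                           if (ms@massWeighted) ms@masses else NULL)
  overlap <- vapply(triv_cols, function(j)
    sqrt(sum(crossprod(basis, ms@vectors[, j])^2)), numeric(1))
  list(trivial = .subsetModes(ms, triv_cols, nTrivial = nTrivial),
       nontrivial = .subsetModes(ms, setdiff(seq_along(ms@values), triv_cols)),
       rigidOverlap = overlap)
}

# Convert a (possibly mass-weighted) mode column to a unit-norm Cartesian
# displacement field.
.cartesianMode <- function(ms, mode) {
  v <- ms@vectors[, mode]
  if (ms@massWeighted) v <- v / sqrt(rep(ms@masses, each = 3))
  v / sqrt(sum(v^2))
}

#' Harmonic trajectory along one mode
#'
#' Generates one full oscillation period
#' \eqn{x(t) = x_{ref} + A \sin(2\pi t/T)\, d} along the unit Cartesian
#' displacement of a mode, for visualising the motion (porcupine-style
#' animations).
#'
#' @param structure the [Structure-class] providing reference coordinates
#'   and atom metadata.
#' @param ms a [ModeSet-class].
#' @param mode column index of the mode within `ms`.
#' @param amplitude peak displacement amplitude, \enc{Å}{Angstrom} (0 gives a
#'   static trajectory).
#' @param nFrames frames per period (default 20).
#' @param period oscillation period in ps (default `nFrames`, i.e. 1 ps per
#'   frame).
#' @return a [Trajectory-class] covering one period; with `nFrames` divisible
#'   by 4 the quarter-period frame is displaced by exactly
#'   `amplitude * d`.
#' @export
harmonicTrajectory <- function(structure, ms, mode, amplitude, nFrames = 20L,
                               period = NULL) {
  stopifnot(is(structure, "Structure"), is(ms, "ModeSet"),
            amplitude >= 0, nFrames >= 1)
  if (3L * nAtoms(structure) != nrow(ms@vectors))
    stop("mode dimension does not match the structure")
  d <- .cartesianMode(ms, mode)
  if (is.null(period)) period <- nFrames
  ref <- .flatten(structure@coords)
  phase <- 2 * pi * (seq_len(nFrames) - 1) / nFrames
  xyz <- outer(amplitude * sin(phase), d) +
    matrix(ref, nFrames, length(ref), byrow = TRUE)
  Trajectory(structure, xyz, times = (seq_len(nFrames) - 1) * period / nFrames)
}

#' Thermal ensemble from normal modes
#'
#' Draws `nConf` conformations \eqn{x_{ref} + \sum_i c_i M^{-1/2} d_i} with
#' independent Gaussian coefficients \eqn{c_i \sim N(0, \sqrt{k_B T /
#' \lambda_i})} in mass-weighted coordinates: classical equipartition, under
#' which the mass-weighted variance along each mode is \eqn{k_B T /
#' \lambda_i}.
#'
#' @param structure the [Structure-class] providing reference coordinates.
#' @param ms a mass-weighted [ModeSet-class].
#' @param modes column indices of the modes to excite (default: all
#'   non-trivial modes of `ms`). Including a trivial mode is an error.
#' @param temperature temperature in K (default 300).
#' @param nConf number of conformations (default 5000).
#' @param seed optional RNG seed for reproducibility.
#' @return a [Trajectory-class] of `nConf` frames (1 ps nominal spacing).
#' @export
thermalEnsemble <- function(structure, ms, modes = NULL, temperature = 300,
                            nConf = 5000L, seed = NULL) {
  stopifnot(is(structure, "Structure"), is(ms, "ModeSet"),
            temperature >= 0, nConf >= 1)
  if (!ms@massWeighted)
    stop("thermal ensembles require a mass-weighted mode set")
  if (3L * nAtoms(structure) != nrow(ms@vectors))
    stop("mode dimension does not match the structure")
  if (is.null(modes))
    modes <- seq.int(ms@nTrivial + 1L, length(ms@values))
  if (any(modes <= ms@nTrivial))
    stop("trivial (rigid-body) modes cannot be thermally excited")
  lam <- ms@values[modes]
  if (any(lam <= 0))
    stop("all excited modes must have positive eigenvalues")
  invsq <- 1 / sqrt(rep(ms@masses, each = 3))
  Dcart <- ms@vectors[, modes, drop = FALSE] * invsq
  sds <- sqrt(.KB_KJ_MOL * temperature / lam)
  xyz <- .withSeed(seed, function() {
    coefs <- sweep(matrix(stats::rnorm(nConf * length(modes)), nConf),
                   2, sds, "*")
    matrix(.flatten(structure@coords), nConf, 3 * nAtoms(structure),
           byrow = TRUE) + tcrossprod(coefs, Dcart)
  })
  Trajectory(structure, xyz, times = seq_len(nConf) - 1)
}

#' Import an externally computed Hessian
#'
#' Reads a dense 3N x 3N whitespace-separated matrix (e.g. a Hessian exported
#' from a force-field minimisation) so it can be run through the same
#' eigen-pipeline as the elastic-network model.
#'
#' @param path text file holding the matrix, row by row.
#' @param structure the matching [Structure-class] (defines N).
#' @return a [HessianModel-class] with origin "imported", symmetrized as
#'   (H + t(H))/2.
#' @details A relative asymmetry above 1e-6 is rejected as an error rather
#'   than silently averaged away.
#' @export
importHessian <- function(path, structure) {
  stopifnot(is(structure, "Structure"))
  vals <- scan(path, quiet = TRUE)
  n3 <- 3L * nAtoms(structure)
  if (length(vals) != n3 * n3)
    stop(sprintf("matrix size mismatch: file has %d values, structure implies %d x %d",
                 length(vals), n3, n3))
  H <- matrix(vals, n3, n3, byrow = TRUE)
  scale <- max(abs(H))
  if (scale > 0) {
    asym <- max(abs(H - t(H))) / scale
    if (asym > 1e-6)
      stop(sprintf("matrix is asymmetric beyond tolerance (relative asymmetry %.2e)", asym))
  }
  H <- (H + t(H)) / 2
  new("HessianModel", matrix = H, origin = "imported",
      refCoords = structure@coords, cutoff = NA_real_,
      forceConstant = NA_real_, massWeighted = FALSE,
      masses = structure@masses)
}

#' Export a Hessian as a dense text matrix
#'
#' @param h a [HessianModel-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
exportHessian <- function(h, path) {
  stopifnot(is(h, "HessianModel"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(h@matrix)))
    writeLines(paste(sprintf("%.17g", h@matrix[i, ]), collapse = " "), con)
  invisible(path)
}
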