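# Cross-system mode comparison: regenerate a thermal ensemble per mode,
# reduce it to an atom set shared by all systems, recover the mode as the
# first principal component of the reduced ensemble, and compare recovered
# modes across systems by absolute eigenvector inner products.

#' Recover a mode through the ensemble-reduction-PCA protocol
#'
#' Generates a single-mode thermal ensemble, reduces every conformation to
#' the atoms matched by `commonSelector` (so systems with different ligand
#' content yield vectors of equal length), and recovers the mode as the first
#' principal component of the reduced ensemble. For a single-mode ensemble
#' only the first eigenvalue is significant; \eqn{\lambda_2/\lambda_1} is
#' reported as a purity diagnostic and a ratio above 0.05 (mode leakage
#' through the reduction) triggers a warning.
#'
#' @param structure the system's [Structure-class].
#' @param ms its mass-weighted [ModeSet-class] (full spectrum).
#' @param mode mode index within `ms` (must be non-trivial).
#' @param commonSelector selection shared across systems (default
#'   `"name CA C O N"`, the protein main chain).
#' @param temperature ensemble temperature in K (default 300).
#' @param nConf conformations per ensemble (default 5000).
#' @param seed optional RNG seed.
#' @return list with `vector` (unit-norm recovered mode on the common atom
#'   set), `values` (leading two ensemble eigenvalues), `purity`
#'   (\eqn{\lambda_2/\lambda_1}), `indices` (common atoms) and `nConf`.
#' @export
modeViaEnsemble <- function(structure, ms, mode,
                            commonSelector = "name CA C O N",
                            temperature = 300, nConf = 5000L, seed = NULL) {
  stopifnot(is(ms, "ModeSet"))
  if (mode <= ms@nTrivial)
    stop("mode ", mode, " is trivial; the protocol applies to non-trivial modes")
  ens <- thermalEnsemble(structure, ms, modes = mode,
                         temperature = temperature, nConf = nConf, seed = seed)
  idx <- selectAtoms(structure, commonSelector)
  X <- ens@coords[, .xyzIndices(idx), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  top <- .topComponents(Xc, k = 2)
  purity <- if (top$values[1] > 0) top$values[2] / top$values[1] else NA_real_
  if (is.finite(purity) && purity > 0.05)
    warning(sprintf("mode leakage through reduction: lambda2/lambda1 = %.3g",
                    purity))
  v <- top$vectors[, 1]
  list(vector = v / sqrt(sum(v^2)), values = top$values[1:2],
       purity = purity, indices = as.integer(idx), nConf = nrow(X))
}

#' Inner product of two mode vectors
#'
#' Absolute value of the dot product of two (defensively renormalised) unit
#' eigenvectors: 1 for identical motions, 0 for orthogonal ones. The absolute
#' value is taken because eigenvector signs are arbitrary.
#'
#' @param a,b numeric vectors of equal length.
#' @return scalar in \[0, 1\].
#' @export
innerProduct <- function(a, b) {
  if (length(a) != length(b))
    stop("eigenvector dimensions differ (", length(a), " vs ", length(b), ")")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-length eigenvector")
  min(abs(sum(a * b)) / (na * nb), 1)
}

#' All-pairs mode-overlap matrix
#'
#' @param modesA,modesB lists of mode vectors (all on the same common atom
#'   set), or matrices with modes in columns.
#' @param labelsA,labelsB row/column labels (default "A1", ..., "B1", ...).
#' @return a [ComparisonMatrix-class] of absolute inner products.
#' @export
compareModes <- function(modesA, modesB, labelsA = NULL, labelsB = NULL) {
  asList <- function(m) if (is.matrix(m)) lapply(seq_len(ncol(m)), function(j) m[, j]) else m
  modesA <- asList(modesA); modesB <- asList(modesB)
  if (is.null(labelsA)) labelsA <- paste0("A", seq_along(modesA))
  if (is.null(labelsB)) labelsB <- paste0("B", seq_along(modesB))
  vals <- matrix(0, length(modesA), length(modesB),
                 dimnames = list(labelsA, labelsB))
  for (i in seq_along(modesA))
    for (j in seq_along(modesB))
      vals[i, j] <- innerProduct(modesA[[i]], modesB[[j]])
  new("ComparisonMatrix", values = vals)
}

#' @export
#' @method as.matrix ComparisonMatrix
as.matrix.ComparisonMatrix <- function(x, ...) x@values
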