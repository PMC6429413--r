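# Accessor generics and show() methods.

#' Number of atoms
#' @param x a Structure or Trajectory
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@structure@atoms))

#' Atom metadata table
#' @param x a Structure or Trajectory
#' @return data.frame with one row per atom
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname atomData
#' @export
setMethod("atomData", "Structure", function(x) x@atoms)

#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@structure@atoms)

#' Coordinates
#' @param x a Structure
#' @return N x 3 matrix (\enc{Å}{Angstrom})
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Structure", function(x) x@coords)

#' Atomic masses (amu)
#' @param x a Structure
#' @return numeric vector, one mass per atom
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' @rdname masses
#' @export
setMethod("masses", "Structure", function(x) x@masses)

#' Number of frames of a trajectory
#' @param x a Trajectory
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) nrow(x@coords))

#' Frame times (ps)
#' @param x a Trajectory or GeometrySeries
#' @return numeric vector of times
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "GeometrySeries", function(x) x@times)

#' Coordinates of one frame
#' @param x a Trajectory
#' @param i frame index (1-based)
#' @return N x 3 coordinate matrix
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nrow(x@coords))
  matrix(x@coords[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
})

#' Eigenvalues
#' @param x a ModeSet, PCResult or HessianModel-derived object
#' @return numeric vector of eigenvalues (ascending for modes, descending
#'   for principal components)
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "ModeSet", function(x) x@values)

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "PCResult", function(x) x@values)

#' Eigenvectors (columns)
#' @param x a ModeSet or PCResult
#' @return matrix with unit-norm eigenvectors in columns
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname eigenvectors
#' @export
setMethod("eigenvectors", "ModeSet", function(x) x@vectors)

#' @rdname eigenvectors
#' @export
setMethod("eigenvectors", "PCResult", function(x) x@vectors)

#' Series values
#' @param x a GeometrySeries
#' @return numeric vector of per-frame values
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "GeometrySeries", function(x) x@values)

#' @export
#' @method as.data.frame GeometrySeries
as.data.frame.GeometrySeries <- function(x, ...) {
  data.frame(time = x@times, value = x@values)
}

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure: %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(sort(unique(a$chain)), collapse = " ")))
})

setMethod("show", "Trajectory", function(object) {
  tt <- object@times
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              nrow(object@coords), nrow(object@structure@atoms),
              if (length(tt)) min(tt) else NA, if (length(tt)) max(tt) else NA))
})

setMethod("show", "HessianModel", function(object) {
  cat(sprintf("HessianModel (%s): %d x %d%s", object@origin,
              nrow(object@matrix), ncol(object@matrix),
              if (object@massWeighted) ", mass-weighted\n" else "\n"))
  if (object@origin == "enm")
    cat(sprintf("  cutoff %g A, force constant %g\n",
                object@cutoff, object@forceConstant))
})

setMethod("show", "ModeSet", function(object) {
  k <- length(object@values)
  cat(sprintf("ModeSet: %d modes (%d trivial)%s\n", k, object@nTrivial,
              if (object@massWeighted) ", mass-weighted" else ""))
  if (k)
    cat("  lowest eigenvalues:",
        paste(signif(utils::head(object@values, 8), 3), collapse = " "), "\n")
})

setMethod("show", "PCResult", function(object) {
  tot <- sum(object@values)
  k <- min(3L, length(object@values))
  cat(sprintf("PCResult: %d components from %d frames\n",
              length(object@values), object@nFrames))
  if (tot > 0)
    cat(sprintf("  first %d components explain %.1f%% of the variance\n",
                k, 100 * sum(object@values[seq_len(k)]) / tot))
})

setMethod("show", "GeometrySeries", function(object) {
  cat(sprintf("GeometrySeries (%s): %d frames", object@kind,
              length(object@times)))
  if (length(object@values))
    cat(sprintf(", range %.3f..%.3f", min(object@values), max(object@values)))
  cat("\n")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A\n", object@rmsd))
})

setMethod("show", "MobilityProfile", function(object) {
  cat(sprintf("MobilityProfile: %d atoms, window %g..%g ps, %d mobile regions\n",
              length(object@rmsf), object@window[1], object@window[2],
              nrow(object@regions)))
})

setMethod("show", "ComparisonMatrix", function(object) {
  cat("ComparisonMatrix of mode overlaps:\n")
  print(round(object@values, 3))
})

setMethod("show", "SiteDefinition", function(object) {
  cat(sprintf("SiteDefinition '%s': closure pair (%d, %d), O: %s -> P %d (leaving O %d)\n",
              object@label, object@closurePair[1], object@closurePair[2],
              paste(sprintf("%s=%d", names(object@nucleophileOxygens),
                            object@nucleophileOxygens), collapse = ", "),
              object@gammaPhosphorus, object@leavingOxygen))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d x %d residues (K domain %d), %s%s\n",
              object@nSubunits, object@nResPerSubunit, object@kDomainSize,
              if (object@withBackbone) "backbone" else "C-alpha",
              if (object@withLigands) " + ligand markers" else ""))
  cat(sprintf("  trajectory: %d frames at %g ps, noise sigma %g A, seed %d\n",
              object@nFrames, object@frameDt, object@noiseSigma, object@seed))
})
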