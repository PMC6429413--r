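# Rigid-body superposition and mobility statistics: Kabsch fitting, per-frame
# RMSD traces, RMSF profiles about the (iterated) mean structure, and
# detection of contiguous high-mobility regions.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`, computed from the SVD of the weighted cross-covariance
#' with the determinant correction that excludes reflections.
#'
#' @param mobile N x 3 coordinates to fit.
#' @param reference N x 3 target coordinates.
#' @param weights optional per-atom weights (e.g. masses); geometric fit by
#'   default.
#' @return a [SuperpositionResult-class]. The fitted coordinates are
#'   `mobile \%*\% rotation + translation` (rows as points); see
#'   [applySuperposition()].
#' @details Degenerate point sets (fewer than 3 points, or collinear points)
#'   are an error: the rotation is not determined by them.
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 atoms")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  wn <- w / sum(w)
  cmM <- colSums(mobile * wn)
  cmR <- colSums(reference * wn)
  A <- sweep(mobile, 2, cmM)
  B <- sweep(reference, 2, cmR)
  # collinearity check on the mobile set
  sv <- svd(A * sqrt(wn), nu = 0, nv = 0)$d
  if (sv[2] <= 1e-8 * max(sv[1], 1e-12))
    stop("degenerate (collinear) point set: rotation is undetermined")
  C <- crossprod(A * wn, B)
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- A %*% R
  rmsd <- sqrt(sum(wn * rowSums((fitted - B)^2)))
  new("SuperpositionResult", rotation = R,
      translation = as.numeric(cmR - cmM %*% R), rmsd = rmsd)
}

#' Apply a superposition to coordinates
#'
#' @param coords N x 3 coordinates.
#' @param fit a [SuperpositionResult-class] from [kabsch()].
#' @return transformed N x 3 coordinates.
#' @export
applySuperposition <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit@rotation, 2, -fit@translation)
}

# Align every frame of a flat frame matrix (F x 3N) to refCoords using the
# fitIdx atoms; return the aligned coordinates of the outIdx atoms (F x 3n).
.alignedFrameBlock <- function(xyz, fitIdx, outIdx, refCoords) {
  fitCols <- .xyzIndices(fitIdx)
  outCols <- .xyzIndices(outIdx)
  out <- matrix(0, nrow(xyz), length(outCols))
  for (f in seq_len(nrow(xyz))) {
    fr <- .unflatten(xyz[f, fitCols])
    ft <- kabsch(fr, refCoords)
    out[f, ] <- .flatten(applySuperposition(.unflatten(xyz[f, outCols]), ft))
  }
  out
}

#' Per-frame RMSD series
#'
#' Each frame is rigidly fitted to the reference on `fitSet`, and the RMSD is
#' then measured over `measureSet`. Restricting `measureSet` to one domain
#' while fitting on another gives per-domain deviation traces.
#'
#' @param traj a [Trajectory-class].
#' @param fitSet atoms used for the superposition ([AtomIndexSet-class] or
#'   integer indices).
#' @param measureSet atoms over which the deviation is computed (default:
#'   `fitSet`).
#' @param reference frame index used as reference (default 1), or an N x 3
#'   coordinate matrix for the full structure.
#' @param window optional time window (ps), half-open.
#' @return a [GeometrySeries-class] of kind "rmsd".
#' @export
rmsdSeries <- function(traj, fitSet, measureSet = fitSet, reference = 1L,
                       window = NULL) {
  fitIdx <- .asIndexSet(fitSet, traj@structure)
  measIdx <- .asIndexSet(measureSet, traj@structure)
  keep <- .framesInWindow(traj@times, window)
  if (!length(keep)) stop("empty time window")
  refAll <- if (is.matrix(reference)) reference else frameCoords(traj, reference)
  refFit <- refAll[fitIdx, , drop = FALSE]
  refMeas <- refAll[measIdx, , drop = FALSE]
  vals <- numeric(length(keep))
  for (k in seq_along(keep)) {
    fr <- traj@coords[keep[k], ]
    ft <- kabsch(.unflatten(fr[.xyzIndices(fitIdx)]), refFit)
    moved <- applySuperposition(.unflatten(fr[.xyzIndices(measIdx)]), ft)
    vals[k] <- sqrt(mean(rowSums((moved - refMeas)^2)))
  }
  new("GeometrySeries", times = traj@times[keep], values = vals, kind = "rmsd")
}

#' RMSF mobility profile
#'
#' Root-mean-square fluctuation of each selected atom about its mean position
#' over a time window, after removing overall translation/rotation. With
#' `fit = "mean"` the frames are fitted to the evolving mean structure
#' (initialised on the first frame and iterated); with `fit = "first"` a
#' single fit to the first window frame is used, which makes the profile
#' share its alignment with [covarianceMatrix()].
#'
#' @param traj a [Trajectory-class].
#' @param atomSet atoms to profile.
#' @param window optional time window in ps, half-open `[start, end)` unless
#'   `closed`.
#' @param fit "mean" (iterated mean-structure fit, default), "first", or
#'   "none" for pre-aligned input.
#' @param iterations mean-fit iterations (default 2).
#' @param closed use a closed time window.
#' @return a [MobilityProfile-class].
#' @export
rmsfProfile <- function(traj, atomSet, window = NULL,
                        fit = c("mean", "first", "none"),
                        iterations = 2, closed = FALSE) {
  fit <- match.arg(fit)
  idx <- .asIndexSet(atomSet, traj@structure)
  keep <- .framesInWindow(traj@times, window, closed = closed)
  if (length(keep) < 2) stop("RMSF window must contain at least 2 frames")
  xyz <- traj@coords[keep, , drop = FALSE]
  if (fit == "none") {
    aligned <- xyz[, .xyzIndices(idx), drop = FALSE]
  } else {
    ref <- .unflatten(xyz[1, .xyzIndices(idx)])
    aligned <- .alignedFrameBlock(xyz, idx, idx, ref)
  }
  if (fit == "mean") {
    for (it in seq_len(iterations)) {
      ref <- .unflatten(colMeans(aligned))
      aligned <- .alignedFrameBlock(xyz, idx, idx, ref)
    }
  }
  mean_flat <- colMeans(aligned)
  dev2 <- sweep(aligned, 2, mean_flat)^2
  per_atom <- matrix(colMeans(dev2), ncol = 3, byrow = TRUE)
  rmsf <- sqrt(rowSums(per_atom))
  win <- if (is.null(window)) range(traj@times[keep]) else window
  new("MobilityProfile", rmsf = rmsf,
      atoms = traj@structure@atoms[idx, c("name", "resid", "chain")],
      window = as.numeric(win),
      regions = data.frame(chain = character(), startRes = integer(),
                           endRes = integer(), label = character()))
}

#' Detect contiguous high-mobility regions
#'
#' Flags contiguous residue runs whose RMSF exceeds a threshold (default:
#' profile mean + 1 SD) and merges runs separated by fewer than `gapMerge`
#' residues. The numeric rule is a configurable convention: reported region
#' counts depend on it.
#'
#' @param profile a [MobilityProfile-class] (one atom per residue, e.g.
#'   C-alpha).
#' @param threshold RMSF cutoff (\enc{Å}{Angstrom}); default mean + 1 SD.
#' @param gapMerge runs separated by fewer than this many residues are
#'   merged (default 2).
#' @return the profile with its `regions` slot filled: a sorted,
#'   non-overlapping data.frame (chain, startRes, endRes, label), labelled
#'   with Roman numerals per chain.
#' @export
detectMobileRegions <- function(profile, threshold = NULL, gapMerge = 2) {
  stopifnot(is(profile, "MobilityProfile"))
  if (is.null(threshold))
    threshold <- mean(profile@rmsf) + stats::sd(profile@rmsf)
  regions <- list()
  for (ch in sort(unique(profile@atoms$chain))) {
    sel <- profile@atoms$chain == ch
    res <- profile@atoms$resid[sel]
    o <- order(res)
    res <- res[o]
    hot <- profile@rmsf[sel][o] > threshold
    hot_res <- res[hot]
    if (!length(hot_res)) next
    runs <- split(hot_res, cumsum(c(1, diff(hot_res) > 1)))
    bounds <- t(vapply(runs, range, numeric(2)))
    # merge runs separated by < gapMerge residues
    merged <- bounds[1, , drop = FALSE]
    if (nrow(bounds) > 1) {
      for (r in 2:nrow(bounds)) {
        gap <- bounds[r, 1] - merged[nrow(merged), 2] - 1
        if (gap < gapMerge) merged[nrow(merged), 2] <- bounds[r, 2]
        else merged <- rbind(merged, bounds[r, ])
      }
    }
    regions[[ch]] <- data.frame(chain = ch, startRes = as.integer(merged[, 1]),
                                endRes = as.integer(merged[, 2]),
                                label = as.character(utils::as.roman(seq_len(nrow(merged)))))
  }
  reg <- if (length(regions)) do.call(rbind, regions)
         else data.frame(chain = character(), startRes = integer(),
                         endRes = integer(), label = character())
  rownames(reg) <- NULL
  methods::initialize(profile, regions = reg)
}
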