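# Active-site geometry stage: closure-marker distance series, O...P approach
# distances, in-line O...P-O attack angles, and the near-attack-conformation
# (NAC) census that couples a distance cutoff with an angle cutoff.

#' Define an active site
#'
#' @param structure the [Structure-class] the indices refer to (for
#'   validation only).
#' @param label site label, e.g. "L2-K1".
#' @param closurePair length-2 atom indices of the closure marker pair (e.g.
#'   the L-domain Mg and the K-domain His N-epsilon-2).
#' @param nucleophileOxygens named atom indices of the candidate attacking
#'   oxygens, e.g. `c(O1 = ..., O3 = ...)`.
#' @param gammaPhosphorus atom index of the attacked phosphorus.
#' @param leavingOxygen atom index of the scissile P-O bridging oxygen.
#' @return a [SiteDefinition-class].
#' @export
siteDefinition <- function(structure, label, closurePair, nucleophileOxygens,
                           gammaPhosphorus, leavingOxygen) {
  idx <- c(closurePair, nucleophileOxygens, gammaPhosphorus, leavingOxygen)
  if (any(idx < 1) || any(idx > nAtoms(structure)))
    stop("site '", label, "': atom index outside the structure")
  new("SiteDefinition", label = label,
      closurePair = as.integer(closurePair),
      nucleophileOxygens = stats::setNames(as.integer(nucleophileOxygens),
                                           names(nucleophileOxygens)),
      gammaPhosphorus = as.integer(gammaPhosphorus),
      leavingOxygen = as.integer(leavingOxygen))
}

# Resolve one atom by selection, insisting on a unique match.
.oneAtom <- function(structure, selector, what) {
  idx <- tryCatch(selectAtoms(structure, selector),
                  error = function(e) stop("site atom not found (", what,
                                           "): ", conditionMessage(e)))
  if (length(idx) != 1)
    stop("site atom ambiguous (", what, "): '", selector, "' matched ",
         length(idx), " atoms")
  as.integer(idx)[1]
}

#' Built-in site preset for triokinase/FMN-cyclase-like structures
#'
#' Encodes the conventional marker atoms of the kinase active site: the
#' L-domain Mg ion (residue name MG), the N-epsilon-2 atom of the catalytic
#' histidine (residue 221 by default), the ATP gamma-phosphorus `PG`, the
#' scissile bridging oxygen `O3B`, and the two equivalent triose hydroxyl
#' oxygens `O1`/`O3`. Works on any structure using these conventions,
#' including the synthetic dimer of [makeToyDimer()].
#'
#' @param structure a [Structure-class].
#' @param kChain chain holding the K domain (His and triose) of this site.
#' @param lChain chain holding the L domain (Mg and ATP) of this site.
#' @param label site label (default "L-K").
#' @param hisResid catalytic histidine residue number (default 221).
#' @return a [SiteDefinition-class].
#' @export
sitePreset <- function(structure, kChain, lChain, label = "L-K",
                       hisResid = 221) {
  mk <- function(sel, what) .oneAtom(structure, sel, what)
  siteDefinition(structure, label,
    closurePair = c(
      mk(sprintf("name MG and resname MG and chain %s", lChain), "Mg"),
      mk(sprintf("name NE2 and resid %d and chain %s", hisResid, kChain),
         "His NE2")),
    nucleophileOxygens = c(
      O1 = mk(sprintf("name O1 and resname DHA and chain %s", kChain), "O1"),
      O3 = mk(sprintf("name O3 and resname DHA and chain %s", kChain), "O3")),
    gammaPhosphorus = mk(sprintf("name PG and resname ATP and chain %s", lChain),
                         "gamma-P"),
    leavingOxygen = mk(sprintf("name O3B and resname ATP and chain %s", lChain),
                       "leaving O"))
}

.pairDistanceSeries <- function(traj, i, j, kind = "distance") {
  ci <- traj@coords[, (3 * i - 2):(3 * i), drop = FALSE]
  cj <- traj@coords[, (3 * j - 2):(3 * j), drop = FALSE]
  new("GeometrySeries", times = traj@times,
      values = sqrt(rowSums((ci - cj)^2)), kind = kind)
}

#' Active-site closure distance series
#'
#' Per-frame Euclidean distance between the closure marker pair; its
#' shortening indicates closure of the site.
#'
#' @param traj a [Trajectory-class].
#' @param site a [SiteDefinition-class].
#' @return a [GeometrySeries-class] of kind "distance".
#' @export
closureSeries <- function(traj, site) {
  stopifnot(is(site, "SiteDefinition"))
  if (max(site@closurePair) > nAtoms(traj))
    stop("site '", site@label, "': closure atoms missing from the structure")
  .pairDistanceSeries(traj, site@closurePair[1], site@closurePair[2])
}

#' O...P approach distance series
#'
#' Per-frame distance between one nucleophile oxygen and the
#' gamma-phosphorus. The two triose hydroxyl oxygens are chemically
#' equivalent, so each is tracked separately by label.
#'
#' @param traj a [Trajectory-class].
#' @param site a [SiteDefinition-class].
#' @param oxygen label of the nucleophile oxygen (e.g. "O1" or "O3").
#' @return a [GeometrySeries-class] of kind "distance". Coincident atoms give
#'   distance 0 with a warning (non-physical input).
#' @export
opDistanceSeries <- function(traj, site, oxygen) {
  stopifnot(is(site, "SiteDefinition"))
  if (!oxygen %in% names(site@nucleophileOxygens))
    stop("unknown oxygen label '", oxygen, "' for site '", site@label, "'")
  o <- site@nucleophileOxygens[[oxygen]]
  ser <- .pairDistanceSeries(traj, o, site@gammaPhosphorus)
  if (any(ser@values == 0))
    warning("coincident O and P atoms in ", sum(ser@values == 0),
            " frame(s): non-physical geometry")
  ser
}

#' In-line attack angle series (O...P-O)
#'
#' Angle at the phosphorus vertex between the vectors P -> nucleophile O and
#' P -> leaving O, in degrees; 180 degrees is a perfect in-line attack on the
#' scissile bond.
#'
#' @param traj a [Trajectory-class].
#' @param site a [SiteDefinition-class].
#' @param oxygen label of the nucleophile oxygen.
#' @return a [GeometrySeries-class] of kind "angle" (values in \[0, 180\]).
#' @export
opoAngleSeries <- function(traj, site, oxygen) {
  stopifnot(is(site, "SiteDefinition"))
  if (!oxygen %in% names(site@nucleophileOxygens))
    stop("unknown oxygen label '", oxygen, "' for site '", site@label, "'")
  o <- site@nucleophileOxygens[[oxygen]]
  p <- site@gammaPhosphorus
  lv <- site@leavingOxygen
  xo <- traj@coords[, (3 * o - 2):(3 * o), drop = FALSE]
  xp <- traj@coords[, (3 * p - 2):(3 * p), drop = FALSE]
  xl <- traj@coords[, (3 * lv - 2):(3 * lv), drop = FALSE]
  u <- xo - xp
  v <- xl - xp
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu == 0 | nv == 0))
    stop("zero-length P-O vector: angle undefined")
  cosang <- pmin(pmax(rowSums(u * v) / (nu * nv), -1), 1)
  new("GeometrySeries", times = traj@times,
      values = acos(cosang) * 180 / pi, kind = "angle")
}

#' Near-attack-conformation census
#'
#' Joint filter on aligned distance and angle series: a frame passes when the
#' O...P distance is strictly below `dCut` and the O...P-O angle strictly
#' above `aCut`. Passing frames within the van der Waals P+O contact distance
#' (3.3 \enc{Å}{Angstrom} by default: P 1.9 + O 1.4) are additionally
#' annotated.
#'
#' @param distances a [GeometrySeries-class] of kind "distance".
#' @param angles a [GeometrySeries-class] of kind "angle", on the identical
#'   frame times (a time-grid mismatch is an error).
#' @param dCut distance cutoff in \enc{Å}{Angstrom} (default 3.5).
#' @param aCut angle cutoff in degrees (default 155).
#' @param vdwContact annotation distance in \enc{Å}{Angstrom} (default 3.3).
#' @param oxygen optional oxygen label recorded with the records.
#' @return data.frame(frame_time, oxygen, distance, angle, passes,
#'   vdw_contact) with a `summary` attribute holding `nPass`,
#'   `fraction` (passing time fraction) and the cutoffs; see [nacSummary()].
#' @export
nacFilter <- function(distances, angles, dCut = 3.5, aCut = 155,
                      vdwContact = 3.3, oxygen = NA_character_) {
  stopifnot(is(distances, "GeometrySeries"), is(angles, "GeometrySeries"))
  if (length(distances@times) != length(angles@times) ||
      any(abs(distances@times - angles@times) > 1e-9))
    stop("distance and angle series are not on the same time grid")
  passes <- distances@values < dCut & angles@values > aCut
  rec <- data.frame(frame_time = distances@times, oxygen = oxygen,
                    distance = distances@values, angle = angles@values,
                    passes = passes,
                    vdw_contact = passes & distances@values < vdwContact)
  attr(rec, "summary") <- list(nPass = sum(passes),
                               fraction = mean(passes),
                               dCut = dCut, aCut = aCut)
  rec
}

#' Summary of a NAC census
#'
#' @param records data.frame from [nacFilter()].
#' @return list with `nPass`, `fraction` and the cutoffs used.
#' @export
nacSummary <- function(records) {
  s <- attr(records, "summary")
  if (is.null(s))
    s <- list(nPass = sum(records$passes), fraction = mean(records$passes),
              dCut = NA_real_, aCut = NA_real_)
  s
}

#' Distance-vs-angle scatter table
#'
#' @param records data.frame from [nacFilter()].
#' @param passingOnly keep only passing snapshots.
#' @return data.frame(distance, angle, time, passes) suitable for
#'   scatter-plotting the census; empty when no snapshot passes and
#'   `passingOnly` is TRUE.
#' @export
nacScatter <- function(records, passingOnly = FALSE) {
  out <- data.frame(distance = records$distance, angle = records$angle,
                    time = records$frame_time, passes = records$passes)
  if (passingOnly) out <- out[out$passes, , drop = FALSE]
  rownames(out) <- NULL
  out
}
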