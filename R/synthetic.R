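# Synthetic-data stage: deterministic toy structures and trajectories with
# the statistical structure the analyses assume. The default recipe mirrors
# the studied system's shape: a dimer of two identical 575-residue subunits,
# each split into a K and an L domain, arranged as four pseudo-globular
# clouds along an axis in the elongated L2-K1-K2-L1 order, with one active
# site per L/K interface (closure markers 14 A apart initially) and,
# optionally, a minimal phosphorus/oxygen triad standing in for the
# ATP/triose reaction centre.

#' Build a synthetic-system recipe
#'
#' @param nResPerSubunit residues per subunit (default 575).
#' @param kDomainSize residues of the K domain (default 330); the remainder
#'   forms the L domain.
#' @param domainSpacing distance between neighbouring domain centres in
#'   \enc{Å}{Angstrom} (default 28, which keeps neighbouring clouds
#'   connected at the default elastic-network cutoff).
#' @param cloudRadius radius of each uniform-density spherical domain cloud
#'   (default 17 \enc{Å}{Angstrom}, giving roughly protein-like C-alpha
#'   density for a 330-residue domain; uniform density keeps the elastic
#'   network rigid where Gaussian fringes would leave floppy mechanisms).
#' @param closureDistance initial separation of the closure marker pair
#'   (default 14 \enc{Å}{Angstrom}, the open-state value).
#' @param withBackbone build N/CA/C/O main-chain atoms (default FALSE:
#'   C-alpha only).
#' @param withLigands add Mg/His markers plus a P/O triad per site (default
#'   TRUE).
#' @param plantedVariances explicit variances (\enc{Å}{Angstrom}^2) of the
#'   planted collective modes; empty (default) solves them from
#'   `targetCumVar`.
#' @param modeRatios relative sizes of the planted variances (default
#'   hinge 0.60, twist 0.25, wobble 0.15).
#' @param targetCumVar cumulative variance fraction the planted modes should
#'   explain over the C-alpha set (default 0.68).
#' @param noiseSigma isotropic per-coordinate jitter, \enc{Å}{Angstrom}
#'   (default 0.25).
#' @param nFrames trajectory frames (default 6001).
#' @param frameDt frame interval, ps (default 20: 6001 frames cover the
#'   closed 0-120 ns window, the analogue of a production run that writes
#'   both endpoints).
#' @param timeOrigin time of the first frame, ps (default 0).
#' @param nacEpisodes data.frame(start, end, minDistance, maxAngle, oxygen)
#'   of near-attack episodes; the default is one O3 episode from 105 to
#'   112 ns reaching 3.16 \enc{Å}{Angstrom} and 178.45 degrees at its
#'   midpoint.
#' @param seed RNG seed (default 1); a fixed seed gives bit-identical
#'   output.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nResPerSubunit = 575L, kDomainSize = 330L,
                          domainSpacing = 28, cloudRadius = 17,
                          closureDistance = 14, withBackbone = FALSE,
                          withLigands = TRUE,
                          plantedVariances = numeric(0),
                          modeRatios = c(hinge = 0.60, twist = 0.25,
                                         wobble = 0.15),
                          targetCumVar = 0.68, noiseSigma = 0.25,
                          nFrames = 6001L, frameDt = 20, timeOrigin = 0,
                          nacEpisodes = NULL, seed = 1L) {
  if (is.null(nacEpisodes))
    nacEpisodes <- data.frame(start = 105000, end = 112000,
                              minDistance = 3.16, maxAngle = 178.45,
                              oxygen = "O3")
  new("SyntheticSpec",
      nResPerSubunit = as.integer(nResPerSubunit), nSubunits = 2L,
      kDomainSize = as.integer(kDomainSize),
      domainSpacing = domainSpacing, cloudRadius = cloudRadius,
      closureDistance = closureDistance, withBackbone = withBackbone,
      withLigands = withLigands,
      plantedVariances = as.numeric(plantedVariances),
      modeRatios = modeRatios, targetCumVar = targetCumVar,
      noiseSigma = noiseSigma, nFrames = as.integer(nFrames),
      frameDt = frameDt, timeOrigin = timeOrigin,
      nacEpisodes = nacEpisodes, seed = as.integer(seed))
}

#' Domain layout of a synthetic recipe
#'
#' @param spec a [SyntheticSpec-class].
#' @return data.frame(domain, chain, role, startRes, endRes, centerX): the
#'   four domains in their axial L2-K1-K2-L1 order.
#' @export
domainLayout <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  k <- spec@kDomainSize
  n <- spec@nResPerSubunit
  s <- spec@domainSpacing
  data.frame(domain = c("L2", "K1", "K2", "L1"),
             chain = c("B", "A", "B", "A"),
             role = c("L", "K", "K", "L"),
             startRes = c(k + 1L, 1L, 1L, k + 1L),
             endRes = c(n, k, k, n),
             centerX = c(0, s, 2 * s, 3 * s))
}

# Domain label of every atom (by chain and residue; site marker and ligand
# atoms follow the domain their anchor belongs to).
.atomDomains <- function(atoms, spec) {
  k <- spec@kDomainSize
  inK <- atoms$resid <= k | atoms$resname %in% c("HIS", "DHA")
  ifelse(atoms$chain == "A", ifelse(inK, "K1", "L1"),
         ifelse(inK, "K2", "L2"))
}

#' Build the synthetic elongated dimer
#'
#' Deterministic given `spec@seed`. Chains A and B each contribute one K and
#' one L domain; the four domains form uniform-density spherical C-alpha
#' clouds (optionally with N/C/O backbone atoms) along the x axis in
#' L2-K1-K2-L1 order. Each
#' L/K interface carries a closure marker pair (an L-domain Mg and the
#' K-domain His-221 N-epsilon-2) placed exactly `closureDistance` apart and,
#' when `withLigands`, a gamma-phosphorus with its scissile bridging oxygen
#' (residue ATP) plus the two equivalent triose hydroxyl oxygens O1/O3
#' (residue DHA).
#'
#' @param spec a [SyntheticSpec-class].
#' @param backbone,ligands optional overrides of the spec flags.
#' @return a [Structure-class].
#' @export
makeToyDimer <- function(spec, backbone = spec@withBackbone,
                         ligands = spec@withLigands) {
  stopifnot(is(spec, "SyntheticSpec"))
  lay <- domainLayout(spec)
  .withSeed(spec@seed, function() {
    rows <- list()
    xyz <- list()
    for (ch in c("A", "B")) {
      for (res in seq_len(spec@nResPerSubunit)) {
        role <- if (res <= spec@kDomainSize) "K" else "L"
        dom <- lay[lay$chain == ch & lay$role == role, ]
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        ca <- c(dom$centerX, 0, 0) +
          spec@cloudRadius * stats::runif(1)^(1 / 3) * u
        if (backbone) {
          jit <- function() 0.05 * stats::rnorm(3)
          rows[[length(rows) + 1]] <- data.frame(
            name = c("N", "CA", "C", "O"),
            element = c("N", "C", "C", "O"),
            resid = res, resname = "ALA", chain = ch)
          xyz[[length(xyz) + 1]] <- rbind(
            ca + c(-1.2, 0.5, 0) + jit(), ca,
            ca + c(1.2, 0.5, 0) + jit(), ca + c(1.4, 1.6, 0) + jit())
        } else {
          rows[[length(rows) + 1]] <- data.frame(
            name = "CA", element = "C", resid = res, resname = "ALA",
            chain = ch)
          xyz[[length(xyz) + 1]] <- matrix(ca, 1)
        }
      }
    }
    s <- spec@domainSpacing
    D <- spec@closureDistance
    addAtom <- function(name, element, resid, resname, chain, pos) {
      rows[[length(rows) + 1]] <<- data.frame(
        name = name, element = element, resid = resid, resname = resname,
        chain = chain)
      xyz[[length(xyz) + 1]] <<- matrix(pos, 1)
    }
    # site 1 (L2-K1): L2 is chain B, K1 chain A
    mg1 <- c(s / 2 - D / 2, 0, 0); ne1 <- c(s / 2 + D / 2, 0, 0)
    addAtom("MG", "MG", 901L, "MG", "B", mg1)
    addAtom("NE2", "N", 221L, "HIS", "A", ne1)
    # site 2 (K2-L1): K2 is chain B, L1 chain A
    mg2 <- c(2.5 * s + D / 2, 0, 0); ne2 <- c(2.5 * s - D / 2, 0, 0)
    addAtom("MG", "MG", 901L, "MG", "A", mg2)
    addAtom("NE2", "N", 221L, "HIS", "B", ne2)
    if (ligands) {
      addLig <- function(mg, ne, lchain, kchain) {
        pg <- mg + c(0, 2.5, 0)
        addAtom("PG", "P", 902L, "ATP", lchain, pg)
        addAtom("O3B", "O", 902L, "ATP", lchain, pg + c(-1.13, -1.13, 0))
        addAtom("O1", "O", 903L, "DHA", kchain, ne + c(-1.0, 1.0, 0))
        addAtom("O3", "O", 903L, "DHA", kchain, ne + c(-1.0, -1.0, 0))
      }
      addLig(mg1, ne1, "B", "A")
      addLig(mg2, ne2, "A", "B")
    }
    Structure(do.call(rbind, rows), do.call(rbind, xyz))
  })
}

# The three planted rigid-domain displacement fields (hinge-bend, twist,
# wobble), linearised as axis x lever-arm rotation fields of the two L
# domains, restricted to C-alpha atoms and Gram-Schmidt orthonormalised.
.plantedFields <- function(structure, spec) {
  atoms <- structure@atoms
  lay <- domainLayout(spec)
  isCA <- atoms$name == "CA" & atoms$resname == "ALA"
  dom <- .atomDomains(atoms, spec)
  n3 <- 3L * nrow(atoms)
  axes <- list(hinge = c(0, 0, 1), twist = c(1, 0, 0), wobble = c(0, 1, 0))
  fields <- matrix(0, n3, 3)
  for (m in seq_along(axes)) {
    f <- numeric(n3)
    for (dlab in c("L1", "L2")) {
      sel <- which(isCA & dom == dlab)
      if (!length(sel)) next
      centre <- colMeans(structure@coords[sel, , drop = FALSE])
      sgn <- if (dlab == "L2") 1 else -1   # mirrored motion of the two lobes
      for (i in sel) {
        u <- crossprod3(sgn * axes[[m]], structure@coords[i, ] - centre)
        f[(3 * i - 2):(3 * i)] <- u
      }
    }
    fields[, m] <- f
  }
  # Gram-Schmidt in the listed order, then unit norm
  for (m in 1:3) {
    v <- fields[, m]
    if (m > 1)
      for (p in 1:(m - 1)) v <- v - sum(v * fields[, p]) * fields[, p]
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("degenerate planted field (no L-domain atoms?)")
    fields[, m] <- v / nv
  }
  colnames(fields) <- names(axes)
  fields
}

# Solve the planted variances so the planted modes explain targetCumVar of
# the total C-alpha variance: (V + k sigma^2) / (V + 3 nCA sigma^2) = t
# with V the summed planted variance and k the number of planted modes
# (noise adds sigma^2 along every direction, including the planted ones).
.solvePlantedVariances <- function(spec, nCA) {
  if (length(spec@plantedVariances))
    return(spec@plantedVariances)
  ratios <- spec@modeRatios / sum(spec@modeRatios)
  s2 <- spec@noiseSigma^2
  if (s2 == 0) return(ratios * 100)
  t <- spec@targetCumVar
  k <- length(ratios)
  V <- (t * 3 * nCA * s2 - k * s2) / (1 - t)
  if (V <= 0)
    stop("targetCumVar unreachable: noise alone already exceeds the target")
  ratios * V
}

#' Synthesize a hinge-motion trajectory
#'
#' Frames are `reference + sum_i a_i(t) d_i + noise` with orthonormal planted
#' displacement fields `d_i` (linearised hinge-bend, twist and wobble of the
#' two L domains), Gaussian amplitudes `a_i(t)` of the planted variances, and
#' isotropic Gaussian jitter on every atom. The covariance of the output
#' converges to the planted spectrum, so essential-dynamics PCA recovers the
#' planted directions and variance fractions.
#'
#' @param structure a dimer from [makeToyDimer()].
#' @param spec the [SyntheticSpec-class] used to build it.
#' @return a [Trajectory-class] of `spec@nFrames` frames at `spec@frameDt`
#'   ps, starting at `spec@timeOrigin`. The planted fields are returned in
#'   the `"plantedFields"` attribute (3N x 3 matrix) and the variances in
#'   `"plantedVariances"`, for closing the recovery loop in analyses.
#' @details Rigid-domain rotations are linearised into displacement fields,
#'   which keeps the planted motion exactly rank-3 and PCA-recoverable; a
#'   planted standard deviation driving per-atom excursions beyond roughly a
#'   quarter of the domain spacing leaves the linear regime and triggers a
#'   warning.
#' @export
makeHingeTrajectory <- function(structure, spec) {
  stopifnot(is(structure, "Structure"), is(spec, "SyntheticSpec"))
  fields <- .plantedFields(structure, spec)
  nCA <- sum(structure@atoms$name == "CA" & structure@atoms$resname == "ALA")
  vars <- .solvePlantedVariances(spec, nCA)
  if (length(vars) != ncol(fields))
    stop("need one planted variance per planted field")
  maxComp <- apply(abs(fields), 2, max)
  excur <- 3 * sqrt(vars) * maxComp   # ~3 sigma largest per-atom excursion
  if (any(excur > spec@domainSpacing / 4))
    warning("planted variance leaves the linearised-rotation regime for mode(s): ",
            paste(colnames(fields)[excur > spec@domainSpacing / 4],
                  collapse = ", "))
  f <- spec@nFrames
  n3 <- 3L * nAtoms(structure)
  seed2 <- as.integer((spec@seed %% (.Machine$integer.max - 1L)) + 1L)
  xyz <- .withSeed(seed2, function() {
    coefs <- sweep(matrix(stats::rnorm(f * length(vars)), f), 2,
                   sqrt(vars), "*")
    base <- matrix(.flatten(structure@coords), f, n3, byrow = TRUE)
    base + tcrossprod(coefs, fields) +
      matrix(stats::rnorm(f * n3, sd = spec@noiseSigma), f)
  })
  traj <- Trajectory(structure, xyz,
                     times = spec@timeOrigin + spec@frameDt * (seq_len(f) - 1))
  attr(traj, "plantedFields") <- fields
  attr(traj, "plantedVariances") <- vars
  traj
}

#' Plant near-attack episodes into a trajectory
#'
#' During each episode the labelled nucleophile oxygen is smoothly driven
#' towards the gamma-phosphorus, in plane with the scissile P-O bond: with
#' `s` running 0..1 across the episode, the O...P distance follows
#' `d0 + (minDistance - d0) * sin(pi * s)` (where `d0` is the pre-episode
#' distance) and the O...P-O angle follows `90 + (maxAngle - 90) * sin(pi *
#' s)` degrees, so the planted extremes are attained exactly at the episode
#' midpoint. Outside episodes the geometry keeps its far, open-state values
#' (> 10 \enc{Å}{Angstrom} for the default recipe).
#'
#' @param traj a [Trajectory-class].
#' @param site the [SiteDefinition-class] whose oxygen is driven.
#' @param episodes data.frame(start, end, minDistance, maxAngle, oxygen)
#'   with times in ps; episodes must lie within the trajectory and must not
#'   overlap.
#' @return the modified [Trajectory-class].
#' @export
plantNacEpisode <- function(traj, site, episodes) {
  stopifnot(is(traj, "Trajectory"), is(site, "SiteDefinition"))
  episodes <- as.data.frame(episodes)
  need <- c("start", "end", "minDistance", "maxAngle", "oxygen")
  if (!all(need %in% names(episodes)))
    stop("episodes need columns: ", paste(need, collapse = ", "))
  if (nrow(episodes) > 1) {
    o <- order(episodes$start)
    if (any(episodes$start[o][-1] < episodes$end[o][-nrow(episodes)]))
      stop("near-attack episodes overlap")
  }
  tt <- traj@times
  # an episode may end on the half-open boundary of the sampled window
  dtLast <- if (length(tt) > 1) tt[length(tt)] - tt[length(tt) - 1] else 0
  if (any(episodes$start < min(tt) | episodes$end > max(tt) + dtLast))
    stop("episode outside the trajectory time range")
  xyz <- traj@coords
  p <- site@gammaPhosphorus
  lv <- site@leavingOxygen
  for (e in seq_len(nrow(episodes))) {
    ox <- episodes$oxygen[e]
    if (!ox %in% names(site@nucleophileOxygens))
      stop("episode oxygen '", ox, "' not defined for site '", site@label, "'")
    o <- site@nucleophileOxygens[[ox]]
    idx <- which(tt >= episodes$start[e] & tt <= episodes$end[e])
    if (length(idx) < 1) next
    d0 <- sqrt(sum((xyz[idx[1], (3 * o - 2):(3 * o)] -
                      xyz[idx[1], (3 * p - 2):(3 * p)])^2))
    for (fi in idx) {
      s <- (tt[fi] - episodes$start[e]) / (episodes$end[e] - episodes$start[e])
      r <- d0 + (episodes$minDistance[e] - d0) * sin(pi * s)
      th <- (90 + (episodes$maxAngle[e] - 90) * sin(pi * s)) * pi / 180
      xp <- xyz[fi, (3 * p - 2):(3 * p)]
      xl <- xyz[fi, (3 * lv - 2):(3 * lv)]
      ehat <- xl - xp; ehat <- ehat / sqrt(sum(ehat^2))
      g <- c(0, 0, 1)
      if (abs(sum(g * ehat)) > 0.99) g <- c(0, 1, 0)
      phat <- g - sum(g * ehat) * ehat
      phat <- phat / sqrt(sum(phat^2))
      xyz[fi, (3 * o - 2):(3 * o)] <- xp + r * (cos(th) * ehat + sin(th) * phat)
    }
  }
  out <- Trajectory(traj@structure, xyz, tt)
  attr(out, "plantedFields") <- attr(traj, "plantedFields")
  attr(out, "plantedVariances") <- attr(traj, "plantedVariances")
  out
}
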