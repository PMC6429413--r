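# End-to-end driver: synthetic system -> elastic-network modes -> cross-system
# mode comparison -> essential dynamics -> mobility -> active-site geometry,
# with every output and a reproducibility manifest written under one run
# directory.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()], with every
#' tunable exposed: synthetic-system size, elastic-network parameters,
#' ensemble settings, analysis selections/windows and the near-attack
#' cutoffs. Values follow the package defaults for the full-size dimer; pass
#' a smaller `nResPerSubunit`/`nFrames`/`nConf` for quick runs.
#'
#' @param ... named overrides of any default entry.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    outputDir = "hingewatch-run",
    # synthetic system
    nResPerSubunit = 575L, kDomainSize = 330L, cloudRadius = 17,
    domainSpacing = 28, nFrames = 6001L, frameDt = 20,
    noiseSigma = 0.25, targetCumVar = 0.68, nacEpisodes = NULL,
    # elastic network
    enmCutoff = 13, forceConstant = 1,
    # mode comparison
    modes = 7:9, temperature = 300, nConf = 5000L, commonSelection = "name CA",
    # essential dynamics & mobility
    analysisSelection = "name CA", analysisWindow = c(20000, 120000),
    nComponents = 25L,
    # near-attack scan
    dCut = 3.5, aCut = 155)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

.validateConfig <- function(cfg) {
  if (cfg$analysisWindow[2] <= cfg$analysisWindow[1])
    stop("config validation: analysisWindow end must exceed its start")
  if (cfg$dCut <= 0 || cfg$aCut <= 0 || cfg$aCut >= 180)
    stop("config validation: bad NAC cutoffs")
  if (any(cfg$modes <= 6))
    stop("config validation: compared modes must be non-trivial (> 6)")
  if (cfg$nConf < 2 || cfg$nFrames < 2)
    stop("config validation: nConf and nFrames must be >= 2")
  invisible(TRUE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic system
#'
#' Sequences the whole workflow: build the ligand-bearing dimer and its apo
#' counterpart, elastic-network normal-mode analysis of both, cross-system
#' comparison of the chosen non-trivial modes through the
#' ensemble-reduction-PCA protocol, essential dynamics of a planted hinge
#' trajectory (with RMSD/RMSF mobility), and the near-attack geometry census
#' on the planted episodes. All outputs land under `config$outputDir`
#' together with `manifest.json` recording parameters, seeds, file hashes
#' and the headline numbers.
#'
#' @param config list from [pipelineConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  .validateConfig(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outputDir, f)
  results <- list()

  spec <- .stage("synth", {
    syntheticSpec(nResPerSubunit = config$nResPerSubunit,
                  kDomainSize = config$kDomainSize,
                  cloudRadius = config$cloudRadius,
                  domainSpacing = config$domainSpacing,
                  nFrames = config$nFrames, frameDt = config$frameDt,
                  noiseSigma = config$noiseSigma,
                  targetCumVar = config$targetCumVar,
                  nacEpisodes = config$nacEpisodes, seed = config$seed)
  })
  holo <- .stage("synth", makeToyDimer(spec))
  apo <- .stage("synth", makeToyDimer(spec, ligands = FALSE))
  .stage("synth", {
    writeStructure(holo, out("system.pdb"))
    writeStructure(apo, out("system_apo.pdb"))
  })
  caSel <- selectAtoms(holo, config$analysisSelection)
  results$nAnalysisAtoms <- length(caSel)

  nmaOf <- function(structure) {
    h <- buildEnmHessian(structure, cutoff = config$enmCutoff,
                         k = config$forceConstant)
    eigenModes(massWeight(h))
  }
  msHolo <- .stage("nma", nmaOf(holo))
  msApo <- .stage("nma", nmaOf(apo))
  .stage("nma", {
    split <- splitTrivial(msHolo)
    results$rigidOverlap <- split$rigidOverlap
    k <- min(length(msHolo@values), 30L)
    writeTable(data.frame(
      mode = seq_len(k), eigenvalue = msHolo@values[seq_len(k)],
      frequency_native = modeFrequencies(msHolo)[seq_len(k)],
      frequency_cm1 = modeFrequencies(msHolo, "cm-1")[seq_len(k)]),
      out("nma_eigenvalues.csv"))
    mcols <- config$modes
    dmat <- vapply(mcols, function(m) .cartesianMode(msHolo, m),
                   numeric(nrow(msHolo@vectors)))
    writeNmd(out("nma_modes.nmd"), msHolo@refCoords, dmat,
             scales = 1 / sqrt(msHolo@values[mcols]),
             atoms = holo@atoms, title = "elastic network modes",
             modeIndices = mcols)
  })

  cmp <- .stage("modecmp", {
    rec <- function(structure, ms, off) lapply(seq_along(config$modes),
      function(i) modeViaEnsemble(structure, ms, config$modes[i],
        commonSelector = config$commonSelection,
        temperature = config$temperature, nConf = config$nConf,
        seed = config$seed + off + i)$vector)
    m <- compareModes(rec(holo, msHolo, 100L), rec(apo, msApo, 200L),
                      labelsA = paste0("holo.NM", config$modes),
                      labelsB = paste0("apo.NM", config$modes))
    writeTable(cbind(data.frame(mode = rownames(m@values)),
                     as.data.frame(m@values)), out("mode_comparison.csv"))
    m
  })
  results$modeComparison <- cmp@values

  traj <- .stage("essdyn", {
    tr <- makeHingeTrajectory(holo, spec)
    site <- sitePreset(holo, kChain = "A", lChain = "B", label = "L2-K1")
    tr <- plantNacEpisode(tr, site, spec@nacEpisodes)
    tr
  })
  pc <- .stage("essdyn", {
    cv <- covarianceMatrix(traj, caSel, window = config$analysisWindow)
    pc <- pcaModes(cv)
    spec25 <- varianceSpectrum(pc, min(config$nComponents, length(pc@values)))
    writeTable(spec25, out("essdyn_eigenvalues.csv"))
    writeTable(projectOnComponent(traj, pc, 1), out("pc1_projection.csv"))
    porcupineField(pc, 1, nmdPath = out("pc1_porcupine.nmd"),
                   atoms = holo@atoms[as.integer(caSel), ])
    ext <- extremeConformations(traj, pc, 1)
    writeStructure(ext$min, out("pc1_extreme_min.pdb"))
    writeStructure(ext$max, out("pc1_extreme_max.pdb"))
    results$cumulative3 <- spec25$cumulative[min(3, nrow(spec25))]
    pc
  })
  .stage("mobility", {
    writeTable(rmsdSeries(traj, caSel), out("rmsd_ca.csv"))
    prof <- rmsfProfile(traj, caSel, window = config$analysisWindow)
    prof <- detectMobileRegions(prof)
    writeTable(data.frame(chain = prof@atoms$chain, resid = prof@atoms$resid,
                          rmsf = prof@rmsf), out("rmsf_ca.csv"))
    writeTable(prof@regions, out("mobile_regions.csv"))
    results$nMobileRegions <- nrow(prof@regions)
  })
  .stage("nacscan", {
    site <- sitePreset(holo, kChain = "A", lChain = "B", label = "L2-K1")
    writeTable(closureSeries(traj, site), out("closure_L2K1.csv"))
    ox <- unique(spec@nacEpisodes$oxygen)[1]
    d <- opDistanceSeries(traj, site, ox)
    a <- opoAngleSeries(traj, site, ox)
    recs <- nacFilter(d, a, dCut = config$dCut, aCut = config$aCut,
                      oxygen = ox)
    writeTable(recs, out("nac_records.csv"))
    writeTable(nacScatter(recs, passingOnly = TRUE), out("nac_passing.csv"))
    s <- nacSummary(recs)
    results$nacCount <- s$nPass
    results$nacFraction <- s$fraction
    results$minOPDistance <- min(d@values)
    results$maxOPOAngle <- max(a@values)
  })

  files <- setdiff(list.files(config$outputDir), "manifest.json")
  manifest <- list(
    package = "hingewatch",
    version = as.character(utils::packageVersion("hingewatch")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "outputDir")],
    stages = c("synth", "nma", "modecmp", "essdyn", "mobility", "nacscan"),
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(file.path(config$outputDir, files)))),
      files),
    results = results)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
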