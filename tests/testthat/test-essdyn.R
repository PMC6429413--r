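# Essential dynamics: covariance, PCA, variance spectra, projections,
# extreme frames, porcupine export.

twoAtomStructure <- function() {
  Structure(data.frame(name = c("CA", "CA"), resid = 1:2, resname = "ALA",
                       chain = "A"),
            rbind(c(0, 0, 0), c(5, 0, 0)), masses = c(1, 1))
}

test_that("covariance matches a pen-and-paper 2-atom, 2-frame computation", {
  s <- twoAtomStructure()
  x1 <- c(0, 0, 0, 5, 0, 0)
  x2 <- c(1, 0, 2, 5, -2, 0)
  cv <- covarianceMatrix(Trajectory(s, rbind(x1, x2)), 1:2, align = FALSE)
  mu <- (x1 + x2) / 2
  Chand <- (tcrossprod(x1 - mu) + tcrossprod(x2 - mu)) / 2
  expect_equal(cv$C, Chand, tolerance = 1e-12)
  expect_equal(as.vector(t(cv$mean)), mu, tolerance = 1e-12)
  # sample normalisation divides by F - 1 instead
  cvs <- covarianceMatrix(Trajectory(s, rbind(x1, x2)), 1:2, align = FALSE,
                          normalization = "sample")
  expect_equal(cvs$C, Chand * 2, tolerance = 1e-12)
  static <- Trajectory(s, rbind(x1, x1, x1))
  expect_equal(max(abs(covarianceMatrix(static, 1:2, align = FALSE)$C)), 0,
               tolerance = 1e-12)
  expect_error(covarianceMatrix(Trajectory(s, rbind(x1)), 1:2), "at least 2")
})

test_that("pcaModes sorts descending, recovers planted rank-1 motion and reconstructs", {
  expect_equal(eigenvalues(pcaModes(diag(c(3, 2, 1, 0, 0, 0)))),
               c(3, 2, 1, 0, 0, 0))
  set.seed(81)
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  pc <- pcaModes(4.2 * tcrossprod(v))
  expect_equal(eigenvalues(pc)[1], 4.2, tolerance = 1e-10)
  expect_lt(max(eigenvalues(pc)[-1]), 1e-10)
  expect_equal(innerProduct(eigenvectors(pc)[, 1], v), 1, tolerance = 1e-9)
  A <- matrix(rnorm(900), 30)
  C <- crossprod(A) / 30
  pc2 <- pcaModes(C)
  R <- eigenvectors(pc2)
  expect_lt(norm(R %*% diag(eigenvalues(pc2)) %*% t(R) - C, "F") / norm(C, "F"),
            1e-10)
  expect_error(pcaModes(matrix(rnorm(36), 6)), "symmetric")
  expect_error(pcaModes(diag(c(1, 1, -1, 0, 0, 0))), "negative eigenvalues")
})

test_that("variance spectra report cumulative percentages", {
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  expect_equal(varianceSpectrum(pcaModes(tcrossprod(v)), 1)$cumulative, 100)
  eq <- pcaModes(diag(rep(2, 30)))
  vs <- varianceSpectrum(eq, 30)
  expect_equal(vs$cumulative, 100 * (1:30) / 30, tolerance = 1e-12)
})

test_that("projections are exact for constructed frames and reproduce eigenvalues", {
  s <- twoAtomStructure()
  set.seed(91)
  mu <- rnorm(6)
  d1 <- rnorm(6); d1 <- d1 / sqrt(sum(d1^2))
  pc <- new("PCResult", values = c(1, rep(0, 5)),
            vectors = cbind(d1, qr.Q(qr(cbind(d1, diag(6))))[, 2:6]),
            meanCoords = matrix(mu, 2, 3, byrow = TRUE),
            refCoords = matrix(numeric(0), 0, 3), nFrames = 2L,
            window = c(NA_real_, NA_real_), atomIndices = 1:2)
  tr <- Trajectory(s, rbind(mu, mu + 2 * d1))
  p <- projectOnComponent(tr, pc, 1)
  expect_equal(seriesValues(p), c(0, 2), tolerance = 1e-12)
  expect_error(projectOnComponent(tr, pc, 7), "out of range")
  # internal consistency on a planted trajectory: var(projection_i) = lambda_i
  spec <- smallSpec(nRes = 20L, kDom = 12L, nFrames = 300L)
  st <- makeToyDimer(spec)
  trj <- makeHingeTrajectory(st, spec)
  ca <- selectAtoms(st, "name CA")
  pcr <- pcaModes(covarianceMatrix(trj, ca))
  for (k in 1:3) {
    pk <- seriesValues(projectOnComponent(trj, pcr, k))
    expect_equal(mean((pk - mean(pk))^2), eigenvalues(pcr)[k],
                 tolerance = 1e-6)
  }
})

test_that("extreme conformations are actual frames at the projection extremes", {
  spec <- smallSpec()
  s <- makeToyDimer(spec)
  ms <- eigenModes(massWeight(buildEnmHessian(s, cutoff = 20)))
  amp <- 3
  tr <- harmonicTrajectory(s, ms, 7, amplitude = amp, nFrames = 16)
  pc <- pcaModes(covarianceMatrix(tr, 1:nAtoms(s), align = FALSE))
  ext <- extremeConformations(tr, pc, 1)
  expect_equal(sort(unname(ext$frames)), c(5L, 13L))  # the +-amplitude frames
  expect_equal(unname(diff(ext$projections)), 2 * amp, tolerance = 1e-9)
  expect_equal(coords(ext$max), frameCoords(tr, ext$frames["max"]))
  flat <- Trajectory(s, matrix(as.vector(t(coords(s))), 3, 3 * nAtoms(s),
                               byrow = TRUE))
  pcf <- suppressWarnings(pcaModes(covarianceMatrix(flat, 1:nAtoms(s),
                                                    align = FALSE)))
  extf <- extremeConformations(flat, pcf, 1)
  expect_equal(coords(extf$min), coords(extf$max))
})

test_that("porcupine fields scale with sqrt(variance) and round trip through NMD", {
  set.seed(101)
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  pc <- pcaModes(9 * tcrossprod(v))   # sd 3 along v
  arrows <- porcupineField(pc, 1, scale = 2)
  expect_equal(as.vector(t(arrows)), 6 * abs(v) * sign(v) *
                 sign(v[which.max(abs(v))]), tolerance = 1e-9)
  expect_equal(max(abs(porcupineField(pc, 12))), 0)
  f <- withr::local_tempfile(fileext = ".nmd")
  porcupineField(pc, 1, nmdPath = f,
                 atoms = data.frame(name = "CA", resid = 1:4, chain = "A"))
  back <- readNmd(f)
  expect_equal(abs(back$modes[, 1]), abs(v), tolerance = 1e-6)
  expect_equal(back$scales, 3, tolerance = 1e-6)
  expect_equal(back$coords, pc@meanCoords, tolerance = 1e-6)
})

test_that("sum of RMSF^2 equals the covariance trace and eigenvalue sum", {
  spec <- smallSpec(nRes = 16L, kDom = 10L, nFrames = 120L)
  s <- makeToyDimer(spec)
  tr <- makeHingeTrajectory(s, spec)
  ca <- selectAtoms(s, "name CA")
  cv <- covarianceMatrix(tr, ca)
  prof <- rmsfProfile(tr, ca, fit = "first")
  lam <- eigenvalues(pcaModes(cv))
  expect_equal(sum(prof@rmsf^2), sum(diag(cv$C)), tolerance = 1e-9)
  expect_equal(sum(prof@rmsf^2), sum(lam), tolerance = 1e-6)
})

test_that("PCA of a single-mode thermal ensemble returns that mode", {
  spec <- smallSpec()
  s <- makeToyDimer(spec)
  ms <- eigenModes(massWeight(buildEnmHessian(s, cutoff = 20)))
  ens <- thermalEnsemble(s, ms, modes = 8L, nConf = 2000L, seed = 9)
  pc <- pcaModes(covarianceMatrix(ens, 1:nAtoms(s), align = FALSE))
  expect_gt(innerProduct(eigenvectors(pc)[, 1], cartMode(ms, 8)), 0.999)
  expect_lt(eigenvalues(pc)[2] / eigenvalues(pc)[1], 1e-3)
})

test_that("essential dynamics agrees with bio3d's PCA on identical input", {
  spec <- smallSpec(nRes = 14L, kDom = 8L, nFrames = 150L)
  s <- makeToyDimer(spec)
  tr <- makeHingeTrajectory(s, spec)
  ca <- selectAtoms(s, "name CA")
  X <- tr@coords[, xyzIdx(as.integer(ca))]
  pc <- pcaModes(covarianceMatrix(tr, ca, align = FALSE,
                                  normalization = "sample"))
  ref <- bio3d::pca.xyz(X)
  expect_equal(eigenvalues(pc)[1:5], ref$L[1:5], tolerance = 1e-8)
  for (k in 1:3)
    expect_gt(innerProduct(eigenvectors(pc)[, k], ref$U[, k]), 0.9999)
})
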