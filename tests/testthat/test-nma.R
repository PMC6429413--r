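# Elastic-network Hessians, eigenanalysis, frequencies, trivial-mode
# handling and mode-based trajectory generators.

diatomic <- function(d = 3, masses = c(1, 1)) {
  Structure(data.frame(name = c("CA", "CA"), resid = 1:2, resname = "ALA",
                       chain = "A"),
            rbind(c(0, 0, 0), c(d, 0, 0)), masses = masses)
}

test_that("diatomic ENM has exactly one stretch mode with the reduced-mass eigenvalue", {
  k <- 2.5
  h <- massWeight(buildEnmHessian(diatomic(), cutoff = 5, k = k))
  ms <- eigenModes(h)
  ev <- eigenvalues(ms)
  expect_equal(ev[1:5], rep(0, 5), tolerance = 1e-10)
  expect_equal(ev[6], 2 * k, tolerance = 1e-8)       # mu = 1/2 at unit masses
  # stretch eigenvector parallel to the bond after sign normalisation
  v <- eigenvectors(ms)[, 6]
  expect_equal(abs(v), c(1, 0, 0, 1, 0, 0) / sqrt(2), tolerance = 1e-6)
  # mixed masses: lambda = k / mu
  h2 <- massWeight(buildEnmHessian(diatomic(masses = c(2, 6)), cutoff = 5, k = k))
  mu <- 1 / (1 / 2 + 1 / 6)
  expect_equal(max(eigenvalues(eigenModes(h2))), k / mu, tolerance = 1e-8)
})

test_that("collinear 3-atom chain reproduces the 1D analytic spectrum", {
  s <- Structure(data.frame(name = rep("CA", 3), resid = 1:3,
                            resname = "ALA", chain = "A"),
                 rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                 masses = rep(1, 3))
  k <- 1.7
  h <- massWeight(buildEnmHessian(s, cutoff = 5, k = k))  # neighbours only
  ev <- eigenvalues(eigenModes(h))
  # 1D chain eigenvalues 0, k, 3k embedded in 3D (transverse directions flat)
  expect_equal(ev[1:7], rep(0, 7), tolerance = 1e-8)
  expect_equal(ev[8:9], c(k, 3 * k), tolerance = 1e-8)
})

test_that("ENM Hessian annihilates uniform translations and warns on isolated atoms", {
  s <- makeToyDimer(smallSpec())
  h <- buildEnmHessian(s, selectAtoms(s, "name CA"), cutoff = 20)
  n <- nrow(h@refCoords)
  for (a in 1:3) {
    tvec <- numeric(3 * n); tvec[seq(a, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(h@matrix %*% tvec)), 1e-10)
  }
  far <- Structure(data.frame(name = rep("CA", 3), resid = 1:3,
                              resname = "ALA", chain = "A"),
                   rbind(c(0, 0, 0), c(3, 0, 0), c(100, 0, 0)))
  expect_warning(buildEnmHessian(far, cutoff = 5), "no neighbour")
})

test_that("mass weighting scales as 1/sqrt(mi mj) and cannot be applied twice", {
  s <- makeToyDimer(smallSpec(nRes = 10L, kDom = 6L))
  h <- buildEnmHessian(s, selectAtoms(s, "name CA"), cutoff = 20)
  w1 <- massWeight(h, rep(1, nrow(h@refCoords)))
  expect_equal(w1@matrix, h@matrix, tolerance = 1e-14)
  w4 <- massWeight(h, rep(4, nrow(h@refCoords)))
  expect_equal(w4@matrix, h@matrix / 4, tolerance = 1e-14)
  expect_error(massWeight(w4), "already mass-weighted")
})

test_that("eigenModes returns orthonormal ascending modes that reconstruct the input", {
  # direct toy: diagonal Hessian -> eigenvalues are the diagonal, axis vectors
  s1 <- Structure(data.frame(name = "CA", resid = 1L, resname = "ALA",
                             chain = "A"), matrix(0, 1, 3), masses = 1)
  hd <- new("HessianModel", matrix = diag(c(2, 3, 1)), origin = "imported",
            refCoords = coords(s1), cutoff = NA_real_,
            forceConstant = NA_real_, massWeighted = TRUE, masses = 1)
  msd <- eigenModes(hd)
  expect_equal(eigenvalues(msd), c(1, 2, 3))
  expect_equal(abs(eigenvectors(msd)), diag(3)[, c(3, 1, 2)], tolerance = 1e-12)
  # random symmetric 12x12: spectral reconstruction and orthonormality
  set.seed(71)
  A <- matrix(rnorm(144), 12); Hm <- (A + t(A)) / 2
  h <- new("HessianModel", matrix = Hm, origin = "imported",
           refCoords = matrix(rnorm(12), 4, 3), cutoff = NA_real_,
           forceConstant = NA_real_, massWeighted = FALSE, masses = numeric(0))
  ms <- eigenModes(h)
  R <- eigenvectors(ms)
  expect_lt(max(abs(crossprod(R) - diag(12))), 1e-10)
  rec <- R %*% diag(eigenvalues(ms)) %*% t(R)
  expect_lt(norm(rec - Hm, "F") / norm(Hm, "F"), 1e-12)
  expect_error(eigenModes(methods::initialize(h, matrix = Hm + 1e-3 * (A - t(A)))),
               "asymmetric")
})

test_that("frequencies follow nu = sqrt(lambda)/(2 pi) with unit-consistent wavenumbers", {
  s1 <- Structure(data.frame(name = "CA", resid = 1L, resname = "ALA",
                             chain = "A"), matrix(0, 1, 3), masses = 1)
  mkms <- function(lams) new("ModeSet", values = lams, vectors = diag(3),
                             frequencies = rep(NA_real_, 3),
                             massWeighted = TRUE, nTrivial = 0L, masses = 1,
                             refCoords = coords(s1))
  nu <- modeFrequencies(mkms(c(0, 1, 4 * pi^2)))
  expect_equal(nu, c(0, 1 / (2 * pi), 1))   # k = m = 1 oscillator in the middle
  expect_equal(modeFrequencies(mkms(c(0, 1, 4 * pi^2)), "cm-1")[2],
               1e13 / (2 * pi * 2.99792458e10), tolerance = 1e-12)
  expect_equal(modeFrequencies(mkms(c(-1e-9, 1, 2)))[1], 0)  # clamped noise
  expect_error(modeFrequencies(mkms(c(-0.5, 1, 2))), "negative eigenvalue")
  expect_true(!is.unsorted(modeFrequencies(mkms(c(0, 1, 2)))))
})

test_that("splitTrivial removes a rigid-body nullspace that projects onto the exact basis", {
  s <- makeToyDimer(smallSpec())
  ms <- eigenModes(massWeight(buildEnmHessian(s, cutoff = 20)))
  split <- splitTrivial(ms)
  ev <- eigenvalues(ms)
  expect_lt(max(abs(ev[1:6])), 1e-8 * max(ev))
  expect_true(all(split$rigidOverlap >= 0.99))
  expect_equal(length(eigenvalues(split$nontrivial)), length(ev) - 6L)
  expect_equal(split$nontrivial@nTrivial, 0L)
  # linear diatomic: 5 rigid degrees of freedom, one genuine stretch
  msd <- eigenModes(massWeight(buildEnmHessian(diatomic(), cutoff = 5)))
  expect_length(eigenvalues(splitTrivial(msd, nTrivial = 5)$nontrivial), 1L)
})

test_that("harmonic trajectories oscillate with exact quarter-period amplitude", {
  spec <- smallSpec()
  s <- makeToyDimer(spec)
  ms <- eigenModes(massWeight(buildEnmHessian(s, cutoff = 20)))
  static <- harmonicTrajectory(s, ms, 7, amplitude = 0, nFrames = 8)
  expect_equal(static@coords, matrix(as.vector(t(coords(s))), 8,
                                     3 * nAtoms(s), byrow = TRUE))
  amp <- 2.5
  tr <- harmonicTrajectory(s, ms, 7, amplitude = amp, nFrames = 16)
  d <- cartMode(ms, 7)
  expect_equal(tr@coords[5, ] - tr@coords[1, ], amp * d, tolerance = 1e-10)
  # PCA of the harmonic frames recovers the mode direction
  pc <- pcaModes(covarianceMatrix(Trajectory(s, tr@coords), 1:nAtoms(s),
                                  align = FALSE))
  expect_gt(innerProduct(eigenvectors(pc)[, 1], d), 0.999)
})

test_that("thermal ensembles respect counts, the T -> 0 limit and equipartition", {
  spec <- smallSpec()
  s <- makeToyDimer(spec)
  ms <- eigenModes(massWeight(buildEnmHessian(s, cutoff = 20)))
  ens <- thermalEnsemble(s, ms, modes = 7L, nConf = 5000L, seed = 5)
  expect_equal(nFrames(ens), 5000L)
  cold <- thermalEnsemble(s, ms, modes = 7L, temperature = 0, nConf = 3L,
                          seed = 5)
  expect_equal(max(abs(sweep(cold@coords, 2,
                             as.vector(t(coords(s)))))), 0)
  expect_error(thermalEnsemble(s, ms, modes = 3L), "trivial")
  # mass-weighted variance along the mode equals kB T / lambda
  kB <- 0.0083144621
  lam <- eigenvalues(ms)[7]
  disp <- sweep(ens@coords, 2, as.vector(t(coords(s))))
  proj <- disp %*% (eigenvectors(ms)[, 7] * sqrt(rep(masses(s), each = 3)))
  expect_equal(var(as.numeric(proj)) * (5000 - 1) / 5000, kB * 300 / lam,
               tolerance = 0.05)
  # reproducibility by seed
  ens2 <- thermalEnsemble(s, ms, modes = 7L, nConf = 10L, seed = 42)
  ens3 <- thermalEnsemble(s, ms, modes = 7L, nConf = 10L, seed = 42)
  expect_identical(ens2@coords, ens3@coords)
})

test_that("Hessian export/import round trips to an identical mode set", {
  s <- makeToyDimer(smallSpec(nRes = 10L, kDom = 6L))
  ca <- selectAtoms(s, "name CA")
  h <- buildEnmHessian(s, ca, cutoff = 20)
  f <- withr::local_tempfile(fileext = ".txt")
  exportHessian(h, f)
  sub <- Structure(atomData(s)[as.integer(ca), ],
                   coords(s)[as.integer(ca), ])
  h2 <- importHessian(f, sub)
  expect_identical(h2@matrix, h@matrix)
  expect_equal(eigenvalues(eigenModes(h2)), eigenvalues(eigenModes(h)))
  wrong <- makeToyDimer(smallSpec())
  expect_error(importHessian(f, wrong), "size mismatch")
  bad <- matrix(seq_len(36), 6)   # asymmetric 6x6 for a 2-atom structure
  writeLines(apply(bad, 1, function(r) paste(r, collapse = " ")), f)
  expect_error(importHessian(f, diatomic()), "asymmetric")
})
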