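# Shared fixtures and independent oracles, all built in code.

# A small, connected synthetic dimer recipe (compact uniform clouds; unit
# tests pair it with a generous 20 A network cutoff to keep it rigid).
smallSpec <- function(nRes = 40L, kDom = 24L, nFrames = 400L, frameDt = 20,
                      seed = 7L, ...) {
  syntheticSpec(nResPerSubunit = nRes, kDomainSize = kDom, cloudRadius = 5,
                domainSpacing = 22, nFrames = nFrames, frameDt = frameDt,
                seed = seed, ...)
}

# xyz column indices of atom indices in the flat 3N layout
xyzIdx <- function(idx) as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))

# De-mass-weight a mode column to a unit Cartesian displacement (oracle-side
# counterpart of the package-internal conversion).
cartMode <- function(ms, mode) {
  v <- eigenvectors(ms)[, mode]
  if (ms@massWeighted) v <- v / sqrt(rep(ms@masses, each = 3))
  v / sqrt(sum(v^2))
}

# Restrict a 3N vector to an atom subset and renormalise.
restrictVec <- function(v, idx) {
  w <- v[xyzIdx(as.integer(idx))]
  w / sqrt(sum(w^2))
}

# Quaternion -> rotation matrix
quatRot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force quaternion-search oracle for the minimal superposition RMSD,
# independent of the SVD route used by kabsch().
oracleRmsd <- function(mobile, reference, nStarts = 150) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) {
    R <- quatRot(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- Inf
  for (i in seq_len(nStarts)) {
    r <- stats::optim(stats::rnorm(4), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
    if (r$value < best) best <- r$value
  }
  best
}

# A random proper rotation + translation
randomRigid <- function() {
  list(R = quatRot(stats::rnorm(4)), t = stats::rnorm(3, sd = 5))
}

applyRigid <- function(coords, rig) {
  sweep(coords %*% rig$R, 2, -rig$t)
}
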