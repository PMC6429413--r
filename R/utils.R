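# Internal helpers shared across modules.

# Run fun() under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  fun()
}

# Indices of frames whose time falls in [start, end) (default) or [start, end].
.framesInWindow <- function(times, window, closed = FALSE) {
  if (is.null(window)) return(seq_along(times))
  stopifnot(length(window) == 2)
  if (window[2] < window[1]) stop("window end precedes window start")
  if (closed) which(times >= window[1] & times <= window[2])
  else which(times >= window[1] & times < window[2])
}

.asIndexSet <- function(idx, structure = NULL, label = "indices") {
  if (is(idx, "AtomIndexSet")) {
    out <- idx
  } else {
    out <- new("AtomIndexSet", as.integer(idx), label = label)
  }
  if (!is.null(structure) && length(out) && max(out) > nAtoms(structure))
    stop("atom index exceeds structure size (", nAtoms(structure), " atoms)")
  out
}

# Expand atom indices to xyz column indices of the flat 3N layout.
.xyzIndices <- function(idx) {
  as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}

.flatten <- function(coords) as.vector(t(coords))        # N x 3 -> 3N
.unflatten <- function(v) matrix(v, ncol = 3, byrow = TRUE) # 3N -> N x 3

# Fix eigenvector signs so the largest-magnitude component is positive.
.normalizeSigns <- function(vectors) {
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  vectors
}

# Orthonormal rigid-body basis (3 translations + 3 rotations about the
# centroid), optionally in mass-weighted coordinates. Returns 3N x 6.
.rigidBodyBasis <- function(refCoords, masses = NULL) {
  n <- nrow(refCoords)
  w <- if (is.null(masses)) rep(1, n) else masses
  com <- colSums(refCoords * w) / sum(w)
  rel <- sweep(refCoords, 2, com)
  basis <- matrix(0, 3 * n, 6)
  sq <- sqrt(w)
  for (a in 1:3) basis[seq(a, 3 * n, by = 3), a] <- sq
  axes <- diag(3)
  for (a in 1:3) {
    rot <- t(apply(rel, 1, function(r) crossprod3(axes[a, ], r)))
    basis[, 3 + a] <- .flatten(rot * sq)
  }
  # rank-aware: a linear molecule has only 5 rigid-body degrees of freedom
  dec <- qr(basis)
  qr.Q(dec)[, seq_len(dec$rank), drop = FALSE]
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Leading eigenpairs of the covariance of a centred frame matrix Xc
# (F x d, population normalisation) by blocked subspace iteration on the
# implicit operator v -> t(Xc) (Xc v) / F. Avoids forming the d x d matrix.
.topComponents <- function(Xc, k = 2, maxIter = 200, tol = 1e-12) {
  f <- nrow(Xc)
  d <- ncol(Xc)
  k <- min(k, d, f)
  # deterministic start inside the row space: the first k frames
  V <- t(Xc[seq_len(min(k, f)), , drop = FALSE])
  if (ncol(V) < k) V <- cbind(V, matrix(1, d, k - ncol(V)))
  V <- qr.Q(qr(V))[, seq_len(k), drop = FALSE]
  lam <- rep(0, k)
  for (it in seq_len(maxIter)) {
    W <- crossprod(Xc, Xc %*% V) / f
    newLam <- colSums(V * W)
    V <- qr.Q(qr(W))[, seq_len(k), drop = FALSE]
    if (max(abs(newLam - lam)) <= tol * max(newLam[1], .Machine$double.eps))
      { lam <- newLam; break }
    lam <- newLam
  }
  # Rayleigh-Ritz refinement in the converged subspace
  B <- crossprod(Xc %*% V) / f
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- V %*% e$vectors
  list(values = pmax(e$values, 0), vectors = .normalizeSigns(V))
}
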