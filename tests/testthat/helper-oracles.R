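# Independent brute-force oracles for the texture-matrix builders and the
# stepwise search. Written as naive enumerations (explicit voxel loops,
# exhaustive subset search) so they share no code with the implementation.

bfOffsets13 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    o <- c(dx, dy, dz)
    if (all(o == 0)) next
    nz <- o[o != 0]
    if (nz[1] > 0) out[[length(out) + 1]] <- o
  }
  out
}

bfInside <- function(d, v) all(v >= 1) && all(v <= d)

bfGLCM <- function(lev, ng, o) {
  d <- dim(lev)
  M <- matrix(0L, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (s in c(1, -1)) {
      v <- c(x, y, z) + s * o
      if (!bfInside(d, v)) next
      b <- lev[v[1], v[2], v[3]]
      if (!is.na(b)) M[a, b] <- M[a, b] + 1L
    }
  }
  M
}

bfGLRLM <- function(lev, ng, o) {
  d <- dim(lev)
  runs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    prev <- c(x, y, z) - o
    if (bfInside(d, prev) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == a) next   # not a run start
    len <- 1
    v <- c(x, y, z) + o
    while (bfInside(d, v) && !is.na(lev[v[1], v[2], v[3]]) &&
             lev[v[1], v[2], v[3]] == a) {
      len <- len + 1
      v <- v + o
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  runs <- do.call(rbind, runs)
  R <- matrix(0L, ng, max(runs[, 2]))
  for (k in seq_len(nrow(runs)))
    R[runs[k, 1], runs[k, 2]] <- R[runs[k, 1], runs[k, 2]] + 1L
  R
}

## queue-based flood fill, 26-connectivity, same level
bfZones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    start <- idx[k, ]
    if (seen[start[1], start[2], start[3]]) next
    a <- lev[start[1], start[2], start[3]]
    queue <- list(start)
    seen[start[1], start[2], start[3]] <- TRUE
    members <- list()
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members[[length(members) + 1]] <- v
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- v + c(dx, dy, dz)
        if (!bfInside(d, w) || seen[w[1], w[2], w[3]]) next
        b <- lev[w[1], w[2], w[3]]
        if (!is.na(b) && b == a) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <-
      list(level = a, members = do.call(rbind, members))
  }
  zones
}

## minimal Chebyshev distance to a non-ROI voxel (outside grid counts)
bfDistance <- function(lev, v) {
  d <- dim(lev)
  edge <- min(v, d - v + 1)
  best <- edge
  nonroi <- which(is.na(lev), arr.ind = TRUE)
  if (nrow(nonroi)) {
    cheb <- apply(nonroi, 1, function(w) max(abs(w - v)))
    best <- min(best, cheb)
  }
  best
}

bfGLSZM <- function(lev, ng) {
  z <- bfZones(lev)
  sizes <- vapply(z, function(zz) nrow(zz$members), numeric(1))
  S <- matrix(0L, ng, max(sizes))
  for (zz in z) {
    s <- nrow(zz$members)
    S[zz$level, s] <- S[zz$level, s] + 1L
  }
  S
}

bfGLDZM <- function(lev, ng) {
  z <- bfZones(lev)
  dists <- vapply(z, function(zz)
    min(apply(zz$members, 1, function(v) bfDistance(lev, v))), numeric(1))
  D <- matrix(0L, ng, max(dists))
  for (k in seq_along(z))
    D[z[[k]]$level, dists[k]] <- D[z[[k]]$level, dists[k]] + 1L
  D
}

bfNeighbours <- function(lev, v) {
  d <- dim(lev)
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    w <- v + c(dx, dy, dz)
    if (bfInside(d, w) && !is.na(lev[w[1], w[2], w[3]]))
      out <- c(out, lev[w[1], w[2], w[3]])
  }
  out
}

bfNGTDM <- function(lev, ng) {
  idx <- which(!is.na(lev), arr.ind = TRUE)
  n_i <- integer(ng); s_i <- numeric(ng)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    nb <- bfNeighbours(lev, v)
    if (!length(nb)) next
    a <- lev[v[1], v[2], v[3]]
    n_i[a] <- n_i[a] + 1L
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  data.frame(level = seq_len(ng), n = n_i, s = s_i)
}

bfNGLDM <- function(lev, ng) {
  idx <- which(!is.na(lev), arr.ind = TRUE)
  recs <- matrix(0L, nrow(idx), 2)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    a <- lev[v[1], v[2], v[3]]
    nb <- bfNeighbours(lev, v)
    recs[k, ] <- c(a, sum(nb == a) + 1L)
  }
  S <- matrix(0L, ng, max(recs[, 2]))
  for (k in seq_len(nrow(recs)))
    S[recs[k, 1], recs[k, 2]] <- S[recs[k, 1], recs[k, 2]] + 1L
  S
}

## random small ROI: levels 1..ng with NA holes, guaranteed non-empty
randomROI <- function(ng, maxdim = 6) {
  d <- sample(2:maxdim, 3, replace = TRUE)
  lev <- array(sample(1:ng, prod(d), replace = TRUE), d)
  lev[stats::runif(prod(d)) < 0.3] <- NA
  if (all(is.na(lev))) lev[1] <- 1L
  lev
}

asDroi <- function(lev, ng) {
  structure(list(levels = lev, ng = as.integer(ng),
                 n_voxels = sum(!is.na(lev))), class = "DiscretizedROI")
}

## exhaustive best-subset search by AIC (gaussian), intercept always in
bfBestSubsetAIC <- function(X, y) {
  p <- ncol(X)
  n <- length(y)
  best <- NULL
  for (mask in 0:(2^p - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    Xm <- cbind(1, X[, cols, drop = FALSE])
    fit <- stats::lm.fit(Xm, y)
    rss <- sum(fit$residuals^2)
    k <- length(cols) + 1
    aic <- n * log(2 * pi) + n * log(rss / n) + n + 2 * (k + 1)
    if (is.null(best) || aic < best$aic)
      best <- list(cols = cols, aic = aic)
  }
  best
}
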