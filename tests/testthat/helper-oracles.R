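# Brute-force oracles and shared fixtures. Oracles are deliberately naive
# (explicit loops / direct formulas) and independent of the implementation
# paths they check.

# squared mm distance from every voxel to the nearest mask voxel, by
# exhaustive pairwise search
bruteDistSq <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  src <- which(mask > 0, arr.ind = TRUE)
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  out <- apply(co, 1, function(p) {
    min(colSums(((t(src) - p) * spacing)^2))
  })
  array(out, dim = d)
}

brutePsnr <- function(y, yhat, mask) {
  idx <- which(mask > 0)
  s <- 0
  for (i in idx) s <- s + (y[i] - yhat[i])^2
  10 * log10(max(y[idx])^2 / (s / length(idx)))
}

bruteRelMean <- function(y, yhat, mask, absolute) {
  idx <- which(mask > 0)
  floor <- 0.01 * mean(y[idx])
  acc <- 0
  n <- 0
  for (i in idx) {
    if (y[i] > floor) {
      r <- (yhat[i] - y[i]) / y[i]
      acc <- acc + if (absolute) abs(r) else r
      n <- n + 1
    }
  }
  100 * acc / n
}

bruteFit <- function(y, yhat, mask) {
  idx <- which(mask > 0)
  yv <- y[idx]
  yh <- yhat[idx]
  sxx <- sum((yv - mean(yv))^2)
  sxy <- sum((yv - mean(yv)) * (yh - mean(yh)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(yh) - slope * mean(yv),
       r2 = sxy^2 / (sxx * sum((yh - mean(yh))^2)))
}

bruteFuse <- function(patches, positions, profile, S) {
  hw <- dim(patches[[1]])[2:3]
  out <- array(0, dim = c(S, hw))
  for (s in 1:S) for (a in 1:hw[1]) for (b in 1:hw[2]) {
    num <- 0
    den <- 0
    for (i in seq_along(patches)) {
      off <- s - positions[i] + 1L
      if (off >= 1 && off <= length(profile)) {
        num <- num + profile[off] * patches[[i]][off, a, b]
        den <- den + profile[off]
      }
    }
    out[s, a, b] <- num / den
  }
  out
}

# double-precision reference of the U-Net generator forward pass
refShift3 <- function(A, dz, dy, dx) {
  d <- dim(A)
  out <- array(0, d)
  ds <- max(1, 1 - dz):min(d[2], d[2] - dz)
  hs <- max(1, 1 - dy):min(d[3], d[3] - dy)
  ws <- max(1, 1 - dx):min(d[4], d[4] - dx)
  out[, ds, hs, ws] <- A[, ds + dz, hs + dy, ws + dx, drop = FALSE]
  out
}
refConv3 <- function(x, Wv, bv, cin, cout, dm) {
  A <- array(x, c(cin, dm))
  Wm <- matrix(Wv, nrow = cout)
  Y <- matrix(rep(bv, prod(dm)), nrow = cout)
  k <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    XS <- matrix(refShift3(A, dz, dy, dx), nrow = cin)
    Y <- Y + Wm[, (k * cin + 1):((k + 1) * cin), drop = FALSE] %*% XS
    k <- k + 1
  }
  Y
}
refLrelu <- function(x) ifelse(x < 0, 0.2 * x, x)
refPool <- function(X, dm) {
  A <- array(X, c(nrow(X), dm))
  out <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    out <- out + A[, seq(1 + dz, dm[1], 2), seq(1 + dy, dm[2], 2),
                   seq(1 + dx, dm[3], 2), drop = FALSE]
  matrix(out / 8, nrow = nrow(X))
}
refUp <- function(X, dmIn) {
  A <- array(X, c(nrow(X), dmIn))
  matrix(A[, rep(seq_len(dmIn[1]), each = 2), rep(seq_len(dmIn[2]), each = 2),
           rep(seq_len(dmIn[3]), each = 2), drop = FALSE], nrow = nrow(X))
}
refUnet <- function(wts, cin, ch, x, dm) {
  L <- length(ch)
  i <- 1
  nextW <- function() {
    w <- wts[[i]]
    i <<- i + 1
    w
  }
  encW <- lapply(1:L, function(l) list(W = nextW(), b = nextW()))
  redW <- if (L > 1) lapply(1:(L - 1), function(j)
    list(W = nextW(), b = nextW())) else list()
  decW <- if (L > 1) lapply(1:(L - 1), function(j)
    list(W = nextW(), b = nextW())) else list()
  outW <- list(W = nextW(), b = nextW())
  A <- list()
  dims <- list(dm)
  A[[1]] <- refLrelu(refConv3(x, encW[[1]]$W, encW[[1]]$b, cin, ch[1], dm))
  if (L > 1) for (l in 2:L) {
    dims[[l]] <- dims[[l - 1]] %/% 2
    P <- refPool(A[[l - 1]], dims[[l - 1]])
    A[[l]] <- refLrelu(refConv3(P, encW[[l]]$W, encW[[l]]$b, ch[l - 1],
                                ch[l], dims[[l]]))
  }
  U <- A[[L]]
  if (L > 1) for (j in (L - 1):1) {
    C <- rbind(refUp(U, dims[[j + 1]]), A[[j]])
    R <- refLrelu(matrix(redW[[j]]$W, nrow = ch[j]) %*% C + redW[[j]]$b)
    U <- refLrelu(refConv3(R, decW[[j]]$W, decW[[j]]$b, ch[j], ch[j],
                           dims[[j]]))
  }
  as.vector(matrix(outW$W, nrow = 1) %*% U + outW$b)
}

# fixtures shared across test files (built once per test run)
.fixtures <- new.env(parent = emptyenv())
fixturePhantom <- function(key = "clean64") {
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  ph <- switch(key,
    clean64 = generatePhantom(phantomParams(gridSize = 64, noiseSd = 0,
                                            biasAmplitude = 0, seed = 11)),
    noisy64 = generatePhantom(phantomParams(gridSize = 64, seed = 11)),
    stop("unknown fixture"))
  .fixtures[[key]] <- ph
  ph
}
fixtureNormalized <- function(key = "clean64") {
  nk <- paste0("norm_", key)
  if (!is.null(.fixtures[[nk]])) return(.fixtures[[nk]])
  .fixtures[[nk]] <- preprocessSubject(fixturePhantom(key))
  .fixtures[[nk]]
}
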