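## Independent brute-force oracles and fixture builders. These deliberately
## avoid the package's own code paths: plain loops, direct formulas.

## minimum distance between two pixel sets, double loop
bruteMinDist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < best) best <- d
  }
  best
}

## surface voxels by explicit 6-neighbor scan
bruteSurface <- function(mask) {
  d <- dim(mask)
  out <- NULL
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
              c(0, 0, -1), c(0, 0, 1))
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    isSurf <- FALSE
    for (j in 1:6) {
      q <- p + nb[j, ]
      if (any(q < 1) || any(q > d) || !mask[q[1], q[2], q[3]]) {
        isSurf <- TRUE; break
      }
    }
    if (isSurf) out <- rbind(out, p)
  }
  out
}

## linear-interpolation percentile written out by hand
brutePercentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

## HD95 from scratch: brute surfaces, all-pairs directed mins, pooled
bruteHD95 <- function(maskP, maskG) {
  P <- bruteSurface(maskP); G <- bruteSurface(maskG)
  dPG <- vapply(seq_len(nrow(P)), function(i)
    min(sqrt(colSums((t(G) - P[i, ])^2))), numeric(1))
  dGP <- vapply(seq_len(nrow(G)), function(i)
    min(sqrt(colSums((t(P) - G[i, ])^2))), numeric(1))
  brutePercentile(c(dPG, dGP), 0.95)
}

bruteHausdorff <- function(maskP, maskG) {
  P <- bruteSurface(maskP); G <- bruteSurface(maskG)
  dPG <- vapply(seq_len(nrow(P)), function(i)
    min(sqrt(colSums((t(G) - P[i, ])^2))), numeric(1))
  dGP <- vapply(seq_len(nrow(G)), function(i)
    min(sqrt(colSums((t(P) - G[i, ])^2))), numeric(1))
  max(max(dPG), max(dGP))
}

## AUC straight from its probabilistic definition:
## P(pos > neg) + 0.5 P(pos == neg) over all pairs
bruteAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

## random connected-ish pixel blob in a (h, w) slice: seeded random walk
randomBlob <- function(n, h = 40, w = 40, start = c(20, 20)) {
  pix <- matrix(start, ncol = 2)
  while (nrow(pix) < n) {
    from <- pix[sample.int(nrow(pix), 1), ]
    step <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample.int(4, 1), ]
    p <- pmin(pmax(from + step, 1), c(h, w))
    pix <- unique(rbind(pix, p))
  }
  pix
}

## random small 3D mask inside a given shape
randomMask3D <- function(nvox, d = c(6, 12, 12)) {
  m <- array(FALSE, dim = d)
  p <- c(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1))
  m[p[1], p[2], p[3]] <- TRUE
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
              c(0, 0, -1), c(0, 0, 1))
  while (sum(m) < nvox) {
    idx <- which(m, arr.ind = TRUE)
    from <- idx[sample.int(nrow(idx), 1), ]
    q <- pmin(pmax(from + nb[sample.int(6, 1), ], 1), d)
    m[q[1], q[2], q[3]] <- TRUE
  }
  m
}

## LabelVolume with the given logical masks (PV may be absent)
volumeFromMasks <- function(la, pv = NULL, caseId = "fixture") {
  v <- array(0L, dim = dim(la))
  v[la] <- 1L
  if (!is.null(pv)) {
    stopifnot(!any(la & pv))
    v[pv] <- 2L
  }
  LabelVolume(v, caseId = caseId)
}

## one-slice volume from explicit pixel coordinate sets
sliceVolume <- function(pvPix, laPix, h = 32, w = 32) {
  v <- array(0L, dim = c(1, h, w))
  v[cbind(1, laPix[, 1], laPix[, 2])] <- 1L
  v[cbind(1, pvPix[, 1], pvPix[, 2])] <- 2L
  LabelVolume(v)
}

## horizontal PV bar pixel set (thickness x length), top-left at (r0, c0)
barPixels <- function(r0, c0, thickness = 3, len = 9) {
  as.matrix(expand.grid(row = r0 + seq_len(thickness) - 1,
                        col = c0 + seq_len(len) - 1))
}
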