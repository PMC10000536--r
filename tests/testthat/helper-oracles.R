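# Independent brute-force oracles and fixture recipes. Everything here is
# deliberately naive (double loops, flood fill, pairwise distances) so the
# package's optimized implementations are checked against a second route.

# Kapur entropy by direct double loop over classes and gray levels
naiveKapur <- function(p, thresholds) {
  bounds <- c(-1L, as.integer(thresholds), 255L)
  total <- 0
  for (i in seq_len(length(thresholds) + 1L)) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
    if (lo > hi) next
    A <- sum(p[(lo:hi) + 1L])
    if (A <= 0) next
    H <- 0
    for (j in lo:hi) {
      pj <- p[j + 1L]
      if (pj > 0) H <- H - (pj / A) * log(pj / A)
    }
    total <- total + H
  }
  total
}

# dilation as an explicit pairwise-distance test
naiveDilate <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1L, arr.ind = TRUE)
  out <- matrix(0L, h, w)
  if (!nrow(fg)) return(out)
  rows <- rep(seq_len(h), times = w)
  cols <- rep(seq_len(w), each = h)
  d2 <- outer(rows, fg[, 1L], "-")^2 + outer(cols, fg[, 2L], "-")^2
  out[matrix(rowSums(d2 <= radius^2) > 0, h, w)] <- 1L
  out
}

# stack-based flood-fill labelling
naiveLabel <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  off <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
         else list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] != 1L || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in off) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] == 1L && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

naiveRemoveSmall <- function(mask, minArea, connectivity = 8) {
  lab <- naiveLabel(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab > 0L & sizes[pmax(lab, 1L)] >= minArea] <- 1L
  out
}

# hole filling by 4-connected flood from the border of the complement
naiveFillHoles <- function(mask) {
  bg <- matrix(as.integer(mask == 0L), nrow(mask), ncol(mask))
  lab <- naiveLabel(bg, connectivity = 4)
  h <- nrow(mask); w <- ncol(mask)
  borderLabs <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  borderLabs <- borderLabs[borderLabs > 0L]
  out <- mask
  out[lab > 0L & !(lab %in% borderLabs)] <- 1L
  out
}

# random blob-plus-salt binary masks for property tests
randomMask <- function(h = 32, w = 32) {
  m <- matrix(rbinom(h * w, 1, 0.25), h, w)
  nrect <- sample(0:2, 1)
  for (q in seq_len(nrect)) {
    r0 <- sample(h - 6, 1); c0 <- sample(w - 6, 1)
    m[r0:(r0 + sample(3:6, 1)), c0:(c0 + sample(3:6, 1))] <- 1L
  }
  storage.mode(m) <- "integer"
  m
}

# well-separated 3-mode mixture landscapes for optimizer/oracle comparisons:
# mode gaps of at least ~3 sigma so the modes are genuinely distinct
mixtureSuite <- function(n = 10, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m1 <- runif(1, 25, 75)
    m2 <- m1 + runif(1, 45, 80)
    m3 <- m2 + runif(1, 45, 80)
    s <- runif(3, 8, 16)
    w <- runif(3, 0.5, 1.5); w <- w / sum(w)
    makeMixtureHistogram(w, c(m1, m2, m3), s)
  })
}

# random histogram with full support (for metric/fitness property tests)
randomHistogram <- function() {
  p <- rexp(256)
  p / sum(p)
}
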