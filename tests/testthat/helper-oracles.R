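# Independent reference implementations used as oracles. These are written
# directly from the documented contracts as literal per-pixel / per-element
# loops and share no code with the package internals.

# plain global histogram equalization: out = cdf(bin(v)) / N
global_he_oracle <- function(img, n_bins = 256) {
  bins <- pmin(floor(img * n_bins), n_bins - 1)
  counts <- tabulate(bins + 1L, nbins = n_bins)
  cdf <- cumsum(counts) / length(img)
  matrix(cdf[bins + 1L], nrow(img), ncol(img))
}

# brute-force CLAHE of the same contract (uniform target shape)
clahe_oracle <- function(img, num_tiles = c(8, 8), clip_limit = 0.01,
                         n_bins = 256) {
  H <- nrow(img); W <- ncol(img)
  tr <- num_tiles[1]; tc <- num_tiles[2]
  bh <- H %/% tr; bw <- W %/% tc
  row_lo <- (seq_len(tr) - 1) * bh + 1
  row_hi <- c(seq_len(tr - 1) * bh, H)
  col_lo <- (seq_len(tc) - 1) * bw + 1
  col_hi <- c(seq_len(tc - 1) * bw, W)
  cen_r <- (row_lo + row_hi) / 2
  cen_c <- (col_lo + col_hi) / 2

  tile_map <- function(vals) {
    counts <- rep(0, n_bins)
    for (v in vals) {
      b <- min(floor(v * n_bins), n_bins - 1) + 1
      counts[b] <- counts[b] + 1
    }
    clip <- ceiling(clip_limit * length(vals))
    repeat {
      excess <- sum(pmax(counts - clip, 0))
      if (excess < 1) break
      counts <- pmin(counts, clip) + excess / n_bins
    }
    cumsum(counts) / length(vals)
  }
  maps <- vector("list", tr * tc)
  for (i in seq_len(tr))
    for (j in seq_len(tc))
      maps[[(i - 1) * tc + j]] <-
        tile_map(as.vector(img[row_lo[i]:row_hi[i], col_lo[j]:col_hi[j]]))

  axis_pos <- function(x, centers) {
    n <- length(centers)
    if (n == 1 || x <= centers[1]) return(c(1, 1, 0))
    if (x >= centers[n]) return(c(n - 1, n, 1))
    i <- max(which(centers <= x))
    c(i, i + 1, (x - centers[i]) / (centers[i + 1] - centers[i]))
  }
  out <- img
  for (r in seq_len(H)) {
    rp <- axis_pos(r, cen_r)
    for (c in seq_len(W)) {
      cp <- axis_pos(c, cen_c)
      b <- min(floor(img[r, c] * n_bins), n_bins - 1) + 1
      m <- function(i, j) maps[[(i - 1) * tc + j]][b]
      out[r, c] <-
        (1 - rp[3]) * (1 - cp[3]) * m(rp[1], cp[1]) +
        (1 - rp[3]) * cp[3]       * m(rp[1], cp[2]) +
        rp[3]       * (1 - cp[3]) * m(rp[2], cp[1]) +
        rp[3]       * cp[3]       * m(rp[2], cp[2])
    }
  }
  out
}

# triple-loop non-local means of the same contract
nlm_oracle <- function(img, kr = 4, wr = 4, h = 0.05) {
  H <- nrow(img); W <- ncol(img); P <- kr + wr
  mirror <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  pad <- img[mirror(seq(1 - P, H + P), H), mirror(seq(1 - P, W + P), W)]
  sigma <- kr / 2
  g1 <- exp(-((-kr:kr)^2) / (2 * sigma^2))
  G <- outer(g1, g1); G <- G / sum(G)
  out <- img
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rp <- r + P; cp <- c + P
      p0 <- pad[(rp - kr):(rp + kr), (cp - kr):(cp + kr)]
      num <- 0; den <- 0; mw <- 0
      for (dy in -wr:wr) {
        for (dx in -wr:wr) {
          if (dx == 0 && dy == 0) next
          pj <- pad[(rp + dy - kr):(rp + dy + kr), (cp + dx - kr):(cp + dx + kr)]
          w <- exp(-sum(G * (p0 - pj)^2) / h^2)
          num <- num + w * pad[rp + dy, cp + dx]
          den <- den + w
          mw <- max(mw, w)
        }
      }
      out[r, c] <- (num + mw * pad[rp, cp]) / (den + mw)
    }
  }
  out
}

# brute-force nearest neighbour under L2, ties to the lowest index
brute_nn <- function(x, centers) {
  apply(x, 1, function(q) which.min(colSums((t(centers) - q)^2)))
}

# bilinear rotation about the image center (inverse mapping); samples
# falling outside the source are filled with `bg`
rotate_bilinear <- function(img, angle, bg = 0) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  out <- matrix(bg, H, W)
  ca <- cos(angle); sa <- sin(angle)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      # destination offset rotated back into the source frame
      dx <- c - cx; dy <- r - cy
      sx <- ca * dx + sa * dy + cx
      sy <- -sa * dx + ca * dy + cy
      x0 <- floor(sx); y0 <- floor(sy)
      if (x0 < 1 || y0 < 1 || x0 + 1 > W || y0 + 1 > H) next
      fx <- sx - x0; fy <- sy - y0
      out[r, c] <- (1 - fy) * ((1 - fx) * img[y0, x0] + fx * img[y0, x0 + 1]) +
                   fy * ((1 - fx) * img[y0 + 1, x0] + fx * img[y0 + 1, x0 + 1])
    }
  }
  out
}
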