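# Independent oracles and shared fixtures, built in code at test time.

# digitized disk mask of radius r (pixel-centre rule)
make_disk <- function(r, side = 2 * r + 21, center = (side - 1) / 2) {
  xs <- matrix(rep(0:(side - 1), each = side), side, side)
  ys <- t(xs)
  binary_mask((xs - center)^2 + (ys - center)^2 <= r^2)
}

make_square <- function(s, margin = 10) {
  side <- s + 2 * margin
  m <- matrix(FALSE, side, side)
  m[(margin + 1):(margin + s), (margin + 1):(margin + s)] <- TRUE
  binary_mask(m)
}

# brute-force rolling-ball oracle: grayscale erosion then dilation with a
# hemispherical structuring element, written as plain double loops over ball
# placements (independent of the package's C++ kernels)
oracle_rolling_ball <- function(img, radius) {
  r <- floor(radius)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  h <- sqrt(radius^2 - offs$di^2 - offs$dj^2)
  H <- nrow(img); W <- ncol(img)
  ero <- matrix(NA_real_, H, W)
  for (i in 1:H) for (j in 1:W) {
    best <- Inf
    for (q in seq_len(nrow(offs))) {
      ii <- i + offs$di[q]; jj <- j + offs$dj[q]
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      best <- min(best, img[ii, jj] - h[q])
    }
    ero[i, j] <- best
  }
  bg <- matrix(NA_real_, H, W)
  for (i in 1:H) for (j in 1:W) {
    best <- -Inf
    for (q in seq_len(nrow(offs))) {
      ii <- i + offs$di[q]; jj <- j + offs$dj[q]
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      best <- max(best, ero[ii, jj] + h[q])
    }
    bg[i, j] <- best
  }
  pmax(img - bg, 0)
}

# brute-force optimal frame-to-frame assignment (all permutations);
# returns per-frame correspondence lists for small scenes
oracle_assignment <- function(prev, cur) {
  na <- nrow(prev); nb <- nrow(cur)
  stopifnot(na == nb, na <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(nb))) {
    cost <- sum(sqrt(rowSums((prev - cur[p, , drop = FALSE])^2)))
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

# permutation test on joint ranks: two-sided p for each group pair using the
# absolute mean-rank difference as statistic; permuting group labels is
# equivalent to permuting the rank vector over fixed index segments
oracle_rank_permutation <- function(groups, n_perm = 1e4, seed = 1) {
  sizes <- lengths(groups)
  r <- rank(unlist(groups, use.names = FALSE))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  k <- length(groups)
  prs <- utils::combn(k, 2)
  mean_ranks <- function(rr)
    vapply(seq_len(k), function(i) mean(rr[starts[i]:ends[i]]), numeric(1))
  stat <- function(rr) {
    mr <- mean_ranks(rr)
    abs(mr[prs[1, ]] - mr[prs[2, ]])
  }
  o <- stat(r)
  set.seed(seed)
  count <- rep(0, ncol(prs))
  for (b in seq_len(n_perm))
    count <- count + (stat(sample(r)) >= o - 1e-12)
  (count + 1) / (n_perm + 1)
}

# tolerance-band mask comparison: a within [erode^k(b), dilate^k(b)]
within_band <- function(a, b, k) {
  lo <- b; hi <- b
  for (i in seq_len(k)) {
    lo <- platemorph:::binary_erode1(lo)
    hi <- platemorph:::binary_dilate1(hi)
  }
  all(a[!hi] == FALSE) && all(a[lo] == TRUE)
}
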