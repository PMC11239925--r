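# Independent brute-force oracles used across the suite.

# all-pairs nearest-true-pixel Euclidean distance (0-based pixel centers)
bf_distmap <- function(mask) {
  tp <- which(mask, arr.ind = TRUE)          # (row, col) of true pixels
  h <- nrow(mask); w <- ncol(mask)
  dc2 <- outer(tp[, 2], seq_len(w), "-")^2   # per true pixel, per column
  out <- matrix(NA_real_, h, w)
  for (r in seq_len(h)) {
    d2 <- (tp[, 1] - r)^2 + dc2              # recycles down the rows
    out[r, ] <- sqrt(apply(d2, 2, min))
  }
  out
}

# quadratic all-pairs mutual-nearest-neighbor scan; ties to the lowest index
bf_mnn <- function(ax, ay, bx, by) {
  na <- length(ax); nb <- length(bx)
  d <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i, j] <- sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2)
  nn_ab <- apply(d, 1, which.min)
  nn_ba <- apply(d, 2, which.min)
  pairs <- NULL
  for (i in seq_len(na))
    if (nn_ba[nn_ab[i]] == i)
      pairs <- rbind(pairs, c(i, nn_ab[i], d[i, nn_ab[i]]))
  pairs
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
enum_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  u_null <- apply(combos, 2, u_of)
  p <- 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))
  min(p, 1)
}

# wrap a hand-made burst window as a network_bursts object
fake_network_bursts <- function(start_s, end_s, bin_counts, bin_s = 0.02) {
  structure(list(
    bursts = data.frame(start_s = start_s, end_s = end_s,
                        n_bins = lengths(bin_counts),
                        participating = 2L),
    bin_s = bin_s, bin_counts = bin_counts), class = "network_bursts")
}
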