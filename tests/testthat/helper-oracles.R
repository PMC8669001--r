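# Shared fixtures and independent oracles, all built in code.

# circular nucleus mask on a square grid; R in pixels, center at the
# middle of the grid (pixel-center convention)
disk_mask <- function(n, R, cy = n / 2, cx = n / 2) {
  y <- matrix(seq_len(n) - 0.5, n, n)
  x <- t(y)
  (y - cy)^2 + (x - cx)^2 <= R^2
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# brute-force masked pixel-sum ratio: mean over sub-mask / mean over full
oracle_mean_ratio <- function(img, sub, full) {
  (sum(img[sub]) / sum(sub)) / (sum(img[full]) / sum(full))
}

# brute-force min distance (um) from a point to any TRUE pixel center
oracle_min_dist <- function(point_um, mask, pixel_size) {
  dims <- dim(mask)
  nd <- length(dims)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, nd)
  idx <- which(mask)
  ai <- arrayInd(idx, dims)
  centers <- sweep(ai - 0.5, 2, pixel_size, `*`)
  sqrt(min(rowSums(sweep(centers, 2, point_um, `-`)^2)))
}

# exact two-tailed Mann-Whitney p by full enumeration of group
# assignments (tie-free samples; null distribution of U is symmetric)
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (N - n1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

noiseless <- list(photon_scale = 0, sigma = 0)
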