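# Independent brute-force oracles used to validate the implementation.

# spike count as the number of strictly-local maxima above 0 mV
brute_force_spike_count <- function(trace) {
  n <- length(trace)
  if (n < 3) return(0L)
  v <- trace
  sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
        v[2:(n - 1)] > 0)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enumerate_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  # two-sided: as extreme or more extreme in either direction
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# minimal-SSE 2-partition by exhaustive enumeration (n <= ~12)
kmeans_brute_force <- function(points, k = 2) {
  stopifnot(k == 2)
  n <- nrow(points)
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {  # fix point 1 in group 0 (symmetry)
    g <- as.integer(intToBits(mask))[1:n]
    if (all(g == 0) || all(g == 1)) next
    sse <- 0
    for (gr in 0:1) {
      p <- points[g == gr, , drop = FALSE]
      c0 <- colMeans(p)
      sse <- sse + sum(sweep(p, 2, c0)^2)
    }
    if (sse < best_sse) { best_sse <- sse; best <- g }
  }
  list(assignment = best + 1L, sse = best_sse)
}

# Monte-Carlo oracle of the expected sweep-wise PPR of the two-pulse
# availability recursion (independent re-implementation of the release rules)
mc_expected_ppr <- function(syn, ipi = 60, n_draws = 2e5) {
  n <- syn$n_sites; p <- syn$release_prob_baseline
  k1 <- rbinom(n_draws, n, p)
  dep <- rbinom(n_draws, k1, syn$depression_fraction)
  rec <- rbinom(n_draws, dep, 1 - exp(-ipi / syn$recovery_time_constant))
  avail <- n - dep + rec
  p2 <- min(1, p * (1 + syn$facilitation_increment))
  k2 <- rbinom(n_draws, avail, p2)
  ok <- k1 > 0 & k2 > 0
  c(mean = mean(k2[ok] / k1[ok]), sd = sd(k2[ok] / k1[ok]))
}
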