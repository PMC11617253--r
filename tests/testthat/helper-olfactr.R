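# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (loops, enumeration) and never call the package code
# they check.

tiny_panel <- function(n = 8) odor_panel(n)

quick_movie_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, height = 80, width = 100, noise_sd = 0,
               shift_range = 0)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

interior_map <- function(n = 2, side = 15, height = 80, width = 100) {
  cy <- round(seq(height * 0.3, height * 0.7, length.out = n))
  cx <- round(seq(width * 0.3, width * 0.7, length.out = n))
  glomerulus_map(paste0("g", seq_len(n)), cy, cx, side = side,
                 height = height, width = width)
}

# brute-force net response: explicit loop over spike times
oracle_count_response <- function(trial) {
  stim <- 0L; pre <- 0L
  for (k in seq_len(nrow(trial$spikes))) {
    if (!identical(trial$spikes$unit[k], "A")) next
    tm <- trial$spikes$time[k]
    if (tm >= trial$onset && tm < trial$onset + trial$duration)
      stim <- stim + 1L
    if (tm >= trial$onset - trial$duration && tm < trial$onset)
      pre <- pre + 1L
  }
  stim - pre
}

# ANOSIM R from first principles (explicit double loop over pairs)
oracle_anosim_R <- function(x, groups) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  dv <- c(); within <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dv <- c(dv, d[i, j])
    within <- c(within, groups[i] == groups[j])
  }
  rk <- rank(dv)
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# exhaustive-permutation ANOSIM p-value (one-tailed, observed included)
oracle_anosim_exhaustive_p <- function(x, groups) {
  perms <- all_permutations(length(groups))
  obs <- oracle_anosim_R(x, groups)
  stats <- apply(perms, 1, function(idx) oracle_anosim_R(x, groups[idx]))
  mean(stats >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# run the exported spatial filter through a 1-frame stack
medfilt_via_stack <- function(img, width) {
  st <- movie_stack(array(img, c(1, nrow(img), ncol(img))),
                    stim_frames = c(1, 1))
  spatial_median_filter(st, width)$data[1, , ]
}

# naive 2-D median filter with symmetric reflection padding
oracle_median_filter <- function(img, width) {
  p <- (width - 1) / 2
  h <- nrow(img); w <- ncol(img)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- img
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (di in -p:p) for (dj in -p:p)
      vals <- c(vals, img[refl(i + di, h), refl(j + dj, w)])
    out[i, j] <- median(vals)
  }
  out
}
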