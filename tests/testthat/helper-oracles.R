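# Fixtures and independent brute-force oracles used across the suite.

# build a track_set from a list of n x 2 position matrices
make_ts <- function(pos_list, cell_ids = NULL, session_ids = NULL,
                    day_ids = NULL, lengths_nm = 10000, widths_nm = 3000,
                    dt = 10) {
  n <- length(pos_list)
  ids <- sprintf("t%02d", seq_len(n))
  names(pos_list) <- ids
  if (is.null(cell_ids)) cell_ids <- rep("c1", n)
  if (is.null(session_ids))
    session_ids <- paste0("s_", cell_ids)
  if (is.null(day_ids)) day_ids <- paste0("d_", session_ids)
  tracks <- data.frame(track_id = ids, cell_id = cell_ids,
                       session_id = session_ids, day_id = day_ids,
                       stringsAsFactors = FALSE)
  u <- !duplicated(cell_ids)
  cells <- data.frame(cell_id = cell_ids[u], session_id = session_ids[u],
                      day_id = day_ids[u],
                      length_nm = rep_len(lengths_nm, sum(u)),
                      width_nm = rep_len(widths_nm, sum(u)),
                      stringsAsFactors = FALSE)
  track_set(pos_list, tracks, cells, frame_interval_ms = dt)
}

random_walk <- function(n, step_sd = 50, origin = c(5000, 1500)) {
  cbind(origin[1] + cumsum(rnorm(n, 0, step_sd)),
        origin[2] + cumsum(rnorm(n, 0, step_sd)))
}

# brute-force nonoverlapping-window MSD: explicit window walk
oracle_msd <- function(m, k) {
  n <- nrow(m)
  sq <- c()
  i <- 1L
  while (i + k <= n) {
    sq <- c(sq, (m[i + k, 1] - m[i, 1])^2 + (m[i + k, 2] - m[i, 2])^2)
    i <- i + k
  }
  if (!length(sq)) return(NA_real_)
  mean(sq)
}

# from-scratch sequential nested sums of squares via explicit group loops
oracle_nested_fractions <- function(values, labels) {
  grand <- mean(values)
  key <- function(cols) do.call(paste, c(labels[cols], sep = "\r"))
  lev_mean <- function(k) {
    out <- numeric(length(values))
    for (g in unique(k)) out[k == g] <- mean(values[k == g])
    out
  }
  md <- lev_mean(key("day_id"))
  ms <- lev_mean(key(c("day_id", "session_id")))
  mc <- lev_mean(key(c("day_id", "session_id", "cell_id")))
  ss <- c(day = sum((md - grand)^2), session = sum((ms - md)^2),
          cell = sum((mc - ms)^2), track = sum((values - mc)^2))
  ss / sum((values - grand)^2)
}

# Levene's classic recipe computed directly
oracle_levene <- function(a, b) {
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  z <- c(za, zb); N <- length(z)
  zg <- mean(z)
  ssb <- length(za) * (mean(za) - zg)^2 + length(zb) * (mean(zb) - zg)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  f <- (ssb / 1) / (ssw / (N - 2))
  c(statistic = f, p = pf(f, 1, N - 2, lower.tail = FALSE))
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_wilcox_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(na + nb, na)
  U_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  lo <- mean(U_all <= U_obs)
  hi <- mean(U_all >= U_obs)
  min(1, 2 * min(lo, hi))
}

# iterative one-bounce-at-a-time reflection
oracle_reflect <- function(v, upper) {
  vapply(v, function(x) {
    while (x < 0 || x > upper) {
      if (x < 0) x <- -x
      if (x > upper) x <- 2 * upper - x
    }
    x
  }, numeric(1))
}

small_ledger <- function(n_cells = 20, seed = 11) {
  generate_experiment_stats(synth_config(n_cells = n_cells, seed = seed))
}
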