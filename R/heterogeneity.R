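#' Log-space summary of a positive-valued distribution
#'
#' Diffusivity distributions are closer to log-normal than normal, so all
#' spread statistics are computed on log10 values: `mu_log` is the mean of
#' the log10 values (the "median order of magnitude"), `sigma_log` their
#' SD, `median_linear = 10^mu_log`, and the fold range is the ratio of the
#' values 2.5 SDs above and below the centre,
#' 10^(mu + 2.5 sigma) / 10^(mu - 2.5 sigma) = 10^(5 sigma).
#'
#' @param values Positive values (e.g. apparent diffusivities).
#' @return A `log_summary`: list with `mu_log`, `sigma_log`,
#'   `median_linear`, `fold_range`, `n`.
#' @export
log_space_summary <- function(values) {
  if (any(!is.finite(values) | values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0)
    stop("log_space_summary(): non-positive or non-finite value at index ",
         bad[1])
  }
  lv <- log10(values)
  mu <- mean(lv)
  sig <- if (length(lv) > 1L) stats::sd(lv) else 0
  structure(list(mu_log = mu, sigma_log = sig, median_linear = 10^mu,
                 fold_range = 10^(5 * sig), n = length(lv)),
            class = "log_summary")
}

#' @export
print.log_summary <- function(x, ...) {
  cat(sprintf(
    "log_summary: median 10^%.3f = %.4g, sigma_log %.3f, fold range %.3g (n = %d)\n",
    x$mu_log, x$median_linear, x$sigma_log, x$fold_range, x$n))
  invisible(x)
}

#' Nested ANOVA variance fractions
#'
#' Sequential nested sums of squares for the hierarchy
#' day -> session(day) -> cell(session) -> residual(track): each level's
#' SS is the size-weighted squared deviation of its group means from the
#' parent-group means, and the residual (within-cell, i.e. track-to-track)
#' SS absorbs the rest.  For a strictly nested hierarchy these four terms
#' decompose the total SS exactly; fractions are SS_level / SS_total.
#'
#' @param values Numeric responses (log10 diffusivities).
#' @param labels data.frame with columns `day_id`, `session_id`, `cell_id`
#'   (one row per value).  The hierarchy must be consistent: each cell in
#'   one session, each session in one day.
#' @return A `variance_decomposition`: list with `fraction_by_level`
#'   (named: day, session, cell, track), `ss_by_level`, `total_variance`
#'   (variance of `values`), `n`.
#' @export
nested_anova_fractions <- function(values, labels) {
  stopifnot(length(values) >= 2, nrow(labels) == length(values))
  if (any(!is.finite(values))) stop("non-finite response value")
  lab <- lapply(labels[c("day_id", "session_id", "cell_id")], as.character)
  # consistency: a session may not span days, a cell may not span sessions
  if (anyDuplicated(unique(data.frame(lab$session_id, lab$day_id))[, 1]))
    stop("inconsistent nesting: a session appears under several days")
  if (anyDuplicated(unique(data.frame(lab$cell_id, lab$session_id))[, 1]))
    stop("inconsistent nesting: a cell appears under several sessions")
  grand <- mean(values)
  gmean <- function(key) stats::ave(values, key)
  m_day <- gmean(lab$day_id)
  m_ses <- gmean(lab$session_id)
  m_cel <- gmean(lab$cell_id)
  ss <- c(day = sum((m_day - grand)^2),
          session = sum((m_ses - m_day)^2),
          cell = sum((m_cel - m_ses)^2),
          track = sum((values - m_cel)^2))
  ss_tot <- sum((values - grand)^2)
  if (ss_tot == 0) {
    frac <- c(day = 0, session = 0, cell = 0, track = 1)
  } else frac <- ss / ss_tot
  structure(list(fraction_by_level = frac, ss_by_level = ss,
                 total_variance = stats::var(values), n = length(values)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("variance_decomposition (fraction of total SS):\n")
  for (nm in names(x$fraction_by_level))
    cat(sprintf("  %-8s %6.2f%%\n", nm, 100 * x$fraction_by_level[nm]))
  invisible(x)
}

.group_comparison <- function(test, statistic, p_value, effect = NULL) {
  structure(list(test = test, statistic = statistic,
                 p_value = p_value, effect = effect),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.3g", x$test, x$statistic,
              x$p_value))
  if (!is.null(x$effect)) cat(" |", x$effect)
  cat("\n")
  invisible(x)
}

#' Levene's test for equality of variances (two groups)
#'
#' The classic form: absolute deviations of each observation from its
#' group mean, followed by a one-way ANOVA F test on those deviations.
#' (Not the median-centred Brown-Forsythe variant.)
#'
#' @param group_a,group_b Numeric vectors (log10 diffusivities), each of
#'   length >= 2.
#' @return A `group_comparison` with the F statistic and p-value; the
#'   `effect` field reports the percent change in variance from a to b.
#' @export
levene_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  z <- c(abs(group_a - mean(group_a)), abs(group_b - mean(group_b)))
  g <- rep(1:2, c(length(group_a), length(group_b)))
  N <- length(z); k <- 2L
  zb <- tapply(z, g, mean); zg <- mean(z)
  ss_b <- sum(tabulate(g) * (zb - zg)^2)
  ss_w <- sum((z - zb[g])^2)
  if (ss_w == 0 && ss_b == 0) {
    return(.group_comparison("levene", 0, 1,
                             "degenerate: zero deviations in both groups"))
  }
  f <- (ss_b / (k - 1)) / (ss_w / (N - k))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  dvar <- 100 * (stats::var(group_b) / stats::var(group_a) - 1)
  .group_comparison("levene", f, p,
                    sprintf("variance change a -> b: %+.1f%%", dvar))
}

#' Wilcoxon rank-sum test for equality of medians (two-sided)
#'
#' Exact null distribution of the Mann-Whitney U statistic when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param group_a,group_b Numeric vectors, each length >= 1.
#' @return A `group_comparison`; the statistic is U for `group_a` and the
#'   `effect` field reports the percent change of median from a to b.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 1, nb >= 1)
  r <- rank(c(group_a, group_b))
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= 20 && !ties) {
    # exact: pwilcox() enumerates the distribution of U under the null
    lo <- stats::pwilcox(U, na, nb)
    hi <- stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    sig2 <- (na * nb / 12) *
      ((na + nb + 1) - sum(tie_tab^3 - tie_tab) /
         ((na + nb) * (na + nb - 1)))
    if (sig2 == 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    }
  }
  dmed <- 100 * (stats::median(group_b) / stats::median(group_a) - 1)
  .group_comparison("ranksum", U, min(p, 1),
                    sprintf("median change a -> b: %+.1f%%", dmed))
}

#' Within-cell pairing of apparent diffusivities
#'
#' Draws one random unordered pair of tracks from every cell with at least
#' two fitted tracks and reports the Spearman correlation of the paired
#' values: a purely extrinsic (cell-level) spread drives r toward 1, a
#' purely intrinsic (track-level) spread toward 0.
#'
#' @param fits A track-level fit table from [fit_hierarchy()] (columns
#'   `cell_id`, `d_app`); rows with NA `d_app` are dropped.
#' @param seed RNG seed for the pair sampling.
#' @return A `group_comparison` (test = "spearman") with attribute
#'   `pairs` holding the sampled pair table.
#' @export
within_cell_pair_correlation <- function(fits, seed = 1) {
  f <- fits[is.finite(fits$d_app), , drop = FALSE]
  sp <- split(f$d_app, f$cell_id)
  sp <- sp[lengths(sp) >= 2L]
  if (length(sp) < 2L)
    stop("need >= 2 cells with >= 2 fitted tracks")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  pairs <- t(vapply(sp, function(v) sample(v, 2L), numeric(2)))
  ct <- suppressWarnings(
    stats::cor.test(pairs[, 1], pairs[, 2], method = "spearman"))
  out <- .group_comparison("spearman", unname(ct$estimate),
                           ct$p.value,
                           sprintf("%d within-cell pairs", nrow(pairs)))
  attr(out, "pairs") <- data.frame(cell_id = names(sp),
                                   d_app_1 = pairs[, 1],
                                   d_app_2 = pairs[, 2])
  out
}

#' Per-cell coefficient of variation of track diffusivities
#'
#' CV is computed on the linear-scale `d_app` within each cell with at
#' least two fitted tracks; Spearman correlations of CV against the cell
#' mean and against the track count diagnose expression-level artefacts.
#'
#' @param fits A track-level fit table from [fit_hierarchy()].
#' @return A `per_cell_cv` object: list with `table` (cell_id,
#'   mean_d_app, cv, n_tracks) and `correlations` (list of
#'   `group_comparison`: `cv_vs_mean`, `cv_vs_n`).
#' @export
per_cell_cv <- function(fits) {
  f <- fits[is.finite(fits$d_app), , drop = FALSE]
  sp <- split(f$d_app, f$cell_id)
  sp <- sp[lengths(sp) >= 2L]
  if (!length(sp)) stop("no cell with >= 2 fitted tracks")
  tab <- data.frame(cell_id = names(sp),
                    mean_d_app = vapply(sp, mean, numeric(1)),
                    cv = vapply(sp, function(v) stats::sd(v) / mean(v),
                                numeric(1)),
                    n_tracks = lengths(sp),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  corr <- function(x, y) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    .group_comparison("spearman", unname(ct$estimate), ct$p.value)
  }
  structure(list(table = tab,
                 correlations = list(
                   cv_vs_mean = corr(tab$cv, tab$mean_d_app),
                   cv_vs_n = corr(tab$cv, tab$n_tracks))),
            class = "per_cell_cv")
}

#' @export
print.per_cell_cv <- function(x, ...) {
  cat(sprintf("per_cell_cv: %d cells, median CV %.2f\n",
              nrow(x$table), stats::median(x$table$cv)))
  cat(sprintf("  CV vs mean: r = %.3f (p = %.3g)\n",
              x$correlations$cv_vs_mean$statistic,
              x$correlations$cv_vs_mean$p_value))
  cat(sprintf("  CV vs n:    r = %.3f (p = %.3g)\n",
              x$correlations$cv_vs_n$statistic,
              x$correlations$cv_vs_n$p_value))
  invisible(x)
}
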