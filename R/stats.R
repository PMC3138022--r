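# Nonparametric trend statistics: Kendall tau-b with tie corrections in
# both variables, the two-sample Wilcoxon rank-sum comparison (exact
# enumeration for small groups, tie-corrected normal approximation with
# continuity correction otherwise), and the standard suite of six
# correlation analyses run on a screening dataset.
#
# Both tests are implemented from the pairwise definitions so the test
# suite can check them against independent brute-force enumeration.

#' Kendall's tau-b rank correlation
#'
#' tau-b corrects the Kendall statistic for ties in both variables:
#' `tau_b = S / sqrt((n0 - n1)(n0 - n2))` with `S` the concordant-minus-
#' discordant pair count, `n0 = n(n-1)/2` and `n1`, `n2` the within-tie
#' pair counts of x and y. The two-sided p-value uses the tie-adjusted
#' normal approximation for `S` (no continuity correction). Pairs with a
#' missing value in either variable are dropped. If either variable is
#' completely tied tau-b is undefined: `NA` is returned with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 2 complete pairs).
#' @param level optional label for where the correlation was computed,
#'   `"per_sample"` (default) or `"group_median"`.
#' @return an object of class `correlation_result`: list with `tau_b`,
#'   `p_value`, `n` (complete pairs used), `S` (the raw pair statistic)
#'   and `level`.
#' @examples
#' kendall_tau_b(1:5, c(2, 1, 4, 3, 5))
#' @export
kendall_tau_b <- function(x, y, level = c("per_sample", "group_median")) {
  level <- match.arg(level)
  if (!is.numeric(x) || !is.numeric(y)) abort("x and y must be numeric")
  if (length(x) != length(y))
    abort("x and y differ in length (%d vs %d)", length(x), length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) abort("need at least 2 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warnf("tau-b undefined: a variable is completely tied")
    out <- list(tau_b = NA_real_, p_value = NA_real_, n = n, S = NA_real_,
                level = level)
    class(out) <- "correlation_result"
    return(out)
  }
  # S = sum over i<j of sign(x_i - x_j) * sign(y_i - y_j); row-wise loop
  # keeps memory O(n) for datasets of thousands of samples
  S <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    S <- S + sum(sign(x[i] - x[j]) * sign(y[i] - y[j]))
  }
  t_x <- as.numeric(table(x)); t_y <- as.numeric(table(y))
  n0 <- n * (n - 1) / 2
  n1 <- sum(t_x * (t_x - 1) / 2)
  n2 <- sum(t_y * (t_y - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  # tie-adjusted variance of S (Kendall 1970)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t_x * (t_x - 1) * (2 * t_x + 5))
  vu <- sum(t_y * (t_y - 1) * (2 * t_y + 5))
  v1 <- sum(t_x * (t_x - 1)) * sum(t_y * (t_y - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2)
    sum(t_x * (t_x - 1) * (t_x - 2)) * sum(t_y * (t_y - 1) * (t_y - 2)) /
      (9 * n * (n - 1) * (n - 2)) else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  p <- if (var_s > 0) 2 * stats::pnorm(-abs(S) / sqrt(var_s)) else NA_real_
  p <- min(p, 1)
  out <- list(tau_b = tau, p_value = p, n = n, S = S, level = level)
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %s (p = %s, n = %d, level = %s)\n",
              format(x$tau_b, digits = 4), format(x$p_value, digits = 4),
              x$n, x$level))
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided comparison of two independent groups (the Mann-Whitney form;
#' the compared groups in an MCR screening — samples with HI below vs
#' above the cutoff — are independent, so the signed-rank form does not
#' apply). The statistic is the rank sum `W` of group `a` in the pooled
#' midranks. When both groups have at most `exact_max` observations the
#' p-value is computed by exact enumeration of all group assignments of
#' the pooled midranks (ties handled naturally); otherwise by the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact_max largest per-group size for exact enumeration
#'   (default 10).
#' @return an object of class `comparison_result`: list with `statistic`
#'   (rank sum of `a`), `p_value`, `group_sizes`, `group_means`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4)) # exact two-sided p = 1/3
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 10L) {
  if (!is.numeric(a) || !is.numeric(b)) abort("both groups must be numeric")
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  e_w <- na * (n + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    combs <- utils::combn(n, na)
    ws <- colSums(matrix(r[combs], nrow = na))
    p <- mean(abs(ws - e_w) >= abs(w - e_w))
    method <- "exact enumeration"
  } else {
    ties <- as.numeric(table(r))
    var_w <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (var_w <= 0) {
      p <- 1  # every pooled value identical: no evidence of a shift
    } else {
      z <- (w - e_w - sign(w - e_w) * 0.5) / sqrt(var_w)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation (tie-corrected, continuity)"
  }
  out <- list(statistic = w, p_value = p,
              group_sizes = c(na, nb),
              group_means = c(mean(a), mean(b)),
              method = method)
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Rank-sum W = %g, p = %s (%s)\n", x$statistic,
              format(x$p_value, digits = 4), x$method))
  cat(sprintf("  groups: n = %d (mean %.4g) vs n = %d (mean %.4g)\n",
              x$group_sizes[1], x$group_means[1],
              x$group_sizes[2], x$group_means[2]))
  invisible(x)
}

#' The standard correlation suite of an MCR screening
#'
#' Runs, for a single-policy metrics table, the six trend analyses of the
#' screening workflow: per-sample HI~n, MCR~n and MCR~HI; MCR~HI restricted
#' to samples with HI above the cutoff; and HI~n and MCR~n on group
#' medians (using only groups with defined medians, i.e. at least 10
#' samples). Records with undefined metrics are dropped pair-wise. An
#' analysis with fewer than 2 usable points (or fewer than 2 defined group
#' medians) is skipped with a warning.
#'
#' @param metrics a `sample_metrics` table (one policy).
#' @param group_summaries optional `group_summary` table from
#'   [group_by_n()]; computed from `metrics` when `NULL`.
#' @param hi_cutoff HI threshold for the above-cutoff subset (default 1).
#' @return a data.frame with one row per analysis: `analysis`, `level`,
#'   `policy`, `tau_b`, `p_value`, `n`.
#' @export
correlation_suite <- function(metrics, group_summaries = NULL, hi_cutoff = 1) {
  if (length(unique(metrics$policy)) > 1L)
    abort("correlation_suite expects metrics computed under a single policy")
  policy <- metrics$policy[1L]
  if (is.null(group_summaries))
    group_summaries <- suppressMessages(group_by_n(metrics))
  gs <- group_summaries[!is.na(group_summaries$median_hi), , drop = FALSE]
  above <- !is.na(metrics$hi) & metrics$hi > hi_cutoff

  specs <- list(
    list(name = "hi_vs_n",        level = "per_sample",
         x = metrics$n_effective, y = metrics$hi),
    list(name = "mcr_vs_n",       level = "per_sample",
         x = metrics$n_effective, y = metrics$mcr),
    list(name = "mcr_vs_hi",      level = "per_sample",
         x = metrics$hi,          y = metrics$mcr),
    list(name = "mcr_vs_hi_above", level = "per_sample",
         x = metrics$hi[above],   y = metrics$mcr[above]),
    list(name = "hi_vs_n",        level = "group_median",
         x = gs$n_value,          y = gs$median_hi),
    list(name = "mcr_vs_n",       level = "group_median",
         x = gs$n_value,          y = gs$median_mcr))

  rows <- lapply(specs, function(s) {
    ok <- !is.na(s$x) & !is.na(s$y)
    if (sum(ok) < 2L) {
      warnf("correlation_suite: skipping %s (%s): fewer than 2 usable points",
            s$name, s$level)
      return(NULL)
    }
    ct <- kendall_tau_b(s$x[ok], s$y[ok], level = s$level)
    data.frame(analysis = s$name, level = s$level, policy = policy,
               tau_b = ct$tau_b, p_value = ct$p_value, n = ct$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("no correlation analysis had enough data")
  rownames(out) <- NULL
  out
}
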