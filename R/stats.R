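#' Bland-Altman limits of repeatability
#'
#' For paired test-retest measurements, computes the differences
#' `second − first`, their mean and sample SD (n − 1 denominator), and the
#' repeatability limits `mean ± k·SD` (k = 1.96 gives the conventional 95%
#' limits). The `range` (upper − lower = 2·k·SD) summarises the width of the
#' repeatability band.
#'
#' @param first,second Equal-length numeric vectors of paired measurements
#'   (first and second trial); `n >= 2`. Pairs with a missing value are
#'   dropped.
#' @param k Limit multiplier, default 1.96.
#' @return Object of class `pspvt_bland_altman`: list with `n_pairs`,
#'   `mean_diff`, `sd_diff`, `lower_limit`, `upper_limit`, `range`, `k`.
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 19, 33))
#' @export
bland_altman <- function(first, second, k = 1.96) {
  if (length(first) != length(second)) {
    stop("first and second must have equal length", call. = FALSE)
  }
  ok <- !is.na(first) & !is.na(second)
  d <- second[ok] - first[ok]
  if (length(d) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  bland_altman_summary(mean(d), stats::sd(d), k = k, n_pairs = length(d))
}

#' Bland-Altman limits from summary statistics
#'
#' Builds the same result object as [bland_altman()] from an already-known
#' mean difference and SD -- e.g. to reconstruct limits and range widths
#' reported in the literature.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Sample SD of the paired differences (>= 0).
#' @param k Limit multiplier, default 1.96.
#' @param n_pairs Number of pairs, if known.
#' @return A `pspvt_bland_altman` object.
#' @export
bland_altman_summary <- function(mean_diff, sd_diff, k = 1.96,
                                 n_pairs = NA_integer_) {
  stopifnot(sd_diff >= 0, k >= 0)
  lower <- mean_diff - k * sd_diff
  upper <- mean_diff + k * sd_diff
  structure(
    list(n_pairs = n_pairs, mean_diff = mean_diff, sd_diff = sd_diff,
         lower_limit = lower, upper_limit = upper,
         range = upper - lower, k = k),
    class = "pspvt_bland_altman"
  )
}

#' @export
print.pspvt_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %s): mean diff %.3f, SD %.3f\n",
              ifelse(is.na(x$n_pairs), "?", x$n_pairs),
              x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of repeatability (k = %g): %.3f to %.3f (range %.3f)\n",
              x$k, x$lower_limit, x$upper_limit, x$range))
  invisible(x)
}

#' Two-way ANOVA with Type III sums of squares
#'
#' Fits `values ~ A * B` as a general linear model with sum-to-zero
#' contrasts and tests each main effect and the interaction with Type III
#' (partial) sums of squares, the appropriate decomposition for unbalanced
#' factorial designs such as an age-group x sex comparison. On balanced
#' designs it coincides with the classical two-way ANOVA table.
#'
#' @param values Numeric response.
#' @param group_a,group_b Factor labels (coerced); each must have >= 2
#'   observed levels, and every A x B cell must be non-empty.
#' @param a_name,b_name Effect names used in the output.
#' @return data.frame with one row per effect (`a_name`, `b_name`,
#'   `a_name:b_name`): columns `effect`, `df`, `df_residual`, `F`, `p`.
#' @export
anova_two_way <- function(values, group_a, group_b,
                          a_name = "A", b_name = "B") {
  a <- factor(group_a)
  b <- factor(group_b)
  ok <- !is.na(values) & !is.na(a) & !is.na(b)
  values <- values[ok]
  a <- droplevels(a[ok])
  b <- droplevels(b[ok])
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("each factor needs at least 2 observed levels", call. = FALSE)
  }
  cells <- table(a, b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: %s = %s, %s = %s",
                 a_name, rownames(cells)[empty[1]],
                 b_name, colnames(cells)[empty[2]]), call. = FALSE)
  }
  dat <- data.frame(y = values, A = a, B = b)
  fit <- stats::lm(y ~ A * B, data = dat,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: model coefficients not estimable", call. = FALSE)
  }
  tab <- car::Anova(fit, type = "III")
  rows <- c("A", "B", "A:B")
  df_res <- tab["Residuals", "Df"]
  out <- data.frame(
    effect = c(a_name, b_name, paste0(a_name, ":", b_name)),
    df = tab[rows, "Df"],
    df_residual = rep(df_res, 3),
    F = tab[rows, "F value"],
    p = tab[rows, "Pr(>F)"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pairwise group comparisons with Bonferroni adjustment
#'
#' All pairwise two-sample t comparisons using the pooled residual variance
#' across every group (df = N − k), with Bonferroni-adjusted p values:
#' `adjusted_p = min(1, raw_p x number of pairs)`. The comparisons are
#' computed unconditionally; gating them on a significant omnibus effect is
#' the caller's workflow decision.
#'
#' @param values Numeric response.
#' @param group Group labels (coerced to factor); every group needs `n >= 2`.
#' @param alpha Significance level for the `significant` flag, default 0.05.
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `mean_diff` (group2 − group1), `raw_p`, `adjusted_p`, `significant`.
#' @export
bonferroni_pairwise <- function(values, group, alpha = 0.05) {
  g <- factor(group)
  ok <- !is.na(values) & !is.na(g)
  values <- values[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  n <- tapply(values, g, length)
  if (any(n < 2)) {
    stop(sprintf("group '%s' has fewer than 2 observations",
                 names(n)[which(n < 2)[1]]), call. = FALSE)
  }
  m <- tapply(values, g, mean)
  # pooled residual variance across all groups
  ss_within <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  df <- length(values) - nlevels(g)
  s2 <- ss_within / df
  pairs <- utils::combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  out <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    mean_diff = NA_real_, raw_p = NA_real_, adjusted_p = NA_real_,
    significant = NA, stringsAsFactors = FALSE
  )
  for (i in seq_len(n_pairs)) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    diff <- m[[g2]] - m[[g1]]
    se <- sqrt(s2 * (1 / n[[g1]] + 1 / n[[g2]]))
    raw <- if (se == 0) {
      if (diff == 0) 1 else 0   # degenerate zero-variance data
    } else {
      2 * stats::pt(-abs(diff / se), df)
    }
    out$mean_diff[i] <- diff
    out$raw_p[i] <- raw
    out$adjusted_p[i] <- min(1, raw * n_pairs)
    out$significant[i] <- out$adjusted_p[i] < alpha
  }
  out
}
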