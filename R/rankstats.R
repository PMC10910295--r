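#' Mid-ranks with tie averaging
#'
#' 1-based ranks where tied values receive the average of the ranks they
#' span, so the rank sum is always `N(N+1)/2`.
#'
#' @param values Nonempty numeric vector (no NAs).
#' @return Numeric vector of ranks.
#' @export
rank_with_ties <- function(values) {
  if (!length(values)) stop("cannot rank an empty vector", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  rank(values, ties.method = "average")
}

# Residual sum of squares of a linear model on ranks; the workhorse of the
# factorial rank decomposition.
.rss <- function(formula, data) {
  sum(stats::lm(formula, data = data)$residuals^2)
}

#' Scheirer-Ray-Hare rank-based factorial test
#'
#' Nonparametric two-way factorial analysis: all `N` observations are ranked
#' jointly (mid-ranks for ties), factorial sums of squares are computed on
#' the ranks, and each effect's statistic is
#' \deqn{H = SS_{effect} / MS_{total}, \quad MS_{total} = SS_{total}/(N-1)}
#' referred to a chi-square distribution with the effect's degrees of
#' freedom. Dividing by the empirical `MS_total` of the ranks absorbs the
#' tie correction, and with a single varying factor the statistic reduces to
#' the tie-corrected Kruskal-Wallis H.
#'
#' For unbalanced designs the sums of squares are obtained by model
#' comparison on the ranks: Type II (default; each main effect adjusted for
#' the other, interaction adjusted for both mains) or Type I (sequential,
#' factor A first).
#'
#' Effect sizes are eta-squared estimates from the Kruskal-Wallis formula
#' (see [kruskal_eta_squared()]); main effects use their own level count and
#' the interaction treats the crossed cells as groups.
#'
#' @param values Numeric dependent variable, one observation per unit. NAs
#'   are dropped together with their factor levels.
#' @param factor_a,factor_b Factor levels per observation (e.g. treatment
#'   and hemisphere).
#' @param ss_type `"II"` (default) or `"I"`.
#' @return An object of class `srh_result`: a data frame with one row per
#'   effect (`A`, `B`, `A:B`) and columns `effect`, `df`, `H`, `p`, `eta2`,
#'   `eta2_label`, plus attributes `n` and `ss_type`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b,
                              ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  keep <- !is.na(values)
  values <- values[keep]
  fa <- factor(factor_a[keep])
  fb <- factor(factor_b[keep])
  n <- length(values)
  if (n < 3L) stop("need at least 3 non-missing observations", call. = FALSE)

  cell_n <- table(fa, fb)
  if (nlevels(fa) > 1L && nlevels(fb) > 1L && any(cell_n == 0L)) {
    empty <- which(cell_n == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: ", rownames(cell_n)[empty[1L]], " x ",
         colnames(cell_n)[empty[2L]], call. = FALSE)
  }

  r <- rank_with_ties(values)
  ss_total <- sum((r - mean(r))^2)
  df <- c(A = nlevels(fa) - 1L, B = nlevels(fb) - 1L,
          `A:B` = (nlevels(fa) - 1L) * (nlevels(fb) - 1L))

  if (ss_total == 0) {
    warning("all observations tied; H statistics undefined")
    ss <- c(A = NA_real_, B = NA_real_, `A:B` = NA_real_)
    H <- ss
    p <- c(A = 1, B = 1, `A:B` = 1)
  } else {
    d <- data.frame(r = r, fa = fa, fb = fb)
    one_way_ss <- function(f) {
      means <- tapply(r, f, mean)
      sum(table(f) * (means - mean(r))^2)
    }
    if (nlevels(fa) == 1L || nlevels(fb) == 1L) {
      # Degenerate to one-way: only the varying factor is testable.
      ss <- c(A = if (nlevels(fa) > 1L) one_way_ss(fa) else NA_real_,
              B = if (nlevels(fb) > 1L) one_way_ss(fb) else NA_real_,
              `A:B` = NA_real_)
    } else if (ss_type == "II") {
      rss_a_b <- .rss(r ~ fa + fb, d)
      rss_full <- .rss(r ~ fa * fb, d)
      ss <- c(A = .rss(r ~ fb, d) - rss_a_b,
              B = .rss(r ~ fa, d) - rss_a_b,
              `A:B` = rss_a_b - rss_full)
    } else {
      rss_0 <- .rss(r ~ 1, d)
      rss_a <- .rss(r ~ fa, d)
      rss_a_b <- .rss(r ~ fa + fb, d)
      rss_full <- .rss(r ~ fa * fb, d)
      ss <- c(A = rss_0 - rss_a, B = rss_a - rss_a_b,
              `A:B` = rss_a_b - rss_full)
    }
    ss <- pmax(ss, 0)   # guard tiny negative round-off
    ms_total <- ss_total / (n - 1)
    H <- ss / ms_total
    p <- ifelse(is.na(H), 1,
                stats::pchisq(H, df, lower.tail = FALSE))
  }

  k <- c(A = nlevels(fa), B = nlevels(fb),
         `A:B` = nlevels(fa) * nlevels(fb))
  eta2 <- rep(NA_real_, 3L)
  label <- rep(NA_character_, 3L)
  for (i in 1:3) {
    if (!is.na(H[i]) && n > k[i] && k[i] >= 2L) {
      e <- kruskal_eta_squared(H[i], k[i], n)
      eta2[i] <- e$eta2
      label[i] <- e$label
    }
  }
  out <- data.frame(effect = c("A", "B", "A:B"), df = as.integer(df),
                    H = as.numeric(H), p = as.numeric(p),
                    eta2 = eta2, eta2_label = label,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "ss_type") <- ss_type
  class(out) <- c("srh_result", "data.frame")
  out
}

#' Kruskal-Wallis eta-squared effect size
#'
#' `eta2 = (H - k + 1) / (n - k)` for a Kruskal-Wallis-type statistic `H`
#' over `k` groups and `n` observations; the share of variance in the
#' dependent variable attributable to the grouping. Size labels follow the
#' conventional cut-offs: below 0.01 negligible, 0.01 to under 0.06 small,
#' 0.06 to under 0.14 moderate, 0.14 and above large.
#'
#' @param H Test statistic (>= 0).
#' @param k Number of groups (>= 2).
#' @param n Total observations (> k).
#' @return List with `eta2` and `label`.
#' @export
kruskal_eta_squared <- function(H, k, n) {
  stopifnot(H >= 0, k >= 2)
  if (n <= k) stop("n must exceed the number of groups", call. = FALSE)
  eta2 <- (H - k + 1) / (n - k)
  label <- if (eta2 < 0.01) "negligible"
           else if (eta2 < 0.06) "small"
           else if (eta2 < 0.14) "moderate"
           else "large"
  list(eta2 = eta2, label = label)
}

#' Dunn's post-hoc pairwise comparisons on joint ranks
#'
#' Pairwise z tests on mean ranks after a Kruskal-Wallis-type analysis, with
#' tie correction:
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' Two-sided p-values from the standard normal; Bonferroni adjustment over
#' the requested comparison set.
#'
#' @param values Numeric observations.
#' @param groups Group label per observation.
#' @param comparisons Two-column character matrix (or list of length-2
#'   vectors) of group pairs to test; default all pairs.
#' @return Data frame with columns `group_i`, `group_j`, `z`, `p_raw`,
#'   `p_bonferroni`.
#' @export
dunn_posthoc <- function(values, groups, comparisons = NULL) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups[keep])
  g <- factor(groups)
  n_i <- table(g)
  if (any(n_i == 0L)) stop("empty group", call. = FALSE)
  N <- length(values)
  r <- rank_with_ties(values)
  mean_rank <- tapply(r, g, mean)

  t_counts <- table(values)
  tie_term <- sum(t_counts^3 - t_counts) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term

  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(levels(g), 2L))
  } else if (is.list(comparisons)) {
    comparisons <- do.call(rbind, comparisons)
  }
  comparisons <- matrix(as.character(comparisons), ncol = 2L)
  bad <- setdiff(unique(as.vector(comparisons)), levels(g))
  if (length(bad)) {
    stop("comparison references unknown group '", bad[1L], "'",
         call. = FALSE)
  }
  m <- nrow(comparisons)
  res <- lapply(seq_len(m), function(i) {
    gi <- comparisons[i, 1L]
    gj <- comparisons[i, 2L]
    se <- sqrt(var_core * (1 / n_i[[gi]] + 1 / n_i[[gj]]))
    z <- if (se > 0) (mean_rank[[gi]] - mean_rank[[gj]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_i = gi, group_j = gj, z = z, p_raw = p,
               p_bonferroni = min(1, m * p), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Wilcoxon rank-sum test with continuity correction
#'
#' Two-sided two-sample rank-sum test using the tie-corrected normal
#' approximation with a 0.5 continuity correction (the variant the unit
#' classifier applies to per-trial peak and window firing rates). The
#' statistic is the Mann-Whitney count
#' `W = sum(ranks of x) - n_x(n_x+1)/2`.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `statistic` (W), `z` and `p_two_sided`. Fully tied
#'   samples give `z = 0`, `p = 1`.
#' @export
wilcoxon_ranksum_cc <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty",
                                     call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r <- rank_with_ties(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  t_counts <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(t_counts^3 - t_counts) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = W, z = 0, p_two_sided = 1))
  }
  diff <- W - mu
  z <- (diff - sign(diff) * 0.5) / sqrt(sigma2)
  list(statistic = W, z = z,
       p_two_sided = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Pooled two-proportion z test
#'
#' Compares two independent proportions with the pooled-variance normal
#' statistic
#' \deqn{z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}, \quad
#'   \hat p = \frac{x_1 + x_2}{n_1 + n_2}}
#' with a two-sided normal p-value. If the pooled proportion is 0 or 1 the
#' statistic is degenerate; `z = 0` is returned with `degenerate = TRUE`.
#'
#' @param x1,n1 Successes and total of the first sample.
#' @param x2,n2 Successes and total of the second sample.
#' @return List with `z`, `p_two_sided`, `p1`, `p2`, `degenerate`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    return(list(z = 0, p_two_sided = 1, p1 = p1, p2 = p2, degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p_two_sided = min(1, 2 * stats::pnorm(-abs(z))),
       p1 = p1, p2 = p2, degenerate = FALSE)
}
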