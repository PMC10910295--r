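test_that("mid-ranks average ties and always sum to N(N+1)/2", {
  expect_equal(rank_with_ties(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rank_with_ties(c(5, 5, 7)), c(1.5, 1.5, 3))
  expect_error(rank_with_ties(numeric(0)), "empty")
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    v <- sample(1:8, n, replace = TRUE)   # heavy ties
    expect_equal(sum(rank_with_ties(v)), n * (n + 1) / 2)
  }
})

test_that("factorial rank test reproduces the 2x2 single-observation case", {
  # Values 1..4 arranged so factor A separates {1,2} from {3,4} and factor B
  # separates {1,3} from {2,4}: ranks 1-4, SS_total = 5, MS_total = 5/3.
  res <- scheirer_ray_hare(c(1, 2, 3, 4),
                           c("a1", "a1", "a2", "a2"),
                           c("b1", "b2", "b1", "b2"))
  expect_equal(res$H[res$effect == "A"], 2.4, tolerance = 1e-12)
  expect_equal(res$H[res$effect == "B"], 0.6, tolerance = 1e-12)
  expect_equal(res$H[res$effect == "A:B"], 0, tolerance = 1e-9)
  expect_equal(res$df, c(1L, 1L, 1L))
})

test_that("all-tied input yields undefined H with p = 1, empty cells error", {
  expect_warning(
    res <- scheirer_ray_hare(rep(2, 8),
                             rep(c("a1", "a2"), each = 4),
                             rep(c("b1", "b2"), 4)),
    "tied")
  expect_true(all(is.na(res$H)))
  expect_equal(res$p, rep(1, 3))
  expect_error(
    scheirer_ray_hare(1:6,
                      c("a1", "a1", "a1", "a1", "a2", "a2"),
                      c("b1", "b1", "b2", "b2", "b1", "b1")),
    "empty design cell")
})

test_that("factorial rank statistics match brute-force rank ANOVA oracles", {
  skip_if_not_installed("car")
  set.seed(101)
  for (i in 1:50) {
    # Balanced, no ties: sequential ANOVA on the ranks is the oracle.
    n_cell <- sample(3:8, 1)
    fa <- factor(rep(c("a1", "a2"), each = 2 * n_cell))
    fb <- factor(rep(rep(c("b1", "b2"), each = n_cell), 2))
    v <- rnorm(4 * n_cell)
    res <- scheirer_ray_hare(v, fa, fb)
    r <- rank(v)
    ms_total <- sum((r - mean(r))^2) / (length(r) - 1)
    aov_tab <- anova(lm(r ~ fa * fb))
    expect_equal(res$H, aov_tab[1:3, "Sum Sq"] / ms_total,
                 tolerance = 1e-9)
  }
  for (i in 1:50) {
    # Unbalanced with ties: Type II sums of squares from an independent
    # implementation (car) on the same ranks.
    n_i <- sample(3:9, 4, replace = TRUE)
    fa <- factor(rep(c("a1", "a1", "a2", "a2"), n_i))
    fb <- factor(rep(c("b1", "b2", "b1", "b2"), n_i))
    v <- sample(1:6, sum(n_i), replace = TRUE)
    res <- scheirer_ray_hare(v, fa, fb)
    r <- rank(v)
    if (sum((r - mean(r))^2) == 0) next
    ms_total <- sum((r - mean(r))^2) / (length(r) - 1)
    fit <- lm(r ~ fa * fb, data = data.frame(r, fa, fb))
    ss2 <- car::Anova(fit, type = 2)[c("fa", "fb", "fa:fb"), "Sum Sq"]
    expect_equal(res$H, ss2 / ms_total, tolerance = 1e-9)
  }
})

test_that("with one varying factor the statistic is tie-corrected Kruskal-Wallis", {
  set.seed(7)
  for (i in 1:20) {
    g <- factor(sample(c("g1", "g2", "g3"), 30, replace = TRUE))
    if (nlevels(g) < 2) next
    v <- sample(1:10, 30, replace = TRUE)
    res <- scheirer_ray_hare(v, g, rep("only", 30))
    kw <- kruskal.test(v, g)
    expect_equal(res$H[res$effect == "A"], unname(kw$statistic),
                 tolerance = 1e-9)
  }
})

test_that("eta-squared follows the Kruskal-Wallis formula and size labels", {
  expect_equal(kruskal_eta_squared(1, 2, 10)$eta2, 0)
  e <- kruskal_eta_squared(5, 2, 100)
  expect_equal(e$eta2, 4 / 98, tolerance = 1e-12)
  expect_equal(e$label, "small")
  # 0.08 falls in the moderate band (0.06 to under 0.14)
  H_for_008 <- 0.08 * (200 - 2) + 1   # invert the formula at n=200, k=2
  expect_equal(kruskal_eta_squared(H_for_008, 2, 200)$label, "moderate")
  expect_equal(kruskal_eta_squared(30, 2, 100)$label, "large")
  expect_equal(kruskal_eta_squared(1.05, 2, 100)$label, "negligible")
  expect_error(kruskal_eta_squared(5, 4, 4), "exceed")
})

test_that("Dunn comparisons: ties handled, antisymmetric, oracle-equal", {
  # Two identical groups: no rank difference.
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("g1", "g2"), each = 3)
  d <- dunn_posthoc(v, g)
  expect_equal(d$z, 0)
  expect_equal(d$p_raw, 1)

  set.seed(202)
  for (i in 1:100) {
    k <- sample(3:5, 1)
    n_i <- sample(3:7, k, replace = TRUE)
    g <- factor(rep(paste0("g", seq_len(k)), n_i))
    v <- sample(1:8, sum(n_i), replace = TRUE)
    d <- dunn_posthoc(v, g)
    # Independent oracle: the tie-corrected variance core equals the total
    # rank variance SS_total/(N-1), computed here without tie counting.
    r <- rank(v)
    N <- length(v)
    var_core <- sum((r - mean(r))^2) / (N - 1)
    mr <- tapply(r, g, mean)
    for (j in seq_len(nrow(d))) {
      se <- sqrt(var_core * (1 / sum(g == d$group_i[j]) +
                               1 / sum(g == d$group_j[j])))
      z_oracle <- (mr[[d$group_i[j]]] - mr[[d$group_j[j]]]) / se
      expect_equal(d$z[j], z_oracle, tolerance = 1e-9)
    }
    # Antisymmetry under pair swap.
    d_swap <- dunn_posthoc(v, g, comparisons = cbind(d$group_j, d$group_i))
    expect_equal(d_swap$z, -d$z, tolerance = 1e-12)
    expect_equal(d_swap$p_raw, d$p_raw, tolerance = 1e-12)
  }
  expect_error(dunn_posthoc(1:4, rep("g1", 4), cbind("g1", "g9")), "unknown")
})

test_that("rank-sum test matches exact enumeration and the reference normal variant", {
  expect_equal(wilcoxon_ranksum_cc(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)
  expect_equal(wilcoxon_ranksum_cc(rep(4, 5), rep(4, 6))$p_two_sided, 1)

  # Small-sample case: exact two-sided enumeration over all C(6,3) = 20 rank
  # assignments gives p = 0.1; the continuity-corrected normal approximation
  # must land close (documented approximation gap of this variant).
  expect_equal(exact_ranksum_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  w <- wilcoxon_ranksum_cc(c(1, 2, 3), c(10, 11, 12))
  expect_lt(abs(w$p_two_sided - 0.1), 0.025)

  # Cross-check against an independently implemented normal approximation
  # with the same tie and continuity corrections.
  set.seed(303)
  for (i in 1:100) {
    x <- sample(1:10, sample(4:20, 1), replace = TRUE)
    y <- sample(1:10, sample(4:20, 1), replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    w <- wilcoxon_ranksum_cc(x, y)
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("rank-sum type-I error is near nominal for same-distribution samples", {
  set.seed(404)
  rejections <- replicate(2000, {
    wilcoxon_ranksum_cc(rnorm(50), rnorm(50))$p_two_sided < 0.05
  })
  expect_gte(mean(rejections), 0.04)
  expect_lte(mean(rejections), 0.06)
})

test_that("pooled two-proportion z reproduces hand-checked values", {
  # Equal proportions are exactly null.
  eq <- two_proportion_z(5, 20, 25, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_two_sided, 1)
  # Hand evaluation of the pooled-variance formula.
  expect_equal(two_proportion_z(10, 20, 5, 20)$z, 1.633, tolerance = 5e-4)
  # Antisymmetry under operand swap.
  a <- two_proportion_z(478, 1544, 824, 1549)
  b <- two_proportion_z(824, 1549, 478, 1544)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(round(a$z, 2), -12.52)
  # Degenerate pooled proportion.
  d <- two_proportion_z(0, 10, 0, 10)
  expect_true(d$degenerate)
  expect_equal(d$z, 0)
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(505)
  v <- rgamma(40, 2)
  fa <- rep(c("a1", "a2"), each = 20)
  fb <- rep(c("b1", "b2"), 20)
  for (f in list(function(x) x, exp, function(x) x^3, function(x) -1 / x)) {
    res <- scheirer_ray_hare(f(v), fa, fb)
    base <- scheirer_ray_hare(v, fa, fb)
    expect_equal(res$H, base$H, tolerance = 1e-12)
    expect_equal(dunn_posthoc(f(v), fa)$z, dunn_posthoc(v, fa)$z,
                 tolerance = 1e-12)
    expect_equal(wilcoxon_ranksum_cc(f(v[1:20]), f(v[21:40]))$p_two_sided,
                 wilcoxon_ranksum_cc(v[1:20], v[21:40])$p_two_sided,
                 tolerance = 1e-12)
  }
})
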