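amp3 <- function(contra, ipsi = 0, bilateral = contra) {
  c(contra = contra, ipsi = ipsi, bilateral = bilateral)
}

test_that("responsiveness screen applies the fold rule and the 5 Hz floor", {
  th <- classifier_thresholds()
  # ON peak 20 over baseline peak 8: 20 >= 16 and >= 5.
  expect_true(is_visually_responsive(make_features(8, 20), th))
  # Best peak 15 < 2 x 8.
  expect_false(is_visually_responsive(make_features(8, 15), th))
  # 4.5x fold but below the absolute 5 Hz floor.
  expect_false(is_visually_responsive(make_features(1, 4.5), th))
  # OFF window alone can qualify a unit.
  expect_true(is_visually_responsive(make_features(1, 0, off_peak = 12), th))
  # Silent baseline leaves only the floor.
  expect_true(is_visually_responsive(make_features(0, 6), th))
  expect_false(is_visually_responsive(make_features(0, 4), th))
})

test_that("ipsilateral sigma criterion thresholds on baseline noise", {
  p <- default_protocol()
  th <- classifier_thresholds()
  # Silent baseline, 12 Hz ON peak: degenerate-s.d. rule fires.
  rate <- numeric(n_bins(p))
  rate[45] <- 12
  fired <- ipsi_sigma_criterion(make_psth(rate, p), th)
  expect_true(fired$fired_ON)
  expect_false(fired$fired_OFF)
  # Baseline mean 5, s.d. 2: a 12 Hz peak stays under 5 + 4 x 2.
  rate <- numeric(n_bins(p))
  rate[1:40] <- rep(c(3, 7), 20)          # mean 5, sd ~2.03
  rate[45] <- 12
  rate[85] <- 14                          # OFF peak above 5 + 4 x sd
  fired <- ipsi_sigma_criterion(make_psth(rate, p), th)
  expect_false(fired$fired_ON)
  expect_true(fired$fired_OFF)
})

test_that("identical contralateral and bilateral trains give p = 1 everywhere", {
  p <- default_protocol()
  set.seed(51)
  a <- unit_archetype("contra_only", 6, amp3(30), amp3(10))
  sp <- simulate_unit(a, p, "u1")
  contra <- sp[sp$condition == "contra", ]
  clone <- contra
  clone$condition <- "bilateral"
  ds <- one_unit_dataset(rbind(contra, clone))
  m <- bilateral_modulation_tests(ds, "u1")
  expect_equal(m$peak_ON_p, 1)
  expect_equal(m$peak_OFF_p, 1)
  expect_equal(m$rate_ON_p, 1)
  expect_equal(m$rate_OFF_p, 1)
  cls <- classify_unit(ds, "u1")
  expect_equal(cls$integration_on, "none")
})

test_that("strong simulated effects are detected at the documented rates", {
  p <- default_protocol()
  th <- classifier_thresholds()
  seeds <- 1:120

  # Ipsilateral response well above baseline noise: sigma criterion fires.
  ipsi_arch <- unit_archetype("bilateral_independent", 2,
                              amp3(40, ipsi = 40), amp3(0))
  sigma_hits <- vapply(seeds, function(s) {
    set.seed(s)
    ds <- one_unit_dataset(simulate_unit(ipsi_arch, p, "u1"))
    ipsi_sigma_criterion(compute_psth(ds, "u1", "ipsi"), th)$fired_ON
  }, logical(1))
  expect_gte(mean(sigma_hits), 0.99)

  # Doubled bilateral amplitude: the ON rate comparison rejects at the
  # power the generative model implies. Oracle: ON-window spike counts are
  # Poisson with mean baseline + amp * integral of the unit Gaussian, and
  # the reference rank-sum implementation gives the attainable power.
  duty <- 0.04 * sqrt(2 * pi) * (pnorm(1, 0.1, 0.04) - pnorm(0, 0.1, 0.04))
  set.seed(1001)
  oracle_power <- mean(replicate(1000, {
    suppressWarnings(wilcox.test(rpois(40, 4 + 20 * duty),
                                 rpois(40, 4 + 40 * duty),
                                 exact = FALSE, correct = TRUE))$p.value < 0.05
  }))
  excit <- unit_archetype("bilateral_excitatory", 4,
                          amp3(20, bilateral = 40), amp3(0))
  rate_hits <- vapply(seeds, function(s) {
    set.seed(s)
    ds <- one_unit_dataset(simulate_unit(excit, p, "u1"))
    bilateral_modulation_tests(ds, "u1", th)$rate_ON_p < 0.05
  }, logical(1))
  expect_gte(mean(rate_hits), 0.80)
  expect_lt(abs(mean(rate_hits) - oracle_power), 0.10)

  # Halved bilateral amplitude: classified bilateral with suppression.
  supp <- unit_archetype("bilateral_suppressive", 4,
                         amp3(40, bilateral = 20), amp3(0))
  supp_calls <- vapply(seeds, function(s) {
    set.seed(s)
    ds <- one_unit_dataset(simulate_unit(supp, p, "u1"))
    cls <- classify_unit(ds, "u1", th)
    cls$response_class == "bilateral" && cls$integration_on == "suppression"
  }, logical(1))
  expect_gte(mean(supp_calls), 0.90)
})

test_that("purely contralateral units are rarely mislabeled bilateral", {
  # Type-I control: with bilateral trains distributed exactly like the
  # contralateral ones, false bilateral calls come only from chance firing
  # of the six criteria; the documented bound is 2 x alpha x 4 tests.
  p <- default_protocol()
  arch <- unit_archetype("contra_only", 4, amp3(40), amp3(12))
  set.seed(53)
  calls <- vapply(1:200, function(i) {
    ds <- one_unit_dataset(simulate_unit(arch, p, "u1"))
    classify_unit(ds, "u1")$response_class
  }, character(1))
  expect_true(all(calls %in% c("bilateral", "contralateral")))
  expect_lte(mean(calls == "bilateral"), 2 * 0.05 * 4)
})

test_that("classification is deterministic and monotone in the thresholds", {
  ds <- simulate_cohort(sim_config(n_units_per_cell = 15L, seed = 61L))
  cls1 <- classify_cohort(ds)
  cls2 <- classify_cohort(ds)
  expect_identical(cls1, cls2)

  n_responsive <- function(fold, floor_hz) {
    sum(classify_cohort(ds, classifier_thresholds(
      responsiveness_fold = fold,
      min_peak_rate = floor_hz))$visually_responsive)
  }
  expect_gte(n_responsive(2, 5), n_responsive(3, 5))
  expect_gte(n_responsive(3, 5), n_responsive(3, 15))

  n_bilateral <- function(alpha) {
    sum(classify_cohort(ds, classifier_thresholds(alpha = alpha))$
          response_class == "bilateral")
  }
  expect_gte(n_bilateral(0.05), n_bilateral(0.01))
  expect_gte(n_bilateral(0.01), n_bilateral(0.001))
})
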