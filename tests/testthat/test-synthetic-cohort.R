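# Synthetic cohort generator: study-design constants, score generation,
# and the missing-at-random deletion mechanism.

test_that("default configuration encodes the reference study design", {
  cfg <- default_cohort_config()
  expect_equal(nrow(cfg$groups), 6L)
  expect_equal(sum(cfg$groups$proportion), 1, tolerance = 1e-12)
  expect_equal(cfg$groups$proportion[cfg$groups$label == "unaffected"],
               0.325 / 0.999)
  adhd <- cfg$scales[cfg$scales$phenotype == "adhd", ]
  expect_equal(adhd$lo, 7)
  expect_equal(adhd$hi, 35)
  expect_equal(length(cfg$ages), 8L)
  # final assessment gap is two years (13 -> 15)
  expect_equal(diff(cfg$ages)[7], 2)
  expect_equal(cfg$n_subjects, 1620L)
  # twelve distal outcomes
  expect_equal(nrow(cfg$outcomes), 12L)
  # missingness calibrated to the per-wave observed counts, e.g.
  # externalising at age 12: 1 - 953/1620
  r <- cfg$missingness$rate[cfg$missingness$phenotype == "externalising" &
                              cfg$missingness$age == 12]
  expect_equal(r, 1 - 953 / 1620, tolerance = 1e-12)
})

test_that("group draws follow the configured proportions", {
  cfg <- one_phen_config(200, groups = 2L)
  sim <- simulate_cohort(cfg, seed = 5)
  counts <- table(sim$truth$group)
  # binomial: 3 * sqrt(n p (1-p)) around n/2
  expect_lt(abs(counts[[1]] - 100), 3 * sqrt(200 * 0.25))
  expect_equal(sum(counts), 200)
})

test_that("degenerate noise gives exact polynomial scores", {
  cfg <- one_phen_config(50, groups = 1L)
  cfg$coeffs$b0 <- 20
  cfg$coeffs$b1 <- 0
  cfg$sigma$sigma <- 1e-12
  sim <- simulate_cohort(cfg, seed = 2)
  expect_true(all(abs(sim$panel$score - 20) < 1e-9))
})

test_that("a mean above the ceiling piles essentially all mass at the ceiling", {
  cfg <- one_phen_config(500, groups = 1L)
  cfg$coeffs$b0 <- 40  # scale is [7, 35]
  cfg$coeffs$b1 <- 0
  cfg$sigma$sigma <- 1
  sim <- simulate_cohort(cfg, seed = 3)
  # Normal-tail oracle: P(Y* < 35) = Phi((35-40)/1) ~ 3e-7
  expect_gte(mean(sim$panel$score == 35), 0.99)
  expect_true(all(sim$panel$score <= 35))
})

test_that("all generated scores lie inside their scale bounds", {
  cfg <- default_cohort_config(300)
  sim <- simulate_cohort(cfg, seed = 7)
  joined <- dplyr::left_join(sim$panel, cfg$scales, by = "phenotype")
  expect_true(all(joined$score >= joined$lo & joined$score <= joined$hi))
})

test_that("equal seeds reproduce bit-identical cohorts; different seeds differ", {
  cfg <- small_cohort_config(80)
  a <- simulate_cohort(cfg, seed = 10)
  b <- simulate_cohort(cfg, seed = 10)
  c <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$panel, b$panel)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$panel$score, c$panel$score))
})

test_that("per-group wave means converge to the generating polynomial without censoring", {
  cfg <- one_phen_config(2000, groups = 2L)
  cfg$scales$lo <- -Inf
  cfg$scales$hi <- Inf
  sim <- simulate_cohort(cfg, seed = 13)
  dat <- dplyr::left_join(sim$panel, sim$truth, by = "subject_id")
  means <- dat |>
    dplyr::group_by(.data$group, .data$age) |>
    dplyr::summarise(m = mean(.data$score), n = dplyr::n(), .groups = "drop")
  cf <- cfg$coeffs
  for (i in seq_len(nrow(means))) {
    g <- means$group[i]
    mu <- cf$b0[g] + cf$b1[g] * (means$age[i] - 11)
    tol <- 3 * cfg$sigma$sigma / sqrt(means$n[i])
    expect_lt(abs(means$m[i] - mu), tol)
  }
})

test_that("MAR deletion hits the target marginal rates", {
  cfg <- default_cohort_config()
  sim <- simulate_cohort(cfg, seed = 21)
  mp <- apply_mar_missingness(sim$panel, cfg, seed = 22)
  obs <- mp |>
    dplyr::group_by(.data$phenotype, .data$age) |>
    dplyr::summarise(miss = mean(is.na(.data$score)), n = dplyr::n(),
                     .groups = "drop")
  chk <- dplyr::inner_join(obs, cfg$missingness, by = c("phenotype", "age"))
  tol <- 3 * sqrt(chk$rate * (1 - chk$rate) / chk$n)
  expect_true(all(abs(chk$miss - chk$rate) <= pmax(tol, 1e-9)))
})

test_that("zero target rate leaves the panel unchanged", {
  cfg <- small_cohort_config(100)
  cfg$missingness$rate <- 0
  cfg$mar_gamma <- 0
  sim <- simulate_cohort(cfg, seed = 1)
  expect_identical(apply_mar_missingness(sim$panel, cfg, seed = 2), sim$panel)
})

test_that("a 50% MCAR target yields an empirical rate within binomial tolerance", {
  cfg <- small_cohort_config(1620)
  cfg$missingness$rate <- 0.5
  cfg$mar_gamma <- 0
  sim <- simulate_cohort(cfg, seed = 4)
  mp <- apply_mar_missingness(sim$panel, cfg, seed = 5)
  rate <- mean(is.na(mp$score))
  expect_lt(abs(rate - 0.5), 0.04)
})

test_that("rates of one are rejected; incomplete panels are rejected", {
  cfg <- small_cohort_config(50)
  sim <- simulate_cohort(cfg, seed = 1)
  bad <- cfg
  bad$missingness$rate[1] <- 0.999999
  bad$missingness$rate <- pmin(bad$missingness$rate, 0.999999)
  expect_error(cohort_config(
    n_subjects = 10, ages = cfg$ages, groups = cfg$groups,
    coeffs = cfg$coeffs, sigma = cfg$sigma, scales = cfg$scales,
    missingness = dplyr::mutate(cfg$missingness, rate = 1)),
    "missingness")
  mp <- apply_mar_missingness(sim$panel, cfg, seed = 2)
  expect_error(apply_mar_missingness(mp, cfg, seed = 3), "complete")
})

test_that("deletion at a wave never depends on that wave's own value", {
  # construction audit: perturbing a final-wave score must not change which
  # final-wave observations are deleted (it may change later waves only,
  # and there are none after the final wave)
  cfg <- small_cohort_config(200)
  sim <- simulate_cohort(cfg, seed = 31)
  panel2 <- sim$panel
  last_age <- max(cfg$ages)
  rows <- which(panel2$age == last_age & panel2$phenotype == "adhd")
  panel2$score[rows] <- pmin(pmax(panel2$score[rows] + 5, 7), 35)
  m1 <- apply_mar_missingness(sim$panel, cfg, seed = 32)
  m2 <- apply_mar_missingness(panel2, cfg, seed = 32)
  expect_identical(is.na(m1$score[rows]), is.na(m2$score[rows]))
})

test_that("monotone dropout carries missingness forward", {
  cfg <- small_cohort_config(300)
  cfg$monotone_dropout <- TRUE
  cfg$missingness$rate <- rep(seq(0.05, 0.4, length.out = 8), 3)
  sim <- simulate_cohort(cfg, seed = 8)
  mp <- apply_mar_missingness(sim$panel, cfg, seed = 9)
  wide <- mp |>
    dplyr::filter(.data$phenotype == "adhd") |>
    tidyr::pivot_wider(names_from = "age", values_from = "score")
  m <- is.na(as.matrix(wide[, -(1:2)]))
  # once missing, always missing afterwards
  for (i in seq_len(nrow(m)))
    expect_true(all(diff(as.integer(m[i, ])) >= 0))
})

test_that("lognormal outcome option matches the requested moments roughly", {
  cfg <- small_cohort_config(4000)
  cfg$outcome_lognormal <- TRUE
  cfg$outcomes$observed_fraction <- 1
  sim <- simulate_cohort(cfg, seed = 17)
  dat <- dplyr::inner_join(sim$outcomes, sim$truth, by = "subject_id") |>
    dplyr::filter(.data$outcome == "outcome_1", .data$group == 1)
  expect_equal(mean(dat$value), 10, tolerance = 0.05)
  expect_gt(moments_skew <- mean(((dat$value - mean(dat$value)) /
                                    sd(dat$value))^3), 0.5)
})
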