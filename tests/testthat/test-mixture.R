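# Multi-trajectory mixture: likelihood pieces, EM fitting, BIC, posteriors.

test_that("trajectory_mean evaluates the centered-age polynomial", {
  expect_equal(trajectory_mean(c(10, 0, 0), 11), 10)
  expect_equal(trajectory_mean(c(0, 1, 0), 13), 2)
  expect_equal(trajectory_mean(c(1, 2, 3), 13), 17)
  # vectorised over age
  expect_equal(trajectory_mean(c(1, 1), c(10, 12)), c(0, 2))
})

test_that("single-group subject loglik equals the plain emission sum", {
  cfg <- one_phen_config(30, groups = 1L)
  sim <- simulate_cohort(cfg, seed = 1)
  fit <- fit_fast(sim$panel, J = 1)
  ll <- subject_logliks(sim$panel, fit)
  # direct: sum of censored-normal log densities under the single group
  cf <- fit$coeffs
  direct <- sim$panel |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ll = sum(censored_normal_loglik(
      .data$score,
      cf$b0 + cf$b1 * (.data$age - 11) + cf$b2 * (.data$age - 11)^2,
      fit$sigma[["adhd"]], 7, 35)), .groups = "drop")
  expect_equal(ll$loglik, direct$ll, tolerance = 1e-10)
})

test_that("identical groups collapse the mixture to one component", {
  cfg <- one_phen_config(25, groups = 1L)
  sim <- simulate_cohort(cfg, seed = 2)
  f1 <- fit_fast(sim$panel, J = 1)
  # hand-build a 3-group model whose groups share f1's parameters
  f3 <- f1
  f3$J <- 3L
  f3$theta <- c(0, 0.7, -0.4)
  f3$pi <- group_membership_probs(f3$theta)
  f3$beta <- lapply(f3$beta, function(B) B[rep(1L, 3L), , drop = FALSE])
  f3$coeffs <- dplyr::bind_rows(f1$coeffs, f1$coeffs, f1$coeffs)
  f3$coeffs$group <- 1:3
  expect_equal(subject_logliks(sim$panel, f3)$loglik,
               subject_logliks(sim$panel, f1)$loglik, tolerance = 1e-10)
  # posteriors equal the prior when groups are indistinguishable
  pa <- posterior_assignments(sim$panel, f3)
  expect_equal(unname(as.matrix(pa[, c("p_1", "p_2", "p_3")])),
               matrix(f3$pi, nrow(pa), 3, byrow = TRUE), tolerance = 1e-9)
  expect_true(all(pa$modal == 2L))  # highest prior wins; ties go lowest index
})

test_that("two-group toy loglik matches a brute-force mixture sum", {
  # hand-set model, two time points, one phenotype
  scales <- scale_specs("adhd", 7, 35)
  panel <- tibble::tibble(subject_id = 1L, age = c(9, 13),
                          phenotype = "adhd", score = c(12, 35))
  model <- list(
    J = 2L, K = 1L, order = 1L, phenotypes = "adhd",
    theta = c(0, log(0.6 / 0.4)), pi = c(0.4, 0.6),
    beta = list(matrix(c(11, 30, 0.5, 1.5), 2, 2)),
    coeffs = tibble::tibble(group = 1:2, phenotype = "adhd",
                            b0 = c(11, 30), b1 = c(0.5, 1.5)),
    sigma = c(adhd = 2), scales = scales, center_age = 11,
    ages = c(9, 13), n_subjects = 1L, subjects = 1L)
  class(model) <- "multitraj_fit"
  got <- subject_logliks(panel, model)$loglik
  # independent two-term summation
  mu1 <- c(11 + 0.5 * (-2), 11 + 0.5 * 2)
  mu2 <- c(30 + 1.5 * (-2), 30 + 1.5 * 2)
  t1 <- dnorm(12, mu1[1], 2, log = TRUE) +
    pnorm(35, mu1[2], 2, lower.tail = FALSE, log.p = TRUE)
  t2 <- dnorm(12, mu2[1], 2, log = TRUE) +
    pnorm(35, mu2[2], 2, lower.tail = FALSE, log.p = TRUE)
  expected <- log(0.4 * exp(t1) + 0.6 * exp(t2))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("subjects with zero observations are rejected with a distinct signal", {
  panel <- tibble::tibble(subject_id = c(1L, 2L, 2L),
                          age = c(7, 7, 9), phenotype = "adhd",
                          score = c(NA, 15, 16))
  expect_error(fit_fast(panel, J = 1, scales = scale_specs("adhd", 7, 35)),
               class = "trajmix_empty_subject")
})

test_that("permuting subject order leaves the maximised loglik unchanged", {
  cfg <- one_phen_config(120, groups = 2L)
  sim <- simulate_cohort(cfg, seed = 6)
  shuffled <- sim$panel[sample(nrow(sim$panel)), ]
  f1 <- fit_fast(sim$panel, J = 2, seed = 3)
  f2 <- fit_fast(shuffled, J = 2, seed = 3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("EM never decreases the log-likelihood", {
  cfg <- small_cohort_config(150)
  sim <- simulate_cohort(cfg, seed = 9)
  mp <- apply_mar_missingness(sim$panel, cfg, seed = 10)
  fit <- fit_fast(mp, J = 3, seed = 4)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("bic follows the -2 logLik + k log n convention", {
  fake <- structure(list(loglik = -100, n_params = 5L, n_subjects = 100L),
                    class = "multitraj_fit")
  expect_equal(bic(fake), 200 + 5 * log(100), tolerance = 1e-4)
  expect_equal(bic(fake), 223.0259, tolerance = 1e-4)
  zero <- structure(list(loglik = 0, n_params = 0L, n_subjects = 10L),
                    class = "multitraj_fit")
  expect_equal(bic(zero), 0)
  plus1 <- structure(list(loglik = -100, n_params = 6L, n_subjects = 100L),
                     class = "multitraj_fit")
  expect_equal(bic(plus1) - bic(fake), log(100))
})

test_that("one-group recovery: coefficients within 3 SE of truth", {
  cfg <- one_phen_config(500, groups = 1L)
  cfg$coeffs$b0 <- 18
  cfg$coeffs$b1 <- 0.8
  sim <- simulate_cohort(cfg, seed = 12)
  fit <- fit_multitrajectory(sim$panel, J = 1, seed = 1, tol = 1e-6,
                             se = TRUE)
  expect_true(fit$se_ok)
  expect_lt(abs(fit$coeffs$b0 - 18), 3 * fit$coeffs$se_b0)
  expect_lt(abs(fit$coeffs$b1 - 0.8), 3 * fit$coeffs$se_b1)
})

test_that("two well-separated groups: proportions recovered within 0.06", {
  cfg <- one_phen_config(400, groups = 2L)
  # separation of 4 sigma at the centering age (17 vs 27 with sigma 2.5)
  cfg$coeffs$b0 <- c(17, 27)
  cfg$coeffs$b1 <- c(0, 0)
  sim <- simulate_cohort(cfg, seed = 14)
  fit <- fit_fast(sim$panel, J = 2, seed = 2)
  expect_lt(max(abs(sort(fit$pi) - 0.5)), 0.06)
})

test_that("posterior rows normalise and extreme subjects are assigned confidently", {
  cfg <- one_phen_config(100, groups = 2L)
  cfg$coeffs$b0 <- c(12, 27)  # 6 sigma apart
  cfg$coeffs$b1 <- c(0, 0)
  cfg$sigma$sigma <- 2.5
  sim <- simulate_cohort(cfg, seed = 15)
  fit <- fit_fast(sim$panel, J = 2, seed = 5)
  pa <- posterior_assignments(sim$panel, fit)
  expect_equal(rowSums(as.matrix(pa[, c("p_1", "p_2")])), rep(1, nrow(pa)),
               tolerance = 1e-9)
  expect_gt(mean(pa$p_modal > 0.99), 0.9)
  app <- average_posterior_prob(pa)
  expect_true(all(app$app >= 0.5 & app$app <= 1))
})

test_that("relabelling groups leaves the likelihood invariant", {
  cfg <- small_cohort_config(120)
  sim <- simulate_cohort(cfg, seed = 16)
  fit <- fit_fast(sim$panel, J = 3, seed = 6)
  perm <- c(3L, 1L, 2L)
  swapped <- relabel_groups(fit, perm)
  expect_equal(subject_logliks(sim$panel, swapped)$loglik,
               subject_logliks(sim$panel, fit)$loglik, tolerance = 1e-9)
})

test_that("warm starts reproduce and continue a previous fit", {
  cfg <- one_phen_config(150, groups = 2L)
  sim <- simulate_cohort(cfg, seed = 18)
  fit <- fit_fast(sim$panel, J = 2, seed = 7)
  warm <- fit_multitrajectory(sim$panel, J = 2, start = fit, tol = 1e-8,
                              max_iter = 200)
  expect_gte(warm$loglik, fit$loglik - 1e-8)
})

test_that("model selection table has one row per candidate and flags small groups", {
  cfg <- one_phen_config(200, groups = 2L)
  sim <- simulate_cohort(cfg, seed = 19)
  sel <- select_model(sim$panel, J_range = 1:3, seed = 8,
                      n_starts = fast$n_starts, short_iter = fast$short_iter,
                      tol = fast$tol, max_iter = fast$max_iter,
                      min_share = 0.05)
  expect_equal(nrow(sel), 3L)
  expect_equal(sel$J, 1:3)
  expect_true(attr(sel, "chosen_J") %in% 1:3)
  expect_true(all(!is.na(sel$bic)))
})

test_that("per-candidate fit failures are recorded in the selection table, not fatal", {
  cfg <- one_phen_config(60, groups = 1L)
  sim <- simulate_cohort(cfg, seed = 22)
  sel <- select_model(sim$panel, J_range = c(0L, 1L), seed = 9,
                      n_starts = fast$n_starts, short_iter = fast$short_iter,
                      tol = fast$tol, max_iter = fast$max_iter)
  expect_equal(nrow(sel), 2L)
  expect_false(is.na(sel$error[sel$J == 0]))
  expect_true(is.na(sel$error[sel$J == 1]))
  expect_equal(attr(sel, "chosen_J"), 1L)
})
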