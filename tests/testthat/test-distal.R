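# One-step joint estimation of trajectory groups and distal outcome means.

make_joint_fixture <- function(n = 200, seed = 1) {
  cfg <- small_cohort_config(n)
  sim <- simulate_cohort(cfg, seed = seed)
  fit <- fit_fast(sim$panel, J = 3, seed = seed)
  list(cfg = cfg, sim = sim, fit = fit)
}

test_that("with no observed outcomes the joint loglik reduces to the mixture loglik", {
  fx <- make_joint_fixture(80, seed = 2)
  jf <- fit_joint(fx$sim$panel, fx$sim$outcomes, start = fx$fit,
                  tol = 1e-5, se = FALSE)
  empty <- fx$sim$outcomes
  empty$value <- NA_real_
  expect_equal(joint_subject_logliks(fx$sim$panel, empty, jf)$loglik,
               subject_logliks(fx$sim$panel, jf)$loglik, tolerance = 1e-10)
})

test_that("equal outcome means leave group posteriors at their trajectory-only values", {
  fx <- make_joint_fixture(60, seed = 3)
  jf <- fit_joint(fx$sim$panel, fx$sim$outcomes, start = fx$fit,
                  tol = 1e-5, se = FALSE)
  # force all groups to share outcome means and variances
  jf$Mu <- matrix(rep(colMeans(jf$Mu), each = 3), nrow = 3)
  ns <- asNamespace("trajmix")
  bl <- ns$panel_blocks(fx$sim$panel, jf$scales, jf$order, jf$center_age)
  ocl <- fx$sim$outcomes[!is.na(fx$sim$outcomes$value), ]
  Z <- ns$outcomes_to_matrix(ocl, bl$subjects, jf$outcome_names)
  A_traj <- ns$cond_loglik_matrix(bl, jf$beta, jf$sigma)
  A_out <- ns$outcome_cond_loglik(Z, jf$Mu, ns$osig_rows(jf$outcome_sd, 3L))
  P_joint <- ns$estep(A_traj + A_out, jf$theta)$P
  P_traj <- ns$estep(A_traj, jf$theta)$P
  expect_equal(P_joint, P_traj, tolerance = 1e-9)
})

test_that("toy two-group joint loglik matches a direct two-term summation", {
  scales <- scale_specs("adhd", 7, 35)
  panel <- tibble::tibble(subject_id = 1L, age = c(9, 13),
                          phenotype = "adhd", score = c(12, 20))
  outcomes <- tibble::tibble(subject_id = 1L, outcome = "y", value = 3.2)
  model <- list(
    J = 2L, K = 1L, order = 1L, phenotypes = "adhd",
    theta = c(0, log(2)), pi = c(1 / 3, 2 / 3),
    beta = list(matrix(c(11, 21, 0.5, -0.5), 2, 2)),
    coeffs = tibble::tibble(group = 1:2, phenotype = "adhd",
                            b0 = c(11, 21), b1 = c(0.5, -0.5)),
    sigma = c(adhd = 2), scales = scales, center_age = 11,
    ages = c(9, 13), n_subjects = 1L, subjects = 1L,
    Mu = matrix(c(2, 5), 2, 1), outcome_sd = c(y = 1.5),
    outcome_names = "y")
  class(model) <- c("joint_fit", "multitraj_fit")
  got <- joint_subject_logliks(panel, outcomes, model)$loglik
  term <- function(b0, b1, muo) {
    dnorm(12, b0 + b1 * (-2), 2, log = TRUE) +
      dnorm(20, b0 + b1 * 2, 2, log = TRUE) +
      dnorm(3.2, muo, 1.5, log = TRUE)
  }
  expected <- log(1 / 3 * exp(term(11, 0.5, 2)) + 2 / 3 * exp(term(21, -0.5, 5)))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("joint EM is monotone and never ends below its warm start", {
  fx <- make_joint_fixture(150, seed = 4)
  jf <- fit_joint(fx$sim$panel, fx$sim$outcomes, start = fx$fit,
                  tol = 1e-6, se = FALSE)
  expect_true(all(diff(jf$loglik_trace) > -1e-8))
  expect_gte(jf$loglik, jf$start_loglik - 1e-8)
})

test_that("doubling every outcome value doubles the estimated means and SDs", {
  fx <- make_joint_fixture(120, seed = 5)
  jf1 <- fit_joint(fx$sim$panel, fx$sim$outcomes, start = fx$fit,
                   tol = 1e-6, se = FALSE)
  doubled <- fx$sim$outcomes
  doubled$value <- doubled$value * 2
  jf2 <- fit_joint(fx$sim$panel, doubled, start = fx$fit,
                   tol = 1e-6, se = FALSE)
  expect_equal(jf2$Mu, 2 * jf1$Mu, tolerance = 1e-3)
  expect_equal(unname(jf2$outcome_sd), unname(2 * jf1$outcome_sd),
               tolerance = 1e-3)
})

test_that("group-specific outcome variances are available behind a flag", {
  fx <- make_joint_fixture(120, seed = 6)
  jf <- suppressWarnings(fit_joint(fx$sim$panel, fx$sim$outcomes,
                                   start = fx$fit, tol = 1e-5,
                                   se = FALSE, group_var = TRUE))
  expect_true(is.matrix(jf$outcome_sd))
  expect_equal(dim(jf$outcome_sd), c(3L, 4L))
  expect_true(all(jf$outcome_sd > 0))
})

test_that("observed-information SEs are positive where groups have members", {
  fx <- make_joint_fixture(200, seed = 7)
  jf <- fit_joint(fx$sim$panel, fx$sim$outcomes, start = fx$fit, tol = 1e-5)
  expect_true(jf$se_ok)
  expect_true(all(jf$outcome_se$se > 0))
  # SEs shrink roughly like 1/sqrt(group size): biggest group has smallest SE
  one_out <- jf$outcome_se[jf$outcome_se$outcome == "outcome_1", ]
  expect_equal(which.min(one_out$se), which.max(jf$pi))
})

test_that("stability report is zero for an unrefitted model and label-invariant", {
  fx <- make_joint_fixture(100, seed = 8)
  jf <- fit_joint(fx$sim$panel, fx$sim$outcomes, start = fx$fit,
                  tol = 1e-5, se = FALSE)
  # "after = before with outcomes appended": same trajectory parameters
  clone <- jf
  clone$beta <- fx$fit$beta
  clone$coeffs <- fx$fit$coeffs
  rep0 <- trajectory_stability_check(fx$fit, clone)
  expect_equal(rep0$max_diff, 0)
  expect_true(rep0$pass)
  # permuted labels give the identical report
  perm <- c(2L, 3L, 1L)
  rep_perm <- trajectory_stability_check(fx$fit, relabel_groups(jf, perm))
  rep_id <- trajectory_stability_check(fx$fit, jf)
  expect_equal(rep_perm$max_diff, rep_id$max_diff, tolerance = 1e-12)
})

test_that("refitting with outcomes moves predicted trajectories less than one score unit", {
  fx <- make_joint_fixture(300, seed = 9)
  jf <- fit_joint(fx$sim$panel, fx$sim$outcomes, start = fx$fit,
                  tol = 1e-5, se = FALSE)
  rep <- trajectory_stability_check(fx$fit, jf, tol = 1.0)
  expect_true(rep$pass)
})

test_that("stability check rejects models with different group counts", {
  fx <- make_joint_fixture(60, seed = 10)
  f2 <- fit_fast(fx$sim$panel, J = 2, seed = 11)
  expect_error(trajectory_stability_check(f2, fx$fit), "different numbers")
})

test_that("null outcomes: estimated group means differ by less than 3 pooled SEs", {
  # outcomes carry no group signal; over replicates the pairwise mean
  # differences should stay within sampling noise
  n_rep <- 10L
  ok <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- null_outcome_config(250)
    sim <- simulate_cohort(cfg, seed = 300 + r)
    fit <- fit_fast(sim$panel, J = 3, seed = r)
    jf <- fit_joint(sim$panel, sim$outcomes, start = fit, tol = 1e-4)
    if (!jf$se_ok) next
    om <- jf$outcome_means[jf$outcome_means$outcome == "outcome_1", ]
    pairs <- utils::combn(3L, 2L)
    within <- all(abs(om$mean[pairs[1, ]] - om$mean[pairs[2, ]]) <
                    3 * sqrt(om$se[pairs[1, ]]^2 + om$se[pairs[2, ]]^2))
    ok <- ok + within
  }
  expect_gte(ok, ceiling(0.9 * n_rep))
})

test_that("outcomes with a 1.5 SD group gap recover the true rank order", {
  n_rep <- 10L
  good <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- small_cohort_config(250)
    sim <- simulate_cohort(cfg, seed = 400 + r)
    fit <- fit_fast(sim$panel, J = 3, seed = r)
    jf <- fit_joint(sim$panel, sim$outcomes, start = fit, tol = 1e-4,
                    se = FALSE)
    perm <- match_groups_to_truth(jf, cfg)
    om <- jf$outcome_means[jf$outcome_means$outcome == "outcome_2", ]
    recovered <- om$mean[match(perm, om$group)]
    good <- good + (all(order(recovered) == 1:3))
  }
  expect_gte(good, ceiling(0.9 * n_rep))
})
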