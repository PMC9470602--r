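#' Tidy a fitted multi-trajectory model
#'
#' @param x A `multitraj_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `component` (`"proportion"`,
#'   `"trajectory"` or `"sigma"`), `group`, `phenotype`, `term`, `estimate`
#'   and, when available, `std.error`.
#' @method tidy multitraj_fit
#' @export
tidy.multitraj_fit <- function(x, ...) {
  props <- tibble::tibble(component = "proportion", group = seq_len(x$J),
                          phenotype = NA_character_, term = "pi",
                          estimate = x$pi)
  bcols <- grep("^b[0-9]+$", names(x$coeffs), value = TRUE)
  traj <- tidyr::pivot_longer(
    x$coeffs[, c("group", "phenotype", bcols)],
    dplyr::all_of(bcols), names_to = "term", values_to = "estimate")
  traj$component <- "trajectory"
  secols <- grep("^se_b[0-9]+$", names(x$coeffs), value = TRUE)
  if (length(secols)) {
    ses <- tidyr::pivot_longer(
      x$coeffs[, c("group", "phenotype", secols)],
      dplyr::all_of(secols), names_to = "term", values_to = "std.error")
    ses$term <- sub("^se_", "", ses$term)
    traj <- dplyr::left_join(traj, ses, by = c("group", "phenotype", "term"))
  }
  sig <- tibble::tibble(component = "sigma", group = NA_integer_,
                        phenotype = x$phenotypes, term = "sigma",
                        estimate = unname(x$sigma))
  dplyr::bind_rows(props, traj[, union(names(props), names(traj))], sig)
}

#' Tidy a joint trajectory-plus-outcomes model
#'
#' @param x A `joint_fit`.
#' @param components Which parameter blocks to return: any of
#'   `"outcomes"`, `"trajectory"`, `"proportion"`, `"sigma"`.
#' @param ... Unused.
#' @return A tibble of parameter estimates; outcome-mean rows carry
#'   `outcome`, `group`, `estimate` and `std.error` (when available).
#' @method tidy joint_fit
#' @export
tidy.joint_fit <- function(x, components = c("outcomes", "trajectory",
                                             "proportion", "sigma"), ...) {
  components <- match.arg(components, several.ok = TRUE)
  base <- tidy.multitraj_fit(x)
  base <- base[base$component %in% components, , drop = FALSE]
  out <- NULL
  if ("outcomes" %in% components) {
    out <- x$outcome_means
    out$component <- "outcomes"
    out$term <- "mean"
    out <- dplyr::rename(out, estimate = "mean")
    if ("se" %in% names(out)) out <- dplyr::rename(out, std.error = "se")
  }
  dplyr::bind_rows(out, base)
}

#' One-row model summary
#'
#' @param x A `multitraj_fit` or `joint_fit`.
#' @param ... Unused.
#' @return Tibble with `logLik`, `n_params`, `BIC`, `J`, `nobs`,
#'   `converged`, `n_iter`.
#' @method glance multitraj_fit
#' @export
glance.multitraj_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_params = x$n_params, BIC = bic(x),
                 J = x$J, nobs = x$n_subjects, converged = x$converged,
                 n_iter = x$n_iter)
}

#' Plot model-predicted trajectories
#'
#' One panel per phenotype, one line per latent group, in the style of the
#' usual trajectory-group figure.
#'
#' @param object A `multitraj_fit` (or `joint_fit`).
#' @param ages Ages at which to draw the curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot multitraj_fit
#' @export
autoplot.multitraj_fit <- function(object, ages = NULL, ...) {
  tr <- predict_trajectories(object, ages)
  tr$group <- factor(tr$group)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$age, y = .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$phenotype, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = "Model-predicted score",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot a pooled outcome table
#'
#' Pooled group means with confidence intervals, one panel per outcome -
#' the figure form of the pooled report.
#'
#' @param object A `pooled_outcomes` tibble from [pool_outcome_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pooled_outcomes
#' @export
autoplot.pooled_outcomes <- function(object, ...) {
  df <- object
  df$group <- factor(df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(~ .data$outcome, scales = "free_y") +
    ggplot2::labs(x = "Trajectory group", y = "Pooled mean (95% CI)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.multitraj_fit
#' @param model A fitted model.
#' @export
plot_trajectories <- function(model, ages = NULL) {
  autoplot.multitraj_fit(model, ages)
}

#' @rdname autoplot.pooled_outcomes
#' @param pooled A `pooled_outcomes` tibble.
#' @export
plot_pooled_outcomes <- function(pooled) {
  autoplot.pooled_outcomes(pooled)
}
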