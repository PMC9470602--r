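# Group labels in a mixture are arbitrary; fits of the same data (or of
# different imputations) can return the same groups in different orders.
# Alignment matches groups across fits by their model-predicted trajectory
# curves, searched exactly over permutations (fine for J <= 8).

all_perms <- function(J) {
  if (J == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(J)) {
    rest <- all_perms(J - 1L)
    out <- c(out, lapply(rest, function(p) {
      q <- seq_len(J)[-i]
      c(i, q[p])
    }))
  }
  out
}

# J x (K * n_ages) matrix of predicted trajectory means
curve_matrix <- function(model, ages) {
  tr <- predict_trajectories(model, ages = ages)
  tr <- tr[order(tr$phenotype, tr$age, tr$group), ]
  matrix(tr$mean, nrow = model$J)
}

# perm[j] = group index in `curves` matching reference group j, minimizing
# the summed squared curve distance.
match_curves <- function(ref_curves, curves) {
  J <- nrow(ref_curves)
  cost <- matrix(0, J, J)
  for (a in seq_len(J))
    for (b in seq_len(J))
      cost[a, b] <- sum((ref_curves[a, ] - curves[b, ])^2)
  perms <- all_perms(J)
  totals <- vapply(perms, function(p) sum(cost[cbind(seq_len(J), p)]),
                   numeric(1L))
  best <- perms[[which.min(totals)]]
  list(perm = best, total = min(totals),
       max_abs = vapply(seq_len(J), function(j)
         max(abs(ref_curves[j, ] - curves[best[j], ])), numeric(1L)))
}

#' Align group labels across fitted models
#'
#' Resolves label switching between fits of the same number of groups
#' (typically one fit per imputed dataset) by matching model-predicted
#' trajectory curves - all phenotypes at all assessment ages - to a
#' reference fit, minimizing the summed squared distance over all label
#' permutations (exact search). Also reports, per group, the largest
#' post-alignment curve discrepancy, the quantitative version of checking
#' that "the same groups" emerged in every fit.
#'
#' @param models List of fitted `multitraj_fit`/`joint_fit` objects with
#'   equal `J`.
#' @param reference Index of the reference model (default 1).
#' @param ages Ages at which curves are compared (default: the reference
#'   model's fitting ages).
#' @return List with `permutations` (per model, `perm[j]` = that model's
#'   group matching reference group `j`; the reference gets the identity)
#'   and `discrepancy`, a tibble (`model`, `group`, `max_abs_diff`) of
#'   post-alignment curve discrepancies in score units.
#' @export
align_group_labels <- function(models, reference = 1L, ages = NULL) {
  J <- unique(vapply(models, `[[`, numeric(1L), "J"))
  if (length(J) != 1L)
    stop("all models must have the same number of groups", call. = FALSE)
  ref <- models[[reference]]
  ages <- ages %||% ref$ages
  ref_curves <- curve_matrix(ref, ages)
  perms <- vector("list", length(models))
  disc <- list()
  for (m in seq_along(models)) {
    if (m == reference) {
      perms[[m]] <- seq_len(J)
      disc[[m]] <- tibble::tibble(model = m, group = seq_len(J),
                                  max_abs_diff = 0)
      next
    }
    mm <- match_curves(ref_curves, curve_matrix(models[[m]], ages))
    perms[[m]] <- mm$perm
    disc[[m]] <- tibble::tibble(model = m, group = seq_len(J),
                                max_abs_diff = mm$max_abs)
  }
  list(permutations = perms, discrepancy = dplyr::bind_rows(disc))
}

#' Relabel the groups of a fitted model
#'
#' Applies a label permutation (as produced by [align_group_labels()]) so
#' that group `j` of the result is the model's former group `perm[j]`.
#'
#' @param model A `multitraj_fit` or `joint_fit`.
#' @param perm Integer permutation of `1:J`.
#' @return The relabelled model.
#' @export
relabel_groups <- function(model, perm) {
  stopifnot(length(perm) == model$J, all(sort(perm) == seq_len(model$J)))
  inv <- order(perm)
  th <- model$theta[perm]
  model$theta <- th - th[1L]
  model$pi <- model$pi[perm]
  model$beta <- lapply(model$beta, function(B) B[perm, , drop = FALSE])
  model$coeffs$group <- inv[model$coeffs$group]
  model$coeffs <- model$coeffs[order(model$coeffs$phenotype, model$coeffs$group), ]
  if (!is.null(model$Mu)) {
    model$Mu <- model$Mu[perm, , drop = FALSE]
    model$outcome_means$group <- inv[model$outcome_means$group]
    model$outcome_means <- model$outcome_means[
      order(model$outcome_means$outcome, model$outcome_means$group), ]
    if (!is.null(model$outcome_se)) {
      model$outcome_se$group <- inv[model$outcome_se$group]
      model$outcome_se <- model$outcome_se[
        order(model$outcome_se$outcome, model$outcome_se$group), ]
    }
    if (is.matrix(model$outcome_sd))
      model$outcome_sd <- model$outcome_sd[perm, , drop = FALSE]
  }
  model
}

#' Match fitted groups to the generating groups of a synthetic cohort
#'
#' For recovery studies on simulated data: matches a fitted model's groups
#' to the generating configuration's groups by their trajectory curves
#' (same exact permutation search as [align_group_labels()]).
#'
#' @param model A fitted `multitraj_fit`/`joint_fit` with `J` equal to the
#'   config's number of groups.
#' @param config The generating [cohort_config()].
#' @param ages Comparison ages (default: the model's fitting ages).
#' @return Integer permutation: element `g` is the fitted group
#'   corresponding to generating group `g`.
#' @export
match_groups_to_truth <- function(model, config, ages = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (model$J != nrow(config$groups))
    stop("model and config have different numbers of groups", call. = FALSE)
  ages <- ages %||% model$ages
  cf <- config$coeffs
  grid <- tidyr::expand_grid(group = config$groups$group,
                             phenotype = config$scales$phenotype, age = ages)
  idx <- match(paste(grid$group, grid$phenotype),
               paste(cf$group, cf$phenotype))
  cc <- grid$age - config$center_age
  grid$mean <- cf$b0[idx] + cf$b1[idx] * cc + cf$b2[idx] * cc^2
  grid <- grid[order(grid$phenotype, grid$age, grid$group), ]
  truth_curves <- matrix(grid$mean, nrow = nrow(config$groups))
  match_curves(truth_curves, curve_matrix(model, ages))$perm
}
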