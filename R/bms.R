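# Random-effects Bayesian model selection: the model identity is a random
# effect in the population with unknown frequencies r ~ Dirichlet(alpha0).
# A variational Dirichlet-multinomial fixed point estimates the posterior
# concentrations; exceedance probabilities come from Monte-Carlo Dirichlet
# sampling; the Bayesian omnibus risk compares the free energy of this
# model against the equal-frequency null.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Variational random-effects model-frequency estimation
#'
#' Fixed-point iteration: subject-model assignment weights proportional to
#' `exp(evidence + digamma(alpha_k) - digamma(sum(alpha)))`, concentrations
#' `alpha = alpha0 + summed assignments`, to convergence. Expected model
#' frequencies (posterior probabilities) are the normalised concentrations.
#'
#' @param L numeric matrix of approximate log model evidences, rows
#'   subjects, columns models (>= 2), all finite.
#' @param alpha0 prior Dirichlet concentration, scalar or per-model vector.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   concentrations.
#' @return list with `alpha`, `pp`, assignment matrix `u`, free energy `F1`
#'   of the random-effects model, null free energy `F0`, `iterations`,
#'   `converged`.
#' @export
rfx_bms <- function(L, alpha0 = 1, max_iter = 1000, tol = 1e-10) {
  L <- as.matrix(L)
  if (nrow(L) < 1 || ncol(L) < 2) abort("need >= 1 subject and >= 2 models")
  if (!all(is.finite(L))) abort("evidence matrix must be finite")
  K <- ncol(L)
  alpha0 <- rep_len(alpha0, K)
  if (any(alpha0 <= 0)) abort("`alpha0` must be positive")
  alpha <- alpha0 + nrow(L) / K
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    lw <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    u <- exp(lw - apply(lw, 1, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged) warn("model-frequency iteration did not converge")
  # free energy of the random-effects model at the variational optimum
  F1 <- sum(u * L) - sum(u * log(pmax(u, 1e-300))) +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
    lgamma(sum(alpha)) + sum(lgamma(alpha))
  # null: all models equally frequent (r fixed at 1/K)
  F0 <- sum(apply(L, 1, logsumexp) - log(K))
  list(alpha = setNames(alpha, colnames(L)),
       pp = setNames(alpha / sum(alpha), colnames(L)), u = u, F1 = F1,
       F0 = F0, iterations = it, converged = converged)
}

rdirichlet_matrix <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Exceedance, omnibus risk and protected exceedance probabilities
#'
#' The exceedance probability (XP) of a model is the posterior probability
#' that its population frequency exceeds all others, estimated by Monte
#' Carlo from the Dirichlet posterior. The Bayesian omnibus risk (BOR) is
#' the posterior probability of the equal-frequency null given the free
#' energies of null and alternative. The protected exceedance probability
#' is `pxp = (1 - bor) * xp + bor / K`.
#'
#' @param bms result of [rfx_bms()].
#' @param n_samples Monte-Carlo sample count (>= 1e4).
#' @param seed integer seed for the Dirichlet draws.
#' @return list with `xp`, `bor`, `pxp`.
#' @export
exceedance_and_protected <- function(bms, n_samples = 1e6, seed = 1L) {
  if (n_samples < 1e4) abort("`n_samples` must be at least 1e4")
  alpha <- bms$alpha
  K <- length(alpha)
  xp <- withr::with_seed(as.integer(seed), {
    r <- rdirichlet_matrix(n_samples, alpha)
    tabulate(max.col(r, ties.method = "first"), K) / n_samples
  })
  bor <- 1 / (1 + exp(bms$F1 - bms$F0))
  list(xp = setNames(xp, names(alpha)), bor = bor,
       pxp = setNames((1 - bor) * xp + bor / K, names(alpha)))
}

#' Family-level random-effects model selection
#'
#' Aggregates model frequencies within disjoint model families under a
#' family-uniform prior: each model's prior concentration is `1 / family
#' size`, so every family carries equal prior mass. Family posterior
#' probabilities are the summed member concentrations (normalised); family
#' exceedance probabilities come from summed sampled Dirichlet frequencies.
#'
#' @param L evidence matrix as in [rfx_bms()].
#' @param partition named list of character vectors of model ids covering
#'   all columns of `L` disjointly.
#' @param n_samples,seed Monte-Carlo settings as in
#'   [exceedance_and_protected()].
#' @return tibble with columns `family`, `size`, `pp`, `xp`.
#' @export
family_bms <- function(L, partition, n_samples = 1e6, seed = 1L) {
  L <- as.matrix(L)
  members <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, colnames(L))) {
    abort("`partition` must cover all models disjointly")
  }
  fam_of <- rep(names(partition), lengths(partition))[
    match(colnames(L), members)]
  alpha0 <- 1 / lengths(partition)[fam_of]
  fit <- rfx_bms(L, alpha0 = alpha0)
  fam_pp <- tapply(fit$pp, fam_of, sum)
  fam_xp <- withr::with_seed(as.integer(seed), {
    r <- rdirichlet_matrix(n_samples, fit$alpha)
    fr <- sapply(names(partition),
                 function(f) rowSums(r[, fam_of == f, drop = FALSE]))
    tabulate(max.col(fr, ties.method = "first"), length(partition)) /
      n_samples
  })
  tibble::tibble(family = names(partition),
                 size = as.integer(lengths(partition)),
                 pp = as.numeric(fam_pp[names(partition)]),
                 xp = fam_xp)
}

#' Default family partitions of the 16-model space
#'
#' Three partitions: with versus without precision feedback, two- versus
#' three-level filters, and the four response models.
#'
#' @param models model ids to partition (default full space).
#' @return named list of partitions, each a named list of model-id vectors.
#' @export
default_families <- function(models = model_space()) {
  list(
    feedback = list(
      HGF = models[!grepl("precfb", models)],
      HGFprecfb = models[grepl("precfb", models)]),
    levels = list(
      `2HGF` = models[grepl("^2", models)],
      `3HGF` = models[grepl("^3", models)]),
    response = setNames(
      lapply(RESPONSE_VARIANTS,
             function(r) models[sub("^[^-]+-", "", models) == r]),
      RESPONSE_VARIANTS))
}

#' Random-effects Bayesian model selection report
#'
#' Runs [rfx_bms()], [exceedance_and_protected()] and (optionally)
#' [family_bms()] on an evidence matrix and assembles a result object.
#'
#' @param L evidence matrix (subjects x models); `NA` cells are rejected.
#' @param alpha0 prior concentration per model.
#' @param n_samples,seed Monte-Carlo settings.
#' @param families optional named list of family partitions (as
#'   [default_families()]); `NULL` skips family inference.
#' @return object of class `"bms_result"` with elements `models` (tibble:
#'   `model_id`, `alpha`, `pp`, `xp`, `pxp`), `bor`, `families` (tibble or
#'   `NULL`), `alpha0`, `fit`.
#' @export
run_bms <- function(L, alpha0 = 1, n_samples = 1e6, seed = 1L,
                    families = NULL) {
  L <- as.matrix(unclass(L))
  if (anyNA(L)) abort("evidence matrix contains NA cells (failed fits?)")
  fit <- rfx_bms(L, alpha0 = alpha0)
  ep <- exceedance_and_protected(fit, n_samples = n_samples, seed = seed)
  fam <- NULL
  if (!is.null(families)) {
    fam <- dplyr::bind_rows(
      purrr::imap(families, function(p, nm) {
        dplyr::mutate(family_bms(L, p, n_samples = n_samples, seed = seed),
                      partition = nm, .before = 1)
      }))
  }
  structure(
    list(models = tibble::tibble(model_id = colnames(L), alpha = fit$alpha,
                                 pp = fit$pp, xp = ep$xp, pxp = ep$pxp),
         bor = ep$bor, families = fam, alpha0 = alpha0, fit = fit,
         n_subjects = nrow(L)),
    class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> ", x$n_subjects, " subjects, ", nrow(x$models),
      " models, BOR = ", format(x$bor, digits = 3), "\n", sep = "")
  print(dplyr::arrange(x$models, dplyr::desc(.data$pxp)), n = 5)
  invisible(x)
}
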