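#' Simulate model-predicted responses from a fitted model
#'
#' Draws `M` examinees by sampling an attribute class from the
#' estimated structural distribution \eqn{\hat p(\alpha_l)} and, per
#' item, a response category from the multinomial
#' \eqn{\hat P_c(\eta_{jh})} of the class's latent group.
#'
#' @param fit A [fit_gpdm()] result.
#' @param M Number of simulated examinees.
#' @param seed Optional seed.
#' @return An `M x J` integer response matrix.
#' @export
simulate_predicted <- function(fit, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(fit$structural)
  cls <- sample.int(L, M, replace = TRUE, prob = fit$structural)
  sim_responses_internal(cls, fit$item_probs, fit$item_maps)
}

sim_responses_internal <- function(cls, item_probs, item_maps) {
  M <- length(cls)
  J <- length(item_probs)
  X <- matrix(0L, M, J)
  for (j in seq_len(J)) {
    g <- item_maps[[j]]$group_of[cls]
    P <- item_probs[[j]]
    C <- nrow(P)
    for (h in seq_len(ncol(P))) {
      idx <- which(g == h)
      if (length(idx)) {
        X[idx, j] <- sample.int(C, length(idx), replace = TRUE, prob = P[, h]) - 1L
      }
    }
  }
  X
}

#' Residual item-pair correlations on the Fisher-z scale
#'
#' For every item pair, the residual is the absolute difference between
#' the Fisher-transformed Pearson correlations of the observed and the
#' model-predicted responses,
#' \eqn{r_{jj'} = |Z[\rho(X_j, X_{j'})] - Z[\rho(\tilde X_j, \tilde X_{j'})]|},
#' with approximate standard error \eqn{(N - 3)^{-1/2}} (N = observed
#' sample size), giving z-scores \eqn{z = r \sqrt{N - 3}}. Polytomous
#' responses enter the correlation as their integer scores. Pairs
#' involving a zero-variance column are flagged `NA` with a warning.
#'
#' @param X_obs Observed N x J response matrix.
#' @param X_pred Predicted response matrix (same J, any number of
#'   rows).
#' @return List with `r` and `z` (J x J symmetric matrices, diagonal
#'   `NA`) and `se` (the scalar \eqn{(N-3)^{-1/2}}).
#' @export
residual_z <- function(X_obs, X_pred) {
  X_obs <- as.matrix(X_obs); X_pred <- as.matrix(X_pred)
  if (ncol(X_obs) != ncol(X_pred)) {
    abort("Observed and predicted matrices must have the same number of items.",
          class = "gpdm_dim_error")
  }
  N <- nrow(X_obs)
  if (N < 4L) abort("Need at least 4 observed examinees for the Fisher SE.",
                    class = "gpdm_dim_error")
  zero_var <- apply(X_obs, 2L, stats::sd) == 0 | apply(X_pred, 2L, stats::sd) == 0
  if (any(zero_var)) {
    warn(sprintf("Zero-variance item(s) %s: their pairs are excluded (NA).",
                 paste(which(zero_var), collapse = ", ")))
  }
  fz <- function(M) {
    cr <- suppressWarnings(cor(M))
    atanh(pmin(pmax(cr, -1 + 1e-12), 1 - 1e-12))
  }
  r <- abs(fz(X_obs) - fz(X_pred))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- NA_real_
  se <- 1 / sqrt(N - 3)
  list(r = r, z = r / se, se = se)
}

#' Item- and test-level RMS residual z statistics
#'
#' \eqn{sr_j = \sqrt{\sum_{j' \ne j} z_{jj'}^2 / (J - 1)}} summarizes
#' one item's residual z-scores; the test-level
#' \eqn{sr = \sqrt{2 \sum_{j' < j} z_{jj'}^2 / (J(J-1))}} is the RMS
#' over all pairs. The item with the largest \eqn{sr_j} (the hit item)
#' is the prime suspect for Q-matrix misspecification.
#'
#' @param z J x J symmetric matrix of residual z-scores (diagonal
#'   ignored).
#' @return List with `sr_item` (length-J vector), `sr_test` (scalar)
#'   and `hit_item` (index of the max `sr_item`).
#' @export
sr_statistics <- function(z) {
  J <- ncol(z)
  if (J < 2L) abort("Need at least 2 items.", class = "gpdm_dim_error")
  z2 <- z^2
  diag(z2) <- NA_real_
  sr_item <- sqrt(rowMeans(z2, na.rm = TRUE))
  pair_sq <- z2[upper.tri(z2)]
  sr_test <- sqrt(mean(pair_sq, na.rm = TRUE))
  list(sr_item = sr_item, sr_test = sr_test,
       hit_item = which.max(sr_item))
}

#' Bonferroni-corrected critical value for the maximum residual z
#'
#' Two-sided normal critical value controlling the family-wise error
#' over all `J(J-1)/2` item pairs:
#' \eqn{z_c = \Phi^{-1}(1 - \alpha / (J(J-1)))}.
#'
#' @param J Number of items (`J >= 2`).
#' @param alpha Family-wise significance level.
#' @return Scalar critical value.
#' @examples
#' bonferroni_critical(20, 0.10)  # 3.47
#' @export
bonferroni_critical <- function(J, alpha) {
  if (J < 2L) abort("Need at least 2 items.", class = "gpdm_dim_error")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  n_pairs <- J * (J - 1) / 2
  qnorm(1 - alpha / (2 * n_pairs))
}

#' Count the independent parameters of a diagnosis model
#'
#' The saturated model has \eqn{(C_j - 1) 2^{G_j}} free item
#' parameters per item; the reduced PDINA/PDINO forms have
#' \eqn{2(C_j - 1)}. All share the \eqn{2^K - 1} free structural
#' parameters of the unconstrained attribute distribution.
#'
#' @param Q Binary J x K Q-matrix.
#' @param category_counts Per-item category counts `C_j` (recycled if
#'   scalar).
#' @param model `"gpdm"`, `"pdina"` or `"pdino"`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(Q, category_counts, model = c("gpdm", "pdina", "pdino")) {
  model <- match.arg(model)
  Q <- validate_qmatrix(Q)
  J <- nrow(Q); K <- ncol(Q)
  if (length(category_counts) == 1L) category_counts <- rep(category_counts, J)
  if (length(category_counts) != J) {
    abort("`category_counts` must have one entry per item.", class = "gpdm_dim_error")
  }
  G <- rowSums(Q)
  item_par <- if (model == "gpdm") {
    sum((category_counts - 1) * 2^G)
  } else {
    sum(2 * (category_counts - 1))
  }
  as.integer(item_par + 2^K - 1)
}

#' Relative fit indices
#'
#' @param loglik Marginal log-likelihood.
#' @param NP Number of independent parameters.
#' @param N Number of examinees.
#' @return Tibble with `minus2LL`, `AIC` (`-2LL + 2 NP`) and `BIC`
#'   (`-2LL + NP log N`).
#' @export
info_criteria <- function(loglik, NP, N) {
  m2 <- -2 * loglik
  tibble(minus2LL = m2, AIC = m2 + 2 * NP, BIC = m2 + NP * log(N))
}

#' Simulation- and residual-based model-fit assessment
#'
#' Simulates a large predicted data set from the fitted model
#' ([simulate_predicted()]), computes the Fisher-z residual
#' correlations against the observed data ([residual_z()]), and
#' summarizes them as the maximum z-score (compared against the
#' Bonferroni critical value at level `alpha`) and the item- and
#' test-level RMS statistics ([sr_statistics()]), alongside the
#' relative fit indices.
#'
#' @param fit A converged [fit_gpdm()] result.
#' @param M Predicted-replicate sample size (default `100 * N`).
#' @param alpha Family-wise level for the max-z test.
#' @param n_pred Number of independent predicted data sets; z-matrices
#'   are averaged across them to damp simulation randomness (default
#'   1, matching a single simulated replicate).
#' @param seed Optional seed for the predicted data.
#' @return An object of class `"gpdm_assessment"`: list with `z`, `r`
#'   matrices, `max_z`, `critical_z`, `sr_item`, `sr_test`,
#'   `hit_item`, `misfit` (max_z > critical_z) and the fit indices
#'   (`NP`, `minus2LL`, `AIC`, `BIC`). Methods: `tidy()`, `glance()`,
#'   `autoplot()`, `print()`.
#' @export
assess_fit <- function(fit, M = 100L * nrow(fit$responses), alpha = 0.10,
                       n_pred = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  zs <- rs <- NULL
  for (b in seq_len(n_pred)) {
    pred <- simulate_predicted(fit, M)
    res <- residual_z(fit$responses, pred)
    zs <- if (is.null(zs)) res$z else zs + res$z
    rs <- if (is.null(rs)) res$r else rs + res$r
  }
  z <- zs / n_pred
  r <- rs / n_pred
  sr <- sr_statistics(z)
  J <- ncol(fit$responses)
  zc <- bonferroni_critical(J, alpha)
  NP <- count_parameters(fit$Q, fit$category_counts,
                         model = if (fit$model == "gpdm") "gpdm" else fit$model)
  ic <- info_criteria(fit$loglik, NP, nrow(fit$responses))
  structure(list(
    r = r, z = z, max_z = max(z, na.rm = TRUE), critical_z = zc,
    alpha = alpha, M = M, n_pred = n_pred,
    sr_item = sr$sr_item, sr_test = sr$sr_test, hit_item = sr$hit_item,
    misfit = max(z, na.rm = TRUE) > zc,
    NP = NP, minus2LL = ic$minus2LL, AIC = ic$AIC, BIC = ic$BIC,
    model = fit$model
  ), class = "gpdm_assessment")
}
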