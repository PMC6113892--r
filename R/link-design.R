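#' Convert between conditional and cumulative category probabilities
#'
#' Under the graded-response item-splitting view, a polytomous item with
#' C categories is described either by the conditional probabilities
#' \eqn{P_c(\eta_{jh})} (a `C x H` column-stochastic matrix) or by the
#' cumulative probabilities \eqn{P^*_c(\eta_{jh}) = P(X \ge c)}
#' (a `(C+1) x H` matrix with first row 1 and last row 0, non-increasing
#' down each column). The two are related by
#' \eqn{P_c = P^*_c - P^*_{c+1}}.
#'
#' @param cum A `(C+1) x H` cumulative-probability matrix.
#' @param tol Numerical tolerance for the invariant checks.
#' @return `conditional_from_cumulative()`: the `C x H` conditional
#'   matrix; `cumulative_from_conditional()`: the `(C+1) x H`
#'   cumulative matrix.
#' @examples
#' conditional_from_cumulative(matrix(c(1, 0.6, 0.3, 0), ncol = 1))
#' @export
conditional_from_cumulative <- function(cum, tol = 1e-10) {
  cum <- as.matrix(cum)
  C <- nrow(cum) - 1L
  if (C < 1L) abort("Cumulative table needs at least 2 rows.", class = "gpdm_dim_error")
  if (any(abs(cum[1L, ] - 1) > tol) || any(abs(cum[C + 1L, ]) > tol)) {
    abort("Cumulative table must have first row 1 and last row 0.",
          class = "gpdm_prob_error")
  }
  probs <- cum[seq_len(C), , drop = FALSE] - cum[seq_len(C) + 1L, , drop = FALSE]
  if (any(probs < -tol)) {
    abort("Cumulative probabilities are not non-increasing; negative conditional probability.",
          class = "gpdm_prob_error")
  }
  pmax(probs, 0)
}

#' @param probs A `C x H` conditional-probability matrix whose columns
#'   sum to 1.
#' @rdname conditional_from_cumulative
#' @export
cumulative_from_conditional <- function(probs, tol = 1e-10) {
  probs <- as.matrix(probs)
  C <- nrow(probs)
  if (any(abs(colSums(probs) - 1) > max(tol, 1e-10))) {
    abort("Conditional probabilities must sum to 1 within each column.",
          class = "gpdm_prob_error")
  }
  cum <- apply(probs, 2L, function(p) rev(cumsum(rev(p))))
  cum <- rbind(cum, 0)
  cum[1L, ] <- 1  # remove rounding noise at the top row
  rownames(cum) <- NULL
  cum
}

subset_labels <- function(G) {
  # effect-column order: baseline, mains by attribute index, interactions by
  # lexicographic subset order, ..., full interaction
  subsets <- list(integer(0))
  for (size in seq_len(G)) {
    subsets <- c(subsets, utils::combn(G, size, simplify = FALSE))
  }
  labs <- vapply(subsets, function(s) {
    if (!length(s)) "(Intercept)" else paste0("b", paste(s, collapse = ""))
  }, character(1))
  list(subsets = subsets, labels = labs)
}

#' Design matrices for saturated and reduced parameterizations
#'
#' `saturated_design()` expands the linear model
#' \eqn{F[P_c(\eta_{jh})] = \beta_0 + \sum_g \beta_g \eta_g +
#' \sum \beta_{gg'} \eta_g \eta_{g'} + \dots}
#' into a square, invertible `H x H` binary matrix: entry (h, S) is 1
#' iff reduced pattern h masters every attribute in the effect subset S.
#' Columns are ordered baseline, main effects by attribute index, then
#' interactions in lexicographic subset order. `pdina_design()` and
#' `pdino_design()` give the two-column designs of the polytomous DINA
#' (baseline + full-conjunction effect) and DINO (baseline + any-mastery
#' effect) models.
#'
#' @param map One element of [build_item_maps()], or an integer `H`
#'   (a power of two) for the reduced designs.
#' @return A binary matrix with effect labels as column names.
#' @export
saturated_design <- function(map) {
  red <- map$reduced_patterns
  G <- ncol(red)
  H <- nrow(red)
  sl <- subset_labels(G)
  D <- vapply(sl$subsets, function(s) {
    if (!length(s)) rep(1L, H) else as.integer(apply(red[, s, drop = FALSE] == 1L, 1L, all))
  }, integer(H))
  D <- matrix(D, nrow = H, dimnames = list(NULL, sl$labels))
  D
}

#' @rdname saturated_design
#' @param H Number of latent groups (`H >= 2`, a power of two).
#' @export
pdina_design <- function(H) {
  if (H < 2L) abort("`H` must be at least 2.", class = "gpdm_dim_error")
  D <- cbind(1L, c(rep(0L, H - 1L), 1L))
  colnames(D) <- c("(Intercept)", "conjunction")
  D
}

#' @rdname saturated_design
#' @export
pdino_design <- function(H) {
  if (H < 2L) abort("`H` must be at least 2.", class = "gpdm_dim_error")
  D <- cbind(1L, c(0L, rep(1L, H - 1L)))
  colnames(D) <- c("(Intercept)", "disjunction")
  D
}

link_fun <- function(link) {
  switch(link,
    identity = list(f = identity, finv = identity, grad = function(p) rep(1, length(p))),
    logit = list(f = stats::qlogis, finv = stats::plogis,
                 grad = function(p) 1 / (p * (1 - p))),
    log = list(f = log, finv = exp, grad = function(p) 1 / p),
    abort(sprintf("Unknown link '%s'; use identity, logit or log.", link),
          class = "gpdm_link_error")
  )
}

clamp_probs <- function(p, link, eps = 1e-10) {
  if (link == "identity") return(p)
  if (any(p <= eps | p >= 1 - eps)) {
    warn(sprintf("Probabilities clamped to [%g, %g] before the %s transform.",
                 eps, 1 - eps, link))
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  p
}

#' Item effects from conditional probabilities
#'
#' Maps one category's conditional probabilities across the latent
#' groups to item effects under a chosen link, via (weighted) least
#' squares on the design matrix:
#' \eqn{\hat\beta = (D'WD)^{-1} D'W F(P)} with `W = diag(weights)`.
#' For a saturated (square) design this is an exact interpolation, so
#' the transform is a bijection between probabilities and effects; for
#' the two-column PDINA/PDINO designs it is the class-size-weighted
#' projection onto the reduced model.
#'
#' @param probs_row Length-H vector of probabilities \eqn{P_c(\eta_{jh})}.
#' @param D Design matrix (`H x V`) from [saturated_design()],
#'   [pdina_design()] or [pdino_design()].
#' @param link `"identity"`, `"logit"` or `"log"`.
#' @param weights Optional non-negative length-H vector of expected
#'   group sizes \eqn{N_{jh}}; equal weights reduce to ordinary least
#'   squares.
#' @return Named numeric vector of effects (length V) with attribute
#'   `link`.
#' @export
effects_from_probs <- function(probs_row, D, link = "identity", weights = NULL) {
  lk <- link_fun(link)
  H <- nrow(D)
  if (length(probs_row) != H) {
    abort("`probs_row` length must equal the number of design rows.",
          class = "gpdm_dim_error")
  }
  y <- lk$f(clamp_probs(as.numeric(probs_row), link))
  if (is.null(weights)) weights <- rep(1, H)
  if (length(weights) != H || any(weights < 0)) {
    abort("`weights` must be a non-negative length-H vector.", class = "gpdm_dim_error")
  }
  if (all(weights == 0)) abort("All weights are zero.", class = "gpdm_rank_error")
  XtW <- t(D * weights)
  XtWX <- XtW %*% D
  qrx <- qr(XtWX)
  if (qrx$rank < ncol(D)) {
    empty <- which(weights == 0)
    abort(sprintf("Design is rank-deficient under these weights%s.",
                  if (length(empty)) paste0(" (zero-weight group(s): ",
                                            paste(empty, collapse = ", "), ")") else ""),
          class = "gpdm_rank_error")
  }
  beta <- drop(solve(qrx, XtW %*% y))
  names(beta) <- colnames(D)
  attr(beta, "link") <- link
  beta
}

#' Probabilities implied by item effects
#'
#' Inverse of [effects_from_probs()] for any design: applies the design
#' matrix and the inverse link, `P = F^{-1}(D beta)`.
#'
#' @param beta Effect vector (length V).
#' @inheritParams effects_from_probs
#' @return Length-H probability vector.
#' @export
probs_from_effects <- function(beta, D, link = "identity") {
  lk <- link_fun(link)
  drop(lk$finv(D %*% as.numeric(beta)))
}

#' Guessing and slip parameters of the reduced models
#'
#' Under the identity link the PDINA/PDINO effect vectors translate into
#' guessing and slip parameters per category:
#' `g = beta0` and `s = 1 - beta0 - beta_effect`. Values outside `[0,1]`
#' are returned with a warning; they signal that the reduced model
#' misfits the probabilities it was projected from.
#'
#' @param beta Two-element effect vector from [effects_from_probs()]
#'   with a PDINA or PDINO design and identity link.
#' @return Named vector `c(guess = ..., slip = ...)`.
#' @export
guess_slip <- function(beta) {
  if (length(beta) != 2L) abort("Reduced-model effect vectors have length 2.",
                                class = "gpdm_dim_error")
  g <- unname(beta[1L])
  s <- 1 - unname(beta[1L]) - unname(beta[2L])
  if (g < 0 || g > 1 || s < 0 || s > 1) {
    warn("Guessing/slip outside [0, 1]: the reduced model misfits these probabilities.")
  }
  c(guess = g, slip = s)
}

#' Delta-method standard errors for transformed item effects
#'
#' Propagates the covariance of the estimated conditional probabilities
#' through the (weighted) least-squares transform
#' \eqn{f(P) = (D'WD)^{-1} D'W F(P)}: the Jacobian is
#' \eqn{(D'WD)^{-1} D'W \, \mathrm{diag}(F'(P))} and
#' \eqn{SE(\hat\beta)^2 = \mathrm{diag}(J \, Var(\hat P) \, J')}.
#'
#' @inheritParams effects_from_probs
#' @param prob_covariance `H x H` symmetric positive semi-definite
#'   covariance matrix of the category's probability estimates.
#' @return Length-V vector of standard errors.
#' @export
delta_method_se <- function(probs_row, prob_covariance, D, link = "identity",
                            weights = NULL) {
  V <- as.matrix(prob_covariance)
  H <- nrow(D)
  if (!isTRUE(all.equal(V, t(V), tolerance = 1e-8)) ||
      any(eigen(V, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    abort("`prob_covariance` must be symmetric positive semi-definite.",
          class = "gpdm_cov_error")
  }
  lk <- link_fun(link)
  p <- clamp_probs(as.numeric(probs_row), link)
  if (is.null(weights)) weights <- rep(1, H)
  A <- solve(t(D * weights) %*% D, t(D * weights))  # V x H
  J <- A %*% diag(lk$grad(p), H)
  sqrt(pmax(diag(J %*% V %*% t(J)), 0))
}

#' Tidy table of item effects for a fitted model
#'
#' Transforms every item/category of a fit into effects under the
#' requested parameterization and link, with delta-method standard
#' errors when the fit carries probability covariances.
#'
#' @param fit A [fit_gpdm()] result.
#' @param model `"saturated"`, `"pdina"` or `"pdino"`. The reduced
#'   models use the class-size-weighted transform.
#' @param link `"identity"`, `"logit"` or `"log"`.
#' @return A tibble with columns `item`, `category`, `effect`,
#'   `estimate`, `se` (and `guess`/`slip` columns via [guess_slip()] for
#'   the reduced models with identity link).
#' @export
transform_effects <- function(fit, model = c("saturated", "pdina", "pdino"),
                              link = "identity") {
  model <- match.arg(model)
  maps <- fit$item_maps
  rows <- list()
  for (j in seq_along(maps)) {
    map <- maps[[j]]
    P <- fit$item_probs[[j]]
    C <- nrow(P)
    D <- switch(model,
                saturated = saturated_design(map),
                pdina = pdina_design(map$H),
                pdino = pdino_design(map$H))
    w <- if (model == "saturated") NULL else fit$group_weights[[j]]
    for (cc in seq_len(C - 1L)) {
      beta <- effects_from_probs(P[cc + 1L, ], D, link, weights = w)
      se <- rep(NA_real_, length(beta))
      if (!is.null(fit$prob_covariances)) {
        Vc <- fit$prob_covariances[[j]][[cc]]
        if (!is.null(Vc) && !anyNA(Vc)) {
          se <- delta_method_se(P[cc + 1L, ], Vc, D, link, weights = w)
        }
      }
      rows[[length(rows) + 1L]] <- tibble(
        item = map$item, category = cc, effect = colnames(D),
        estimate = as.numeric(beta), se = se)
    }
  }
  dplyr::bind_rows(rows)
}
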