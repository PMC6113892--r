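validate_responses <- function(X, category_counts = NULL, J = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.numeric(X)) abort("Responses must be numeric.", class = "gpdm_parse_error")
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    abort(sprintf("Missing response at examinee %d, item %d; missing data are not supported.",
                  bad[1L], bad[2L]),
          class = "gpdm_parse_error")
  }
  if (any(X != round(X)) || any(X < 0)) {
    abort("Responses must be non-negative integers (categories 0, 1, ...).",
          class = "gpdm_parse_error")
  }
  storage.mode(X) <- "integer"
  if (!is.null(J) && ncol(X) != J) {
    abort(sprintf("Response matrix has %d columns but the Q-matrix has %d items.",
                  ncol(X), J), class = "gpdm_dim_error")
  }
  if (is.null(category_counts)) {
    category_counts <- pmax(apply(X, 2L, max) + 1L, 2L)
  }
  category_counts <- as.integer(category_counts)
  if (length(category_counts) == 1L) category_counts <- rep(category_counts, ncol(X))
  if (length(category_counts) != ncol(X)) {
    abort("`category_counts` must have one entry per item.", class = "gpdm_dim_error")
  }
  over <- which(apply(X, 2L, max) > category_counts - 1L)
  if (length(over)) {
    abort(sprintf("Item(s) %s contain categories beyond their declared range.",
                  paste(over, collapse = ", ")), class = "gpdm_parse_error")
  }
  list(X = X, category_counts = category_counts)
}

groups_matrix <- function(item_maps) {
  vapply(item_maps, `[[`, integer(length(item_maps[[1L]]$group_of)), "group_of")
}

#' Conditional likelihood of one response vector given each latent class
#'
#' Computes \eqn{L(X_i | \alpha_l) = \prod_j P_{X_{ij}}(\eta_{jh})},
#' where each class l is reduced to item j's latent group h.
#'
#' @param x_i Integer response vector of length J (categories 0-based).
#' @param item_probs List of `C_j x H_j` conditional-probability
#'   matrices.
#' @param item_maps Output of [build_item_maps()].
#' @return Numeric vector of length `L = 2^K`.
#' @export
conditional_likelihood <- function(x_i, item_probs, item_maps) {
  L <- length(item_maps[[1L]]$group_of)
  lik <- rep(1, L)
  for (j in seq_along(item_probs)) {
    lik <- lik * item_probs[[j]][x_i[j] + 1L, item_maps[[j]]$group_of]
  }
  if (all(lik == 0)) {
    warn("Response vector has zero likelihood under every latent class.")
  }
  lik
}

#' Marginal log-likelihood of a response matrix
#'
#' \eqn{\log L(X) = \sum_i \log \sum_l L(X_i|\alpha_l)\, p(\alpha_l)}.
#'
#' @param X N x J integer response matrix (categories 0-based).
#' @inheritParams conditional_likelihood
#' @param structural Length-L prior class distribution \eqn{p(\alpha_l)}.
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(X, item_probs, structural, item_maps) {
  es <- e_step(X, item_probs, structural, item_maps)
  es$loglik
}

#' E-step: posteriors and expected counts
#'
#' Applies Bayes' rule class-by-class,
#' \eqn{p(\alpha_l|X_i) \propto L(X_i|\alpha_l) p(\alpha_l)}, and
#' accumulates the expected latent-group sizes
#' \eqn{N_{jh} = \sum_i p(\eta_{jh}|X_i)} and expected category counts
#' \eqn{R_{jhc} = \sum_i X_{ijc}\, p(\eta_{jh}|X_i)} per item.
#'
#' @inheritParams marginal_loglik
#' @return A list: `loglik`, `post` (N x L posterior, rows sum to 1),
#'   `lik` (raw conditional likelihoods), `group_counts` (per item the
#'   `C_j x H_j` matrix \eqn{R_{jhc}}), `group_weights` (per item the
#'   length-`H_j` vector \eqn{N_{jh}}).
#' @export
e_step <- function(X, item_probs, structural, item_maps) {
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "integer"
  res <- gpdm_estep_cpp(X, item_probs, groups_matrix(item_maps), structural)
  res$group_weights <- lapply(res$counts, colSums)
  names(res)[names(res) == "counts"] <- "group_counts"
  res
}

#' M-step: closed-form parameter updates
#'
#' \eqn{\hat P_c(\eta_{jh}) = R_{jhc} / N_{jh}} and
#' \eqn{\hat p(\alpha_l) = N^{-1} \sum_i p(\alpha_l|X_i)} — the
#' complete-data maximum-likelihood updates given the E-step's expected
#' counts. Empty groups (\eqn{N_{jh} = 0}) keep their previous
#' probabilities and are flagged.
#'
#' @param estep Result of [e_step()].
#' @param prev_item_probs Previous parameter tables (fallback for empty
#'   groups).
#' @return A list with `item_probs`, `structural` and `empty_groups`
#'   (list of group indices that had zero expected weight).
#' @export
m_step <- function(estep, prev_item_probs) {
  item_probs <- prev_item_probs
  empty <- vector("list", length(prev_item_probs))
  for (j in seq_along(prev_item_probs)) {
    R <- estep$group_counts[[j]]
    Nh <- colSums(R)
    ok <- Nh > 0
    Pnew <- prev_item_probs[[j]]
    Pnew[, ok] <- sweep(R[, ok, drop = FALSE], 2L, Nh[ok], "/")
    item_probs[[j]] <- Pnew
    empty[[j]] <- which(!ok)
  }
  structural <- colMeans(estep$post)
  structural <- structural / sum(structural)
  list(item_probs = item_probs, structural = structural, empty_groups = empty)
}

init_item_probs <- function(item_maps, category_counts, jitter = 0) {
  lapply(seq_along(item_maps), function(j) {
    map <- item_maps[[j]]
    C <- category_counts[j]
    m <- rowSums(map$reduced_patterns)
    base <- 0.2 + 0.6 * m / max(map$G, 1L)  # cumulative success grows with mastery
    cum <- matrix(0, C + 1L, map$H)
    cum[1L, ] <- 1
    for (cc in seq_len(C - 1L)) {
      cum[cc + 1L, ] <- base * (C - cc) / (C - 1L)
    }
    if (jitter > 0) {
      mid <- cum[seq(2L, C), , drop = FALSE]
      mid <- mid + matrix(runif(length(mid), -jitter, jitter), nrow(mid))
      cum[seq(2L, C), ] <- pmin(pmax(mid, 0.01), 0.99)
      # keep rows non-increasing down each column
      for (cc in seq(2L, C)) cum[cc, ] <- pmin(cum[cc, ], cum[cc - 1L] - 1e-6)
    }
    P <- conditional_from_cumulative(cum)
    dimnames(P) <- list(paste0("c", 0:(C - 1L)), group_labels(map))
    P
  })
}

project_reduced <- function(item_probs, group_weights, model, eps = 1e-6) {
  for (j in seq_along(item_probs)) {
    P <- item_probs[[j]]
    H <- ncol(P); C <- nrow(P)
    if (H < 2L) next
    D <- if (model == "pdina") pdina_design(H) else pdino_design(H)
    w <- pmax(group_weights[[j]], 1e-8)
    A <- solve(t(D * w) %*% D, t(D * w))
    for (cc in seq_len(C - 1L)) {
      P[cc + 1L, ] <- pmin(pmax(drop(D %*% (A %*% P[cc + 1L, ])), eps), 1 - eps)
    }
    top <- colSums(P[-1L, , drop = FALSE])
    scale <- ifelse(top > 1 - eps, (1 - eps) / top, 1)
    P[-1L, ] <- sweep(P[-1L, , drop = FALSE], 2L, scale, "*")
    P[1L, ] <- 1 - colSums(P[-1L, , drop = FALSE])
    item_probs[[j]] <- P
  }
  item_probs
}

#' Fit the general polytomous diagnosis model by EM
#'
#' Marginal maximum likelihood estimation of the saturated polytomous
#' diagnosis model: one free conditional probability per category and
#' latent group per item (`(C_j - 1) * 2^{G_j}` free item parameters),
#' plus an unconstrained structural distribution over the `2^K`
#' attribute classes. Estimation alternates the E-step ([e_step()]) and
#' the closed-form M-step ([m_step()]) until the marginal
#' log-likelihood change falls below `tol`. With all `C_j = 2` the model
#' is exactly the saturated dichotomous (G-DINA-type) model, estimated
#' by the same code path.
#'
#' `model = "pdina"` / `"pdino"` estimate the reduced two-parameter
#' forms by applying the class-size-weighted design-matrix projection
#' after every M-step, which is equivalent to direct MML estimation of
#' the reduced model.
#'
#' @param X N x J response matrix or data frame, categories coded
#'   `0 ... C_j - 1`.
#' @param Q Binary J x K Q-matrix (matrix or data frame).
#' @param category_counts Per-item number of categories `C_j`
#'   (recycled if scalar; inferred from the data when `NULL`).
#' @param model `"gpdm"` (saturated), `"pdina"` or `"pdino"`.
#' @param monotone `"off"` (default; check post hoc with
#'   [check_monotonicity()]) or `"updown"` to impose the cumulative
#'   monotonicity constraint each iteration via
#'   [impose_monotonicity()].
#' @param max_iter,tol EM stopping rule: stop when the absolute
#'   log-likelihood change drops below `tol` (default `1e-6`) or after
#'   `max_iter` iterations (default 2000).
#' @param init_jitter Half-width of uniform jitter added to the initial
#'   cumulative probabilities (0 = deterministic monotone start).
#' @param seed Optional seed for the jittered initialization.
#' @param se If `TRUE`, compute information-matrix standard errors via
#'   [information_se()] after convergence.
#' @return An object of class `"gpdm"`: a list with `item_probs`,
#'   `structural`, `posterior`, `group_weights`, `loglik`, `n_iter`,
#'   `converged`, `item_maps`, `patterns`, plus the inputs needed to
#'   reproduce the fit. Methods: [tidy.gpdm()], [glance.gpdm()],
#'   [autoplot.gpdm()], `print()`.
#' @examples
#' Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
#' sim <- sim_gpdm_data(n = 150, Q = Q, category_counts = 3, seed = 7)
#' fit <- fit_gpdm(sim$responses, Q, category_counts = 3)
#' glance(fit)
#' @export
fit_gpdm <- function(X, Q, category_counts = NULL,
                     model = c("gpdm", "pdina", "pdino"),
                     monotone = c("off", "updown"),
                     max_iter = 2000L, tol = 1e-6,
                     init_jitter = 0, seed = NULL, se = FALSE) {
  model <- match.arg(model)
  monotone <- match.arg(monotone)
  Q <- validate_qmatrix(Q)
  v <- validate_responses(X, category_counts, J = nrow(Q))
  X <- v$X; category_counts <- v$category_counts
  patterns <- attribute_patterns(ncol(Q))
  item_maps <- build_item_maps(Q, patterns)
  L <- nrow(patterns)

  if (!is.null(seed)) set.seed(seed)
  item_probs <- init_item_probs(item_maps, category_counts, init_jitter)
  structural <- rep(1 / L, L)

  if (model == "gpdm" && monotone == "off") {
    # fast path: the whole closed-form EM runs in the compiled kernel
    em <- gpdm_em_cpp(X, item_probs, groups_matrix(item_maps), structural,
                      as.integer(max_iter), tol)
    item_probs <- em$item_probs
    structural <- as.numeric(em$structural)
    es <- em$estep
    es$group_weights <- lapply(es$counts, colSums)
    names(es)[names(es) == "counts"] <- "group_counts"
    loglik_trace <- as.numeric(em$loglik_trace)
    iter <- em$n_iter
    converged <- em$converged
    if (!converged) {
      warn(sprintf("EM did not converge in %d iterations (last change %.2e).",
                   max_iter, abs(diff(utils::tail(loglik_trace, 2L)))))
    }
    for (j in seq_along(item_probs)) {
      dimnames(item_probs[[j]]) <- list(paste0("c", 0:(nrow(item_probs[[j]]) - 1L)),
                                        group_labels(item_maps[[j]]))
    }
    return(finalize_gpdm_fit(item_probs, structural, es, loglik_trace, iter,
                             converged, item_maps, patterns, Q, category_counts,
                             X, model, monotone, max_iter, tol, init_jitter,
                             seed, se))
  }

  loglik_prev <- -Inf
  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  es <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    es <- e_step(X, item_probs, structural, item_maps)
    loglik_trace[iter] <- es$loglik
    if (is.finite(loglik_prev) && abs(es$loglik - loglik_prev) < tol) {
      converged <- TRUE
      break
    }
    loglik_prev <- es$loglik
    ms <- m_step(es, item_probs)
    item_probs <- ms$item_probs
    structural <- ms$structural
    if (model != "gpdm") {
      item_probs <- project_reduced(item_probs, es$group_weights, model)
    }
    if (monotone == "updown") {
      item_probs <- impose_monotonicity(item_probs, es$group_weights, item_maps)
    }
  }
  if (!converged) {
    warn(sprintf("EM did not converge in %d iterations (last change %.2e).",
                 max_iter, abs(loglik_trace[iter] - loglik_prev)))
    es <- e_step(X, item_probs, structural, item_maps)
  }

  finalize_gpdm_fit(item_probs, structural, es, loglik_trace, iter, converged,
                    item_maps, patterns, Q, category_counts, X, model,
                    monotone, max_iter, tol, init_jitter, seed, se)
}

finalize_gpdm_fit <- function(item_probs, structural, es, loglik_trace, iter,
                              converged, item_maps, patterns, Q,
                              category_counts, X, model, monotone, max_iter,
                              tol, init_jitter, seed, se) {
  names(structural) <- apply(patterns, 1L, paste0, collapse = "")
  fit <- structure(list(
    item_probs = item_probs,
    structural = structural,
    posterior = es$post,
    group_weights = es$group_weights,
    group_counts = es$group_counts,
    loglik = es$loglik,
    loglik_trace = loglik_trace,
    n_iter = iter,
    converged = converged,
    item_maps = item_maps,
    patterns = patterns,
    Q = Q,
    category_counts = category_counts,
    responses = X,
    model = model,
    monotone = monotone,
    settings = list(max_iter = max_iter, tol = tol,
                    init_jitter = init_jitter, seed = seed),
    se_tables = NULL,
    prob_covariances = NULL
  ), class = "gpdm")
  if (se) fit <- information_se(fit)
  fit
}

#' Information-matrix standard errors for the fitted probabilities
#'
#' Approximates the covariance of the free conditional probabilities
#' and structural parameters by the inverse of the empirical
#' (outer-product) information: \eqn{I = \sum_i s_i s_i'} with
#' \eqn{s_i} the per-examinee score of the log marginal likelihood.
#' Non-identified parameters (empty latent groups) and singular
#' information matrices yield missing SEs with a warning.
#'
#' @param fit A converged [fit_gpdm()] result.
#' @return The fit with `se_tables` (per item, `C_j x H_j` SEs, the
#'   category-0 row derived from the covariance of the free rows) and
#'   `prob_covariances` (per item a list over categories `c >= 1` of
#'   the `H_j x H_j` covariance blocks used by [delta_method_se()]).
#' @export
information_se <- function(fit) {
  X <- fit$responses
  N <- nrow(X)
  maps <- fit$item_maps
  L <- nrow(fit$patterns)
  es <- e_step(X, fit$item_probs, fit$structural, maps)
  marg_rel <- rowSums(sweep(es$lik, 2L, fit$structural, "*"))

  # index bookkeeping: per item/category block of free probabilities
  blocks <- list()
  p <- 0L
  for (j in seq_along(maps)) {
    C <- nrow(fit$item_probs[[j]]); H <- maps[[j]]$H
    blocks[[j]] <- lapply(seq_len(C - 1L), function(cc) p + (cc - 1L) * H + seq_len(H))
    p <- p + (C - 1L) * H
  }
  n_item_par <- p
  n_par <- p + (L - 1L)
  S <- matrix(0, N, n_par)
  A_list <- lapply(maps, function(m) {
    A <- matrix(0, L, m$H); A[cbind(seq_len(L), m$group_of)] <- 1; A
  })
  for (j in seq_along(maps)) {
    P <- fit$item_probs[[j]]
    C <- nrow(P)
    post_g <- es$post %*% A_list[[j]]       # N x H
    x <- X[, j]
    is0 <- x == 0L
    for (cc in seq_len(C - 1L)) {
      isc <- x == cc
      for (h in seq_len(maps[[j]]$H)) {
        sc <- numeric(N)
        if (P[cc + 1L, h] > 0) sc[isc] <- post_g[isc, h] / P[cc + 1L, h]
        if (P[1L, h] > 0) sc[is0] <- sc[is0] - post_g[is0, h] / P[1L, h]
        S[, blocks[[j]][[cc]][h]] <- sc
      }
    }
  }
  # structural scores: d log Li / d p_l = (L_il - L_i1) / marg, l = 2..L
  S[, n_item_par + seq_len(L - 1L)] <-
    (es$lik[, -1L, drop = FALSE] - es$lik[, 1L]) / marg_rel

  info <- crossprod(S)
  Vfull <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(Vfull)) {
    warn("Information matrix is singular; standard errors reported as missing.")
  }

  se_tables <- vector("list", length(maps))
  prob_cov <- vector("list", length(maps))
  for (j in seq_along(maps)) {
    P <- fit$item_probs[[j]]
    C <- nrow(P); H <- maps[[j]]$H
    se <- matrix(NA_real_, C, H, dimnames = dimnames(P))
    pcov <- vector("list", C - 1L)
    if (!is.null(Vfull)) {
      empty <- fit$group_weights[[j]] <= 1e-8
      for (cc in seq_len(C - 1L)) {
        idx <- blocks[[j]][[cc]]
        Vc <- Vfull[idx, idx, drop = FALSE]
        pcov[[cc]] <- Vc
        se[cc + 1L, ] <- sqrt(pmax(diag(Vc), 0))
      }
      # category 0 is 1 - sum of the free categories
      idx_all <- unlist(blocks[[j]])
      Vj <- Vfull[idx_all, idx_all, drop = FALSE]
      for (h in seq_len(H)) {
        pick <- seq(h, by = H, length.out = C - 1L)
        se[1L, h] <- sqrt(max(sum(Vj[pick, pick]), 0))
      }
      se[, empty] <- NA_real_
    }
    se_tables[[j]] <- se
    prob_cov[[j]] <- pcov
  }
  fit$se_tables <- se_tables
  fit$prob_covariances <- prob_cov
  fit
}

#' Classify examinees from the posterior distribution
#'
#' MAP picks the attribute class with the largest posterior probability
#' (ties broken toward the lowest class index); EAP thresholds each
#' marginal attribute-mastery posterior at 0.5 (probability >= 0.5 is
#' classified as mastered).
#'
#' @param fit A [fit_gpdm()] result (or an N x L posterior matrix, in
#'   which case `patterns` must be supplied).
#' @param method `"MAP"` or `"EAP"`.
#' @param patterns Attribute-pattern matrix when `fit` is a bare
#'   posterior.
#' @return A tibble with `examinee`, `class` (MAP class index, `NA` for
#'   EAP) and one 0/1 column per attribute.
#' @export
classify <- function(fit, method = c("MAP", "EAP"), patterns = NULL) {
  method <- match.arg(method)
  if (inherits(fit, "gpdm")) {
    post <- fit$posterior
    patterns <- fit$patterns
  } else {
    post <- fit
    if (is.null(patterns)) abort("Supply `patterns` with a bare posterior matrix.")
  }
  if (method == "MAP") {
    cls <- max.col(post, ties.method = "first")
    attrs <- patterns[cls, , drop = FALSE]
  } else {
    cls <- rep(NA_integer_, nrow(post))
    marg <- post %*% patterns
    attrs <- 1L * (marg >= 0.5)
  }
  out <- tibble(examinee = seq_len(nrow(post)), class = cls)
  dplyr::bind_cols(out, as_tibble(`colnames<-`(attrs, colnames(patterns))))
}

map_attributes <- function(post, patterns) {
  patterns[max.col(post, ties.method = "first"), , drop = FALSE]
}

eap_attributes <- function(post, patterns) {
  1L * ((post %*% patterns) >= 0.5)
}
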