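#' Generate correlated binary attributes by the MVN threshold method
#'
#' Draws latent vectors from \eqn{MVN(0, \Sigma)} with unit variances
#' and common correlation `R`, then dichotomizes:
#' \eqn{\alpha_{ik} = 1} iff the latent value exceeds `thresholds[k]`.
#' Zero thresholds give attribute prevalence 0.5; with `R = 0` the
#' attributes are independent.
#'
#' @param n Number of examinees.
#' @param K Number of attributes.
#' @param R Common latent correlation in `(-1, 1)`.
#' @param thresholds Length-K (or scalar) thresholds; default 0.
#' @param seed Optional seed.
#' @return `n x K` binary integer matrix.
#' @export
sim_attributes <- function(n, K, R = 0.5, thresholds = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(thresholds) == 1L) thresholds <- rep(thresholds, K)
  Sigma <- matrix(R, K, K); diag(Sigma) <- 1
  ch <- tryCatch(chol(Sigma), error = function(e)
    abort("Attribute correlation matrix is not positive definite.",
          class = "gpdm_cov_error"))
  Z <- matrix(rnorm(n * K), n, K) %*% ch
  alpha <- 1L * sweep(Z, 2L, thresholds, ">")
  colnames(alpha) <- paste0("A", seq_len(K))
  alpha
}

#' Generate true item parameters for the simulation design
#'
#' Implements the additive (equal-main-effect, identity link) polytomous
#' generating model: per item, the cumulative probability of reaching
#' category 1 or above is drawn as \eqn{P^*_1(0) \sim U(0, 0.3)} for
#' the no-mastery group and \eqn{P^*_1(1) \sim U(0.7, 1.0)} for the
#' full-mastery group, with the top-category cumulative fixed at half,
#' \eqn{P^*_2 = P^*_1 / 2}, so the two above-zero categories contribute
#' equally (\eqn{P_1(0) = P_2(0)}, \eqn{P_1(1) = P_2(1)}).
#' Intermediate latent groups interpolate every conditional probability
#' linearly in the fraction of mastered required attributes (equal main
#' effects). Dichotomous items use the drawn cumulative directly as
#' `P(X = 1)`.
#'
#' @param Q Binary J x K Q-matrix.
#' @param category_counts Per-item category counts (2 or 3; recycled if
#'   scalar).
#' @param seed Optional seed.
#' @return List with `item_probs` (per item `C_j x H_j` tables) and
#'   `endpoints` (tibble of the drawn `pstar1_0`, `pstar1_1`).
#' @export
sim_item_params <- function(Q, category_counts = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- validate_qmatrix(Q)
  J <- nrow(Q)
  if (length(category_counts) == 1L) category_counts <- rep(category_counts, J)
  maps <- build_item_maps(Q)
  u0 <- runif(J, 0.0, 0.3)
  u1 <- runif(J, 0.7, 1.0)
  item_probs <- vector("list", J)
  for (j in seq_len(J)) {
    map <- maps[[j]]
    C <- category_counts[j]
    frac <- rowSums(map$reduced_patterns) / map$G
    cond0 <- cond_endpoint(u0[j], C)
    cond1 <- cond_endpoint(u1[j], C)
    P <- vapply(frac, function(f) cond0 + f * (cond1 - cond0), numeric(C))
    dimnames(P) <- list(paste0("c", 0:(C - 1L)), group_labels(map))
    item_probs[[j]] <- P
  }
  list(item_probs = item_probs,
       endpoints = tibble(item = rownames(Q), pstar1_0 = u0, pstar1_1 = u1))
}

cond_endpoint <- function(u, C) {
  if (C == 2L) return(c(1 - u, u))
  if (C != 3L) abort("The generating design covers 2- or 3-category items.",
                     class = "gpdm_dim_error")
  # cumulative (1, u, u/2, 0) -> conditional (1-u, u/2, u/2)
  c(1 - u, u / 2, u / 2)
}

#' Simulate polytomous responses from item probability tables
#'
#' Each examinee's attribute pattern selects a latent group per item;
#' the response category is drawn from that group's multinomial.
#'
#' @param attributes `n x K` binary attribute matrix.
#' @param item_probs Per-item `C_j x H_j` probability tables.
#' @param item_maps Output of [build_item_maps()] for the matching
#'   Q-matrix.
#' @param seed Optional seed.
#' @return `n x J` integer response matrix.
#' @export
sim_responses <- function(attributes, item_probs, item_maps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(attributes)
  pow <- 2L^((K - 1L):0L)
  cls <- as.integer(attributes %*% pow) + 1L
  sim_responses_internal(cls, item_probs, item_maps)
}

#' One-call data simulation from a random additive generating model
#'
#' Convenience wrapper: draws attributes ([sim_attributes()]), true
#' item parameters ([sim_item_params()]) and responses
#' ([sim_responses()]) in one seeded call.
#'
#' @inheritParams sim_attributes
#' @inheritParams sim_item_params
#' @param Q Binary J x K Q-matrix.
#' @return List with `responses`, `attributes`, `item_probs`,
#'   `endpoints`.
#' @export
sim_gpdm_data <- function(n, Q, category_counts = 3L, R = 0.5, thresholds = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- validate_qmatrix(Q)
  maps <- build_item_maps(Q)
  attrs <- sim_attributes(n, ncol(Q), R, thresholds)
  pars <- sim_item_params(Q, category_counts)
  X <- sim_responses(attrs, pars$item_probs, maps)
  list(responses = X, attributes = attrs,
       item_probs = pars$item_probs, endpoints = pars$endpoints)
}

#' Dichotomize polytomous responses
#'
#' Recodes responses as 1 iff the top category was observed
#' (`X == C_j - 1`) and 0 otherwise — the information-losing reduction
#' used to compare polytomous and dichotomous fits.
#'
#' @param X N x J integer response matrix.
#' @param category_counts Per-item category counts (recycled if
#'   scalar).
#' @return N x J binary integer matrix.
#' @export
dichotomize <- function(X, category_counts) {
  X <- as.matrix(X)
  if (length(category_counts) == 1L) category_counts <- rep(category_counts, ncol(X))
  out <- 1L * sweep(X, 2L, category_counts - 1L, "==")
  dimnames(out) <- dimnames(X)
  out
}

#' Attribute classification accuracy
#'
#' @param true_attrs,estimated_attrs Binary matrices of identical
#'   dimension (examinees x attributes).
#' @return List with `pattern` (fraction of examinees with the whole
#'   attribute vector correct) and `attribute` (per-attribute fraction
#'   correct).
#' @export
classification_accuracy <- function(true_attrs, estimated_attrs) {
  true_attrs <- as.matrix(true_attrs); estimated_attrs <- as.matrix(estimated_attrs)
  if (!all(dim(true_attrs) == dim(estimated_attrs))) {
    abort("Attribute matrices must have identical dimensions.",
          class = "gpdm_dim_error")
  }
  match_mat <- true_attrs == estimated_attrs
  list(pattern = mean(rowSums(!match_mat) == 0L),
       attribute = colMeans(match_mat))
}

#' Specify a simulation-study design
#'
#' Bundles the study conditions: Q-matrix, sample size, category
#' counts, the latent attribute correlation and thresholds of the MVN
#' threshold method, the replicate count and the master seed. Defaults
#' reproduce the additive-true-model design: `C = 3`, `R = 0.5`, zero
#' thresholds.
#'
#' @param Q Binary J x K Q-matrix (e.g. [qmatrix_sim20()], stacked for
#'   J = 40).
#' @param N Examinees per replicate.
#' @param category_counts Per-item category counts (scalar recycled).
#' @param R Latent attribute correlation.
#' @param thresholds MVN dichotomization thresholds.
#' @param replicates Number of replicates.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param fit_dichotomized Also fit the dichotomous saturated model to
#'   top-category-recoded data within each replicate.
#' @param max_iter,tol EM settings passed to [fit_gpdm()].
#' @return A list of class `"gpdm_design"`.
#' @export
sim_design <- function(Q, N = 500L, category_counts = 3L, R = 0.5,
                       thresholds = 0, replicates = 100L, seed = 1L,
                       fit_dichotomized = TRUE, max_iter = 2000L, tol = 1e-6) {
  Q <- validate_qmatrix(Q)
  stopifnot(replicates >= 1L, R > -1, R < 1)
  structure(list(Q = Q, N = as.integer(N), category_counts = category_counts,
                 R = R, thresholds = thresholds,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 fit_dichotomized = fit_dichotomized,
                 max_iter = max_iter, tol = tol),
            class = "gpdm_design")
}

#' Run a classification-accuracy and parameter-recovery study
#'
#' Per replicate: draw attributes and a fresh set of additive true
#' item parameters, simulate polytomous responses, fit the saturated
#' polytomous model (and optionally the dichotomous saturated model to
#' top-category-recoded data), classify examinees (MAP for the whole
#' pattern, marginal-EAP thresholding for single attributes) and score
#' accuracy against the generating attributes. Bias and RMSE of the
#' fitted conditional probabilities at the no-mastery and full-mastery
#' reduced patterns, \eqn{P_c(0)} and \eqn{P_c(1)}, are pooled over
#' items and replicates. Everything is driven by the design's seed:
#' replicate r re-seeds with `seed + r`.
#'
#' @param design A [sim_design()].
#' @param progress Print a dot every 10 replicates.
#' @return An object of class `"gpdm_study"`: list with `summary` (a
#'   one-row-per-model tibble of mean/SD classification accuracies),
#'   `recovery` (bias/RMSE tibble for \eqn{P_c(0)}, \eqn{P_c(1)}),
#'   `replicates` (per-replicate tibble) and `failed` (count of
#'   replicates excluded for fit failure).
#' @export
run_study <- function(design, progress = FALSE) {
  stopifnot(inherits(design, "gpdm_design"))
  Q <- design$Q
  K <- ncol(Q)
  maps <- build_item_maps(Q)
  patterns <- attribute_patterns(K)
  J <- nrow(Q)
  cc <- design$category_counts
  if (length(cc) == 1L) cc <- rep(cc, J)

  rep_rows <- vector("list", design$replicates)
  err_gpdm <- list(); err_dich <- list()  # per-replicate J x C error matrices
  failed <- 0L
  for (r in seq_len(design$replicates)) {
    seed_r <- design$seed + r
    res <- tryCatch({
      set.seed(seed_r)
      attrs <- sim_attributes(design$N, K, design$R, design$thresholds)
      pars <- sim_item_params(Q, cc)
      X <- sim_responses(attrs, pars$item_probs, maps)
      fit <- fit_gpdm(X, Q, cc, max_iter = design$max_iter, tol = design$tol)
      ca <- classification_accuracy(attrs, map_attributes(fit$posterior, patterns))
      ca_attr <- classification_accuracy(attrs, eap_attributes(fit$posterior, patterns))
      # probability errors at the all-zero / all-one reduced patterns
      err <- t(vapply(seq_len(J), function(j) {
        H <- maps[[j]]$H
        est <- fit$item_probs[[j]]; tru <- pars$item_probs[[j]]
        c(est[-1L, 1L] - tru[-1L, 1L], est[-1L, H] - tru[-1L, H])
      }, numeric(2L * (cc[1L] - 1L))))
      row <- tibble(replicate = r, model = "gpdm",
                    ca_pattern = ca$pattern,
                    ca_attribute = mean(ca_attr$attribute),
                    converged = fit$converged, n_iter = fit$n_iter)
      out <- list(rows = row, err = err, err_d = NULL)
      if (design$fit_dichotomized) {
        Xd <- dichotomize(X, cc)
        fit_d <- fit_gpdm(Xd, Q, 2L, max_iter = design$max_iter, tol = design$tol)
        ca_d <- classification_accuracy(attrs, map_attributes(fit_d$posterior, patterns))
        ca_attr_d <- classification_accuracy(attrs, eap_attributes(fit_d$posterior, patterns))
        out$rows <- dplyr::bind_rows(row, tibble(
          replicate = r, model = "dichotomized",
          ca_pattern = ca_d$pattern, ca_attribute = mean(ca_attr_d$attribute),
          converged = fit_d$converged, n_iter = fit_d$n_iter))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      warn(sprintf("Replicate %d failed (%s); excluded.", r, conditionMessage(res)))
      next
    }
    rep_rows[[r]] <- res$rows
    err_gpdm[[length(err_gpdm) + 1L]] <- res$err
    if (progress && r %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  reps <- dplyr::bind_rows(rep_rows)
  summary <- reps |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      sd_pattern = stats::sd(.data$ca_pattern),
      sd_attribute = stats::sd(.data$ca_attribute),
      ca_pattern = mean(.data$ca_pattern),
      ca_attribute = mean(.data$ca_attribute),
      replicates = dplyr::n(), .groups = "drop") |>
    dplyr::select("model", "ca_pattern", "sd_pattern", "ca_attribute",
                  "sd_attribute", "replicates")

  Cm1 <- cc[1L] - 1L
  err_all <- do.call(rbind, err_gpdm)  # (J * reps) x (2 * (C-1))
  par_names <- c(paste0("P", seq_len(Cm1), "(0)"), paste0("P", seq_len(Cm1), "(1)"))
  recovery <- tibble(parameter = par_names,
                     bias = colMeans(err_all),
                     rmse = sqrt(colMeans(err_all^2)))

  structure(list(summary = summary, recovery = recovery, replicates = reps,
                 failed = failed, design = design),
            class = "gpdm_study")
}
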