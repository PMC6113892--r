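#' Tidy a fitted polytomous diagnosis model
#'
#' One row per item, category and latent group, with the estimated
#' conditional probability and (when computed) its standard error.
#'
#' @param x A [fit_gpdm()] result.
#' @param ... Unused.
#' @return A tibble with columns `item`, `category`, `group`,
#'   `pattern`, `estimate`, `se`.
#' @export
tidy.gpdm <- function(x, ...) {
  rows <- lapply(seq_along(x$item_probs), function(j) {
    P <- x$item_probs[[j]]
    labs <- group_labels(x$item_maps[[j]])
    se <- if (!is.null(x$se_tables)) x$se_tables[[j]] else matrix(NA_real_, nrow(P), ncol(P))
    tidyr::expand_grid(category = 0:(nrow(P) - 1L), group = seq_len(ncol(P))) |>
      dplyr::mutate(item = x$item_maps[[j]]$item,
                    pattern = labs[.data$group],
                    estimate = P[cbind(.data$category + 1L, .data$group)],
                    se = se[cbind(.data$category + 1L, .data$group)]) |>
      dplyr::select("item", "category", "group", "pattern", "estimate", "se")
  })
  dplyr::bind_rows(rows)
}

#' Glance at a fitted polytomous diagnosis model
#'
#' @param x A [fit_gpdm()] result.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `minus2LL`, `AIC`, `BIC`, `NP`,
#'   `n_iter`, `converged`, `N`, `J`, `K`, `model`.
#' @export
glance.gpdm <- function(x, ...) {
  NP <- count_parameters(x$Q, x$category_counts, model = x$model)
  ic <- info_criteria(x$loglik, NP, nrow(x$responses))
  tibble(logLik = x$loglik, minus2LL = ic$minus2LL, AIC = ic$AIC, BIC = ic$BIC,
         NP = NP, n_iter = x$n_iter, converged = x$converged,
         N = nrow(x$responses), J = nrow(x$Q), K = ncol(x$Q), model = x$model)
}

#' @export
print.gpdm <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<gpdm> %s fit: %d examinees, %d items, %d attributes\n",
              toupper(x$model), g$N, g$J, g$K))
  cat(sprintf("  logLik %.2f | NP %d | AIC %.1f | BIC %.1f\n",
              g$logLik, g$NP, g$AIC, g$BIC))
  cat(sprintf("  EM: %d iterations, %s\n", g$n_iter,
              if (g$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Plot estimated category probabilities by latent group
#'
#' One panel per item; bars stack the conditional category
#' probabilities across the item's reduced attribute patterns, making
#' the mastery gradient (and any monotonicity violations) visible.
#'
#' @param object A [fit_gpdm()] result.
#' @param items Items to plot (indices; default first 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gpdm <- function(object, items = seq_len(min(12L, nrow(object$Q))), ...) {
  td <- tidy(object)
  keep <- vapply(object$item_maps[items], `[[`, character(1), "item")
  td <- dplyr::filter(td, .data$item %in% keep)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$pattern, y = .data$estimate,
                                   fill = factor(.data$category))) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~item, scales = "free_x") +
    ggplot2::labs(x = "reduced attribute pattern", y = "P(category | pattern)",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' Tidy a model-fit assessment
#'
#' @param x A [assess_fit()] result.
#' @param ... Unused.
#' @return A tibble of item pairs with `r` and `z`.
#' @export
tidy.gpdm_assessment <- function(x, ...) {
  J <- ncol(x$z)
  idx <- which(upper.tri(x$z), arr.ind = TRUE)
  tibble(item_a = idx[, 1L], item_b = idx[, 2L],
         r = x$r[idx], z = x$z[idx]) |>
    dplyr::arrange(dplyr::desc(.data$z))
}

#' @export
glance.gpdm_assessment <- function(x, ...) {
  tibble(max_z = x$max_z, critical_z = x$critical_z, misfit = x$misfit,
         sr = x$sr_test, hit_item = x$hit_item, alpha = x$alpha,
         NP = x$NP, minus2LL = x$minus2LL, AIC = x$AIC, BIC = x$BIC)
}

#' @export
print.gpdm_assessment <- function(x, ...) {
  cat(sprintf("<gpdm_assessment> (%s, M = %d predicted examinees)\n", x$model, x$M))
  cat(sprintf("  max z = %.2f vs critical z = %.2f (alpha = %.2f): %s\n",
              x$max_z, x$critical_z, x$alpha,
              if (x$misfit) "MISFIT flagged" else "no misfit flagged"))
  cat(sprintf("  sr = %.2f | hit item = %d (sr_j = %.2f)\n",
              x$sr_test, x$hit_item, x$sr_item[x$hit_item]))
  cat(sprintf("  NP %d | -2LL %.0f | AIC %.0f | BIC %.0f\n",
              x$NP, x$minus2LL, x$AIC, x$BIC))
  invisible(x)
}

#' Plot residual z-scores of item pairs
#'
#' Heatmap of the Fisher-z residual-correlation z-scores; cells beyond
#' the Bonferroni critical value mark misfitting pairs.
#'
#' @param object A [assess_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gpdm_assessment <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$item_a, y = .data$item_b,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "item", y = "item",
                  title = sprintf("Residual z (critical = %.2f)", object$critical_z)) +
    ggplot2::theme_minimal()
}

#' @export
print.gpdm_study <- function(x, ...) {
  cat(sprintf("<gpdm_study> %d replicates (%d failed), N = %d, J = %d\n",
              x$design$replicates, x$failed, x$design$N, nrow(x$design$Q)))
  print(x$summary)
  print(x$recovery)
  invisible(x)
}

#' Plot per-replicate classification accuracy
#'
#' @param object A [run_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gpdm_study <- function(object, ...) {
  td <- tidyr::pivot_longer(object$replicates,
                            c("ca_pattern", "ca_attribute"),
                            names_to = "measure", values_to = "accuracy")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$model, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "classification accuracy") +
    ggplot2::theme_minimal()
}
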