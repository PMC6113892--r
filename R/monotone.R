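comparable_geq <- function(red) {
  # geq[h, h2] TRUE iff reduced pattern h masters at least what h2 masters
  H <- nrow(red)
  geq <- matrix(FALSE, H, H)
  for (h in seq_len(H)) {
    geq[h, ] <- apply(t(red) <= red[h, ], 2L, all)
  }
  geq
}

#' Weighted isotonic regression over the mastery partial order
#'
#' Projects a vector indexed by an item's latent groups onto the cone of
#' functions that are non-decreasing in the mastery partial order
#' (\eqn{\eta \ge \eta'} elementwise), minimizing the weighted squared
#' distance. For `H <= 16` groups the exact solution is computed by the
#' lower/upper-set min-max characterization; larger tables fall back on
#' cyclic pairwise pooling iterated to convergence.
#'
#' @param y Numeric vector of length H (one value per latent group).
#' @param w Non-negative weights (expected group sizes); zero-weight
#'   groups get a small floor so the projection stays defined.
#' @param red `H x G` matrix of reduced patterns defining the order.
#' @return Numeric vector of length H, monotone in the partial order.
#' @export
poset_isoreg <- function(y, w, red) {
  H <- length(y)
  stopifnot(nrow(red) == H, length(w) == H, all(w >= 0))
  w <- pmax(w, 1e-8)
  geq <- comparable_geq(red)
  if (!any(geq & t(!geq) & upper.tri(geq) | geq & !t(geq))) {
    # no strict comparabilities at all (cannot happen on a power-set lattice)
    return(y)
  }
  if (H <= 16L) {
    masks <- 0:(2L^H - 1L)
    member <- vapply(seq_len(H), function(h) bitwAnd(masks, bitwShiftL(1L, h - 1L)) != 0L,
                     logical(length(masks)))
    # down[h]/up[h]: bit masks of groups below / above h in the order
    down <- vapply(seq_len(H), function(h) {
      sum(bitwShiftL(1L, which(geq[h, ]) - 1L))
    }, integer(1))
    up <- vapply(seq_len(H), function(h) {
      sum(bitwShiftL(1L, which(geq[, h]) - 1L))
    }, integer(1))
    is_lower <- rep(TRUE, length(masks))
    is_upper <- rep(TRUE, length(masks))
    for (h in seq_len(H)) {
      inset <- member[, h]
      is_lower <- is_lower & (!inset | bitwAnd(masks, down[h]) == down[h])
      is_upper <- is_upper & (!inset | bitwAnd(masks, up[h]) == up[h])
    }
    lower_sets <- masks[is_lower & masks > 0L]
    upper_sets <- masks[is_upper & masks > 0L]
    avg <- function(mask) {
      idx <- which(vapply(seq_len(H), function(h)
        bitwAnd(mask, bitwShiftL(1L, h - 1L)) != 0L, logical(1)))
      sum(w[idx] * y[idx]) / sum(w[idx])
    }
    out <- numeric(H)
    for (h in seq_len(H)) {
      bit <- bitwShiftL(1L, h - 1L)
      Ls <- lower_sets[bitwAnd(lower_sets, bit) != 0L]
      Us <- upper_sets[bitwAnd(upper_sets, bit) != 0L]
      # g(h) = max over upper sets ∋ h of min over lower sets ∋ h of Av(U ∩ L)
      best <- -Inf
      for (uo in Us) {
        worst <- Inf
        for (lo in Ls) {
          inter <- bitwAnd(uo, lo)
          if (inter != 0L) worst <- min(worst, avg(inter))
        }
        best <- max(best, worst)
      }
      out[h] <- best
    }
    return(out)
  }
  # fallback: cyclic pooling of violating comparable pairs
  out <- y
  pairs <- which(geq & !t(geq), arr.ind = TRUE)  # row masters more than col
  for (iter in seq_len(1000L)) {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      hi <- pairs[r, 1L]; lo <- pairs[r, 2L]
      if (out[hi] < out[lo] - 1e-12) {
        m <- (w[hi] * out[hi] + w[lo] * out[lo]) / (w[hi] + w[lo])
        out[hi] <- m; out[lo] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out
}

#' Impose the monotonicity assumption on item probability tables
#'
#' Enforces, per item and category, that the cumulative probability
#' \eqn{P^*_c(\eta_{jh})} never decreases when moving to a reduced
#' pattern that masters more required attributes. The constraint is
#' applied top-down: first the highest category
#' (\eqn{P^*_{C-1} = P_{C-1}}), then
#' \eqn{P^*_{C-2} = P_{C-2} + P^*_{C-1}}, and so on down to category 1,
#' each cumulative row projected by class-size-weighted isotonic
#' regression over the mastery partial order and kept within
#' `[P*_{c+1}, 1]` so the recovered conditional probabilities stay
#' non-negative and columns still sum to 1.
#'
#' @param item_probs List of `C_j x H_j` conditional-probability
#'   matrices.
#' @param group_weights List of length-`H_j` expected group sizes
#'   \eqn{N_{jh}} (equal weights if `NULL`).
#' @param item_maps Output of [build_item_maps()].
#' @return List of adjusted probability matrices.
#' @export
impose_monotonicity <- function(item_probs, group_weights = NULL, item_maps) {
  out <- item_probs
  for (j in seq_along(item_probs)) {
    P <- item_probs[[j]]
    C <- nrow(P)
    red <- item_maps[[j]]$reduced_patterns
    w <- if (is.null(group_weights)) rep(1, ncol(P)) else group_weights[[j]]
    cum_above <- rep(0, ncol(P))         # P*_{c+1}, starts at P*_C = 0
    cum_rows <- matrix(0, C + 1L, ncol(P))
    cum_rows[C + 1L, ] <- 0
    for (cc in (C - 1L):1L) {            # top category downward
      target <- P[cc + 1L, ] + cum_above
      iso <- poset_isoreg(target, w, red)
      iso <- pmin(pmax(iso, cum_above), 1)
      cum_rows[cc + 1L, ] <- iso
      cum_above <- iso
    }
    cum_rows[1L, ] <- 1
    out[[j]] <- conditional_from_cumulative(cum_rows)
    dimnames(out[[j]]) <- dimnames(P)
  }
  out
}

#' Check the monotonicity assumption post hoc
#'
#' Scans every pair of comparable reduced patterns per item and
#' category and reports cumulative-probability reversals
#' (\eqn{P^*_c(\eta_{jh}) < P^*_c(\eta_{jh'})} with
#' \eqn{\eta_{jh} > \eta_{jh'}}).
#'
#' @inheritParams impose_monotonicity
#' @param tol Violations smaller than `tol` are ignored.
#' @return A tibble with columns `item`, `category`, `pattern_hi`,
#'   `pattern_lo`, `magnitude` (empty if the tables are monotone).
#' @export
check_monotonicity <- function(item_probs, item_maps, tol = 1e-10) {
  rows <- list()
  for (j in seq_along(item_probs)) {
    P <- item_probs[[j]]
    C <- nrow(P)
    red <- item_maps[[j]]$reduced_patterns
    labs <- group_labels(item_maps[[j]])
    cum <- cumulative_from_conditional(P)
    geq <- comparable_geq(red)
    for (cc in seq_len(C - 1L)) {
      for (hi in seq_len(nrow(red))) {
        for (lo in seq_len(nrow(red))) {
          if (hi != lo && geq[hi, lo] && !geq[lo, hi]) {
            gap <- cum[cc + 1L, lo] - cum[cc + 1L, hi]
            if (gap > tol) {
              rows[[length(rows) + 1L]] <- tibble(
                item = item_maps[[j]]$item, category = cc,
                pattern_hi = labs[hi], pattern_lo = labs[lo],
                magnitude = gap)
            }
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble(item = character(), category = integer(),
                  pattern_hi = character(), pattern_lo = character(),
                  magnitude = numeric()))
  }
  dplyr::bind_rows(rows)
}
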