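#' Enumerate all attribute patterns for K binary attributes
#'
#' A cognitive-diagnosis model with K dichotomous attributes has
#' `L = 2^K` latent classes, one per binary mastery pattern
#' \eqn{\alpha_l}. Patterns are returned in lexicographic order with
#' attribute 1 as the most significant bit, so pattern `l` spells the
#' base-2 digits of `l - 1`. Row 1 is the all-zero (no mastery) pattern
#' and row `L` the all-one pattern. This ordering is used consistently
#' throughout the package so class indices are reproducible.
#'
#' @param K Number of attributes (integer, `1 <= K <= max_K`).
#' @param max_K Practical cap on K (default 15; `2^K` classes are
#'   enumerated explicitly).
#'
#' @return An `L x K` binary integer matrix with rows \eqn{\alpha_l}.
#' @examples
#' attribute_patterns(2)
#' @export
attribute_patterns <- function(K, max_K = 15L) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 1 || K != round(K)) {
    abort("`K` must be a single positive integer.", class = "gpdm_dim_error")
  }
  if (K > max_K) {
    abort(sprintf("`K` = %d exceeds the practical cap of %d attributes.", K, max_K),
          class = "gpdm_dim_error")
  }
  K <- as.integer(K)
  L <- 2L^K
  pat <- matrix(0L, L, K)
  for (k in seq_len(K)) {
    # attribute 1 is the most significant bit
    pat[, k] <- rep(rep(0:1, each = 2L^(K - k)), length.out = L)
  }
  colnames(pat) <- paste0("A", seq_len(K))
  pat
}

#' Reduce an attribute pattern to an item's required attributes
#'
#' For item j with q-vector `q_row`, the full attribute pattern
#' \eqn{\alpha_l} collapses to the reduced attribute vector
#' \eqn{\eta_{jh}}: the sub-vector at the positions where
#' `q_row == 1`, preserving attribute order.
#'
#' @param alpha Binary vector of length K (a full attribute pattern).
#' @param q_row Binary vector of length K (an item's Q-matrix row).
#'
#' @return Binary vector of length `sum(q_row)`.
#' @examples
#' reduce_pattern(c(1, 0, 1, 1), c(1, 0, 1, 0))
#' @export
reduce_pattern <- function(alpha, q_row) {
  if (length(alpha) != length(q_row)) {
    abort("`alpha` and `q_row` must have the same length.", class = "gpdm_dim_error")
  }
  alpha[q_row == 1]
}

validate_qmatrix <- function(Q) {
  Q <- as.matrix(Q)
  if (!all(Q %in% c(0, 1))) {
    abort("Q-matrix entries must all be 0 or 1.", class = "gpdm_parse_error")
  }
  storage.mode(Q) <- "integer"
  if (nrow(Q) < 1L || ncol(Q) < 1L) {
    abort("Q-matrix must have at least one item and one attribute.",
          class = "gpdm_dim_error")
  }
  if (any(rowSums(Q) == 0L)) {
    bad <- which(rowSums(Q) == 0L)
    abort(sprintf("Item(s) %s measure no attribute (all-zero q-vector); the model is undefined for them.",
                  paste(bad, collapse = ", ")),
          class = "gpdm_parse_error")
  }
  if (any(colSums(Q) == 0L)) {
    warn(sprintf("Attribute(s) %s are never measured by any item; they are not identifiable.",
                 paste(which(colSums(Q) == 0L), collapse = ", ")))
  }
  if (is.null(rownames(Q))) rownames(Q) <- paste0("item", seq_len(nrow(Q)))
  if (is.null(colnames(Q))) colnames(Q) <- paste0("A", seq_len(ncol(Q)))
  Q
}

#' Build per-item latent-group maps from a Q-matrix
#'
#' Each item j requires `G_j = sum(q_j)` attributes, so the `L = 2^K`
#' latent classes collapse into `H_j = 2^{G_j}` latent groups for that
#' item: two classes land in the same group exactly when they agree on
#' the item's required attributes. The map records, for every class l,
#' the group index h whose reduced pattern \eqn{\eta_{jh}} equals the
#' required-attribute sub-vector of \eqn{\alpha_l}. Every group collects
#' exactly `L / H_j` classes.
#'
#' @param Q A binary J x K Q-matrix (matrix or data frame).
#' @param patterns Optional pattern matrix from [attribute_patterns()];
#'   enumerated from `ncol(Q)` when omitted.
#'
#' @return A list of length J; element j is a list with
#'   `required` (indices of required attributes), `G`, `H`,
#'   `group_of` (length-L integer vector mapping class l to group h) and
#'   `reduced_patterns` (`H_j x G_j` binary matrix, rows \eqn{\eta_{jh}}
#'   in the same lexicographic order convention).
#' @export
build_item_maps <- function(Q, patterns = NULL) {
  Q <- validate_qmatrix(Q)
  K <- ncol(Q)
  if (is.null(patterns)) patterns <- attribute_patterns(K)
  if (ncol(patterns) != K) {
    abort("`patterns` and `Q` disagree on the number of attributes.",
          class = "gpdm_dim_error")
  }
  lapply(seq_len(nrow(Q)), function(j) {
    req <- which(Q[j, ] == 1L)
    G <- length(req)
    H <- as.integer(2^G)
    red <- attribute_patterns(G)
    sub <- patterns[, req, drop = FALSE]
    # group index = 1 + binary value of the required sub-vector (attr 1 = MSB)
    pow <- 2L^((G - 1L):0L)
    group_of <- as.integer(sub %*% pow) + 1L
    list(item = rownames(Q)[j], required = req, G = G, H = H,
         group_of = group_of, reduced_patterns = red)
  })
}

#' Label a latent group by its reduced pattern
#'
#' @param map One element of [build_item_maps()].
#' @return Character vector of length `H_j`, e.g. `"10"` for
#'   \eqn{\eta = (1,0)}.
#' @keywords internal
group_labels <- function(map) {
  apply(map$reduced_patterns, 1L, paste0, collapse = "")
}
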