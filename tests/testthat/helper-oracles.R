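# Independent reference implementations used as oracles. These are
# deliberately written as plain loops, separate from the package's code
# paths.

# plain-loop E-step / marginal likelihood by full enumeration
ref_e_step <- function(X, item_probs, structural, item_maps) {
  X <- as.matrix(X)
  N <- nrow(X)
  L <- length(structural)
  lik <- matrix(1, N, L)
  for (j in seq_along(item_probs)) {
    for (l in seq_len(L)) {
      h <- item_maps[[j]]$group_of[l]
      lik[, l] <- lik[, l] * item_probs[[j]][X[, j] + 1L, h]
    }
  }
  unnorm <- sweep(lik, 2L, structural, "*")
  marg <- rowSums(unnorm)
  list(loglik = sum(log(marg)), post = unnorm / marg, lik = lik)
}

ref_marginal_loglik <- function(X, item_probs, structural, item_maps) {
  ref_e_step(X, item_probs, structural, item_maps)$loglik
}

# independent EM for the saturated model, plain loops, same deterministic
# monotone initialization
ref_saturated_em <- function(X, Q, category_counts, max_iter = 2000, tol = 1e-6) {
  X <- as.matrix(X)
  maps <- build_item_maps(Q)
  J <- nrow(Q)
  if (length(category_counts) == 1L) category_counts <- rep(category_counts, J)
  L <- 2^ncol(Q)
  probs <- lapply(seq_len(J), function(j) {
    m <- rowSums(maps[[j]]$reduced_patterns)
    base <- 0.2 + 0.6 * m / max(maps[[j]]$G, 1)
    C <- category_counts[j]
    P <- matrix(0, C, maps[[j]]$H)
    for (h in seq_len(maps[[j]]$H)) {
      cum <- c(1, base[h] * (C - seq_len(C - 1)) / (C - 1), 0)
      P[, h] <- cum[seq_len(C)] - cum[seq_len(C) + 1L]
    }
    P
  })
  prior <- rep(1 / L, L)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    es <- ref_e_step(X, probs, prior, maps)
    if (is.finite(prev) && abs(es$loglik - prev) < tol) break
    prev <- es$loglik
    for (j in seq_len(J)) {
      C <- category_counts[j]
      R <- matrix(0, C, maps[[j]]$H)
      for (l in seq_len(L)) {
        h <- maps[[j]]$group_of[l]
        for (cc in seq_len(C)) {
          R[cc, h] <- R[cc, h] + sum(es$post[X[, j] == cc - 1L, l])
        }
      }
      Nh <- colSums(R)
      for (h in which(Nh > 0)) probs[[j]][, h] <- R[, h] / Nh[h]
    }
    prior <- colMeans(es$post)
  }
  list(item_probs = probs, structural = prior, loglik = es$loglik, n_iter = it)
}

# direct numerical maximization of the marginal likelihood over
# softmax-parameterized probabilities (brute-force oracle for tiny cases)
ref_mml_optim <- function(X, Q, category_counts, reltol = 1e-14) {
  X <- as.matrix(X)
  maps <- build_item_maps(Q)
  J <- nrow(Q)
  if (length(category_counts) == 1L) category_counts <- rep(category_counts, J)
  L <- 2^ncol(Q)
  n_item <- sum((category_counts - 1) * vapply(maps, `[[`, integer(1), "H"))
  unpack <- function(par) {
    probs <- vector("list", J)
    pos <- 0L
    for (j in seq_len(J)) {
      C <- category_counts[j]; H <- maps[[j]]$H
      P <- matrix(0, C, H)
      for (h in seq_len(H)) {
        z <- c(0, par[pos + seq_len(C - 1L)])
        pos <- pos + C - 1L
        P[, h] <- exp(z) / sum(exp(z))
      }
      probs[[j]] <- P
    }
    z <- c(0, par[pos + seq_len(L - 1L)])
    list(probs = probs, prior = exp(z) / sum(exp(z)))
  }
  nll <- function(par) {
    u <- unpack(par)
    -ref_marginal_loglik(X, u$probs, u$prior, maps)
  }
  # multi-start: a symmetric start sits on the label-switching saddle
  set.seed(987)
  best <- NULL
  for (s in 1:8) {
    start <- stats::rnorm(n_item + L - 1L, sd = 1)
    opt <- stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 10000, reltol = reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  c(unpack(best$par), loglik = -best$value)
}

# weighted isotonic regression over the poset by Dykstra's alternating
# projections onto the pairwise half-spaces (exact projection in the
# w-weighted norm as the sweep count grows)
ref_isoreg_dykstra <- function(y, w, red, sweeps = 20000) {
  H <- length(y)
  geq <- matrix(FALSE, H, H)
  for (h in seq_len(H)) geq[h, ] <- apply(t(red) <= red[h, ], 2, all)
  pairs <- which(geq & !t(geq), arr.ind = TRUE)  # row >= col strictly
  P <- nrow(pairs)
  g <- y
  inc <- matrix(0, P, H)
  for (it in seq_len(sweeps)) {
    for (r in seq_len(P)) {
      hi <- pairs[r, 1]; lo <- pairs[r, 2]
      z <- g + inc[r, ]
      gnew <- z
      if (z[hi] < z[lo]) {
        m <- (w[hi] * z[hi] + w[lo] * z[lo]) / (w[hi] + w[lo])
        gnew[hi] <- m; gnew[lo] <- m
      }
      inc[r, ] <- z - gnew
      g <- gnew
    }
  }
  g
}

# small PDINA-generated probability tables (Eq-8-style structure)
ref_pdina_tables <- function(maps, category_counts, guess, slip) {
  lapply(seq_along(maps), function(j) {
    C <- category_counts[j]; H <- maps[[j]]$H
    P <- matrix(0, C, H)
    for (cc in seq_len(C - 1L)) {
      pc <- rep(guess, H)
      pc[H] <- 1 - slip
      P[cc + 1L, ] <- pc / (C - 1L)
    }
    P[1L, ] <- 1 - colSums(P[-1L, , drop = FALSE])
    P
  })
}
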