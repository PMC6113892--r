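toy_setup <- function() {
  Q <- rbind(c(1), c(1))
  maps <- build_item_maps(Q)
  probs <- list(rbind(c(0.8, 0.3), c(0.2, 0.7)),
                rbind(c(0.6, 0.1), c(0.4, 0.9)))
  list(Q = Q, maps = maps, probs = probs, prior = c(0.45, 0.55))
}

test_that("conditional likelihood multiplies per-item table lookups", {
  s <- toy_setup()
  # X = (1, 0): L(X|alpha=0) = 0.2 * 0.6, L(X|alpha=1) = 0.7 * 0.1
  expect_equal(conditional_likelihood(c(1L, 0L), s$probs, s$maps),
               c(0.2 * 0.6, 0.7 * 0.1))

  # an uninformative item gives a constant likelihood
  flat <- list(rbind(c(0.55, 0.55), c(0.45, 0.45)))
  maps1 <- build_item_maps(matrix(1, 1, 1))
  expect_equal(conditional_likelihood(1L, flat, maps1), c(0.45, 0.45))

  # a deterministic item confines the posterior to its group's classes
  det <- list(rbind(c(1, 0), c(0, 1)), rbind(c(0.6, 0.1), c(0.4, 0.9)))
  lik <- conditional_likelihood(c(1L, 1L), det, s$maps)
  expect_equal(lik[1], 0)
  expect_gt(lik[2], 0)
})

test_that("marginal log-likelihood matches exhaustive enumeration", {
  s <- toy_setup()
  X <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  want <- sum(apply(X, 1, function(x) {
    log(sum(conditional_likelihood(x, s$probs, s$maps) * s$prior))
  }))
  expect_equal(marginal_loglik(X, s$probs, s$prior, s$maps), want)
  expect_equal(ref_marginal_loglik(X, s$probs, s$prior, s$maps), want)

  # additivity: duplicating an examinee adds exactly its contribution
  X2 <- rbind(X, X[2, ])
  expect_equal(marginal_loglik(X2, s$probs, s$prior, s$maps),
               want + log(sum(conditional_likelihood(X[2, ], s$probs, s$maps) * s$prior)))
})

test_that("the compiled E-step agrees with the plain-loop reference", {
  set.seed(41)
  Q <- rbind(c(1, 0, 0), c(0, 1, 1), c(1, 1, 0), c(1, 1, 1))
  sim <- sim_gpdm_data(60, Q, 3, seed = 41)
  maps <- build_item_maps(Q)
  probs <- sim$item_probs
  prior <- rnorm(8)^2; prior <- prior / sum(prior)
  got <- e_step(sim$responses, probs, prior, maps)
  want <- ref_e_step(sim$responses, probs, prior, maps)
  expect_equal(got$loglik, want$loglik, tolerance = 1e-12)
  expect_equal(got$post, want$post, tolerance = 1e-12)

  # conservation: group weights add to N, category counts to group weights
  for (j in seq_along(maps)) {
    expect_equal(sum(got$group_weights[[j]]), 60, tolerance = 1e-9)
    expect_equal(colSums(got$group_counts[[j]]), got$group_weights[[j]],
                 tolerance = 1e-9)
  }
})

test_that("posterior equals the prior when items carry no information", {
  maps <- build_item_maps(rbind(c(1, 0), c(0, 1)))
  flat <- list(rbind(c(0.5, 0.5), c(0.5, 0.5)), rbind(c(0.3, 0.3), c(0.7, 0.7)))
  prior <- c(0.1, 0.2, 0.3, 0.4)
  X <- rbind(c(0L, 1L), c(1L, 1L))
  es <- e_step(X, flat, prior, maps)
  expect_equal(es$post, rbind(prior, prior), tolerance = 1e-12, ignore_attr = TRUE)

  # two-class Bayes rule by hand on the toy
  s <- toy_setup()
  es <- e_step(rbind(c(1L, 0L)), s$probs, s$prior, s$maps)
  lik <- c(0.2 * 0.6, 0.7 * 0.1)
  expect_equal(drop(es$post), lik * s$prior / sum(lik * s$prior))
})

test_that("the M-step is the complete-data MLE and keeps the simplex", {
  s <- toy_setup()
  X <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 1L))
  # hard posterior: examinees 1-2 in class 1, examinees 3-4 in class 2
  es <- list(post = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
  es$group_counts <- lapply(1:2, function(j) {
    R <- matrix(0, 2, 2)
    for (i in 1:4) {
      h <- s$maps[[j]]$group_of[which(es$post[i, ] == 1)]
      R[X[i, j] + 1, h] <- R[X[i, j] + 1, h] + 1
    }
    R
  })
  ms <- m_step(es, s$probs)
  # within-class observed frequencies
  expect_equal(unname(ms$item_probs[[1]][, 1]), c(1, 0))      # item 1, class 0: both answered 0
  expect_equal(unname(ms$item_probs[[1]][, 2]), c(0, 1))
  expect_equal(unname(ms$item_probs[[2]][, 1]), c(0.5, 0.5))
  expect_equal(sum(ms$structural), 1)
  expect_equal(ms$structural, c(0.5, 0.5))
})

test_that("one EM step from the truth stays near the truth on large samples", {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1))
  set.seed(43)
  sim <- sim_gpdm_data(20000, Q, 3, seed = 43)
  maps <- build_item_maps(Q)
  prior_true <- as.numeric(table(factor(
    sim$attributes %*% c(2, 1) + 1, levels = 1:4)) / 20000)
  es <- e_step(sim$responses, sim$item_probs, prior_true, maps)
  ms <- m_step(es, sim$item_probs)
  moved <- unlist(Map(function(a, b) abs(a - b), ms$item_probs, sim$item_probs))
  expect_lt(max(moved), 0.05)  # O(N^{-1/2}) drift only
})

test_that("EM increases the marginal likelihood and converges", {
  Q <- qmatrix_sim20()[1:10, ]
  sim <- sim_gpdm_data(300, Q, 3, seed = 47)
  fit <- fit_gpdm(sim$responses, Q, 3)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # probability tables and structural distribution stay on the simplex
  for (P in fit$item_probs) {
    expect_equal(colSums(P), rep(1, ncol(P)), tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
  expect_equal(sum(fit$structural), 1, tolerance = 1e-12)
})

test_that("the EM fixed point matches brute-force likelihood maximization", {
  Q <- rbind(c(1), c(1), c(1))
  set.seed(53)
  X <- cbind(rbinom(20, 1, rep(c(0.25, 0.8), each = 10)),
             rbinom(20, 1, rep(c(0.3, 0.85), each = 10)),
             rbinom(20, 1, rep(c(0.2, 0.9), each = 10)))
  fit <- fit_gpdm(X, Q, 2, tol = 1e-10)
  opt <- ref_mml_optim(X, Q, 2)
  expect_lt(abs(fit$loglik - opt$loglik), 1e-4)

  # K = 2 three-item designs: best EM restart against best optimizer restart
  Q2 <- rbind(c(1, 0), c(0, 1), c(1, 1))
  for (sd in c(7, 83, 19)) {
    sim <- sim_gpdm_data(20, Q2, 2, seed = sd)
    em_best <- max(vapply(1:8, function(s) suppressWarnings(
      fit_gpdm(sim$responses, Q2, 2, tol = 1e-12, max_iter = 20000,
               init_jitter = 0.2, seed = s)$loglik), numeric(1)))
    opt2 <- ref_mml_optim(sim$responses, Q2, 2)
    expect_lt(abs(em_best - opt2$loglik), 1e-4)
  }
})

test_that("parameters of the generating model are recovered at scale", {
  Q <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(0, 1, 1),
             c(1, 0, 1), c(1, 1, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  sim <- sim_gpdm_data(5000, Q, 3, seed = 59)
  fit <- fit_gpdm(sim$responses, Q, 3)
  err <- unlist(Map(`-`, fit$item_probs, sim$item_probs))
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("all-dichotomous data reproduce an independent dichotomous EM", {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0))
  sim <- sim_gpdm_data(400, Q, 2, seed = 61)
  fit <- fit_gpdm(sim$responses, Q, 2, tol = 1e-8)
  ref <- ref_saturated_em(sim$responses, Q, 2, tol = 1e-8)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
  for (j in 1:4) {
    expect_equal(unname(fit$item_probs[[j]]), ref$item_probs[[j]], tolerance = 1e-4)
  }
})

test_that("responses are validated before estimation", {
  Q <- rbind(c(1), c(1))
  expect_error(fit_gpdm(rbind(c(0L, NA)), Q), class = "gpdm_parse_error")
  expect_error(fit_gpdm(rbind(c(0L, 3L)), Q, category_counts = 2),
               class = "gpdm_parse_error")
  expect_error(fit_gpdm(rbind(c(0L, 1L, 0L)), Q), class = "gpdm_dim_error")
})

test_that("information-matrix SEs approach the binomial form with hard classes", {
  # one nearly deterministic item pins down class membership; the SE of the
  # other items' probabilities then behaves like a within-group binomial SE
  Q <- rbind(c(1), c(1), c(1))
  maps <- build_item_maps(Q)
  probs <- list(rbind(c(0.98, 0.02), c(0.02, 0.98)),
                rbind(c(0.7, 0.4), c(0.3, 0.6)),
                rbind(c(0.8, 0.25), c(0.2, 0.75)))
  set.seed(67)
  cls <- sample(1:2, 3000, replace = TRUE)
  X <- gpdm:::sim_responses_internal(cls, probs, maps)
  fit <- fit_gpdm(X, Q, 2, se = TRUE)
  for (j in 2:3) {
    Nh <- fit$group_weights[[j]]
    phat <- fit$item_probs[[j]][2, ]
    expect_equal(unname(fit$se_tables[[j]][2, ]),
                 unname(sqrt(phat * (1 - phat) / Nh)), tolerance = 0.2)
  }
})

test_that("SEs shrink roughly by sqrt(2) when the sample doubles", {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1))
  sim <- sim_gpdm_data(2400, Q, 3, seed = 71)
  f1 <- fit_gpdm(sim$responses[1:1200, ], Q, 3, se = TRUE)
  f2 <- fit_gpdm(sim$responses, Q, 3, se = TRUE)
  r <- unlist(f1$se_tables) / unlist(f2$se_tables)
  r <- r[is.finite(r)]
  expect_gt(median(r), 1.2)
  expect_lt(median(r), 1.7)
})

test_that("a singular information matrix yields missing SEs with a warning", {
  Q <- rbind(c(1, 1), c(1, 1))
  sim <- sim_gpdm_data(6, Q, 3, seed = 73)  # far fewer examinees than parameters
  fit <- suppressWarnings(fit_gpdm(sim$responses, Q, 3, max_iter = 50))
  expect_warning(fit <- information_se(fit), "singular|missing")
  expect_true(all(is.na(unlist(fit$se_tables))))
})

test_that("classification follows MAP and EAP rules with documented tie-breaks", {
  pat <- attribute_patterns(2)
  post <- rbind(c(0, 0, 0, 1),              # degenerate
                c(0.25, 0.25, 0.25, 0.25),  # uniform: tie -> class 1
                c(0.1, 0.5, 0.3, 0.1))
  cl <- classify(post, "MAP", patterns = pat)
  expect_equal(cl$class, c(4L, 1L, 2L))
  expect_equal(unname(as.matrix(cl[, c("A1", "A2")])), pat[c(4, 1, 2), ],
               ignore_attr = TRUE)
  cle <- classify(post, "EAP", patterns = pat)
  # marginals row 3: P(A1) = 0.4, P(A2) = 0.6
  expect_equal(unname(as.matrix(cle[3, c("A1", "A2")])), cbind(0L, 1L),
               ignore_attr = TRUE)
  # threshold is inclusive at 0.5
  expect_equal(unname(as.matrix(cle[2, c("A1", "A2")])), cbind(1L, 1L),
               ignore_attr = TRUE)

  # cross-module consistency: MAP accuracy equals a manual computation
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
  sim <- sim_gpdm_data(200, Q, 3, seed = 79)
  fit <- fit_gpdm(sim$responses, Q, 3)
  cl <- classify(fit, "MAP")
  est <- as.matrix(cl[, c("A1", "A2")])
  acc <- classification_accuracy(sim$attributes, est)
  expect_equal(acc$pattern, mean(rowSums(sim$attributes != est) == 0))
})
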