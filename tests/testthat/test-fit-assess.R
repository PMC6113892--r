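small_fit <- function(seed = 101, N = 250) {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1), c(1, 1))
  sim <- sim_gpdm_data(N, Q, 3, seed = seed)
  list(fit = fit_gpdm(sim$responses, Q, 3), sim = sim, Q = Q)
}

test_that("predicted responses follow the fitted mixture distribution", {
  s <- small_fit()
  fit <- s$fit
  pred <- simulate_predicted(fit, 1e5, seed = 1)
  L <- nrow(fit$patterns)
  for (j in c(1, 3)) {
    A <- matrix(0, L, fit$item_maps[[j]]$H)
    A[cbind(seq_len(L), fit$item_maps[[j]]$group_of)] <- 1
    want <- drop(fit$item_probs[[j]] %*% t(A) %*% fit$structural)
    got <- as.numeric(table(factor(pred[, j], levels = 0:2)) / 1e5)
    expect_equal(got, want, tolerance = 0.01, ignore_attr = TRUE)
  }

  # fixed seed reproduces the matrix exactly
  expect_identical(simulate_predicted(fit, 500, seed = 9),
                   simulate_predicted(fit, 500, seed = 9))

  # deterministic tables make responses a function of the sampled class
  Q1 <- rbind(c(1), c(1))
  maps1 <- build_item_maps(Q1)
  det <- list(rbind(c(1, 0), c(0, 1)), rbind(c(1, 0), c(0, 1)))
  cls <- c(1L, 2L, 1L, 2L)
  X <- gpdm:::sim_responses_internal(cls, det, maps1)
  expect_equal(unname(X), cbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L)))
})

test_that("residual z-scores are Fisher-z residuals over item pairs", {
  set.seed(107)
  X <- matrix(sample(0:2, 103 * 3, replace = TRUE), 103, 3)
  # identical predicted data: all residuals vanish
  r0 <- residual_z(X, X)
  expect_equal(unname(r0$r[upper.tri(r0$r)]), rep(0, 3))
  # the Fisher SE at N = 103 is exactly 0.1
  expect_equal(r0$se, 0.1)

  Y <- matrix(sample(0:2, 500 * 3, replace = TRUE), 500, 3)
  res <- residual_z(X, Y)
  fisher <- function(M, a, b) atanh(cor(M[, a], M[, b]))
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    want <- abs(fisher(X, p[1], p[2]) - fisher(Y, p[1], p[2]))
    expect_equal(res$r[p[1], p[2]], want, tolerance = 1e-12)
    expect_equal(res$z[p[1], p[2]], want / 0.1, tolerance = 1e-12)
  }

  # zero-variance columns are flagged and excluded
  Xz <- X; Xz[, 2] <- 1L
  expect_warning(rz <- residual_z(Xz, Y), "Zero-variance")
  expect_true(all(is.na(rz$r[2, ])))
  expect_false(anyNA(rz$r[1, 3]))
})

test_that("sr statistics are the RMS of residual z-scores", {
  z <- matrix(2, 4, 4); diag(z) <- NA
  sr <- sr_statistics(z)
  expect_equal(sr$sr_item, rep(2, 4))
  expect_equal(sr$sr_test, 2)

  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- 2
  sr <- sr_statistics(z)
  expect_equal(sr$sr_item, c(2 / sqrt(2), 2 / sqrt(2), 0))
  expect_equal(sr$sr_test, 2 / sqrt(3))
  expect_equal(sr$hit_item, 1L)

  # identity: sr^2 is the mean of all squared pairwise z
  set.seed(109)
  z <- matrix(0, 5, 5)
  z[upper.tri(z)] <- rnorm(10)
  z <- z + t(z)
  expect_equal(sr_statistics(z)$sr_test^2, mean(z[upper.tri(z)]^2))
})

test_that("the Bonferroni critical value controls over all item pairs", {
  expect_equal(round(bonferroni_critical(20, 0.10), 2), 3.47)
  expect_equal(bonferroni_critical(2, 0.05), qnorm(0.975))
  zc <- vapply(2:30, bonferroni_critical, numeric(1), alpha = 0.10)
  expect_true(all(diff(zc) > 0))
})

test_that("parameter counts follow the saturated and reduced formulas", {
  pisa <- qmatrix_pisa_reading()
  expect_equal(count_parameters(pisa$Q, pisa$category_counts, "gpdm"), 161L)
  expect_equal(count_parameters(pisa$Q, pisa$category_counts, "pdina"), 81L)
  expect_equal(count_parameters(pisa$Q, pisa$category_counts, "pdino"), 81L)
  expect_equal(count_parameters(matrix(1, 1, 1), 2, "gpdm"), 3L)
  # saturated count dominates the reduced count whenever some G_j > 1
  expect_gt(count_parameters(qmatrix_sim20(), 3, "gpdm"),
            count_parameters(qmatrix_sim20(), 3, "pdina"))
})

test_that("information criteria are standard arithmetic on the deviance", {
  ic <- info_criteria(-100, 3, 50)
  expect_equal(ic$minus2LL, 200)
  expect_equal(ic$AIC, 206)
  expect_equal(ic$BIC, 200 + 3 * log(50))
})

test_that("model comparison favors the generating reduced model by BIC", {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 1), c(1, 0), c(0, 1), c(1, 1), c(1, 1))
  maps <- build_item_maps(Q)
  tabs <- ref_pdina_tables(maps, rep(3L, 8), guess = 0.2, slip = 0.2)
  set.seed(113)
  attrs <- sim_attributes(400, 2, R = 0.3)
  X <- sim_responses(attrs, tabs, maps)
  fit_sat <- fit_gpdm(X, Q, 3)
  fit_red <- fit_gpdm(X, Q, 3, model = "pdina")
  expect_lte(fit_red$loglik, fit_sat$loglik + 1e-6)
  expect_lt(glance(fit_red)$BIC, glance(fit_sat)$BIC)
  # the projected tables really carry the two-parameter structure
  P <- fit_red$item_probs[[3]]
  expect_lt(max(abs(P[2, 1] - P[2, 2])), 1e-6)
})

test_that("assessment flags no misfit under the true model and reports indices", {
  s <- small_fit()
  rep <- assess_fit(s$fit, M = 20000, alpha = 0.10, seed = 3)
  expect_s3_class(rep, "gpdm_assessment")
  expect_equal(rep$critical_z, bonferroni_critical(6, 0.10))
  expect_equal(rep$NP, count_parameters(s$Q, 3, "gpdm"))
  g <- glance(rep)
  expect_equal(g$max_z, max(rep$z, na.rm = TRUE))
  td <- tidy(rep)
  expect_equal(nrow(td), 15L)
  expect_equal(sr_statistics(rep$z)$sr_test, rep$sr_test)
})

test_that("max-z exceeds the critical value in about alpha of true-model replicates", {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1))
  maps <- build_item_maps(Q)
  n_rep <- 120
  rejections <- 0
  for (r in seq_len(n_rep)) {
    set.seed(2000 + r)
    attrs <- sim_attributes(150, 2, R = 0.5)
    pars <- sim_item_params(Q, 3)
    X <- sim_responses(attrs, pars$item_probs, maps)
    fit <- suppressWarnings(fit_gpdm(X, Q, 3, tol = 1e-5))
    rep_out <- assess_fit(fit, M = 6000, alpha = 0.10)
    rejections <- rejections + rep_out$misfit
  }
  expect_lte(rejections / n_rep, 0.10 + 0.05)
})

test_that("correcting a misspecified q-vector reduces the sr statistic", {
  Q_true <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1), c(1, 1))
  Q_wrong <- Q_true
  Q_wrong[3, ] <- c(1, 0)  # drop a required attribute on item 3
  maps <- build_item_maps(Q_true)
  set.seed(127)
  attrs <- sim_attributes(600, 2, R = 0.5)
  pars <- sim_item_params(Q_true, 3)
  X <- sim_responses(attrs, pars$item_probs, maps)
  fit_true <- fit_gpdm(X, Q_true, 3)
  fit_wrong <- fit_gpdm(X, Q_wrong, 3)
  a_true <- assess_fit(fit_true, M = 30000, seed = 5)
  a_wrong <- assess_fit(fit_wrong, M = 30000, seed = 5)
  expect_lt(a_true$sr_test, a_wrong$sr_test)
})
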