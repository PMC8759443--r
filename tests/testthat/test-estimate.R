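make_fit <- function(gamma, base, Q, X = NULL, taxa = NULL) {
  # minimal logratio_fit skeleton for testing the estimation layer
  p <- nrow(gamma)
  structure(list(gamma = gamma, sigma = diag(Q - 1), base = base, rho = 0.5,
                 X = X %||% matrix(1, 3, p), taxa = taxa %||% paste0("t", 1:Q),
                 samples = NULL, trace = tibble::tibble(),
                 mh = mh_config(), em = em_config(), seed = 1,
                 n = 3, Q = Q, p = p, M = rep(100, 3)),
            class = "logratio_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fitted compositions: zero coefficients give uniform, duplicates share values", {
  Q <- 5
  fit <- make_fit(matrix(0, 2, Q - 1), base = Q, Q = Q,
                  X = rbind(c(1, 0), c(1, 1), c(1, 0)))
  fc <- fitted_compositions(fit)
  expect_equal(unname(fc$z), matrix(0.2, 3, Q), ignore_attr = TRUE)
  expect_equal(fc$profile, c(1, 2, 1)) # rows 1 and 3 share a profile
  expect_equal(fc$z[1, ], fc$z[3, ])
  expect_error(fitted_compositions(fit, newdata = matrix(1, 2, 3)), "columns")
})

test_that("fitted compositions work for unseen covariate profiles", {
  set.seed(3)
  Q <- 6
  gamma <- matrix(rnorm(2 * (Q - 1), 0, 0.5), 2)
  fit <- make_fit(gamma, base = Q, Q = Q, X = cbind(1, c(0, 0, 1)))
  new_X <- rbind(c(1, 0.5)) # halfway between the training groups
  fc <- fitted_compositions(fit, newdata = new_X)
  expect_equal(nrow(fc$z), 1)
  check_z <- alr_inverse(as.vector(new_X %*% gamma), Q)
  expect_equal(unname(fc$z[1, ]), check_z)
})

test_that("alpha estimates match the indices applied row-wise", {
  Q <- 100
  fit <- make_fit(matrix(0, 1, Q - 1), base = Q, Q = Q, X = matrix(1, 3, 1))
  fc <- fitted_compositions(fit)
  a <- alpha_estimates(fc, c("shannon", "simpson"))
  expect_equal(a$estimate[a$index == "shannon"], rep(log(100), 3))
  expect_equal(a$estimate[a$index == "simpson"], rep(0.01, 3))

  set.seed(8)
  gamma <- matrix(rnorm(9), 1)
  fit2 <- make_fit(gamma, base = 10, Q = 10, X = matrix(1, 2, 1))
  fc2 <- fitted_compositions(fit2)
  a2 <- alpha_estimates(fc2, "shannon")
  expect_equal(a2$estimate, unname(apply(fc2$z, 1, shannon)))
  expect_error(alpha_estimates(fc2, "richness"))
})

test_that("beta estimates are symmetric, zero-diagonal, and match pairwise indices", {
  set.seed(9)
  gamma <- matrix(rnorm(2 * 7, 0, 0.8), 2)
  fit <- make_fit(gamma, base = 8, Q = 8, X = cbind(1, c(0, 1, 0, 1)))
  fc <- fitted_compositions(fit)
  for (ix in c("bray_curtis", "euclidean")) {
    B <- beta_estimates(fc, ix)
    expect_equal(B, t(B))
    expect_equal(diag(B), rep(0, 4), ignore_attr = TRUE)
    g <- if (ix == "bray_curtis") bray_curtis else euclidean
    expect_equal(B[1, 2], g(fc$z[1, ], fc$z[2, ]))
    expect_equal(B[1, 3], 0) # same profile -> identical fitted composition
  }
  # identical profiles everywhere -> zero matrix
  fit0 <- make_fit(gamma[1, , drop = FALSE], base = 8, Q = 8,
                   X = matrix(1, 3, 1))
  B0 <- beta_estimates(fitted_compositions(fit0), "bray_curtis")
  expect_equal(unname(B0), matrix(0, 3, 3))
})

test_that("estimates are continuous in gamma", {
  set.seed(10)
  Q <- 6
  gamma <- matrix(rnorm(Q - 1), 1)
  fit <- make_fit(gamma, base = Q, Q = Q, X = matrix(1, 1, 1))
  base_val <- alpha_estimates(fitted_compositions(fit), "shannon")$estimate
  for (eps in c(1e-4, 1e-6)) {
    fit_p <- make_fit(gamma + eps, base = Q, Q = Q, X = matrix(1, 1, 1))
    val <- alpha_estimates(fitted_compositions(fit_p), "shannon")$estimate
    expect_lt(abs(val - base_val), 100 * eps)
  }
})

test_that("sensitivity scans reduce to a plain fit and are rho-stable without zeros", {
  sim <- small_sim(n = 6, Q = 8, seed = 71, depth_range = c(3000, 6000))
  one <- sensitivity_scan(sim$W, sim$design$X, scan = "base_taxon",
                          candidates = 8, indices = "shannon",
                          mh = fast_mh(), em = fast_em(), seed = 4)
  fit <- fit_logratio(sim$W, sim$design$X, base = 8, mh = fast_mh(),
                      em = fast_em(), seed = 4)
  plain <- alpha_estimates(fitted_compositions(fit), "shannon")
  expect_equal(one$estimate, plain$estimate)

  # zero-free counts: rho has (almost) nothing to perturb
  W_pos <- sim$W + 1
  scan <- sensitivity_scan(W_pos, sim$design$X, scan = "rho",
                           candidates = c(0.1, 0.5), indices = "shannon",
                           base = 8, mh = fast_mh(), em = fast_em(), seed = 4)
  by_cand <- split(scan$estimate, scan$candidate)
  expect_equal(by_cand[[1]], by_cand[[2]], tolerance = 0.02)

  expect_error(sensitivity_scan(sim$W, scan = "base_taxon", candidates = 99),
               "outside")
  expect_error(sensitivity_scan(sim$W, scan = "rho", candidates = numeric(0)),
               "nonempty")
})

test_that("netdiv wrapper ties the pipeline together with tidy accessors", {
  sim <- small_sim(n = 6, Q = 8, seed = 81)
  est <- netdiv(sim$W, sim$design$X, variance = "none", mh = fast_mh(),
                em = fast_em(), seed = 5)
  expect_s3_class(est, "netdiv_fit")
  td <- tidy(est)
  expect_true(all(c("sample", "profile", "index", "estimate") %in% names(td)))
  expect_equal(sort(unique(td$index)), c("shannon", "simpson"))
  tdm <- tidy(est, matrices = TRUE)
  expect_true(any(tdm$index == "bray_curtis"))
  gl <- glance(est)
  expect_equal(gl$n, 6)
  expect_equal(gl$Q, 8)
  tc <- tidy(est$fit)
  expect_equal(nrow(tc), 2 * 7) # p terms x (Q - 1) taxa
  p <- autoplot(est)
  expect_s3_class(p, "ggplot")
  p2 <- plot_trace(est)
  expect_s3_class(p2, "ggplot")
})
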