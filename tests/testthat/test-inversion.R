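# analytic log marginal likelihood of the conjugate linear-Gaussian model
# y = X theta + e, theta ~ N(0, V0), e ~ N(0, s2 I)
lml_linear <- function(y, X, V0, s2) {
  n <- length(y)
  S <- s2 * diag(n) + X %*% V0 %*% t(X)
  -0.5 * (n * log(2 * pi) +
            as.numeric(determinant(S)$modulus) +
            drop(t(y) %*% solve(S, y)))
}

test_that("variational Laplace is exact on the conjugate linear model", {
  set.seed(1)
  n <- 40
  x <- rnorm(n)
  s2 <- 0.25
  v0 <- 2
  y <- 0.7 * x + rnorm(n, 0, sqrt(s2))
  fit <- variational_laplace(
    function(th) th[["b"]] * x, y,
    data.frame(name = "b", mean = 0, var = v0),
    hyper = list(lambda0 = log(1 / s2), lambda_var = 0))
  expect_lt(abs(fit$F - lml_linear(y, cbind(x), diag(v0, 1), s2)), 1e-3)
  # conjugate posterior
  vp <- 1 / (1 / v0 + sum(x^2) / s2)
  expect_equal(unname(fit$mu_post), vp * sum(x * y) / s2,
               tolerance = 1e-8)
  expect_equal(unname(diag(fit$Sigma_post)), vp, tolerance = 1e-8)
  expect_true(all(diff(fit$F_trace) >= -1e-9))
})

test_that("an irrelevant free parameter cannot raise the evidence", {
  set.seed(2)
  n <- 40
  x <- rnorm(n)
  x2 <- rnorm(n)
  s2 <- 0.25
  v0 <- 2
  y <- 0.7 * x + rnorm(n, 0, sqrt(s2))
  hy <- list(lambda0 = log(1 / s2), lambda_var = 0)
  f1 <- variational_laplace(function(th) th[["b"]] * x, y,
                            data.frame(name = "b", mean = 0, var = v0),
                            hyper = hy)
  f2 <- variational_laplace(
    function(th) th[["b"]] * x + th[["c"]] * x2, y,
    data.frame(name = c("b", "c"), mean = 0, var = v0), hyper = hy)
  expect_lt(abs(f2$F - lml_linear(y, cbind(x, x2), diag(v0, 2), s2)),
            1e-3)
  expect_gt(f1$F, f2$F)
})

test_that("free energy separates accuracy from complexity", {
  e <- c(0.1, -0.2, 0.3)
  # at the prior mean with an uninformative Jacobian the parameter
  # complexity vanishes
  fe <- free_energy(e, matrix(0, 3, 2), c(0, 0), c(1, 1), lambda = 0,
                    hyper = list(lambda0 = 0, lambda_var = 0))
  expect_equal(fe$complexity, 0)
  expect_equal(fe$F, fe$accuracy)
  # moving away from the prior or sharpening the posterior costs
  fe2 <- free_energy(e, matrix(1, 3, 2), c(0.5, -0.5), c(1, 1),
                     lambda = 0, hyper = list(lambda0 = 0,
                                              lambda_var = 0))
  expect_gt(fe2$complexity, 0)
})

test_that("a fully fixed model needs a single evaluation", {
  y <- c(1, 2, 3)
  calls <- 0
  f <- function(th) {
    calls <<- calls + 1
    rep(2, 3)
  }
  fit <- variational_laplace(f, y,
                             data.frame(name = "b", mean = 0, var = 0),
                             hyper = list(lambda0 = 0, lambda_var = 0))
  expect_equal(fit$iterations, 0)
  expect_equal(calls, 1)
  expect_length(fit$mu_post, 0)
})

test_that("noise precision is recovered when estimated", {
  set.seed(4)
  n <- 400
  s <- 0.2
  y <- rnorm(n, 0, s)
  fit <- variational_laplace(function(th) rep(0, n), y,
                             data.frame(name = "b", mean = 0, var = 0),
                             hyper = list(lambda0 = 0, lambda_var = 16))
  expect_equal(fit$lambda, log(1 / s^2), tolerance = 0.25)
})

test_that("multi-condition fits recover planted modulations", {
  design <- fix_design()
  base <- fix_base()
  fwd <- fix_fwd()
  v <- enumerate_intrinsic_space()[[6]]     # A1+IFG
  truth <- plant_group_effects(base, default_effect_config(), design,
                               seed = 5)
  dat <- simulate_evoked_modes(truth, fwd, seed = 5)
  fit <- fit_multicondition(dat, design, v, fwd, base,
                            preset = "reduced", max_iter = 24)
  expect_true(all(diff(fit$F_trace) >= -1e-9))
  # every free modulation is within 2 prior SD of its planted value
  pv <- fit$priors$var[match(names(fit$mu_post), fit$priors$name)]
  truth_theta <- setNames(rep(0, length(fit$mu_post)),
                          names(fit$mu_post))
  for (e in rownames(truth$B_true)) {
    for (s in colnames(truth$B_true)) {
      nm <- paste0("B.", e, ".", s)
      if (nm %in% names(truth_theta)) {
        truth_theta[nm] <- truth$B_true[e, s]
      }
    }
  }
  expect_true(all(abs(fit$mu_post - truth_theta) < 2 * sqrt(pv)))
})

test_that("effect-free noiseless cells shrink modulations toward zero", {
  design <- fix_design()
  base <- fix_base()
  fwd <- fix_fwd()
  v <- enumerate_intrinsic_space()[[2]]     # A1 only
  # no planted effects: groups are identical, conditions differ only
  # through the stimulus input, so every modulation should shrink to
  # (well below) its prior SD
  truth0 <- plant_group_effects(base, list(), design, seed = 6)
  dat <- simulate_evoked_modes(truth0, fwd,
                               noise_sd = c(standard = 0, deviant = 0),
                               seed = 6)
  fit <- fit_multicondition(dat, design, v, fwd, base,
                            preset = "reduced", max_iter = 16)
  expect_true(all(abs(fit$mu_post) < sqrt(1 / 16)))
})

test_that("relabeling cells together with design rows leaves F unchanged", {
  design <- fix_design()
  base <- fix_base()
  fwd <- fix_fwd()
  v <- enumerate_intrinsic_space()[[4]]     # IFG only (cheap)
  truth <- plant_group_effects(base, default_effect_config(), design,
                               seed = 7)
  dat <- simulate_evoked_modes(truth, fwd, seed = 7)
  fit1 <- fit_multicondition(dat, design, v, fwd, base,
                             preset = "reduced", max_iter = 16)
  perm <- c(3, 4, 5, 6, 1, 2)
  design2 <- design
  design2$X <- design$X[perm, , drop = FALSE]
  design2$cells <- design$cells[perm, ]
  dat2 <- dat
  dat2$Y <- dat$Y[, , perm]
  dimnames(dat2$Y)[[3]] <- dimnames(dat$Y)[[3]][perm]
  dat2$cells <- dat$cells[perm]
  fit2 <- fit_multicondition(dat2, design2, v, fwd, base,
                             preset = "reduced", max_iter = 16)
  expect_equal(fit1$F, fit2$F, tolerance = 1e-6)
})
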