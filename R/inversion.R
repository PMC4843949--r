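#' Prior specification for model inversion
#'
#' Diagonal Gaussian priors over log-scaling parameters. A zero prior
#' variance fixes a parameter at its prior mean (it is excluded from the
#' free subspace). The `full` preset frees the condition/group modulations
#' together with extrinsic couplings, input gain and dipole moments; the
#' `reduced` preset frees only the modulations (all shared dynamics pinned
#' to their prior means), which is the configuration used by the
#' recovery studies.
#'
#' @param variant a model variant from [enumerate_intrinsic_space()] or
#'   [enumerate_effecttype_space()].
#' @param design a [build_factorial_design()]; its effect columns define
#'   the modulation parameters.
#' @param network the source network (for shared parameter names).
#' @param preset `"full"` or `"reduced"`.
#' @param b_var,a_var prior variances for modulations and couplings.
#' @return data.frame with columns `name`, `mean`, `var`.
#' @export
cmc_priors <- function(variant, design, network = mmn_network(),
                       preset = c("full", "reduced"),
                       b_var = 1 / 16, a_var = 1 / 8) {
  preset <- match.arg(preset)
  nm <- network$sources$name
  shared_var <- if (preset == "full") a_var else 0
  pr <- data.frame(name = character(0), mean = numeric(0),
                   var = numeric(0), stringsAsFactors = FALSE)
  add <- function(names, var) {
    rbind(pr, data.frame(name = names, mean = 0, var = var,
                         stringsAsFactors = FALSE))
  }
  pr <- add(paste0("G_sp.", nm), if (preset == "full") 1 / 16 else 0)
  pr <- add(paste0("A_F.", seq_len(nrow(network$forward))), shared_var)
  pr <- add(paste0("A_B.", seq_len(nrow(network$backward))), shared_var)
  pr <- add(paste0("A_L.", seq_len(nrow(network$lateral) / 2)), shared_var)
  pr <- add("C", shared_var)
  pr <- add(paste0("J.", unique(nm[c(1, 3, 5)])), shared_var)
  effs <- colnames(design$X)
  for (s in variant$sources) {
    pr <- add(paste0("B.", effs, ".", s), b_var)
  }
  for (ty in variant$ext_types) {
    key <- c(forward = "BF", backward = "BB")[[ty]]
    pr <- add(paste0(key, ".", effs), b_var)
  }
  pr
}

# expand a named theta vector into a cmc_params object (shared parameters
# only; modulations are applied per cell by the multi-condition forward
# map)
params_from_theta <- function(base, theta) {
  p <- base
  nm <- names(theta)
  ns <- nrow(p$network$sources)
  src <- p$network$sources$name
  for (i in seq_along(theta)) {
    key <- strsplit(nm[i], ".", fixed = TRUE)[[1]]
    v <- theta[[i]]
    switch(key[1],
      G_sp = { p$G_sp[key[2]] <- v },
      A_F = { p$A_F[as.integer(key[2])] <- v },
      A_B = { p$A_B[as.integer(key[2])] <- v },
      A_L = { e <- as.integer(key[2]); p$A_L[c(2 * e - 1, 2 * e)] <- v },
      C = { p$C <- v },
      J = {
        grp <- switch(key[2], lA1 = c("lA1", "rA1"),
                      lSTG = c("lSTG", "rSTG"), key[2])
        p$J[grp] <- v
      },
      mu_u = { p$mu_u <- p$constants$input$mu_ms + v },
      sigma_u = { p$sigma_u <- p$constants$input$sigma_ms * exp(v) },
      B = , BF = , BB = { }  # handled by the multi-condition map
    )
  }
  p
}

#' Free energy of a parameter/hyperparameter point
#'
#' Laplace (fixed-form Gaussian) free energy under IID Gaussian
#' observation noise with log-precision `lambda`:
#' accuracy minus complexity, where accuracy is the expected
#' log-likelihood of the residuals and complexity the KL-type penalty of
#' the posterior against the prior (parameters and hyperparameter).
#'
#' @param e residual vector (data minus prediction).
#' @param J Jacobian of the prediction w.r.t. the free parameters (N x p;
#'   may have zero columns).
#' @param dtheta deviation of the free parameters from their prior mean.
#' @param prior_var free-parameter prior variances (length p).
#' @param lambda noise log-precision.
#' @param hyper list with `lambda0` (prior mean) and `lambda_var` (prior
#'   variance; 0 fixes lambda).
#' @return list with `F`, `accuracy`, `complexity`, `Sigma_post`,
#'   `lambda_curv`.
#' @export
free_energy <- function(e, J, dtheta, prior_var, lambda, hyper) {
  N <- length(e)
  p <- length(dtheta)
  tau <- exp(lambda)
  accuracy <- -0.5 * tau * sum(e^2) + 0.5 * N * (lambda - log(2 * pi))
  if (p > 0) {
    P0 <- diag(1 / prior_var, p)
    H <- tau * crossprod(J) + P0
    R <- chol(H)
    Sigma_post <- chol2inv(R)
    # ln det(P0 Sigma_q) = ln det P0 - ln det H
    logdet_term <- sum(log(1 / prior_var)) - 2 * sum(log(diag(R)))
    ctheta <- 0.5 * sum(dtheta^2 / prior_var) - 0.5 * logdet_term
  } else {
    Sigma_post <- matrix(0, 0, 0)
    ctheta <- 0
    H <- matrix(0, 0, 0)
  }
  chyper <- 0
  lambda_curv <- NA_real_
  if (hyper$lambda_var > 0) {
    # curvature of F in lambda (for the hyperparameter Laplace term)
    peff <- if (p > 0) tau * sum(crossprod(J) * Sigma_post) else 0
    curv <- 0.5 * tau * sum(e^2) + 0.5 * peff + 1 / hyper$lambda_var
    lambda_curv <- curv
    chyper <- 0.5 * (lambda - hyper$lambda0)^2 / hyper$lambda_var -
      0.5 * log(1 / (curv * hyper$lambda_var))
  }
  complexity <- ctheta + chyper
  list(F = accuracy - complexity, accuracy = accuracy,
       complexity = complexity, Sigma_post = Sigma_post,
       lambda_curv = lambda_curv)
}

# central finite-difference Jacobian of f at theta (free columns only)
fd_jacobian <- function(f, theta, free_ix, step = 1e-3) {
  y0 <- f(theta)
  J <- matrix(0, length(y0), length(free_ix))
  for (k in seq_along(free_ix)) {
    tp <- theta
    tm <- theta
    tp[free_ix[k]] <- tp[free_ix[k]] + step
    tm[free_ix[k]] <- tm[free_ix[k]] - step
    J[, k] <- (f(tp) - f(tm)) / (2 * step)
  }
  J
}

#' Variational Laplace inversion
#'
#' Gauss-Newton ascent on the free-energy approximation to log model
#' evidence, with Levenberg-style step-size control (steps that decrease
#' the free energy are rejected and the regularization increased) and
#' interleaved closed-form-style optimization of the IID noise
#' log-precision. Parameters with zero prior variance stay fixed at their
#' prior mean.
#'
#' @param f forward map: `function(theta)` (full named parameter vector)
#'   returning a numeric prediction vector.
#' @param y data vector.
#' @param priors data.frame with `name`, `mean`, `var` (see
#'   [cmc_priors()]).
#' @param hyper list with noise hyperprior `lambda0` and `lambda_var`.
#' @param max_iter iteration cap (default 128).
#' @param tol convergence: |dF| < tol on 4 consecutive accepted iterations
#'   (default 0.01).
#' @param fd_step finite-difference step in (log-)parameter space.
#' @return object of class `inversion_result`: posterior means and
#'   covariance of the free parameters, noise posterior, free energy with
#'   accuracy/complexity split, F trace over accepted iterations,
#'   convergence flag, and identifiability warnings (posterior
#'   correlations above 0.95).
#' @export
variational_laplace <- function(f, y, priors,
                                hyper = list(lambda0 = 0, lambda_var = 16),
                                max_iter = 128, tol = 0.01,
                                fd_step = 1e-3) {
  theta <- stats::setNames(priors$mean, priors$name)
  free_ix <- which(priors$var > 0)
  pv <- priors$var[free_ix]
  p <- length(free_ix)
  N <- length(y)
  lambda <- hyper$lambda0
  ev <- function(th) {
    out <- f(th)
    if (length(out) != N || any(!is.finite(out))) {
      stop("forward map returned a non-finite or mis-sized prediction")
    }
    out
  }
  e <- y - ev(theta)
  optimise_lambda <- function(e, J, dtheta) {
    if (hyper$lambda_var <= 0) return(lambda)
    obj <- function(l) {
      free_energy(e, J, dtheta, pv, l, hyper)$F
    }
    o <- stats::optimize(obj, lower = lambda - 8, upper = lambda + 8,
                         maximum = TRUE, tol = 1e-4)
    o$maximum
  }
  if (p == 0) {
    lambda <- optimise_lambda(e, matrix(0, N, 0), numeric(0))
    fe <- free_energy(e, matrix(0, N, 0), numeric(0), numeric(0),
                      lambda, hyper)
    return(structure(list(theta = theta, mu_post = numeric(0),
                          Sigma_post = matrix(0, 0, 0), lambda = lambda,
                          F = fe$F, accuracy = fe$accuracy,
                          complexity = fe$complexity, F_trace = fe$F,
                          converged = TRUE, iterations = 0,
                          priors = priors, warnings = character(0)),
                     class = "inversion_result"))
  }
  J <- fd_jacobian(ev, theta, free_ix, fd_step)
  lambda <- optimise_lambda(e, J, theta[free_ix] - priors$mean[free_ix])
  fe <- free_energy(e, J, theta[free_ix] - priors$mean[free_ix], pv,
                    lambda, hyper)
  Fcur <- fe$F
  trace_F <- Fcur
  nu <- 1e-4        # Levenberg factor
  n_small <- 0
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    tau <- exp(lambda)
    dtheta <- theta[free_ix] - priors$mean[free_ix]
    g <- tau * crossprod(J, e) - dtheta / pv
    H <- tau * crossprod(J) + diag(1 / pv, p)
    accepted <- FALSE
    for (try in 1:8) {
      Hreg <- H + nu * diag(diag(H), p)
      step <- drop(solve(Hreg, g))
      cand <- theta
      cand[free_ix] <- cand[free_ix] + step
      e_c <- tryCatch(y - ev(cand), error = function(err) NULL)
      if (!is.null(e_c)) {
        J_c <- fd_jacobian(ev, cand, free_ix, fd_step)
        l_c <- optimise_lambda(e_c, J_c,
                               cand[free_ix] - priors$mean[free_ix])
        fe_c <- free_energy(e_c, J_c,
                            cand[free_ix] - priors$mean[free_ix], pv,
                            l_c, hyper)
        if (is.finite(fe_c$F) && fe_c$F > Fcur - 1e-12) {
          dF <- fe_c$F - Fcur
          theta <- cand
          e <- e_c
          J <- J_c
          lambda <- l_c
          fe <- fe_c
          Fcur <- fe_c$F
          trace_F <- c(trace_F, Fcur)
          nu <- max(nu / 2, 1e-8)
          accepted <- TRUE
          n_small <- if (dF < tol) n_small + 1 else 0
          break
        }
      }
      nu <- nu * 8
    }
    if (!accepted) break         # no acceptable step found
    if (n_small >= 4) {
      converged <- TRUE
      break
    }
  }
  Sp <- fe$Sigma_post
  dimnames(Sp) <- list(priors$name[free_ix], priors$name[free_ix])
  warn <- character(0)
  if (p > 1) {
    sd_ <- sqrt(diag(Sp))
    Cr <- Sp / outer(sd_, sd_)
    hi <- which(abs(Cr) > 0.95 & upper.tri(Cr), arr.ind = TRUE)
    if (nrow(hi)) {
      warn <- apply(hi, 1, function(ix) {
        paste0("|posterior corr| > 0.95: ", rownames(Cr)[ix[1]], " ~ ",
               colnames(Cr)[ix[2]])
      })
    }
  }
  structure(list(theta = theta,
                 mu_post = stats::setNames(theta[free_ix],
                                           priors$name[free_ix]),
                 Sigma_post = Sp, lambda = lambda, F = Fcur,
                 accuracy = fe$accuracy, complexity = fe$complexity,
                 F_trace = trace_F, converged = converged,
                 iterations = it, priors = priors, warnings = warn),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("Variational Laplace inversion:", length(x$mu_post),
      "free parameters\n")
  cat(sprintf(" F = %.2f (accuracy %.2f, complexity %.2f), %s after %d iterations\n",
              x$F, x$accuracy, x$complexity,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf(" noise log-precision: %.2f\n", x$lambda))
  if (length(x$warnings)) cat(" ", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Project evoked responses onto the modeled window and spatial modes
#'
#' @param evoked_list named list of `evoked_response` (the six grand
#'   averages, `group.condition` names).
#' @param fwd a [forward_setup()].
#' @param window_ms modeled window, default c(0, 250).
#' @return list with `Y` (modes x time x cells array), `time_ms`, `cells`.
#' @export
project_evoked <- function(evoked_list, fwd, window_ms = c(0, 250)) {
  cells <- names(evoked_list)
  tix <- which(evoked_list[[1]]$time_ms >= window_ms[1] &
                 evoked_list[[1]]$time_ms <= window_ms[2])
  M <- fwd$projection$modes
  Y <- vapply(evoked_list, function(ev) {
    t(M) %*% ev$data[, tix, drop = FALSE]
  }, matrix(0, ncol(M), length(tix)))
  list(Y = Y, time_ms = evoked_list[[1]]$time_ms[tix], cells = cells)
}

# build the multi-condition forward map closure: theta -> stacked
# mode-space predictions for all design cells
multicondition_forward <- function(base, design, variant, fwd,
                                   time_ms, dt = 0.5) {
  effs <- colnames(design$X)
  cells <- rownames(design$X)
  duration <- max(time_ms)
  keep <- round(time_ms / dt) + 1L
  b_names <- if (length(variant$sources)) {
    as.vector(outer(effs, variant$sources,
                    function(a, b) paste0("B.", a, ".", b)))
  } else {
    character(0)
  }
  function(theta) {
    shared <- params_from_theta(base, theta)
    B <- NULL
    if (length(variant$sources)) {
      B <- matrix(theta[b_names], length(effs), length(variant$sources),
                  dimnames = list(effs, variant$sources))
    }
    BF <- if ("forward" %in% variant$ext_types) {
      theta[paste0("BF.", effs)]
    } else {
      NULL
    }
    BB <- if ("backward" %in% variant$ext_types) {
      theta[paste0("BB.", effs)]
    } else {
      NULL
    }
    out <- lapply(cells, function(cl) {
      pc <- apply_condition_modulation(shared, design$X[cl, ], B,
                                       allowed_sources = variant$sources,
                                       B_F = BF, B_B = BB)
      cnd <- design$cells$condition[match(cl, cells)]
      erp <- integrate_erp(pc, cnd, duration_ms = duration, dt = dt)
      y <- observe(list(vsp = erp$vsp[, keep, drop = FALSE],
                        vdp = erp$vdp[, keep, drop = FALSE]),
                   pc, fwd$dipoles, fwd$gain, fwd$projection)
      as.numeric(y)
    })
    unlist(out)
  }
}

#' Fit one model variant jointly to the six factorial cells
#'
#' A single shared parameter set plus effect-specific modulation
#' parameters is fitted to all cells of the factorial design; per-cell
#' predictions are generated through [apply_condition_modulation()] with
#' the cell's design row.
#'
#' @param data result of [project_evoked()] (or an equally shaped list
#'   with `Y` modes x time x cells and `time_ms`).
#' @param design a [build_factorial_design()].
#' @param variant model variant (see [enumerate_intrinsic_space()]).
#' @param fwd a [forward_setup()].
#' @param base baseline [cmc_parameters()].
#' @param priors optional priors (default [cmc_priors()] with the given
#'   preset).
#' @param preset prior preset when `priors` is missing.
#' @param ... passed to [variational_laplace()].
#' @return an `inversion_result` with the variant attached.
#' @export
fit_multicondition <- function(data, design, variant, fwd,
                               base = cmc_parameters(), priors = NULL,
                               preset = "reduced", ...) {
  if (dim(data$Y)[3] != nrow(design$X)) {
    stop("number of data cells (", dim(data$Y)[3],
         ") does not match the design (", nrow(design$X), ")")
  }
  if (is.null(priors)) {
    priors <- cmc_priors(variant, design, base$network, preset)
  }
  f <- multicondition_forward(base, design, variant, fwd, data$time_ms)
  res <- variational_laplace(f, as.numeric(data$Y), priors, ...)
  res$variant <- variant
  res$design <- design
  res
}
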