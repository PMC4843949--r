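#' @useDynLib mmndcm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# population order used throughout: ss, sp, ii, dp
.pops <- c("ss", "sp", "ii", "dp")

# centered sigmoid firing-rate function and its derivative
cmc_sigmoid <- function(v, R) 1 / (1 + exp(-R * v)) - 0.5
cmc_sigmoid_deriv <- function(v, R) {
  e <- exp(-R * v)
  R * e / (1 + e)^2
}

# assemble the numeric ingredients of the dynamics from a cmc_params object:
# per-source intrinsic strength matrix (with gain-scaled sp self-inhibition)
# and ns x ns extrinsic weight matrices per target population
cmc_assemble <- function(params) {
  cn <- params$constants
  net <- params$network
  ns <- nrow(net$sources)
  G <- matrix(rep(cn$G_base, each = ns), ns, 10)
  G[, 7] <- G[, 7] * exp(params$G_sp)
  WFss <- WFdp <- WBsp <- WBii <- matrix(0, ns, ns)
  fe <- net$forward
  if (nrow(fe)) {
    for (e in seq_len(nrow(fe))) {
      g <- exp(params$A_F[e])
      WFss[fe[e, 2], fe[e, 1]] <- WFss[fe[e, 2], fe[e, 1]] + cn$E["F_ss"] * g
      WFdp[fe[e, 2], fe[e, 1]] <- WFdp[fe[e, 2], fe[e, 1]] + cn$E["F_dp"] * g
    }
  }
  be <- net$backward
  if (nrow(be)) {
    for (e in seq_len(nrow(be))) {
      g <- exp(params$A_B[e])
      WBsp[be[e, 2], be[e, 1]] <- WBsp[be[e, 2], be[e, 1]] + cn$E["B_sp"] * g
      WBii[be[e, 2], be[e, 1]] <- WBii[be[e, 2], be[e, 1]] + cn$E["B_ii"] * g
    }
  }
  le <- net$lateral
  if (nrow(le)) {
    for (e in seq_len(nrow(le))) {
      g <- exp(params$A_L[e])
      WFss[le[e, 2], le[e, 1]] <- WFss[le[e, 2], le[e, 1]] + cn$E["L_ss"] * g
      WFdp[le[e, 2], le[e, 1]] <- WFdp[le[e, 2], le[e, 1]] + cn$E["L_dp"] * g
    }
  }
  Uamp <- numeric(ns)
  Uamp[net$input_targets] <- cn$input$amp * exp(params$C)
  list(G = G, Tms = cn$T_ms * exp(-params$kappa), Hpop = exp(params$H),
       R = cn$R, WFss = WFss, WFdp = WFdp, WBsp = WBsp, WBii = WBii,
       Uamp = Uamp)
}

#' Exogenous input waveform
#'
#' Gaussian bump drive modelling the thalamic volley of a tone. Standards
#' get a single bump at the onset latency; deviants get an additional bump
#' delayed by the tone-duration difference (duration deviance is detectable
#' only at the standard tone's offset).
#'
#' @param t time points (ms).
#' @param params [cmc_parameters()] object.
#' @param condition `"standard"` or `"deviant"`.
#' @return numeric vector of drive values (unit peak per bump).
#' @export
cmc_input <- function(t, params, condition = c("standard", "deviant")) {
  condition <- match.arg(condition)
  mu <- params$mu_u
  sg <- params$sigma_u
  u <- exp(-(t - mu)^2 / (2 * sg^2))
  if (condition == "deviant") {
    off <- params$constants$input$deviant_offset_ms
    u <- u + exp(-(t - mu - off)^2 / (2 * sg^2))
  }
  u
}

#' Instantaneous state derivatives of the CMC network
#'
#' Delay-free evaluation of the state equations (used for linearization and
#' stability analysis; the integrator itself applies conduction delays).
#' The state is ordered source-major, population (ss, sp, ii, dp) next,
#' with voltage before current: `(v[s1,ss], i[s1,ss], v[s1,sp], ...)`.
#'
#' @param state numeric state vector of length `8 * n_sources`.
#' @param params [cmc_parameters()] object.
#' @param u scalar exogenous drive value.
#' @return derivative vector of the same length.
#' @export
state_derivatives <- function(state, params, u = 0) {
  if (any(!is.finite(state))) stop("non-finite values in state")
  a <- cmc_assemble(params)
  ns <- nrow(a$G)
  stopifnot(length(state) == 8 * ns)
  sm <- matrix(state, nrow = 8)          # per source: v1,i1,v2,i2,...
  v <- sm[c(1, 3, 5, 7), , drop = FALSE] # 4 x ns voltages
  i <- sm[c(2, 4, 6, 8), , drop = FALSE]
  S <- cmc_sigmoid(v, a$R)
  aff <- matrix(0, 4, ns)
  aff[1, ] <- a$Hpop[1] * (-a$G[, 1] * S[1, ] - a$G[, 2] * S[2, ] -
                             a$G[, 3] * S[3, ] +
                             drop(a$WFss %*% S[2, ]) + a$Uamp * u)
  aff[2, ] <- a$Hpop[2] * (a$G[, 8] * S[1, ] - a$G[, 7] * S[2, ] -
                             drop(a$WBsp %*% S[4, ]))
  aff[3, ] <- a$Hpop[3] * (a$G[, 5] * S[1, ] + a$G[, 6] * S[4, ] -
                             a$G[, 4] * S[3, ] + drop(a$WBii %*% S[4, ]))
  aff[4, ] <- a$Hpop[4] * (drop(a$WFdp %*% S[2, ]) - a$G[, 9] * S[3, ] -
                             a$G[, 10] * S[4, ])
  Tm <- matrix(a$Tms, 4, ns)
  dv <- i
  di <- (aff - 2 * i - v / Tm) / Tm
  out <- matrix(0, 8, ns)
  out[c(1, 3, 5, 7), ] <- dv
  out[c(2, 4, 6, 8), ] <- di
  as.numeric(out)
}

#' Analytic Jacobian of the delay-free CMC dynamics
#'
#' @inheritParams state_derivatives
#' @return `8 ns` x `8 ns` Jacobian matrix of [state_derivatives()] at
#'   `state`.
#' @export
cmc_jacobian <- function(state, params, u = 0) {
  a <- cmc_assemble(params)
  ns <- nrow(a$G)
  stopifnot(length(state) == 8 * ns)
  sm <- matrix(state, nrow = 8)
  v <- sm[c(1, 3, 5, 7), , drop = FALSE]
  Sd <- cmc_sigmoid_deriv(v, a$R)        # 4 x ns
  n <- 8 * ns
  J <- matrix(0, n, n)
  vix <- function(s, p) (s - 1) * 8 + (p - 1) * 2 + 1
  iix <- function(s, p) (s - 1) * 8 + (p - 1) * 2 + 2
  # d(aff[p,s]) / d v[q,j]  (gain-weighted chain rule through sigmoid)
  for (s in seq_len(ns)) {
    for (p in 1:4) {
      Tp <- a$Tms[p]
      J[vix(s, p), iix(s, p)] <- 1
      J[iix(s, p), iix(s, p)] <- -2 / Tp
      J[iix(s, p), vix(s, p)] <- J[iix(s, p), vix(s, p)] - 1 / Tp^2
      # intrinsic terms
      w <- matrix(0, 4, ns)  # weight of S[q, j] in aff[p, s]
      if (p == 1) {
        w[1, s] <- w[1, s] - a$G[s, 1]
        w[2, s] <- w[2, s] - a$G[s, 2]
        w[3, s] <- w[3, s] - a$G[s, 3]
        w[2, ] <- w[2, ] + a$WFss[s, ]
      } else if (p == 2) {
        w[1, s] <- w[1, s] + a$G[s, 8]
        w[2, s] <- w[2, s] - a$G[s, 7]
        w[4, ] <- w[4, ] - a$WBsp[s, ]
      } else if (p == 3) {
        w[1, s] <- w[1, s] + a$G[s, 5]
        w[4, s] <- w[4, s] + a$G[s, 6]
        w[3, s] <- w[3, s] - a$G[s, 4]
        w[4, ] <- w[4, ] + a$WBii[s, ]
      } else {
        w[2, ] <- w[2, ] + a$WFdp[s, ]
        w[3, s] <- w[3, s] - a$G[s, 9]
        w[4, s] <- w[4, s] - a$G[s, 10]
      }
      w <- w * a$Hpop[p]
      for (j in seq_len(ns)) {
        for (q in 1:4) {
          if (w[q, j] != 0) {
            J[iix(s, p), vix(j, q)] <- J[iix(s, p), vix(j, q)] +
              w[q, j] * Sd[q, j] / Tp
          }
        }
      }
    }
  }
  J
}

#' Apply condition-specific modulation of superficial-pyramidal gain
#'
#' Adds the weighted sum of effect-specific log-scale modulations to the
#' sp self-inhibition of the modulated sources (and, optionally, to
#' extrinsic forward/backward couplings), leaving every other parameter
#' untouched. With all modulations zero the input parameters are returned
#' exactly.
#'
#' @param params [cmc_parameters()] object.
#' @param design_row numeric vector of effect weights (one per effect).
#' @param B matrix of intrinsic modulations, `n_effects` x `n_modulated`,
#'   with column names naming modulated sources; may be `NULL`.
#' @param allowed_sources character vector of sources the model variant
#'   allows to be modulated; a `B` column outside this set is an error.
#' @param B_F,B_B optional numeric vectors (length `n_effects`) of log-scale
#'   modulations applied uniformly to all forward / backward couplings.
#' @return modified `cmc_params` object.
#' @export
apply_condition_modulation <- function(params, design_row, B = NULL,
                                       allowed_sources = NULL,
                                       B_F = NULL, B_B = NULL) {
  if (!is.null(B)) {
    if (is.null(colnames(B))) stop("B must have source names as colnames")
    if (nrow(B) != length(design_row)) {
      stop("nrow(B) must equal length(design_row)")
    }
    if (!is.null(allowed_sources) &&
        !all(colnames(B) %in% allowed_sources)) {
      bad <- setdiff(colnames(B), allowed_sources)
      stop("modulation requested on source(s) outside the model's allowed ",
           "set: ", paste(bad, collapse = ", "))
    }
    idx <- source_index(params$network, colnames(B))
    params$G_sp[idx] <- params$G_sp[idx] + drop(design_row %*% B)
  }
  if (!is.null(B_F)) params$A_F <- params$A_F + sum(design_row * B_F)
  if (!is.null(B_B)) params$A_B <- params$A_B + sum(design_row * B_B)
  params
}

#' Integrate the evoked response of the CMC network
#'
#' Deterministic fixed-step RK4 trajectory from rest under the Gaussian
#' bump input, with 1 ms intrinsic and 16 ms extrinsic conduction delays
#' handled by history-buffer interpolation.
#'
#' @param params [cmc_parameters()] object.
#' @param condition `"standard"` or `"deviant"` (selects the input).
#' @param duration_ms integration window (ms), default 300.
#' @param dt step size (ms), default 0.5; must be <= 1.
#' @return list with `time` (ms), `vsp` and `vdp` (`n_sources` x
#'   `n_time` voltage matrices, mV); `vsp` is the observation-relevant
#'   output.
#' @export
integrate_erp <- function(params, condition = "standard",
                          duration_ms = 300, dt = 0.5) {
  if (dt > 1) stop("dt must be <= 1 ms")
  a <- cmc_assemble(params)
  nsteps <- round(duration_ms / dt)
  th <- seq(0, duration_ms, by = dt / 2)
  ut <- cmc_input(th, params, condition)
  cn <- params$constants
  out <- cmc_integrate_cpp(a$G, a$Tms, a$Hpop, a$R, a$WFss, a$WFdp,
                           a$WBsp, a$WBii, a$Uamp, ut,
                           cn$delay_intrinsic_ms / dt,
                           cn$delay_extrinsic_ms / dt, dt, nsteps)
  rownames(out$vsp) <- rownames(out$vdp) <- params$network$sources$name
  list(time = seq(0, duration_ms, by = dt), vsp = out$vsp, vdp = out$vdp)
}
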