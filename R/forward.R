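#' Three-shell spherical head model
#'
#' Concentric-sphere volume conductor: brain, skull and scalp shells with
#' standard conductivities. Dipoles must lie within `dipole_max_mm` of the
#' centre. A user-supplied lead-field matrix can be passed to downstream
#' functions instead, see [lead_field()].
#'
#' @param radii_mm outer radii of brain, skull and scalp shells (mm).
#' @param sigma conductivities of the three shells (S/m).
#' @param dipole_max_mm maximum admissible dipole eccentricity (mm).
#' @return list of class `head_model`.
#' @export
head_model <- function(radii_mm = c(brain = 85, skull = 88, scalp = 92),
                       sigma = c(brain = 0.33, skull = 0.0042,
                                 scalp = 0.33),
                       dipole_max_mm = 80) {
  stopifnot(length(radii_mm) == length(sigma), all(diff(radii_mm) > 0),
            dipole_max_mm < radii_mm[1])
  structure(list(radii_mm = radii_mm, sigma = sigma,
                 dipole_max_mm = dipole_max_mm), class = "head_model")
}

#' Equivalent-current-dipole specification for a source network
#'
#' One dipole per source at the (MNI) prior location, mapped into the head
#' sphere. Homologous left/right pairs are constrained to bilateral
#' symmetry: their positions are mirror-averaged across the midsagittal
#' plane and their moment scalings are tied during inversion.
#'
#' @param network an [mmn_network()].
#' @param orientations `n_sources` x 3 matrix of dipole orientations
#'   (rows are normalised); default radial.
#' @param pairs list of length-2 integer vectors of mirrored source pairs.
#' @return list of class `dipole_spec` with `positions` (mm), `orientations`
#'   (unit rows), `pairs`, and `moment_groups` (integer vector tying moment
#'   scalings of paired sources).
#' @export
dipole_spec <- function(network = mmn_network(), orientations = NULL,
                        pairs = list(c(1, 2), c(3, 4))) {
  pos <- as.matrix(network$sources[, c("x", "y", "z")])
  rownames(pos) <- network$sources$name
  for (pr in pairs) {
    a <- pos[pr[1], ]
    b <- pos[pr[2], ]
    m <- (c(-a[1], a[2], a[3]) + b) / 2   # mirror left into right, average
    pos[pr[1], ] <- c(-m[1], m[2], m[3])
    pos[pr[2], ] <- m
  }
  if (is.null(orientations)) {
    orientations <- pos / sqrt(rowSums(pos^2))
  } else {
    orientations <- orientations / sqrt(rowSums(orientations^2))
  }
  groups <- seq_len(nrow(pos))
  for (pr in pairs) groups[pr[2]] <- groups[pr[1]]
  structure(list(positions = pos, orientations = orientations,
                 pairs = pairs, moment_groups = match(groups,
                                                      unique(groups))),
            class = "dipole_spec")
}

# Legendre polynomials P_n(x) and associated P_n^1(x) (positive convention,
# P_1^1 = sqrt(1-x^2)) for n = 1..N, vectorized over x; returns list of two
# N x length(x) matrices
legendre_table <- function(x, N) {
  s <- sqrt(pmax(0, 1 - x^2))
  P <- matrix(0, N, length(x))
  P1 <- matrix(0, N, length(x))
  P[1, ] <- x
  P1[1, ] <- s
  if (N >= 2) {
    P[2, ] <- (3 * x^2 - 1) / 2
    P1[2, ] <- 3 * x * s
    pm2 <- rep(1, length(x)) # P_0
    for (n in 2:(N - 1)) {
      P[n + 1, ] <- ((2 * n + 1) * x * P[n, ] - n * P[n - 1, ]) / (n + 1)
      P1[n + 1, ] <- ((2 * n + 1) * x * P1[n, ] -
                        (n + 1) * P1[n - 1, ]) / n
    }
  }
  list(P = P, P1 = P1)
}

# per-harmonic surface solution of the concentric-shell conductor:
# returns, for n = 1..N, the scalp-surface factor V_n such that the scalp
# potential is sum_n c_n * V_n * [angular part], where c_n carries the
# source strength; solves the 2L-1 unknown radial coefficients per n
multishell_surface_factors <- function(head, N) {
  Rs <- max(head$radii_mm)
  rho <- head$radii_mm / Rs
  sig <- head$sigma
  L <- length(sig)
  vn <- numeric(N)
  for (n in seq_len(N)) {
    nu <- 2 * L - 1
    A <- matrix(0, nu, nu)
    b <- numeric(nu)
    # unknown order: A1, A2, B2, ..., AL, BL
    aix <- function(j) if (j == 1) 1 else 2 * j - 2
    bix <- function(j) 2 * j - 1
    row <- 0
    for (j in seq_len(L - 1)) {
      rj <- rho[j]
      # potential continuity at rho_j
      row <- row + 1
      A[row, aix(j)] <- rj^n
      if (j > 1) A[row, bix(j)] <- rj^(-(n + 1))
      A[row, aix(j + 1)] <- -rj^n
      A[row, bix(j + 1)] <- -rj^(-(n + 1))
      if (j == 1) b[row] <- -rj^(-(n + 1))   # source term (c_n = 1)
      # radial current continuity at rho_j
      row <- row + 1
      A[row, aix(j)] <- sig[j] * n * rj^(n - 1)
      if (j > 1) A[row, bix(j)] <- -sig[j] * (n + 1) * rj^(-(n + 2))
      A[row, aix(j + 1)] <- -sig[j + 1] * n * rj^(n - 1)
      A[row, bix(j + 1)] <- sig[j + 1] * (n + 1) * rj^(-(n + 2))
      if (j == 1) b[row] <- sig[1] * (n + 1) * rj^(-(n + 2))
    }
    # insulating outer boundary at rho = 1
    row <- row + 1
    A[row, aix(L)] <- n
    if (L > 1) {
      A[row, bix(L)] <- -(n + 1)
    } else {
      b[row] <- (n + 1)  # single-shell: A1*n - c_n*(n+1) = 0
    }
    x <- solve(A, b)
    vn[n] <- if (L > 1) x[aix(L)] + x[bix(L)] else x[1] + 1
  }
  vn
}

#' Lead field of the spherical head model
#'
#' Analytic series solution for the scalp potential of equivalent current
#' dipoles in a concentric-shell spherical conductor, average-referenced
#' across channels. Columns are the x/y/z unit-moment components of each
#' dipole in order.
#'
#' @param montage data.frame with `label`, `x`, `y`, `z` electrode positions
#'   on the scalp sphere (mm), e.g. [montage_1020()].
#' @param dipoles a [dipole_spec()].
#' @param head a [head_model()].
#' @param n_terms number of spherical-harmonic terms (default 60).
#' @return `n_channels` x `3 * n_sources` gain matrix in microvolts per
#'   nA m of dipole moment.
#' @export
lead_field <- function(montage, dipoles, head = head_model(),
                       n_terms = 60) {
  Rs_mm <- max(head$radii_mm)
  E <- as.matrix(montage[, c("x", "y", "z")])
  E <- E / sqrt(rowSums(E^2))            # unit vectors; potentials on scalp
  nch <- nrow(E)
  pos <- dipoles$positions
  ns <- nrow(pos)
  ecc <- sqrt(rowSums(pos^2))
  if (any(ecc > head$dipole_max_mm)) {
    stop("dipole(s) outside the inner shell: ",
         paste(rownames(pos)[ecc > head$dipole_max_mm], collapse = ", "))
  }
  vn <- multishell_surface_factors(head, n_terms)
  nseq <- seq_len(n_terms)
  # volts per (A m) prefactor, converted to microvolts per nA m
  pref <- 1 / (4 * pi * head$sigma[1] * (Rs_mm / 1000)^2) * 1e-9 * 1e6
  G <- matrix(0, nch, 3 * ns)
  for (s in seq_len(ns)) {
    b <- ecc[s] / Rs_mm
    if (ecc[s] < 1e-9) {
      zhat <- c(0, 0, 1)
    } else {
      zhat <- pos[s, ] / ecc[s]
    }
    # orthonormal frame with zhat radial
    ref <- if (abs(zhat[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    xhat <- ref - sum(ref * zhat) * zhat
    xhat <- xhat / sqrt(sum(xhat^2))
    yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
              zhat[3] * xhat[1] - zhat[1] * xhat[3],
              zhat[1] * xhat[2] - zhat[2] * xhat[1])
    ez <- drop(E %*% zhat)               # cos(gamma)
    ex <- drop(E %*% xhat)
    ey <- drop(E %*% yhat)
    st <- sqrt(pmax(1e-12, ex^2 + ey^2))
    cphi <- ex / st
    sphi <- ey / st
    leg <- legendre_table(ez, n_terms)
    bn <- b^(nseq - 1)
    rad <- drop(t(leg$P) %*% (vn * nseq * bn))      # radial angular sum
    tan1 <- drop(t(leg$P1) %*% (vn * bn))           # tangential angular sum
    # unit moments along head axes: decompose into local frame
    for (ax in 1:3) {
      u <- c(0, 0, 0)
      u[ax] <- 1
      qr <- sum(u * zhat)
      qx <- sum(u * xhat)
      qy <- sum(u * yhat)
      V <- pref * (qr * rad + tan1 * (qx * cphi + qy * sphi))
      G[, (s - 1) * 3 + ax] <- V - mean(V)          # average reference
    }
  }
  rownames(G) <- montage$label
  G
}

#' Leading spatial modes of the prior predictive sensor covariance
#'
#' Computes the eigenvectors of `G %*% Sigma_prior %*% t(G)` where
#' `Sigma_prior` is the (isotropic, unit-variance) prior covariance of the
#' dipole moment components, and returns the `n_modes` leading ones.
#'
#' @param gain channels x moment-components lead-field matrix.
#' @param n_modes number of modes to retain (default 8).
#' @return list of class `spatial_projection` with `modes` (orthonormal
#'   channels x n_modes matrix) and `var_explained` (fractions).
#' @export
compute_spatial_modes <- function(gain, n_modes = 8) {
  C <- gain %*% t(gain)
  e <- eigen(C, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  if (n_modes > rank) {
    stop("n_modes (", n_modes, ") exceeds the rank (", rank,
         ") of the prior predictive covariance")
  }
  structure(list(modes = e$vectors[, seq_len(n_modes), drop = FALSE],
                 var_explained = e$values[seq_len(n_modes)] /
                   sum(pmax(e$values, 0))),
            class = "spatial_projection")
}

#' Map source dynamics to (projected) sensor predictions
#'
#' The sensor prediction is the linear map `M' G diag(m) X(t)` where `X`
#' is the population-weighted source depolarization (superficial-pyramidal
#' dominant), `m` the per-source dipole moments and `M` the spatial modes
#' (identity if `projection` is `NULL`).
#'
#' @param erp result of [integrate_erp()] (or any list with `vsp`, `vdp`
#'   matrices, sources x time, in mV).
#' @param params [cmc_parameters()] (provides moment log-scalings `J` and
#'   observation weights).
#' @param dipoles a [dipole_spec()].
#' @param gain lead-field matrix from [lead_field()] (or user-supplied).
#' @param projection optional [compute_spatial_modes()] result.
#' @return matrix (channels or modes) x time, in microvolts.
#' @export
observe <- function(erp, params, dipoles, gain, projection = NULL) {
  ns <- nrow(dipoles$positions)
  stopifnot(nrow(erp$vsp) == ns, ncol(gain) == 3 * ns)
  w <- params$constants$obs_weights
  X <- w["sp"] * erp$vsp + w["dp"] * erp$vdp
  if (w["ss"] != 0 || w["ii"] != 0) {
    stop("only sp/dp observation weights are supported")
  }
  mom <- params$constants$moment_base * exp(params$J)
  # tie moments across mirrored pairs via their group mean (log scale)
  gl <- split(seq_len(ns), dipoles$moment_groups)
  for (g in gl) mom[g] <- exp(mean(log(mom[g])))
  Ls <- vapply(seq_len(ns), function(s) {
    drop(gain[, (s - 1) * 3 + (1:3)] %*% dipoles$orientations[s, ]) * mom[s]
  }, numeric(nrow(gain)))
  y <- Ls %*% X
  if (!is.null(projection)) y <- t(projection$modes) %*% y
  y
}
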