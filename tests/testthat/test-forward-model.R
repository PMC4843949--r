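test_that("single-shell lead field matches the direct dipole-plus-boundary oracle", {
  mon <- montage_1020()
  dip <- dipole_spec()
  hm1 <- head_model(radii_mm = c(scalp = 92), sigma = c(scalp = 0.33),
                    dipole_max_mm = 80)
  G1 <- lead_field(mon, dip, hm1, n_terms = 50)
  # oracle: infinite-medium potential evaluated directly, plus the
  # insulating-boundary correction series with coefficients (n+1)/n
  s <- 5                       # rIFG dipole, y-oriented unit moment
  p <- dip$positions[s, ]
  q <- c(0, 1, 0) * 1e-9
  Rs <- 0.092
  E <- as.matrix(mon[, c("x", "y", "z")])
  E <- E / sqrt(rowSums(E^2)) * Rs
  pm <- p / 1000
  Vinf <- vapply(seq_len(nrow(E)), function(i) {
    r <- E[i, ] - pm
    sum(q * r) / (4 * pi * 0.33 * sum(r^2)^1.5)
  }, numeric(1))
  b <- sqrt(sum(pm^2))
  zhat <- pm / b
  ref <- c(0, 0, 1)
  xhat <- ref - sum(ref * zhat) * zhat
  xhat <- xhat / sqrt(sum(xhat^2))
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  Eu <- E / Rs
  ez <- drop(Eu %*% zhat)
  ex <- drop(Eu %*% xhat)
  ey <- drop(Eu %*% yhat)
  st <- sqrt(pmax(1e-12, ex^2 + ey^2))
  leg <- mmndcm:::legendre_table(ez, 50)
  qr_ <- sum(q * zhat)
  qt_ <- c(sum(q * xhat), sum(q * yhat))
  bh <- b / Rs
  pref <- 1 / (4 * pi * 0.33 * Rs^2)
  corr <- vapply(seq_len(nrow(E)), function(i) {
    acc <- 0
    for (n in 1:50) {
      A1 <- (n + 1) / n * bh^(n - 1)
      acc <- acc + pref * A1 *
        (qr_ * n * leg$P[n, i] +
           (qt_[1] * ex[i] / st[i] + qt_[2] * ey[i] / st[i]) *
             leg$P1[n, i])
    }
    acc
  }, numeric(1))
  Vor <- (Vinf + corr) * 1e6
  Vor <- Vor - mean(Vor)
  expect_lt(max(abs(Vor - G1[, (s - 1) * 3 + 2])) / max(abs(Vor)), 1e-6)
})

test_that("lead field is linear and average-referenced", {
  fwd <- fix_fwd()
  G <- fwd$gain
  expect_lt(max(abs(colMeans(G))), 1e-12)
  # doubling the moment doubles every channel potential (linearity of
  # the observation map)
  tr0 <- fix_truth0()
  erp <- integrate_erp(tr0$base, "standard", duration_ms = 100)
  y1 <- observe(erp, tr0$base, fwd$dipoles, G)
  p2 <- tr0$base
  p2$J[] <- log(2)
  y2 <- observe(erp, p2, fwd$dipoles, G)
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
  # dipole outside the inner shell is refused
  bad <- fwd$dipoles
  bad$positions[1, ] <- c(0, 0, 85)
  expect_error(lead_field(fwd$montage, bad), "outside the inner shell")
})

test_that("spatial modes are orthonormal, ordered and capture the data", {
  fwd <- fix_fwd()
  proj <- fwd$projection
  expect_equal(crossprod(proj$modes), diag(8), tolerance = 1e-12)
  expect_true(all(diff(proj$var_explained) <= 1e-12))
  expect_error(compute_spatial_modes(fwd$gain, 16), "rank")
  # with as many modes as the gain rank, reconstruction is lossless
  r <- qr(fwd$gain)$rank
  pf <- compute_spatial_modes(fwd$gain, r)
  tr0 <- fix_truth0()
  y <- cell_sensor_erp(tr0, "controls.deviant")
  yr <- pf$modes %*% (t(pf$modes) %*% y)
  expect_equal(yr, y, tolerance = 1e-9, ignore_attr = TRUE)
  # eight modes keep >= 95% of simulated sensor variance
  y8 <- proj$modes %*% (t(proj$modes) %*% y)
  expect_gte(sum(y8^2) / sum(y^2), 0.95)
})

test_that("observation is linear and spatially faithful", {
  fwd <- fix_fwd()
  p <- fix_base()
  erp <- integrate_erp(p, "deviant", duration_ms = 200)
  zero <- list(vsp = erp$vsp * 0, vdp = erp$vdp * 0)
  expect_equal(max(abs(observe(zero, p, fwd$dipoles, fwd$gain))), 0)
  # superposition
  half <- list(vsp = erp$vsp / 2, vdp = erp$vdp / 2)
  ya <- observe(half, p, fwd$dipoles, fwd$gain)
  yb <- observe(erp, p, fwd$dipoles, fwd$gain)
  expect_equal(ya + ya, yb, tolerance = 1e-12)
  # a unilateral right-A1 source is right-lateralized at the sensors
  solo <- erp
  solo$vsp[-2, ] <- 0
  solo$vdp[-2, ] <- 0
  ys <- observe(solo, p, fwd$dipoles, fwd$gain)
  expect_gt(sum(ys["T4", ]^2), sum(ys["T3", ]^2))
})

test_that("dipole spec enforces symmetry and unit orientations", {
  dip <- dipole_spec()
  expect_equal(sqrt(rowSums(dip$orientations^2)), rep(1, 5),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (pr in dip$pairs) {
    a <- dip$positions[pr[1], ]
    b <- dip$positions[pr[2], ]
    expect_equal(unname(a), unname(c(-b[1], b[2], b[3])))
    expect_equal(dip$moment_groups[pr[1]], dip$moment_groups[pr[2]])
  }
})
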