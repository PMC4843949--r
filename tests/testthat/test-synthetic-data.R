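test_that("stimulus sequence honors counts, blocks and spacing", {
  sq <- generate_stimulus_sequence(1200, 0.15, 3, seed = 2)
  ev <- sq$events
  expect_equal(nrow(ev), 1200)
  expect_equal(sum(ev$condition == "deviant"), 180)
  expect_equal(as.numeric(table(ev$block)), rep(400, 3))
  # deviants split equally across blocks
  expect_equal(as.numeric(table(ev$block[ev$condition == "deviant"])),
               rep(60, 3))
  # onsets strictly increasing, spaced by tone duration + ISI
  expect_true(all(diff(ev$onset) > 0))
  dur <- ifelse(ev$condition == "standard", 0.025, 0.050)
  expect_equal(diff(ev$onset), (dur + 0.3)[-1200], tolerance = 1e-12)
})

test_that("degenerate fractions and seeds behave", {
  sq0 <- generate_stimulus_sequence(40, 0, 2, seed = 1)
  expect_true(all(sq0$events$condition == "standard"))
  a <- generate_stimulus_sequence(20, 0.15, 2, seed = 1)
  b <- generate_stimulus_sequence(20, 0.15, 2, seed = 2)
  expect_equal(sum(a$events$condition == "deviant"),
               sum(b$events$condition == "deviant"))
  expect_false(identical(a$events$condition, b$events$condition))
  expect_identical(generate_stimulus_sequence(20, 0.15, 2, seed = 1),
                   a)
  expect_error(generate_stimulus_sequence(10, 0.15, 3), "divisible")
  expect_error(generate_stimulus_sequence(10, 1.5, 2), "\\[0, 1\\]")
})

test_that("planted effects express the factorial pattern at rIFG", {
  tr <- plant_group_effects(fix_base(), default_effect_config(),
                            fix_design())
  g <- vapply(tr$params_by_cell, function(p) p$G_sp[["rIFG"]], numeric(1))
  cs <- g[["controls.standard"]]; cd <- g[["controls.deviant"]]
  rs <- g[["relatives.standard"]]; rd <- g[["relatives.deviant"]]
  ps <- g[["patients.standard"]]; pd <- g[["patients.deviant"]]
  # controls: deviant less self-inhibited; risk groups reversed
  expect_lt(cd, cs)
  expect_gt(rd, rs)
  expect_gt(pd, ps)
  # overall self-inhibition: controls > relatives > patients
  expect_gt(mean(c(cs, cd)), mean(c(rs, rd)))
  expect_gt(mean(c(rs, rd)), mean(c(ps, pd)))
})

test_that("null effects give identical parameter sets, deltas are exact", {
  tr0 <- plant_group_effects(fix_base(), list(), fix_design())
  for (p in tr0$params_by_cell) expect_identical(p, fix_base())
  # a pure risk delta d on rIFG separates controls and relatives by 2d
  d <- -0.37
  tr <- plant_group_effects(fix_base(), list(risk = c(rIFG = d)),
                            fix_design())
  diff_ <- tr$params_by_cell[["relatives.standard"]]$G_sp[["rIFG"]] -
    tr$params_by_cell[["controls.standard"]]$G_sp[["rIFG"]]
  expect_equal(diff_, 2 * d)   # deviation coding: -1 vs +1
  expect_error(plant_group_effects(fix_base(),
                                   list(risk = c(nowhere = 1))),
               "unknown source")
  expect_error(plant_group_effects(fix_base(),
                                   list(oddity = c(rIFG = 1))),
               "unknown effect")
})

test_that("cohort simulation is seed-deterministic with frontal blinks", {
  tr <- plant_group_effects(fix_base(), default_effect_config(),
                            fix_design(), noise_sd = 5, seed = 4)
  sq <- generate_stimulus_sequence(30, 0.2, 1, seed = 4)
  r1 <- simulate_cohort(tr, sq, 1, blink_rate = 20, seed = 9,
                        fwd = fix_fwd())
  r2 <- simulate_cohort(tr, sq, 1, blink_rate = 20, seed = 9,
                        fwd = fix_fwd())
  expect_identical(r1[[1]]$data, r2[[1]]$data)
  expect_equal(length(r1), 3)   # one subject per group
  # blinks dominate frontal-polar channels
  lab <- r1[[1]]$labels
  expect_gt(stats::var(r1[[1]]$data[lab == "FP1", ]),
            stats::var(r1[[1]]$data[lab == "PZ", ]))
  # markers inside the data
  expect_true(all(r1[[1]]$events$sample <= ncol(r1[[1]]$data)))
})

test_that("evoked energy scales linearly with dipole moment", {
  tr0 <- fix_truth0()
  y1 <- cell_sensor_erp(tr0, "controls.standard")
  tr2 <- tr0
  tr2$params_by_cell <- lapply(tr0$params_by_cell, function(p) {
    p$J[] <- log(2)   # double every moment
    p
  })
  y2 <- cell_sensor_erp(tr2, "controls.standard")
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})
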