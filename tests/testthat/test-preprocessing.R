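test_that("common average reference zeroes the channel mean", {
  rec <- toy_recording(n_ch = 2, n_samp = 10)
  rec$data <- matrix(c(1, -3), 2, 10)
  out <- rereference_common_average(rec)
  expect_equal(out$data[, 1], c(2, -2))
  # invariance to a common offset
  rec2 <- toy_recording(n_ch = 4, n_samp = 50)
  off <- rec2
  off$data <- off$data + 42
  expect_equal(rereference_common_average(off)$data,
               rereference_common_average(rec2)$data)
  # idempotence on zero-mean input
  z <- rereference_common_average(rec2)
  expect_equal(rereference_common_average(z)$data, z$data,
               tolerance = 1e-12)
  one <- toy_recording(n_ch = 1, n_samp = 10)
  expect_error(rereference_common_average(one), "2 channels")
})

test_that("filter chain attenuates stop bands and passes the MMN band", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  probe <- function(freq) {
    rec <- structure(list(data = matrix(sin(2 * pi * freq * t), 1),
                          fs = fs, labels = "P"),
                     class = "raw_recording")
    rms_in <- sqrt(mean(rec$data^2))
    out <- apply_filters(rec)
    mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
    sqrt(mean(out$data[, mid]^2)) / rms_in
  }
  expect_lt(probe(49.5), 0.10)    # line-noise notch
  expect_gt(probe(10), 0.70)      # MMN band passes
  expect_lt(probe(0.05), 0.10)    # far below the high-pass cutoff
  # DC is removed entirely
  rec <- structure(list(data = matrix(1, 1, 5000), fs = fs, labels = "P"),
                   class = "raw_recording")
  expect_lt(max(abs(apply_filters(rec)$data)), 1e-2)
  expect_error(apply_filters(structure(list(
    data = matrix(0, 1, 100), fs = 100, labels = "P"),
    class = "raw_recording")), "Nyquist")
})

test_that("downsampling preserves amplitude and remaps markers", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- structure(list(data = matrix(sin(2 * pi * 5 * t), 1), fs = fs,
                        labels = "P",
                        events = data.frame(sample = 501,
                                            condition = "standard")),
                   class = "raw_recording")
  out <- downsample_recording(rec, 200)
  expect_equal(ncol(out$data), 2000)
  mid <- 100:1900
  expect_equal(max(abs(out$data[, mid])), 1, tolerance = 0.02)
  # marker at t = 1.000 s stays at t = 1.000 s on the new grid
  expect_equal((out$events$sample - 1) / 200, 1.0)
  expect_error(downsample_recording(rec, 1000), "exceeds")
})

test_that("epoching yields 81-sample baseline-corrected trials", {
  fs <- 200
  n <- 5000
  rec <- structure(list(data = matrix(stats::rnorm(2 * n), 2), fs = fs,
                        labels = c("A", "B"),
                        events = data.frame(
                          sample = seq(100, 4800, by = 100),
                          condition = "standard")),
                   class = "raw_recording")
  ep <- epoch_and_baseline(rec)
  expect_equal(dim(ep$data)[3], 81)
  expect_equal(range(ep$time_ms), c(-100, 300))
  bl <- ep$time_ms <= 0
  for (i in c(1, 10)) {
    expect_equal(mean(ep$data[i, 1, bl]), 0, tolerance = 1e-12)
  }
  # constant channel -> all-zero epochs
  rec$data[1, ] <- 7
  expect_equal(max(abs(epoch_and_baseline(rec)$data[, 1, ])), 0)
  # markers too close to an edge are dropped with a warning
  rec$events$sample[1] <- 5
  expect_warning(ep2 <- epoch_and_baseline(rec), "dropped")
  expect_equal(dim(ep2$data)[1], nrow(rec$events) - 1)
})

test_that("amplitude rejection flags exactly the exceeding trials", {
  ep <- structure(list(
    data = array(0, dim = c(10, 3, 20)),
    time_ms = seq(-25, 70, by = 5), conditions = rep("standard", 10),
    rejected = rep(FALSE, 10), fs = 200, labels = c("A", "B", "C")),
    class = "epoched_data")
  ep$data[c(2, 5, 9), 2, 7] <- c(100, -90, 71)
  out <- reject_artifacts(ep, 70)
  expect_equal(which(out$rejected), c(2, 5, 9))
  expect_equal(sum(reject_artifacts(ep, 200)$rejected), 0)
  # monotone in threshold: lowering the threshold never un-rejects
  lo <- reject_artifacts(ep, 50)
  expect_true(all(which(out$rejected) %in% which(lo$rejected)))
  expect_error(reject_artifacts(ep, -1), "positive")
})

test_that("robust average resists outlier trials and bounds weights", {
  # identical trials: equals the plain mean, all weights 1
  ep <- structure(list(
    data = array(rep(3, 5 * 2 * 11), dim = c(5, 2, 11)),
    time_ms = seq(0, 50, by = 5), conditions = rep("deviant", 5),
    rejected = rep(FALSE, 5), fs = 200, labels = c("A", "B")),
    class = "epoched_data")
  av <- robust_average(ep, "deviant", lowpass_hz = NA)
  expect_equal(av$data, matrix(3, 2, 11))
  expect_true(all(av$weights == 1))
  # 19 trials at v, 1 at 100v: robust mean near v, plain mean far away
  v <- 2
  y <- c(rep(v, 19), 100 * v)
  ep2 <- structure(list(
    data = array(y, dim = c(20, 1, 1)), time_ms = 0,
    conditions = rep("standard", 20), rejected = rep(FALSE, 20),
    fs = 200, labels = "A"), class = "epoched_data")
  av2 <- robust_average(ep2, "standard", lowpass_hz = NA)
  expect_lt(abs(av2$data[1, 1] - v) / v, 0.05)
  expect_equal(mean(y), 5.95 * v)   # the plain mean is dominated
  # weights stay within [0, 1] on random fixtures
  set.seed(3)
  ep3 <- ep
  ep3$data <- array(stats::rnorm(5 * 2 * 11), dim = c(5, 2, 11))
  av3 <- robust_average(ep3, "deviant", lowpass_hz = NA)
  expect_true(all(av3$weights >= 0 & av3$weights <= 1))
  expect_error(robust_average(ep3, "standard"), "at least 2")
})

test_that("grand averaging forms exactly one response per cell", {
  mk <- function(g, cn, val) structure(list(
    data = matrix(val, 2, 3), time_ms = c(0, 5, 10), condition = cn,
    group = g, n_trials = 10, fs = 200, labels = c("A", "B")),
    class = "evoked_response")
  evs <- list()
  for (g in c("controls", "relatives", "patients")) {
    for (cn in c("standard", "deviant")) {
      evs <- c(evs, list(mk(g, cn, 1), mk(g, cn, 3)))
    }
  }
  ga <- grand_average(evs)
  expect_length(ga, 6)
  expect_equal(names(ga)[1], "controls.standard")
  expect_true(all(vapply(ga, function(e) all(e$data == 2), logical(1))))
  # a single subject per cell passes through unchanged
  ga1 <- grand_average(evs[seq(1, 12, by = 2)])
  expect_equal(ga1[["patients.deviant"]]$data, matrix(1, 2, 3))
  # symmetric responses cancel
  ga2 <- grand_average(list(mk("controls", "standard", 5),
                            mk("controls", "standard", -5),
                            mk("controls", "deviant", 1),
                            mk("relatives", "standard", 1),
                            mk("relatives", "deviant", 1),
                            mk("patients", "standard", 1),
                            mk("patients", "deviant", 1)))
  expect_equal(ga2[["controls.standard"]]$data, matrix(0, 2, 3))
  expect_error(grand_average(evs[1:2]), "controls, deviant")
})

test_that("ocular stage removes planted blinks and spares the evoked response", {
  tr <- fix_truth0()
  tr$noise_sd <- 5
  sq <- generate_stimulus_sequence(150, 0.2, 1, isi = 0.3, seed = 21)
  mk_ep <- function(blink_rate) {
    rec <- simulate_cohort(tr, sq, 1, blink_rate = blink_rate, seed = 22,
                           fwd = fix_fwd())[[1]]
    rec <- rereference_common_average(rec)
    rec <- apply_filters(rec)
    rec <- downsample_recording(rec)
    epoch_and_baseline(rec)
  }
  ep_clean <- mk_ep(0)
  ep_blink <- mk_ep(20)
  out_clean <- remove_ocular_components(ep_clean)
  expect_equal(nrow(out_clean$ocular_report), 17)
  expect_equal(sum(out_clean$ocular_report$removed), 0)
  out <- remove_ocular_components(ep_blink)
  expect_gte(sum(out$ocular_report$removed), 1)
  expect_lte(sum(out$ocular_report$removed), 2)
  # FP1 blink-band (0.5-4 Hz) power drops by >= 80%
  flat <- function(ep, ch) as.numeric(t(ep$data[, ch, ]))
  bl <- signal::butter(2, c(0.5, 4) / 100, type = "pass")
  bp <- function(x) mean(signal::filtfilt(bl, x)^2)
  fp1 <- which(ep_blink$labels == "FP1")
  expect_lt(bp(flat(out, fp1)), 0.2 * bp(flat(ep_blink, fp1)))
  # evoked response at CZ preserved within 15% of the blink-free chain
  cz <- which(ep_blink$labels == "CZ")
  avg_cz <- function(ep) {
    keep <- ep$conditions == "standard"
    apply(ep$data[keep, cz, , drop = FALSE], 3, mean)
  }
  ref <- avg_cz(ep_clean)
  got <- avg_cz(out)
  expect_lt(sqrt(mean((got - ref)^2)) / sqrt(mean(ref^2)), 0.15)
})

test_that("at most two components are removed even when more correlate", {
  tr <- fix_truth0()
  sq <- generate_stimulus_sequence(60, 0.2, 1, seed = 31)
  rec <- simulate_cohort(tr, sq, 1, blink_rate = 15, seed = 31,
                         fwd = fix_fwd())[[1]]
  rec <- rereference_common_average(rec)
  rec <- apply_filters(rec)
  rec <- downsample_recording(rec)
  ep <- epoch_and_baseline(rec)
  # with a permissive threshold many components pass; the cap still holds
  out <- remove_ocular_components(ep, threshold = 0.005)
  expect_gt(sum(abs(out$ocular_report$r) > 0.005), 2)
  expect_equal(sum(out$ocular_report$removed), 2)
  ord <- order(-abs(out$ocular_report$r))
  expect_setequal(which(out$ocular_report$removed), ord[1:2])
})

test_that("noiseless full chain reproduces the generating ERP", {
  tr0 <- fix_truth0()
  sq <- generate_stimulus_sequence(20, 0, 1, isi = 0.3, seed = 41)
  rec <- simulate_cohort(tr0, sq, 1, blink_rate = 0, seed = 41,
                         fwd = fix_fwd())[[1]]
  rec <- rereference_common_average(rec)
  rec <- apply_filters(rec)
  rec <- downsample_recording(rec)
  ep <- epoch_and_baseline(rec)
  ep <- reject_artifacts(ep)
  av <- robust_average(ep, "standard")
  y <- cell_sensor_erp(tr0, "controls.standard")
  y <- sweep(y, 2, colMeans(y))
  got <- av$data[, av$time_ms >= 0]
  expect_lt(sqrt(mean((got - y)^2)) / sqrt(mean(y^2)), 0.05)
})
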