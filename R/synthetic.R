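# run expr with a local, seeded RNG state, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a duration-deviant oddball stimulus sequence
#'
#' Tones are presented with a fixed inter-stimulus interval; the deviant
#' count is exactly `round(deviant_fraction * total)`, split across blocks
#' as equally as rounding allows, with positions shuffled uniformly within
#' each block under the given seed. Standards last 25 ms, deviants 50 ms;
#' successive onsets differ by tone duration plus the ISI.
#'
#' @param total total number of tones (default 1200).
#' @param deviant_fraction proportion of deviants in `[0, 1]` (default
#'   0.15).
#' @param n_blocks number of equally sized blocks (default 3); must divide
#'   `total`.
#' @param isi inter-stimulus interval in seconds (default 0.3).
#' @param seed integer RNG seed.
#' @param durations named numeric: tone durations (s) for standard and
#'   deviant.
#' @return object of class `stim_sequence`: list with `events` (data.frame
#'   `onset` (s), `condition`, `block`), `isi`, `n_blocks`.
#' @export
generate_stimulus_sequence <- function(total = 1200, deviant_fraction = 0.15,
                                       n_blocks = 3, isi = 0.3, seed = 1,
                                       durations = c(standard = 0.025,
                                                     deviant = 0.050)) {
  if (deviant_fraction < 0 || deviant_fraction > 1) {
    stop("deviant_fraction must be in [0, 1]")
  }
  if (total %% n_blocks != 0) {
    stop("total (", total, ") is not divisible by n_blocks (", n_blocks, ")")
  }
  per_block <- total / n_blocks
  n_dev <- round(deviant_fraction * total)
  base <- n_dev %/% n_blocks
  extra <- n_dev %% n_blocks
  dev_per_block <- rep(base, n_blocks) + (seq_len(n_blocks) <= extra)
  cond <- with_local_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) {
      v <- rep("standard", per_block)
      v[sample.int(per_block, dev_per_block[b])] <- "deviant"
      v
    }))
  })
  dur <- unname(durations[cond])
  onset <- cumsum(c(0, (dur + isi)[-total]))
  structure(list(events = data.frame(onset = onset, condition = cond,
                                     block = rep(seq_len(n_blocks),
                                                 each = per_block),
                                     stringsAsFactors = FALSE),
                 isi = isi, n_blocks = n_blocks, durations = durations,
                 seed = seed),
            class = "stim_sequence")
}

#' @export
print.stim_sequence <- function(x, ...) {
  tb <- table(x$events$condition)
  cat("Oddball sequence:", nrow(x$events), "tones in", x$n_blocks,
      "blocks;", tb["deviant"], "deviants; ISI", x$isi * 1000, "ms\n")
  invisible(x)
}

#' Default planted group effects on superficial-pyramidal gain
#'
#' Log-scale modulations of sp self-inhibition per factorial effect and
#' source, emulating the qualitative pattern of a psychosis MMN study:
#' all groups become more excitable (less self-inhibited) to deviants in
#' bilateral A1; in rIFG the genetic-risk groups are more excitable than
#' controls across conditions (patients most), and their condition effect
#' is reversed relative to controls.
#'
#' @return named list: one named numeric vector of source deltas per
#'   factorial effect.
#' @export
default_effect_config <- function() {
  list(
    condition = c(lA1 = -0.2, rA1 = -0.2, rIFG = 0.05),
    risk = c(rIFG = -0.3),
    diagnosis = c(rIFG = -0.15),
    risk_condition = c(rIFG = 0.2),
    diagnosis_condition = c(rIFG = 0.05)
  )
}

#' Plant factorial group effects into ground-truth parameters
#'
#' Expands per-effect, per-source log-scale deltas on sp self-inhibition
#' into the six (group x condition) parameter sets of the factorial design,
#' via [apply_condition_modulation()]. With all deltas zero the six sets
#' are identical to `base`.
#'
#' @param base a [cmc_parameters()] object (shared baseline).
#' @param effect_config named list of effects (names must match design
#'   effect columns), each a named numeric vector of per-source log deltas;
#'   see [default_effect_config()].
#' @param design a [build_factorial_design()] result.
#' @param noise_sd sensor noise standard deviation (microvolts) to be used
#'   when simulating recordings.
#' @param seed integer seed stored with the truth.
#' @return object of class `ground_truth`: list with `base`, `B_true`
#'   (effects x sources matrix), `design`, `params_by_cell` (list of 6
#'   `cmc_params`), `noise_sd`, `seed`.
#' @export
plant_group_effects <- function(base = cmc_parameters(),
                                effect_config = default_effect_config(),
                                design = build_factorial_design(),
                                noise_sd = 5, seed = 1) {
  eff_names <- colnames(design$X)
  bad <- setdiff(names(effect_config), eff_names)
  if (length(bad)) {
    stop("unknown effect name(s): ", paste(bad, collapse = ", "))
  }
  src <- unique(unlist(lapply(effect_config, names)))
  source_index(base$network, src)   # errors on unknown source names
  if (length(src) == 0) src <- character(0)
  B <- matrix(0, length(eff_names), length(src),
              dimnames = list(eff_names, src))
  for (e in names(effect_config)) {
    B[e, names(effect_config[[e]])] <- effect_config[[e]]
  }
  cells <- rownames(design$X)
  params_by_cell <- lapply(cells, function(cl) {
    if (ncol(B)) {
      apply_condition_modulation(base, design$X[cl, ], B)
    } else {
      base
    }
  })
  names(params_by_cell) <- cells
  structure(list(base = base, B_true = B, design = design,
                 params_by_cell = params_by_cell, noise_sd = noise_sd,
                 seed = seed),
            class = "ground_truth")
}

#' Forward-model setup for a network
#'
#' Convenience bundle of montage, dipoles, lead field and spatial modes
#' used by the simulator and the inversion.
#'
#' @param network an [mmn_network()].
#' @param n_modes spatial modes to retain (default 8).
#' @param gain optional user-supplied lead field overriding the spherical
#'   head model.
#' @return list with `montage`, `dipoles`, `gain`, `projection`.
#' @export
forward_setup <- function(network = mmn_network(), n_modes = 8,
                          gain = NULL) {
  montage <- montage_1020()
  dipoles <- dipole_spec(network)
  if (is.null(gain)) gain <- lead_field(montage, dipoles)
  list(montage = montage, dipoles = dipoles, gain = gain,
       projection = compute_spatial_modes(gain, n_modes))
}

# stereotyped blink topography: amplitude decays steeply with distance
# from the eyes (EOG-like fall-off); weights are normalised to 1 at the
# strongest frontal-polar channel so blink amplitudes are specified at
# FP1/FP2
blink_topography <- function(montage, decay_mm = 25) {
  eye <- c(0, 92, -25)
  d <- sqrt((montage$x - eye[1])^2 + (montage$y - eye[2])^2 +
              (montage$z - eye[3])^2)
  w <- exp(-d / decay_mm)
  w / max(w)
}

#' Simulate a synthetic cohort of raw oddball EEG recordings
#'
#' For each subject, the condition- and group-appropriate simulated ERP
#' (CMC dynamics through the dipole forward model) is inserted at every
#' tone onset of the stimulus sequence in a continuous 500 Hz recording;
#' IID Gaussian sensor noise and stereotyped low-frequency, frontally
#' dominant blink transients are added.
#'
#' @param truth a [plant_group_effects()] ground truth.
#' @param sequence a [generate_stimulus_sequence()] sequence.
#' @param n_subjects_per_group subjects per group (default 12).
#' @param blink_rate blink events per minute (default 12).
#' @param seed integer seed; fully determines the output.
#' @param fwd a [forward_setup()]; built from the truth's network if
#'   missing.
#' @param fs sampling rate in Hz (default 500).
#' @param erp_ms length of each trial's simulated evoked contribution
#'   (ms); the final `taper_ms` are faded out with a raised cosine so the
#'   inserted transient ends smoothly. Successive contributions superpose
#'   when they outlast the stimulus spacing, as in real recordings.
#' @param taper_ms taper length (ms).
#' @return list of `raw_recording` objects (one per subject), each a list
#'   with `data` (channels x samples, microvolts), `fs`, `labels`,
#'   `events` (data.frame `sample`, `condition`), `group`, `subject`.
#' @export
simulate_cohort <- function(truth, sequence,
                            n_subjects_per_group = 12, blink_rate = 12,
                            seed = 1, fwd = NULL, fs = 500,
                            erp_ms = 450, taper_ms = 100) {
  if (n_subjects_per_group < 1) stop("n_subjects_per_group must be >= 1")
  if (is.null(fwd)) fwd <- forward_setup(truth$base$network)
  groups <- truth$design$groups
  conds <- truth$design$conditions
  ev <- sequence$events
  dt_erp <- 1000 / fs      # sample ERP on the recording grid (2 ms)
  # per group x condition sensor-level ERP (channels x samples, uV)
  erp_bank <- lapply(groups, function(g) {
    out <- lapply(conds, function(cn) {
      pp <- truth$params_by_cell[[paste(g, cn, sep = ".")]]
      erp <- integrate_erp(pp, cn, duration_ms = erp_ms, dt = 0.5)
      keep <- seq(1, length(erp$time), by = round(dt_erp / 0.5))
      y <- observe(list(vsp = erp$vsp[, keep], vdp = erp$vdp[, keep]),
                   pp, fwd$dipoles, fwd$gain)
      tk <- erp$time[keep]
      taper <- rep(1, length(tk))
      ix <- tk > erp_ms - taper_ms
      taper[ix] <- 0.5 * (1 + cos(pi * (tk[ix] - (erp_ms - taper_ms)) /
                                    taper_ms))
      sweep(y, 2, taper, "*")
    })
    names(out) <- conds
    out
  })
  names(erp_bank) <- groups
  nch <- nrow(fwd$gain)
  pad <- 0.5
  n_samp <- ceiling((pad + max(ev$onset) + erp_ms / 1000 + 0.1) * fs)
  n_erp <- ncol(erp_bank[[1]][[1]])
  marker <- round((pad + ev$onset) * fs) + 1L
  btop <- blink_topography(fwd$montage)
  with_local_seed(seed, {
    recs <- list()
    for (g in groups) {
      for (s in seq_len(n_subjects_per_group)) {
        X <- matrix(stats::rnorm(nch * n_samp, 0, truth$noise_sd),
                    nch, n_samp)
        for (i in seq_len(nrow(ev))) {
          ix <- marker[i]:(marker[i] + n_erp - 1)
          X[, ix] <- X[, ix] + erp_bank[[g]][[ev$condition[i]]]
        }
        if (blink_rate > 0) {
          t_end <- n_samp / fs
          bt <- cumsum(stats::rexp(ceiling(blink_rate / 60 * t_end * 3) + 5,
                                   blink_rate / 60))
          bt <- bt[bt < t_end - 0.35]
          blink_len <- round(0.3 * fs)
          shape <- (1 - cos(2 * pi * seq_len(blink_len) / blink_len)) / 2
          for (b in bt) {
            amp <- stats::rnorm(1, 120, 20)
            ix <- round(b * fs) + seq_len(blink_len)
            X[, ix] <- X[, ix] + (btop * amp) %o% shape
          }
        }
        recs[[length(recs) + 1]] <- structure(
          list(data = X, fs = fs, labels = fwd$montage$label,
               events = data.frame(sample = marker,
                                   condition = ev$condition,
                                   stringsAsFactors = FALSE),
               group = g, subject = s),
          class = "raw_recording")
      }
    }
    recs
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("Raw recording:", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$fs, "Hz;", nrow(x$events), "events")
  if (!is.null(x$group)) cat(" [", x$group, "subject", x$subject, "]")
  cat("\n")
  invisible(x)
}
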