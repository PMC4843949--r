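# shared fixtures, built once per test run

fix <- new.env()

fix_base <- function() {
  if (is.null(fix$base)) fix$base <- cmc_parameters()
  fix$base
}

fix_fwd <- function() {
  if (is.null(fix$fwd)) fix$fwd <- forward_setup()
  fix$fwd
}

fix_design <- function() {
  if (is.null(fix$design)) fix$design <- build_factorial_design()
  fix$design
}

# small noiseless truth shared by several tests
fix_truth0 <- function() {
  if (is.null(fix$truth0)) {
    fix$truth0 <- plant_group_effects(fix_base(), default_effect_config(),
                                      fix_design(), noise_sd = 0, seed = 11)
  }
  fix$truth0
}

# a toy raw recording: deterministic sine/noise mixture with events
toy_recording <- function(n_ch = 4, n_samp = 4000, fs = 500, seed = 7,
                          events = NULL) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n_ch * n_samp), n_ch, n_samp)
  structure(list(data = X, fs = fs,
                 labels = paste0("CH", seq_len(n_ch)),
                 events = events),
            class = "raw_recording")
}

# sensor-level prediction of a ground-truth cell on the 500 Hz grid
cell_sensor_erp <- function(truth, cell, duration_ms = 300, every = 10) {
  fwd <- fix_fwd()
  pp <- truth$params_by_cell[[cell]]
  cnd <- sub(".*\\.", "", cell)
  erp <- integrate_erp(pp, cnd, duration_ms = duration_ms, dt = 0.5)
  keep <- seq(1, length(erp$time), by = every)
  observe(list(vsp = erp$vsp[, keep, drop = FALSE],
               vdp = erp$vdp[, keep, drop = FALSE]),
          pp, fwd$dipoles, fwd$gain)
}
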