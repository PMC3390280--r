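# Shared fixtures: the hepatocellular growth law and a cache for expensive
# intermediate results reused across test files.

hepato_params <- function() gompertz_params(b = 7.3e10, mu = 0.00286)

hepato_circ <- function() circulation_params(T_env = 1, c_frac = 1e-4)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# calibrated hepatocellular MS cascade (shared by cascade + acceptance tests)
hepato_ms_calibration <- function() {
  cached("ms_cal", calibrate_m_to_iks("MS", hepato_params(),
                                      iks_params(), hepato_circ()))
}

hepato_gdr_calibration <- function() {
  cached("gdr_cal", calibrate_m_to_iks("GDR", hepato_params(),
                                       iks_params(), hepato_circ()))
}

hepato_ms_cascade <- function(horizon = 1400) {
  key <- paste0("ms_casc_", horizon)
  cached(key, {
    cal <- hepato_ms_calibration()
    metastatic_cascade(hepato_params(), cal$cfg, hepato_circ(),
                       horizon = horizon)
  })
}

run_engine_for_test <- function(p, cfg, horizon) {
  if (cfg$engine == "MS") ms_trajectory(p, cfg, horizon)
  else gdr_trajectory(p, cfg, horizon)
}

gdr_log_asymptote_for_test <- function(d_i, eps)
  metacascade:::gdr_log_asymptote(d_i, eps)
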