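# Shared fixtures for the test suite. Simulation results that several
# files need (notably the pre-paced control steady state) are computed
# once per test run and cached here.

.cipaddi_test_cache <- new.env(parent = emptyenv())

cache_once <- function(key, expr) {
  if (is.null(.cipaddi_test_cache[[key]]))
    assign(key, force(expr), envir = .cipaddi_test_cache)
  .cipaddi_test_cache[[key]]
}

# reduced pacing design used by simulation tests: enough pre-pacing for a
# stable (if not fully converged) beat, short drug phase
test_profile <- function(drug_beats = 20, candidate_window = 5, ...) {
  protocol_profile("test", drug_beats = drug_beats,
                   candidate_window = candidate_window, ...)
}

cached_test_control <- function() {
  cache_once("test_control", run_control(test_profile()))
}

# piecewise-linear synthetic action potential: rest -> peak at t_peak ->
# linear repolarization to v_end at t_end -> flat to 2000 ms
triangle_beat <- function(v_rest = -85, v_peak = 40, t_peak = 50,
                          t_end = 300, v_end = -85, out_dt = 1,
                          cl = 2000, ca = NULL) {
  t <- seq(0, cl, by = out_dt)
  vm <- approx(x = c(0, t_peak, t_end, cl),
               y = c(v_rest, v_peak, v_end, v_end), xout = t)$y
  if (is.null(ca))
    ca <- approx(x = c(0, 100, 800, cl),
                 y = c(1e-4, 6e-4, 1e-4, 1e-4), xout = t)$y
  zero <- numeric(length(t))
  beat_trace(data.frame(time = t, vm = vm, cai = ca, ikr = zero,
                        ical = zero, inal = zero, ito = zero, iks = zero,
                        ik1 = zero))
}

# constant-net-current beat on a flat AP-like trace
constant_current_beat <- function(inet = 0.05, out_dt = 1, cl = 2000) {
  b <- triangle_beat(out_dt = out_dt, cl = cl)
  b$ikr <- rep(inet, nrow(b))
  b
}

# tiny deterministic population (spread 0 -> identical samples)
tiny_pop <- function(name, cmax, nominal, n = 2, spread = 0.2, seed = 42) {
  synthesize_population(name, cmax, nominal, n_samples = n, spread = spread,
                        seed = seed)
}

no_block_pop <- function(n = 2) {
  drug_population("inert", cmax = 100,
                  data.frame(sample = seq_len(n) - 1L))
}
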