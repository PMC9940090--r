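#' Drug-target channel identifiers
#'
#' The seven ion channels that carry drug block in the CiPA assay:
#' fast sodium (`Na`), late sodium (`NaL`), transient outward potassium
#' (`to`), L-type calcium (`CaL`), rapid delayed rectifier / hERG (`Kr`),
#' slow delayed rectifier (`Ks`) and inward rectifier (`K1`).
#'
#' @return Character vector of channel tags.
#' @export
ord_channels <- function() {
  c("Na", "NaL", "to", "CaL", "Kr", "Ks", "K1")
}

#' CiPA conductance rescaling factors
#'
#' Multiplicative rescaling of five maximal conductances of the
#' O'Hara-Rudy endocardial model, from the CiPA optimization against APD
#' rate-dependence data (Dutta et al. / FDA CiPA model v1.0). Applied on
#' top of the published base conductances by [conductance_set()].
#'
#' @return Named numeric vector of scale factors for NaL, CaL, Kr, Ks, K1.
#' @export
cipa_scaling <- function() {
  c(NaL = 2.661, CaL = 1.007, Kr = 1.013, Ks = 1.870, K1 = 1.698)
}

# published base maximal conductances/permeabilities, endocardial cell
# (GNa mS/uF, PCa cm/s-scaled permeability, etc. -- source-model units)
ord_base_conductances <- function() {
  c(GNa = 75, GNaL = 0.0075, Gto = 0.02, PCa = 1e-4,
    GKr = 0.046, GKs = 0.0034, GK1 = 0.1908,
    Gncx = 0.0008, Pnak = 30, GKb = 0.003,
    PNab = 3.75e-10, PCab = 2.5e-8, GpCa = 0.0005)
}

# map drug-target channel tag -> conductance name
channel_conductance <- c(Na = "GNa", NaL = "GNaL", to = "Gto", CaL = "PCa",
                         Kr = "GKr", Ks = "GKs", K1 = "GK1")

#' Maximal conductance set of the myocyte model
#'
#' The full set of maximal conductances/permeabilities of the
#' endocardial O'Hara-Rudy model. By default the published values are
#' rescaled by the CiPA optimization factors ([cipa_scaling()]); the
#' drug-free model used throughout the package is exactly this set.
#' Scaling the `CaL` entry (`PCa`) scales the shared L-type permeability,
#' so ICaL, ICaNa and ICaK are blocked together.
#'
#' @param scaling Named numeric vector of rescaling factors on the five
#'   CiPA-optimized channels (default [cipa_scaling()]). Use
#'   `scaling = NULL` for the unscaled source model.
#' @return Named numeric vector of class `conductance_set`.
#' @export
conductance_set <- function(scaling = cipa_scaling()) {
  g <- ord_base_conductances()
  if (!is.null(scaling)) {
    stopifnot(all(names(scaling) %in% ord_channels()))
    idx <- channel_conductance[names(scaling)]
    g[idx] <- g[idx] * scaling
  }
  if (any(g < 0)) stop("conductances must be non-negative")
  structure(g, class = "conductance_set")
}

as_gvec <- function(g) {
  ref <- names(ord_base_conductances())
  if (!all(ref %in% names(g)))
    stop("conductance set must contain: ", paste(ref, collapse = ", "))
  g <- unclass(g)[ref]
  if (any(!is.finite(g)) || any(g < 0))
    stop("conductances must be finite and non-negative")
  g
}

#' Initial state of the myocyte model
#'
#' The published O'Hara-Rudy endocardial initial conditions (the hERG
#' Markov gating states start fully closed). This state is not a paced
#' steady state: protocols pre-pace the drug-free model from here (see
#' [run_control()]).
#'
#' @return Named numeric vector with membrane potential `v` (mV), ionic
#'   concentrations (mM), gating variables (dimensionless) and CaMK
#'   state.
#' @export
initial_state <- function() {
  ord_init_state()
}

check_cell_state <- function(state) {
  nm <- ord_state_names()
  if (!is.numeric(state) || length(state) != length(nm))
    stop("state must be a numeric vector of length ", length(nm))
  if (is.null(names(state))) names(state) <- nm
  state <- state[nm]
  if (any(!is.finite(state)))
    stop("model divergence: non-finite state component")
  state
}

#' Time derivatives and ionic currents of the myocyte model
#'
#' Evaluates the model right-hand side at a given state: the rate of
#' change of every state variable (per ms) and the 14 ionic membrane
#' currents plus their sum. `dVm/dt = -(Iion + Istim)/Cm` with
#' `Cm = 1 uF/cm^2`.
#'
#' @param state Cell state as returned by [initial_state()].
#' @param conductances A [conductance_set()].
#' @param stim_current Stimulus current density (uA/uF), depolarizing
#'   negative.
#' @param ikr `"markov"` (hERG Markov gating, the CiPA model; default) or
#'   `"hh"` (original Hodgkin-Huxley IKr).
#' @return List with `dstate` (named derivative vector) and `currents`
#'   (named vector of the ionic currents, uA/uF).
#' @export
derivatives <- function(state, conductances = conductance_set(),
                        stim_current = 0, ikr = c("markov", "hh")) {
  ikr <- match.arg(ikr)
  state <- check_cell_state(state)
  ord_derivs_cpp(state, as_gvec(conductances), stim_current,
                 as.integer(ikr == "markov"))
}

#' Stimulus protocol
#'
#' Pacing stimulus description: a depolarizing rectangular pulse applied
#' at the start of each beat.
#'
#' @param amplitude Current density, uA/uF (negative = depolarizing).
#' @param duration Pulse duration, ms.
#' @param cycle_length Beat length, ms (2000 ms for all risk protocols).
#' @param beat_count Number of beats.
#' @return List of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = -80, duration = 0.5,
                              cycle_length = 2000, beat_count = 1) {
  if (duration >= cycle_length)
    stop("stimulus duration must be shorter than the cycle length")
  if (beat_count < 1 || beat_count != round(beat_count))
    stop("beat_count must be a positive integer")
  structure(list(amplitude = amplitude, duration = duration,
                 cycle_length = cycle_length,
                 beat_count = as.integer(beat_count)),
            class = "stimulus_protocol")
}

#' Integrate the model over paced beats
#'
#' Advances the state by `beat_count` beats of `cycle_length` ms with a
#' fixed-step scheme (Rush-Larsen for Hodgkin-Huxley gates, forward
#' Euler otherwise), optionally recording the last beat(s) on a uniform
#' output grid. The integrator is deterministic: identical inputs give
#' bit-identical results.
#'
#' @inheritParams derivatives
#' @param stim A [stimulus_protocol()].
#' @param record Logical; record a [beat_trace] of the final beat?
#' @param record_last Number of trailing beats to record when `record`
#'   is `TRUE`.
#' @param dt Integration step, ms.
#' @param out_dt Output sampling interval, ms (integer multiple of `dt`).
#' @param ss_tol Early-exit tolerance on the maximum relative end-of-beat
#'   state change; `0` (default) disables early exit.
#' @return List with `state` (end-of-run state), `beats_run`,
#'   `converged` (early-exit flag), and `traces` (list of [beat_trace]
#'   objects, most recent last) when recording.
#' @export
integrate_beat <- function(state, conductances = conductance_set(),
                           stim = stimulus_protocol(), record = TRUE,
                           record_last = 1L, dt = 0.005, out_dt = 1,
                           ss_tol = 0, ikr = c("markov", "hh")) {
  ikr <- match.arg(ikr)
  state <- check_cell_state(state)
  res <- ord_pace_cpp(state, as_gvec(conductances), stim$beat_count,
                      stim$cycle_length, dt, stim$amplitude, stim$duration,
                      out_dt, if (record) as.integer(record_last) else 0L,
                      ss_tol, as.integer(ikr == "markov"))
  res$traces <- traces_to_beats(res$traces)
  res
}

traces_to_beats <- function(tr) {
  if (is.null(tr)) return(NULL)
  lapply(seq_along(tr$beat), function(k) {
    beat_trace(data.frame(time = tr$time, vm = tr$vm[, k], cai = tr$cai[, k],
                          ikr = tr$ikr[, k], ical = tr$ical[, k],
                          inal = tr$inal[, k], ito = tr$ito[, k],
                          iks = tr$iks[, k], ik1 = tr$ik1[, k]),
               beat = tr$beat[k])
  })
}

#' Beat trace
#'
#' One recorded beat: membrane potential, intracellular calcium and the
#' six qNet currents (IKr, ICaL, INaL, Ito, IKs, IK1) on a uniform time
#' grid from stimulus onset (t = 0) to the end of the beat.
#'
#' @param df Data frame with columns `time` (ms), `vm` (mV), `cai` (mM),
#'   `ikr`, `ical`, `inal`, `ito`, `iks`, `ik1` (uA/uF).
#' @param beat Beat index within its run (optional).
#' @return `df` with class `beat_trace`.
#' @export
beat_trace <- function(df, beat = NA_integer_) {
  need <- c("time", "vm", "cai", "ikr", "ical", "inal", "ito", "iks", "ik1")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("beat trace is missing series: ", paste(miss, collapse = ", "))
  dt <- diff(df$time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
    stop("beat trace time grid must be uniform and increasing")
  structure(as.data.frame(df)[need], beat = as.integer(beat),
            class = c("beat_trace", "data.frame"))
}

#' @export
print.beat_trace <- function(x, ...) {
  cat(sprintf("<beat_trace> %d samples, t = %g..%g ms, Vm in [%.1f, %.1f] mV\n",
              nrow(x), x$time[1], x$time[nrow(x)], min(x$vm), max(x$vm)))
  invisible(x)
}

#' @export
plot.beat_trace <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$time, x$vm, type = "l", xlab = "time (ms)", ylab = "Vm (mV)", ...)
  plot(x$time, x$cai * 1e3, type = "l", xlab = "time (ms)",
       ylab = "[Ca]i (uM)", ...)
  invisible(x)
}
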