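#' Pacing protocol configuration
#'
#' Settings of the control / drug pacing protocol: drug-free pre-pacing
#' to steady state, drug-on pacing from that steady state, and the
#' trailing window of candidate beats kept for biomarker extraction.
#' The risk-assessment protocol paces 1000 control beats and 1000 drug
#' beats of 2000 ms and examines the last 250 drug beats; named profiles
#' provide smaller, clearly-labelled designs for fast exploratory runs.
#'
#' @param control_beats Drug-free pre-pacing beats.
#' @param drug_beats Beats paced with block applied.
#' @param candidate_window Trailing drug beats recorded as biomarker
#'   candidates (must not exceed `drug_beats`).
#' @param cycle_length Beat length, ms.
#' @param output_sampling Trace output interval, ms.
#' @param dt Integration step, ms.
#' @param stim_amplitude,stim_duration Stimulus pulse (uA/uF, ms).
#' @param ss_tol Early-exit tolerance on the relative end-of-beat state
#'   change during pre-pacing (`0` disables; the full-length protocol is
#'   the default).
#' @param ikr IKr formulation, `"markov"` (default) or `"hh"`.
#' @return List of class `protocol_config`.
#' @export
protocol_config <- function(control_beats = 1000, drug_beats = 1000,
                            candidate_window = 250, cycle_length = 2000,
                            output_sampling = 1, dt = 0.005,
                            stim_amplitude = -80, stim_duration = 0.5,
                            ss_tol = 0, ikr = c("markov", "hh")) {
  ikr <- match.arg(ikr)
  counts <- c(control_beats, drug_beats, candidate_window)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("beat counts must be positive integers")
  if (candidate_window > drug_beats)
    stop("candidate_window must not exceed drug_beats")
  if (stim_duration >= cycle_length)
    stop("stimulus duration must be shorter than the cycle length")
  structure(list(control_beats = as.integer(control_beats),
                 drug_beats = as.integer(drug_beats),
                 candidate_window = as.integer(candidate_window),
                 cycle_length = cycle_length,
                 output_sampling = output_sampling, dt = dt,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration,
                 ss_tol = ss_tol, ikr = ikr),
            class = "protocol_config")
}

#' Named protocol profiles
#'
#' `"paper"` is the full risk protocol (1000/1000 beats, last 250).
#' `"scaled"` (200/200, last 50) and `"test"` (100/30, last 8, dt = 0.01)
#' are reduced designs for exploration and fast checks; outputs carry
#' the profile name so a scaled run is never mistaken for the full one.
#'
#' @param name Profile name.
#' @param ... Overrides passed to [protocol_config()].
#' @return A `protocol_config` with attribute `profile`.
#' @export
protocol_profile <- function(name = c("paper", "scaled", "test"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    paper = list(),
    scaled = list(control_beats = 200, drug_beats = 200,
                  candidate_window = 50),
    test = list(control_beats = 100, drug_beats = 30, candidate_window = 8))
  cfg <- do.call(protocol_config, modifyList(base, list(...)))
  attr(cfg, "profile") <- name
  cfg
}

config_stim <- function(config, beats) {
  stimulus_protocol(config$stim_amplitude, config$stim_duration,
                    config$cycle_length, beats)
}

#' Drug-free pre-pacing to steady state
#'
#' Paces the drug-free model `control_beats` times from the published
#' initial conditions and returns the end state with the final beat's
#' trace and biomarkers. Deterministic: repeated runs are identical.
#'
#' @param config A [protocol_config()].
#' @param conductances Drug-free [conductance_set()].
#' @param state Starting state (default [initial_state()]).
#' @return List of class `control_run`: `state`, `trace` (final beat),
#'   `beats_run`, `converged`, `qnet`, `apd90`, `config`.
#' @export
run_control <- function(config = protocol_config(),
                        conductances = conductance_set(),
                        state = initial_state()) {
  res <- integrate_beat(state, conductances,
                        config_stim(config, config$control_beats),
                        record = TRUE, record_last = 1L, dt = config$dt,
                        out_dt = config$output_sampling,
                        ss_tol = config$ss_tol, ikr = config$ikr)
  trace <- res$traces[[length(res$traces)]]
  structure(list(state = res$state, trace = trace,
                 beats_run = res$beats_run, converged = res$converged,
                 qnet = qnet(trace), apd90 = as.numeric(apd90(trace)),
                 config = config),
            class = "control_run")
}

#' @export
print.control_run <- function(x, ...) {
  cat(sprintf(paste0("<control_run> %d beats (CL %g ms)%s\n",
                     "  qNet %.4f uC/uF, APD90 %.1f ms\n"),
              x$beats_run, x$config$cycle_length,
              if (x$converged) ", early exit at steady-state tolerance" else "",
              x$qnet, x$apd90))
  invisible(x)
}

#' Drug-on pacing from the control steady state
#'
#' Applies a per-channel block vector to the drug-free conductances and
#' paces `drug_beats` beats from the supplied steady state, recording
#' the last `candidate_window` beats as biomarker candidates. A
#' diverging run (e.g. numerical blow-up under extreme block) is
#' reported as a failed run, not dropped.
#'
#' @param steady End state of [run_control()] (or a `control_run`).
#' @param block Named block vector over [ord_channels()].
#' @param config A [protocol_config()].
#' @param conductances Drug-free [conductance_set()].
#' @return List of class `drug_run`: `candidates` (list of
#'   [beat_trace]), `state`, `failed`, `message`, `config`.
#' @export
run_drug <- function(steady, block, config = protocol_config(),
                     conductances = conductance_set()) {
  if (inherits(steady, "control_run")) steady <- steady$state
  g <- apply_block(conductances, block)
  res <- tryCatch(
    integrate_beat(steady, g, config_stim(config, config$drug_beats),
                   record = TRUE, record_last = config$candidate_window,
                   dt = config$dt, out_dt = config$output_sampling,
                   ikr = config$ikr),
    error = function(e) e)
  if (inherits(res, "error")) {
    return(structure(list(candidates = list(), state = NULL, failed = TRUE,
                          message = conditionMessage(res), config = config),
                     class = "drug_run"))
  }
  structure(list(candidates = res$traces, state = res$state, failed = FALSE,
                 message = NULL, config = config),
            class = "drug_run")
}

#' @export
print.drug_run <- function(x, ...) {
  if (x$failed) {
    cat("<drug_run> FAILED:", x$message, "\n")
  } else {
    cat(sprintf("<drug_run> %d candidate beats recorded\n",
                length(x$candidates)))
  }
  invisible(x)
}

#' Biomarkers of a drug run's selected beat
#'
#' Applies [select_beat()] to the candidate window and extracts the
#' biomarker set of the selected beat. A failed run yields `NA`
#' biomarkers with `failed = TRUE`.
#'
#' @param run A `drug_run`.
#' @inheritParams apd90
#' @return One-row data frame (see [biomarkers()]) plus `failed`.
#' @export
run_biomarkers <- function(run, ap_threshold = -30) {
  if (run$failed || !length(run$candidates)) {
    return(data.frame(apd90 = NA_real_, apd90_failure = NA,
                      cad90 = NA_real_, cad90_failure = NA,
                      qnet = NA_real_, dvdt_repol_max = NA_real_,
                      repol90_reached = NA, failed = TRUE))
  }
  bm <- biomarkers(select_beat(run$candidates, ap_threshold), ap_threshold)
  bm$failed <- FALSE
  bm
}

#' Export recorded beats as one long table
#'
#' Writes every candidate beat of a run as plain CSV with a `beat`
#' column followed by the trace series.
#'
#' @param run A `drug_run` or `control_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_beat_traces <- function(run, path) {
  beats <- if (inherits(run, "control_run")) list(run$trace) else run$candidates
  tab <- do.call(rbind, lapply(beats, function(b) {
    cbind(beat = attr(b, "beat"), as.data.frame(b))
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
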