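# Biomarker extraction from a beat trace.
#
# Repolarization percentages are measured relative to the beat's
# amplitude: x% repolarization means crossing
# peak - x/100 * (peak - minimum-of-beat). Crossings are located by
# linear interpolation between grid samples; "peak" is the absolute
# maximum of the series within the beat.

# first linear-interpolated downward crossing of `level` at/after index i0
first_crossing <- function(t, y, level, i0) {
  n <- length(y)
  if (i0 >= n) return(NA_real_)
  below <- which(y[(i0 + 1):n] < level)
  if (!length(below)) return(NA_real_)
  i <- i0 + below[1]            # first sample strictly below the level
  if (i == i0) return(t[i0])
  y0 <- y[i - 1]; y1 <- y[i]
  if (y0 <= level) return(t[i - 1])
  t[i - 1] + (t[i] - t[i - 1]) * (y0 - level) / (y0 - y1)
}

duration_to_90 <- function(t, y, what) {
  ipk <- which.max(y)
  ymax <- y[ipk]
  ymin <- min(y)
  if (ymax - ymin <= 0) stop("no ", what, " present: flat series")
  lvl <- ymax - 0.9 * (ymax - ymin)
  tc <- first_crossing(t, y, lvl, ipk)
  if (is.na(tc)) return(structure(NA_real_, failure = TRUE))
  structure(tc - t[ipk], failure = FALSE)
}

check_ap <- function(beat, ap_threshold) {
  if (max(beat$vm) < ap_threshold)
    stop("no beat: action-potential peak below ", ap_threshold, " mV")
}

#' Action potential duration at 90% repolarization
#'
#' Time from the action-potential peak to the first crossing of the 90%
#' repolarization level `Vpeak - 0.9 (Vpeak - Vmin)`, where `Vmin` is
#' the beat's minimum potential. The crossing is linearly interpolated;
#' if the potential never falls below the level the beat is flagged as
#' repolarization failure.
#'
#' @param beat A [beat_trace].
#' @param ap_threshold Minimum peak Vm (mV) for the beat to count as an
#'   elicited action potential.
#' @return Duration in ms, or `NA` with attribute `failure = TRUE` on
#'   repolarization failure.
#' @export
apd90 <- function(beat, ap_threshold = -30) {
  check_ap(beat, ap_threshold)
  duration_to_90(beat$time, beat$vm, "action potential")
}

#' Calcium transient duration at 90% recovery
#'
#' Analogue of [apd90()] on the intracellular calcium series: time from
#' the calcium peak to the interpolated crossing of
#' `Capeak - 0.9 (Capeak - Camin)`.
#'
#' @param beat A [beat_trace].
#' @return Duration in ms, or `NA` with attribute `failure = TRUE` if the
#'   transient never decays to the 90% level.
#' @export
cad90 <- function(beat) {
  duration_to_90(beat$time, beat$cai, "calcium transient")
}

#' Net charge of the six CiPA currents over one beat
#'
#' Trapezoidal integral of `IKr + ICaL + INaL + Ito + IKs + IK1` from
#' stimulus onset to the end of the beat, in uC/uF (numerically the
#' integral of uA/uF over seconds).
#'
#' @param beat A [beat_trace].
#' @return qNet in uC/uF.
#' @export
qnet <- function(beat) {
  inet <- beat$ikr + beat$ical + beat$inal + beat$ito + beat$iks + beat$ik1
  if (any(!is.finite(inet))) stop("non-finite current samples in beat trace")
  t <- beat$time
  sum(diff(t) * (inet[-1] + inet[-length(inet)]) / 2) / 1000
}

#' Steepest repolarization gradient of a beat
#'
#' Maximum centered-finite-difference `dVm/dt` within the repolarization
#' window: from the first 30% repolarization crossing after the peak to
#' the first 90% crossing. If the potential repolarizes past 30% but
#' never reaches 90%, the window extends to the end of the beat and the
#' `repol90_reached` flag is `FALSE`. A positive value signals a
#' depolarizing deflection (early afterdepolarization) inside the
#' window.
#'
#' @inheritParams apd90
#' @return List with `dvdt_max` (mV/ms) and `repol90_reached`.
#' @export
dvdt_repol <- function(beat, ap_threshold = -30) {
  check_ap(beat, ap_threshold)
  t <- beat$time; v <- beat$vm
  ipk <- which.max(v)
  vmax <- v[ipk]; vmin <- min(v)
  l30 <- vmax - 0.3 * (vmax - vmin)
  l90 <- vmax - 0.9 * (vmax - vmin)
  t30 <- first_crossing(t, v, l30, ipk)
  if (is.na(t30))
    return(list(dvdt_max = NA_real_, repol90_reached = FALSE))
  t90 <- first_crossing(t, v, l90, ipk)
  reached <- !is.na(t90)
  tend <- if (reached) t90 else t[length(t)]
  # centered differences on the output grid
  n <- length(t)
  dv <- (v[c(2:n, n)] - v[c(1, 1:(n - 1))]) / (t[c(2:n, n)] - t[c(1, 1:(n - 1))])
  win <- t >= t30 & t <= tend
  if (!any(win)) win <- seq_len(n) == max(which(t <= tend))
  list(dvdt_max = max(dv[win]), repol90_reached = reached)
}

#' Select the candidate beat with the steepest repolarization gradient
#'
#' Among candidate beats (the trailing window of a drug run) returns the
#' one maximizing [dvdt_repol()], i.e. the beat most prone to a
#' repolarization abnormality. Ties are broken in favour of the latest
#' beat, as the closest to limiting behaviour.
#'
#' @param candidates List of [beat_trace] objects, chronological order.
#' @inheritParams apd90
#' @return The selected [beat_trace].
#' @export
select_beat <- function(candidates, ap_threshold = -30) {
  if (!length(candidates)) stop("no candidate beats")
  slopes <- vapply(candidates, function(b)
    dvdt_repol(b, ap_threshold)$dvdt_max, numeric(1))
  if (all(is.na(slopes))) return(candidates[[length(candidates)]])
  best <- max(slopes, na.rm = TRUE)
  candidates[[max(which(slopes == best))]]
}

#' All biomarkers of one beat
#'
#' @inheritParams apd90
#' @return One-row data frame with `apd90`, `cad90`, `qnet`,
#'   `dvdt_repol_max`, `repol90_reached` and failure flags.
#' @export
biomarkers <- function(beat, ap_threshold = -30) {
  a <- apd90(beat, ap_threshold)
  ca <- cad90(beat)
  dv <- dvdt_repol(beat, ap_threshold)
  data.frame(apd90 = as.numeric(a),
             apd90_failure = isTRUE(attr(a, "failure")),
             cad90 = as.numeric(ca),
             cad90_failure = isTRUE(attr(ca, "failure")),
             qnet = qnet(beat),
             dvdt_repol_max = dv$dvdt_max,
             repol90_reached = dv$repol90_reached)
}
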