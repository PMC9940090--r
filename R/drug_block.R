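#' Hill conductance-block inhibition fraction
#'
#' Fraction of a channel's conductance blocked by a drug at
#' concentration `conc`: `E = 1 - 1/(1 + (D/IC50)^n)`. The blocked
#' channel keeps the fraction `1 - E` of its maximal conductance.
#' An infinite or missing (`NA`) IC50 encodes "no measurable block"
#' (`E = 0`).
#'
#' @param conc Drug concentration, nM (non-negative; vectorized).
#' @param ic50 Half-inhibitory concentration, nM (> 0, `Inf`/`NA` for no
#'   block).
#' @param hill Hill coefficient (> 0).
#' @return Inhibition fraction in `[0, 1)`.
#' @export
hill_inhibition <- function(conc, ic50, hill) {
  if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  n <- max(length(conc), length(ic50), length(hill))
  conc <- rep_len(conc, n); ic50 <- rep_len(ic50, n); hill <- rep_len(hill, n)
  e <- numeric(n)
  act <- !is.na(ic50) & is.finite(ic50)
  if (any(act)) {
    if (any(ic50[act] <= 0)) stop("IC50 must be positive")
    if (any(is.na(hill[act]) | hill[act] <= 0))
      stop("Hill coefficient must be positive")
    r <- (conc[act] / ic50[act])^hill[act]
    e[act] <- r / (1 + r)
  }
  e
}

check_fraction <- function(e, what) {
  if (any(!is.finite(e)) || any(e < 0) || any(e > 1))
    stop(what, " must lie in [0, 1]")
  invisible(e)
}

#' Allotopic (independent-site) combination of two block fractions
#'
#' Two drugs acting at independent sites block a channel with the union
#' probability of two independent events:
#' `E_AB = E_A + E_B - E_A * E_B` (Bliss-independence-like).
#'
#' @param ea,eb Single-drug inhibition fractions in `[0, 1]` (vectorized).
#' @return Combined inhibition fraction in `[max(ea, eb), 1]`.
#' @export
combine_allotopic <- function(ea, eb) {
  check_fraction(ea, "ea"); check_fraction(eb, "eb")
  ea + eb - ea * eb
}

#' Syntopic (shared-site) combination of two block fractions
#'
#' Two drugs competing for one binding site (while one is bound the
#' other cannot bind) combine as
#' `E_AB = (E_A + E_B - 2 E_A E_B) / (1 - E_A E_B)`
#' (Loewe-additivity-like). The removable singularity at
#' `E_A = E_B = 1` is continuously extended to 1.
#'
#' @inheritParams combine_allotopic
#' @return Combined inhibition fraction in `[max(ea, eb), 1]`; never
#'   exceeds [combine_allotopic()] on the same inputs.
#' @export
combine_syntopic <- function(ea, eb) {
  check_fraction(ea, "ea"); check_fraction(eb, "eb")
  n <- max(length(ea), length(eb))
  ea <- rep_len(ea, n); eb <- rep_len(eb, n)
  out <- numeric(n)
  sing <- ea * eb >= 1
  out[sing] <- 1
  out[!sing] <- (ea[!sing] + eb[!sing] - 2 * ea[!sing] * eb[!sing]) /
    (1 - ea[!sing] * eb[!sing])
  out
}

#' Per-channel block of one drug sample at a concentration
#'
#' Evaluates [hill_inhibition()] for each of the seven target channels
#' of one bootstrap (IC50, Hill) sample. Channels without measured
#' parameters get zero block.
#'
#' @param sample One row of a [drug_population] (or any list/row with
#'   `<ch>_IC50` / `<ch>_h` entries).
#' @param conc Drug concentration, nM.
#' @return A block vector: named inhibition fractions over
#'   [ord_channels()].
#' @export
sample_block <- function(sample, conc) {
  ch <- ord_channels()
  e <- vapply(ch, function(c0) {
    ic50 <- sample[[paste0(c0, "_IC50")]]
    h <- sample[[paste0(c0, "_h")]]
    if (is.null(ic50) || length(ic50) != 1 || is.na(ic50)) return(0)
    hill_inhibition(conc, ic50, h)
  }, numeric(1))
  setNames(e, ch)
}

check_block <- function(block) {
  ch <- ord_channels()
  if (is.null(names(block)) || !all(names(block) %in% ch))
    stop("block vector must be named with channels: ",
         paste(ch, collapse = ", "))
  full <- setNames(numeric(length(ch)), ch)
  full[names(block)] <- block
  check_fraction(full, "block fractions")
  full
}

#' Combined two-drug block vector
#'
#' Evaluates each drug's Hill inhibition per channel at its own
#' concentration and combines them with the chosen drug-drug interaction
#' model. A channel measured for only one of the two drugs keeps that
#' drug's single effect (the other contributes `E = 0`, under which both
#' combiners reduce to the single-drug block).
#'
#' @param sampleA,sampleB One (IC50, Hill) sample per drug (rows of
#'   [drug_population] objects).
#' @param concA,concB Concentrations, nM.
#' @param model `"allotopic"` or `"syntopic"`.
#' @return Named block vector over [ord_channels()].
#' @export
combined_block <- function(sampleA, concA, sampleB, concB,
                           model = c("allotopic", "syntopic")) {
  model <- match.arg(model)
  ea <- sample_block(sampleA, concA)
  eb <- sample_block(sampleB, concB)
  comb <- if (model == "allotopic") combine_allotopic else combine_syntopic
  setNames(comb(ea, eb), ord_channels())
}

#' Apply a block vector to a conductance set
#'
#' Scales each targeted channel's maximal conductance by `1 - E`;
#' blocking `CaL` scales the shared L-type permeability (ICaL, ICaNa and
#' ICaK together). All other conductances are unchanged.
#'
#' @param base A [conductance_set()].
#' @param block Named block vector (inhibition fractions over
#'   [ord_channels()], possibly partial).
#' @return A new `conductance_set`.
#' @export
apply_block <- function(base, block) {
  block <- check_block(block)
  g <- unclass(base)
  idx <- channel_conductance[names(block)]
  g[idx] <- g[idx] * (1 - block)
  structure(g, class = "conductance_set")
}
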