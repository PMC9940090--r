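# Drug-sample populations: bootstrap (IC50, Hill) draws per drug.
#
# Table layout (one row per sample): a `sample` column (0-based dense
# ids) and, for each measured channel `<ch>` in ord_channels(), a pair
# of columns `<ch>_IC50` (nM) and `<ch>_h` (Hill coefficient). Channels
# without columns, or with NA entries, carry no measurable block. The
# same layout is used on disk (plain CSV, see read_drug_csv), with an
# optional leading `drug` column.

population_columns <- function() {
  ch <- ord_channels()
  as.vector(rbind(paste0(ch, "_IC50"), paste0(ch, "_h")))
}

#' Construct and validate a drug-sample population
#'
#' @param name Drug name.
#' @param cmax Maximum therapeutic concentration, nM (> 0).
#' @param samples Data frame with a `sample` column and per-channel
#'   `<ch>_IC50` / `<ch>_h` columns (missing columns are filled with
#'   `NA` = no block).
#' @return Data frame of class `drug_population` with attributes
#'   `drug_name` and `cmax`; sample ids are dense `0..N-1`.
#' @export
drug_population <- function(name, cmax, samples) {
  if (!is.numeric(cmax) || length(cmax) != 1 || !is.finite(cmax) || cmax <= 0)
    stop("cmax must be a single positive number (nM)")
  samples <- as.data.frame(samples)
  if (!nrow(samples)) stop("a drug population must contain at least one sample")
  for (col in population_columns())
    if (is.null(samples[[col]])) samples[[col]] <- NA_real_
  samples$sample <- seq_len(nrow(samples)) - 1L
  samples <- samples[c("sample", population_columns())]
  bad <- character(0)
  for (ch in ord_channels()) {
    ic <- samples[[paste0(ch, "_IC50")]]
    h <- samples[[paste0(ch, "_h")]]
    measured <- !is.na(ic)
    if (any(!is.na(h) & !measured))
      bad <- c(bad, sprintf("%s: Hill without IC50 in rows %s", ch,
                            paste(which(!is.na(h) & !measured), collapse = ",")))
    off <- measured & (ic <= 0 | is.na(h) | h <= 0)
    if (any(off))
      bad <- c(bad, sprintf("%s: non-positive IC50/Hill in rows %s", ch,
                            paste(which(off), collapse = ",")))
  }
  if (length(bad))
    stop("invalid dose-response parameters:\n  ", paste(bad, collapse = "\n  "))
  structure(samples, drug_name = as.character(name), cmax = cmax,
            class = c("drug_population", "data.frame"))
}

#' @export
print.drug_population <- function(x, ...) {
  measured <- vapply(ord_channels(), function(ch)
    any(!is.na(x[[paste0(ch, "_IC50")]])), logical(1))
  cat(sprintf("<drug_population> %s: %d samples, cmax %g nM, channels: %s\n",
              attr(x, "drug_name"), nrow(x),
              attr(x, "cmax"),
              paste(ord_channels()[measured], collapse = ", ")))
  invisible(x)
}

#' Read a per-drug (IC50, Hill) sample CSV
#'
#' Reads the per-sample bootstrap layout documented above. Channel
#' columns may use other tags (e.g. the FDA CiPA naming) via
#' `channel_map`.
#'
#' @param path CSV path.
#' @param cmax Maximum therapeutic concentration, nM (not stored in the
#'   file).
#' @param name Drug name; default taken from a `drug` column or the file
#'   name.
#' @param channel_map Optional named character vector translating file
#'   column tags to [ord_channels()] tags, e.g.
#'   `c(hERG = "Kr")` maps `hERG_IC50`/`hERG_h` columns.
#' @return A [drug_population].
#' @export
read_drug_csv <- function(path, cmax, name = NULL, channel_map = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty drug sample file: ", path)
  if (!is.null(channel_map)) {
    for (from in names(channel_map)) {
      to <- channel_map[[from]]
      names(tab)[names(tab) == paste0(from, "_IC50")] <- paste0(to, "_IC50")
      names(tab)[names(tab) == paste0(from, "_h")] <- paste0(to, "_h")
    }
  }
  if (is.null(name)) {
    name <- if (!is.null(tab$drug)) as.character(tab$drug[1]) else
      sub("\\.csv$", "", basename(path))
  }
  known <- c("drug", "sample", population_columns())
  for (col in setdiff(names(tab), known))
    warning("ignoring unrecognized column: ", col)
  num_cols <- intersect(population_columns(), names(tab))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(v) & !is.na(tab[[col]]) & tab[[col]] != ""))
      stop("malformed numeric in column ", col, " of ", path)
    tab[[col]] <- v
  }
  drug_population(name, cmax, tab[setdiff(names(tab), "drug")])
}

#' Write a drug population to CSV
#'
#' Inverse of [read_drug_csv()]: values round-trip exactly (full double
#' precision).
#'
#' @param pop A [drug_population].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_csv <- function(pop, path) {
  tab <- cbind(drug = attr(pop, "drug_name"), as.data.frame(pop))
  # keep full precision so read-back reproduces values exactly
  for (col in population_columns())
    tab[[col]] <- sprintf("%.17g", tab[[col]])
  tab[tab == "nan" | tab == "NA"] <- NA
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Synthesize a bootstrap-like drug-sample population
#'
#' Emulates the statistical shape of the MCMC-bootstrap (IC50, Hill)
#' samples used in CiPA assessments: per channel, IC50 is drawn
#' log-normally around its nominal value and the Hill coefficient
#' normally (truncated positive) around its nominal value. The default
#' spreads mimic a well-constrained patch-clamp fit; `spread = 0`
#' reproduces the nominal drug exactly in every sample.
#'
#' @param name Drug name.
#' @param cmax Maximum therapeutic concentration, nM.
#' @param nominal Named list over (a subset of) [ord_channels()]; each
#'   element `c(ic50 = , h = )` in nM / dimensionless.
#' @param n_samples Population size (the CiPA datasets use 100).
#' @param spread Log-scale standard deviation of IC50 draws.
#' @param hill_spread Standard deviation of Hill draws (absolute).
#' @param seed Optional integer seed (local to this call).
#' @return A [drug_population].
#' @export
synthesize_population <- function(name, cmax, nominal, n_samples = 100,
                                  spread = 0.2, hill_spread = 0.1,
                                  seed = NULL) {
  if (n_samples < 1 || n_samples != round(n_samples))
    stop("n_samples must be a positive integer")
  if (spread < 0 || hill_spread < 0) stop("spreads must be >= 0")
  if (!length(nominal) || is.null(names(nominal)) ||
      !all(names(nominal) %in% ord_channels()))
    stop("nominal must be a named list over channels ",
         paste(ord_channels(), collapse = ", "))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  samples <- data.frame(sample = seq_len(n_samples) - 1L)
  for (ch in names(nominal)) {
    par <- nominal[[ch]]
    if (is.na(par["ic50"]) || par["ic50"] <= 0 || is.na(par["h"]) || par["h"] <= 0)
      stop("invalid nominal parameters for channel ", ch)
    ic <- rlnorm(n_samples, meanlog = log(par[["ic50"]]), sdlog = spread)
    h <- rnorm(n_samples, mean = par[["h"]], sd = hill_spread)
    h <- pmax(h, 0.05)  # truncate positive
    samples[[paste0(ch, "_IC50")]] <- ic
    samples[[paste0(ch, "_h")]] <- h
  }
  drug_population(name, cmax, samples)
}

#' Bundled synthetic three-drug panel
#'
#' Three synthetic drugs spanning the qualitative channel profiles seen
#' across the CiPA reference drugs (all parameter values are synthetic,
#' not measurements):
#' * `synthA_herg` - potent, selective hERG blocker
#'   (high-risk-like profile),
#' * `synthB_multi` - balanced multichannel blocker (hERG + CaL + NaL,
#'   intermediate-risk-like),
#' * `synthC_cal` - predominantly L-type calcium blocker with weak hERG
#'   affinity (low-risk-like).
#'
#' @param n_samples Samples per drug.
#' @param seed Integer seed for the bootstrap-like spread.
#' @param spread,hill_spread Passed to [synthesize_population()].
#' @return Named list of three [drug_population] objects.
#' @export
synthetic_panel <- function(n_samples = 100, seed = 20260927,
                            spread = 0.2, hill_spread = 0.1) {
  list(
    synthA_herg = synthesize_population(
      "synthA_herg", cmax = 2,
      nominal = list(Kr = c(ic50 = 1.2, h = 0.9)),
      n_samples = n_samples, spread = spread, hill_spread = hill_spread,
      seed = seed),
    synthB_multi = synthesize_population(
      "synthB_multi", cmax = 100,
      nominal = list(Kr = c(ic50 = 350, h = 0.8),
                     CaL = c(ic50 = 600, h = 1.1),
                     NaL = c(ic50 = 1500, h = 1.0)),
      n_samples = n_samples, spread = spread, hill_spread = hill_spread,
      seed = seed + 1),
    synthC_cal = synthesize_population(
      "synthC_cal", cmax = 120,
      nominal = list(CaL = c(ic50 = 250, h = 1.0),
                     Kr = c(ic50 = 12000, h = 0.9),
                     Na = c(ic50 = 30000, h = 1.0)),
      n_samples = n_samples, spread = spread, hill_spread = hill_spread,
      seed = seed + 2)
  )
}
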