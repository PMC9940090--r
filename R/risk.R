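#' qNet risk thresholds
#'
#' The two qNet thresholds separating low, intermediate and high torsade
#' risk (from the ordinal-regression calibration of the CiPA training
#' drugs; configuration constants here).
#'
#' @param threshold1 Upper threshold, uC/uF (low risk above).
#' @param threshold2 Lower threshold, uC/uF (high risk below).
#' @return List of class `risk_thresholds`.
#' @export
risk_thresholds <- function(threshold1 = 0.0652, threshold2 = 0.0516) {
  if (!(threshold2 < threshold1))
    stop("threshold2 must be below threshold1")
  structure(list(threshold1 = threshold1, threshold2 = threshold2),
            class = "risk_thresholds")
}

risk_levels <- function() c("low", "intermediate", "high", "unclassifiable")

#' Classify qNet into a torsade-risk class
#'
#' `qnet > threshold1` is low risk, `threshold2 < qnet <= threshold1`
#' intermediate, `qnet <= threshold2` high. A non-finite qNet (failed
#' run) is unclassifiable. Vectorized; monotone: a higher qNet never
#' maps to a higher-risk class.
#'
#' @param q qNet value(s), uC/uF.
#' @param th A [risk_thresholds()].
#' @return Factor with levels low, intermediate, high, unclassifiable.
#' @export
classify_qnet <- function(q, th = risk_thresholds()) {
  out <- ifelse(!is.finite(q), "unclassifiable",
         ifelse(q > th$threshold1, "low",
         ifelse(q > th$threshold2, "intermediate", "high")))
  factor(out, levels = risk_levels())
}

#' Number of unique unordered drug pairs
#'
#' `n (n - 1) / 2`, excluding same-drug pairs.
#'
#' @param n_drugs Number of drugs (>= 0).
#' @return Integer pair count.
#' @export
count_unique_combinations <- function(n_drugs) {
  if (length(n_drugs) != 1 || is.na(n_drugs) || n_drugs < 0 ||
      n_drugs != round(n_drugs))
    stop("n_drugs must be a non-negative integer")
  as.integer(n_drugs * (n_drugs - 1) / 2)
}

# shared simulation context: control steady state + protocol settings
new_sim_context <- function(steady, config, conductances, thresholds,
                            cache = NULL) {
  list(steady = if (inherits(steady, "control_run")) steady$state else steady,
       config = config, conductances = conductances,
       thresholds = thresholds,
       cache = if (is.null(cache)) new.env(parent = emptyenv()) else cache)
}

#' Simulation result cache
#'
#' An empty cache that [build_combination_map()] and
#' [tdp_metric_single()] can share, so identical block vectors (e.g. the
#' transposed map of a swapped drug pair, or the single-drug rows of
#' several maps against the same drug) are simulated once.
#'
#' @return An environment keyed by block vector.
#' @export
qnet_cache <- function() new.env(parent = emptyenv())

# selected-beat biomarkers for one block vector, cached on the block
cached_block_qnet <- function(ctx, block) {
  key <- paste(signif(block, 12), collapse = "|")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  run <- run_drug(ctx$steady, block, ctx$config, ctx$conductances)
  bm <- run_biomarkers(run)
  val <- list(qnet = bm$qnet, failed = bm$failed, biomarkers = bm)
  assign(key, val, envir = ctx$cache)
  val
}

#' Single-drug TdP metric: mean qNet over 1-4x cmax
#'
#' For each bootstrap sample of a drug, simulates the single-drug
#' protocol at 1, 2, 3 and 4 times cmax and averages the four qNet
#' values; the per-sample distribution of this average is the
#' single-drug torsade metric, and its classification gives the drug's
#' prior risk label. A sample whose run fails at any concentration is
#' unclassifiable.
#'
#' @param pop A [drug_population].
#' @param steady Control steady state ([run_control()] result or state).
#' @param config A [protocol_config()].
#' @param conductances Drug-free [conductance_set()].
#' @param thresholds A [risk_thresholds()].
#' @param multiples Concentration multiples averaged over (default 1:4).
#' @param cache Optional shared [qnet_cache()].
#' @return Data frame: `sample`, `qnet_mean`, `class`, `failed`.
#' @export
tdp_metric_single <- function(pop, steady, config = protocol_config(),
                              conductances = conductance_set(),
                              thresholds = risk_thresholds(),
                              multiples = 1:4, cache = NULL) {
  if (!nrow(pop)) stop("population is empty")
  ctx <- new_sim_context(steady, config, conductances, thresholds, cache)
  cmax <- attr(pop, "cmax")
  res <- lapply(seq_len(nrow(pop)), function(i) {
    qs <- vapply(multiples, function(m) {
      r <- cached_block_qnet(ctx, sample_block(pop[i, ], m * cmax))
      if (r$failed) NA_real_ else r$qnet
    }, numeric(1))
    data.frame(sample = pop$sample[i], qnet_mean = mean(qs),
               failed = any(is.na(qs)))
  })
  out <- do.call(rbind, res)
  out$class <- classify_qnet(ifelse(out$failed, NA_real_, out$qnet_mean),
                             thresholds)
  out[c("sample", "qnet_mean", "class", "failed")]
}

#' Drug-combination risk map for one pair
#'
#' For every concentration pair on the `multiples x multiples` grid
#' (default 0-4x each drug's cmax) and every paired bootstrap sample,
#' combines the two drugs' channel block with the chosen interaction
#' model, paces the model from the control steady state, extracts the
#' selected beat's qNet and classifies it. The 0 row/column reproduce
#' single-drug effects and the (0,0) cell the drug-free control.
#'
#' @param popA,popB [drug_population]s of equal size; sample `i` of A is
#'   paired with sample `i` of B.
#' @param model `"allotopic"` or `"syntopic"`.
#' @param steady Control steady state.
#' @param config A [protocol_config()].
#' @param conductances Drug-free [conductance_set()].
#' @param thresholds A [risk_thresholds()].
#' @param multiples Integer concentration multiples of cmax (default 0:4).
#' @param cache Optional shared [qnet_cache()].
#' @return Object of class `combination_map`: count matrices `n_low`,
#'   `n_int`, `n_high`, `n_failed` (rows = drug A multiple, columns =
#'   drug B multiple), the per-cell-per-sample `qnet` array, a long
#'   `biomarkers` table (one row per drug pair, concentration pair and
#'   sample with all selected-beat biomarkers, ready for `write.csv()`),
#'   and run metadata.
#' @export
build_combination_map <- function(popA, popB,
                                  model = c("allotopic", "syntopic"),
                                  steady, config = protocol_config(),
                                  conductances = conductance_set(),
                                  thresholds = risk_thresholds(),
                                  multiples = 0:4, cache = NULL) {
  model <- match.arg(model)
  if (nrow(popA) != nrow(popB))
    stop("populations must have the same size (paired samples)")
  if (any(multiples < 0) || any(multiples != round(multiples)))
    stop("multiples must be non-negative integers")
  ns <- nrow(popA)
  nm <- length(multiples)
  ctx <- new_sim_context(steady, config, conductances, thresholds, cache)
  cmaxA <- attr(popA, "cmax"); cmaxB <- attr(popB, "cmax")
  qnets <- array(NA_real_, dim = c(nm, nm, ns),
                 dimnames = list(multA = multiples, multB = multiples,
                                 sample = popA$sample))
  bmrows <- vector("list", nm * nm * ns)
  for (ia in seq_len(nm)) for (ib in seq_len(nm)) for (s in seq_len(ns)) {
    blk <- combined_block(popA[s, ], multiples[ia] * cmaxA,
                          popB[s, ], multiples[ib] * cmaxB, model)
    r <- cached_block_qnet(ctx, blk)
    qnets[ia, ib, s] <- if (r$failed) NA_real_ else r$qnet
    bmrows[[((ia - 1) * nm + (ib - 1)) * ns + s]] <- cbind(
      data.frame(drugA = attr(popA, "drug_name"),
                 drugB = attr(popB, "drug_name"), model = model,
                 multA = multiples[ia], multB = multiples[ib],
                 concA = multiples[ia] * cmaxA, concB = multiples[ib] * cmaxB,
                 sample = popA$sample[s]),
      r$biomarkers)
  }
  biomarker_table <- do.call(rbind, bmrows)
  cls <- array(as.character(classify_qnet(as.vector(qnets), thresholds)),
               dim = dim(qnets))
  count <- function(lvl) apply(cls == lvl, c(1, 2), sum)
  mk <- function(m) matrix(m, nm, nm, dimnames = dimnames(qnets)[1:2])
  structure(list(drugA = attr(popA, "drug_name"),
                 drugB = attr(popB, "drug_name"),
                 model = model, multiples = multiples,
                 n_samples = ns,
                 n_low = mk(count("low")), n_int = mk(count("intermediate")),
                 n_high = mk(count("high")),
                 n_failed = mk(apply(is.na(qnets), c(1, 2), sum)),
                 qnet = qnets, biomarkers = biomarker_table,
                 thresholds = thresholds,
                 profile = attr(config, "profile")),
            class = "combination_map")
}

#' @export
print.combination_map <- function(x, ...) {
  cat(sprintf("<combination_map> %s x %s (%s model), %d samples, grid %s\n",
              x$drugA, x$drugB, x$model, x$n_samples,
              paste(range(x$multiples), collapse = "-")))
  cat("high-risk counts (rows = ", x$drugA, " multiple):\n", sep = "")
  print(x$n_high)
  invisible(x)
}

#' Long-format table of a combination map
#'
#' @param x A `combination_map`.
#' @param ... Unused.
#' @return Data frame: drugA, drugB, model, multA, multB, n_low, n_int,
#'   n_high, n_failed.
#' @export
as.data.frame.combination_map <- function(x, ...) {
  grid <- expand.grid(multA = x$multiples, multB = x$multiples)
  data.frame(drugA = x$drugA, drugB = x$drugB, model = x$model,
             multA = grid$multA, multB = grid$multB,
             n_low = as.vector(x$n_low), n_int = as.vector(x$n_int),
             n_high = as.vector(x$n_high),
             n_failed = as.vector(x$n_failed))
}

#' Render a combination map as per-class heat maps
#'
#' One panel per predicted class, shaded 0-100% (black = no sample in
#' that class at that concentration pair, white = all samples).
#'
#' @param x A `combination_map`.
#' @param ... Unused.
#' @export
plot.combination_map <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(par(op))
  panels <- list(low = x$n_low, intermediate = x$n_int, high = x$n_high)
  for (nm in names(panels)) {
    frac <- panels[[nm]] / x$n_samples   # rows = drug A multiple = x-axis
    image(x = x$multiples, y = x$multiples, z = frac,
          zlim = c(0, 1), col = gray(seq(0, 1, length.out = 64)),
          xlab = paste0(x$drugA, " (x cmax)"),
          ylab = paste0(x$drugB, " (x cmax)"),
          main = paste0(nm, " (", x$model, ")"))
  }
  invisible(x)
}

#' Tally predicted classes by prior-risk pair
#'
#' Aggregates, per unordered pair of prior single-drug risk labels
#' (e.g. high-high, high-low), the predicted per-sample class counts
#' over all supplied maps. Zero-concentration rows and columns are
#' excluded: those cells are single-drug (or control) effects, not
#' combinations.
#'
#' @param maps List of `combination_map` objects.
#' @param labels Named character vector of prior risk labels
#'   (`"low"`/`"intermediate"`/`"high"`) for every drug appearing in the
#'   maps.
#' @return Data frame: `pair` (e.g. `"high-low"`), `predicted`, `n`.
#' @export
summarize_risk_pairs <- function(maps, labels) {
  if (inherits(maps, "combination_map")) maps <- list(maps)
  lv <- c("low", "intermediate", "high")
  tal <- list()
  for (m in maps) {
    lab <- function(nm) {
      i <- match(nm, names(labels))
      if (is.na(i)) stop("missing prior risk label for drug ", nm)
      as.character(labels[[i]])
    }
    la <- lab(m$drugA); lb <- lab(m$drugB)
    pair <- paste(sort(factor(c(la, lb), levels = lv)), collapse = "-")
    keep <- m$multiples > 0
    for (cls in c("low", "int", "high", "failed")) {
      cnt <- m[[paste0("n_", cls)]][keep, keep, drop = FALSE]
      key <- paste(pair, cls)
      tal[[key]] <- (if (is.null(tal[[key]])) 0 else tal[[key]]) + sum(cnt)
    }
  }
  keys <- strsplit(names(tal), " ")
  out <- data.frame(pair = vapply(keys, `[`, "", 1),
                    predicted = vapply(keys, `[`, "", 2),
                    n = unlist(tal, use.names = FALSE))
  out$predicted <- c(low = "low", int = "intermediate", high = "high",
                     failed = "failed")[out$predicted]
  rownames(out) <- NULL
  out
}
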