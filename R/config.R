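# Run configuration and command-style entry points. Every command
# writes, next to its outputs, the exact configuration, package version
# and seed needed to reproduce the run.

#' Run configuration
#'
#' A fully serializable description of one assessment run: protocol
#' settings (or a named profile), interaction model, thresholds, drug
#' inputs (CSV paths with cmax, or synthetic-drug specifications),
#' concentration multiples, seed and output directory.
#'
#' @param outdir Output directory (created on demand).
#' @param profile Protocol profile name (see [protocol_profile()]).
#' @param protocol Named list of [protocol_config()] overrides.
#' @param model Interaction model, `"allotopic"` or `"syntopic"`.
#' @param thresholds Named list `threshold1`/`threshold2` (uC/uF).
#' @param multiples Concentration multiples of cmax.
#' @param drugs List of drug inputs; each element either
#'   `list(csv = path, cmax = , name = )` or
#'   `list(synthetic = list(name =, cmax =, nominal =, n_samples =,
#'   spread =, hill_spread = ))`.
#' @param seed Integer seed for synthetic-population draws.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir = "cipaddi-run", profile = "paper",
                       protocol = list(), model = "allotopic",
                       thresholds = list(), multiples = 0:4,
                       drugs = list(), seed = 1L) {
  cfg <- structure(list(outdir = outdir, profile = profile,
                        protocol = protocol, model = model,
                        thresholds = thresholds, multiples = multiples,
                        drugs = drugs, seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  problems <- character(0)
  if (!cfg$model %in% c("allotopic", "syntopic"))
    problems <- c(problems, paste("unknown interaction model:", cfg$model))
  pc <- tryCatch(config_protocol(cfg), error = conditionMessage)
  if (is.character(pc)) problems <- c(problems, pc)
  th <- tryCatch(config_thresholds(cfg), error = conditionMessage)
  if (is.character(th)) problems <- c(problems, th)
  if (any(cfg$multiples < 0) || any(cfg$multiples != round(cfg$multiples)))
    problems <- c(problems, "multiples must be non-negative integers")
  if (length(problems))
    stop("invalid run configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(cfg)
}

config_protocol <- function(cfg) {
  do.call(protocol_profile, c(list(name = cfg$profile), cfg$protocol))
}

config_thresholds <- function(cfg) {
  do.call(risk_thresholds, cfg$thresholds)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [run_config()] for `read_run_config`; `path` invisibly for
#'   `write_run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg A [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_drugs <- function(cfg) {
  if (!length(cfg$drugs)) stop("no drugs configured")
  pops <- lapply(seq_along(cfg$drugs), function(i) {
    d <- cfg$drugs[[i]]
    if (!is.null(d$csv)) {
      read_drug_csv(d$csv, cmax = d$cmax, name = d$name,
                    channel_map = unlist(d$channel_map))
    } else if (!is.null(d$synthetic)) {
      s <- d$synthetic
      nominal <- lapply(s$nominal, function(p)
        c(ic50 = as.numeric(p[["ic50"]]), h = as.numeric(p[["h"]])))
      synthesize_population(s$name, s$cmax, nominal,
                            n_samples = s$n_samples %||% 100,
                            spread = s$spread %||% 0.2,
                            hill_spread = s$hill_spread %||% 0.1,
                            seed = cfg$seed + i)
    } else stop("drug entry ", i, " has neither $csv nor $synthetic")
  })
  names(pops) <- vapply(pops, attr, "", "drug_name")
  pops
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stamp_run <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(cfg, file.path(dir, "config.yaml"))
  writeLines(c(paste("cipaddi version:", as.character(packageVersion("cipaddi"))),
               paste("seed:", cfg$seed),
               paste("profile:", cfg$profile)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' Drug-free control run command
#'
#' Validates the configuration, runs the drug-free protocol, and writes
#' the control beat trace and biomarker report (CSV) plus provenance
#' into the output directory.
#'
#' @param cfg A [run_config()].
#' @return The [run_control()] result, invisibly.
#' @export
cmd_control <- function(cfg) {
  validate_run_config(cfg)
  pc <- config_protocol(cfg)
  ctrl <- run_control(pc)
  dir <- stamp_run(cfg, file.path(cfg$outdir, "control"))
  write_beat_traces(ctrl, file.path(dir, "control_beat.csv"))
  bm <- biomarkers(ctrl$trace)
  bm$beats_run <- ctrl$beats_run
  bm$converged <- ctrl$converged
  write.csv(bm, file.path(dir, "control_biomarkers.csv"), row.names = FALSE)
  message(sprintf("control: qNet %.4f uC/uF, APD90 %.1f ms (%d beats)",
                  ctrl$qnet, ctrl$apd90, ctrl$beats_run))
  invisible(ctrl)
}

map_cell_file <- function(dir, model, ma, mb) {
  file.path(dir, sprintf("cell_%s_%dx%d.csv", model, ma, mb))
}

#' Combination-map command for one drug pair
#'
#' Orchestrates the population-by-grid runs for the first two configured
#' drugs and writes the long-format map plus per-sample qNet tables.
#' Completed cells found in the output directory are skipped, so an
#' interrupted run resumes where it stopped.
#'
#' @param cfg A [run_config()] with at least two drugs.
#' @return The [build_combination_map()] result, invisibly.
#' @export
cmd_pair <- function(cfg) {
  validate_run_config(cfg)
  pops <- config_drugs(cfg)
  if (length(pops) < 2) stop("cmd_pair needs two configured drugs")
  popA <- pops[[1]]; popB <- pops[[2]]
  pc <- config_protocol(cfg)
  th <- config_thresholds(cfg)
  dir <- stamp_run(cfg, file.path(cfg$outdir, paste0(
    "pair_", attr(popA, "drug_name"), "_", attr(popB, "drug_name"))))
  ctrl <- run_control(pc)
  ctx <- new_sim_context(ctrl, pc, conductance_set(), th)
  cmaxA <- attr(popA, "cmax"); cmaxB <- attr(popB, "cmax")
  nm <- length(cfg$multiples)
  qnets <- array(NA_real_, dim = c(nm, nm, nrow(popA)),
                 dimnames = list(multA = cfg$multiples, multB = cfg$multiples,
                                 sample = popA$sample))
  for (ia in seq_len(nm)) for (ib in seq_len(nm)) {
    f <- map_cell_file(dir, cfg$model, cfg$multiples[ia], cfg$multiples[ib])
    if (file.exists(f)) {  # cell-level resume
      done <- read.csv(f)
      qnets[ia, ib, ] <- done$qnet
      next
    }
    for (s in seq_len(nrow(popA))) {
      blk <- combined_block(popA[s, ], cfg$multiples[ia] * cmaxA,
                            popB[s, ], cfg$multiples[ib] * cmaxB, cfg$model)
      r <- cached_block_qnet(ctx, blk)
      qnets[ia, ib, s] <- if (r$failed) NA_real_ else r$qnet
    }
    write.csv(data.frame(sample = popA$sample, qnet = qnets[ia, ib, ]),
              f, row.names = FALSE)
  }
  map <- qnet_array_to_map(qnets, popA, popB, cfg$model, th,
                           attr(pc, "profile"))
  write.csv(as.data.frame(map), file.path(dir, "map.csv"), row.names = FALSE)
  invisible(map)
}

# assemble a combination_map from a precomputed qNet array
qnet_array_to_map <- function(qnets, popA, popB, model, thresholds, profile) {
  nm <- dim(qnets)[1]
  cls <- array(as.character(classify_qnet(as.vector(qnets), thresholds)),
               dim = dim(qnets))
  mk <- function(m) matrix(m, nm, nm, dimnames = dimnames(qnets)[1:2])
  structure(list(drugA = attr(popA, "drug_name"),
                 drugB = attr(popB, "drug_name"),
                 model = model,
                 multiples = as.integer(dimnames(qnets)$multA),
                 n_samples = dim(qnets)[3],
                 n_low = mk(apply(cls == "low", c(1, 2), sum)),
                 n_int = mk(apply(cls == "intermediate", c(1, 2), sum)),
                 n_high = mk(apply(cls == "high", c(1, 2), sum)),
                 n_failed = mk(apply(is.na(qnets), c(1, 2), sum)),
                 qnet = qnets, biomarkers = NULL,
                 thresholds = thresholds, profile = profile),
            class = "combination_map")
}

#' All-pairs panel command
#'
#' Enumerates every unique pair of the configured drugs
#' ([count_unique_combinations()] of them), builds each combination
#' map, labels each drug by its single-drug TdP metric, and writes the
#' per-pair maps plus the prior-risk-pair tally. `shard`/`n_shards`
#' restrict the run to every `n_shards`-th pair for simple cluster
#' sharding.
#'
#' @param cfg A [run_config()].
#' @param shard,n_shards 1-based shard index and shard count.
#' @return List with `maps`, `labels` and `tally`, invisibly.
#' @export
cmd_panel <- function(cfg, shard = 1L, n_shards = 1L) {
  validate_run_config(cfg)
  pops <- config_drugs(cfg)
  pc <- config_protocol(cfg)
  th <- config_thresholds(cfg)
  dir <- stamp_run(cfg, file.path(cfg$outdir, "panel"))
  ctrl <- run_control(pc)
  labels <- vapply(pops, function(p) {
    met <- tdp_metric_single(p, ctrl, pc, thresholds = th)
    cls <- table(droplevels(met$class[met$class != "unclassifiable"]))
    names(which.max(cls))
  }, "")
  pairs <- utils::combn(length(pops), 2)
  stopifnot(ncol(pairs) == count_unique_combinations(length(pops)))
  keep <- seq_len(ncol(pairs)) %% n_shards == shard %% n_shards
  maps <- list()
  for (k in which(keep)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    map <- build_combination_map(pops[[i]], pops[[j]], cfg$model, ctrl,
                                 pc, thresholds = th,
                                 multiples = cfg$multiples)
    write.csv(as.data.frame(map),
              file.path(dir, sprintf("map_%s_%s.csv", map$drugA, map$drugB)),
              row.names = FALSE)
    maps[[length(maps) + 1]] <- map
  }
  tally <- summarize_risk_pairs(maps, labels)
  write.csv(tally, file.path(dir, "risk_pair_tally.csv"), row.names = FALSE)
  invisible(list(maps = maps, labels = labels, tally = tally))
}

#' Write a synthetic drug population command
#'
#' Synthesizes the configured drugs and writes each as a per-sample CSV.
#'
#' @param cfg A [run_config()] whose drugs are synthetic specs.
#' @return Paths of the written CSVs, invisibly.
#' @export
cmd_synth_drug <- function(cfg) {
  validate_run_config(cfg)
  pops <- config_drugs(cfg)
  dir <- stamp_run(cfg, file.path(cfg$outdir, "drugs"))
  paths <- vapply(pops, function(p) {
    f <- file.path(dir, paste0(attr(p, "drug_name"), ".csv"))
    write_drug_csv(p, f)
    f
  }, "")
  invisible(paths)
}
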