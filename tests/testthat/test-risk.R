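test_that("qNet classification follows the two thresholds monotonically", {
  th <- risk_thresholds()   # 0.0652 / 0.0516 uC/uF
  expect_identical(as.character(classify_qnet(0.072, th)), "low")
  expect_identical(as.character(classify_qnet(0.060, th)), "intermediate")
  expect_identical(as.character(classify_qnet(0.050, th)), "high")
  expect_identical(as.character(classify_qnet(NA_real_, th)), "unclassifiable")
  q <- sort(runif(100, 0, 0.12))
  sev <- c(low = 1, intermediate = 2, high = 3)
  r <- sev[as.character(classify_qnet(q, th))]
  expect_true(all(diff(r) <= 0))  # higher qNet never raises the risk class
  expect_error(risk_thresholds(0.05, 0.06), "below")
})

test_that("unique pair counting excludes the same-drug diagonal", {
  expect_identical(count_unique_combinations(12), 66L)
  expect_identical(count_unique_combinations(2), 1L)
  expect_identical(count_unique_combinations(1), 0L)
  expect_identical(count_unique_combinations(0), 0L)
  expect_error(count_unique_combinations(-2), "non-negative")
})

test_that("a block-free drug's TdP metric equals the control qNet", {
  ctrl <- cached_test_control()
  met <- tdp_metric_single(no_block_pop(3), ctrl, test_profile())
  expect_identical(nrow(met), 3L)
  expect_false(any(met$failed))
  # all four concentrations and all samples collapse to the same
  # drug-free run; the metric sits at the (continued) control qNet
  expect_lt(stats::sd(met$qnet_mean), 1e-12)
  expect_lt(abs(met$qnet_mean[1] - ctrl$qnet), 0.005)
  expect_error(tdp_metric_single(no_block_pop(0), ctrl, test_profile()),
               "at least one")
})

test_that("combination maps conserve samples and transpose under drug swap", {
  ctrl <- cached_test_control()
  pc <- test_profile()
  popA <- tiny_pop("hergA", 2, list(Kr = c(ic50 = 1.2, h = 0.9)), n = 2)
  popB <- tiny_pop("calB", 120, list(CaL = c(ic50 = 250, h = 1)), n = 2,
                   seed = 8)
  cache <- qnet_cache()
  mAB <- build_combination_map(popA, popB, "allotopic", ctrl, pc,
                               multiples = 0:1, cache = cache)
  # conservation at every cell
  expect_true(all(mAB$n_low + mAB$n_int + mAB$n_high + mAB$n_failed == 2))
  # swapping the drugs transposes the map exactly (shared cache makes
  # the swapped run hit identical block vectors)
  mBA <- build_combination_map(popB, popA, "allotopic", ctrl, pc,
                               multiples = 0:1, cache = cache)
  expect_identical(unname(mBA$n_high), unname(t(mAB$n_high)))
  expect_identical(unname(mBA$n_low), unname(t(mAB$n_low)))
  expect_identical(unname(mBA$n_int), unname(t(mAB$n_int)))
  expect_equal(unname(mBA$qnet[, , 1]), unname(t(mAB$qnet[, , 1])))
  # long-format export carries the conservation too
  tab <- as.data.frame(mAB)
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$n_low + tab$n_int + tab$n_high + tab$n_failed == 2))
  # per-sample biomarker table: one row per cell and sample
  expect_identical(nrow(mAB$biomarkers), 8L)
  expect_true(all(is.finite(mAB$biomarkers$apd90)))
  expect_identical(names(mAB$biomarkers)[1:8],
                   c("drugA", "drugB", "model", "multA", "multB",
                     "concA", "concB", "sample"))
  expect_error(build_combination_map(popA, tiny_pop("x", 1,
    list(Kr = c(ic50 = 1, h = 1)), n = 3), "allotopic", ctrl, pc),
    "same size")
})

test_that("risk-pair tallies aggregate maps additively, excluding 0x cells", {
  ctrl <- cached_test_control()
  pc <- test_profile()
  popA <- tiny_pop("hergA", 2, list(Kr = c(ic50 = 1.2, h = 0.9)), n = 2)
  popB <- tiny_pop("calB", 120, list(CaL = c(ic50 = 250, h = 1)), n = 2,
                   seed = 8)
  m <- build_combination_map(popA, popB, "allotopic", ctrl, pc,
                             multiples = 0:1, cache = qnet_cache())
  labels <- c(hergA = "high", calB = "low")
  t1 <- summarize_risk_pairs(list(m), labels)
  # only the single non-zero cell (1,1) contributes: 2 samples
  expect_equal(sum(t1$n), 2)
  t2 <- summarize_risk_pairs(list(m, m), labels)
  expect_equal(sum(t2$n), 4)
  expect_equal(t2$n, 2 * t1$n)
  expect_error(summarize_risk_pairs(list(m), c(hergA = "high")), "label")
})
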