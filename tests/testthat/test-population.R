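test_that("synthesized populations are reproducible and sized correctly", {
  nom <- list(Kr = c(ic50 = 100, h = 1), CaL = c(ic50 = 400, h = 1.2))
  p1 <- synthesize_population("d", 50, nom, n_samples = 100, seed = 11)
  p2 <- synthesize_population("d", 50, nom, n_samples = 100, seed = 11)
  p3 <- synthesize_population("d", 50, nom, n_samples = 100, seed = 12)
  expect_identical(nrow(p1), 100L)
  expect_identical(p1$sample, 0:99)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_false(identical(p1$Kr_IC50, p3$Kr_IC50))
  # zero spread reproduces the nominal drug in every sample
  p0 <- synthesize_population("d", 50, nom, n_samples = 5, spread = 0,
                              hill_spread = 0, seed = 1)
  expect_equal(p0$Kr_IC50, rep(100, 5))
  expect_equal(p0$CaL_h, rep(1.2, 5))
  # unmeasured channels are no-block
  expect_true(all(is.na(p0$Na_IC50)))
  expect_identical(sample_block(p0[1, ], 1e9)[["Na"]], 0)
})

test_that("synthesized IC50 medians converge to the nominal value", {
  p <- synthesize_population("d", 50, list(Kr = c(ic50 = 250, h = 1)),
                             n_samples = 1e4, seed = 3)
  expect_lt(abs(log(median(p$Kr_IC50) / 250)), 0.01)
  expect_lt(abs(median(p$Kr_h) - 1), 0.01)
})

test_that("population validation rejects malformed inputs", {
  expect_error(synthesize_population("d", -1, list(Kr = c(ic50 = 1, h = 1))),
               "cmax")
  expect_error(synthesize_population("d", 10, list(Kr = c(ic50 = -1, h = 1))),
               "nominal")
  expect_error(synthesize_population("d", 10, list(Qq = c(ic50 = 1, h = 1))),
               "channels")
  expect_error(drug_population("d", 10, data.frame(sample = integer(0))),
               "at least one")
  bad <- data.frame(sample = 0:1, Kr_IC50 = c(10, -4), Kr_h = c(1, 1))
  expect_error(drug_population("d", 10, bad), "rows 2")
})

test_that("drug CSVs round-trip exactly and map foreign channel tags", {
  pop <- synthesize_population("rt", 33, list(Kr = c(ic50 = 80, h = 0.9),
                                              NaL = c(ic50 = 900, h = 1.1)),
                               n_samples = 7, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_drug_csv(pop, f)
  back <- read_drug_csv(f, cmax = 33)
  expect_identical(as.data.frame(back), as.data.frame(pop))
  expect_identical(attr(back, "drug_name"), "rt")
  # FDA-style channel tags via channel_map
  tab <- read.csv(f)
  names(tab) <- sub("^Kr_", "hERG_", names(tab))
  f2 <- tempfile(fileext = ".csv")
  write.csv(tab, f2, row.names = FALSE)
  mapped <- read_drug_csv(f2, cmax = 33, channel_map = c(hERG = "Kr"))
  expect_equal(mapped$Kr_IC50, pop$Kr_IC50)
  # empty file is an error, not an empty population
  f3 <- tempfile(fileext = ".csv")
  writeLines("drug,sample,Kr_IC50,Kr_h", f3)
  expect_error(read_drug_csv(f3, cmax = 1), "empty")
})

test_that("bundled synthetic fixtures load as two-channel-profile panel", {
  for (fx in c(synthA_herg = "synthetic_synthA_herg.csv",
               synthB_multi = "synthetic_synthB_multi.csv",
               synthC_cal = "synthetic_synthC_cal.csv")) {
    f <- system.file("extdata", fx, package = "cipaddi")
    expect_true(nzchar(f))
    pop <- read_drug_csv(f, cmax = 100)
    expect_identical(nrow(pop), 8L)
  }
  herg <- read_drug_csv(system.file("extdata", "synthetic_synthA_herg.csv",
                                    package = "cipaddi"), cmax = 2)
  expect_true(all(!is.na(herg$Kr_IC50)))
  expect_true(all(is.na(herg$CaL_IC50)))  # selective hERG blocker
})
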