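test_that("Hill inhibition matches hand-computed values and edge cases", {
  expect_identical(hill_inhibition(0, 100, 1), 0)
  # half-maximal at D = IC50 for any Hill coefficient
  for (n in c(0.5, 1, 2.7)) expect_equal(hill_inhibition(100, 100, n), 0.5)
  expect_equal(hill_inhibition(300, 100, 1), 0.75)  # 300 / (300 + 100)
  expect_identical(hill_inhibition(1e9, NA, NA), 0) # no measurable block
  expect_identical(hill_inhibition(1e9, Inf, 1), 0)
  expect_error(hill_inhibition(-1, 100, 1), ">= 0")
  expect_error(hill_inhibition(10, -5, 1), "IC50")
  expect_error(hill_inhibition(10, 5, 0), "Hill")
})

test_that("Hill inhibition is monotone and depends on (D/IC50, n) via k^n", {
  d <- seq(0, 1000, by = 50)
  e <- hill_inhibition(d, 120, 1.3)
  expect_true(all(diff(e) > 0))
  expect_true(all(e >= 0 & e < 1))
  # lower IC50 blocks more at fixed dose
  expect_true(all(hill_inhibition(d[-1], 60, 1.3) > e[-1]))
  # E(k * IC50) is the same for any IC50 at fixed k^n
  expect_equal(hill_inhibition(3 * 50, 50, 2), hill_inhibition(3 * 7000, 7000, 2))
})

test_that("combiners match hand-evaluated values", {
  expect_equal(combine_allotopic(0.5, 0.5), 0.75)
  expect_equal(combine_syntopic(0.5, 0.5), 2 / 3)
  expect_equal(combine_syntopic(0.9, 0.1), 0.82 / 0.91)
  e <- runif(20)
  expect_equal(combine_allotopic(e, 0), e)   # single-drug reduction
  expect_equal(combine_syntopic(e, 0), e)
  expect_identical(combine_syntopic(1, 1), 1)  # continuous extension
  expect_error(combine_allotopic(1.2, 0.5), "\\[0, 1\\]")
  expect_error(combine_syntopic(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("allotopic equals the independent-events union probability", {
  set.seed(101)
  for (k in 1:5) {
    ea <- runif(1); eb <- runif(1)
    n <- 1e6
    hits <- mean(runif(n) < ea | runif(n) < eb)
    p <- combine_allotopic(ea, eb)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(hits - p), 3 * se + 1e-12)
  }
})

test_that("max(eA,eB) <= syntopic <= allotopic <= 1 on a dense grid", {
  g <- seq(0, 1, length.out = 101)
  grid <- expand.grid(ea = g, eb = g)
  syn <- combine_syntopic(grid$ea, grid$eb)
  allo <- combine_allotopic(grid$ea, grid$eb)
  expect_true(all(syn >= pmax(grid$ea, grid$eb) - 1e-12))
  expect_true(all(allo >= syn - 1e-12))
  expect_true(all(allo <= 1 + 1e-12))
  # commutativity and monotonicity on random draws
  set.seed(7)
  a <- runif(200); b <- runif(200); d <- runif(200) * (1 - a)
  expect_equal(combine_allotopic(a, b), combine_allotopic(b, a))
  expect_equal(combine_syntopic(a, b), combine_syntopic(b, a))
  expect_true(all(combine_allotopic(a + d, b) >= combine_allotopic(a, b) - 1e-12))
  expect_true(all(combine_syntopic(a + d, b) >= combine_syntopic(a, b) - 1e-12))
})

test_that("combined_block reduces to single-drug and zero block correctly", {
  popA <- tiny_pop("A", 50, list(Kr = c(ic50 = 40, h = 1),
                                 CaL = c(ic50 = 200, h = 1.2)))
  popB <- tiny_pop("B", 80, list(Kr = c(ic50 = 100, h = 0.8),
                                 NaL = c(ic50 = 500, h = 1)), seed = 9)
  bAB0 <- combined_block(popA[1, ], 0, popB[1, ], 160, "allotopic")
  expect_equal(bAB0, sample_block(popB[1, ], 160))
  b00 <- combined_block(popA[1, ], 0, popB[1, ], 0, "syntopic")
  expect_identical(unname(b00), rep(0, 7))
  # channels measured for one drug only keep that drug's effect
  bAB <- combined_block(popA[1, ], 100, popB[1, ], 160, "allotopic")
  expect_equal(bAB[["CaL"]], sample_block(popA[1, ], 100)[["CaL"]])
  expect_equal(bAB[["NaL"]], sample_block(popB[1, ], 160)[["NaL"]])
  expect_identical(bAB[["K1"]], 0)
  expect_error(combined_block(popA[1, ], 1, popB[1, ], 1, "bliss"))
})

test_that("allotopic dominates syntopic channel-wise for shared targets", {
  popA <- tiny_pop("A", 50, list(Kr = c(ic50 = 40, h = 1)))
  popB <- tiny_pop("B", 80, list(Kr = c(ic50 = 100, h = 0.8)), seed = 9)
  for (mult in 1:4) {
    ba <- combined_block(popA[1, ], mult * 50, popB[1, ], mult * 80, "allotopic")
    bs <- combined_block(popA[1, ], mult * 50, popB[1, ], mult * 80, "syntopic")
    expect_true(all(ba >= bs - 1e-12))
  }
})

test_that("apply_block scales targeted conductances by 1 - E", {
  base <- conductance_set()
  expect_equal(apply_block(base, setNames(rep(0, 7), ord_channels())), base)
  b <- apply_block(base, c(Kr = 1))
  expect_identical(unname(b["GKr"]), 0)
  expect_equal(b[names(b) != "GKr"], base[names(base) != "GKr"])
  # half CaL block halves the shared L-type permeability and all three
  # L-type currents at fixed state
  bc <- apply_block(base, c(CaL = 0.5))
  expect_equal(unname(bc["PCa"]), unname(base["PCa"]) / 2)
  y <- initial_state(); y["v"] <- 0; y["d"] <- 0.5
  c1 <- derivatives(y, base)$currents
  c2 <- derivatives(y, bc)$currents
  expect_equal(unname(c2[c("ICaL", "ICaNa", "ICaK")]),
               unname(c1[c("ICaL", "ICaNa", "ICaK")]) / 2)
  expect_error(apply_block(base, c(Kr = 1.4)), "\\[0, 1\\]")
})
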