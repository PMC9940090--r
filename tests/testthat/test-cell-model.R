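test_that("drug-target channels carry no current at zero conductance", {
  g <- conductance_set()
  g[c("GNa", "GNaL", "Gto", "PCa", "GKr", "GKs", "GK1")] <- 0
  d <- derivatives(initial_state(), g)
  cur <- d$currents
  expect_identical(unname(cur[c("INa", "INaL", "Ito", "ICaL", "ICaNa",
                                "ICaK", "IKr", "IKs", "IK1")]),
                   rep(0, 9))
})

test_that("IKr is linear in its maximal conductance (ohmic driving force)", {
  y <- initial_state()
  y["hO"] <- 0.5; y["hC2"] <- 0.5  # put the hERG channel half-open
  y["v"] <- 0
  g1 <- conductance_set()
  g2 <- g1; g2["GKr"] <- 2 * g2["GKr"]
  i1 <- derivatives(y, g1)$currents["IKr"]
  i2 <- derivatives(y, g2)$currents["IKr"]
  expect_gt(abs(i1), 0)
  expect_equal(unname(i2), 2 * unname(i1), tolerance = 1e-12)
})

test_that("unstimulated model relaxes to a quiescent state", {
  y <- initial_state()
  res <- integrate_beat(y, stim = stimulus_protocol(amplitude = 0,
                                                    beat_count = 10),
                        record = FALSE)
  d <- derivatives(res$state, stim_current = 0)
  expect_lt(abs(d$dstate["v"]), 0.01)
  expect_true(res$state["v"] < -80 && res$state["v"] > -95)
})

test_that("integration is deterministic and respects the beat clock", {
  y <- initial_state()
  r1 <- integrate_beat(y, stim = stimulus_protocol(beat_count = 2))
  r2 <- integrate_beat(y, stim = stimulus_protocol(beat_count = 2))
  expect_identical(r1$state, r2$state)
  tr <- r1$traces[[1]]
  expect_identical(tr$time[1], 0)
  expect_identical(tr$time[nrow(tr)], 2000)
  # physiological sanity of the advanced state
  gates <- setdiff(names(r1$state),
                   c("v", "nai", "nass", "ki", "kss", "cai", "cass",
                     "cansr", "cajsr", "Jrelnp", "Jrelp", "CaMKt"))
  expect_true(all(r1$state[gates] >= 0 & r1$state[gates] <= 1))
  conc <- c("nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr")
  expect_true(all(r1$state[conc] > 0))
})

test_that("invalid states are rejected with a divergence signal", {
  y <- initial_state()
  y["v"] <- NaN
  expect_error(derivatives(y), "divergence")
  y <- initial_state()
  y["v"] <- 500
  expect_error(integrate_beat(y, record = FALSE), "divergence")
})

test_that("APD90 converges as the time step is refined", {
  y <- initial_state()
  apd_at <- function(dt) {
    r <- integrate_beat(y, dt = dt)
    as.numeric(apd90(r$traces[[1]]))
  }
  a1 <- apd_at(0.005)
  a2 <- apd_at(0.0025)
  a3 <- apd_at(0.00125)
  expect_lt(abs(a2 - a1), 0.5)          # halving dt moves APD90 < 0.5 ms
  expect_lte(abs(a3 - a2), abs(a2 - a1) + 0.05)  # refinement shrinks change
})

test_that("a sealed membrane conserves total Na, K and Ca over a beat", {
  g <- conductance_set()
  g[] <- 0  # all sarcolemmal currents off; internal fluxes still active
  y0 <- initial_state()
  res <- integrate_beat(y0, g, stim = stimulus_protocol(amplitude = 0),
                        record = FALSE)
  # cell geometry and buffer parameters of the source model
  vcell <- 1000 * 3.14 * 0.0011^2 * 0.01
  vmyo <- 0.68 * vcell; vss <- 0.02 * vcell
  vnsr <- 0.0552 * vcell; vjsr <- 0.0048 * vcell
  buf <- function(cmax, km, ca) cmax * ca / (km + ca)
  content <- function(y) {
    ca_myo <- y["cai"] + buf(0.05, 0.00238, y["cai"]) +
      buf(0.07, 0.0005, y["cai"])
    ca_ss <- y["cass"] + buf(0.047, 0.00087, y["cass"]) +
      buf(1.124, 0.0087, y["cass"])
    ca_jsr <- y["cajsr"] + buf(10, 0.8, y["cajsr"])
    c(na = unname(y["nai"] * vmyo + y["nass"] * vss),
      k = unname(y["ki"] * vmyo + y["kss"] * vss),
      ca = unname(ca_myo * vmyo + ca_ss * vss + y["cansr"] * vnsr +
                    ca_jsr * vjsr))
  }
  c0 <- content(y0); c1 <- content(res$state)
  expect_equal(c1, c0, tolerance = 1e-6)
})

test_that("the shipped constants file agrees with the model code", {
  f <- system.file("extdata", "ord_constants.yaml", package = "cipaddi")
  expect_true(nzchar(f))
  const <- yaml::read_yaml(f)
  expect_equal(unlist(const$base_conductances),
               unclass(cipaddi:::ord_base_conductances()))
  expect_equal(unlist(const$cipa_scaling), cipa_scaling())
  expect_equal(unlist(const$initial_state), unclass(initial_state()),
               tolerance = 1e-9)
  th <- risk_thresholds()
  expect_identical(const$qnet_thresholds$threshold1, th$threshold1)
  expect_identical(const$qnet_thresholds$threshold2, th$threshold2)
})
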