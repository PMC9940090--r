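test_that("APD90 of a triangular AP matches hand geometry", {
  # peak +40 mV at 50 ms, linear to -85 mV at 300 ms: V90 = -72.5 mV,
  # crossed at 275 ms, so APD90 = 225 ms
  b <- triangle_beat(v_rest = -85, v_peak = 40, t_peak = 50, t_end = 300)
  expect_equal(as.numeric(apd90(b)), 225)
  # affine invariance: shifting the trace by +10 mV changes nothing
  b2 <- b; b2$vm <- b2$vm + 10
  expect_equal(as.numeric(apd90(b2)), 225)
})

test_that("APD90 flags repolarization failure and absent APs", {
  b <- triangle_beat()
  b$vm[b$time >= 50] <- 40            # clamped at peak forever
  a <- apd90(b)
  expect_true(is.na(a))
  expect_true(attr(a, "failure"))
  flat <- triangle_beat(v_peak = -80, v_rest = -85)
  expect_error(apd90(flat), "no beat")
})

test_that("CaD90 mirrors the APD90 geometry on the calcium series", {
  t <- seq(0, 2000)
  ca <- approx(c(0, 50, 300, 2000), c(1e-4, 1e-3, 1e-4, 1e-4), xout = t)$y
  b <- triangle_beat(ca = ca)
  # amplitude 9e-4, 90% recovery level 1.9e-4, linear decay from
  # (50, 1e-3) at -3.6e-6/ms: crossing at 275 -> duration 225
  expect_equal(as.numeric(cad90(b)), 225)
  b2 <- b; b2$cai <- b2$cai * 7.3     # positive scaling is irrelevant
  expect_equal(as.numeric(cad90(b2)), 225)
  b3 <- b; b3$cai <- seq(1e-4, 2e-3, length.out = nrow(b))  # never decays
  expect_true(is.na(cad90(b3)))
  b4 <- b; b4$cai <- rep(2e-4, nrow(b))
  expect_error(cad90(b4), "flat")
})

test_that("qNet integrates the six currents over the beat", {
  b <- constant_current_beat(inet = 0.05)
  expect_equal(qnet(b), 0.1, tolerance = 1e-12)    # 0.05 uA/uF * 2 s
  # linearity in each series
  b2 <- b; b2$ikr <- 2 * b2$ikr
  expect_equal(qnet(b2), 2 * qnet(b), tolerance = 1e-12)
  # odd net current about t = 1000 ms integrates to zero
  b3 <- triangle_beat()
  b3$iks <- b3$time - 1000
  expect_equal(qnet(b3), 0, tolerance = 1e-9)
  # distributing a current across channels changes nothing
  b4 <- b
  b4$ical <- b4$ikr / 2; b4$ikr <- b4$ikr / 2
  expect_equal(qnet(b4), qnet(b), tolerance = 1e-12)
  # grid refinement barely moves qNet on smooth traces
  fine <- constant_current_beat(inet = 0.05, out_dt = 0.5)
  expect_lt(abs(qnet(fine) - qnet(b)), 1e-4)
})

test_that("steepest repolarization gradient handles the three regimes", {
  # strictly linear repolarization: slope -0.5 mV/ms everywhere in window
  b <- triangle_beat(v_rest = -85, v_peak = 40, t_peak = 50, t_end = 300)
  d <- dvdt_repol(b)
  expect_true(d$repol90_reached)
  expect_equal(d$dvdt_max, -0.5, tolerance = 1e-9)
  # EAD-like bump inside the 30-90% window gives a positive slope
  t <- seq(0, 2000)
  vm <- approx(c(0, 50, 150, 170, 300, 2000),
               c(-85, 40, -30, -10, -85, -85), xout = t)$y
  be <- b; be$vm <- vm
  de <- dvdt_repol(be)
  expect_equal(de$dvdt_max, 1, tolerance = 0.35)  # bump rises 20 mV / 20 ms
  expect_gt(de$dvdt_max, 0)
  # AP that stalls above the 90% level: window extends to the beat end
  vm2 <- approx(c(0, 50, 300, 2000), c(-85, 40, -20, -20), xout = t)$y
  bs <- b; bs$vm <- vm2
  ds <- dvdt_repol(bs)
  expect_false(ds$repol90_reached)
})

test_that("select_beat picks the steepest-gradient beat, ties to latest", {
  base <- triangle_beat()
  one <- select_beat(list(base))
  expect_identical(as.data.frame(one), as.data.frame(base))
  # all identical -> latest wins (documented tie rule)
  cands <- lapply(1:4, function(i) {
    b <- triangle_beat(); attr(b, "beat") <- i; b
  })
  expect_identical(attr(select_beat(cands), "beat"), 4L)
  # one EAD-bearing beat among control-like beats is selected
  t <- seq(0, 2000)
  ead <- triangle_beat()
  ead$vm <- approx(c(0, 50, 150, 170, 300, 2000),
                   c(-85, 40, -30, -10, -85, -85), xout = t)$y
  attr(ead, "beat") <- 3L
  cands <- lapply(c(1, 2, 4, 5), function(i) {
    b <- triangle_beat(); attr(b, "beat") <- as.integer(i); b
  })
  cands <- append(cands, list(ead), after = 2)
  expect_identical(attr(select_beat(cands), "beat"), 3L)
  expect_error(select_beat(list()), "no candidate")
})
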