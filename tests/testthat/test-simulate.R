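test_that("the beat waveform evaluates its Gaussian terms and repeats", {
  w1 <- beat_waveform(a = c(0.5, 0), b = c(0.2, 0), c = c(0.1, 1))
  expect_equal(beat_flow(w1, 0.2), 0.5)           # peak of the single term
  w2 <- beat_waveform(a = c(1, 0), b = c(0, 0), c = c(1, 1), period = 10)
  expect_equal(beat_flow(w2, 1), exp(-1))
  w <- beat_waveform()
  t <- c(0.03, 0.41, 0.77)
  expect_equal(beat_flow(w, t + w$period), beat_flow(w, t))
  expect_equal(beat_flow(w, t + 7 * w$period), beat_flow(w, t))
  expect_error(beat_waveform(c = c(0, 0.1)), "nonzero")
  expect_error(beat_waveform(period = -1), "period")
})

test_that("waveform files round-trip", {
  w <- beat_waveform(a = c(3e-4, 5e-5), b = c(0.12, 0.4), c = c(0.07, 0.2),
                     period = 0.8)
  f <- tempfile(fileext = ".json")
  write_waveform(w, f)
  w2 <- read_waveform(f)
  expect_equal(w2$terms, w$terms)
  expect_equal(w2$period, w$period)
  unlink(f)
})

test_that("zero input from zero state stays at equilibrium", {
  seg <- make_segment("initial", "s", list(l = 0.1, r = 0.01))
  sys <- assemble_ode(seg)
  sim <- simulate_ode(sys, inputs = list(cardiac_inflow = 0), t_end = 0.5)
  expect_true(all(as.matrix(sim[, -1]) == 0))
})

test_that("a pure integrator grows linearly", {
  v0 <- 2e-5
  sys <- assemble_ode(single_c_module(v0 = v0))
  sim <- simulate_ode(sys, t_end = 1)
  expect_equal(sim$C.q, v0 * sim$time, tolerance = 1e-8)
})

test_that("missing external inputs fail early and t_end is checked", {
  seg <- make_segment("initial", "s", list(l = 0.1, r = 0.01))
  sys <- assemble_ode(seg)
  expect_error(simulate_ode(sys, t_end = 1), "not supplied")
  expect_error(simulate_ode(sys, inputs = list(cardiac_inflow = 0), t_end = 0),
               "t_end")
})

test_that("the driven toy tree settles into a periodic regime", {
  toy <- toy_tree()
  sys <- assemble_ode(lump(toy$plan, toy$modules))
  sim <- simulate_ode(sys, inputs = list(cardiac_inflow = beat_waveform()),
                      t_end = 10)
  lastc <- last_cycle(sim, 1)
  prevc <- last_cycle(sim[sim$time <= 9 + 1e-9, ], 1)
  for (v in c("root.j_src.u", grep("j_in\\.v$", names(sim), value = TRUE)[1])) {
    va <- lastc[[v]][seq_len(1000)]
    vb <- prevc[[v]][seq_len(1000)]
    expect_lt(max(abs(va - vb)) / max(abs(va)), 1e-3)
  }
})

test_that("last_cycle rebases, errors on short spans, and is idempotent", {
  sys <- assemble_ode(single_c_module())
  sim <- simulate_ode(sys, t_end = 10)
  lc <- last_cycle(sim, 1)
  expect_equal(min(lc$time), 0)
  expect_equal(max(lc$time), 1)
  expect_equal(lc$C.q, sim$C.q[sim$time >= 9 - 1e-12], tolerance = 1e-12)
  expect_error(last_cycle(lc, 2), "shorter")
  lc2 <- last_cycle(lc, 1)
  expect_equal(lc2, lc)
})

test_that("volume is conserved when nothing flows in or out", {
  # capped three-segment chain: source silenced, outlet ports unbound
  geom <- tibble::tibble(
    segment_id = c("a", "b", "c"),
    kind = c("initial", "intermediate", "intermediate"),
    length_m = c(0.1, 0.08, 0.08),
    radius_m = c(0.01, 0.007, 0.007),
    parent_id = c(NA, "a", "b")
  )
  sm <- segment_modules(geom)
  sys <- assemble_ode(lump(sm$plan, sm$modules))
  qs <- sys$states$id[sys$states$kind == "q"]
  init <- setNames(numeric(nrow(sys$states)), sys$states$id)
  init[qs[1]] <- 1e-6
  sim <- simulate_ode(sys, inputs = list(cardiac_inflow = 0), t_end = 1,
                      init = init, rtol = 1e-10, atol = 1e-14)
  total <- rowSums(as.matrix(sim[, qs]))
  expect_lt(max(abs(total - total[1])) / abs(total[1]), 1e-9)
})

test_that("tightening solver tolerances barely moves the traces", {
  toy <- toy_tree()
  sys <- assemble_ode(lump(toy$plan, toy$modules))
  w <- beat_waveform()
  a <- simulate_ode(sys, inputs = list(cardiac_inflow = w), t_end = 2,
                    rtol = 1e-8, atol = 1e-12)
  b <- simulate_ode(sys, inputs = list(cardiac_inflow = w), t_end = 2,
                    rtol = 1e-9, atol = 1e-13)
  v <- "root.j_src.u"
  expect_lt(max(abs(a[[v]] - b[[v]])) / max(abs(b[[v]])), 1e-5)
})

test_that("scaling the beat amplitudes scales every trace linearly", {
  toy <- toy_tree()
  sys <- assemble_ode(lump(toy$plan, toy$modules))
  w1 <- beat_waveform()
  w3 <- beat_waveform(a = 3 * w1$terms$a, b = w1$terms$b, c = w1$terms$c)
  s1 <- simulate_ode(sys, inputs = list(cardiac_inflow = w1), t_end = 1)
  s3 <- simulate_ode(sys, inputs = list(cardiac_inflow = w3), t_end = 1)
  m1 <- as.matrix(s1[, -1]); m3 <- as.matrix(s3[, -1])
  scale <- max(abs(m1))
  expect_lt(max(abs(m3 - 3 * m1)) / scale, 1e-5)
})
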