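test_that("refractory draw is the affine map of the uniform deviate", {
  expect_equal(draw_refractory(50, 10, 0.0), 50.0)
  expect_equal(draw_refractory(50, 10, 1.0), 60.0)
  expect_equal(draw_refractory(50, 10, 0.37), 53.7)
  expect_error(draw_refractory(0, 10, 0.5), "r0")
  expect_error(draw_refractory(50, 10, 1.5), "xi")
  expect_error(draw_refractory(50, -1, 0.5), "r_noise")
})

test_that("intrinsic step follows the cyclic transition system", {
  tm <- cell_timers(f = 5, r0 = 70, a = 40)
  # guard met -> transition with clock reset
  expect_equal(intrinsic_step("F", 4, tm), list(phase = "R", x = 0))
  expect_equal(intrinsic_step("R", 69, tm), list(phase = "A", x = 0))
  expect_equal(intrinsic_step("A", 39, tm), list(phase = "F", x = 0))
  # time pass below the guard
  expect_equal(intrinsic_step("A", 10, tm), list(phase = "A", x = 11))
  expect_equal(intrinsic_step("F", 0, tm), list(phase = "F", x = 1))
  # refusal keeps the cell in A past the invariant a
  expect_equal(intrinsic_step("A", 39, tm, refuse_draw = 0.1, p_refuse = 1),
               list(phase = "A", x = 40))
  expect_equal(intrinsic_step("A", 45, tm, refuse_draw = 0.1, p_refuse = 1),
               list(phase = "A", x = 46))
  expect_error(intrinsic_step("Q", 0, tm), "phase")
})

test_that("interaction rules take precedence and halve or force as specified", {
  tm <- cell_timers(f = 5, r0 = 50, a = 1150)
  thr <- interaction_thresholds(N_R = 3, N_F = 0)
  # supra-threshold stimulation in R halves the clock (floor), stays R
  expect_equal(interact_step("R", 10, tm, n_firing = 4, thr),
               list(phase = "R", x = 5, fired = FALSE))
  expect_equal(interact_step("R", 11, tm, n_firing = 4, thr),
               list(phase = "R", x = 5, fired = FALSE))
  # halving is idempotent at x in {0, 1}
  expect_equal(interact_step("R", 0, tm, n_firing = 4, thr)$x, 0)
  expect_equal(interact_step("R", 1, tm, n_firing = 4, thr)$x, 0)
  # forced firing from A with a single firing neighbor (strict >, N_F = 0)
  expect_equal(interact_step("A", 7, tm, n_firing = 1, thr),
               list(phase = "F", x = 0, fired = TRUE))
  # forced firing is subject to the refusal test
  expect_equal(interact_step("A", 7, tm, n_firing = 1, thr,
                             refuse_draw = 0.0, p_refuse = 0.5),
               list(phase = "A", x = 8, fired = FALSE))
  # below threshold: plain time pass
  expect_equal(interact_step("R", 10, tm, n_firing = 2, thr),
               list(phase = "R", x = 11, fired = FALSE))
  # exactly at threshold is not enough (strict >)
  expect_equal(interact_step("R", 10, tm, n_firing = 3, thr)$x, 11)
})

test_that("isolated cell fires exactly every f + r + a steps", {
  tm <- cell_timers(f = 5, r0 = 70, a = 40)
  expect_equal(cycle_period(tm), 115)
  expect_equal(cycle_period(cell_timers(1, 1, 1)), 3)
  sc <- simulate_cell(tm, 10 * 115 + 39)
  expect_equal(sc$fire_steps[1], 40) # first self-excitation after a steps
  expect_length(sc$fire_steps, 10)
  expect_equal(unique(diff(sc$fire_steps)), 115)
  # fractional refractory guard lasts ceiling(r) steps
  tmf <- cell_timers(f = 2, r0 = 3, a = 4, r_noise = 1, r = 3.4)
  scf <- simulate_cell(tmf, 50)
  expect_equal(unique(diff(scf$fire_steps)), 2 + 4 + 4) # ceil(3.4) = 4
})

test_that("phase sequence is always the cycle F, R, A with no skips", {
  tm <- cell_timers(f = 3, r0 = 4, a = 5)
  set.seed(7)
  sc <- simulate_cell(tm, 500, p_refuse = 0.3)
  ph <- rle(sc$phases)$values
  nxt <- c(F = "R", R = "A", A = "F")
  expect_true(all(ph[-1] == nxt[ph[-length(ph)]]))
})

test_that("per-step refusal delay beyond a is geometric", {
  tm <- cell_timers(f = 1, r0 = 1, a = 1)
  p <- 0.4
  set.seed(11)
  sc <- simulate_cell(tm, 40000, p_refuse = p)
  delays <- diff(sc$fire_steps) - cycle_period(tm)
  expect_gte(length(delays), 8000)
  kmax <- 6
  obs <- tabulate(pmin(delays, kmax) + 1L, nbins = kmax + 1L)
  probs <- c(stats::dgeom(0:(kmax - 1), prob = 1 - p),
             1 - stats::pgeom(kmax - 1, prob = 1 - p))
  ct <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(ct$p.value, 0.01)
})
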