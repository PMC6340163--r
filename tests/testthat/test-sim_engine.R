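test_that("AVN event detection is edge triggered", {
  expect_equal(detect_avn_event(c(0, 1, 3, 4, 3, 1, 0, 3), k = 3), c(3, 8))
  expect_equal(detect_avn_event(c(3, 3, 3), k = 3), 1) # one wavefront, one event
  expect_equal(detect_avn_event(c(2, 2, 1, 0), k = 3), integer(0))
  expect_equal(detect_avn_event(c(0, 5, 5, 2, 5), k = 3), c(2, 5))
})

test_that("a lone firing cell forces its resting neighbor next step", {
  tis <- build_tissue(lattice_spec(L = 12, p_H = 1, p_L = 1),
                      small_regions(12), seed = 1)
  st <- initial_state(tis)
  # all-A tissue: one step is pure time pass
  st1 <- step_tissue(st, tis)
  expect_true(all(st1$phase == st$phase))
  expect_true(all(st1$clock == 1))
  # plant a firing atrial cell; its out-neighbors must fire next step
  i <- which(tis$roles == "ATRIAL" & tis$row == 8 & tis$col == 8)
  out <- which(as.vector(tis$adj[, i]) > 0)
  st$phase[i] <- 1L # F
  st2 <- step_tissue(st, tis)
  expect_true(all(st2$phase[out] == 1L))
  expect_true(all(st2$clock[out] == 0))
  # certain refusal: the neighbors never fire
  st3 <- st
  for (k in 1:10) st3 <- step_tissue(st3, tis, p_refuse = 1)
  expect_true(all(st3$phase[out] != 1L))
})

test_that("synchronous update matches a per-cell reference implementation", {
  for (dens in c(0.5, 1)) {
    tis <- build_tissue(lattice_spec(L = 12, p_H = dens, p_L = dens),
                        small_regions(12), seed = 20 + dens * 10)
    nbrs <- in_neighbor_lists(tis)
    code <- c("F", "R", "A")
    st <- initial_state(tis)
    ora <- list(ph = code[st$phase], x = st$clock)
    mismatch <- NA_integer_
    for (t in 1:500) {
      st <- step_tissue(st, tis)
      ora <- oracle_step(ora$ph, ora$x, nbrs,
                         tis$timers$f, tis$timers$r, tis$timers$a)
      if (!identical(code[st$phase], ora$ph) ||
          !identical(as.numeric(st$clock), as.numeric(ora$x))) {
        mismatch <- t
        break
      }
    }
    expect_true(is.na(mismatch),
                label = sprintf("state equal to oracle at density %g (first mismatch step %s)",
                                dens, mismatch))
  }
})

test_that("runs are bit-reproducible from the seed", {
  cfg <- small_config(L = 30, p_H = 0.5, p_L = 0.5, p_refuse = 0.3,
                      r_noise = 10, total_steps = 1500, seed = 77)
  a <- run_sim(cfg, keep_tissue = FALSE)
  b <- run_sim(cfg, keep_tissue = FALSE)
  expect_identical(a$avn_events, b$avn_events)
  expect_identical(a$rr, b$rr)
  expect_identical(a$t_bottom_first, b$t_bottom_first)
})

test_that("full density, zero refusal: constant RR equal to the SAN period", {
  res <- run_sim(small_config(L = 40, total_steps = 3000, seed = 4))
  rr <- analysis_rr(res)
  expect_gt(length(rr), 5)
  expect_true(all(rr == T_SAN_DEFAULT))
  expect_equal(classify_rhythm(rr, res$t_san), "normal")
  # conservation of fronts: every SAN firing episode yields one AVN event
  expect_lte(abs(length(res$san_fires) - length(res$avn_events)), 1)
  # engine's incremental detection agrees with the standalone detector
  expect_identical(res$avn_events,
                   detect_avn_event(res$avn_counts, res$avn_k))
  expect_equal(scale_rr(rr[1:2]), c(805, 805))
})

test_that("certain refusal everywhere silences the tissue", {
  cfg <- small_config(L = 20, total_steps = 1500, seed = 6, p_refuse = 1)
  res <- run_sim(cfg, keep_tissue = FALSE)
  expect_length(res$avn_events, 0)
  expect_length(res$rr, 0)
  expect_equal(classify_rhythm(analysis_rr(res), res$t_san), "dead")
})

test_that("the refusal random walk respects its interval by rejection", {
  wk <- walk_spec(p_walk = 0.5, eps = 0.07, z = 0.45) # eps does not divide z
  expect_equal(walk_refuse(0.44, walk_spec(), zeta = 0, sign = +1), 0.44)
  expect_equal(walk_refuse(0.40, walk_spec(), zeta = 0, sign = +1), 0.45)
  expect_equal(walk_refuse(0.40, walk_spec(), zeta = 1, sign = +1), 0.40)
  expect_equal(walk_refuse(0.02, walk_spec(), zeta = 0, sign = -1), 0.02)
  set.seed(13)
  tr <- run_refuse_walk(10000, wk, p0 = 0)
  expect_true(all(tr >= 0 & tr <= wk$z))
  # rejection, not clamping: every value sits on the eps grid
  expect_true(all(abs(tr / wk$eps - round(tr / wk$eps)) < 1e-9))
  expect_gt(max(tr), 0.4) # the walk actually explores the interval
})

test_that("accepted-move count matches the binomial law", {
  wk <- walk_spec(p_walk = 0.001, eps = 0.001, z = 1)
  set.seed(21)
  tr <- run_refuse_walk(1e6, wk, p0 = 0.5)
  moves <- sum(diff(c(0.5, tr)) != 0)
  expect_lt(abs(moves - 1000), 3 * sqrt(1000))
})

test_that("scale_rr multiplies element-wise and validates its factor", {
  expect_equal(scale_rr(c(115, 115)), c(805, 805))
  expect_equal(scale_rr(integer(0)), integer(0))
  expect_equal(scale_rr(c(100, 200), factor = 1), c(100, 200))
  expect_error(scale_rr(c(1, 2), factor = 0), "positive")
})
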