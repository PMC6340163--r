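test_that("artifact runs are patched with the 7-beat median", {
  s <- annotated_rr(c(800, 790, 810, 805, 795, 800, 790, 500, 1300, 805),
                    c(rep("normal", 7), "artifact", "artifact", "normal"))
  cl <- clean_rr(s)
  # median of (800, 790, 810, 805, 795, 800, 790) is 800
  expect_equal(cl$rr, c(800, 790, 810, 805, 795, 800, 790, 800, 800, 805))
  expect_equal(cl$log$action, "patch")
  expect_equal(cl$log$value, 800)
  expect_length(cl$junctions, 0)
})

test_that("long runs are deleted and the junction is logged", {
  rr <- c(rep(800, 10), rep(400, 6), rep(810, 10))
  labels <- c(rep("normal", 10), rep("bad", 6), rep("normal", 10))
  cl <- clean_rr(rr, labels)
  expect_equal(cl$rr, c(rep(800, 10), rep(810, 10)))
  expect_equal(cl$log$action, "delete")
  expect_equal(cl$junctions, 10)
  # a run of exactly max_patch beats is deleted too (strict <)
  cl5 <- clean_rr(c(rep(800, 10), rep(400, 5), rep(810, 10)),
                  c(rep("normal", 10), rep("bad", 5), rep("normal", 10)))
  expect_equal(cl5$log$action, "delete")
  # a patchable run without 7 preceding beats is removed instead
  cl_pre <- clean_rr(c(800, 400, 400, rep(805, 10)),
                     c("normal", "bad", "bad", rep("normal", 10)))
  expect_equal(cl_pre$log$action, "delete_short_prefix")
  expect_equal(cl_pre$rr, c(800, rep(805, 10)))
})

test_that("clean_rr is the identity on all-normal input and idempotent", {
  rr <- c(800, 790, 810, 805, 795, 800, 790, 808, 792)
  cl <- clean_rr(rr)
  expect_equal(cl$rr, rr)
  expect_equal(nrow(cl$log), 0)
  s <- annotated_rr(c(rep(800, 12), 400, 400, rep(810, 12)),
                    c(rep("normal", 12), "x", "x", rep("normal", 12)))
  once <- clean_rr(s)
  twice <- clean_rr(once$rr)
  expect_equal(twice$rr, once$rr)
  expect_equal(nrow(twice$log), 0)
})

test_that("output is truncated to the target length", {
  cl <- clean_rr(rep(800, 50), target_len = 30)
  expect_length(cl$rr, 30)
})

test_that("increments are the first difference", {
  expect_equal(rr_increments(c(800, 808, 800)), c(8, -8))
  expect_equal(rr_increments(rep(750, 5)), rep(0, 4))
  expect_equal(rr_increments(c(805, 790)), -15)
  expect_error(rr_increments(800), "at least two")
})

test_that("pattern matrix counts consecutive increment pairs", {
  P <- pattern_matrix(c(0, 0, 0), bin_width = 8)
  expect_equal(dim(P), c(1, 1))
  expect_equal(P[["0", "0"]], 1)
  P2 <- pattern_matrix(c(8, -8, 8, -8), bin_width = 8)
  expect_equal(P2[["8", "-8"]], 2 / 3)
  expect_equal(P2[["-8", "8"]], 1 / 3)
  expect_equal(sum(P2), 1)
  # binning is half-open around centers at multiples of the width
  P3 <- pattern_matrix(c(4, -4, 4), bin_width = 8) # 4 -> bin 8, -4 -> bin 0
  expect_equal(P3[["8", "0"]], 1 / 2)
  expect_equal(P3[["0", "8"]], 1 / 2)
  expect_error(pattern_matrix(5), "at least two")
})

test_that("pattern matrix mass sums to 1 and reverses to the transpose", {
  set.seed(3)
  drr <- sample(seq(-40, 40, by = 8), 300, replace = TRUE)
  P <- pattern_matrix(drr, bin_width = 8)
  expect_equal(sum(P), 1)
  Prev <- pattern_matrix(rev(drr), bin_width = 8)
  expect_equal(matrix(Prev, nrow(Prev)), t(matrix(P, nrow(P))))
  expect_equal(rownames(Prev), rownames(P))
})

test_that("pairs are not formed across deletion junctions", {
  rr <- c(790, 800, 810, 820, 830, 840)
  # junction between beats 3 and 4: increments 3->4 and pairs across it drop
  P <- pattern_from_rr(rr, bin_width = 8, junctions = 3L)
  # segments (790,800,810) and (820,830,840): 4 increments of +10 -> bin 8,
  # valid pairs: (8,8) within each segment = 2 pairs... increments per
  # segment: 2 each, pairs within segment: 1 each
  expect_equal(attr(P, "n_pairs"), 2)
  expect_equal(P[["8", "8"]], 1)
})

test_that("a constant scaled model rhythm concentrates all mass at the origin", {
  rr <- scale_rr(rep(115, 40)) # 805 ms beats
  P <- pattern_matrix(rr_increments(rr), bin_width = 7)
  expect_equal(off_origin_mass(P), 0)
})

test_that("RR series and pattern matrices round-trip through CSV", {
  s <- gen_synthetic_rr(n = 50, jitter_quanta = 1, seed = 2,
                        artifact_starts = 20, artifact_lengths = 3)
  path <- tempfile(fileext = ".csv")
  write_rr_csv(s, path)
  back <- read_rr_csv(path)
  expect_equal(back$rr, s$rr)
  expect_equal(back$labels, s$labels)
  P <- pattern_matrix(rr_increments(clean_rr(s)$rr), bin_width = 8)
  mpath <- tempfile(fileext = ".csv")
  write_pattern_csv(P, mpath)
  df <- utils::read.csv(mpath, check.names = FALSE)
  expect_equal(nrow(df), nrow(P))
  expect_equal(sum(as.matrix(df[, -1])), 1)
})
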