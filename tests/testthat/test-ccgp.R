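# Cross-condition generalization: chunking, design construction, transfer
# classification, shuffle nulls, decoding-axis geometry.

# A session of known captured duration with controllable positions.
ccgp_session <- function(seconds, seed = 1) {
  n <- as.integer(seconds * 60)
  with_seed_test(seed, make_const_session(n, pos = function(f)
    cbind(runif(length(f), 0, 1800), runif(length(f), 0, 1000)),
    variables = c("self", "chosen_prey")))
}

test_that("chunking discards the trailing remainder and aligns to frames", {
  s200 <- ccgp_session(200)
  spk <- matrix(0L, s200$n_frames, 2)
  attr(spk, "frame_dt") <- 1 / 60
  ch <- chunk_session(s200, spk, chunk_s = 40)
  expect_identical(ch$n_chunks, 5L)
  expect_identical(ch$discarded_frames, 0L)
  s199 <- ccgp_session(199)
  spk <- matrix(0L, s199$n_frames, 2); attr(spk, "frame_dt") <- 1 / 60
  ch2 <- chunk_session(s199, spk, chunk_s = 40)
  expect_identical(ch2$n_chunks, 4L)
  expect_identical(ch2$discarded_frames, as.integer(39 * 60)) # 39 s dropped
  expect_identical(ch2$frames_per_chunk, 2400L)
  expect_error(chunk_session(ccgp_session(50), {
    m <- matrix(0L, 3000, 1); attr(m, "frame_dt") <- 1 / 60; m
  }, chunk_s = 40), "2 chunks")
})

test_that("design selection follows occupancy ranking with index tie-breaks", {
  s <- ccgp_session(420, seed = 2)
  spk <- matrix(rpois(s$n_frames * 3, 0.2), ncol = 3)
  attr(spk, "frame_dt") <- 1 / 60
  ch <- chunk_session(s, spk, chunk_s = 40)
  expect_identical(ch$n_chunks, 10L)
  d <- build_ccgp_design(ch, "self")
  # left candidates are columns 1-2, right 5-6, 6 kept per side
  rc <- pursuitgeom:::bin_coords(spatial_grid())
  expect_true(all(rc[d$selected_bins$left, "col"] <= 2))
  expect_true(all(rc[d$selected_bins$right, "col"] >= 5))
  expect_length(d$selected_bins$left, 6)
  # occupancy ranking oracle
  socc <- ch$session_occupancy$self
  left_cand <- which(rc[, "col"] <= 2)
  expect_setequal(d$selected_bins$left,
                  left_cand[order(-socc[left_cand], left_cand)][1:6])
  # 10 chunks x 12 bins, nothing dropped at this occupancy
  expect_identical(nrow(d$X), 120L - d$n_dropped)
  expect_identical(sum(d$labels == "left"), sum(d$labels == "right"))
  # uniform occupancy: deterministic lowest-index tie-break
  ch_u <- ch
  ch_u$session_occupancy$self <- rep(100L, 36)
  d_u <- build_ccgp_design(ch_u, "self")
  expect_identical(sort(d_u$selected_bins$left), left_cand[1:6])
  # the random bin rule is available and reproducible
  d_r1 <- build_ccgp_design(ch, "self", bin_rule = "random", seed = 5)
  d_r2 <- build_ccgp_design(ch, "self", bin_rule = "random", seed = 5)
  expect_identical(d_r1$selected_bins, d_r2$selected_bins)
})

test_that("transfer accuracy tracks the planted axis relation", {
  set.seed(71)
  a <- rnorm(120)
  b <- rnorm(120); b <- b - sum(b * a) / sum(a^2) * a
  d_tr <- synthetic_ccgp_design(a, n_chunks = 20, strength = 4, seed = 1,
                                variable = "self")
  d_sh <- synthetic_ccgp_design(a, n_chunks = 20, strength = 4, seed = 2,
                                variable = "shared")
  d_in <- synthetic_ccgp_design(-a, n_chunks = 20, strength = 4, seed = 3,
                                variable = "inverted")
  d_or <- synthetic_ccgp_design(b, n_chunks = 20, strength = 4, seed = 4,
                                variable = "orthogonal")
  self <- ccgp(d_tr, d_tr, n_reps = 20, seed = 9)$ccgp
  sh <- ccgp(d_tr, d_sh, n_reps = 20, seed = 9)$ccgp
  inv <- ccgp(d_tr, d_in, n_reps = 20, seed = 9)$ccgp
  orth <- ccgp(d_tr, d_or, n_reps = 20, seed = 9)$ccgp
  expect_gt(self, 0.9)
  expect_gt(sh, 0.8)
  expect_lt(inv, 0.2)
  expect_gt(orth, 0.35); expect_lt(orth, 0.65)
  # transfer is monotone in planted axis similarity
  expect_gt(sh, orth)
  expect_gt(orth, inv)
  # shuffle null: significance and direction
  ns <- ccgp_null(d_tr, d_sh, n_shuffles = 60, n_reps = 10, seed = 2)
  expect_identical(ns$direction, "above")
  expect_identical(ns$p, 1 / 61)
  ni <- ccgp_null(d_tr, d_in, n_shuffles = 60, n_reps = 10, seed = 3)
  expect_identical(ni$direction, "below")
  expect_lt(ni$p, 0.05)
})

test_that("the shuffle null is centred on chance", {
  set.seed(72)
  a <- rnorm(80)
  d_tr <- synthetic_ccgp_design(a, n_chunks = 15, strength = 2, seed = 5,
                                variable = "self")
  d_te <- synthetic_ccgp_design(a, n_chunks = 15, strength = 2, seed = 6,
                                variable = "other")
  ns <- ccgp_null(d_tr, d_te, n_shuffles = 80, n_reps = 10, seed = 4)
  expect_gt(ns$null_mean, 0.48)
  expect_lt(ns$null_mean, 0.52)
})

test_that("decoding axes recover planted angles and embed exactly", {
  set.seed(73)
  a <- rnorm(200); b <- rnorm(200); b <- b - sum(b * a) / sum(a^2) * a
  designs <- list(
    self = synthetic_ccgp_design(a, 100, strength = 200, seed = 1,
                                 variable = "self"),
    shared = synthetic_ccgp_design(a, 100, strength = 200, seed = 2,
                                   variable = "shared"),
    inverted = synthetic_ccgp_design(-a, 100, strength = 200, seed = 3,
                                     variable = "inverted"),
    orthogonal = synthetic_ccgp_design(b, 100, strength = 200, seed = 4,
                                       variable = "orthogonal")
  )
  ax <- axis_geometry(designs)
  expect_true(all(abs(colSums(ax$axes^2) - 1) < 1e-10))
  expect_lt(ax$angles_deg["self", "shared"], 10)
  expect_gt(ax$angles_deg["self", "inverted"], 170)
  expect_lt(abs(ax$angles_deg["self", "orthogonal"] - 90), 10)
  # identical designs: angle 0, coincident embedding
  ax2 <- axis_geometry(list(a = designs$self, b = designs$self))
  expect_lt(ax2$angles_deg["a", "b"], 1e-4)
  expect_lt(sqrt(sum((ax2$mds["a", ] - ax2$mds["b", ])^2)), 1e-6)
  # 4 axes embed exactly in <= 3 dimensions; check the residual
  m3 <- cmdscale(ax$D, k = 3)
  expect_lt(max(abs(as.matrix(dist(m3)) - ax$D)), 1e-8)
})
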