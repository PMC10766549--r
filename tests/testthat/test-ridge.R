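# Ridge DP, trimming, MAPE and the greedy penalty search.

test_that("DP ridge equals exhaustive search on small matrices", {
  set.seed(17)
  cases <- list(c(3, 5), c(4, 6), c(5, 7), c(6, 8))
  for (dims in cases) {
    for (penalty in c(0, 0.1, 1, 10)) {
      power <- matrix(runif(dims[1] * dims[2]), nrow = dims[1])
      dp <- fastcwt:::ridge_dp_path(power, penalty)
      oracle <- brute_force_ridge(power, penalty)
      dp_score <- sum(power[cbind(dp, seq_len(dims[2]))]) - penalty * sum(diff(dp)^2)
      expect_equal(dp_score, oracle$score, tolerance = 1e-12)
    }
  }
})

test_that("a single nonzero row is the ridge at any penalty", {
  m <- matrix(0, nrow = 12, ncol = 20)
  m[7, ] <- 1
  sc <- generate_scales(1, 10, 12, 100, morlet(6))
  tf <- fastcwt:::new_tf_matrix(m + 0i, sc, 100)
  for (penalty in c(0, 1, 1000)) {
    rs <- extract_ridges(tf, 1, penalty)
    expect_true(all(rs$rows == 7L))
  }
})

test_that("zero penalty reduces to the per-column argmax of power", {
  set.seed(29)
  vals <- matrix(rnorm(30 * 40), nrow = 30)
  sc <- generate_scales(1, 10, 30, 100, morlet(6))
  tf <- fastcwt:::new_tf_matrix(vals + 0i, sc, 100)
  rs <- extract_ridges(tf, 1, penalty = 0)
  expect_equal(as.integer(rs$rows[1, ]),
               apply(abs(vals)^2, 2, which.max))
})

test_that("a pure tone's ridge tracks its frequency to within one scale bin", {
  fs <- 500
  w <- morlet(6)
  sc <- generate_scales(5, 100, 200, fs, w)
  sig <- make_tone(20, fs, 1000)
  tf <- fcwt_transform(sig, sc, w)
  rs <- extract_ridges(tf, 1, penalty = 1, samples = 151:850)
  bin_ratio <- 2^sc$delta_a
  expect_true(all(rs$freq_hz[1, ] / 20 < bin_ratio^1.5 &
                  rs$freq_hz[1, ] / 20 > bin_ratio^-1.5))
})

test_that("too many ridges for the exclusion geometry is an error", {
  sc <- generate_scales(1, 10, 20, 100, morlet(6))
  tf <- fastcwt:::new_tf_matrix(matrix(0i, 20, 5), sc, 100)
  expect_error(extract_ridges(tf, 3, 0), class = "fastcwt_domain_error")
})

test_that("scored spans trim 0.5 s at edges and 3.0 s from the third packet's end", {
  fs <- 500
  b <- data.frame(packet = 1:3, start = c(1L, 3001L, 5751L),
                  end = c(2500L, 5500L, 10750L))
  sp <- trim_segments(b, fs)
  expect_equal(sp$end - sp$start + 1, c(2000L, 2000L, 3250L))
  expect_equal(sp$start, b$start + 250L)
  # empty span stays empty
  tiny <- trim_segments(data.frame(packet = 1L, start = 1L, end = 100L), fs)
  expect_lt(tiny$end, tiny$start)
})

test_that("MAPE matches its closed form on fixtures", {
  truth <- matrix(rep(c(10, 2), each = 50), nrow = 2, byrow = TRUE)
  expect_equal(mape_score(truth, truth)$mape, 0)
  expect_equal(mape_score(truth * 1.1, truth)$mape, 10, tolerance = 1e-12)
  flat2 <- matrix(2, nrow = 1, ncol = 40)
  expect_equal(mape_score(flat2 + 1, flat2)$mape, 50)
  expect_error(mape_score(flat2, flat2 * 0), class = "fastcwt_domain_error")
})

test_that("MAPE strictly increases under a constant positive offset", {
  set.seed(43)
  truth <- matrix(runif(60, 5, 20), nrow = 3)
  est <- truth * (1 + 0.02 * matrix(rnorm(60), nrow = 3))
  base <- mape_score(est, truth)$mape
  for (delta in c(0.5, 1, 2)) {
    expect_gt(mape_score(est + delta, truth)$mape, base)
  }
})

test_that("ridges are matched to truth components by mean frequency", {
  # estimated rows deliberately out of order
  truth <- rbind(rep(10, 20), rep(2, 20))
  est <- rbind(rep(2.1, 20), rep(9.8, 20))
  rep_ <- mape_score(est, truth)
  expect_equal(rep_$assignment, c(2L, 1L))
  expect_lt(rep_$mape, 5)
})

test_that("greedy search evaluates 7 then 10 candidates and breaks ties low", {
  calls <- numeric(0)
  flat <- function(pen) { calls <<- c(calls, pen); 1 }
  g <- greedy_penalty_search(flat)
  expect_length(g$magnitudes, 7)
  expect_length(g$fine_coefficients, 10)
  expect_length(calls, 17)
  expect_identical(g$chosen, 0)   # smallest candidate on a flat objective

  # convex profile: chosen lands in the bracketing magnitude range
  convex <- function(pen) (log10(pen + 1e-12) - 1)^2   # minimum near 10
  g2 <- greedy_penalty_search(convex)
  expect_gte(g2$chosen, 1)
  expect_lte(g2$chosen, 100)
  # exhaustive check over the same grids
  cand <- c(g2$magnitudes, g2$fine_coefficients)
  expect_equal(convex(g2$chosen), min(sapply(g2$fine_coefficients, convex)))
})

test_that("validation runs are reproducible and correlate the two transforms", {
  v1 <- run_validation(n_runs = 2, seed = 7, fs = 500, n_scales = 48,
                       f0 = 1, f1 = 110)
  v2 <- run_validation(n_runs = 2, seed = 7, fs = 500, n_scales = 48,
                       f0 = 1, f1 = 110)
  expect_identical(v1$per_run, v2$per_run)
  expect_equal(nrow(v1$per_run), 2 * 3 * 2)
  expect_true(all(v1$per_run$mape_percent >= 0))
  expect_error(run_validation(n_runs = 1, seed = 1), class = "fastcwt_domain_error")
})
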