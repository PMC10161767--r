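test_that("Poisson noise keeps an all-zero curve at zero", {
  z <- ichi_curve(rep(0, 36), grid = chi_grid(36))
  expect_identical(add_poisson_noise(z, 100, seed = 1)$intensity, rep(0, 36))
})

test_that("Poisson noise has the right mean and variance", {
  grid <- chi_grid(36)
  clean <- ichi_curve(seq(0.05, 1, length.out = 36), grid = grid)
  counts <- 400
  reps <- 10000
  draws <- vapply(
    seq_len(reps),
    function(s) add_poisson_noise(clean, counts, seed = s)$intensity,
    double(36)
  )
  # on the counts scale each bin is Poisson(lambda = intensity * counts)
  lam <- clean$intensity * counts
  counts_draws <- draws * counts
  mhat <- rowMeans(counts_draws)
  expect_true(all(abs(mhat - lam) <= 3 * sqrt(lam / reps) + 1e-9))
  vhat <- apply(counts_draws, 1, var)
  big <- lam >= 50
  expect_true(all(vhat[big] / lam[big] > 0.9 & vhat[big] / lam[big] < 1.1))
})

test_that("blockwise masking reaches the exact bin count, over ratios and seeds", {
  cu <- bump_curve(0)
  expect_equal(sum(!blockwise_mask(cu, 0.3, seed = 1)$valid_mask), 108)
  for (ratio in seq(0, 0.6, by = 0.1)) {
    for (s in 1:5) {
      out <- blockwise_mask(cu, ratio, seed = s)
      expect_equal(sum(!out$valid_mask), round(ratio * 360))
    }
  }
  expect_identical(blockwise_mask(cu, 0, seed = 4), cu)
})

test_that("masked blocks are circularly contiguous and can wrap the seam", {
  cu <- bump_curve(0)
  wrapped <- FALSE
  for (s in 1:100) {
    out <- blockwise_mask(cu, 20 / 360, block_len_range = c(20, 20), seed = s)
    m <- !out$valid_mask
    expect_equal(sum(m), 20)
    # one block of 20: on the circle, exactly one FALSE->TRUE transition
    trans <- sum(m != m[c(2:360, 1)]) / 2
    expect_equal(trans, 1)
    if (m[1] && m[360]) wrapped <- TRUE
  }
  expect_true(wrapped) # some seeds mask across the head-tail seam
})

test_that("masking zeroes masked bins and leaves valid bins untouched", {
  cu <- bump_curve(45)
  out <- blockwise_mask(cu, 0.3, seed = 9)
  expect_true(all(out$intensity[!out$valid_mask] == 0))
  expect_identical(
    out$intensity[out$valid_mask], cu$intensity[out$valid_mask]
  )
})

test_that("random scaling sets the maximum to the drawn value", {
  cu <- bump_curve(10.5) # bump apex exactly on a bin center, max exactly 1
  one <- random_scale(cu, c(1, 1), seed = 2)
  expect_identical(max(one$intensity), 1)
  maxima <- vapply(
    1:10000,
    function(s) max(random_scale(cu, c(0.95, 1.05), seed = s)$intensity),
    double(1)
  )
  expect_gt(stats::ks.test(maxima, "punif", 0.95, 1.05)$p.value, 0.01)
  # shape preserved: the output is the input times one scalar
  sc <- random_scale(cu, c(0.9, 1.1), seed = 3)
  expect_identical(sc$intensity, cu$intensity * max(sc$intensity))
})

test_that("the identity corruption config is an identity transform", {
  cu <- bump_curve(-60)
  cfg <- corruption_config(
    counts_level_range = c(Inf, Inf), mask_ratio = 0, scale_range = c(1, 1)
  )
  expect_identical(corrupt(cu, cfg), cu)
})

test_that("corruption is seeded and jointly satisfies its sub-contracts", {
  cu <- bump_curve(30)
  cfg <- corruption_config(seed = 31)
  a <- corrupt(cu, cfg)
  b <- corrupt(cu, cfg)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$valid_mask, b$valid_mask)
  expect_equal(sum(!a$valid_mask), round(0.3 * 360))
  # valid-bin intensities differ from clean only via noise and one scale
  expect_true(all(a$intensity[!a$valid_mask] == 0))
  expect_true(max(a$intensity) >= 0.95 && max(a$intensity) <= 1.05)
})

test_that("the default masking ratio is 0.3", {
  expect_equal(corruption_config()$mask_ratio, 0.3)
})
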