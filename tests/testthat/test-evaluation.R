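test_that("reconstruction is the deterministic forward model", {
  p <- random_params(1, seed = 41)
  clean <- simulate_ichi(p)
  expect_identical(reconstruct(p)$intensity, clean$intensity)
  # codec round trip does not perturb the reconstruction
  rt <- decode_labels(encode_labels(canonical_order(p)))
  expect_lt(max(abs(reconstruct(rt)$intensity - clean$intensity)), 1e-9)
  # wrong parameters give a strictly positive error
  wrong <- p
  wrong$gamma1 <- norm_angle180(wrong$gamma1 + 45)
  expect_gt(rmse(reconstruct(canonical_order(wrong)), clean), 0)
})

test_that("rmse satisfies its identities and matches a brute-force oracle", {
  grid <- chi_grid(60)
  a <- bump_curve(20, grid = grid)
  expect_identical(rmse(a, a), 0)

  # curves differing by a constant offset away from the shared maximum
  v <- rep(0.5, 60)
  v[10] <- 1
  b1 <- ichi_curve(v, grid = grid)
  v2 <- v
  v2[-10] <- v[-10] + 0.1
  b2 <- ichi_curve(v2, grid = grid)
  expect_equal(rmse(b1, b2), 0.1 * sqrt(59 / 60), tolerance = 1e-12)

  # brute-force formula on random masked pairs
  set.seed(33)
  for (i in 1:100) {
    x <- ichi_curve(runif(60, 0.1, 1),
      grid = grid,
      valid_mask = runif(60) > 0.2
    )
    y <- ichi_curve(runif(60, 0.1, 1),
      grid = grid,
      valid_mask = runif(60) > 0.2
    )
    ok <- x$valid_mask & y$valid_mask
    xa <- x$intensity[ok] / max(x$intensity[ok])
    ya <- y$intensity[ok] / max(y$intensity[ok])
    expect_equal(rmse(x, y), sqrt(mean((xa - ya)^2)), tolerance = 1e-12)
    expect_equal(rmse(x, y), rmse(y, x)) # symmetry
  }

  # disjoint masks are an error
  left <- ichi_curve(runif(60), grid = grid, valid_mask = rep(c(TRUE, FALSE), each = 30))
  right <- ichi_curve(runif(60), grid = grid, valid_mask = rep(c(FALSE, TRUE), each = 30))
  expect_error(rmse(left, right), "overlapping")
})

test_that("peak detection finds bumps, ignores flats, caps at four peaks", {
  pk <- detect_peaks(bump_curve(30))
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$location - 30), 1.01)

  flat <- ichi_curve(rep(0.5, 360))
  expect_equal(nrow(detect_peaks(flat)), 0)

  p <- orientation_params(0, 0, 60, 20, 0, 0, -30, 20, lam_ratio = 1.5)
  pk4 <- detect_peaks(simulate_ichi(p))
  expect_equal(nrow(pk4), 4)
})

test_that("detected peak locations shift monotonically with gamma", {
  locs <- vapply(seq(10, 40, by = 5), function(g) {
    p <- canonical_order(
      orientation_params(0, 0, g, 20, 0, 0, -60, 20, lam_ratio = 2)
    )
    pk <- detect_peaks(simulate_ichi(p))
    # follow the arc near gamma + 90
    pk$location[which.min(abs(pk$location - (g + 90)))]
  }, double(1))
  expect_true(all(diff(locs) > 0))
})

test_that("peak correlation behaves on identical, permuted and printed pairs", {
  # identical peak sets give perfect correlation
  sets <- lapply(1:20, function(i) {
    pk <- detect_peaks(simulate_ichi(random_params(1, seed = 700 + i)))
    list(recon = pk, ref = pk)
  })
  res <- peak_pearson(sets)
  expect_equal(res$r_location, 1)
  expect_equal(res$r_intensity, 1)

  # permuting intensities across matches decorrelates intensity only
  set.seed(8)
  locs <- runif(200, -170, 170)
  ints <- runif(200, 0.2, 1)
  pairs <- lapply(1:200, function(i) {
    list(
      recon = tibble::tibble(location = locs[i], intensity = sample(ints, 1)),
      ref = tibble::tibble(location = locs[i], intensity = ints[i])
    )
  })
  res2 <- peak_pearson(pairs)
  expect_equal(res2$r_location, 1, tolerance = 1e-9)
  expect_lt(abs(res2$r_intensity), 0.2)

  # hand-computed Pearson on five printed pairs
  ref <- c(-120, -40, 10, 90, 150)
  rec <- c(-118, -44, 15, 88, 149)
  pairs5 <- lapply(1:5, function(i) {
    list(
      recon = tibble::tibble(location = rec[i], intensity = rec[i] / 100),
      ref = tibble::tibble(location = ref[i], intensity = ref[i] / 100)
    )
  })
  res5 <- peak_pearson(pairs5)
  hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(res5$r_location, hand(ref, rec), tolerance = 1e-12)
  expect_equal(res5$r_intensity, hand(ref / 100, rec / 100), tolerance = 1e-12)
})

test_that("label metrics satisfy the R-squared and MAE identities", {
  truth <- random_params(200, seed = 51)
  perfect <- label_metrics(truth, truth)
  expect_equal(perfect$r2, rep(1, 9))
  expect_equal(perfect$mae, rep(0, 9))

  # predicting the (circular) truth mean gives R-squared of zero
  const <- truth
  for (nm in fiborient:::ANGLE_NAMES) {
    m <- fiborient:::circular_mean180(truth[[nm]])
    # spreads live on [0, 180); the same circle point, valid representative
    if (grepl("^dgamma", nm) && m < 0) m <- m + 180
    const[[nm]] <- m
  }
  const$lam_ratio <- mean(truth$lam_ratio)
  zero <- label_metrics(const, truth)
  expect_equal(zero$r2, rep(0, 9), tolerance = 1e-9)

  # brute-force oracle for the linear (ratio) label and one angle label
  pred <- random_params(200, seed = 52)
  m <- label_metrics(pred, truth)
  res <- pred$lam_ratio - truth$lam_ratio
  dev <- truth$lam_ratio - mean(truth$lam_ratio)
  expect_equal(
    m$r2[m$label == "lam_ratio"], 1 - sum(res^2) / sum(dev^2),
    tolerance = 1e-12
  )
  expect_equal(
    m$mae[m$label == "lam_ratio"], mean(abs(res)),
    tolerance = 1e-12
  )
  wrap <- function(x) (x + 90) %% 180 - 90 # independent circular reduction
  resg <- wrap(pred$gamma1 - truth$gamma1)
  expect_equal(
    m$mae[m$label == "gamma1"], mean(abs(resg)),
    tolerance = 1e-12
  )

  expect_error(
    label_metrics(truth, dplyr::mutate(truth, lam_ratio = 1)),
    "zero-variance"
  )
})

test_that("a perfect oracle model scores perfectly in phase 1", {
  labels <- sample_labels(60, seed = 61)
  ds <- build_dataset(labels,
    grid = chi_grid(120), corruption = NULL, seed = 61,
    split_fracs = c(train = 0.5, val = 0.2, test = 0.3)
  )
  te <- which(ds$split == "test")
  oracle <- structure(
    list(
      algo = "knn",
      fit = list(
        X = fiborient:::dataset_features(ds, te),
        Y = ds$labels[te, , drop = FALSE], k = 1L
      ),
      input_len = 2L * 120L, n_bins = 120L,
      train_fingerprint = c(n_train = length(te), seed = 61L)
    ),
    class = c("knn_model", "fib_model")
  )
  rep <- evaluate(oracle, ds, phase = "phase1")
  expect_lt(rep$rmse_mean, 1e-9)
  expect_equal(rep$pearson_location, 1, tolerance = 1e-9)
  expect_equal(rep$pearson_intensity, 1, tolerance = 1e-6)
  expect_true(all(rep$label_metrics$r2 > 1 - 1e-9))
  g <- glance(rep)
  expect_equal(g$n_repetitions, 1L)
})

test_that("single-repetition aggregates report zero standard deviations", {
  labels <- sample_labels(50, seed = 63)
  ds <- build_dataset(labels,
    grid = chi_grid(90),
    corruption = corruption_config(block_len_range = c(3, 15)),
    split_fracs = c(train = 0.6, val = 0.2, test = 0.2), seed = 63
  )
  trainer <- function(d, s) train_baseline(d, "knn", hyperparams = list(k = 3))
  rep <- repeat_phase1(ds, trainer, n_repetitions = 1, seed = 5)
  expect_equal(rep$rmse_sd, 0)
  expect_equal(rep$pearson_location_sd, 0)
  expect_equal(rep$n_repetitions, 1L)
  expect_s3_class(tidy(rep), "tbl_df")
})
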