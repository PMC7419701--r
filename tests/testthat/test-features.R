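# Seed-correlation features: parcel series, correlation volumes, example
# sets and the per-voxel inference stream.

test_that("train/validation partitioning is exact and conserved", {
  part <- partition_indices(1000, c(0.7, 0.3), seed = 1)
  expect_identical(sum(part == "train"), 700L)
  expect_identical(sum(part == "validation"), 300L)
  # deterministic
  expect_identical(part, partition_indices(1000, c(0.7, 0.3), seed = 1))
  expect_false(identical(part, partition_indices(1000, c(0.7, 0.3), seed = 2)))
  expect_error(partition_indices(10, c(0.6, 0.3)), "summing to 1")
})

test_that("parcel mean series equal hand-computed voxel averages", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  proto <- tiny_protocol(40, grid)
  run <- simulate_rest_run(atlas, proto, snr = 2, seed = 6)
  M <- run_matrix(run)
  ts <- extract_roi_timeseries(run, atlas)
  lv <- as.vector(atlas$label_volume)
  for (r in 1:4)
    expect_equal(ts[, r], rowMeans(M[, lv == r, drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  # censoring drops frames from the series
  cm <- structure(list(keep = c(rep(TRUE, 38), FALSE, FALSE)),
                  class = "censor_mask")
  expect_identical(nrow(extract_roi_timeseries(run, atlas, cm)), 38L)
  # a parcel of identical voxels equals any member voxel
  M2 <- M
  M2[, lv == 1] <- M[, which(lv == 1)[1]]
  run2 <- run
  run2$data <- array(t(M2), dim = dim(run$data))
  ts2 <- extract_roi_timeseries(run2, atlas)
  expect_equal(ts2[, 1], M[, which(lv == 1)[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("seed correlation volumes match the covariance formula", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  run <- simulate_rest_run(atlas, tiny_protocol(100, grid), snr = 1, seed = 8)
  M <- run_matrix(run)
  inmask <- which(as.vector(atlas$brain_mask))
  sv <- inmask[200]
  seed_series <- M[, sv]
  cv <- seed_correlation_volume(run, seed_series)
  # textbook covariance / (sd sd) formula, voxel by voxel (spot checks)
  for (v in c(inmask[1], inmask[50], sv, inmask[800])) {
    r <- sum((M[, v] - mean(M[, v])) * (seed_series - mean(seed_series))) /
      sqrt(sum((M[, v] - mean(M[, v]))^2) * sum((seed_series - mean(seed_series))^2))
    expect_equal(as.vector(cv$values)[v], atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)),
                 tolerance = 1e-12)
  }
  # perfect and anti-perfect correlation clamp at atanh(1 - 1e-7)
  expect_equal(as.vector(cv$values)[sv], atanh(1 - 1e-7))
  neg <- seed_correlation_volume(run, -seed_series)
  expect_equal(as.vector(neg$values)[sv], -atanh(1 - 1e-7))
  expect_error(seed_correlation_volume(run, rep(1, 100)), "degenerate seed")
})

test_that("correlation is symmetric between seed and target voxels", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  run <- simulate_rest_run(atlas, tiny_protocol(60, grid), snr = 1, seed = 9)
  M <- run_matrix(run)
  inmask <- which(as.vector(atlas$brain_mask))
  a <- inmask[100]; b <- inmask[901]
  va <- seed_correlation_volume(run, M[, a])
  vb <- seed_correlation_volume(run, M[, b])
  expect_equal(as.vector(va$values)[b], as.vector(vb$values)[a],
               tolerance = 1e-12)
})

test_that("example sets count, label and partition correctly", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  proto <- tiny_protocol(60, grid)
  cohort <- lapply(1:3, function(s)
    pool_runs(list(preprocess_run(simulate_rest_run(atlas, proto, snr = 5,
                                                    seed = 40 + s),
                                  preprocess_config()))))
  ex <- build_training_examples(cohort, atlas, seed = 2)
  expect_identical(nrow(ex$volumes), 12L)  # 3 subjects x 4 parcels
  expect_identical(ncol(ex$volumes), as.integer(prod(grid)))
  expect_identical(sort(unique(ex$labels)), 1:2)
  expect_identical(sum(ex$partition == "train") +
                     sum(ex$partition == "validation"), 12L)
  ex2 <- build_training_examples(cohort, atlas, seed = 2)
  expect_identical(ex$partition, ex2$partition)
  # labels follow the seed parcel's network
  expect_identical(ex$labels, rep(as.integer(atlas$network_of_roi), 3))
  # min_frames exclusion warns and drops the subject
  short <- cohort
  short[[1]]$mat <- short[[1]]$mat[1:10, ]
  expect_warning(ex3 <- build_training_examples(short, atlas, seed = 2,
                                                min_frames = 30),
                 "excluded")
  expect_identical(nrow(ex3$volumes), 8L)
})

test_that("inference stream covers the mask in raster order", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  proto <- tiny_protocol(60, grid)
  pooled <- pool_runs(list(preprocess_run(
    simulate_rest_run(atlas, proto, snr = 5, seed = 77),
    preprocess_config())))
  stream <- build_inference_examples(pooled, mask = atlas$brain_mask,
                                     chunk_size = 100)
  expect_identical(attr(stream, "n_voxels"), sum(atlas$brain_mask))
  seen <- integer(0)
  repeat {
    ch <- stream()
    if (is.null(ch)) break
    expect_lte(nrow(ch$z), 100)
    seen <- c(seen, ch$voxels)
  }
  # masked-out voxels are never emitted; order is the raster order
  expect_identical(seen, which(as.vector(atlas$brain_mask)))
})

test_that("noiseless parcel voxels reproduce their training example", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 3, 2)
  proto <- tiny_protocol(80, grid)
  pooled <- pool_runs(list(preprocess_run(
    simulate_rest_run(atlas, proto, snr = Inf, drift_amplitude = 0, seed = 5),
    preprocess_config(nuisance = FALSE, smooth_fwhm_mm = 0))))
  ex <- build_training_examples(list(pooled), atlas, seed = 1)
  stream <- build_inference_examples(pooled, mask = atlas$brain_mask,
                                     chunk_size = prod(grid))
  ch <- stream()
  lv <- as.vector(atlas$label_volume)[ch$voxels]
  i <- which(lv == 1)[1]     # a voxel inside the Broca-like parcel
  train_vol <- ex$volumes[which(ex$labels == 1)[1], ]
  cosine <- sum(ch$z[i, ] * train_vol) /
    sqrt(sum(ch$z[i, ]^2) * sum(train_vol^2))
  expect_gte(cosine, 0.99)
})

test_that("pure-noise background voxels yield near-zero correlation volumes", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  proto <- acquisition_protocol(2.2, 160, 1, 3, grid)
  lv <- as.vector(atlas$label_volume)
  bg <- which(as.vector(atlas$brain_mask) & lv == 0 &
                !as.vector(atlas$wm_mask) & !as.vector(atlas$csf_mask))[1]
  for (s in 1:20) {
    run <- simulate_rest_run(atlas, proto, snr = 5, seed = 700 + s)
    # detrend only: smoothing/filtering would induce trivial neighbor
    # correlations around the seed voxel itself
    pp <- preprocess_run(run, preprocess_config(lowpass_hz = NULL,
                                                smooth_fwhm_mm = 0,
                                                nuisance = FALSE))
    M <- run_matrix(pp$run)
    z <- langmap:::corr_with_seed(M, M[, bg])
    z[bg] <- 0   # self-correlation excluded
    expect_lt(max(abs(z)), atanh(0.5))
  }
})

test_that("censoring uncorrelated frames moves correlations only slightly", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  proto <- acquisition_protocol(2.2, 120, 1, 3, grid)
  lv <- as.vector(atlas$label_volume)
  v1 <- which(lv == 1)[1]; v2 <- which(lv == 1)[2]
  for (s in 1:10) {
    run <- simulate_rest_run(atlas, proto, snr = 5, seed = 900 + s)
    M <- run_matrix(run)
    r_full <- cor(M[, v1], M[, v2])
    drop <- seq(5, 115, by = 10)
    r_cens <- cor(M[-drop, v1], M[-drop, v2])
    expect_lt(abs(r_full - r_cens), 3 / sqrt(120 - length(drop)))
  }
})
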