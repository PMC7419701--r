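# Dense 3D CNN: layer accounting, kernel correctness, gradients, training
# behavior, prediction and probability-map smoothing.

test_that("layer accounting reproduces the reference and desk configurations", {
  ref <- densenet3d_config(n_dense_blocks = 3, total_layers = 49,
                           n_classes = 11)
  expect_identical(ref$layers_per_block, rep(15L, 3))
  m <- build_model(ref, c(16, 16, 16), seed = 1)
  expect_identical(nrow(m$manifest), 49L)
  expect_identical(sum(m$manifest$kind == "conv3d"), 48L)
  expect_identical(sum(m$manifest$kind == "dense"), 1L)

  desk <- densenet3d_config(n_dense_blocks = 2, total_layers = 14,
                            n_classes = 6)
  expect_identical(sum(desk$layers_per_block), 11L)
  md <- build_model(desk, c(16, 16, 16), seed = 1)
  expect_identical(nrow(md$manifest), 14L)

  expect_error(densenet3d_config(kernel_edges = c(3, 4)), "odd")
  expect_error(densenet3d_config(n_dense_blocks = 4, total_layers = 6),
               "configuration error")
  expect_error(densenet3d_config(pooling = "max"), "average")
})

test_that("the 3D convolution kernel matches a brute-force oracle", {
  set.seed(42)
  x <- array(rnorm(6 * 5 * 4 * 2 * 2), c(6, 5, 4, 2, 2))
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  got <- langmap:::.conv3d_fwd_cpp(x, dim(x), as.numeric(w), 3L, b)
  d <- dim(x)
  r <- 1
  want <- array(0, c(d[1:3], 3, d[5]))
  for (n in 1:d[5]) for (co in 1:3) {
    acc <- array(b[co], d[1:3])
    for (ci in 1:d[4]) for (kz in -r:r) for (ky in -r:r) for (kx in -r:r)
      for (z in 1:d[3]) for (y in 1:d[2]) for (xx in 1:d[1]) {
        xs <- xx + kx; ys <- y + ky; zs <- z + kz
        if (xs >= 1 && xs <= d[1] && ys >= 1 && ys <= d[2] &&
            zs >= 1 && zs <= d[3])
          acc[xx, y, z] <- acc[xx, y, z] +
            w[kx + 2, ky + 2, kz + 2, ci, co] * x[xs, ys, zs, ci, n]
      }
    want[, , , co, n] <- acc
  }
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("average pooling handles full and partial windows", {
  x <- array(seq_len(5 * 5 * 5), c(5, 5, 5, 1, 1))
  p <- langmap:::.avgpool3d_fwd_cpp(as.numeric(x), dim(x), 2L)
  expect_identical(dim(p), c(3L, 3L, 3L, 1L, 1L))
  expect_equal(p[1, 1, 1, 1, 1], mean(x[1:2, 1:2, 1:2, 1, 1]))
  expect_equal(p[3, 1, 1, 1, 1], mean(x[5, 1:2, 1:2, 1, 1]))   # partial in x
  expect_equal(p[3, 3, 3, 1, 1], x[5, 5, 5, 1, 1])             # corner voxel
  # backward distributes gradients uniformly and conserves their sum
  g <- array(rnorm(27), c(3, 3, 3, 1, 1))
  gi <- langmap:::.avgpool3d_bwd_cpp(dim(x), as.numeric(g), 2L)
  expect_equal(sum(gi), sum(g), tolerance = 1e-12)
  expect_equal(gi[1, 1, 1, 1, 1], g[1, 1, 1, 1, 1] / 8, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(7)
  cfg <- densenet3d_config(n_dense_blocks = 2, total_layers = 6,
                           kernel_edges = c(3, 5), growth_rate = 2,
                           n_stem_channels = 3, n_classes = 3)
  model <- build_model(cfg, c(8, 8, 8), seed = 1)
  n <- 3
  X <- matrix(rnorm(n * 512), n, 512)
  y <- c(1, 2, 3)
  loss_of <- function(m) {
    xx <- langmap:::examples_as_input(X, m$input_shape)
    pr <- langmap:::softmax_rows(
      langmap:::net_forward(m, xx, training = TRUE)$logits)
    -mean(log(pr[cbind(seq_len(n), y)]))
  }
  xx <- langmap:::examples_as_input(X, model$input_shape)
  fw <- langmap:::net_forward(model, xx, training = TRUE)
  pr <- langmap:::softmax_rows(fw$logits)
  g <- pr
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  grads <- langmap:::net_backward(model, fw$cache, g / n)
  eps <- 1e-5
  for (key in c("stem.conv", "b1.l2.conv", "b1.l1.bn", "t1.conv",
                "b2.l1.conv", "head.fc")) {
    for (fld in names(grads[[key]])) {
      arr <- model$params[[key]][[fld]]
      set.seed(100)
      for (trial in 1:3) {
        i <- sample(length(arr), 1)
        up <- model; up$params[[key]][[fld]][i] <- arr[i] + eps
        dn <- model; dn$params[[key]][[fld]][i] <- arr[i] - eps
        num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
        ana <- as.numeric(grads[[key]][[fld]])[i]
        expect_equal(ana, num, tolerance = 1e-3)
      }
    }
  }
})

test_that("batch normalization standardizes batch statistics", {
  set.seed(5)
  x <- array(rnorm(64 * 2 * 10, mean = 3, sd = 2), c(4, 4, 4, 2, 10))
  r <- langmap:::.bn_fwd_cpp(as.numeric(x), 64, 2L, 10L, c(1, 1), c(0, 0),
                             c(0, 0), c(1, 1), 1e-5, TRUE)
  y <- array(r$y, dim(x))
  for (c in 1:2) {
    expect_equal(mean(y[, , , c, ]), 0, tolerance = 1e-8)
    expect_equal(var(as.vector(y[, , , c, ])), 1, tolerance = 1e-2)
  }
  # eval mode uses the provided running statistics
  r2 <- langmap:::.bn_fwd_cpp(as.numeric(x), 64, 2L, 10L, c(1, 1), c(0, 0),
                              c(3, 3), c(4, 4), 0, FALSE)
  expect_equal(array(r2$y, dim(x)), (x - 3) / 2, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the early-stop rule fires after the configured stall", {
  # monotone worsening after the first validation: stops after exactly
  # patience more validations
  expect_identical(langmap:::early_stop_index(c(0.8, 0.7, 0.6, 0.5, 0.4), 3), 4L)
  expect_identical(langmap:::early_stop_index(c(0.5, 0.6, 0.7, 0.8), 3),
                   NA_integer_)
  expect_identical(langmap:::early_stop_index(c(0.8, 0.8, 0.8, 0.8), 3), 4L)
})

test_that("training separates planted classes and collapses on shuffled labels", {
  set.seed(33)
  # synthetic separable correlation-volume analogs: one blob per class
  grid <- c(8, 8, 8)
  centers <- list(c(3, 3, 3), c(6, 6, 3), c(3, 6, 6))
  make_example <- function(cl) {
    v <- array(rnorm(512, sd = 0.3), grid)
    cc <- centers[[cl]]
    v[cc[1] + (-1:1), cc[2] + (-1:1), cc[3] + (-1:1)] <-
      v[cc[1] + (-1:1), cc[2] + (-1:1), cc[3] + (-1:1)] + 3
    as.vector(v)
  }
  n_per <- 60
  labs <- rep(1:3, each = n_per)
  vols <- t(vapply(labs, make_example, numeric(512)))
  ex <- structure(list(volumes = vols, labels = labs,
                       partition = partition_indices(length(labs),
                                                     c(0.7, 0.3), seed = 4),
                       input_shape = grid, n_classes = 3L),
                  class = "example_set")
  cfg <- densenet3d_config(n_dense_blocks = 2, total_layers = 6,
                           growth_rate = 3, n_stem_channels = 4,
                           n_classes = 3, batch_size = 16, max_epochs = 25,
                           patience_validations = 4)
  fit <- rsn_densenet(ex, cfg, seed = 1)
  expect_gte(fit$history$best_accuracy, 0.95)
  # invariant: early stop implies no improvement over the trailing window
  h <- fit$history$table
  if (fit$history$stop_reason == "early-stop") {
    k <- cfg$patience_validations
    expect_lte(max(tail(h$accuracy, k)), max(head(h$accuracy, -k)) + 1e-12)
  }
  # shuffled labels -> chance-level validation accuracy
  ex_sh <- ex
  ex_sh$labels <- sample(ex$labels)
  fit_sh <- rsn_densenet(ex_sh, cfg, seed = 1)
  expect_lt(abs(fit_sh$history$best_accuracy - 1 / 3), 0.2)
  # degenerate label sets are refused
  ex_one <- ex
  ex_one$labels <- rep(1L, length(ex$labels))
  expect_error(rsn_densenet(ex_one, cfg, seed = 1), "degeneracy")
})

test_that("probability volumes are proper distributions with flagged voxels", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  proto <- tiny_protocol(60, grid)
  pooled <- pool_runs(list(preprocess_run(
    simulate_rest_run(atlas, proto, snr = 5, seed = 3),
    preprocess_config())))
  # force one in-mask voxel to be constant (degenerate seed)
  degen_vox <- which(as.vector(atlas$brain_mask))[5]
  pooled$mat[, degen_vox] <- 7
  cohort <- list(pooled)
  ex <- build_training_examples(cohort, atlas, seed = 1)
  cfg <- densenet3d_config(n_dense_blocks = 1, total_layers = 4,
                           growth_rate = 2, n_stem_channels = 3,
                           n_classes = 2, batch_size = 4, max_epochs = 2)
  fit <- rsn_densenet(ex, cfg, seed = 1)
  stream <- build_inference_examples(pooled, mask = atlas$brain_mask)
  pv <- predict_volume(fit, stream, atlas$brain_mask)
  sums <- apply(pv$probs, 1:3, sum)
  expect_lt(max(abs(sums[atlas$brain_mask] - 1)), 1e-5)
  expect_equal(max(abs(sums[!atlas$brain_mask])), 0)
  expect_gte(pv$n_flagged, 1L)
  idx <- arrayInd(degen_vox, grid)
  expect_equal(pv$probs[idx[1], idx[2], idx[3], ], c(0.5, 0.5))
  # coverage mismatch is an error
  stream2 <- build_inference_examples(pooled, mask = atlas$brain_mask)
  expect_error(predict_volume(fit, stream2, array(TRUE, grid)), "coverage")
})

test_that("probability smoothing preserves sums and removes salt noise", {
  grid <- c(10, 10, 10)
  K <- 3
  mask <- array(TRUE, grid)
  probs <- array(0, c(grid, K))
  probs[, , , 1] <- 0.8; probs[, , , 2] <- 0.15; probs[, , , 3] <- 0.05
  # single-voxel salt noise inside the homogeneous region
  probs[5, 5, 5, ] <- c(0.05, 0.05, 0.9)
  pv <- structure(list(probs = probs, class_names = paste0("n", 1:K),
                       mask = mask, n_flagged = 0L),
                  class = "probability_volume")
  sm <- smooth_probability(pv, mode_window = 3, box_length = 0)
  labs <- langmap:::winner_labels(sm$probs, mask)
  expect_identical(labs[5, 5, 5], 1L)          # mode filter removed the speck
  sums <- apply(sm$probs, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # box filter stage matches a 3-tap moving-average oracle (one class plane)
  sm2 <- smooth_probability(pv, mode_window = 0, box_length = 3)
  oracle_1d <- function(v) {
    n <- length(v)
    vp <- c(v[1], v, v[n])                     # symmetric reflection
    (vp[1:n] + vp[2:(n + 1)] + vp[3:(n + 2)]) / 3
  }
  p1 <- probs[, , , 1]
  for (z in 1:10) for (y in 1:10) p1[, y, z] <- oracle_1d(p1[, y, z])
  for (z in 1:10) for (x in 1:10) p1[x, , z] <- oracle_1d(p1[x, , z])
  for (y in 1:10) for (x in 1:10) p1[x, y, ] <- oracle_1d(p1[x, y, ])
  raw_box <- array(langmap:::.sepconv3d_cpp(as.numeric(probs), 10, 10, 10, K,
                                            rep(list(rep(1 / 3, 3)), 3)),
                   c(grid, K))
  expect_equal(raw_box[, , , 1], p1, tolerance = 1e-12)
  sums2 <- apply(sm2$probs, 1:3, sum)
  expect_lt(max(abs(sums2 - 1)), 1e-5)
  # uniform volumes are fixed points of both stages
  up <- pv
  up$probs <- array(1 / K, c(grid, K))
  usm <- smooth_probability(up, 3, 3)
  expect_equal(usm$probs, up$probs, tolerance = 1e-10)
  expect_error(smooth_probability(pv, mode_window = 4), "odd")
  expect_error(smooth_probability(pv, box_length = 2), "odd")
})

test_that("class permutation equivariance holds through smoothing", {
  set.seed(12)
  grid <- c(8, 8, 8)
  K <- 3
  raw <- array(runif(prod(grid) * K), c(grid, K))
  norm <- sweep(raw, 1:3, apply(raw, 1:3, sum), "/")
  mask <- array(TRUE, grid)
  pv <- structure(list(probs = norm, class_names = paste0("n", 1:K),
                       mask = mask, n_flagged = 0L),
                  class = "probability_volume")
  perm <- c(2, 3, 1)
  pv_perm <- pv
  pv_perm$probs <- pv$probs[, , , perm]
  # note: permuting classes changes mode-filter tie-breaks, so equivariance
  # is exact for the box stage and for tie-free mode inputs
  a <- smooth_probability(pv, mode_window = 0, box_length = 3)
  b <- smooth_probability(pv_perm, mode_window = 0, box_length = 3)
  expect_equal(b$probs, a$probs[, , , perm], tolerance = 1e-12)
})
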