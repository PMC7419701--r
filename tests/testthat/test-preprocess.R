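# Denoising chain: detrending, zero-phase low-pass, smoothing, nuisance
# regression, frame censoring, and the assembled pipeline.

test_that("detrending removes exact lines and nothing else it shouldn't", {
  grid <- c(16, 16, 16)
  nt <- 40
  line <- outer(seq_len(nt), rep(1, prod(grid)), function(a, b) 2 + 3 * a)
  run <- manual_run(line, grid)
  out <- detrend_run(run)
  expect_lt(max(abs(out$data)), 1e-9)

  # a sinusoid keeps its shape up to its own best-fit line
  tt <- seq_len(nt)
  s <- sin(2 * pi * tt / 15)
  sin_mat <- matrix(rep(s, prod(grid)), nt)
  out2 <- detrend_run(manual_run(sin_mat, grid))
  resid_slope <- coef(lm(run_matrix(out2)[, 1] ~ tt))[2]
  expect_lt(abs(resid_slope), 1e-10)

  expect_error(detrend_run(manual_run(matrix(1, 2, prod(grid)), grid)),
               "3 frames")
})

test_that("the low-pass filter has the stated band behavior", {
  tr <- 2.2
  nt <- 320
  tt <- (seq_len(nt) - 1) * tr
  ratio <- function(f_hz) {
    x <- sin(2 * pi * f_hz * tt)
    y <- as.vector(langmap:::zero_phase_lowpass(matrix(x, ncol = 1), 0.1, tr))
    X <- abs(fft(x))[1:(nt / 2)]
    Y <- abs(fft(y))[1:(nt / 2)]
    i <- which.max(X)
    Y[i] / X[i]
  }
  expect_gte(ratio(0.05), 0.9)   # passband
  expect_lte(ratio(0.2), 0.1)    # stopband
  # squared-magnitude response matches the analytic Butterworth form
  expect_equal(ratio(0.05), 1 / (1 + (0.05 / 0.1)^4), tolerance = 0.03)

  grid <- c(16, 16, 16)
  const <- manual_run(matrix(7, 64, prod(grid)), grid)
  out <- lowpass_filter(const, 0.1)
  expect_equal(out$data, const$data, tolerance = 1e-10)
  expect_error(lowpass_filter(const, 0.5), "Nyquist")
})

test_that("the zero-phase filter is linear and agrees with a reference filtfilt", {
  tr <- 2.2
  set.seed(11)
  x <- rnorm(300)
  y <- rnorm(300)
  f <- function(v) as.vector(langmap:::zero_phase_lowpass(matrix(v, ncol = 1),
                                                          0.1, tr))
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-10)
  # interior agreement with signal::filtfilt (edge handling differs by design)
  ba <- signal::butter(2, 0.1 / (1 / (2 * tr)), "low")
  ref <- signal::filtfilt(ba, x)
  expect_equal(f(x)[40:260], ref[40:260], tolerance = 1e-8)
})

test_that("spatial smoothing is a mass-conserving separable Gaussian", {
  v <- array(0, c(16, 16, 16))
  v[8, 8, 8] <- 1
  s <- spatial_smooth(v, 6, 3)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  k <- exp(-(-3:3)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # impulse response = separable product of the 1D kernel
  expect_equal(s[8, 8, 8], k[4]^3, tolerance = 1e-12)
  expect_equal(s[8 + 1, 8, 8], k[5] * k[4]^2, tolerance = 1e-12)
  expect_equal(s[8 + 1, 8 - 2, 8], k[5] * k[2] * k[4], tolerance = 1e-12)
  expect_equal(sum(s), 1, tolerance = 1e-6)
  # identity and uniform fixed points
  expect_identical(spatial_smooth(v, 0, 3), v)
  u <- array(5, c(16, 16, 16))
  expect_equal(spatial_smooth(u, 6, 3), u, tolerance = 1e-10)
  expect_error(spatial_smooth(v, -1, 3), ">= 0")
})

test_that("nuisance regression produces residuals orthogonal to the design", {
  grid <- c(16, 16, 16)
  nt <- 50
  set.seed(21)
  M <- matrix(rnorm(nt * prod(grid)), nt)
  X <- cbind(rnorm(nt), rnorm(nt), rnorm(nt))
  run <- manual_run(M, grid)
  out <- regress_nuisance(run, X)
  R <- run_matrix(out)
  # residuals match the explicit pseudo-inverse solution
  Xi <- cbind(1, X)
  oracle <- M - Xi %*% (solve(crossprod(Xi)) %*% crossprod(Xi, M))
  expect_equal(R, oracle, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(Xi, R))) / nt, 1e-8)

  # a voxel equal to a regressor is annihilated; an orthogonal one survives
  M2 <- M
  M2[, 1] <- X[, 1]
  out2 <- regress_nuisance(manual_run(M2, grid), X)
  expect_lt(max(abs(run_matrix(out2)[, 1])), 1e-10)

  expect_error(regress_nuisance(run, cbind(X, X[, 1])), "rank deficient")
})

test_that("frame censoring applies the percent-RMS rule", {
  grid <- c(16, 16, 16)
  atlas <- tiny_atlas(grid, 2, 2)
  proto <- tiny_protocol(60, grid)
  # constant run: nothing censored
  run <- simulate_rest_run(atlas, proto, snr = Inf, drift_amplitude = 0,
                           seed = 1)
  run$data <- array(1000, dim = dim(run$data))
  cm <- censor_frames(run)
  expect_true(all(cm$keep))
  # +5% uniform offset at frame 7 flags frames 7 and 8
  noisy <- simulate_rest_run(atlas, proto, snr = 5, seed = 2)
  noisy$data[, , , 7] <- noisy$data[, , , 7] * 1.05
  cm2 <- censor_frames(noisy, 0.5)
  expect_identical(which(!cm2$keep), c(7L, 8L))
  expect_gt(cm2$rms_trace[7], 4.5)
  # threshold zero censors every frame after the first on noisy data
  cm3 <- censor_frames(noisy, 0)
  expect_identical(which(cm3$keep), 1L)
  # censoring the already-censored frame set is idempotent
  keep_mat <- run_matrix(noisy)[cm2$keep, , drop = FALSE]
  cm4 <- censor_frames(manual_run(keep_mat, grid,
                                  brain_mask = noisy$brain_mask), 0.5)
  expect_true(all(cm4$keep))
  bad <- noisy
  bad$brain_mask <- array(FALSE, grid)
  expect_error(censor_frames(bad), "empty")
})

test_that("the assembled chain preserves planted correlation structure", {
  atlas <- make_phantom_atlas(c(20, 20, 20), 2, 2, seed = 3)
  proto <- acquisition_protocol(2.2, 160, 1, 3, c(20, 20, 20))
  run <- simulate_rest_run(atlas, proto, snr = Inf, drift_amplitude = 1,
                           seed = 7)
  lat <- attr(run, "latents")
  # detrend + filter + smooth leave noiseless parcel series essentially
  # equal to their latents; nuisance regression is checked separately since
  # it removes chance-correlated variance even from noiseless data
  pp <- preprocess_run(run, preprocess_config(nuisance = FALSE))
  ts <- extract_roi_timeseries(pp$run, atlas, pp$censor)
  cors <- vapply(seq_len(ncol(ts)), function(r)
    cor(ts[, r], lat[pp$censor$keep, atlas$network_of_roi[r]]), 0)
  expect_true(all(cors >= 0.99))
  # with wm/csf (no global) regression the loss stays small
  ppn <- preprocess_run(run, preprocess_config(global_signal = FALSE))
  tsn <- extract_roi_timeseries(ppn$run, atlas, ppn$censor)
  corsn <- vapply(seq_len(ncol(tsn)), function(r)
    cor(tsn[, r], lat[ppn$censor$keep, atlas$network_of_roi[r]]), 0)
  expect_true(all(corsn >= 0.9))
  # global-signal regression necessarily dilutes network latents: the global
  # mean of a K-network noiseless phantom is ~ (1/K) sum of latents, so the
  # residual correlation is about (1-1/K)/sqrt((1-1/K)^2 + (K-1)/K^2)
  # (~0.71 for K = 2); assert we stay in that regime rather than collapse
  ppf <- preprocess_run(run, preprocess_config())
  tsf <- extract_roi_timeseries(ppf$run, atlas, ppf$censor)
  corsf <- vapply(seq_len(ncol(tsf)), function(r)
    cor(tsf[, r], lat[ppf$censor$keep, atlas$network_of_roi[r]]), 0)
  expect_true(all(abs(corsf) >= 0.55))
})

test_that("chain stages can be toggled and the chain is deterministic", {
  atlas <- tiny_atlas(c(16, 16, 16), 2, 2)
  proto <- tiny_protocol(40, c(16, 16, 16))
  run <- simulate_rest_run(atlas, proto, snr = 5, seed = 5)
  cfg_nosmooth <- preprocess_config(smooth_fwhm_mm = 0)
  pp1 <- preprocess_run(run, cfg_nosmooth)
  # equivalent manual chain without the smoothing stage
  manual <- regress_nuisance(
    lowpass_filter(detrend_run(run), 0.1),
    build_nuisance(lowpass_filter(detrend_run(run), 0.1),
                   global_signal = TRUE, lowpass_hz = 0.1))
  expect_equal(pp1$run$data, manual$data, tolerance = 1e-10)
  expect_false(any(grepl("smooth", pp1$stages)))
  # determinism
  pp2 <- preprocess_run(run, cfg_nosmooth)
  expect_identical(pp1$run$data, pp2$run$data)
  expect_identical(pp1$censor$keep, pp2$censor$keep)
})

test_that("pooled runs concatenate kept frames and subset contiguously", {
  atlas <- tiny_atlas(c(16, 16, 16), 2, 2)
  proto <- acquisition_protocol(2.2, 160, 2, 3, c(16, 16, 16))
  pps <- lapply(1:2, function(r)
    preprocess_run(simulate_rest_run(atlas, proto, snr = 5, seed = 30 + r,
                                     spike_frames = c(10, 20)),
                   preprocess_config()))
  pooled <- pool_runs(pps)
  expect_identical(nrow(pooled$mat), sum(pps[[1]]$censor$keep) +
                     sum(pps[[2]]$censor$keep))
  sub <- subset_frames(pooled, 100)
  expect_identical(nrow(sub$mat), 100L)
  expect_identical(sub$mat, pooled$mat[1:100, ])
  expect_error(subset_frames(pooled, 10000), "kept frames")
})
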