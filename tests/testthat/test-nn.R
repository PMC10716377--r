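test_that("autodiff gradients match numerical differentiation", {
  set.seed(1)
  C <- 3; H <- 8; W <- 8; Cout <- 4
  x <- flfm:::nn_tensor(array(rnorm(C * H * W), c(C, H, W)))
  w1 <- flfm:::nn_param(array(rnorm(Cout * C * 9, 0, 0.2), c(Cout, C, 3, 3)))
  b1 <- flfm:::nn_param(rnorm(Cout, 0, 0.1))
  g1 <- flfm:::nn_param(runif(Cout, 0.5, 1.5))
  be1 <- flfm:::nn_param(rnorm(Cout, 0, 0.1))
  w2 <- flfm:::nn_param(array(rnorm(2 * Cout * 9, 0, 0.2), c(2, Cout, 3, 3)))
  b2 <- flfm:::nn_param(rnorm(2, 0, 0.1))
  wd <- flfm:::nn_param(matrix(rnorm(4, 0, 0.3), 2, 2))
  bd <- flfm:::nn_param(rnorm(2, 0, 0.1))
  tgt <- array(rnorm(2 * H * W), c(2, H, W))
  fwd <- function() {
    h1 <- flfm:::op_leaky_relu(flfm:::op_instance_norm(
      flfm:::op_conv2d(x, w1, b1, dilation = 2), g1, be1), 0.1)
    h2 <- flfm:::op_conv2d(h1, w2, b2)
    gate <- flfm:::op_sigmoid(flfm:::op_dense(flfm:::op_gap(h2), wd, bd))
    h3 <- flfm:::op_scale_channels(h2, gate)
    h4 <- flfm:::op_add(h3, flfm:::op_upsample2(flfm:::op_avgpool2(h3)))
    e <- flfm:::op_sub_const(h4, tgt)
    flfm:::op_scalar_comb(
      list(flfm:::op_mean_abs(e), flfm:::op_mean_sq(e),
           flfm:::op_sum_sq(flfm:::op_axis_diff(e, 2))),
      c(0.3, 0.5, 0.01))
  }
  loss <- fwd()
  flfm:::nn_backward(loss)
  eps <- 1e-5
  for (p in list(x, w1, b1, g1, be1, w2, b2, wd, bd)) {
    for (i in sample(length(p$v), min(5, length(p$v)))) {
      v0 <- p$v[i]
      p$v[i] <- v0 + eps; lp <- fwd()$v
      p$v[i] <- v0 - eps; lm <- fwd()$v
      p$v[i] <- v0
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - p$g[i]) / max(1e-8, abs(num) + abs(p$g[i])), 1e-4)
    }
  }
})

test_that("networks preserve the contracted tensor shapes", {
  den <- build_denoiser(denoise_net_spec(feature_width = 6), seed = 2)
  x <- array(runif(3 * 24 * 24), c(3, 24, 24))
  expect_equal(dim(den$forward(x)$v), c(3, 24, 24))
  rec <- build_reconstructor(recon_net_spec(depth_planes = 41, feature_width = 6,
                                            unet_width = 6), seed = 2)
  out <- rec$forward(x)
  expect_equal(dim(out$v), c(41, 24, 24))  # 41 depth slices
  rec2 <- build_reconstructor(recon_net_spec(depth_planes = 9, feature_width = 6,
                                             unet_width = 6, upscale = 2), seed = 2)
  expect_equal(dim(rec2$forward(x)$v), c(9, 48, 48))
})

test_that("the recommended pretraining and joint patch sizes pass through the forward graphs", {
  # pretraining at 160 x 160 x 3, joint at 80 x 80 x 3
  cfg <- training_config()
  expect_equal(cfg$pretrain_patch, 160)
  expect_equal(cfg$joint_patch, 80)
  den <- build_denoiser(denoise_net_spec(feature_width = 4), seed = 1)
  expect_equal(dim(den$forward(array(0.1, c(3, 160, 160)))$v), c(3, 160, 160))
  rec <- build_reconstructor(recon_net_spec(depth_planes = 9, feature_width = 4,
                                            unet_width = 4), seed = 1)
  expect_equal(dim(rec$forward(array(0.1, c(3, 80, 80)))$v), c(9, 80, 80))
})

test_that("disabling view attention reduces the denoiser to plain RCAN", {
  spec_on <- denoise_net_spec(feature_width = 8, view_attention = TRUE)
  spec_off <- denoise_net_spec(feature_width = 8, view_attention = FALSE)
  m_on <- build_denoiser(spec_on, seed = 3)
  m_off <- build_denoiser(spec_off, seed = 3)
  # branch = two 3x3 dense gates on the three views: 2*(9+3) parameters
  expect_equal(count_parameters(m_on) - count_parameters(m_off), 24)
  expect_setequal(setdiff(names(m_on$params), names(m_off$params)),
                  c("va1_w", "va1_b", "va2_w", "va2_b"))
})

test_that("training runs are reproducible and guard against divergence", {
  set.seed(99)
  clean <- array(runif(3 * 20 * 20), c(3, 20, 20))
  noisy <- pmax(clean + array(rnorm(length(clean), 0, 0.2), dim(clean)), 0)
  tr <- list(hr_stack = volume(array(runif(5 * 20 * 20), c(5, 20, 20)), c(1, 1, 1)),
             clean_views = view_stack(clean), noisy_views = view_stack(noisy))
  ds <- list(tr)
  tc <- training_config(pretrain_patch = 16, pretrain_steps = 5,
                        joint_steps = 5, learning_rate = 1e-3,
                        batch_size = 1, seed = 12)
  a <- pretrain_denoise(ds, tc, spec = denoise_net_spec(feature_width = 4))
  b <- pretrain_denoise(ds, tc, spec = denoise_net_spec(feature_width = 4))
  expect_identical(a$loss_curve, b$loss_curve)
  expect_identical(model_weights(a$model), model_weights(b$model))
  # a colossal learning rate must be caught as divergence with a step index
  # an absurd learning rate overflows the squared-error loss to Inf within
  # a few Adam steps (updates are +-lr each); must be caught with the step
  tc_bad <- training_config(pretrain_patch = 16, pretrain_steps = 20,
                            learning_rate = 1e200, batch_size = 1, seed = 12)
  expect_error(pretrain_denoise(ds, tc_bad, spec = denoise_net_spec(feature_width = 4)),
               "step")
})

test_that("checkpoint selection is the argmax/argmin contract", {
  trace <- c(0.5, 0.3, 0.35, 0.2, 0.4)
  expect_equal(select_best_checkpoint(trace, maximize = FALSE), 4)
  expect_equal(select_best_checkpoint(trace, maximize = TRUE), 1)
  expect_equal(select_best_checkpoint(c(1, 3, 3), maximize = TRUE), 2)  # first max
})

test_that("inference reproduces the training-time forward pass and tiles seamlessly", {
  den <- build_denoiser(denoise_net_spec(feature_width = 4), seed = 5)
  set.seed(21)
  x <- array(runif(3 * 96 * 96), c(3, 96, 96))
  # same graph as training: inference equals the training-time forward pass
  rec <- build_reconstructor(recon_net_spec(depth_planes = 7, feature_width = 4,
                                            unet_width = 6), seed = 5)
  whole <- fvcd_infer(x, den, rec)
  expect_equal(whole$denoised$data, pmax(den$forward(x)$v, 0))
  expect_equal(dim(whole$volume$data)[1], 7)
  expect_true(all(whole$volume$data >= 0))
  # tiled inference is exact (interior pixels) for models free of global
  # statistics: no instance norm, no pooled attention gates
  den_fc <- build_denoiser(denoise_net_spec(feature_width = 4,
                                            n_residual_groups = 0,
                                            view_attention = FALSE), seed = 5)
  rec_fc <- build_reconstructor(recon_net_spec(depth_planes = 7, feature_width = 4,
                                               unet_width = 6,
                                               normalization = "none"), seed = 5)
  whole_fc <- fvcd_infer(x, den_fc, rec_fc)
  tiled <- fvcd_infer(x, den_fc, rec_fc, tile = 76, overlap = 30)
  inner <- 36:60
  rel <- max(abs(tiled$volume$data[, inner, inner] -
                 whole_fc$volume$data[, inner, inner])) /
    max(abs(whole_fc$volume$data[, inner, inner]))
  expect_lt(rel, 1e-3)
})

test_that("a freshly built denoiser is the identity map (zero-initialised correction)", {
  den <- build_denoiser(denoise_net_spec(feature_width = 4), seed = 8)
  x <- array(runif(3 * 32 * 32, 0.1, 1), c(3, 32, 32))
  expect_equal(den$forward(x)$v, x, tolerance = 1e-12)
})
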