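# The two-stage F-VCD model.
#
# Stage 1 (denoiser): a residual channel attention network (RCAN) trunk on
# the 3-view stack plus a view-attention branch that pools the view axis of
# the input and gates the per-view output correction — for a three-view
# stack processed with views as channels, permuting (view, h, w, c) ->
# (c, h, w, view) before the attention pooling reduces to gating the three
# view channels.
#
# Stage 2 (reconstructor): three dilated convolution blocks (rates 1/2/4)
# extract and aggregate multi-scale features from the three views,
# optionally sub-pixel upscaled, followed by a small U-Net with residual
# blocks, instance normalisation and LeakyReLU, ending in a plain
# convolution onto the depth axis (one output channel per depth plane);
# no final activation — outputs are clamped at zero at inference only, to
# avoid truncating weak signals during optimisation.

#' Denoiser architecture specification
#'
#' @param n_residual_groups residual groups in the RCAN trunk.
#' @param n_channel_attention_blocks channel-attention blocks per group.
#' @param feature_width trunk feature channels.
#' @param reduction squeeze-excitation channel reduction ratio.
#' @param view_attention enable the view-attention branch.
#' @param lrelu_slope LeakyReLU negative slope.
#' @return an `flfm_denoise_spec`.
#' @export
denoise_net_spec <- function(n_residual_groups = 1,
                             n_channel_attention_blocks = 2,
                             feature_width = 8,
                             reduction = 2,
                             view_attention = TRUE,
                             lrelu_slope = 0.1) {
  structure(list(n_residual_groups = n_residual_groups,
                 n_channel_attention_blocks = n_channel_attention_blocks,
                 feature_width = feature_width,
                 reduction = reduction,
                 view_attention = view_attention,
                 lrelu_slope = lrelu_slope),
            class = "flfm_denoise_spec")
}

#' Reconstructor architecture specification
#'
#' @param dilations dilation rates of the three feature-extraction blocks.
#' @param feature_width channels of each dilation block.
#' @param unet_width channels at the top U-Net level (doubled below).
#' @param upscale integer lateral upscale factor applied by sub-pixel
#'   (pixel-shuffle) layers before the U-Net (1 = none; the default, where
#'   the dataset's HR grid equals the view grid).
#' @param depth_planes output depth slices.
#' @param residual_blocks use residual blocks in the U-Net (else plain
#'   double convolutions).
#' @param normalization `"instance"` or `"none"`.
#' @param lrelu_slope LeakyReLU negative slope.
#' @return an `flfm_recon_spec`.
#' @export
recon_net_spec <- function(dilations = c(1, 2, 4),
                           feature_width = 12,
                           unet_width = 16,
                           upscale = 1,
                           depth_planes = 41,
                           residual_blocks = TRUE,
                           normalization = c("instance", "none"),
                           lrelu_slope = 0.1) {
  normalization <- match.arg(normalization)
  stopifnot(length(dilations) == 3, upscale >= 1, upscale == round(upscale))
  structure(list(dilations = dilations, feature_width = feature_width,
                 unet_width = unet_width, upscale = as.integer(upscale),
                 depth_planes = depth_planes,
                 residual_blocks = residual_blocks,
                 normalization = normalization,
                 lrelu_slope = lrelu_slope),
            class = "flfm_recon_spec")
}

# He-normal conv weight (Cout, Cin, k, k) + zero bias
init_conv <- function(params, name, cout, cin, k) {
  sd <- sqrt(2 / (cin * k * k))
  params[[paste0(name, "_w")]] <- nn_param(
    array(rnorm(cout * cin * k * k, 0, sd), c(cout, cin, k, k)), name)
  params[[paste0(name, "_b")]] <- nn_param(numeric(cout), name)
  params
}

init_dense <- function(params, name, cout, cin) {
  sd <- sqrt(2 / cin)
  params[[paste0(name, "_w")]] <- nn_param(matrix(rnorm(cout * cin, 0, sd), cout, cin), name)
  params[[paste0(name, "_b")]] <- nn_param(numeric(cout), name)
  params
}

init_norm <- function(params, name, c) {
  params[[paste0(name, "_g")]] <- nn_param(rep(1, c), name)
  params[[paste0(name, "_be")]] <- nn_param(numeric(c), name)
  params
}

#' Build the F-Denoise network
#'
#' @param spec an `flfm_denoise_spec`.
#' @param seed seed for the (deterministic) weight initialisation.
#' @return an `flfm_model` with `$params` (named `nn_tensor` list) and
#'   `$forward(x)` mapping a `(3, h, w)` array or node to a `(3, h, w)` node.
#' @export
build_denoiser <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "flfm_denoise_spec"))
  C <- spec$feature_width
  red <- max(1, round(C / spec$reduction))
  P <- list()
  with_seed(seed, {
    P <- init_conv(P, "head", C, 3, 3)
    for (g in seq_len(spec$n_residual_groups)) {
      for (b in seq_len(spec$n_channel_attention_blocks)) {
        nm <- sprintf("g%db%d", g, b)
        P <- init_conv(P, paste0(nm, "_c1"), C, C, 3)
        P <- init_conv(P, paste0(nm, "_c2"), C, C, 3)
        P <- init_dense(P, paste0(nm, "_d1"), red, C)
        P <- init_dense(P, paste0(nm, "_d2"), C, red)
      }
      P <- init_conv(P, sprintf("g%d_tail", g), C, C, 3)
    }
    P <- init_conv(P, "fuse", C, C, 3)
    P <- init_conv(P, "tail", 3, C, 3)
    # zero-initialised correction: the fresh denoiser is exactly the
    # identity map, the usual starting point for residual denoisers
    P$tail_w$v[] <- 0
    if (spec$view_attention) {
      P <- init_dense(P, "va1", 3, 3)
      P <- init_dense(P, "va2", 3, 3)
    }
  })
  sl <- spec$lrelu_slope
  forward <- function(x) {
    if (!inherits(x, "nn_tensor")) x <- nn_tensor(x)
    h <- op_conv2d(x, P$head_w, P$head_b)
    trunk_in <- h
    for (g in seq_len(spec$n_residual_groups)) {
      gin <- h
      for (b in seq_len(spec$n_channel_attention_blocks)) {
        nm <- sprintf("g%db%d", g, b)
        f <- op_leaky_relu(op_conv2d(h, P[[paste0(nm, "_c1_w")]], P[[paste0(nm, "_c1_b")]]), sl)
        f <- op_conv2d(f, P[[paste0(nm, "_c2_w")]], P[[paste0(nm, "_c2_b")]])
        s <- op_sigmoid(op_dense(op_relu(op_dense(op_gap(f),
               P[[paste0(nm, "_d1_w")]], P[[paste0(nm, "_d1_b")]])),
               P[[paste0(nm, "_d2_w")]], P[[paste0(nm, "_d2_b")]]))
        h <- op_add(h, op_scale_channels(f, s))
      }
      h <- op_add(gin, op_conv2d(h, P[[sprintf("g%d_tail_w", g)]], P[[sprintf("g%d_tail_b", g)]]))
    }
    h <- op_add(trunk_in, op_conv2d(h, P$fuse_w, P$fuse_b))
    corr <- op_conv2d(h, P$tail_w, P$tail_b)
    if (spec$view_attention) {
      vg <- op_sigmoid(op_dense(op_relu(op_dense(op_gap(x), P$va1_w, P$va1_b)),
                                P$va2_w, P$va2_b))
      corr <- op_scale_channels(corr, vg)
    }
    op_add(x, corr)
  }
  structure(list(spec = spec, params = P, forward = forward, seed = seed),
            class = "flfm_model")
}

#' Build the F-Reconstruction network
#'
#' @param spec an `flfm_recon_spec`.
#' @param seed seed for weight initialisation.
#' @return an `flfm_model`; `$forward(x)` maps `(3, h, w)` to
#'   `(depth_planes, upscale*h, upscale*w)`.
#' @export
build_reconstructor <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "flfm_recon_spec"))
  C <- spec$feature_width
  U <- spec$unet_width
  r <- spec$upscale
  P <- list()
  with_seed(seed, {
    P <- init_conv(P, "dil1", C, 3, 3)
    P <- init_conv(P, "dil2", C, C, 3)
    P <- init_conv(P, "dil3", C, C, 3)
    P <- init_conv(P, "aggr", U, 3 * C, 3)
    if (r > 1) P <- init_conv(P, "shuf", U * r^2, U, 3)
    P <- init_conv(P, "e1a", U, U, 3); P <- init_conv(P, "e1b", U, U, 3)
    P <- init_conv(P, "wide", 2 * U, U, 3)
    P <- init_conv(P, "e2a", 2 * U, 2 * U, 3); P <- init_conv(P, "e2b", 2 * U, 2 * U, 3)
    P <- init_conv(P, "up", U, 2 * U, 3)
    P <- init_conv(P, "red", U, 2 * U, 3)
    P <- init_conv(P, "d1a", U, U, 3); P <- init_conv(P, "d1b", U, U, 3)
    P <- init_conv(P, "out", spec$depth_planes, U, 3)
    P$out_w$v[] <- P$out_w$v * 0.1  # gentle start for the depth head
    for (nm in c("dil1", "dil2", "dil3", "aggr", "e1a", "e1b", "wide",
                 "e2a", "e2b", "up", "red", "d1a", "d1b"))
      P <- init_norm(P, nm, dim(P[[paste0(nm, "_w")]]$v)[1])
  })
  sl <- spec$lrelu_slope
  use_in <- spec$normalization == "instance"
  norm <- function(h, nm) {
    if (use_in) op_instance_norm(h, P[[paste0(nm, "_g")]], P[[paste0(nm, "_be")]]) else h
  }
  cnl <- function(h, nm, dilation = 1) {
    op_leaky_relu(norm(op_conv2d(h, P[[paste0(nm, "_w")]], P[[paste0(nm, "_b")]],
                                 dilation = dilation), nm), sl)
  }
  block <- function(h, nma, nmb) {
    y <- cnl(h, nma)
    y <- norm(op_conv2d(y, P[[paste0(nmb, "_w")]], P[[paste0(nmb, "_b")]]), nmb)
    if (spec$residual_blocks) op_leaky_relu(op_add(h, y), sl)
    else op_leaky_relu(y, sl)
  }
  forward <- function(x) {
    if (!inherits(x, "nn_tensor")) x <- nn_tensor(x)
    f1 <- cnl(x, "dil1", spec$dilations[1])
    f2 <- cnl(f1, "dil2", spec$dilations[2])
    f3 <- cnl(f2, "dil3", spec$dilations[3])
    h <- cnl(op_concat_channels(list(f1, f2, f3)), "aggr")
    if (r > 1)
      h <- op_pixel_shuffle(op_conv2d(h, P$shuf_w, P$shuf_b), r)
    e1 <- block(h, "e1a", "e1b")
    p1 <- op_avgpool2(e1)
    p1 <- cnl(p1, "wide")
    e2 <- block(p1, "e2a", "e2b")
    u1 <- cnl(op_upsample2(e2), "up")
    d1 <- cnl(op_concat_channels(list(u1, e1)), "red")
    d1 <- block(d1, "d1a", "d1b")
    op_conv2d(d1, P$out_w, P$out_b)
  }
  structure(list(spec = spec, params = P, forward = forward, seed = seed),
            class = "flfm_model")
}

#' Total trainable parameter count of a model
#' @param model an `flfm_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$v), numeric(1)))
}

#' Extract / restore model weights as plain arrays
#'
#' `model_weights` returns a named list of numeric arrays;
#' `set_model_weights` writes such a list back into the model (shapes must
#' match). Used for checkpointing the best validation state.
#'
#' @param model an `flfm_model`.
#' @param weights named list from `model_weights`.
#' @return weights list / the model, invisibly.
#' @export
model_weights <- function(model) lapply(model$params, function(p) p$v)

#' @rdname model_weights
#' @export
set_model_weights <- function(model, weights) {
  stopifnot(identical(names(model$params), names(weights)))
  for (nm in names(weights)) {
    stopifnot(identical(dim(model$params[[nm]]$v), dim(weights[[nm]])))
    model$params[[nm]]$v <- weights[[nm]]
  }
  invisible(model)
}
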