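#' Training configuration for the two-stage model
#'
#' The denoise and reconstruction losses are combined with weights 0.2/0.8;
#' the denoiser uses a weighted L1-L2 loss (L1 for denoising strength, L2
#' for convexity) and the reconstructor an L2 plus finite-difference
#' gradient loss for pixelwise regression with high-frequency recovery.
#' Optimisation is Adam with a step-decayed learning rate. Denoiser
#' pretraining uses larger lateral patches (default 160 x 160 x 3 views)
#' than joint optimisation (80 x 80 x 3).
#'
#' @param denoise_loss_weight,recon_loss_weight joint weighting; must sum
#'   to 1 (defaults 0.2 and 0.8).
#' @param l1_fraction alpha in `alpha*L1 + (1-alpha)*L2` (default 0.5).
#' @param gradient_loss_weight beta on the gradient term of the
#'   reconstruction loss.
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay_factor multiplicative decay factor.
#' @param lr_decay_every steps between decays.
#' @param pretrain_patch lateral patch size for denoiser pretraining, px.
#' @param joint_patch lateral patch size for joint optimisation, px.
#' @param pretrain_steps,joint_steps optimisation steps.
#' @param batch_size triplets per step.
#' @param val_fraction held-out fraction during joint training.
#' @param eval_every validation cadence (steps).
#' @param seed master RNG seed for sampling and initialisation.
#' @return an `flfm_training_config`.
#' @export
training_config <- function(denoise_loss_weight = 0.2,
                            recon_loss_weight = 0.8,
                            l1_fraction = 0.5,
                            gradient_loss_weight = 0.1,
                            learning_rate = 1e-4,
                            lr_decay_factor = 0.5,
                            lr_decay_every = 500,
                            pretrain_patch = 160,
                            joint_patch = 80,
                            pretrain_steps = 300,
                            joint_steps = 300,
                            batch_size = 2,
                            val_fraction = 0.25,
                            eval_every = 25,
                            seed = 1L) {
  if (abs(denoise_loss_weight + recon_loss_weight - 1) > 1e-9)
    stop("denoise and reconstruction loss weights must sum to 1")
  stopifnot(l1_fraction >= 0, l1_fraction <= 1, learning_rate > 0)
  structure(as.list(environment()), class = "flfm_training_config")
}

#' Weighted L1-L2 denoising loss
#'
#' `alpha * mean|pred - gt| + (1 - alpha) * mean (pred - gt)^2`.
#' Symmetric in its arguments.
#'
#' @param pred,gt equal-shaped arrays (or `flfm_views`).
#' @param alpha L1 fraction (default 0.5).
#' @return scalar loss.
#' @export
denoise_loss <- function(pred, gt, alpha = 0.5) {
  p <- if (inherits(pred, "flfm_views")) pred$data else pred
  g <- if (inherits(gt, "flfm_views")) gt$data else gt
  if (!identical(dim(p), dim(g))) stop("shape mismatch")
  e <- p - g
  alpha * mean(abs(e)) + (1 - alpha) * mean(e^2)
}

# graph version used in training
denoise_loss_node <- function(pred_node, gt, alpha = 0.5) {
  e <- op_sub_const(pred_node, gt)
  op_scalar_comb(list(op_mean_abs(e), op_mean_sq(e)), c(alpha, 1 - alpha))
}

#' L2 + gradient reconstruction loss
#'
#' Mean squared error plus `beta` times the pooled mean squared
#' finite-difference of the error along every spatial axis of length >= 2
#' (depth, row, column).
#'
#' @param pred,gt equal-shaped 3D arrays (or `flfm_volume`).
#' @param beta gradient-term weight.
#' @return scalar loss.
#' @export
recon_loss <- function(pred, gt, beta = 0.1) {
  p <- if (inherits(pred, "flfm_volume")) pred$data else pred
  g <- if (inherits(gt, "flfm_volume")) gt$data else gt
  if (!identical(dim(p), dim(g))) stop("shape mismatch")
  e <- p - g
  d <- dim(e)
  ss <- 0; nn <- 0
  for (ax in 1:3) {
    if (d[ax] < 2) next
    dd <- switch(ax,
      e[2:d[1], , , drop = FALSE] - e[1:(d[1] - 1), , , drop = FALSE],
      e[, 2:d[2], , drop = FALSE] - e[, 1:(d[2] - 1), , drop = FALSE],
      e[, , 2:d[3], drop = FALSE] - e[, , 1:(d[3] - 1), drop = FALSE])
    ss <- ss + sum(dd^2); nn <- nn + length(dd)
  }
  mean(e^2) + if (nn > 0) beta * ss / nn else 0
}

recon_loss_node <- function(pred_node, gt, beta = 0.1) {
  e <- op_sub_const(pred_node, gt)
  d <- dim(gt)
  parts <- list(op_mean_sq(e))
  w <- 1
  sq <- list(); nn <- 0
  for (ax in 1:3) {
    if (d[ax] < 2) next
    dn <- op_axis_diff(e, ax)
    sq[[length(sq) + 1]] <- op_sum_sq(dn)
    nn <- nn + length(dn$v)
  }
  if (nn > 0) {
    parts <- c(parts, sq)
    w <- c(w, rep(beta / nn, length(sq)))
  }
  op_scalar_comb(parts, w)
}

#' Joint F-VCD loss
#'
#' Weighted combination of the two stage losses, by default
#' `0.2 * denoise + 0.8 * reconstruction`.
#'
#' @param denoise_term,recon_term scalar stage losses.
#' @param cfg an `flfm_training_config`.
#' @return scalar.
#' @export
joint_loss <- function(denoise_term, recon_term, cfg = training_config()) {
  cfg$denoise_loss_weight * denoise_term + cfg$recon_loss_weight * recon_term
}

#' Index of the best checkpoint in a validation-metric trace
#' @param trace numeric vector of per-checkpoint validation metrics.
#' @param maximize `TRUE` to pick the maximum (e.g. SSIM), `FALSE` for a loss.
#' @return integer index of the selected checkpoint.
#' @export
select_best_checkpoint <- function(trace, maximize = FALSE) {
  stopifnot(length(trace) >= 1)
  if (maximize) which.max(trace) else which.min(trace)
}

# random lateral patch coordinates (top-left) for an (., h, w) stack
sample_patch <- function(h, w, patch) {
  patch <- min(patch, h, w)
  r0 <- if (h > patch) sample.int(h - patch + 1, 1) else 1
  c0 <- if (w > patch) sample.int(w - patch + 1, 1) else 1
  list(r = r0:(r0 + patch - 1), c = c0:(c0 + patch - 1))
}

step_lr <- function(cfg, step)
  cfg$learning_rate * cfg$lr_decay_factor^((step - 1) %/% cfg$lr_decay_every)

#' Pretrain the denoiser on (noisy, clean) view pairs
#'
#' Minimises the weighted L1-L2 loss on random lateral patches of size
#' `cfg$pretrain_patch` (larger patches than joint training help the
#' denoiser). Deterministic under `cfg$seed`.
#'
#' @param dataset an `flfm_dataset`.
#' @param cfg an `flfm_training_config`.
#' @param model optional prebuilt denoiser (else built from `spec`).
#' @param spec denoiser spec used when `model` is `NULL`.
#' @param stop_below optional early-stop threshold on the running loss.
#' @return list with `model` and `loss_curve`; errors with the step index
#'   if the loss diverges to NaN.
#' @export
pretrain_denoise <- function(dataset, cfg = training_config(), model = NULL,
                             spec = denoise_net_spec(), stop_below = NULL) {
  stopifnot(length(dataset) >= 1)
  model <- model %||% build_denoiser(spec, seed = cfg$seed)
  params <- model$params
  st <- adam_state(params)
  curve <- numeric(0)
  with_seed(cfg$seed + 1L, {
    for (step in seq_len(cfg$pretrain_steps)) {
      lr <- step_lr(cfg, step)
      batch_nodes <- vector("list", cfg$batch_size)
      for (bi in seq_len(cfg$batch_size)) {
        tr <- dataset[[sample.int(length(dataset), 1)]]
        d <- dim(tr$noisy_views$data)
        pc <- sample_patch(d[2], d[3], cfg$pretrain_patch)
        noisy <- tr$noisy_views$data[, pc$r, pc$c, drop = FALSE]
        clean <- tr$clean_views$data[, pc$r, pc$c, drop = FALSE]
        pred <- model$forward(noisy)
        batch_nodes[[bi]] <- denoise_loss_node(pred, clean, cfg$l1_fraction)
      }
      loss <- op_scalar_comb(batch_nodes, rep(1 / cfg$batch_size, cfg$batch_size))
      if (!is.finite(loss$v))
        stop(sprintf("denoiser training diverged (non-finite loss) at step %d", step))
      nn_backward(loss)
      st <- adam_step(params, st, lr)
      curve <- c(curve, loss$v)
      if (!is.null(stop_below) && loss$v < stop_below) break
    }
  })
  list(model = model, loss_curve = curve)
}

#' Pretrain the reconstructor on (clean views, HR stack) pairs
#'
#' Clean views feed the reconstructor during pretraining (the denoiser's
#' targets are its inputs' clean counterparts, so the stages meet on the
#' clean-view interface). Loss: L2 + gradient.
#'
#' @inheritParams pretrain_denoise
#' @param spec reconstructor spec used when `model` is `NULL`.
#' @return list with `model` and `loss_curve`.
#' @export
pretrain_recon <- function(dataset, cfg = training_config(), model = NULL,
                           spec = NULL, stop_below = NULL) {
  stopifnot(length(dataset) >= 1)
  d_planes <- dim(dataset[[1]]$hr_stack$data)[1]
  spec <- spec %||% recon_net_spec(depth_planes = d_planes)
  stopifnot(spec$depth_planes == d_planes)
  model <- model %||% build_reconstructor(spec, seed = cfg$seed)
  params <- model$params
  st <- adam_state(params)
  curve <- numeric(0)
  r <- model$spec$upscale
  with_seed(cfg$seed + 2L, {
    for (step in seq_len(cfg$joint_steps)) {
      lr <- step_lr(cfg, step)
      batch_nodes <- vector("list", cfg$batch_size)
      for (bi in seq_len(cfg$batch_size)) {
        tr <- dataset[[sample.int(length(dataset), 1)]]
        d <- dim(tr$clean_views$data)
        pc <- sample_patch(d[2], d[3], cfg$joint_patch)
        clean <- tr$clean_views$data[, pc$r, pc$c, drop = FALSE]
        hr <- hr_patch(tr$hr_stack$data, pc, r)
        pred <- model$forward(clean)
        batch_nodes[[bi]] <- recon_loss_node(pred, hr, cfg$gradient_loss_weight)
      }
      loss <- op_scalar_comb(batch_nodes, rep(1 / cfg$batch_size, cfg$batch_size))
      if (!is.finite(loss$v))
        stop(sprintf("reconstructor training diverged (non-finite loss) at step %d", step))
      nn_backward(loss)
      st <- adam_step(params, st, lr)
      curve <- c(curve, loss$v)
      if (!is.null(stop_below) && loss$v < stop_below) break
    }
  })
  list(model = model, loss_curve = curve)
}

# HR-stack patch matching a view patch under lateral upscale r
hr_patch <- function(hr, pc, r) {
  if (r == 1) return(hr[, pc$r, pc$c, drop = FALSE])
  rr <- ((min(pc$r) - 1) * r + 1):(max(pc$r) * r)
  cc <- ((min(pc$c) - 1) * r + 1):(max(pc$c) * r)
  hr[, rr, cc, drop = FALSE]
}

#' Jointly train the two-stage F-VCD model
#'
#' Both sub-networks are updated simultaneously on the weighted
#' denoise-reconstruction loss (default 0.2/0.8): the denoiser output feeds
#' the reconstructor, the denoise loss is evaluated against the clean views
#' and the reconstruction loss against the HR stack. A validation split is
#' evaluated every `eval_every` steps and the weights with the best
#' validation loss are restored at the end.
#'
#' @param dataset an `flfm_dataset`.
#' @param denoiser,reconstructor pretrained `flfm_model`s (or fresh builds).
#' @param cfg an `flfm_training_config`.
#' @return list with `denoiser`, `reconstructor`, `loss_curve`,
#'   `val_steps`, `val_curve` and `best_checkpoint`.
#' @export
train_joint <- function(dataset, denoiser, reconstructor,
                        cfg = training_config()) {
  n_val <- max(1, round(length(dataset) * cfg$val_fraction))
  if (n_val >= length(dataset)) stop("validation split leaves no training data")
  val_idx <- with_seed(cfg$seed + 3L, sample.int(length(dataset), n_val))
  train_set <- dataset[-val_idx]
  val_set <- dataset[val_idx]
  params <- c(denoiser$params, reconstructor$params)
  st <- adam_state(params)
  r <- reconstructor$spec$upscale
  curve <- numeric(0)
  val_curve <- numeric(0)
  val_steps <- integer(0)
  best <- list(val = Inf, wd = model_weights(denoiser),
               wr = model_weights(reconstructor))
  val_loss <- function() {
    mean(vapply(val_set, function(tr) {
      d <- dim(tr$noisy_views$data)
      # deterministic centred-origin patch for a stable validation metric
      pc <- list(r = seq_len(min(cfg$joint_patch, d[2])),
                 c = seq_len(min(cfg$joint_patch, d[3])))
      den <- denoiser$forward(tr$noisy_views$data[, pc$r, pc$c, drop = FALSE])
      rec <- reconstructor$forward(den)
      dl <- denoise_loss(den$v, tr$clean_views$data[, pc$r, pc$c, drop = FALSE],
                         cfg$l1_fraction)
      rl <- recon_loss(rec$v, hr_patch(tr$hr_stack$data, pc, r),
                       cfg$gradient_loss_weight)
      joint_loss(dl, rl, cfg)
    }, numeric(1)))
  }
  with_seed(cfg$seed + 4L, {
    for (step in seq_len(cfg$joint_steps)) {
      lr <- step_lr(cfg, step)
      batch_nodes <- vector("list", cfg$batch_size)
      for (bi in seq_len(cfg$batch_size)) {
        tr <- train_set[[sample.int(length(train_set), 1)]]
        d <- dim(tr$noisy_views$data)
        pc <- sample_patch(d[2], d[3], cfg$joint_patch)
        noisy <- tr$noisy_views$data[, pc$r, pc$c, drop = FALSE]
        clean <- tr$clean_views$data[, pc$r, pc$c, drop = FALSE]
        hr <- hr_patch(tr$hr_stack$data, pc, r)
        den <- denoiser$forward(noisy)
        rec <- reconstructor$forward(den)
        dl <- denoise_loss_node(den, clean, cfg$l1_fraction)
        rl <- recon_loss_node(rec, hr, cfg$gradient_loss_weight)
        batch_nodes[[bi]] <- op_scalar_comb(list(dl, rl),
          c(cfg$denoise_loss_weight, cfg$recon_loss_weight))
      }
      loss <- op_scalar_comb(batch_nodes, rep(1 / cfg$batch_size, cfg$batch_size))
      if (!is.finite(loss$v))
        stop(sprintf("joint training diverged (non-finite loss) at step %d", step))
      nn_backward(loss)
      st <- adam_step(params, st, lr)
      curve <- c(curve, loss$v)
      if (step %% cfg$eval_every == 0 || step == cfg$joint_steps) {
        vl <- val_loss()
        val_curve <- c(val_curve, vl)
        val_steps <- c(val_steps, step)
        if (vl < best$val)
          best <- list(val = vl, wd = model_weights(denoiser),
                       wr = model_weights(reconstructor))
      }
    }
  })
  set_model_weights(denoiser, best$wd)
  set_model_weights(reconstructor, best$wr)
  list(denoiser = denoiser, reconstructor = reconstructor,
       loss_curve = curve, val_steps = val_steps, val_curve = val_curve,
       best_checkpoint = select_best_checkpoint(val_curve, maximize = FALSE))
}

#' F-VCD inference
#'
#' Runs the two trained stages on a raw light field (realigned and cropped
#' to views via the calibration) or directly on a view stack. Outputs are
#' clamped at zero (the networks themselves carry no final activation).
#' Optional tiled inference splits the lateral plane into overlapping tiles
#' and keeps each tile's interior; exact only for normalisation-free
#' reconstructors since instance normalisation ties activations to whole-
#' image statistics.
#'
#' @param input an `flfm_lf`, `flfm_views`, or `(3, h, w)` array.
#' @param denoiser,reconstructor trained `flfm_model`s.
#' @param cal calibration, required when `input` is a raw light field.
#' @param tile optional tile side, px.
#' @param overlap tile overlap, px (default 16; must exceed the network
#'   receptive-field radius for seamless stitching).
#' @return list with `denoised` (an `flfm_views`) and `volume` (an
#'   `flfm_volume` of `depth_planes` slices).
#' @export
fvcd_infer <- function(input, denoiser, reconstructor, cal = NULL,
                       tile = NULL, overlap = 16) {
  if (inherits(input, "flfm_lf")) {
    if (is.null(cal)) stop("calibration required for raw light-field input")
    input <- extract_views(input, cal)
  }
  x <- if (inherits(input, "flfm_views")) input$data else input
  stopifnot(dim(x)[1] == 3)
  r <- reconstructor$spec$upscale
  run <- function(patch) {
    d <- dim(patch)
    # pad odd lateral sizes to even for the U-Net's 2x downsampling
    pr <- d[2] %% 2; pcl <- d[3] %% 2
    if (pr || pcl) {
      padded <- array(0, dim = c(d[1], d[2] + pr, d[3] + pcl))
      padded[, seq_len(d[2]), seq_len(d[3])] <- patch
      patch <- padded
    }
    den <- denoiser$forward(patch)$v
    vol <- reconstructor$forward(nn_tensor(den))$v
    if (pr || pcl) {
      den <- den[, seq_len(d[2]), seq_len(d[3]), drop = FALSE]
      vol <- vol[, seq_len(r * d[2]), seq_len(r * d[3]), drop = FALSE]
    }
    list(den = den, vol = vol)
  }
  if (is.null(tile)) {
    res <- run(x)
  } else {
    res <- tiled_run(x, run, tile, overlap, reconstructor$spec$depth_planes, r)
  }
  list(denoised = view_stack(pmax(res$den, 0), provenance = "denoised"),
       volume = volume(pmax(res$vol, 0), c(NA, NA, NA)))
}

tiled_run <- function(x, run, tile, overlap, d_planes, r) {
  h <- dim(x)[2]; w <- dim(x)[3]
  den <- array(0, dim = dim(x))
  vol <- array(0, dim = c(d_planes, r * h, r * w))
  step <- tile - 2 * overlap
  stopifnot(step > 0)
  starts <- function(n) {
    s <- seq(1, max(1, n - tile + 1), by = step)
    if (s[length(s)] + tile - 1 < n) s <- c(s, n - tile + 1)
    s
  }
  for (r0 in starts(h)) for (c0 in starts(w)) {
    rr <- r0:(min(r0 + tile - 1, h))
    cc <- c0:(min(c0 + tile - 1, w))
    res <- run(x[, rr, cc, drop = FALSE])
    # interior of the tile (keep the border only at the image edge)
    keep_r <- seq_along(rr)
    keep_c <- seq_along(cc)
    if (r0 > 1) keep_r <- keep_r[-seq_len(overlap)]
    if (max(rr) < h) keep_r <- keep_r[seq_len(length(keep_r) - overlap)]
    if (c0 > 1) keep_c <- keep_c[-seq_len(overlap)]
    if (max(cc) < w) keep_c <- keep_c[seq_len(length(keep_c) - overlap)]
    den[, rr[keep_r], cc[keep_c]] <- res$den[, keep_r, keep_c]
    vr <- ((rr[keep_r] - 1) * r + 1)
    vc <- ((cc[keep_c] - 1) * r + 1)
    if (r == 1) {
      vol[, vr, vc] <- res$vol[, keep_r, keep_c]
    } else {
      for (i in seq_along(keep_r)) for (j in seq_along(keep_c))
        vol[, vr[i]:(vr[i] + r - 1), vc[j]:(vc[j] + r - 1)] <-
          res$vol[, ((keep_r[i] - 1) * r + 1):(keep_r[i] * r),
                  ((keep_c[j] - 1) * r + 1):(keep_c[j] * r)]
    }
  }
  list(den = den, vol = vol)
}
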