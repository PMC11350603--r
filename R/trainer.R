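# Mean-teacher training loop: the student takes Adam steps on the
# combined labeled + unlabeled loss; the teacher's parameters are an
# exponential moving average of the student's and never receive
# gradients; unlabeled student inputs are patch-masked.

#' Training configuration
#'
#' The `"full"` profile carries the reference settings for GPU-scale
#' training (256 crop, batch 16, 500 epochs, learning rate 1e-5); the
#' `"reduced"` profile is a first-class desk-scale profile (thin network,
#' small crops, larger learning rate) so the complete pipeline runs on
#' one CPU in minutes.
#'
#' @param profile `"reduced"` or `"full"`.
#' @param crop_size training crop edge (divisible by 8).
#' @param batch_size images per batch (labeled and unlabeled each).
#' @param epochs training epochs.
#' @param masked_patch_size,masking_ratio masking knobs (defaults 16, 0.1).
#' @param ema_alpha asymptotic EMA decay of the teacher (ramped in from 0
#'   as `min(alpha, 1 - 1/(step + 1))`). The full profile uses 0.99; the
#'   reduced profile uses 0.9 so that the teacher's averaging horizon
#'   `1/(1 - alpha)` stays small relative to the desk-scale step budget.
#' @param lr,weight_decay Adam learning rate and L2 weight decay.
#' @param epsilon density segmentation threshold.
#' @param lambda1 total-variation weight in the labeled regression loss.
#' @param ssim an [ssim_params()].
#' @param smooth_l1_beta transition point of the consistency losses.
#' @param n_classes density classes.
#' @param brightness_jitter,flip_prob,scale_range augmentation knobs.
#' @param mask_fill fill intensity for masked patches.
#' @param seed master seed for batch sampling, augmentation and masking.
#' @param init_seed seed for weight initialization.
#' @param eval_model `"teacher"` (mean-teacher convention) or `"student"`.
#' @param use_unlabeled include the unsupervised branch when unlabeled
#'   images exist.
#' @return a `train_config` list.
#' @export
train_config <- function(profile = c("reduced", "full"),
                         crop_size = NULL, batch_size = NULL, epochs = NULL,
                         masked_patch_size = 16L, masking_ratio = 0.1,
                         ema_alpha = NULL, lr = NULL, weight_decay = 1e-4,
                         epsilon = 1e-3, lambda1 = 0.01,
                         ssim = ssim_params(), smooth_l1_beta = 1,
                         n_classes = 5L, brightness_jitter = 0.2,
                         flip_prob = 0.5, scale_range = c(1, 1),
                         mask_fill = 0.5, seed = 1L, init_seed = 1L,
                         eval_model = c("teacher", "student"),
                         use_unlabeled = TRUE) {
  profile <- match.arg(profile)
  eval_model <- match.arg(eval_model)
  full <- profile == "full"
  crop_size <- crop_size %||% if (full) 256L else 64L
  batch_size <- batch_size %||% if (full) 16L else 4L
  epochs <- epochs %||% if (full) 500L else 10L
  lr <- lr %||% if (full) 1e-5 else 1e-3
  ema_alpha <- ema_alpha %||% if (full) 0.99 else 0.9
  if (crop_size %% 8 != 0) stop_cfg("crop_size must be divisible by 8")
  if (masking_ratio < 0 || masking_ratio > 1)
    stop_cfg("masking_ratio must be in [0, 1]")
  if (ema_alpha < 0 || ema_alpha >= 1) stop_cfg("ema_alpha must be in [0, 1)")
  structure(list(profile = profile, crop_size = as.integer(crop_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 masked_patch_size = as.integer(masked_patch_size),
                 masking_ratio = masking_ratio, ema_alpha = ema_alpha,
                 lr = lr, weight_decay = weight_decay, epsilon = epsilon,
                 lambda1 = lambda1, ssim = ssim,
                 smooth_l1_beta = smooth_l1_beta,
                 n_classes = as.integer(n_classes),
                 brightness_jitter = brightness_jitter,
                 flip_prob = flip_prob, scale_range = scale_range,
                 mask_fill = mask_fill, seed = as.integer(seed),
                 init_seed = as.integer(init_seed), eval_model = eval_model,
                 use_unlabeled = isTRUE(use_unlabeled)),
            class = "train_config")
}

#' Read a training configuration from YAML
#'
#' Keys mirror the arguments of [train_config()]; absent keys take the
#' profile's defaults.
#'
#' @param path YAML file.
#' @return a `train_config`.
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ssim)) y$ssim <- do.call(ssim_params, y$ssim)
  do.call(train_config, y)
}

#' Exponential moving-average update of the teacher
#'
#' Each teacher parameter becomes `alpha * teacher + (1 - alpha) *
#' student`. The teacher is never part of any gradient computation.
#'
#' @param teacher,student parameter lists of identical structure.
#' @param alpha decay in `[0, 1)`.
#' @return updated teacher parameter list.
#' @export
ema_update <- function(teacher, student, alpha) {
  if (alpha < 0 || alpha >= 1) stop_cfg("alpha must be in [0, 1)")
  walk2 <- function(tp, sp) {
    if (is.list(tp)) {
      if (!identical(names(tp), names(sp)))
        stop_cfg("teacher/student parameter structures differ")
      return(mapply(walk2, tp, sp, SIMPLIFY = FALSE))
    }
    if (!identical(dim(tp), dim(sp)) || length(tp) != length(sp))
      stop_cfg("teacher/student parameter shapes differ")
    alpha * tp + (1 - alpha) * sp
  }
  walk2(teacher, student)
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  step_leaf <- function(p, g, m, v, decay) {
    g <- g + decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p_new <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p_new, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p) && !identical(names(p), c("W", "b"))) {
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    rw <- step_leaf(p$W, g$W, m$W, v$W, weight_decay)
    rb <- step_leaf(p$b, g$b, m$b, v$b, 0)
    list(p = list(W = rw$p, b = rb$p), m = list(W = rw$m, b = rb$m),
         v = list(W = rw$v, b = rb$v))
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

add_grads <- function(a, b, scale = 1) {
  walk <- function(x, y) {
    if (is.list(x)) return(mapply(walk, x, y, SIMPLIFY = FALSE))
    x + scale * y
  }
  walk(a, b)
}

# ---- one training step ------------------------------------------------

#' One mean-teacher training step
#'
#' Runs the student on the labeled crops and on the masked unlabeled
#' crops, runs the teacher on the unmasked unlabeled crops (as constant
#' targets), backpropagates the combined loss into the student only,
#' applies one Adam update, then updates the teacher by EMA.
#'
#' @param student list with `params`, `cfg` ([mtsc_config()]), `opt`
#'   (Adam state) and `step` counter.
#' @param teacher list with `params` (same structure as the student's).
#' @param labeled_batch list of items `list(image, d_gt8, y_gt)`: training
#'   crop, ground-truth density at 1/8 resolution, 0-based class label.
#' @param unlabeled_batch `NULL`, or list of items
#'   `list(student_image, teacher_image, mask)` where `student_image` is
#'   the masked crop and `mask` its `patch_mask`.
#' @param config a [train_config()].
#' @return list with `breakdown` (a `loss_breakdown`), updated `student`
#'   and `teacher`.
#' @export
train_step <- function(student, teacher, labeled_batch, unlabeled_batch,
                       config) {
  cfg <- student$cfg
  grads <- zero_like_params(student$params)
  nl <- length(labeled_batch)
  if (nl == 0) stop_cfg("labeled batch is empty")
  l_rl <- 0; l_cl <- 0
  for (item in labeled_batch) {
    out <- model_forward(student$params, item$image, cfg, with_cache = TRUE)
    reg <- labeled_regression_impl(out$density, item$d_gt8,
                                   epsilon = config$epsilon,
                                   lambda1 = config$lambda1,
                                   params = config$ssim, grad = TRUE)
    ce <- classification_cross_entropy(item$y_gt, out$class_probs)
    onehot <- numeric(length(out$class_probs)); onehot[item$y_gt + 1L] <- 1
    d_logits <- (out$class_probs - onehot) / nl
    g <- model_backward(student$params, out$cache,
                        d_density = reg$grad / nl, d_logits = d_logits,
                        cfg = cfg)
    grads <- add_grads(grads, g)
    l_rl <- l_rl + reg$value / nl
    l_cl <- l_cl + ce / nl
  }
  l_ru <- 0; l_cu <- 0
  nu <- length(unlabeled_batch %||% list())
  if (nu > 0) {
    if (config$masking_ratio == 0)
      stop_cfg("masking_ratio is 0 but unlabeled images were supplied; ",
               "the consistency loss is undefined over zero patches")
    for (item in unlabeled_batch) {
      t_out <- model_forward(teacher$params, item$teacher_image, cfg)
      s_out <- model_forward(student$params, item$student_image, cfg,
                             with_cache = TRUE)
      ul <- unsupervised_losses(s_out, t_out, item$mask,
                                beta = config$smooth_l1_beta)
      d_logits <- softmax_bwd(s_out$class_probs, ul$grad_probs) / nu
      g <- model_backward(student$params, s_out$cache,
                          d_density = ul$grad_density / nu,
                          d_logits = d_logits, cfg = cfg)
      grads <- add_grads(grads, g)
      l_ru <- l_ru + ul$l_ru / nu
      l_cu <- l_cu + ul$l_cu / nu
    }
  }
  breakdown <- total_loss(l_rl, l_cl, l_ru, l_cu)
  upd <- adam_step(student$params, grads, student$opt, lr = config$lr,
                   weight_decay = config$weight_decay)
  student$params <- upd$params
  student$opt <- upd$state
  student$step <- (student$step %||% 0L) + 1L
  alpha_t <- min(config$ema_alpha, 1 - 1 / (student$step + 1))
  teacher$params <- ema_update(teacher$params, student$params, alpha_t)
  list(breakdown = breakdown, student = student, teacher = teacher)
}

# ---- dataset access helpers -------------------------------------------

load_entry <- function(root, row) {
  img <- read_image(file.path(root, row$image_path))
  pts <- if (!is.na(row$annotation_path) && nzchar(row$annotation_path))
    read_points(file.path(root, row$annotation_path))
  else NULL
  list(image = img, points = pts)
}

# Random training crop of one entry; recomputes the ground-truth density
# from the transformed points so labels stay consistent with pixels.
make_labeled_item <- function(entry, config) {
  ap <- sample_augment_params(dim(entry$image)[1], dim(entry$image)[2], config)
  aug <- augment(entry$image, entry$points, brightness = ap$brightness,
                 flip = ap$flip, scale = ap$scale,
                 crop_origin = ap$crop_origin, crop_size = ap$crop_size)
  d <- geometric_adaptive_density(aug$points, dim(aug$image)[1],
                                  dim(aug$image)[2])
  d8 <- downsample_sum_preserving(d, 8L)
  list(image = aug$image, d_gt8 = d8, count = length(aug$points),
       points = aug$points)
}

make_unlabeled_item <- function(entry, config, mask_seed) {
  ap <- sample_augment_params(dim(entry$image)[1], dim(entry$image)[2], config)
  crop <- augment(entry$image, NULL, brightness = 1, flip = ap$flip,
                  scale = ap$scale, crop_origin = ap$crop_origin,
                  crop_size = ap$crop_size)$image
  student_view <- clamp01(crop * ap$brightness)
  mask <- random_patch_mask(dim(crop)[1], dim(crop)[2],
                            mask_spec(config$masked_patch_size,
                                      config$masking_ratio,
                                      config$mask_fill),
                            seed = mask_seed)
  list(student_image = apply_mask(student_view, mask, config$mask_fill),
       teacher_image = crop, mask = mask)
}

#' Predicted count for one image
#'
#' @param params network parameters.
#' @param image (H, W, 3) array.
#' @param cfg a [mtsc_config()].
#' @return the integral (sum) of the predicted density map.
#' @export
predict_count <- function(params, image, cfg) {
  sum(model_forward(params, image, cfg)$density)
}

# ---- the full training loop -------------------------------------------

#' Train the counting network on a manifest
#'
#' Loads the dataset named by the manifest, builds 1/8-resolution
#' ground-truth densities and quantile density-class bins from the
#' labeled training images, then runs the mean-teacher loop: per step,
#' one labeled batch and (when unlabeled images exist) one unlabeled
#' batch drawn independently; per epoch, evaluation on the validation
#' split using the EMA teacher (by convention; configurable). The
#' best-validation checkpoint and a per-epoch CSV log are written to
#' `out_dir`.
#'
#' @param manifest manifest `data.frame` (see [read_manifest()]).
#' @param config a [train_config()].
#' @param root dataset root directory the manifest paths are relative to.
#' @param out_dir output directory for `checkpoint.rds` and `log.csv`.
#' @param verbose print per-epoch progress.
#' @return list with `student`, `teacher`, `log` (data.frame),
#'   `bin_edges`, `best_val_mae`, `checkpoint` (path or NULL).
#' @export
fit <- function(manifest, config = train_config(), root = ".",
                out_dir = NULL, verbose = FALSE) {
  tr_lab <- manifest[manifest$split == "train" & manifest$labeled, ]
  tr_unl <- manifest[manifest$split == "train" & !manifest$labeled, ]
  val <- manifest[manifest$split == "val", ]
  if (nrow(tr_lab) == 0) stop_cfg("manifest has no labeled training images")
  lab_entries <- lapply(seq_len(nrow(tr_lab)),
                        function(i) load_entry(root, tr_lab[i, ]))
  unl_entries <- if (config$use_unlabeled && nrow(tr_unl) > 0)
    lapply(seq_len(nrow(tr_unl)), function(i) load_entry(root, tr_unl[i, ]))
  else list()
  val_entries <- lapply(seq_len(nrow(val)),
                        function(i) load_entry(root, val[i, ]))
  counts <- vapply(lab_entries, function(e) nrow(e$points$points), numeric(1))
  bin_edges <- count_bin_edges(counts, config$n_classes)
  cfg <- mtsc_config(config$profile, n_classes = length(bin_edges))
  params <- init_mtsc_params(cfg, seed = config$init_seed)
  student <- list(params = params, cfg = cfg, opt = adam_init(params),
                  step = 0L)
  teacher <- list(params = params, cfg = cfg)
  nl <- length(lab_entries); nu <- length(unl_entries)
  steps_per_epoch <- max(1L, ceiling(nl / config$batch_size))
  log <- NULL
  best <- Inf
  ckpt_path <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, "checkpoint.rds")
  } else NULL
  set.seed(config$seed)
  mask_counter <- 0L
  for (epoch in seq_len(config$epochs)) {
    ep <- c(l_rl = 0, l_cl = 0, l_ru = 0, l_cu = 0)
    for (s in seq_len(steps_per_epoch)) {
      li <- sample.int(nl, min(config$batch_size, nl))
      labeled_batch <- lapply(lab_entries[li], function(e) {
        it <- make_labeled_item(e, config)
        it$y_gt <- density_class_label(it$count, bin_edges)
        it
      })
      unlabeled_batch <- NULL
      if (nu > 0) {
        ui <- sample.int(nu, min(config$batch_size, nu))
        unlabeled_batch <- lapply(unl_entries[ui], function(e) {
          mask_counter <<- mask_counter + 1L
          make_unlabeled_item(e, config,
                              combine_seeds(config$seed, mask_counter))
        })
      }
      res <- train_step(student, teacher, labeled_batch, unlabeled_batch,
                        config)
      student <- res$student; teacher <- res$teacher
      b <- res$breakdown
      ep <- ep + c(b$l_rl, b$l_cl, b$l_ru, b$l_cu) / steps_per_epoch
    }
    eval_params <- if (config$eval_model == "teacher") teacher$params
    else student$params
    vm <- if (length(val_entries)) {
      pairs <- t(vapply(val_entries, function(e) {
        c(predict_count(eval_params, e$image, cfg), nrow(e$points$points))
      }, numeric(2)))
      compute_metrics(pairs)
    } else list(mae = NA_real_, rmse = NA_real_)
    log <- rbind(log, data.frame(epoch = epoch, l_rl = ep["l_rl"],
                                 l_cl = ep["l_cl"], l_ru = ep["l_ru"],
                                 l_cu = ep["l_cu"], val_mae = vm$mae,
                                 val_rmse = vm$rmse, row.names = NULL))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val MAE %.3f", epoch,
                      sum(ep), vm$mae))
    if (!is.na(vm$mae) && vm$mae < best) {
      best <- vm$mae
      if (!is.null(ckpt_path))
        save_checkpoint(ckpt_path, student, teacher, config, bin_edges,
                        val_mae = vm$mae)
    }
  }
  if (!is.null(out_dir))
    utils::write.csv(log, file.path(out_dir, "log.csv"), row.names = FALSE)
  list(student = student, teacher = teacher, log = log,
       bin_edges = bin_edges, best_val_mae = best, checkpoint = ckpt_path)
}

#' Save / load a training checkpoint
#'
#' @param path `.rds` destination.
#' @param student,teacher model lists (see [train_step()]).
#' @param config the [train_config()] used.
#' @param bin_edges density-class bin edges.
#' @param val_mae validation MAE at save time.
#' @return `path` / the checkpoint list.
#' @export
save_checkpoint <- function(path, student, teacher, config, bin_edges,
                            val_mae = NA_real_) {
  saveRDS(list(student = student[c("params", "cfg", "step")],
               teacher = teacher["params"], cfg = student$cfg,
               config = config, bin_edges = bin_edges, val_mae = val_mae),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Evaluate a trained model on a manifest split
#'
#' @param ckpt a checkpoint list from [load_checkpoint()].
#' @param manifest manifest `data.frame`.
#' @param root dataset root.
#' @param split `"test"`, `"val"` or `"train"`.
#' @param model `"teacher"` or `"student"` weights.
#' @return an `eval_result` (see [compute_metrics()]) with a `per_image`
#'   data.frame attached.
#' @export
evaluate_split <- function(ckpt, manifest, root = ".", split = "test",
                           model = c("teacher", "student")) {
  model <- match.arg(model)
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0) stop_cfg("split '", split, "' is empty")
  params <- if (model == "teacher") ckpt$teacher$params
  else ckpt$student$params
  pairs <- t(vapply(seq_len(nrow(rows)), function(i) {
    e <- load_entry(root, rows[i, ])
    c(predict_count(params, e$image, ckpt$cfg), nrow(e$points$points))
  }, numeric(2)))
  res <- compute_metrics(pairs)
  res$per_image <- data.frame(image_id = rows$image_path,
                              predicted = pairs[, 1], actual = pairs[, 2])
  res
}
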