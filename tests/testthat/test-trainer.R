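test_that("EMA updates follow the geometric closed form", {
  # scalar surrogate: one 1x1 "parameter"
  t0 <- list(a = list(W = matrix(0), b = 0))
  s <- list(a = list(W = matrix(1), b = 1))
  th <- t0
  for (n in 1:10) th <- ema_update(th, s, 0.9)
  expect_equal(th$a$W[1], 1 - 0.9^10, tolerance = 1e-12)
  # teacher equal to a static student is a fixed point
  fixed <- ema_update(s, s, 0.97)
  expect_identical(fixed$a$W, s$a$W)
  # alpha = 0 copies the student outright
  expect_equal(ema_update(t0, s, 0)$a$W[1], 1)
  expect_error(ema_update(t0, list(b = list(W = matrix(1), b = 1)), 0.9),
               "structures differ")
})

make_batches <- function(n_lab = 2, n_unl = 2, seed = 1) {
  spec <- tiny_spec(c(8, 8))
  lab <- lapply(seq_len(n_lab), function(i) {
    sc <- generate_scene(spec, seed = seed + i)
    d8 <- downsample_sum_preserving(
      geometric_adaptive_density(sc$points, 64, 64), 8)
    list(image = sc$image, d_gt8 = d8, y_gt = 2L)
  })
  unl <- if (n_unl > 0) lapply(seq_len(n_unl), function(i) {
    sc <- generate_scene(spec, seed = seed + 100 + i)
    mk <- random_patch_mask(64, 64, mask_spec(16, 0.1), seed = seed + i)
    list(student_image = apply_mask(sc$image, mk, 0.5),
         teacher_image = sc$image, mask = mk)
  }) else NULL
  list(lab = lab, unl = unl)
}

fresh_student <- function(seed = 1) {
  tm <- tiny_model(seed)
  list(params = tm$params, cfg = tm$cfg,
       opt = shootcount:::adam_init(tm$params), step = 0L)
}

test_that("a training step is deterministic and the teacher is pure EMA", {
  b <- make_batches()
  config <- train_config("reduced", epochs = 1)
  st <- fresh_student(); te <- list(params = st$params, cfg = st$cfg)
  r1 <- train_step(st, te, b$lab, b$unl, config)
  r2 <- train_step(st, te, b$lab, b$unl, config)
  expect_identical(unclass(r1$breakdown), unclass(r2$breakdown))
  expect_identical(r1$student$params, r2$student$params)
  # teacher_new = alpha * teacher_old + (1 - alpha) * student_new exactly,
  # i.e. no gradient ever reaches the teacher
  alpha1 <- min(config$ema_alpha, 1 - 1 / 2)
  expect_equal(r1$teacher$params$reg2$W,
               alpha1 * te$params$reg2$W +
                 (1 - alpha1) * r1$student$params$reg2$W, tolerance = 1e-12)
  expect_true(all(is.finite(unlist(r1$breakdown))))
})

test_that("supervised-only steps report a zero unsupervised loss", {
  b <- make_batches(n_unl = 0)
  config <- train_config("reduced")
  st <- fresh_student(); te <- list(params = st$params, cfg = st$cfg)
  r <- train_step(st, te, b$lab, NULL, config)
  expect_equal(r$breakdown$l_u, 0)
  expect_gt(r$breakdown$l_l, 0)
})

test_that("unlabeled data with zero masking ratio is a configuration error", {
  b <- make_batches()
  config <- train_config("reduced", masking_ratio = 0)
  st <- fresh_student(); te <- list(params = st$params, cfg = st$cfg)
  expect_error(train_step(st, te, b$lab, b$unl, config), "masking_ratio")
})

test_that("the student overfits a single labeled image (loss decreases)", {
  b <- make_batches(n_lab = 1, n_unl = 0, seed = 5)
  config <- train_config("reduced")
  st <- fresh_student(seed = 2); te <- list(params = st$params, cfg = st$cfg)
  first <- NULL; last <- NULL
  for (i in 1:20) {
    r <- train_step(st, te, b$lab, NULL, config)
    st <- r$student; te <- r$teacher
    if (i == 1) first <- r$breakdown$total
    last <- r$breakdown$total
  }
  expect_lt(last, first)
})

test_that("fit trains, logs, checkpoints, and reloads reproducibly", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(8, tiny_spec(c(5, 12)), dir, seed = 3)
  man <- select_labeled(man, 1, seed = 1)
  config <- train_config("reduced", epochs = 2, batch_size = 2, seed = 4)
  run <- fit(man, config, root = dir, out_dir = file.path(dir, "run"))
  expect_equal(nrow(run$log), 2)
  expect_true(all(c("l_rl", "l_cl", "l_ru", "l_cu", "val_mae", "val_rmse")
                  %in% names(run$log)))
  expect_true(file.exists(run$checkpoint))
  expect_true(file.exists(file.path(dir, "run", "log.csv")))
  # full labeling means no unsupervised loss anywhere
  expect_true(all(run$log$l_ru == 0))
  ck <- load_checkpoint(run$checkpoint)
  ev <- evaluate_split(ck, man, root = dir, split = "val", model = "teacher")
  expect_equal(ev$mae, run$best_val_mae, tolerance = 1e-6)
  et <- evaluate_split(ck, man, root = dir, split = "test")
  expect_s3_class(et, "eval_result")
  expect_true(all(c("predicted", "actual") %in% names(et$per_image)))
})

test_that("fit refuses a manifest without labeled training images", {
  man <- split_dataset(sprintf("i%02d", 1:10), seed = 1)
  man$labeled[man$split == "train"] <- FALSE
  expect_error(fit(man, train_config("reduced")), "no labeled")
})

test_that("YAML training configs round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("profile: reduced", "epochs: 7", "masking_ratio: 0.3",
               "ssim:", "  window: 7"), f)
  cfg <- read_train_config(f)
  expect_equal(cfg$epochs, 7L)
  expect_equal(cfg$masking_ratio, 0.3)
  expect_equal(cfg$ssim$window, 7L)
  expect_equal(cfg$crop_size, 64L)  # reduced profile default
})
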