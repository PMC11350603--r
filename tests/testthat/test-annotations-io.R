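test_that("JSON point annotations round-trip losslessly", {
  pts <- point_set(cbind(c(1.25, 10.5, 63.999), c(0, 7.125, 3)), "img_a")
  f <- withr::local_tempfile(fileext = ".json")
  write_points(pts, f)
  back <- read_points(f)
  expect_equal(back$points, pts$points, tolerance = 1e-6)
  expect_equal(back$image_id, "img_a")
})

test_that("CSV point annotations round-trip and tolerate empty files", {
  pts <- point_set(cbind(c(3.5, 2), c(1, 60)), "b")
  f <- withr::local_tempfile(fileext = ".csv")
  write_points(pts, f)
  expect_equal(read_points(f)$points, pts$points, tolerance = 1e-6)
  # header-only CSV is a valid zero-count image
  writeLines("x,y", f)
  expect_equal(nrow(read_points(f)$points), 0)
  # empty JSON points list likewise
  fj <- withr::local_tempfile(fileext = ".json")
  write_points(point_set(NULL, "z"), fj)
  expect_equal(nrow(read_points(fj)$points), 0)
})

test_that("invalid coordinates fail with the offending row named", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "3,4", "-1,2"), f)
  expect_error(read_points(f), "row\\(s\\) 2")
  writeLines(c("x,y", "3,4", "a,2"), f)
  expect_error(read_points(f), "non-numeric")
})

test_that("7:2:1 split sizes follow the floor rule", {
  man <- split_dataset(sprintf("i%03d", 1:313), c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(as.integer(table(man$split)[c("train", "val", "test")]),
               c(219L, 62L, 32L))
  man10 <- split_dataset(sprintf("i%02d", 1:10), c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(as.integer(table(man10$split)[c("train", "val", "test")]),
               c(7L, 2L, 1L))
})

test_that("split covers every id exactly once for any n and ratios", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:400, 1)
    r <- c(0.5, 0.3, 0.2)
    ids <- sprintf("id%04d", sample(1e5, n))
    man <- split_dataset(ids, r, seed = i)
    expect_setequal(man$image_path, ids)
    expect_equal(nrow(man), n)
  }
})

test_that("bad ratios are rejected", {
  expect_error(split_dataset(letters, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(split_dataset(letters, c(0.9, 0.2, -0.1)), "positive")
})

test_that("labeled selection sizes follow floor(percentage x train)", {
  man <- split_dataset(sprintf("i%03d", 1:313), seed = 7)
  m5 <- select_labeled(man, 0.05, seed = 2)
  expect_equal(sum(m5$labeled & m5$split == "train"), 10)
  expect_true(all(m5$labeled[m5$split != "train"]))
  m50 <- select_labeled(man, 0.5, seed = 2)
  expect_equal(sum(m50$labeled & m50$split == "train"), 109)
  m100 <- select_labeled(man, 1, seed = 2)
  expect_true(all(m100$labeled))
})

test_that("selection is order-independent and idempotent under fixed seeds", {
  ids <- sprintf("im%03d", 1:50)
  a <- select_labeled(split_dataset(ids, seed = 3), 0.2, seed = 5)
  b <- select_labeled(split_dataset(rev(ids), seed = 3), 0.2, seed = 5)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c2 <- select_labeled(split_dataset(sample(ids), seed = 3), 0.2, seed = 5)
  expect_equal(as.data.frame(a), as.data.frame(c2))
})

test_that("selection yielding zero labeled images is an error", {
  man <- split_dataset(sprintf("i%02d", 1:10), seed = 1)
  expect_error(select_labeled(man, 0.01, seed = 1), "zero labeled")
  expect_error(select_labeled(man, 0, seed = 1), "in \\(0, 1\\]")
})

test_that("density maps round-trip through the HDF5 container", {
  f <- withr::local_tempfile(fileext = ".h5")
  z <- density_map(matrix(0, 32, 32))
  write_density(z, f)
  expect_equal(sum(read_density(f)), 0)
  set.seed(1)
  m <- matrix(runif(64 * 48), 64, 48)
  m <- density_map(m * 150 / sum(m), scale = 8L)
  write_density(m, f)
  back <- read_density(f)
  expect_equal(sum(back), 150, tolerance = 1e-4)  # float32 storage
  expect_equal(dim(back), c(64L, 48L))
  expect_equal(attr(back, "scale"), 8L)
})

test_that("invalid density maps and corrupt containers are rejected", {
  f <- withr::local_tempfile(fileext = ".h5")
  expect_error(write_density(matrix(c(-1, 0, 0, 0), 2), f), "negative")
  expect_error(write_density(matrix(c(NaN, 0, 0, 0), 2), f), "non-finite")
  writeLines("not an hdf5 file", f)
  expect_error(read_density(f), "failed to read")
})
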