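test_that("min-max normalization maps extrema to 0 and 1", {
  expect_equal(minmax_normalize(matrix(c(2, 4, 6), 1L)),
               matrix(c(0, 0.5, 1), 1L))
  x <- matrix(rnorm(32L * 32L, sd = 7), 32L)
  y <- minmax_normalize(x)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  # brute-force per-pixel evaluation of the formula
  oracle <- matrix(0, 32L, 32L)
  for (i in 1:32) for (j in 1:32)
    oracle[i, j] <- (x[i, j] - min(x)) / (max(x) - min(x))
  expect_equal(y, oracle)
  # idempotence on non-constant input
  expect_equal(minmax_normalize(y), y)
})

test_that("constant images normalize to zeros and non-finite input errors", {
  expect_equal(minmax_normalize(matrix(3, 4L, 4L)), array(0, c(4L, 4L)))
  bad <- matrix(1, 2L, 2L); bad[1L] <- NaN
  expect_error(minmax_normalize(bad), "NaN")
  bad[1L] <- Inf
  expect_error(minmax_normalize(bad), "NaN|infinite")
})

test_that("default augmentation yields ten independently transformed outputs", {
  s <- generate_phantom(tiny_phantom_config(lesion_probability = 1,
                                            seed = 2L))
  aug <- augment_sample(s)
  expect_length(aug, 10L)
  trans <- vapply(aug, function(a) attr(a, "transform"), character(1))
  expect_identical(sum(grepl("^rotate", trans)), 4L)
  expect_identical(sum(grepl("^shift", trans)), 4L)
  expect_identical(sum(grepl("^scale", trans)), 2L)
  for (a in aug) {
    expect_identical(dim(a$image), dim(s$image))   # shape preserved
    expect_true(all(a$mask %in% 0:2))              # label alphabet closed
  }
})

test_that("zero-degree rotation is the identity copy", {
  s <- generate_phantom(tiny_phantom_config(seed = 4L))
  aug <- augment_sample(s)
  id <- aug[[which(vapply(aug, function(a)
    attr(a, "transform"), character(1)) == "rotate:0")]]
  expect_identical(id$image, s$image)
  expect_identical(id$mask, s$mask)
})

test_that("shifts move the foreground the configured number of pixels", {
  m <- matrix(0L, 16L, 16L); m[8L, 8L] <- 1L
  img <- matrix(0, 16L, 16L); img[8L, 8L] <- 1
  s <- image_sample(img, m, "pt")
  cfg <- augmentation_config(rotation_degrees = 0, shift_fraction = 0.25)
  aug <- augment_sample(s, cfg)
  down <- aug[[which(vapply(aug, function(a)
    attr(a, "transform"), character(1)) == "shift:down")]]
  expect_identical(which(down$mask == 1L, arr.ind = TRUE)[1L, ],
                   c(row = 12L, col = 8L))
})

test_that("augmentation configs reject empty or invalid settings", {
  expect_error(augmentation_config(rotation_degrees = numeric(0)),
               "rotation_degrees")
  expect_error(augmentation_config(scale_factors = numeric(0)),
               "scale_factors")
  expect_error(augmentation_config(shift_fraction = 0), "shift_fraction")
})

test_that("the 70/30 split produces the documented sizes", {
  ds <- generate_dataset(tiny_phantom_config(image_size = 16L,
                                             lesion_probability = 0.3,
                                             seed = 31L), 100L)
  sp <- train_test_split(ds, split_spec(seed = 1L))
  expect_length(sp$train, 70L)
  expect_length(sp$test, 30L)
  ds10 <- ds[1:10]
  sp10 <- train_test_split(ds10, split_spec(seed = 1L))
  expect_length(sp10$train, 7L)
  expect_length(sp10$test, 3L)
  # disjoint partition
  ids <- function(x) vapply(x, function(s) s$sample_id, character(1))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(ds))
})

test_that("splitting is deterministic and stratified by lesion presence", {
  ds <- generate_dataset(tiny_phantom_config(image_size = 16L,
                                             lesion_probability = 0.3,
                                             seed = 55L), 60L)
  a <- train_test_split(ds, split_spec(seed = 9L))
  b <- train_test_split(ds, split_spec(seed = 9L))
  ids <- function(x) vapply(x, function(s) s$sample_id, character(1))
  expect_identical(ids(a$train), ids(b$train))
  frac <- function(x) mean(vapply(x, daunet:::has_lesion, logical(1)))
  # stratification keeps prevalence within one sample of the global rate
  expect_lt(abs(frac(a$train) - frac(ds)), 1 / length(a$train) + 1e-9)
})

test_that("cross-validation folds partition the training set", {
  ds <- generate_dataset(tiny_phantom_config(image_size = 16L, seed = 6L),
                         80L)
  folds <- make_folds(ds, split_spec(n_folds = 4L, seed = 2L))
  expect_length(folds, 4L)
  val_sizes <- vapply(folds, function(f) length(f$validation), integer(1))
  expect_identical(val_sizes, rep(20L, 4L))
  for (f in folds) {
    expect_length(f$train, 60L)
    expect_length(intersect(f$train, f$validation), 0L)
  }
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_identical(all_val, 1:80)    # each sample validates exactly once
  expect_identical(make_folds(ds, split_spec(n_folds = 4L, seed = 2L)),
                   folds)
})

test_that("degenerate split requests are rejected", {
  ds <- generate_dataset(tiny_phantom_config(image_size = 16L, seed = 1L),
                         3L)
  expect_error(split_spec(n_folds = 1L), "n_folds")
  expect_error(make_folds(ds, split_spec(n_folds = 4L)), "at least")
  expect_error(train_test_split(ds[1L], split_spec()), "at least 2")
})
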