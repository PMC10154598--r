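small_dataset <- function(n = 4L, seed = 1L, lesion_probability = 1) {
  generate_dataset(tiny_phantom_config(seed = seed,
                                       lesion_probability =
                                         lesion_probability), n)
}

test_that("training runs the requested epochs and logs both curves", {
  ds <- small_dataset(4L)
  net <- build_network(tiny_net_config())
  res <- train(net, ds[1:3], ds[4L], tiny_train_config(epochs = 1L))
  expect_s3_class(res, "train_result")
  expect_identical(nrow(res$loss_curve), 1L)
  expect_identical(nrow(res$iou_curve), 1L)
  expect_identical(res$best_epoch, 1L)
  expect_true(file.exists(res$best_checkpoint))
  expect_error(train_config(epochs = 0L), "epochs")
})

test_that("seeded training is exactly reproducible", {
  ds <- small_dataset(4L, seed = 21L)
  r1 <- train(build_network(tiny_net_config(seed = 2L)), ds[1:3], ds[4L],
              tiny_train_config(epochs = 3L, seed = 5L))
  r2 <- train(build_network(tiny_net_config(seed = 2L)), ds[1:3], ds[4L],
              tiny_train_config(epochs = 3L, seed = 5L))
  expect_identical(r1$loss_curve, r2$loss_curve)
  expect_identical(r1$iou_curve, r2$iou_curve)
})

test_that("a zero learning rate leaves every parameter untouched", {
  ds <- small_dataset(3L, seed = 4L)
  net <- build_network(tiny_net_config(seed = 8L))
  before <- daunet:::get_param_state(net$modules)
  train(net, ds, NULL, tiny_train_config(epochs = 2L,
                                         learning_rate = 0))
  expect_equal(daunet:::get_param_state(net$modules), before,
               tolerance = 0)
})

test_that("the best checkpoint reproduces its validation metrics exactly", {
  ds <- small_dataset(6L, seed = 31L)
  net <- build_network(tiny_net_config(seed = 3L))
  res <- train(net, ds[1:4], ds[5:6], tiny_train_config(epochs = 4L))
  best_logged <- res$loss_curve$val_loss[res$best_epoch]
  expect_equal(min(res$loss_curve$val_loss), best_logged)
  fresh <- build_network(tiny_net_config(seed = 3L))
  load_checkpoint(fresh, res$best_checkpoint)
  revalidated <- daunet:::validate_epoch(fresh, ds[5:6], "gland")
  expect_equal(revalidated$loss, best_logged, tolerance = 1e-12)
})

test_that("prediction is an argmax with low-index tie-breaking", {
  ds <- small_dataset(1L)
  net <- build_network(tiny_net_config())
  pred <- predict_mask(net, minmax_normalize(ds[[1L]]$image))
  expect_identical(dim(pred), dim(ds[[1L]]$mask))
  expect_true(all(pred %in% c(0L, 1L)))
  # brute-force per-pixel max scan on random logits
  withr::with_seed(14L, {
    logits <- array(rnorm(8L * 8L * 3L), c(8L, 8L, 3L))
    lab <- daunet:::argmax_classes(logits)
    for (i in 1:8) for (j in 1:8)
      expect_identical(lab[i, j], which.max(logits[i, j, ]) - 1L)
    # exact ties resolve to the lower class
    tied <- array(0, c(2L, 2L, 3L))
    expect_true(all(daunet:::argmax_classes(tied) == 0L))
  })
})

test_that("label domains are validated against the class count", {
  expect_error(daunet:::check_labels(matrix(2L, 2L, 2L), 2L, "s1"), "s1")
  m <- matrix(0L, 4L, 4L); m[2L, 2L] <- 2L
  expect_identical(map_labels(m, "gland")[2L, 2L], 1L)
  expect_identical(map_labels(m, "lesion")[2L, 2L], 1L)
  expect_identical(sum(map_labels(m, "lesion")), 1L)
  expect_identical(map_labels(m, "joint"), m)
  net3 <- build_network(tiny_net_config(num_classes = 3L))
  expect_error(train(net3, small_dataset(2L), NULL, tiny_train_config(),
                     label_mode = "gland"), "num_classes")
})

test_that("cross-validation produces one report per fold and aggregates them", {
  ds <- small_dataset(8L, seed = 41L, lesion_probability = 0.5)
  cv <- run_cross_validation(ds, tiny_net_config(seed = 2L),
                             tiny_train_config(epochs = 2L),
                             split_spec(n_folds = 4L, seed = 3L))
  expect_length(cv$fold_reports, 4L)
  for (r in cv$fold_reports) expect_s3_class(r, "metric_report")
  expect_identical(unique(cv$summary$n[cv$summary$metric != "hd95"]), 4)
  # aggregation identity: the mean of identical reports is that report
  rep1 <- cv$fold_reports[[1L]]
  agg <- aggregate_reports(list(rep1, rep1, rep1, rep1))
  expect_equal(agg$mean[agg$metric == "dice"], rep1$dice)
  expect_equal(agg$sd[agg$metric == "dice"], 0)
})

test_that("an oracle predictor scores perfectly on every fold", {
  ds <- small_dataset(4L, seed = 51L)
  folds <- make_folds(ds, split_spec(n_folds = 4L, seed = 1L))
  for (f in folds) {
    s <- ds[[f$validation]]
    gt <- map_labels(s$mask, "gland")
    rep <- evaluate_pair(gt, gt, 1L)   # prediction == ground truth
    expect_equal(rep$dice, 1)
    expect_equal(rep$hd95, 0)
  }
})

test_that("the ablation runner enumerates the toggle grid deterministically", {
  ds <- small_dataset(6L, seed = 61L, lesion_probability = 0.5)
  grid <- ablation_grid()
  expect_identical(nrow(grid), 6L)
  expect_identical(sum(rowSums(grid[2:4, ]) == 1L), 3L)  # one-component rows
  one_off <- grid[1L, , drop = FALSE]                     # plain backbone
  t1 <- run_ablation(ds, tiny_net_config(seed = 4L),
                     tiny_train_config(epochs = 2L),
                     split_spec(seed = 5L), toggle_grid = one_off)
  t2 <- run_ablation(ds, tiny_net_config(seed = 4L),
                     tiny_train_config(epochs = 2L),
                     split_spec(seed = 5L), toggle_grid = one_off)
  expect_identical(t1$dice, t2$dice)   # bit-for-bit reproducible
  expect_identical(t1$hd95, t2$hd95)
  expect_identical(nrow(t1), 1L)
  expect_false(t1$use_dense[1L] || t1$use_cbam[1L] || t1$use_aspp[1L])
})
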