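#' Training configuration
#'
#' @param epochs Maximum number of epochs (default 150).
#' @param learning_rate Adam learning rate (default 1e-4; 0 is allowed and
#'   leaves parameters untouched, which is useful for plumbing tests).
#' @param batch_size Samples per gradient step (default 4).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (must not exceed `epochs`).
#' @param checkpoint_dir Directory receiving the best-validation checkpoint.
#' @param seed Seed for shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 150L, learning_rate = 1e-4,
                         batch_size = 4L, early_stop_patience = 15L,
                         checkpoint_dir = tempfile("daunet_ckpt_"),
                         seed = 1L) {
  epochs <- check_count(epochs, "epochs", min = 1L)
  learning_rate <- check_number(learning_rate, "learning_rate", min = 0)
  batch_size <- check_count(batch_size, "batch_size", min = 1L)
  early_stop_patience <- check_count(early_stop_patience,
                                     "early_stop_patience", min = 1L)
  if (early_stop_patience > epochs)
    abort_config("early_stop_patience", "must not exceed epochs")
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size,
                 early_stop_patience = early_stop_patience,
                 checkpoint_dir = checkpoint_dir, seed = seed),
            class = "train_config")
}

#' Map a 3-label mask onto a model's label space
#'
#' `"joint"` keeps \{0, 1, 2\}; `"gland"` merges gland and lesion into the
#' foreground (the whole organ, labels >= 1); `"lesion"` keeps only label 2
#' as foreground. The two binary modes correspond to training separate
#' single-target models for the organ and for the lesion.
#'
#' @param mask Integer matrix with labels in \{0, 1, 2\}.
#' @param label_mode One of `"joint"`, `"gland"`, `"lesion"`.
#' @return Integer matrix of training labels.
#' @export
map_labels <- function(mask, label_mode = c("gland", "lesion", "joint")) {
  label_mode <- match.arg(label_mode)
  out <- switch(label_mode,
                joint = mask,
                gland = (mask >= 1L) * 1L,
                lesion = (mask == 2L) * 1L)
  storage.mode(out) <- "integer"
  out
}

required_classes <- function(label_mode) if (label_mode == "joint") 3L else 2L

sample_to_input <- function(sample) {
  as_cube(minmax_normalize(sample$image))
}

# Per-pixel softmax cross-entropy; returns the mean loss and the gradient
# w.r.t. the logits (already divided by the pixel count).
softmax_ce <- function(logits, labels) {
  d <- dim(logits)
  hw <- d[1L] * d[2L]
  k <- d[3L]
  m <- matrix(logits, hw, k)
  mx <- do.call(pmax, lapply(seq_len(k), function(c) m[, c]))
  ex <- exp(m - mx)
  z <- rowSums(ex)
  p <- ex / z
  idx <- cbind(seq_len(hw), as.vector(labels) + 1L)
  loss <- -mean(log(p[idx]) )
  dm <- p
  dm[idx] <- dm[idx] - 1
  list(loss = loss, dlogits = array(dm / hw, dim = d))
}

check_labels <- function(labels, num_classes, sample_id) {
  if (any(labels < 0L) || any(labels >= num_classes))
    stop(sprintf("sample '%s' has labels outside [0, %d)", sample_id,
                 num_classes), call. = FALSE)
  invisible(NULL)
}

# Mean validation loss and foreground IoU (mean over foreground classes for
# the joint model) in eval mode.
validate_epoch <- function(net, samples, label_mode) {
  k <- net$config$num_classes
  losses <- numeric(length(samples))
  ious <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    lab <- map_labels(s$mask, label_mode)
    logits <- net_forward(net, sample_to_input(s), train = FALSE)
    losses[i] <- softmax_ce(logits, lab)$loss
    pred <- argmax_classes(logits)
    fg <- seq_len(k - 1L)
    ious[i] <- mean(vapply(fg, function(cl) iou(confusion(pred, lab, cl)),
                           numeric(1)))
  }
  list(loss = mean(losses), iou = mean(ious))
}

#' Train the network
#'
#' Minimizes per-pixel cross-entropy with Adam. After every epoch the
#' validation loss and IoU are logged; the parameters achieving the best
#' validation loss are checkpointed, and training stops early once the
#' validation loss has not improved for `early_stop_patience` consecutive
#' epochs. The run is fully seeded (shuffling and dropout from
#' `config$seed`; initialization from the network's own seed), so repeating
#' it with the same inputs reproduces the loss curves exactly.
#'
#' @param net A built [build_network()] network (trained in place).
#' @param train_set,val_set Lists of [image_sample()] objects. `val_set` may
#'   be `NULL`, in which case the training loss drives checkpointing and
#'   early stopping.
#' @param config A [train_config()].
#' @param label_mode See [map_labels()].
#' @param verbose Print one line per epoch.
#' @param resume Continue a previous [train()] call on the same network:
#'   keeps the Adam moment estimates and step counter instead of starting
#'   the optimizer afresh. Used to train in stages while inspecting metrics
#'   in between.
#' @return A list of class `train_result` with `loss_curve` (data frame
#'   epoch/train_loss/val_loss), `iou_curve` (epoch/val_iou), `best_epoch`,
#'   `best_checkpoint`, and `epochs_run`.
#' @export
train <- function(net, train_set, val_set = NULL, config = train_config(),
                  label_mode = c("gland", "lesion", "joint"),
                  verbose = FALSE, resume = FALSE) {
  stopifnot(inherits(net, "daunet_network"),
            inherits(config, "train_config"))
  label_mode <- match.arg(label_mode)
  if (length(train_set) == 0L)
    stop("train_set must be non-empty", call. = FALSE)
  if (net$config$num_classes != required_classes(label_mode))
    stop(sprintf("label_mode '%s' needs num_classes = %d, network has %d",
                 label_mode, required_classes(label_mode),
                 net$config$num_classes), call. = FALSE)
  for (s in train_set)
    check_labels(map_labels(s$mask, label_mode), net$config$num_classes,
                 s$sample_id)

  n <- length(train_set)
  best_path <- file.path(config$checkpoint_dir, "best.rds")
  curves <- vector("list", config$epochs)
  best_loss <- Inf
  best_epoch <- 0L
  stall <- 0L
  if (!resume) {
    for (m in net$modules) m$opt <- NULL
    net$t_adam <- 0L
  }
  t_adam <- net$t_adam %||% 0L
  epochs_run <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        zero_grads(net$modules)
        for (i in b) {
          s <- train_set[[i]]
          lab <- map_labels(s$mask, label_mode)
          logits <- net_forward(net, sample_to_input(s), train = TRUE)
          lo <- softmax_ce(logits, lab)
          ep_loss <- ep_loss + lo$loss
          net_backward(net, lo$dlogits / length(b))
        }
        t_adam <- t_adam + 1L
        adam_step(net$modules, config$learning_rate, t_adam)
      }
      ep_loss <- ep_loss / n
      val <- if (is.null(val_set)) list(loss = NA_real_, iou = NA_real_)
             else validate_epoch(net, val_set, label_mode)
      curves[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                    val_loss = val$loss, val_iou = val$iou)
      monitor <- if (is.null(val_set)) ep_loss else val$loss
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  iou %.4f", epoch,
                        ep_loss, val$loss, val$iou))
      if (monitor < best_loss) {
        best_loss <- monitor
        best_epoch <- epoch
        stall <- 0L
        save_checkpoint(net, best_path,
                        meta = list(epoch = epoch, monitor = monitor))
      } else {
        stall <- stall + 1L
      }
      epochs_run <- epoch
      net$t_adam <- t_adam
      if (stall >= config$early_stop_patience) break
    }
  })

  log <- do.call(rbind, curves[seq_len(epochs_run)])
  structure(list(loss_curve = log[, c("epoch", "train_loss", "val_loss")],
                 iou_curve = log[, c("epoch", "val_iou")],
                 best_epoch = best_epoch, best_checkpoint = best_path,
                 epochs_run = epochs_run),
            class = "train_result")
}

#' Predict a label mask
#'
#' Per-pixel argmax over the class logits in eval mode; ties resolve to the
#' lower class index. The image is expected on the normalized `[0, 1]` scale
#' (see [minmax_normalize()]).
#'
#' @param net A built network.
#' @param image `(H, W)` matrix or `(H, W, in_channels)` array.
#' @return Integer matrix of labels in `0 .. num_classes - 1`.
#' @export
predict_mask <- function(net, image) {
  logits <- net_forward(net, image, train = FALSE)
  argmax_classes(logits)
}

#' Evaluate a network on a set of samples
#'
#' @param net A built (trained) network.
#' @param samples List of [image_sample()] objects.
#' @param label_mode See [map_labels()].
#' @param target_class Class evaluated one-vs-rest (default 1, the
#'   foreground of the binary modes).
#' @param spec A [surface_spec()].
#' @return List with `reports` (per-sample `metric_report`s) and `summary`
#'   (an [aggregate_reports()] data frame).
#' @export
evaluate_network <- function(net, samples,
                             label_mode = c("gland", "lesion", "joint"),
                             target_class = 1L, spec = surface_spec()) {
  label_mode <- match.arg(label_mode)
  reports <- lapply(samples, function(s) {
    lab <- map_labels(s$mask, label_mode)
    pred <- predict_mask(net, sample_to_input(s))
    evaluate_pair(pred, lab, target_class, spec)
  })
  list(reports = reports, summary = aggregate_reports(reports))
}

mean_report <- function(reports) {
  agg <- aggregate_reports(reports)
  vals <- setNames(agg$mean, agg$metric)
  structure(list(dice = vals[["dice"]], iou = vals[["iou"]],
                 accuracy = vals[["accuracy"]],
                 sensitivity = vals[["sensitivity"]],
                 hd95 = vals[["hd95"]],
                 hd95_valid = !is.na(vals[["hd95"]])),
            class = "metric_report")
}

#' Four-fold cross-validation runner
#'
#' Partitions the dataset with [make_folds()]; in each round a fresh network
#' is built from `net_config` (identical initialization in every round),
#' trained on the other folds with the held-out fold as validation, restored
#' to its best checkpoint and evaluated on the held-out fold.
#'
#' @param dataset List of [image_sample()] objects.
#' @param net_config A [network_config()].
#' @param tr_config A [train_config()].
#' @param spec A [split_spec()] (its `n_folds` drives the partition).
#' @param label_mode See [map_labels()].
#' @param target_class Class evaluated one-vs-rest.
#' @param verbose Print fold progress.
#' @return List with `fold_reports` (one mean `metric_report` per fold),
#'   `summary` (mean/sd across folds), `fold_details` (per-sample reports),
#'   and `train_results`.
#' @export
run_cross_validation <- function(dataset, net_config, tr_config,
                                 spec = split_spec(),
                                 label_mode = c("gland", "lesion", "joint"),
                                 target_class = 1L, verbose = FALSE) {
  label_mode <- match.arg(label_mode)
  folds <- make_folds(dataset, spec)
  fold_reports <- vector("list", length(folds))
  fold_details <- vector("list", length(folds))
  train_results <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    if (verbose) message(sprintf("fold %d / %d", k, length(folds)))
    net <- build_network(net_config)
    cfg_k <- tr_config
    cfg_k$checkpoint_dir <- file.path(tr_config$checkpoint_dir,
                                      sprintf("fold%d", k))
    tr <- train(net, dataset[folds[[k]]$train], dataset[folds[[k]]$validation],
                cfg_k, label_mode, verbose = FALSE)
    load_checkpoint(net, tr$best_checkpoint)
    ev <- evaluate_network(net, dataset[folds[[k]]$validation], label_mode,
                           target_class)
    fold_reports[[k]] <- mean_report(ev$reports)
    fold_details[[k]] <- ev$reports
    train_results[[k]] <- tr
  }
  list(fold_reports = fold_reports,
       summary = aggregate_reports(fold_reports),
       fold_details = fold_details, train_results = train_results)
}

#' Default ablation grid
#'
#' The six toggle combinations tabulated in ablation studies of this
#' architecture: the plain backbone, each component alone, dense+CBAM, and
#' the full model.
#'
#' @return Data frame with logical columns `use_dense`, `use_cbam`,
#'   `use_aspp`.
#' @export
ablation_grid <- function() {
  data.frame(use_dense = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
             use_cbam  = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
             use_aspp  = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE))
}

#' Ablation runner
#'
#' Trains and evaluates one model per toggle combination under identical
#' conditions: the same train/test split, the same seeds, the same optimizer
#' and loss. With all toggles off the model is the plain fusion U-Net
#' backbone, so that row is the ablation baseline.
#'
#' @param dataset List of [image_sample()] objects.
#' @param net_config A [network_config()]; its toggles are overridden row by
#'   row.
#' @param tr_config A [train_config()].
#' @param spec A [split_spec()] used once for the shared train/test split.
#' @param toggle_grid Data frame of toggle combinations (default
#'   [ablation_grid()]).
#' @param label_mode See [map_labels()].
#' @param target_class Class evaluated one-vs-rest.
#' @param verbose Print row progress.
#' @return Data frame: toggles plus mean test Dice, IoU and HD95.
#' @export
run_ablation <- function(dataset, net_config, tr_config,
                         spec = split_spec(), toggle_grid = ablation_grid(),
                         label_mode = c("gland", "lesion", "joint"),
                         target_class = 1L, verbose = FALSE) {
  stopifnot(nrow(toggle_grid) >= 1L,
            all(c("use_dense", "use_cbam", "use_aspp") %in%
                  names(toggle_grid)))
  label_mode <- match.arg(label_mode)
  sp <- train_test_split(dataset, spec)
  rows <- lapply(seq_len(nrow(toggle_grid)), function(i) {
    if (verbose) message(sprintf("ablation row %d / %d", i,
                                 nrow(toggle_grid)))
    cfg <- net_config
    cfg$use_dense <- toggle_grid$use_dense[i]
    cfg$use_cbam <- toggle_grid$use_cbam[i]
    cfg$use_aspp <- toggle_grid$use_aspp[i]
    net <- build_network(cfg)
    cfg_i <- tr_config
    cfg_i$checkpoint_dir <- file.path(tr_config$checkpoint_dir,
                                      sprintf("ablation%d", i))
    tr <- train(net, sp$train, sp$test, cfg_i, label_mode, verbose = FALSE)
    load_checkpoint(net, tr$best_checkpoint)
    rep <- mean_report(evaluate_network(net, sp$test, label_mode,
                                        target_class)$reports)
    data.frame(use_dense = cfg$use_dense, use_cbam = cfg$use_cbam,
               use_aspp = cfg$use_aspp, dice = rep$dice, iou = rep$iou,
               hd95 = rep$hd95, parameters = count_parameters(net))
  })
  do.call(rbind, rows)
}
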