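# Training recipe and experiment drivers: Adam over the nested parameter
# tree, reduce-on-plateau learning-rate scheduling, the class-balanced
# training loop with per-epoch augmentation, and the open-set
# train/evaluate protocol.

# ---- optimizer over nested parameter trees ----

adam_update <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(g)) {
    if (is.null(m)) {
      m <- vector("list", length(g)); names(m) <- names(g)
      v <- m
    }
    keys <- if (!is.null(names(g))) names(g) else seq_along(g)
    for (k in keys) {
      r <- adam_update(p[[k]], g[[k]], m[[k]], v[[k]], lr, b1, b2, eps, t)
      p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
    }
  } else {
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
  }
  list(p = p, m = m, v = v)
}

# ---- reduce-on-plateau scheduler ----

#' Reduce-on-plateau learning-rate scheduler
#'
#' Multiplies the learning rate by `factor` whenever the monitored
#' validation loss has not improved for `patience` consecutive epochs
#' (patience is counted in epochs, the unit at which validation loss is
#' observed).
#'
#' @param lr Initial learning rate.
#' @param factor Multiplicative decay (0.1 by default).
#' @param patience Epochs without improvement before decaying (20).
#' @return A scheduler state list; update it with [plateau_update()].
#' @export
plateau_scheduler <- function(lr = 0.001, factor = 0.1, patience = 20L) {
  list(lr = lr, factor = factor, patience = as.integer(patience),
       best = Inf, wait = 0L)
}

#' Advance a plateau scheduler by one epoch
#'
#' @param state A [plateau_scheduler()] state.
#' @param val_loss The epoch's validation loss.
#' @return The updated state (`state$lr` holds the current learning rate).
#' @export
plateau_update <- function(state, val_loss) {
  if (val_loss < state$best - 1e-12) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr * state$factor
      state$wait <- 0L
    }
  }
  state
}

# ---- run configuration ----

#' Training run configuration
#'
#' Bundles every knob of a training run. The defaults are the standard
#' finger-vein recipe: Adam at learning rate 0.001, reduce-on-plateau
#' scheduling (factor 0.1, patience 20 epochs on validation loss), at most
#' 100 epochs, batches of 32 classes x 4 samples, the geometric augmentation
#' policy of [augment_config()], and a joint softmax + center loss with
#' lambda = 0.1.
#'
#' @param attention,input_size,stem_channels,stage_widths,blocks_per_stage,gem_p_init
#'   Passed to [network_config()] once the number of training classes is
#'   known.
#' @param lambda Center-loss weight (see [loss_config()]).
#' @param center_lr Center update rate (see [center_state()]).
#' @param augment An [augment_config()].
#' @param classes_per_batch,samples_per_class Batch composition.
#' @param lr,scheduler_factor,scheduler_patience Optimizer and scheduler.
#' @param max_epochs Maximum training epochs.
#' @param seed Master seed for the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(attention = c("sa", "none"), input_size = 224L,
                       stem_channels = 32L,
                       stem_pool = TRUE,
                       stage_widths = c(32L, 64L, 128L, 256L),
                       blocks_per_stage = c(1L, 1L, 1L, 1L),
                       gem_p_init = 3, kernel_sizes = c(3L, 5L, 7L, 9L),
                       groups = c(1L, 4L, 8L, 16L),
                       lambda = 0.1, center_lr = 0.5,
                       augment = augment_config(),
                       classes_per_batch = 32L, samples_per_class = 4L,
                       lr = 0.001, scheduler_factor = 0.1,
                       scheduler_patience = 20L, max_epochs = 100L,
                       seed = 1L) {
  attention <- match.arg(attention)
  structure(list(attention = attention, input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 stem_pool = isTRUE(stem_pool),
                 stage_widths = as.integer(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 gem_p_init = gem_p_init,
                 kernel_sizes = as.integer(kernel_sizes),
                 groups = as.integer(groups), lambda = lambda,
                 center_lr = center_lr, augment = augment,
                 classes_per_batch = as.integer(classes_per_batch),
                 samples_per_class = as.integer(samples_per_class),
                 lr = lr, scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_to_network <- function(config, n_classes) {
  network_config(n_classes = n_classes, input_size = config$input_size,
                 stem_channels = config$stem_channels,
                 stem_pool = config$stem_pool,
                 stage_widths = config$stage_widths,
                 blocks_per_stage = config$blocks_per_stage,
                 attention = config$attention,
                 gem_p_init = config$gem_p_init,
                 kernel_sizes = config$kernel_sizes,
                 groups = config$groups)
}

# ---- training ----

#' Train the network on a labeled dataset
#'
#' Runs the joint softmax + center-loss recipe: class-balanced batches,
#' per-epoch geometric augmentation, Adam with reduce-on-plateau scheduling,
#' and an exponential-moving center update after every optimizer step. One
#' sample per class is held out as the validation set; the parameters with
#' the best validation loss are kept as the returned model. The whole run is
#' a pure function of `config$seed`.
#'
#' @param dataset A [vein_dataset()] of the training classes.
#' @param config A [run_config()].
#' @param epochs Number of epochs (defaults to `config$max_epochs`).
#' @param verbose Print one line per epoch.
#' @return An object of class `veinnet_fit`: `model` (best-validation
#'   parameters), `history` (per-epoch losses and learning rate), `centers`,
#'   and `config`.
#' @export
run_train <- function(dataset, config = run_config(),
                      epochs = config$max_epochs, verbose = FALSE) {
  stopifnot(inherits(dataset, "vein_dataset"), inherits(config, "run_config"))
  set.seed(config$seed)
  n_classes <- dataset$n_classes
  # hold out one sample per class for validation
  by_class <- split(seq_along(dataset$labels), dataset$labels)
  val_idx <- vapply(by_class, function(ix) ix[sample.int(length(ix), 1L)],
                    integer(1))
  train_idx <- setdiff(seq_along(dataset$labels), val_idx)
  model <- build_network(config_to_network(config, n_classes))
  cstate <- center_state(n_classes, model$config$embedding_size,
                         config$center_lr)
  sched <- plateau_scheduler(config$lr, config$scheduler_factor,
                             config$scheduler_patience)
  opt <- list(m = NULL, v = NULL, t = 0L)
  cpb <- min(config$classes_per_batch, n_classes)
  val_x <- preprocess_batch(dataset$images[val_idx], config$input_size)
  val_y <- dataset$labels[val_idx]
  history <- NULL
  best_val <- Inf
  best_params <- model$params
  best_buffers <- model$buffers
  lcfg <- loss_config(config$lambda)
  for (ep in seq_len(epochs)) {
    batches <- balanced_batch_sampler(dataset$labels[train_idx], cpb,
                                      config$samples_per_class)
    ep_ls <- 0; ep_lc <- 0
    for (bi in seq_along(batches)) {
      idx <- train_idx[batches[[bi]]]
      imgs <- lapply(dataset$images[idx], augment, config = config$augment)
      x <- preprocess_batch(imgs, config$input_size)
      y <- dataset$labels[idx]
      fw <- network_forward(model, x, training = TRUE)
      model$buffers <- fw$buffers
      ce <- softmax_xent(t(fw$logits), y)
      emb <- t(fw$embedding)
      cstate <- init_unseen_centers(cstate, emb, y)
      lc <- center_loss(emb, y, cstate)
      ep_ls <- ep_ls + ce$loss; ep_lc <- ep_lc + lc
      demb <- t(lcfg$lambda * center_loss_grad(emb, y, cstate))
      grads <- network_backward(model, fw$caches,
                                dembedding = demb, dlogits = t(ce$grad))
      opt$t <- opt$t + 1L
      r <- adam_update(model$params, grads, opt$m, opt$v,
                       sched$lr, 0.9, 0.999, 1e-8, opt$t)
      model$params <- r$p; opt$m <- r$m; opt$v <- r$v
      cstate <- update_centers(cstate, emb, y)
    }
    vf <- network_forward(model, val_x, training = FALSE)
    vce <- softmax_xent(t(vf$logits), val_y)
    vlc <- center_loss(t(vf$embedding), val_y, cstate)
    val_loss <- vce$loss + lcfg$lambda * vlc
    sched <- plateau_update(sched, val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- model$params
      best_buffers <- model$buffers
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss_softmax = ep_ls / length(batches),
      loss_center = ep_lc / length(batches), val_loss = val_loss,
      lr = sched$lr))
    if (verbose)
      message(sprintf("epoch %3d  L_s %.4f  L_c %.1f  val %.4f  lr %.2e",
                      ep, ep_ls / length(batches), ep_lc / length(batches),
                      val_loss, sched$lr))
  }
  model$params <- best_params
  model$buffers <- best_buffers
  structure(list(model = model, history = history, centers = cstate,
                 config = config, best_val_loss = best_val),
            class = "veinnet_fit")
}

#' @export
print.veinnet_fit <- function(x, ...) {
  cat(sprintf("veinnet fit: %d epochs, best validation loss %.4f\n",
              nrow(x$history), x$best_val_loss))
  invisible(x)
}

# ---- evaluation ----

#' Evaluate a model under the open-set verification protocol
#'
#' For each fold seed, splits the classes half/half, embeds the test-class
#' images with the model, builds genuine/impostor pairs and computes
#' EER/accuracy. Folds are independent seeded repetitions; the mean row
#' summarizes them.
#'
#' @param model A `veinnet_model` (e.g. `fit$model`).
#' @param dataset A [vein_dataset()] covering all classes.
#' @param fold_seeds One seed per fold (4 by default).
#' @param metric Similarity for [score_pairs()].
#' @param impostor Impostor-pair convention for [make_pairs()].
#' @return A `verification_summary` data frame (one row per fold plus a
#'   `"mean"` row) with columns `fold`, `eer`, `acc`, `n_genuine`,
#'   `n_impostor`; the per-fold [verification_result()] objects are attached
#'   as attribute `results`.
#' @export
run_evaluate <- function(model, dataset, fold_seeds = 1:4,
                         metric = "cosine", impostor = "representative") {
  stopifnot(inherits(model, "veinnet_model"),
            inherits(dataset, "vein_dataset"))
  splits <- split_open_set(seq_len(dataset$n_classes), fold_seeds)
  rows <- NULL; results <- list()
  for (k in seq_along(splits)) {
    test_i <- which(dataset$labels %in% splits[[k]]$test)
    emb <- embed(model, dataset$images[test_i])
    pairs <- make_pairs(dataset$labels[test_i], impostor = impostor,
                        seed = fold_seeds[k])
    res <- verification_result(score_pairs(emb, pairs, metric))
    results[[k]] <- res
    rows <- rbind(rows, data.frame(fold = as.character(k), eer = res$eer,
                                   acc = res$acc, n_genuine = res$n_genuine,
                                   n_impostor = res$n_impostor))
  }
  rows <- rbind(rows, data.frame(fold = "mean", eer = mean(rows$eer),
                                 acc = mean(rows$acc),
                                 n_genuine = mean(rows$n_genuine),
                                 n_impostor = mean(rows$n_impostor)))
  structure(rows, results = results, class = c("verification_summary",
                                               "data.frame"))
}

#' Run one open-set training + evaluation fold
#'
#' Splits the classes half/half with `fold_seed`, trains on the training
#' half and scores verification on the held-out half, alongside the same
#' measurement for the untrained (freshly initialized) model from the same
#' seed.
#'
#' @param dataset A [vein_dataset()].
#' @param config A [run_config()].
#' @param fold_seed Seed of the class split.
#' @param epochs Training epochs.
#' @return List with `fit`, `trained` and `untrained`
#'   ([verification_result()] objects on the test classes), and the class
#'   `split`.
#' @export
run_open_set <- function(dataset, config = run_config(), fold_seed = 1L,
                         epochs = config$max_epochs) {
  split <- split_open_set(seq_len(dataset$n_classes), fold_seed)[[1]]
  train_i <- which(dataset$labels %in% split$train)
  test_i <- which(dataset$labels %in% split$test)
  train_ds <- vein_dataset(dataset$images[train_i],
                           dataset$labels[train_i])
  eval_one <- function(model) {
    emb <- embed(model, dataset$images[test_i])
    pairs <- make_pairs(dataset$labels[test_i], seed = fold_seed)
    verification_result(score_pairs(emb, pairs))
  }
  set.seed(config$seed)
  untrained <- build_network(config_to_network(config, train_ds$n_classes))
  fit <- run_train(train_ds, config, epochs = epochs)
  list(fit = fit, trained = eval_one(fit$model),
       untrained = eval_one(untrained), split = split)
}

# ---- model inspection ----

#' Per-block parameter and FLOP accounting
#'
#' Reports, for every residual block, the idealized pyramidal-convolution
#' parameter count (the analytic depth schedule under which every level
#' costs exactly one `K1 x K1` standard convolution; see
#' [pyconv_param_count()]), the realized count with the integer group
#' schedule, and the corresponding multiply--accumulate FLOPs at the block's
#' feature-map size.
#'
#' @param model A `veinnet_model`.
#' @return A data frame with one row per block.
#' @export
inspect_model <- function(model) {
  cfg <- model$config
  size <- cfg$input_size %/% (if (cfg$stem_pool) 4L else 2L)
  rows <- NULL
  for (s in seq_along(cfg$stage_widths)) {
    if (s > 1) size <- (size + 1L) %/% 2L
    for (b in seq_len(cfg$blocks_per_stage[s])) {
      key <- sprintf("stage%d_block%d", s, b)
      spec <- model$params[[key]]$spec
      ideal <- pyconv_param_count(spec$in_channels, spec$kernel_sizes,
                                  spec$out_channels)
      real <- pyconv_realized_params(spec)
      fl <- pyconv_flop_count(spec$in_channels, spec$kernel_sizes,
                              spec$out_channels, size, size)
      rows <- rbind(rows, data.frame(
        block = key, in_channels = spec$in_channels,
        width = spec$out_channels[1], map_size = size,
        params_ideal = ideal$total, params_realized = real$total,
        flops_ideal = fl$total))
    }
  }
  rows
}
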