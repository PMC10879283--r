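#' Optimizer specification for network training
#'
#' Stochastic gradient descent with L2 weight decay (defaults: learning
#' rate 1e-3, decay 1e-5) plus classical momentum and mini-batches of 32.
#' Training runs up to `max_epochs`, checkpoints the epoch with the best
#' validation overall balanced accuracy, and stops early after `patience`
#' epochs without improvement.
#'
#' @param lr Learning rate.
#' @param weight_decay L2 penalty coefficient applied to weights (not
#'   biases).
#' @param momentum Classical momentum coefficient.
#' @param batch_size Mini-batch size.
#' @param max_epochs,patience Epoch budget and early-stopping patience.
#' @return An `sgd_spec` list.
#' @export
sgd_spec <- function(lr = 1e-3, weight_decay = 1e-5, momentum = 0.9,
                     batch_size = 32, max_epochs = 300, patience = 30) {
  structure(list(lr = lr, weight_decay = weight_decay, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "sgd_spec")
}

safe_overall_ba <- function(confusion) {
  present <- which(rowSums(confusion) > 0)
  mean(vapply(present, function(k) balanced_accuracy(confusion, k),
              numeric(1)))
}

model_params <- function(model) list(arms = model$arms, fusion = model$fusion)

set_model_params <- function(model, params) {
  model$arms <- params$arms
  model$fusion <- params$fusion
  model
}

zero_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

apply_update <- function(model, grads, velocity, opt) {
  upd_stack <- function(layers, g, v) {
    for (i in seq_along(layers)) {
      v[[i]]$W <- opt$momentum * v[[i]]$W -
        opt$lr * (g[[i]]$W + opt$weight_decay * layers[[i]]$W)
      v[[i]]$b <- opt$momentum * v[[i]]$b - opt$lr * g[[i]]$b
      layers[[i]]$W <- layers[[i]]$W + v[[i]]$W
      layers[[i]]$b <- layers[[i]]$b + v[[i]]$b
    }
    list(layers = layers, v = v)
  }
  for (nm in names(model$arms)) {
    r <- upd_stack(model$arms[[nm]], grads$arm_grads[[nm]],
                   velocity$arms[[nm]])
    model$arms[[nm]] <- r$layers
    velocity$arms[[nm]] <- r$v
  }
  r <- upd_stack(model$fusion, grads$fusion_grads, velocity$fusion)
  model$fusion <- r$layers
  velocity$fusion <- r$v
  list(model = model, velocity = velocity)
}

#' Train one network on an inner train/validation split
#'
#' Mini-batch SGD on the class-weighted cross-entropy; the returned model
#' is the checkpoint of the epoch with the best validation overall
#' balanced accuracy. Fully deterministic given `seed` (batch order,
#' dropout masks and initialization all derive from it).
#'
#' @param x_train,x_val Numeric matrices of harmonized features
#'   (subjects x 735, schema order).
#' @param y_train,y_val Integer class indices 1..3 (or diagnosis factors).
#' @param config A [parallel_net_config()]; its `seed` is overridden by
#'   `seed` so ensemble members differ.
#' @param opt An [sgd_spec()].
#' @param class_weights Per-class loss weights; default computed from
#'   `y_train` via [compute_class_weights()].
#' @param seed Integer seed for this training run.
#' @return List with `model` (best checkpoint), `history` (tibble of
#'   epoch, train loss, validation overall BA) and `best_epoch`.
#' @export
train_net <- function(x_train, y_train, x_val, y_val, config,
                      opt = sgd_spec(), class_weights = NULL, seed = 1L) {
  y_train <- as.integer(y_train)
  y_val <- as.integer(y_val)
  if (length(unique(y_train)) < config$n_classes) {
    stop("training set lacks at least one class", call. = FALSE)
  }
  if (is.null(class_weights)) {
    counts <- tabulate(y_train, nbins = config$n_classes)
    class_weights <- compute_class_weights(counts)
  }
  config$seed <- as.integer(seed)
  model <- build_model(config)
  velocity <- zero_like(model_params(model))
  n <- nrow(x_train)
  best <- list(ba = -Inf, params = model_params(model), epoch = 0L)
  history <- vector("list", opt$max_epochs)
  with_seed(child_seed(seed, 13L), {
    for (epoch in seq_len(opt$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = opt$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + opt$batch_size - 1, n)]
        xb <- x_train[rows, , drop = FALSE]
        yb <- y_train[rows]
        fwd <- net_forward(model, xb, dropout = config$dropout)
        epoch_loss <- epoch_loss +
          weighted_cross_entropy(fwd$logits, yb, class_weights) *
          length(rows)
        dlog <- wce_gradient(fwd$logits, yb, class_weights)
        grads <- net_backward(model, fwd, dlog)
        st <- apply_update(model, grads, velocity, opt)
        model <- st$model
        velocity <- st$velocity
      }
      val_logits <- net_forward(model, x_val)$logits
      val_pred <- max.col(val_logits, ties.method = "first")
      cm <- confusion_matrix(DIAGNOSES[y_val], DIAGNOSES[val_pred])
      val_ba <- safe_overall_ba(cm)
      history[[epoch]] <- c(epoch = epoch, train_loss = epoch_loss / n,
                            val_ba = val_ba)
      if (val_ba > best$ba + 1e-12) {
        best <- list(ba = val_ba, params = model_params(model),
                     epoch = epoch)
      }
      if (epoch - best$epoch >= opt$patience) break
    }
  })
  history <- tibble::as_tibble(do.call(rbind, history[!vapply(history,
                                                              is.null,
                                                              logical(1))]))
  list(model = set_model_params(model, best$params),
       history = history, best_epoch = best$epoch,
       best_val_ba = best$ba)
}
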