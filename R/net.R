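#' Configuration of the two-level parallel feature-embedding network
#'
#' The classifier embeds each morphometric feature type through its own
#' first-level multi-layer-perceptron arm — thickness (360 inputs) and
#' volume (360 cortical + 15 subcortical = 375 inputs) — concatenates the
#' arm embeddings into a fused latent vector, and passes it through a
#' second-level fusion stack ending in three class logits
#' (bvFTD/nfvPPA/svPPA). All hidden layers use ReLU with inverted dropout
#' during training.
#'
#' Arms are named by feature block: `"thickness"`, `"volume"`, or `"all"`
#' (the naive single-stack concatenation baseline). Defaults: thickness arm
#' 360-128-32, volume arm 375-128-32, fusion 64-32-3.
#'
#' @param arms Named list of hidden-layer width vectors, one per arm.
#' @param fusion Hidden widths of the second-level stack (the final
#'   3-logit layer is appended automatically).
#' @param n_classes Number of output classes.
#' @param dropout Dropout probability in \[0, 1) after each hidden layer.
#' @param seed Integer seed for deterministic He initialization.
#' @return A `parallel_net_config`.
#' @export
parallel_net_config <- function(arms = list(thickness = c(128, 32),
                                            volume = c(128, 32)),
                                fusion = 32,
                                n_classes = 3,
                                dropout = 0.2,
                                seed = 1L) {
  valid_arms <- c("thickness", "volume", "all")
  if (is.null(names(arms)) || !all(names(arms) %in% valid_arms)) {
    stop("arm names must be among: ", paste(valid_arms, collapse = ", "),
         call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  if (any(unlist(arms) < 1) || any(fusion < 1)) {
    stop("layer widths must be >= 1", call. = FALSE)
  }
  structure(list(arms = arms, fusion = fusion,
                 n_classes = as.integer(n_classes),
                 dropout = dropout, seed = as.integer(seed)),
            class = "parallel_net_config")
}

#' Baseline architecture configurations for the ablation study
#'
#' `naive_concat_config()` is the "naive concatenation" baseline: the 735
#' features enter a single conventional MLP stack (735-256-64-32-3) with a
#' comparable number of nodes per level instead of the two parallel arms.
#' `thickness_only_config()` / `volume_only_config()` consume a single
#' feature block.
#'
#' @inheritParams parallel_net_config
#' @return A `parallel_net_config`.
#' @export
naive_concat_config <- function(dropout = 0.2, seed = 1L) {
  parallel_net_config(arms = list(all = c(256, 64)), fusion = 32,
                      dropout = dropout, seed = seed)
}

#' @rdname naive_concat_config
#' @export
thickness_only_config <- function(dropout = 0.2, seed = 1L) {
  parallel_net_config(arms = list(thickness = c(128, 32)), fusion = 32,
                      dropout = dropout, seed = seed)
}

#' @rdname naive_concat_config
#' @export
volume_only_config <- function(dropout = 0.2, seed = 1L) {
  parallel_net_config(arms = list(volume = c(128, 32)), fusion = 32,
                      dropout = dropout, seed = seed)
}

arm_input_indices <- function(schema) {
  blocks <- feature_blocks(schema)
  list(thickness = blocks$thickness, volume = blocks$volume, all = 1:735)
}

he_layer <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)),
                  n_in, n_out),
       b = rep(0, n_out))
}

make_stack <- function(n_in, widths) {
  layers <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    layers[[i]] <- he_layer(n_in, widths[i])
    n_in <- widths[i]
  }
  layers
}

#' Build a parallel embedding network
#'
#' Parameters are He-initialized deterministically from `config$seed`.
#'
#' @param config A [parallel_net_config()].
#' @param schema An [atlas_schema()] fixing the input feature order.
#' @return An `ftdnet_model`: arm stacks, fusion stack (with the final
#'   linear class layer), and the input index map.
#' @export
build_model <- function(config, schema = default_atlas_schema()) {
  stopifnot(inherits(config, "parallel_net_config"))
  idx <- arm_input_indices(schema)
  with_seed(config$seed, {
    arms <- purrr::imap(config$arms, function(widths, name) {
      make_stack(length(idx[[name]]), widths)
    })
    concat_width <- sum(vapply(config$arms, function(w) w[length(w)],
                               numeric(1)))
    fusion <- make_stack(concat_width, c(config$fusion, config$n_classes))
    structure(list(config = config, arms = arms, fusion = fusion,
                   arm_indices = idx[names(config$arms)]),
              class = "ftdnet_model")
  })
}

#' @export
print.ftdnet_model <- function(x, ...) {
  arms <- vapply(names(x$arms), function(nm) {
    widths <- vapply(x$arms[[nm]], function(l) ncol(l$W), numeric(1))
    paste0(nm, ": ", nrow(x$arms[[nm]][[1]]$W), "-",
           paste(widths, collapse = "-"))
  }, character(1))
  fus <- vapply(x$fusion, function(l) ncol(l$W), numeric(1))
  cat("<ftdnet_model> arms [", paste(arms, collapse = "; "),
      "] fusion -", paste(fus, collapse = "-"), "\n")
  invisible(x)
}

relu <- function(z) z * (z > 0)

# forward pass through one stack; relu on all but (optionally) the last
# layer; inverted dropout applied after relu when dropout > 0
stack_forward <- function(layers, X, relu_last, dropout) {
  n_l <- length(layers)
  cache <- vector("list", n_l)
  h <- X
  for (i in seq_len(n_l)) {
    z <- sweep(h %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    act <- if (i < n_l || relu_last) relu(z) else z
    mask <- NULL
    if (dropout > 0 && (i < n_l || relu_last)) {
      mask <- matrix(stats::runif(length(act)) >= dropout,
                     nrow(act), ncol(act)) / (1 - dropout)
      act <- act * mask
    }
    cache[[i]] <- list(input = h, z = z, mask = mask)
    h <- act
  }
  list(out = h, cache = cache)
}

stack_backward <- function(layers, cache, d_out, relu_last) {
  n_l <- length(layers)
  grads <- vector("list", n_l)
  dh <- d_out
  for (i in rev(seq_len(n_l))) {
    cc <- cache[[i]]
    if (!is.null(cc$mask)) dh <- dh * cc$mask
    dz <- if (i < n_l || relu_last) dh * (cc$z > 0) else dh
    grads[[i]] <- list(W = crossprod(cc$input, dz), b = colSums(dz))
    dh <- tcrossprod(dz, layers[[i]]$W)
  }
  list(d_input = dh, grads = grads)
}

net_forward <- function(model, X, dropout = 0) {
  arm_res <- purrr::imap(model$arms, function(layers, name) {
    stack_forward(layers, X[, model$arm_indices[[name]], drop = FALSE],
                  relu_last = TRUE, dropout = dropout)
  })
  concat <- do.call(cbind, purrr::map(arm_res, "out"))
  fus <- stack_forward(model$fusion, concat, relu_last = FALSE,
                       dropout = dropout)
  list(logits = fus$out, arm_res = arm_res, fus = fus)
}

# backward from d_logits to parameter grads and input gradient
net_backward <- function(model, fwd, d_logits) {
  fb <- stack_backward(model$fusion, fwd$fus$cache, d_logits,
                       relu_last = FALSE)
  widths <- vapply(fwd$arm_res, function(a) ncol(a$out), numeric(1))
  offsets <- cumsum(c(0, widths))
  d_input <- NULL
  arm_grads <- vector("list", length(model$arms))
  names(arm_grads) <- names(model$arms)
  n <- nrow(d_logits)
  p <- max(unlist(model$arm_indices))
  dX <- matrix(0, n, p)
  for (i in seq_along(model$arms)) {
    nm <- names(model$arms)[i]
    d_arm_out <- fb$d_input[, (offsets[i] + 1):offsets[i + 1], drop = FALSE]
    ab <- stack_backward(model$arms[[nm]], fwd$arm_res[[nm]]$cache,
                         d_arm_out, relu_last = TRUE)
    arm_grads[[nm]] <- ab$grads
    dX[, model$arm_indices[[nm]]] <- dX[, model$arm_indices[[nm]]] +
      ab$d_input
  }
  list(arm_grads = arm_grads, fusion_grads = fb$grads, d_input = dX)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Predict class probabilities or labels from a trained network
#'
#' @param object An `ftdnet_model`.
#' @param newdata Numeric matrix (subjects x 735 features, schema order) or
#'   a harmonized feature table.
#' @param type `"prob"` for softmax probabilities, `"class"` for labels
#'   (argmax, ties broken toward the lower class index).
#' @param schema Schema used to extract columns when `newdata` is a tibble.
#' @param ... Unused.
#' @return A numeric matrix of probabilities or a factor of labels.
#' @export
predict.ftdnet_model <- function(object, newdata, type = c("prob", "class"),
                                 schema = default_atlas_schema(), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata, schema)
  probs <- softmax_rows(net_forward(object, X)$logits)
  colnames(probs) <- DIAGNOSES[seq_len(ncol(probs))]
  if (type == "prob") return(probs)
  factor(DIAGNOSES[apply(probs, 1, which.max)], levels = DIAGNOSES)
}

#' Inverse-proportion class weights
#'
#' Weights counteracting class imbalance in the cross-entropy loss:
#' \eqn{w_c \propto N / (K n_c)}, rescaled so the mean of the K weights
#' is 1. Doubling all counts leaves the weights unchanged.
#'
#' @param class_counts Named integer vector of per-class sample counts.
#' @return Named numeric weights with mean 1.
#' @examples
#' compute_class_weights(c(bvFTD = 173, nfvPPA = 63, svPPA = 41))
#' @export
compute_class_weights <- function(class_counts) {
  if (any(class_counts < 1)) stop("all class counts must be >= 1",
                                  call. = FALSE)
  w <- sum(class_counts) / (length(class_counts) * class_counts)
  w / mean(w)
}

#' Class-weighted cross-entropy loss
#'
#' Weighted-mean reduction: \eqn{\sum_i w_{y_i} \,\mathrm{nll}_i / \sum_i
#' w_{y_i}}, so a batch of one sample yields the same loss whatever its
#' class weight.
#'
#' @param logits Numeric matrix, batch x classes.
#' @param labels Integer class indices in 1..K (or a factor over the
#'   diagnosis levels).
#' @param weights Per-class weights, e.g. [compute_class_weights()];
#'   uniform by default.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(logits, labels,
                                   weights = rep(1, ncol(logits))) {
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  stopifnot(all(y >= 1), all(y <= ncol(logits)))
  z <- logits - apply(logits, 1, max)
  log_p <- z - log(rowSums(exp(z)))
  nll <- -log_p[cbind(seq_along(y), y)]
  w <- weights[y]
  sum(w * nll) / sum(w)
}

# gradient of weighted_cross_entropy wrt logits
wce_gradient <- function(logits, labels, weights = rep(1, ncol(logits))) {
  y <- as.integer(labels)
  P <- softmax_rows(logits)
  Y <- matrix(0, nrow(P), ncol(P))
  Y[cbind(seq_along(y), y)] <- 1
  w <- weights[y]
  (P - Y) * (w / sum(w))
}
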