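#' Training configuration
#'
#' Defaults follow the reference protocol for the DEAP-style experiments:
#' batch size 240, learning rate 0.001, AdamW (decoupled weight decay at
#' the optimiser's conventional default 0.01), cross-entropy loss, fixed
#' epoch count with no schedule or early stopping, five folds.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate AdamW learning rate.
#' @param epochs Number of passes over the training data (100 for DEAP,
#'   50 for DREAMER in the reference protocol).
#' @param folds Number of cross-validation folds.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed Seed for shuffling and fold assignment.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 240, learning_rate = 1e-3, epochs = 100,
                         folds = 5, weight_decay = 0.01, seed = 1) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1, folds >= 2)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 folds = as.integer(folds), weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0

# one AdamW step over the whole (nested) parameter tree
adamw_update <- function(p, g, m, v, t, lr, wd,
                         b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adamw_update(p[[i]], g[[i]], m[[i]], v[[i]], t, lr, wd, b1, b2, eps)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  if (!identical(dim(g), dim(p))) dim(g) <- dim(p)  # compiled path may hand
                                                    # back 1 x k row vectors
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
  list(p = p, m = m, v = v)
}

as_tensor_list <- function(x) {
  if (is.data.frame(x)) {
    if (!"tensor" %in% names(x)) abort("feature table has no 'tensor' column")
    return(x$tensor)
  }
  if (is.array(x) && length(dim(x)) == 4) {
    return(lapply(seq_len(dim(x)[4]), function(i) x[, , , i, drop = TRUE]))
  }
  if (is.list(x)) return(x)
  abort("x must be a feature table, a list of tensors, or a (C,H,W,N) array")
}

#' Train the classifier
#'
#' Mini-batch AdamW training with cross-entropy loss, deterministic given
#' the config and training seeds. The final-epoch parameters are returned
#' (no model selection).
#'
#' @param x Feature table from [build_feature_tensors()], a list of
#'   (C, H, W) tensors, or a (C, H, W, N) array.
#' @param y Class labels (factor, or vector coerced to factor).
#' @param config A [model_config()]; by default one is built from the data
#'   (C from the tensors, classes from `y`).
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `eeg_model` with elements `params`,
#'   `config`, `train_cfg`, `classes`, `loss_history`.
#' @export
train_model <- function(x, y, config = NULL, train_cfg = train_config(),
                        verbose = FALSE) {
  tensors <- as_tensor_list(x)
  # factors keep their full level set so a scheme-fixed head size survives
  # folds where a rare class happens to be absent from the training split
  y <- if (is.factor(y)) y else factor(y)
  if (length(tensors) != length(y)) abort("x and y lengths differ")
  classes <- levels(y)
  dims <- dim(tensors[[1]])
  if (is.null(config)) {
    config <- model_config(C = dims[1], H = dims[2], W = dims[3],
                           n_classes = length(classes))
  }
  if (config$n_classes != length(classes)) {
    abort(sprintf("config has %d classes but labels have %d",
                  config$n_classes, length(classes)))
  }
  if (!all(dims == c(config$C, config$H, config$W))) {
    abort("tensor shape does not match the model config")
  }

  X4 <- stack_tensors(tensors)
  y_idx <- as.integer(y)
  N <- length(y_idx)
  params <- init_params(config)
  m <- zero_like(params)
  v <- zero_like(params)
  step <- 0L
  losses <- numeric(train_cfg$epochs)
  use_cpp <- config$variant == "isa"   # compiled fast path; R path is the
                                       # reference and serves "original"

  withr::with_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(N)
      starts <- seq(1L, N, by = train_cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + train_cfg$batch_size - 1L, N)]
        if (use_cpp) {
          res <- .cpp_net_grad(X4[, , , idx, drop = FALSE], params, config,
                               y_idx[idx])
          loss <- res$loss
          gr <- res$grads
        } else {
          fw <- net_fwd(X4[, , , idx, drop = FALSE], params, config)
          ce <- cross_entropy(fw$logits, y_idx[idx])
          loss <- ce$loss
          gr <- net_bwd(ce$dlogits, fw, params, config)
        }
        step <- step + 1L
        upd <- adamw_update(params, gr, m, v, step,
                            train_cfg$learning_rate, train_cfg$weight_decay)
        params <- upd$p; m <- upd$m; v <- upd$v
        ep_loss <- ep_loss + loss * length(idx)
      }
      losses[ep] <- ep_loss / N
      if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, losses[ep]))
    }
  })

  structure(list(params = params, config = config, train_cfg = train_cfg,
                 classes = classes, loss_history = losses),
            class = "eeg_model")
}

#' @export
print.eeg_model <- function(x, ...) {
  cat(sprintf("<eeg_model> %s encoder, L=%d, %d classes, %d parameters\n",
              x$config$variant, x$config$L, x$config$n_classes,
              sum(rapply(x$params, length, how = "unlist"))))
  cat(sprintf("  final training loss %.4f after %d epochs\n",
              utils::tail(x$loss_history, 1), length(x$loss_history)))
  invisible(x)
}

#' Predict classes or probabilities
#'
#' @param object An `eeg_model`.
#' @param newdata Feature table, list of tensors, or (C, H, W, N) array.
#' @param type `"class"` (factor) or `"prob"` (matrix of class
#'   probabilities).
#' @param batch_size Forward-pass chunk size.
#' @param ... Unused.
#' @export
predict.eeg_model <- function(object, newdata, type = c("class", "prob"),
                              batch_size = 512, ...) {
  type <- match.arg(type)
  tensors <- as_tensor_list(newdata)
  X4 <- stack_tensors(tensors)
  N <- dim(X4)[4]
  P <- matrix(NA_real_, N, object$config$n_classes,
              dimnames = list(NULL, object$classes))
  for (s in seq(1L, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, N)
    logits <- if (object$config$variant == "isa") {
      .cpp_net_logits(X4[, , , idx, drop = FALSE], object$params, object$config)
    } else {
      net_fwd(X4[, , , idx, drop = FALSE], object$params, object$config,
              keep_cache = FALSE)$logits
    }
    P[idx, ] <- softmax_rows(logits)
  }
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Save / load a trained model
#'
#' The checkpoint is a single RDS file with the parameters and both
#' configurations embedded.
#'
#' @param model An `eeg_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "eeg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "eeg_model")) abort("file does not contain an eeg_model")
  m
}
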