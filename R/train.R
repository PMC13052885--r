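#' Training configuration
#'
#' Adam with an initial learning rate of 0.001 and a step schedule that
#' multiplies the rate by `decay_factor` every `decay_every` epochs
#' (`lr(e) = learning_rate * decay_factor^floor(e / decay_every)`).
#' Augmentation follows [augment_config()]. The full-scale schedule is 200
#' epochs; desk-scale runs use fewer.
#'
#' @param learning_rate initial Adam learning rate.
#' @param epochs number of epochs.
#' @param decay_factor multiplicative decay per step.
#' @param decay_every epochs between decay steps.
#' @param batch_size minibatch size.
#' @param seed RNG seed for shuffling, augmentation and initialisation.
#' @param augment an [augment_config()].
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 200,
                         decay_factor = 0.3, decay_every = 50,
                         batch_size = 8, seed = 1L,
                         augment = augment_config()) {
  stopifnot(learning_rate > 0, decay_factor > 0, decay_factor < 1,
            decay_every >= 1, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = augment), class = "train_config")
}

#' Learning rate at a given (0-based) epoch under the step schedule
#' @param config a `train_config`.
#' @param epoch 0-based epoch index.
#' @return numeric learning rate.
#' @export
learning_rate_at <- function(config, epoch) {
  config$learning_rate *
    config$decay_factor^floor(epoch / config$decay_every)
}

# --- Adam ------------------------------------------------------------------
.adam_init <- function(P) {
  list(m = lapply(P, function(p) p * 0), v = lapply(P, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(P, gacc, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(P)) {
    g <- gacc[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(P = P, opt = opt)
}

#' Train a point-cloud classifier
#'
#' Builds the model from `spec` and trains it on the train split of
#' `dataset` with cross-entropy loss, Adam, the step learning-rate schedule
#' and per-sample augmentation (dropout-to-first-point, random scale,
#' random shift) redrawn every epoch. Deterministic given `config$seed`.
#'
#' @param spec a `model_spec`; every training category must appear in
#'   `spec$classes`.
#' @param dataset a `shape_dataset` with a non-empty train split.
#' @param config a `train_config`.
#' @param verbose print per-epoch progress.
#' @return A trained `point_classifier` with a `log` data.frame (epoch,
#'   learning rate, mean loss, training accuracy).
#' @export
train <- function(spec, dataset, config = train_config(), verbose = FALSE) {
  validate_spec(spec)
  clouds <- dataset_split(dataset, "train")
  if (!length(clouds)) stop("empty train split", call. = FALSE)
  cats <- vapply(clouds, function(pc) pc$category, character(1))
  targets <- match(cats, spec$classes)
  if (anyNA(targets)) {
    stop("training categories not in spec classes: ",
         paste(unique(cats[is.na(targets)]), collapse = ", "), call. = FALSE)
  }
  model <- build_model(spec, seed = derive_seed(config$seed, 97))
  opt <- .adam_init(model$params)
  n <- length(clouds)
  log_rows <- vector("list", config$epochs)
  with_seed(derive_seed(config$seed, 131), {
    for (e in seq_len(config$epochs) - 1L) {
      lr <- learning_rate_at(config, e)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
      for (bt in batches) {
        gacc <- new.env(parent = emptyenv())
        aug <- lapply(clouds[bt], function(pc)
          augment_train(pc, config$augment,
                        seed = floor(stats::runif(1) * 2^30)))
        coords <- lapply(aug, function(pc) pc$coords)
        if (spec$family == "dgcnn") {
          bb <- .dgcnn_backbone_fwd(model, coords, training = TRUE)
          hd <- .dgcnn_head_fwd(model, bb$pooled, training = TRUE)
          ce <- softmax_xent(hd$logits, targets[bt])
          dPool <- .dgcnn_head_bwd(hd$cache, ce$dlogits, model$params, gacc)
          .dgcnn_backbone_bwd(bb$cache, dPool, model$params, gacc)
        } else {
          fwd <- .pt_fwd(model, coords, training = TRUE)
          ce <- softmax_xent(fwd$logits, targets[bt])
          .pt_bwd(fwd$cache, ce$dlogits, model$params, gacc)
        }
        upd <- .adam_step(model$params, gacc, opt, lr)
        model$params <- upd$P
        opt <- upd$opt
        pred <- max.col(ce$probs, ties.method = "first")
        ep_correct <- ep_correct + sum(pred == targets[bt])
        ep_loss <- ep_loss + ce$loss * length(bt)
        ep_n <- ep_n + length(bt)
      }
      log_rows[[e + 1L]] <- data.frame(
        epoch = e, lr = lr, loss = ep_loss / max(ep_n, 1L),
        train_acc = ep_correct / max(ep_n, 1L))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f", e, lr,
                        ep_loss / max(ep_n, 1L), ep_correct / max(ep_n, 1L)))
      }
    }
  })
  model$log <- do.call(rbind, log_rows)
  model
}

#' Predict within a restricted category subset
#'
#' Takes the argmax over only the logits of `category_subset` (the
#' experiment's response alternatives), ignoring all other classes. Ties
#' resolve to the category with the lowest model class index.
#'
#' @param model a `point_classifier`.
#' @param pc a `point_cloud`.
#' @param category_subset character vector of class names.
#' @return the predicted category name (length-1 character).
#' @export
restrict_predict <- function(model, pc, category_subset) {
  logits <- predict_logits(model, pc)
  argmax_subset(logits, model$spec$classes, category_subset)
}

#' Argmax of logits restricted to a category subset
#'
#' @param logits numeric vector, one entry per class.
#' @param classes class names aligned with `logits`.
#' @param category_subset subset of `classes`; ties resolve to the lowest
#'   class index.
#' @return predicted category name.
#' @export
argmax_subset <- function(logits, classes, category_subset) {
  if (!length(category_subset)) {
    stop("category_subset must be non-empty", call. = FALSE)
  }
  idx <- match(category_subset, classes)
  if (anyNA(idx)) {
    stop("unknown categories in subset: ",
         paste(category_subset[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx <- sort(idx)
  classes[idx][which.max(logits[idx])]
}
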