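#' Training configuration
#'
#' Defaults reproduce the reference schedule: Adam, batch size 512, 50
#' epochs, initial learning rate 0.001 multiplied by 0.1 every 10 epochs,
#' and an l2 penalty of 1e-3 on convolution and dense weight kernels (not
#' biases, not batch-norm parameters).
#'
#' @param batch_size Mini-batch size.
#' @param max_epochs Number of epochs.
#' @param base_lr Initial learning rate.
#' @param lr_decay_factor Multiplicative decay.
#' @param lr_decay_every_epochs Epochs between decays (0-based epoch
#'   indexing: decays take effect at epochs 10, 20, 30, 40).
#' @param l2_penalty Coefficient of the squared-weight penalty.
#' @param seed Integer seed for initialization and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 512L, max_epochs = 50L, base_lr = 1e-3,
                         lr_decay_factor = 0.1, lr_decay_every_epochs = 10L,
                         l2_penalty = 1e-3, seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, base_lr > 0,
            lr_decay_factor > 0, lr_decay_every_epochs >= 1, l2_penalty >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), base_lr = base_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every_epochs = as.integer(lr_decay_every_epochs),
                 l2_penalty = l2_penalty, optimizer = "adam",
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given (0-based) epoch
#'
#' `base_lr * lr_decay_factor ^ floor(epoch / lr_decay_every_epochs)`.
#'
#' @param epoch 0-based epoch index.
#' @param cfg A [train_config()].
#' @return Positive learning rate.
#' @export
#' @examples
#' lr_at_epoch(0, train_config())   # 0.001
#' lr_at_epoch(10, train_config())  # 0.0001
lr_at_epoch <- function(epoch, cfg = train_config()) {
  stopifnot(epoch >= 0)
  cfg$base_lr * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every_epochs)
}

beats_to_matrices <- function(beats) {
  rr_cols <- c("prev_rr_s", "post_rr_s", "ratio_rr", "local_rr_s")
  if (!all(c(rr_cols, "segment", "label") %in% names(beats))) {
    abort("beat table needs segment, label and the four RR feature columns.")
  }
  list(X = do.call(rbind, beats$segment),
       R = as.matrix(beats[, rr_cols]),
       y = as.integer(factor(beats$label, levels = aami_classes)))
}

# weights subject to the l2 penalty: conv/dense kernels only
l2_param_names <- function(model) {
  nm <- names(model$params)
  nm[grepl("_W$", nm)]
}

# Replace the exponentially averaged batch-norm running statistics with
# statistics estimated over the whole training set after the final weight
# update. The momentum average trails the weights badly in short runs; a
# single full-data training-mode pass (chunked only to bound memory, with
# chunk statistics averaged) makes inference-mode normalization match the
# trained weights.
recalibrate_bn <- function(model, X, R, chunk = 16384L) {
  n <- nrow(X)
  starts <- seq(1L, n, by = chunk)
  acc <- NULL
  m0 <- model
  m0$bn_momentum <- 0  # one pass: running stats := chunk statistics
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    fw <- nn_forward(m0, X[idx, , drop = FALSE], R[idx, , drop = FALSE],
                     training = TRUE)
    w <- length(idx) / n
    if (is.null(acc)) {
      acc <- purrr::map(fw$bn, ~ list(mean = .x$mean * w, var = .x$var * w))
    } else {
      for (k in names(acc)) {
        acc[[k]]$mean <- acc[[k]]$mean + fw$bn[[k]]$mean * w
        acc[[k]]$var <- acc[[k]]$var + fw$bn[[k]]$var * w
      }
    }
  }
  acc
}

#' Train the classifier
#'
#' Joint one-step training of the convolutional branch and the MLP head by
#' mini-batch Adam under the configured loss. Each epoch reshuffles the
#' training beats (partial final batches are kept); the learning rate
#' follows [lr_at_epoch()]; the l2 penalty `lambda * sum(W^2)` applies to
#' convolution and dense kernels. Fully reproducible given
#' `config$seed`.
#'
#' @param beats Beat tibble from [prepare_beats()]/[prepare_cohort()]
#'   (training split only).
#' @param loss A [loss_config()] (default: focal, gamma 2).
#' @param config A [train_config()].
#' @param arch An [hb_architecture()].
#' @param verbose Print per-epoch loss.
#' @return A trained `hb_model` carrying `$history` (tibble of `epoch`,
#'   `loss`, `lr`), the training record ids, and the configurations used.
#' @export
hb_train <- function(beats, loss = loss_config("focal", gamma = 2),
                     config = train_config(), arch = hb_architecture(),
                     verbose = FALSE) {
  if (nrow(beats) == 0L) abort("training set is empty.")
  dat <- beats_to_matrices(beats)
  present <- sort(unique(dat$y))
  if (length(present) < 4L) {
    warn(paste0("training set lacks class(es): ",
                paste(aami_classes[setdiff(1:4, present)], collapse = ", ")))
  }
  model <- NULL
  with_seed(config$seed, {
    plan <- plan_layers(arch)
    ini <- init_params(plan)
    model <- structure(
      list(arch = arch, plan = plan, params = ini$params, bn = ini$bn,
           bn_eps = 1e-3, bn_momentum = 0.99, seed = config$seed,
           train_records = sort(unique(as.character(beats$record_id))),
           history = NULL),
      class = "hb_model")

    n <- nrow(dat$X)
    adam_m <- purrr::map(model$params, ~ .x * 0)
    adam_v <- purrr::map(model$params, ~ .x * 0)
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-7; t_step <- 0L
    wl2 <- l2_param_names(model)
    hist <- vector("list", config$max_epochs)

    for (epoch in seq_len(config$max_epochs) - 1L) {
      lr <- lr_at_epoch(epoch, config)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        fw <- nn_forward(model, dat$X[idx, , drop = FALSE],
                         dat$R[idx, , drop = FALSE], training = TRUE)
        model$bn <- fw$bn
        lg <- loss_grad_logits(loss, fw$probs, dat$y[idx])
        bk <- nn_backward(model, fw$cache, lg$dlogits)
        g <- bk$grads
        pen <- 0
        if (config$l2_penalty > 0) {
          for (w in wl2) {
            g[[w]] <- g[[w]] + 2 * config$l2_penalty * model$params[[w]]
            pen <- pen + config$l2_penalty * sum(model$params[[w]]^2)
          }
        }
        t_step <- t_step + 1L
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        for (p in names(g)) {
          adam_m[[p]] <- b1 * adam_m[[p]] + (1 - b1) * g[[p]]
          adam_v[[p]] <- b2 * adam_v[[p]] + (1 - b2) * g[[p]]^2
          model$params[[p]] <- model$params[[p]] -
            lr * (adam_m[[p]] / corr1) / (sqrt(adam_v[[p]] / corr2) + adam_eps)
        }
        ep_loss <- ep_loss + (lg$loss + pen) * length(idx)
        ep_n <- ep_n + length(idx)
      }
      hist[[epoch + 1L]] <- tibble(epoch = epoch, loss = ep_loss / ep_n, lr = lr)
      if (verbose) {
        message(sprintf("epoch %2d  lr %.1e  loss %.5f", epoch, lr,
                        ep_loss / ep_n))
      }
    }
    model$history <- bind_rows(hist)
    model$bn <- recalibrate_bn(model, dat$X, dat$R)
  })
  model$loss_config <- loss
  model$train_config <- config
  model
}

#' Predict class probabilities or labels for beats
#'
#' @param object A trained `hb_model`.
#' @param beats Beat tibble.
#' @param type `"prob"` for per-class probabilities, `"class"` for the
#'   argmax label (ties resolved to the lowest class index).
#' @param ... Unused.
#' @return A tibble of probabilities (`.pred_N`, ...) or a factor of labels.
#' @export
predict.hb_model <- function(object, beats, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  dat <- beats_to_matrices(beats)
  probs <- forward(object, dat$X, dat$R, training = FALSE)
  if (type == "class") {
    return(factor(aami_classes[max.col(probs, ties.method = "first")],
                  levels = aami_classes))
  }
  out <- as_tibble(as.data.frame(probs))
  names(out) <- paste0(".pred_", aami_classes)
  out
}
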