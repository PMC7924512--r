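#' Output length of a valid (un-padded) convolution or pooling
#'
#' `floor((in_len - kernel) / stride) + 1`; all convolution and pooling in
#' the architecture is un-padded, so this fully determines the shape trace.
#'
#' @param in_len Input length (must be at least `kernel`).
#' @param kernel Kernel size.
#' @param stride Stride.
#' @return Output length (positive integer).
#' @export
#' @examples
#' conv_output_length(200, 11, 3)  # 64
conv_output_length <- function(in_len, kernel, stride) {
  stopifnot(kernel >= 1, stride >= 1)
  if (in_len < kernel) {
    abort(sprintf("input length %d is shorter than the kernel (%d).",
                  in_len, kernel))
  }
  (in_len - kernel) %/% stride + 1L
}

#' The layer-by-layer classifier architecture
#'
#' The morphological branch takes a 200-sample, single-channel heartbeat
#' segment through three convolution blocks (convolution, batch
#' normalization, ReLU) each followed by max-pooling, then flattens to a
#' 320-dimensional feature vector. The four RR features are concatenated
#' (324) and a 64-unit hidden dense layer (ReLU) feeds the 4-class softmax
#' output. Kernel sizes shrink with depth (11, 5, 3) while filter counts
#' grow (16, 32, 64).
#'
#' @param input_len Segment length (default 200).
#' @param rr_dim Number of RR features (default 4).
#' @param hidden_units Hidden dense width (default 64).
#' @param n_classes Output classes (default 4).
#' @return An `hb_architecture` tibble with one row per layer: `layer`,
#'   `name`, `kernel`, `filters`, `stride`, `units`.
#' @export
hb_architecture <- function(input_len = 200L, rr_dim = 4L,
                            hidden_units = 64L, n_classes = 4L) {
  arch <- tibble(
    layer = 0:17,
    name = c("input1", "conv1d", "batch_norm", "relu", "max_pool",
             "conv1d", "batch_norm", "relu", "max_pool",
             "conv1d", "batch_norm", "relu", "max_pool",
             "flatten", "input2", "concat", "dense", "dense"),
    kernel = c(NA, 11, NA, NA, 3, 5, NA, NA, 3, 3, NA, NA, 3, NA, NA, NA, NA, NA),
    filters = c(NA, 16, NA, NA, NA, 32, NA, NA, NA, 64, NA, NA, NA, NA, NA, NA, NA, NA),
    stride = c(NA, 3, NA, NA, 2, 1, NA, NA, 2, 1, NA, NA, 2, NA, NA, NA, NA, NA),
    units = c(input_len, rep(NA, 12), NA, rr_dim, NA, hidden_units, n_classes)
  )
  structure(arch, class = c("hb_architecture", class(arch)))
}

# Walk the architecture and annotate every layer with its input/output
# shape (length x channels for the convolutional branch, flat widths after
# flatten/concat). Errors name the first shape-inconsistent layer.
plan_layers <- function(arch) {
  len <- NA_integer_; ch <- NA_integer_; flat <- NA_integer_
  plan <- vector("list", nrow(arch))
  for (i in seq_len(nrow(arch))) {
    row <- arch[i, ]
    lay <- list(layer = row$layer, name = row$name, kernel = row$kernel,
                filters = row$filters, stride = row$stride, units = row$units)
    ok <- TRUE
    if (row$name == "input1") {
      len <- as.integer(row$units); ch <- 1L
    } else if (row$name == "conv1d") {
      if (is.na(len) || len < row$kernel) ok <- FALSE
      else {
        lay$in_len <- len; lay$in_ch <- ch
        len <- conv_output_length(len, row$kernel, row$stride)
        ch <- as.integer(row$filters)
      }
    } else if (row$name == "max_pool") {
      if (is.na(len) || len < row$kernel) ok <- FALSE
      else {
        lay$in_len <- len
        len <- conv_output_length(len, row$kernel, row$stride)
      }
    } else if (row$name %in% c("batch_norm", "relu")) {
      if (is.na(len) && is.na(flat)) ok <- FALSE
    } else if (row$name == "flatten") {
      if (is.na(len)) ok <- FALSE else { flat <- len * ch }
    } else if (row$name == "input2") {
      lay$rr_dim <- as.integer(row$units)
    } else if (row$name == "concat") {
      rr_dim <- arch$units[arch$name == "input2"][1]
      if (is.na(flat) || is.na(rr_dim)) ok <- FALSE else flat <- flat + as.integer(rr_dim)
    } else if (row$name == "dense") {
      if (is.na(flat)) ok <- FALSE
      else { lay$in_dim <- flat; flat <- as.integer(row$units) }
    }
    if (!ok) {
      abort(sprintf("architecture is shape-inconsistent at layer %d (%s).",
                    row$layer, row$name))
    }
    lay$is_output <- i == nrow(arch)  # final dense: softmax, no hidden ReLU
    lay$out_len <- len; lay$out_ch <- ch; lay$out_flat <- flat
    if (row$name %in% c("flatten", "input2", "concat", "dense")) {
      lay$out_len <- NA_integer_; lay$out_ch <- NA_integer_
    }
    if (row$name == "input2") lay$out_flat <- as.integer(row$units)
    plan[[i]] <- lay
  }
  plan
}

#' Per-layer shape trace of the architecture
#'
#' @param arch An [hb_architecture()].
#' @return A tibble with `layer`, `name`, `out_len`, `out_ch`, `out_flat`
#'   and a human-readable `shape` string (e.g. `"64 x 16"` or `"320"`).
#' @export
architecture_shapes <- function(arch = hb_architecture()) {
  plan <- plan_layers(arch)
  purrr::map_dfr(plan, function(l) {
    shape <- if (!is.na(l$out_len)) {
      sprintf("%d x %d", l$out_len, l$out_ch)
    } else sprintf("%d", l$out_flat)
    tibble(layer = l$layer, name = l$name,
           out_len = l$out_len %||% NA_integer_,
           out_ch = l$out_ch %||% NA_integer_,
           out_flat = l$out_flat %||% NA_integer_, shape = shape)
  })
}

#' Per-layer trainable / non-trainable parameter counts
#'
#' Convolutions contribute `kernel * in_channels * filters + filters`
#' trainable weights; batch normalization contributes `2 * channels`
#' trainable (scale, shift) and `2 * channels` non-trainable (running mean,
#' running variance); dense layers `in_dim * units + units`; activation,
#' pooling, flatten and concatenation layers none.
#'
#' @param arch An [hb_architecture()].
#' @return A tibble with `layer`, `name`, `trainable`, `non_trainable`.
#' @export
count_parameters <- function(arch = hb_architecture()) {
  plan <- plan_layers(arch)
  ch_before <- 1L
  out <- purrr::map_dfr(seq_along(plan), function(i) {
    l <- plan[[i]]
    tr <- 0L; ntr <- 0L
    if (l$name == "conv1d") {
      tr <- as.integer(l$kernel * l$in_ch * l$filters + l$filters)
    } else if (l$name == "batch_norm") {
      ch <- plan[[i - 1L]]$out_ch
      tr <- 2L * ch; ntr <- 2L * ch
    } else if (l$name == "dense") {
      tr <- as.integer(l$in_dim * l$units + l$units)
    }
    tibble(layer = l$layer, name = l$name, trainable = tr, non_trainable = ntr)
  })
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# Glorot-uniform draw with convolutional fan counting
glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# Initialize parameters from the current RNG stream. Conv kernels are stored
# as (kernel * in_ch) x filters matrices matching the im2col layout.
init_params <- function(plan) {
  params <- list(); bn <- list()
  for (l in plan) {
    key <- sprintf("L%02d", l$layer)
    if (l$name == "conv1d") {
      params[[paste0(key, "_W")]] <-
        glorot(l$kernel * l$in_ch, l$kernel * l$filters,
               c(l$kernel * l$in_ch, l$filters))
      params[[paste0(key, "_b")]] <- numeric(l$filters)
    } else if (l$name == "batch_norm") {
      ch <- l$out_ch
      params[[paste0(key, "_gamma")]] <- rep(1, ch)
      params[[paste0(key, "_beta")]] <- numeric(ch)
      bn[[key]] <- list(mean = numeric(ch), var = rep(1, ch))
    } else if (l$name == "dense") {
      params[[paste0(key, "_W")]] <- glorot(l$in_dim, l$units,
                                            c(l$in_dim, l$units))
      params[[paste0(key, "_b")]] <- numeric(l$units)
    }
  }
  list(params = params, bn = bn)
}

#' Build the classifier model
#'
#' Instantiates the architecture with Glorot-uniform weights (seeded), unit
#' batch-norm scales and zero shifts/biases. The model is a single jointly
#' trainable object: segments and RR features flow through it in one forward
#' pass and one backward pass.
#'
#' @param arch An [hb_architecture()].
#' @param seed Integer seed controlling initialization.
#' @param bn_eps,bn_momentum Batch-normalization variance floor and running
#'   statistics momentum.
#' @return An `hb_model` object (untrained).
#' @export
build_model <- function(arch = hb_architecture(), seed = 1L,
                        bn_eps = 1e-3, bn_momentum = 0.99) {
  plan <- plan_layers(arch)  # validates shapes
  ini <- with_seed(seed, init_params(plan))
  structure(
    list(arch = arch, plan = plan, params = ini$params, bn = ini$bn,
         bn_eps = bn_eps, bn_momentum = bn_momentum,
         seed = as.integer(seed), train_records = NULL, history = NULL),
    class = "hb_model"
  )
}

#' @export
print.hb_model <- function(x, ...) {
  pc <- count_parameters(x$arch)
  trained <- !is.null(x$history)
  cat(sprintf("<hb_model>  %s trainable parameters (%s non-trainable), %s\n",
              format(sum(pc$trainable), big.mark = ","),
              format(sum(pc$non_trainable), big.mark = ","),
              if (trained) sprintf("trained %d epochs", nrow(x$history))
              else "untrained"))
  invisible(x)
}

# im2col gather: A is [n, len, ch]; returns [n * out_len, kernel * ch] with
# row index (i, o), i fastest, and column index (c - 1) * kernel + j.
im2col <- function(A, kernel, stride, out_len) {
  n <- dim(A)[1]; len <- dim(A)[2]; ch <- dim(A)[3]
  o <- rep(seq_len(out_len), each = 1L)
  # column index into the [n, len*ch] matrix for (j, c, o)
  idx <- outer(
    as.vector(outer(seq_len(kernel), (seq_len(ch) - 1L) * len, `+`)),
    (o - 1L) * stride, `+`
  )  # (kernel*ch) x out_len
  Amat <- A; dim(Amat) <- c(n, len * ch)
  big <- Amat[, as.vector(idx), drop = FALSE]      # n x (kernel*ch*out_len)
  dim(big) <- c(n, kernel * ch, out_len)
  big <- aperm(big, c(1, 3, 2))                    # n x out_len x kernel*ch
  dim(big) <- c(n * out_len, kernel * ch)
  big
}

# scatter-add the im2col gradient back to the input array
col2im <- function(dcol, n, len, ch, kernel, stride, out_len) {
  dim(dcol) <- c(n, out_len, kernel * ch)
  dA <- array(0, dim = c(n, len, ch))
  for (j in seq_len(kernel)) {
    pos <- (seq_len(out_len) - 1L) * stride + j
    sel <- (seq_len(ch) - 1L) * kernel + j
    dA[, pos, ] <- dA[, pos, ] + dcol[, , sel]
  }
  dA
}

# Forward pass. X: [n, input_len]; R: [n, rr_dim]. In training mode batch
# statistics are used for batch norm (and running stats updated); in
# inference mode the stored running statistics are used.
nn_forward <- function(model, X, R, training = FALSE) {
  plan <- model$plan
  n <- nrow(X)
  A <- array(X, dim = c(n, ncol(X), 1L))
  flat <- NULL
  cache <- list()
  bn <- model$bn
  for (i in seq_along(plan)) {
    l <- plan[[i]]
    key <- sprintf("L%02d", l$layer)
    if (l$name == "conv1d") {
      Xc <- im2col(A, l$kernel, l$stride, l$out_len)
      Y <- Xc %*% model$params[[paste0(key, "_W")]]
      Y <- sweep(Y, 2, model$params[[paste0(key, "_b")]], `+`)
      if (training) cache[[key]] <- list(Xc = Xc, in_len = dim(A)[2], in_ch = dim(A)[3])
      dim(Y) <- c(n, l$out_len, l$filters)
      A <- Y
    } else if (l$name == "batch_norm") {
      ch <- dim(A)[3]; m <- n * dim(A)[2]
      M <- A; dim(M) <- c(m, ch)
      if (training) {
        mu <- colMeans(M)
        va <- colMeans(M^2) - mu^2
        mom <- model$bn_momentum
        bn[[key]]$mean <- mom * bn[[key]]$mean + (1 - mom) * mu
        bn[[key]]$var  <- mom * bn[[key]]$var  + (1 - mom) * va * m / max(m - 1, 1)
      } else {
        mu <- bn[[key]]$mean
        va <- bn[[key]]$var
      }
      istd <- 1 / sqrt(va + model$bn_eps)
      xhat <- sweep(sweep(M, 2, mu, `-`), 2, istd, `*`)
      Y <- sweep(sweep(xhat, 2, model$params[[paste0(key, "_gamma")]], `*`),
                 2, model$params[[paste0(key, "_beta")]], `+`)
      if (training) cache[[key]] <- list(xhat = xhat, istd = istd, m = m, ch = ch,
                                         shape = dim(A))
      dim(Y) <- dim(A)
      A <- Y
    } else if (l$name == "relu") {
      if (is.null(flat)) {
        mask <- A > 0
        A <- A * mask
      } else {
        mask <- flat > 0
        flat <- flat * mask
      }
      if (training) cache[[key]] <- list(mask = mask)
    } else if (l$name == "max_pool") {
      len_in <- dim(A)[2]
      V <- vector("list", l$kernel)
      for (j in seq_len(l$kernel)) {
        pos <- (seq_len(l$out_len) - 1L) * l$stride + j
        V[[j]] <- A[, pos, , drop = FALSE]
      }
      M <- V[[1]]; amax <- array(1L, dim = dim(M))
      for (j in 2:l$kernel) {
        upd <- V[[j]] > M
        M[upd] <- V[[j]][upd]
        amax[upd] <- j
      }
      if (training) cache[[key]] <- list(amax = amax, in_len = len_in)
      A <- M
    } else if (l$name == "flatten") {
      if (training) cache[[key]] <- list(shape = dim(A))
      flat <- A; dim(flat) <- c(n, dim(A)[2] * dim(A)[3])
    } else if (l$name == "concat") {
      if (training) cache[[key]] <- list(flat_dim = ncol(flat))
      flat <- cbind(flat, R)
    } else if (l$name == "dense") {
      if (training) cache[[key]] <- list(Z = flat)
      flat <- sweep(flat %*% model$params[[paste0(key, "_W")]], 2,
                    model$params[[paste0(key, "_b")]], `+`)
      if (!isTRUE(l$is_output)) {  # hidden dense uses ReLU
        hmask <- flat > 0
        flat <- flat * hmask
        if (training) cache[[key]]$hmask <- hmask
      }
    }
  }
  # softmax over the final logits
  logits <- flat
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, logits = logits, cache = cache, bn = bn)
}

# Backward pass from d(loss)/d(logits); returns gradients named like params.
nn_backward <- function(model, cache, dlogits) {
  plan <- rev(model$plan)
  grads <- list()
  dflat <- dlogits
  dA <- NULL
  dR <- NULL
  for (l in plan) {
    key <- sprintf("L%02d", l$layer)
    if (l$name == "dense") {
      if (!isTRUE(l$is_output)) dflat <- dflat * cache[[key]]$hmask
      Z <- cache[[key]]$Z
      grads[[paste0(key, "_W")]] <- crossprod(Z, dflat)
      grads[[paste0(key, "_b")]] <- colSums(dflat)
      dflat <- dflat %*% t(model$params[[paste0(key, "_W")]])
    } else if (l$name == "concat") {
      fd <- cache[[key]]$flat_dim
      dR <- dflat[, (fd + 1L):ncol(dflat), drop = FALSE]
      dflat <- dflat[, seq_len(fd), drop = FALSE]
    } else if (l$name == "flatten") {
      sh <- cache[[key]]$shape
      dA <- dflat
      dim(dA) <- sh
      dflat <- NULL
    } else if (l$name == "relu") {
      mask <- cache[[key]]$mask
      if (is.null(dflat)) dA <- dA * mask else dflat <- dflat * mask
    } else if (l$name == "max_pool") {
      am <- cache[[key]]$amax
      n <- dim(dA)[1]; ch <- dim(dA)[3]
      dIn <- array(0, dim = c(n, cache[[key]]$in_len, ch))
      for (j in seq_len(l$kernel)) {
        pos <- (seq_len(l$out_len) - 1L) * l$stride + j
        dIn[, pos, ] <- dIn[, pos, ] + dA * (am == j)
      }
      dA <- dIn
    } else if (l$name == "batch_norm") {
      cc <- cache[[key]]
      dY <- dA; dim(dY) <- c(cc$m, cc$ch)
      gamma <- model$params[[paste0(key, "_gamma")]]
      grads[[paste0(key, "_gamma")]] <- colSums(dY * cc$xhat)
      grads[[paste0(key, "_beta")]] <- colSums(dY)
      # standard batch-norm input gradient with batch statistics
      sdy <- colMeans(dY)
      sdyx <- colMeans(dY * cc$xhat)
      dX <- sweep(sweep(sweep(dY, 2, sdy, `-`) -
                          sweep(cc$xhat, 2, sdyx, `*`),
                        2, gamma, `*`), 2, cc$istd, `*`)
      dim(dX) <- cc$shape
      dA <- dX
    } else if (l$name == "conv1d") {
      cc <- cache[[key]]
      n <- dim(dA)[1]
      dY <- dA; dim(dY) <- c(n * l$out_len, l$filters)
      grads[[paste0(key, "_W")]] <- crossprod(cc$Xc, dY)
      grads[[paste0(key, "_b")]] <- colSums(dY)
      dcol <- dY %*% t(model$params[[paste0(key, "_W")]])
      dA <- col2im(dcol, n, cc$in_len, cc$in_ch, l$kernel, l$stride, l$out_len)
    }
  }
  list(grads = grads, dR = dR)
}

#' Forward pass: class probabilities for a batch of beats
#'
#' @param model An `hb_model`.
#' @param segments Numeric matrix `[batch, 200]` of baseline-corrected
#'   segments.
#' @param rr Numeric matrix `[batch, 4]` of normalized RR features.
#' @param training If `TRUE`, batch statistics are used in batch
#'   normalization (training mode); default is inference with running
#'   statistics, so each row's output is independent of the rest of the
#'   batch.
#' @return A `[batch, 4]` matrix of class probabilities (columns in
#'   [aami_classes] order) whose rows sum to 1.
#' @export
forward <- function(model, segments, rr, training = FALSE) {
  stopifnot(inherits(model, "hb_model"))
  segments <- as.matrix(segments); rr <- as.matrix(rr)
  in_len <- model$arch$units[model$arch$name == "input1"][1]
  rr_dim <- model$arch$units[model$arch$name == "input2"][1]
  if (ncol(segments) != in_len || ncol(rr) != rr_dim ||
      nrow(segments) != nrow(rr)) {
    abort(sprintf(
      "expected segments [n, %d] and rr [n, %d] with matching n; got [%d, %d] and [%d, %d].",
      in_len, rr_dim, nrow(segments), ncol(segments), nrow(rr), ncol(rr)))
  }
  out <- nn_forward(model, segments, rr, training = training)
  colnames(out$probs) <- aami_classes
  out$probs
}
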