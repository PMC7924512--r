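#' Loss configuration
#'
#' The default replicates the training setup of the method: plain
#' (non-alpha-balanced) focal loss with modulating factor `gamma = 2`.
#'
#' @param kind One of `"cross_entropy"`, `"focal"`, `"alpha_focal"`.
#' @param gamma Non-negative modulating exponent (focal variants).
#' @param alpha Four positive per-class weights (`alpha_focal` only).
#' @return A `loss_config` list.
#' @export
loss_config <- function(kind = c("focal", "cross_entropy", "alpha_focal"),
                        gamma = 2, alpha = NULL) {
  kind <- match.arg(kind)
  if (gamma < 0) abort("`gamma` must be non-negative.")
  if (kind == "alpha_focal") {
    if (is.null(alpha) || length(alpha) != 4L || any(alpha <= 0)) {
      abort("`alpha` must be 4 positive class weights for alpha_focal.")
    }
  }
  structure(list(kind = kind, gamma = gamma, alpha = alpha),
            class = "loss_config")
}

.loss_eps <- 1e-7

check_loss_args <- function(targets, probs) {
  targets <- as.matrix(targets); probs <- as.matrix(probs)
  if (!all(dim(targets) == dim(probs))) {
    abort(sprintf("targets are %d x %d but probs are %d x %d.",
                  nrow(targets), ncol(targets), nrow(probs), ncol(probs)))
  }
  list(p_true = pmax(rowSums(targets * probs), .loss_eps),
       class_idx = max.col(targets, ties.method = "first"))
}

#' Cross-entropy loss
#'
#' Mean over the batch of `-log(p)` at the true class, with probabilities
#' clipped to `[1e-7, 1]` before the (natural) log.
#'
#' @param targets One-hot matrix `[batch, 4]`.
#' @param probs Probability matrix `[batch, 4]` (rows sum to 1).
#' @return Non-negative scalar.
#' @export
#' @examples
#' cross_entropy(diag(4), matrix(0.25, 4, 4))  # log(4)
cross_entropy <- function(targets, probs) {
  p <- check_loss_args(targets, probs)$p_true
  mean(-log(p))
}

#' Focal loss
#'
#' Cross-entropy reshaped by the modulating factor `(1 - p)^gamma`, which
#' shrinks the contribution of well-classified examples so gradient mass
#' concentrates on hard (typically minority-class) beats. `gamma = 0`
#' recovers cross-entropy exactly.
#'
#' @inheritParams cross_entropy
#' @param gamma Non-negative modulating exponent (default 2).
#' @return Non-negative scalar (batch mean).
#' @export
focal_loss <- function(targets, probs, gamma = 2) {
  if (gamma < 0) abort("`gamma` must be non-negative.")
  p <- check_loss_args(targets, probs)$p_true
  mean(-(1 - p)^gamma * log(p))
}

#' Alpha-balanced focal loss
#'
#' Focal loss with an additional per-class weight `alpha[i]` multiplying
#' each example's term according to its true class.
#'
#' @inheritParams focal_loss
#' @param alpha Four positive class weights in [aami_classes] order.
#' @return Non-negative scalar (batch mean).
#' @export
alpha_focal_loss <- function(targets, probs, gamma = 2, alpha = rep(1, 4)) {
  if (gamma < 0) abort("`gamma` must be non-negative.")
  if (length(alpha) != 4L) abort("`alpha` must have length 4.")
  ca <- check_loss_args(targets, probs)
  mean(-alpha[ca$class_idx] * (1 - ca$p_true)^gamma * log(ca$p_true))
}

#' Evaluate a configured loss
#'
#' @param config A [loss_config()].
#' @inheritParams cross_entropy
#' @return Non-negative scalar.
#' @export
compute_loss <- function(config, targets, probs) {
  switch(config$kind,
         cross_entropy = cross_entropy(targets, probs),
         focal = focal_loss(targets, probs, config$gamma),
         alpha_focal = alpha_focal_loss(targets, probs, config$gamma,
                                        config$alpha))
}

# Batch-mean loss and its gradient wrt the logits, for softmax outputs.
# y_idx: integer true classes 1..4. Returns list(loss, dlogits).
loss_grad_logits <- function(config, probs, y_idx) {
  n <- nrow(probs)
  eps <- .loss_eps
  pc <- pmax(probs[cbind(seq_len(n), y_idx)], eps)
  gamma <- if (config$kind == "cross_entropy") 0 else config$gamma
  a <- if (config$kind == "alpha_focal") config$alpha[y_idx] else rep(1, n)
  loss <- mean(-a * (1 - pc)^gamma * log(pc))
  # g = dL_i/dp_c (per-example); guard the gamma<1 singularity at p -> 1
  one_m <- 1 - pc
  term1 <- ifelse(one_m <= 0, 0, gamma * one_m^(gamma - 1) * log(pc))
  g <- a * (term1 - one_m^gamma / pc)
  # chain through softmax: dz_j = g * p_c * (delta_cj - p_j)
  gpc <- g * pc
  dlogits <- -probs * gpc
  dlogits[cbind(seq_len(n), y_idx)] <- dlogits[cbind(seq_len(n), y_idx)] + gpc
  list(loss = loss, dlogits = dlogits / n)
}
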