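# Composite training objective: segmentation (BCE + soft Dice), expert load
# balance, and attention-sparsity terms.

#' Loss weights
#'
#' Reference weights: segmentation 1.0, balance `lambda1 = 0.01`, sparsity
#' `lambda2 = 0.001` (an alternative sparsity weight of 0.002 appears in
#' the training-recipe variant and can be selected here).
#'
#' @param lambda_seg segmentation weight.
#' @param lambda1 balance-loss weight.
#' @param lambda2 attention-sparsity weight.
#' @param epsilon soft-Dice smoothing term.
#' @export
loss_weights <- function(lambda_seg = 1.0, lambda1 = 0.01, lambda2 = 0.001,
                         epsilon = 1.0) {
  stopifnot(lambda_seg >= 0, lambda1 >= 0, lambda2 >= 0, epsilon >= 0)
  structure(list(lambda_seg = lambda_seg, lambda1 = lambda1,
                 lambda2 = lambda2, epsilon = epsilon),
            class = "loss_weights")
}

#' Segmentation loss: binary cross-entropy plus soft Dice
#'
#' `BCE(Yhat, Y) + 1 - (2 sum(Yhat * Y) + eps) / (sum(Yhat) + sum(Y) + eps)`
#' with probabilities clamped at `1e-7` inside the cross-entropy.
#'
#' @param y_hat predicted probabilities in `(0, 1)`.
#' @param y ground-truth 0/1 mask of the same shape.
#' @param epsilon Dice smoothing term.
#' @return Scalar loss (>= 0; ~0 only at an exact match, up to clamping).
#' @export
seg_loss <- function(y_hat, y, epsilon = 1.0) {
  if (!all(dim(y_hat) == dim(y) %||% length(y)) &&
      length(y_hat) != length(y))
    stop("prediction and target shapes differ")
  p <- pmin(pmax(y_hat, 1e-7), 1 - 1e-7)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dice <- 1 - (2 * sum(y_hat * y) + epsilon) /
    (sum(y_hat) + sum(y) + epsilon)
  bce + dice
}

#' Attention sparsity regularizer
#'
#' Mean absolute attention weight per layer map, `(1/n) sum_ij |A_ij|`
#' with n the number of query positions, summed over the collected maps.
#' For row-stochastic maps each map contributes exactly 1.
#'
#' @param attention_maps a matrix, an `attention_map`, or a list of either
#'   (one entry per sparse layer).
#' @return Scalar loss.
#' @export
sparsity_loss <- function(attention_maps) {
  flatten <- function(x) {
    if (is.matrix(x)) return(list(x))
    if (inherits(x, "attention_map")) return(x$weights)
    if (is.list(x)) return(do.call(c, lapply(x, flatten)))
    stop("unsupported attention map input")
  }
  maps <- flatten(attention_maps)
  if (length(maps) == 0L) return(0)
  sum(vapply(maps, function(A) sum(abs(A)) / nrow(A), numeric(1)))
}

#' Assemble the total training loss
#'
#' `L_total = lambda_seg * L_seg + lambda1 * L_balance + lambda2 *
#' L_sparsity`, an exact identity over the supplied components. Diversity
#' and routing-entropy terms are carried for logging and only enter the
#' total when given nonzero optional weights.
#'
#' @param l_seg,l_balance,l_sparsity finite loss components.
#' @param weights a [loss_weights()].
#' @param l_diversity,l_entropy optional logged components.
#' @param lambda_diversity,lambda_entropy optional weights for them.
#' @return A `loss_bundle` with every component and `l_total`.
#' @export
total_loss <- function(l_seg, l_balance, l_sparsity,
                       weights = loss_weights(), l_diversity = NULL,
                       l_entropy = NULL, lambda_diversity = 0,
                       lambda_entropy = 0) {
  comps <- c(l_seg = l_seg, l_balance = l_balance, l_sparsity = l_sparsity)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad)) stop("non-finite loss component: ", paste(bad, collapse = ", "))
  total <- weights$lambda_seg * l_seg + weights$lambda1 * l_balance +
    weights$lambda2 * l_sparsity
  if (lambda_diversity != 0 && !is.null(l_diversity))
    total <- total + lambda_diversity * l_diversity
  if (lambda_entropy != 0 && !is.null(l_entropy))
    total <- total + lambda_entropy * l_entropy
  structure(list(l_seg = l_seg, l_balance = l_balance,
                 l_sparsity = l_sparsity, l_diversity = l_diversity,
                 l_entropy = l_entropy, l_total = total, weights = weights),
            class = "loss_bundle")
}
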