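# Gumbel-TopK sparse multi-head self-attention and its dense oracle.
#
# Per query i only a retained key set J_i (|J_i| = k) participates in the
# softmax; in eval mode J_i holds the k largest similarity logits (ties to
# the lowest index), in train mode logits are perturbed with
# temperature-scaled Gumbel noise before selection, which anneals the
# stochastic exploration of retained-key sets.

#' Sparse attention configuration
#'
#' @param n_tokens sequence length n.
#' @param model_dim model dimension d.
#' @param n_heads number of attention heads (must divide `model_dim`).
#' @param rho sparsity ratio in `(0, 1]`; `k = max(1, round(rho * n))`.
#' @param tau Gumbel temperature (> 0 in train mode).
#' @param mode `"eval"` (noiseless top-k) or `"train"` (Gumbel-perturbed).
#' @param seed seed for the train-mode noise draw.
#' @return An `attention_config`.
#' @export
attention_config <- function(n_tokens, model_dim, n_heads = 1L, rho = 0.1,
                             tau = 1.0, mode = c("eval", "train"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(rho > 0, rho <= 1, n_tokens >= 1, model_dim >= 1,
            model_dim %% n_heads == 0)
  if (mode == "train" && tau <= 0) stop("tau must be > 0 in train mode")
  k <- max(1L, as.integer(round(rho * n_tokens)))
  if (k > n_tokens) stop("k exceeds n_tokens")
  structure(list(n_tokens = as.integer(n_tokens),
                 model_dim = as.integer(model_dim),
                 n_heads = as.integer(n_heads), rho = rho, k = k,
                 tau = tau, mode = mode, seed = as.integer(seed)),
            class = "attention_config")
}

#' Dense scaled dot-product attention (oracle)
#'
#' `softmax(Q K^T / sqrt(d)) V` over full support; serves as the reference
#' implementation the sparse layer must match at `k = n`.
#'
#' @param Q,K,V numeric matrices; `Q` is n_q x d, `K` n_k x d, `V` n_k x d_v.
#' @return n_q x d_v output matrix.
#' @export
dense_attention <- function(Q, K, V) {
  d <- ncol(Q)
  if (is.null(d) || d == 0) stop("query dimension d must be positive")
  logits <- Q %*% t(K) / sqrt(d)
  logits <- logits - apply(logits, 1, max)
  w <- exp(logits)
  w <- w / rowSums(w)
  w %*% V
}

#' Top-k key selection with optional Gumbel perturbation
#'
#' Eval mode returns, per query, the indices of the k largest logits (ties
#' broken toward the lowest index). Train mode perturbs the logits with
#' `tau * g_j`, `g_j ~ Gumbel(0, 1)` drawn once per key, before selection;
#' the draw is deterministic under the config seed.
#'
#' @param logits n_q x n_k similarity matrix (finite).
#' @param config an [attention_config()]; `config$k` keys are retained.
#' @return A `sparse_selection`: list(index_sets, perturbed_logits,
#'   gumbel_noise, k, seed). Index sets are in descending-logit order.
#' @export
topk_select <- function(logits, config) {
  stopifnot(all(is.finite(logits)))
  k <- config$k
  if (k > ncol(logits)) stop("k exceeds number of keys")
  noise <- NULL
  pl <- logits
  if (config$mode == "train") {
    noise <- with_seed(config$seed,
                       -log(-log(stats::runif(ncol(logits)))))
    pl <- sweep(logits, 2L, config$tau * noise, "+")
  }
  sets <- lapply(seq_len(nrow(pl)), function(i) topk_idx(pl[i, ], k))
  structure(list(index_sets = sets, perturbed_logits = pl,
                 gumbel_noise = noise, k = k, seed = config$seed),
            class = "sparse_selection")
}

#' Sparse multi-head self-attention over a token matrix
#'
#' Per head: project `X` to queries/keys/values, retain the top-k keys per
#' query (regenerated per head and per call), renormalize the softmax over
#' the retained set, and aggregate values. Head outputs are concatenated.
#'
#' @param X n x d token matrix.
#' @param weights list with one element per head, each holding `W_Q`,
#'   `W_K`, `W_V` (d x d_head); see [attention_weights_init()].
#' @param config an [attention_config()].
#' @return list(output = n x d matrix, map = `attention_map` with per-head
#'   weight matrices (zero outside the retained sets), the observed
#'   sparsity ratio and mean per-query entropy in bits per head).
#' @export
sparse_attention <- function(X, weights, config) {
  n <- nrow(X)
  if (!all(is.finite(X))) stop("non-finite activations entering sparse attention")
  head_out <- vector("list", length(weights))
  head_maps <- vector("list", length(weights))
  for (h in seq_along(weights)) {
    w <- weights[[h]]
    Q <- X %*% w$W_Q; K <- X %*% w$W_K; V <- X %*% w$W_V
    dh <- ncol(Q)
    logits <- Q %*% t(K) / sqrt(dh)
    hcfg <- config
    hcfg$seed <- config$seed + h  # fresh selection per head
    sel <- topk_select(logits, hcfg)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      J <- sel$index_sets[[i]]
      e <- exp(logits[i, J] - max(logits[i, J]))
      A[i, J] <- e / sum(e)
    }
    if (!all(is.finite(A)))
      stop("non-finite attention weights in sparse attention head ", h)
    head_out[[h]] <- A %*% V
    head_maps[[h]] <- A
  }
  obs_sparsity <- mean(vapply(head_maps, function(A) mean(A == 0), numeric(1)))
  ent <- vapply(head_maps, function(A) {
    mean(apply(A, 1, function(p) { p <- p[p > 0]; -sum(p * log2(p)) }))
  }, numeric(1))
  map <- structure(list(weights = head_maps,
                        sparsity_ratio_observed = obs_sparsity,
                        entropy_per_head = ent),
                   class = "attention_map")
  list(output = do.call(cbind, head_out), map = map)
}

#' Initialize per-head projection weights
#'
#' @param model_dim model dimension d.
#' @param n_heads number of heads; `d_head = model_dim / n_heads`.
#' @param seed seed for the Xavier draws.
#' @return List of per-head lists with `W_Q`, `W_K`, `W_V`.
#' @export
attention_weights_init <- function(model_dim, n_heads = 1L, seed = 1L) {
  d_head <- model_dim %/% n_heads
  with_seed(seed, lapply(seq_len(n_heads), function(h)
    list(W_Q = init_xavier(model_dim, d_head),
         W_K = init_xavier(model_dim, d_head),
         W_V = init_xavier(model_dim, d_head))))
}

#' Attention diversity regularizer
#'
#' Negated mean per-query entropy of the retained attention weights, as
#' printed in the source formulation:
#' `-(1/n) sum_i sum_{j in J_i} p_ij log2 p_ij`. Minimizing this value as a
#' loss concentrates attention; set `maximize_diversity = TRUE` to flip the
#' sign so that minimization spreads attention instead.
#'
#' @param map an `attention_map` from [sparse_attention()].
#' @param maximize_diversity flip the sign convention.
#' @return Scalar loss.
#' @export
diversity_loss <- function(map, maximize_diversity = FALSE) {
  v <- mean(vapply(map$weights, function(A) {
    mean(apply(A, 1, function(p) { p <- p[p > 0]; sum(p * log2(p)) }))
  }, numeric(1)))
  # v is already the negated entropy averaged over queries
  if (maximize_diversity) -v else v
}

#' Sparse-attention complexity accounting
#'
#' Dense attention costs `n^2 d` multiply-adds against `n k d` for the
#' sparse variant; the reduction factor is `n / k = 1 / rho`, e.g. 10x for
#' `rho = 0.1`. Per-head score memory shrinks from `n^2` to `n k` entries.
#'
#' @param n tokens, @param d feature dimension, @param k retained keys.
#' @return list(dense_cost, sparse_cost, reduction_factor, dense_entries,
#'   sparse_entries)
#' @export
complexity_report <- function(n, d, k) {
  stopifnot(n >= 1, d >= 1, k >= 1, k <= n)
  list(dense_cost = n^2 * d, sparse_cost = n * k * d,
       reduction_factor = n / k, dense_entries = n^2, sparse_entries = n * k)
}
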