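# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorized implementations.

# elementwise-loop scaled dot-product attention
loop_attention <- function(Q, K, V) {
  n <- nrow(Q); d <- ncol(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) {
      acc <- 0
      for (t in seq_len(d)) acc <- acc + Q[i, t] * K[j, t]
      s[j] <- acc / sqrt(d)
    }
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# dense attention with non-retained logits masked to -Inf
masked_dense_attention <- function(Q, K, V, sets) {
  d <- ncol(Q)
  logits <- Q %*% t(K) / sqrt(d)
  for (i in seq_len(nrow(logits)))
    logits[i, -sets[[i]]] <- -Inf
  w <- exp(logits - apply(logits, 1, max))
  w <- w / rowSums(w)
  w %*% V
}

# 4-connected flood-fill component count
flood_components <- function(mask) {
  m <- mask > 0
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (!m[r, c] || lab[r, c] > 0L) next
    comp <- comp + 1L
    stack <- list(c(r, c))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nrow(m) || p[2] < 1 || p[2] > ncol(m)) next
      if (!m[p[1], p[2]] || lab[p[1], p[2]] > 0L) next
      lab[p[1], p[2]] <- comp
      stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                             c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
    }
  }
  comp
}

# pixel-count occlusion statistic, straight from its definition
pixel_count_kappa <- function(masks) {
  vals <- vapply(seq_along(masks), function(k) {
    others <- Reduce(`|`, lapply(masks[-k], function(x) x > 0))
    sum((masks[[k]] > 0) & others) / sum(masks[[k]] > 0)
  }, numeric(1))
  mean(vals)
}

# central-difference gradient of f at x0
finite_diff_grad <- function(f, x0, eps = 1e-5) {
  g <- x0 * 0
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# a small fast model configuration for training-behaviour tests
tiny_model_config <- function(seed = 1L) {
  model_config(image_size = 16L, patch_size = 4L, encoder_depth = 1L,
               encoder_dim = 8L, n_heads = 2L, rho = 0.5,
               aspp_rates = c(1L), aspp_branch_channels = 4L,
               fusion_k = 4L, gate_hidden = 8L, seed = seed)
}

tiny_scene <- function(seed = 1L, ...) {
  generate_scene(scene_config(image_size = c(16L, 16L), n_leaves = 1L,
                              n_lesions = 1L, lesion_mu = 3, lesion_sigma = 0.5,
                              occlusion_target = 0, background_clutter = 0.1,
                              seed = seed, ...))
}
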