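# Heterogeneous convolutional experts, gating MLP, noisy top-k routing,
# balance/entropy regularizers and utilization statistics.
#
# Feature grids cross the module boundary as H x W x C arrays; internally
# they are flattened to (H*W) x C raster-order matrices (see nn-ops.R).

grid_to_mat <- function(A) {
  d <- dim(A)
  if (length(d) == 2L) d <- c(d, 1L)
  m <- matrix(0, d[1] * d[2], d[3])
  for (ch in seq_len(d[3])) m[, ch] <- as.vector(t(A[, , ch]))
  as_grid(m, d[1], d[2])
}

mat_to_grid <- function(m, H = NULL, W = NULL) {
  if (is.null(H)) { gd <- grid_dim(m); H <- gd[1]; W <- gd[2] }
  A <- array(0, c(H, W, ncol(m)))
  for (ch in seq_len(ncol(m))) A[, , ch] <- matrix(m[, ch], H, W, byrow = TRUE)
  A
}

#' Expert specification
#'
#' Four expert topologies share input/output shape `H x W x channels`:
#' `standard` (3x3 convolution), `dilated` (3x3 with dilation rate from
#' \{2, 4, 6\}), `depthwise_separable` (per-channel 3x3 then 1x1 channel
#' mixing) and `replica` (standard topology, Xavier initialization, group
#' normalization — a stochastic re-draw of the standard expert). Each
#' applies normalization then a rectifier after its convolution stack.
#'
#' @param kind one of `"standard"`, `"dilated"`, `"depthwise_separable"`,
#'   `"replica"`.
#' @param channels feature channels D (input = output).
#' @param dilation_rate dilation for the dilated kind (2, 4 or 6).
#' @param init `"orthogonal"` or `"xavier"`.
#' @param norm `"batch"` (per-channel over positions) or `"group"` (joint).
#' @param dropout_p expert dropout probability (training-time).
#' @export
expert_spec <- function(kind = c("standard", "dilated",
                                 "depthwise_separable", "replica"),
                        channels, dilation_rate = 2L,
                        init = NULL, norm = NULL, dropout_p = 0.1) {
  kind <- match.arg(kind)
  init <- init %||% if (kind == "replica") "xavier" else "orthogonal"
  norm <- norm %||% if (kind == "replica") "group" else "batch"
  structure(list(kind = kind, channels = as.integer(channels),
                 dilation_rate = as.integer(dilation_rate), init = init,
                 norm = norm, dropout_p = dropout_p),
            class = "expert_spec")
}

# parameter initialization for one expert, named with `prefix.`
expert_params <- function(spec, prefix, seed) {
  C <- spec$channels
  mk <- function(nin, nout)
    if (spec$init == "orthogonal") init_orthogonal(nin, nout)
    else init_xavier(nin, nout)
  with_seed(seed, {
    p <- list()
    if (spec$kind == "depthwise_separable") {
      p[[paste0(prefix, ".wdw")]] <- stats::rnorm(9L * C, 0, sqrt(2 / 9))
      p[[paste0(prefix, ".Wpw")]] <- mk(C, C)
      p[[paste0(prefix, ".b")]] <- rep(0, C)
    } else {
      p[[paste0(prefix, ".Wconv")]] <- mk(9L * C, C)
      p[[paste0(prefix, ".b")]] <- rep(0, C)
    }
    p[[paste0(prefix, ".gamma")]] <- rep(1, C)
    p[[paste0(prefix, ".beta")]] <- rep(0, C)
    p
  })
}

# tape forward for one expert; `getp` resolves parameter nodes by name
expert_forward_node <- function(spec, getp, prefix, x, H, W) {
  rate <- if (spec$kind == "dilated") spec$dilation_rate else 1L
  idx <- conv3_index(H, W, rate)
  y <- if (spec$kind == "depthwise_separable") {
    dw <- ad_dwconv3(x, idx, getp(paste0(prefix, ".wdw")), spec$channels)
    ad_add_rowvec(ad_mm(dw, getp(paste0(prefix, ".Wpw"))),
                  getp(paste0(prefix, ".b")))
  } else {
    ad_conv3(x, idx, getp(paste0(prefix, ".Wconv")), getp(paste0(prefix, ".b")))
  }
  y <- if (spec$norm == "group") ad_flatnorm(y) else ad_colnorm(y)
  y <- ad_add_rowvec(ad_scale_cols(y, getp(paste0(prefix, ".gamma"))),
                     getp(paste0(prefix, ".beta")))
  ad_relu(y)
}

#' Create an expert network
#'
#' @param spec an [expert_spec()].
#' @param seed initialization seed.
#' @return An `expert` holding the spec and its parameters.
#' @export
create_expert <- function(spec, seed = 1L) {
  structure(list(spec = spec, params = expert_params(spec, "e", seed)),
            class = "expert")
}

#' Run one expert over a feature grid
#'
#' Applies the expert's convolution stack, normalization and rectifier;
#' spatial shape is preserved (dilated variants pad with zeros).
#'
#' @param expert an [create_expert()] object.
#' @param F H x W x D feature array.
#' @return H x W x D output array.
#' @export
expert_forward <- function(expert, F) {
  d <- dim(F)
  if (d[3] != expert$spec$channels)
    stop("channel mismatch: expert expects ", expert$spec$channels,
         " channels, got ", d[3])
  ctx <- param_ctx(expert$params)
  x <- ad_const(unclass(grid_to_mat(F)))
  y <- expert_forward_node(expert$spec, ctx$get, "e", x, d[1], d[2])
  mat_to_grid(y$value, d[1], d[2])
}

#' Learnable parameter count of an expert
#'
#' @param spec an [expert_spec()].
#' @param include_norm count the normalization affine parameters too.
#' @return Integer parameter count.
#' @export
expert_param_count <- function(spec, include_norm = FALSE) {
  C <- spec$channels
  n <- if (spec$kind == "depthwise_separable") 9L * C + C * C + C
  else 9L * C * C + C
  if (include_norm) n <- n + 2L * C
  n
}

#' Gating network
#'
#' Two-layer MLP mapping a D-dimensional feature vector to a distribution
#' over M experts: `softmax(W2 gelu(W1 F_p + b1) + b2)`, with optional
#' train-time Gaussian logit noise of standard deviation `noise_sigma`.
#'
#' @param channels input feature dimension D.
#' @param n_experts number of experts M.
#' @param hidden hidden width of the MLP.
#' @param noise_sigma train-time logit noise sd.
#' @param seed initialization seed.
#' @export
gating_net <- function(channels, n_experts, hidden = 32L, noise_sigma = 1.0,
                       seed = 1L) {
  p <- with_seed(seed, list(
    "g.W1" = init_xavier(channels, hidden), "g.b1" = rep(0, hidden),
    "g.W2" = init_xavier(hidden, n_experts), "g.b2" = rep(0, n_experts)))
  structure(list(params = p, channels = as.integer(channels),
                 n_experts = as.integer(n_experts), hidden = as.integer(hidden),
                 noise_sigma = noise_sigma),
            class = "gating_net")
}

gate_logits_node <- function(getp, x) {
  h <- ad_gelu(ad_add_rowvec(ad_mm(x, getp("g.W1")), getp("g.b1")))
  ad_add_rowvec(ad_mm(h, getp("g.W2")), getp("g.b2"))
}

#' Gate feature vectors to an expert distribution
#'
#' @param F n x D matrix of per-position features (or H x W x D array).
#' @param net a [gating_net()].
#' @param mode `"eval"` or `"train"` (adds `N(0, noise_sigma^2)` logit
#'   noise, deterministic under `seed`).
#' @param seed noise seed for train mode.
#' @return n x M matrix of per-position expert probabilities.
#' @export
gate <- function(F, net, mode = c("eval", "train"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(dim(F)) == 3L) F <- unclass(grid_to_mat(F))
  if (is.null(dim(F))) F <- matrix(F, 1L)
  ctx <- param_ctx(net$params)
  logits <- gate_logits_node(ctx$get, ad_const(F))$value
  if (!all(is.finite(logits))) stop("non-finite gating logits")
  if (mode == "train" && net$noise_sigma > 0)
    logits <- logits + with_seed(seed,
      matrix(stats::rnorm(length(logits), 0, net$noise_sigma), nrow(logits)))
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Top-k expert routing
#'
#' Keeps the k largest gate probabilities per position (ties to the lowest
#' index), renormalizes them to sum to one and zeroes the rest.
#'
#' @param alpha n x M matrix (or length-M vector) of gate probabilities.
#' @param k experts kept per position (default 2).
#' @return A `routing_decision`: list(alpha, topk_sets, alpha_renorm, k).
#' @export
route_topk <- function(alpha, k = 2L) {
  if (k <= 0) stop("k must be positive")
  if (is.null(dim(alpha))) alpha <- matrix(alpha, 1L)
  if (k > ncol(alpha)) stop("k exceeds the number of experts")
  sets <- lapply(seq_len(nrow(alpha)), function(i) topk_idx(alpha[i, ], k))
  ren <- matrix(0, nrow(alpha), ncol(alpha))
  for (i in seq_len(nrow(alpha))) {
    J <- sets[[i]]
    ren[i, J] <- alpha[i, J] / sum(alpha[i, J])
  }
  structure(list(alpha = alpha, topk_sets = sets, alpha_renorm = ren,
                 k = as.integer(k)),
            class = "routing_decision")
}

#' Mixture-of-experts forward pass
#'
#' Routes every spatial position to its top-k experts and returns the
#' renormalized convex combination of the routed experts' outputs.
#'
#' @param F H x W x D feature array.
#' @param pool list of [create_expert()] objects sharing channel width.
#' @param net a [gating_net()] over the pool.
#' @param k experts kept per position.
#' @param mode `"eval"` or `"train"` (noisy gating).
#' @param seed train-mode noise seed.
#' @return list(output = H x W x D array, decision = `routing_decision`).
#' @export
moe_forward <- function(F, pool, net, k = 2L, mode = c("eval", "train"),
                        seed = 1L) {
  mode <- match.arg(mode)
  d <- dim(F)
  outs <- vector("list", length(pool))
  for (i in seq_along(pool)) {
    o <- expert_forward(pool[[i]], F)
    if (!all(dim(o) == d))
      stop("expert ", i, " changed the feature shape")
    outs[[i]] <- unclass(grid_to_mat(o))
  }
  alpha <- gate(F, net, mode, seed)
  dec <- route_topk(alpha, k)
  acc <- matrix(0, d[1] * d[2], d[3])
  for (i in seq_along(pool)) {
    w <- dec$alpha_renorm[, i]
    if (any(w > 0)) acc <- acc + outs[[i]] * w
  }
  list(output = mat_to_grid(acc, d[1], d[2]), decision = dec)
}

#' Load-balancing loss over expert routing frequencies
#'
#' Default is the variance form `(1/E) sum_i (f_i - mean(f))^2`; the
#' importance form `M * sum f_i^2 / (sum f_i)^2` is available as the
#' documented alternative.
#'
#' @param f nonnegative per-expert routing frequencies.
#' @param form `"variance"` or `"importance"`.
#' @return Scalar loss (0 at uniform usage for the variance form).
#' @export
balance_loss <- function(f, form = c("variance", "importance")) {
  form <- match.arg(form)
  if (length(f) == 0L) stop("empty frequency vector")
  if (any(f < 0)) stop("frequencies must be nonnegative")
  if (form == "variance") mean((f - mean(f))^2)
  else length(f) * sum(f^2) / sum(f)^2
}

#' Routing entropy regularizer
#'
#' Mean per-position entropy (bits) of the gate distributions:
#' `-(1/HW) sum_p sum_i alpha_{p,i} log2 alpha_{p,i}`. Uniform routing
#' over M experts attains the maximum `log2 M`.
#'
#' @param alpha n x M matrix of per-position gate probabilities.
#' @return Entropy in bits.
#' @export
routing_entropy_loss <- function(alpha) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, 1L)
  mean(apply(alpha, 1L, function(p) { p <- p[p > 0]; -sum(p * log2(p)) }))
}

#' Expert utilization statistics over a set of routing decisions
#'
#' `U_i` is the fraction of (sample, position) pairs whose top-k set
#' contains expert i. Reports the base-2 entropy and Gini coefficient of
#' the normalized utilization, its variance, and a collapse flag when any
#' normalized share exceeds `collapse_threshold`.
#'
#' @param decisions a `routing_decision` or list of them.
#' @param collapse_threshold normalized share that triggers the flag.
#' @return A `utilization_stats`: list(frequencies, utilization,
#'   entropy_bits, gini, variance, collapse_flag).
#' @export
utilization <- function(decisions, collapse_threshold = 0.9) {
  if (inherits(decisions, "routing_decision")) decisions <- list(decisions)
  stopifnot(length(decisions) >= 1L)
  M <- ncol(decisions[[1]]$alpha)
  hits <- rep(0, M)
  total <- 0L
  for (d in decisions) {
    sets <- d$topk_sets
    if (is.matrix(sets)) {
      hits <- hits + tabulate(as.vector(sets), nbins = M)
      total <- total + nrow(sets)
    } else {
      for (J in sets) hits[J] <- hits[J] + 1
      total <- total + length(sets)
    }
  }
  U <- hits / total                     # in [0, 1], sums to k
  f <- U / sum(U)                       # normalized shares
  ent <- { p <- f[f > 0]; -sum(p * log2(p)) }
  xs <- sort(f)
  n <- length(xs)
  gini <- if (sum(xs) > 0)
    sum((2 * seq_len(n) - n - 1) * xs) / (n * sum(xs)) else 0
  structure(list(frequencies = f, utilization = U, entropy_bits = ent,
                 gini = gini, variance = stats::var(U) * (M - 1) / M,
                 collapse_flag = any(f > collapse_threshold)),
            class = "utilization_stats")
}
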