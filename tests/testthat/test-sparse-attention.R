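test_that("dense attention matches the elementwise loop oracle", {
  set.seed(31)
  Q <- matrix(rnorm(6), 3, 2); K <- matrix(rnorm(6), 3, 2)
  V <- matrix(rnorm(6), 3, 2)
  expect_lt(max(abs(dense_attention(Q, K, V) - loop_attention(Q, K, V))), 1e-10)
  # single key: output is the value row
  expect_equal(dense_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                               matrix(c(3, 4), 1, 2)),
               matrix(c(3, 4), 1, 2))
  # identical keys: uniform average of values
  Ke <- matrix(1, 4, 2)[rep(1, 4), ]
  Vv <- matrix(rnorm(8), 4, 2)
  out <- dense_attention(matrix(rnorm(2), 1, 2), Ke, Vv)
  expect_equal(as.numeric(out), colMeans(Vv), tolerance = 1e-12)
})

test_that("top-k selection orders, tie-breaks and perturbs as specified", {
  cfg <- attention_config(n_tokens = 4, model_dim = 4, rho = 0.5)
  sel <- topk_select(matrix(c(0.9, 0.1, 0.5, 0.4), 1), cfg)
  expect_equal(sel$index_sets[[1]], c(1L, 3L))
  # k = n retains everything
  cfg1 <- attention_config(n_tokens = 4, model_dim = 4, rho = 1)
  sel1 <- topk_select(matrix(c(0.9, 0.1, 0.5, 0.4), 1), cfg1)
  expect_setequal(sel1$index_sets[[1]], 1:4)
  # ties break toward the lowest index
  selt <- topk_select(matrix(c(0.5, 0.9, 0.5, 0.1), 1), cfg)
  expect_equal(selt$index_sets[[1]], c(2L, 1L))
  expect_error(topk_select(matrix(c(Inf, 1), 1),
                           attention_config(2, 4, rho = 0.5)), "finite")

  # Monte-Carlo: as tau -> 0 the noiseless top-k set dominates
  logits <- matrix(c(2.0, 0.3, 1.5, -0.5), 1)
  hits <- 0
  for (s in 1:1000) {
    cfgt <- attention_config(n_tokens = 4, model_dim = 4, rho = 0.5,
                             tau = 1e-4, mode = "train", seed = s)
    J <- topk_select(logits, cfgt)$index_sets[[1]]
    if (setequal(J, c(1, 3))) hits <- hits + 1
  }
  expect_gte(hits / 1000, 0.99)
})

test_that("full-support sparse attention equals the dense oracle on fuzz cases", {
  set.seed(33)
  for (case in 1:100) {
    n <- sample(2:16, 1); d <- sample(c(2, 4, 8), 1)
    X <- matrix(rnorm(n * d), n, d)
    w <- attention_weights_init(d, n_heads = 1, seed = case)
    cfg <- attention_config(n, d, rho = 1)
    sp <- sparse_attention(X, w, cfg)
    dn <- dense_attention(X %*% w[[1]]$W_Q, X %*% w[[1]]$W_K, X %*% w[[1]]$W_V)
    expect_lt(max(abs(sp$output - dn)), 1e-6)
  }
})

test_that("restricted attention matches the masked-dense oracle and its contracts", {
  set.seed(34)
  n <- 4; d <- 2
  X <- matrix(rnorm(n * d), n, d)
  w <- list(list(W_Q = diag(d), W_K = diag(d), W_V = diag(d)))
  cfg <- attention_config(n, d, rho = 0.5)   # k = 2
  sp <- sparse_attention(X, w, cfg)
  sel <- topk_select((X %*% t(X)) / sqrt(d), cfg)
  oracle <- masked_dense_attention(X, X, X, sel$index_sets)
  expect_lt(max(abs(sp$output - oracle)), 1e-12)

  A <- sp$map$weights[[1]]
  expect_true(all(A >= 0))
  expect_equal(rowSums(A), rep(1, n), tolerance = 1e-12)
  expect_equal(sp$map$sparsity_ratio_observed, 1 - cfg$k / n)

  # k = 1 copies exactly one value row per query
  cfg1 <- attention_config(n, d, rho = 1e-9)
  sp1 <- sparse_attention(X, w, cfg1)
  for (i in seq_len(n))
    expect_true(any(apply(X, 1, function(v) max(abs(v - sp1$output[i, ])) < 1e-12)))
})

test_that("diversity loss is the negated retained-weight entropy", {
  one_hot <- diag(4)  # k = 1 rows
  map1 <- structure(list(weights = list(one_hot)), class = "attention_map")
  expect_equal(diversity_loss(map1), 0)
  unif <- matrix(0.25, 4, 4)
  map2 <- structure(list(weights = list(unif)), class = "attention_map")
  expect_equal(diversity_loss(map2), -2)
  expect_equal(diversity_loss(map2, maximize_diversity = TRUE), 2)
  set.seed(35)
  m <- matrix(rexp(12), 3, 4); m <- m / rowSums(m)
  map3 <- structure(list(weights = list(m)), class = "attention_map")
  oracle <- mean(apply(m, 1, function(p) sum(p * log2(p))))
  expect_equal(diversity_loss(map3), oracle, tolerance = 1e-12)
})

test_that("complexity accounting reports the n/k reduction factor", {
  r <- complexity_report(100, 8, 10)   # rho = 0.1
  expect_identical(r$reduction_factor, 10)
  expect_equal(complexity_report(64, 4, 64)$reduction_factor, 1)
  r2 <- complexity_report(64, 16, 8)
  expect_equal(r2$reduction_factor, 8)
  expect_equal(r2$dense_entries, 4096)
  expect_equal(r2$sparse_entries, 512)
  expect_equal(r2$dense_cost, 64^2 * 16)
  expect_equal(r2$sparse_cost, 64 * 8 * 16)
})

test_that("Gumbel-relaxed selection passes gradients: a toy attention layer learns", {
  # 1-layer sparse-attention regressor trained 50 steps must reduce loss
  ns <- asNamespace("sparsemoeseg")
  set.seed(36)
  n <- 8; d <- 4
  X <- matrix(rnorm(n * d), n, d)
  Y <- matrix(rnorm(n * d), n, d)
  params <- list(Wq = ns$init_xavier(d, d), Wk = ns$init_xavier(d, d),
                 Wv = ns$init_xavier(d, d))
  step_loss <- function(params, s) {
    ctx <- ns$param_ctx(params)
    Q <- ns$ad_mm(X, ctx$get("Wq")); K <- ns$ad_mm(X, ctx$get("Wk"))
    V <- ns$ad_mm(X, ctx$get("Wv"))
    pl <- Q$value %*% t(K$value) / sqrt(d)
    gn <- ns$with_seed(s, -log(-log(stats::runif(n))))
    pl <- sweep(pl, 2, 0.5 * gn, "+")
    mask <- ns$topk_mask_matrix(pl, 4)$mask
    A <- ns$ad_softmax_rows(ns$ad_mul(ns$ad_mm(Q, ns$ad_t(K)), 1 / sqrt(d)), mask)
    out <- ns$ad_mm(A, V)
    e <- ns$ad_sub(out, Y)
    list(loss = ns$ad_mean(ns$ad_mul(e, e)), ctx = ctx)
  }
  opt <- ns$adamw_init()
  losses <- numeric(50)
  for (s in 1:50) {
    r <- step_loss(params, s)
    ns$ad_backward(r$loss)
    g <- ns$param_grads(r$ctx)
    st <- ns$adamw_step(params, g, opt, function(nm) 5e-2, weight_decay = 0)
    params <- st$params; opt <- st$state
    losses[s] <- r$loss$value
  }
  expect_lt(mean(losses[41:50]), mean(losses[1:10]))
})
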