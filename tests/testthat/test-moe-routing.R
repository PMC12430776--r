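test_that("experts preserve shape, respond to zero input and count parameters", {
  F0 <- array(0, c(8, 8, 4))
  for (kind in c("standard", "dilated", "depthwise_separable", "replica")) {
    ex <- create_expert(expert_spec(kind, channels = 4), seed = 3)
    out <- expert_forward(ex, F0)
    expect_equal(dim(out), dim(F0))
    expect_equal(max(abs(out)), 0)   # zero in, zero out at init affine
  }
  expect_error(expert_forward(create_expert(expert_spec("standard", 4)),
                              array(0, c(8, 8, 3))), "channel mismatch")
  # depthwise separable uses fewer weights than standard: 9D + D^2 < 9D^2
  D <- 8
  std <- expert_param_count(expert_spec("standard", D))
  dws <- expert_param_count(expert_spec("depthwise_separable", D))
  expect_equal(std, 9 * D * D + D)
  expect_equal(dws, 9 * D + D * D + D)
  expect_lt(dws, std)
})

test_that("dilated convolutions reach exactly the rate-displaced taps", {
  # gradient-footprint probe on the convolution stage: the input gradient
  # of one output position is nonzero exactly on its 3x3 tap lattice
  ns <- asNamespace("sparsemoeseg")
  H <- 15; W <- 15; C <- 2; ctr <- 8
  probe <- function(rate) {
    idx <- ns$conv3_index(H, W, rate)
    set.seed(9)
    Wc <- matrix(rnorm(9 * C * C), 9 * C, C)
    x <- ns$ad_node(matrix(rnorm(H * W * C), H * W, C))
    y <- ns$ad_conv3(x, idx, Wc, rep(0, C))
    sel <- matrix(0, H * W, C); sel[(ctr - 1) * W + ctr, ] <- 1
    ns$ad_backward(ns$ad_sum(ns$ad_mul(y, sel)))
    matrix(rowSums(abs(x$grad)), H, W, byrow = TRUE)
  }
  g4 <- probe(4)
  expect_gt(abs(g4[ctr, ctr + 4]), 0)
  expect_gt(abs(g4[ctr + 4, ctr + 4]), 0)
  expect_equal(g4[ctr, ctr + 1], 0)   # not on the dilated lattice
  expect_equal(g4[ctr + 2, ctr], 0)
  # receptive extent 2*rate + 1: 9 pixels for rate 4, 3 for rate 1
  expect_equal(diff(range(which(rowSums(g4) > 0))) + 1, 9)
  g1 <- probe(1)
  expect_equal(diff(range(which(rowSums(g1) > 0))) + 1, 3)
  expect_gt(abs(g1[ctr, ctr + 1]), 0)
  expect_equal(g1[ctr, ctr + 4], 0)
})

test_that("gating produces calibrated distributions", {
  net <- gating_net(channels = 4, n_experts = 3, hidden = 5, seed = 2)
  net0 <- net
  net0$params <- lapply(net0$params, function(p) p * 0)
  F <- matrix(rnorm(8), 2, 4)
  a0 <- gate(F, net0)
  expect_equal(a0, matrix(1 / 3, 2, 3))
  # saturated logit -> near one-hot
  netb <- net0
  netb$params[["g.b2"]] <- c(10, 0, 0)
  ab <- gate(F, netb)
  expect_true(all(abs(ab[, 1] - 1) < 1e-3))
  # sigma = 0 train mode equals eval mode
  net$noise_sigma <- 0
  expect_equal(gate(F, net, mode = "train", seed = 1), gate(F, net))
})

test_that("top-k routing renormalizes exactly and keeps one-hots fixed", {
  d <- route_topk(c(0.5, 0.3, 0.15, 0.05), k = 2)
  expect_equal(d$topk_sets[[1]], c(1L, 2L))
  expect_equal(d$alpha_renorm[1, ], c(0.625, 0.375, 0, 0))
  dM <- route_topk(c(0.1, 0.2, 0.3, 0.4), k = 4)
  expect_equal(dM$alpha_renorm[1, ], c(0.1, 0.2, 0.3, 0.4))
  d1 <- route_topk(c(0, 1, 0, 0), k = 2)
  expect_equal(d1$alpha_renorm[1, ], c(0, 1, 0, 0))
  expect_error(route_topk(c(0.5, 0.5), k = 0), "positive")
  expect_error(route_topk(c(0.5, 0.5), k = 3), "exceeds")
})

test_that("MoE forward is an exact convex combination of routed experts", {
  set.seed(41)
  F <- array(rnorm(8 * 8 * 4, sd = 0.5), c(8, 8, 4))
  pool1 <- list(create_expert(expert_spec("standard", 4), seed = 1))
  net1 <- gating_net(4, 1, hidden = 4, seed = 1)
  r1 <- moe_forward(F, pool1, net1, k = 1)
  expect_equal(r1$output, expert_forward(pool1[[1]], F), tolerance = 1e-12)

  # saturated gate routes everything to expert 2 (direct-call oracle)
  pool2 <- list(create_expert(expert_spec("standard", 4), seed = 2),
                create_expert(expert_spec("dilated", 4), seed = 3))
  net2 <- gating_net(4, 2, hidden = 4, seed = 4)
  net2$params <- lapply(net2$params, function(p) p * 0)
  net2$params[["g.b2"]] <- c(-30, 30)
  r2 <- moe_forward(F, pool2, net2, k = 1)
  expect_lt(max(abs(r2$output - expert_forward(pool2[[2]], F))), 1e-6)

  # convexity: with shared expert outputs the mixture equals that output
  pool3 <- list(create_expert(expert_spec("standard", 4), seed = 7),
                create_expert(expert_spec("standard", 4), seed = 7))
  net3 <- gating_net(4, 2, hidden = 4, seed = 9)
  r3 <- moe_forward(F, pool3, net3, k = 2)
  expect_equal(r3$output, expert_forward(pool3[[1]], F), tolerance = 1e-9)
  # mixture stays inside the elementwise hull of the expert outputs
  e1 <- expert_forward(pool2[[1]], F); e2 <- expert_forward(pool2[[2]], F)
  net4 <- gating_net(4, 2, hidden = 4, seed = 10)
  r4 <- moe_forward(F, pool2, net4, k = 2)
  expect_true(all(r4$output <= pmax(e1, e2) + 1e-9))
  expect_true(all(r4$output >= pmin(e1, e2) - 1e-9))
})

test_that("balance and entropy regularizers match hand evaluation", {
  expect_equal(balance_loss(rep(0.25, 4)), 0)
  expect_equal(balance_loss(c(0.5, 0.5, 0, 0)), 0.0625)
  expect_equal(balance_loss(c(0, 0.5, 0, 0.5)), 0.0625)  # permutation invariant
  expect_equal(balance_loss(rep(0.25, 4), form = "importance"), 1)
  expect_error(balance_loss(numeric(0)), "empty")

  onehot <- diag(4)
  expect_equal(routing_entropy_loss(onehot), 0)
  expect_equal(routing_entropy_loss(matrix(0.25, 5, 4)), 2)
  set.seed(42)
  a <- matrix(rexp(20), 5, 4); a <- a / rowSums(a)
  oracle <- mean(apply(a, 1, function(p) -sum(p * log2(p))))
  expect_equal(routing_entropy_loss(a), oracle, tolerance = 1e-12)
})

test_that("utilization statistics: entropy, Gini and collapse detection", {
  mk_dec <- function(sets, M = 4) {
    alpha <- matrix(1 / M, length(sets), M)
    structure(list(alpha = alpha, topk_sets = sets,
                   alpha_renorm = alpha, k = length(sets[[1]])),
              class = "routing_decision")
  }
  balanced <- mk_dec(list(1L, 2L, 3L, 4L))
  u <- utilization(balanced)
  expect_equal(u$entropy_bits, 2.0)
  expect_equal(u$gini, 0)
  expect_false(u$collapse_flag)

  collapsed <- mk_dec(rep(list(1L), 8))
  uc <- utilization(collapsed)
  expect_equal(uc$utilization, c(1, 0, 0, 0))
  expect_equal(uc$entropy_bits, 0)
  expect_true(uc$collapse_flag)

  # Gini against a Lorenz-curve (sort and cumulate) oracle
  sets <- c(rep(list(1L), 4), rep(list(2L), 3), rep(list(3L), 2), list(4L))
  ug <- utilization(mk_dec(sets))
  f <- ug$frequencies
  lorenz <- cumsum(sort(f)) / sum(f)
  gini_oracle <- 1 - 2 * sum(lorenz) / length(f) + 1 / length(f)
  expect_equal(ug$gini, gini_oracle, tolerance = 1e-12)
  expect_equal(f, c(0.4, 0.3, 0.2, 0.1))

  # permutation equivariance: relabeling experts permutes utilization
  perm <- c(3L, 1L, 4L, 2L)
  sets_p <- lapply(sets, function(J) perm[J])
  up <- utilization(mk_dec(sets_p))
  expect_equal(up$utilization[perm], ug$utilization)
  expect_equal(up$entropy_bits, ug$entropy_bits)
})

test_that("the balance loss raises utilization entropy in a toy MoE", {
  # The toy uses four identical experts, so the task loss is indifferent
  # to routing and the gate init is biased toward expert 1; only the
  # balance term (lambda1 = 0.01) has a reason to spread the routing.
  ns <- asNamespace("sparsemoeseg")
  run_toy <- function(seed, lambda1) {
    set.seed(seed)
    n <- 32; D <- 4; M <- 4; k <- 2
    X <- matrix(rnorm(n * D), n, D)
    Y <- matrix(rnorm(n), n, 1)
    E <- ns$init_xavier(D, 1)
    params <- ns$with_seed(seed, list(
      "g.W1" = ns$init_xavier(D, 8), "g.b1" = rep(0, 8),
      "g.W2" = ns$init_xavier(8, M), "g.b2" = c(2, 1, -1, -2),
      E1 = E, E2 = E, E3 = E, E4 = E))
    opt <- ns$adamw_init()
    dec <- NULL
    for (s in 1:60) {
      ctx <- ns$param_ctx(params)
      louts <- lapply(1:M, function(i) ns$ad_mm(X, ctx$get(paste0("E", i))))
      mix <- ns$moe_mix_node(ctx$get, "g", X, louts, k, "eval", 0, seed + s)
      e <- ns$ad_sub(mix$output, Y)
      loss <- ns$ad_mean(ns$ad_mul(e, e))
      if (lambda1 > 0)
        loss <- ns$ad_add(loss, ns$ad_mul(ns$balance_loss_node(mix$alpha),
                                          lambda1))
      ns$ad_backward(loss)
      st <- ns$adamw_step(params, ns$param_grads(ctx), opt,
                          function(nm) 0.05, weight_decay = 0)
      params <- st$params; opt <- st$state
      dec <- mix$decision
    }
    utilization(dec)$entropy_bits
  }
  ents <- vapply(1:5, function(s)
    c(run_toy(s, 0.01), run_toy(s, 0)), numeric(2))
  expect_gt(mean(ents[1, ]), mean(ents[2, ]))
})
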