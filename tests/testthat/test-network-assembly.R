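test_that("forward obeys the contract: shape, range, determinism, ladder", {
  cfg <- tiny_model_config(seed = 4)
  m <- build_model(cfg)
  sc <- tiny_scene(seed = 2)
  fw1 <- forward(sc$image, m, mode = "eval")
  fw2 <- forward(sc$image, m, mode = "eval")
  expect_identical(fw1$y_hat, fw2$y_hat)
  expect_equal(dim(fw1$y_hat), dim(sc$mask))
  expect_true(all(fw1$y_hat > 0 & fw1$y_hat < 1))
  # resolution ladder: stage 1 at 1/4 scale, stage 2 at 1/2, head at image
  expect_equal(dim(fw1$aux$m1), c(4, 4))
  expect_equal(dim(fw1$aux$m2), c(8, 8))
  expect_equal(nrow(fw1$aux$attention_maps[[1]]), 16)
  expect_error(forward(array(0.5, c(20, 20, 3)), m), "16")
})

test_that("the rho = 1 encoder equals a dense-attention twin computed externally", {
  ns <- asNamespace("sparsemoeseg")
  cfg <- model_config(image_size = 16L, patch_size = 4L, encoder_depth = 2L,
                      encoder_dim = 8L, n_heads = 2L, rho = 1,
                      aspp_rates = c(1L), aspp_branch_channels = 4L,
                      fusion_k = 4L, gate_hidden = 8L, seed = 6)
  m <- build_model(cfg)
  sc <- tiny_scene(seed = 3)
  enc <- encode(sc$image, m, mode = "eval")

  # external dense twin sharing the weights
  p <- m$params
  X <- unclass(ns$grid_to_mat(sc$image))
  tok <- ns$cpp_im2col(X, m$geom$patch_idx) %*% p[["patch.W"]]
  tok <- sweep(tok, 2, p[["patch.b"]], "+") + p[["pos"]]
  lnorm <- function(x) {
    mu <- rowMeans(x); xc <- x - mu
    xc / sqrt(rowMeans(xc^2) + 1e-5)
  }
  for (l in 1:2) {
    pre <- paste0("enc", l)
    h_in <- lnorm(tok)
    heads <- lapply(1:2, function(h) {
      dense_attention(h_in %*% p[[paste0(pre, ".h", h, ".Wq")]],
                      h_in %*% p[[paste0(pre, ".h", h, ".Wk")]],
                      h_in %*% p[[paste0(pre, ".h", h, ".Wv")]])
    })
    tok <- tok + sweep(do.call(cbind, heads) %*% p[[paste0(pre, ".Wo")]],
                       2, p[[paste0(pre, ".bo")]], "+")
    m_in <- lnorm(tok)
    h1 <- sweep(m_in %*% p[[paste0(pre, ".Wm1")]], 2, p[[paste0(pre, ".bm1")]], "+")
    h1 <- h1 * pnorm(h1)
    tok <- tok + sweep(h1 %*% p[[paste0(pre, ".Wm2")]], 2, p[[paste0(pre, ".bm2")]], "+")
  }
  twin <- ns$mat_to_grid(ns$as_grid(tok, 4, 4), 4, 4)
  expect_lt(max(abs(enc$features - twin)), 1e-5)
  expect_equal(dim(enc$features)[1:2], c(16 / 4, 16 / 4))
})

test_that("lateral alignment projects then upsamples bilinearly", {
  cfg <- tiny_model_config(seed = 8)
  m <- build_model(cfg)
  # constant map stays constant under bilinear upsampling
  Fc <- array(1, c(4, 4, 8))
  up <- lateral_align(Fc, m, level = 1)
  expect_equal(dim(up)[1:2], c(8, 8))
  for (ch in seq_len(dim(up)[3]))
    expect_lt(diff(range(up[, , ch])), 1e-12)
  # level 0: projection only
  up0 <- lateral_align(Fc, m, level = 0)
  expect_equal(dim(up0)[1:2], c(4, 4))

  # 4x4 ramp doubled: independent half-pixel-center bilinear oracle
  r <- matrix(rep(1:4, each = 4), 4, 4)
  U <- sparsemoeseg:::bilinear_matrix(4, 4, 8, 8)
  got <- matrix(as.matrix(U %*% matrix(as.vector(t(r)), ncol = 1)), 8, 8,
                byrow = TRUE)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    sy <- (i - 0.5) / 2 - 0.5; sx <- (j - 0.5) / 2 - 0.5
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    cl <- function(v) pmin(pmax(v, 0), 3)
    vals <- r[cbind(cl(c(y0, y0, y0 + 1, y0 + 1)) + 1,
                    cl(c(x0, x0 + 1, x0, x0 + 1)) + 1)]
    oracle[i, j] <- vals[1] * (1 - fy) * (1 - fx) + vals[2] * (1 - fy) * fx +
      vals[3] * fy * (1 - fx) + vals[4] * fy * fx
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("decoder stages route exactly k experts and compose from parts", {
  cfg <- tiny_model_config(seed = 10)
  m <- build_model(cfg)
  set.seed(11)
  F <- array(rnorm(4 * 4 * 8, sd = 0.5), c(4, 4, 8))
  s1 <- stage1_decode(F, m)
  expect_equal(dim(s1$m1), c(4, 4))
  expect_true(is.matrix(s1$decision$topk_sets))
  expect_equal(ncol(s1$decision$topk_sets), 2)   # |J_p| = 2 everywhere
  expect_equal(rowSums(s1$decision$alpha_renorm), rep(1, 16), tolerance = 1e-12)

  F_low <- array(rnorm(8 * 8 * 8, sd = 0.5), c(8, 8, 8))
  ig <- integrate(F_low, s1$m1, m)
  expect_true(all(ig$I > 0 & ig$I < 1))
  # elementwise oracle for the gated fusion
  ns <- asNamespace("sparsemoeseg")
  p <- m$params
  m1u <- as.matrix(m$geom$up_g_2g %*% matrix(as.vector(t(s1$m1)), ncol = 1))
  fl <- unclass(ns$grid_to_mat(F_low))
  I_o <- 1 / (1 + exp(-(fl %*% p[["int.Wf"]] + m1u %*% p[["int.Wy"]] + p[["int.b"]])))
  yf <- sweep(m1u %*% p[["yproj.W"]], 2, p[["yproj.b"]], "+")
  fref_o <- fl * as.numeric(I_o) + yf * (1 - as.numeric(I_o))
  expect_equal(unclass(ns$grid_to_mat(ig$f_ref)), fref_o, tolerance = 1e-10,
               ignore_attr = TRUE)

  # forced gate limits
  m2 <- m
  m2$params[["int.b"]] <- 30
  ig1 <- integrate(F_low, s1$m1, m2)
  expect_equal(ig1$f_ref, F_low, tolerance = 1e-8)

  s2 <- stage2_decode(ig$f_ref, matrix(0, 8, 8), m)   # empty coarse mask
  expect_equal(dim(s2$m2), c(8, 8))
  expect_equal(ncol(s2$decision$topk_sets), 2)
})

test_that("signed distance matches a brute-force nearest-boundary search", {
  msk <- matrix(0, 32, 32)
  msk[13:20, 13:20] <- 1   # centered square, side 8
  d <- signed_distance(msk)
  # center pixel: half-side to the nearest background
  expect_equal(d[16, 16], -4)
  expect_equal(d[17, 17], -4)
  # brute force: distance to the nearest opposite-class pixel
  fg <- which(msk == 1, arr.ind = TRUE)
  bg <- which(msk == 0, arr.ind = TRUE)
  brute <- function(r, c) {
    pts <- if (msk[r, c] == 1) bg else fg
    s <- min(sqrt((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
    if (msk[r, c] == 1) -s else s
  }
  for (pr in list(c(16, 16), c(13, 13), c(1, 1), c(16, 21), c(20, 20)))
    expect_equal(d[pr[1], pr[2]], brute(pr[1], pr[2]), tolerance = 1e-12)
  # degenerate masks give a constant field
  expect_equal(signed_distance(matrix(0, 8, 8)), matrix(0, 8, 8))
  expect_equal(signed_distance(matrix(1, 8, 8)), matrix(0, 8, 8))
})

test_that("the refinement head is a sigmoid with residual correction", {
  cfg <- tiny_model_config(seed = 12)
  m <- build_model(cfg)
  M2 <- matrix(rnorm(64), 8, 8)
  y0 <- refine_and_head(M2, matrix(0, 8, 8), m)
  expect_equal(dim(y0), c(16, 16))
  yc <- refine_and_head(matrix(0, 8, 8), matrix(0, 8, 8), m)
  expect_equal(yc, matrix(0.5, 16, 16), tolerance = 1e-12)
  # monotone: raising a logit raises the nearby probabilities
  M2b <- M2; M2b[4, 4] <- M2b[4, 4] + 1
  yb <- refine_and_head(M2b, matrix(0, 8, 8), m)
  expect_gt(yb[8, 8], y0[8, 8])
})

test_that("a training step through the full model keeps every term finite", {
  ns <- asNamespace("sparsemoeseg")
  cfg <- tiny_model_config(seed = 14)
  m <- build_model(cfg)
  sc <- tiny_scene(seed = 5)
  fw <- ns$model_forward_node(m, sc$image, mode = "train", tau = 1, seed = 3)
  lseg <- ns$seg_loss_node(fw$y_hat, t(sc$mask))
  lbal <- ns$balance_loss_node(fw$aux$s1_alpha)
  lsp <- ns$sparsity_loss_node(fw$aux$attn)
  total <- ns$ad_add(ns$ad_add(lseg, ns$ad_mul(lbal, 0.01)),
                     ns$ad_mul(lsp, 0.001))
  expect_true(is.finite(total$value))
  ns$ad_backward(total)
  g <- ns$param_grads(fw$ctx)
  expect_true(all(vapply(g, function(x) all(is.finite(x)), logical(1))))
  expect_gt(sum(vapply(g, function(x) sum(abs(x)), numeric(1))), 0)
})
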