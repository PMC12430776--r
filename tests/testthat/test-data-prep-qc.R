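test_that("class entropy matches direct summation and its bounds", {
  expect_equal(class_entropy(c(5, 0, 0, 0)), 0)
  expect_equal(class_entropy(rep(3, 4)), 2.0)
  # counts (4,2,1,1): hand evaluation of the definition
  p <- c(4, 2, 1, 1) / 8
  expect_equal(class_entropy(c(4, 2, 1, 1)), -sum(p * log2(p)))
  expect_equal(class_entropy(c(4, 2, 1, 1)), 1.75)
  expect_equal(class_entropy(rep(1, 16)), log2(16))
  expect_error(class_entropy(c(0, 0)), "zero")
  s <- dataset_summary(c(a = 4, b = 2, c = 1, d = 1))
  expect_equal(s$class_entropy, 1.75)
  expect_equal(sum(s$class_probs), 1)
})

test_that("occlusion complexity counts overlap fractions exactly", {
  a <- matrix(0, 12, 12); a[2:5, 2:5] <- 1
  b <- matrix(0, 12, 12); b[8:11, 8:11] <- 1
  expect_equal(occlusion_complexity(list(a, b)), 0)
  expect_equal(occlusion_complexity(list(a, a)), 1)
  m1 <- matrix(0, 12, 12); m1[1:10, 1:10] <- 1        # 100 px
  m2 <- matrix(0, 12, 12); m2[1:10, 6:10] <- 1        # right half, 50 px
  expect_equal(occlusion_complexity(list(m1, m2)), (50 / 100 + 50 / 50) / 2)
  expect_error(occlusion_complexity(list(m1, matrix(0, 12, 12))), "empty")
})

test_that("Cohen's kappa follows its defining identity and the 0.85 gate", {
  a <- rep(c("x", "y"), 10)
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  # confusion table [[45,5],[5,45]]: P_o = 0.9, P_e = 0.5, kappa = 0.8
  la <- rep(c(0, 0, 1, 1), c(45, 5, 5, 45))
  lb <- rep(c(0, 1, 0, 1), c(45, 5, 5, 45))
  k <- cohens_kappa(la, lb)
  expect_equal(k$p_o, 0.9)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.8)
  expect_false(k$pass)
  # independent implementation agrees
  if (requireNamespace("e1071", quietly = TRUE)) {
    tab <- table(la, lb)
    expect_equal(k$kappa, e1071::classAgreement(tab)$kappa)
  }
  # P_o equal to P_e gives exactly zero
  set.seed(2)
  expect_equal(cohens_kappa(c(0, 0, 1, 1), c(0, 1, 0, 1))$kappa, 0)
})

test_that("image entropy filter implements the 256-bin histogram rule", {
  expect_equal(image_entropy_filter(matrix(0.5, 8, 8))$entropy, 0)
  expect_false(image_entropy_filter(matrix(0.5, 8, 8))$keep)
  two <- matrix(rep(c(0, 1), 32), 8, 8)
  r <- image_entropy_filter(two)
  expect_equal(r$entropy, 1)
  expect_false(r$keep)
  full <- matrix((0:255) / 255, 16, 16)
  r <- image_entropy_filter(full)
  expect_equal(r$entropy, 8)
  expect_true(r$keep)
})

test_that("Jensen-Shannon divergence is symmetric, bounded and exact", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  P <- c(0.5, 0.5); Q <- c(0.9, 0.1)
  M <- (P + Q) / 2
  oracle <- 0.5 * sum(P * log2(P / M)) + 0.5 * sum(Q * log2(Q / M))
  expect_equal(js_divergence(P, Q), oracle)
  expect_equal(js_divergence(P, Q), js_divergence(Q, P))
  expect_error(js_divergence(c(0.5, 0.6), c(0.5, 0.5)), "normalized")
  expect_error(js_divergence(c(-0.1, 1.1), c(0.5, 0.5)), "nonnegative")
})

test_that("preprocess resizes, normalizes and binarizes as specified", {
  # identity resize on an already-sized constant image; field-mode
  # domain normalization of a constant image yields all zeros pre-channel
  img <- array(0.4, c(256, 256, 3))
  msk <- matrix(0L, 256, 256); msk[100:120, 100:120] <- 3L
  out <- preprocess(img, msk, mode = "field", l_disease = 3L)
  np <- normalization_params()
  for (c in 1:3)
    expect_equal(out$image[, , c],
                 matrix((0 - np$mu_c[c]) / np$sigma_c[c], 256, 256),
                 tolerance = 1e-9)
  expect_equal(out$mask, (msk == 3L) * 1L)
  expect_error(preprocess(img, msk, l_disease = 5L), "unknown mask labels")

  # bicubic downsample preserves the mean of a balanced checkerboard
  cb <- (outer(1:512, 1:512, "+") %% 2)
  cb3 <- array(rep(cb, 3), c(512, 512, 3))
  rs <- bicubic_resize(cb3, c(256, 256))
  expect_lt(abs(mean(rs) - mean(cb)), 1e-6)
  # resizing at identity scale is exact, so preprocessing is idempotent
  x <- matrix(runif(64), 8, 8)
  expect_equal(bicubic_resize(x, c(8, 8)), x, tolerance = 1e-12)
})

test_that("texture QC flags outliers and duplicates within classes", {
  set.seed(5)
  noise <- lapply(1:10, function(i) matrix(runif(64 * 64), 64, 64))
  const <- matrix(0.5, 64, 64)
  rep1 <- texture_quality_report(list(a = c(noise, list(const))))
  expect_true(rep1$texture_outlier[11])
  expect_false(any(rep1$texture_outlier[1:10]))

  same <- lapply(1:3, function(i) noise[[1]])
  rep2 <- texture_quality_report(list(b = same))
  expect_false(any(rep2$texture_outlier))
  expect_equal(unique(rep2$ssim_mean), 1)
  expect_true(all(rep2$duplicate_flag))

  # a single-image class is flagged as undefined, not an error
  rep3 <- texture_quality_report(list(c = noise[1]))
  expect_false(rep3$stats_defined[1])

  # GLCM oracle: direct pair counting at 4-level quantization
  img <- matrix(c(0, 0.3, 0.6, 0.9), 2, 2)
  f <- glcm_features(img, levels = 4)
  q <- pmin(floor(img * 4), 3) + 1
  pairs <- cbind(as.vector(q[, 1]), as.vector(q[, 2]))
  P <- matrix(0, 4, 4)
  for (r in seq_len(nrow(pairs))) P[pairs[r, 1], pairs[r, 2]] <-
      P[pairs[r, 1], pairs[r, 2]] + 1
  P <- P / sum(P)
  expect_equal(f$contrast, sum(P * (row(P) - col(P))^2))
})
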