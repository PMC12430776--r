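test_that("scene generation honours the lesion model and determinism contract", {
  cfg <- scene_config(seed = 7)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1, s2)

  # lesion pixels always lie inside some leaf instance
  inst_union <- Reduce(`|`, lapply(s1$instance_masks, function(m) m > 0))
  expect_true(all(s1$mask[!inst_union] == 0))
  expect_true(all(s1$image >= 0 & s1$image <= 1))

  # no lesions requested -> empty mask
  s0 <- generate_scene(scene_config(n_lesions = 0, seed = 3))
  expect_equal(sum(s0$mask), 0)

  # metadata kappa agrees with an independent pixel-count recomputation
  expect_equal(s1$metadata$kappa, pixel_count_kappa(s1$instance_masks),
               tolerance = 1e-12)
})

test_that("disjoint lesion placement yields the requested component count", {
  cfg <- scene_config(image_size = c(96, 96), n_leaves = 1, n_lesions = 3,
                      lesion_mu = 6, lesion_sigma = 0, occlusion_target = 0,
                      background_clutter = 0, allow_overlap = FALSE, seed = 21)
  sc <- generate_scene(cfg)
  expect_equal(flood_components(sc$mask), 3)
  # cross-check the flood-fill oracle itself against EBImage labeling
  expect_equal(max(EBImage::bwlabel(sc$mask)), 3)
})

test_that("oversized lesions are rejected with an informative error", {
  expect_error(generate_scene(scene_config(lesion_mu = 60, seed = 1)),
               "lesion")
})

test_that("occlusion adjustment reaches the target within tolerance", {
  cfg <- scene_config(n_leaves = 2, occlusion_target = 0, seed = 5)
  sc <- generate_scene(cfg)
  expect_error(occlude(generate_scene(scene_config(n_leaves = 1, seed = 2)), 0.3),
               "single-leaf")
  out <- occlude(sc, 0.4)
  k_oracle <- pixel_count_kappa(out$instance_masks)
  expect_equal(out$metadata$kappa, k_oracle, tolerance = 1e-12)
  expect_gte(k_oracle, 0.35)
  expect_lte(k_oracle, 0.45)
  # fully coincident instances give kappa 1 by definition
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  expect_equal(occlusion_complexity(list(m, m)), 1)
})

test_that("low-light degradation is linear, clamped and seed-deterministic", {
  sc <- generate_scene(scene_config(seed = 9, background_clutter = 0))
  img <- sc$image
  expect_equal(apply_low_light(img, photometric_degradation(1.0, 0, seed = 1)), img)
  half <- apply_low_light(img, photometric_degradation(0.5, 0, seed = 1))
  expect_equal(mean(half), 0.5 * mean(img), tolerance = 1e-12)
  expect_error(photometric_degradation(0, 0.05), "positive")

  d <- photometric_degradation(0.3, 0.05, seed = 4)
  a <- apply_low_light(img, d)
  b <- apply_low_light(img, d)
  expect_identical(a, b)
  # noise is zero-mean: output mean within 3 standard errors of 0.3 x input
  se <- 0.05 / sqrt(length(img))
  expect_lt(abs(mean(a) - 0.3 * mean(img)), 3 * se + 1e-6)
})

test_that("augmentation applies shared geometry and preserves mask binarity", {
  sc <- generate_scene(scene_config(seed = 13))
  id_pol <- augmentation_policy(p_flip_h = 0, p_flip_v = 0, rotation_deg = 0,
                                scale_range = c(1, 1), brightness_jitter = 0,
                                contrast_jitter = 0, saturation_jitter = 0,
                                p_noise = 0)
  out <- augment(sc$image, sc$mask, id_pol, seed = 1)
  expect_equal(out$image, sc$image)
  expect_equal(out$mask, matrix(as.integer(sc$mask), nrow(sc$mask)))

  # forced horizontal flip applied twice is the identity
  flip_pol <- augmentation_policy(p_flip_h = 1, p_flip_v = 0, rotation_deg = 0,
                                  scale_range = c(1, 1), brightness_jitter = 0,
                                  contrast_jitter = 0, saturation_jitter = 0,
                                  p_noise = 0)
  once <- augment(sc$image, sc$mask, flip_pol, seed = 2)
  twice <- augment(once$image, once$mask, flip_pol, seed = 3)
  expect_equal(twice$image, sc$image)
  expect_equal(twice$mask, matrix(as.integer(sc$mask), nrow(sc$mask)))
  expect_true(all(once$mask %in% c(0L, 1L)))

  # rotation round trip loses little mask area for an interior mask
  rp <- rotate_pair(sc$image, sc$mask, 15)
  rt <- rotate_pair(rp$image, rp$mask, -15)
  inter <- sum(rt$mask & sc$mask)
  uni <- sum(rt$mask | sc$mask)
  expect_gte(inter / uni, 0.95)
})

test_that("dataset builder writes a stratified, reproducible manifest", {
  dir1 <- file.path(tempdir(), "ds1"); dir2 <- file.path(tempdir(), "ds2")
  configs <- lapply(1:10, function(i)
    scene_config(class_label = ifelse(i <= 5, 1L, 2L), seed = 100 + i))
  man <- build_dataset(configs, dir1, seed = 3)
  expect_equal(unname(unlist(man$class_counts)), c(5L, 5L))
  sizes <- unlist(man$split_sizes)
  expect_equal(sum(sizes), 10)
  expect_equal(unname(sizes[["train"]]), 7)
  expect_true(all(sort(unname(sizes[c("val", "test")])) %in% c(1, 2)))

  man2 <- build_dataset(configs, dir2, seed = 3)
  expect_identical(man$manifest_md5, man2$manifest_md5)

  # PNG round trip preserves the binary mask
  pair <- load_scene_pair(dir1, man$items[[1]])
  sc <- generate_scene(configs[[1]])
  expect_equal(pair$mask, matrix(as.integer(sc$mask), nrow(sc$mask)))
  expect_lt(max(abs(pair$image - sc$image)), 1 / 255)
})

test_that("stratified split proportions track class probabilities", {
  configs <- lapply(1:100, function(i)
    scene_config(class_label = ifelse(i <= 70, 1L, 2L), n_lesions = 0L,
                 seed = 500 + i))
  man <- build_dataset(configs, file.path(tempdir(), "ds3"), seed = 1)
  splits <- vapply(man$items, `[[`, character(1), "split")
  cls <- vapply(man$items, `[[`, integer(1), "class_label")
  for (s in c("train", "val", "test")) {
    n_s <- sum(splits == s)
    expect_lte(abs(sum(splits == s & cls == 1L) - 0.7 * n_s), 1)
  }
})
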