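# Synthetic leaf-lesion scene generator.
#
# Scenes are built from superellipse-shaped leaves over a soil-toned
# background, with lesions rendered as radial Gaussian intensity blobs whose
# half-maximum contour defines the binary mask. Later leaves occlude earlier
# ones (painter's order); instance masks record the full, pre-occlusion
# support of each leaf so the occlusion statistic can be computed exactly.

#' Scene configuration
#'
#' Describes one synthetic leaf-lesion scene. The defaults define the study
#' conditions used throughout the package's tests and benchmarks: small
#' (64x64) scenes with two partially occluding leaves carrying two
#' necrotic-style lesions each.
#'
#' @param image_size integer length-2, height and width in pixels (>= 16).
#' @param n_leaves number of leaf instances (>= 1).
#' @param n_lesions lesions per leaf (>= 0).
#' @param lesion_mu mean lesion radius in pixels (radius at half-maximum of
#'   the Gaussian intensity profile).
#' @param lesion_sigma standard deviation of the lesion radius (>= 0).
#' @param occlusion_target desired occlusion complexity in `[0, 1]`.
#' @param background_clutter background clutter level in `[0, 1]`.
#' @param class_label integer disease-class label carried into metadata.
#' @param allow_overlap if `FALSE`, lesions on a leaf are placed pairwise
#'   disjoint (used when a known connected-component count is needed).
#' @param seed integer seed; `(config, seed)` fully determines the scene.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(64L, 64L), n_leaves = 2L,
                         n_lesions = 2L, lesion_mu = 8, lesion_sigma = 2,
                         occlusion_target = 0.15, background_clutter = 0.25,
                         class_label = 1L, allow_overlap = TRUE, seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  stopifnot(all(image_size >= 16L), n_leaves >= 1L, n_lesions >= 0L,
            lesion_sigma >= 0, occlusion_target >= 0, occlusion_target <= 1,
            background_clutter >= 0, background_clutter <= 1)
  structure(list(image_size = image_size, n_leaves = as.integer(n_leaves),
                 n_lesions = as.integer(n_lesions), lesion_mu = lesion_mu,
                 lesion_sigma = lesion_sigma,
                 occlusion_target = occlusion_target,
                 background_clutter = background_clutter,
                 class_label = as.integer(class_label),
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# superellipse support |x'/a|^m + |y'/b|^m <= 1 on the pixel grid
leaf_support <- function(H, W, leaf) {
  yx <- expand.grid(x = seq_len(W) - 0.5, y = seq_len(H) - 0.5)
  dx <- yx$x - leaf$cx
  dy <- yx$y - leaf$cy
  xr <- cos(leaf$theta) * dx + sin(leaf$theta) * dy
  yr <- -sin(leaf$theta) * dx + cos(leaf$theta) * dy
  v <- (abs(xr / leaf$a))^leaf$m + (abs(yr / leaf$b))^leaf$m
  matrix(as.numeric(v <= 1), H, W, byrow = TRUE)
}

sample_leaf_params <- function(config) {
  H <- config$image_size[1]; W <- config$image_size[2]
  s <- min(H, W)
  lapply(seq_len(config$n_leaves), function(k) {
    a <- stats::runif(1, 0.24, 0.34) * s
    list(cx = stats::runif(1, 0.3, 0.7) * W,
         cy = stats::runif(1, 0.3, 0.7) * H,
         a = a, b = a * stats::runif(1, 0.55, 0.9),
         theta = stats::runif(1, 0, pi),
         m = stats::runif(1, 2, 3),
         color = c(0.18, 0.52, 0.16) +
           stats::runif(3, -0.04, 0.04) * c(1, 1.5, 1))
  })
}

# sample lesion centers (relative to leaf center) and radii for one leaf
sample_lesions <- function(config, support, leaf) {
  if (config$n_lesions == 0L) return(list())
  H <- nrow(support); W <- ncol(support)
  dm <- as.matrix(EBImage::distmap(support))  # interior distance to boundary
  placed <- list()
  for (j in seq_len(config$n_lesions)) {
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      r <- max(2, stats::rnorm(1, config$lesion_mu, config$lesion_sigma))
      elig <- which(dm > r, arr.ind = TRUE)   # disk fits inside the leaf
      if (nrow(elig) == 0L) next              # this radius draw cannot fit
      pick <- elig[sample.int(nrow(elig), 1L), ]
      cy <- pick[["row"]] - 0.5; cx <- pick[["col"]] - 0.5
      if (config$allow_overlap ||
          all(vapply(placed, function(p) {
            sqrt((p$cx - cx)^2 + (p$cy - cy)^2) >= p$r + r + 2
          }, logical(1)))) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place a lesion after 100 attempts; ",
                  "lesion_mu too large for the leaf size")
    placed[[j]] <- list(cx = cx, cy = cy, r = r,
                        rel_x = cx - leaf$cx, rel_y = cy - leaf$cy)
  }
  placed
}

# deterministic rendering given sampled leaf/lesion parameters
render_scene <- function(config, leaves, lesions, render_seed) {
  H <- config$image_size[1]; W <- config$image_size[2]
  with_seed(render_seed, {
    # background: soil tone + low-frequency clutter blobs + speckle
    img <- array(0, c(H, W, 3))
    soil <- c(0.45, 0.38, 0.30)
    for (c in 1:3) img[, , c] <- soil[c]
    cl <- config$background_clutter
    if (cl > 0) {
      yx <- expand.grid(x = seq_len(W) - 0.5, y = seq_len(H) - 0.5)
      for (b in seq_len(6L)) {
        bx <- stats::runif(1, 0, W); by <- stats::runif(1, 0, H)
        bs <- stats::runif(1, 0.08, 0.2) * min(H, W)
        amp <- stats::runif(1, -0.12, 0.12) * cl
        bump <- matrix(exp(-((yx$x - bx)^2 + (yx$y - by)^2) / (2 * bs^2)),
                       H, W, byrow = TRUE)
        for (c in 1:3) img[, , c] <- img[, , c] + amp * bump
      }
      for (c in 1:3)
        img[, , c] <- img[, , c] + stats::rnorm(H * W, 0, 0.03 * cl)
    }
    instance_masks <- lapply(leaves, function(lf) leaf_support(H, W, lf))
    # painter's visibility: highest-index leaf wins
    vis <- matrix(0L, H, W)
    for (k in seq_along(leaves)) vis[instance_masks[[k]] == 1] <- k
    yx <- expand.grid(x = seq_len(W) - 0.5, y = seq_len(H) - 0.5)
    gx <- matrix(yx$x, H, W, byrow = TRUE)
    gy <- matrix(yx$y, H, W, byrow = TRUE)
    mask <- matrix(0L, H, W)
    lesion_color <- c(0.33, 0.19, 0.08)
    for (k in seq_along(leaves)) {
      lf <- leaves[[k]]
      sel <- vis == k
      if (!any(sel)) next
      shade <- 1 - 0.25 * ((gx - lf$cx)^2 / lf$a^2 + (gy - lf$cy)^2 / lf$b^2)
      tex <- matrix(stats::rnorm(H * W, 0, 0.015), H, W)
      for (c in 1:3)
        img[, , c][sel] <- lf$color[c] * shade[sel] + tex[sel]
      for (ls in lesions[[k]]) {
        s2 <- (ls$r / sqrt(2 * log(2)))^2
        prof <- exp(-((gx - ls$cx)^2 + (gy - ls$cy)^2) / (2 * s2))
        blend <- 0.9 * prof
        for (c in 1:3)
          img[, , c][sel] <- img[, , c][sel] * (1 - blend[sel]) +
            lesion_color[c] * blend[sel]
        mask[sel & prof >= 0.5] <- 1L
      }
    }
    img <- pmin(pmax(img, 0), 1)
    kappa <- if (length(leaves) > 1L)
      occlusion_complexity(instance_masks) else 0
    structure(list(image = img, mask = mask, instance_masks = instance_masks,
                   metadata = list(config = config, leaves = leaves,
                                   lesions = lesions, kappa = kappa,
                                   render_seed = render_seed)),
              class = "synthetic_scene")
  })
}

#' Generate a synthetic leaf-lesion scene
#'
#' Places superellipse leaves with randomized axes, rotation and color, then
#' draws each lesion as a radial Gaussian intensity profile whose radius is
#' drawn from `N(lesion_mu, lesion_sigma^2)`. Lesion centers are sampled
#' uniformly over the leaf positions where the half-maximum disk fits
#' entirely inside the leaf; a config whose lesions cannot be placed after
#' 100 attempts is rejected with an error. The binary mask is the union of
#' half-maximum lesion supports restricted to the visible part of their
#' leaf, so every mask pixel lies inside some leaf instance.
#'
#' @param config a [scene_config()].
#' @return A `synthetic_scene`: list with `image` (HxWx3 array in `[0,1]`),
#'   `mask` (HxW 0/1 matrix), `instance_masks` (per-leaf full supports), and
#'   `metadata` (realized parameters plus achieved occlusion `kappa`).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    leaves <- sample_leaf_params(config)
    lesions <- lapply(seq_along(leaves), function(k)
      sample_lesions(config, leaf_support(H, W, leaves[[k]]), leaves[[k]]))
    render_seed <- config$seed %% 1000000L + 7L
    scene <- render_scene(config, leaves, lesions, render_seed)
    if (config$n_leaves > 1L && config$occlusion_target > 0)
      scene <- occlude(scene, config$occlusion_target)
    scene
  })
}

#' Adjust leaf overlap toward a target occlusion complexity
#'
#' Translates leaf instances radially about their common centroid and
#' re-renders the scene until the occlusion complexity (mean fraction of
#' each instance covered by the union of the others) is within 0.05 of the
#' target, using bisection on the spread factor. The achieved value is
#' stored in `metadata$kappa`.
#'
#' @param scene a `synthetic_scene` with at least two leaves.
#' @param target occlusion complexity target in `[0, 1]`.
#' @param max_iter maximum bisection iterations.
#' @return The re-rendered `synthetic_scene`.
#' @export
occlude <- function(scene, target, max_iter = 40L) {
  stopifnot(inherits(scene, "synthetic_scene"), target >= 0, target <= 1)
  md <- scene$metadata
  if (length(md$leaves) < 2L)
    stop("occlusion is undefined for a single-leaf scene")
  if (abs(md$kappa - target) <= 0.05) return(scene)
  cx0 <- mean(vapply(md$leaves, `[[`, numeric(1), "cx"))
  cy0 <- mean(vapply(md$leaves, `[[`, numeric(1), "cy"))
  spread_scene <- function(s) {
    leaves <- lapply(md$leaves, function(lf) {
      lf$cx <- cx0 + s * (lf$cx - cx0)
      lf$cy <- cy0 + s * (lf$cy - cy0)
      lf
    })
    lesions <- lapply(seq_along(leaves), function(k) {
      lapply(md$lesions[[k]], function(ls) {
        ls$cx <- leaves[[k]]$cx + ls$rel_x
        ls$cy <- leaves[[k]]$cy + ls$rel_y
        ls
      })
    })
    render_scene(md$config, leaves, lesions, md$render_seed)
  }
  kappa_at <- function(s) spread_scene(s)$metadata$kappa
  lo <- 0; hi <- 1
  # ensure the bracket contains the target: kappa decreases with spread
  while (kappa_at(hi) > target && hi < 8) hi <- hi * 1.6
  best <- NULL; best_err <- Inf
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    sc <- spread_scene(mid)
    err <- sc$metadata$kappa - target
    if (abs(err) < best_err) { best <- sc; best_err <- abs(err) }
    if (abs(err) <= 0.05) break
    if (err > 0) lo <- mid else hi <- mid
  }
  best
}

#' Photometric degradation settings
#'
#' Low-light simulation: multiplicative brightness reduction followed by
#' additive Gaussian sensor noise on the `[0, 1]` scale. The reference
#' brightness factors are 0.7, 0.5 and 0.3 (moderate, low, very low light)
#' with noise sigma 0.05.
#'
#' @param brightness_factor multiplier in `(0, 1]`.
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param seed integer seed for the noise draw.
#' @export
photometric_degradation <- function(brightness_factor = 0.5,
                                    noise_sigma = 0.05, seed = 1L) {
  if (brightness_factor <= 0) stop("brightness_factor must be positive")
  stopifnot(brightness_factor <= 1, noise_sigma >= 0)
  structure(list(brightness_factor = brightness_factor,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "photometric_degradation")
}

#' Apply low-light degradation to an image
#'
#' @param image numeric array in `[0, 1]`.
#' @param deg a [photometric_degradation()].
#' @return Degraded image, clamped to `[0, 1]`; deterministic under the
#'   degradation's seed.
#' @export
apply_low_light <- function(image, deg) {
  stopifnot(inherits(deg, "photometric_degradation"),
            min(image) >= 0, max(image) <= 1)
  out <- image * deg$brightness_factor
  if (deg$noise_sigma > 0)
    out <- out + with_seed(deg$seed,
                           array(stats::rnorm(length(image), 0, deg$noise_sigma),
                                 dim = dim(image) %||% length(image)))
  pmin(pmax(out, 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Augmentation policy
#'
#' Composite augmentation: geometric transforms (flips, rotation, isotropic
#' scaling) applied identically to image and mask, and photometric jitter
#' (brightness/contrast/saturation, Gaussian noise) applied to the image
#' only. Defaults follow the training recipe: flip probability 0.5,
#' rotation up to 15 degrees (30 available via this argument), scaling
#' 0.8-1.2, brightness/contrast jitter 0.2, saturation jitter 0.1, noise
#' sigma 0.01 with probability 0.3.
#'
#' @param p_flip_h,p_flip_v flip probabilities in `[0, 1]`.
#' @param rotation_deg maximum rotation magnitude in degrees.
#' @param scale_range length-2 numeric, low <= high.
#' @param brightness_jitter,contrast_jitter,saturation_jitter magnitudes.
#' @param p_noise probability of adding Gaussian noise.
#' @param noise_sigma noise standard deviation.
#' @export
augmentation_policy <- function(p_flip_h = 0.5, p_flip_v = 0.5,
                                rotation_deg = 15, scale_range = c(0.8, 1.2),
                                brightness_jitter = 0.2, contrast_jitter = 0.2,
                                saturation_jitter = 0.1, p_noise = 0.3,
                                noise_sigma = 0.01) {
  stopifnot(p_flip_h >= 0, p_flip_h <= 1, p_flip_v >= 0, p_flip_v <= 1,
            p_noise >= 0, p_noise <= 1, scale_range[1] <= scale_range[2])
  structure(as.list(environment()), class = "augmentation_policy")
}

# inverse-mapped affine resample about the image center; bilinear for the
# image, nearest for masks; identity parameters reproduce the input exactly
affine_sample <- function(x, angle_deg, scale, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3L) d[3] else 1L
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  out_r <- matrix(seq_len(H), H, W)
  out_c <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse map: rotate by -angle, scale by 1/scale
  dy <- out_r - cy; dx <- out_c - cx
  src_r <- (cos(th) * dy - sin(th) * dx) / scale + cy
  src_c <- (sin(th) * dy + cos(th) * dx) / scale + cx
  sample_plane <- function(pl) {
    if (method == "nearest") {
      r <- pmin(pmax(round(src_r), 1), H)
      c <- pmin(pmax(round(src_c), 1), W)
      matrix(pl[cbind(as.vector(r), as.vector(c))], H, W)
    } else {
      r0 <- floor(src_r); c0 <- floor(src_c)
      fr <- src_r - r0; fc <- src_c - c0
      cl <- function(v, n) pmin(pmax(v, 1), n)
      g <- function(r, c) matrix(pl[cbind(as.vector(cl(r, H)), as.vector(cl(c, W)))], H, W)
      g(r0, c0) * (1 - fr) * (1 - fc) + g(r0 + 1, c0) * fr * (1 - fc) +
        g(r0, c0 + 1) * (1 - fr) * fc + g(r0 + 1, c0 + 1) * fr * fc
    }
  }
  if (length(d) == 3L) {
    out <- array(0, d)
    for (c in seq_len(C)) out[, , c] <- sample_plane(x[, , c])
    out
  } else sample_plane(x)
}

#' Rotate an image/mask pair by a fixed angle
#'
#' Shared geometric transform used by [augment()]: bilinear interpolation
#' for the image, nearest-neighbour for the mask (kept binary).
#'
#' @param image HxWxC array or HxW matrix.
#' @param mask HxW 0/1 matrix.
#' @param degrees rotation angle (counter-clockwise).
#' @param scale isotropic scale factor.
#' @return list(image, mask)
#' @export
rotate_pair <- function(image, mask, degrees, scale = 1) {
  list(image = affine_sample(image, degrees, scale, "bilinear"),
       mask = affine_sample(mask, degrees, scale, "nearest"))
}

#' Apply a sampled augmentation to an image/mask pair
#'
#' @param image HxWx3 array in `[0, 1]`.
#' @param mask HxW 0/1 matrix with matching spatial shape.
#' @param policy an [augmentation_policy()].
#' @param seed integer seed; the draw is fully determined by it.
#' @return list(image, mask); the mask remains binary.
#' @export
augment <- function(image, mask, policy, seed = 1L) {
  stopifnot(inherits(policy, "augmentation_policy"),
            all(dim(image)[1:2] == dim(mask)[1:2]))
  with_seed(seed, {
    img <- image; msk <- mask
    if (stats::runif(1) < policy$p_flip_h) {
      img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk)))]
    }
    if (stats::runif(1) < policy$p_flip_v) {
      img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
      msk <- msk[rev(seq_len(nrow(msk))), ]
    }
    ang <- if (policy$rotation_deg > 0)
      stats::runif(1, -policy$rotation_deg, policy$rotation_deg) else 0
    sc <- if (policy$scale_range[1] < policy$scale_range[2])
      stats::runif(1, policy$scale_range[1], policy$scale_range[2])
    else policy$scale_range[1]
    if (ang != 0 || sc != 1) {
      rp <- rotate_pair(img, msk, ang, sc)
      img <- rp$image; msk <- rp$mask
    }
    if (policy$brightness_jitter > 0)
      img <- img * (1 + stats::runif(1, -policy$brightness_jitter,
                                     policy$brightness_jitter))
    if (policy$contrast_jitter > 0) {
      f <- 1 + stats::runif(1, -policy$contrast_jitter, policy$contrast_jitter)
      img <- mean(img) + (img - mean(img)) * f
    }
    if (policy$saturation_jitter > 0) {
      f <- 1 + stats::runif(1, -policy$saturation_jitter,
                            policy$saturation_jitter)
      gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
      for (c in 1:3) img[, , c] <- gray + (img[, , c] - gray) * f
    }
    if (policy$p_noise > 0 && stats::runif(1) < policy$p_noise)
      img <- img + array(stats::rnorm(length(img), 0, policy$noise_sigma),
                         dim = dim(img))
    list(image = pmin(pmax(img, 0), 1), mask = (msk > 0.5) * 1L)
  })
}

#' Build a synthetic dataset on disk
#'
#' Renders every configuration, writes 8-bit RGB PNG images, single-channel
#' 0/255 PNG masks and per-item JSON metadata, and records a manifest with
#' per-class counts and a stratified train/validation/test split. The split
#' rule: global sizes are `round(0.70 N)` train and `round(0.15 N)`
#' validation with the remainder as test; per-class allocations follow by
#' largest remainder, after a seeded shuffle within class.
#'
#' @param configs list of [scene_config()] objects.
#' @param out_dir writable output directory (created if missing).
#' @param split numeric length-3 fractions summing to 1.
#' @param seed seed for the within-class shuffle.
#' @return The manifest (invisibly also written as `manifest.json`), with a
#'   `manifest_md5` checksum of the manifest body.
#' @export
build_dataset <- function(configs, out_dir, split = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  stopifnot(length(split) == 3L, abs(sum(split) - 1) < 1e-9)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(configs)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_scene(configs[[i]])
    id <- sprintf("%04d", i)
    img_path <- file.path(out_dir, paste0("img_", id, ".png"))
    mask_path <- file.path(out_dir, paste0("mask_", id, ".png"))
    meta_path <- file.path(out_dir, paste0("meta_", id, ".json"))
    png::writePNG(sc$image, img_path)
    png::writePNG(sc$mask * 1.0, mask_path)
    jsonlite::write_json(list(class_label = sc$metadata$config$class_label,
                              seed = sc$metadata$config$seed,
                              kappa = sc$metadata$kappa,
                              lesions = lapply(sc$metadata$lesions, function(l)
                                lapply(l, function(x) x[c("cx", "cy", "r")])),
                              image = basename(img_path),
                              mask = basename(mask_path)),
                         meta_path, auto_unbox = TRUE, digits = NA)
    items[[i]] <- list(id = id, class_label = sc$metadata$config$class_label,
                       image = basename(img_path), mask = basename(mask_path),
                       meta = basename(meta_path))
  }
  cls <- vapply(items, `[[`, integer(1), "class_label")
  n_train <- round(split[1] * n); n_val <- round(split[2] * n)
  n_test <- n - n_train - n_val
  # per-class largest-remainder allocation against the global totals
  tab <- table(cls)
  alloc <- function(total) {
    raw <- as.numeric(tab) * total / n
    base <- floor(raw)
    rem <- total - sum(base)
    if (rem > 0) {
      extra <- utils::head(order(-(raw - base), seq_along(raw)), rem)
      base[extra] <- base[extra] + 1L
    }
    stats::setNames(base, names(tab))
  }
  a_train <- alloc(n_train); a_val <- alloc(n_val)
  assignment <- character(n)
  for (cl in names(tab)) {
    idx <- which(cls == as.integer(cl))
    idx <- with_seed(seed + as.integer(cl), sample(idx))
    k1 <- a_train[[cl]]; k2 <- a_val[[cl]]
    assignment[idx[seq_len(k1)]] <- "train"
    if (k2 > 0) assignment[idx[k1 + seq_len(k2)]] <- "val"
    rest <- idx[-seq_len(k1 + k2)]
    assignment[rest] <- "test"
  }
  for (i in seq_len(n)) items[[i]]$split <- assignment[i]
  manifest <- list(n_items = n,
                   class_counts = as.list(stats::setNames(as.integer(tab), names(tab))),
                   split_sizes = list(train = sum(assignment == "train"),
                                      val = sum(assignment == "val"),
                                      test = sum(assignment == "test")),
                   items = items)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest$manifest_md5 <- unname(tools::md5sum(path))
  manifest
}

#' Load a scene pair (image + mask) from a dataset directory
#'
#' @param dir dataset directory produced by [build_dataset()].
#' @param item one element of the manifest's `items` list.
#' @return list(image, mask)
#' @export
load_scene_pair <- function(dir, item) {
  img <- png::readPNG(file.path(dir, item$image))
  msk <- png::readPNG(file.path(dir, item$mask))
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  list(image = img, mask = (msk > 0.5) * 1L)
}
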