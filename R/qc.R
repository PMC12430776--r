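# Preprocessing chain and dataset quality-control statistics.
#
# All entropies and divergences are reported in bits (base-2 logs).

#' Shannon entropy of a class-count vector
#'
#' `H_c = -sum p_i log2 p_i` with `p_i = n_i / sum n_j` and `0 log 0 := 0`.
#' For a dataset of `N_c` classes the value lies in `[0, log2 N_c]`.
#'
#' @param counts nonnegative per-class sample counts, sum > 0.
#' @return Entropy in bits.
#' @export
class_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("counts must not be all zero")
  p <- counts / sum(counts)
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (h == 0) 0 else h   # avoid IEEE negative zero for degenerate counts
}

#' Occlusion complexity of a set of instance masks
#'
#' Mean, over instances, of the fraction of each instance covered by the
#' union of all other instances:
#' `kappa = mean_k |M_k intersect union_{j != k} M_j| / |M_k|`.
#'
#' @param instance_masks list of 0/1 matrices of identical shape.
#' @return Occlusion complexity in `[0, 1]`.
#' @export
occlusion_complexity <- function(instance_masks) {
  stopifnot(length(instance_masks) >= 1L)
  masks <- lapply(instance_masks, function(m) m > 0)
  areas <- vapply(masks, sum, numeric(1))
  if (any(areas == 0)) stop("empty instance mask: occlusion fraction undefined")
  if (length(masks) == 1L) return(0)
  total <- Reduce(`+`, masks)
  mean(vapply(masks, function(m) sum(m & (total - m) > 0) / sum(m), numeric(1)))
}

# ---- bicubic resampling ----------------------------------------------------

# Catmull-Rom cubic convolution kernel (a = -0.5); weights at any phase sum
# to 1 exactly, so constant images are preserved
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# 1-D bicubic interpolation matrix (n_out x n_in), half-pixel centers,
# edge-clamped taps
bicubic_axis_matrix <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  W <- matrix(0, n_out, n_in)
  for (t in -1:2) {
    it <- pmin(pmax(i0 + t, 0), n_in - 1)
    w <- cubic_kernel(src - (i0 + t))
    W[cbind(seq_len(n_out), it + 1)] <- W[cbind(seq_len(n_out), it + 1)] + w
  }
  W
}

#' Bicubic image resampling
#'
#' Separable Catmull-Rom cubic convolution with half-pixel sample centers
#' and edge clamping; applied per channel.
#'
#' @param image HxW matrix or HxWxC array.
#' @param size target `c(height, width)`.
#' @return Resampled image.
#' @export
bicubic_resize <- function(image, size) {
  d <- dim(image)
  Wy <- bicubic_axis_matrix(d[1], size[1])
  Wx <- bicubic_axis_matrix(d[2], size[2])
  if (length(d) == 2L) return(Wy %*% image %*% t(Wx))
  out <- array(0, c(size[1], size[2], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Wy %*% image[, , c] %*% t(Wx)
  out
}

#' Per-channel normalization constants
#'
#' Fixed channel statistics used for input standardization (the standard
#' published RGB constants), plus the stabilizer for the per-image
#' domain-adaptive variant.
#'
#' @param mu_c,sigma_c length-3 per-channel mean and standard deviation.
#' @param epsilon stabilizer added to the per-image luminance sd.
#' @export
normalization_params <- function(mu_c = c(0.485, 0.456, 0.406),
                                 sigma_c = c(0.229, 0.224, 0.225),
                                 epsilon = 1e-6) {
  stopifnot(all(sigma_c > 0), epsilon > 0)
  structure(list(mu_c = mu_c, sigma_c = sigma_c, epsilon = epsilon),
            class = "normalization_params")
}

#' Preprocess an image/mask pair
#'
#' Resizes the image to `size` with bicubic interpolation, standardizes it
#' per channel as `(I' - mu_c) / sigma_c`, and in `mode = "field"`
#' additionally applies the per-image domain-adaptive transform
#' `(I - mu_env) / (sigma_env + epsilon)` with `mu_env`, `sigma_env`
#' estimated from the image's own luminance channel. The mask is mapped to
#' `{0, 1}` by membership in `l_disease` and resized with nearest-neighbour
#' interpolation.
#'
#' @param image HxWx3 RGB array in `[0, 1]`.
#' @param mask HxW labeled or binary mask.
#' @param mode `"lab"` (channel normalization only) or `"field"` (adds the
#'   domain-adaptive transform before channel normalization).
#' @param l_disease integer label set mapped to foreground.
#' @param size target spatial size, default `c(256, 256)`.
#' @param params a [normalization_params()].
#' @return list(image, mask) with the normalized image and binary mask.
#' @export
preprocess <- function(image, mask, mode = c("lab", "field"),
                       l_disease = 1L, size = c(256L, 256L),
                       params = normalization_params()) {
  mode <- match.arg(mode)
  labs <- sort(unique(as.vector(mask)))
  unknown <- setdiff(labs, c(0L, l_disease))
  if (length(unknown))
    stop("unknown mask labels not in the disease-label set or background: ",
         paste(unknown, collapse = ", "))
  img <- bicubic_resize(image, size)
  if (mode == "field") {
    lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    mu_env <- mean(lum)
    sigma_env <- stats::sd(as.vector(lum))
    img <- (img - mu_env) / (sigma_env + params$epsilon)
  }
  for (c in 1:3) img[, , c] <- (img[, , c] - params$mu_c[c]) / params$sigma_c[c]
  idx <- nearest_index(nrow(mask), ncol(mask), size[1], size[2])
  mflat <- as.vector(t(mask))[idx]  # raster-order gather
  mbin <- matrix(as.integer(mflat %in% l_disease), size[1], size[2],
                 byrow = TRUE)
  list(image = img, mask = mbin)
}

#' Cohen's kappa for two annotators
#'
#' `kappa = (P_o - P_e) / (1 - P_e)` with observed agreement `P_o` and
#' chance agreement `P_e` from the marginal label frequencies. The
#' acceptance gate flags `kappa > 0.85` as acceptable agreement.
#'
#' @param labels_a,labels_b equal-length categorical vectors.
#' @return list(kappa, p_o, p_e, pass)
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  n <- length(labels_a)
  lev <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  p_o <- mean(a == b)
  p_e <- sum(table(a) / n * table(b) / n)
  if (1 - p_e < .Machine$double.eps) {
    if (p_o == 1) return(list(kappa = 1, p_o = 1, p_e = p_e, pass = TRUE))
    stop("chance agreement is 1 but observed agreement is not: kappa undefined")
  }
  k <- (p_o - p_e) / (1 - p_e)
  list(kappa = k, p_o = p_o, p_e = p_e, pass = k > 0.85)
}

#' Image entropy filter
#'
#' Shannon entropy over the 256-bin grayscale histogram of an 8-bit image;
#' images below 2.0 bits are flagged as low-information and discarded.
#'
#' @param image grayscale matrix or RGB array in `[0, 1]`.
#' @return list(entropy, keep)
#' @export
image_entropy_filter <- function(image) {
  g <- if (length(dim(image)) == 3L)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  else image
  lev <- pmin(pmax(round(g * 255), 0), 255)
  p <- tabulate(as.vector(lev) + 1L, nbins = 256L) / length(lev)
  p <- p[p > 0]
  H <- -sum(p * log2(p))
  list(entropy = H, keep = H >= 2.0)
}

#' Jensen-Shannon divergence between two distributions
#'
#' `D_JS = 0.5 KL(P || M) + 0.5 KL(Q || M)` with `M = (P + Q) / 2`, base-2
#' logs; bounded by 1 bit for two distributions.
#'
#' @param P,Q nonnegative vectors on the same support, each summing to 1.
#' @return Divergence in bits.
#' @export
js_divergence <- function(P, Q) {
  stopifnot(length(P) == length(Q))
  if (any(P < 0) || any(Q < 0)) stop("distributions must be nonnegative")
  if (abs(sum(P) - 1) > 1e-8 || abs(sum(Q) - 1) > 1e-8)
    stop("inputs must be normalized distributions")
  M <- (P + Q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(P, M) + 0.5 * kl(Q, M)
}

# ---- texture statistics ----------------------------------------------------

#' Gray-level co-occurrence features
#'
#' GLCM at one offset (distance 1, angle 0 degrees) on an image quantized
#' to `levels` gray levels; returns contrast, correlation and entropy of
#' the normalized co-occurrence matrix.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param levels number of quantization levels.
#' @return list(contrast, correlation, entropy)
#' @export
glcm_features <- function(image, levels = 4L) {
  q <- pmin(floor(image * levels), levels - 1L) + 1L
  H <- nrow(q); W <- ncol(q)
  i <- as.vector(q[, -W]); j <- as.vector(q[, -1])
  P <- matrix(0, levels, levels)
  tab <- table(factor(i, levels = seq_len(levels)),
               factor(j, levels = seq_len(levels)))
  P[] <- tab / sum(tab)
  ii <- row(P); jj <- col(P)
  contrast <- sum(P * (ii - jj)^2)
  mu_i <- sum(ii * P); mu_j <- sum(jj * P)
  s_i <- sqrt(sum((ii - mu_i)^2 * P)); s_j <- sqrt(sum((jj - mu_j)^2 * P))
  corr <- if (s_i > 0 && s_j > 0)
    sum((ii - mu_i) * (jj - mu_j) * P) / (s_i * s_j) else NA_real_
  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))
  list(contrast = contrast, correlation = corr, entropy = ent)
}

#' Global structural similarity between two grayscale images
#'
#' Single-window SSIM on the full image with the standard stabilizers
#' `C1 = 0.01^2`, `C2 = 0.03^2` on the `[0, 1]` dynamic range.
#'
#' @param x,y grayscale matrices in `[0, 1]` of identical shape.
#' @return SSIM score.
#' @export
ssim_global <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  C1 <- 0.01^2; C2 <- 0.03^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' 8x8 average perceptual hash
#'
#' Block-mean downsample to 8x8, threshold at the mean; two images are
#' duplicates when the 64-bit hashes are identical (Hamming distance 0).
#'
#' @param image grayscale matrix or RGB array in `[0, 1]`.
#' @return Character hash (64 characters of 0/1).
#' @export
average_hash <- function(image) {
  g <- if (length(dim(image)) == 3L)
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3 else image
  H <- nrow(g); W <- ncol(g)
  ry <- ceiling(seq_len(H) / (H / 8))
  rx <- ceiling(seq_len(W) / (W / 8))
  small <- rowsum(t(rowsum(g, ry)), rx) / tcrossprod(tabulate(rx, 8), tabulate(ry, 8))
  bits <- as.integer(t(small) >= mean(small))
  paste(bits, collapse = "")
}

#' Texture and coherence quality report per class
#'
#' For each class: GLCM contrast/correlation/entropy per image with
#' outlier flags beyond 3 class standard deviations from the class mean;
#' mean pairwise global SSIM as a structural-coherence score; and
#' average-hash duplicate detection. Classes with fewer than two images
#' have undefined statistics and are flagged, not errored.
#'
#' @param images_by_class named list; each element a list of grayscale
#'   matrices (or RGB arrays, converted internally) in `[0, 1]`.
#' @return Data frame with one row per image: class, index, the three GLCM
#'   statistics, `texture_outlier`, `ssim_mean` (class level),
#'   `duplicate_flag`, and `stats_defined`.
#' @export
texture_quality_report <- function(images_by_class) {
  to_gray <- function(im) if (length(dim(im)) == 3L)
    (im[, , 1] + im[, , 2] + im[, , 3]) / 3 else im
  rows <- list()
  for (cl in names(images_by_class)) {
    imgs <- lapply(images_by_class[[cl]], to_gray)
    n <- length(imgs)
    feats <- t(vapply(imgs, function(im) {
      f <- glcm_features(im)
      c(f$contrast, ifelse(is.na(f$correlation), 0, f$correlation), f$entropy)
    }, numeric(3)))
    colnames(feats) <- c("contrast", "correlation", "entropy")
    defined <- n >= 2L
    outlier <- rep(FALSE, n)
    if (defined) {
      mu <- colMeans(feats); sd3 <- 3 * apply(feats, 2, stats::sd)
      for (i in seq_len(n))
        outlier[i] <- any(abs(feats[i, ] - mu) > sd3 & sd3 > 0)
    }
    ssim_mean <- if (defined) {
      pairs <- utils::combn(n, 2)
      mean(apply(pairs, 2, function(p) ssim_global(imgs[[p[1]]], imgs[[p[2]]])))
    } else NA_real_
    hashes <- vapply(imgs, average_hash, character(1))
    dup <- duplicated(hashes) | duplicated(hashes, fromLast = TRUE)
    rows[[cl]] <- data.frame(class = cl, index = seq_len(n),
                             contrast = feats[, 1], correlation = feats[, 2],
                             entropy = feats[, 3], texture_outlier = outlier,
                             ssim_mean = ssim_mean, duplicate_flag = dup,
                             stats_defined = defined)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dataset summary statistics
#'
#' @param counts named or unnamed per-class counts.
#' @return list(per_class_counts, n_classes, class_probs, class_entropy)
#' @export
dataset_summary <- function(counts) {
  list(per_class_counts = counts, n_classes = length(counts),
       class_probs = counts / sum(counts),
       class_entropy = class_entropy(counts))
}
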