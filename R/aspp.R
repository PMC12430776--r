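# Sparse-enhanced atrous spatial pyramid pooling.
#
# Parallel dilated 3x3 branches plus a global-average-pooling branch are
# concatenated, normalized and rectified; a top-k spatial mask keeps only
# the most salient positions; a projected sparse spatial attention fuses the
# retained context; a squeeze-and-excitation block recalibrates channels.

#' ASPP block configuration
#'
#' @param rates dilation rates of the parallel branches (reference set
#'   1, 6, 12, 18; smaller sets suit small feature grids since a branch
#'   whose effective kernel extent `2*rate + 1` exceeds the grid is
#'   rejected).
#' @param in_channels input channels C.
#' @param branch_channels channels per branch (and for the pooling branch).
#' @param proj_dim fused embedding dimension d.
#' @param mask_rho spatial keep fraction in `(0, 1]`.
#' @param fusion_k retained positions per query in the fusion attention.
#' @param se_hidden bottleneck width of the squeeze-excitation block.
#' @export
aspp_config <- function(rates = c(1L, 6L, 12L, 18L), in_channels,
                        branch_channels = 8L, proj_dim = 16L, mask_rho = 1.0,
                        fusion_k = 8L, se_hidden = 8L) {
  stopifnot(length(rates) >= 1L, mask_rho > 0, mask_rho <= 1)
  structure(list(rates = as.integer(rates),
                 in_channels = as.integer(in_channels),
                 branch_channels = as.integer(branch_channels),
                 proj_dim = as.integer(proj_dim), mask_rho = mask_rho,
                 fusion_k = as.integer(fusion_k),
                 se_hidden = as.integer(se_hidden)),
            class = "aspp_config")
}

aspp_params <- function(cfg, prefix = "aspp", seed = 1L) {
  C <- cfg$in_channels; Cb <- cfg$branch_channels
  D <- (length(cfg$rates) + 1L) * Cb
  d <- cfg$proj_dim
  with_seed(seed, {
    p <- list()
    for (i in seq_along(cfg$rates)) {
      p[[paste0(prefix, ".Wb", i)]] <- init_xavier(9L * C, Cb)
      p[[paste0(prefix, ".bb", i)]] <- rep(0, Cb)
    }
    p[[paste0(prefix, ".Wg")]] <- init_xavier(C, Cb)
    p[[paste0(prefix, ".bg")]] <- rep(0, Cb)
    p[[paste0(prefix, ".gamma")]] <- rep(1, D)
    p[[paste0(prefix, ".beta")]] <- rep(0, D)
    p[[paste0(prefix, ".Wp")]] <- init_xavier(D, d)
    p[[paste0(prefix, ".Wq")]] <- init_xavier(d, d)
    p[[paste0(prefix, ".Wk")]] <- init_xavier(d, d)
    p[[paste0(prefix, ".Wv")]] <- init_xavier(d, d)
    p[[paste0(prefix, ".Wse1")]] <- init_xavier(d, cfg$se_hidden)
    p[[paste0(prefix, ".Wse2")]] <- init_xavier(cfg$se_hidden, d)
    p
  })
}

#' Create an ASPP block
#'
#' @param cfg an [aspp_config()].
#' @param seed initialization seed.
#' @return An `aspp_block` with the config and its parameters.
#' @export
aspp_create <- function(cfg, seed = 1L) {
  structure(list(cfg = cfg, params = aspp_params(cfg, "aspp", seed)),
            class = "aspp_block")
}

# tape forward of the branch stack; returns list of nodes
aspp_branches_node <- function(cfg, getp, prefix, x, H, W,
                               normalize = TRUE) {
  for (r in cfg$rates)
    if (min(H, W) < 2L * r + 1L)
      stop("feature grid ", H, "x", W, " smaller than the effective kernel ",
           "extent ", 2L * r + 1L, " of dilation rate ", r)
  branches <- lapply(seq_along(cfg$rates), function(i) {
    idx <- conv3_index(H, W, cfg$rates[i])
    ad_conv3(x, idx, getp(paste0(prefix, ".Wb", i)),
             getp(paste0(prefix, ".bb", i)))
  })
  gap <- ad_broadcast_row(
    ad_add_rowvec(ad_mm(ad_colmeans_row(x), getp(paste0(prefix, ".Wg"))),
                  getp(paste0(prefix, ".bg"))), H * W)
  cc <- ad_cbind(c(branches, list(gap)))
  out <- if (normalize) {
    ad_relu(ad_add_rowvec(ad_scale_cols(ad_colnorm(cc),
                                        getp(paste0(prefix, ".gamma"))),
                          getp(paste0(prefix, ".beta"))))
  } else cc
  list(branches = branches, gap = gap, concat = cc, out = out)
}

#' Run the ASPP branch stack
#'
#' Applies each dilated branch (shape-preserving zero padding) and the
#' global-average-pooling branch (1x1 projection, broadcast back), then
#' concatenates along channels and applies normalization + rectifier.
#'
#' @param F H x W x C feature array.
#' @param block an [aspp_create()] block.
#' @param normalize apply the post-concatenation normalization/rectifier.
#' @return list(concat = H x W x D array, branches = list of per-branch
#'   arrays, gap = pooled-branch array).
#' @export
aspp_branches <- function(F, block, normalize = TRUE) {
  d <- dim(F)
  ctx <- param_ctx(block$params)
  x <- ad_const(unclass(grid_to_mat(F)))
  nb <- aspp_branches_node(block$cfg, ctx$get, "aspp", x, d[1], d[2],
                           normalize = normalize)
  list(concat = mat_to_grid(nb$out$value, d[1], d[2]),
       branches = lapply(nb$branches, function(b) mat_to_grid(b$value, d[1], d[2])),
       gap = mat_to_grid(nb$gap$value, d[1], d[2]))
}

#' Top-k spatial saliency mask
#'
#' Scores each position by the channel-mean absolute activation and keeps
#' the `ceil(rho * H * W)` highest-scoring positions (ties to the lowest
#' raster index), zeroing the rest.
#'
#' @param F H x W x C feature array.
#' @param mask_rho keep fraction in `(0, 1]`.
#' @return list(masked = masked array, mask = H x W 0/1 matrix, rho =
#'   exact achieved keep ratio).
#' @export
topk_spatial_mask <- function(F, mask_rho) {
  stopifnot(mask_rho > 0, mask_rho <= 1)
  d <- dim(F)
  m <- unclass(grid_to_mat(F))
  score <- rowMeans(abs(m))
  keep_n <- as.integer(ceiling(mask_rho * length(score)))
  keep <- topk_idx(score, keep_n)
  mask_vec <- rep(0, length(score))
  mask_vec[keep] <- 1
  masked <- m * mask_vec
  list(masked = mat_to_grid(masked, d[1], d[2]),
       mask = matrix(mask_vec, d[1], d[2], byrow = TRUE),
       rho = keep_n / length(score))
}

# tape fusion: projection -> masked spatial attention -> residual -> SE
aspp_fusion_node <- function(cfg, getp, prefix, concat_node, H, W,
                             mask_vec = NULL) {
  n <- H * W
  fproj <- ad_mm(concat_node, getp(paste0(prefix, ".Wp")))
  if (!is.null(mask_vec)) fproj <- ad_mul_colvec(fproj, mask_vec)
  Q <- ad_mm(fproj, getp(paste0(prefix, ".Wq")))
  K <- ad_mm(fproj, getp(paste0(prefix, ".Wk")))
  V <- ad_mm(fproj, getp(paste0(prefix, ".Wv")))
  d <- cfg$proj_dim
  logits <- Q$value %*% t(K$value) / sqrt(d)
  k <- min(cfg$fusion_k, n)
  mask <- topk_mask_matrix(logits, k)$mask
  A <- ad_softmax_rows(ad_mul(ad_mm(Q, ad_t(K)), 1 / sqrt(d)), mask)
  attended <- ad_mm(A, V)
  fused <- ad_add(attended, fproj)            # residual from pre-fusion
  # squeeze-excitation recalibration
  z <- ad_colmeans_row(fused)
  s <- ad_sigmoid(ad_mm(ad_relu(ad_mm(z, getp(paste0(prefix, ".Wse1")))),
                        getp(paste0(prefix, ".Wse2"))))
  out <- ad_scale_cols(fused, s)
  list(out = out, attention = A, scale = s)
}

#' Sparse attention fusion of concatenated ASPP features
#'
#' Projects the concatenated features to `proj_dim` channels, computes
#' query/key/value maps, restricts each query to its top-k content-based
#' neighborhood, renormalizes within the neighborhood, aggregates values,
#' and residual-adds the projected pre-fusion features. A squeeze-and-
#' excitation block then recalibrates channels.
#'
#' @param F_concat H x W x D concatenated feature array.
#' @param block an [aspp_create()] block (supplies weights and `fusion_k`).
#' @param k optional override of the retained positions per query.
#' @return list(refined = H x W x proj_dim array, attention = (HW) x (HW)
#'   attention matrix, se_scale = per-channel gates).
#' @export
sparse_fusion <- function(F_concat, block, k = NULL) {
  d <- dim(F_concat)
  cfg <- block$cfg
  if (!is.null(k)) cfg$fusion_k <- as.integer(k)
  D <- (length(cfg$rates) + 1L) * cfg$branch_channels
  if (cfg$proj_dim > D)
    stop("projection dimension ", cfg$proj_dim,
         " exceeds concatenated channels ", D)
  ctx <- param_ctx(block$params)
  x <- ad_const(unclass(grid_to_mat(F_concat)))
  fz <- aspp_fusion_node(cfg, ctx$get, "aspp", x, d[1], d[2])
  list(refined = mat_to_grid(fz$out$value, d[1], d[2]),
       attention = fz$attention$value, se_scale = as.numeric(fz$scale$value))
}

#' Squeeze-and-excitation channel recalibration
#'
#' Per channel c: descriptor `z_c` = global average, gate
#' `s_c = sigmoid(W2 relu(W1 z))`, output channel scaled by `s_c`.
#'
#' @param F H x W x C feature array.
#' @param W1 C x hidden bottleneck matrix.
#' @param W2 hidden x C expansion matrix.
#' @return list(scaled = recalibrated array, scale = per-channel gates).
#' @export
se_recalibrate <- function(F, W1, W2) {
  d <- dim(F)
  m <- unclass(grid_to_mat(F))
  z <- matrix(colMeans(m), 1L)
  s <- as.numeric(1 / (1 + exp(-(pmax(z %*% W1, 0) %*% W2))))
  list(scaled = mat_to_grid(sweep(m, 2L, s, "*"), d[1], d[2]), scale = s)
}

#' Full ASPP forward pass
#'
#' Branch stack, top-k spatial masking, sparse fusion and recalibration.
#'
#' @param F H x W x C feature array.
#' @param block an [aspp_create()] block.
#' @return list(output = H x W x proj_dim array, mask, rho, attention).
#' @export
aspp_forward <- function(F, block) {
  d <- dim(F)
  cfg <- block$cfg
  ctx <- param_ctx(block$params)
  x <- ad_const(unclass(grid_to_mat(F)))
  nb <- aspp_branches_node(cfg, ctx$get, "aspp", x, d[1], d[2])
  msk <- topk_spatial_mask(mat_to_grid(nb$out$value, d[1], d[2]), cfg$mask_rho)
  mask_vec <- as.vector(t(msk$mask))
  fz <- aspp_fusion_node(cfg, ctx$get, "aspp", nb$out, d[1], d[2],
                         mask_vec = mask_vec)
  list(output = mat_to_grid(fz$out$value, d[1], d[2]), mask = msk$mask,
       rho = msk$rho, attention = fz$attention$value)
}
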