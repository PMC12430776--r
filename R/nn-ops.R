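# Layer plumbing shared by the attention, MoE, ASPP and decoder modules.
#
# Feature grids are stored as (H*W) x C matrices in row-major raster order:
# position p = (row - 1) * W + col, origin top-left, 0-based pixel centers.
# Convolutions are expressed as a constant row-gather (im2col) followed by a
# dense matrix product, so the autodiff tape needs no convolution-specific
# adjoint. Index maps and upsampling matrices are cached per geometry.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic package internals route through
# this so that (config, seed) fully determines outputs.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- initializers ----------------------------------------------------------

init_xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# orthogonal init via QR; rows/cols padded when non-square
init_orthogonal <- function(n_in, n_out, gain = 1) {
  n <- max(n_in, n_out)
  a <- matrix(stats::rnorm(n * n), n, n)
  q <- qr.Q(qr(a))
  gain * q[seq_len(n_in), seq_len(n_out), drop = FALSE]
}

# ---- convolution geometry --------------------------------------------------

# im2col row-index matrix for a 3x3 kernel with dilation `rate` and zero
# padding: entry [p, t] is the row in rbind(X, 0) supplying tap t for output
# position p. Row H*W + 1 is the zero-padding row.
conv3_index <- function(H, W, rate = 1L) {
  offs <- expand.grid(dy = c(-rate, 0L, rate), dx = c(-rate, 0L, rate))
  pos <- expand.grid(col = seq_len(W), row = seq_len(H))  # raster order
  idx <- matrix(0L, H * W, 9L)
  for (t in seq_len(9L)) {
    r <- pos$row + offs$dy[t]
    c <- pos$col + offs$dx[t]
    ok <- r >= 1L & r <= H & c >= 1L & c <= W
    idx[, t] <- ifelse(ok, (r - 1L) * W + c, H * W + 1L)
  }
  idx
}

# gather taps for all channels in one fused node: returns shape
# (nrow(idx)) x (T*C), tap-major blocks [tap1 ch1..C | tap2 ch1..C | ...].
# Index value n+1 refers to an implicit zero-padding row.
ad_im2col3 <- function(x, idx) {
  x <- ad_wrap(x)
  n <- nrow(x$value)
  ad_node(cpp_im2col(x$value, idx), list(x), function(g) {
    list(cpp_col2im(g, idx, n))
  })
}

# standard 3x3 convolution: weight (9*C_in) x C_out, bias length C_out
ad_conv3 <- function(x, idx, W, b) {
  ad_add_rowvec(ad_mm(ad_im2col3(x, idx), W), b)
}

# depthwise 3x3: w is a length 9*C parameter vector (tap-major, matching
# ad_im2col3 layout); followed by tap-summing selection into C channels
ad_dwconv3 <- function(x, idx, w, C) {
  col <- ad_im2col3(x, idx)                      # (HW) x 9C
  scaled <- ad_scale_cols(col, w)
  sel <- Matrix::sparseMatrix(i = seq_len(9L * C),
                              j = rep(seq_len(C), times = 9L),
                              x = 1, dims = c(9L * C, C))
  # right-multiplication by a constant selection matrix
  ad_node(as.matrix(scaled$value %*% sel), list(scaled), function(g) {
    list(as.matrix(g %*% Matrix::t(sel)))
  })
}

# ---- resampling maps -------------------------------------------------------

# bilinear interpolation matrix (Hout*Wout) x (Hin*Win), align-corners false,
# half-pixel centers, edge clamped; rows sum to 1
bilinear_matrix <- function(Hin, Win, Hout, Wout) {
  axis_w <- function(n_in, n_out) {
    # returns (n_out x n_in) 1-D interpolation weights
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    i0 <- floor(src)
    f <- src - i0
    i0c <- pmin(pmax(i0, 0), n_in - 1)
    i1c <- pmin(pmax(i0 + 1, 0), n_in - 1)
    Wm <- matrix(0, n_out, n_in)
    for (r in seq_len(n_out)) {
      Wm[r, i0c[r] + 1] <- Wm[r, i0c[r] + 1] + (1 - f[r])
      Wm[r, i1c[r] + 1] <- Wm[r, i1c[r] + 1] + f[r]
    }
    Wm
  }
  Wy <- axis_w(Hin, Hout)
  Wx <- axis_w(Win, Wout)
  # raster-order kron: out[(r-1)Wout+c] = sum Wy[r,i] Wx[c,j] in[(i-1)Win+j]
  Matrix::Matrix(kronecker(Wy, Wx), sparse = TRUE)
}

# nearest-neighbour index map (for masks)
nearest_index <- function(Hin, Win, Hout, Wout) {
  ry <- pmin(pmax(floor((seq_len(Hout) - 0.5) * Hin / Hout) + 1, 1), Hin)
  rx <- pmin(pmax(floor((seq_len(Wout) - 0.5) * Win / Wout) + 1, 1), Win)
  as.integer(outer((ry - 1) * Win, rx, "+"))
}

# ---- parameter store & optimizer -------------------------------------------

# A module's parameters live in a named list of numeric matrices/vectors.
# During a forward pass, param_ctx() hands out tape nodes lazily and records
# them so gradients can be harvested after ad_backward().
param_ctx <- function(params) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$nodes <- list()
  ctx$get <- function(name) {
    if (is.null(ctx$nodes[[name]])) {
      p <- ctx$params[[name]]
      if (is.null(p)) stop("unknown parameter: ", name)
      ctx$nodes[[name]] <- ad_node(p)
    }
    ctx$nodes[[name]]
  }
  ctx
}

param_grads <- function(ctx) {
  lapply(ctx$nodes, function(n) if (is.null(n$grad)) n$value * 0 else n$grad)
}

# decoupled-weight-decay Adam; state created on first call per parameter
adamw_init <- function() list(m = list(), v = list(), t = 0L)

adamw_step <- function(params, grads, state, lr_for, weight_decay = 1e-2,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       clip_norm = 1.0, frozen = character(0)) {
  live <- setdiff(names(grads), frozen)
  if (length(live) == 0L) return(list(params = params, state = state))
  if (is.finite(clip_norm)) {
    gn <- sqrt(sum(vapply(live, function(nm) sum(grads[[nm]]^2), numeric(1))))
    if (gn > clip_norm) for (nm in live) grads[[nm]] <- grads[[nm]] * (clip_norm / gn)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in live) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0 }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    lr <- lr_for(nm)
    params[[nm]] <- params[[nm]] - lr * (mh / (sqrt(vh) + eps) +
                                         weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# ---- shared small utilities ------------------------------------------------

# indices of the k largest entries, ties broken by lowest index, returned in
# descending-value order (radix sort is stable, so ties keep input order)
topk_idx <- function(x, k) {
  if (k < 1L || k > length(x)) stop("k out of range")
  if (k == length(x)) return(sort.list(x, decreasing = TRUE, method = "radix"))
  sort.list(x, decreasing = TRUE, method = "radix")[seq_len(k)]
}

# 0/-Inf additive mask from per-row retained index sets
mask_from_sets <- function(sets, n_rows, n_cols) {
  m <- matrix(-Inf, n_rows, n_cols)
  m[cbind(rep(seq_len(n_rows), lengths(sets)), unlist(sets))] <- 0
  m
}

# row-wise top-k over a whole matrix with one radix sort; ties go to the
# lowest column index. Returns the 0/-Inf mask and an n x k column-index
# matrix (columns ordered by descending value).
topk_mask_matrix <- function(X, k) {
  n <- nrow(X); m <- ncol(X)
  if (k >= m) {
    sets <- matrix(rep(seq_len(m), each = n), n)
    return(list(mask = NULL, sets = sets))
  }
  ord <- order(rep(seq_len(n), times = m), -as.vector(X))  # linear indices
  sel <- ord[rep((seq_len(n) - 1L) * m, each = k) + seq_len(k)]
  cols <- (sel - 1L) %/% n + 1L
  rows <- (sel - 1L) %% n + 1L  # equals rep(1:n, each = k)
  mask <- matrix(-Inf, n, m)
  mask[cbind(rows, cols)] <- 0
  sets <- matrix(cols[order(rows)], n, k, byrow = TRUE)
  list(mask = mask, sets = sets)
}

# row-wise top-k for small column counts via repeated max.col
topk_sets_small <- function(X, k) {
  n <- nrow(X)
  out <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    idx <- max.col(X, ties.method = "first")
    out[, j] <- idx
    if (j < k) X[cbind(seq_len(n), idx)] <- -Inf
  }
  out
}

as_grid <- function(x, H, W) {
  structure(x, grid_dim = c(H, W))
}

grid_dim <- function(x) attr(x, "grid_dim")
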