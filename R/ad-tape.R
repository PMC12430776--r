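# Reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is an `ad_node`: an environment holding the
# forward value, the list of parent nodes, and a closure that maps the
# incoming adjoint to per-parent adjoints. Nodes carry a monotonically
# increasing id, so reverse sweep order is simply decreasing id (parents are
# always created before children). The graph is rebuilt on every forward
# pass; nothing is retained between passes.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_node <- function(value, parents = list(), bwd = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$bwd <- bwd
  e$grad <- NULL
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  class(e) <- "ad_node"
  e
}

is_ad <- function(x) inherits(x, "ad_node")

#' @noRd
ad_const <- function(v) ad_node(v)

ad_wrap <- function(x) if (is_ad(x)) x else ad_const(x)

ad_value <- function(x) if (is_ad(x)) x$value else x

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse sweep from a scalar node. After the call every reachable node's
# $grad holds dLoss/dnode.
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  # collect reachable nodes (visited flag lives on the node itself)
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (isTRUE(nd$.visited)) next
    nd$.visited <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  for (nd in nodes) nd$.visited <- FALSE
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  loss$grad <- 1
  for (nd in nodes) {
    if (is.null(nd$grad) || is.null(nd$bwd)) next
    gs <- nd$bwd(nd$grad)
    for (i in seq_along(nd$parents)) {
      if (!is.null(gs[[i]])) ad_accum(nd$parents[[i]], gs[[i]])
    }
  }
  invisible(loss)
}

# ---- elementwise arithmetic ------------------------------------------------

ad_add <- function(x, y) {
  x <- ad_wrap(x); y <- ad_wrap(y)
  sx <- length(x$value); sy <- length(y$value)
  ad_node(x$value + y$value, list(x, y), function(g) {
    gx <- if (sx == 1L && length(g) > 1L) sum(g) else g
    gy <- if (sy == 1L && length(g) > 1L) sum(g) else g
    list(gx, gy)
  })
}

ad_sub <- function(x, y) {
  x <- ad_wrap(x); y <- ad_wrap(y)
  sx <- length(x$value); sy <- length(y$value)
  ad_node(x$value - y$value, list(x, y), function(g) {
    gx <- if (sx == 1L && length(g) > 1L) sum(g) else g
    gy <- if (sy == 1L && length(g) > 1L) sum(g) else g
    list(gx, -gy)
  })
}

ad_mul <- function(x, y) {
  x <- ad_wrap(x); y <- ad_wrap(y)
  xv <- x$value; yv <- y$value
  sx <- length(xv); sy <- length(yv)
  ad_node(xv * yv, list(x, y), function(g) {
    gx <- g * yv; gy <- g * xv
    if (sx == 1L && length(gx) > 1L) gx <- sum(gx)
    if (sy == 1L && length(gy) > 1L) gy <- sum(gy)
    list(gx, gy)
  })
}

ad_div <- function(x, y) {
  x <- ad_wrap(x); y <- ad_wrap(y)
  xv <- x$value; yv <- y$value
  sx <- length(xv); sy <- length(yv)
  ad_node(xv / yv, list(x, y), function(g) {
    gx <- g / yv; gy <- -g * xv / yv^2
    if (sx == 1L && length(gx) > 1L) gx <- sum(gx)
    if (sy == 1L && length(gy) > 1L) gy <- sum(gy)
    list(gx, gy)
  })
}

# add a length-ncol(x) row vector to every row
ad_add_rowvec <- function(x, b) {
  x <- ad_wrap(x); b <- ad_wrap(b)
  bv <- as.numeric(b$value)
  ad_node(sweep(x$value, 2L, bv, "+"), list(x, b), function(g) {
    list(g, colSums(g))
  })
}

# scale row i of x by w[i] (w length nrow(x)); column-major recycling does it
ad_mul_colvec <- function(x, w) {
  x <- ad_wrap(x); w <- ad_wrap(w)
  xv <- x$value; wv <- as.numeric(w$value)
  wd <- dim(w$value)
  ad_node(xv * wv, list(x, w), function(g) {
    gw <- rowSums(g * xv)
    if (!is.null(wd)) dim(gw) <- wd
    list(g * wv, gw)
  })
}

# scale column j of x by w[j] (w length ncol(x))
ad_scale_cols <- function(x, w) {
  x <- ad_wrap(x); w <- ad_wrap(w)
  xv <- x$value; wv <- as.numeric(w$value)
  wd <- dim(w$value)
  ad_node(sweep(xv, 2L, wv, "*"), list(x, w), function(g) {
    gw <- colSums(g * xv)
    if (!is.null(wd)) dim(gw) <- wd
    list(sweep(g, 2L, wv, "*"), gw)
  })
}

# ---- linear algebra --------------------------------------------------------

ad_mm <- function(x, y) {
  x <- ad_wrap(x); y <- ad_wrap(y)
  xv <- x$value; yv <- y$value
  ad_node(xv %*% yv, list(x, y), function(g) {
    list(g %*% t(yv), crossprod(xv, g))
  })
}

# y = S %*% x with S a constant (possibly sparse Matrix) map
ad_spmm <- function(S, x) {
  x <- ad_wrap(x)
  ad_node(as.matrix(S %*% x$value), list(x), function(g) {
    list(as.matrix(Matrix::crossprod(S, g)))
  })
}

ad_t <- function(x) {
  x <- ad_wrap(x)
  ad_node(t(x$value), list(x), function(g) list(t(g)))
}

# row gather with scatter-add adjoint; idx may repeat rows
ad_gather_rows <- function(x, idx) {
  x <- ad_wrap(x)
  n <- nrow(x$value)
  ad_node(x$value[idx, , drop = FALSE], list(x), function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, n, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, ad_wrap)
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(do.call(cbind, lapply(nodes, function(n) n$value)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_slice_cols <- function(x, cols) {
  x <- ad_wrap(x)
  nc <- ncol(x$value)
  ad_node(x$value[, cols, drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, cols] <- g
    list(out)
  })
}

# ---- nonlinearities --------------------------------------------------------

ad_relu <- function(x) {
  x <- ad_wrap(x)
  m <- x$value > 0
  ad_node(x$value * m, list(x), function(g) list(g * m))
}

ad_gelu <- function(x) {
  x <- ad_wrap(x)
  xv <- x$value
  ph <- stats::pnorm(xv)
  ad_node(xv * ph, list(x), function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

ad_sigmoid <- function(x) {
  x <- ad_wrap(x)
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ad_abs <- function(x) {
  x <- ad_wrap(x)
  sg <- sign(x$value)
  ad_node(abs(x$value), list(x), function(g) list(g * sg))
}

ad_log <- function(x, floor = 1e-12) {
  x <- ad_wrap(x)
  xv <- pmax(x$value, floor)
  ad_node(log(xv), list(x), function(g) list(g / xv))
}

# row-wise softmax with an optional additive constant mask (0 / -Inf entries)
ad_softmax_rows <- function(x, mask = NULL) {
  x <- ad_wrap(x)
  z <- x$value
  if (!is.null(mask)) z <- z + mask
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  ez <- exp(z)
  p <- ez / rowSums(ez)
  ad_node(p, list(x), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# normalize each row to sum to one (rows must have positive sums)
ad_rownorm_sum1 <- function(x) {
  x <- ad_wrap(x)
  xv <- x$value
  s <- rowSums(xv)
  y <- xv / s
  ad_node(y, list(x), function(g) {
    list((g - rowSums(g * y)) / s)
  })
}

# ---- normalization ---------------------------------------------------------

# standardize each row over its columns (token-wise layer normalization)
ad_rownorm <- function(x, eps = 1e-5) {
  x <- ad_wrap(x)
  xv <- x$value
  n <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc^2)
  s <- sqrt(v + eps)
  xh <- xc / s
  ad_node(xh, list(x), function(g) {
    gm <- rowMeans(g)
    gxh <- rowMeans(g * xh)
    list((g - gm - xh * gxh) / s)
  })
}

# standardize each column over rows (per-channel normalization over positions)
ad_colnorm <- function(x, eps = 1e-5) {
  x <- ad_wrap(x)
  xv <- x$value
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu)
  v <- colMeans(xc^2)
  s <- sqrt(v + eps)
  xh <- sweep(xc, 2L, s, "/")
  ad_node(xh, list(x), function(g) {
    gm <- colMeans(g)
    gxh <- colMeans(g * xh)
    list(sweep(sweep(g, 2L, gm) - sweep(xh, 2L, gxh, "*"), 2L, s, "/"))
  })
}

# standardize the whole matrix jointly (single-group normalization)
ad_flatnorm <- function(x, eps = 1e-5) {
  x <- ad_wrap(x)
  xv <- x$value
  mu <- mean(xv)
  xc <- xv - mu
  v <- mean(xc^2)
  s <- sqrt(v + eps)
  xh <- xc / s
  ad_node(xh, list(x), function(g) {
    gm <- mean(g)
    gxh <- mean(g * xh)
    list((g - gm - xh * gxh) / s)
  })
}

# ---- reductions ------------------------------------------------------------

ad_sum <- function(x) {
  x <- ad_wrap(x)
  d <- dim(x$value); n <- length(x$value)
  ad_node(sum(x$value), list(x), function(g) {
    out <- rep(g, n)
    if (!is.null(d)) dim(out) <- d
    list(out)
  })
}

ad_mean <- function(x) {
  x <- ad_wrap(x)
  d <- dim(x$value); n <- length(x$value)
  ad_node(mean(x$value), list(x), function(g) {
    out <- rep(g / n, n)
    if (!is.null(d)) dim(out) <- d
    list(out)
  })
}

# column means as a 1 x C row; used by pooling branches and SE squeeze
ad_colmeans_row <- function(x) {
  x <- ad_wrap(x)
  n <- nrow(x$value)
  ad_node(matrix(colMeans(x$value), 1L), list(x), function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

# broadcast a 1 x C row to n rows
ad_broadcast_row <- function(x, n) {
  x <- ad_wrap(x)
  ad_node(matrix(rep(as.numeric(x$value), each = n), n), list(x), function(g) {
    list(matrix(colSums(g), 1L))
  })
}

# binary cross-entropy of probabilities against a fixed 0/1 target, with
# probability clamping; returns the mean over entries
ad_bce <- function(p, y, clamp = 1e-7) {
  p <- ad_wrap(p)
  pv <- pmin(pmax(p$value, clamp), 1 - clamp)
  n <- length(pv)
  val <- -mean(y * log(pv) + (1 - y) * log(1 - pv))
  inside <- p$value > clamp & p$value < 1 - clamp
  ad_node(val, list(p), function(g) {
    list(g * inside * (pv - y) / (pv * (1 - pv)) / n)
  })
}
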