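# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value on the tape is a base R matrix (scalars are 1x1). A tape is an
# environment holding nodes in creation order; ad_backward() sweeps it in
# reverse, accumulating gradients. Leaves created with ad_leaf() carry a name
# under which their gradient is collected. The engine supports exactly the
# operations the attention model needs; gradients are verified against
# central finite differences in the test suite.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backfn = NULL, name = NULL) {
  # Force arguments before touching the tape: lazy evaluation would otherwise
  # let a nested ad_node() call interleave with this one and corrupt ids.
  force(value); force(parents); force(backfn); force(name)
  nd <- new.env(parent = emptyenv())
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$name <- name
  tape$nodes[[nd$id]] <- nd
  nd
}

# Trainable or constant leaf. Named leaves are the parameters whose gradients
# ad_backward() returns; unnamed leaves are constants.
ad_leaf <- function(tape, value, name = NULL) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_node(tape, value, name = name)
}

ad_value <- function(x) x$value

# Reverse sweep. Returns a named list of gradients for all named leaves.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- matrix(1, 1, 1)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$backfn)) next
    pg <- nd$backfn(g)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      gj <- pg[[j]]
      if (is.null(gj)) next
      grads[[p$id]] <- if (is.null(grads[[p$id]])) gj else grads[[p$id]] + gj
    }
  }
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$name) && !is.null(grads[[i]])) {
      out[[nd$name]] <- if (is.null(out[[nd$name]])) grads[[i]] else out[[nd$name]] + grads[[i]]
    }
  }
  out
}

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# Broadcast helper: expand `v` to shape (n x d). Supports 1x1, 1xd, nx1.
.bc_expand <- function(v, n, d) {
  dv <- dim(v)
  if (dv[1] == n && dv[2] == d) return(v)
  if (dv[1] == 1 && dv[2] == 1) return(matrix(v[1], n, d))
  if (dv[1] == 1 && dv[2] == d) return(matrix(v, n, d, byrow = TRUE))
  if (dv[1] == n && dv[2] == 1) return(matrix(v, n, d))
  stop("incompatible broadcast: ", dv[1], "x", dv[2], " to ", n, "x", d)
}

# Reduce a gradient of shape (n x d) back to the shape of the operand.
.bc_reduce <- function(g, dv) {
  if (dv[1] == nrow(g) && dv[2] == ncol(g)) return(g)
  if (dv[1] == 1 && dv[2] == 1) return(matrix(sum(g), 1, 1))
  if (dv[1] == 1) return(matrix(colSums(g), 1, dv[2]))
  if (dv[2] == 1) return(matrix(rowSums(g), dv[1], 1))
  stop("incompatible gradient reduction")
}

.bc_dims <- function(a, b) {
  c(max(nrow(a$value), nrow(b$value)), max(ncol(a$value), ncol(b$value)))
}

ad_add <- function(tape, a, b) {
  nd <- .bc_dims(a, b)
  av <- .bc_expand(a$value, nd[1], nd[2]); bv <- .bc_expand(b$value, nd[1], nd[2])
  ad_node(tape, av + bv, list(a, b), function(g) {
    list(.bc_reduce(g, dim(a$value)), .bc_reduce(g, dim(b$value)))
  })
}

ad_sub <- function(tape, a, b) {
  nd <- .bc_dims(a, b)
  av <- .bc_expand(a$value, nd[1], nd[2]); bv <- .bc_expand(b$value, nd[1], nd[2])
  ad_node(tape, av - bv, list(a, b), function(g) {
    list(.bc_reduce(g, dim(a$value)), .bc_reduce(-g, dim(b$value)))
  })
}

ad_mul <- function(tape, a, b) {
  nd <- .bc_dims(a, b)
  av <- .bc_expand(a$value, nd[1], nd[2]); bv <- .bc_expand(b$value, nd[1], nd[2])
  ad_node(tape, av * bv, list(a, b), function(g) {
    list(.bc_reduce(g * bv, dim(a$value)), .bc_reduce(g * av, dim(b$value)))
  })
}

ad_div <- function(tape, a, b) {
  nd <- .bc_dims(a, b)
  av <- .bc_expand(a$value, nd[1], nd[2]); bv <- .bc_expand(b$value, nd[1], nd[2])
  ad_node(tape, av / bv, list(a, b), function(g) {
    list(.bc_reduce(g / bv, dim(a$value)), .bc_reduce(-g * av / (bv * bv), dim(b$value)))
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(g) list(g * s))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_node(tape, v, list(a), function(g) list(g * (1 - v * v)))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

ad_relu <- function(tape, a) {
  v <- a$value
  pos <- v > 0
  v[!pos] <- 0
  ad_node(tape, v, list(a), function(g) { g[!pos] <- 0; list(g) })
}

ad_lrelu <- function(tape, a, alpha = 0.2) {
  v <- a$value
  neg <- v < 0
  v[neg] <- v[neg] * alpha
  ad_node(tape, v, list(a), function(g) { g[neg] <- g[neg] * alpha; list(g) })
}

# log(1 + exp(x)), numerically stable; used for logit-form cross-entropy.
ad_softplus <- function(tape, a) {
  x <- a$value
  v <- ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  s <- 1 / (1 + exp(-x))
  ad_node(tape, v, list(a), function(g) list(g * s))
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1, 1), list(a), function(g) {
    list(matrix(g[1], nrow(a$value), ncol(a$value)))
  })
}

ad_mean <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1, 1), list(a), function(g) {
    list(matrix(g[1] / n, nrow(a$value), ncol(a$value)))
  })
}

# Row gather: out = a[idx, ]. Backward scatters with accumulation.
ad_rows <- function(tape, a, idx) {
  idx <- as.integer(idx)
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    gz <- matrix(0, nrow(a$value), ncol(a$value))
    rs <- rowsum(g, idx)
    gz[as.integer(rownames(rs)), ] <- rs
    list(gz)
  })
}

# Column gather with repetition allowed.
ad_cols <- function(tape, a, idx) {
  idx <- as.integer(idx)
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    gz <- matrix(0, nrow(a$value), ncol(a$value))
    rs <- rowsum(t(g), idx)
    gz[, as.integer(rownames(rs))] <- t(rs)
    list(gz)
  })
}

# Segment sum over rows: out[k, ] = sum of a[i, ] with group[i] == k,
# for k in 1..ngroups (missing groups give zero rows).
ad_rowsum_by <- function(tape, a, group, ngroups) {
  group <- as.integer(group)
  out <- matrix(0, ngroups, ncol(a$value))
  rs <- rowsum(a$value, group)
  out[as.integer(rownames(rs)), ] <- rs
  ad_node(tape, out, list(a), function(g) list(g[group, , drop = FALSE]))
}

# Column-wise softmax within row segments (attention normalization).
ad_softmax_by <- function(tape, a, group, ngroups) {
  group <- as.integer(group)
  x <- a$value
  mx <- apply(x, 2, function(col) {
    m <- tapply(col, group, max)
    as.numeric(m[as.character(group)])
  })
  if (!is.matrix(mx)) mx <- matrix(mx, nrow = nrow(x))
  e <- exp(x - mx)
  den <- matrix(0, ngroups, ncol(x))
  rs <- rowsum(e, group)
  den[as.integer(rownames(rs)), ] <- rs
  v <- e / den[group, , drop = FALSE]
  ad_node(tape, v, list(a), function(g) {
    sg <- matrix(0, ngroups, ncol(x))
    rs2 <- rowsum(g * v, group)
    sg[as.integer(rownames(rs2)), ] <- rs2
    list(v * (g - sg[group, , drop = FALSE]))
  })
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, ad_value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_rbind <- function(tape, nodes) {
  vals <- lapply(nodes, ad_value)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_node(tape, do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

# Dropout with a fixed mask drawn by the caller (so seeding is explicit).
ad_dropout <- function(tape, a, mask) {
  ad_node(tape, a$value * mask, list(a), function(g) list(g * mask))
}

# Row-wise layer normalization with learnable gain/bias (1 x d each).
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  s <- sqrt(va + eps)
  y <- xc / s
  gv <- .bc_expand(gamma$value, nrow(x), d)
  out <- y * gv + .bc_expand(beta$value, nrow(x), d)
  ad_node(tape, out, list(a, gamma, beta), function(g) {
    gh <- g * gv
    m1 <- rowMeans(gh)
    m2 <- rowMeans(gh * y)
    dx <- (gh - m1 - y * m2) / s
    list(dx,
         matrix(colSums(g * y), 1, d),
         matrix(colSums(g), 1, d))
  })
}

# Column-wise (feature) batch normalization using batch statistics.
ad_batchnorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  n <- nrow(x); d <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  va <- colMeans(xc * xc)
  s <- sqrt(va + eps)
  y <- sweep(xc, 2, s, "/")
  gv <- .bc_expand(gamma$value, n, d)
  out <- y * gv + .bc_expand(beta$value, n, d)
  ad_node(tape, out, list(a, gamma, beta), function(g) {
    gh <- g * gv
    c1 <- colMeans(gh)
    c2 <- colMeans(gh * y)
    dx <- sweep(sweep(gh, 2, c1) - y * matrix(c2, n, d, byrow = TRUE), 2, s, "/")
    list(dx,
         matrix(colSums(g * y), 1, d),
         matrix(colSums(g), 1, d))
  })
}

# Adam optimizer over a named list of parameter matrices, with per-parameter
# learning-rate groups and optional weight decay (L2, skipped per group).
adam_new <- function(params, lr, betas = c(0.9, 0.999), eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$lr <- lr         # named numeric: learning rate per parameter name
  st$betas <- betas
  st$eps <- eps
  st
}

adam_step <- function(st, params, grads, weight_decay = 0, decay_skip = character(0)) {
  st$t <- st$t + 1L
  b1 <- st$betas[1]; b2 <- st$betas[2]
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && !(nm %in% decay_skip)) {
      g <- g + weight_decay * params[[nm]]
    }
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - st$lr[[nm]] * mhat / (sqrt(vhat) + st$eps)
  }
  params
}
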