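# Reverse-mode automatic differentiation on a flat tape of matrix ops.
#
# The trainable parts of the model (gated attention, class heads, graph
# message passing) are small dense networks, so a minimal tape with exact
# gradients is all that is needed.  Nodes are environments holding a value,
# an accumulated gradient and a backward closure; creation order is a valid
# topological order, so backward() is a single reverse sweep.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_push <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd$idx <- tape$n
  nd
}

#' Wrap a constant or parameter matrix as a tape leaf
#'
#' Leaves have no backward closure; after [ad_backward()] their `grad`
#' field holds the gradient of the sweep's output with respect to them.
#'
#' @param tape a tape from `ad_tape()`
#' @param val numeric matrix (vectors are promoted to 1-row matrices)
#' @return a tape node
#' @keywords internal
ad_leaf <- function(tape, val) {
  if (!is.matrix(val)) val <- matrix(val, nrow = 1L)
  ad_push(tape, val)
}

ad_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run the backward sweep from an output node
#' @param out scalar (1x1) output node
#' @keywords internal
ad_backward <- function(out) {
  tape <- out$tape
  out$grad <- array(1, dim(out$val))
  for (i in seq(out$idx, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
  }
  invisible(NULL)
}

ad_matmul <- function(a, b) {
  ad_push(a$tape, a$val %*% b$val, list(a, b), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad %*% t(nd$parents[[2L]]$val))
    ad_acc(nd$parents[[2L]], t(nd$parents[[1L]]$val) %*% nd$grad)
  })
}

# a n x k, b either same shape or a 1 x k row broadcast over rows of a
ad_add <- function(a, b) {
  av <- a$val; bv <- b$val
  broadcast <- nrow(bv) == 1L && nrow(av) > 1L
  val <- if (broadcast) sweep(av, 2L, bv, "+") else av + bv
  ad_push(a$tape, val, list(a, b), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad)
    g <- nd$grad
    if (nrow(nd$parents[[2L]]$val) == 1L && nrow(g) > 1L)
      g <- matrix(colSums(g), 1L)
    ad_acc(nd$parents[[2L]], g)
  })
}

ad_sub <- function(a, b) {
  ad_push(a$tape, a$val - b$val, list(a, b), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad)
    ad_acc(nd$parents[[2L]], -nd$grad)
  })
}

ad_mul <- function(a, b) {
  ad_push(a$tape, a$val * b$val, list(a, b), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$val)
    ad_acc(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$val)
  })
}

# multiply/add by a plain numeric constant (scalar or conformable array)
ad_cmul <- function(a, k) {
  ad_push(a$tape, a$val * k, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * k)
  })
}

ad_cadd <- function(a, k) {
  ad_push(a$tape, a$val + k, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad)
  })
}

# scale row i of a by constant s[i] (degree scalers, isolated-node masks)
ad_rowscale <- function(a, s) {
  ad_push(a$tape, a$val * s, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * s)
  })
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$val))
  nd <- ad_push(a$tape, y, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * nd$val * (1 - nd$val))
  })
  nd
}

ad_tanh <- function(a) {
  y <- tanh(a$val)
  ad_push(a$tape, y, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * (1 - nd$val^2))
  })
}

ad_relu <- function(a) {
  y <- pmax(a$val, 0)
  ad_push(a$tape, y, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * (nd$parents[[1L]]$val > 0))
  })
}

ad_exp <- function(a) {
  ad_push(a$tape, exp(a$val), list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * nd$val)
  })
}

ad_log <- function(a) {
  ad_push(a$tape, log(a$val), list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad / nd$parents[[1L]]$val)
  })
}

ad_sqrt <- function(a) {
  y <- sqrt(a$val)
  ad_push(a$tape, y, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad / (2 * nd$val))
  })
}

# sqrt clamped at zero: value sqrt(max(x, 0)); the gradient is routed
# only where the output exceeds `tol` (subgradient 0 at the clamp), so a
# zero-variance standard deviation stays exactly 0.
ad_sqrt0 <- function(a, tol = 1e-12) {
  y <- sqrt(pmax(a$val, 0))
  ad_push(a$tape, y, list(a), function(nd) {
    g <- ifelse(nd$val > tol, nd$grad / (2 * nd$val), 0)
    ad_acc(nd$parents[[1L]], g)
  })
}

ad_square <- function(a) {
  ad_push(a$tape, a$val^2, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * 2 * nd$parents[[1L]]$val)
  })
}

ad_recip <- function(a) {
  ad_push(a$tape, 1 / a$val, list(a), function(nd) {
    ad_acc(nd$parents[[1L]], -nd$grad / nd$parents[[1L]]$val^2)
  })
}

ad_t <- function(a) {
  ad_push(a$tape, t(a$val), list(a), function(nd) {
    ad_acc(nd$parents[[1L]], t(nd$grad))
  })
}

# row-wise softmax (numerically stabilised)
ad_softmax_rows <- function(a) {
  z <- a$val - apply(a$val, 1L, max)
  e <- exp(z)
  y <- e / rowSums(e)
  ad_push(a$tape, y, list(a), function(nd) {
    y <- nd$val; g <- nd$grad
    ad_acc(nd$parents[[1L]], (g - rowSums(g * y)) * y)
  })
}

ad_logsoftmax_rows <- function(a) {
  z <- a$val - apply(a$val, 1L, max)
  lse <- log(rowSums(exp(z)))
  y <- z - lse
  ad_push(a$tape, y, list(a), function(nd) {
    g <- nd$grad
    ad_acc(nd$parents[[1L]], g - exp(nd$val) * rowSums(g))
  })
}

ad_sum <- function(a) {
  ad_push(a$tape, matrix(sum(a$val), 1L, 1L), list(a), function(nd) {
    ad_acc(nd$parents[[1L]], array(nd$grad[1L], dim(nd$parents[[1L]]$val)))
  })
}

ad_mean <- function(a) {
  n <- length(a$val)
  ad_push(a$tape, matrix(mean(a$val), 1L, 1L), list(a), function(nd) {
    ad_acc(nd$parents[[1L]], array(nd$grad[1L] / n, dim(nd$parents[[1L]]$val)))
  })
}

# column means -> 1 x k (global mean pooling over rows)
ad_mean_rows <- function(a) {
  n <- nrow(a$val)
  ad_push(a$tape, matrix(colMeans(a$val), 1L), list(a), function(nd) {
    ad_acc(nd$parents[[1L]],
           matrix(rep(nd$grad / n, each = n), n))
  })
}

ad_rows <- function(a, idx) {
  ad_push(a$tape, a$val[idx, , drop = FALSE], list(a), function(nd) {
    g <- array(0, dim(nd$parents[[1L]]$val))
    for (k in seq_along(idx)) g[idx[k], ] <- g[idx[k], ] + nd$grad[k, ]
    ad_acc(nd$parents[[1L]], g)
  })
}

ad_cols <- function(a, idx) {
  ad_push(a$tape, a$val[, idx, drop = FALSE], list(a), function(nd) {
    g <- array(0, dim(nd$parents[[1L]]$val))
    g[, idx] <- nd$grad
    ad_acc(nd$parents[[1L]], g)
  })
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(nd) nd$val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_push(nodes[[1L]]$tape, do.call(cbind, vals), nodes, function(nd) {
    for (k in seq_along(nd$parents))
      ad_acc(nd$parents[[k]],
             nd$grad[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_pick <- function(a, i, j) {
  ad_push(a$tape, matrix(a$val[i, j], 1L, 1L), list(a), function(nd) {
    g <- array(0, dim(nd$parents[[1L]]$val))
    g[i, j] <- nd$grad[1L]
    ad_acc(nd$parents[[1L]], g)
  })
}

# Per-row neighbourhood mean: out[i, ] = colMeans(a[groups[[i]], ]).
# Empty groups give a zero row.
ad_group_mean <- function(a, groups) {
  r <- length(groups); k <- ncol(a$val)
  y <- matrix(0, r, k)
  for (i in seq_len(r)) {
    gi <- groups[[i]]
    if (length(gi))
      y[i, ] <- colMeans(a$val[gi, , drop = FALSE])
  }
  ad_push(a$tape, y, list(a), function(nd) {
    g <- array(0, dim(nd$parents[[1L]]$val))
    for (i in seq_len(r)) {
      gi <- groups[[i]]
      if (length(gi))
        g[gi, ] <- g[gi, ] + matrix(rep(nd$grad[i, ] / length(gi),
                                        each = length(gi)), length(gi))
    }
    ad_acc(nd$parents[[1L]], g)
  })
}

# Per-row neighbourhood max or min with argmax routing of the gradient.
ad_group_extreme <- function(a, groups, which = c("max", "min")) {
  which <- match.arg(which)
  f <- if (which == "max") max.col else function(m, ties.method) max.col(-m, ties.method)
  r <- length(groups); k <- ncol(a$val)
  y <- matrix(0, r, k)
  arg <- matrix(NA_integer_, r, k)
  for (i in seq_len(r)) {
    gi <- groups[[i]]
    if (length(gi)) {
      sub <- a$val[gi, , drop = FALSE]
      pos <- f(t(sub), ties.method = "first")
      arg[i, ] <- gi[pos]
      y[i, ] <- sub[cbind(pos, seq_len(k))]
    }
  }
  ad_push(a$tape, y, list(a), function(nd) {
    g <- array(0, dim(nd$parents[[1L]]$val))
    for (i in seq_len(r)) {
      if (is.na(arg[i, 1L])) next
      ix <- cbind(arg[i, ], seq_len(k))
      g[ix] <- g[ix] + nd$grad[i, ]
    }
    ad_acc(nd$parents[[1L]], g)
  })
}

#' Adam optimiser state for a named list of parameter matrices
#' @keywords internal
adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))),
       t = 0L)
}

# Adam with decoupled weight decay (AdamW-style; decay 0 recovers Adam)
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * ((state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps) +
            weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
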