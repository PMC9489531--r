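# Minimal tape-based reverse-mode automatic differentiation over matrices.
# Internal machinery for training the perception and dynamics networks; the
# op set is exactly what those models need.  Nodes are integer ids into a
# growing tape; values are numeric matrices.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- vector("list", 256L)
  tp$parents <- vector("list", 256L)
  tp$back <- vector("list", 256L)
  tp
}

ad_push <- function(tp, val, parents = integer(0), back = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * n
    length(tp$parents) <- 2L * n
    length(tp$back) <- 2L * n
  }
  tp$vals[[n]] <- val
  tp$parents[[n]] <- parents
  tp$back[[n]] <- back
  tp$n <- n
  n
}

ad_input <- function(tp, x) ad_push(tp, as.matrix(x))
ad_value <- function(tp, id) tp$vals[[id]]

ad_matmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A %*% B, c(a, b), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b), function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b), function(g) list(g, -g))
}

ad_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

# add a bias row vector (length ncol) to every row
ad_bias <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; bv <- as.numeric(tp$vals[[b]])
  ad_push(tp, A + rep(bv, each = nrow(A)), c(a, b), function(g) {
    list(g, matrix(colSums(g), nrow = 1))
  })
}

ad_scale <- function(tp, a, k) {
  force(a)
  ad_push(tp, tp$vals[[a]] * k, a, function(g) list(g * k))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-tp$vals[[a]]))
  ad_push(tp, y, a, function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(tp, a) {
  force(a)
  y <- tanh(tp$vals[[a]])
  ad_push(tp, y, a, function(g) list(g * (1 - y^2)))
}

ad_exp <- function(tp, a) {
  force(a)
  y <- exp(tp$vals[[a]])
  ad_push(tp, y, a, function(g) list(g * y))
}

ad_relu <- function(tp, a) {
  force(a)
  x <- tp$vals[[a]]
  y <- x; y[y < 0] <- 0
  ad_push(tp, y, a, function(g) list(g * (x > 0)))
}

ad_elu <- function(tp, a) {
  force(a)
  x <- tp$vals[[a]]
  y <- ifelse(x > 0, x, exp(pmin(x, 30)) - 1)
  ad_push(tp, y, a, function(g) list(g * ifelse(x > 0, 1, y + 1)))
}

# exact GELU: x * Phi(x)
ad_gelu <- function(tp, a) {
  force(a)
  x <- tp$vals[[a]]
  Phi <- stats::pnorm(x)
  ad_push(tp, x * Phi, a, function(g) {
    list(g * (Phi + x * stats::dnorm(x)))
  })
}

ad_cbind <- function(tp, ids) {
  ids <- vapply(ids, identity, integer(1))
  vals <- lapply(ids, function(i) tp$vals[[i]])
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_push(tp, do.call(cbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_rbind <- function(tp, ids) {
  ids <- vapply(ids, identity, integer(1))
  vals <- lapply(ids, function(i) tp$vals[[i]])
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_push(tp, do.call(rbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# select rows (with repetition allowed); backward scatter-adds
ad_rows <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A)
  ad_push(tp, A[idx, , drop = FALSE], a, function(g) {
    out <- matrix(0, nr, ncol(A))
    agg <- rowsum(g, group = idx)
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

ad_cols <- function(tp, a, jdx) {
  force(a)
  A <- tp$vals[[a]]
  nc <- ncol(A)
  ad_push(tp, A[, jdx, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(A), nc)
    for (j in seq_along(jdx)) out[, jdx[j]] <- out[, jdx[j]] + g[, j]
    list(out)
  })
}

ad_sum <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  ad_push(tp, matrix(sum(A), 1, 1), a, function(g) {
    list(matrix(g[1, 1], nrow(A), ncol(A)))
  })
}

# sum rows by group -> ngroup x ncol
ad_group_sum <- function(tp, a, groups, ngroup) {
  force(a)
  A <- tp$vals[[a]]
  out <- rowsum(A, group = groups)
  full <- matrix(0, ngroup, ncol(A))
  full[as.integer(rownames(out)), ] <- out
  ad_push(tp, full, a, function(g) list(g[groups, , drop = FALSE]))
}

# columnwise max within groups; ties broken by first occurrence
ad_group_max <- function(tp, a, groups, ngroup) {
  force(a)
  A <- tp$vals[[a]]
  nc <- ncol(A)
  out <- matrix(-Inf, ngroup, nc)
  argrow <- matrix(0L, ngroup, nc)
  for (r in seq_len(nrow(A))) {
    gset <- groups[r]
    better <- A[r, ] > out[gset, ]
    if (any(better)) {
      out[gset, better] <- A[r, better]
      argrow[gset, better] <- r
    }
  }
  ad_push(tp, out, a, function(g) {
    gr <- matrix(0, nrow(A), nc)
    for (j in seq_len(nc)) {
      rows <- argrow[, j]
      ok <- rows > 0L
      gr[cbind(rows[ok], j)] <- gr[cbind(rows[ok], j)] + g[ok, j]
    }
    list(gr)
  })
}

# binary cross-entropy from logits against a constant target, summed
ad_bce_logits <- function(tp, a, target) {
  force(a)
  x <- tp$vals[[a]]
  val <- sum(pmax(x, 0) - x * target + log1p(exp(-abs(x))))
  ad_push(tp, matrix(val, 1, 1), a, function(g) {
    list(g[1, 1] * (1 / (1 + exp(-x)) - target))
  })
}

#' @noRd
ad_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- matrix(1, 1, 1)
  for (i in seq.int(loss_id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ps <- tp$parents[[i]]
    if (!length(ps)) next
    pg <- tp$back[[i]](g)
    for (j in seq_along(ps)) {
      p <- ps[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# ---- parameter plumbing ----------------------------------------------------

# register a flat named list of matrices on a tape; returns list of node ids
ad_params <- function(tp, params) {
  lapply(params, function(p) ad_input(tp, p))
}

# extract gradients for registered params after backward
ad_param_grads <- function(grads, ids, params) {
  out <- params
  for (nm in names(ids)) {
    g <- grads[[ids[[nm]]]]
    out[[nm]] <- if (is.null(g)) params[[nm]] * 0 else g
  }
  out
}

# one RMSProp update; state holds the running squared-gradient cache
rmsprop_update <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  if (is.null(state)) state <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * grads[[nm]] / sqrt(state[[nm]] + eps)
  }
  list(params = params, state = state)
}
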