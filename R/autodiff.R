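# Minimal reverse-mode automatic differentiation on a linear tape. Every node
# holds a dense value (matrix or array), its parent nodes and a backward
# closure mapping the output gradient to parent gradients. Node creation order
# is a topological order, so the backward sweep is a single reverse pass.
# This is the differentiation substrate for the encoder/decoder/reward/
# predictor networks; all training-path operations are expressed with these
# primitives so gradients flow end-to-end without any argmax.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$params <- list()
  tp
}

ad_node <- function(tp, value, parents = NULL, back = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$back <- back
  nd$grad <- NULL
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  nd$id <- tp$n
  tp$nodes[[tp$n]] <- nd
  nd
}

ad_const <- function(tp, value) ad_node(tp, value)

ad_param <- function(tp, name, value) {
  nd <- ad_node(tp, value)
  nd$param_name <- name
  tp$params[[name]] <- nd
  nd
}

.acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

# Backward sweep from a scalar (1x1) loss node.
ad_backward <- function(tp, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (k in seq(loss$id, 1L)) {
    nd <- tp$nodes[[k]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$back)) next
    gs <- nd$back(nd$grad, nd)
    for (i in seq_along(nd$parents)) {
      if (!is.null(gs[[i]])) .acc_grad(nd$parents[[i]], gs[[i]])
    }
  }
  invisible(NULL)
}

# Named list of gradients for all parameters on the tape (zero if unused).
ad_grads <- function(tp) {
  out <- list()
  for (nm in names(tp$params)) {
    nd <- tp$params[[nm]]
    out[[nm]] <- if (is.null(nd$grad)) array(0, dim = dim(nd$value)) else nd$grad
  }
  out
}

# ---- elementwise and linear-algebra primitives -----------------------------

ad_add <- function(a, b, tp) ad_node(tp, a$value + b$value, list(a, b),
  function(g, nd) list(g, g))

ad_sub <- function(a, b, tp) ad_node(tp, a$value - b$value, list(a, b),
  function(g, nd) list(g, -g))

ad_mul <- function(a, b, tp) ad_node(tp, a$value * b$value, list(a, b),
  function(g, nd) list(g * nd$parents[[2]]$value, g * nd$parents[[1]]$value))

ad_scale <- function(a, s, tp) ad_node(tp, a$value * s, list(a),
  function(g, nd) list(g * s))

ad_matmul <- function(a, b, tp) ad_node(tp, a$value %*% b$value, list(a, b),
  function(g, nd) list(g %*% t(nd$parents[[2]]$value),
                       crossprod(nd$parents[[1]]$value, g)))

ad_add_bias <- function(a, bias, tp) {
  n <- nrow(a$value)
  ad_node(tp, a$value + matrix(bias$value, n, ncol(a$value), byrow = TRUE),
          list(a, bias),
          function(g, nd) list(g, matrix(colSums(g), 1)))
}

ad_sigmoid <- function(a, tp) {
  v <- 1 / (1 + exp(-a$value))
  nd <- ad_node(tp, v, list(a), function(g, nd) list(g * nd$value * (1 - nd$value)))
  nd
}

ad_tanh <- function(a, tp) {
  v <- tanh(a$value)
  ad_node(tp, v, list(a), function(g, nd) list(g * (1 - nd$value^2)))
}

ad_exp <- function(a, tp) {
  v <- exp(a$value)
  ad_node(tp, v, list(a), function(g, nd) list(g * nd$value))
}

ad_log <- function(a, tp) ad_node(tp, log(a$value), list(a),
  function(g, nd) list(g / nd$parents[[1]]$value))

ad_leaky_relu <- function(a, tp, alpha = 0.01) {
  x <- a$value
  pos <- x > 0
  ad_node(tp, x * (pos + alpha * !pos), list(a),
          function(g, nd) {
            pp <- nd$parents[[1]]$value > 0
            list(g * (pp + alpha * !pp))
          })
}

ad_clamp <- function(a, lo, hi, tp) {
  x <- a$value
  ad_node(tp, pmin(pmax(x, lo), hi), list(a),
          function(g, nd) {
            xx <- nd$parents[[1]]$value
            list(g * ((xx > lo) & (xx < hi)))
          })
}

ad_sum <- function(a, tp) ad_node(tp, matrix(sum(a$value), 1, 1), list(a),
  function(g, nd) {
    v <- nd$parents[[1]]$value
    list(array(as.numeric(g), dim = if (is.null(dim(v))) length(v) else dim(v)))
  })

# Row-wise softmax: each row of the input is one categorical block.
ad_softmax_rows <- function(a, tp) {
  x <- a$value
  rmax <- x[, 1]
  for (c in seq_len(ncol(x))[-1]) rmax <- pmax(rmax, x[, c])
  e <- exp(x - rmax)
  p <- e / rowSums(e)
  ad_node(tp, p, list(a),
          function(g, nd) {
            pp <- nd$value
            list(pp * (g - rowSums(g * pp)))
          })
}

ad_concat_cols <- function(nodes, tp) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tp, do.call(cbind, vals), nodes,
          function(g, nd) {
            lapply(seq_along(widths), function(i) g[, starts[i]:ends[i], drop = FALSE])
          })
}

ad_slice_cols <- function(a, idx, tp) {
  ad_node(tp, a$value[, idx, drop = FALSE], list(a),
          function(g, nd) {
            out <- matrix(0, nrow(nd$parents[[1]]$value), ncol(nd$parents[[1]]$value))
            out[, idx] <- g
            list(out)
          })
}

# B x (k*p)  ->  (B*k) x p, rows grouped example-major (example 1 block 1..k,
# example 2 block 1..k, ...). Inverse shape transform in the backward pass.
ad_blocks_to_rows <- function(a, k, p, tp) {
  ad_node(tp, matrix(as.vector(t(a$value)), ncol = p, byrow = TRUE), list(a),
          function(g, nd) list(matrix(as.vector(t(g)), ncol = k * p, byrow = TRUE)))
}

# (B*k) x d  ->  B x d by summing each example's contiguous k rows.
ad_pool_sum <- function(a, B, k, tp) {
  v <- a$value
  ad_node(tp, colSums(array(v, dim = c(k, B, ncol(v))), dims = 1), list(a),
          function(g, nd) list(g[rep(seq_len(B), each = k), , drop = FALSE]))
}

# Scale each row of a by the matching entry of column vector v (n x 1).
ad_mul_colvec <- function(a, v, tp) {
  ad_node(tp, a$value * as.vector(v$value), list(a, v),
          function(g, nd) list(g * as.vector(nd$parents[[2]]$value),
                               matrix(rowSums(g * nd$parents[[1]]$value), ncol = 1)))
}

# Directed edge index table for a batch of B padded graphs: every unordered
# pair (i, j) contributes both directions, so each node sends and receives
# exactly m - 1 messages. Message passing and the count profiles are
# gather/scatter operations over this table; the fixed degree lets grouped
# sums be computed as a reshape + colSums instead of hashed aggregation.
edge_indices <- function(B, m, pairs) {
  np <- nrow(pairs)
  off_n <- rep((seq_len(B) - 1L) * m, each = np)
  off_p <- rep((seq_len(B) - 1L) * np, each = np)
  i <- rep(pairs[, 1], B) + off_n
  j <- rep(pairs[, 2], B) + off_n
  pid <- rep(seq_len(np), B) + off_p
  list(src = as.integer(c(i, j)), dst = as.integer(c(j, i)),
       pid = as.integer(c(pid, pid)),
       B = B, m = m, np = np)
}

# Edge-weighted message aggregation: out[d, ] = sum over directed edges
# (s -> d) of E[pair(s,d), channel] * X[s, ]. X is (B*m) x h, E is
# (B*np) x q. Forward and backward are compiled scatter/dot kernels.
ad_edge_message <- function(X, E, channel, idx, tp) {
  n_nodes <- idx$B * idx$m
  half <- idx$B * idx$np
  w <- E$value[idx$pid, channel]
  M <- edge_scatter(X$value, w, idx$src, idx$dst, n_nodes)
  ad_node(tp, M, list(X, E),
          function(g, nd) {
            Xv <- nd$parents[[1]]$value
            Ev <- nd$parents[[2]]$value
            ww <- Ev[idx$pid, channel]
            dX <- edge_scatter(g, ww, idx$dst, idx$src, n_nodes)
            dE <- matrix(0, nrow(Ev), ncol(Ev))
            v <- edge_dot(g, Xv, idx$dst, idx$src)
            dE[, channel] <- v[seq_len(half)] + v[half + seq_len(half)]
            list(dX, dE)
          })
}

ad_concat_rows <- function(nodes, tp) {
  vals <- lapply(nodes, function(n) n$value)
  hts <- vapply(vals, nrow, integer(1))
  ends <- cumsum(hts)
  starts <- ends - hts + 1L
  ad_node(tp, do.call(rbind, vals), nodes,
          function(g, nd) {
            lapply(seq_along(hts), function(i) g[starts[i]:ends[i], , drop = FALSE])
          })
}

ad_slice_rows <- function(a, idx, tp) {
  ad_node(tp, a$value[idx, , drop = FALSE], list(a),
          function(g, nd) {
            out <- matrix(0, nrow(nd$parents[[1]]$value), ncol(nd$parents[[1]]$value))
            out[idx, ] <- g
            list(out)
          })
}

# Per-example outer pooling: for each example g, t(V_g) %*% M_g flattened
# column-major into row g of a B x (ncol(V) * ncol(M)) matrix.
ad_pool_outer <- function(V, M, B, m, tp) {
  vv <- V$value; mv <- M$value
  out <- matrix(0, B, ncol(vv) * ncol(mv))
  for (g in seq_len(B)) {
    idx <- ((g - 1L) * m + 1L):(g * m)
    out[g, ] <- as.vector(crossprod(vv[idx, , drop = FALSE], mv[idx, , drop = FALSE]))
  }
  ad_node(tp, out, list(V, M),
          function(gr, nd) {
            vvv <- nd$parents[[1]]$value; mvv <- nd$parents[[2]]$value
            dV <- matrix(0, nrow(vvv), ncol(vvv))
            dM <- matrix(0, nrow(mvv), ncol(mvv))
            for (g in seq_len(B)) {
              idx <- ((g - 1L) * m + 1L):(g * m)
              D <- matrix(gr[g, ], ncol(vvv), ncol(mvv))
              dV[idx, ] <- mvv[idx, , drop = FALSE] %*% t(D)
              dM[idx, ] <- vvv[idx, , drop = FALSE] %*% D
            }
            list(dV, dM)
          })
}

# Fused three-channel message aggregation (one tape node): the per-bond-type
# transformed states X1, X2, X3 are mixed by their edge-type probabilities and
# scattered to the receiving nodes in a single kernel pass.
ad_edge_message3 <- function(X1, X2, X3, E, channels, idx, tp) {
  n_nodes <- idx$B * idx$m
  half <- idx$B * idx$np
  M <- edge_scatter3(X1$value, X2$value, X3$value, E$value, channels,
                     idx$src, idx$dst, idx$pid, n_nodes)
  ad_node(tp, M, list(X1, X2, X3, E),
          function(g, nd) {
            bw <- edge_scatter3_backward(g, nd$parents[[1]]$value,
                                         nd$parents[[2]]$value,
                                         nd$parents[[3]]$value,
                                         nd$parents[[4]]$value,
                                         channels, idx$src, idx$dst, idx$pid)
            dE <- matrix(0, nrow(nd$parents[[4]]$value), ncol(nd$parents[[4]]$value))
            sel <- seq_len(half)
            dE[, channels[1]] <- bw$v1[sel] + bw$v1[half + sel]
            dE[, channels[2]] <- bw$v2[sel] + bw$v2[half + sel]
            dE[, channels[3]] <- bw$v3[sel] + bw$v3[half + sel]
            list(bw$d1, bw$d2, bw$d3, dE)
          })
}

# Fused GRU-style state update (one tape node): given messages M and node
# states H, computes H' = (1-z) o H + z o tanh(M Wh + (r o H) Uh + bh) with
# update gate z = sigmoid(M Wz + H Uz + bz) and reset gate
# r = sigmoid(M Wr + H Ur + br). Parents: M, H, Wz, Uz, Wr, Ur, Wh, Uh,
# bz, br, bh.
ad_gru <- function(M, H, Wz, Uz, Wr, Ur, Wh, Uh, bz, br, bh, tp) {
  Mv <- M$value; Hv <- H$value
  n <- nrow(Mv); h <- ncol(Hv)
  brow <- function(b) matrix(b$value, n, h, byrow = TRUE)
  z <- 1 / (1 + exp(-(Mv %*% Wz$value + Hv %*% Uz$value + brow(bz))))
  r <- 1 / (1 + exp(-(Mv %*% Wr$value + Hv %*% Ur$value + brow(br))))
  rH <- r * Hv
  tt <- tanh(Mv %*% Wh$value + rH %*% Uh$value + brow(bh))
  Hn <- (1 - z) * Hv + z * tt
  nd <- ad_node(tp, Hn, list(M, H, Wz, Uz, Wr, Ur, Wh, Uh, bz, br, bh),
                function(g, nd) {
                  e <- nd$cache
                  zz <- e$z; rr <- e$r; ttt <- e$tt; rHh <- e$rH
                  Mvv <- nd$parents[[1]]$value; Hvv <- nd$parents[[2]]$value
                  dz <- g * (ttt - Hvv)
                  dH <- g * (1 - zz)
                  dah <- (g * zz) * (1 - ttt^2)
                  dM <- dah %*% t(nd$parents[[7]]$value)
                  drH <- dah %*% t(nd$parents[[8]]$value)
                  dH <- dH + drH * rr
                  dar <- (drH * Hvv) * rr * (1 - rr)
                  dM <- dM + dar %*% t(nd$parents[[5]]$value)
                  dH <- dH + dar %*% t(nd$parents[[6]]$value)
                  daz <- dz * zz * (1 - zz)
                  dM <- dM + daz %*% t(nd$parents[[3]]$value)
                  dH <- dH + daz %*% t(nd$parents[[4]]$value)
                  list(dM, dH,
                       crossprod(Mvv, daz), crossprod(Hvv, daz),
                       crossprod(Mvv, dar), crossprod(Hvv, dar),
                       crossprod(Mvv, dah), crossprod(rHh, dah),
                       matrix(colSums(daz), 1), matrix(colSums(dar), 1),
                       matrix(colSums(dah), 1))
                })
  nd$cache <- list(z = z, r = r, tt = tt, rH = rH)
  nd
}

# ---- parameter initialization and RMSProp ----------------------------------

glorot_matrix <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros_row <- function(d) matrix(0, 1, d)

# RMSProp with global-norm gradient clipping over the selected parameters.
rmsprop_step <- function(params, grads, state, names_sel, lr,
                         rho = 0.9, eps = 1e-8, clip = 10) {
  gn <- sqrt(sum(vapply(names_sel, function(nm) sum(grads[[nm]]^2), numeric(1))))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  for (nm in names_sel) {
    if (is.null(state[[nm]])) state[[nm]] <- matrix(0, nrow(params[[nm]]), ncol(params[[nm]]))
    up <- rmsprop_update(params[[nm]], grads[[nm]], state[[nm]],
                         lr, rho, eps, scale)
    params[[nm]] <- up$param
    state[[nm]] <- up$state
  }
  list(params = params, state = state)
}
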