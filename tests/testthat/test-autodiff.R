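# Finite-difference verification of the reverse-mode primitives, and
# equivalence of the compiled kernels with naive R references.

fd_check <- function(build, xs, tol = 1e-5, eps = 1e-6) {
  # build: function(list of constant matrices wrapped as nodes, tape) -> node
  tp <- ad_tape()
  nodes <- lapply(seq_along(xs), function(i) ad_param(tp, paste0("x", i), xs[[i]]))
  out <- build(nodes, tp)
  loss <- ad_sum(ad_mul(out, out, tp), tp)  # sum of squares -> scalar
  ad_backward(tp, loss)
  gr <- ad_grads(tp)
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    for (k in sample(length(x), min(4, length(x)))) {
      up <- xs; up[[i]][k] <- up[[i]][k] + eps
      dn <- xs; dn[[i]][k] <- dn[[i]][k] - eps
      f <- function(vals) {
        tp2 <- ad_tape()
        nd <- lapply(vals, function(v) ad_const(tp2, v))
        o <- build(nd, tp2)
        sum(o$value^2)
      }
      fd <- (f(up) - f(dn)) / (2 * eps)
      an <- gr[[paste0("x", i)]][k]
      expect_lt(abs(an - fd), tol * max(1, abs(an) + abs(fd)))
    }
  }
}

test_that("linear-algebra and activation primitives differentiate correctly", {
  set.seed(21)
  A <- matrix(rnorm(12), 3, 4); B <- matrix(rnorm(20), 4, 5)
  fd_check(function(n, tp) ad_matmul(n[[1]], n[[2]], tp), list(A, B))
  fd_check(function(n, tp) ad_add_bias(n[[1]], n[[2]], tp),
           list(A, matrix(rnorm(4), 1, 4)))
  fd_check(function(n, tp) ad_sigmoid(n[[1]], tp), list(A))
  fd_check(function(n, tp) ad_tanh(n[[1]], tp), list(A))
  fd_check(function(n, tp) ad_leaky_relu(n[[1]], tp), list(A), tol = 1e-5)
  fd_check(function(n, tp) ad_exp(n[[1]], tp), list(A))
  fd_check(function(n, tp) ad_log(n[[1]], tp), list(abs(A) + 1))
  fd_check(function(n, tp) ad_softmax_rows(n[[1]], tp), list(A))
  fd_check(function(n, tp) ad_clamp(n[[1]], -0.5, 0.5, tp), list(A))
  fd_check(function(n, tp) ad_mul(n[[1]], n[[2]], tp),
           list(A, matrix(rnorm(12), 3, 4)))
})

test_that("shape and pooling primitives differentiate correctly", {
  set.seed(22)
  X <- matrix(rnorm(24), 6, 4)
  fd_check(function(n, tp) ad_blocks_to_rows(n[[1]], 2, 4, tp),
           list(matrix(rnorm(16), 2, 8)))
  fd_check(function(n, tp) ad_pool_sum(n[[1]], 2, 3, tp), list(X))
  fd_check(function(n, tp) ad_slice_cols(n[[1]], 2:3, tp), list(X))
  fd_check(function(n, tp) ad_slice_rows(n[[1]], c(1, 4), tp), list(X))
  fd_check(function(n, tp) ad_concat_cols(n, tp), list(X, matrix(rnorm(12), 6, 2)))
  fd_check(function(n, tp) ad_concat_rows(n, tp), list(X, matrix(rnorm(8), 2, 4)))
  fd_check(function(n, tp) ad_mul_colvec(n[[1]], n[[2]], tp),
           list(X, matrix(rnorm(6), 6, 1)))
  fd_check(function(n, tp) ad_pool_outer(n[[1]], n[[2]], 2, 3, tp),
           list(X, matrix(rnorm(18), 6, 3)))
})

test_that("edge message ops differentiate and match a dense reference", {
  set.seed(23)
  B <- 2; m <- 4
  pairs <- pair_index(m)
  idx <- edge_indices(B, m, pairs)
  X <- matrix(rnorm(B * m * 3), B * m, 3)
  E <- matrix(runif(B * nrow(pairs) * 4), B * nrow(pairs), 4)
  fd_check(function(n, tp) ad_edge_message(n[[1]], n[[2]], 2, idx, tp), list(X, E))
  fd_check(function(n, tp) ad_edge_message3(n[[1]], n[[2]], n[[3]], n[[4]],
                                            c(1L, 2L, 3L), idx, tp),
           list(X, matrix(rnorm(B * m * 3), B * m, 3),
                matrix(rnorm(B * m * 3), B * m, 3), E))
  # dense reference: M[d,] = sum_s A[d,s] X[s,] per graph
  tp <- ad_tape()
  M <- ad_edge_message(ad_const(tp, X), ad_const(tp, E), 2, idx, tp)$value
  ref <- matrix(0, B * m, 3)
  for (g in 1:B) {
    A <- matrix(0, m, m)
    for (k in seq_len(nrow(pairs))) {
      w <- E[(g - 1) * nrow(pairs) + k, 2]
      A[pairs[k, 1], pairs[k, 2]] <- w
      A[pairs[k, 2], pairs[k, 1]] <- w
    }
    rows <- (g - 1) * m + 1:m
    ref[rows, ] <- A %*% X[rows, ]
  }
  expect_equal(M, ref)
})

test_that("the fused GRU node differentiates correctly", {
  set.seed(24)
  n <- 5; h <- 3
  mats <- c(list(matrix(rnorm(n * h), n, h), matrix(rnorm(n * h), n, h)),
            replicate(6, matrix(rnorm(h * h) / 2, h, h), simplify = FALSE),
            replicate(3, matrix(rnorm(h) / 2, 1, h), simplify = FALSE))
  fd_check(function(nd, tp) do.call(ad_gru, c(nd, list(tp))), mats, tol = 1e-5)
})

test_that("rmsprop kernel matches the arithmetic definition", {
  set.seed(25)
  p <- matrix(rnorm(20), 4, 5); g <- matrix(rnorm(20), 4, 5)
  v <- matrix(abs(rnorm(20)), 4, 5)
  up <- rmsprop_update(p, g, v, lr = 1e-2, rho = 0.9, eps = 1e-8, scale = 0.5)
  gs <- g * 0.5
  v2 <- 0.9 * v + 0.1 * gs^2
  expect_equal(up$state, v2)
  expect_equal(up$param, p - 1e-2 * gs / (sqrt(v2) + 1e-8))
})

test_that("backward accumulates gradients over shared subexpressions", {
  tp <- ad_tape()
  x <- ad_param(tp, "x", matrix(2, 1, 1))
  y <- ad_add(ad_mul(x, x, tp), x, tp)  # x^2 + x -> d/dx = 2x + 1 = 5
  ad_backward(tp, ad_sum(y, tp))
  expect_equal(as.numeric(ad_grads(tp)$x), 5)
})
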