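# Measurement matrix, truncated SVD and respiratory-component selection.

random_model <- function(seed, M = 60L, N = 40L, r = 5L) {
  # A synthetic lowrank_model with exact orthonormal factors.
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(M * r), M, r)))
  V <- qr.Q(qr(matrix(rnorm(N * r), N, r)))
  S <- sort(abs(rnorm(r, sd = 10)), decreasing = TRUE)
  structure(list(left_vectors = U, singular_values = S, right_vectors = V,
                 scaled_right = sweep(V, 2, S, `*`), rank = r,
                 sv_full = S, tr_s = 1.15),
            class = "lowrank_model")
}

test_that("measurement matrix is the exact reshape and scatters back", {
  d <- c(10L, 9L, 6L)
  mask <- ellipsoid_mask(d, semi = c(4, 3, 2))
  set.seed(31)
  nt <- 7L
  v <- array(0, c(d, nt))
  m4 <- array(mask, c(d, nt))
  v[m4] <- rnorm(sum(m4))
  fs <- field_volume_series(v, mask, "harmonic")
  P <- build_measurement_matrix(fs, mask, tr_s = 1.15)
  expect_identical(dim(P$values), c(sum(mask), nt))
  back <- scatter_to_series(P$values, mask)
  expect_equal(back$values, fs$values)
  # single-voxel mask: 1 x N row equals that voxel's time course
  m1 <- array(FALSE, d); m1[5, 5, 3] <- TRUE
  P1 <- build_measurement_matrix(v, brain_mask(m1), 1.15)
  expect_equal(as.numeric(P1$values), v[5, 5, 3, ])
})

test_that("rank-1 input has one singular value and exact reconstruction", {
  set.seed(41)
  u <- rnorm(30); u <- u / sqrt(sum(u^2))
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  mod <- truncated_svd(outer(u, v), rank = 5, tr_s = 1)
  expect_equal(mod$singular_values[1], 1, tolerance = 1e-12)
  expect_lt(max(mod$singular_values[-1]), 1e-12)
  expect_error(truncated_svd(outer(u, v), rank = 13), "rank")
})

test_that("truncation satisfies Eckart-Young against an eigendecomposition oracle", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    P <- matrix(rnorm(200 * 60), 200, 60)
    mod <- truncated_svd(P, rank = 5, tr_s = 1)
    # independent oracle: singular values squared are eigenvalues of P'P
    lam <- sort(eigen(crossprod(P), symmetric = TRUE,
                      only.values = TRUE)$values, decreasing = TRUE)
    PL <- mod$left_vectors %*% (mod$singular_values * t(mod$right_vectors))
    err2 <- sum((P - PL)^2)
    expect_equal(err2, sum(lam[-(1:5)]), tolerance = 1e-10)
    expect_equal(sum(mod$sv_full^2), sum(P^2), tolerance = 1e-10)
    expect_equal(mod$sv_full^2, lam, tolerance = 1e-8)
  }
})

test_that("SVD factors are orthonormal and scaled_right carries the spectrum", {
  set.seed(7)
  P <- matrix(rnorm(80 * 30), 80, 30)
  mod <- truncated_svd(P, rank = 5, tr_s = 1)
  expect_equal(crossprod(mod$left_vectors), diag(5), tolerance = 1e-8)
  expect_equal(crossprod(mod$right_vectors), diag(5), tolerance = 1e-8)
  expect_equal(sqrt(colSums(mod$scaled_right^2)), mod$singular_values,
               tolerance = 1e-10)
  expect_true(all(diff(mod$singular_values) <= 1e-12))
})

test_that("a lone varying component is selected among constants", {
  N <- 50L
  V <- cbind(rep(1, N), rep(1, N), sin(2 * pi * 0.3 * (0:(N - 1)) * 1.15),
             rep(1, N), rep(1, N))
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  S <- c(50, 20, 10, 5, 2)
  mod <- structure(list(left_vectors = matrix(1 / sqrt(10), 10, 5),
                        singular_values = S, right_vectors = V,
                        scaled_right = sweep(V, 2, S, `*`), rank = 5L,
                        sv_full = S, tr_s = 1.15),
                   class = "lowrank_model")
  comp <- select_respiratory_component(mod)
  expect_identical(comp$index, 3L)
  expect_true(comp$sign_fixed)
})

test_that("selection matches the direct L1-derivative score oracle", {
  set.seed(55)
  N <- 60L
  t <- (0:(N - 1)) * 1.15
  V <- cbind(10 * t / max(t),                       # slow drift, amp 10
             2 * sin(2 * pi * 0.3 * t),             # respiration-like
             0.5 * rnorm(N),                        # white noise
             rep(1, N), rep(2, N))                  # constants
  mod <- structure(list(left_vectors = matrix(1 / sqrt(8), 8, 5),
                        singular_values = rep(1, 5), right_vectors = V,
                        scaled_right = V, rank = 5L, sv_full = rep(1, 5),
                        tr_s = 1.15),
                   class = "lowrank_model")
  oracle <- apply(V, 2, function(col) sum(abs(diff(col)))) / 1.15
  comp <- select_respiratory_component(mod)
  expect_identical(comp$index, which.max(oracle))
  expect_equal(comp$scores, oracle)
})

test_that("selection is invariant to column sign flips and reordering", {
  for (seed in 1:10) {
    mod <- random_model(seed)
    base <- select_respiratory_component(mod)
    # sign flips
    flip <- sample(c(-1, 1), mod$rank, replace = TRUE)
    m2 <- mod
    m2$scaled_right <- sweep(mod$scaled_right, 2, flip, `*`)
    m2$right_vectors <- sweep(mod$right_vectors, 2, flip, `*`)
    m2$left_vectors <- sweep(mod$left_vectors, 2, flip, `*`)
    expect_identical(select_respiratory_component(m2)$index, base$index)
    # reordering
    perm <- sample(mod$rank)
    m3 <- mod
    m3$scaled_right <- mod$scaled_right[, perm]
    m3$right_vectors <- mod$right_vectors[, perm]
    m3$left_vectors <- mod$left_vectors[, perm]
    m3$singular_values <- mod$singular_values[perm]
    expect_identical(perm[select_respiratory_component(m3)$index],
                     base$index)
  }
})

test_that("selected component trace matches scaled_right up to global sign", {
  mod <- random_model(77)
  comp <- select_respiratory_component(mod)
  col <- mod$scaled_right[, comp$index]
  expect_true(isTRUE(all.equal(comp$temporal_trace, col)) ||
              isTRUE(all.equal(comp$temporal_trace, -col)))
  expect_gte(mean(comp$spatial_map), 0)
})

test_that("component field series is rank-1 with Frobenius norm sigma_r", {
  d <- c(8L, 8L, 6L)
  mask <- ellipsoid_mask(d, semi = c(3, 3, 2))
  M <- sum(mask)
  mod <- random_model(88, M = M, N = 20L)
  comp <- select_respiratory_component(mod)
  fs <- component_field_series(mod, comp, mask)
  P <- build_measurement_matrix(fs, mask, 1.15)$values
  # all pairwise column cross products consistent with rank 1
  G <- crossprod(P)
  expect_equal(G, outer(comp$temporal_trace, comp$temporal_trace),
               tolerance = 1e-10)
  expect_equal(sqrt(sum(P^2)), mod$singular_values[comp$index],
               tolerance = 1e-10)
  # zero temporal trace gives a zero series
  comp0 <- comp; comp0$temporal_trace <- comp$temporal_trace * 0
  fs0 <- component_field_series(mod, comp0, mask)
  expect_true(all(fs0$values == 0))
  compx <- comp; compx$index <- 9L
  expect_error(component_field_series(mod, compx, mask), "out of range")
})

test_that("derivative needs at least two timepoints", {
  mod <- random_model(5)
  mod$scaled_right <- mod$scaled_right[1, , drop = FALSE]
  expect_error(select_respiratory_component(mod), "at least 2")
})
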