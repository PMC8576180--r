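make_random_field <- function(n = 60, ns = 2, seed = 5) {
  set.seed(seed)
  coords <- matrix(runif(3 * n, 0, 50), n, 3)
  u <- array(rnorm(n * 3 * ns), c(n, 3, ns))
  probe_field(coords, u)
}

test_that("probe field validates its inputs", {
  f <- make_random_field()
  expect_equal(dim(f$u), c(60L, 3L, 2L))
  coords <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(probe_field(coords, array(0, c(2, 3, 1))), "duplicate")
  expect_error(probe_field(matrix(0, 2, 3), array(0, c(3, 3, 1))),
               "row counts")
})

test_that("kNN prediction behaves at its exact and degenerate limits", {
  f <- make_random_field(n = 5)
  # k = probe count: every query averages all probes
  mod_all <- fit_interpolator(f, k = 5L)
  pred <- predict(mod_all, rbind(c(10, 10, 10), c(40, 0, 3)), stage = 1)
  expect_equal(pred[1, ], colMeans(f$u[, , 1]), tolerance = 1e-12)
  expect_equal(pred[2, ], colMeans(f$u[, , 1]), tolerance = 1e-12)

  # exact hit with k = 1 returns that probe's displacement
  mod1 <- fit_interpolator(f, k = 1L)
  expect_equal(as.numeric(predict(mod1, f$coords[3, , drop = FALSE], 1)),
               f$u[3, , 1], tolerance = 1e-14)

  # spatially constant field predicts the constant everywhere
  fc <- probe_field(f$coords, array(rep(c(1, 2, 3), each = 5), c(5, 3, 1)))
  modc <- fit_interpolator(fc, k = 3L)
  expect_equal(predict(modc, matrix(runif(9, 0, 50), 3, 3), 1),
               matrix(rep(c(1, 2, 3), each = 3), 3, 3), tolerance = 1e-14)

  expect_error(fit_interpolator(f, k = 6L), "probe count")
  expect_error(predict(mod1, f$coords, stage = 99), "unknown stage")
})

test_that("neighbor sets match a brute-force all-pairs search", {
  set.seed(8)
  ref <- matrix(runif(3 * 800, 0, 100), 800, 3)
  q <- matrix(runif(3 * 40, 0, 100), 40, 3)
  idx <- pulmem:::knn_cpp(ref, q, 5L)
  for (i in seq_len(nrow(q))) {
    d <- sqrt(colSums((t(ref) - q[i, ])^2))
    expect_identical(sort(idx[i, ]), sort(order(d)[1:5]))
  }
})

test_that("prediction of a linear field obeys the neighborhood Lipschitz bound", {
  set.seed(12)
  n <- 2000
  coords <- matrix(runif(3 * n, 0, 100), n, 3)
  A <- matrix(c(0.02, 0.01, 0, -0.01, 0.03, 0.005, 0, 0.01, 0.02), 3, 3)
  u <- coords %*% t(A)
  f <- probe_field(coords, array(u, c(n, 3, 1)))
  mod <- fit_interpolator(f, k = 5L)
  q <- matrix(runif(3 * 50, 10, 90), 50, 3)
  pred <- predict(mod, q, 1)
  truth <- q %*% t(A)
  nb <- pulmem:::knn_cpp(coords, q, 5L)
  opA <- svd(A)$d[1]
  for (i in 1:50) {
    r5 <- max(sqrt(colSums((t(coords[nb[i, ], ]) - q[i, ])^2)))
    expect_lte(sqrt(sum((pred[i, ] - truth[i, ])^2)), opA * r5 + 1e-12)
  }
})

test_that("prediction is invariant under probe reordering", {
  f <- make_random_field(n = 80, seed = 21)
  set.seed(3)
  perm <- sample(80)
  f2 <- probe_field(f$coords[perm, ], f$u[perm, , , drop = FALSE])
  q <- matrix(runif(15, 0, 50), 5, 3)
  p1 <- predict(fit_interpolator(f, 5L), q, 1)
  p2 <- predict(fit_interpolator(f2, 5L), q, 1)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("cross-validation scores smooth fields high and noise near zero", {
  # smooth synthetic displacement field sampled densely
  set.seed(7)
  n <- 1500
  coords <- matrix(runif(3 * n, 0, 100), n, 3)
  u_smooth <- array(0, c(n, 3, 2))
  for (s in 1:2) {
    u_smooth[, 1, s] <- s * sin(coords[, 1] / 30) * cos(coords[, 2] / 40)
    u_smooth[, 2, s] <- s * coords[, 3] / 50
    u_smooth[, 3, s] <- s * cos(coords[, 1] / 25)
  }
  cv <- cross_validate(probe_field(coords, u_smooth), folds = 10L, k = 5L,
                       seed = 1L)
  expect_gt(cv$mean_accuracy, 0.95)

  # pure i.i.d. noise carries no spatial structure
  u_noise <- array(rnorm(n * 6), c(n, 3, 2))
  cvn <- cross_validate(probe_field(coords, u_noise), folds = 10L, k = 5L,
                        seed = 1L)
  expect_lt(cvn$mean_accuracy, 0.2)

  # seeded determinism
  cv2 <- cross_validate(probe_field(coords, u_smooth), folds = 10L, k = 5L,
                        seed = 1L)
  expect_identical(cv$scores, cv2$scores)

  # accuracy decreases monotonically with added noise
  accs <- vapply(c(0, 0.05, 0.2), function(sd_) {
    set.seed(99)
    un <- u_smooth + array(rnorm(length(u_smooth), sd = sd_),
                           dim(u_smooth))
    cross_validate(probe_field(coords, un), folds = 5L, k = 5L,
                   seed = 2L)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) < 0))

  # zero-variance component is excluded with a warning
  u0 <- u_smooth
  u0[, 2, ] <- 0
  w <- capture_warnings(cv0 <- cross_validate(probe_field(coords, u0),
                                              folds = 5L, k = 5L, seed = 1L))
  expect_true(all(grepl("zero-variance", w)))
  expect_true(all(is.na(cv0$scores[, 2])))
  expect_false(is.na(cv0$mean_accuracy))
})

test_that("training-set kNN predictions with k = 1 are exact", {
  f <- make_random_field(n = 40, seed = 10)
  mod <- fit_interpolator(f, k = 1L)
  expect_equal(predict(mod, f$coords, 1), f$u[, , 1], tolerance = 1e-14)
})

test_that("probe CSV round trips and rejects malformed files", {
  f <- make_random_field(n = 25, ns = 3)
  tmp <- tempfile(fileext = ".csv")
  write_probe_csv(f, tmp)
  f2 <- read_probe_csv(tmp)
  expect_lt(max(abs(f2$coords - f$coords)), 1e-9)
  expect_lt(max(abs(f2$u - f$u)), 1e-9)

  empty <- tempfile(fileext = ".csv")
  writeLines("probe_id,x,y,z,stage,ux,uy,uz", empty)
  expect_error(read_probe_csv(empty), "empty")
  writeLines(c("a,b", "1,2"), empty)
  expect_error(read_probe_csv(empty), "columns")
})

test_that("the sparse interpolation operator reproduces predict()", {
  f <- make_random_field(n = 100, seed = 30)
  q <- matrix(runif(30, 0, 50), 10, 3)
  W <- interpolation_matrix(f$coords, q, k = 5L)
  expect_equal(dim(W), c(10L, 100L))
  expect_equal(Matrix::rowSums(W), rep(1, 10), tolerance = 1e-14,
               ignore_attr = TRUE)
  pred_mat <- as.matrix(W %*% f$u[, , 1])
  expect_equal(pred_mat, predict(fit_interpolator(f, 5L), q, 1),
               tolerance = 1e-12)
  # expanded operator acts on stacked per-node (x, y, z) vectors
  W3 <- expand_operator(W)
  uv <- as.numeric(t(f$u[, , 1]))
  expect_equal(matrix(as.numeric(W3 %*% uv), ncol = 3, byrow = TRUE),
               pred_mat, tolerance = 1e-12)
  tmp <- tempfile(fileext = ".csv")
  write_operator_triplets(W, tmp)
  tri <- read.csv(tmp)
  expect_equal(nrow(tri), 50L)
  expect_true(all(tri$value == 0.2))
})

test_that("a full-size probe field (7000 x 5 stages) parses quickly", {
  set.seed(44)
  coords <- matrix(runif(21000, 0, 300), 7000, 3)
  u <- array(rnorm(7000 * 15), c(7000, 3, 5))
  f <- probe_field(coords, u)
  tmp <- tempfile(fileext = ".csv")
  write_probe_csv(f, tmp)
  t0 <- proc.time()
  f2 <- read_probe_csv(tmp)
  expect_lt((proc.time() - t0)[["elapsed"]], 5)
  expect_equal(dim(f2$u), c(7000L, 3L, 5L))
  expect_lt(max(abs(f2$u - f$u)), 1e-9)
})
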