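test_that("the objective matches a naive loop-based recomputation", {
  # single probe, single stage, residual (3, 4, 0): the un-normalized sum of
  # squares is 25, so Pi * normalizer = 12.5
  u_exp <- array(c(1, 2, 3), c(1, 3, 1))
  spec <- objective_spec(u_exp)
  res <- objective(c(1), function(p) array(c(4, 6, 3), c(1, 3, 1)), spec)
  expect_equal(res$Pi * spec$normalizer, 12.5)
  expect_equal(res$rho, 0)

  # random case vs an explicit double loop
  set.seed(14)
  u_exp <- array(rnorm(30 * 3 * 5), c(30, 3, 5))
  u_sim <- u_exp + array(rnorm(450, sd = 0.3), c(30, 3, 5))
  spec <- objective_spec(u_exp)
  got <- objective(c(1), function(p) u_sim, spec)
  acc <- 0
  for (s in 1:5) for (i in 1:30) for (c in 1:3)
    acc <- acc + (u_sim[i, c, s] - u_exp[i, c, s])^2
  expect_equal(got$Pi, 0.5 * acc / spec$normalizer, tolerance = 1e-12)

  # perfect fit gives exactly zero
  expect_equal(objective(c(1), function(p) u_exp, spec)$Pi, 0)
  # forward failure propagates as NA with a warning
  expect_warning(bad <- objective(c(1), function(p) stop("boom"), spec))
  expect_true(is.na(bad$Pi))
})

test_that("displacement error metrics match hand values and a loop oracle", {
  u <- array(rnorm(60), c(10, 3, 2))
  expect_equal(mean_error_mm(u, u)$mean_mm, 0)
  off <- u
  off[, 2, ] <- off[, 2, ] + 2
  expect_equal(mean_error_mm(off, u)$mean_mm, 2, tolerance = 1e-12)
  set.seed(5)
  v <- u + array(rnorm(60, sd = 0.5), dim(u))
  got <- mean_error_mm(v, u)
  acc <- 0
  for (s in 1:2) for (i in 1:10)
    acc <- acc + sqrt(sum((v[i, , s] - u[i, , s])^2))
  expect_equal(got$mean_mm, acc / 20, tolerance = 1e-12)
  expect_equal(got$percent_by_component[["ux"]],
               100 * mean(abs(v[, 1, ] - u[, 1, ])) / max(abs(u[, 1, ])),
               tolerance = 1e-12)
})

test_that("finite-difference gradients are exact on quadratics and count evaluations", {
  set.seed(2)
  p <- rnorm(6)
  g <- fd_gradient(p, function(x) sum(x^2) / 2, rel_step = 1e-7)
  expect_equal(as.numeric(g), p, tolerance = 1e-8)
  expect_identical(attr(g, "n_evals"), 12L)

  # the heterogeneous fine-mesh problem size: 914 parameters cost 1828
  # evaluations per central-difference gradient
  p914 <- rnorm(914)
  g914 <- fd_gradient(p914, function(x) sum(x^2) / 2)
  expect_identical(attr(g914, "n_evals"), 1828L)
  expect_error(fd_gradient(p, function(x) 0, rel_step = 0), "underflow")
})

test_that("adjoint gradient is stationary at a perfect fit and matches FD", {
  sc <- hetero_scenario()
  mesh <- sc$mesh
  m <- nrow(mesh$triangles)
  W <- interpolation_matrix(mesh$nodes, sc$data$probes$coords, k = 5L)
  pressures <- pressure_at(sc$profile, sc$profile$stage_times)
  truth <- flatten_params(sc$field)

  # u_exp generated by the same forward model: gradient vanishes at truth
  g0 <- adjoint_gradient(truth, mesh, sc$data$probes$u, W, pressures,
                         boundary = sc$data$boundary)
  expect_identical(attr(g0, "solve_count"), 2L)
  expect_lt(max(abs(g0)), 1e-10)
  expect_equal(attr(g0, "Pi"), 0, tolerance = 1e-12)

  # agreement with central differences at a random interior point
  bounds <- default_bounds("hetero_iso_linear", m)
  set.seed(17)
  p0 <- runif(2 * m, bounds$lower, bounds$upper)
  frames <- compute_local_frames(mesh)
  ga <- adjoint_gradient(p0, mesh, sc$data$probes$u, W, pressures,
                         boundary = sc$data$boundary, frames = frames)
  gf <- fd_gradient(p0, function(p)
    attr(adjoint_gradient(p, mesh, sc$data$probes$u, W, pressures,
                          boundary = sc$data$boundary, frames = frames),
         "Pi"),
    rel_step = 1e-6, bounds = bounds)
  expect_lt(max(abs(ga - gf)) / max(abs(gf)), 1e-5)

  # regularization contributes its exact analytic gradient
  gr <- adjoint_gradient(truth, mesh, sc$data$probes$u, W, pressures,
                         boundary = sc$data$boundary, alpha = 1e-6,
                         bounds = bounds)
  pt <- (truth - bounds$lower) / (bounds$upper - bounds$lower)
  expect_equal(as.numeric(gr),
               1e-6 * (pt - 0.5) / (bounds$upper - bounds$lower),
               tolerance = 1e-6)
})

test_that("the particle swarm converges on the sphere function with clamped bounds", {
  cfg <- swarm_config(24L, var_min = c(-5, -5), var_max = c(5, 5), seed = 7L,
                      max_iter = 200L, stall_iters = 60L)
  visited <- new.env(parent = emptyenv())
  visited$bad <- FALSE
  fit <- pso_minimize(function(x) {
    if (any(x < -5 - 1e-12) || any(x > 5 + 1e-12)) visited$bad <- TRUE
    sum(x^2)
  }, cfg)
  expect_false(visited$bad)
  expect_lt(sqrt(sum(fit$par^2)), 1e-3)
  expect_lte(fit$iterations, 200L)
  # inertia schedule: 1.0 multiplied by 0.99 after each iteration
  expect_equal(fit$w_history[2], 0.99)
  expect_equal(fit$w_history[3], 0.9801)
  # global best is non-increasing by construction
  expect_true(all(diff(fit$history) <= 0))

  # seeded reproducibility
  fit2 <- pso_minimize(function(x) sum(x^2), cfg)
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$history, fit2$history)

  # failed evaluations are penalized, not fatal
  w <- capture_warnings(
    fitf <- pso_minimize(function(x) if (x[1] > 0) sum(x^2) else NA_real_,
                         swarm_config(10L, var_min = c(-5, -5),
                                      var_max = c(5, 5), seed = 1L,
                                      max_iter = 30L)))
  expect_true(all(grepl("penalized", w)))
  expect_true(is.finite(fitf$value))
  expect_error(pso_minimize(function(x) NA_real_,
                            swarm_config(4L, var_min = -1, var_max = 1,
                                         seed = 1L)),
               "all particles failed")
})

test_that("calibration is seeded, bound-respecting, and recovers a small scenario", {
  sc <- small_scenario()
  truth <- flatten_params(sc$field)
  fit1 <- suppressWarnings(
    calibrate("homo_iso_hyper", sc$mesh, sc$data$probes, sc$profile,
              n_starts = 2L, seed = 5L))
  fit2 <- suppressWarnings(
    calibrate("homo_iso_hyper", sc$mesh, sc$data$probes, sc$profile,
              n_starts = 2L, seed = 5L))
  expect_identical(fit1$par, fit2$par)
  expect_identical(fit1$per_start$objective, fit2$per_start$objective)
  expect_equal(nrow(fit1$per_start), 2L)
  bounds <- default_bounds("homo_iso_hyper")
  expect_true(all(fit1$par >= bounds$lower & fit1$par <= bounds$upper))
  expect_lt(max(abs(fit1$par - truth) / truth), 0.02)
  expect_lt(fit1$mean_error_mm, 1e-6)
})

test_that("PSO calibration recovers the homogeneous parameters", {
  sc <- small_scenario()
  truth <- flatten_params(sc$field)
  fit <- suppressWarnings(
    calibrate("homo_iso_hyper", sc$mesh, sc$data$probes, sc$profile,
              method = "pso", seed = 2L,
              pso = list(n_pop = 16L, max_iter = 60L, stall_iters = 25L)))
  expect_equal(fit$algorithm, "PSO")
  # a desk-scale swarm localizes the displacement response; the full-budget
  # swarm sizes of the study conditions are exercised by pso_minimize above
  bounds <- default_bounds("homo_iso_hyper")
  expect_true(all(fit$par >= bounds$lower & fit$par <= bounds$upper))
  expect_lt(fit$mean_error_mm, 0.5)
  expect_true(all(diff(fit$history) <= 0))
})
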