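test_that("pressure profiles validate and interpolate", {
  p <- pressure_profile(c(0, 1, 2), c(0, 1.5, 2.5))
  expect_equal(p$stage_times, c(0.4, 0.8, 1.2, 1.6, 2.0))
  expect_equal(pressure_at(p, 0.5), 0.75)
  expect_error(pressure_profile(c(0, 0, 1), c(0, 1, 2)), "increasing")
  expect_error(pressure_profile(c(0, 1), c(0, -1)), "non-negative")
  expect_error(pressure_profile(c(0, 1), c(0, 1), stage_times = 2), "span")
  expect_equal(cmh2o_to_kpa(1), 0.0980665)
})

test_that("residual vanishes at the unloaded reference state", {
  cap <- generate_cap_mesh(60, seed = 2)
  fld <- make_ground_truth_field(cap, "homo_iso_hyper")
  a <- assemble(cap, fld, matrix(0, nrow(cap$nodes), 3), pressure = 0)
  # roundoff floor of the assembled internal force is O(stiffness x 1e-16)
  expect_lt(max(abs(a$residual)), 1e-6)
  expect_lt(abs(a$energy), 1e-8)
})

test_that("assembled tangent matches a finite-difference Jacobian", {
  cap <- generate_cap_mesh(20, seed = 6)
  fld <- make_ground_truth_field(cap, "homo_iso_hyper")
  n <- nrow(cap$nodes)
  set.seed(6)
  u <- matrix(rnorm(3 * n, sd = 0.2), n, 3)
  a <- assemble(cap, fld, u, pressure = 1.0)
  K <- as.matrix(a$tangent)
  uv <- as.numeric(t(u))
  h <- 1e-5
  for (d in sample(3 * n, 8)) {
    up <- uv; up[d] <- up[d] + h
    um <- uv; um[d] <- um[d] - h
    col <- (assemble(cap, fld, up, 1.0, want_tangent = FALSE)$residual -
            assemble(cap, fld, um, 1.0, want_tangent = FALSE)$residual) / (2 * h)
    expect_lt(max(abs(K[, d] - col)) / max(abs(K[, d]), 1), 2e-5)
  }
})

test_that("linear tangent equals an independent dense assembly on a patch", {
  # two-element flat patch in the xy-plane
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1.5, 0), c(0, 1.5, 0))
  tris <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  mesh <- surface_mesh(nodes, tris, thickness = 1.3)
  E <- c(120, 340); nu <- c(0.3, 0.42)
  fld <- material_field("hetero_iso_linear", E = E, nu = nu, n_elements = 2L)
  K <- as.matrix(assemble(mesh, fld, matrix(0, 4, 3), pressure = 0)$tangent)

  # textbook CST plane-stress stiffness, assembled independently
  K_ref <- matrix(0, 12, 12)
  for (e in 1:2) {
    id <- tris[e, ]
    x <- nodes[id, 1]; y <- nodes[id, 2]
    A <- 0.5 * abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1]))
    b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2]) / (2 * A)
    c_ <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / (2 * A)
    B <- matrix(0, 3, 6)
    for (a_ in 1:3) {
      B[1, 2 * a_ - 1] <- b[a_]
      B[2, 2 * a_] <- c_[a_]
      B[3, 2 * a_ - 1] <- c_[a_]
      B[3, 2 * a_] <- b[a_]
    }
    Dm <- linear_plane_stress_matrix(linear_elastic(E[e], nu[e]))
    Ke <- A * mesh$thickness * t(B) %*% Dm %*% B
    dofs <- as.vector(rbind(3 * id - 2, 3 * id - 1))
    K_ref[dofs, dofs] <- K_ref[dofs, dofs] + Ke
  }
  # in-plane block of the assembled tangent must match; z rows/cols are zero
  inplane <- sort(c(seq(1, 12, 3), seq(2, 12, 3)))
  expect_lt(max(abs(K[inplane, inplane] - K_ref[inplane, inplane])), 1e-9)
  expect_lt(max(abs(K[seq(3, 12, 3), ])), 1e-9)
})

test_that("null load gives the null solution and linear scaling holds", {
  cap <- generate_cap_mesh(60, seed = 2)
  fld <- make_ground_truth_field(cap, "homo_iso_hyper")
  sol <- solve_stage(cap, fld, pressure = 0)
  expect_true(sol$converged)
  expect_lt(max(abs(sol$u)), 1e-12)

  # heterogeneous linear case: doubling E halves u; scaling (E, f) -> (cE, cf)
  # leaves u unchanged
  hcap <- generate_cap_mesh(40, seed = 1)
  m <- nrow(hcap$triangles)
  f1 <- make_ground_truth_field(hcap, "hetero_iso_linear")
  f2 <- material_field("hetero_iso_linear", E = 2 * f1$E, nu = f1$nu,
                       n_elements = m)
  load <- pulmem:::reference_pressure_load_cpp(hcap$nodes, hcap$triangles - 1L, 1.2)
  # scaling invariance is a property of the unregularized operator, so the
  # (material-independent) stabilization is switched off here
  u1 <- solve_linear(hcap, f1, load, stabilization = 0)$u
  u2 <- solve_linear(hcap, f2, load, stabilization = 0)$u
  expect_lt(max(abs(u2 - u1 / 2)), 1e-9 * max(abs(u1)))
  u3 <- solve_linear(hcap, f2, 2 * load, stabilization = 0)$u
  expect_lt(max(abs(u3 - u1)), 1e-9 * max(abs(u1)))
  # residual check on the free dofs
  sl <- solve_linear(hcap, f1, load)
  K <- sl$Kff
  r <- K %*% sl$u[sl$fdof, 1] - load[sl$fdof]
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(load[sl$fdof]^2)), 1e-10)
})

test_that("rigid translation of the boundary translates the solution", {
  cap <- generate_cap_mesh(60, seed = 2)
  fld <- make_ground_truth_field(cap, "homo_iso_hyper")
  n <- nrow(cap$nodes)
  perim <- perimeter_nodes(cap)
  t0 <- c(1.3, -0.7, 2.1)
  # residual invariance: a translated configuration carries the same
  # (vanishing) residual as the reference
  u_exact <- matrix(rep(t0, each = n), ncol = 3)
  r <- assemble(cap, fld, u_exact, pressure = 0, want_tangent = FALSE)
  expect_lt(max(abs(r$residual)), 1e-7)
  expect_equal(r$energy, 0, tolerance = 1e-10)
  # a ramped solve tracks the rigid motion (a single large step can land in
  # a wrinkled metastable equilibrium instead, which is physical)
  ub <- matrix(rep(t0, each = length(perim)), ncol = 3)
  sol <- solve_stage(cap, fld, pressure = 0, boundary_displacements = ub,
                     n_increments = 8L)
  expect_lt(max(abs(sweep(sol$u, 2, t0))), 1e-8)
})

test_that("pre-tensioned membrane matches the series solution and converges under refinement", {
  pr <- mr_canonical()
  eps_pre <- 0.05
  lam <- 1 + eps_pre
  # membrane tension per unit length: T = S11 * t at equibiaxial stretch
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  st <- deformation_state(X, X * (lam - 1), global_frame())
  Tn <- mr_stress(pr, st)$S[1, 1] * 1.0
  a <- 40
  p <- 0.05
  w_ref <- membrane_series_deflection(p, a * lam, Tn)
  errs <- vapply(c(8L, 16L), function(nref) {
    mesh <- flat_square_mesh(nref, a)
    fld <- material_field("homo_iso_hyper", params = pr,
                          n_elements = nrow(mesh$triangles))
    perim <- perimeter_nodes(mesh)
    ub <- mesh$nodes[perim, ] * eps_pre
    sol <- solve_stage(mesh, fld, pressure = p, boundary_displacements = ub,
                       n_increments = 2L)
    center <- which.min(rowSums((mesh$nodes[, 1:2] - a / 2)^2))
    abs(sol$u[center, 3] - w_ref) / w_ref
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_lt(errs[2], errs[1] + 1e-6)
})

test_that("inflation stages are monotone in volume and energy", {
  cap <- generate_cap_mesh(120, seed = 4)
  fld <- make_ground_truth_field(cap, "homo_iso_hyper")
  prof <- generate_pressure_profile()
  run <- run_inflation(cap, fld, prof)
  expect_length(run$stages, 5L)
  expect_true(all(diff(run$pv$volume_mm3) > 0))
  expect_true(all(vapply(run$stages, `[[`, logical(1), "converged")))
  en <- vapply(run$stages, function(s) sum(s$fields$W), numeric(1))
  expect_true(all(en > 0))
  expect_true(all(diff(en) > 0))

  # re-running with identical inputs reproduces the fields exactly
  run2 <- run_inflation(cap, fld, prof)
  expect_equal(run2$stages[[5]]$u, run$stages[[5]]$u, tolerance = 1e-12)
})

test_that("principal strains match the closed-form 2x2 eigensolver", {
  # equibiaxial: degenerate eigenvalues, orthonormal directions
  mesh <- flat_square_mesh(2, 10)
  m <- nrow(mesh$triangles)
  fld <- material_field("homo_iso_hyper", params = mr_canonical(),
                        n_elements = m)
  lam <- 1.07
  sol <- solve_stage(mesh, fld, pressure = 0,
                     boundary_displacements =
                       mesh$nodes[perimeter_nodes(mesh), ] * (lam - 1))
  ps <- principal_strains(sol)
  expect_equal(ps$major, rep(lam - 1, m), tolerance = 1e-8)
  expect_equal(ps$minor, rep(lam - 1, m), tolerance = 1e-8)
  expect_lt(max(abs(rowSums(ps$dir_major * ps$dir_minor))), 1e-10)

  # uniaxial stretch along x: major direction parallel to local x
  ubx <- mesh$nodes[perimeter_nodes(mesh), ] %*% diag(c(0.1, 0, 0))
  solx <- solve_stage(mesh, fld, pressure = 0, boundary_displacements = ubx)
  psx <- principal_strains(solx)
  expect_equal(psx$major, rep(0.1, m), tolerance = 1e-8)
  expect_lt(max(abs(abs(psx$dir_major[, 1]) - 1)), 1e-8)

  # random strain states vs a brute-force eigensolve of C2d
  cap <- generate_cap_mesh(30, seed = 8)
  fcap <- make_ground_truth_field(cap, "homo_iso_hyper")
  prof <- generate_pressure_profile()
  r <- run_inflation(cap, fcap, prof)
  st <- r$stages[[5]]
  C <- st$fields$C2d
  for (e in sample(nrow(C), 6)) {
    ev <- eigen(matrix(c(C[e, 1], C[e, 3], C[e, 3], C[e, 2]), 2, 2),
                symmetric = TRUE, only.values = TRUE)$values
    expect_equal(st$fields$eps_major[e], sqrt(ev[1]) - 1, tolerance = 1e-10)
    expect_equal(st$fields$eps_minor[e], sqrt(ev[2]) - 1, tolerance = 1e-10)
  }
  expect_true(all(st$fields$eps_major >= st$fields$eps_minor))
})

test_that("stage and run outputs are written as VTK and CSV", {
  cap <- generate_cap_mesh(40, seed = 1)
  fld <- make_ground_truth_field(cap, "homo_iso_hyper")
  prof <- generate_pressure_profile()
  run <- run_inflation(cap, fld, prof)
  out <- file.path(tempdir(), "runvtk")
  write_run_vtk(run, cap, out)
  expect_length(list.files(out, pattern = "\\.vtk$"), 5L)
  pv <- read.csv(file.path(out, "stage_pv.csv"))
  expect_equal(nrow(pv), 5L)
  unlink(out, recursive = TRUE)
})
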