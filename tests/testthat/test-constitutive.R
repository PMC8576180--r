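# helper: deformation state of the unit triangle under a homogeneous
# in-plane deformation gradient F2 (2x2, local = global xy here)
state_from_F2 <- function(F2) {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  x <- t(apply(X, 1, function(r) c(F2 %*% r[1:2], 0)))
  deformation_state(X, x - X, global_frame())
}

# independent evaluation of the Mooney-Rivlin energy from a full 3x3 F
mr_energy_3d <- function(F3, C10, C01, D1) {
  C <- t(F3) %*% F3
  J <- sqrt(det(C))
  i1 <- sum(diag(C))
  i2 <- (i1^2 - sum(C * C)) / 2
  C10 * (J^(-2 / 3) * i1 - 3) + C01 * (J^(-4 / 3) * i2 - 3) + (J - 1)^2 / D1
}

test_that("deformation state reproduces identity and is objective", {
  st0 <- state_from_F2(diag(2))
  expect_equal(st0$I1bar, 3, tolerance = 1e-14)
  expect_equal(st0$I2bar, 3, tolerance = 1e-14)
  expect_equal(st0$J, 1, tolerance = 1e-14)
  expect_equal(st0$I4bar, 1, tolerance = 1e-14)

  th <- 0.7
  R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  set.seed(4)
  F2 <- diag(2) + matrix(rnorm(4, sd = 0.1), 2, 2)
  s1 <- state_from_F2(F2)
  s2 <- state_from_F2(R2 %*% F2)
  for (f in c("I1bar", "I2bar", "I4bar", "J"))
    expect_equal(s2[[f]], s1[[f]], tolerance = 1e-12)

  # collinear reference nodes are rejected
  expect_error(deformation_state(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                 matrix(0, 3, 3), global_frame()),
               "inversion|collinear")
})

test_that("Mooney-Rivlin stress is plane-stress consistent with the 3-D energy", {
  pr <- mr_canonical()
  st0 <- state_from_F2(diag(2))
  r0 <- mr_stress(pr, st0)
  expect_equal(r0$W, 0, tolerance = 1e-12)
  expect_lt(max(abs(r0$S)), 1e-8)
  expect_equal(r0$lambda3, 1, tolerance = 1e-10)

  # equibiaxial stretch: invariants match a symbolic 3x3 evaluation using
  # the solved thickness stretch
  lam <- 1.05
  st <- state_from_F2(diag(c(lam, lam)))
  r <- mr_stress(pr, st)
  F3 <- diag(c(lam, lam, r$lambda3))
  expect_equal(r$W, mr_energy_3d(F3, pr$C10, pr$C01, pr$D1),
               tolerance = 1e-10)
  expect_equal(r$state$J, lam^2 * r$lambda3, tolerance = 1e-12)
  # plane stress: perturbing lambda3 must not decrease the energy
  h <- 1e-5
  wp <- mr_energy_3d(diag(c(lam, lam, r$lambda3 + h)), pr$C10, pr$C01, pr$D1)
  wm <- mr_energy_3d(diag(c(lam, lam, r$lambda3 - h)), pr$C10, pr$C01, pr$D1)
  expect_lt(abs((wp - wm) / (2 * h)), 1e-5)
})

test_that("hyperelastic stress equals the numerical energy derivative", {
  # S = dW/dE checked by central differences of condensed W over random
  # in-plane states with stretches in [0.8, 1.5]
  set.seed(11)
  for (rep in 1:6) {
    U <- svd(matrix(rnorm(4), 2, 2))
    F2 <- U$u %*% diag(runif(2, 0.8, 1.5)) %*% t(U$v)
    if (det(F2) < 0) F2[, 1] <- -F2[, 1]
    C <- t(F2) %*% F2
    for (law in c("mr", "hgo")) {
      state_of <- function(Cm) state_from_F2(chol(Cm))  # C = F^T F
      eval_fn <- if (law == "mr") {
        function(Cm) mr_stress(mr_canonical(), state_of(Cm))
      } else {
        function(Cm) hgo_stress(hgo(116.4, 43.6e-4, 1.0, 0.12, 0.1),
                                state_of(Cm))
      }
      S <- eval_fn(C)$S
      # dW/dE_ab with E = (C - I)/2 -> dC = 2 dE
      h <- 1e-6
      for (ab in list(c(1, 1), c(2, 2), c(1, 2))) {
        dC <- matrix(0, 2, 2)
        dC[ab[1], ab[2]] <- dC[ab[2], ab[1]] <- 1
        wp <- eval_fn(C + h * dC)$W
        wm <- eval_fn(C - h * dC)$W
        dWdE <- (wp - wm) / (2 * h) * 2    # dE = dC/2
        Sab <- if (ab[1] == ab[2]) S[ab[1], ab[2]] else 2 * S[ab[1], ab[2]]
        expect_equal(dWdE, Sab, tolerance = 1e-6 * max(abs(S), 1))
      }
    }
  }
})

test_that("small strains reproduce the initial moduli", {
  pr <- mr_canonical()
  mods <- initial_moduli(pr)
  # isotropic small-strain constants implied by (mu0, K0), converted to the
  # linear plane-stress matrix: the condensed response must match it to
  # first order in the strain
  nu0 <- (3 * mods$K0 - 2 * mods$mu0) / (2 * (3 * mods$K0 + mods$mu0))
  E0 <- 2 * mods$mu0 * (1 + nu0)
  D_ps <- linear_plane_stress_matrix(linear_elastic(E0, nu0))
  eps <- 1e-5
  r <- mr_stress(pr, state_from_F2(diag(c(1 + eps, 1))))
  expect_equal(r$S[1, 1] / eps, D_ps[1, 1], tolerance = 1e-3)
  expect_equal(r$S[2, 2] / eps, D_ps[2, 1], tolerance = 1e-3)
})

test_that("HGO dispersion bound reduces the law to isotropy", {
  set.seed(3)
  F2 <- diag(2) + matrix(rnorm(4, sd = 0.15), 2, 2)
  if (det(F2) < 0) F2[, 1] <- -F2[, 1]
  st <- state_from_F2(F2)
  w_ref <- NULL
  for (ang in runif(5, 0, 2 * pi)) {
    pr <- hgo(116.4, 43.6e-4, 50, 0.12, 1 / 3, a0 = c(cos(ang), sin(ang)))
    w <- hgo_stress(pr, st)$W
    if (is.null(w_ref)) w_ref <- w else expect_equal(w, w_ref,
                                                     tolerance = 1e-12)
  }
  # identity state is stress free
  r0 <- hgo_stress(hgo(116.4, 43.6e-4, 1, 0.12, 0.1), state_from_F2(diag(2)))
  expect_equal(r0$W, 0, tolerance = 1e-14)
  expect_lt(max(abs(r0$S)), 1e-12)
})

test_that("fully aligned fibers stiffen the fiber direction only", {
  lam <- 1.1
  along <- state_from_F2(diag(c(lam, 1)))
  across <- state_from_F2(diag(c(1, lam)))
  pr <- hgo(116.4, 43.6e-4, 50, 0.5, 0, a0 = c(1, 0))
  w_along <- hgo_stress(pr, along)$W
  w_across <- hgo_stress(pr, across)$W
  expect_gt(w_along, w_across)
  # tension-only: fiber in compression contributes nothing
  comp <- state_from_F2(diag(c(0.9, 1)))
  pr0 <- hgo(116.4, 43.6e-4, 0, 0.5, 0, a0 = c(1, 0))
  expect_equal(hgo_stress(pr, comp)$W, hgo_stress(pr0, comp)$W,
               tolerance = 1e-14)
})

test_that("the k2 -> 0 limit is continuous (series evaluation)", {
  st <- state_from_F2(diag(c(1.15, 1.02)))
  w <- vapply(c(1e-12, 1e-9, 1e-7, 1e-4),
              function(k2) hgo_stress(hgo(116.4, 43.6e-4, 30, k2, 0.05),
                                      st)$W, numeric(1))
  # quadratic-form limit: W_aniso -> k1/2 Ef^2, so values converge smoothly
  expect_lt(diff(range(w[1:3])) / w[1], 1e-6)
  expect_equal(w[4], w[1], tolerance = 1e-3 * w[1])
})

test_that("plane-stress matrix and derived moduli match closed forms", {
  expect_equal(linear_plane_stress_matrix(linear_elastic(1, 0)),
               diag(c(1, 1, 0.5)), tolerance = 1e-15)
  expect_equal(linear_elastic(2.6, 0.3)$mu, 1.0, tolerance = 1e-12)
  set.seed(9)
  for (nu in runif(8, 0, 0.49)) {
    ev <- eigen(linear_plane_stress_matrix(linear_elastic(10, nu)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(linear_elastic(1, 0.5), "nu")

  mods <- initial_moduli(mr_canonical())
  expect_equal(mods$mu0, 275)
  expect_equal(mods$K0, 2 / 13.43e-4, tolerance = 1e-12)
  hg <- initial_moduli(hgo(116.4, 43.6e-4, 1, 0.12, 0.33))
  expect_equal(hg$mu0, 232.8)
  expect_true(is.na(hg$K0))
  lin <- initial_moduli(linear_elastic(2.86, 0.43))
  expect_equal(lin$mu0, 2.86 / 2.86, tolerance = 1e-12)
})

test_that("material fields flatten and unflatten as inverse bijections", {
  m <- 12L
  f1 <- material_field("homo_iso_hyper", params = mr_canonical(),
                       n_elements = m)
  p1 <- flatten_params(f1)
  expect_named(p1, c("C10", "C01", "D1"))
  expect_equal(flatten_params(unflatten_params(f1, p1)), p1)

  f2 <- material_field("homo_aniso_hyper",
                       params = hgo(116.4, 43.6e-4, 1, 0.12, 0.33),
                       n_elements = m)
  p2 <- flatten_params(f2)
  expect_length(p2, 5L)
  expect_equal(unname(flatten_params(unflatten_params(f2, p2))), unname(p2))

  set.seed(2)
  f3 <- material_field("hetero_iso_linear", E = runif(m, 100, 500),
                       nu = runif(m, 0.3, 0.45), n_elements = m)
  p3 <- flatten_params(f3)
  expect_length(p3, 2L * m)
  f3b <- unflatten_params(f3, p3)
  expect_equal(f3b$E, f3$E)
  expect_equal(f3b$nu, f3$nu)
})

test_that("material configs round-trip through YAML", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("case: homo_iso_hyper", "C10: 136.5", "C01: 1.0",
               "D1: 1.343e-3"), tmp)
  f <- read_material_config(tmp, 10L)
  expect_equal(f$params$C10, 136.5)

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(element = 1:10, E = seq(200, 500, length.out = 10),
                       nu = 0.43), csv, row.names = FALSE)
  writeLines(c("case: hetero_iso_linear", paste0("field_csv: ", csv)), tmp)
  f2 <- read_material_config(tmp, 10L)
  expect_equal(f2$E[10], 500)
  writeLines("C10: 1", tmp)
  expect_error(read_material_config(tmp, 10L), "case")
})
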