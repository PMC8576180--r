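#' Constitutive parameter sets
#'
#' Constructors for the three membrane material laws. All stresses are in kPa
#' (= mN/mm^2).
#'
#' `mooney_rivlin()` is the compressible Mooney-Rivlin law
#' \deqn{W = C_{10}(\bar I_1 - 3) + C_{01}(\bar I_2 - 3) + \frac{1}{D_1}(J-1)^2,}
#' used for the homogeneous isotropic hyperelastic case. The through-thickness
#' stretch is condensed internally so the normal stress vanishes (plane
#' stress).
#'
#' `hgo()` is the Holzapfel-Gasser-Ogden law
#' \deqn{W = C_{10}(\bar I_1-3) + \frac{1}{D}\left(\frac{J^2-1}{2}-\ln J\right)
#'  + \frac{k_1}{2k_2}\left[e^{k_2[\kappa(\bar I_1-3)+(1-3\kappa)(\bar I_4-1)]^2}-1\right]}
#' with fiber dispersion \eqn{\kappa \in [0, 1/3]} (1/3 = fully dispersed,
#' i.e. isotropic). The membrane formulation constrains J = 1, setting the
#' thickness stretch from the in-plane deformation; the volumetric term then
#' vanishes identically and `D` is inert (it is retained in the parameter
#' vector but does not influence the response). The fiber term is active only
#' in tension.
#'
#' `linear_elastic()` is isotropic linear elasticity in plane stress with
#' Young's modulus `E` and Poisson's ratio `nu`; the derived shear modulus is
#' \eqn{\mu = E / (2(1+\nu))}.
#'
#' @param C10,C01 deviatoric stiffness coefficients, kPa.
#' @param D1,D volumetric compliance, kPa^-1.
#' @param k1 fiber stiffness, kPa; `k2` dimensionless fiber exponent.
#' @param kappa fiber dispersion in `[0, 1/3]`.
#' @param a0 unit fiber direction in the element local frame (2-vector;
#'   default along local x, the medial-lateral direction).
#' @param E Young's modulus, kPa; `nu` Poisson's ratio in `[0, 0.5)`.
#' @return a parameter object with class `mooney_rivlin`, `hgo`, or
#'   `linear_elastic`.
#' @name constitutive_params
NULL

#' @rdname constitutive_params
#' @export
mooney_rivlin <- function(C10, C01, D1) {
  if (C10 <= 0) stop("C10 must be positive")
  if (D1 <= 0) stop("D1 must be positive")
  structure(list(C10 = C10, C01 = C01, D1 = D1), class = "mooney_rivlin")
}

#' @rdname constitutive_params
#' @export
hgo <- function(C10, D, k1, k2, kappa, a0 = c(1, 0)) {
  if (C10 <= 0) stop("C10 must be positive")
  if (k1 < 0) stop("k1 must be non-negative")
  if (kappa < 0 || kappa > 1 / 3 + 1e-12)
    stop("kappa must lie in [0, 1/3]")
  a0 <- as.numeric(a0)
  a0 <- a0 / sqrt(sum(a0^2))
  structure(list(C10 = C10, D = D, k1 = k1, k2 = k2, kappa = kappa, a0 = a0),
            class = "hgo")
}

#' @rdname constitutive_params
#' @export
linear_elastic <- function(E, nu) {
  if (E <= 0) stop("E must be positive")
  if (nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  structure(list(E = E, nu = nu, mu = E / (2 * (1 + nu))),
            class = "linear_elastic")
}

#' Membrane deformation state of a triangular element
#'
#' Computes the (constant) in-plane deformation gradient of a linear triangle
#' in its reference local frame, the in-plane right Cauchy-Green tensor, and
#' the kinematic invariants. The through-thickness stretch `lambda3` is
#' initialized to 1 and overwritten by the plane-stress / incompressibility
#' condensation inside [mr_stress()] / [hgo_stress()].
#'
#' @param ref_coords 3x3 matrix of reference node positions (rows).
#' @param elem_displacements 3x3 matrix of nodal displacements (rows).
#' @param frame list with unit vectors `x_axis`, `y_axis`, `z_axis` (the
#'   element local frame; z outward normal).
#' @param a0 fiber direction in the local frame (2-vector), used for the
#'   fiber pseudo-invariant `I4bar`.
#' @return object of class `deformation_state` with fields `F` (3x2, global
#'   by local-reference), `C2d`, `J`, `I1bar`, `I2bar`, `I4bar`,
#'   `lambda_fiber`, `lambda3`.
#' @export
deformation_state <- function(ref_coords, elem_displacements,
                              frame, a0 = c(1, 0)) {
  X <- as.matrix(ref_coords)
  u <- as.matrix(elem_displacements)
  ex <- frame$x_axis; ey <- frame$y_axis
  d1 <- X[2, ] - X[1, ]; d2 <- X[3, ] - X[1, ]
  Dm <- matrix(c(sum(ex * d1), sum(ey * d1),
                 sum(ex * d2), sum(ey * d2)), 2, 2)
  det <- Dm[1, 1] * Dm[2, 2] - Dm[1, 2] * Dm[2, 1]
  if (det <= 0) stop("element inversion: in-plane Jacobian <= 0 (or collinear reference nodes)")
  B <- solve(Dm)
  x <- X + u
  P <- cbind(x[2, ] - x[1, ], x[3, ] - x[1, ])
  F32 <- P %*% B
  C2d <- t(F32) %*% F32
  st <- structure(list(F = F32, C2d = C2d, lambda3 = 1.0,
                       a0 = a0 / sqrt(sum(a0^2)), area = det / 2),
                  class = "deformation_state")
  state_update_invariants(st)
}

# recompute full invariants given current lambda3
state_update_invariants <- function(state) {
  C <- state$C2d
  c33 <- state$lambda3^2
  det2 <- C[1, 1] * C[2, 2] - C[1, 2]^2
  if (det2 <= 0) stop("element inversion: in-plane Jacobian <= 0")
  J <- sqrt(det2 * c33)
  i1 <- C[1, 1] + C[2, 2] + c33
  trC2 <- C[1, 1]^2 + 2 * C[1, 2]^2 + C[2, 2]^2 + c33^2
  i2 <- (i1^2 - trC2) / 2
  a <- state$a0
  i4 <- a[1]^2 * C[1, 1] + 2 * a[1] * a[2] * C[1, 2] + a[2]^2 * C[2, 2]
  state$J <- J
  state$I1bar <- J^(-2 / 3) * i1
  state$I2bar <- J^(-4 / 3) * i2
  state$I4bar <- J^(-2 / 3) * i4
  state$lambda_fiber <- sqrt(state$I4bar)
  state
}

#' Mooney-Rivlin membrane stress
#'
#' Evaluates the strain-energy density and condensed in-plane second
#' Piola-Kirchhoff stress at a membrane deformation state. The through-
#' thickness stretch is solved internally by a safeguarded scalar root find
#' so that the normal stress vanishes (plane stress); the returned state
#' carries the solved `lambda3` and updated invariants.
#'
#' @param params a [mooney_rivlin()] parameter set.
#' @param state a [deformation_state()].
#' @return list with `W` (kPa), `S` (2x2 in-plane 2nd PK stress, kPa, in the
#'   element local frame), `lambda3`, and the updated `state`.
#' @export
mr_stress <- function(params, state) {
  stopifnot(inherits(params, "mooney_rivlin"))
  C <- state$C2d
  r <- mr_eval_cpp(c(C[1, 1], C[2, 2], C[1, 2]),
                   params$C10, params$C01, params$D1)
  state$lambda3 <- r$lambda3
  state <- state_update_invariants(state)
  list(W = r$W, S = matrix(c(r$S[1], r$S[3], r$S[3], r$S[2]), 2, 2),
       lambda3 = r$lambda3, state = state)
}

#' Holzapfel-Gasser-Ogden membrane stress
#'
#' As [mr_stress()], for the anisotropic law. The membrane formulation uses
#' the incompressibility condition J = 1 to set the thickness stretch, so the
#' volumetric compliance `D` does not enter the response. The fiber term is
#' included only when its strain-like argument is positive (tension).
#' The `k2 -> 0` limit is evaluated by a series expansion of the exponential
#' term.
#'
#' @param params an [hgo()] parameter set.
#' @param state a [deformation_state()].
#' @return list with `W`, `S`, `lambda3`, `state` as in [mr_stress()].
#' @export
hgo_stress <- function(params, state) {
  stopifnot(inherits(params, "hgo"))
  C <- state$C2d
  r <- hgo_eval_cpp(c(C[1, 1], C[2, 2], C[1, 2]),
                    params$C10, params$k1, params$k2, params$kappa,
                    params$a0)
  state$lambda3 <- r$lambda3
  state$a0 <- params$a0
  state <- state_update_invariants(state)
  list(W = r$W, S = matrix(c(r$S[1], r$S[3], r$S[3], r$S[2]), 2, 2),
       lambda3 = r$lambda3, state = state)
}

#' Isotropic plane-stress constitutive matrix
#'
#' Standard 3x3 matrix relating in-plane technical strains
#' (eps_xx, eps_yy, gamma_xy) to stresses (sigma_xx, sigma_yy, tau_xy).
#'
#' @param params a [linear_elastic()] parameter set.
#' @return 3x3 numeric matrix, kPa.
#' @export
linear_plane_stress_matrix <- function(params) {
  stopifnot(inherits(params, "linear_elastic"))
  E <- params$E; nu <- params$nu
  E / (1 - nu^2) * matrix(c(1, nu, 0,
                            nu, 1, 0,
                            0, 0, (1 - nu) / 2), 3, 3, byrow = TRUE)
}

#' Derived small-strain moduli
#'
#' Initial (zero-strain) shear and bulk moduli implied by a parameter set:
#' Mooney-Rivlin `mu0 = 2(C10 + C01)`, `K0 = 2/D1`; HGO `mu0 = 2 C10` with
#' `K0` undefined (`NA`) because the membrane formulation constrains J = 1
#' and ignores compressibility; linear elastic `mu = E/(2(1+nu))`,
#' `K = E/(3(1-2 nu))`.
#'
#' @param params a constitutive parameter object.
#' @return list with `mu0` and `K0`, kPa.
#' @export
initial_moduli <- function(params) {
  if (inherits(params, "mooney_rivlin")) {
    list(mu0 = 2 * (params$C10 + params$C01), K0 = 2 / params$D1)
  } else if (inherits(params, "hgo")) {
    list(mu0 = 2 * params$C10, K0 = NA_real_)
  } else if (inherits(params, "linear_elastic")) {
    list(mu0 = params$E / (2 * (1 + params$nu)),
         K0 = params$E / (3 * (1 - 2 * params$nu)))
  } else stop("unknown parameter class")
}

# ---------------------------------------------------------------------------
# Material fields (per-element parameter records + flatten/unflatten)
# ---------------------------------------------------------------------------

#' Material field over a mesh
#'
#' Binds a constitutive case to a mesh: a single parameter set for the
#' homogeneous cases, or per-element `(E, nu)` vectors for the heterogeneous
#' linear-elastic case. The field can be flattened to the unknown-parameter
#' vector `p` used by the calibration engine and restored with
#' [unflatten_params()] (inverse bijections). For the heterogeneous case
#' `length(p) = 2 * n_elements` (all `E` values followed by all `nu` values).
#'
#' @param case one of `"homo_iso_hyper"`, `"homo_aniso_hyper"`,
#'   `"hetero_iso_linear"`.
#' @param params a [mooney_rivlin()] or [hgo()] object (homogeneous cases).
#' @param E,nu numeric vectors, one value per element (heterogeneous case).
#' @param n_elements number of mesh elements.
#' @return object of class `material_field`.
#' @export
material_field <- function(case, params = NULL, E = NULL, nu = NULL,
                           n_elements) {
  case <- match.arg(case,
                    c("homo_iso_hyper", "homo_aniso_hyper", "hetero_iso_linear"))
  if (case == "hetero_iso_linear") {
    stopifnot(length(E) == n_elements, length(nu) == n_elements)
    if (any(E <= 0)) stop("E must be positive")
    if (any(nu < 0 | nu >= 0.5)) stop("nu must lie in [0, 0.5)")
    out <- list(case = case, E = as.numeric(E), nu = as.numeric(nu),
                n_elements = n_elements)
  } else {
    want <- if (case == "homo_iso_hyper") "mooney_rivlin" else "hgo"
    if (!inherits(params, want))
      stop("case ", case, " requires ", want, " parameters")
    out <- list(case = case, params = params, n_elements = n_elements)
  }
  structure(out, class = "material_field")
}

#' @method print material_field
#' @export
print.material_field <- function(x, ...) {
  cat(sprintf("material_field (%s), %d elements, %d unknown parameters\n",
              x$case, x$n_elements, length(flatten_params(x))))
  invisible(x)
}

#' @rdname material_field
#' @param field a `material_field`.
#' @export
flatten_params <- function(field) {
  switch(field$case,
    homo_iso_hyper = c(C10 = field$params$C10, C01 = field$params$C01,
                       D1 = field$params$D1),
    homo_aniso_hyper = c(C10 = field$params$C10, D = field$params$D,
                         k1 = field$params$k1, k2 = field$params$k2,
                         kappa = field$params$kappa),
    hetero_iso_linear = c(field$E, field$nu))
}

#' @rdname material_field
#' @param p flattened parameter vector.
#' @export
unflatten_params <- function(field, p) {
  p <- unname(p)
  switch(field$case,
    homo_iso_hyper = material_field("homo_iso_hyper",
      params = mooney_rivlin(p[1], p[2], p[3]),
      n_elements = field$n_elements),
    homo_aniso_hyper = material_field("homo_aniso_hyper",
      params = hgo(p[1], p[2], p[3], p[4], p[5],
                   a0 = field$params$a0),
      n_elements = field$n_elements),
    hetero_iso_linear = {
      m <- field$n_elements
      stopifnot(length(p) == 2 * m)
      material_field("hetero_iso_linear", E = p[seq_len(m)],
                     nu = p[m + seq_len(m)], n_elements = m)
    })
}

#' Default calibration search ranges
#'
#' Box bounds for the unknown parameters of each constitutive case. The
#' hyperelastic coefficient ranges are 1-200 kPa for `C10`, `C01`, `k1`,
#' 1e-4 to 1e-2 kPa^-1 for `D1` and `D`, `[0, 1]` for `k2` and `[0, 0.33]`
#' for `kappa`. For the heterogeneous case each element's `E` is bounded in
#' 50-1000 kPa and `nu` in 0.30-0.49.
#'
#' @param case constitutive case tag.
#' @param n_elements required for the heterogeneous case.
#' @return list with `lower` and `upper` numeric vectors.
#' @export
default_bounds <- function(case, n_elements = NULL) {
  switch(match.arg(case, c("homo_iso_hyper", "homo_aniso_hyper",
                           "hetero_iso_linear")),
    homo_iso_hyper = list(lower = c(C10 = 1, C01 = 1, D1 = 1e-4),
                          upper = c(C10 = 200, C01 = 200, D1 = 1e-2)),
    homo_aniso_hyper = list(
      lower = c(C10 = 1, D = 1e-4, k1 = 1, k2 = 0, kappa = 0),
      upper = c(C10 = 200, D = 1e-2, k1 = 200, k2 = 1, kappa = 0.33)),
    hetero_iso_linear = {
      if (is.null(n_elements)) stop("n_elements required for hetero case")
      list(lower = c(rep(50, n_elements), rep(0.30, n_elements)),
           upper = c(rep(1000, n_elements), rep(0.49, n_elements)))
    })
}

# internal: material field -> (mat_case int, n_elem x 5 matrix, fiber matrix)
material_arrays <- function(field, mesh, frames = NULL) {
  m <- nrow(mesh$triangles)
  stopifnot(field$n_elements == m)
  fiber <- matrix(rep(c(1, 0), each = m), m, 2)
  if (field$case == "homo_iso_hyper") {
    p <- field$params
    list(mat_case = 0L,
         params = matrix(rep(c(p$C10, p$C01, p$D1, 0, 0), each = m), m, 5),
         fiber = fiber)
  } else if (field$case == "homo_aniso_hyper") {
    p <- field$params
    fiber <- matrix(rep(p$a0, each = m), m, 2)
    list(mat_case = 1L,
         params = matrix(rep(c(p$C10, p$D, p$k1, p$k2, p$kappa), each = m),
                         m, 5),
         fiber = fiber)
  } else {
    list(mat_case = 2L,
         params = cbind(field$E, field$nu, 0, 0, 0),
         fiber = fiber)
  }
}

#' Read a material definition from a YAML config
#'
#' The config holds a `case` tag plus either scalar parameter values
#' (homogeneous cases) or a path to a per-element CSV with columns
#' `element,E,nu` (heterogeneous case).
#'
#' @param path YAML file path.
#' @param n_elements number of mesh elements the field must cover.
#' @return a [material_field()].
#' @export
read_material_config <- function(path, n_elements) {
  cfg <- yaml::read_yaml(path)
  case <- cfg$case
  if (is.null(case)) stop("material config must have a 'case' field")
  if (case == "homo_iso_hyper") {
    material_field(case, params = mooney_rivlin(cfg$C10, cfg$C01, cfg$D1),
                   n_elements = n_elements)
  } else if (case == "homo_aniso_hyper") {
    a0 <- if (is.null(cfg$a0)) c(1, 0) else as.numeric(cfg$a0)
    material_field(case,
                   params = hgo(cfg$C10, cfg$D, cfg$k1, cfg$k2, cfg$kappa, a0),
                   n_elements = n_elements)
  } else if (case == "hetero_iso_linear") {
    tab <- utils::read.csv(cfg$field_csv)
    if (!all(c("element", "E", "nu") %in% names(tab)))
      stop("per-element CSV must have columns element,E,nu")
    tab <- tab[order(tab$element), ]
    material_field(case, E = tab$E, nu = tab$nu, n_elements = n_elements)
  } else stop("unknown material case: ", case)
}
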