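#' Pressure-time loading profile
#'
#' @param time strictly increasing sample times, s.
#' @param pressure non-negative pressures, kPa (use [cmh2o_to_kpa()] for
#'   cmH2O inputs).
#' @param stage_times times at which displacement error is evaluated
#'   (default: five evenly spaced increments of the profile span, the 20%
#'   inflation steps).
#' @return object of class `pressure_profile`.
#' @export
pressure_profile <- function(time, pressure, stage_times = NULL) {
  stopifnot(length(time) == length(pressure), length(time) >= 2L)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(pressure < 0)) stop("pressure must be non-negative")
  if (is.null(stage_times))
    stage_times <- time[1] + diff(range(time)) * seq(0.2, 1, by = 0.2)
  if (any(stage_times < min(time) - 1e-12 | stage_times > max(time) + 1e-12))
    stop("stage_times must lie within the profile time span")
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 stage_times = as.numeric(stage_times)),
            class = "pressure_profile")
}

#' @rdname pressure_profile
#' @param profile a `pressure_profile`.
#' @param t query time(s), s.
#' @export
pressure_at <- function(profile, t) {
  stats::approx(profile$time, profile$pressure, xout = t, rule = 2)$y
}

#' Convert cmH2O to kPa
#'
#' 1 cmH2O = 0.0980665 kPa. The package works internally in mm / kPa / mN.
#' @param p pressure in cmH2O.
#' @export
cmh2o_to_kpa <- function(p) 0.0980665 * p

#' Read a pressure profile from CSV
#'
#' Expects columns `time` (s) and `pressure`; `units` selects conversion.
#' @param path CSV path.
#' @param units `"kPa"` (default) or `"cmH2O"`.
#' @param stage_times optional stage times.
#' @export
read_pressure_csv <- function(path, units = c("kPa", "cmH2O"),
                              stage_times = NULL) {
  units <- match.arg(units)
  tab <- utils::read.csv(path)
  if (!all(c("time", "pressure") %in% names(tab)))
    stop("pressure CSV must have columns time,pressure")
  p <- tab$pressure
  if (units == "cmH2O") p <- cmh2o_to_kpa(p)
  pressure_profile(tab$time, p, stage_times)
}

# ---------------------------------------------------------------------------
# Assembly
# ---------------------------------------------------------------------------

#' Assemble residual and tangent of the membrane system
#'
#' For the hyperelastic cases the residual is internal force minus the
#' follower-pressure load, both evaluated on the current configuration; the
#' tangent (central finite difference of the exact element residual) carries
#' material, geometric and follower-pressure stiffness. For the linear
#' heterogeneous case the residual is `K u - f` with `K` the small-strain
#' membrane stiffness and `f` the reference-configuration pressure load.
#'
#' @param mesh a [surface_mesh()].
#' @param field a [material_field()].
#' @param u displacement (n x 3 matrix or length-3n vector).
#' @param pressure applied pressure, kPa.
#' @param frames precomputed [compute_local_frames()] (optional).
#' @param want_tangent assemble the sparse tangent as well.
#' @return list with `residual` (length 3n, mN), `tangent`
#'   (`dgCMatrix`, if requested), `energy` (total strain energy, mJ for the
#'   hyperelastic cases).
#' @export
assemble <- function(mesh, field, u, pressure, frames = NULL,
                     want_tangent = TRUE) {
  if (is.null(frames)) frames <- compute_local_frames(mesh)
  n <- nrow(mesh$nodes)
  uv <- as_disp_vector(u, n)
  ma <- material_arrays(field, mesh)
  if (ma$mat_case == 2L) {
    tr <- linear_stiffness_cpp(mesh$nodes, mesh$triangles - 1L,
                               mesh$thickness, field$E, field$nu,
                               frames$x_axis, frames$y_axis)
    K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                              dims = c(3 * n, 3 * n))
    f <- reference_pressure_load_cpp(mesh$nodes, mesh$triangles - 1L, pressure)
    out <- list(residual = as.numeric(K %*% uv) - f, energy = NA_real_)
    if (want_tangent) out$tangent <- K
    return(out)
  }
  r <- membrane_assemble_cpp(mesh$nodes, mesh$triangles - 1L, uv,
                             mesh$thickness, ma$mat_case, ma$params,
                             ma$fiber, pressure,
                             frames$x_axis, frames$y_axis, want_tangent)
  out <- list(residual = r$residual, energy = r$energy)
  if (want_tangent) out$tangent <- r$tangent
  out
}

# dof indices (1-based into the length-3n vector) for a set of nodes
node_dofs <- function(nodes_idx) {
  as.integer(rbind(3 * nodes_idx - 2L, 3 * nodes_idx - 1L, 3 * nodes_idx))
}

default_solver_control <- function(control = list()) {
  # tol_abs is a floor against the roundoff noise of the assembled internal
  # force (forces here are O(1e2-1e4) mN, so 1e-6 mN is ~1e-9 relative)
  utils::modifyList(list(tol_rel = 1e-8, tol_abs = 1e-6, max_iter = 30L,
                         max_halvings = 6L, stabilization = 1e-6,
                         line_search = TRUE), control)
}

#' Solve one quasi-static load stage
#'
#' Newton iteration with adaptive load incrementation from a starting state
#' `(pressure_init, boundary_init, u_init)` to the target
#' `(pressure, boundary_displacements)`. Convergence requires the free-dof
#' residual norm to fall below `tol_rel` times the increment load norm (or
#' `tol_abs` mN absolute). On divergence the increment is halved, up to
#' `max_halvings` times. A small diagonal stabilization
#' (`stabilization` x mean tangent diagonal) regularizes wrinkling-prone
#' (compression / normal-direction) null modes of the membrane tangent; it
#' enters only the iteration matrix, never the residual, so converged states
#' are unaffected.
#'
#' @param mesh a [surface_mesh()].
#' @param field a [material_field()] (hyperelastic cases).
#' @param pressure target pressure, kPa.
#' @param boundary_displacements n_perim x 3 matrix of prescribed
#'   displacements for `sort(perimeter_nodes(mesh))` (default zero).
#' @param n_increments minimum number of load increments (default 1).
#' @param u_init,pressure_init,boundary_init starting state (default:
#'   reference configuration, zero load).
#' @param frames,perimeter precomputed mesh data (optional).
#' @param control solver settings; see Details above.
#' @param stage stage index label stored on the result.
#' @return object of class `stage_solution`: `u` (n x 3 mm), per-element
#'   fields (stress, strain, principal values/directions), `converged`,
#'   `iterations`, `pressure`.
#' @export
solve_stage <- function(mesh, field, pressure,
                        boundary_displacements = NULL, n_increments = 1L,
                        u_init = NULL, pressure_init = 0,
                        boundary_init = NULL, frames = NULL,
                        perimeter = NULL, control = list(), stage = NA_integer_) {
  control <- default_solver_control(control)
  if (is.null(frames)) frames <- compute_local_frames(mesh)
  if (is.null(perimeter)) perimeter <- perimeter_nodes(mesh)
  n <- nrow(mesh$nodes)
  np <- length(perimeter)
  if (is.null(boundary_displacements))
    boundary_displacements <- matrix(0, np, 3)
  if (is.null(boundary_init)) boundary_init <- matrix(0, np, 3)
  stopifnot(nrow(boundary_displacements) == np)
  cdof <- node_dofs(perimeter)
  fdof <- setdiff(seq_len(3L * n), cdof)
  u <- if (is.null(u_init)) numeric(3 * n) else as_disp_vector(u_init, n)
  ub0 <- as.numeric(t(boundary_init))
  ub1 <- as.numeric(t(boundary_displacements))
  total_iter <- 0L
  lam <- 0; dlam <- 1 / max(1L, n_increments)
  halvings <- 0L
  while (lam < 1 - 1e-12) {
    lam_try <- min(1, lam + dlam)
    p_now <- pressure_init + lam_try * (pressure - pressure_init)
    ub_now <- ub0 + lam_try * (ub1 - ub0)
    res <- newton_solve(mesh, field, u, p_now, ub_now, cdof, fdof, frames,
                        control)
    if (res$converged) {
      u <- res$u
      lam <- lam_try
      total_iter <- total_iter + res$iterations
    } else {
      halvings <- halvings + 1L
      if (halvings > control$max_halvings)
        stop(sprintf(
          "stage solve did not converge at load factor %.3g (pressure %.4g kPa) after %d increment halvings; last residual %.3g",
          lam_try, p_now, control$max_halvings, res$res_norm))
      dlam <- dlam / 2
    }
  }
  um <- matrix(u, ncol = 3, byrow = TRUE)
  ma <- material_arrays(field, mesh)
  flds <- element_fields_cpp(mesh$nodes, mesh$triangles - 1L, u,
                             mesh$thickness, ma$mat_case, ma$params,
                             ma$fiber, frames$x_axis, frames$y_axis)
  structure(list(stage = stage, u = um, pressure = pressure,
                 converged = TRUE, iterations = total_iter,
                 fields = flds),
            class = "stage_solution")
}

# Newton iteration at fixed load. The line search evaluates the (cheap)
# residual only; the tangent is reassembled at each accepted iterate.
newton_solve <- function(mesh, field, u_start, pressure, ub, cdof, fdof,
                         frames, control) {
  u <- u_start
  u[cdof] <- ub
  resid_at <- function(uv) {
    a <- tryCatch(assemble(mesh, field, uv, pressure, frames,
                           want_tangent = FALSE),
                  error = function(e) NULL)
    if (is.null(a)) return(NULL)
    a$residual[fdof]
  }
  r <- resid_at(u)
  if (is.null(r))
    return(list(converged = FALSE, u = u, iterations = 0L, res_norm = Inf))
  fref <- reference_pressure_load_cpp(mesh$nodes, mesh$triangles - 1L, pressure)
  ref <- max(sqrt(sum(fref^2)), sqrt(sum(r^2)))
  tol <- max(control$tol_rel * ref, control$tol_abs)
  rn <- sqrt(sum(r^2))
  if (rn < tol)
    return(list(converged = TRUE, u = u, iterations = 0L, res_norm = rn))
  for (it in seq_len(control$max_iter)) {
    a <- assemble(mesh, field, u, pressure, frames, want_tangent = TRUE)
    K <- a$tangent[fdof, fdof, drop = FALSE]
    dmean <- mean(abs(Matrix::diag(K)))
    if (control$stabilization > 0)
      K <- K + Matrix::Diagonal(length(fdof), control$stabilization * dmean)
    du <- tryCatch(as.numeric(Matrix::solve(K, -r)),
                   error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du)))
      return(list(converged = FALSE, u = u, iterations = it, res_norm = rn))
    alpha <- 1
    repeat {
      u_try <- u
      u_try[fdof] <- u[fdof] + alpha * du
      r_try <- resid_at(u_try)
      if (!is.null(r_try)) {
        rn_try <- sqrt(sum(r_try^2))
        if (is.finite(rn_try) && (rn_try < rn || !control$line_search)) break
      }
      alpha <- alpha / 2
      if (alpha < 1 / 64) break
    }
    if (is.null(r_try) || !is.finite(sqrt(sum(r_try^2))))
      return(list(converged = FALSE, u = u, iterations = it, res_norm = rn))
    u <- u_try
    r <- r_try
    rn_new <- sqrt(sum(r^2))
    if (rn_new < tol)
      return(list(converged = TRUE, u = u, iterations = it, res_norm = rn_new))
    if (rn_new > 10 * rn && alpha < 1 / 32)
      return(list(converged = FALSE, u = u, iterations = it, res_norm = rn_new))
    rn <- rn_new
  }
  list(converged = rn < tol, u = u, iterations = control$max_iter,
       res_norm = rn)
}

#' @method print stage_solution
#' @export
print.stage_solution <- function(x, ...) {
  cat(sprintf(
    "stage_solution (stage %s): pressure %.4g kPa, max |u| %.4g mm, %d Newton iterations\n",
    x$stage, x$pressure, max(sqrt(rowSums(x$u^2))), x$iterations))
  invisible(x)
}

#' Run a multi-stage inflation
#'
#' Solves one converged quasi-static equilibrium per stage time of the
#' pressure profile, each stage continuing from the previous solution with
#' boundary displacements interpolated linearly between stages. Also returns
#' the pressure-volume samples via [enclosed_volume_change()].
#'
#' @param mesh a [surface_mesh()].
#' @param field a [material_field()].
#' @param profile a [pressure_profile()].
#' @param boundary optional list with `nodes` (perimeter node indices,
#'   sorted) and `u` (n_perim x 3 x n_stages array of prescribed
#'   displacements); default: perimeter held fixed.
#' @param n_increments minimum load increments per stage.
#' @param control passed to [solve_stage()].
#' @param warm_start optional list of per-stage displacement matrices used
#'   as Newton starting guesses at the target load (e.g. the solutions of a
#'   previous run at nearby material parameters); each stage falls back to
#'   the incremental path if the warm solve fails.
#' @return object of class `inflation_run`: list of `stages`
#'   ([solve_stage()] solutions) and `pv` (data.frame time, pressure_kPa,
#'   volume_mm3).
#' @export
run_inflation <- function(mesh, field, profile, boundary = NULL,
                          n_increments = 1L, control = list(),
                          warm_start = NULL) {
  if (field$case == "hetero_iso_linear")
    return(run_inflation_linear(mesh, field, profile, boundary))
  frames <- compute_local_frames(mesh)
  perim <- perimeter_nodes(mesh)
  ns <- length(profile$stage_times)
  if (!is.null(boundary)) {
    stopifnot(identical(sort(boundary$nodes), perim),
              dim(boundary$u)[1] == length(perim),
              dim(boundary$u)[3] == ns)
  }
  stages <- vector("list", ns)
  u_prev <- NULL; p_prev <- 0
  ub_prev <- matrix(0, length(perim), 3)
  vol <- numeric(ns)
  for (s in seq_len(ns)) {
    p_s <- pressure_at(profile, profile$stage_times[s])
    ub_s <- if (is.null(boundary)) matrix(0, length(perim), 3) else
      boundary$u[, , s]
    sol <- NULL
    if (!is.null(warm_start) && length(warm_start) >= s &&
        !is.null(warm_start[[s]])) {
      # direct Newton at the target load from a nearby cached solution;
      # fall back to the incremental path if it fails
      ctrl <- utils::modifyList(control, list(max_halvings = 0L))
      sol <- tryCatch(
        solve_stage(mesh, field, p_s, ub_s, n_increments = 1L,
                    u_init = warm_start[[s]], pressure_init = p_s,
                    boundary_init = ub_s, frames = frames,
                    perimeter = perim, control = ctrl, stage = s),
        error = function(e) NULL)
    }
    if (is.null(sol))
      sol <- solve_stage(mesh, field, p_s, ub_s,
                         n_increments = n_increments,
                         u_init = u_prev, pressure_init = p_prev,
                         boundary_init = ub_prev, frames = frames,
                         perimeter = perim, control = control,
                         stage = s)
    stages[[s]] <- sol
    u_prev <- stages[[s]]$u; p_prev <- p_s; ub_prev <- ub_s
    vol[s] <- enclosed_volume_change(mesh, stages[[s]]$u)
  }
  structure(list(stages = stages,
                 pv = data.frame(time = profile$stage_times,
                                 pressure_kPa = pressure_at(profile,
                                                            profile$stage_times),
                                 volume_mm3 = vol)),
            class = "inflation_run")
}

# heterogeneous linear case: geometrically linear, one solve per stage
run_inflation_linear <- function(mesh, field, profile, boundary = NULL) {
  frames <- compute_local_frames(mesh)
  perim <- perimeter_nodes(mesh)
  ns <- length(profile$stage_times)
  n <- nrow(mesh$nodes)
  p_s <- pressure_at(profile, profile$stage_times)
  f <- vapply(p_s, function(p)
    reference_pressure_load_cpp(mesh$nodes, mesh$triangles - 1L, p),
    numeric(3 * n))
  ub <- array(0, c(length(perim), 3, ns))
  if (!is.null(boundary)) {
    stopifnot(identical(sort(boundary$nodes), perim))
    ub <- boundary$u
  }
  U <- solve_linear(mesh, field, f, perim, ub, frames = frames)$u
  stages <- vector("list", ns)
  vol <- numeric(ns)
  ma <- material_arrays(field, mesh)
  for (s in seq_len(ns)) {
    um <- matrix(U[, s], ncol = 3, byrow = TRUE)
    flds <- element_fields_cpp(mesh$nodes, mesh$triangles - 1L, U[, s],
                               mesh$thickness, ma$mat_case, ma$params,
                               ma$fiber, frames$x_axis, frames$y_axis)
    stages[[s]] <- structure(list(stage = s, u = um, pressure = p_s[s],
                                  converged = TRUE, iterations = 1L,
                                  fields = flds),
                             class = "stage_solution")
    vol[s] <- enclosed_volume_change(mesh, um)
  }
  structure(list(stages = stages,
                 pv = data.frame(time = profile$stage_times,
                                 pressure_kPa = p_s, volume_mm3 = vol)),
            class = "inflation_run")
}

#' Linear heterogeneous solve K(p) u = f
#'
#' Assembles the heterogeneous small-strain membrane stiffness and solves the
#' reduced system on the free degrees of freedom with prescribed-dof
#' elimination (sparse Cholesky; the reduced operator is symmetric positive
#' definite after diagonal stabilization of the membrane's normal-direction
#' null modes). Multiple right-hand sides (stages) share one factorization.
#'
#' @param mesh a [surface_mesh()].
#' @param field a `hetero_iso_linear` [material_field()].
#' @param f load vector(s): length-3n vector or 3n x n_stages matrix, mN.
#' @param prescribed_nodes node indices with prescribed displacements
#'   (default: the mesh perimeter).
#' @param prescribed_u n_presc x 3 matrix or n_presc x 3 x n_stages array of
#'   prescribed values (default zero).
#' @param stabilization diagonal regularization factor. The absolute
#'   stabilization added to the free-dof diagonal is
#'   `stabilization x mean diag of a unit-modulus reference assembly x E_ref`
#'   with `E_ref = 500` kPa (the midpoint of the default heterogeneous search
#'   range), so the regularized operator does not depend on the material
#'   parameters being calibrated — a requirement for the adjoint gradient to
#'   be exact.
#' @param frames optional precomputed frames.
#' @return list with `u` (3n x n_stages matrix of full displacement vectors)
#'   and `solve_count` (number of factorized solves performed, always 1 here).
#' @export
solve_linear <- function(mesh, field, f, prescribed_nodes = NULL,
                         prescribed_u = NULL, stabilization = 1e-6,
                         frames = NULL) {
  stopifnot(field$case == "hetero_iso_linear")
  if (is.null(frames)) frames <- compute_local_frames(mesh)
  if (is.null(prescribed_nodes)) prescribed_nodes <- perimeter_nodes(mesh)
  n <- nrow(mesh$nodes)
  f <- as.matrix(f)
  ns <- ncol(f)
  npn <- length(prescribed_nodes)
  if (npn == 0) stop("singular system: no prescribed displacements")
  if (is.null(prescribed_u)) prescribed_u <- array(0, c(npn, 3, ns))
  if (length(dim(prescribed_u)) == 2L)
    prescribed_u <- array(prescribed_u, c(npn, 3, ns))
  tr <- linear_stiffness_cpp(mesh$nodes, mesh$triangles - 1L, mesh$thickness,
                             field$E, field$nu, frames$x_axis, frames$y_axis)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(3 * n, 3 * n))
  cdof <- node_dofs(prescribed_nodes)
  fdof <- setdiff(seq_len(3L * n), cdof)
  Kff <- K[fdof, fdof, drop = FALSE]
  if (stabilization > 0) {
    # material-independent scale: unit-modulus reference assembly x 500 kPa
    m <- nrow(mesh$triangles)
    tru <- linear_stiffness_cpp(mesh$nodes, mesh$triangles - 1L,
                                mesh$thickness, rep(1, m), rep(0.3, m),
                                frames$x_axis, frames$y_axis)
    Ku <- Matrix::sparseMatrix(i = tru$i, j = tru$j, x = tru$x,
                               dims = c(3 * n, 3 * n))
    dmean <- mean(abs(Matrix::diag(Ku)[fdof])) * 500
    Kff <- Kff + Matrix::Diagonal(length(fdof), stabilization * dmean)
  }
  Kfc <- K[fdof, cdof, drop = FALSE]
  U <- matrix(0, 3 * n, ns)
  uc <- vapply(seq_len(ns), function(s) as.numeric(t(prescribed_u[, , s])),
               numeric(3 * npn))
  rhs <- f[fdof, , drop = FALSE] - as.matrix(Kfc %*% uc)
  sol <- tryCatch(Matrix::solve(Kff, rhs),
                  error = function(e)
                    stop("rank error: reduced stiffness not solvable (",
                         conditionMessage(e), ")"))
  U[fdof, ] <- as.matrix(sol)
  U[cdof, ] <- uc
  list(u = U, solve_count = 1L, Kff = Kff, fdof = fdof, cdof = cdof)
}

#' Principal in-plane technical strains
#'
#' Major and minor principal technical strains (principal stretch minus one)
#' of each element with their direction vectors in global coordinates
#' (tangent to the element plane).
#'
#' @param solution a [solve_stage()] result.
#' @return list of class `strain_field`: `major`, `minor` (numeric vectors),
#'   `dir_major`, `dir_minor` (n_elem x 3 matrices, unit rows).
#' @export
principal_strains <- function(solution) {
  f <- solution$fields
  structure(list(major = as.numeric(f$eps_major),
                 minor = as.numeric(f$eps_minor),
                 dir_major = f$dir_major, dir_minor = f$dir_minor),
            class = "strain_field")
}

#' Write an inflation run to VTK files
#'
#' One legacy VTK file per stage with nodal displacement, element principal
#' strains/stresses and principal strain directions, plus the P-V samples as
#' CSV.
#'
#' @param run an [run_inflation()] result.
#' @param mesh the mesh it was computed on.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @export
write_run_vtk <- function(run, mesh, dir, prefix = "stage") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(run$stages)) {
    st <- run$stages[[s]]
    write_vtk(mesh, file.path(dir, sprintf("%s_%02d.vtk", prefix, s)),
              point_vectors = list(displacement = st$u),
              cell_scalars = list(eps_major = st$fields$eps_major,
                                  eps_minor = st$fields$eps_minor,
                                  sigma_major = st$fields$sigma_principal[, 1],
                                  sigma_minor = st$fields$sigma_principal[, 2]),
              cell_vectors = list(dir_major = st$fields$dir_major,
                                  dir_minor = st$fields$dir_minor))
  }
  utils::write.csv(run$pv, file.path(dir, paste0(prefix, "_pv.csv")),
                   row.names = FALSE)
  invisible(dir)
}
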