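#' Objective specification for the inverse problem
#'
#' Defines the displacement-mismatch functional
#' \deqn{\Pi(p) = \frac{1}{2\,s}\sum_{n=1}^{n_{stages}} \|W u^{sim}_n(p) - u^{exp}_n\|^2
#'   + \frac{\alpha}{2}\|\tilde p - \tfrac12\|^2,}
#' where `W` maps nodal displacements to probe locations, the normalizer
#' `s = n_probes * n_stages * max ||u_exp||^2` renders Pi dimensionless, and
#' the Tikhonov term acts on bound-normalized parameters
#' \eqn{\tilde p = (p - lower)/(upper - lower)}, centered on the midpoint
#' of the search range so that weakly informed parameters settle at an
#' unbiased prior rather than at a bound (heterogeneous gradient-based
#' calibration only; `alpha = 0` elsewhere).
#'
#' @param u_exp n_probes x 3 x n_stages array of measured probe displacements.
#' @param alpha regularization weight (default 0).
#' @param bounds list with `lower`/`upper` for the normalized penalty
#'   (required when `alpha > 0`).
#' @return object of class `objective_spec` with the precomputed normalizer.
#' @export
objective_spec <- function(u_exp, alpha = 0, bounds = NULL) {
  stopifnot(length(dim(u_exp)) == 3L, alpha >= 0)
  if (alpha > 0 && is.null(bounds))
    stop("bounds are required when alpha > 0")
  umax2 <- max(u_exp[, 1, ]^2 + u_exp[, 2, ]^2 + u_exp[, 3, ]^2)
  if (umax2 == 0) umax2 <- 1
  structure(list(u_exp = u_exp, alpha = alpha, bounds = bounds,
                 n_probes = dim(u_exp)[1], n_stages = dim(u_exp)[3],
                 normalizer = dim(u_exp)[1] * dim(u_exp)[3] * umax2),
            class = "objective_spec")
}

normalize_p <- function(p, bounds) {
  (p - bounds$lower) / (bounds$upper - bounds$lower)
}

#' Evaluate the calibration objective
#'
#' @param p parameter vector.
#' @param forward_fn function of `p` returning the simulated probe
#'   displacements as an n_probes x 3 x n_stages array, or `NULL` on solver
#'   failure.
#' @param spec an [objective_spec()].
#' @return list with `Pi` (`NA` on forward failure: the optimizers convert
#'   this to a large penalty), `rho` (regularization term), and `stages`
#'   (per-stage residual record: sum of squares and RMS residual in mm).
#' @export
objective <- function(p, forward_fn, spec) {
  u_sim <- tryCatch(forward_fn(p), error = function(e) {
    warning("forward solve failed: ", conditionMessage(e))
    NULL
  })
  if (is.null(u_sim))
    return(list(Pi = NA_real_, rho = NA_real_, stages = NULL))
  res <- u_sim - spec$u_exp
  ss <- vapply(seq_len(spec$n_stages),
               function(s) sum(res[, , s]^2), numeric(1))
  rho <- 0
  if (spec$alpha > 0) {
    pt <- normalize_p(p, spec$bounds)
    rho <- spec$alpha / 2 * sum((pt - 0.5)^2)
  }
  list(Pi = 0.5 * sum(ss) / spec$normalizer + rho, rho = rho,
       stages = data.frame(stage = seq_len(spec$n_stages), sum_sq = ss,
                           rms_mm = sqrt(ss / (3 * spec$n_probes))))
}

#' Displacement error metrics
#'
#' Mean Euclidean residual between simulated and measured probe
#' displacements over all probes and stages (the "error (mm)" reported by a
#' calibration), plus component-wise mean absolute errors as a percent of
#' the maximum measured displacement magnitude of that component.
#'
#' @param u_sim,u_exp matching n_probes x 3 x n_stages arrays (or n x 3
#'   matrices), mm.
#' @return list with `mean_mm` and `percent_by_component` (length 3).
#' @export
mean_error_mm <- function(u_sim, u_exp) {
  stopifnot(identical(dim(u_sim), dim(u_exp)))
  if (length(dim(u_sim)) == 2L) {
    u_sim <- array(u_sim, c(dim(u_sim), 1L))
    u_exp <- array(u_exp, c(dim(u_exp), 1L))
  }
  res <- u_sim - u_exp
  mean_mm <- mean(sqrt(res[, 1, ]^2 + res[, 2, ]^2 + res[, 3, ]^2))
  pct <- vapply(1:3, function(c) {
    mx <- max(abs(u_exp[, c, ]))
    if (mx == 0) return(NA_real_)
    100 * mean(abs(res[, c, ])) / mx
  }, numeric(1))
  names(pct) <- c("ux", "uy", "uz")
  list(mean_mm = mean_mm, percent_by_component = pct)
}

#' Central-difference objective gradient
#'
#' Classical finite-difference sensitivity: each parameter is perturbed by a
#' relative step (default 1e-6 of its bound range) and the objective is
#' re-evaluated, costing `2 N` forward evaluations for `N` parameters — the
#' cost the adjoint method avoids. The evaluation count is attached as
#' `attr(, "n_evals")`.
#'
#' @param p parameter vector.
#' @param objective_fn scalar function of `p`.
#' @param rel_step relative step size.
#' @param bounds optional `lower`/`upper` list; steps scale with the bound
#'   range instead of `|p|` when given.
#' @return gradient vector with attribute `n_evals = 2 * length(p)`.
#' @export
fd_gradient <- function(p, objective_fn, rel_step = 1e-6, bounds = NULL) {
  n <- length(p)
  scale <- if (!is.null(bounds)) bounds$upper - bounds$lower else
    pmax(abs(p), 1)
  h <- rel_step * scale
  if (any(h <= 0) || any(p + h == p))
    stop("finite-difference step underflow")
  g <- numeric(n)
  for (i in seq_len(n)) {
    pp <- p; pp[i] <- p[i] + h[i]
    pm <- p; pm[i] <- p[i] - h[i]
    g[i] <- (objective_fn(pp) - objective_fn(pm)) / (2 * h[i])
  }
  attr(g, "n_evals") <- 2L * n
  g
}

#' Adjoint-method objective gradient (heterogeneous linear case)
#'
#' Computes the exact gradient of the displacement objective with respect to
#' the per-element `(E, nu)` parameters with two factorized linear solves
#' regardless of the parameter count: one forward solve `K(p) u = f` and one
#' adjoint solve `K(p) lambda = W^T (W u - u_exp)` (the stiffness is
#' symmetric), each with all stages as simultaneous right-hand sides. The
#' per-parameter stiffness derivatives are assembled analytically per element
#' (`dK/dE = K_e / E`; `dK/dnu` from the plane-stress matrix derivative) and
#' contracted as `-lambda^T (dK/dp_i) u`.
#'
#' @param p parameter vector `c(E_1..E_m, nu_1..nu_m)`.
#' @param mesh a [surface_mesh()].
#' @param u_exp n_probes x 3 x n_stages measured displacement array.
#' @param W Q x n_nodes interpolation operator ([interpolation_matrix()]).
#' @param pressures stage pressures, kPa.
#' @param boundary optional perimeter displacement series (list `nodes`,
#'   `u`); default fixed perimeter.
#' @param alpha,bounds Tikhonov regularization on bound-normalized
#'   parameters (see [objective_spec()]).
#' @param stabilization diagonal regularization of the reduced stiffness.
#' @param frames optional precomputed local frames.
#' @return gradient vector (length `2 m`) with attributes `solve_count = 2`
#'   and `Pi` (the objective value at `p`, a free by-product).
#' @export
adjoint_gradient <- function(p, mesh, u_exp, W, pressures, boundary = NULL,
                             alpha = 0, bounds = NULL, stabilization = 1e-6,
                             frames = NULL) {
  m <- nrow(mesh$triangles)
  stopifnot(length(p) == 2 * m)
  if (is.null(frames)) frames <- compute_local_frames(mesh)
  field <- material_field("hetero_iso_linear", E = p[seq_len(m)],
                          nu = p[m + seq_len(m)], n_elements = m)
  n <- nrow(mesh$nodes)
  ns <- length(pressures)
  spec <- objective_spec(u_exp, alpha = alpha, bounds = bounds)
  f <- vapply(pressures, function(pr)
    reference_pressure_load_cpp(mesh$nodes, mesh$triangles - 1L, pr),
    numeric(3 * n))
  perim <- perimeter_nodes(mesh)
  ub <- if (is.null(boundary)) array(0, c(length(perim), 3, ns)) else
    boundary$u
  fw <- solve_linear(mesh, field, f, perim, ub,
                     stabilization = stabilization, frames = frames)
  U <- fw$u                                    # forward solve (1)
  W3 <- expand_operator(W)
  R <- as.matrix(W3 %*% U) - matrix(aperm(u_exp, c(2, 1, 3)),
                                    nrow = 3 * dim(u_exp)[1])
  Pi <- 0.5 * sum(R^2) / spec$normalizer
  rhs_full <- as.matrix(Matrix::t(W3) %*% R) / spec$normalizer
  Lam <- matrix(0, 3 * n, ns)
  Lam[fw$fdof, ] <- as.matrix(Matrix::solve(fw$Kff,
                                            rhs_full[fw$fdof, , drop = FALSE]))
  # adjoint solve (2); Lam zero at constrained dofs
  gt <- linear_grad_terms_cpp(mesh$nodes, mesh$triangles - 1L, mesh$thickness,
                              field$E, field$nu, frames$x_axis, frames$y_axis,
                              U, Lam)
  g <- c(gt$grad_E, gt$grad_nu)
  if (alpha > 0) {
    pt <- normalize_p(p, bounds)
    g <- g + alpha * (pt - 0.5) / (bounds$upper - bounds$lower)
    Pi <- Pi + alpha / 2 * sum((pt - 0.5)^2)
  }
  attr(g, "solve_count") <- 2L
  attr(g, "Pi") <- Pi
  g
}

# ---------------------------------------------------------------------------
# Particle swarm optimization
# ---------------------------------------------------------------------------

#' Particle swarm configuration
#'
#' Hyperparameters of the custom PSO: velocity update
#' `v <- w*v + c1*rand*(pbest - x) + c2*rand*(gbest - x)` with inertia `w`
#' starting at `w_init` and multiplied by `w_damp` after each iteration;
#' velocities clamped to `[v_min, v_max]` before the position update; a
#' position that would leave `[var_min, var_max]` has the offending velocity
#' component zeroed and the position set to the violated bound.
#'
#' @param n_pop swarm size (>= 2).
#' @param var_min,var_max per-dimension position bounds.
#' @param v_min,v_max velocity bounds (scalar or per dimension; default
#'   +/- 10% of the position range).
#' @param c1,c2 cognitive/social weights (default 2.0 each).
#' @param w_init,w_damp inertia schedule (default 1.0, 0.99).
#' @param max_iter iteration cap (default 200).
#' @param tol relative convergence tolerance on the global best objective
#'   (default 1e-6 of its initial value), assessed over `stall_iters`
#'   iterations.
#' @param stall_iters window for the convergence check (default 30).
#' @param seed RNG seed.
#' @param workers parallel workers for the per-particle objective batch
#'   (forked processes; 1 = serial).
#' @return object of class `swarm_config`.
#' @export
swarm_config <- function(n_pop, var_min, var_max, v_min = NULL, v_max = NULL,
                         c1 = 2, c2 = 2, w_init = 1.0, w_damp = 0.99,
                         max_iter = 200L, tol = 1e-6, stall_iters = 30L,
                         seed = 1L, workers = 1L) {
  if (n_pop < 2L) stop("n_pop must be at least 2")
  var_min <- as.numeric(var_min); var_max <- as.numeric(var_max)
  if (any(var_min >= var_max)) stop("var_min must be below var_max")
  d <- length(var_min)
  if (is.null(v_max)) v_max <- 0.1 * (var_max - var_min)
  if (is.null(v_min)) v_min <- -v_max
  v_min <- rep_len(as.numeric(v_min), d)
  v_max <- rep_len(as.numeric(v_max), d)
  if (any(v_min >= v_max)) stop("v_min must be below v_max")
  structure(list(n_pop = as.integer(n_pop), var_min = var_min,
                 var_max = var_max, v_min = v_min, v_max = v_max,
                 c1 = c1, c2 = c2, w_init = w_init, w_damp = w_damp,
                 max_iter = as.integer(max_iter), tol = tol,
                 stall_iters = as.integer(stall_iters),
                 seed = as.integer(seed), workers = as.integer(workers)),
            class = "swarm_config")
}

#' Minimize an objective with the particle swarm
#'
#' Fully seeded gradient-free minimization under box constraints with the
#' clamping rules described in [swarm_config()]. Positions are initialized
#' uniformly in the bounds, velocities uniformly in one tenth of the velocity
#' bounds. A failed objective evaluation (`NA`/`Inf`/error) is replaced by a
#' large penalty (1e6 x the current global best, or 1e12 before one exists)
#' and logged as a warning.
#'
#' @param objective_fn scalar function of a parameter vector.
#' @param config a [swarm_config()].
#' @return object of class `pso_result`: `par`, `value`, `history`
#'   (global-best objective per iteration), `w_history`, `iterations`,
#'   `n_evals`.
#' @export
pso_minimize <- function(objective_fn, config) {
  stopifnot(inherits(config, "swarm_config"))
  set.seed(config$seed)
  d <- length(config$var_min)
  np <- config$n_pop
  X <- matrix(stats::runif(np * d, rep(config$var_min, each = np),
                           rep(config$var_max, each = np)), np, d)
  V <- matrix(stats::runif(np * d, rep(0.1 * config$v_min, each = np),
                           rep(0.1 * config$v_max, each = np)), np, d)
  eval_batch <- function(Xm) {
    evals <- if (config$workers > 1L) {
      parallel::mclapply(seq_len(nrow(Xm)), function(i)
        tryCatch(objective_fn(Xm[i, ]), error = function(e) NA_real_),
        mc.cores = config$workers)
    } else {
      lapply(seq_len(nrow(Xm)), function(i)
        tryCatch(objective_fn(Xm[i, ]), error = function(e) NA_real_))
    }
    unlist(evals)
  }
  n_evals <- 0L
  scores <- eval_batch(X); n_evals <- n_evals + np
  bad <- !is.finite(scores)
  if (all(bad)) stop("all particles failed objective evaluation")
  if (any(bad)) {
    warning(sum(bad), " particle(s) failed evaluation; penalized")
    scores[bad] <- 1e12
  }
  pbest_x <- X; pbest_s <- scores
  gi <- which.min(pbest_s)
  gbest_x <- pbest_x[gi, ]; gbest_s <- pbest_s[gi]
  w <- config$w_init
  history <- gbest_s
  w_history <- w
  initial_ref <- max(abs(gbest_s), .Machine$double.eps)
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    r1 <- matrix(stats::runif(np * d), np, d)
    r2 <- matrix(stats::runif(np * d), np, d)
    V <- w * V + config$c1 * r1 * (pbest_x - X) +
      config$c2 * r2 * (matrix(gbest_x, np, d, byrow = TRUE) - X)
    # clamp velocity
    V <- pmin(pmax(V, matrix(config$v_min, np, d, byrow = TRUE)),
              matrix(config$v_max, np, d, byrow = TRUE))
    Xn <- X + V
    lo <- matrix(config$var_min, np, d, byrow = TRUE)
    hi <- matrix(config$var_max, np, d, byrow = TRUE)
    below <- Xn < lo; above <- Xn > hi
    V[below | above] <- 0
    Xn[below] <- lo[below]; Xn[above] <- hi[above]
    X <- Xn
    scores <- eval_batch(X); n_evals <- n_evals + np
    bad <- !is.finite(scores)
    if (any(bad)) {
      warning(sum(bad), " particle(s) failed evaluation; penalized")
      scores[bad] <- 1e6 * max(abs(gbest_s), 1e6)
    }
    imp <- scores < pbest_s
    pbest_x[imp, ] <- X[imp, , drop = FALSE]
    pbest_s[imp] <- scores[imp]
    gi <- which.min(pbest_s)
    if (pbest_s[gi] < gbest_s) {
      gbest_s <- pbest_s[gi]; gbest_x <- pbest_x[gi, ]
    }
    w <- w * config$w_damp
    history <- c(history, gbest_s)
    w_history <- c(w_history, w)
    if (it > config$stall_iters) {
      drop <- history[it + 1L - config$stall_iters] - history[it + 1L]
      if (drop < config$tol * initial_ref) break
    }
  }
  structure(list(par = gbest_x, value = gbest_s, history = history,
                 w_history = w_history, iterations = it, n_evals = n_evals),
            class = "pso_result")
}

#' @method print pso_result
#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("pso_result: best objective %.6g after %d iterations (%d evaluations)\n",
              x$value, x$iterations, x$n_evals))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Multi-start calibration driver
# ---------------------------------------------------------------------------

#' Calibrate a constitutive model against probe displacements
#'
#' The IFEA engine: estimates the unknown material parameters of a chosen
#' constitutive case by minimizing the displacement objective (see
#' [objective_spec()]) between forward-model predictions and measured probe
#' displacements at each inflation stage.
#'
#' The gradient method is bounded nonlinear least squares
#' (Levenberg-Marquardt with box constraints) for the homogeneous
#' hyperelastic cases, and bound-constrained quasi-Newton minimization
#' (L-BFGS-B, in bound-normalized coordinates) driven by the
#' [adjoint_gradient()] for the heterogeneous linear case (with Tikhonov
#' weight `alpha`). Starting points are drawn uniformly within the search
#' bounds from the given seed; the best-of-starts (lowest objective, ties by
#' mean displacement error) is returned together with the per-start table.
#' `method = "pso"` runs the particle swarm instead (one swarm; `n_starts`
#' is ignored).
#'
#' @param case `"homo_iso_hyper"`, `"homo_aniso_hyper"`, or
#'   `"hetero_iso_linear"`.
#' @param mesh a [surface_mesh()].
#' @param probes a [probe_field()].
#' @param profile a [pressure_profile()].
#' @param boundary optional perimeter displacement series (default: fixed
#'   perimeter).
#' @param method `"gradient"` or `"pso"`.
#' @param n_starts number of random starts (default 7).
#' @param seed RNG seed.
#' @param bounds search bounds (default [default_bounds()]).
#' @param alpha Tikhonov weight, heterogeneous gradient path only (default
#'   1e-6 there, 0 elsewhere).
#' @param fiber_a0 fiber direction in the element local frame (HGO case).
#' @param n_increments forward solver load increments per stage.
#' @param solver_control passed to the nonlinear solver.
#' @param pso overrides for the [swarm_config()] (e.g. `n_pop`, `max_iter`).
#' @param maxit_lbfgs iteration cap of the heterogeneous minimization.
#' @param workers parallel workers for PSO particle batches.
#' @return object of class `calibration_result`.
#' @export
calibrate <- function(case, mesh, probes, profile, boundary = NULL,
                      method = c("gradient", "pso"), n_starts = 7L,
                      seed = 1L, bounds = NULL, alpha = NULL,
                      fiber_a0 = c(1, 0), n_increments = 1L,
                      solver_control = list(), pso = list(),
                      maxit_lbfgs = 500L, workers = 1L) {
  method <- match.arg(method)
  case <- match.arg(case, c("homo_iso_hyper", "homo_aniso_hyper",
                            "hetero_iso_linear"))
  m <- nrow(mesh$triangles)
  if (is.null(bounds)) bounds <- default_bounds(case, n_elements = m)
  if (is.null(alpha))
    alpha <- if (case == "hetero_iso_linear" && method == "gradient") 1e-6 else 0
  W <- interpolation_matrix(mesh$nodes, probes$coords, k = 5L)
  u_exp <- probes$u
  spec <- objective_spec(u_exp, alpha = alpha, bounds = bounds)
  pressures <- pressure_at(profile, profile$stage_times)
  if (case == "hetero_iso_linear") {
    res <- calibrate_hetero(mesh, u_exp, W, pressures, boundary, method,
                            n_starts, seed, bounds, alpha, spec, pso,
                            maxit_lbfgs, workers)
  } else {
    res <- calibrate_homo(case, mesh, probes, profile, boundary, method,
                          n_starts, seed, bounds, spec, W, fiber_a0,
                          n_increments, solver_control, pso, workers)
  }
  res$case <- case
  res$method <- method
  res$seed <- seed
  class(res) <- "calibration_result"
  res
}

#' @method print calibration_result
#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: %s via %s (%s)\n", x$case, x$method,
              x$algorithm))
  cat("  optimal parameters:\n")
  if (length(x$par) <= 8) {
    print(round(x$par, 6))
  } else {
    cat(sprintf("    %d-parameter field; E range %.4g-%.4g kPa\n",
                length(x$par), min(x$par[seq_len(length(x$par) / 2)]),
                max(x$par[seq_len(length(x$par) / 2)])))
  }
  cat(sprintf("  objective %.6g; mean displacement error %.4g mm\n",
              x$objective, x$mean_error_mm))
  if (!is.null(x$per_start) && nrow(x$per_start) > 1)
    cat(sprintf("  %d starts, %d converged\n", nrow(x$per_start),
                sum(x$per_start$converged)))
  invisible(x)
}

probe_forward_fn <- function(case, mesh, profile, boundary, W, fiber_a0,
                             n_increments, solver_control,
                             warm_cache = TRUE) {
  m <- nrow(mesh$triangles)
  force(case); force(W)
  cache <- new.env(parent = emptyenv())
  cache$stages <- NULL
  function(p) {
    field <- if (case == "homo_iso_hyper")
      material_field(case, params = mooney_rivlin(p[1], p[2], p[3]),
                     n_elements = m)
    else
      material_field(case, params = hgo(p[1], p[2], p[3], p[4],
                                        min(p[5], 1 / 3), a0 = fiber_a0),
                     n_elements = m)
    run <- run_inflation(mesh, field, profile, boundary = boundary,
                         n_increments = n_increments,
                         control = solver_control,
                         warm_start = if (warm_cache) cache$stages)
    ns <- length(run$stages)
    if (warm_cache) cache$stages <- lapply(run$stages, `[[`, "u")
    out <- array(0, c(nrow(W), 3, ns))
    for (s in seq_len(ns))
      out[, , s] <- as.matrix(W %*% run$stages[[s]]$u)
    out
  }
}

# smooth box-bound transform (lsqnonlin-style): p = lo + (hi-lo) sin^2(theta)
bounds_to_theta <- function(p, bounds) {
  z <- (p - bounds$lower) / (bounds$upper - bounds$lower)
  asin(sqrt(pmin(pmax(z, 1e-8), 1 - 1e-8)))
}
theta_to_bounds <- function(theta, bounds) {
  bounds$lower + (bounds$upper - bounds$lower) * sin(theta)^2
}

# One bounded least-squares start: LM in transformed coordinates, then an
# active-set polish for parameters that converged onto a bound, then bound
# probes (each parameter trialed at either bound, strict improvements kept)
# to step out of the shallow local dips that flat directions produce.
lm_bounded_start <- function(p0, resid_fn, bounds, snap_tol = 0.02,
                             max_probe = 3L) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 50L, ftol = 1e-10,
                                     ptol = 1e-10, epsfcn = 1e-8)
  d <- length(p0)
  niter <- 0L
  pi_of <- function(p) 0.5 * sum(resid_fn(p)^2)
  # LM over the parameters marked free, the rest held at p_fix
  refit <- function(p_fix, free) {
    if (!any(free)) return(list(p = p_fix, Pi = pi_of(p_fix), niter = 0L,
                                info = 1L))
    sub <- list(lower = bounds$lower[free], upper = bounds$upper[free])
    rf <- function(thf) {
      q <- p_fix
      q[free] <- theta_to_bounds(thf, sub)
      resid_fn(q)
    }
    fit <- minpack.lm::nls.lm(par = bounds_to_theta(p_fix[free], sub),
                              fn = rf, control = ctrl)
    q <- p_fix
    q[free] <- theta_to_bounds(unname(fit$par), sub)
    list(p = q, Pi = 0.5 * sum(fit$fvec^2), niter = fit$niter,
         info = fit$info)
  }
  r <- refit(p0, rep(TRUE, d))
  p <- r$p; Pi <- r$Pi; niter <- niter + r$niter; info <- r$info
  rng <- bounds$upper - bounds$lower
  # snap near-bound parameters onto the bound and refit the others
  at_lo <- (p - bounds$lower) / rng < snap_tol
  at_hi <- (bounds$upper - p) / rng < snap_tol
  if (any(at_lo | at_hi)) {
    p_snap <- p
    p_snap[at_lo] <- bounds$lower[at_lo]
    p_snap[at_hi] <- bounds$upper[at_hi]
    r <- refit(p_snap, !(at_lo | at_hi))
    niter <- niter + r$niter
    if (r$Pi <= Pi) {
      p <- r$p; Pi <- r$Pi
    }
  }
  # Bound probes: trial each parameter at either bound, refit the remaining
  # interior parameters, and keep strict improvements. Probes that leave the
  # objective unchanged belong to inert directions and are skipped; probes
  # that degrade it by more than a few percent cannot be rescued by a refit.
  for (probe in seq_len(max_probe)) {
    cand <- list()
    for (j in seq_len(d)) {
      for (b in c(bounds$lower[j], bounds$upper[j])) {
        if (p[j] == b) next
        q <- p; q[j] <- b
        Pij <- pi_of(q)
        moved <- abs(Pij - Pi) > 1e-11 * max(Pi, .Machine$double.eps)
        if (moved && Pij < Pi * 1.05)
          cand[[length(cand) + 1L]] <- list(j = j, p = q, Pi = Pij)
      }
    }
    if (!length(cand)) break
    cand <- cand[order(vapply(cand, `[[`, numeric(1), "Pi"))]
    cand <- cand[seq_len(min(2L, length(cand)))]
    improved <- FALSE
    for (cd in cand) {
      free <- !(cd$p == bounds$lower | cd$p == bounds$upper)
      free[cd$j] <- FALSE
      r <- refit(cd$p, free)
      niter <- niter + r$niter
      Pf <- min(r$Pi, cd$Pi)
      if (Pf < Pi * (1 - 1e-9)) {
        p <- if (r$Pi <= cd$Pi) r$p else cd$p
        Pi <- Pf
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(par_p = p, Pi = Pi, niter = niter,
       converged = info %in% c(1:4) || Pi < .Machine$double.eps)
}

calibrate_homo <- function(case, mesh, probes, profile, boundary, method,
                           n_starts, seed, bounds, spec, W, fiber_a0,
                           n_increments, solver_control, pso, workers) {
  # each optimization trajectory gets its own forward solver (and its own
  # warm-start cache): evaluations along one trajectory are close together,
  # while sharing cached states across independent starts would make each
  # start's path depend on the previous ones
  new_forward_fn <- function(warm = TRUE)
    probe_forward_fn(case, mesh, profile, boundary, W, fiber_a0,
                     n_increments, solver_control, warm_cache = warm)
  forward_fn <- new_forward_fn(warm = FALSE)
  nrm <- sqrt(spec$normalizer)
  new_resid_fn <- function() {
    fwd <- new_forward_fn()
    function(p) {
      u_sim <- tryCatch(fwd(p), error = function(e) NULL)
      if (is.null(u_sim)) return(rep(1e3, length(spec$u_exp)))
      as.numeric(u_sim - spec$u_exp) / nrm
    }
  }
  pi_fn <- function(p) {
    r <- new_resid_fn()(p)
    0.5 * sum(r^2)
  }
  d <- length(bounds$lower)
  pnames <- names(bounds$lower)
  if (method == "pso") {
    defaults <- list(n_pop = if (case == "homo_iso_hyper") 24L else 48L,
                     var_min = bounds$lower, var_max = bounds$upper,
                     v_min = -5, v_max = 5, seed = seed, workers = workers)
    cfg <- do.call(swarm_config, utils::modifyList(defaults, pso))
    fit <- pso_minimize(pi_fn, cfg)
    best <- stats::setNames(fit$par, pnames)
    err <- mean_error_mm(forward_fn(best), spec$u_exp)
    per_start <- data.frame(start = 1L, objective = fit$value,
                            mean_error_mm = err$mean_mm, converged = TRUE,
                            iterations = fit$iterations)
    return(list(par = best, objective = fit$value,
                mean_error_mm = err$mean_mm,
                error_percent = err$percent_by_component,
                per_start = per_start, history = fit$history,
                iterations = fit$iterations, algorithm = "PSO"))
  }
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * d, rep(bounds$lower, each = n_starts),
                                rep(bounds$upper, each = n_starts)),
                   n_starts, d)
  # Levenberg-Marquardt on smoothly bound-transformed parameters; a plain
  # box projection tends to freeze parameters that touch a bound mid-run.
  # The transform flattens near a bound, so parameters whose optimum sits
  # on a bound creep; an active-set polish snaps near-bound parameters to
  # the bound and refits the remaining free ones (kept only if no worse).
  rows <- vector("list", n_starts)
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      lm_bounded_start(starts[i, ], new_resid_fn(), bounds),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("start ", i, " failed; skipped")
      rows[[i]] <- data.frame(start = i, objective = NA_real_,
                              mean_error_mm = NA_real_, converged = FALSE,
                              iterations = NA_integer_)
      next
    }
    fits[[i]] <- fit
    rows[[i]] <- data.frame(start = i, objective = fit$Pi,
                            mean_error_mm = NA_real_,
                            converged = fit$converged,
                            iterations = fit$niter)
  }
  per_start <- do.call(rbind, rows)
  init <- as.data.frame(starts)
  conv <- t(vapply(seq_len(n_starts), function(i)
    if (is.null(fits[[i]])) rep(NA_real_, d) else fits[[i]]$par_p,
    numeric(d)))
  colnames(init) <- paste0("init_", pnames)
  colnames(conv) <- paste0("opt_", pnames)
  per_start <- cbind(per_start, init, conv)
  ok <- which(!is.na(per_start$objective))
  if (length(ok) == 0) stop("all calibration starts failed")
  # ties on objective broken by mean displacement error
  best_Pi <- min(per_start$objective[ok])
  cand <- ok[per_start$objective[ok] <= best_Pi * (1 + 1e-9)]
  errs <- vapply(cand, function(i) {
    e <- mean_error_mm(forward_fn(fits[[i]]$par_p), spec$u_exp)
    e$mean_mm
  }, numeric(1))
  win <- cand[which.min(errs)]
  per_start$mean_error_mm[cand] <- errs
  best <- stats::setNames(fits[[win]]$par_p, pnames)
  err <- mean_error_mm(forward_fn(best), spec$u_exp)
  list(par = best, objective = per_start$objective[win],
       mean_error_mm = err$mean_mm,
       error_percent = err$percent_by_component,
       per_start = per_start, iterations = per_start$iterations[win],
       algorithm = "bounded nonlinear least squares (LM)")
}

calibrate_hetero <- function(mesh, u_exp, W, pressures, boundary, method,
                             n_starts, seed, bounds, alpha, spec, pso,
                             maxit_lbfgs, workers) {
  m <- nrow(mesh$triangles)
  frames <- compute_local_frames(mesh)
  d <- 2L * m
  rng <- bounds$upper - bounds$lower
  pi_only <- function(p) {
    g <- adjoint_gradient(p, mesh, u_exp, W, pressures, boundary,
                          alpha = alpha, bounds = bounds, frames = frames)
    attr(g, "Pi")
  }
  if (method == "pso") {
    alpha <- 0  # regularization applies to the gradient-based path only
    defaults <- list(n_pop = min(1000L, 25L * d), var_min = bounds$lower,
                     var_max = bounds$upper, v_min = -40, v_max = 40,
                     seed = seed, workers = workers)
    cfg <- do.call(swarm_config, utils::modifyList(defaults, pso))
    fit <- pso_minimize(function(p) {
      g <- adjoint_gradient(p, mesh, u_exp, W, pressures, boundary,
                            alpha = 0, bounds = bounds, frames = frames)
      attr(g, "Pi")
    }, cfg)
    best <- fit$par
    err <- hetero_error(best, mesh, u_exp, W, pressures, boundary, frames)
    per_start <- data.frame(start = 1L, objective = fit$value,
                            mean_error_mm = err$mean_mm, converged = TRUE,
                            iterations = fit$iterations)
    return(list(par = best, objective = fit$value,
                mean_error_mm = err$mean_mm,
                error_percent = err$percent_by_component,
                per_start = per_start, history = fit$history,
                iterations = fit$iterations, algorithm = "PSO"))
  }
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * d), n_starts, d)  # normalized
  solve_counter <- 0L
  fn <- function(z) {
    p <- bounds$lower + z * rng
    g <- adjoint_gradient(p, mesh, u_exp, W, pressures, boundary,
                          alpha = alpha, bounds = bounds, frames = frames)
    solve_counter <<- solve_counter + attr(g, "solve_count")
    attr(g, "Pi")
  }
  gr <- function(z) {
    p <- bounds$lower + z * rng
    g <- adjoint_gradient(p, mesh, u_exp, W, pressures, boundary,
                          alpha = alpha, bounds = bounds, frames = frames)
    solve_counter <<- solve_counter + attr(g, "solve_count")
    as.numeric(g) * rng
  }
  rows <- vector("list", n_starts)
  pars <- matrix(NA_real_, n_starts, d)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B", lower = 0,
                   upper = 1,
                   control = list(maxit = maxit_lbfgs, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("start ", i, " failed; skipped")
      rows[[i]] <- data.frame(start = i, objective = NA_real_,
                              mean_error_mm = NA_real_, converged = FALSE,
                              iterations = NA_integer_)
      next
    }
    pars[i, ] <- bounds$lower + fit$par * rng
    rows[[i]] <- data.frame(start = i, objective = fit$value,
                            mean_error_mm = NA_real_,
                            converged = fit$convergence == 0,
                            iterations = fit$counts[1])
  }
  per_start <- do.call(rbind, rows)
  ok <- which(!is.na(per_start$objective))
  if (length(ok) == 0) stop("all calibration starts failed")
  win <- ok[which.min(per_start$objective[ok])]
  best <- pars[win, ]
  err <- hetero_error(best, mesh, u_exp, W, pressures, boundary, frames)
  per_start$mean_error_mm[win] <- err$mean_mm
  list(par = best, objective = per_start$objective[win],
       mean_error_mm = err$mean_mm,
       error_percent = err$percent_by_component,
       per_start = per_start, iterations = per_start$iterations[win],
       solve_count = solve_counter,
       algorithm = "adjoint-gradient bound-constrained minimization (L-BFGS-B)")
}

hetero_error <- function(p, mesh, u_exp, W, pressures, boundary, frames) {
  m <- nrow(mesh$triangles)
  field <- material_field("hetero_iso_linear", E = p[seq_len(m)],
                          nu = p[m + seq_len(m)], n_elements = m)
  n <- nrow(mesh$nodes)
  ns <- length(pressures)
  f <- vapply(pressures, function(pr)
    reference_pressure_load_cpp(mesh$nodes, mesh$triangles - 1L, pr),
    numeric(3 * n))
  perim <- perimeter_nodes(mesh)
  ub <- if (is.null(boundary)) array(0, c(length(perim), 3, ns)) else boundary$u
  U <- solve_linear(mesh, field, f, perim, ub, frames = frames)$u
  u_sim <- array(0, dim(u_exp))
  for (s in seq_len(ns))
    u_sim[, , s] <- as.matrix(W %*% matrix(U[, s], ncol = 3, byrow = TRUE))
  mean_error_mm(u_sim, u_exp)
}

#' Shear modulus map of a heterogeneous calibration
#'
#' Per-element shear modulus `mu = E / (2 (1 + nu))` from a heterogeneous
#' parameter vector, for regional mapping onto the lung surface.
#'
#' @param p parameter vector `c(E, nu)` (length 2 m).
#' @return numeric vector of length m, kPa.
#' @export
shear_modulus_map <- function(p) {
  m <- length(p) / 2
  E <- p[seq_len(m)]; nu <- p[m + seq_len(m)]
  E / (2 * (1 + nu))
}
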