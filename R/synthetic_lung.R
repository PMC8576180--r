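#' Generate an open ellipsoidal-cap surface mesh
#'
#' Constructive triangulation of a lobe-like curved open surface: a
#' structured ring layout on the unit disc (center fan plus annulus strips
#' merged by angle) is mapped onto an ellipsoidal cap. The ring node budget
#' is chosen so the element count equals `n_target` exactly; interior nodes
#' receive a small seeded jitter so elements are irregular, as in meshes
#' derived from stereo-camera surface reconstructions. Winding is
#' consistently outward (away from the ellipsoid center).
#'
#' @param n_target exact number of triangular elements (>= 4).
#' @param semi_axes ellipsoid semi-axes (a, b, c), mm.
#' @param seed RNG seed for the jitter.
#' @param phi_max polar half-angle of the cap, rad (default pi/3).
#' @param jitter relative in-plane node jitter (0 disables).
#' @param thickness,ap_axis stored on the mesh.
#' @return a [surface_mesh()].
#' @export
generate_cap_mesh <- function(n_target, semi_axes = c(60, 50, 40), seed = 1L,
                              phi_max = pi / 3, jitter = 0.15,
                              thickness = 1.0, ap_axis = c(0, 1, 0)) {
  if (n_target < 4L) stop("n_target must be at least 4")
  # ring sizes proportional to radius (m_r ~ c*r with c = T/R^2 so rings and
  # angular spacing stay balanced); the outer ring absorbs the remainder so
  # the triangle count m_1 + sum_{r>=2} (m_{r-1} + m_r) = c R^2 hits
  # n_target exactly
  R <- max(1L, as.integer(round(sqrt(n_target / 6))))
  repeat {
    if (R == 1L) {
      m <- n_target
      break
    }
    cdens <- n_target / R^2
    m <- pmax(3L, as.integer(round(cdens * seq_len(R - 1L))))
    m_outer <- n_target - 2L * sum(m)
    if (m_outer >= max(3L, m[R - 1L] %/% 2L)) {
      m <- c(m, m_outer)
      break
    }
    R <- R - 1L
  }
  set.seed(seed)
  # parameter-plane nodes: center + rings at radius r/R
  theta <- list()
  nodes2 <- matrix(0, 1, 2)  # center
  ring_start <- integer(R)
  for (r in seq_len(R)) {
    th <- 2 * pi * (seq_len(m[r]) - 1L) / m[r]
    rad <- rep(r / R, m[r])
    if (jitter > 0 && r < R) {  # keep the perimeter ring regular
      dth <- 2 * pi / m[r]
      th <- th + stats::runif(m[r], -jitter, jitter) * dth
      rad <- rad + stats::runif(m[r], -jitter, jitter) * (1 / R) * 0.5
    }
    ring_start[r] <- nrow(nodes2) + 1L
    nodes2 <- rbind(nodes2, cbind(rad * cos(th), rad * sin(th)))
    theta[[r]] <- th
  }
  ring_idx <- lapply(seq_len(R), function(r) ring_start[r] + seq_len(m[r]) - 1L)
  tris <- matrix(0L, 0, 3)
  # center fan
  A <- ring_idx[[1L]]
  ka <- seq_len(m[1])
  tris <- rbind(tris, cbind(1L, A[ka], A[c(ka[-1L], ka[1L])]))
  # annulus strips, merged by unwrapped angle (a + b triangles each)
  if (R >= 2L) for (r in 2:R) {
    A <- ring_idx[[r - 1L]]; B <- ring_idx[[r]]
    a <- m[r - 1L]; b <- m[r]
    ka <- 0L; kb <- 0L
    while (ka < a || kb < b) {
      adv_a <- if (ka >= a) FALSE else if (kb >= b) TRUE else
        (ka + 1) / a <= (kb + 1) / b
      if (adv_a) {
        tris <- rbind(tris, c(A[ka %% a + 1L], B[kb %% b + 1L],
                              A[(ka + 1L) %% a + 1L]))
        ka <- ka + 1L
      } else {
        tris <- rbind(tris, c(B[kb %% b + 1L], B[(kb + 1L) %% b + 1L],
                              A[ka %% a + 1L]))
        kb <- kb + 1L
      }
    }
  }
  stopifnot(nrow(tris) == n_target)
  # map unit disc -> ellipsoidal cap (rho in [0,1] -> polar angle)
  rho <- pmin(sqrt(rowSums(nodes2^2)), 1)
  th <- atan2(nodes2[, 2], nodes2[, 1])
  phi <- rho * phi_max
  nodes3 <- cbind(semi_axes[1] * sin(phi) * cos(th),
                  semi_axes[2] * sin(phi) * sin(th),
                  semi_axes[3] * cos(phi))
  surface_mesh(nodes3, tris, thickness = thickness, ap_axis = ap_axis)
}

#' Generate a concave inflation pressure ramp
#'
#' Smooth, monotone, concave-down pressure-time ramp from 0 to `peak_kPa`
#' over `duration_s` (the shape of a controlled-inflation loading curve:
#' fast early rise, flattening toward peak), with stage times at the five
#' 20% increments of the duration.
#'
#' @param peak_kPa peak pressure, kPa (default 2.5).
#' @param duration_s inflation duration, s (default 2, i.e. the inhalation
#'   half of a 15 breaths-per-minute cycle).
#' @param n_samples number of samples (default 51).
#' @return a [pressure_profile()].
#' @export
generate_pressure_profile <- function(peak_kPa = 2.5, duration_s = 2,
                                      n_samples = 51L) {
  stopifnot(peak_kPa > 0, duration_s > 0, n_samples >= 2L)
  t <- seq(0, duration_s, length.out = n_samples)
  s <- t / duration_s
  p <- peak_kPa * (1 - (1 - s)^2)
  pressure_profile(t, p,
                   stage_times = duration_s * seq(0.2, 1, by = 0.2))
}

#' Ground-truth material fields for synthetic scenarios
#'
#' Homogeneous scenarios emit a single parameter set (defaults: the
#' calibrated optima of the corresponding case, i.e. the canonical test
#' point); the heterogeneous scenario emits a smooth per-element Young's
#' modulus field varying linearly along the anterior-posterior axis between
#' `E_range` (rescaled so the extremes land exactly on the bounds) with
#' constant Poisson's ratio.
#'
#' @param mesh a [surface_mesh()].
#' @param case constitutive case tag.
#' @param spec named list overriding defaults (`C10`, `C01`, `D1`; `D`,
#'   `k1`, `k2`, `kappa`, `a0`; `E_range`, `nu`).
#' @return a [material_field()].
#' @export
make_ground_truth_field <- function(mesh, case, spec = list()) {
  m <- nrow(mesh$triangles)
  case <- match.arg(case, c("homo_iso_hyper", "homo_aniso_hyper",
                            "hetero_iso_linear"))
  g <- function(name, default) if (is.null(spec[[name]])) default else spec[[name]]
  if (case == "homo_iso_hyper") {
    material_field(case, params = mooney_rivlin(g("C10", 136.5), g("C01", 1.0),
                                                g("D1", 13.43e-4)),
                   n_elements = m)
  } else if (case == "homo_aniso_hyper") {
    material_field(case,
                   params = hgo(g("C10", 116.4), g("D", 43.6e-4), g("k1", 1.0),
                                g("k2", 0.12), g("kappa", 0.33),
                                a0 = g("a0", c(1, 0))),
                   n_elements = m)
  } else {
    E_range <- g("E_range", c(200, 500))
    nu <- g("nu", 0.43)
    cent <- (mesh$nodes[mesh$triangles[, 1], ] +
             mesh$nodes[mesh$triangles[, 2], ] +
             mesh$nodes[mesh$triangles[, 3], ]) / 3
    s <- as.numeric(cent %*% mesh$ap_axis)
    s <- (s - min(s)) / (max(s) - min(s))  # exact 0..1 span
    material_field(case, E = E_range[1] + s * (E_range[2] - E_range[1]),
                   nu = rep(nu, m), n_elements = m)
  }
}

# seeded blue-noise (dart-throwing) sampling of points on the mesh surface
sample_surface_points <- function(mesh, n_points, seed = 1L) {
  set.seed(seed)
  tri <- mesh$triangles
  areas <- triangle_areas(mesh$nodes, tri)
  total <- sum(areas)
  r_min <- 0.55 * sqrt(total / n_points / pi)
  cell <- max(r_min, 1e-9)
  pts <- matrix(NA_real_, n_points, 3)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  key_of <- function(p) paste(floor(p / cell), collapse = "/")
  neighbors_clear <- function(p) {
    base <- floor(p / cell)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(base + c(dx, dy, dz), collapse = "/")
      occ <- grid[[k]]
      if (!is.null(occ)) {
        for (i in occ)
          if (sum((pts[i, ] - p)^2) < r_min^2) return(FALSE)
      }
    }
    TRUE
  }
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 60L * n_points
  while (accepted < n_points) {
    if (attempts > max_attempts) {  # relax the radius and keep going
      r_min <- r_min * 0.8
      attempts <- 0L
    }
    e <- sample.int(nrow(tri), 1L, prob = areas)
    b <- stats::runif(2)
    if (sum(b) > 1) b <- 1 - b
    p <- (1 - b[1] - b[2]) * mesh$nodes[tri[e, 1], ] +
      b[1] * mesh$nodes[tri[e, 2], ] + b[2] * mesh$nodes[tri[e, 3], ]
    attempts <- attempts + 1L
    if (neighbors_clear(p)) {
      accepted <- accepted + 1L
      pts[accepted, ] <- p
      k <- key_of(p)
      grid[[k]] <- c(grid[[k]], accepted)
    }
  }
  pts
}

#' Seeded non-proportional perimeter displacement series
#'
#' Emulates the experimentally recorded boundary motion of the visible lobe
#' region: the perimeter of the surface is not clamped in a real inflation
#' but follows the surrounding tissue, and the recorded series is not
#' proportional to the applied pressure (nor low-rank across stages). The
#' series is a monotone base motion (in-plane radial bulge plus normal lift,
#' scaled by the load fraction) superposed with an independent smooth
#' low-order harmonic perturbation per stage. Each stage therefore applies a
#' genuinely independent boundary excitation, which is what renders the
#' per-element parameters of the heterogeneous (linear elastic) inverse
#' problem identifiable from multi-stage data.
#'
#' @param mesh a [surface_mesh()].
#' @param profile a [pressure_profile()].
#' @param amplitude overall displacement scale, mm (default 2).
#' @param seed seed for the random phases and per-stage harmonics.
#' @return list with `nodes` (sorted perimeter indices) and `u`
#'   (n_perim x 3 x n_stages array, mm).
#' @export
make_boundary_series <- function(mesh, profile, amplitude = 2, seed = 1L) {
  perim <- perimeter_nodes(mesh)
  np <- length(perim)
  ns <- length(profile$stage_times)
  xy <- mesh$nodes[perim, , drop = FALSE]
  ctr <- colMeans(mesh$nodes)
  rad <- xy - matrix(ctr, np, 3, byrow = TRUE)
  rad[, 3] <- 0
  rn <- sqrt(rowSums(rad^2))
  rad <- rad / pmax(rn, 1e-12)
  theta <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
  set.seed(seed)
  ph <- stats::runif(2, 0, 2 * pi)
  base <- 0.6 * rad * (1 + 0.3 * cos(theta + ph[1])) +
    0.5 * cbind(0, 0, 1 + 0.4 * sin(2 * theta + ph[2]))
  s <- pressure_at(profile, profile$stage_times) /
    max(pressure_at(profile, profile$stage_times))
  u <- array(0, c(np, 3, ns))
  for (n in seq_len(ns)) {
    # smooth per-stage harmonic perturbation (orders 0..2 in theta)
    pert <- matrix(0, np, 3)
    for (h in 0:2) {
      coefc <- stats::rnorm(3, sd = 0.25 / (1 + h))
      coefs <- stats::rnorm(3, sd = 0.25 / (1 + h))
      pert <- pert + outer(cos(h * theta), coefc) + outer(sin(h * theta), coefs)
    }
    u[, , n] <- amplitude * (s[n] * base + pert)
  }
  list(nodes = perim, u = u)
}

#' Forward-simulate synthetic probe data with known ground truth
#'
#' Runs the forward model for a scenario and emulates the DIC pipeline
#' output: probe points sampled quasi-uniformly (seeded dart throwing) on
#' the surface, probe displacements obtained from the nodal solution through
#' the same k-nearest-neighbor operator the calibration objective uses
#' (k = 5), plus optional i.i.d. Gaussian noise per component, and the
#' perimeter displacement series extracted from the same forward solution
#' (equal to `boundary` when one is prescribed).
#'
#' @param mesh a [surface_mesh()].
#' @param field ground-truth [material_field()].
#' @param profile a [pressure_profile()].
#' @param n_probes number of probe points (default 7000).
#' @param noise_sd displacement noise standard deviation, mm (default 0;
#'   the stereo-DIC accuracy scale is about 0.1 mm).
#' @param seed RNG seed (probe sampling and noise).
#' @param k_interp neighbor count of the node-to-probe operator.
#' @param n_increments forward solver increments per stage.
#' @param boundary optional prescribed perimeter displacement series (e.g.
#'   [make_boundary_series()]); default: perimeter held fixed.
#' @return list of class `synthetic_scenario_data`: `probes`
#'   (a [probe_field()] with noise), `boundary` (perimeter series), `truth`
#'   (list: `field`, `run`, `probe_u` pre-noise array, `W` operator), `seed`.
#' @export
synthesize_probe_data <- function(mesh, field, profile, n_probes = 7000L,
                                  noise_sd = 0, seed = 1L, k_interp = 5L,
                                  n_increments = 1L, boundary = NULL) {
  stopifnot(noise_sd >= 0)
  run <- run_inflation(mesh, field, profile, boundary = boundary,
                       n_increments = n_increments)
  coords <- sample_surface_points(mesh, n_probes, seed = seed)
  W <- interpolation_matrix(mesh$nodes, coords, k = k_interp)
  ns <- length(run$stages)
  u_true <- array(0, c(n_probes, 3, ns))
  for (s in seq_len(ns))
    u_true[, , s] <- as.matrix(W %*% run$stages[[s]]$u)
  set.seed(seed + 1L)
  u_noisy <- u_true
  if (noise_sd > 0)
    u_noisy <- u_true + array(stats::rnorm(length(u_true), sd = noise_sd),
                              dim(u_true))
  perim <- perimeter_nodes(mesh)
  ub <- array(0, c(length(perim), 3, ns))
  for (s in seq_len(ns)) ub[, , s] <- run$stages[[s]]$u[perim, ]
  structure(list(
    probes = probe_field(coords, u_noisy),
    boundary = list(nodes = perim, u = ub),
    truth = list(field = field, run = run, probe_u = u_true, W = W),
    seed = seed),
    class = "synthetic_scenario_data")
}

#' Bundle a complete synthetic scenario
#'
#' Convenience wrapper generating mesh, profile, ground-truth material and
#' probe data in one call; the default settings are the package's standard
#' study conditions (457-element cap for homogeneous scenarios, 2.5 kPa /
#' 2 s concave ramp, 7000 noise-free probes).
#'
#' @param case constitutive case tag.
#' @param n_elements cap element count.
#' @param n_probes probe count.
#' @param noise_sd probe noise sd, mm.
#' @param seed scenario seed.
#' @param material_spec overrides for [make_ground_truth_field()].
#' @param peak_kPa,duration_s profile settings.
#' @param n_increments forward solver increments per stage.
#' @return list with `mesh`, `profile`, `field`, `data`
#'   (a [synthesize_probe_data()] result), and a scenario `hash`.
#' @export
make_scenario <- function(case = "homo_iso_hyper", n_elements = 457L,
                          n_probes = 7000L, noise_sd = 0, seed = 1L,
                          material_spec = list(), peak_kPa = 2.5,
                          duration_s = 2, n_increments = 1L) {
  mesh <- generate_cap_mesh(n_elements, seed = seed)
  profile <- generate_pressure_profile(peak_kPa, duration_s)
  field <- make_ground_truth_field(mesh, case, material_spec)
  # the heterogeneous scenario is driven by moving (non-proportional)
  # perimeter displacements: with a clamped perimeter every stage of the
  # linear model is a multiple of the same field and the per-element
  # parameters are not identifiable
  boundary <- if (case == "hetero_iso_linear")
    make_boundary_series(mesh, profile, seed = seed) else NULL
  data <- synthesize_probe_data(mesh, field, profile, n_probes = n_probes,
                                noise_sd = noise_sd, seed = seed,
                                n_increments = n_increments,
                                boundary = boundary)
  hash <- sprintf("%s-%d-%d-%g-%d", case, n_elements, n_probes, noise_sd,
                  seed)
  list(mesh = mesh, profile = profile, field = field, data = data,
       hash = hash)
}
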