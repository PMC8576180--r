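# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# canonical Mooney-Rivlin test point (calibrated optima of the homogeneous
# isotropic case)
mr_canonical <- function() mooney_rivlin(136.5, 1.0, 13.43e-4)

unit_triangle_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L)), ap_axis = c(0, 1, 0))
}

global_frame <- function() {
  list(x_axis = c(1, 0, 0), y_axis = c(0, 1, 0), z_axis = c(0, 0, 1))
}

# closed octahedron (no boundary), outward winding
octahedron_mesh <- function(r = 1) {
  v <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
             c(0, 0, r), c(0, 0, -r))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  surface_mesh(v, f, ap_axis = c(0.3, 0.9, 0.1))
}

# structured flat square membrane [0, a]^2 in the xy-plane, +z winding
flat_square_mesh <- function(n = 8, a = 40) {
  g <- seq(0, a, length.out = n + 1)
  nodes <- as.matrix(expand.grid(x = g, y = g))
  nodes <- cbind(nodes, 0)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  tris <- matrix(0L, 0, 3)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    tris <- rbind(tris,
                  c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                  c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  surface_mesh(nodes, tris, ap_axis = c(0, 1, 0))
}

# standard homogeneous scenario: 457-element cap, noise-free, 7000 probes
std_scenario <- function() {
  memo("std_scenario", function()
    make_scenario("homo_iso_hyper", n_elements = 457L, n_probes = 7000L,
                  noise_sd = 0, seed = 1L))
}

# smaller homogeneous scenario for optimizer-level tests
small_scenario <- function() {
  memo("small_scenario", function()
    make_scenario("homo_iso_hyper", n_elements = 60L, n_probes = 250L,
                  noise_sd = 0, seed = 1L))
}

# heterogeneous 40-element scenario with non-proportional boundary drive
hetero_scenario <- function() {
  memo("hetero_scenario", function()
    make_scenario("hetero_iso_linear", n_elements = 40L, n_probes = 400L,
                  noise_sd = 0, seed = 1L))
}

# center deflection of a pre-tensioned square membrane under uniform lateral
# pressure: series solution of T lap(w) = -p with w = 0 on the boundary
membrane_series_deflection <- function(p, a, T, terms = 99) {
  w <- 0
  for (mm in seq(1, terms, by = 2)) for (nn in seq(1, terms, by = 2)) {
    w <- w + 16 * p * a^2 / (T * pi^4 * mm * nn * (mm^2 + nn^2)) *
      sin(mm * pi / 2) * sin(nn * pi / 2)
  }
  w
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
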