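## shared fixtures, all built in code; heavyweight results are memoised so
## several test files can reuse one computation

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

## structured block mesh of an Lx x Ly x Lz box with n^3 hexes; base_ring is
## a single corner node so rigid-mode handling stays compatible with free
## homogeneous growth about that corner
block_mesh <- function(n = 2, L = 10) {
  g <- seq(0, L, length.out = n + 1)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))[, 1:3]
  colnames(nodes) <- NULL
  id <- function(i, j, k) i + (n + 1) * (j - 1) + (n + 1)^2 * (k - 1)
  elems <- matrix(0L, n^3, 8)
  e <- 1L
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    elems[e, ] <- c(id(i, j, k), id(i + 1, j, k), id(i + 1, j + 1, k),
                    id(i, j + 1, k), id(i, j, k + 1), id(i + 1, j, k + 1),
                    id(i + 1, j + 1, k + 1), id(i, j + 1, k + 1))
    e <- e + 1L
  }
  ## bottom and top faces as labelled surfaces (outward normals)
  bot <- matrix(0L, n^2, 4); top <- matrix(0L, n^2, 4)
  q <- 1L
  for (j in 1:n) for (i in 1:n) {
    bot[q, ] <- c(id(i, j, 1), id(i, j + 1, 1), id(i + 1, j + 1, 1),
                  id(i + 1, j, 1))
    top[q, ] <- c(id(i, j, n + 1), id(i + 1, j, n + 1),
                  id(i + 1, j + 1, n + 1), id(i, j + 1, n + 1))
    q <- q + 1L
  }
  structure(list(nodes = nodes, elements = elems,
                 surfaces = list(endo = bot, epi = top,
                                 base = matrix(0L, 0, 4)),
                 node_sets = list(base_ring = id(1, 1, 1)),
                 meta = list(kind = "block")),
            class = "hex_mesh")
}

uniform_fibers <- function(mesh, f = c(1, 0, 0), s = c(0, 1, 0),
                           n = c(0, 0, 1)) {
  nE <- nrow(mesh$elements)
  structure(list(f = matrix(f, nE, 3, byrow = TRUE),
                 s = matrix(s, nE, 3, byrow = TRUE),
                 n = matrix(n, nE, 3, byrow = TRUE),
                 t_m = rep(0.5, nE),
                 helix_angle_endo = 0, helix_angle_epi = 0),
            class = "fiber_field")
}

## hemispherical thick shell posed as a degenerate "LV": with u_z = 0 on the
## equatorial base it reproduces full-sphere symmetry
sphere_spec <- function(r_in = 10, wall = 2) {
  lv_shape_spec(endo_long_radius = r_in, endo_short_radius = r_in,
                wall_thickness_apex = wall, wall_thickness_equator = wall,
                truncation_fraction = 0.5,
                n_circumferential = 16, n_transmural = 3, n_longitudinal = 8)
}

tiny_lv_spec <- function() {
  lv_shape_spec(n_circumferential = 8, n_transmural = 2, n_longitudinal = 4)
}

coarse_model <- function() {
  memo("coarse_model", {
    mesh <- generate_idealized_lv(coarse_lv_spec())
    list(mesh = mesh, fibers = assign_fibers(mesh),
         shell = build_pericardium(mesh))
  })
}

## 1D static oracle for a pressurized thick-walled sphere of the isotropic
## reduced material: total-potential minimization over the radial
## displacement field (independent of the explicit dynamic solver)
sphere_oracle_inner_displacement <- function(Ri, Ro, p, mat, n = 60) {
  Rn <- seq(Ri, Ro, length.out = n)
  psi <- function(lr, lt) {
    J <- lr * lt^2
    I1b <- J^(-2 / 3) * (lr^2 + 2 * lt^2)
    mat$a / (2 * mat$b) * exp(mat$b * (I1b - 3)) + mat$kappa / 2 * log(J)^2
  }
  Pi <- function(u) {
    tot <- 0
    for (i in 1:(n - 1)) {
      h <- Rn[i + 1] - Rn[i]
      for (g in c(-1, 1) / sqrt(3)) {
        R <- (Rn[i] + Rn[i + 1]) / 2 + g * h / 2
        du <- (u[i + 1] - u[i]) / h
        uu <- u[i] + (R - Rn[i]) / h * (u[i + 1] - u[i])
        lr <- 1 + du; lt <- 1 + uu / R
        if (lr <= 0 || lt <= 0) return(1e12)
        tot <- tot + h / 2 * 4 * pi * R^2 * psi(lr, lt)
      }
    }
    ri <- Ri + u[1]
    tot - p * 4 * pi / 3 * (ri^3 - Ri^3)
  }
  op <- stats::optim(rep(0, n), Pi, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12))
  op$par[1]
}

## quick solver settings for small unit-test problems
fast_settings <- function(n = 3000, ...) solver_settings(n_increments = n, ...)
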