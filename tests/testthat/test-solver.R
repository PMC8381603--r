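test_that("internal forces vanish at rest and are translation invariant", {
  mesh <- block_mesh(n = 2, L = 10)
  fib <- uniform_fibers(mesh)
  mat <- material_params()
  n <- nrow(mesh$nodes)
  f0 <- assemble_internal_forces(mesh, fib, mat, rep(0, 3 * n))
  expect_lt(max(abs(f0)), 1e-9)
  ## rigid translation leaves internal forces unchanged
  set.seed(5)
  u <- matrix(stats::rnorm(3 * n, 0, 0.2), n, 3)
  f1 <- assemble_internal_forces(mesh, fib, mat, u)
  f2 <- assemble_internal_forces(mesh, fib, mat,
                                 sweep(u, 2, c(3, -2, 7), "+"))
  expect_lt(max(abs(f1 - f2)), 1e-7 * max(1, max(abs(f1))))
})

test_that("single-element nodal forces match the energy gradient", {
  ## one unit cube under a homogeneous deformation gradient: the assembled
  ## nodal forces contracted with X give dE/dF, which must match central
  ## finite differences of the closed-form total energy E(F) = Jg psi(F) V
  mesh <- block_mesh(n = 1, L = 1)
  fib <- uniform_fibers(mesh)
  mat <- material_params()
  gp <- growth_params(0.3, 0.1)
  jg <- (1 + gp$alpha_f) * (1 + gp$alpha_n)^2
  F <- diag(3) + matrix(c(0.05, 0.02, 0, 0.01, -0.03, 0.02, 0, 0.01, 0.04), 3)
  u <- mesh$nodes %*% t(F) - mesh$nodes
  fa <- matrix(assemble_internal_forces(mesh, fib, mat, u, gp),
               ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colSums(fa))), 1e-9)   # self-equilibrated
  ## analytic dE/dF from nodal forces: dE/dF_ij = sum_a f_a,i X_a,j
  dEdF_an <- t(fa) %*% mesh$nodes
  energy_of <- function(Fh) jg * strain_energy(deformation_state(Fh, gp), mat)
  h <- 1e-6
  dEdF_fd <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    dF <- matrix(0, 3, 3); dF[i, j] <- h
    dEdF_fd[i, j] <- (energy_of(F + dF) - energy_of(F - dF)) / (2 * h)
  }
  expect_lt(max(abs(dEdF_an - dEdF_fd)) / max(abs(dEdF_fd)), 1e-5)
})

test_that("follower pressure balances on closed surfaces and scales with area", {
  mesh <- coarse_model()$mesh
  ## the union of endo, epi and base facets closes the wall: net force zero
  all_facets <- do.call(rbind, mesh$surfaces)
  f <- apply_pressure_load(mesh, all_facets, p = 2.5)
  fm <- matrix(f, ncol = 3, byrow = TRUE)
  ## net force below 1e-8 x (p x total surface area)
  expect_lt(sqrt(sum(colSums(fm)^2)), 1e-8 * 2.5 * 5000)
  ## single flat square facet: net force = p * A along the normal
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0),
                 c(0, 0, 1), c(2, 0, 1), c(2, 2, 1), c(0, 2, 1))
  mesh1 <- structure(list(nodes = nodes,
                          elements = matrix(1:8, 1),
                          surfaces = list(endo = matrix(c(1L, 2L, 3L, 4L), 1)),
                          node_sets = list(base_ring = 1L)),
                     class = "hex_mesh")
  f1 <- matrix(apply_pressure_load(mesh1, "endo", p = 3), ncol = 3,
               byrow = TRUE)
  net <- colSums(f1)
  expect_equal(sqrt(sum(net^2)), 3 * 4, tolerance = 1e-12)  # p * area
  expect_equal(abs(net[3]), 12, tolerance = 1e-12)          # along the normal
  ## zero pressure gives a zero vector
  expect_equal(max(abs(apply_pressure_load(mesh1, "endo", p = 0))), 0)
})

test_that("penalty contact is inactive when separated and obeys Newton's third law", {
  m <- coarse_model()
  mesh <- m$mesh
  shell <- build_pericardium(mesh)
  ## push the shell outward: separation, no force
  shell_out <- shell
  shell_out$nodes <- shell$nodes * 1.05
  cp0 <- contact_penalty(mesh, shell_out, slope = 2)
  expect_equal(max(abs(cp0$force_epi)), 0)
  ## inflate the LV into the shell: equal and opposite totals
  cp <- contact_penalty(mesh, shell, u_epi = mesh$nodes * 0.02, slope = 2)
  fe <- colSums(matrix(cp$force_epi, ncol = 3, byrow = TRUE))
  fp <- colSums(matrix(cp$force_peri, ncol = 3, byrow = TRUE))
  expect_gt(max(abs(cp$force_epi)), 0)
  expect_lt(max(abs(fe + fp)), 1e-10 * max(abs(cp$force_epi)))
})

test_that("a single node penetrating a flat shell feels slope * h * area", {
  ## flat shell at z = 0 (normal +z), one-element mesh whose epi face pokes
  ## h = 0.5 above it
  nodes <- rbind(c(-1, -1, -2), c(1, -1, -2), c(1, 1, -2), c(-1, 1, -2),
                 c(-1, -1, 0.5), c(1, -1, 0.5), c(1, 1, 0.5), c(-1, 1, 0.5))
  mesh1 <- structure(list(nodes = nodes, elements = matrix(1:8, 1),
                          surfaces = list(epi = matrix(c(5L, 6L, 7L, 8L), 1)),
                          node_sets = list(base_ring = 1L)),
                     class = "hex_mesh")
  shell <- list(nodes = rbind(c(-10, -10, 0), c(10, -10, 0),
                              c(10, 10, 0), c(-10, 10, 0)),
                elements = matrix(1:4, 1))
  class(shell) <- "pericardial_shell"
  cp <- contact_penalty(mesh1, shell, slope = 2)
  fm <- matrix(cp$force_epi, ncol = 3, byrow = TRUE)
  ## each epi node: pressure 2 * 0.5 = 1, tributary area = facet area / 4 = 1
  expect_equal(fm[5, 3], -1, tolerance = 1e-9)
  expect_equal(sum(fm[, 3]), -4, tolerance = 1e-9)
})

test_that("no load and no growth leaves the mesh at rest", {
  mesh <- block_mesh(n = 2, L = 10)
  fib <- uniform_fibers(mesh)
  res <- run_growth_simulation(mesh, fib, material_params(), NULL,
                               boundary_conditions(p_ed = 0),
                               fast_settings(500),
                               growth_params(0, 0))
  expect_false(res$diverged)
  expect_lt(max(abs(res$final_nodes - mesh$nodes)), 1e-6)
})

test_that("free isotropic growth multiplies volume by (1+alpha)^3", {
  mesh <- block_mesh(n = 2, L = 10)
  fib <- uniform_fibers(mesh)
  a <- 0.3
  res <- run_growth_simulation(mesh, fib, material_params(), NULL,
                               boundary_conditions(p_ed = 0),
                               fast_settings(3000),
                               growth_params(a, a))
  expect_false(res$diverged)
  m2 <- mesh; m2$nodes <- res$final_nodes
  ratio <- sum(element_volumes(m2)) / sum(element_volumes(mesh))
  expect_lt(abs(ratio - (1 + a)^3) / (1 + a)^3, 0.01)
})

test_that("pressurized thick sphere matches the 1D static oracle within 5%", {
  mesh <- generate_idealized_lv(sphere_spec(10, 2))
  mat <- material_params(a_f = 0, a_s = 0, a_fs = 0)
  fib <- assign_fibers(mesh)
  p <- 10 * MMHG_TO_KPA
  res <- run_growth_simulation(mesh, fib, mat, NULL,
                               boundary_conditions(p_ed = p),
                               fast_settings(6000),
                               growth_params(0, 0))
  expect_false(res$diverged)
  en <- sort(unique(as.integer(mesh$surfaces$endo)))
  ur_fe <- mean(sqrt(rowSums(res$final_nodes[en, ]^2)) -
                  sqrt(rowSums(mesh$nodes[en, ]^2)))
  ur_1d <- memo("sphere_oracle",
                suppressWarnings(
                  sphere_oracle_inner_displacement(10, 12, p, mat)))
  expect_lt(abs(ur_fe - ur_1d) / abs(ur_1d), 0.05)
})

test_that("checkpoints are emitted ascending with proportionally scaled parameters", {
  mesh <- block_mesh(n = 2, L = 10)
  fib <- uniform_fibers(mesh)
  res <- run_growth_simulation(mesh, fib, material_params(), NULL,
                               boundary_conditions(p_ed = 0),
                               fast_settings(1000),
                               growth_params(0.4, 0.2))
  fr <- vapply(res$checkpoints, function(cp) cp$growth_fraction, 0)
  expect_identical(fr, sort(fr))
  expect_equal(length(fr), 5L)
  for (cp in res$checkpoints) {
    expect_false(is.null(cp$nodes))
    expect_equal(cp$params$alpha_f, 0.4 * cp$growth_fraction)
    expect_equal(cp$params$alpha_n, 0.2 * cp$growth_fraction)
  }
})

test_that("the solver is deterministic", {
  mesh <- block_mesh(n = 2, L = 10)
  fib <- uniform_fibers(mesh)
  r1 <- run_growth_simulation(mesh, fib, material_params(), NULL,
                              boundary_conditions(), fast_settings(800),
                              growth_params(0.2, 0.1))
  r2 <- run_growth_simulation(mesh, fib, material_params(), NULL,
                              boundary_conditions(), fast_settings(800),
                              growth_params(0.2, 0.1))
  expect_identical(r1$final_nodes, r2$final_nodes)
  expect_identical(r1$energy_trace, r2$energy_trace)
})

test_that("halving the pseudo-time increment changes the final state by < 0.5%", {
  mesh <- generate_idealized_lv(tiny_lv_spec())
  fib <- assign_fibers(mesh)
  shell <- build_pericardium(mesh)
  r1 <- run_growth_simulation(mesh, fib, material_params(), shell,
                              boundary_conditions(), fast_settings(4000),
                              growth_params(0.3, 0.2))
  r2 <- run_growth_simulation(mesh, fib, material_params(), shell,
                              boundary_conditions(), fast_settings(8000),
                              growth_params(0.3, 0.2))
  scale <- max(abs(r2$final_nodes - mesh$nodes))
  expect_lt(max(abs(r1$final_nodes - r2$final_nodes)) / scale, 0.005)
})
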