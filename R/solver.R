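#' Boundary conditions for the LV growth simulation
#'
#' End-diastolic endocardial pressure (applied as a follower load ramped
#' linearly over the preload step, then held during the growth step),
#' pericardial penalty contact slope, and the longitudinal fixation of the
#' basal plane.
#'
#' @param p_ed End-diastolic pressure in kPa.  The default is 10 mmHg
#'   (1.33322 kPa).
#' @param penalty_slope Contact penalty pressure per unit overclosure
#'   (kPa/mm); the pericardial pressure is p = slope * h, the p = 2h rule
#'   in model units (kPa, mm).
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(p_ed = 10 * MMHG_TO_KPA, penalty_slope = 2) {
  stopifnot(p_ed >= 0, penalty_slope >= 0)
  structure(list(p_ed = p_ed, penalty_slope = penalty_slope),
            class = "boundary_conditions")
}

#' Explicit solver settings
#'
#' The quasi-static explicit solver integrates the damped equations of
#' motion over two unit pseudo-time steps (preload, then growth).  Nodal
#' masses are scaled so that the requested number of increments per step is
#' stable (mass scaling); `mass_safety` multiplies that estimate.  The
#' kinetic-energy criterion (peak KE / total energy below `ke_tolerance`
#' after the preload ramp) is the quasi-staticity contract.
#'
#' @param n_increments Increments per unit pseudo-time step.
#' @param settle_increments Extra increments at constant load and full
#'   growth after the ramps, relaxing the final state to statics (default
#'   a third of `n_increments`).
#' @param damping Mass-proportional damping coefficient (1/pseudo-time).
#' @param mass_safety Safety factor on the stable-mass estimate.
#' @param checkpoint_fractions Growth fractions at which intermediate
#'   configurations are emitted.
#' @param ke_check_interval Increments between energy-trace samples.
#' @param contact_interval Increments between contact-search rebuilds and
#'   stable-mass re-estimates.
#' @param ke_tolerance Convergence bound on the peak kinetic/total-energy
#'   ratio.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(n_increments = 12000,
                            settle_increments = n_increments %/% 3,
                            damping = 90, mass_safety = 4,
                            checkpoint_fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                            ke_check_interval = 50, contact_interval = 10,
                            ke_tolerance = 0.05) {
  stopifnot(n_increments >= 10, mass_safety > 0,
            all(checkpoint_fractions > 0), all(checkpoint_fractions <= 1))
  structure(list(n_increments = as.integer(n_increments),
                 settle_increments = as.integer(settle_increments),
                 damping = damping,
                 mass_safety = mass_safety,
                 checkpoint_fractions = sort(checkpoint_fractions),
                 ke_check_interval = as.integer(ke_check_interval),
                 contact_interval = as.integer(contact_interval),
                 ke_tolerance = ke_tolerance),
            class = "solver_settings")
}

#' Build a pericardial shell from the epicardial surface
#'
#' A quadrilateral shell conforming to the epicardium at generation time
#' (zero initial gap), modeled as a linear elastic membrane.  Its basal ring
#' is fixed longitudinally during simulation.
#'
#' @param mesh A `hex_mesh` with an `epi` surface set.
#' @param thickness Shell thickness in mm (the pericardial thickness is an
#'   assumption; default 1 mm).
#' @param E Young's modulus in MPa (default 10 MPa).
#' @param nu Poisson ratio (default 0.3).
#' @param rigid If TRUE (default) the shell is treated as a fixed surface
#'   during simulation: the penalty pressure acts against the undeformed
#'   pericardial geometry.  At 10 MPa the membrane's radial compliance is
#'   below 3 percent, and a fixed surface keeps the contact response
#'   mesh-independent; set FALSE for the dynamic elastic membrane.
#' @return An object of class `pericardial_shell` with `nodes`, `elements`
#'   (quads), `base_ring_nodes`, `thickness`, `youngs_modulus` (MPa),
#'   `poisson_ratio`.
#' @export
build_pericardium <- function(mesh, thickness = 1, E = 10, nu = 0.3,
                              rigid = TRUE) {
  stopifnot(thickness > 0, E > 0)
  ep <- mesh$surfaces$epi
  ids <- sort(unique(as.integer(ep)))
  remap <- integer(nrow(mesh$nodes))
  remap[ids] <- seq_along(ids)
  quads <- matrix(remap[ep], nrow(ep), 4)
  nodes <- mesh$nodes[ids, , drop = FALSE]
  zb <- max(nodes[, 3])
  ring <- which(nodes[, 3] > zb - 1e-8)
  structure(list(nodes = nodes, elements = quads, base_ring_nodes = ring,
                 thickness = thickness, youngs_modulus = E,
                 poisson_ratio = nu, rigid = isTRUE(rigid),
                 epi_node_ids = ids),
            class = "pericardial_shell")
}

#' Run the preload + growth finite-element simulation
#'
#' Quasi-static explicit (dynamic relaxation) integration: the endocardial
#' pressure ramps linearly over pseudo-time t in [0, 1] and is held during
#' t in [1, 2] while the growth coefficients ramp linearly from zero to
#' `target`.  Intermediate configurations are emitted at the configured
#' growth fractions; each is a valid solution at the proportionally scaled
#' growth parameters.
#'
#' @param mesh A `hex_mesh`.
#' @param fibers A `fiber_field` from [assign_fibers()].
#' @param mat A [material_params()].
#' @param shell A [build_pericardium()] shell, or NULL for no contact.
#' @param bc A [boundary_conditions()].
#' @param settings A [solver_settings()].
#' @param target A [growth_params()]: the growth reached at the end of the
#'   growth step.
#' @return An object of class `simulation_result`: `checkpoints` (list of
#'   `growth_fraction`, `params`, `nodes`), `energy_trace` (data.frame with
#'   t, kinetic, internal, external_work, pressure, growth_fraction),
#'   `peak_ke_ratio`, `converged`, `diverged`, `final_nodes`.
#' @export
run_growth_simulation <- function(mesh, fibers, mat = material_params(),
                                  shell = NULL,
                                  bc = boundary_conditions(),
                                  settings = solver_settings(),
                                  target = growth_params()) {
  if (is.null(shell)) {
    snodes <- matrix(0, 0, 3)
    squads <- matrix(0L, 0, 4)
    sE <- 0; snu <- 0.3; sth <- 1; sring <- integer(0)
    slope <- 0
  } else {
    snodes <- shell$nodes
    squads <- shell$elements
    sE <- shell$youngs_modulus * 1000  # MPa -> kPa
    snu <- shell$poisson_ratio
    sth <- shell$thickness
    sring <- shell$base_ring_nodes
    slope <- bc$penalty_slope
  }
  res <- run_solver_cpp(mesh$nodes, mesh$elements, fiber_matrix(fibers),
                        mat_vector(mat), mat$macaulay,
                        target$alpha_f, target$alpha_n,
                        mesh$surfaces$endo, mesh$surfaces$epi,
                        snodes, squads, sE, snu, sth,
                        isTRUE(shell$rigid),
                        as.integer(sring), slope,
                        as.integer(mesh$node_sets$base_ring),
                        integer(0), integer(0),
                        bc$p_ed,
                        settings$n_increments, settings$settle_increments,
                        settings$damping,
                        settings$mass_safety, settings$checkpoint_fractions,
                        settings$ke_check_interval,
                        settings$contact_interval)
  if (res$diverged)
    warning("simulation diverged at pseudo-time ", signif(res$diverge_time, 4),
            if (res$bad_element > 0) paste0(" (element ", res$bad_element, ")"))
  fr <- settings$checkpoint_fractions
  cps <- vector("list", length(fr))
  for (i in seq_along(fr)) {
    cps[[i]] <- list(growth_fraction = fr[i],
                     params = growth_params(fr[i] * target$alpha_f,
                                            fr[i] * target$alpha_n),
                     nodes = if (res$cp_done[i] > 0) res$checkpoints[[i]] else NULL)
  }
  tr <- as.data.frame(res$trace)
  names(tr) <- c("t", "kinetic", "internal", "external_work", "pressure",
                 "growth_fraction", "kinetic_shell", "vmax_lv", "vmax_shell")
  structure(list(checkpoints = cps, energy_trace = tr,
                 peak_ke_ratio = res$peak_ke_ratio,
                 converged = !res$diverged &&
                   res$peak_ke_ratio < settings$ke_tolerance,
                 diverged = res$diverged,
                 diverge_time = res$diverge_time,
                 final_nodes = res$final_nodes,
                 final_shell = if (nrow(snodes) > 0) res$final_shell else NULL,
                 target = target, dt = res$dt),
            class = "simulation_result")
}

#' Assemble internal nodal forces
#'
#' Total-Lagrangian assembly of the internal force vector at a given
#' displacement and scaled growth state (2x2x2 Gauss integration).
#'
#' @param mesh A `hex_mesh`.
#' @param fibers A `fiber_field`.
#' @param mat A [material_params()].
#' @param u Displacement vector (3n, node-major) or n x 3 matrix.
#' @param growth A [growth_params()] (already scaled by the growth fraction).
#' @return Numeric vector of length 3n (node-major x, y, z).
#' @export
assemble_internal_forces <- function(mesh, fibers, mat, u,
                                     growth = growth_params()) {
  if (is.matrix(u)) u <- as.numeric(t(u))
  r <- internal_forces_cpp(mesh$nodes, mesh$elements, fiber_matrix(fibers),
                           u, growth$alpha_f, growth$alpha_n,
                           mat_vector(mat), mat$macaulay)
  if (!r$ok)
    stop("negative Jacobian / diverged state in element ", r$bad_element)
  r$force
}

#' Follower pressure load on a facet set
#'
#' Pressure acts along current (deformed) facet normals with magnitude
#' p x current area; on a closed surface the net force vanishes.
#'
#' @param mesh A `hex_mesh`.
#' @param surface Name of the facet set (default "endo") or a facet matrix.
#' @param p Pressure (kPa).
#' @param u Displacements (3n vector or n x 3 matrix), default zero.
#' @return Numeric force vector of length 3n.
#' @export
apply_pressure_load <- function(mesh, surface = "endo", p,
                                u = rep(0, 3 * nrow(mesh$nodes))) {
  if (is.matrix(u)) u <- as.numeric(t(u))
  facets <- if (is.character(surface)) mesh$surfaces[[surface]] else surface
  coords <- mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
  pressure_forces_cpp(coords, facets, p)
}

#' Pericardial penalty contact forces
#'
#' For each epicardial surface node, the signed gap h to its nearest
#' pericardial facet (h > 0 = penetration beyond the shell) generates a
#' frictionless normal penalty pressure p = slope * h, applied over the
#' node's tributary area and equal-and-opposite on the shell facet.
#'
#' @param mesh A `hex_mesh` with an `epi` surface set.
#' @param shell A [build_pericardium()] shell.
#' @param u_epi Displacements of the mesh nodes (n x 3 matrix or 3n vector).
#' @param u_peri Displacements of the shell nodes.
#' @param slope Penalty slope (kPa/mm), default 2.
#' @return List with `force_epi` (3n vector on the mesh) and `force_peri`
#'   (3s vector on the shell); their sums are equal and opposite.
#' @export
contact_penalty <- function(mesh, shell, u_epi = NULL, u_peri = NULL,
                            slope = 2) {
  n <- nrow(mesh$nodes)
  s <- nrow(shell$nodes)
  if (is.null(u_epi)) u_epi <- matrix(0, n, 3)
  if (!is.matrix(u_epi)) u_epi <- matrix(u_epi, ncol = 3, byrow = TRUE)
  if (is.null(u_peri)) u_peri <- matrix(0, s, 3)
  if (!is.matrix(u_peri)) u_peri <- matrix(u_peri, ncol = 3, byrow = TRUE)
  x <- mesh$nodes + u_epi
  xs <- shell$nodes + u_peri
  ep_nodes <- sort(unique(as.integer(mesh$surfaces$epi)))
  ## tributary areas from current epi facets
  trib <- numeric(n)
  fm <- mesh$surfaces$epi
  for (i in seq_len(nrow(fm))) {
    xq <- x[fm[i, ], , drop = FALSE]
    av <- crossp(xq[3, ] - xq[1, ], xq[4, ] - xq[2, ]) / 2
    trib[fm[i, ]] <- trib[fm[i, ]] + sqrt(sum(av^2)) / 4
  }
  ## shell facet centroids and normals
  nq <- nrow(shell$elements)
  cent <- matrix(0, nq, 3)
  nrm <- matrix(0, nq, 3)
  for (q in seq_len(nq)) {
    xq <- xs[shell$elements[q, ], , drop = FALSE]
    cent[q, ] <- colMeans(xq)
    nv <- crossp(xq[3, ] - xq[1, ], xq[4, ] - xq[2, ])
    nrm[q, ] <- nv / max(sqrt(sum(nv^2)), 1e-300)
  }
  f_epi <- matrix(0, n, 3)
  f_peri <- matrix(0, s, 3)
  for (nd in ep_nodes) {
    d2 <- rowSums((cent - matrix(x[nd, ], nq, 3, byrow = TRUE))^2)
    q <- which.min(d2)
    h <- sum((x[nd, ] - cent[q, ]) * nrm[q, ])
    if (h <= 0) next
    fv <- slope * h * trib[nd] * nrm[q, ]
    f_epi[nd, ] <- f_epi[nd, ] - fv
    qq <- shell$elements[q, ]
    f_peri[qq, ] <- f_peri[qq, ] + matrix(fv / 4, 4, 3, byrow = TRUE)
  }
  list(force_epi = as.numeric(t(f_epi)), force_peri = as.numeric(t(f_peri)))
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("LV growth simulation\n")
  cat(sprintf("  target growth: alpha_f = %.3f, alpha_n = %.3f\n",
              x$target$alpha_f, x$target$alpha_n))
  cat(sprintf("  peak KE/total energy: %.2f%%  (converged: %s)\n",
              100 * x$peak_ke_ratio, x$converged))
  cat(sprintf("  checkpoints: %d at fractions %s\n", length(x$checkpoints),
              paste(vapply(x$checkpoints, function(c) c$growth_fraction, 0),
                    collapse = ", ")))
  invisible(x)
}
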