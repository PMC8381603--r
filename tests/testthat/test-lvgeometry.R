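test_that("idealized LV mesh satisfies its geometric contract", {
  mesh <- coarse_model()$mesh
  expect_true(jacobians_positive(mesh))
  expect_setequal(names(mesh$surfaces), c("endo", "epi", "base"))
  expect_gt(length(mesh$node_sets$base_ring), 0)
  ## base facets in the basal plane
  zb <- mesh$meta$z_base
  expect_lt(max(abs(mesh$nodes[unique(as.integer(mesh$surfaces$base)), 3] - zb)),
            1e-8)
  ## divergence-theorem volume oracle: enclosed boundary volume equals the
  ## summed element volumes
  ev <- sum(element_volumes(mesh))
  expect_lt(abs(enclosed_volume(mesh) - ev) / ev, 0.01)
})

test_that("geometric similarity: doubling all lengths doubles coordinates", {
  s1 <- coarse_lv_spec()
  s2 <- coarse_lv_spec(endo_long_radius = 60, endo_short_radius = 30,
                       wall_thickness_apex = 8, wall_thickness_equator = 14)
  m1 <- generate_idealized_lv(s1)
  m2 <- generate_idealized_lv(s2)
  expect_identical(m1$elements, m2$elements)
  expect_lt(max(abs(m2$nodes - 2 * m1$nodes)), 1e-9)
})

test_that("element-edge-driven spec yields 4-6 transmural layers for a 9 mm wall", {
  spec <- lv_shape_spec(wall_thickness_apex = 9, wall_thickness_equator = 9,
                        element_edge = 1.5)
  expect_gte(spec$n_transmural, 4)
  expect_lte(spec$n_transmural, 6)
  mesh <- generate_idealized_lv(lv_shape_spec(
    wall_thickness_apex = 9, wall_thickness_equator = 9,
    n_circumferential = 16, n_transmural = spec$n_transmural,
    n_longitudinal = 6))
  expect_true(jacobians_positive(mesh))
})

test_that("a wall thinner than two element edges is rejected", {
  expect_error(lv_shape_spec(wall_thickness_apex = 2,
                             wall_thickness_equator = 2, element_edge = 1.5),
               "transmural")
  expect_error(lv_shape_spec(n_circumferential = 16, n_transmural = 1,
                             n_longitudinal = 4), "n_transmural")
})

test_that("mesh refinement (halving the element edge) changes wall volume by < 1%", {
  v1 <- sum(element_volumes(generate_idealized_lv(lv_shape_spec(
    n_circumferential = 48, n_transmural = 4, n_longitudinal = 10))))
  v2 <- sum(element_volumes(generate_idealized_lv(lv_shape_spec(
    n_circumferential = 96, n_transmural = 8, n_longitudinal = 20))))
  expect_lt(abs(v1 - v2) / v2, 0.01)
})

test_that("pericardial shell conforms to the epicardium", {
  mesh <- coarse_model()$mesh
  shell <- build_pericardium(mesh)
  expect_equal(shell$youngs_modulus, 10)          # MPa default
  ep_ids <- sort(unique(as.integer(mesh$surfaces$epi)))
  expect_equal(nrow(shell$nodes), length(ep_ids)) # conforming node count
  ## facet-area sum within 1% of the epicardial surface area
  quad_area <- function(nodes, quads) {
    cp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    s <- 0
    for (i in seq_len(nrow(quads))) {
      x <- nodes[quads[i, ], , drop = FALSE]
      av <- cp(x[3, ] - x[1, ], x[4, ] - x[2, ]) / 2
      s <- s + sqrt(sum(av^2))
    }
    s
  }
  a_shell <- quad_area(shell$nodes, shell$elements)
  a_epi <- quad_area(mesh$nodes, mesh$surfaces$epi)
  expect_lt(abs(a_shell - a_epi) / a_epi, 0.01)
  expect_gt(length(shell$base_ring_nodes), 0)
})

test_that("contour smoothing reproduces smooth data and damps outliers", {
  ## control points on a smooth quadric (a cone: radius linear in z): the
  ## least-squares spline reproduces them for any smoothing budget
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  cone <- lapply(seq(-20, -4, length.out = 8), function(z) {
    r <- -z / 2
    list(slice_z = z, endo = cbind(r * cos(ang), r * sin(ang)),
         epi = cbind((r + 4) * cos(ang), (r + 4) * sin(ang)))
  })
  cstack <- contour_stack(cone)
  smc <- smooth_contour_stack(cstack, smoothing = 5)
  for (i in seq_along(cone)) {
    expect_lt(max(abs(smc$slices[[i]]$endo - cstack$slices[[i]]$endo)), 1e-6)
    expect_lt(max(abs(smc$slices[[i]]$epi - cstack$slices[[i]]$epi)), 1e-6)
  }
  spec <- coarse_lv_spec()
  stack <- sample_lv_contours(spec, n_slices = 8, n_points = 24)
  ## zero smoothing is the interpolation limit for arbitrary smooth stacks
  sm0 <- smooth_contour_stack(stack, smoothing = 0)
  expect_equal(sm0$slices[[3]]$endo, stack$slices[[3]]$endo, tolerance = 1e-12)
  ## a 1 mm spike at one slice is damped and spread to neighbors
  pert <- stack
  pert$slices[[4]]$endo[5, 1] <- pert$slices[[4]]$endo[5, 1] + 1
  smp <- smooth_contour_stack(pert, smoothing = 0.5)
  resid_before <- abs(pert$slices[[4]]$endo[5, 1] - stack$slices[[4]]$endo[5, 1])
  resid_after <- abs(smp$slices[[4]]$endo[5, 1] - stack$slices[[4]]$endo[5, 1])
  expect_lt(resid_after, resid_before)
  neighbor_shift <- abs(smp$slices[[3]]$endo[5, 1] - stack$slices[[3]]$endo[5, 1])
  expect_gt(neighbor_shift, 0)
})

test_that("contour stacks validate their invariants", {
  spec <- coarse_lv_spec()
  stack <- sample_lv_contours(spec, n_slices = 6)
  ## epi must strictly enclose endo
  bad <- stack$slices
  tmp <- bad[[2]]$endo; bad[[2]]$endo <- bad[[2]]$epi; bad[[2]]$epi <- tmp
  expect_error(contour_stack(bad), "enclose")
  ## slice_z strictly increasing
  bad2 <- stack$slices
  bad2[[2]]$slice_z <- bad2[[1]]$slice_z
  expect_error(contour_stack(bad2), "increasing")
})

test_that("mesh from contours reproduces the analytic surface", {
  spec <- coarse_lv_spec()
  stack <- sample_lv_contours(spec, n_slices = 9, n_points = 32)
  mesh <- mesh_from_contours(stack, n_transmural = 2, n_circumferential = 16)
  expect_true(jacobians_positive(mesh))
  ev <- sum(element_volumes(mesh))
  expect_lt(abs(enclosed_volume(mesh) - ev) / ev, 0.01)
  ## endo surface nodes lie on the endocardial spheroid within half the
  ## in-plane spacing
  en <- sort(unique(as.integer(mesh$surfaces$endo)))
  p <- mesh$nodes[en, ]
  a <- spec$endo_long_radius; b <- spec$endo_short_radius
  ## distance to quadric estimated by radial residual at each node's z
  r_expect <- b * sqrt(pmax(0, 1 - (p[, 3] / a)^2))
  r_actual <- sqrt(p[, 1]^2 + p[, 2]^2)
  expect_lt(stats::quantile(abs(r_actual - r_expect), 0.98),
            stack$in_plane_spacing / 2)
})

test_that("identical circular contours give an axisymmetric tube with coplanar rings", {
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  mk <- function(r) cbind(r * cos(ang), r * sin(ang))
  slices <- lapply(seq(-20, 0, length.out = 6), function(z)
    list(slice_z = z, endo = mk(10), epi = mk(14)))
  stack <- contour_stack(slices)
  mesh <- mesh_from_contours(stack, n_transmural = 2, n_circumferential = 16)
  ## tube rings (nodes at the slice heights) are coplanar
  for (z in seq(-20, 0, length.out = 6)) {
    ring <- which(abs(mesh$nodes[, 3] - z) < 1e-9)
    expect_gte(length(ring), 16)
    r <- sqrt(mesh$nodes[ring, 1]^2 + mesh$nodes[ring, 2]^2)
    expect_true(all(abs(r - 10) < 1e-6 | abs(r - 12) < 1e-6 |
                      abs(r - 14) < 1e-6))
  }
})

test_that("epi radius below endo radius raises an error", {
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  mk <- function(r) cbind(r * cos(ang), r * sin(ang))
  slices <- lapply(c(-10, -5, 0), function(z)
    list(slice_z = z, endo = mk(10), epi = mk(12)))
  expect_error(contour_stack(lapply(slices, function(s) {
    s$epi <- mk(8); s
  })), "enclose")
})

test_that("mesh and contour files round-trip", {
  mesh <- generate_idealized_lv(tiny_lv_spec())
  f <- tempfile(fileext = ".vtu")
  write_vtu(mesh, f, cell_data = list(vol = element_volumes(mesh)))
  m2 <- read_vtu(f)
  expect_equal(m2$nodes, mesh$nodes, tolerance = 1e-6)
  expect_identical(dim(m2$elements), dim(mesh$elements))
  expect_setequal(sort(unique(as.integer(m2$surfaces$endo))),
                  sort(unique(as.integer(mesh$surfaces$endo))))
  fi <- tempfile(fileext = ".inp")
  write_inp(mesh, fi)
  expect_true(any(grepl("C3D8", readLines(fi))))

  stack <- sample_lv_contours(coarse_lv_spec(), n_slices = 5, n_points = 12)
  fc <- tempfile(fileext = ".csv")
  write_contours_csv(stack, fc)
  s2 <- read_contours_csv(fc)
  expect_equal(s2$slices[[2]]$epi, stack$slices[[2]]$epi, tolerance = 1e-9)
  fj <- tempfile(fileext = ".json")
  write_contours_json(stack, fj)
  s3 <- read_contours_json(fj)
  expect_equal(s3$slices[[4]]$endo, stack$slices[[4]]$endo, tolerance = 1e-9)
})
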