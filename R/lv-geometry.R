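#' @useDynLib cardiogrow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Shape specification for an idealized left ventricle
#'
#' Describes a truncated prolate-spheroid LV wall: confocal-style endocardial
#' and epicardial quadrics with a prescribed apex-to-equator thickness
#' interpolation, cut by a flat basal plane.  All lengths are in mm.  The long
#' axis is +z with the base at high z and the apex at low z.
#'
#' @param endo_long_radius Endocardial long semi-axis (mm).
#' @param endo_short_radius Endocardial short semi-axis (mm).
#' @param wall_thickness_apex Wall thickness at the apex, measured along z (mm).
#' @param wall_thickness_equator Wall thickness at the equator, radial (mm).
#' @param truncation_fraction Fraction of the endocardial long axis retained
#'   below the basal plane, in (0, 1).  0.5 truncates at the equator
#'   (hemisphere), 0.75 keeps the typical LV three-quarters.
#' @param n_circumferential Circumferential element count (multiple of 8; the
#'   apex cap uses a butterfly block layout with `n_circumferential / 8`
#'   elements per core-square half-side).
#' @param n_transmural Transmural element count (>= 2).
#' @param n_longitudinal Apex-to-base element count outside the apex core.
#' @param element_edge Optional target element edge length (mm).  When the
#'   three counts are `NULL` they are derived from this edge length; a spec
#'   whose wall cannot honor two transmural layers at this edge is rejected.
#' @return An object of class `lv_shape_spec`.
#' @export
lv_shape_spec <- function(endo_long_radius = 30,
                          endo_short_radius = 15,
                          wall_thickness_apex = 4,
                          wall_thickness_equator = 7,
                          truncation_fraction = 0.75,
                          n_circumferential = NULL,
                          n_transmural = NULL,
                          n_longitudinal = NULL,
                          element_edge = 1.5) {
  stopifnot(endo_long_radius > 0, endo_short_radius > 0,
            wall_thickness_apex > 0, wall_thickness_equator > 0)
  if (truncation_fraction <= 0 || truncation_fraction >= 1)
    stop("truncation_fraction must lie in (0, 1) (open basal plane)")
  min_wall <- min(wall_thickness_apex, wall_thickness_equator)
  if (is.null(n_transmural)) {
    if (min_wall < 2 * element_edge)
      stop("wall thickness ", min_wall, " mm cannot honor >= 2 transmural ",
           "layers at element edge ", element_edge, " mm")
    n_transmural <- max(2L, round(min_wall / element_edge))
  }
  if (n_transmural < 2) stop("n_transmural must be >= 2")
  if (is.null(n_circumferential)) {
    circ <- 2 * pi * (endo_short_radius + wall_thickness_equator / 2)
    n_circumferential <- max(8L, 8L * round(circ / element_edge / 8))
  }
  if (n_circumferential %% 8 != 0 || n_circumferential < 8)
    stop("n_circumferential must be a positive multiple of 8")
  if (is.null(n_longitudinal)) {
    ## meridian arc from apex to base, rough mid-wall estimate
    a <- endo_long_radius + wall_thickness_apex / 2
    b <- endo_short_radius + wall_thickness_equator / 2
    zb <- endo_long_radius * (2 * truncation_fraction - 1)
    th <- acos(pmin(1, -zb / a))
    arc <- (pi - th) * (a + b) / 2
    n_longitudinal <- max(3L, round(arc / element_edge))
  }
  if (n_longitudinal < 1) stop("n_longitudinal must be >= 1")
  structure(list(endo_long_radius = endo_long_radius,
                 endo_short_radius = endo_short_radius,
                 wall_thickness_apex = wall_thickness_apex,
                 wall_thickness_equator = wall_thickness_equator,
                 truncation_fraction = truncation_fraction,
                 n_circumferential = as.integer(n_circumferential),
                 n_transmural = as.integer(n_transmural),
                 n_longitudinal = as.integer(n_longitudinal)),
            class = "lv_shape_spec")
}

## Butterfly ("O-grid") quad mesh of the unit disk: a (2m x 2m) core square
## surrounded by n_rad rings whose outer boundary carries 8m uniformly spaced
## angular nodes.  Returns node radial fractions rho in [0,1], angles phi and
## CCW quads.  rho advances one "edge" per core step (m steps center->edge)
## and one per ring, so element sizes stay balanced.
butterfly_disk <- function(m, n_rad, core_half = 0.45) {
  ncore <- 2L * m + 1L
  ## core grid nodes
  xs <- seq(-core_half, core_half, length.out = ncore)
  core_xy <- cbind(rep(xs, times = ncore), rep(xs, each = ncore))
  core_id <- matrix(seq_len(ncore^2), ncore, ncore)   # [ix, iy]
  n_core <- ncore^2
  nb <- 8L * m                                         # boundary node count
  ## core boundary node ids ordered CCW starting at (core_half, 0)
  bd <- integer(nb)
  k <- 1L
  for (i in (m + 1L):(2L * m + 1L)) { bd[k] <- core_id[ncore, i]; k <- k + 1L }  # right edge up
  for (i in (2L * m):1L)            { bd[k] <- core_id[i, ncore]; k <- k + 1L }  # top edge left
  for (i in 2L:ncore)               { bd[k] <- core_id[1L, ncore - i + 1L]; k <- k + 1L } # left edge down
  for (i in 2L:ncore)               { bd[k] <- core_id[i, 1L]; k <- k + 1L }     # bottom edge right
  for (i in 2L:m)                   { bd[k] <- core_id[ncore, i]; k <- k + 1L }  # right edge to start
  bd <- bd[seq_len(nb)]
  stopifnot(!anyDuplicated(bd))
  phi_b <- 2 * pi * (seq_len(nb) - 1L) / nb
  circle_xy <- cbind(cos(phi_b), sin(phi_b))
  sq_xy <- core_xy[bd, , drop = FALSE]
  ## ring nodes j = 1..n_rad interpolate square boundary -> unit circle
  ring_xy <- NULL
  ring_ids <- matrix(0L, n_rad + 1L, nb)
  ring_ids[1L, ] <- bd
  nid <- n_core
  for (j in seq_len(n_rad)) {
    w <- j / n_rad
    xy <- (1 - w) * sq_xy + w * circle_xy
    ring_xy <- rbind(ring_xy, xy)
    ring_ids[j + 1L, ] <- nid + seq_len(nb)
    nid <- nid + nb
  }
  xy <- rbind(core_xy, ring_xy)
  n_nodes <- nrow(xy)
  ## radial fraction: core uses max-norm steps (m of them), rings add n_rad
  ntot <- m + n_rad
  rho <- numeric(n_nodes)
  rho[seq_len(n_core)] <- (pmax(abs(core_xy[, 1]), abs(core_xy[, 2])) /
                             core_half) * m / ntot
  for (j in seq_len(n_rad))
    rho[ring_ids[j + 1L, ]] <- (m + j) / ntot
  phi <- atan2(xy[, 2], xy[, 1])
  phi[ring_ids[1L, ]] <- phi_b   # exact uniform angles on shared boundary
  for (j in seq_len(n_rad)) phi[ring_ids[j + 1L, ]] <- phi_b
  ## quads (CCW in the plane)
  quads <- matrix(0L, 4L * m^2 + nb * n_rad, 4L)
  q <- 1L
  for (i in seq_len(2L * m)) for (jj in seq_len(2L * m)) {
    quads[q, ] <- c(core_id[i, jj], core_id[i + 1L, jj],
                    core_id[i + 1L, jj + 1L], core_id[i, jj + 1L])
    q <- q + 1L
  }
  for (j in seq_len(n_rad)) for (kk in seq_len(nb)) {
    k2 <- if (kk == nb) 1L else kk + 1L
    quads[q, ] <- c(ring_ids[j, kk], ring_ids[j + 1L, kk],
                    ring_ids[j + 1L, k2], ring_ids[j, k2])
    q <- q + 1L
  }
  list(xy = xy, rho = rho, phi = phi, quads = quads,
       boundary = ring_ids[n_rad + 1L, ], n_nodes = n_nodes)
}

hex_from_layers <- function(layer_nodes, disk, n_layers) {
  ## layer_nodes: function(k) -> node id offset of layer k (0-based layers)
  n_q <- nrow(disk$quads)
  elems <- matrix(0L, n_q * n_layers, 8L)
  e <- 1L
  for (k in seq_len(n_layers)) {
    lo <- layer_nodes(k - 1L); hi <- layer_nodes(k)
    for (q in seq_len(n_q)) {
      elems[e, ] <- c(lo + disk$quads[q, ], hi + disk$quads[q, ])
      e <- e + 1L
    }
  }
  elems
}

#' Generate an idealized truncated prolate-spheroid LV mesh
#'
#' Builds a structured hexahedral mesh of the LV wall between endocardial and
#' epicardial spheroids, closed at the apex by a butterfly block layout (no
#' degenerate hexes), and truncated by a flat basal plane.  Boundary facet
#' sets `endo`, `epi` and `base` and the node set `base_ring` are populated;
#' all facets are stored with outward (away from the wall interior) normals.
#'
#' @param spec An [lv_shape_spec()].
#' @return An object of class `hex_mesh` with fields `nodes` (n x 3 mm),
#'   `elements` (e x 8, 1-based), `surfaces` (named list of facet matrices),
#'   `node_sets`, and `meta`.
#' @export
generate_idealized_lv <- function(spec) {
  stopifnot(inherits(spec, "lv_shape_spec"))
  m <- spec$n_circumferential / 8L
  disk <- butterfly_disk(m, spec$n_longitudinal)
  n_t <- spec$n_transmural
  z_base <- spec$endo_long_radius * (2 * spec$truncation_fraction - 1)
  nd <- disk$n_nodes
  nodes <- matrix(0, nd * (n_t + 1L), 3L)
  for (k in 0:n_t) {
    tau <- k / n_t
    a <- spec$endo_long_radius + tau * spec$wall_thickness_apex
    b <- spec$endo_short_radius + tau * spec$wall_thickness_equator
    th_base <- acos(pmin(1, pmax(-1, -z_base / a)))
    th <- disk$rho * th_base
    r <- b * sin(th)
    nodes[k * nd + seq_len(nd), ] <- cbind(r * cos(disk$phi),
                                           r * sin(disk$phi),
                                           -a * cos(th))
  }
  elems <- hex_from_layers(function(k) k * nd, disk, n_t)
  ## orient for positive Jacobians (flip bottom/top where needed)
  neg <- which(hex_volumes_cpp(nodes, elems) < 0)
  if (length(neg) > 0)
    elems[neg, ] <- elems[neg, c(5:8, 1:4), drop = FALSE]
  endo <- disk$quads                       # layer 0
  epi  <- disk$quads + n_t * nd            # layer n_t
  nb <- length(disk$boundary)
  base <- matrix(0L, nb * n_t, 4L)
  q <- 1L
  for (k in seq_len(n_t)) for (kk in seq_len(nb)) {
    k2 <- if (kk == nb) 1L else kk + 1L
    base[q, ] <- c((k - 1L) * nd + disk$boundary[kk],
                   (k - 1L) * nd + disk$boundary[k2],
                   k * nd + disk$boundary[k2],
                   k * nd + disk$boundary[kk])
    q <- q + 1L
  }
  mesh <- structure(list(nodes = nodes, elements = elems,
                         surfaces = list(endo = endo, epi = epi, base = base),
                         node_sets = list(
                           base_ring = sort(unique(as.integer(base)))),
                         meta = list(kind = "idealized_lv",
                                     apex_layout = "butterfly",
                                     spec = unclass(spec),
                                     z_base = z_base)),
                    class = "hex_mesh")
  mesh <- orient_surfaces_outward(mesh)
  mesh
}

## Re-orient each surface facet so its normal points away from the wall
## interior (checked against the vector from the element centroid).
orient_surfaces_outward <- function(mesh) {
  ## node -> elements incidence for facet-owner lookup
  ne <- nrow(mesh$elements)
  inc <- split(rep(seq_len(ne), 8L), as.integer(mesh$elements))
  elem_of_facet <- function(f) {
    cand <- inc[[as.character(f[1])]]
    for (k in 2:4) cand <- intersect(cand, inc[[as.character(f[k])]])
    cand[1]
  }
  for (s in names(mesh$surfaces)) {
    fm <- mesh$surfaces[[s]]
    for (i in seq_len(nrow(fm))) {
      f <- fm[i, ]
      x <- mesh$nodes[f, , drop = FALSE]
      nrm <- crossp(x[3, ] - x[1, ], x[4, ] - x[2, ]) / 2
      e <- elem_of_facet(f)
      ec <- colMeans(mesh$nodes[mesh$elements[e, ], , drop = FALSE])
      fc <- colMeans(x)
      if (sum(nrm * (fc - ec)) < 0) fm[i, ] <- rev(f)
    }
    mesh$surfaces[[s]] <- fm
  }
  mesh
}

crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Hexahedral element volumes
#'
#' Volumes by 2x2x2 Gauss integration of the trilinear Jacobian determinant.
#' @param mesh A `hex_mesh`.
#' @return Numeric vector of element volumes (mm^3).
#' @export
element_volumes <- function(mesh) {
  as.numeric(hex_volumes_cpp(mesh$nodes, mesh$elements))
}

#' Check Jacobian positivity at all Gauss points
#' @param mesh A `hex_mesh`.
#' @return TRUE if every 2x2x2 Gauss-point Jacobian determinant is positive.
#' @export
jacobians_positive <- function(mesh) {
  min_jacobian_cpp(mesh$nodes, mesh$elements) > 0
}

#' Volume enclosed by the mesh boundary surfaces
#'
#' Divergence-theorem volume over the closed boundary (all surface facet
#' sets, outward-oriented): V = sum over facets of (x_c . A_vec) / 3.
#' @param mesh A `hex_mesh`.
#' @return Enclosed volume (mm^3).
#' @export
enclosed_volume <- function(mesh) {
  v <- 0
  for (fm in mesh$surfaces) {
    for (i in seq_len(nrow(fm))) {
      x <- mesh$nodes[fm[i, ], , drop = FALSE]
      av <- crossp(x[3, ] - x[1, ], x[4, ] - x[2, ]) / 2
      v <- v + sum(colMeans(x) * av) / 3
    }
  }
  v
}

#' Cavity volume of an LV mesh
#'
#' Volume enclosed by the endocardial surface plus its flat basal cap.
#' @param mesh A `hex_mesh` with an `endo` surface set.
#' @param nodes Optional deformed node coordinates (defaults to reference).
#' @return Cavity volume (mm^3).
#' @export
cavity_volume <- function(mesh, nodes = mesh$nodes) {
  fm <- mesh$surfaces$endo
  v <- 0
  for (i in seq_len(nrow(fm))) {
    x <- nodes[fm[i, ], , drop = FALSE]
    ## endo facets are outward from the wall, i.e. inward into the cavity:
    ## flip sign so the cavity is treated as the enclosed solid
    av <- -crossp(x[3, ] - x[1, ], x[4, ] - x[2, ]) / 2
    v <- v + sum(colMeans(x) * av) / 3
  }
  ## flat cap closing the cavity at the basal plane, outward normal +z:
  ## divergence-theorem term (1/3) * zb * A over the rim polygon
  rim <- endo_rim_polygon(mesh)
  if (!is.null(rim)) {
    p <- nodes[rim, , drop = FALSE]
    zb <- mean(p[, 3])
    a2 <- 0
    n <- nrow(p)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a2 <- a2 + (p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2])
    }
    v <- v + zb * (abs(a2) / 2) / 3
  }
  v
}

## ordered polygon of endo nodes on the basal rim (largest-z ring)
endo_rim_polygon <- function(mesh) {
  en <- unique(as.integer(mesh$surfaces$endo))
  zb <- max(mesh$nodes[en, 3])
  rim <- en[mesh$nodes[en, 3] > zb - 1e-8]
  if (length(rim) < 3) return(NULL)
  ang <- atan2(mesh$nodes[rim, 2] - mean(mesh$nodes[rim, 2]),
               mesh$nodes[rim, 1] - mean(mesh$nodes[rim, 1]))
  rim[order(ang)]
}

#' Mean wall thickness of an LV mesh
#'
#' Average distance between paired endocardial and epicardial surface nodes
#' (the structured generator keeps transmural node columns index-aligned).
#' @param mesh A `hex_mesh` from [generate_idealized_lv()] or
#'   [mesh_from_contours()].
#' @param nodes Optional deformed coordinates.
#' @return Mean thickness (mm).
#' @export
wall_thickness <- function(mesh, nodes = mesh$nodes) {
  en <- sort(unique(as.integer(mesh$surfaces$endo)))
  ep <- sort(unique(as.integer(mesh$surfaces$epi)))
  stopifnot(length(en) == length(ep))
  mean(sqrt(rowSums((nodes[ep, , drop = FALSE] -
                       nodes[en, , drop = FALSE])^2)))
}

#' Apex-to-base length of an LV mesh
#' @param mesh A `hex_mesh`.
#' @param nodes Optional deformed coordinates.
#' @return Length (mm) from the lowest epicardial point to the basal plane.
#' @export
apex_base_length <- function(mesh, nodes = mesh$nodes) {
  max(nodes[, 3]) - min(nodes[, 3])
}
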