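#' Contour stack (emulated CMR segmentation output)
#'
#' Per-slice endocardial and epicardial contours in slice-local mm
#' coordinates, ordered from apex to base.
#'
#' @param slices List of `list(slice_z, endo, epi)` with `endo`/`epi` k x 2
#'   point matrices; `slice_z` strictly increasing.
#' @param in_plane_spacing In-plane resolution (mm).
#' @param slice_thickness Slice spacing (mm).
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(slices, in_plane_spacing = 1.4,
                          slice_thickness = 2.5) {
  stopifnot(length(slices) >= 3)
  z <- vapply(slices, function(s) s$slice_z, 0)
  if (any(diff(z) <= 0))
    stop("slice_z must be strictly increasing from apex to base")
  for (s in slices) {
    stopifnot(is.matrix(s$endo), is.matrix(s$epi),
              ncol(s$endo) == 2, ncol(s$epi) == 2)
    if (!contour_encloses(s$epi, s$endo))
      stop("each slice's epi contour must strictly enclose its endo contour")
  }
  structure(list(slices = slices, in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness),
            class = "contour_stack")
}

## resample a closed polygon to radii at uniform angles about a center
polar_resample <- function(pts, angles, center = colMeans(pts)) {
  a <- atan2(pts[, 2] - center[2], pts[, 1] - center[1])
  r <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  o <- order(a)
  a <- a[o]; r <- r[o]
  aa <- c(a - 2 * pi, a, a + 2 * pi)
  rr <- c(r, r, r)
  stats::approx(aa, rr, xout = angles, rule = 2)$y
}

contour_encloses <- function(outer, inner) {
  c0 <- colMeans(outer)
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  ro <- polar_resample(outer, ang, c0)
  ri <- polar_resample(inner, ang, c0)
  all(ro > ri)
}

## does a closed polygon self-intersect? (O(k^2) segment test)
polygon_self_intersects <- function(pts) {
  k <- nrow(pts)
  seg <- function(i) rbind(pts[i, ], pts[if (i == k) 1L else i + 1L, ])
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  inter <- function(p1, p2, p3, p4)
    ccw(p1, p3, p4) != ccw(p2, p3, p4) && ccw(p1, p2, p3) != ccw(p1, p2, p4)
  for (i in seq_len(k - 2)) {
    s1 <- seg(i)
    jmax <- if (i == 1) k - 1 else k
    for (j in (i + 2):jmax) {
      s2 <- seg(j)
      if (inter(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(TRUE)
    }
  }
  FALSE
}

## least-squares cubic B-spline with the fewest interior knots whose
## summed squared residual is <= s; s = 0 reduces to interpolation
ls_spline_fit <- function(z, y, s) {
  n <- length(z)
  if (s <= 0) return(y)  # evaluated at the data sites: exact reproduction
  for (nk in 0:(n - 4)) {
    knots <- if (nk > 0)
      stats::quantile(z, probs = seq_len(nk) / (nk + 1), names = FALSE)
    else numeric(0)
    basis <- splines::bs(z, knots = knots, degree = 3, intercept = TRUE)
    fit <- stats::lm.fit(basis, y)
    if (sum(fit$residuals^2) <= s) return(fit$fitted.values)
  }
  y
}

#' Smooth a contour stack along the slice direction
#'
#' Fits, per control-point index and coordinate, a least-squares cubic
#' B-spline along z with the fewest knots whose residual sum of squares is
#' below the smoothing parameter, removing through-slice discontinuities
#' while preserving in-plane topology.  `smoothing = 0` reproduces the
#' input exactly.
#'
#' @param stack A [contour_stack()] with >= 4 slices and equal point counts
#'   per contour across slices.
#' @param smoothing Non-negative residual budget (mm^2) per control-point
#'   track.
#' @return A smoothed `contour_stack`.
#' @export
smooth_contour_stack <- function(stack, smoothing = 1) {
  stopifnot(inherits(stack, "contour_stack"), smoothing >= 0)
  ns <- length(stack$slices)
  if (ns < 4) stop("need >= 4 slices for cubic smoothing along z")
  z <- vapply(stack$slices, function(s) s$slice_z, 0)
  out <- stack
  for (which in c("endo", "epi")) {
    k <- nrow(stack$slices[[1]][[which]])
    if (!all(vapply(stack$slices, function(s) nrow(s[[which]]), 0L) == k))
      stop("control-point counts must match across slices")
    for (pt in seq_len(k)) for (d in 1:2) {
      y <- vapply(stack$slices, function(s) s[[which]][pt, d], 0)
      sm <- ls_spline_fit(z, y, smoothing)
      for (si in seq_len(ns)) out$slices[[si]][[which]][pt, d] <- sm[si]
    }
  }
  for (si in seq_len(ns)) for (which in c("endo", "epi"))
    if (polygon_self_intersects(out$slices[[si]][[which]]))
      stop("smoothing produced a self-intersecting ", which,
           " contour at slice ", si)
  out
}

#' Sample synthetic contours from an idealized LV surface
#'
#' Emulates short-axis segmentation output for an [lv_shape_spec()]:
#' circular endo/epi contours at the requested slice heights.
#'
#' @param spec An [lv_shape_spec()].
#' @param n_slices Number of slices between just above the endocardial apex
#'   and the basal plane.
#' @param n_points Contour points per slice.
#' @param in_plane_spacing,slice_thickness Stored acquisition metadata (mm).
#' @return A [contour_stack()].
#' @export
sample_lv_contours <- function(spec, n_slices = 8, n_points = 48,
                               in_plane_spacing = 1.4,
                               slice_thickness = NULL) {
  a_en <- spec$endo_long_radius
  b_en <- spec$endo_short_radius
  a_ep <- a_en + spec$wall_thickness_apex
  b_ep <- b_en + spec$wall_thickness_equator
  z_base <- a_en * (2 * spec$truncation_fraction - 1)
  z_lo <- -a_en * 0.85  # first slice above the endocardial apex
  zs <- seq(z_lo, z_base, length.out = n_slices)
  ang <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  mk <- function(b, a, z) {
    r <- b * sqrt(pmax(0, 1 - (z / a)^2))
    cbind(r * cos(ang), r * sin(ang))
  }
  slices <- lapply(zs, function(z)
    list(slice_z = z, endo = mk(b_en, a_en, z), epi = mk(b_ep, a_ep, z)))
  contour_stack(slices, in_plane_spacing,
                slice_thickness %||% diff(zs[1:2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a labelled hexahedral LV mesh from a contour stack
#'
#' Rings are interpolated transmurally between matched endo/epi contours and
#' stacked along z; the apex is closed by a butterfly cap whose nodes follow
#' per-angle quadratic fits of r^2 against z over the most apical slices (a
#' prolate-spheroid profile is reproduced exactly).  Same contract as
#' [generate_idealized_lv()].
#'
#' @param stack A (smoothed) [contour_stack()].
#' @param n_transmural Transmural element count (>= 2).
#' @param n_circumferential Circumferential count (multiple of 8); default
#'   chosen near the input contour point count.
#' @return A `hex_mesh`.
#' @export
mesh_from_contours <- function(stack, n_transmural = 3,
                               n_circumferential = NULL) {
  stopifnot(inherits(stack, "contour_stack"), n_transmural >= 2)
  ns <- length(stack$slices)
  if (ns < 3) stop("need >= 3 slices")
  np <- nrow(stack$slices[[1]]$endo)
  if (is.null(n_circumferential))
    n_circumferential <- max(8L, 8L * round(np / 8))
  if (n_circumferential %% 8 != 0)
    stop("n_circumferential must be a multiple of 8")
  nc <- n_circumferential
  n_t <- n_transmural
  ang <- 2 * pi * (seq_len(nc) - 1) / nc
  z <- vapply(stack$slices, function(s) s$slice_z, 0)
  ## rings[s, k, j]: radius of slice s, layer k (0..n_t), angle j, about the
  ## per-slice epi centroid (shared center keeps angles matched)
  centers <- t(vapply(stack$slices, function(s) colMeans(s$epi), c(0, 0)))
  r_endo <- t(vapply(seq_len(ns), function(s)
    polar_resample(stack$slices[[s]]$endo, ang, centers[s, ]), numeric(nc)))
  r_epi <- t(vapply(seq_len(ns), function(s)
    polar_resample(stack$slices[[s]]$epi, ang, centers[s, ]), numeric(nc)))
  if (any(r_epi <= r_endo))
    stop("epi radius <= endo radius at some slice/angle")
  ## cap: butterfly disk with 2 transition rings
  m <- nc / 8L
  disk <- butterfly_disk(m, 2L)
  bd <- disk$boundary
  interior <- setdiff(seq_len(disk$n_nodes), bd)
  n_int <- length(interior)
  n_ring_nodes <- ns * nc           # per layer
  n_layer <- n_ring_nodes + n_int
  nodes <- matrix(0, n_layer * (n_t + 1L), 3)
  ring_id <- function(k, s, j) k * n_layer + (s - 1L) * nc + j
  int_id0 <- function(k) k * n_layer + n_ring_nodes
  nfit <- min(4L, ns)
  for (k in 0:n_t) {
    tau <- k / n_t
    r_lay <- (1 - tau) * r_endo + tau * r_epi
    for (s in seq_len(ns)) {
      idx <- ring_id(k, s, seq_len(nc))
      nodes[idx, ] <- cbind(centers[s, 1] + r_lay[s, ] * cos(ang),
                            centers[s, 2] + r_lay[s, ] * sin(ang),
                            z[s])
    }
    ## per-angle quadratic fit of r^2 over the apical slices
    zs <- z[seq_len(nfit)]
    co <- vapply(seq_len(nc), function(j)
      stats::lm.fit(cbind(1, zs, zs^2), r_lay[seq_len(nfit), j]^2)$coefficients,
      numeric(3))
    apex_z <- vapply(seq_len(nc), function(j) {
      cc <- co[, j]
      disc <- cc[2]^2 - 4 * cc[3] * cc[1]
      if (!is.finite(disc) || disc < 0 || abs(cc[3]) < 1e-12)
        return(z[1] - (z[2] - z[1]))
      roots <- (-cc[2] + c(-1, 1) * sqrt(disc)) / (2 * cc[3])
      below <- roots[roots < z[1] + 1e-9]
      if (length(below) == 0) z[1] - (z[2] - z[1]) else max(below)
    }, 0)
    za <- mean(apex_z)
    ## cap interior nodes follow the fitted profile from apex to slice 1
    cap_center <- centers[1, ]
    for (ii in seq_along(interior)) {
      d <- interior[ii]
      rho <- disk$rho[d]
      phi <- disk$phi[d]
      zc <- za + (z[1] - za) * (1 - cos(rho * pi / 2))
      ## radius from the per-angle fit, interpolated in angle
      rj <- vapply(seq_len(nc), function(j) {
        cc <- co[, j]
        sqrt(max(0, cc[1] + cc[2] * zc + cc[3] * zc^2))
      }, 0)
      ## scale so the profile meets the ring exactly at rho = 1
      r1_fit <- vapply(seq_len(nc), function(j) {
        cc <- co[, j]
        sqrt(max(0, cc[1] + cc[2] * z[1] + cc[3] * z[1]^2))
      }, 0)
      scale <- ifelse(r1_fit > 1e-9, r_lay[1, ] / r1_fit, 1)
      rphi <- stats::approx(c(ang, 2 * pi), c(rj * scale, (rj * scale)[1]),
                            xout = phi %% (2 * pi), rule = 2)$y
      nodes[int_id0(k) + ii, ] <- c(cap_center[1] + rphi * cos(phi),
                                    cap_center[2] + rphi * sin(phi), zc)
    }
  }
  ## element connectivity: cap disk quads (with boundary mapped to slice-1
  ## rings) + tube quads between consecutive slices
  map_disk <- function(k) {
    mp <- integer(disk$n_nodes)
    mp[interior] <- int_id0(k) + seq_len(n_int)
    mp[bd] <- ring_id(k, 1L, seq_len(nc))
    mp
  }
  quads_of_layer <- function(k) {
    mp <- map_disk(k)
    cap <- matrix(mp[disk$quads], nrow(disk$quads), 4)
    tube <- matrix(0L, (ns - 1L) * nc, 4)
    q <- 1L
    for (s in seq_len(ns - 1L)) for (j in seq_len(nc)) {
      j2 <- if (j == nc) 1L else j + 1L
      tube[q, ] <- c(ring_id(k, s, j), ring_id(k, s, j2),
                     ring_id(k, s + 1L, j2), ring_id(k, s + 1L, j))
      q <- q + 1L
    }
    rbind(cap, tube)
  }
  q0 <- quads_of_layer(0L)
  nq <- nrow(q0)
  elems <- matrix(0L, nq * n_t, 8)
  for (k in seq_len(n_t)) {
    qa <- quads_of_layer(k - 1L)
    qb <- quads_of_layer(k)
    elems[(k - 1L) * nq + seq_len(nq), ] <- cbind(qa, qb)
  }
  neg <- which(hex_volumes_cpp(nodes, elems) < 0)
  if (length(neg) > 0)
    elems[neg, ] <- elems[neg, c(5:8, 1:4), drop = FALSE]
  endo <- quads_of_layer(0L)
  epi <- quads_of_layer(n_t)
  base <- matrix(0L, nc * n_t, 4)
  q <- 1L
  for (k in seq_len(n_t)) for (j in seq_len(nc)) {
    j2 <- if (j == nc) 1L else j + 1L
    base[q, ] <- c(ring_id(k - 1L, ns, j), ring_id(k - 1L, ns, j2),
                   ring_id(k, ns, j2), ring_id(k, ns, j))
    q <- q + 1L
  }
  mesh <- structure(list(nodes = nodes, elements = elems,
                         surfaces = list(endo = endo, epi = epi, base = base),
                         node_sets = list(
                           base_ring = sort(unique(as.integer(base)))),
                         meta = list(kind = "contour_lv",
                                     apex_layout = "butterfly",
                                     n_slices = ns, z_base = z[ns])),
                    class = "hex_mesh")
  orient_surfaces_outward(mesh)
}
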