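#' Voxel grid specification
#'
#' @param spacing Isotropic voxel edge length (mm), default 1.
#' @param origin World coordinates (mm) of the center of voxel (1,1,1).
#' @param dims Integer grid dimensions.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(spacing = 1, origin = c(0, 0, 0), dims) {
  stopifnot(spacing > 0, length(origin) == 3, length(dims) == 3)
  structure(list(spacing = spacing, origin = as.numeric(origin),
                 dims = as.integer(dims)), class = "grid_spec")
}

#' Grid covering a point cloud
#'
#' Builds an isotropic voxel grid enclosing the points with a margin of at
#' least the deposition kernel width on every side.
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param spacing Voxel size (mm).
#' @param margin Margin in voxels (>= 4, the kernel width).
#' @return A [grid_spec()].
#' @export
grid_for_points <- function(points, spacing = 1, margin = 6) {
  stopifnot(margin >= 4)
  lo <- apply(points, 2, min) - margin * spacing
  hi <- apply(points, 2, max) + margin * spacing
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(spacing = spacing, origin = lo, dims = dims)
}

ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g <- g[sqrt(rowSums(g^2)) <= radius + 1e-9, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

#' Binary LV mask from FE node positions
#'
#' Kernel density deposition: each node deposits a separable cubic B-spline
#' kernel of width 4 voxels (normalized so an isolated node's peak value is
#' 1) at its exact sub-voxel position; the summed field is thresholded at
#' > 0.25 and closed morphologically with a spherical structuring element of
#' diameter 6 voxels.
#'
#' @param points n x 3 matrix of node coordinates (mm), n >= 8.
#' @param grid A [grid_spec()]; defaults to [grid_for_points()] at 1 mm.
#' @param threshold Density threshold (default 0.25).
#' @param closing_diameter Structuring-element diameter in voxels (default 6).
#' @return An object of class `binary_mask`: `grid` (0/1 integer array),
#'   `spacing`, `origin`.
#' @export
mask_from_nodes <- function(points, grid = grid_for_points(points),
                            threshold = 0.25, closing_diameter = 6) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 8)
  vox <- sweep(points, 2, grid$origin) / grid$spacing
  dens <- bspline_deposit_cpp(vox, grid$dims)
  mask <- array(as.integer(dens > threshold), dim = grid$dims)
  if (sum(mask) == 0)
    stop("empty mask after thresholding: grid too coarse for the point cloud")
  if (closing_diameter > 0) {
    off <- ball_offsets(closing_diameter / 2)
    d <- binary_morph_cpp(as.integer(mask), grid$dims, off, TRUE)
    mask <- array(binary_morph_cpp(d, grid$dims, off, FALSE), dim = grid$dims)
  }
  structure(list(grid = mask, spacing = grid$spacing, origin = grid$origin),
            class = "binary_mask")
}

#' DICE similarity of two binary masks
#'
#' 2 |A and B| / (|A| + |B|) on identical grids.  Two empty masks give 0
#' with a warning.
#'
#' @param A,B `binary_mask` objects (or plain 0/1 arrays of equal dims).
#' @return DICE score in [0, 1].
#' @export
dice <- function(A, B) {
  ga <- if (inherits(A, "binary_mask")) A$grid else A
  gb <- if (inherits(B, "binary_mask")) B$grid else B
  if (inherits(A, "binary_mask") && inherits(B, "binary_mask")) {
    if (!isTRUE(all.equal(A$spacing, B$spacing)) ||
        !isTRUE(all.equal(A$origin, B$origin)))
      stop("masks must share grid spacing and origin")
  }
  if (!all(dim(ga) == dim(gb))) stop("masks must share grid dimensions")
  sa <- sum(ga); sb <- sum(gb)
  if (sa + sb == 0) {
    warning("both masks empty; DICE defined as 0")
    return(0)
  }
  2 * sum(ga * gb) / (sa + sb)
}

#' Foreground voxel centers of a mask
#' @param mask A `binary_mask`.
#' @return m x 3 matrix of world coordinates (mm).
#' @export
mask_points <- function(mask) {
  idx <- which(mask$grid == 1L, arr.ind = TRUE)
  sweep((idx - 1) * mask$spacing, 2, mask$origin, "+")
}

#' Rigid registration (iterative closest point)
#'
#' Aligns a source point cloud onto a target cloud with a proper rigid
#' transform (no scaling, no shear): centroid + principal-axes
#' initialization followed by ICP iterations with Kabsch (SVD) updates on
#' nearest-neighbor pairs.
#'
#' @param source,target n x 3 / m x 3 matrices (>= 4 non-coplanar points).
#' @param max_iter Maximum ICP iterations.
#' @param tol Convergence tolerance on the mean squared distance change.
#' @return An object of class `rigid_transform`: `rotation` (3x3, det +1),
#'   `translation` (mm), `rmse`, `converged`.
#' @export
rigid_register <- function(source, target, max_iter = 50, tol = 1e-10) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) >= 4, nrow(target) >= 4)
  cs <- colMeans(source); ct <- colMeans(target)
  ## principal-axes initialization with sign disambiguation
  es <- eigen(stats::cov(source), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(target), symmetric = TRUE)$vectors
  best <- NULL
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    D <- diag(c(s1, s2, s1 * s2))  # keeps det(R) = +1
    R0 <- et %*% D %*% t(es)
    if (det(R0) < 0) R0 <- et %*% (D %*% diag(c(1, 1, -1))) %*% t(es)
    t0 <- ct - R0 %*% cs
    src <- sweep(source %*% t(R0), 2, as.numeric(t0), "+")
    d <- mean(nn_index_cpp(src, target)$dist^2)
    if (is.null(best) || d < best$d) best <- list(R = R0, t = as.numeric(t0), d = d)
  }
  R <- best$R; tv <- best$t
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    src <- sweep(source %*% t(R), 2, tv, "+")
    nn <- nn_index_cpp(src, target)
    pairs <- target[nn$index, , drop = FALSE]
    msd <- mean(nn$dist^2)
    if (abs(prev - msd) < tol * max(msd, 1e-12)) { converged <- TRUE; break }
    prev <- msd
    ## Kabsch on (source, matched target)
    cs2 <- colMeans(source); cp <- colMeans(pairs)
    H <- t(sweep(source, 2, cs2)) %*% sweep(pairs, 2, cp)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tv <- as.numeric(cp - R %*% cs2)
  }
  src <- sweep(source %*% t(R), 2, tv, "+")
  rmse <- sqrt(mean(nn_index_cpp(src, target)$dist^2))
  structure(list(rotation = R, translation = tv, rmse = rmse,
                 converged = converged),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform A `rigid_transform`.
#' @param points n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
transform_points <- function(transform, points) {
  sweep(as.matrix(points) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Write a binary mask as NIfTI
#' @param mask A `binary_mask`.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return The file path, invisibly.
#' @export
write_mask_nifti <- function(mask, file) {
  img <- RNifti::asNifti(array(as.double(mask$grid), dim = dim(mask$grid)))
  RNifti::pixdim(img) <- rep(mask$spacing, 3)
  ## spacing and world origin live in the qform
  img <- RNifti::`qform<-`(img, structure(
    rbind(cbind(diag(3) * mask$spacing, mask$origin), c(0, 0, 0, 1)),
    code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a binary mask from NIfTI
#' @param file Path written by [write_mask_nifti()].
#' @return A `binary_mask`.
#' @export
read_mask_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  xf <- RNifti::xform(img)
  structure(list(grid = array(as.integer(img > 0.5), dim = dim(img)),
                 spacing = sqrt(sum(xf[1:3, 1]^2)),
                 origin = as.numeric(xf[1:3, 4])),
            class = "binary_mask")
}

#' Volumetric sample points of a deformed hex mesh
#'
#' Nodes plus trilinearly interpolated element-interior lattice points.
#' Each element is subdivided until the sub-point spacing falls below
#' `target_spacing`, so the point cloud that represents the wall is equally
#' dense regardless of mesh resolution and the kernel-density field
#' saturates identically for coarse and refined models.
#'
#' @param mesh A `hex_mesh`.
#' @param nodes Deformed node coordinates (default reference).
#' @param target_spacing Desired sub-point spacing in mm (default 1).
#' @return m x 3 matrix of points (mm).
#' @export
mesh_sample_points <- function(mesh, nodes = mesh$nodes,
                               target_spacing = 1) {
  el <- mesh$elements
  vol <- hex_volumes_cpp(nodes, el)
  subdiv <- pmax(1L, as.integer(ceiling(abs(vol)^(1/3) / target_spacing)))
  corners <- rbind(c(-1,-1,-1), c(1,-1,-1), c(1,1,-1), c(-1,1,-1),
                   c(-1,-1,1), c(1,-1,1), c(1,1,1), c(-1,1,1))
  pts <- list(nodes)
  for (s in sort(unique(subdiv))) {
    rows <- which(subdiv == s)
    u <- (2 * seq_len(s) - 1) / s - 1  # interior lattice in [-1, 1]
    offs <- as.matrix(expand.grid(u, u, u))
    for (i in seq_len(nrow(offs))) {
      xi <- offs[i, ]
      N <- apply(corners, 1, function(sgn) prod(1 + sgn * xi) / 8)
      p <- matrix(0, length(rows), 3)
      for (a in 1:8) p <- p + N[a] * nodes[el[rows, a], , drop = FALSE]
      pts[[length(pts) + 1L]] <- p
    }
  }
  do.call(rbind, pts)
}
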