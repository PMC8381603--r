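## Laplace-Dirichlet rule-based fiber assignment for a single-LV wall:
## a transmural harmonic coordinate (endo = 0, epi = 1) and an apicobasal
## one (apex = 0, base = 1) define the local wall directions; the helix
## angle interpolates linearly across the wall.

solve_laplace <- function(mesh, dirichlet_nodes, dirichlet_values) {
  n <- nrow(mesh$nodes)
  tr <- laplace_stiffness_cpp(mesh$nodes, mesh$elements)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$v, dims = c(n, n))
  fixed <- dirichlet_nodes
  if (anyDuplicated(fixed)) {
    keep <- !duplicated(fixed)
    fixed <- fixed[keep]
    dirichlet_values <- dirichlet_values[keep]
  }
  free <- setdiff(seq_len(n), fixed)
  xd <- dirichlet_values
  rhs <- -K[free, fixed, drop = FALSE] %*% xd
  xf <- tryCatch(
    as.numeric(Matrix::solve(K[free, free], rhs)),
    error = function(e) stop("singular Laplace system: mesh may be ",
                             "disconnected (", conditionMessage(e), ")"))
  out <- numeric(n)
  out[fixed] <- xd
  out[free] <- xf
  out
}

surface_nodes <- function(mesh, set) sort(unique(as.integer(mesh$surfaces[[set]])))

#' Transmural harmonic coordinate
#'
#' Solves the discrete Laplace equation on the wall with t_m = 0 on the
#' endocardium, t_m = 1 on the epicardium and a natural (zero-flux)
#' condition on the base.  By the discrete maximum principle all values lie
#' in [0, 1].
#'
#' @param mesh A `hex_mesh` with `endo` and `epi` surface sets.
#' @return Per-node numeric vector t_m in [0, 1].
#' @export
solve_transmural_laplace <- function(mesh) {
  en <- surface_nodes(mesh, "endo")
  ep <- surface_nodes(mesh, "epi")
  solve_laplace(mesh, c(en, ep), c(rep(0, length(en)), rep(1, length(ep))))
}

#' Apicobasal harmonic coordinate
#'
#' Laplace solve with 0 at the apex pole nodes and 1 on the basal plane;
#' its gradient supplies the longitudinal wall direction.
#'
#' @param mesh A `hex_mesh`.
#' @return Per-node numeric vector in [0, 1].
#' @export
solve_apicobasal_laplace <- function(mesh) {
  r_xy <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  apex <- which(r_xy <= min(r_xy) + 1e-8)
  base <- mesh$node_sets$base_ring
  solve_laplace(mesh, c(apex, base),
                c(rep(0, length(apex)), rep(1, length(base))))
}

normalize_rows <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-300)

#' Assign rule-based fiber, sheetlet and sheet-normal directions
#'
#' Per element: the transmural direction is the normalized gradient of t_m,
#' the longitudinal direction comes from the apicobasal field orthogonalized
#' against it, and the circumferential direction completes the frame.  The
#' helix angle interpolates linearly from `angles[1]` at the endocardium to
#' `angles[2]` at the epicardium; the fiber is
#' f = cos(theta) e_c + sin(theta) e_l, the sheetlet s is the transmural
#' direction orthogonalized against f, and n = f x s.
#'
#' @param mesh A `hex_mesh`.
#' @param t_m Per-node transmural coordinate (defaults to
#'   [solve_transmural_laplace()]).
#' @param angles Helix angles (degrees) at endo and epi; default +60 at the
#'   endocardium and -60 at the epicardium (right-handed helix at endo).
#' @return An object of class `fiber_field`: list with per-element matrices
#'   `f`, `s`, `n` (unit rows), per-element `t_m` and the angles.
#' @export
assign_fibers <- function(mesh, t_m = solve_transmural_laplace(mesh),
                          angles = c(60, -60)) {
  nE <- nrow(mesh$elements)
  grad_t <- field_gradient_cpp(mesh$nodes, mesh$elements, t_m)
  gnorm <- sqrt(rowSums(grad_t^2))
  if (any(gnorm < 1e-12))
    stop("zero transmural gradient in element(s) ",
         paste(which(gnorm < 1e-12), collapse = ", "))
  e_t <- grad_t / gnorm
  ab <- solve_apicobasal_laplace(mesh)
  grad_ab <- field_gradient_cpp(mesh$nodes, mesh$elements, ab)
  ## longitudinal: apicobasal gradient orthogonalized against e_t
  e_l <- grad_ab - rowSums(grad_ab * e_t) * e_t
  ln <- sqrt(rowSums(e_l^2))
  if (any(ln < 1e-12))
    stop("degenerate longitudinal direction in element(s) ",
         paste(which(ln < 1e-12), collapse = ", "))
  e_l <- e_l / ln
  ## circumferential completes a right-handed (e_c, e_l, e_t) frame
  e_c <- cbind(e_l[, 2] * e_t[, 3] - e_l[, 3] * e_t[, 2],
               e_l[, 3] * e_t[, 1] - e_l[, 1] * e_t[, 3],
               e_l[, 1] * e_t[, 2] - e_l[, 2] * e_t[, 1])
  e_c <- normalize_rows(e_c)
  tm_e <- rowMeans(matrix(t_m[mesh$elements], nE))
  theta <- (angles[1] + (angles[2] - angles[1]) * tm_e) * pi / 180
  f <- cos(theta) * e_c + sin(theta) * e_l
  f <- normalize_rows(f)
  s <- e_t - rowSums(e_t * f) * f
  s <- normalize_rows(s)
  n <- cbind(f[, 2] * s[, 3] - f[, 3] * s[, 2],
             f[, 3] * s[, 1] - f[, 1] * s[, 3],
             f[, 1] * s[, 2] - f[, 2] * s[, 1])
  structure(list(f = f, s = s, n = n, t_m = tm_e,
                 helix_angle_endo = angles[1], helix_angle_epi = angles[2]),
            class = "fiber_field")
}

## fiber field as an (nE x 9) matrix with rows (f, s, n) for the solver
fiber_matrix <- function(fibers) {
  cbind(fibers$f, fibers$s, fibers$n)
}
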