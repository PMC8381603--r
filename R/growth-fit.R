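#' Estimate myocardial growth parameters from a target geometry
#'
#' The central fitting function: given a post-growth target mask, builds the
#' pre-growth idealized LV model (mesh, fibers, pericardium), and runs the
#' Gaussian-process Bayesian-optimization loop that maximizes the DICE score
#' between the simulated grown LV and the target.  Returns a fitted-model
#' object with the usual accessor methods.
#'
#' @param target_mask A `binary_mask` of the post-growth LV wall (e.g. from
#'   [generate_synthetic_target()] or [read_mask_nifti()]).
#' @param spec Pre-growth LV shape ([lv_shape_spec()]).
#' @param mat A [material_params()].
#' @param bc A [boundary_conditions()].
#' @param solver A [solver_settings()].
#' @param bo A [bo_settings()].
#' @param pericardium Include the pericardial shell (default TRUE).
#' @param register Rigidly register simulated geometries to the target
#'   before voxelization (default TRUE).
#' @return An object of class `growth_fit`.
#' @export
estimate_growth <- function(target_mask, spec = coarse_lv_spec(),
                            mat = material_params(),
                            bc = boundary_conditions(),
                            solver = solver_settings(),
                            bo = bo_settings(),
                            pericardium = TRUE, register = TRUE) {
  forward <- make_forward_model(spec, mat, bc, solver, pericardium)
  mesh <- attr(forward, "mesh")
  surf <- sort(unique(c(as.integer(mesh$surfaces$endo),
                        as.integer(mesh$surfaces$epi))))
  opt <- optimize_growth(forward, target_mask, bo,
                         surface_nodes = surf, register = register,
                         mesh = mesh)
  structure(list(best = opt$best, trace = opt$trace,
                 surrogate = opt$surrogate, mesh = mesh,
                 spec = spec, mat = mat, bc = bc, solver = solver, bo = bo,
                 target_mask = target_mask, forward = forward),
            class = "growth_fit")
}

coef_params <- function(fit) growth_params(fit$best$alpha_f, fit$best$alpha_n)

#' @export
coef.growth_fit <- function(object, ...) {
  c(alpha_f = object$best$alpha_f, alpha_n = object$best$alpha_n)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Myocardial growth estimate (FE + Bayesian optimization)\n")
  cat(sprintf("  alpha_f (longitudinal): %.3f\n", x$best$alpha_f))
  cat(sprintf("  alpha_n (transverse):   %.3f\n", x$best$alpha_n))
  cat(sprintf("  best DICE score: %.3f\n", x$best$score))
  cat(sprintf("  simulations: %d (%d samples)\n",
              nrow(x$bo$init_params) + x$bo$n_iterations, nrow(x$trace)))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  tr <- object$trace
  best_by_iter <- vapply(sort(unique(tr$iteration)), function(it)
    max(tr$score[tr$iteration <= it]), 0)
  out <- list(coef = coef(object), best_score = object$best$score,
              n_samples = nrow(tr),
              best_by_iteration = best_by_iter,
              length_scales = object$surrogate$length_scales)
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat("Growth-fit summary\n")
  cat(sprintf("  estimate: alpha_f = %.3f, alpha_n = %.3f (DICE %.3f)\n",
              x$coef[1], x$coef[2], x$best_score))
  cat(sprintf("  %d cost-function samples; GP length scales %.2f / %.2f\n",
              x$n_samples, x$length_scales[1], x$length_scales[2]))
  cat("  best score by iteration:",
      paste(sprintf("%.3f", x$best_by_iteration), collapse = " "), "\n")
  invisible(x)
}

#' Plot the DICE posterior-mean heatmap of a growth fit
#'
#' Renders the Gaussian-process posterior mean over the growth-parameter
#' square, the evaluated samples, and the best estimate.
#'
#' @param x A `growth_fit`.
#' @param n Heatmap resolution per axis.
#' @param ... Passed to [graphics::image()].
#' @export
plot.growth_fit <- function(x, n = 51, ...) {
  hm <- dice_heatmap(x$surrogate, n)
  g <- sort(unique(hm$alpha_f))
  z <- matrix(hm$mu, n, n)  # rows alpha_f, cols alpha_n
  graphics::image(g, g, z, xlab = expression(alpha[f]),
                  ylab = expression(alpha[n]),
                  main = "GP posterior mean of DICE", ...)
  graphics::contour(g, g, z, add = TRUE)
  graphics::points(x$trace$alpha_f, x$trace$alpha_n, pch = 20)
  graphics::points(x$best$alpha_f, x$best$alpha_n, pch = 8, cex = 2,
                   col = "blue")
  invisible(x)
}

#' Re-simulate the fitted growth
#'
#' Runs the forward model at the estimated (or supplied) parameters.
#' @param object A `growth_fit`.
#' @param params Optional [growth_params()]; default the estimate.
#' @param ... Unused.
#' @return A `simulation_result`.
#' @export
predict.growth_fit <- function(object, params = NULL, ...) {
  if (is.null(params)) params <- coef_params(object)
  object$forward(params)
}
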