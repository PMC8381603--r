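## Gaussian-process surrogate (Matern-5/2, ARD) + upper-confidence-bound
## acquisition over the growth-parameter square [0,1]^2.

matern52 <- function(X1, X2, ls, sigma2) {
  r2 <- outer(X1[, 1] / ls[1], X2[, 1] / ls[1], "-")^2 +
        outer(X1[, 2] / ls[2], X2[, 2] / ls[2], "-")^2
  r <- sqrt(pmax(r2, 0))
  s5 <- sqrt(5) * r
  sigma2 * (1 + s5 + 5 * r2 / 3) * exp(-s5)
}

#' Bayesian-optimization settings
#'
#' @param beta UCB exploration weight; default 10.
#' @param beta_scale How beta enters the acquisition: "sqrt" (default;
#'   mu + sqrt(beta) sigma, the scaling of the reference UCB
#'   implementations) or "linear" (mu + beta sigma, the plain formula).
#' @param n_iterations Number of proposal-simulation rounds after the three
#'   initialization simulations; default 10.
#' @param init_params Matrix of initialization growth-parameter pairs; the
#'   default evaluates (0,1), (1,0) and (1,1).
#' @param acquisition_grid Grid resolution per axis for the acquisition
#'   argmax (default 101, i.e. a 0.01 step).
#' @param noise_floor GP noise-variance floor in standardized units,
#'   absorbing voxelization discretization noise.
#' @param seed Integer seed controlling hyperparameter multi-starts.
#' @return An object of class `bo_settings`.
#' @export
bo_settings <- function(beta = 10, beta_scale = c("sqrt", "linear"),
                        n_iterations = 10,
                        init_params = rbind(c(0, 1), c(1, 0), c(1, 1)),
                        acquisition_grid = 101, noise_floor = 1e-4,
                        seed = 1L) {
  beta_scale <- match.arg(beta_scale)
  stopifnot(beta >= 0, n_iterations >= 0,
            all(init_params >= 0), all(init_params <= 1))
  structure(list(beta = beta, beta_scale = beta_scale,
                 n_iterations = as.integer(n_iterations),
                 init_params = init_params,
                 acquisition_grid = as.integer(acquisition_grid),
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "bo_settings")
}

#' Fit the Gaussian-process surrogate
#'
#' Matern-5/2 kernel with per-dimension length scales on [0,1]^2 inputs and
#' standardized outputs; hyperparameters by marginal-likelihood maximization
#' from a fixed set of multi-starts.
#'
#' @param samples Data frame with columns `alpha_f`, `alpha_n`, `score`.
#' @param settings A [bo_settings()].
#' @return An object of class `gp_surrogate` with a `$predict(X)` function
#'   returning `mu` and `sd` on the original score scale.
#' @export
fit_surrogate <- function(samples, settings = bo_settings()) {
  stopifnot(nrow(samples) >= 2)
  X <- as.matrix(samples[, c("alpha_f", "alpha_n")])
  y <- samples$score
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y < 1e-8) sd_y <- 1e-8
  ys <- (y - mu_y) / sd_y
  n <- nrow(X)
  ## hyperparameters: log length scales, log signal variance, log noise
  ## variance (noise estimated, floored to absorb voxelization noise)
  nfloor <- settings$noise_floor
  nll <- function(par) {
    ls <- exp(par[1:2]); s2 <- exp(par[3]); nv <- exp(par[4])
    K <- matern52(X, X, ls, s2) + diag(nv + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(ch))) +
                 0.5 * n * log(2 * pi))
  }
  starts <- expand.grid(l = log(c(0.15, 0.4, 1.0)), s = log(c(0.5, 2)),
                        nv = log(c(0.01, 0.1)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$l[i], starts$l[i], starts$s[i], starts$nv[i])
    op <- tryCatch(stats::optim(p0, nll, method = "L-BFGS-B",
                                lower = log(c(0.1, 0.1, 1e-3, nfloor)),
                                upper = log(c(10, 10, 1e3, 1))),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) best <- list(par = c(log(0.3), log(0.3), 0, log(0.01)))
  ls <- exp(best$par[1:2]); s2 <- exp(best$par[3])
  noise <- exp(best$par[4])
  K <- matern52(X, X, ls, s2) + diag(noise + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  jit <- 1e-8
  while (is.null(ch) && jit < 1e-2) {
    jit <- jit * 100
    ch <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
  }
  if (is.null(ch)) stop("degenerate GP kernel matrix despite jitter")
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  pred <- function(Xnew) {
    Xnew <- matrix(Xnew, ncol = 2)
    Ks <- matern52(Xnew, X, ls, s2)
    mu <- as.numeric(Ks %*% alpha)
    v <- forwardsolve(t(ch), t(Ks))
    var <- pmax(s2 - colSums(v^2), 0)
    list(mu = mu * sd_y + mu_y, sd = sqrt(var) * sd_y)
  }
  structure(list(predict = pred, length_scales = ls, signal_var = s2,
                 noise_var = noise, samples = samples,
                 mu_y = mu_y, sd_y = sd_y),
            class = "gp_surrogate")
}

#' Propose the next growth-parameter pair (UCB)
#'
#' Maximizes mu(x) + beta * sigma(x) over a uniform candidate grid on
#' [0,1]^2; ties break toward the lowest lexicographic (alpha_f, alpha_n).
#'
#' @param surrogate A fitted [fit_surrogate()].
#' @param settings A [bo_settings()].
#' @return A [growth_params()].
#' @export
propose_next <- function(surrogate, settings = bo_settings()) {
  g <- seq(0, 1, length.out = settings$acquisition_grid)
  ## lexicographic order (alpha_f major) so ties resolve to the lowest pair
  cand <- as.matrix(expand.grid(alpha_n = g, alpha_f = g))[, c(2, 1)]
  p <- surrogate$predict(cand)
  w <- if (identical(settings$beta_scale, "linear")) settings$beta else
    sqrt(settings$beta)
  acq <- p$mu + w * p$sd
  i <- which.max(acq)  # first index = lowest lexicographic among exact ties
  growth_params(cand[i, 1], cand[i, 2])
}

#' Estimate growth parameters by Bayesian optimization
#'
#' Protocol: evaluate the three initialization parameter pairs, harvesting
#' the five intermediate growth checkpoints of every simulation as
#' additional cost-function samples at the proportionally scaled parameters;
#' then `n_iterations` rounds of GP fit, UCB proposal, simulation and DICE
#' scoring.  Every scoring step rigidly registers the checkpoint geometry to
#' the target, voxelizes it on the target grid and computes the DICE score.
#'
#' @param forward Callable `function(params)` returning a
#'   `simulation_result` (see [run_growth_simulation()]).
#' @param target_mask A `binary_mask`: the post-growth target.
#' @param settings A [bo_settings()].
#' @param surface_nodes Optional integer vector of node indices (endo + epi
#'   surfaces) used for registration; default all nodes.
#' @param target_points Optional registration target point cloud; defaults
#'   to the `points` attribute of `target_mask` (attached by
#'   [generate_synthetic_target()]) or, failing that, the foreground voxel
#'   centers of the mask.
#' @param register If FALSE skip rigid registration (geometries already in
#'   a common frame).
#' @param mesh Optional `hex_mesh` matching the forward model's node
#'   numbering; when given, voxelization uses [mesh_sample_points()]
#'   (nodes + element-interior points) for solid masks at coarse mesh
#'   density.
#' @return List with `best` (a `bo_sample` row), `trace` (data frame of all
#'   samples: iteration, alpha_f, alpha_n, score, provenance) and
#'   `surrogate` (final GP fit).
#' @export
optimize_growth <- function(forward, target_mask, settings = bo_settings(),
                            surface_nodes = NULL, target_points = NULL,
                            register = TRUE, mesh = NULL) {
  set.seed(settings$seed)
  tgrid <- grid_spec(spacing = target_mask$spacing,
                     origin = target_mask$origin,
                     dims = dim(target_mask$grid))
  if (register && is.null(target_points)) {
    target_points <- attr(target_mask, "points")
    if (is.null(target_points)) target_points <- mask_points(target_mask)
  }
  if (register && nrow(target_points) > 2000)
    target_points <- target_points[seq(1, nrow(target_points),
                                       length.out = 2000), , drop = FALSE]
  dice_of <- function(nodes, tf = NULL) {
    pts <- if (is.null(mesh)) nodes else
      mesh_sample_points(mesh, nodes, target_spacing = tgrid$spacing / 2)
    if (!is.null(tf)) pts <- transform_points(tf, pts)
    m <- tryCatch(mask_from_nodes(pts, tgrid), error = function(e) NULL)
    if (is.null(m)) return(0)
    dice(m$grid, target_mask$grid)
  }
  score_nodes <- function(nodes) {
    d0 <- dice_of(nodes)
    if (!register) return(d0)
    src <- if (is.null(surface_nodes)) nodes else
      nodes[surface_nodes, , drop = FALSE]
    tf <- rigid_register(src, target_points)
    ## registration must never reduce the achievable overlap
    max(d0, dice_of(nodes, tf))
  }
  samples <- data.frame(iteration = integer(), alpha_f = numeric(),
                        alpha_n = numeric(), score = numeric(),
                        provenance = character())
  run_and_score <- function(params, iter, prov) {
    res <- tryCatch(forward(params), error = function(e) NULL)
    if (is.null(res) || isTRUE(res$diverged)) {
      samples[nrow(samples) + 1L, ] <<- list(iter, params$alpha_f,
                                             params$alpha_n, 0, prov)
      return(invisible(NULL))
    }
    for (cp in res$checkpoints) {
      if (is.null(cp$nodes)) next
      sc <- score_nodes(cp$nodes)
      pv <- if (cp$growth_fraction >= 1) prov else "intermediate-checkpoint"
      samples[nrow(samples) + 1L, ] <<- list(iter, cp$params$alpha_f,
                                             cp$params$alpha_n, sc, pv)
    }
    invisible(NULL)
  }
  for (i in seq_len(nrow(settings$init_params)))
    run_and_score(growth_params(settings$init_params[i, 1],
                                settings$init_params[i, 2]),
                  0L, "initialization")
  surrogate <- NULL
  for (it in seq_len(settings$n_iterations)) {
    surrogate <- fit_surrogate(samples, settings)
    prop <- propose_next(surrogate, settings)
    run_and_score(prop, it, "proposed")
  }
  surrogate <- fit_surrogate(samples, settings)
  best <- samples[which.max(samples$score), ]
  list(best = best, trace = samples, surrogate = surrogate)
}

#' Posterior-mean DICE heatmap over the growth-parameter square
#' @param surrogate A fitted `gp_surrogate`.
#' @param n Grid resolution per axis.
#' @return Data frame with alpha_f, alpha_n, mu, sd.
#' @export
dice_heatmap <- function(surrogate, n = 51) {
  g <- seq(0, 1, length.out = n)
  cand <- as.matrix(expand.grid(alpha_f = g, alpha_n = g))
  p <- surrogate$predict(cand)
  data.frame(alpha_f = cand[, 1], alpha_n = cand[, 2], mu = p$mu, sd = p$sd)
}
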