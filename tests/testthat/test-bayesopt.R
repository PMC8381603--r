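test_that("the GP surrogate regresses a linear function and interpolates", {
  set.seed(1)
  s <- data.frame(alpha_f = stats::runif(40), alpha_n = stats::runif(40))
  s$score <- 0.2 + 0.3 * s$alpha_f + 0.5 * s$alpha_n
  gp <- fit_surrogate(s, bo_settings())
  test <- cbind(stats::runif(20), stats::runif(20))
  p <- gp$predict(test)
  expect_lt(max(abs(p$mu - (0.2 + 0.3 * test[, 1] + 0.5 * test[, 2]))), 1e-3)
  ## near-interpolation at a noise-free sample
  expect_lt(gp$predict(as.matrix(s[1, 1:2]))$sd, 0.05 * stats::sd(s$score))
})

test_that("the surrogate posterior matches a direct GP computation", {
  ## independent dense-matrix GP formula with the surrogate's fitted
  ## hyperparameters, on a small grid
  set.seed(2)
  s <- data.frame(alpha_f = stats::runif(15), alpha_n = stats::runif(15))
  s$score <- sin(3 * s$alpha_f) + s$alpha_n^2
  gp <- fit_surrogate(s, bo_settings())
  X <- as.matrix(s[, 1:2])
  ys <- (s$score - gp$mu_y) / gp$sd_y
  k_fun <- function(A, B) {
    r <- sqrt(outer(A[, 1] / gp$length_scales[1],
                    B[, 1] / gp$length_scales[1], "-")^2 +
              outer(A[, 2] / gp$length_scales[2],
                    B[, 2] / gp$length_scales[2], "-")^2)
    gp$signal_var * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
  K <- k_fun(X, X) + diag(gp$noise_var + 1e-8, nrow(X))
  grid <- as.matrix(expand.grid(seq(0.1, 0.9, 0.2), seq(0.1, 0.9, 0.2)))
  Ks <- k_fun(grid, X)
  mu_direct <- as.numeric(Ks %*% solve(K, ys)) * gp$sd_y + gp$mu_y
  var_direct <- pmax(gp$signal_var - diag(Ks %*% solve(K, t(Ks))), 0)
  p <- gp$predict(grid)
  expect_equal(p$mu, mu_direct, tolerance = 1e-6)
  expect_equal(p$sd, sqrt(var_direct) * gp$sd_y, tolerance = 1e-6)
  ## posterior mean stays within the observed range deep inside the samples
  expect_true(all(p$mu <= max(s$score) + 0.25 * diff(range(s$score))))
  expect_true(all(p$mu >= min(s$score) - 0.25 * diff(range(s$score))))
})

test_that("UCB proposal degenerates to the posterior-mean argmax at beta = 0", {
  set.seed(3)
  s <- data.frame(alpha_f = stats::runif(30), alpha_n = stats::runif(30))
  s$score <- -(s$alpha_f - 0.3)^2 - (s$alpha_n - 0.7)^2
  gp <- fit_surrogate(s, bo_settings())
  p0 <- propose_next(gp, bo_settings(beta = 0))
  g <- seq(0, 1, length.out = 101)
  cand <- as.matrix(expand.grid(alpha_n = g, alpha_f = g))[, c(2, 1)]
  mu <- gp$predict(cand)$mu
  best <- cand[which.max(mu), ]
  expect_equal(unname(c(p0$alpha_f, p0$alpha_n)), unname(best))
  ## large beta proposes far from existing samples (exploration), verified
  ## against a brute-force evaluation of mu + beta * sigma
  st <- bo_settings(beta = 50, beta_scale = "linear")
  pb <- propose_next(gp, st)
  pr <- gp$predict(cand)
  acq <- pr$mu + 50 * pr$sd
  expect_equal(unname(c(pb$alpha_f, pb$alpha_n)),
               unname(cand[which.max(acq), ]))
  nn_dist <- min(sqrt((s$alpha_f - pb$alpha_f)^2 + (s$alpha_n - pb$alpha_n)^2))
  expect_gt(nn_dist, 0.05)
  ## proposals always within bounds
  expect_true(pb$alpha_f >= 0 && pb$alpha_f <= 1)
  expect_true(pb$alpha_n >= 0 && pb$alpha_n <= 1)
})

## lightweight geometric forward model: node cloud of an ellipsoidal shell
## whose axes respond to the growth parameters; runs in milliseconds and
## exercises the full optimize_growth protocol
fake_forward <- function(params) {
  mk_nodes <- function(af, an) {
    th <- seq(0, pi, length.out = 14)
    ph <- seq(0, 2 * pi, length.out = 21)[-21]
    g <- expand.grid(th = th, ph = ph)
    r <- 15 * (1 + 0.4 * an)
    c_ax <- 25 * (1 + 0.5 * af)
    t(vapply(seq_len(nrow(g)), function(i) {
      s <- sin(g$th[i])
      c(r * s * cos(g$ph[i]), r * s * sin(g$ph[i]), c_ax * cos(g$th[i]))
    }, numeric(3)))
  }
  cps <- lapply(c(0.2, 0.4, 0.6, 0.8, 1), function(fr)
    list(growth_fraction = fr,
         params = growth_params(fr * params$alpha_f, fr * params$alpha_n),
         nodes = mk_nodes(fr * params$alpha_f, fr * params$alpha_n)))
  structure(list(checkpoints = cps, diverged = FALSE),
            class = "simulation_result")
}

test_that("optimize_growth follows the protocol and recovers a known optimum", {
  true <- growth_params(0.45, 0.6)
  tgt_nodes <- fake_forward(true)$checkpoints[[5]]$nodes
  grid <- grid_for_points(tgt_nodes, spacing = 2, margin = 8)
  target <- mask_from_nodes(tgt_nodes, grid)
  attr(target, "points") <- tgt_nodes
  st <- bo_settings(n_iterations = 6, seed = 4)
  out <- optimize_growth(fake_forward, target, st, register = FALSE)
  tr <- out$trace
  ## 3 + n_iterations simulations, five evaluations each
  expect_equal(nrow(tr), 5 * (3 + 6))
  expect_equal(sum(tr$provenance == "initialization"), 3)
  expect_equal(sum(tr$provenance == "proposed"), 6)
  expect_equal(sum(tr$provenance == "intermediate-checkpoint"), 4 * 9)
  ## best-so-far is non-decreasing over iterations
  best_by <- vapply(0:6, function(it) max(tr$score[tr$iteration <= it]), 0)
  expect_true(all(diff(best_by) >= -1e-12))
  ## decent recovery of the optimum of this cheap landscape
  expect_gt(out$best$score, 0.9)
  expect_lt(abs(out$best$alpha_f - 0.45), 0.2)
  expect_lt(abs(out$best$alpha_n - 0.6), 0.2)
})

test_that("the optimization trace is reproducible under a fixed seed", {
  true <- growth_params(0.3, 0.4)
  tgt_nodes <- fake_forward(true)$checkpoints[[5]]$nodes
  grid <- grid_for_points(tgt_nodes, spacing = 2, margin = 8)
  target <- mask_from_nodes(tgt_nodes, grid)
  st <- bo_settings(n_iterations = 3, seed = 7)
  o1 <- optimize_growth(fake_forward, target, st, register = FALSE)
  o2 <- optimize_growth(fake_forward, target, st, register = FALSE)
  expect_identical(o1$trace, o2$trace)
})

test_that("a diverged simulation scores zero and the loop continues", {
  calls <- 0L
  flaky <- function(params) {
    calls <<- calls + 1L
    if (calls == 4L) stop("synthetic divergence")
    fake_forward(params)
  }
  true <- growth_params(0.3, 0.4)
  tgt_nodes <- fake_forward(true)$checkpoints[[5]]$nodes
  grid <- grid_for_points(tgt_nodes, spacing = 2, margin = 8)
  target <- mask_from_nodes(tgt_nodes, grid)
  out <- optimize_growth(flaky, target, bo_settings(n_iterations = 3, seed = 2),
                         register = FALSE)
  expect_true(any(out$trace$score == 0))
  expect_equal(max(out$trace$iteration), 3)
})
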