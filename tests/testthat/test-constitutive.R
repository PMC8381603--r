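random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("growth tensor has the prescribed eigenstructure and determinant", {
  ## det Fg = (1 + alpha_f)(1 + alpha_n)^2 to machine precision
  set.seed(11)
  for (i in 1:100) {
    af <- stats::runif(1); an <- stats::runif(1)
    Q <- random_rotation()
    Fg <- growth_tensor(growth_params(af, an), Q)
    expect_equal(det(Fg), (1 + af) * (1 + an)^2, tolerance = 1e-12)
    ev <- sort(eigen(Fg, symmetric = TRUE)$values)
    expect_equal(ev, sort(c(1 + af, 1 + an, 1 + an)), tolerance = 1e-12)
  }
  expect_equal(growth_tensor(growth_params(0, 0)), diag(3))
  expect_equal(growth_tensor(growth_params(1, 0)), diag(c(2, 1, 1)))
  expect_equal(det(growth_tensor(growth_params(0.9, 0.3))), 3.211,
               tolerance = 1e-12)
})

test_that("the reference configuration and compatible growth are stress free", {
  mat <- material_params()
  st <- deformation_state(diag(3))
  expect_equal(strain_energy(st, mat), mat$a / (2 * mat$b), tolerance = 1e-12)
  expect_lt(max(abs(pk2_stress(st, mat))), 1e-12)
  ## F = Fg (any growth): Fe = I, stress-free grown state
  for (gp in list(growth_params(0.9, 0.3), growth_params(0.2, 0.8))) {
    Q <- random_rotation()
    st2 <- deformation_state(growth_tensor(gp, Q), gp, Q)
    expect_lt(max(abs(pk2_stress(st2, mat))), 1e-10)
  }
})

test_that("analytic stress matches finite differences of the energy", {
  ## S = 2 dpsi/dC by symmetric central differences on 50 random states
  set.seed(42)
  mat <- material_params()
  n_ok <- 0
  while (n_ok < 50) {
    F <- diag(3) + matrix(stats::rnorm(9, 0, 0.08), 3)
    if (det(F) < 0.8 || det(F) > 1.3) next
    Q <- random_rotation()
    gp <- growth_params(stats::runif(1), stats::runif(1))
    S <- pk2_stress(deformation_state(F, gp, Q), mat)
    C <- t(F) %*% F
    psiC <- function(Cm) {
      ee <- eigen(Cm, symmetric = TRUE)
      Fs <- ee$vectors %*% diag(sqrt(ee$values)) %*% t(ee$vectors)
      strain_energy(deformation_state(Fs, gp, Q), mat)
    }
    h <- 1e-6
    Sfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      dC <- matrix(0, 3, 3)
      dC[i, j] <- dC[i, j] + h / 2
      dC[j, i] <- dC[j, i] + h / 2
      Sfd[i, j] <- 2 * (psiC(C + dC) - psiC(C - dC)) / (2 * h)
    }
    expect_lt(max(abs(S - Sfd)) / max(abs(S)), 1e-5)
    n_ok <- n_ok + 1
  }
})

test_that("uniaxial fiber stretch matches an independent scalar evaluation", {
  ## lambda = 1.1 along f with isochoric transverse contraction: invariants
  ## computed by hand and the energy evaluated from the printed formula
  mat <- material_params(kappa = 1000)
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  st <- deformation_state(F)
  I1 <- lam^2 + 2 / lam
  I4f <- lam^2
  I4s <- 1 / lam
  psi_hand <- mat$a / (2 * mat$b) * exp(mat$b * (I1 - 3)) +
    mat$a_f / (2 * mat$b_f) * (exp(mat$b_f * (I4f - 1)^2) - 1)
  ## sheet term inactive (I4s < 1, tension-only); J = 1 so no volumetric part
  expect_equal(st$I1e, I1, tolerance = 1e-12)
  expect_equal(st$I4fe, I4f, tolerance = 1e-12)
  expect_equal(st$I4se, I4s, tolerance = 1e-12)
  expect_equal(strain_energy(st, mat), psi_hand, tolerance = 1e-10)
  ## without the Macaulay bracket the compressed sheet term engages too
  mat2 <- material_params(macaulay = FALSE)
  psi_hand2 <- psi_hand +
    mat2$a_s / (2 * mat2$b_s) * (exp(mat2$b_s * (I4s - 1)^2) - 1)
  expect_equal(strain_energy(st, mat2), psi_hand2, tolerance = 1e-10)
})

test_that("energy is frame indifferent", {
  set.seed(7)
  mat <- material_params()
  F <- diag(3) + matrix(stats::rnorm(9, 0, 0.05), 3)
  psi0 <- strain_energy(deformation_state(F), mat)
  for (k in 1:20) {
    Q <- random_rotation()
    expect_equal(strain_energy(deformation_state(Q %*% F), mat), psi0,
                 tolerance = 1e-10)
  }
})

test_that("energy grows monotonically along radial stretch paths", {
  set.seed(3)
  mat <- material_params()
  for (k in 1:5) {
    D <- matrix(stats::rnorm(9, 0, 1), 3)
    D <- (D + t(D)) / 20
    lams <- seq(0, 0.25, length.out = 8)
    psis <- vapply(lams, function(l) {
      F <- diag(3) + l * D
      if (det(F) <= 0) return(NA_real_)
      strain_energy(deformation_state(F), mat)
    }, 0)
    psis <- psis[!is.na(psis)]
    expect_true(all(diff(psis) > 0))
  }
})

test_that("with fiber terms removed the response is isotropic", {
  set.seed(9)
  mat <- material_params(a_f = 0, a_s = 0, a_fs = 0)
  F <- diag(3) + matrix(stats::rnorm(9, 0, 0.06), 3)
  S <- pk2_stress(deformation_state(F), mat)
  for (k in 1:5) {
    Q <- random_rotation()
    ## S(FQ) = Q^T S(F) Q for isotropic materials (material rotation)
    S2 <- pk2_stress(deformation_state(F %*% Q), mat)
    expect_equal(S2, t(Q) %*% S %*% Q, tolerance = 1e-9)
  }
})

test_that("material parameter validation enforces the near-incompressibility bound", {
  expect_error(material_params(kappa = 10), "kappa")
  expect_error(growth_params(1.2, 0), "\\[0, 1\\]")
  expect_silent(material_params())
})
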