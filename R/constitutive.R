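#' Growth parameter pair
#'
#' The two kinematic growth coefficients being estimated: `alpha_f` scales
#' stretch along the fiber direction (longitudinal cardiomyocyte growth,
#' series sarcomerogenesis) and `alpha_n` scales stretch in the sheetlet /
#' sheet-normal plane (transverse growth, parallel sarcomerogenesis).  Both
#' are dimensionless on [0, 1]; 1 corresponds to a doubling of size along
#' the respective direction.
#'
#' @param alpha_f Longitudinal growth coefficient.
#' @param alpha_n Transverse growth coefficient.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(alpha_f = 0, alpha_n = 0) {
  stopifnot(is.numeric(alpha_f), is.numeric(alpha_n))
  if (alpha_f < 0 || alpha_f > 1 || alpha_n < 0 || alpha_n > 1)
    stop("growth coefficients must lie in [0, 1]")
  structure(list(alpha_f = unname(alpha_f), alpha_n = unname(alpha_n)),
            class = "growth_params")
}

#' Holzapfel-Ogden material parameters
#'
#' Invariant-based anisotropic hyperelastic myocardium model with isotropic,
#' fiber, sheet and fiber-sheet coupling terms, augmented by a volumetric
#' penalty kappa/2 (ln Je)^2 enforcing near-incompressibility.  Defaults are
#' the swine parameter set used throughout the package.  Stresses in kPa.
#'
#' @param a,b Isotropic term: stress scale (kPa) and exponent.
#' @param a_f,b_f Fiber term.
#' @param a_s,b_s Sheet term.
#' @param a_fs,b_fs Fiber-sheet coupling term.
#' @param kappa Bulk penalty modulus (kPa).
#' @param macaulay If TRUE (default) the fiber/sheet terms are tension-only
#'   (Macaulay bracket on I4 - 1), avoiding nonphysical compressive fiber
#'   stiffening; FALSE activates them unconditionally.
#' @return An object of class `material_params`.
#' @export
material_params <- function(a = 1.05, b = 7.542, a_f = 3.465, b_f = 14.472,
                            a_s = 0.481, b_s = 12.548, a_fs = 0.283,
                            b_fs = 3.088, kappa = 1000, macaulay = TRUE) {
  stopifnot(a >= 0, a_f >= 0, a_s >= 0, a_fs >= 0,
            b > 0, b_f > 0, b_s > 0, b_fs > 0)
  if (kappa < 100 * a)
    stop("kappa must be at least 100 * a for near-incompressibility")
  structure(list(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
                 a_fs = a_fs, b_fs = b_fs, kappa = kappa,
                 macaulay = isTRUE(macaulay)),
            class = "material_params")
}

mat_vector <- function(mat) {
  c(mat$a, mat$b, mat$a_f, mat$b_f, mat$a_s, mat$b_s, mat$a_fs, mat$b_fs,
    mat$kappa)
}

#' kPa per mmHg conversion factor
#' @export
MMHG_TO_KPA <- 0.133322

#' Kinematic growth tensor
#'
#' Fg = (1 + alpha_f) f x f + (1 + alpha_n) (s x s + n x n): a transversely
#' isotropic stretch with eigenvalues (1 + alpha_f) along the fiber and
#' (1 + alpha_n) twice in the sheet plane, so
#' det Fg = (1 + alpha_f)(1 + alpha_n)^2.
#'
#' @param params A [growth_params()].
#' @param triad 3x3 matrix with columns f, s, n (orthonormal).
#' @return 3x3 symmetric growth tensor.
#' @export
growth_tensor <- function(params, triad = diag(3)) {
  stopifnot(inherits(params, "growth_params"), all(dim(triad) == c(3, 3)))
  f <- triad[, 1]; s <- triad[, 2]; n <- triad[, 3]
  (1 + params$alpha_f) * tcrossprod(f) +
    (1 + params$alpha_n) * (tcrossprod(s) + tcrossprod(n))
}

#' Deformation state for the constitutive model
#'
#' Packages a total deformation gradient with a growth configuration: the
#' elastic part Fe = F Fg^-1 carries all stress.
#'
#' @param F Total deformation gradient (3x3, det > 0).
#' @param params A [growth_params()].
#' @param triad 3x3 matrix with columns f, s, n.
#' @return An object of class `deformation_state` with `F`, `Fg`, `Fe`, `Ce`
#'   and the elastic invariants `I1e`, `I4fe`, `I4se`, `I8fse`.
#' @export
deformation_state <- function(F, params = growth_params(), triad = diag(3)) {
  stopifnot(all(dim(F) == c(3, 3)))
  if (det(F) <= 0) stop("det F must be positive")
  Fg <- growth_tensor(params, triad)
  Fe <- F %*% solve(Fg)
  Ce <- t(Fe) %*% Fe
  f <- triad[, 1]; s <- triad[, 2]
  structure(list(F = F, Fg = Fg, Fe = Fe, Ce = Ce,
                 I1e = sum(diag(Ce)),
                 I4fe = drop(t(f) %*% Ce %*% f),
                 I4se = drop(t(s) %*% Ce %*% s),
                 I8fse = drop(t(f) %*% Ce %*% s),
                 params = params, triad = triad),
            class = "deformation_state")
}

#' Strain energy density
#'
#' Holzapfel-Ogden energy evaluated on the elastic invariants of a
#' [deformation_state()], with the isochoric split applied to I1 and the
#' volumetric penalty kappa/2 (ln Je)^2.  At Fe = I the anisotropic and
#' volumetric parts vanish and the isotropic part equals the constant
#' offset a/(2b).
#'
#' @param state A [deformation_state()].
#' @param mat A [material_params()].
#' @return Energy density (kPa), per unit grown volume.
#' @export
strain_energy <- function(state, mat = material_params()) {
  r <- ho_point_cpp(state$F, state$triad, state$params$alpha_f,
                    state$params$alpha_n, mat_vector(mat), mat$macaulay)
  if (!r$ok) stop("non-finite strain energy: element state diverged")
  r$psi
}

#' Second Piola-Kirchhoff stress
#'
#' Analytic derivative of the strain energy with respect to the elastic
#' right Cauchy-Green tensor, pulled back through the growth tensor to the
#' reference configuration: S = 2 d(psi)/dC = Fg^-1 Se Fg^-T.  Symmetric;
#' zero at Fe = I (stress-free reference and stress-free compatible growth).
#'
#' @param state A [deformation_state()].
#' @param mat A [material_params()].
#' @return 3x3 symmetric stress tensor (kPa).
#' @export
pk2_stress <- function(state, mat = material_params()) {
  r <- ho_point_cpp(state$F, state$triad, state$params$alpha_f,
                    state$params$alpha_n, mat_vector(mat), mat$macaulay)
  if (!r$ok) stop("non-finite stress: element state diverged")
  S <- r$S
  (S + t(S)) / 2
}
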