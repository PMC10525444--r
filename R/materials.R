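## Yeoh hyperelastic material law and the model's material table.

#' Yeoh hyperelastic material
#'
#' Isotropic incompressible Yeoh strain-energy function, cubic in the
#' first invariant:
#' \deqn{W = C_1(I_1 - 3) + C_2(I_1 - 3)^2 + C_3(I_1 - 3)^3}
#' The membrane solver enforces incompressibility exactly through the
#' plane-stress thickness stretch (`det F = 1`), so the volumetric
#' penalty parameter `d` is carried for completeness but does not enter
#' the solution.
#'
#' @param C1,C2,C3 Yeoh constants, Pa (`C1 > 0`).
#' @param d incompressibility penalty parameter (inverse stiffness of the
#'   volumetric term); must be > 0.
#' @return object of class `yeoh_material`.
#' @export
yeoh_material <- function(C1, C2 = 0, C3 = 0, d = 1e-5) {
  if (C1 <= 0) stop("C1 must be positive")
  if (d <= 0) stop("d must be positive")
  structure(list(C1 = C1, C2 = C2, C3 = C3, d = d), class = "yeoh_material")
}

#' Material table of the corneal model
#'
#' Yeoh constants (Pa), incompressibility parameter and layer thicknesses
#' (um) for the healthy stroma (anterior/posterior layers), the two
#' keratoconic weakened regions, and the sclera, plus the elastic PMMA
#' constants of the ICRS implant. The keratoconic rows are 70% (region 1)
#' and 30% (region 2) of the healthy stiffness.
#'
#' @return list with data.frame `stroma` (columns `part`, `layer`, `C1`,
#'   `C2`, `C3`, `d`, `thickness_um`) and list `icrs`
#'   (`E_MPa`, `rho_kg_m3`, `nu`).
#' @export
material_table <- function() {
  stroma <- data.frame(
    part = c("healthy", "healthy", "KC region1", "KC region1",
             "KC region2", "KC region2", "sclera"),
    layer = c("anterior", "posterior", "anterior", "posterior",
              "anterior", "posterior", "-"),
    C1 = c(35.5e3, 32.0e3, 24.9e3, 22.4e3, 10.7e3, 9.6e3, 0.8e6),
    C2 = c(3.2e3, 2.9e3, 2.2e3, 2.0e3, 1.0e3, 0.86e3, 56.1e6),
    C3 = c(1.9e3, 1.7e3, 1.3e3, 1.2e3, 0.57e3, 0.51e3, 2332e6),
    d = 1e-5,
    thickness_um = c(385, 165, 270, 116, 193, 83, 1000),
    stringsAsFactors = FALSE)
  list(stroma = stroma, icrs = list(E_MPa = 3300, rho_kg_m3 = 1062, nu = 0.40))
}

#' Healthy stroma merged into one membrane layer
#'
#' The membrane simplification merges the anterior and posterior stromal
#' layers into a single layer with the summed thickness (550 um) and
#' thickness-weighted Yeoh constants.
#'
#' @return list with `material` (a [yeoh_material()]) and `thickness_um`.
#' @export
merged_stroma_material <- function() {
  st <- material_table()$stroma
  h <- st[st$part == "healthy", ]
  w <- h$thickness_um / sum(h$thickness_um)
  list(material = yeoh_material(sum(w * h$C1), sum(w * h$C2), sum(w * h$C3)),
       thickness_um = sum(h$thickness_um))
}

#' Small-strain shear modulus of a Yeoh material
#'
#' @param material a [yeoh_material()].
#' @return `2 * C1`, Pa.
#' @export
initial_shear_modulus <- function(material) 2 * material$C1

## W(I1) and dW/dI1, Pa; I1 must satisfy I1 >= 3 - tol
yeoh_W <- function(I1, material, tol = 1e-9) {
  if (any(I1 < 3 - tol)) stop("non-physical stretch state: I1 < 3")
  x <- pmax(I1 - 3, 0)
  material$C1 * x + material$C2 * x^2 + material$C3 * x^3
}
yeoh_dW <- function(I1, material, tol = 1e-9) {
  if (any(I1 < 3 - tol)) stop("non-physical stretch state: I1 < 3")
  x <- pmax(I1 - 3, 0)
  material$C1 + 2 * material$C2 * x + 3 * material$C3 * x^2
}

#' Yeoh energy density and membrane stress
#'
#' Strain-energy density and in-plane Cauchy stress of an incompressible
#' Yeoh membrane in plane stress, given the first invariant `I1` and the
#' areal stretch `J = lambda1 * lambda2`. Incompressibility sets the
#' thickness stretch to `lambda3 = 1/J`, so
#' `I1 = lambda1^2 + lambda2^2 + 1/J^2`. The reported stress is the mean
#' in-plane Cauchy stress `2 W'(I1) ((lambda1^2 + lambda2^2)/2 -
#' lambda3^2)`; the corresponding membrane stress resultant is this
#' stress times the deformed thickness `t0 * lambda3`.
#'
#' @param I1 first strain invariant (>= 3 up to tolerance).
#' @param areal_stretch areal stretch J (> 0); default 1 + (I1 - 3)/2, the
#'   equibiaxial value to leading order... supply the actual J for
#'   element states.
#' @param material a [yeoh_material()].
#' @return list with `energy` (Pa), `dW` (Pa), `cauchy_stress` (Pa),
#'   `thickness_stretch`.
#' @export
yeoh_energy_and_stress <- function(I1, areal_stretch = NULL, material) {
  if (is.null(areal_stretch)) {
    ## equibiaxial state consistent with I1: lambda1 = lambda2 = lambda,
    ## 2 lambda^2 + lambda^-4 = I1 solved for lambda^2
    l2 <- vapply(I1, function(i1) {
      f <- function(u) 2 * u + u^-2 - i1
      stats::uniroot(f, c(1 - 1e-9, max(2, i1)))$root
    }, numeric(1))
    areal_stretch <- l2
  }
  lam3_sq <- 1 / areal_stretch^2
  W <- yeoh_W(I1, material)
  dW <- yeoh_dW(I1, material)
  sig <- 2 * dW * ((I1 - lam3_sq) / 2 - lam3_sq)
  list(energy = W, dW = dW, cauchy_stress = sig,
       thickness_stretch = sqrt(lam3_sq))
}
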