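#' Second Piola-Kirchhoff stress field of a solution
#'
#' Per-element quadrature-averaged 2nd Piola-Kirchhoff tensors, reported at
#' reference element centroids (no nodal smoothing, so zone peaks are not
#' diluted across material interfaces). The out-of-plane component follows the
#' plane-strain constraint `E33 = 0`, giving `S33 = lambda (E11 + E22)`.
#'
#' @param sol a `fem_solution`.
#' @param mesh the `planar_mesh` the solution was computed on.
#' @param mat the material map used in the solve.
#' @return a `stress_field` data.frame with columns `S11, S22, S12, S33`
#'   (MPa), `area` (mm^2), `x, y` (reference centroid, mm) and `label`.
#' @export
second_pk_stress <- function(sol, mesh, mat) {
  if (nrow(sol$u) != nrow(mesh$nodes))
    stop("solution and mesh sizes differ", call. = FALSE)
  el <- element_lame(mesh, mat)
  st <- tri6_stress_cpp(mesh$nodes, mesh$tri, sol$u, el$lambda, el$mu,
                        sol$small_strain)
  out <- data.frame(S11 = st$S[, 1], S22 = st$S[, 2], S12 = st$S[, 3],
                    S33 = st$S[, 4], area = st$area,
                    x = st$centroid[, 1], y = st$centroid[, 2],
                    label = mesh$label, stringsAsFactors = FALSE)
  class(out) <- c("stress_field", "data.frame")
  out
}

#' Principal stresses of in-plane-plus-out-of-plane tensors
#'
#' Eigenvalues of `[[S11, S12, 0], [S12, S22, 0], [0, 0, S33]]` sorted
#' descending: the in-plane pair comes from the 2x2 closed form, the third is
#' `S33`.
#'
#' @param S11,S22,S12,S33 tensor components (vectorised).
#' @return matrix with columns `s1 >= s2 >= s3` (MPa).
#' @export
principal_stresses <- function(S11, S22, S12, S33 = 0) {
  if (is.data.frame(S11)) {
    df <- S11
    S22 <- df$S22; S12 <- df$S12; S33 <- df$S33; S11 <- df$S11
  }
  c0 <- (S11 + S22) / 2
  r <- sqrt(((S11 - S22) / 2)^2 + S12^2)
  p <- cbind(c0 + r, c0 - r, S33)
  out <- t(apply(p, 1, sort, decreasing = TRUE))
  colnames(out) <- c("s1", "s2", "s3")
  out
}

#' Octahedral shear stress
#'
#' `tau_oct = sqrt((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2) / 3`, the
#' shape-distorting (deviatoric) stress intensity.
#' @param s1,s2,s3 principal stresses, or a 3-column matrix in `s1`.
#' @export
octahedral_shear <- function(s1, s2 = NULL, s3 = NULL) {
  if (is.matrix(s1)) { s2 <- s1[, 2]; s3 <- s1[, 3]; s1 <- s1[, 1] }
  sqrt((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2) / 3
}

#' Hydrostatic (mean) stress
#'
#' `(s1 + s2 + s3) / 3`, using the full 3D trace including the out-of-plane
#' plane-strain component. `plotting = TRUE` returns the sign-flipped value
#' used in compression-dominated figures.
#' @param s1,s2,s3 principal stresses, or a 3-column matrix in `s1`.
#' @param plotting flip sign for display of compressive states.
#' @export
hydrostatic_stress <- function(s1, s2 = NULL, s3 = NULL, plotting = FALSE) {
  if (is.matrix(s1)) { s2 <- s1[, 2]; s3 <- s1[, 3]; s1 <- s1[, 1] }
  h <- (s1 + s2 + s3) / 3
  if (plotting) -h else h
}

#' Scalar stress measures of a stress field
#'
#' Adds the three scalar measures used to read the simulations: hydrostatic
#' stress, lowest principal stress (compressive in the loading regimes
#' considered; reported unclamped) and octahedral shear stress.
#' @param field a `stress_field` from [second_pk_stress()].
#' @return the field with columns `s1, s2, s3, hydrostatic, min_principal,
#'   tau_oct` appended.
#' @export
scalar_measures <- function(field) {
  pr <- principal_stresses(field)
  field$s1 <- pr[, 1]; field$s2 <- pr[, 2]; field$s3 <- pr[, 3]
  field$hydrostatic <- hydrostatic_stress(pr)
  field$min_principal <- pr[, 3]
  field$tau_oct <- octahedral_shear(pr)
  field
}

#' Peak and area-weighted mean of a measure over a zone
#'
#' @param field a `stress_field` with scalar measures (see
#'   [scalar_measures()]).
#' @param zone integer element indices (e.g. [zone_elements()]).
#' @param measures character vector of column names to summarise.
#' @return data.frame with one row per measure: `n`, `peak` (value of largest
#'   magnitude, sign preserved), `mean` (area-weighted).
#' @export
zone_summary <- function(field, zone,
                         measures = c("hydrostatic", "min_principal",
                                      "tau_oct")) {
  if (length(zone) == 0) {
    warning("empty zone: returning empty summary", call. = FALSE)
    return(data.frame(measure = character(0), n = integer(0),
                      peak = numeric(0), mean = numeric(0)))
  }
  w <- field$area[zone]
  do.call(rbind, lapply(measures, function(m) {
    v <- field[[m]][zone]
    data.frame(measure = m, n = length(zone),
               peak = v[which.max(abs(v))],
               mean = sum(w * v) / sum(w), stringsAsFactors = FALSE)
  }))
}

#' Deflection under the load sector
#'
#' Displacement magnitude at the top-arc node nearest the load-sector center,
#' the scalar used to compare the overall stiffness of model variants.
#' @param sol a `fem_solution`.
#' @param mesh the mesh solved on.
#' @param lc the load case (for the sector center angle).
#' @export
deflection <- function(sol, mesh, lc) {
  arcn <- which(!is.na(mesh$node_theta))
  if (length(arcn) == 0) stop("mesh has no top arc", call. = FALSE)
  i <- arcn[which.min(abs(mesh$node_theta[arcn] - lc$sector_center_angle))]
  sqrt(sum(sol$u[i, ]^2))
}

#' Deformed node coordinates
#'
#' `x_def = X + u`, with no magnification of the deformation.
#' @param mesh a `planar_mesh`.
#' @param sol a `fem_solution` on that mesh.
#' @export
deformed_coordinates <- function(mesh, sol) {
  mesh$nodes + sol$u
}
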