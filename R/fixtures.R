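# Synthetic-data generators with embedded ground truth. Every generator is
# deterministic given its seed, and returns objects in the same shapes the
# analysis functions consume, so the whole pipeline is testable without any
# instrument recordings.

#' Generate synthetic Hertzian force-distance curves
#'
#' Curves consist of a zero-force baseline region followed by a Hertzian
#' contact region, with additive i.i.d. Gaussian force noise. Instrument
#' presets mirror the two instruments used on cartilage: AFM colloidal probes
#' (k drawn in 0.06-0.09 N/m, R = 5 um, indentation to 10 percent of R) and a
#' spherical nanoindenter (k = 4.14 N/m, R = 45.5 um, 5 um immersion).
#'
#' @param E_true true modulus (kPa).
#' @param z0 true contact point (um).
#' @param noise_sd force noise SD as a fraction of the maximum force.
#' @param n number of curves.
#' @param instrument `"afm"` or `"nanoindenter"`.
#' @param nu sample Poisson ratio.
#' @param n_samples samples per curve.
#' @param seed integer seed; fully determines the output.
#' @return list of [force_curve()] objects with ground truth in `$meta`.
#' @export
gen_force_curves <- function(E_true, z0 = 0.3, noise_sd = 0.02, n = 1,
                             instrument = c("afm", "nanoindenter"), nu = 0.5,
                             n_samples = 400, seed = 1) {
  instrument <- match.arg(instrument)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (E_true <= 0) stop("E_true must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  R <- if (instrument == "afm") 5 else 45.5
  dmax <- if (instrument == "afm") 0.1 * R else 5
  lapply(seq_len(n), function(i) {
    k <- if (instrument == "afm") stats::runif(1, 0.06, 0.09) else 4.14
    delta <- seq(-dmax, dmax, length.out = n_samples)  # <0: baseline approach
    f <- hertz_force(delta, E_true, nu, R)
    d_um <- if (instrument == "afm") f / k / 1000 else 0
    z <- z0 + delta + d_um  # piezo travel = contact + indentation + deflection
    fn <- f + stats::rnorm(n_samples, 0, noise_sd * max(f))
    force_curve(z = z, force = fn, k = k, R = R, direction = "retract",
                instrument = instrument,
                meta = list(E_true = E_true, z0_true = z0, nu = nu,
                            noise_sd = noise_sd, seed = seed, index = i,
                            delta_true = delta, force_true = f))
  })
}

#' Generate a synthetic load-deformation record
#'
#' Bilinear response: elastic loading at `stiffness_true` up to the yield
#' stress (over the oval top area), then a post-yield branch at 20 percent of
#' the elastic slope, sampled at a 0.1 N/s loading rate with additive Gaussian
#' position noise.
#'
#' @param stiffness_true elastic stiffness (N/mm).
#' @param yield_stress_true yield stress (MPa) over the top oval area.
#' @param dims an [epiphysis_dims()].
#' @param noise_sd position noise SD as a fraction of the full deformation
#'   range.
#' @param load_rate loading rate (N/s).
#' @param sample_dt sampling interval (s).
#' @param max_load final load (N).
#' @param seed integer seed.
#' @return a `load_deformation_record`: list with `time_s`, `position_mm`,
#'   `load_N` and ground-truth metadata in `$meta`.
#' @export
gen_load_deformation <- function(stiffness_true, yield_stress_true, dims,
                                 noise_sd = 0.01, load_rate = 0.1,
                                 sample_dt = 0.1, max_load = NULL, seed = 1) {
  if (stiffness_true <= 0 || yield_stress_true <= 0)
    stop("parameters must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  A <- oval_area(dims$top_d1, dims$top_d2)
  f_yield <- yield_stress_true * A
  if (is.null(max_load)) max_load <- 2 * f_yield
  t <- seq(0, max_load / load_rate, by = sample_dt)
  load <- load_rate * t
  d_yield <- f_yield / stiffness_true
  pos <- ifelse(load <= f_yield, load / stiffness_true,
                d_yield + (load - f_yield) / (0.2 * stiffness_true))
  if (noise_sd > 0)
    pos <- pos + stats::rnorm(length(pos), 0, noise_sd * diff(range(pos)))
  structure(list(time_s = t, position_mm = pos, load_N = load,
                 meta = list(stiffness_true = stiffness_true,
                             yield_stress_true = yield_stress_true,
                             post_yield_frac = 0.2, noise_sd = noise_sd,
                             dims = dims, seed = seed)),
            class = "load_deformation_record")
}

#' Homogeneous block verification fixture
#'
#' Rectangular plane-strain block with vertical rollers at the bottom (one
#' node pinned horizontally), free sides and a uniform dead pressure on the
#' top edge. The analytic record carries the closed-form uniaxial plane-strain
#' state: `u_top = -p h (1 - nu^2) / E`, `S22 = -p`, `S11 = 0`, `S33 = -nu p`.
#'
#' @param width,height block size (mm).
#' @param E,nu material constants (MPa, -).
#' @param p top pressure (MPa).
#' @param target_h mesh target edge length (mm).
#' @return list with `mesh`, `bc`, `lc`, `mat` and `analytic`.
#' @export
gen_block_fixture <- function(width = 10, height = 10, E = 6, nu = 0.47,
                              p = 0.01, target_h = 1) {
  if (nu >= 0.5) stop("nu must be < 0.5", call. = FALSE)
  polys <- block_polygons(width, height)
  mesh <- generate_mesh(polys, target_h)
  bc <- boundary_conditions(mesh, "block")
  lc <- load_case(peak_pressure = p, tag = "top", follower = FALSE,
                  n_steps = 1, profile = function(x, y, th) rep(p, length(x)))
  list(mesh = mesh, bc = bc, lc = lc, mat = list(E = E, nu = nu),
       analytic = list(u_top = -p * height * (1 - nu^2) / E,
                       S22 = -p, S11 = 0, S33 = -nu * p))
}

#' Random plane-strain-compatible stress tensors with oracle records
#'
#' Symmetric tensors with `S13 = S23 = 0`; the principal triple and the three
#' scalar measures stored alongside are computed with the generic dense
#' eigensolver, independent of the closed forms in the stress module.
#'
#' @param n number of tensors.
#' @param scale stress scale (MPa).
#' @param seed integer seed.
#' @return data.frame with components, eigenvalues `o1 >= o2 >= o3` and
#'   oracle measures `o_hyd`, `o_tau`.
#' @export
gen_stress_tensors <- function(n, scale = 1, seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  S <- data.frame(S11 = stats::rnorm(n, 0, scale),
                  S22 = stats::rnorm(n, 0, scale),
                  S12 = stats::rnorm(n, 0, scale),
                  S33 = stats::rnorm(n, 0, scale))
  ev <- t(vapply(seq_len(n), function(i) {
    M <- matrix(c(S$S11[i], S$S12[i], 0,
                  S$S12[i], S$S22[i], 0,
                  0, 0, S$S33[i]), 3, 3)
    sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }, numeric(3)))
  S$o1 <- ev[, 1]; S$o2 <- ev[, 2]; S$o3 <- ev[, 3]
  S$o_hyd <- rowMeans(ev)
  # deviatoric second invariant J2, via the tensor components
  sm <- (S$S11 + S$S22 + S$S33) / 3
  J2 <- ((S$S11 - sm)^2 + (S$S22 - sm)^2 + (S$S33 - sm)^2) / 2 + S$S12^2
  S$o_tau <- sqrt(2 * J2 / 3)
  S
}

# save/restore the RNG state so generators do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
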