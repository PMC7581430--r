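#' Epiphysis dimensions measured by caliper
#'
#' @param height epiphysis height (mm).
#' @param top_d1,top_d2 two diameters of the (oval) top surface (mm).
#' @param side_d1,side_d2 two diameters of the (oval) side surface (mm).
#' @export
epiphysis_dims <- function(height, top_d1, top_d2, side_d1, side_d2) {
  v <- c(height, top_d1, top_d2, side_d1, side_d2)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all dimensions must be positive", call. = FALSE)
  structure(list(height = height, top_d1 = top_d1, top_d2 = top_d2,
                 side_d1 = side_d1, side_d2 = side_d2),
            class = "epiphysis_dims")
}

oval_area <- function(d1, d2) pi * (d1 / 2) * (d2 / 2)

#' Contact-referenced deformation of a load-position record
#'
#' The instrument position at first contact (first sample whose load exceeds
#' `threshold` times the peak load) is subtracted, so deformation counts from
#' the moment the platen meets the bone. No machine-compliance correction is
#' applied.
#'
#' @param rec a `load_deformation_record` (see [read_curve_table()] or
#'   [gen_load_deformation()]): list with `position_mm` and `load_N`.
#' @param threshold contact threshold as a fraction of peak load.
#' @return numeric vector of deformations (mm), zero before contact.
#' @export
deformation_series <- function(rec, threshold = 0.02) {
  ld <- rec$load_N
  pos <- rec$position_mm
  if (max(ld) <= 0)
    stop("no contact: no sample above the contact threshold", call. = FALSE)
  thr <- threshold * max(ld)
  i0 <- which(ld >= thr)[1]
  if (i0 > 1 && ld[i0] > ld[i0 - 1]) {
    # interpolate the position at the threshold crossing (local, bounded)
    frac <- (thr - ld[i0 - 1]) / (ld[i0] - ld[i0 - 1])
    pos0 <- pos[i0 - 1] + frac * (pos[i0] - pos[i0 - 1])
  } else {
    pos0 <- pos[i0]
  }
  pmax(pos - pos0, 0)
}

#' Stiffness as the slope of the initial linear portion
#'
#' The initial linear portion is selected automatically: sliding windows of at
#' least `min_frac` of the samples, confined to the first `range_frac` of the
#' load range, are fitted by least squares and the window maximising R^2 wins
#' (ties go to the earliest window).
#'
#' @param deformation deformation samples (mm).
#' @param load load samples (N).
#' @param min_frac minimum window length as a fraction of the samples.
#' @param range_frac fraction of the load range the window may cover.
#' @return list with `stiffness` (N/mm), `window` (index range), `r2`.
#' @export
stiffness_fit <- function(deformation, load, min_frac = 0.2,
                          range_frac = 0.5) {
  n <- length(load)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  if (diff(range(load)) <= 0) stop("degenerate record: constant load",
                                   call. = FALSE)
  imax <- max(which(load <= min(load) + range_frac * diff(range(load))))
  wmin <- max(5L, ceiling(min_frac * n))
  if (imax < wmin) imax <- min(n, wmin)
  # candidate windows of several lengths; R-squared rewards long clean
  # (single-regime) windows, so the longest window inside the initial linear
  # portion wins; ties break toward longer, then earlier windows
  lens <- sort(unique(pmax(wmin, round(imax * c(1, 0.75, 0.55, 0.4, 0.28,
                                                0.2)))), decreasing = TRUE)
  lens <- lens[lens <= imax]
  best <- NULL
  for (L in lens) {
    step <- max(1L, L %/% 8L)
    for (s in seq(1L, imax - L + 1L, by = step)) {
      i <- s:(s + L - 1L)
      x <- deformation[i]; y <- load[i]
      if (diff(range(x)) <= 0 || diff(range(y)) <= 0) next
      # regress the measured (noisy) deformation on the programmed load and
      # invert the slope: load is the machine's error-free control variable,
      # so this direction avoids regression-dilution of the stiffness
      f <- stats::lm.fit(cbind(1, y), x)
      b <- unname(f$coefficients[2])
      if (!is.finite(b) || b <= 0) next
      r2 <- stats::cor(x, y)^2
      if (is.null(best) || r2 > best$r2 + 1e-10) {
        best <- list(stiffness = 1 / b, window = c(s, s + L - 1L), r2 = r2)
      }
    }
  }
  if (is.null(best) || !is.finite(best$stiffness))
    stop("degenerate record: stiffness fit failed", call. = FALSE)
  best
}

#' Convert a load-deformation record to stress and strain
#'
#' Stress distributes the load over the oval loaded surface
#' (`pi * d1/2 * d2/2`; top diameters for vertical loading, side diameters for
#' angled loading); strain distributes the deformation along the epiphysis
#' height.
#'
#' @param rec record with `position_mm` and `load_N`.
#' @param dims an [epiphysis_dims()].
#' @param orientation `"vertical"` or `"angled"`.
#' @param threshold contact threshold passed to [deformation_series()].
#' @return a `stress_strain_curve` data.frame with `strain` and `stress_MPa`.
#' @export
to_stress_strain <- function(rec, dims, orientation = c("vertical", "angled"),
                             threshold = 0.02) {
  orientation <- match.arg(orientation)
  A <- if (orientation == "vertical") oval_area(dims$top_d1, dims$top_d2)
       else oval_area(dims$side_d1, dims$side_d2)
  if (A <= 0) stop("zero loaded area", call. = FALSE)
  def <- deformation_series(rec, threshold)
  out <- data.frame(strain = def / dims$height, stress_MPa = rec$load_N / A)
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

#' 0.2 percent offset yield strength
#'
#' Intersects the offset line `sigma = E0 (eps - offset)`, with `E0` the
#' initial modulus from [stiffness_fit()] applied to the stress-strain curve,
#' with the measured curve; the first crossing (located by linear
#' interpolation between bracketing samples) is the offset yield strength.
#'
#' @param curve a `stress_strain_curve` (columns `strain`, `stress_MPa`).
#' @param offset strain offset (default 0.002, i.e. 0.2 percent).
#' @return list with `yield_MPa`, `yield_strain`, `modulus_MPa`.
#' @export
offset_yield <- function(curve, offset = 0.002) {
  eps <- curve$strain; sig <- curve$stress_MPa
  n <- length(eps)
  fit <- stiffness_fit(eps, sig)
  E0 <- fit$stiffness
  g <- sig - E0 * (eps - offset)  # >0 while the curve is above the line
  # measured strain carries noise comparable to the 0.2 percent offset, so
  # the crossing is located on a lightly smoothed curve and must persist
  w <- max(1L, round(0.01 * n))
  gs <- if (n > 2 * w + 1) as.numeric(stats::filter(g, rep(1, 2 * w + 1) /
                                                    (2 * w + 1))) else g
  gs[is.na(gs)] <- g[is.na(gs)]
  khold <- max(3L, round(0.02 * n))
  cross <- which(gs[-1] <= 0 & gs[-n] > 0)
  cross <- cross[eps[cross + 1] > offset]
  cross <- cross[vapply(cross, function(i) {
    mean(g[(i + 1):min(i + khold, n)]) < 0
  }, logical(1))]
  if (length(cross) == 0)
    stop("no yield: offset line does not intersect the curve", call. = FALSE)
  i <- cross[1]
  t <- gs[i] / (gs[i] - gs[i + 1])
  list(yield_MPa = sig[i] + t * (sig[i + 1] - sig[i]),
       yield_strain = eps[i] + t * (eps[i + 1] - eps[i]),
       modulus_MPa = E0)
}

#' Summary of one mechanical-test record
#'
#' @param rec record with `position_mm`, `load_N`.
#' @param dims an [epiphysis_dims()].
#' @param orientation `"vertical"` or `"angled"`.
#' @return a one-row data.frame: stiffness (N/mm) with window and R^2, and
#'   0.2 percent offset yield strength (MPa, `NA` if the specimen did not
#'   yield within the record).
#' @export
mech_summary <- function(rec, dims, orientation = "vertical") {
  def <- deformation_series(rec)
  sf <- stiffness_fit(def, rec$load_N)
  ss <- to_stress_strain(rec, dims, orientation)
  y <- tryCatch(offset_yield(ss), error = function(e) NULL)
  data.frame(stiffness_N_mm = sf$stiffness, fit_start = sf$window[1],
             fit_end = sf$window[2], fit_r2 = sf$r2,
             yield_MPa = if (is.null(y)) NA_real_ else y$yield_MPa,
             yield_strain = if (is.null(y)) NA_real_ else y$yield_strain)
}

#' Load producing a target pressure on the oval top surface
#'
#' Inverts pressure = load / oval area; used to pressure-match loads across
#' ages (e.g. 0.023 MPa corresponds to 0.2 N on a 8.70 mm^2 top surface).
#'
#' @param target_pressure MPa.
#' @param dims an [epiphysis_dims()].
#' @export
load_for_pressure <- function(target_pressure, dims) {
  if (target_pressure < 0) stop("pressure must be >= 0", call. = FALSE)
  target_pressure * oval_area(dims$top_d1, dims$top_d2)
}

#' Fold-increase in tolerable load conferred by the ossification center
#'
#' Ratio of the load at which hypertrophic chondrocytes start dying with a
#' developed ossification center to the load at which they die without one
#' (defaults 5 N vs 0.2 N: twenty-five-fold protection).
#' @param load_with_soc,load_without_soc loads in N.
#' @export
soc_protection_fold <- function(load_with_soc = 5, load_without_soc = 0.2) {
  if (load_without_soc <= 0) stop("loads must be positive", call. = FALSE)
  load_with_soc / load_without_soc
}
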