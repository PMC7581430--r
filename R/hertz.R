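#' Hertzian force of a sphere indenting an elastic half-space
#'
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` for positive indentation,
#' zero otherwise. With `delta` and `R` in micrometers and `E` in kPa the
#' force comes out in nanonewtons.
#'
#' @param delta indentation depth (um), vectorised.
#' @param E elastic modulus (kPa).
#' @param nu Poisson ratio of the sample (0.5 = incompressible).
#' @param R probe radius (um).
#' @return force (nN).
#' @export
hertz_force <- function(delta, E, nu = 0.5, R) {
  if (R <= 0 || E <= 0) stop("E and R must be positive", call. = FALSE)
  if (nu < 0 || nu > 0.5) stop("nu must be in [0, 0.5]", call. = FALSE)
  ifelse(delta > 0,
         (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5,
         0)
}

#' Construct a force-distance curve object
#'
#' @param z piezo displacement (um), monotone within a direction.
#' @param force force (nN); give either `force` or `deflection`.
#' @param deflection cantilever deflection (nm); converted via `F = k d`.
#' @param k cantilever spring constant (N/m).
#' @param R probe radius (um).
#' @param direction `"approach"` or `"retract"`.
#' @param instrument `"afm"` (deflection subtracted from indentation) or
#'   `"nanoindenter"` (instrument reports probe indentation directly).
#' @param meta optional list of metadata (e.g. generator ground truth).
#' @export
force_curve <- function(z, force = NULL, deflection = NULL, k, R,
                        direction = c("retract", "approach"),
                        instrument = c("afm", "nanoindenter"), meta = list()) {
  direction <- match.arg(direction)
  instrument <- match.arg(instrument)
  if (is.null(force) == is.null(deflection))
    stop("give exactly one of force or deflection", call. = FALSE)
  if (k <= 0 || R <= 0) stop("k and R must be positive", call. = FALSE)
  if (is.null(force)) force <- k * deflection  # N/m * nm = nN
  structure(list(z_um = z, force_nN = force, k_N_per_m = k, R_um = R,
                 direction = direction, instrument = instrument, meta = meta),
            class = "force_curve")
}

#' Indentation curve from a force-distance curve
#'
#' For AFM curves the cantilever deflection (`d = F / k`) is subtracted from
#' the piezo travel beyond the contact point: `delta = (z - z0) - d` (with
#' deflection converted to um); nanoindenter curves report probe indentation,
#' so `delta = z - z0`.
#'
#' @param curve a [force_curve()].
#' @param z0 contact point (um).
#' @return data.frame with `delta_um` and `force_nN`.
#' @export
to_indentation <- function(curve, z0) {
  d_um <- if (curve$instrument == "afm")
    (curve$force_nN / curve$k_N_per_m) / 1000 else 0
  data.frame(delta_um = (curve$z_um - z0) - d_um,
             force_nN = curve$force_nN)
}

#' Fit the Hertz model to a force-distance curve
#'
#' The contact point `z0` and modulus `E` are fitted jointly: for a candidate
#' `z0` the modulus has a closed-form least-squares value (the model is linear
#' in `E`), and the profiled residual is minimised over `z0` by golden-section
#' search. Only non-negative forces are fitted (adhesion wells in retract
#' curves are excluded) and the indentation is capped at `max_indentation`.
#' An optional constant force baseline can be co-estimated.
#'
#' @param curve a [force_curve()].
#' @param nu assumed Poisson ratio of the sample.
#' @param max_indentation fit cap (um); default 10 percent of the probe
#'   radius for AFM, 5 um for the nanoindenter.
#' @param baseline co-estimate a constant force offset.
#' @return a `hertz_fit`: list with `E_kPa`, `z0_um`, `baseline_nN`,
#'   `rms_nN`, `nu`, `valid` plus a `flags` character vector.
#' @export
fit_hertz <- function(curve, nu = 0.5, max_indentation = NULL,
                      baseline = FALSE) {
  if (length(curve$z_um) < 50)
    stop("need at least 50 samples spanning baseline and contact",
         call. = FALSE)
  if (is.null(max_indentation))
    max_indentation <- if (curve$instrument == "afm") 0.1 * curve$R_um else 5
  pref <- (4 / 3) / (1 - nu^2) * sqrt(curve$R_um)

  sse_at <- function(z0) {
    ind <- to_indentation(curve, z0)
    use <- ind$force_nN >= 0 & ind$delta_um <= max_indentation
    d <- pmax(ind$delta_um[use], 0)^1.5
    f <- ind$force_nN[use]
    npos <- sum(d > 0 & f > 0)
    if (npos < 5)  # candidate excludes the contact region entirely
      return(list(sse = 1e30, E = NA_real_, b = 0, n = sum(use)))
    if (baseline) {
      X <- cbind(d, 1)
      fit <- stats::lm.fit(X, f)
      co <- fit$coefficients
      list(sse = sum(fit$residuals^2), E = co[1] / pref, b = co[2],
           n = sum(use))
    } else {
      E <- if (sum(d^2) > 0) sum(d * f) / sum(d^2) else 0
      list(sse = sum((f - E * d)^2), E = E / pref, b = 0, n = sum(use))
    }
  }

  # bracket the contact point by the force transition so the search cannot
  # drift into regimes where the whole contact branch is excluded
  ord <- order(curve$z_um)
  zs <- curve$z_um[ord]; fs <- curve$force_nN[ord]
  fmax <- max(fs)
  span <- diff(range(zs))
  i_hi <- which(fs >= 0.25 * fmax)[1]
  z_hi <- if (is.na(i_hi)) max(zs) else zs[i_hi]
  low <- which(fs <= 0.02 * fmax & zs < z_hi)
  z_lo <- if (length(low) > 0) zs[max(low)] else min(zs)
  zr <- c(max(min(zs), z_lo - 0.1 * span), z_hi)
  opt <- stats::optimize(function(z0) sse_at(z0)$sse,
                         interval = zr, tol = 1e-7 * diff(zr))
  best <- sse_at(opt$minimum)
  flags <- character(0)
  if (!is.finite(best$E) || best$E <= 0) flags <- c(flags, "nonpositive_E")
  # modulus at the identifiability bound: contact point pushed to the data
  # edge, or E beyond any soft-tissue plausibility given the fit cap
  if (opt$minimum <= zr[1] + 1e-6 * diff(zr) ||
      opt$minimum >= zr[2] - 1e-6 * diff(zr))
    flags <- c(flags, "z0_at_bound")
  if (is.finite(best$E) && best$E > 1e6) flags <- c(flags, "E_at_bound")
  if (best$n < 10) flags <- c(flags, "too_few_contact_samples")
  structure(list(E_kPa = unname(best$E), z0_um = opt$minimum,
                 baseline_nN = unname(best$b),
                 rms_nN = sqrt(best$sse / max(best$n, 1)), nu = nu,
                 valid = length(flags) == 0, flags = flags),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("hertz_fit: E = %.4g kPa (nu = %g), z0 = %.4g um, rms %.3g nN%s\n",
              x$E_kPa, x$nu, x$z0_um, x$rms_nN,
              if (x$valid) "" else paste0(" [", paste(x$flags,
                                                      collapse = ","), "]")))
  invisible(x)
}

#' Aggregate Hertz fits
#'
#' `scheme = "mean_sd"` pools all valid fits; `scheme = "median_per_unit"`
#' takes the median within each unit (cell, animal) first -- the estimator
#' used for skewed indentation maps -- and then mean and SD across units.
#'
#' @param fits list of `hertz_fit` objects (or numeric moduli).
#' @param scheme aggregation scheme.
#' @param unit factor of the same length as `fits` for `median_per_unit`.
#' @return data.frame with `mean`, `sd`, `n` (and per-unit medians as an
#'   attribute for the per-unit scheme).
#' @export
aggregate_fits <- function(fits, scheme = c("mean_sd", "median_per_unit"),
                           unit = NULL) {
  scheme <- match.arg(scheme)
  E <- if (is.numeric(fits)) fits
       else vapply(fits, function(f) if (isTRUE(f$valid)) f$E_kPa else
                   NA_real_, numeric(1))
  keep <- is.finite(E)
  if (!any(keep)) stop("no valid fits to aggregate", call. = FALSE)
  if (scheme == "mean_sd") {
    data.frame(mean = mean(E[keep]), sd = stats::sd(E[keep]), n = sum(keep))
  } else {
    if (is.null(unit)) stop("median_per_unit needs a unit vector",
                            call. = FALSE)
    med <- tapply(E[keep], droplevels(factor(unit)[keep]), stats::median)
    out <- data.frame(mean = mean(med), sd = stats::sd(med), n = length(med))
    attr(out, "per_unit_median") <- med
    out
  }
}
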