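#' Lamé constants from engineering constants
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio, `0 <= nu < 0.5`.
#' @return named vector with `lambda` and `mu` (MPa).
#' @export
lame_parameters <- function(E, nu) {
  if (any(E <= 0)) stop("E must be > 0", call. = FALSE)
  if (any(nu < 0) || any(nu >= 0.5))
    stop("nu must satisfy 0 <= nu < 0.5 (incompressible limit excluded)",
         call. = FALSE)
  c(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Per-subdomain elastic materials
#'
#' Builds the material map of the epiphysis model. Cartilage and the stiff
#' insert follow the study constants (cartilage E = 6 MPa, nu = 0.47; dense
#' cancellous bone E = 500 MPa, nu = 0.20, i.e. about eighty-fold stiffer).
#' Cortical and metaphyseal bone values are reconstructions in the spirit of
#' the source model (they sit far from the growth plate and barely influence
#' the band stresses); both are configurable. For the `no_soc` variant the
#' insert subdomain keeps its polygons but is assigned the cartilage material,
#' so with/without comparisons run on the identical mesh.
#'
#' @param variant one of [variant_ids()]; `no_soc` maps the insert to
#'   cartilage.
#' @param cartilage,insert,cortical,metaphyseal lists with elements `E` (MPa)
#'   and `nu`.
#' @return a `material_map`: named list of `(E, nu, lambda, mu)` per label.
#' @export
material_map <- function(variant = "with_soc",
                         cartilage = list(E = 6, nu = 0.47),
                         insert = list(E = 500, nu = 0.20),
                         cortical = list(E = 5000, nu = 0.30),
                         metaphyseal = list(E = 500, nu = 0.20)) {
  if (identical(variant, "no_soc")) insert <- cartilage
  mk <- function(m) {
    lp <- lame_parameters(m$E, m$nu)
    list(E = m$E, nu = m$nu, lambda = unname(lp["lambda"]),
         mu = unname(lp["mu"]))
  }
  structure(list(epiphyseal_cartilage = mk(cartilage),
                 stiff_insert = mk(insert),
                 growth_plate_band = mk(cartilage),
                 cortical_bone = mk(cortical),
                 metaphyseal_bone = mk(metaphyseal)),
            class = "material_map", variant = variant)
}

# per-element Lame vectors for any mesh/material combination
element_lame <- function(mesh, mat) {
  if (inherits(mat, "material_map") || (is.list(mat) && is.null(mat$E))) {
    miss <- setdiff(unique(mesh$label), names(mat))
    if (length(miss) > 0)
      stop("no material for label(s): ", paste(miss, collapse = ", "))
    lam <- vapply(mat, `[[`, numeric(1), "lambda")[mesh$label]
    mu <- vapply(mat, `[[`, numeric(1), "mu")[mesh$label]
  } else {
    lp <- lame_parameters(mat$E, mat$nu)
    lam <- rep(unname(lp["lambda"]), nrow(mesh$tri))
    mu <- rep(unname(lp["mu"]), nrow(mesh$tri))
  }
  list(lambda = unname(lam), mu = unname(mu))
}

#' Quadratic sector pressure profile on the top arc
#'
#' Pressure is maximal at the sector center and falls quadratically and
#' symmetrically to zero at the sector borders:
#' `p(theta) = peak * max(0, 1 - ((theta - center)/half_width)^2)`.
#'
#' @param theta polar angle(s) on the top arc, degrees (90 is the apex).
#' @param lc a [load_case()].
#' @return pressure in MPa (zero outside the loaded sector).
#' @export
sector_pressure <- function(theta, lc) {
  lc$peak_pressure * pmax(0, 1 - ((theta - lc$sector_center_angle) /
                                  lc$sector_half_width)^2)
}

#' Define a sector pressure load case
#'
#' @param sector_center_angle center of the loaded sector in degrees on the
#'   top arc (90 = vertical apex load, 45 = angled load from the right).
#' @param peak_pressure peak pressure in MPa (0.3 physiological, 3
#'   supra-physiological).
#' @param sector_half_width half-width of the pressure support in degrees.
#'   The default 22.5 reads the load as one 45-degree sector with zeros at its
#'   own borders; `wide_support = TRUE` switches to the alternative reading
#'   (zeros at the borders of the two neighbouring sectors, half-width 67.5).
#' @param follower if `TRUE` (default) the pressure acts on the deformed
#'   surface; otherwise it is a dead load on the reference configuration.
#' @param n_steps number of equal load increments for the Newton continuation.
#'   `NULL` picks 1 for peak pressures up to 0.5 MPa and 10 beyond.
#' @param wide_support use the 135-degree support interpretation.
#' @param tag boundary tag carrying the load.
#' @param profile optional function `(x, y, theta) -> MPa` overriding the
#'   sector profile (used for uniform loads on block fixtures).
#' @export
load_case <- function(sector_center_angle = 90, peak_pressure = 0.3,
                      sector_half_width = if (wide_support) 67.5 else 22.5,
                      follower = TRUE, n_steps = NULL, wide_support = FALSE,
                      tag = "top_arc", profile = NULL) {
  if (peak_pressure < 0) stop("peak_pressure must be >= 0", call. = FALSE)
  if (sector_half_width <= 0 || sector_half_width > 90)
    stop("sector_half_width must be in (0, 90]", call. = FALSE)
  if (is.null(n_steps)) n_steps <- if (peak_pressure <= 0.5) 1L else 10L
  structure(list(sector_center_angle = sector_center_angle,
                 peak_pressure = peak_pressure,
                 sector_half_width = sector_half_width, follower = follower,
                 n_steps = as.integer(n_steps), tag = tag, profile = profile),
            class = "load_case")
}

#' Fixed-displacement boundary conditions
#'
#' For the epiphysis model (`kind = "epiphysis"`): zero vertical displacement
#' on the bottom edge and zero horizontal displacement on the outer cortical
#' edges. For block fixtures (`kind = "block"`): vertical rollers on the
#' bottom edge with the node nearest the bottom-left corner pinned
#' horizontally.
#'
#' @param mesh a `planar_mesh`.
#' @param kind `"epiphysis"` or `"block"`.
#' @return a `boundary_conditions` object: integer dof indices (x dof of node
#'   i is `2i-1`, y dof `2i`) and prescribed values (all zero here).
#' @export
boundary_conditions <- function(mesh, kind = c("epiphysis", "block")) {
  kind <- match.arg(kind)
  be <- mesh$boundary_edges
  nds <- function(tags) unique(unlist(be[be$tag %in% tags,
                                         c("n1", "n2", "mid")]))
  bottom <- nds("bottom")
  if (kind == "epiphysis") {
    sides <- nds(c("cortical_outer_left", "cortical_outer_right"))
    dofs <- c(2 * bottom, 2 * sides - 1)
  } else {
    pin <- bottom[which.min(mesh$nodes[bottom, 1])]
    dofs <- c(2 * bottom, 2 * pin - 1)
  }
  new_bc(dofs, 0)
}

#' Construct boundary conditions from raw dof indices
#' @param dofs integer dof indices (x dof of node i is `2i-1`, y dof `2i`).
#' @param values prescribed values, recycled to `length(dofs)`.
#' @export
new_bc <- function(dofs, values = 0) {
  dofs <- as.integer(dofs)
  structure(list(dofs = dofs, values = rep_len(values, length(dofs))),
            class = "boundary_conditions")
}

# nodal pressures on the loaded boundary edges
edge_pressures <- function(mesh, lc) {
  be <- mesh$boundary_edges
  le <- be[be$tag == lc$tag, , drop = FALSE]
  if (nrow(le) == 0) stop("no boundary edges carry tag ", lc$tag)
  em <- as.matrix(le[, c("n1", "n2", "mid")])
  if (is.null(lc$profile)) {
    th <- mesh$node_theta
    pv <- matrix(sector_pressure(th[em], lc), nrow(em), 3)
  } else {
    pv <- matrix(lc$profile(mesh$nodes[em, 1], mesh$nodes[em, 2],
                            mesh$node_theta[em]), nrow(em), 3)
  }
  list(edges = em, p = pv)
}

#' Solve plane-strain elastostatics on a labeled mesh
#'
#' Total-Lagrangian Newton solution of the Saint Venant-Kirchhoff plane-strain
#' problem with incremental loading: the Green-Lagrange strain
#' `E = (F'F - I)/2` enters a stress `S = lambda tr(E) I + 2 mu E` (linear
#' elastic constants, non-linear strains), and the sector pressure acts as a
#' follower load on the deformed surface unless the load case says otherwise.
#' Failed load steps are bisected up to `max_halvings` times.
#'
#' @param mesh a `planar_mesh` from [generate_mesh()].
#' @param mat a `material_map` or a single `list(E, nu)`.
#' @param bc a `boundary_conditions` object.
#' @param lc a [load_case()].
#' @param small_strain use the linearised kinematics (single linear solve per
#'   load level); used for verification against closed-form solutions.
#' @param tol relative residual tolerance of the Newton iteration.
#' @param max_iter maximum Newton iterations per load step.
#' @param max_halvings maximum number of automatic step bisections.
#' @return a `fem_solution`: displacement matrix `u` (n x 2, mm), convergence
#'   log, and the inputs needed by the post-processors.
#' @export
solve_elasticity <- function(mesh, mat, bc, lc, small_strain = FALSE,
                             tol = 1e-8, max_iter = 80, max_halvings = 6) {
  el <- element_lame(mesh, mat)
  ep <- edge_pressures(mesh, lc)
  nn <- nrow(mesh$nodes)
  nd <- 2L * nn
  fixed <- unique(bc$dofs)
  free <- setdiff(seq_len(nd), fixed)
  isfree <- rep(FALSE, nd); isfree[free] <- TRUE
  fmap <- integer(nd); fmap[free] <- seq_along(free)
  bcval <- numeric(nd); bcval[bc$dofs] <- bc$values

  u <- matrix(0, nn, 2)
  log <- list()
  chol_fac <- NULL

  solve_K <- function(sys, r_free) {
    keep <- isfree[sys$i] & isfree[sys$j]
    K <- Matrix::sparseMatrix(i = fmap[sys$i[keep]], j = fmap[sys$j[keep]],
                              x = sys$v[keep],
                              dims = c(length(free), length(free)))
    K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
    fac <- tryCatch({
      if (is.null(chol_fac)) Matrix::Cholesky(K, LDL = FALSE, super = TRUE)
      else stats::update(chol_fac, K)
    }, error = function(e) NULL)
    if (!is.null(fac)) {
      chol_fac <<- fac
      as.numeric(Matrix::solve(fac, r_free))
    } else {
      as.numeric(Matrix::solve(K, r_free))
    }
  }

  resid_at <- function(u, gamma) {
    sys <- fem_tri6_system_cpp(mesh$nodes, mesh$tri, u, el$lambda, el$mu,
                               small_strain)
    fext <- fem_edge_pressure_cpp(mesh$nodes, ep$edges, gamma * ep$p, u,
                                  lc$follower)
    r <- fext - sys$fint
    # the reference includes reaction forces (fixed dofs) so pure-Dirichlet
    # problems keep a finite convergence scale
    list(sys = sys, r = r,
         rn = sqrt(sum(r[free]^2)),
         ref = max(sqrt(sum(fext^2)), sqrt(sum(sys$fint^2))))
  }

  newton_at <- function(u, gamma) {
    u[cbind((fixed + 1L) %/% 2L, 2L - (fixed %% 2L))] <- gamma * bcval[fixed]
    st <- resid_at(u, gamma)
    for (it in seq_len(max_iter)) {
      if (st$sys$min_detF <= 0)
        return(list(ok = FALSE, u = u, iters = it, res = Inf,
                    why = "inverted element"))
      if (st$rn <= tol * max(st$ref, 1e-14))
        return(list(ok = TRUE, u = u, iters = it, res = st$rn))
      du <- solve_K(st$sys, st$r[free])
      if (any(!is.finite(du)))
        return(list(ok = FALSE, u = u, iters = it, res = st$rn,
                    why = "singular system"))
      du_full <- numeric(nd)
      du_full[free] <- du
      step <- cbind(du_full[seq(1, nd, 2)], du_full[seq(2, nd, 2)])
      # backtracking line search on the residual norm; full Newton steps are
      # taken whenever they reduce the residual (quadratic convergence), and
      # damped steps carry the iteration through locally indefinite regions
      accepted <- FALSE
      for (s in c(1, 0.5, 0.25, 0.1, 0.05)) {
        ut <- u + s * step
        stt <- resid_at(ut, gamma)
        if (is.finite(stt$rn) && stt$rn < st$rn && stt$sys$min_detF > 0) {
          u <- ut; st <- stt; accepted <- TRUE
          break
        }
      }
      if (!accepted)
        return(list(ok = FALSE, u = u, iters = it, res = st$rn,
                    why = "line search stalled"))
    }
    list(ok = FALSE, u = u, iters = max_iter, res = st$rn,
         why = "max iterations")
  }

  gamma <- 0
  dg <- 1 / lc$n_steps
  halvings <- 0
  u_ok <- u
  u_prev <- NULL; g_prev <- NA_real_
  while (gamma < 1 - 1e-12) {
    g_try <- min(1, gamma + dg)
    # secant predictor from the two previous converged states
    u0 <- u_ok
    if (!is.null(u_prev) && gamma > g_prev)
      u0 <- u_ok + (u_ok - u_prev) * ((g_try - gamma) / (gamma - g_prev))
    st <- newton_at(u0, g_try)
    if (!st$ok && !identical(u0, u_ok)) st <- newton_at(u_ok, g_try)
    if (st$ok) {
      u_prev <- u_ok; g_prev <- gamma
      u_ok <- st$u
      gamma <- g_try
      log[[length(log) + 1L]] <- data.frame(load_fraction = gamma,
                                            iterations = st$iters,
                                            residual = st$res)
    } else {
      halvings <- halvings + 1
      if (halvings > max_halvings)
        stop(sprintf(paste0("Newton iteration failed (%s) at load fraction ",
                            "%.4g; last converged fraction %.4g"),
                     st$why, g_try, gamma), call. = FALSE)
      dg <- dg / 2
    }
  }

  structure(list(u = u_ok, converged = TRUE,
                 log = do.call(rbind, log), small_strain = small_strain,
                 lc = lc, tol = tol),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf(paste0("fem_solution: %d nodes, %s kinematics, %d load",
                     " step(s), max |u| = %.4g mm\n"),
              nrow(x$u), if (x$small_strain) "small-strain" else
                "finite-strain", nrow(x$log),
              max(sqrt(rowSums(x$u^2)))))
  invisible(x)
}
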