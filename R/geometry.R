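#' Parameters of the idealised epiphysis domain
#'
#' Builds the parameter set for the parametric 2D epiphysis: a semicircular
#' cartilaginous head of radius `top_radius` sitting on a trapezoidal shaft of
#' total height `total_height` and bottom width `bottom_width`, with cortical
#' walls of horizontal width `cortical_width`, a horizontal growth-plate band,
#' and a candidate stiff region (semi-elliptical secondary ossification
#' center, or ossified protrusion fingers). All lengths are in mm; the
#' out-of-plane thickness is 1 mm by definition.
#'
#' @param total_height total domain height (mm).
#' @param top_radius radius of the semicircular top (mm).
#' @param bottom_width width of the bottom edge (mm).
#' @param cortical_width horizontal width of the cortical walls (mm).
#' @param thickness out-of-plane thickness (mm).
#' @param gp_band_y vertical position of the growth-plate band center (mm).
#' @param gp_band_height height of the growth-plate band (mm).
#' @param soc_center_y vertical center of the semi-elliptical ossification
#'   center insert (mm); its horizontal center is on the symmetry axis.
#' @param soc_rx,soc_ry semi-axes of the insert ellipse (mm).
#' @param prot_count number of protrusion fingers (placed symmetrically).
#' @param prot_width,prot_spacing finger width and center-to-center spacing
#'   (mm).
#' @param prot_depth_small,prot_depth_extended finger penetration depth into
#'   the cartilage for the two protrusion variants (mm).
#' @param prot_gap cartilage layer between the growth-plate band top and the
#'   base of any stiff element (mm); keeps the hypertrophic band free of bony
#'   elements.
#' @param curve_chord target chord length used to sample curved boundaries
#'   (mm).
#' @return an object of class `epiphysis_params`.
#' @export
epiphysis_params <- function(total_height = 66, top_radius = 17,
                             bottom_width = 25, cortical_width = 2.5,
                             thickness = 1, gp_band_y = 42,
                             gp_band_height = 3, soc_center_y = 53,
                             soc_rx = 12, soc_ry = 8, prot_count = 5,
                             prot_width = 2, prot_spacing = 5,
                             prot_depth_small = 4, prot_depth_extended = 10,
                             prot_gap = 1.5, curve_chord = 1) {
  p <- list(total_height = total_height, top_radius = top_radius,
            bottom_width = bottom_width, cortical_width = cortical_width,
            thickness = thickness, gp_band_y = gp_band_y,
            gp_band_height = gp_band_height, soc_center_y = soc_center_y,
            soc_rx = soc_rx, soc_ry = soc_ry, prot_count = prot_count,
            prot_width = prot_width, prot_spacing = prot_spacing,
            prot_depth_small = prot_depth_small,
            prot_depth_extended = prot_depth_extended, prot_gap = prot_gap,
            curve_chord = curve_chord)
  lens <- unlist(p[c("total_height", "top_radius", "bottom_width",
                     "cortical_width", "thickness", "gp_band_height",
                     "soc_rx", "soc_ry", "prot_width", "prot_spacing",
                     "curve_chord")])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths must be strictly positive", call. = FALSE)
  if (top_radius > bottom_width)
    stop("top_radius must not exceed bottom_width", call. = FALSE)
  band_top <- gp_band_y + gp_band_height / 2
  if (soc_center_y - soc_ry < band_top)
    stop("growth-plate band must lie below the stiff insert", call. = FALSE)
  shaft_h <- total_height - top_radius
  if (gp_band_y - gp_band_height / 2 <= 0 || band_top >= shaft_h)
    stop("growth-plate band must lie inside the shaft", call. = FALSE)
  # insert strictly inside the cartilage region: every sampled ellipse point
  # must lie within the head arc and, below the arc center, inside the
  # cortical inner walls
  phi <- seq(-pi / 2, pi / 2, length.out = 181)
  ex <- soc_rx * cos(phi); ey <- soc_center_y + soc_ry * sin(phi)
  xin <- function(y) (bottom_width / 2 - cortical_width) +
    (top_radius - bottom_width / 2) * y / shaft_h
  inside <- ifelse(ey >= shaft_h,
                   sqrt(ex^2 + (ey - shaft_h)^2) < top_radius,
                   ex < xin(ey) & ey > band_top)
  if (!all(inside))
    stop("ossification-center insert must lie strictly inside the cartilage",
         call. = FALSE)
  class(p) <- "epiphysis_params"
  p
}

#' @export
print.epiphysis_params <- function(x, ...) {
  cat("Epiphysis domain parameters (mm):\n")
  cat(sprintf("  outer: height %g, top radius %g, bottom width %g, cortical %g\n",
              x$total_height, x$top_radius, x$bottom_width, x$cortical_width))
  cat(sprintf("  growth-plate band: center y %g, height %g\n",
              x$gp_band_y, x$gp_band_height))
  cat(sprintf("  SOC insert: center (0, %g), semi-axes %g x %g\n",
              x$soc_center_y, x$soc_rx, x$soc_ry))
  cat(sprintf("  protrusions: %d fingers, width %g, spacing %g, depth %g/%g\n",
              x$prot_count, x$prot_width, x$prot_spacing,
              x$prot_depth_small, x$prot_depth_extended))
  invisible(x)
}

#' Subdomain labels of the epiphysis model
#' @export
subdomain_labels <- function() {
  c("epiphyseal_cartilage", "stiff_insert", "growth_plate_band",
    "cortical_bone", "metaphyseal_bone")
}

#' Model variants
#' @export
variant_ids <- function() {
  c("no_soc", "with_soc", "protrusions_small", "protrusions_extended")
}

new_polygon <- function(label, rings, seg_curve = NULL, seg_tag = NULL,
                        mirror_of = NA_integer_) {
  k <- vapply(rings, nrow, integer(1))
  if (is.null(seg_curve))
    seg_curve <- lapply(k, function(n) rep(NA_character_, n))
  if (is.null(seg_tag))
    seg_tag <- lapply(k, function(n) rep(NA_character_, n))
  structure(list(label = label, rings = rings, seg_curve = seg_curve,
                 seg_tag = seg_tag, mirror_of = mirror_of),
            class = "epi_polygon")
}

ring_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Area of a labeled polygon (outer ring minus holes)
#' @param poly an `epi_polygon`.
#' @export
polygon_area <- function(poly) {
  sum(vapply(poly$rings, ring_area_signed, numeric(1)))
}

# mirror a polygon about x = 0, restoring CCW orientation and remapping
# side-specific boundary tags
mirror_polygon <- function(poly, index) {
  swap_tag <- function(tg) {
    tg[tg == "cortical_outer_right"] <- "__L"
    tg[tg == "cortical_outer_left"] <- "cortical_outer_right"
    tg[tg == "__L"] <- "cortical_outer_left"
    tg
  }
  rings <- list(); scs <- list(); sts <- list()
  for (r in seq_along(poly$rings)) {
    P <- poly$rings[[r]]
    k <- nrow(P)
    Q <- cbind(-P[, 1] + 0, P[, 2])     # +0 normalises -0
    idx <- rev(seq_len(k))
    Q <- Q[idx, , drop = FALSE]
    # segment i of Q connects Q[i] -> Q[i+1]; Q[i] = P[k-i+1], so it mirrors
    # the old segment P[k-i] -> P[k-i+1], i.e. old segment index k-i
    segmap <- c(k - seq_len(k - 1), k)
    rings[[r]] <- Q
    scs[[r]] <- poly$seg_curve[[r]][segmap]
    sts[[r]] <- swap_tag(poly$seg_tag[[r]][segmap])
  }
  new_polygon(poly$label, rings, scs, sts, mirror_of = index)
}

arc_pts <- function(cx, cy, rx, ry, a0, a1, n) {
  a <- seq(a0, a1, length.out = n + 1)
  cbind(cx + rx * cos(a), cy + ry * sin(a))
}

# stadium (rounded-end finger) outline, CCW; polygonal caps with n_cap
# segments per semicircle. Biological protrusions have rounded tips; sharp
# inclusion corners would inject artificial stress singularities.
stadium_ring <- function(cc, base, top, r, n_cap = 8) {
  bot <- arc_pts(cc, base + r, r, r, pi, 2 * pi, n_cap)        # left->right
  topc <- arc_pts(cc, top - r, r, r, 0, pi, n_cap)             # right->left
  ring <- rbind(bot, topc)
  ring[!duplicated(round(ring, 12)), , drop = FALSE]
}

# right half of a centerline stadium finger (cc = 0), CCW, closing down the
# centerline; tips forced exactly onto x = 0 so the mirror dedups
stadium_half_ring <- function(base, top, r, n_cap = 8) {
  bot <- arc_pts(0, base + r, r, r, 3 * pi / 2, 2 * pi, max(4, n_cap %/% 2))
  topc <- arc_pts(0, top - r, r, r, 0, pi / 2, max(4, n_cap %/% 2))
  bot[1, ] <- c(0, base)
  topc[nrow(topc), ] <- c(0, top)
  rbind(bot, topc)
}

#' Construct the labeled polygonal partition of the epiphysis domain
#'
#' Builds the five-subdomain plane-strain geometry for a given variant. To
#' guarantee a mirror-symmetric mesh, every subdomain is returned as
#' half-domain polygons split along the symmetry axis x = 0; polygons on the
#' left carry a `mirror_of` reference to their right-hand twin and are meshed
#' by reflection. The `no_soc` variant shares the `with_soc` geometry (the
#' insert is made stiff or cartilage-like by the material map, never by
#' deleting the polygon), so comparisons are mesh-identical.
#'
#' @param params an [epiphysis_params()] object.
#' @param variant one of [variant_ids()].
#' @return an object of class `epi_polygons`: a list of labeled polygons with
#'   attributes `curves` (analytic curve definitions used to place boundary
#'   and midside nodes exactly on arcs) and `params`.
#' @export
build_geometry <- function(params = epiphysis_params(),
                           variant = c("with_soc", "no_soc",
                                       "protrusions_small",
                                       "protrusions_extended")) {
  variant <- match.arg(variant)
  p <- params
  R <- p$top_radius
  hb <- p$bottom_width / 2
  sh <- p$total_height - R          # shaft height; arc center (0, sh)
  cw <- p$cortical_width
  b0 <- p$gp_band_y - p$gp_band_height / 2
  b1 <- p$gp_band_y + p$gp_band_height / 2
  xi <- function(y) (hb - cw) + (R - cw - (hb - cw)) * y / sh  # inner wall
  curves <- list(top_arc = list(cx = 0, cy = sh, rx = R, ry = R),
                 soc = list(cx = 0, cy = p$soc_center_y,
                            rx = p$soc_rx, ry = p$soc_ry))

  n_arc <- max(12L, ceiling((pi / 2 * R) / p$curve_chord))
  arcR <- arc_pts(0, sh, R, R, 0, pi / 2, n_arc)  # (R, sh) ... (0, sh + R)
  arcR[1, ] <- c(R, sh)
  arcR[n_arc + 1, ] <- c(0, sh + R)  # exact apex so the mirror dedups

  polys <- list()
  add <- function(pl) { polys[[length(polys) + 1L]] <<- pl; invisible(NULL) }

  # metaphyseal bone (right half)
  add(new_polygon("metaphyseal_bone",
                  list(rbind(c(0, 0), c(hb - cw, 0), c(xi(b0), b0), c(0, b0))),
                  seg_tag = list(c("bottom", NA, NA, NA))))
  # growth-plate band (right half)
  add(new_polygon("growth_plate_band",
                  list(rbind(c(0, b0), c(xi(b0), b0), c(xi(b1), b1),
                             c(0, b1)))))
  # cortical wall (right); the inner wall is split at the band corners so the
  # metaphysis/band/cartilage interfaces conform edge-for-edge
  add(new_polygon("cortical_bone",
                  list(rbind(c(hb - cw, 0), c(hb, 0), c(R, sh),
                             c(R - cw, sh), c(xi(b1), b1), c(xi(b0), b0))),
                  seg_tag = list(c("bottom", "cortical_outer_right", NA, NA,
                                   NA, NA))))

  base <- b1 + p$prot_gap
  if (variant %in% c("with_soc", "no_soc")) {
    s <- curves$soc
    n_ell <- max(12L, ceiling((pi / 2 * (s$rx + s$ry)) / p$curve_chord))
    ellR <- arc_pts(0, s$cy, s$rx, s$ry, -pi / 2, pi / 2, n_ell)  # bottom->top
    ellR[1, 1] <- 0; ellR[nrow(ellR), 1] <- 0
    kE <- nrow(ellR)
    # cartilage (right half): neck + cap with the insert as centerline notch
    ring <- rbind(c(0, b1), c(xi(b1), b1), c(R - cw, sh),
                  arcR,                                   # includes (R, sh)
                  ellR[rev(seq_len(kE)), , drop = FALSE]) # top -> bottom
    nr <- nrow(ring)
    sc <- rep(NA_character_, nr); st <- rep(NA_character_, nr)
    # segments: 1 band-top, 2 inner wall, 3 cortical-top interface,
    # 4..(3+n_arc) arc, (4+n_arc) centerline apex->insert top,
    # (5+n_arc)..(nr-1) insert ellipse, nr centerline back to band top
    sc[seq(4, 3 + n_arc)] <- "top_arc"
    st[seq(4, 3 + n_arc)] <- "top_arc"
    sc[seq(5 + n_arc, nr - 1)] <- "soc"
    add(new_polygon("epiphyseal_cartilage", list(ring), list(sc), list(st)))
    # insert (right half), bottom -> bulge -> top -> centerline down
    sci <- c(rep("soc", kE - 1), NA)
    add(new_polygon("stiff_insert", list(ellR), list(sci)))
  } else {
    depth <- if (variant == "protrusions_small") p$prot_depth_small
             else p$prot_depth_extended
    top <- base + depth
    nf <- p$prot_count
    wf <- p$prot_width / 2
    centers <- (seq_len(nf) - (nf + 1) / 2) * p$prot_spacing
    cR <- sort(centers[centers > 1e-9])
    has_mid <- any(abs(centers) < 1e-9)
    # validate fingers inside cartilage
    xr <- max(c(cR + wf, if (has_mid) wf))
    if (top >= sh + sqrt(max(R^2 - xr^2, 0)) || xr >= xi(b1) - 1e-9)
      stop("protrusion fingers must lie strictly inside the cartilage",
           call. = FALSE)
    fingers <- lapply(cR, function(cc) stadium_ring(cc, base, top, wf))
    holes <- lapply(fingers, function(fr)
      fr[rev(seq_len(nrow(fr))), , drop = FALSE])  # CW holes
    if (has_mid) {
      half <- stadium_half_ring(base, top, wf)
      # centerline notch: walk the half finger's outline top -> bottom
      notch <- half[rev(seq_len(nrow(half))), , drop = FALSE]
      ring <- rbind(c(0, b1), c(xi(b1), b1), c(R - cw, sh), arcR, notch)
      nr <- nrow(ring)
      sc <- rep(NA_character_, nr); st <- rep(NA_character_, nr)
      sc[seq(4, 3 + n_arc)] <- "top_arc"
      st[seq(4, 3 + n_arc)] <- "top_arc"
      add(new_polygon("epiphyseal_cartilage", c(list(ring), holes),
                      c(list(sc), lapply(holes, function(h)
                        rep(NA_character_, nrow(h)))),
                      c(list(st), lapply(holes, function(h)
                        rep(NA_character_, nrow(h))))))
      add(new_polygon("stiff_insert", list(half)))
    } else {
      ring <- rbind(c(0, b1), c(xi(b1), b1), c(R - cw, sh), arcR)
      nr <- nrow(ring)
      sc <- rep(NA_character_, nr); st <- rep(NA_character_, nr)
      sc[seq(4, 3 + n_arc)] <- "top_arc"
      st[seq(4, 3 + n_arc)] <- "top_arc"
      add(new_polygon("epiphyseal_cartilage", c(list(ring), holes),
                      c(list(sc), lapply(holes, function(h)
                        rep(NA_character_, nrow(h)))),
                      c(list(st), lapply(holes, function(h)
                        rep(NA_character_, nrow(h))))))
    }
    for (fr in fingers) add(new_polygon("stiff_insert", list(fr)))
  }

  # mirrored left halves
  nright <- length(polys)
  for (i in seq_len(nright)) add(mirror_polygon(polys[[i]], i))

  # sanity: interior-disjoint partition with positive areas
  areas <- vapply(polys, polygon_area, numeric(1))
  if (any(areas <= 0))
    stop(sprintf("geometry error: polygon %d (%s) has non-positive area",
                 which(areas <= 0)[1], polys[[which(areas <= 0)[1]]]$label),
         call. = FALSE)

  structure(polys, class = "epi_polygons", curves = curves, params = p,
            variant = variant)
}

#' Outer boundary polygon of the epiphysis domain
#'
#' Returns the full outer ring (both halves) at the same boundary sampling as
#' [build_geometry()], for area-conservation checks.
#' @param params an [epiphysis_params()] object.
#' @export
outer_boundary <- function(params = epiphysis_params()) {
  p <- params
  R <- p$top_radius; hb <- p$bottom_width / 2; sh <- p$total_height - R
  n_arc <- max(12L, ceiling((pi / 2 * R) / p$curve_chord))
  arcR <- arc_pts(0, sh, R, R, 0, pi / 2, n_arc)
  arcR[1, ] <- c(R, sh); arcR[n_arc + 1, ] <- c(0, sh + R)
  arcL <- cbind(-arcR[rev(seq_len(nrow(arcR))), 1] + 0,
                arcR[rev(seq_len(nrow(arcR))), 2])
  rbind(c(-hb, 0), c(hb, 0), arcR, arcL[-1, , drop = FALSE])
}

#' Total area of a labeled polygon set
#' @param polys an `epi_polygons` object (or any list of `epi_polygon`).
#' @export
polygons_area <- function(polys) {
  sum(vapply(polys, polygon_area, numeric(1)))
}

#' Select elements whose centroid lies in a rectangular band
#'
#' @param mesh a `planar_mesh`.
#' @param y_range numeric length-2 vertical interval (mm).
#' @param x_range optional numeric length-2 horizontal interval (mm).
#' @param label optional subdomain label filter.
#' @return integer vector of element indices (possibly empty, with a warning).
#' @export
zone_elements <- function(mesh, y_range = NULL, x_range = NULL, label = NULL) {
  cen <- mesh$centroid
  keep <- rep(TRUE, nrow(cen))
  if (!is.null(y_range))
    keep <- keep & cen[, 2] >= min(y_range) & cen[, 2] <= max(y_range)
  if (!is.null(x_range))
    keep <- keep & cen[, 1] >= min(x_range) & cen[, 1] <= max(x_range)
  if (!is.null(label)) keep <- keep & mesh$label %in% label
  idx <- which(keep)
  if (length(idx) == 0)
    warning("zone selection is empty", call. = FALSE)
  idx
}

#' Partition a zone into left/middle/right thirds by centroid x
#'
#' The selected elements are split into three equal-width intervals spanning
#' their centroid x-range, as used to compare stress across the medial-lateral
#' axis of the growth plate.
#' @param mesh a `planar_mesh`.
#' @param zone integer element indices (e.g. from [zone_elements()]).
#' @return named list of integer vectors `left`, `middle`, `right`.
#' @export
zone_thirds <- function(mesh, zone) {
  if (length(zone) == 0)
    return(list(left = integer(0), middle = integer(0), right = integer(0)))
  x <- mesh$centroid[zone, 1]
  br <- seq(min(x), max(x), length.out = 4)
  g <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  list(left = zone[g == 1], middle = zone[g == 2], right = zone[g == 3])
}

#' Rectangular block polygon set (verification fixture geometry)
#'
#' A single homogeneous block with boundary tags `bottom`, `right`, `top`,
#' `left`, used for closed-form verification of the solver.
#' @param width,height block dimensions (mm).
#' @param label subdomain label.
#' @export
block_polygons <- function(width, height, label = "block") {
  ring <- rbind(c(-width / 2, 0), c(width / 2, 0), c(width / 2, height),
                c(-width / 2, height))
  pl <- new_polygon(label, list(ring),
                    seg_tag = list(c("bottom", "right", "top", "left")))
  structure(list(pl), class = "epi_polygons", curves = list(),
            params = NULL, variant = "block")
}
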