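# Mesh generation: Delaunay triangulation of boundary + interior lattice
# points, filtered by the labeled polygons (distmesh-style), then elevated to
# 6-node quadratic triangles with curved-boundary midside placement.

# canonical subdivision of one segment: interior points are computed from the
# lexicographically smaller endpoint so the two polygons sharing an interface
# produce bit-identical coordinates
subdivide_segment <- function(a, b, n, curve = NULL) {
  if (n <= 1) return(matrix(numeric(0), 0, 2))
  swap <- (b[1] < a[1]) || (b[1] == a[1] && b[2] < a[2])
  p1 <- if (swap) b else a
  p2 <- if (swap) a else b
  tt <- seq_len(n - 1) / n
  if (!is.null(curve)) {
    # parametrise by the angle measured from the vertical axis (positive
    # toward +x); with the curve centered on x = 0 this makes mirrored
    # subdivisions exactly antisymmetric in floating point
    phi1 <- atan2((p1[1] - curve$cx) / curve$rx, (p1[2] - curve$cy) / curve$ry)
    phi2 <- atan2((p2[1] - curve$cx) / curve$rx, (p2[2] - curve$cy) / curve$ry)
    if (phi2 - phi1 > pi) phi2 <- phi2 - 2 * pi
    if (phi1 - phi2 > pi) phi2 <- phi2 + 2 * pi
    phi <- (1 - tt) * phi1 + tt * phi2
    pts <- cbind(curve$cx + curve$rx * sin(phi),
                 curve$cy + curve$ry * cos(phi))
  } else {
    pts <- cbind((1 - tt) * p1[1] + tt * p2[1], (1 - tt) * p1[2] + tt * p2[2])
  }
  if (swap) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# hexagonal interior lattice aligned to a global origin (so meshes of
# adjacent and mirrored polygons use consistent, symmetric point sets)
hex_lattice <- function(bbox, h) {
  dy <- h * sqrt(3) / 2
  ks <- seq(ceiling(bbox[3] / dy), floor(bbox[4] / dy))
  if (length(ks) == 0) return(matrix(numeric(0), 0, 2))
  out <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    off <- if (k %% 2 == 0) 0 else 0.5
    ms <- seq(ceiling(bbox[1] / h - off), floor(bbox[2] / h - off))
    if (length(ms) == 0) { out[[i]] <- matrix(numeric(0), 0, 2); next }
    out[[i]] <- cbind((ms + off) * h, k * dy)
  }
  do.call(rbind, out)
}

node_key <- function(x, y) sprintf("%.15g_%.15g", x + 0, y + 0)

# mesh a single polygon (rings already subdivided): returns local triangles
# as indices into `pts`
triangulate_polygon <- function(pts, rings_idx, rings_pts, h, margin) {
  segs <- do.call(rbind, lapply(rings_pts, function(P) {
    k <- nrow(P)
    cbind(P[, 1], P[, 2], P[c(2:k, 1), 1], P[c(2:k, 1), 2])
  }))
  bb <- c(min(segs[, c(1, 3)]), max(segs[, c(1, 3)]),
          min(segs[, c(2, 4)]), max(segs[, c(2, 4)]))
  cand <- hex_lattice(bb, h)
  if (nrow(cand) > 0) {
    ok <- as.logical(points_in_rings_cpp(cand, rings_pts))
    cand <- cand[ok, , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    d <- min_seg_dist_cpp(cand, segs)
    cand <- cand[d >= margin * h, , drop = FALSE]
  }
  allpts <- rbind(pts, cand)
  tri <- delaunay_cpp(allpts)
  cen <- (allpts[tri[, 1], , drop = FALSE] + allpts[tri[, 2], , drop = FALSE] +
          allpts[tri[, 3], , drop = FALSE]) / 3
  keep <- as.logical(points_in_rings_cpp(cen, rings_pts))
  tri <- tri[keep, , drop = FALSE]
  list(tri = tri, pts = allpts)
}

#' Generate a conforming labeled triangulation of a polygon set
#'
#' Each polygon ring is resampled to the target edge length (points on tagged
#' curves are placed exactly on the analytic arc/ellipse), interior points are
#' laid on a hexagonal lattice, and each polygon is triangulated by Delaunay
#' triangulation restricted to its interior. Interfaces between polygons are
#' shared point-for-point, so the global mesh conforms to all subdomain
#' boundaries; polygons carrying a `mirror_of` attribute are meshed by exact
#' reflection of their twin, which makes symmetric geometries yield exactly
#' mirror-symmetric meshes. Triangles are then elevated to 6-node quadratic
#' elements with midside nodes projected onto curved boundaries.
#'
#' @param polygons an `epi_polygons` set from [build_geometry()] or
#'   [block_polygons()].
#' @param target_edge_length target element edge length h (mm).
#' @return an object of class `planar_mesh` with fields `nodes` (n x 2),
#'   `tri` (m x 6 node indices, corners counter-clockwise then midsides),
#'   `label` (length m), `boundary_edges` (data.frame n1, n2, mid, tag),
#'   `node_theta` (polar angle in degrees on the top arc, `NA` elsewhere),
#'   `area` and `centroid` per element.
#' @export
generate_mesh <- function(polygons, target_edge_length) {
  h <- target_edge_length
  if (!is.numeric(h) || h <= 0) stop("target_edge_length must be > 0")
  curves <- attr(polygons, "curves")

  env <- new.env(parent = emptyenv())
  coords <- list(); ncoord <- 0L
  reg <- function(x, y) {
    key <- node_key(x, y)
    id <- env[[key]]
    if (is.null(id)) {
      ncoord <<- ncoord + 1L
      id <- ncoord
      env[[key]] <- id
      coords[[id]] <<- c(x, y)
    }
    id
  }

  polymesh <- vector("list", length(polygons))
  all_tri <- list(); all_lab <- list()
  segrec <- list()  # data.frames a,b,curve,tag

  for (pi_ in seq_along(polygons)) {
    pl <- polygons[[pi_]]
    if (!is.na(pl$mirror_of)) {
      src <- polymesh[[pl$mirror_of]]
      if (is.null(src)) stop("mirror_of must reference an earlier polygon")
      # mirror nodes of the source triangulation
      map <- vapply(src$node_ids, function(id) {
        xy <- coords[[id]]
        reg(-xy[1] + 0, xy[2])
      }, integer(1))
      tri <- cbind(map[src$tri_local[, 1]], map[src$tri_local[, 3]],
                   map[src$tri_local[, 2]])  # swap to restore CCW
      all_tri[[length(all_tri) + 1L]] <- tri
      all_lab[[length(all_lab) + 1L]] <- rep(pl$label, nrow(tri))
      sg <- src$segs
      swap_tag <- function(tg) {
        tg[tg == "cortical_outer_right"] <- "__L"
        tg[tg == "cortical_outer_left"] <- "cortical_outer_right"
        tg[tg == "__L"] <- "cortical_outer_left"
        tg
      }
      sg2 <- data.frame(a = map[match(sg$a, src$node_ids)],
                        b = map[match(sg$b, src$node_ids)],
                        curve = sg$curve, tag = swap_tag(sg$tag),
                        stringsAsFactors = FALSE)
      segrec[[length(segrec) + 1L]] <- sg2
      polymesh[[pi_]] <- list(done = TRUE)
      next
    }

    # subdivide rings
    rings_pts <- list(); seg_a <- c(); seg_b <- c(); seg_cv <- c(); seg_tg <- c()
    ring_ids <- list()
    for (r in seq_along(pl$rings)) {
      P <- pl$rings[[r]]
      k <- nrow(P)
      cv <- pl$seg_curve[[r]]; tg <- pl$seg_tag[[r]]
      rp <- list(); rcv <- c(); rtg <- c()
      for (s in seq_len(k)) {
        a <- P[s, ]; b <- P[if (s == k) 1 else s + 1, ]
        n <- max(1L, ceiling(sqrt(sum((b - a)^2)) / h))
        crv <- if (!is.na(cv[s])) curves[[cv[s]]] else NULL
        mid <- subdivide_segment(a, b, n, crv)
        rp[[s]] <- rbind(a, mid)
        rcv <- c(rcv, rep(cv[s], n))
        rtg <- c(rtg, rep(tg[s], n))
      }
      RP <- do.call(rbind, rp)
      rings_pts[[r]] <- RP
      ids <- vapply(seq_len(nrow(RP)), function(i) reg(RP[i, 1], RP[i, 2]),
                    integer(1))
      ring_ids[[r]] <- ids
      kk <- length(ids)
      seg_a <- c(seg_a, ids)
      seg_b <- c(seg_b, ids[c(2:kk, 1)])
      seg_cv <- c(seg_cv, rcv)
      seg_tg <- c(seg_tg, rtg)
    }
    bpts <- do.call(rbind, rings_pts)
    bids <- unlist(ring_ids)

    # triangulate with increasing clearance if a boundary edge goes missing
    tri <- NULL
    for (margin in c(0.6, 0.75, 0.95)) {
      tm <- triangulate_polygon(bpts, NULL, rings_pts, h, margin)
      ek <- c(paste(pmin(tm$tri[, 1], tm$tri[, 2]),
                    pmax(tm$tri[, 1], tm$tri[, 2])),
              paste(pmin(tm$tri[, 2], tm$tri[, 3]),
                    pmax(tm$tri[, 2], tm$tri[, 3])),
              paste(pmin(tm$tri[, 3], tm$tri[, 1]),
                    pmax(tm$tri[, 3], tm$tri[, 1])))
      nb <- nrow(bpts)
      li_a <- seq_len(nb)
      # local ring indices follow bpts order ring by ring
      off <- 0L; li_b <- integer(nb)
      for (P in rings_pts) {
        kk <- nrow(P)
        li_b[off + seq_len(kk)] <- off + c(2:kk, 1)
        off <- off + kk
      }
      want <- paste(pmin(li_a, li_b), pmax(li_a, li_b))
      if (all(want %in% ek)) { tri <- tm; break }
    }
    if (is.null(tri))
      stop(sprintf("meshing error: boundary of polygon %d (%s) not recovered",
                   pi_, pl$label), call. = FALSE)

    # register interior points
    npt <- nrow(tri$pts)
    node_ids <- integer(npt)
    node_ids[seq_len(nrow(bpts))] <- bids
    if (npt > nrow(bpts))
      for (i in seq(nrow(bpts) + 1L, npt))
        node_ids[i] <- reg(tri$pts[i, 1], tri$pts[i, 2])

    gtri <- cbind(node_ids[tri$tri[, 1]], node_ids[tri$tri[, 2]],
                  node_ids[tri$tri[, 3]])
    all_tri[[length(all_tri) + 1L]] <- gtri
    all_lab[[length(all_lab) + 1L]] <- rep(pl$label, nrow(gtri))
    segrec[[length(segrec) + 1L]] <-
      data.frame(a = seg_a, b = seg_b, curve = seg_cv, tag = seg_tg,
                 stringsAsFactors = FALSE)
    polymesh[[pi_]] <- list(tri_local = tri$tri, node_ids = node_ids,
                            segs = segrec[[length(segrec)]])
  }

  nodes <- do.call(rbind, coords)
  tri3 <- do.call(rbind, all_tri)
  lab <- unlist(all_lab)

  # orientation: make all triangles CCW
  ax <- nodes[tri3[, 1], 1]; ay <- nodes[tri3[, 1], 2]
  bx <- nodes[tri3[, 2], 1]; by <- nodes[tri3[, 2], 2]
  cx <- nodes[tri3[, 3], 1]; cy <- nodes[tri3[, 3], 2]
  a2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  flip <- a2 < 0
  if (any(flip)) tri3[flip, c(2, 3)] <- tri3[flip, c(3, 2)]
  if (any(a2 == 0)) stop("meshing error: degenerate (zero-area) triangle")

  # segment lookup: edge key -> curve/tag
  segs <- do.call(rbind, segrec)
  skey <- paste(pmin(segs$a, segs$b), pmax(segs$a, segs$b))
  first <- !duplicated(skey)
  seg_curve <- segs$curve[first]; seg_tag <- segs$tag[first]
  names(seg_curve) <- skey[first]; names(seg_tag) <- skey[first]

  # unique corner edges; midside node per edge
  e_all <- rbind(tri3[, c(1, 2)], tri3[, c(2, 3)], tri3[, c(3, 1)])
  ekey <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  ue <- !duplicated(ekey)
  uedge <- e_all[ue, , drop = FALSE]
  ukey <- ekey[ue]
  mid_id <- integer(length(ukey))
  for (i in seq_along(ukey)) {
    a <- nodes[uedge[i, 1], ]; b <- nodes[uedge[i, 2], ]
    cvn <- unname(seg_curve[ukey[i]])
    crv <- if (length(cvn) == 1 && !is.na(cvn)) curves[[cvn]] else NULL
    mp <- subdivide_segment(a, b, 2L, crv)
    mid_id[i] <- reg(mp[1, 1], mp[1, 2])
  }
  names(mid_id) <- ukey
  nodes <- do.call(rbind, coords)

  m <- nrow(tri3)
  k12 <- paste(pmin(tri3[, 1], tri3[, 2]), pmax(tri3[, 1], tri3[, 2]))
  k23 <- paste(pmin(tri3[, 2], tri3[, 3]), pmax(tri3[, 2], tri3[, 3]))
  k31 <- paste(pmin(tri3[, 3], tri3[, 1]), pmax(tri3[, 3], tri3[, 1]))
  tri6 <- cbind(tri3, mid_id[k12], mid_id[k23], mid_id[k31])
  dimnames(tri6) <- NULL

  # boundary edges: corner edges used exactly once, oriented as in their
  # triangle (domain to the left)
  cnt <- table(ekey)
  is_bnd <- cnt[ekey] == 1
  bedge <- e_all[is_bnd, , drop = FALSE]
  bkey <- ekey[is_bnd]
  btag <- unname(seg_tag[bkey])
  if (any(is.na(btag)))
    stop("meshing error: untagged boundary edge (interface reached the hull)")
  boundary_edges <- data.frame(n1 = bedge[, 1], n2 = bedge[, 2],
                               mid = unname(mid_id[bkey]), tag = btag,
                               stringsAsFactors = FALSE)

  node_theta <- rep(NA_real_, nrow(nodes))
  if (!is.null(curves$top_arc)) {
    arcn <- unique(c(boundary_edges$n1[boundary_edges$tag == "top_arc"],
                     boundary_edges$n2[boundary_edges$tag == "top_arc"],
                     boundary_edges$mid[boundary_edges$tag == "top_arc"]))
    ca <- curves$top_arc
    node_theta[arcn] <- atan2(nodes[arcn, 2] - ca$cy,
                              nodes[arcn, 1] - ca$cx) * 180 / pi
  }

  area <- (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by)) / 2
  area <- abs(area)
  centroid <- cbind((ax + bx + cx) / 3, (ay + by + cy) / 3)

  structure(list(nodes = nodes, tri = tri6, label = lab,
                 boundary_edges = boundary_edges, node_theta = node_theta,
                 curves = curves, target_h = h, area = area,
                 centroid = centroid),
            class = "planar_mesh")
}

#' @export
print.planar_mesh <- function(x, ...) {
  cat(sprintf("planar_mesh: %d nodes, %d quadratic triangles (h = %g mm)\n",
              nrow(x$nodes), nrow(x$tri), x$target_h))
  print(table(x$label))
  invisible(x)
}

#' Validate mesh invariants
#'
#' Checks positive element areas, a single closed boundary loop, top-arc nodes
#' on the analytic circle, interface conformity (every interior edge shared by
#' exactly two elements) and the circumradius bound.
#' @param mesh a `planar_mesh`.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_mesh <- function(mesh) {
  nodes <- mesh$nodes; tri <- mesh$tri
  ax <- nodes[tri[, 1], 1]; ay <- nodes[tri[, 1], 2]
  bx <- nodes[tri[, 2], 1]; by <- nodes[tri[, 2], 2]
  cx <- nodes[tri[, 3], 1]; cy <- nodes[tri[, 3], 2]
  a2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  if (any(a2 <= 0)) stop("non-positive element signed area")
  # circumradius = abc / (4 A)
  la <- sqrt((bx - cx)^2 + (by - cy)^2)
  lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  cr <- la * lb * lc / (2 * abs(a2))
  if (max(cr) > 2 * mesh$target_h)
    stop(sprintf("circumradius bound violated: max %.3g > 2h = %.3g",
                 max(cr), 2 * mesh$target_h))
  # edge use counts
  e_all <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ekey <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  cnt <- table(ekey)
  if (any(cnt > 2)) stop("edge shared by more than two elements")
  be <- mesh$boundary_edges
  if (sum(cnt == 1) != nrow(be)) stop("boundary edge bookkeeping mismatch")
  # single closed loop: every boundary node appears exactly twice as endpoint
  endp <- c(be$n1, be$n2)
  if (!all(table(endp) == 2)) stop("boundary is not a union of closed loops")
  # walk the loop from the first edge
  start <- be$n1[1]
  cur <- be$n2[1]
  visited <- 1L
  while (cur != start && visited <= nrow(be)) {
    i <- match(cur, be$n1)
    if (is.na(i)) stop("boundary loop broken")
    cur <- be$n2[i]
    visited <- visited + 1L
  }
  if (visited != nrow(be)) stop("boundary has more than one loop")
  # arc nodes on circle
  if (!is.null(mesh$curves$top_arc)) {
    arcn <- which(!is.na(mesh$node_theta))
    ca <- mesh$curves$top_arc
    r <- sqrt((nodes[arcn, 1] - ca$cx)^2 + (nodes[arcn, 2] - ca$cy)^2)
    if (any(abs(r - ca$rx) > 1e-6 * ca$rx))
      stop("top-arc node off the analytic circle")
  }
  invisible(TRUE)
}
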