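#' Anisotropic Euclidean distance transform of a mask
#'
#' Distance (nm) from each foreground voxel center to the nearest
#' background voxel center, respecting anisotropic spacing. Voxels beyond
#' the grid count as background (the mask is padded internally), so
#' objects touching the crop edge are bounded there.
#'
#' @param mask logical 3D array.
#' @param voxel_size `(dx, dy, dz)` nm.
#' @return numeric array of distances, 0 on background.
#' @export
mask_distance_transform <- function(mask, voxel_size = c(10, 10, 30)) {
  d <- dim(mask)
  dp <- d + 2L
  padded <- array(FALSE, dp)
  padded[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  dt <- array(cpp_edt(as.logical(padded), dp, as.numeric(voxel_size)), dp)
  dt[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3]), drop = FALSE]
}

#' External diameter profile along a skeleton
#'
#' Per-node external diameter, `2 x` the distance-transform value at the
#' node (the local inscribed-sphere diameter), in nm.
#'
#' @param skel a [skeleton_graph()] with nodes in the mask's physical
#'   frame (voxel `(1,1,1)` center at `0.5 * voxel_size`).
#' @param mask logical 3D array the skeleton lies in.
#' @param voxel_size `(dx, dy, dz)` nm.
#' @return numeric vector, one diameter per node.
#' @export
radius_profile <- function(skel, mask, voxel_size = c(10, 10, 30)) {
  stopifnot(inherits(skel, "skeleton_graph"))
  idx <- coord_to_voxel(skel$nodes, voxel_size, dim(mask))
  inside <- mask[idx]
  if (any(!inside))
    stop(sum(!inside), " skeleton node(s) outside the mask", call. = FALSE)
  dt <- mask_distance_transform(mask, voxel_size)
  2 * dt[idx]
}

coord_to_voxel <- function(coords, voxel_size, dims) {
  idx <- sweep(coords, 2, as.numeric(voxel_size), "/") + 0.5
  idx <- round(idx)
  idx[] <- pmax(1, pmin(rep(dims, each = nrow(coords)), idx))
  matrix(as.integer(idx), ncol = 3)
}

# 26-neighborhood voxel graph over a set of linear indices
voxel_graph <- function(lin_idx, dims, voxel_size) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  k <- (lin_idx - 1L) %/% (nx * ny)
  j <- ((lin_idx - 1L) %% (nx * ny)) %/% nx
  i <- (lin_idx - 1L) %% nx
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0 & seq_len(27) > 14, , drop = FALSE]
  edges <- NULL; weights <- NULL
  pos <- seq_along(lin_idx)
  lut <- new.env(hash = TRUE)
  for (p in pos) assign(as.character(lin_idx[p]), p, envir = lut)
  for (r in seq_len(nrow(off))) {
    ii <- i + off[r, 1]; jj <- j + off[r, 2]; kk <- k + off[r, 3]
    ok <- ii >= 0 & ii < nx & jj >= 0 & jj < ny & kk >= 0 & kk < nz
    nb <- ii + nx * (jj + ny * kk) + 1L
    hit <- ok & nb %in% lin_idx
    if (!any(hit)) next
    tgt <- match(nb[hit], lin_idx)
    edges <- rbind(edges, cbind(pos[hit], tgt))
    w <- sqrt(sum((off[r, ] * voxel_size)^2))
    weights <- c(weights, rep(w, sum(hit)))
  }
  g <- igraph::make_empty_graph(n = length(lin_idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges), weight = weights)
  g
}

lin_to_coord <- function(lin_idx, dims, voxel_size) {
  nx <- dims[1]; ny <- dims[2]
  k <- (lin_idx - 1L) %/% (nx * ny)
  j <- ((lin_idx - 1L) %% (nx * ny)) %/% nx
  i <- (lin_idx - 1L) %% nx
  cbind((i + 0.5) * voxel_size[1], (j + 0.5) * voxel_size[2],
        (k + 0.5) * voxel_size[3])
}

empty_nanotunnel_table <- function() {
  structure(data.frame(
    organelle_id = integer(), nanotunnel_id = integer(),
    length_nm = numeric(), d_ext_min_nm = numeric(),
    d_ext_max_nm = numeric(), lumen_min_nm = numeric(),
    lumen_clamped = logical(), end_status = character()),
    centerlines = list(), class = c("nanotunnel_set", "data.frame"))
}

#' Detect nanotunnels
#'
#' Nanotunnels are thin double-membrane projections of a mitochondrion,
#' either free-ended or connecting two mitochondrial bodies. Detection on
#' a voxel mask works on the anisotropic distance transform: mitochondrial
#' *bodies* are the morphological opening of the mask by a ball of radius
#' `d_max / 2` (everything a nanotunnel-scale ball can sweep); the
#' remaining thin regions attached to at least one body are candidate
#' nanotunnels. Each candidate's centerline is the geodesic voxel path
#' between its body attachments (or to its farthest tip when free-ended),
#' its external diameter profile is twice the distance transform along the
#' path, and candidates shorter than `l_min` are dropped. The operational
#' thresholds bracket reported nanotunnel dimensions (external diameter
#' up to ~200 nm, lengths from tens of nm to 2 um) and are configurable.
#'
#' On a [skeleton_graph()] with radii, the same logic runs on the graph:
#' maximal sub-paths whose diameter stays at or below `d_max` over at
#' least `l_min`, classified by whether both termini attach to thick
#' (body) nodes.
#'
#' @param x a [labeled_volume()], a logical mask array, or a
#'   [skeleton_graph()] with `radius`.
#' @param d_max maximum external diameter of a nanotunnel (nm).
#' @param l_min minimum length (nm).
#' @param voxel_size for mask input, `(dx, dy, dz)` nm.
#' @param membrane_correction subtracted from the minimum external
#'   diameter to estimate the matrix lumen (nm); see [estimate_lumen()].
#' @param ... passed between methods.
#' @return A `nanotunnel_set` data.frame: one row per nanotunnel with
#'   `length_nm`, `d_ext_min_nm`, `d_ext_max_nm`, `lumen_min_nm`,
#'   `lumen_clamped`, `end_status` (`"free_ended"` or `"connecting"`);
#'   centerline polylines in `attr(, "centerlines")`.
#' @export
detect_nanotunnels <- function(x, d_max = 250, l_min = 50, ...) {
  UseMethod("detect_nanotunnels")
}

#' @rdname detect_nanotunnels
#' @export
detect_nanotunnels.labeled_volume <- function(x, d_max = 250, l_min = 50,
                                              membrane_correction = 24,
                                              ...) {
  oset <- extract_organelles(x, exclude_border = FALSE, min_voxels = 1)
  out <- empty_nanotunnel_table()
  cls <- list()
  for (oid in oset$table$organelle_id) {
    m <- organelle_mask(oset, oid, pad = 1L)
    nt <- detect_nanotunnels(m, d_max = d_max, l_min = l_min,
                             voxel_size = x$voxel_size,
                             membrane_correction = membrane_correction)
    if (nrow(nt)) {
      nt$organelle_id <- oid
      cls <- c(cls, attr(nt, "centerlines"))
      out <- rbind(out, nt)
    }
  }
  if (nrow(out)) out$nanotunnel_id <- seq_len(nrow(out))
  attr(out, "centerlines") <- cls
  class(out) <- c("nanotunnel_set", "data.frame")
  out
}

#' @rdname detect_nanotunnels
#' @export
detect_nanotunnels.default <- function(x, d_max = 250, l_min = 50,
                                       voxel_size = c(10, 10, 30),
                                       membrane_correction = 24, ...) {
  mask <- x
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- mask > 0
  d <- dim(mask)
  voxel_size <- as.numeric(voxel_size)
  out <- empty_nanotunnel_table()
  if (!any(mask)) return(out)
  dt <- mask_distance_transform(mask, voxel_size)
  r_body <- d_max / 2
  ero <- dt >= r_body
  if (!any(ero)) return(out)   # no body anywhere: object is all-thin
  dist_to_core <- array(cpp_edt(as.logical(!ero), d, voxel_size), d)
  # one voxel diagonal of slack absorbs the discretization rind the
  # opening leaves on curved body surfaces
  vdiag <- sqrt(sum(voxel_size^2))
  bodies <- mask & (ero | dist_to_core <= r_body + vdiag)
  body_lab <- array(cpp_label_components(as.logical(bodies), d), d)
  thin <- mask & !bodies
  if (!any(thin)) return(out)
  thin_lab <- array(cpp_label_components(as.logical(thin), d), d)
  cls <- list()
  rows <- list()
  for (tc in seq_len(max(thin_lab))) {
    vox <- which(thin_lab == tc)
    touch <- adjacent_body_labels(vox, body_lab, d, dt[vox])
    if (length(touch$labels) == 0) next
    g <- voxel_graph(vox, d, voxel_size)
    # start: voxel attached to the body with the largest contact,
    # anchored at the mouth center (maximal clearance)
    ord <- order(-touch$contact)
    start <- touch$anchor[ord[1]]
    if (length(touch$labels) >= 2) {
      end <- touch$anchor[ord[2]]
      status <- "connecting"
    } else {
      dists <- igraph::distances(g, v = start)[1, ]
      dists[!is.finite(dists)] <- -1
      end <- which.max(dists)
      status <- "free_ended"
    }
    sp <- igraph::shortest_paths(g, from = start, to = end)$vpath[[1]]
    if (length(sp) < 2) next
    path_vox <- vox[as.integer(sp)]
    coords <- lin_to_coord(path_vox, d, voxel_size)
    profile <- 2 * dt[path_vox]
    if (nrow(coords) < 2) next
    # nanotunnel length runs body surface to body surface: add back the
    # gap between each attached terminus and the ideal body surface
    n_attached <- if (status == "connecting") c(1L, nrow(coords)) else 1L
    end_gap <- sum(pmax(dist_to_core[path_vox[n_attached]] - r_body, 0))
    len <- sum(sqrt(rowSums(diff(coords)^2))) + end_gap
    if (len < l_min) next
    # diameter extremes over the tunnel proper: nodes near an attached
    # terminus see into the body and inflate the local inscribed sphere,
    # nodes near a free tip taper toward zero -- both ends are excluded
    # from the profile (falling back to the midpoint for short tunnels)
    arc <- c(0, cumsum(sqrt(rowSums(diff(coords)^2))))
    interior <- arc > d_max / 2 & (arc[length(arc)] - arc) > d_max / 2
    if (!any(interior))
      interior[which.min(abs(arc - arc[length(arc)] / 2))] <- TRUE
    mm <- measure_nanotunnel(coords, profile,
                             membrane_correction, interior = interior)
    rows[[length(rows) + 1L]] <- data.frame(
      organelle_id = 1L, nanotunnel_id = length(rows) + 1L,
      length_nm = mm$length_nm, d_ext_min_nm = mm$d_ext_min_nm,
      d_ext_max_nm = mm$d_ext_max_nm, lumen_min_nm = mm$lumen_min_nm,
      lumen_clamped = mm$lumen_clamped, end_status = status)
    rows[[length(rows)]]$length_nm <- len
    cls[[length(cls) + 1L]] <- coords
  }
  if (length(rows)) out <- do.call(rbind, rows)
  attr(out, "centerlines") <- cls
  class(out) <- c("nanotunnel_set", "data.frame")
  out
}

# which body labels are 26-adjacent to the voxel set; for each, the
# contact size and an anchor voxel (position within `vox`) of maximal
# distance-transform clearance
adjacent_body_labels <- function(vox, body_lab, dims, clearance) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  k <- (vox - 1L) %/% (nx * ny)
  j <- ((vox - 1L) %% (nx * ny)) %/% nx
  i <- (vox - 1L) %% nx
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  hits <- list()
  for (r in seq_len(nrow(off))) {
    ii <- i + off[r, 1]; jj <- j + off[r, 2]; kk <- k + off[r, 3]
    ok <- ii >= 0 & ii < nx & jj >= 0 & jj < ny & kk >= 0 & kk < nz
    nb <- ii + nx * (jj + ny * kk) + 1L
    lab <- rep(0L, length(vox))
    lab[ok] <- body_lab[nb[ok]]
    sel <- lab > 0L
    if (any(sel))
      hits[[length(hits) + 1L]] <- data.frame(pos = which(sel),
                                              lab = lab[sel])
  }
  if (length(hits) == 0)
    return(list(labels = integer(), anchor = integer(),
                contact = integer()))
  h <- do.call(rbind, hits)
  labs <- sort(unique(h$lab))
  anchor <- integer(length(labs)); contact <- integer(length(labs))
  for (q in seq_along(labs)) {
    sub <- unique(h$pos[h$lab == labs[q]])
    contact[q] <- length(sub)
    anchor[q] <- sub[which.max(clearance[sub])]
  }
  list(labels = labs, anchor = anchor, contact = contact)
}

#' @rdname detect_nanotunnels
#' @export
detect_nanotunnels.skeleton_graph <- function(x, d_max = 250, l_min = 50,
                                              membrane_correction = 24,
                                              ...) {
  if (is.null(x$radius))
    stop("skeleton has no radius profile; see radius_profile()",
         call. = FALSE)
  diam <- 2 * x$radius
  thin <- which(diam <= d_max + 1e-9)
  out <- empty_nanotunnel_table()
  if (length(thin) == 0) return(out)
  g <- igraph::make_empty_graph(n = nrow(x$nodes), directed = FALSE)
  if (nrow(x$edges)) {
    len <- sqrt(rowSums((x$nodes[x$edges[, 1], , drop = FALSE] -
                           x$nodes[x$edges[, 2], , drop = FALSE])^2))
    g <- igraph::add_edges(g, t(x$edges), weight = len)
  }
  sub <- igraph::induced_subgraph(g, thin)
  comp <- igraph::components(sub)
  cls <- list(); rows <- list()
  for (cid in seq_len(comp$no)) {
    nodes_sub <- which(comp$membership == cid)
    nodes_full <- thin[nodes_sub]
    # termini: farthest pair within the component (weighted diameter)
    s2 <- igraph::induced_subgraph(sub, nodes_sub)
    dpath <- igraph::get_diameter(s2, weights = igraph::E(s2)$weight)
    path_full <- nodes_full[as.integer(dpath)]
    if (length(path_full) < 2) next
    coords <- x$nodes[path_full, , drop = FALSE]
    len <- sum(sqrt(rowSums(diff(coords)^2)))
    if (len < l_min) next
    # a terminus "attaches" if some original edge links it to a body node
    attach <- vapply(path_full[c(1, length(path_full))], function(v) {
      nb <- igraph::neighbors(g, v)
      any(diam[as.integer(nb)] > d_max)
    }, logical(1))
    if (!any(attach)) next
    status <- if (all(attach)) "connecting" else "free_ended"
    mm <- measure_nanotunnel(coords, diam[path_full],
                             membrane_correction)
    rows[[length(rows) + 1L]] <- data.frame(
      organelle_id = 1L, nanotunnel_id = length(rows) + 1L,
      length_nm = mm$length_nm, d_ext_min_nm = mm$d_ext_min_nm,
      d_ext_max_nm = mm$d_ext_max_nm, lumen_min_nm = mm$lumen_min_nm,
      lumen_clamped = mm$lumen_clamped, end_status = status)
    cls[[length(cls) + 1L]] <- coords
  }
  if (length(rows)) out <- do.call(rbind, rows)
  attr(out, "centerlines") <- cls
  class(out) <- c("nanotunnel_set", "data.frame")
  out
}

#' Measure one nanotunnel
#'
#' Length is the centerline arc length; diameter extremes are taken over
#' the external diameter profile; the minimum matrix lumen subtracts the
#' double-membrane correction from the minimum external diameter.
#'
#' @param centerline n x 3 matrix of centerline points (nm).
#' @param profile external diameter (nm) at each centerline point.
#' @param membrane_correction nm subtracted from the minimal external
#'   diameter (default 24: 2 nm OMM + 2 nm IMM + 8 nm intermembrane
#'   space, on both sides).
#' @param interior optional logical mask over centerline points: only
#'   these enter the diameter extremes (length always uses the full
#'   centerline).
#' @return list with `length_nm`, `d_ext_min_nm`, `d_ext_max_nm`,
#'   `lumen_min_nm`, `lumen_clamped`.
#' @export
measure_nanotunnel <- function(centerline, profile,
                               membrane_correction = 24,
                               interior = NULL) {
  centerline <- as.matrix(centerline)
  stopifnot(nrow(centerline) == length(profile), nrow(centerline) >= 2)
  len <- sum(sqrt(rowSums(diff(centerline)^2)))
  prof <- if (is.null(interior)) profile else profile[interior]
  dmin <- min(prof); dmax <- max(prof)
  if (len <= 0 || dmin <= 0)
    stop("degenerate nanotunnel measurement", call. = FALSE)
  lum <- estimate_lumen(dmin, membrane_correction)
  list(length_nm = len, d_ext_min_nm = dmin, d_ext_max_nm = dmax,
       lumen_min_nm = lum, lumen_clamped = lum == 0)
}

#' Estimated matrix lumen diameter
#'
#' `max(d_ext_min - correction, 0)`: the external diameter minus two
#' membranes plus intermembrane space on each side (default 24 nm total).
#' Negative estimates clamp to zero.
#'
#' @param d_ext_min minimal external diameter(s), nm.
#' @param membrane_correction nm, default 24.
#' @return lumen diameter(s), nm.
#' @examples
#' estimate_lumen(c(26.1, 204.2))  # 2.1 and 180.2 nm
#' @export
estimate_lumen <- function(d_ext_min, membrane_correction = 24) {
  if (any(d_ext_min <= 0)) stop("diameters must be positive",
                                call. = FALSE)
  pmax(d_ext_min - membrane_correction, 0)
}

#' Nanotunnel frequency per 100 mitochondria
#'
#' @param n_nanotunnels count of nanotunnels.
#' @param n_mitochondria number of mitochondria surveyed (>= 1).
#' @return `100 * n_nanotunnels / n_mitochondria`.
#' @export
nanotunnel_frequency <- function(n_nanotunnels, n_mitochondria) {
  if (any(n_mitochondria < 1))
    stop("`n_mitochondria` must be >= 1", call. = FALSE)
  100 * n_nanotunnels / n_mitochondria
}

#' Fraction of nanotunnels passable by an mtDNA nucleoid
#'
#' Fraction of lumen diameters strictly greater than the nucleoid size
#' (~110 nm), the structural bound for nucleoid transit.
#'
#' @param lumens lumen diameters (nm), non-empty.
#' @param d_nuc nucleoid diameter (nm), default 110.
#' @return proportion in \[0, 1\].
#' @export
nucleoid_passable_fraction <- function(lumens, d_nuc = 110) {
  if (length(lumens) == 0) stop("no lumens supplied", call. = FALSE)
  mean(lumens > d_nuc)
}
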