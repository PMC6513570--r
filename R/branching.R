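#' Branch counts for the mitochondrial branching index
#'
#' The MBI scores branching anisotropy of an organelle relative to the
#' muscle fiber: transverse branching is counted as the number of
#' myofibrils bridged, longitudinal branching as the sarcomeres, half
#' sarcomeres and z-bands traversed. Counts come from annotation (as
#' scored against visible myofibrils and z-bands) or, approximately, from
#' skeleton geometry ([branch_counts_geometric()]).
#'
#' @param myofibrils_bridged,sarcomeres,half_sarcomeres,z_bands
#'   non-negative integer counts.
#' @return An object of class `branch_counts`.
#' @export
branch_counts <- function(myofibrils_bridged = 0, sarcomeres = 0,
                          half_sarcomeres = 0, z_bands = 0) {
  v <- c(myofibrils_bridged = myofibrils_bridged, sarcomeres = sarcomeres,
         half_sarcomeres = half_sarcomeres, z_bands = z_bands)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("branch counts must be non-negative integers", call. = FALSE)
  structure(as.list(as.integer(v)), names = names(v),
            class = "branch_counts")
}

#' Mitochondrial branching index from counts
#'
#' Transverse branching indicator `tbi = myofibrils_bridged + 1`;
#' longitudinal branching indicator
#' `lbi = 2*sarcomeres + half_sarcomeres + z_bands + 1`;
#' `MBI = tbi / lbi`. Classification is by exact integer comparison, so
#' there is no floating-point ambiguity at MBI = 1: `transverse` if
#' `tbi > lbi`, `equal` if `tbi == lbi`, `longitudinal` if `tbi < lbi`.
#' An unbranched organelle (all counts zero) scores MBI = 1.
#'
#' @param counts a [branch_counts()] (or list with its fields).
#' @return List of class `mbi_result`: `tbi`, `lbi` (integers), `mbi`
#'   (numeric ratio) and `mbi_class`.
#' @examples
#' mbi_from_counts(branch_counts(3, 0, 1, 1))  # tbi 4 / lbi 3, transverse
#' @export
mbi_from_counts <- function(counts) {
  if (!inherits(counts, "branch_counts"))
    counts <- do.call(branch_counts, as.list(counts))
  tbi <- counts$myofibrils_bridged + 1L
  lbi <- 2L * counts$sarcomeres + counts$half_sarcomeres +
    counts$z_bands + 1L
  cls <- if (tbi > lbi) "transverse" else if (tbi == lbi) "equal" else
    "longitudinal"
  structure(list(tbi = tbi, lbi = lbi, mbi = tbi / lbi, mbi_class = cls),
            class = "mbi_result")
}

#' @export
print.mbi_result <- function(x, ...) {
  cat(sprintf("<mbi_result> MBI = %d/%d = %.3f (%s)\n",
              x$tbi, x$lbi, x$mbi, x$mbi_class))
  invisible(x)
}

#' Skeleton graph of an organelle
#'
#' Centerline graph in physical nm: node coordinates, edges (centerline
#' segments) and optionally a per-node local radius. The graph must be
#' connected (one organelle) and edges must have positive arc length.
#'
#' @param nodes numeric n x 3 matrix (nm).
#' @param edges integer m x 2 matrix of node indices.
#' @param radius optional per-node local radius (nm).
#' @return An object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, edges, radius = NULL) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 3) stop("nodes must be n x 3", call. = FALSE)
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  if (nrow(edges) > 0) {
    if (min(edges) < 1 || max(edges) > nrow(nodes))
      stop("edge indices out of range", call. = FALSE)
    len <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                           nodes[edges[, 2], , drop = FALSE])^2))
    if (any(len <= 0)) stop("zero-length skeleton edge", call. = FALSE)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < nrow(nodes))
      g <- igraph::add_vertices(g, nrow(nodes) - igraph::vcount(g))
    if (igraph::components(g)$no > 1)
      stop("skeleton graph must be connected", call. = FALSE)
  } else if (nrow(nodes) > 1) {
    stop("skeleton graph must be connected", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, radius = radius),
            class = "skeleton_graph")
}

axis_index <- function(axis) match(match.arg(axis, c("x", "y", "z")),
                                   c("x", "y", "z"))

skeleton_extent <- function(skel, axis_i) {
  if (nrow(skel$nodes) == 0) return(0)
  diff(range(skel$nodes[, axis_i]))
}

#' Approximate branch counts from skeleton geometry
#'
#' Geometric stand-in for annotation-based counting, against a regular
#' myofibril lattice: myofibrils bridged is the transverse extent in units
#' of the myofibril width, taking the larger of the two transverse
#' directions (when branching differs between sides the greater value
#' counts); full and half sarcomeres come from the longitudinal extent in
#' units of the sarcomere length. When z-band plane positions are supplied
#' the z-band planes crossed beyond the organelle's home plane (the plane
#' nearest its centroid) are counted once each, minus those already
#' accounted for by counted sarcomeres/half sarcomeres; without them
#' z-band counts are zero and the result is flagged approximate.
#'
#' @param skel a [skeleton_graph()].
#' @param fiber_axis longitudinal axis, `"x"`, `"y"` or `"z"`.
#' @param myofibril_width nm, default 1000.
#' @param sarcomere_length nm, default 2000.
#' @param zband_positions numeric, z-band plane coordinates (nm) along the
#'   fiber axis, or `NULL`.
#' @return A [branch_counts()] with attribute `approximate`.
#' @export
branch_counts_geometric <- function(skel, fiber_axis = "z",
                                    myofibril_width = 1000,
                                    sarcomere_length = 2000,
                                    zband_positions = NULL) {
  stopifnot(inherits(skel, "skeleton_graph"),
            myofibril_width > 0, sarcomere_length > 0)
  li <- axis_index(fiber_axis)
  ti <- setdiff(1:3, li)
  eps <- 1e-9
  ext_t <- max(skeleton_extent(skel, ti[1]), skeleton_extent(skel, ti[2]))
  ext_l <- skeleton_extent(skel, li)
  myo <- floor(ext_t / myofibril_width + eps)
  sarc <- floor(ext_l / sarcomere_length + eps)
  half <- as.integer((ext_l - sarc * sarcomere_length) >=
                       sarcomere_length / 2 - eps)
  zb <- 0L
  approx <- is.null(zband_positions)
  if (!approx && nrow(skel$nodes) > 0) {
    zr <- range(skel$nodes[, li])
    cen <- mean(skel$nodes[, li])
    home <- zband_positions[which.min(abs(zband_positions - cen))]
    crossed <- sum(zband_positions >= zr[1] - eps &
                     zband_positions <= zr[2] + eps &
                     zband_positions != home)
    zb <- max(0L, crossed - 2L * sarc - half)
  }
  out <- branch_counts(myo, sarc, half, zb)
  attr(out, "approximate") <- approx
  out
}

#' Does an organelle span a full sarcomere?
#'
#' `TRUE` when the skeleton's longitudinal extent is at least the
#' sarcomere length (inclusive at the boundary: an extent exactly equal to
#' the sarcomere length spans it).
#'
#' @inheritParams branch_counts_geometric
#' @return logical.
#' @export
spans_sarcomere <- function(skel, sarcomere_length = 2000,
                            fiber_axis = "z") {
  stopifnot(inherits(skel, "skeleton_graph"))
  skeleton_extent(skel, axis_index(fiber_axis)) >=
    sarcomere_length - 1e-9
}

#' MBI class proportions of a population
#'
#' @param x character vector of MBI classes, a list of
#'   [mbi_from_counts()] results, or a data.frame with an `mbi_class`
#'   column.
#' @return Named proportions `(transverse, equal, longitudinal)` summing
#'   to 1, with attribute `n`. Cross-cohort comparison of these
#'   proportions is a contingency test; see [chi_square_proportions()].
#' @export
classify_mbi_population <- function(x) {
  cls <- if (is.data.frame(x)) x$mbi_class
  else if (is.list(x) && length(x) && inherits(x[[1]], "mbi_result"))
    vapply(x, `[[`, character(1), "mbi_class")
  else as.character(x)
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) stop("no MBI classes supplied", call. = FALSE)
  lv <- c("transverse", "equal", "longitudinal")
  if (!all(cls %in% lv)) stop("invalid MBI class label", call. = FALSE)
  p <- table(factor(cls, levels = lv)) / length(cls)
  structure(as.vector(p), names = lv, n = length(cls))
}
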