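# Connectome point-cloud geometry: PCA projection plane perpendicular to a
# transmedullary neuron's axis, convex-hull area of projected presynaptic
# sites, and column span normalized by the medulla column pitch.

#' Synapse point cloud
#'
#' @param points Numeric matrix `[n, 3]` of XYZ coordinates in micrometres.
#' @param labels Optional per-point presynaptic partner labels.
#' @return An object of class `synapse_cloud`.
#' @export
synapse_cloud <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || any(!is.finite(points))) {
    stop_invalid("'points' must be a finite [n, 3] coordinate matrix")
  }
  if (!is.null(labels) && length(labels) != nrow(points)) {
    stop_invalid("'labels' must have one entry per point")
  }
  structure(list(points = points, labels = labels), class = "synapse_cloud")
}

#' @export
print.synapse_cloud <- function(x, ...) {
  cat(sprintf("Synapse cloud: %d points%s\n", nrow(x$points),
              if (is.null(x$labels)) "" else
                sprintf(", %d partner labels", length(unique(x$labels)))))
  invisible(x)
}

# Deterministic eigenvector sign: positive dot product with +z, falling back
# to +y then +x for vectors orthogonal to the earlier axes.
canonical_sign <- function(v) {
  for (ref in list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))) {
    d <- sum(v * ref)
    if (abs(d) > 1e-12) return(v * sign(d))
  }
  v
}

#' Projection plane perpendicular to a neuron's principal axis
#'
#' The neuron's transmedullary axis is the leading principal component of its
#' presynaptic-site coordinates; the second and third components span the
#' perpendicular plane. Eigenvector signs are canonicalized (positive dot
#' product with +z, then +y, +x) so the basis is reproducible.
#'
#' @param reference_cloud A [synapse_cloud()] with >= 3 points and a
#'   non-degenerate covariance.
#' @return List with `axis` (unit vector), `basis` (3 x 2 matrix of in-plane
#'   unit vectors), `center` (centroid) and `sdev` (PCA standard deviations).
#' @export
projection_plane <- function(reference_cloud) {
  stopifnot(inherits(reference_cloud, "synapse_cloud"))
  pts <- reference_cloud$points
  if (nrow(pts) < 3) stop_invalid("need >= 3 points for a projection plane")
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-9 * max(pc$sdev[1], 1e-300)) {
    stop_invalid("degenerate geometry: points are (near) collinear")
  }
  axis <- canonical_sign(pc$rotation[, 1])
  basis <- cbind(canonical_sign(pc$rotation[, 2]),
                 canonical_sign(pc$rotation[, 3]))
  list(axis = axis, basis = basis, center = colMeans(pts), sdev = pc$sdev)
}

# Shoelace area of a polygon given by vertex indices into 2-D points.
polygon_area <- function(p2) {
  n <- nrow(p2)
  if (n < 3) return(0)
  x <- p2[, 1]; y <- p2[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Hull area and column span of a projected partner cloud
#'
#' Projects a presynaptic partner's synapse coordinates onto the plane
#' perpendicular to the reference neuron's axis; the covered area is the
#' 2-D convex-hull area, the maximal extent the largest pairwise projected
#' distance (over all points; hull vertices give the same value), and the
#' column span that extent divided by the medulla column pitch (11.2 um).
#'
#' @param partner_cloud A [synapse_cloud()].
#' @param plane Result of [projection_plane()].
#' @param column_pitch Column diameter in micrometres (default 11.2).
#' @return List with `area` (um^2), `max_extent` (um), `column_span`
#'   (columns) and the projected coordinates.
#' @export
hull_metrics <- function(partner_cloud, plane, column_pitch = 11.2) {
  stopifnot(inherits(partner_cloud, "synapse_cloud"))
  check_number(column_pitch, "column_pitch", lower = 1e-12)
  pts <- partner_cloud$points
  if (nrow(pts) < 2) stop_invalid("need >= 2 points for span metrics")
  proj <- sweep(pts, 2, plane$center) %*% plane$basis
  max_extent <- max(stats::dist(proj))
  area <- if (nrow(proj) >= 3) {
    h <- grDevices::chull(proj)
    polygon_area(proj[h, , drop = FALSE])
  } else 0
  list(area = area, max_extent = max_extent,
       column_span = max_extent / column_pitch, projected = proj)
}

#' Read a synapse cloud from CSV
#'
#' Expects columns `x`, `y`, `z` and optionally `label`.
#'
#' @param path CSV file path.
#' @return A [synapse_cloud()].
#' @export
read_synapse_cloud <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(tab))) stop_invalid("CSV needs columns x, y, z")
  synapse_cloud(as.matrix(tab[, need]), tab$label)
}
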