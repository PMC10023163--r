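#' Cluster geometry along the inter-centre axis
#'
#' The geometry convention used throughout: each probe's cluster is reduced to
#' its centre of mass; an axis is drawn from the origin probe's centre to the
#' target probe's centre; every localization is collapsed onto that axis as a
#' signed scalar coordinate with the origin centre at 0. Spread statistics
#' (binned profiles, the 95 percent-interval "diameter") are computed on those
#' signed axial coordinates. Bins are 33 nm wide to match the electron
#' microscopy section thickness.
#'
#' @name clustergeom
NULL

.as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_nm", "y_nm") %in% names(points)))
      return(cbind(points$x_nm, points$y_nm))
    points <- as.matrix(points)
  }
  stopifnot(is.matrix(points), ncol(points) >= 2)
  points[, 1:2, drop = FALSE]
}

#' Centre of mass of a point set
#'
#' Unweighted arithmetic mean of the coordinates.
#'
#' @param points matrix or data frame of 2D points (columns `x_nm`, `y_nm` or
#'   first two columns).
#' @return numeric length-2 vector `(x, y)` in nm.
#' @export
center_of_mass <- function(points) {
  xy <- .as_xy(points)
  if (!nrow(xy)) stop("cannot take the centre of an empty point set",
                      call. = FALSE)
  c(x = mean(xy[, 1]), y = mean(xy[, 2]))
}

#' Project two clusters onto their centre-to-centre axis
#'
#' The axis is the unit vector from the origin cluster's centre to the target
#' cluster's centre. Every localization of both probes gets a signed axial
#' coordinate: the scalar projection of (point - origin centre) onto the
#' axis. The origin centre maps to 0 and the target centre to the (positive)
#' centre separation.
#'
#' @param origin_cluster,target_cluster point sets (see [center_of_mass()]).
#' @return list with `axis` (unit vector), `origin_center`, `target_center`,
#'   `center_distance` (nm), `origin_axial`, `target_axial` (signed nm).
#' @export
axial_projection <- function(origin_cluster, target_cluster) {
  o <- .as_xy(origin_cluster)
  t <- .as_xy(target_cluster)
  if (!nrow(o) || !nrow(t)) stop("both clusters must be non-empty",
                                 call. = FALSE)
  co <- c(mean(o[, 1]), mean(o[, 2]))
  ct <- c(mean(t[, 1]), mean(t[, 2]))
  v <- ct - co
  d <- sqrt(sum(v^2))
  if (d == 0)
    stop("cluster centres coincide; no axis is defined - choose a fixed ",
         "axis explicitly for this degenerate pair", call. = FALSE)
  u <- v / d
  list(axis = u, origin_center = co, target_center = ct, center_distance = d,
       origin_axial = (o[, 1] - co[1]) * u[1] + (o[, 2] - co[2]) * u[2],
       target_axial = (t[, 1] - co[1]) * u[1] + (t[, 2] - co[2]) * u[2])
}

#' Binned fraction profile of axial coordinates
#'
#' Half-open bins `[k*bin, (k+1)*bin)` on the signed axis, edges anchored at
#' 0 (the origin centre). Fractions sum to 1.
#'
#' @param axial signed axial coordinates, nm.
#' @param bin bin width in nm, default 33.
#' @return data frame with `bin_lo_nm`, `bin_hi_nm`, `count`, `fraction`.
#' @export
binned_profile <- function(axial, bin = 33) {
  stopifnot(length(axial) >= 1, bin > 0)
  k <- floor(axial / bin)
  ks <- seq(min(k), max(k))
  cnt <- tabulate(k - min(k) + 1L, nbins = length(ks))
  data.frame(bin_lo_nm = ks * bin, bin_hi_nm = (ks + 1) * bin,
             count = cnt, fraction = cnt / length(axial))
}

#' Cluster diameter as the central 95 percent interval
#'
#' The diameter of a cluster is the width of the central 95 percent interval
#' of its localizations' signed axial coordinates about the cluster's own
#' centre: the 97.5th minus the 2.5th percentile, percentiles by linear
#' interpolation between order statistics. A spread measure, so it is 0 iff
#' all coordinates are equal and scales linearly with the point cloud.
#'
#' @param axial signed axial coordinates of one probe about its own centre.
#' @return diameter in nm.
#' @export
cluster_diameter <- function(axial) {
  if (length(axial) < 2)
    stop("cluster diameter needs at least 2 localizations", call. = FALSE)
  q <- stats::quantile(axial, c(0.025, 0.975), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Fraction of target localizations inside an interval on the shared axis
#'
#' Used to ask how much of one probe falls within another probe's cluster:
#' the interval is normally the origin probe's central 95 percent interval on
#' the shared axis. Inclusive at both ends.
#'
#' @param target_axial signed axial coordinates of the target probe.
#' @param interval numeric length-2 `(lo, hi)` nm, `lo < hi`.
#' @return fraction in `[0, 1]`.
#' @export
fraction_within <- function(target_axial, interval) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  if (!length(target_axial)) return(0)
  mean(target_axial >= interval[1] & target_axial <= interval[2])
}

#' Detect probe clusters along a nerve cord
#'
#' One-dimensional density clustering along the cord's principal axis: the
#' probe's localizations are projected onto the first principal component,
#' sorted, and split wherever consecutive localizations are more than
#' `gap_nm` apart; runs of at least `min_size` localizations are clusters.
#' Returns the 2D cluster centres ordered along the cord, consecutive-centre
#' spacings and a clusters-per-micron density over the spanned length.
#'
#' @param locs a `loc_set`.
#' @param probe probe label to cluster.
#' @param gap_nm linking distance along the axis, default 250.
#' @param min_size minimum localizations per cluster, default 20.
#' @return list with `centers` (data frame: `cluster_id`, `x_nm`, `y_nm`,
#'   `axial_nm`, `n`), `spacing_um` (consecutive centre spacings),
#'   `density_per_um` ((n-1)/span; `NA` and flagged when fewer than 2
#'   clusters) and `axis` (cord unit vector).
#' @export
detect_cord_clusters <- function(locs, probe, gap_nm = 250, min_size = 20) {
  pts <- locs[locs$probe == probe, , drop = FALSE]
  empty <- list(centers = data.frame(cluster_id = integer(), x_nm = numeric(),
                                     y_nm = numeric(), axial_nm = numeric(),
                                     n = integer()),
                spacing_um = numeric(), density_per_um = NA_real_,
                axis = c(NA_real_, NA_real_))
  if (nrow(pts) < min_size) {
    warning("fewer than ", min_size, " localizations for probe '", probe, "'")
    return(empty)
  }
  xy <- cbind(pts$x_nm, pts$y_nm)
  pc <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  u <- pc$rotation[, 1]
  proj <- as.numeric(scale(xy, center = TRUE, scale = FALSE) %*% u)
  o <- order(proj)
  gaps <- which(diff(proj[o]) > gap_nm)
  starts <- c(1L, gaps + 1L)
  ends <- c(gaps, length(proj))
  rows <- lapply(seq_along(starts), function(i) {
    idx <- o[starts[i]:ends[i]]
    if (length(idx) < min_size) return(NULL)
    data.frame(x_nm = mean(xy[idx, 1]), y_nm = mean(xy[idx, 2]),
               axial_nm = mean(proj[idx]), n = length(idx))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || !nrow(rows)) {
    warning("no cluster of >= ", min_size, " localizations for probe '",
            probe, "'")
    return(empty)
  }
  rows <- rows[order(rows$axial_nm), , drop = FALSE]
  rows <- cbind(cluster_id = seq_len(nrow(rows)), rows)
  rownames(rows) <- NULL
  spacing <- diff(rows$axial_nm) / 1000
  span_um <- (max(rows$axial_nm) - min(rows$axial_nm)) / 1000
  dens <- if (nrow(rows) >= 2) (nrow(rows) - 1) / span_um else NA_real_
  list(centers = rows, spacing_um = spacing, density_per_um = dens, axis = u)
}
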