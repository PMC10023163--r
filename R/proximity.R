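#' Nearest-neighbour colocalization between probe point sets
#'
#' For every localization of a source probe, the Euclidean 2D distance to the
#' closest localization of a target probe; the headline statistic is the
#' fraction of source localizations with a target neighbour within 100 nm.
#' The relation is asymmetric by design (source to target differs from target
#' to source). Distances are computed within a synapse ROI and pooled across
#' synapses for reporting.
#'
#' @name proximity
NULL

# grid-accelerated first-nearest-neighbour search; ring expansion guarantees
# exactness because the search only stops once the best distance cannot be
# beaten by any unexamined cell
.grid_nn <- function(src, tgt, cell) {
  m <- nrow(tgt)
  gx <- floor(tgt[, 1] / cell); gy <- floor(tgt[, 2] / cell)
  key <- paste(gx, gy)
  buckets <- split(seq_len(m), key)
  bx <- range(tgt[, 1]); by <- range(tgt[, 2])
  diag_bbox <- sqrt(diff(bx)^2 + diff(by)^2)
  max_ring <- ceiling(diag_bbox / cell) + 2L
  out <- numeric(nrow(src))
  for (i in seq_len(nrow(src))) {
    # a source far outside the target cloud would walk many empty rings;
    # one vectorized scan over all targets is cheaper and exact
    dx <- max(0, bx[1] - src[i, 1], src[i, 1] - bx[2])
    dy <- max(0, by[1] - src[i, 2], src[i, 2] - by[2])
    if (sqrt(dx^2 + dy^2) > 2 * cell) {
      out[i] <- sqrt(min((tgt[, 1] - src[i, 1])^2 +
                           (tgt[, 2] - src[i, 2])^2))
      next
    }
    cx <- floor(src[i, 1] / cell); cy <- floor(src[i, 2] / cell)
    best <- Inf
    for (r in 0:max_ring) {
      # any point in a cell of Chebyshev ring > r is at least (r)*cell away
      if (best <= (r - 1) * cell && r > 0) break
      if (r == 0) {
        keys <- paste(cx, cy)
      } else {
        xs <- (cx - r):(cx + r)
        keys <- c(paste(xs, cy - r), paste(xs, cy + r),
                  paste(cx - r, (cy - r + 1):(cy + r - 1)),
                  paste(cx + r, (cy - r + 1):(cy + r - 1)))
      }
      idx <- unlist(buckets[keys], use.names = FALSE)
      if (length(idx)) {
        d2 <- (tgt[idx, 1] - src[i, 1])^2 + (tgt[idx, 2] - src[i, 2])^2
        best <- min(best, min(d2)^0.5)
      }
    }
    out[i] <- best
  }
  out
}

#' First-nearest-neighbour distances from source to target
#'
#' @param source,target point sets (matrix or data frame with `x_nm`, `y_nm`).
#' @return numeric vector, one distance (nm) per source localization.
#' @export
nn_distances <- function(source, target) {
  src <- .as_xy(source)
  tgt <- .as_xy(target)
  if (!nrow(src)) stop("empty source point set", call. = FALSE)
  if (!nrow(tgt)) stop("empty target point set", call. = FALSE)
  span <- max(diff(range(tgt[, 1])), diff(range(tgt[, 2])), 1)
  cell <- max(span / max(1, ceiling(sqrt(nrow(tgt)))), 1e-6)
  .grid_nn(src, tgt, cell)
}

#' Fraction of distances within a threshold
#'
#' Inclusive comparison `d <= threshold`.
#'
#' @param distances nearest-neighbour distances, nm.
#' @param threshold nm, default 100.
#' @return fraction in `[0, 1]`.
#' @export
fraction_within_threshold <- function(distances, threshold = 100) {
  stopifnot(length(distances) >= 1)
  mean(distances <= threshold)
}

#' Nearest-neighbour summary for a probe pair over synapse ROIs
#'
#' Runs [nn_distances()] within each ROI and pools the per-localization
#' distances across synapses for the headline fraction.
#'
#' @param rois list of `synapse_roi` objects from [segment_rois()].
#' @param source_probe,target_probe probe labels.
#' @param threshold nm, default 100.
#' @return list with `distances` (data frame: `roi_id`, `distance_nm`),
#'   `fraction_within` (pooled), `per_roi` (data frame of per-synapse
#'   fractions) and `threshold`.
#' @export
nn_summary <- function(rois, source_probe, target_probe, threshold = 100) {
  res <- lapply(rois, function(roi) {
    s <- roi$members[roi$members$probe == source_probe, , drop = FALSE]
    t <- roi$members[roi$members$probe == target_probe, , drop = FALSE]
    if (!nrow(s) || !nrow(t)) return(NULL)
    data.frame(roi_id = roi$roi_id, distance_nm = nn_distances(s, t))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || !nrow(res))
    return(list(distances = data.frame(roi_id = integer(),
                                       distance_nm = numeric()),
                fraction_within = NA_real_, per_roi = NULL,
                threshold = threshold))
  per <- stats::aggregate(distance_nm ~ roi_id, res,
                          function(d) mean(d <= threshold))
  names(per)[2] <- "fraction_within"
  list(distances = res,
       fraction_within = fraction_within_threshold(res$distance_nm, threshold),
       per_roi = per, threshold = threshold)
}
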