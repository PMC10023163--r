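#' Channel counting from blink statistics
#'
#' A single fluorophore blinks a few times during an imaging session, so the
#' number of blinks at a synapse overestimates the number of channels.
#' Counting proceeds by (i) grouping blinks that lie within 60 nm of each
#' other into putative single channels (density clustering; singlet blinks
#' are channels too), (ii) fitting a Poisson mean m to blinks-per-channel,
#' and then estimating channel counts per synapse by three routes: total
#' blinks / m, total photons / mean photons per channel, and total blinks /
#' (blink rate x duration). Circle packing gives geometric capacity bounds
#' for channels in a dense cluster.
#'
#' @name chancount
NULL

# eps-neighbourhood lists via a bucket grid (cell size = eps, so neighbours
# of a point can only lie in the surrounding 3 x 3 cells)
.eps_neighbors <- function(xy, eps) {
  n <- nrow(xy)
  gx <- floor(xy[, 1] / eps); gy <- floor(xy[, 2] / eps)
  buckets <- split(seq_len(n), paste(gx, gy))
  nbr <- vector("list", n)
  eps2 <- eps^2
  for (i in seq_len(n)) {
    keys <- paste(rep(gx[i] + (-1:1), each = 3), gy[i] + (-1:1))
    cand <- unlist(buckets[keys], use.names = FALSE)
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    nbr[[i]] <- cand[d2 <= eps2 & cand != i]
  }
  nbr
}

#' Group blinks into putative channels
#'
#' Density clustering (DBSCAN) with radius `eps` and core threshold
#' `min_pts`: points with at least `min_pts` neighbours within `eps`
#' (counting themselves) are cores; clusters are grown through cores, border
#' points join the first reachable cluster. Noise points -- blinks with no
#' neighbour, at the default `min_pts = 2` -- are promoted to singleton
#' groups, since a lone blink is still a channel. At `min_pts = 2` the result
#' equals the connected components of the eps-neighbourhood graph and is
#' independent of input order.
#'
#' @param locs a `loc_set` (precision-filtered), or a 2-column matrix.
#' @param eps grouping radius in nm, default 60.
#' @param min_pts core threshold, default 2.
#' @return data frame of groups: `group_id`, `blink_count`, `x_nm`, `y_nm`
#'   (centroid), `photon_sum` (NA without a photons column), `is_singlet`;
#'   the per-blink group assignment is attached as attribute `membership`.
#' @export
group_blinks <- function(locs, eps = 60, min_pts = 2) {
  xy <- .as_xy(locs)
  photons <- if (is.data.frame(locs) && !is.null(locs$photons))
    locs$photons else rep(NA_real_, nrow(xy))
  n <- nrow(xy)
  if (n == 0) {
    out <- data.frame(group_id = integer(), blink_count = integer(),
                      x_nm = numeric(), y_nm = numeric(),
                      photon_sum = numeric(), is_singlet = logical())
    attr(out, "membership") <- integer()
    return(out)
  }
  nbr <- .eps_neighbors(xy, eps)
  core <- lengths(nbr) + 1L >= min_pts
  lab <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cid <- cid + 1L
    queue <- i
    lab[i] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in nbr[[v]]) {
        if (lab[u] == 0L) {
          lab[u] <- cid
          if (core[u]) queue <- c(queue, u)
        }
      }
    }
  }
  for (i in which(lab == 0L)) {  # noise -> singleton channel
    cid <- cid + 1L
    lab[i] <- cid
  }
  out <- data.frame(
    group_id = seq_len(cid),
    blink_count = tabulate(lab, cid),
    x_nm = vapply(seq_len(cid), function(g) mean(xy[lab == g, 1]), numeric(1)),
    y_nm = vapply(seq_len(cid), function(g) mean(xy[lab == g, 2]), numeric(1)),
    photon_sum = vapply(seq_len(cid), function(g) sum(photons[lab == g]),
                        numeric(1)))
  out$is_singlet <- out$blink_count == 1L
  attr(out, "membership") <- lab
  out
}

#' Poisson mean of blinks per channel
#'
#' Maximum-likelihood Poisson mean on the observed per-group blink counts,
#' i.e. their sample mean (no zero-truncation correction: unobservable
#' silent channels are a generator concern, not an estimator one).
#'
#' @param blink_counts pooled per-group blink counts.
#' @return the fitted mean m.
#' @export
fit_blink_poisson <- function(blink_counts) {
  stopifnot(length(blink_counts) >= 1)
  mean(blink_counts)
}

#' Channel count from total blinks and the blink mean
#'
#' @param total_blinks per-synapse total blink count (vectorized).
#' @param m pooled blinks-per-channel mean, > 0.
#' @return estimated channels per synapse.
#' @export
estimate_by_blink_mean <- function(total_blinks, m) {
  if (!is.finite(m) || m <= 0) stop("blink mean must be positive",
                                    call. = FALSE)
  total_blinks / m
}

#' Channel count from total photons and the per-channel photon mean
#'
#' The divisor is the mean photons per grouped channel pooled across all
#' synapses of a condition (a per-synapse mean would make the ratio
#' degenerate).
#'
#' @param total_photons per-synapse photon total (vectorized).
#' @param mean_photons_per_channel pooled mean, > 0.
#' @return estimated channels per synapse.
#' @export
estimate_by_photon_flux <- function(total_photons, mean_photons_per_channel) {
  if (!is.finite(mean_photons_per_channel) || mean_photons_per_channel <= 0)
    stop("pooled photons-per-channel mean must be positive", call. = FALSE)
  total_photons / mean_photons_per_channel
}

#' Channel count from the dye blink rate
#'
#' Cyanine-type dyes in oxygen-scavenging buffer blink about six times per
#' minute, so total blinks / (rate x duration) bounds the channel count when
#' channels cannot be spatially resolved (the dense CaV2 cluster).
#'
#' @param total_blinks per-synapse total blink count (vectorized).
#' @param rate blinks per channel per minute, default 6.
#' @param duration_min imaging duration in minutes, default 1.
#' @return estimated channels per synapse.
#' @export
estimate_by_blink_rate <- function(total_blinks, rate = 6, duration_min = 1) {
  stopifnot(rate > 0, duration_min > 0)
  total_blinks / (rate * duration_min)
}

# histogram mode on fixed-width bins anchored at 0; returns the bin centre
.binned_mode <- function(x, width) {
  k <- floor(x / width)
  tab <- table(k)
  (as.numeric(names(tab)[which.max(tab)]) + 0.5) * width
}

#' Photon statistics per blink and per grouped channel
#'
#' Modes are computed on 50-photon bins (bin centre reported); means are
#' arithmetic.
#'
#' @param locs a `loc_set` with a `photons` column (the pooled blinks).
#' @param groups output of [group_blinks()] on those blinks.
#' @param bin_width histogram bin width for modes, default 50 photons.
#' @return list with `mode_per_blink`, `mean_per_blink`,
#'   `mean_per_channel`, `mode_per_channel`.
#' @export
photon_stats <- function(locs, groups, bin_width = 50) {
  stopifnot(nrow(locs) >= 1, !is.null(locs$photons))
  list(mode_per_blink = .binned_mode(locs$photons, bin_width),
       mean_per_blink = mean(locs$photons),
       mean_per_channel = mean(groups$photon_sum),
       mode_per_channel = .binned_mode(groups$photon_sum, bin_width))
}

#' Run the counting pipeline over a cohort of synapses
#'
#' Groups each synapse's blinks, pools the blink-count Poisson fit and the
#' photon-per-channel mean across synapses, and applies the three estimators.
#'
#' @param loc_sets list of `loc_set` objects, one synapse each.
#' @param eps,min_pts grouping parameters, see [group_blinks()].
#' @param blink_rate,duration_min blink-rate estimator parameters.
#' @return list with `per_synapse` (data frame: `synapse`, `total_blinks`,
#'   `n_groups`, `total_photons`, `est_blink_mean`, `est_photon_flux`,
#'   `est_blink_rate`) and `pooled` (list: `m`, `photons_per_blink_mode`,
#'   `photons_per_blink_mean`, `photons_per_channel_mean`,
#'   `photons_per_channel_mode`).
#' @export
count_channels <- function(loc_sets, eps = 60, min_pts = 2,
                           blink_rate = 6, duration_min = 1) {
  stopifnot(length(loc_sets) >= 1)
  groups <- lapply(loc_sets, group_blinks, eps = eps, min_pts = min_pts)
  counts <- unlist(lapply(groups, `[[`, "blink_count"))
  m <- fit_blink_poisson(counts)
  pooled_photon_mean <- mean(unlist(lapply(groups, `[[`, "photon_sum")))
  all_photons <- unlist(lapply(loc_sets, `[[`, "photons"))
  per <- data.frame(
    synapse = seq_along(loc_sets),
    total_blinks = vapply(loc_sets, nrow, numeric(1)),
    n_groups = vapply(groups, nrow, numeric(1)),
    total_photons = vapply(loc_sets, function(l) sum(l$photons), numeric(1)))
  per$est_blink_mean <- estimate_by_blink_mean(per$total_blinks, m)
  per$est_photon_flux <- estimate_by_photon_flux(per$total_photons,
                                                 pooled_photon_mean)
  per$est_blink_rate <- estimate_by_blink_rate(per$total_blinks, blink_rate,
                                               duration_min)
  list(per_synapse = per,
       pooled = list(
         m = m,
         photons_per_blink_mode = .binned_mode(all_photons, 50),
         photons_per_blink_mean = mean(all_photons),
         photons_per_channel_mean = pooled_photon_mean,
         photons_per_channel_mode =
           .binned_mode(unlist(lapply(groups, `[[`, "photon_sum")), 50)))
}

# circle packing --------------------------------------------------------------

# best-known (optimal for N <= 13, best published for 14-20) ratios of
# container diameter to circle diameter for N equal circles in a circle
.packing_ratios <- c(
  1, 2, 1 + 2 / sqrt(3), 1 + sqrt(2), 2.701301617,
  3, 3, 3.304764871, 3.613125930, 3.813898249,
  3.923804430, 4.029602305, 2 + sqrt(5), 4.328428546, 4.521356516,
  4.615425253, 4.792033930, 1 + sqrt(2) + sqrt(6), 1 + sqrt(2) + sqrt(6),
  5.122321437)

#' Circle-packing capacity of a cluster
#'
#' How many channels of a given footprint fit in a circular cluster.
#' `optimal_ratio` uses the published optimal packings of N equal circles in
#' a circle (N <= 20; proven optimal through 13, best known beyond): the
#' largest N whose container-to-circle diameter ratio does not exceed
#' `container_diameter / circle_diameter`. `hex_lattice` counts points of a
#' hexagonal lattice with spacing `circle_diameter`, one lattice point at the
#' container centre and fixed orientation, whose circles fit entirely inside
#' the container (centres within `(container - circle)/2`); a reproducible
#' construction rather than a search, appropriate for large N.
#'
#' @param container_diameter,circle_diameter nm.
#' @param method `"optimal_ratio"` (falls back to the lattice above N = 20)
#'   or `"hex_lattice"`.
#' @return integer capacity (0 when the circle exceeds the container).
#' @export
packing_bound <- function(container_diameter, circle_diameter,
                          method = c("optimal_ratio", "hex_lattice")) {
  method <- match.arg(method)
  stopifnot(container_diameter > 0, circle_diameter > 0)
  if (circle_diameter > container_diameter) return(0L)
  ratio <- container_diameter / circle_diameter
  if (method == "optimal_ratio") {
    fits <- which(.packing_ratios <= ratio + 1e-9)
    if (length(fits) && max(fits) < 20L) return(max(fits))
    # beyond the table, use the lattice construction (a lower bound)
    method <- "hex_lattice"
  }
  rmax <- (container_diameter - circle_diameter) / 2 + 1e-9
  d <- circle_diameter
  kmax <- floor(rmax / (d * sqrt(3) / 2))
  count <- 0L
  for (k in -kmax:kmax) {
    y <- k * d * sqrt(3) / 2
    half <- sqrt(rmax^2 - y^2)
    if (k %% 2 == 0) {
      count <- count + 2L * floor(half / d) + 1L
    } else {
      count <- count + 2L * floor(half / d + 0.5)
    }
  }
  as.integer(count)
}
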