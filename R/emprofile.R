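#' Docked-vesicle distance profiles and fusion estimates
#'
#' Flash-and-freeze electron microscopy captures docked vesicles (in contact
#' with the plasma membrane) at fixed delays after stimulation. The number of
#' vesicles that fused is the number of docked vesicles lost to stimulation:
#' per 33 nm distance bin from the dense projection, the mean docked count
#' per synapse without stimulation minus the mean with stimulation. Three
#' zones summarize the active zone: adjacent to the dense projection
#' (0-33 nm), intermediate (33-165 nm) and lateral (165-594 nm).
#'
#' @name emprofile
NULL

#' Per-synapse docked-vesicle histograms
#'
#' Half-open 33 nm bins `[k*33, (k+1)*33)` covering `[0, max_nm)`. Synapses
#' listed in the table's `synapses` attribute (or argument) but holding no
#' vesicles contribute rows of zeros, not absence. Negative distances are
#' rejected with a report.
#'
#' @param table vesicle distance table: data frame with `synapse_id` and
#'   `distance_nm` (e.g. from [simulate_vesicle_profiles()] or an annotation
#'   export).
#' @param bin bin width nm, default 33.
#' @param max_nm upper edge of the last bin, default 594 (= 18 bins).
#' @param synapses optional roster of synapse ids (so empty synapses count).
#' @return matrix of counts, one row per synapse, one column per bin
#'   (named by lower edge); attribute `n_rejected` counts dropped rows.
#' @export
bin_docked <- function(table, bin = 33, max_nm = 594, synapses = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(synapses)) synapses <- attr(table, "synapses")
  if (is.null(synapses)) synapses <- unique(table$synapse_id)
  if (!length(synapses)) stop("no synapses in table or roster", call. = FALSE)
  neg <- table$distance_nm < 0
  if (any(neg)) {
    warning(sum(neg), " negative distance(s) rejected")
    table <- table[!neg, , drop = FALSE]
  }
  nb <- ceiling(max_nm / bin)
  out <- matrix(0L, length(synapses), nb,
                dimnames = list(synapses, (seq_len(nb) - 1L) * bin))
  keep <- table$distance_nm < nb * bin
  k <- floor(table$distance_nm[keep] / bin) + 1L
  sid <- match(table$synapse_id[keep], synapses)
  for (i in seq_along(k)) out[sid[i], k[i]] <- out[sid[i], k[i]] + 1L
  attr(out, "n_rejected") <- sum(neg)
  out
}

#' Fusion profile: docked vesicles lost to stimulation, per bin
#'
#' Per-bin mean docked count across synapses within each condition (the
#' synapse is the statistical unit), the no-stim minus stim difference, and
#' per-condition SEMs. Negative differences (apparent docking increase) are
#' retained and flagged, never clipped.
#'
#' @param no_stim,stim per-synapse histogram matrices from [bin_docked()]
#'   with identical bin structure.
#' @return object of class `fusion_profile`: data frame with `bin_lo_nm`,
#'   `bin_hi_nm`, `mean_no_stim`, `sem_no_stim`, `mean_stim`, `sem_stim`,
#'   `fusion` (difference), `negative` flag; attributes `n_no_stim`,
#'   `n_stim`, `bin`.
#' @export
fusion_profile <- function(no_stim, stim) {
  stopifnot(ncol(no_stim) == ncol(stim), nrow(no_stim) >= 1, nrow(stim) >= 1)
  bin <- diff(as.numeric(colnames(no_stim)[1:2]))
  sem <- function(m) apply(m, 2, stats::sd) / sqrt(nrow(m))
  out <- data.frame(
    bin_lo_nm = as.numeric(colnames(no_stim)),
    bin_hi_nm = as.numeric(colnames(no_stim)) + bin,
    mean_no_stim = colMeans(no_stim), sem_no_stim = sem(no_stim),
    mean_stim = colMeans(stim), sem_stim = sem(stim))
  out$fusion <- out$mean_no_stim - out$mean_stim
  out$negative <- out$fusion < 0
  rownames(out) <- NULL
  structure(out, class = c("fusion_profile", "data.frame"),
            n_no_stim = nrow(no_stim), n_stim = nrow(stim), bin = bin)
}

#' Three-zone summary of a fusion profile
#'
#' Zone totals are sums of member-bin means; the release probability of a
#' zone is (no-stim total - stim total) / no-stim total, flagged undefined
#' when the zone holds no docked vesicles without stimulation.
#'
#' @param profile a `fusion_profile` whose bins cover the zones.
#' @param zone_edges upper edges of the zones in nm, default
#'   `c(33, 165, 594)`.
#' @return data frame with `zone`, `lo_nm`, `hi_nm`, `docked_no_stim`,
#'   `docked_stim`, `fusion`, `release_probability`, `undefined` flag.
#' @export
zone_summary <- function(profile, zone_edges = c(33, 165, 594)) {
  stopifnot(inherits(profile, "fusion_profile"))
  if (max(profile$bin_hi_nm) < max(zone_edges))
    stop("profile bins do not cover the outermost zone", call. = FALSE)
  lo <- c(0, zone_edges[-length(zone_edges)])
  out <- lapply(seq_along(zone_edges), function(z) {
    member <- profile$bin_lo_nm >= lo[z] & profile$bin_hi_nm <= zone_edges[z]
    ns <- sum(profile$mean_no_stim[member])
    st <- sum(profile$mean_stim[member])
    data.frame(zone = z, lo_nm = lo[z], hi_nm = zone_edges[z],
               docked_no_stim = ns, docked_stim = st, fusion = ns - st,
               release_probability = if (ns > 0) (ns - st) / ns else NA_real_,
               undefined = ns <= 0)
  })
  do.call(rbind, out)
}
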