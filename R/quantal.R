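#' Quantal decomposition of miniature-current amplitudes
#'
#' The modal amplitude of miniature postsynaptic currents is the
#' single-vesicle (one-quantum) response; simultaneous fusion of k vesicles
#' sums to roughly k times the mode. The amplitude histogram (1 pA bins) is
#' decomposed into a sum of Gaussian terms whose means are constrained to
#' k x mode +/- k pA while widths and amplitudes are free; the area under
#' each fitted term gives the fraction of events of each quantal class, and
#' 1 minus the single-quantum fraction is the multiquantal fraction.
#'
#' @name quantal
NULL

#' Amplitude histogram in 1 pA bins
#'
#' Half-open bins `[k, k+1)` anchored at 0. Non-positive amplitudes are
#' rejected and counted.
#'
#' @param amps amplitudes in pA.
#' @param bin bin width in pA, default 1.
#' @return object of class `amp_hist`: list with `breaks`, `mids`, `counts`,
#'   `n`, `n_rejected`, `bin`.
#' @export
amplitude_histogram <- function(amps, bin = 1) {
  bad <- !is.finite(amps) | amps <= 0
  n_rejected <- sum(bad)
  if (n_rejected)
    warning(n_rejected, " non-positive or non-finite amplitude(s) rejected")
  amps <- amps[!bad]
  if (!length(amps)) stop("no positive amplitudes to bin", call. = FALSE)
  breaks <- seq(0, (floor(max(amps) / bin) + 1) * bin, by = bin)
  counts <- tabulate(floor(amps / bin) + 1L, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, mids = breaks[-1] - bin / 2,
                 counts = counts, n = length(amps),
                 n_rejected = n_rejected, bin = bin),
            class = "amp_hist")
}

#' Modal amplitude of a histogram
#'
#' The lower edge of the highest-count bin (the convention behind integer
#' printed modes like "7 pA"); ties go to the lowest bin and are flagged.
#'
#' @param hist an `amp_hist`.
#' @return modal amplitude in pA, with attribute `ambiguous` when tied.
#' @export
modal_amplitude <- function(hist) {
  stopifnot(inherits(hist, "amp_hist"), length(hist$counts) >= 1)
  top <- which(hist$counts == max(hist$counts))
  structure(hist$breaks[top[1]], ambiguous = length(top) > 1)
}

#' Constrained multi-term Gaussian fit to an amplitude histogram
#'
#' Nonlinear least squares of `sum_k a_k exp(-(x - mu_k)^2 / (2 s_k^2))` on
#' the bin-centre/count pairs, with the term-k mean box-constrained to
#' `[k (mode - 1), k (mode + 1)]` (the "k x mode +/- k" rule: quanta sum, so
#' both the centre and its latitude scale with k), amplitudes non-negative
#' and widths positive but otherwise free. Nine deterministic starts (three
#' mean offsets x three width scales, ordered) are run and the best residual
#' kept, so the fit is reproducible.
#'
#' @param hist an `amp_hist`.
#' @param mode single-quantum modal amplitude in pA (> 0).
#' @param n_terms number of quantal terms, default 3.
#' @return object of class `quantal_fit`: list with `mode`, `means`, `sds`,
#'   `amplitudes`, `fractions` (trapezoid area fractions), `rss`, `n_terms`,
#'   `hist`.
#' @export
fit_quantal_gaussians <- function(hist, mode, n_terms = 3) {
  stopifnot(inherits(hist, "amp_hist"), mode > 0, n_terms >= 1)
  if (max(hist$breaks) < n_terms * mode)
    stop("histogram support does not span ", n_terms, " x mode; ",
         "fewer terms or more data needed", call. = FALSE)
  x <- hist$mids
  y <- hist$counts
  k <- seq_len(n_terms)
  model <- function(p, x) {
    a <- p[k]; mu <- p[n_terms + k]; s <- p[2 * n_terms + k]
    y_hat <- 0
    for (j in k) y_hat <- y_hat + a[j] * exp(-(x - mu[j])^2 / (2 * s[j]^2))
    y_hat
  }
  lower <- c(rep(0, n_terms), k * (mode - 1), rep(0.1, n_terms))
  upper <- c(rep(Inf, n_terms), k * (mode + 1), rep(Inf, n_terms))
  best <- NULL
  for (off in c(-0.5, 0, 0.5)) {
    for (sscale in c(0.5, 1, 2)) {
      mu0 <- pmin(pmax(k * mode + off * k, lower[n_terms + k]),
                  upper[n_terms + k])
      a0 <- vapply(mu0, function(m) max(y[which.min(abs(x - m))], 1),
                   numeric(1))
      p0 <- c(a0, mu0, pmax(sscale * k, 0.2))
      fit <- try(minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper,
        fn = function(p) y - model(p, x),
        control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
        best <- fit
    }
  }
  if (is.null(best))
    stop("constrained Gaussian fit failed to converge from all starts",
         call. = FALSE)
  p <- stats::coef(best)
  out <- structure(list(mode = mode, n_terms = n_terms,
                        amplitudes = unname(p[k]),
                        means = unname(p[n_terms + k]),
                        sds = unname(p[2 * n_terms + k]),
                        rss = stats::deviance(best), hist = hist),
                   class = "quantal_fit")
  out$fractions <- quantal_fractions(out)
  out
}

#' Per-term area fractions of a quantal fit
#'
#' Each fitted term is integrated by the trapezoid rule over the histogram
#' support at 0.1 pA resolution; fractions are areas over the total area.
#'
#' @param fit a `quantal_fit`.
#' @return numeric vector of fractions summing to 1.
#' @export
quantal_fractions <- function(fit) {
  stopifnot(inherits(fit, "quantal_fit"))
  xs <- seq(min(fit$hist$breaks), max(fit$hist$breaks), by = 0.1)
  areas <- vapply(seq_len(fit$n_terms), function(j) {
    pracma::trapz(xs, fit$amplitudes[j] *
                    exp(-(xs - fit$means[j])^2 / (2 * fit$sds[j]^2)))
  }, numeric(1))
  areas / sum(areas)
}

#' Multiquantal fraction
#'
#' One minus the single-quantum area fraction: the fraction of miniature
#' currents arising from simultaneous fusion of more than one vesicle.
#'
#' @param fractions per-term area fractions (term 1 first), or a
#'   `quantal_fit`.
#' @return fraction in `[0, 1]`.
#' @export
multiquantal_fraction <- function(fractions) {
  if (inherits(fractions, "quantal_fit")) fractions <- fractions$fractions
  stopifnot(length(fractions) >= 1, all(fractions >= -1e-9),
            abs(sum(fractions) - 1) < 1e-6)
  1 - fractions[1]
}

#' @export
print.quantal_fit <- function(x, ...) {
  cat(sprintf("quantal fit: %d terms on mode %.4g pA\n", x$n_terms, x$mode))
  cat("  means (pA):    ", paste(sprintf("%.2f", x$means), collapse = "  "), "\n")
  cat("  sds (pA):      ", paste(sprintf("%.2f", x$sds), collapse = "  "), "\n")
  cat("  area fractions:", paste(sprintf("%.3f", x$fractions), collapse = "  "), "\n")
  cat(sprintf("  RSS: %.4g\n", x$rss))
  invisible(x)
}
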