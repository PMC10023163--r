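# small fixture builders and independent oracles used across test files

make_locs <- function(x, y, probe = "X", photons = 500,
                      precision = 20, z = NULL, frame = NULL) {
  df <- data.frame(x_nm = x, y_nm = y,
                   photons = rep_len(photons, length(x)),
                   precision_nm = rep_len(precision, length(x)),
                   probe = rep_len(probe, length(x)))
  if (!is.null(z)) df$z_nm <- rep_len(z, length(x))
  if (!is.null(frame)) df$frame <- rep_len(frame, length(x))
  localization_set(df)
}

# a tight blob usable as a fiducial cluster
make_blob <- function(cx, cy, n = 30, sd = 20, probe = "ELKS") {
  make_locs(cx + seq(-sd, sd, length.out = n),
            cy + rep(c(-sd / 2, sd / 2), length.out = n), probe = probe)
}

# O(n^2) exhaustive nearest-neighbour oracle
brute_nn <- function(src, tgt) {
  apply(src, 1, function(p) sqrt(min((tgt[, 1] - p[1])^2 +
                                       (tgt[, 2] - p[2])^2)))
}

# eps-graph connected components by matrix flood fill (grouping oracle)
brute_components <- function(xy, eps) {
  n <- nrow(xy)
  adj <- as.matrix(stats::dist(xy)) <= eps
  comp <- integer(n); cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cid <- cid + 1L
    q <- i
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      q <- c(q, setdiff(nb, v))
    }
    comp[i] <- cid
  }
  comp
}

rotate_xy <- function(xy, theta, about = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(sweep(xy, 2, about) %*% t(R), 2, about, `+`)
}
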