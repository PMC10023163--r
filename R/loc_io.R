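#' Localization tables: reading, validation, filtering and synapse windows
#'
#' A localization set is a data frame with one row per blink (one detected
#' emission event of a single fluorophore) and the canonical columns
#' `x_nm`, `y_nm`, optional `z_nm`, `photons`, optional `frame`,
#' `precision_nm` (Cramer-Rao lower bound) and `probe`. All coordinates are
#' absolute nanometres in the camera frame. Vendor exports with other column
#' names or units are mapped onto this schema through a dialect (see
#' [loc_dialect()]).
#'
#' @name loc_io
NULL

.required_cols <- c("x_nm", "y_nm", "photons", "probe")
.numeric_cols <- c("x_nm", "y_nm", "z_nm", "photons", "frame", "precision_nm")

#' Construct and validate a localization set
#'
#' @param df data frame carrying at least `x_nm`, `y_nm`, `photons`, `probe`.
#' @param palette optional character vector of allowed probe labels; if given,
#'   any probe outside the palette is an error.
#' @return the validated data frame with class `loc_set`.
#' @export
localization_set <- function(df, palette = NULL) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.required_cols, names(df))
  if (length(missing))
    stop("localization table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (cl in intersect(.numeric_cols, names(df))) {
    if (!is.numeric(df[[cl]]))
      stop("column '", cl, "' must be numeric", call. = FALSE)
  }
  if (nrow(df)) {
    if (any(!is.finite(df$x_nm)) || any(!is.finite(df$y_nm)))
      stop("non-finite coordinates in localization table", call. = FALSE)
    if (any(df$photons < 0)) stop("negative photon counts", call. = FALSE)
    if (!is.null(df$precision_nm) && any(df$precision_nm <= 0, na.rm = TRUE))
      stop("localization precision must be > 0", call. = FALSE)
    if (!is.null(palette)) {
      bad <- setdiff(unique(df$probe), palette)
      if (length(bad))
        stop("probe label(s) outside declared palette: ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  df$probe <- as.character(df$probe)
  class(df) <- unique(c("loc_set", class(df)))
  df
}

# dialect registry ------------------------------------------------------------

.dialects <- new.env(parent = emptyenv())

#' Define a localization-table dialect
#'
#' A dialect maps vendor column names onto the canonical schema and declares
#' the length unit of each coordinate column, so that arbitrary particle-file
#' exports can be read without editing them. Registered dialects are looked up
#' by name in [read_localizations()].
#'
#' @param map named character vector; names are canonical columns
#'   (`x_nm`, `y_nm`, `z_nm`, `photons`, `frame`, `precision_nm`, `probe`),
#'   values are the column names in the file.
#' @param units named character vector over a subset of
#'   `c("x_nm","y_nm","z_nm","precision_nm")` with values `"nm"` or `"um"`;
#'   columns declared `"um"` are multiplied by 1000 on read. Default all nm.
#' @return an object of class `loc_dialect`.
#' @export
loc_dialect <- function(map, units = NULL) {
  stopifnot(is.character(map), !is.null(names(map)))
  unknown <- setdiff(names(map), c(.numeric_cols, "probe"))
  if (length(unknown))
    stop("unknown canonical column(s) in dialect map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(units)) {
    stopifnot(all(units %in% c("nm", "um")))
    stopifnot(all(names(units) %in% c("x_nm", "y_nm", "z_nm", "precision_nm")))
  }
  structure(list(map = map, units = units), class = "loc_dialect")
}

#' @rdname loc_dialect
#' @param name registry key.
#' @param dialect a `loc_dialect` object.
#' @export
register_dialect <- function(name, dialect) {
  stopifnot(is.character(name), inherits(dialect, "loc_dialect"))
  assign(name, dialect, envir = .dialects)
  invisible(dialect)
}

#' @rdname loc_dialect
#' @export
get_dialect <- function(name) {
  if (!exists(name, envir = .dialects))
    stop("unknown dialect '", name, "'; register it with register_dialect()",
         call. = FALSE)
  get(name, envir = .dialects)
}

.init_dialects <- function() {
  register_dialect("canonical", loc_dialect(
    c(x_nm = "x_nm", y_nm = "y_nm", z_nm = "z_nm", photons = "photons",
      frame = "frame", precision_nm = "precision_nm", probe = "probe")))
  # generic micron-unit export, e.g. tables written in um with short names
  register_dialect("xy_um", loc_dialect(
    c(x_nm = "x", y_nm = "y", z_nm = "z", photons = "photons",
      frame = "frame", precision_nm = "precision", probe = "probe"),
    units = c(x_nm = "um", y_nm = "um", z_nm = "um", precision_nm = "um")))
}

# reading / writing -----------------------------------------------------------

#' Read a localization table
#'
#' Reads a delimited text file (comma or tab separated, header required),
#' applies a dialect to map and unit-convert columns onto the canonical
#' schema, and validates the result. Unknown columns are preserved untouched.
#'
#' @param path file path.
#' @param dialect a dialect name (see [register_dialect()]) or a
#'   `loc_dialect` object. Default `"canonical"`.
#' @param palette optional allowed probe labels, passed to
#'   [localization_set()].
#' @return a `loc_set` data frame.
#' @export
read_localizations <- function(path, dialect = "canonical", palette = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(dialect)) dialect <- get_dialect(dialect)
  stopifnot(inherits(dialect, "loc_dialect"))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  map <- dialect$map
  present <- map[map %in% names(raw)]
  req_src <- map[.required_cols]
  miss <- .required_cols[!(req_src %in% names(raw))]
  if (length(miss))
    stop("input lacks column(s) for: ", paste(miss, collapse = ", "),
         " (expected file column(s) ", paste(map[miss], collapse = ", "), ")",
         call. = FALSE)
  out <- raw
  names(out)[match(present, names(out))] <- names(present)
  for (cl in intersect(.numeric_cols, names(out))) {
    v <- suppressWarnings(as.numeric(out[[cl]]))
    bad <- which(is.na(v) & !is.na(out[[cl]]) & nzchar(trimws(out[[cl]])))
    if (length(bad))
      stop("non-numeric value in column '", cl, "' at file line ",
           bad[1] + 1L, call. = FALSE)
    out[[cl]] <- v
  }
  if (!is.null(dialect$units)) {
    um <- names(dialect$units)[dialect$units == "um"]
    for (cl in intersect(um, names(out))) out[[cl]] <- out[[cl]] * 1000
  }
  localization_set(out, palette = palette)
}

#' Write a localization set as canonical CSV
#'
#' @param locs a `loc_set`.
#' @param path output path.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  invisible(path)
}

# filtering -------------------------------------------------------------------

#' Filter localizations by precision
#'
#' Retains blinks whose Cramer-Rao localization precision is at or below the
#' threshold (the 80 nm standard filter; the boundary is inclusive). Record
#' order is preserved and the operation is idempotent.
#'
#' @param locs a `loc_set` with a `precision_nm` column.
#' @param max_precision threshold in nm, default 80.
#' @return the filtered `loc_set`.
#' @export
filter_precision <- function(locs, max_precision = 80) {
  if (is.null(locs$precision_nm))
    stop("precision filtering requires a 'precision_nm' column; ",
         "declare it through the dialect", call. = FALSE)
  locs[locs$precision_nm <= max_precision, , drop = FALSE]
}

#' Discard the axial dimension
#'
#' Chromatic aberration makes the z estimate unreliable across channels, so
#' all geometry downstream is two-dimensional. Drops `z_nm` if present;
#' lateral coordinates are untouched.
#'
#' @param locs a `loc_set`.
#' @return the `loc_set` without a `z_nm` column.
#' @export
flatten_z <- function(locs) {
  locs$z_nm <- NULL
  locs
}

# synapse windows -------------------------------------------------------------

#' Segment a field of view into synapse windows
#'
#' Detects fiducial (dense-projection marker) clusters along the cord with
#' [detect_cord_clusters()] and assigns every localization of every probe
#' lying within `half_width` of a fiducial cluster centre to that synapse.
#' A localization within reach of two centres goes to the nearer one; exact
#' ties go to the lower `roi_id`. ROI ids are ordered along the cord axis.
#'
#' @param locs a `loc_set` containing the fiducial probe.
#' @param fiducial probe label marking the dense projection (e.g. `"ELKS"`).
#' @param half_width window half-width in nm, default 700 (chosen around the
#'   ~580 nm average synapse size so one window holds one synapse).
#' @param gap_nm,min_size cluster-detection parameters, see
#'   [detect_cord_clusters()].
#' @return a list of `synapse_roi` objects, each with elements `roi_id`,
#'   `fiducial`, `center` (x, y in nm), `half_width` and `members` (a
#'   `loc_set` of all probes in the window). Empty list with a warning when no
#'   fiducial localization is present.
#' @export
segment_rois <- function(locs, fiducial, half_width = 700,
                         gap_nm = 250, min_size = 20) {
  fid <- locs[locs$probe == fiducial, , drop = FALSE]
  if (!nrow(fid)) {
    warning("no localizations for fiducial probe '", fiducial, "'")
    return(list())
  }
  cc <- detect_cord_clusters(locs, fiducial, gap_nm = gap_nm,
                             min_size = min_size)
  if (!nrow(cc$centers)) {
    warning("no fiducial cluster of >= ", min_size, " localizations")
    return(list())
  }
  centers <- as.matrix(cc$centers[, c("x_nm", "y_nm")])
  d2 <- outer(locs$x_nm, centers[, 1], "-")^2 +
    outer(locs$y_nm, centers[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  within <- sqrt(d2[cbind(seq_len(nrow(locs)), nearest)]) <= half_width
  lapply(seq_len(nrow(centers)), function(i) {
    structure(list(
      roi_id = i,
      fiducial = fiducial,
      center = centers[i, ],
      half_width = half_width,
      members = locs[within & nearest == i, , drop = FALSE]
    ), class = "synapse_roi")
  })
}

#' @export
print.synapse_roi <- function(x, ...) {
  cat(sprintf("synapse ROI %d: fiducial %s centre (%.0f, %.0f) nm, %d localizations\n",
              x$roi_id, x$fiducial, x$center[1], x$center[2], nrow(x$members)))
  invisible(x)
}
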