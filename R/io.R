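# File I/O: images (via EBImage readers), pair tables, OD JSON.

#' Read a fundus image file
#'
#' Reads PNG/TIFF/JPEG with EBImage and returns a normalized `fundus_image`.
#' 8-bit files arrive already scaled to \[0, 1\] by the reader, so no further
#' division is applied; raw in-memory 0-255 arrays should go through
#' [normalize_image()] instead.
#'
#' @param path Image file.
#' @param fov_deg Field of view in degrees.
#' @return A `fundus_image`.
#' @export
read_fundus <- function(path, fov_deg) {
  eb <- EBImage::readImage(path)
  d <- from_eb(eb)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3] > 3L) d <- d[, , 1:3]
  d[d < 0] <- 0; d[d > 1] <- 1
  new_fundus_image(d, fov_deg, resize_factor = 1, source_path = path)
}

#' Read a binary mask image
#'
#' @param path Image file; any nonzero pixel is foreground.
#' @param provenance Provenance tag for the mask.
#' @return A `vessel_mask`.
#' @export
read_mask <- function(path, provenance = "isodata") {
  d <- from_eb(EBImage::readImage(path))
  if (length(dim(d)) == 3L) d <- d[, , 1]
  new_vessel_mask(d > 0.5, provenance)
}

#' Read an RGB ground-truth label map
#'
#' @param path Image file with red/blue/green vessel annotations.
#' @return An `av_labels` object (see [classify_hsv()]).
#' @export
read_labels <- function(path) {
  d <- from_eb(EBImage::readImage(path))
  if (length(dim(d)) == 2L) stop("label map must be RGB")
  if (dim(d)[3] > 3L) d <- d[, , 1:3]
  classify_hsv(d)
}

#' Write a binary mask or matrix as an image
#'
#' @param m `vessel_mask`, `vessel_skeleton`, matrix, or H x W x 3 array.
#' @param path Output file (format from the extension, e.g. `.png`).
#' @export
write_image <- function(m, path) {
  if (inherits(m, "vessel_mask")) m <- m$mask
  if (inherits(m, "vessel_skeleton")) m <- m$grid
  EBImage::writeImage(as_eb(m * 1), path)
  invisible(path)
}

#' Write a start/end pair table
#'
#' CSV with `Start (x,y)` and `End (x,y)` columns holding "(x, y)" strings.
#'
#' @param pairs Tibble from [validate_pairs()].
#' @param path Output CSV.
#' @export
write_pairs <- function(pairs, path) {
  df <- data.frame(
    `Start (x,y)` = format_xy(pairs$start_x, pairs$start_y),
    `End (x,y)` = format_xy(pairs$end_x, pairs$end_y),
    check.names = FALSE
  )
  if ("vessel_class" %in% names(pairs)) df$Class <- pairs$vessel_class
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a start/end pair table
#'
#' Parses "(x, y)" string cells back into integer coordinates.
#'
#' @param path CSV with `Start (x,y)` and `End (x,y)` columns.
#' @return Tibble with `start_x`, `start_y`, `end_x`, `end_y` (and
#'   `vessel_class` if a Class column is present).
#' @export
read_pairs <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  s <- parse_xy(df[["Start (x,y)"]])
  e <- parse_xy(df[["End (x,y)"]])
  out <- tibble(start_x = s[, "x"], start_y = s[, "y"],
                end_x = e[, "x"], end_y = e[, "y"])
  if ("Class" %in% names(df)) out$vessel_class <- as.character(df$Class)
  out
}

#' Write / read an optic disc as JSON
#'
#' @param od An `optic_disc`.
#' @param path JSON file.
#' @export
write_od <- function(od, path) {
  stopifnot(inherits(od, "optic_disc"))
  jsonlite::write_json(
    list(x = od$center_xy[["x"]], y = od$center_xy[["y"]],
         r = od$radius_px, scale = od$restore_scale, ppd_od = od$ppd_od),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_od
#' @export
read_od <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  od <- optic_disc(j$x, j$y, j$r, restore_scale = j$scale)
  if (!is.null(j$ppd_od) && !is.na(j$ppd_od)) od$ppd_od <- j$ppd_od
  od
}
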