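#' Optic disc circle
#'
#' Constructs the optic-disc record that anchors vessel start points and
#' defines the tracing exclusion zone: a circle in pixel coordinates
#' (x = column, y = row) plus the bookkeeping scale used to restore the
#' radius to the original image resolution.
#'
#' @param x,y Centre coordinates in pixels.
#' @param r Radius in pixels (positive).
#' @param restore_scale Factor mapping radius back to the original image
#'   resolution (default 1).
#' @param fov_deg Optional field of view; when supplied, `ppd_od` =
#'   `r * restore_scale / fov_deg` is recorded.
#' @return An `optic_disc` object.
#' @export
optic_disc <- function(x, y, r, restore_scale = 1, fov_deg = NULL) {
  if (!is.numeric(r) || r <= 0) stop("radius must be positive")
  if (restore_scale <= 0) stop("restore_scale must be positive")
  structure(
    list(
      center_xy = c(x = as.numeric(x), y = as.numeric(y)),
      radius_px = as.numeric(r),
      restore_scale = as.numeric(restore_scale),
      ppd_od = if (is.null(fov_deg)) NA_real_ else r * restore_scale / fov_deg
    ),
    class = "optic_disc"
  )
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf("<optic_disc> centre (%.4g, %.4g), radius %.4g px, scale %.3g\n",
              x$center_xy[["x"]], x$center_xy[["y"]], x$radius_px,
              x$restore_scale))
  invisible(x)
}

#' Detect the optic disc
#'
#' Localizes the bright optic disc as the best-scoring circle of a Hough
#' circular transform: the intensity image is contrast-equalized (CLAHE), an
#' edge map is taken at the upper gradient-magnitude quantile, and ring
#' kernels over a radius range derived from the image's pixels-per-degree
#' ratio (disc diameter assumed about 5 degrees of visual angle) vote for
#' centre positions. The winning centre must lie within the bounding region
#' of the vessel mask; if the Hough stage fails, the centroid of the
#' brightest region is used with the nominal 2.5-degree radius. A manual
#' circle bypasses detection entirely.
#'
#' @param img A `fundus_image`.
#' @param mask A `vessel_mask` used to validate the detected centre.
#' @param manual Optional `optic_disc` supplied by the user; returned
#'   verbatim.
#' @param radius_range Multiplicative search range around the nominal radius
#'   `ppd * 5 / 2` (default `c(0.5, 2.5)`).
#' @param edge_quantile Gradient-magnitude quantile defining edge pixels.
#' @return An `optic_disc`.
#' @export
detect_od <- function(img, mask = NULL, manual = NULL,
                      radius_range = c(0.5, 2.5), edge_quantile = 0.97) {
  if (!is.null(manual)) {
    stopifnot(inherits(manual, "optic_disc"))
    return(manual)
  }
  stopifnot(inherits(img, "fundus_image"))
  gray <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3
  if (diff(range(gray)) < .Machine$double.eps) {
    stop("OD not found: image has no contrast; supply the disc manually")
  }
  eq <- tryCatch(
    from_eb(EBImage::clahe(as_eb(gray), nx = 8, ny = 8)),
    error = function(e) gray
  )
  nominal_r <- img$ppd * 5 / 2
  radii <- unique(round(seq(max(3, radius_range[1] * nominal_r),
                            max(4, radius_range[2] * nominal_r),
                            length.out = 12)))
  # smooth before the gradient so thin vessels stop voting and only
  # disc-scale boundaries produce edges
  eq <- from_eb(EBImage::gblur(as_eb(eq), sigma = 3))
  gx <- (shift_mat(eq, 0, 1, 0) - shift_mat(eq, 0, -1, 0)) / 2
  gy <- (shift_mat(eq, 1, 0, 0) - shift_mat(eq, -1, 0, 0)) / 2
  gm <- sqrt(gx^2 + gy^2)
  edges <- (gm >= quantile(gm, edge_quantile)) * 1
  gmean <- mean(gray)
  best <- NULL
  for (r in radii) {
    outer_k <- disc_kernel(r)
    inner <- disc_kernel(max(1, r - 2))
    pad <- (nrow(outer_k) - nrow(inner)) / 2
    ring <- outer_k
    ring[(pad + 1):(pad + nrow(inner)), (pad + 1):(pad + ncol(inner))] <-
      ring[(pad + 1):(pad + nrow(inner)), (pad + 1):(pad + ncol(inner))] - inner
    ring[ring < 0] <- 0
    # Hough votes normalized by sqrt(ring area): plain counts favour the
    # largest ring (background hits grow with area), plain means favour
    # tiny rings on thick edge blobs; sqrt-normalization scores by
    # signal-to-noise of the accumulated votes
    acc <- from_eb(EBImage::filter2(as_eb(edges), as_eb(ring) / sqrt(sum(ring))))
    # the disc is a bright structure: dark-interior candidates are rejected
    interior <- from_eb(EBImage::filter2(as_eb(gray),
                                         as_eb(inner) / sum(inner)))
    acc[interior <= gmean] <- 0
    idx <- which.max(acc)
    score <- acc[idx]
    if (is.null(best) || score > best$score) {
      rc <- arrayInd(idx, dim(acc))
      best <- list(score = score, row = rc[1], col = rc[2], r = r)
    }
  }
  ok <- !is.null(best) && best$score > 0
  if (ok && !is.null(mask) && any(mask$mask)) {
    rr <- range(which(rowSums(mask$mask) > 0))
    cr <- range(which(colSums(mask$mask) > 0))
    margin <- 0.1 * max(dim(mask$mask))
    ok <- best$row >= rr[1] - margin && best$row <= rr[2] + margin &&
      best$col >= cr[1] - margin && best$col <= cr[2] + margin
  }
  if (ok) {
    return(optic_disc(best$col, best$row, best$r,
                      restore_scale = 1 / img$resize_factor,
                      fov_deg = img$fov_deg))
  }
  # fallback: brightest-region centroid with nominal radius
  thr <- quantile(gray, 0.999)
  bright <- gray >= thr
  if (!any(bright) || thr <= min(gray)) {
    stop("OD not found: no circle and no bright region; supply the disc manually")
  }
  lab <- from_eb(EBImage::bwlabel(as_eb(bright * 1)))
  biggest <- which.max(tabulate(lab[lab > 0]))
  idx <- which(lab == biggest, arr.ind = TRUE)
  optic_disc(mean(idx[, 2]), mean(idx[, 1]), nominal_r,
             restore_scale = 1 / img$resize_factor, fov_deg = img$fov_deg)
}

#' Rescale an optic disc to another resolution
#'
#' Multiplies centre and radius by `s` (e.g. to restore original image
#' dimensions) and records `ppd_od = r * s / fov_deg`, the disc radius per
#' degree of visual angle at the original scale.
#'
#' @param od An `optic_disc`.
#' @param s Positive scale factor.
#' @param fov_deg Field of view in degrees.
#' @return The rescaled `optic_disc`.
#' @export
rescale_od <- function(od, s, fov_deg) {
  stopifnot(inherits(od, "optic_disc"))
  if (!is.numeric(s) || s <= 0) stop("scale must be positive")
  out <- optic_disc(od$center_xy[["x"]] * s, od$center_xy[["y"]] * s,
                    od$radius_px * s, restore_scale = od$restore_scale)
  out$ppd_od <- od$radius_px * s / fov_deg
  out
}
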