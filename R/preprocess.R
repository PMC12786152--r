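#' Normalize a raw 8-bit fundus image
#'
#' Converts an integer RGB image (values 0-255) to double precision in
#' \[0, 1\] by dividing every channel by 255, and attaches the acquisition
#' metadata needed downstream: field of view (degrees) and the derived
#' pixels-per-degree ratio `ppd = height / fov_deg`.
#'
#' @param raw H x W x 3 numeric array with values in \[0, 255\].
#' @param fov_deg Field of view in degrees (45 for DRIVE/HRF-style images,
#'   30 for LES-AV-style images).
#' @param source_path Optional provenance string.
#' @return A `fundus_image` object: list with `pixels` (H x W x 3 in \[0,1\]),
#'   `height_px`, `width_px`, `fov_deg`, `resize_factor` (1 until the resize
#'   policy is applied), `ppd`, `source_path`.
#' @seealso [apply_resize_policy()], [extract_b_channel()]
#' @export
normalize_image <- function(raw, fov_deg, source_path = NA_character_) {
  if (is.null(dim(raw)) || length(raw) == 0L) stop("empty image")
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (length(dim(raw)) != 3L || dim(raw)[3] != 3L) {
    stop("expected an H x W x 3 image array")
  }
  if (anyNA(raw) || min(raw) < 0 || max(raw) > 255) {
    stop("pixel values outside [0, 255]")
  }
  if (!is.numeric(fov_deg) || fov_deg <= 0) stop("fov_deg must be positive")
  px <- raw / 255
  new_fundus_image(px, fov_deg, resize_factor = 1, source_path = source_path)
}

new_fundus_image <- function(pixels, fov_deg, resize_factor, source_path = NA_character_) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  structure(
    list(
      pixels = pixels, height_px = h, width_px = w, fov_deg = fov_deg,
      resize_factor = resize_factor, ppd = h / fov_deg,
      source_path = source_path
    ),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf(
    "<fundus_image> %d x %d px, FOV %.5g deg, ppd %.4g, resize factor %.3g\n",
    x$height_px, x$width_px, x$fov_deg, x$ppd, x$resize_factor
  ))
  invisible(x)
}

resize_fundus <- function(img, factor) {
  h <- max(1L, round(img$height_px * factor))
  w <- max(1L, round(img$width_px * factor))
  eb <- EBImage::resize(as_eb(img$pixels), w = w, h = h, filter = "bilinear")
  px <- from_eb(eb)
  px[px < 0] <- 0; px[px > 1] <- 1
  new_fundus_image(px, img$fov_deg,
                   resize_factor = img$resize_factor * factor,
                   source_path = img$source_path)
}

#' Apply the working-resolution resize policy
#'
#' Images whose largest dimension exceeds 1,000 pixels are rescaled by a
#' fixed factor of 0.5; the pixels-per-degree ratio `ppd = height / fov` is
#' then recomputed, and images still above 50 ppd are rescaled by a further
#' 50%. `resize_factor` accumulates the applied scale so results can be
#' mapped back to the original resolution.
#'
#' @param img A `fundus_image`.
#' @param max_dim_px Size trigger for the first rescale (default 1000;
#'   strictly "exceeding", so 1000 itself is untouched).
#' @param max_ppd ppd trigger for the second rescale (default 50).
#' @param factor Rescale factor (default 0.5).
#' @return The (possibly resized) `fundus_image` with updated `ppd` and
#'   `resize_factor`.
#' @export
apply_resize_policy <- function(img, max_dim_px = 1000, max_ppd = 50, factor = 0.5) {
  stopifnot(inherits(img, "fundus_image"))
  if (img$fov_deg <= 0) stop("fov_deg must be positive")
  if (max(img$height_px, img$width_px) > max_dim_px) {
    img <- resize_fundus(img, factor)
  }
  if (img$ppd > max_ppd) {
    img <- resize_fundus(img, factor)
  }
  img
}

#' Extract the normalized LAB b channel
#'
#' Converts the RGB image to CIE LAB and min-max normalizes the b
#' (yellow-blue) channel to \[0, 1\]. Vessels and background separate well in
#' b for typical fundus colouring. A constant b channel (e.g. a flat image)
#' normalizes to all zeros by convention.
#'
#' @param img A `fundus_image` (3-channel).
#' @return H x W numeric matrix in \[0, 1\].
#' @export
extract_b_channel <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  px <- img$pixels
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) stop("3-channel input required")
  h <- dim(px)[1]; w <- dim(px)[2]
  flat <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  b <- matrix(lab[, 3], h, w)
  rng <- range(b)
  if (diff(rng) < .Machine$double.eps) return(matrix(0, h, w))
  (b - rng[1]) / diff(rng)
}

#' ISODATA (intermeans) threshold
#'
#' Iterates `T_{k+1} = (mean(values < T_k) + mean(values >= T_k)) / 2` from
#' the global mean until the update falls below `tol` (default 1e-6) or
#' `max_iter` iterations, returning the fixed point. This is the classic
#' unsupervised intermeans rule: the converged threshold is equidistant from
#' the means of the two classes it induces.
#'
#' @param grid Numeric matrix or vector with at least two distinct values.
#' @param tol Convergence tolerance on the threshold update.
#' @param max_iter Iteration cap.
#' @return The threshold (scalar).
#' @export
isodata_threshold <- function(grid, tol = 1e-6, max_iter = 100L) {
  v <- as.numeric(grid)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty input")
  if (diff(range(v)) < .Machine$double.eps) {
    stop("degenerate histogram: input is constant")
  }
  t_cur <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v < t_cur]
    hi <- v[v >= t_cur]
    if (length(lo) == 0L || length(hi) == 0L) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

new_vessel_mask <- function(mask, provenance) {
  structure(list(mask = as_logical_mask(mask), provenance = provenance),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d, %d foreground px, provenance: %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$provenance))
  invisible(x)
}

#' Threshold the b channel into a binary vessel mask
#'
#' Foreground is `grid >= threshold` (set `invert = TRUE` when vessels are
#' dark in the b channel), followed by removal of 8-connected components
#' smaller than `min_area` pixels.
#'
#' @param grid Normalized b channel (H x W in \[0,1\]).
#' @param threshold Scalar threshold, typically from [isodata_threshold()].
#' @param invert If TRUE, foreground is `grid < threshold` (dark vessels).
#' @param min_area Minimum component area kept by cleanup (pixels); 0 or 1
#'   disables cleanup.
#' @return A `vessel_mask` with provenance `"isodata"`.
#' @export
segment_vessels <- function(grid, threshold, invert = FALSE, min_area = 20L) {
  stopifnot(is.matrix(grid))
  m <- if (invert) grid < threshold else grid >= threshold
  m <- remove_small_components(m, as.integer(min_area))
  new_vessel_mask(m, "isodata")
}

#' Enhance a vessel mask with a multiscale vesselness filter
#'
#' Adds to the mask every pixel whose tube-likeness (Gaussian-Hessian
#' vesselness, maximum over `scales`) exceeds `threshold`; the input mask is
#' never eroded (output foreground is a superset of the input). With
#' `method = "none"` the mask is returned unchanged.
#'
#' @param mask A `vessel_mask`.
#' @param img The `fundus_image` the mask annotates (same H x W).
#' @param method `"vesselness"` (default) or `"none"`.
#' @param scales Gaussian scales in pixels for the vesselness filter.
#' @param threshold Response threshold on the min-max-normalized vesselness.
#' @param dark_vessels Vessels darker than background (TRUE for fundus
#'   photographs).
#' @return A `vessel_mask` with provenance `"enhanced"`.
#' @export
enhance_vessels <- function(mask, img, method = c("vesselness", "none"),
                            scales = c(1, 2, 3), threshold = 0.15,
                            dark_vessels = TRUE) {
  stopifnot(inherits(mask, "vessel_mask"), inherits(img, "fundus_image"))
  method <- match.arg(method)
  if (!all(dim(mask$mask) == c(img$height_px, img$width_px))) {
    stop("mask and image dimensions differ")
  }
  if (method == "none") return(mask)
  gray <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3
  v <- frangi_vesselness(gray, scales = scales, dark = dark_vessels)
  out <- mask$mask | (v > threshold)
  new_vessel_mask(out, "enhanced")
}

#' Restore vessel continuity using ground-truth labels
#'
#' Unions the segmentation with the artery, vein and overlap masks derived
#' from an RGB ground-truth label map (resized to the mask's dimensions with
#' nearest-neighbour interpolation if needed), then applies morphological
#' closing with a disc structuring element to bridge small gaps. Output
#' foreground is a superset of the input foreground.
#'
#' @param mask A `vessel_mask`.
#' @param labels An `av_labels` object (see [classify_hsv()]).
#' @param close_radius Disc radius for the closing (default 2 px).
#' @return A `vessel_mask` with provenance `"gt_restored"`.
#' @export
restore_with_gt <- function(mask, labels, close_radius = 2L) {
  stopifnot(inherits(mask, "vessel_mask"), inherits(labels, "av_labels"))
  labels <- resize_labels(labels, dim(mask$mask))
  m <- mask$mask | labels$m_artery | labels$m_vein | labels$m_overlap
  m <- mat_closing(m, close_radius) | m
  new_vessel_mask(m, "gt_restored")
}
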