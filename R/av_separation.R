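#' Classify a ground-truth label map into artery/vein/overlap masks
#'
#' Converts the RGB label map to HSV (all channels in \[0, 1\]) and applies
#' the hue/saturation/value bands used by the colour-coded annotation scheme:
#' arteries are red (`H <= 0.1` or `H >= 0.9`, `S > 0.4`, `V > 0.3`), veins
#' blue (`0.55 <= H <= 0.75`, `S > 0.4`, `V > 0.3`) and artery-vein crossings
#' green (`0.2 <= H <= 0.45`, `S > 0.3`, `V > 0.3`). The hue bands are
#' disjoint, so the three masks are pairwise disjoint on any input.
#'
#' @param rgb H x W x 3 array in \[0, 1\].
#' @return An `av_labels` object: list with `rgb` and binary matrices
#'   `m_artery`, `m_vein`, `m_overlap`.
#' @export
classify_hsv <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("expected an H x W x 3 RGB array")
  }
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  hsv <- grDevices::rgb2hsv(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
                            as.vector(rgb[, , 3]), maxColorValue = 1)
  H <- matrix(hsv[1, ], h, w)
  S <- matrix(hsv[2, ], h, w)
  V <- matrix(hsv[3, ], h, w)
  m_artery <- ((H >= 0 & H <= 0.1) | (H >= 0.9 & H <= 1)) & S > 0.4 & V > 0.3
  m_vein <- H >= 0.55 & H <= 0.75 & S > 0.4 & V > 0.3
  m_overlap <- H >= 0.2 & H <= 0.45 & S > 0.3 & V > 0.3
  structure(list(rgb = rgb, m_artery = m_artery, m_vein = m_vein,
                 m_overlap = m_overlap),
            class = "av_labels")
}

#' @export
print.av_labels <- function(x, ...) {
  cat(sprintf("<av_labels> %d x %d: %d artery, %d vein, %d overlap px\n",
              nrow(x$m_artery), ncol(x$m_artery), sum(x$m_artery),
              sum(x$m_vein), sum(x$m_overlap)))
  invisible(x)
}

# Resize a label map to target dimensions with nearest-neighbour
# interpolation (preserves binarity of the derived masks).
resize_labels <- function(labels, dims) {
  stopifnot(inherits(labels, "av_labels"))
  if (all(dim(labels$m_artery) == dims)) return(labels)
  eb <- EBImage::resize(as_eb(labels$rgb), w = dims[2], h = dims[1],
                        filter = "none")
  classify_hsv(from_eb(eb))
}

#' Build per-class vessel masks from segmentation and labels
#'
#' Intersects the segmented vessel map with the labelled colour regions:
#' `artery = seg AND (m_artery OR m_overlap)` and
#' `vein = seg AND (m_vein OR m_overlap)` -- crossing pixels are deliberately
#' included in both classes to keep each class map connected -- then closes
#' each mask with a disc structuring element (radius 2 by default) to heal
#' minor discontinuities.
#'
#' @param seg A `vessel_mask`.
#' @param labels An `av_labels` map (resized with nearest neighbour if its
#'   dimensions differ from the segmentation).
#' @param close_radius Disc radius for the closing, in pixels.
#' @return List with `artery` and `vein`, both `vessel_mask` objects.
#' @export
build_av_masks <- function(seg, labels, close_radius = 2L) {
  stopifnot(inherits(seg, "vessel_mask"), inherits(labels, "av_labels"))
  labels <- resize_labels(labels, dim(seg$mask))
  if (!all(dim(labels$m_artery) == dim(seg$mask))) {
    stop("label map and segmentation dimensions differ after resize")
  }
  artery <- seg$mask & (labels$m_artery | labels$m_overlap)
  vein <- seg$mask & (labels$m_vein | labels$m_overlap)
  list(
    artery = new_vessel_mask(mat_closing(artery, close_radius), seg$provenance),
    vein = new_vessel_mask(mat_closing(vein, close_radius), seg$provenance)
  )
}

# One pass of Guo-Hall thinning (both subiterations); returns the updated
# logical matrix. Vectorized over the whole image with shifted copies.
# Guo-Hall is preferred over Zhang-Suen because the latter progressively
# erodes two-pixel-wide diagonal ribbons, truncating oblique vessels.
gh_pass <- function(img) {
  for (sub in 1:2) {
    p2 <- shift_mat(img, -1, 0); p3 <- shift_mat(img, -1, 1)
    p4 <- shift_mat(img, 0, 1);  p5 <- shift_mat(img, 1, 1)
    p6 <- shift_mat(img, 1, 0);  p7 <- shift_mat(img, 1, -1)
    p8 <- shift_mat(img, 0, -1); p9 <- shift_mat(img, -1, -1)
    cn <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
      (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
    n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
    n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
    nn <- pmin(n1, n2)
    m <- if (sub == 1L) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
    cond <- img & cn == 1 & nn >= 2 & nn <= 3 & !m
    img <- img & !cond
  }
  img
}

# Adjacency among the 8 ring positions of a 3x3 neighbourhood (neigh8 order:
# NW N NE W E SW S SE); two positions are linked iff the pixels they denote
# are themselves 8-adjacent.
ring_adj <- list(
  c(2L, 4L),              # NW: N, W
  c(1L, 3L, 4L, 5L),      # N: NW, NE, W, E
  c(2L, 5L),              # NE: N, E
  c(1L, 2L, 6L, 7L),      # W: NW, N, SW, S
  c(2L, 3L, 7L, 8L),      # E: N, NE, S, SE
  c(4L, 7L),              # SW: W, S
  c(4L, 5L, 6L, 8L),      # S: W, E, SW, SE
  c(5L, 7L)               # SE: E, S
)

# TRUE iff the foreground neighbours of a pixel form one 8-connected
# component within the ring (deleting the pixel then cannot split its
# component locally); isolated and end pixels (0-1 neighbours) are kept.
locally_deletable <- function(nb) {
  present <- which(nb)
  if (length(present) < 2L) return(FALSE)
  seen <- rep(FALSE, 8L)
  stack <- present[1]
  seen[stack] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[[1]]; stack <- stack[-1]
    for (u in ring_adj[[v]]) {
      if (nb[u] && !seen[u]) {
        seen[u] <- TRUE
        stack <- c(stack, u)
      }
    }
  }
  all(seen[present])
}

# Remove residual 2x2 foreground blocks left by thinning: sequentially
# delete block pixels whose neighbours stay locally connected, so component
# structure and endpoints are preserved.
prune_squares <- function(img) {
  h <- nrow(img); w <- ncol(img)
  for (k in 1:8) {
    blk <- img & shift_mat(img, 0, 1) & shift_mat(img, 1, 0) & shift_mat(img, 1, 1)
    if (!any(blk)) break
    in_block <- blk | shift_mat(blk, 0, -1) | shift_mat(blk, -1, 0) |
      shift_mat(blk, -1, -1)
    cand <- which(in_block & img)
    removed <- FALSE
    for (idx in cand) {
      r <- (idx - 1L) %% h + 1L
      c <- (idx - 1L) %/% h + 1L
      if (r <= 1L || c <= 1L || r >= h || c >= w) next
      # still part of a 2x2 block in the current (updated) image?
      still <- FALSE
      for (dr in c(-1L, 0L)) for (dc in c(-1L, 0L)) {
        if (img[r + dr, c + dc] && img[r + dr + 1L, c + dc] &&
            img[r + dr, c + dc + 1L] && img[r + dr + 1L, c + dc + 1L]) {
          still <- TRUE
        }
      }
      if (!still) next
      nb <- img[cbind(r + neigh8[, 1], c + neigh8[, 2])]
      if (locally_deletable(nb)) {
        img[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  img
}

#' Skeletonize a vessel mask
#'
#' Reduces the binary mask to a one-pixel-wide centerline by iterative
#' two-subiteration parallel thinning (Guo-Hall) run to a fixpoint,
#' preserving the 8-connectivity of each component. A final pruning pass
#' removes any residual 2 x 2 foreground block by deleting 8-simple pixels
#' only.
#'
#' @param mask A `vessel_mask` or a binary matrix.
#' @param vessel_class Optional class tag (`"artery"` or `"vein"`).
#' @return A `vessel_skeleton`: list with `grid` (logical H x W),
#'   `vessel_class`, and `od` (attached later by [overlay_od()]).
#' @export
skeletonize <- function(mask, vessel_class = NA_character_) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else as_logical_mask(mask)
  stopifnot(is.matrix(m))
  h <- nrow(m); w <- ncol(m)
  # pad with a 1-px background ring so border pixels get full neighbourhoods
  mp <- matrix(FALSE, h + 2L, w + 2L)
  mp[2:(h + 1L), 2:(w + 1L)] <- m
  repeat {
    nxt <- gh_pass(mp)
    if (identical(nxt, mp)) break
    mp <- nxt
  }
  mp <- prune_squares(mp)
  m <- mp[2:(h + 1L), 2:(w + 1L)]
  structure(list(grid = m, vessel_class = vessel_class, od = NULL),
            class = "vessel_skeleton")
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("<vessel_skeleton> %d x %d, %d px, class: %s, OD: %s\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid),
              ifelse(is.na(x$vessel_class), "unset", x$vessel_class),
              if (is.null(x$od)) "none" else "attached"))
  invisible(x)
}

#' Attach the optic disc to a skeleton
#'
#' Records the disc as tracing metadata. The skeleton grid itself is not
#' modified; the circle is drawn only when rendering visualization output.
#'
#' @param skel A `vessel_skeleton`.
#' @param od An `optic_disc` lying within the image bounds.
#' @return The skeleton with `od` attached.
#' @export
overlay_od <- function(skel, od) {
  stopifnot(inherits(skel, "vessel_skeleton"), inherits(od, "optic_disc"))
  cx <- od$center_xy[["x"]]; cy <- od$center_xy[["y"]]
  if (cx < 1 || cy < 1 || cx > ncol(skel$grid) || cy > nrow(skel$grid)) {
    stop("optic disc centre outside the image")
  }
  skel$od <- od
  skel
}
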