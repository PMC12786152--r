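# Multiscale Gaussian-Hessian vesselness (Frangi-type tube enhancement).
#
# At each scale s the image is smoothed with a Gaussian of sigma = s, the
# Hessian is estimated by finite differences and scale-normalized by s^2, and
# the two eigenvalues l1, l2 (|l1| <= |l2|) give
#   Rb = l1 / l2, S2 = l1^2 + l2^2,
#   V  = exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S2 / (2 c^2)))
# for pixels where l2 has the tube polarity (l2 > 0 for dark vessels on a
# bright background), 0 elsewhere. The response is the maximum over scales,
# min-max normalized to [0, 1].

#' Multiscale vesselness response
#'
#' @param gray H x W intensity matrix in \[0, 1\].
#' @param scales Gaussian sigmas in pixels.
#' @param beta Blobness sensitivity (default 0.5).
#' @param c Structureness sensitivity; `NULL` (default) uses half the maximum
#'   Hessian norm, the usual automatic choice.
#' @param dark TRUE enhances dark tubes on bright background.
#' @return H x W vesselness matrix in \[0, 1\].
#' @export
frangi_vesselness <- function(gray, scales = c(1, 2, 3), beta = 0.5,
                              c = NULL, dark = TRUE) {
  stopifnot(is.matrix(gray))
  best <- matrix(0, nrow(gray), ncol(gray))
  for (s in scales) {
    g <- from_eb(EBImage::gblur(as_eb(gray), sigma = s))
    # second derivatives by central differences (x = col, y = row)
    gxx <- shift_mat(g, 0, -1, 0) - 2 * g + shift_mat(g, 0, 1, 0)
    gyy <- shift_mat(g, -1, 0, 0) - 2 * g + shift_mat(g, 1, 0, 0)
    gxy <- (shift_mat(g, -1, -1, 0) + shift_mat(g, 1, 1, 0) -
              shift_mat(g, -1, 1, 0) - shift_mat(g, 1, -1, 0)) / 4
    norm <- s^2
    gxx <- gxx * norm; gyy <- gyy * norm; gxy <- gxy * norm
    # eigenvalues of [[gxx, gxy], [gxy, gyy]]
    tr2 <- (gxx + gyy) / 2
    disc <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
    e1 <- tr2 + disc
    e2 <- tr2 - disc
    # order by magnitude: l2 is the larger-|.| eigenvalue
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    pol <- if (dark) l2 > 0 else l2 < 0
    rb2 <- (l1 / ifelse(l2 == 0, .Machine$double.eps, l2))^2
    s2 <- l1^2 + l2^2
    cc <- if (is.null(c)) max(sqrt(s2)) / 2 else c
    if (cc <= 0) cc <- .Machine$double.eps
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[!pol] <- 0
    best <- pmax(best, v)
  }
  rng <- range(best)
  if (diff(rng) < .Machine$double.eps) return(best * 0)
  (best - rng[1]) / diff(rng)
}
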