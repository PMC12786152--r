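#' Extract skeleton pixel coordinates
#'
#' @param skel A `vessel_skeleton`.
#' @return Tibble with integer columns `x` (column) and `y` (row), one row
#'   per foreground pixel; empty skeletons give zero rows.
#' @export
extract_skeleton_pixels <- function(skel) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  idx <- which(skel$grid, arr.ind = TRUE)
  tibble(x = as.integer(idx[, 2]), y = as.integer(idx[, 1]))
}

#' Euclidean distance from pixels to the optic-disc centre
#'
#' @param p Two-column matrix (or length-2 vector) of (x, y) coordinates.
#' @param od An `optic_disc`.
#' @return Numeric vector of distances.
#' @export
distance_to_od <- function(p, od) {
  stopifnot(inherits(od, "optic_disc"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  sqrt((p[, 1] - od$center_xy[["x"]])^2 + (p[, 2] - od$center_xy[["y"]])^2)
}

#' Candidate start points on the optic-disc boundary band
#'
#' Keeps the skeleton pixels whose distance d to the disc centre satisfies
#' `r_OD < d <= r_OD + delta` (strict lower bound: pixels on or inside the
#' disc are never starts).
#'
#' @param pixels Tibble/data frame with `x`, `y` columns (skeleton pixels).
#' @param od An `optic_disc`.
#' @param delta Band width in pixels beyond the disc radius (default 5).
#' @return The subset of `pixels` inside the band.
#' @export
candidate_starts <- function(pixels, od, delta = 5) {
  stopifnot(delta >= 0)
  d <- distance_to_od(cbind(pixels$x, pixels$y), od)
  pixels[d > od$radius_px & d <= od$radius_px + delta, , drop = FALSE]
}

#' Detect skeleton endpoints
#'
#' An endpoint is a foreground pixel with exactly one foreground 8-neighbour;
#' isolated pixels (zero neighbours) are discarded.
#'
#' @param skel A `vessel_skeleton`.
#' @return Tibble with `x`, `y` columns.
#' @export
detect_endpoints <- function(skel) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  g <- skel$grid
  nb <- matrix(0L, nrow(g), ncol(g))
  for (k in seq_len(8)) {
    nb <- nb + shift_mat(g, neigh8[k, 1], neigh8[k, 2])
  }
  idx <- which(g & nb == 1L, arr.ind = TRUE)
  tibble(x = as.integer(idx[, 2]), y = as.integer(idx[, 1]))
}

# Level-synchronous BFS over the 8-connected foreground graph.
#
# fg:      logical H x W matrix (the traversable pixels)
# from:    linear index of the source pixel
# targets: integer vector of linear indices; BFS stops at the first level
#          containing any target (ties broken by smallest linear index)
# Returns list(reached = linear index or NA, pred = integer matrix of
# predecessors, 0 = unvisited, -1 = source).
bfs_grid <- function(fg, from, targets = integer(0)) {
  h <- nrow(fg); w <- ncol(fg)
  pred <- matrix(0L, h, w)
  if (!fg[from]) return(list(reached = NA_integer_, pred = pred))
  pred[from] <- -1L
  frontier <- from
  target_set <- targets[fg[targets]]
  if (from %in% target_set) return(list(reached = from, pred = pred))
  offsets <- neigh8[, 1] + neigh8[, 2] * h  # linear-index deltas
  fr <- (from - 1L) %% h + 1L
  repeat {
    nxt <- integer(0)
    rows <- (frontier - 1L) %% h + 1L
    cols <- (frontier - 1L) %/% h + 1L
    for (k in seq_len(8)) {
      nr <- rows + neigh8[k, 1]
      nc <- cols + neigh8[k, 2]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      if (!any(ok)) next
      cand <- frontier[ok] + offsets[k]
      src <- frontier[ok]
      keep <- fg[cand] & pred[cand] == 0L
      if (!any(keep)) next
      cand <- cand[keep]; src <- src[keep]
      # first writer wins within this level (fixed neighbour order)
      first <- !duplicated(cand)
      cand <- cand[first]; src <- src[first]
      pred[cand] <- src
      nxt <- c(nxt, cand)
    }
    if (length(nxt) == 0L) return(list(reached = NA_integer_, pred = pred))
    hit <- intersect(nxt, target_set)
    if (length(hit) > 0L) return(list(reached = min(hit), pred = pred))
    frontier <- nxt
  }
}

backtrack_path <- function(pred, to) {
  path <- integer(0)
  cur <- to
  repeat {
    path <- c(path, cur)
    p <- pred[cur]
    if (p == -1L) break
    if (p == 0L) stop("backtrack from unvisited pixel")
    cur <- p
  }
  rev(path)
}

lin_to_xy <- function(idx, h) {
  cbind(x = (idx - 1L) %/% h + 1L, y = (idx - 1L) %% h + 1L)
}

xy_to_lin <- function(x, y, h) (x - 1L) * h + y

# Traversable grid: skeleton foreground minus the closed optic-disc interior.
skel_foreground <- function(skel, od = NULL) {
  g <- skel$grid
  if (!is.null(od)) {
    h <- nrow(g); w <- ncol(g)
    dx <- matrix(rep(seq_len(w), each = h), h, w) - od$center_xy[["x"]]
    dy <- matrix(rep(seq_len(h), w), h, w) - od$center_xy[["y"]]
    g <- g & (dx^2 + dy^2 > od$radius_px^2)
  }
  g
}

#' Validate start/end pairs by BFS connectivity
#'
#' For each endpoint `e` outside the disc (`dist(e, OD) > r_OD`), a
#' breadth-first search runs over the skeleton graph with the closed disc
#' interior excluded; if any candidate start is reached, the pair
#' (first-reached start, e) is emitted. Endpoints that are themselves
#' candidate starts are vessel origins on the disc band, not terminal
#' endpoints, and are skipped. When several starts are reached at the same
#' BFS depth the smallest linear index wins, so results are deterministic.
#'
#' @param skel A `vessel_skeleton` (with or without `od` attached).
#' @param starts Tibble of candidate start pixels (`x`, `y`).
#' @param endpoints Tibble of endpoint pixels (`x`, `y`).
#' @param od An `optic_disc`; defaults to the one attached to `skel`.
#' @param vessel_class Class tag copied onto the output rows.
#' @return Tibble with columns `start_x`, `start_y`, `end_x`, `end_y`,
#'   `vessel_class`.
#' @export
validate_pairs <- function(skel, starts, endpoints, od = NULL,
                           vessel_class = NULL) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  if (is.null(od)) od <- skel$od
  if (is.null(od)) stop("OD required: attach one with overlay_od() or pass od=")
  if (is.null(vessel_class)) vessel_class <- skel$vessel_class
  empty <- tibble(start_x = integer(0), start_y = integer(0),
                  end_x = integer(0), end_y = integer(0),
                  vessel_class = character(0))
  if (nrow(endpoints) == 0L) return(empty)
  if (nrow(starts) == 0L) {
    warning("no candidate starts on the OD band; every endpoint dropped")
    return(empty)
  }
  h <- nrow(skel$grid)
  fg <- skel_foreground(skel, od)
  start_idx <- xy_to_lin(starts$x, starts$y, h)
  start_idx <- start_idx[fg[start_idx]]
  if (length(start_idx) == 0L) {
    warning("all candidate starts fall inside the excluded OD disc")
    return(empty)
  }
  d_e <- distance_to_od(cbind(endpoints$x, endpoints$y), od)
  rows <- list()
  for (i in seq_len(nrow(endpoints))) {
    if (d_e[i] <= od$radius_px) next
    e_idx <- xy_to_lin(endpoints$x[i], endpoints$y[i], h)
    if (!fg[e_idx]) next
    if (e_idx %in% start_idx) next  # vessel origin on the band, not terminal
    res <- bfs_grid(fg, e_idx, setdiff(start_idx, e_idx))
    if (!is.na(res$reached)) {
      s_xy <- lin_to_xy(res$reached, h)
      rows[[length(rows) + 1L]] <- tibble(
        start_x = s_xy[1, "x"][[1]], start_y = s_xy[1, "y"][[1]],
        end_x = endpoints$x[i], end_y = endpoints$y[i],
        vessel_class = as.character(vessel_class)
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Rounded Euclidean chord length between start and end
#'
#' `round(sqrt((x_e - x_s)^2 + (y_e - y_s)^2))`. Coincident points give 0
#' (the corresponding record is flagged invalid downstream, since tortuosity
#' divides by this length).
#'
#' @param pair One row with `start_x`, `start_y`, `end_x`, `end_y` (or a
#'   list with those names).
#' @return Integer chord length.
#' @export
straight_length <- function(pair) {
  as.integer(round(chord_exact(pair)))
}

chord_exact <- function(pair) {
  sqrt((pair$end_x - pair$start_x)^2 + (pair$end_y - pair$start_y)^2)
}

#' Trace a validated pair and measure its curve length
#'
#' Runs a breadth-first search with unit edge weights over the 8-connected
#' skeleton graph (disc interior excluded when `od` is given) from start to
#' end and reconstructs the shortest path by predecessor backtracking.
#' `l_curve` is the number of pixels on the path, inclusive of both ends.
#'
#' @param skel A `vessel_skeleton`.
#' @param pair One pair row (see [validate_pairs()]).
#' @param od Optional `optic_disc` excluded from traversal; defaults to the
#'   one attached to the skeleton.
#' @return A `traced_path`: list with `pair`, `pixels` (n x 2 matrix of x, y
#'   along the path, start first), `l_curve` (integer pixel count, NA when
#'   unreachable), `l_straight` (rounded chord), `chord` (exact chord).
#' @export
curve_length <- function(skel, pair, od = NULL) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  if (is.null(od)) od <- skel$od
  h <- nrow(skel$grid)
  fg <- skel_foreground(skel, od)
  s_idx <- xy_to_lin(pair$start_x, pair$start_y, h)
  e_idx <- xy_to_lin(pair$end_x, pair$end_y, h)
  if (!skel$grid[s_idx] || !skel$grid[e_idx]) {
    stop("pair endpoints must lie on the skeleton")
  }
  out <- list(pair = pair, pixels = NULL, l_curve = NA_integer_,
              l_straight = straight_length(pair), chord = chord_exact(pair))
  if (fg[s_idx] && fg[e_idx]) {
    res <- bfs_grid(fg, s_idx, e_idx)
    if (!is.na(res$reached)) {
      path <- backtrack_path(res$pred, e_idx)
      out$pixels <- lin_to_xy(path, h)
      out$l_curve <- length(path)
    }
  }
  structure(out, class = "traced_path")
}

#' @export
print.traced_path <- function(x, ...) {
  cat(sprintf("<traced_path> (%d, %d) -> (%d, %d): l_curve %s, l_straight %d\n",
              x$pair$start_x, x$pair$start_y, x$pair$end_x, x$pair$end_y,
              ifelse(is.na(x$l_curve), "NA", x$l_curve), x$l_straight))
  invisible(x)
}

#' Find and trace every vessel in a skeleton
#'
#' Convenience wrapper chaining [extract_skeleton_pixels()],
#' [candidate_starts()], [detect_endpoints()], [validate_pairs()] and
#' [curve_length()].
#'
#' @param skel A `vessel_skeleton` with an attached `optic_disc`.
#' @param delta Start-band width in pixels (default 5).
#' @return List of `traced_path` objects.
#' @export
trace_vessels <- function(skel, delta = 5) {
  stopifnot(inherits(skel, "vessel_skeleton"))
  if (is.null(skel$od)) stop("OD required: attach one with overlay_od()")
  px <- extract_skeleton_pixels(skel)
  starts <- candidate_starts(px, skel$od, delta)
  ends <- detect_endpoints(skel)
  pairs <- validate_pairs(skel, starts, ends)
  lapply(seq_len(nrow(pairs)), function(i) {
    curve_length(skel, pairs[i, ])
  })
}
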