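# Internal helpers: matrix shifts, EBImage bridges, coordinate bookkeeping.
#
# Convention used throughout the package: images are plain R matrices (or
# H x W x 3 arrays) indexed [row, col], 1-based. Exported coordinates are
# always (x, y) with x = column and y = row, so that "(x, y)" strings in pair
# tables read the usual Cartesian way.

# Shift a logical/numeric matrix so that result[r, c] == m[r + dr, c + dc],
# padding out-of-bounds cells with `fill`.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) + dr
  cs <- seq_len(w) + dc
  rok <- rs >= 1L & rs <= h
  cok <- cs >= 1L & cs <= w
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# 8-neighbourhood offsets in fixed row-major order: (dr, dc) over
# (-1,-1), (-1,0), (-1,+1), (0,-1), (0,+1), (+1,-1), (+1,0), (+1,+1).
neigh8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# EBImage stores images with the first dimension = x (width); the package
# stores matrices [row = y, col = x]. These two bridges transpose at the
# boundary so EBImage operations can be used without touching conventions.
as_eb <- function(m) {
  if (length(dim(m)) == 2L) {
    EBImage::Image(t(m))
  } else {
    EBImage::Image(aperm(m, c(2L, 1L, 3L)), colormode = "Color")
  }
}

from_eb <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
}

# Disc structuring element; EBImage's makeBrush needs an odd size.
disc_kernel <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

mat_closing <- function(m, radius) {
  out <- from_eb(EBImage::closing(as_eb(m * 1), disc_kernel(radius)))
  out > 0.5
}

mat_dilate <- function(m, radius) {
  out <- from_eb(EBImage::dilate(as_eb(m * 1), disc_kernel(radius)))
  out > 0.5
}

# Label 8-connected foreground components (EBImage's bwlabel is
# 4-connected, which splits diagonal skeleton chains). Level-synchronous
# flood fill, vectorized over the frontier.
label8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  todo <- which(m)
  cur <- 0L
  offs <- neigh8[, 1] + neigh8[, 2] * h
  for (seed in todo) {
    if (lab[seed] > 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0L) {
      rows <- (frontier - 1L) %% h + 1L
      cols <- (frontier - 1L) %/% h + 1L
      nxt <- integer(0)
      for (k in seq_len(8)) {
        nr <- rows + neigh8[k, 1]
        nc <- cols + neigh8[k, 2]
        ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
        if (!any(ok)) next
        cand <- frontier[ok] + offs[k]
        keep <- m[cand] & lab[cand] == 0L
        if (!any(keep)) next
        cand <- unique(cand[keep])
        lab[cand] <- cur
        nxt <- c(nxt, cand)
      }
      frontier <- nxt
    }
  }
  lab
}

# Remove 8-connected foreground components smaller than min_area pixels.
remove_small_components <- function(m, min_area) {
  if (min_area <= 1L || !any(m)) return(m)
  lab <- label8(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  m & matrix(lab %in% keep, nrow(m), ncol(m))
}

count_components <- function(m) {
  if (!any(m)) return(0L)
  max(label8(m))
}

# Format / parse the "(x, y)" cell strings used by pair tables.
format_xy <- function(x, y) sprintf("(%d, %d)", as.integer(x), as.integer(y))

parse_xy <- function(s) {
  m <- regmatches(s, regexec("\\(\\s*(-?\\d+)\\s*,\\s*(-?\\d+)\\s*\\)", s))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("cannot parse \"(x, y)\" string: ", paste(s[bad], collapse = ", "))
  }
  out <- t(vapply(m, function(g) as.integer(g[2:3]), integer(2)))
  colnames(out) <- c("x", "y")
  out
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_binary_mat <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_logical_mask <- function(m) {
  if (is.logical(m)) m else m > 0.5
}
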