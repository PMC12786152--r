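# Synthetic vascular phantoms.
#
# A phantom is a fundus-like RGB image, a binary vessel mask, a colour-coded
# artery/vein label map (red/blue/green), a circular optic disc, and a truth
# table of analytic arc lengths, chords and tortuosities per vessel. Vessels
# are parametric curves radiating from the OD boundary band to the periphery;
# arc lengths come from closed forms (lines, circular arcs) or adaptive
# quadrature (sinusoids, Bezier curves), so the truth error is negligible
# against the 5% recovery band used in tests.

# --- parametric curves -------------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

# Each curve constructor returns list(f = function(s) n x 2 matrix of (x, y),
# arc = analytic/quadrature arc length, chord = |p1 - p0|).
curve_line <- function(p0, p1) {
  v <- p1 - p0
  list(
    f = function(s) cbind(p0[1] + s * v[1], p0[2] + s * v[2]),
    arc = sqrt(sum(v^2)),
    chord = sqrt(sum(v^2))
  )
}

# Circular arc through p0, p1 with sagitta `h` (bulge toward the left normal
# of p0 -> p1); 0 < h <= chord/2, h = chord/2 gives a semicircle.
curve_arc <- function(p0, p1, h) {
  v <- p1 - p0
  chord <- sqrt(sum(v^2))
  stopifnot(h > 0, h <= chord / 2 + 1e-9)
  n <- unit(c(-v[2], v[1]))
  r <- (h^2 + (chord / 2)^2) / (2 * h)
  mid <- (p0 + p1) / 2
  ctr <- mid + n * (h - r)
  a0 <- atan2(p0[2] - ctr[2], p0[1] - ctr[1])
  a1 <- atan2(p1[2] - ctr[2], p1[1] - ctr[1])
  am <- atan2(mid[2] + n[2] * h - ctr[2], mid[1] + n[1] * h - ctr[1])
  delta <- (a1 - a0) %% (2 * pi)
  if (delta > pi + 1e-12) delta <- delta - 2 * pi   # prefer the short way
  onway <- function(d) {
    t <- ((am - a0) %% (2 * pi))
    if (d < 0) t <- t - 2 * pi
    abs(t) <= abs(d) + 1e-9
  }
  if (!onway(delta)) delta <- delta - sign(delta) * 2 * pi
  list(
    f = function(s) cbind(ctr[1] + r * cos(a0 + s * delta),
                          ctr[2] + r * sin(a0 + s * delta)),
    arc = r * abs(delta),
    chord = chord
  )
}

# Sinusoidal perpendicular displacement, zero at both ends:
# gamma(s) = p0 + s v + A sin(pi k s) n, k = number of half-waves.
curve_sinusoid <- function(p0, p1, amplitude, k = 2L) {
  v <- p1 - p0
  n <- unit(c(-v[2], v[1]))
  f <- function(s) cbind(p0[1] + s * v[1] + amplitude * sin(pi * k * s) * n[1],
                         p0[2] + s * v[2] + amplitude * sin(pi * k * s) * n[2])
  speed <- function(s) {
    dx <- v[1] + amplitude * pi * k * cos(pi * k * s) * n[1]
    dy <- v[2] + amplitude * pi * k * cos(pi * k * s) * n[2]
    sqrt(dx^2 + dy^2)
  }
  arc <- if (amplitude == 0) sqrt(sum(v^2)) else {
    integrate(speed, 0, 1, rel.tol = 1e-8, subdivisions = 400L)$value
  }
  list(f = f, arc = arc, chord = sqrt(sum(v^2)))
}

# Cubic Bezier with control points displaced perpendicular to the chord at
# s = 1/3 and 2/3 by o1, o2 pixels.
curve_bezier <- function(p0, p1, o1, o2) {
  v <- p1 - p0
  n <- unit(c(-v[2], v[1]))
  c1 <- p0 + v / 3 + o1 * n
  c2 <- p0 + 2 * v / 3 + o2 * n
  f <- function(s) {
    b0 <- (1 - s)^3; b1 <- 3 * (1 - s)^2 * s; b2 <- 3 * (1 - s) * s^2; b3 <- s^3
    cbind(b0 * p0[1] + b1 * c1[1] + b2 * c2[1] + b3 * p1[1],
          b0 * p0[2] + b1 * c1[2] + b2 * c2[2] + b3 * p1[2])
  }
  speed <- function(s) {
    d0 <- 3 * (1 - s)^2; d1 <- 6 * (1 - s) * s; d2 <- 3 * s^2
    dx <- d0 * (c1[1] - p0[1]) + d1 * (c2[1] - c1[1]) + d2 * (p1[1] - c2[1])
    dy <- d0 * (c1[2] - p0[2]) + d1 * (c2[2] - c1[2]) + d2 * (p1[2] - c2[2])
    sqrt(dx^2 + dy^2)
  }
  arc <- integrate(speed, 0, 1, rel.tol = 1e-8, subdivisions = 400L)$value
  list(f = f, arc = arc, chord = sqrt(sum(v^2)))
}

make_curve <- function(kind, p0, p1, params = list()) {
  switch(kind,
    line = curve_line(p0, p1),
    arc = curve_arc(p0, p1, params$sagitta),
    sinusoid = curve_sinusoid(p0, p1, params$amplitude,
                              if (is.null(params$k)) 2L else params$k),
    bezier = curve_bezier(p0, p1, params$o1, params$o2),
    stop("unknown curve kind: ", kind)
  )
}

# Rasterize a curve to an 8-connected pixel chain (x, y integer matrix).
rasterize_curve <- function(curve, dims) {
  n <- max(64L, ceiling(4 * curve$arc))
  pts <- curve$f(seq(0, 1, length.out = n))
  px <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px <- px[keep, , drop = FALSE]
  if (any(px[, 1] < 1 | px[, 1] > dims[2] | px[, 2] < 1 | px[, 2] > dims[1])) {
    stop("curve leaves the image bounds")
  }
  steps <- apply(abs(diff(px)), 1, max)
  if (any(steps > 1)) stop("rasterized chain is not 8-connected")
  storage.mode(px) <- "integer"
  colnames(px) <- c("x", "y")
  px
}

chain_to_mask <- function(chain, dims, width_px, extend_inward = NULL) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[cbind(chain[, "y"], chain[, "x"])] <- TRUE
  if (!is.null(extend_inward)) {
    # real vessels continue into the optic disc; extending the tube a few
    # pixels inward keeps the thinned skeleton inside the start band even
    # though end caps retract under thinning (the truth chain is untouched)
    dir <- unit(c(chain[1, "x"], chain[1, "y"]) - extend_inward$center)
    for (s in seq_len(extend_inward$len)) {
      p <- round(c(chain[1, "x"], chain[1, "y"]) - s * dir)
      if (p[1] >= 1 && p[2] >= 1 && p[1] <= dims[2] && p[2] <= dims[1]) {
        m[p[2], p[1]] <- TRUE
      }
    }
  }
  if (width_px > 1) m <- mat_dilate(m, floor(width_px / 2))
  m
}

# --- phantom specification and generation ------------------------------------

#' Phantom specification
#'
#' Describes a synthetic fundus phantom: image size, optic disc, and a list
#' of vessels. With `vessels = NULL`, `n_vessels` curves are laid out
#' radially from the disc band to the periphery in evenly spaced, jittered
#' angular sectors, alternating artery/vein. Each vessel receives an
#' analytic tortuosity target drawn from its class distribution
#' (`t_artery`, `t_vein`) and the curve's displacement parameter is solved
#' to meet it, so the phantom population reproduces the artery-vein
#' tortuosity contrast seen in real fundus images. When `n_crossings > 0`,
#' that many artery/vein pairs are placed in adjacent sectors with a
#' sinusoid amplitude large enough to cross, exercising the green overlap
#' labels.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param od_center `c(x, y)` of the optic disc (defaults to the centre).
#' @param od_radius Disc radius in pixels.
#' @param n_vessels Number of vessels when `vessels` is NULL.
#' @param vessels Optional explicit list of vessels; each element is a list
#'   with `class` ("artery"/"vein"), `kind` ("line", "arc", "sinusoid",
#'   "bezier"), `params`, `width_px`, and either `angle` (radial layout) or
#'   explicit `p0`/`p1` endpoints.
#' @param kinds Curve kinds sampled for the automatic layout.
#' @param width_px Vessel width for the automatic layout.
#' @param n_crossings Number of crossing artery/vein pairs.
#' @param delta Start-band width (the inner terminus is placed strictly
#'   inside `(r_OD, r_OD + delta]`).
#' @param t_artery,t_vein Mean and SD of the analytic tortuosity targets
#'   drawn per vessel class. The defaults (arteries 1.11 +/- 0.05, veins
#'   1.21 +/- 0.07) emulate the magnitudes typical of healthy 45-degree
#'   fundus photographs, where veins run systematically more tortuous than
#'   arteries.
#' @param fov_deg Field of view recorded on the rendered image.
#' @param seed Integer seed; the phantom is fully determined by it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(512L, 512L), od_center = NULL,
                         od_radius = 40, n_vessels = 20L, vessels = NULL,
                         kinds = c("line", "arc", "sinusoid", "bezier"),
                         width_px = 3L, n_crossings = 1L, delta = 5,
                         t_artery = c(1.11, 0.05), t_vein = c(1.21, 0.07),
                         fov_deg = 45, seed = 1L) {
  if (is.null(od_center)) od_center <- c(image_size[2] / 2, image_size[1] / 2)
  structure(
    list(image_size = as.integer(image_size), od_center = od_center,
         od_radius = od_radius, n_vessels = as.integer(n_vessels),
         vessels = vessels, kinds = kinds, width_px = as.integer(width_px),
         n_crossings = as.integer(n_crossings), delta = delta,
         t_artery = t_artery, t_vein = t_vein,
         fov_deg = fov_deg, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Solve a curve parameter so the analytic tortuosity hits `target`.
# Each family is monotone in its displacement parameter, so uniroot on
# [0, cap] suffices; an unattainable target returns the cap.
solve_sinusoid <- function(p0, p1, k, target, cap) {
  f <- function(a) {
    crv <- curve_sinusoid(p0, p1, a, k)
    crv$arc / crv$chord - target
  }
  if (f(cap) < 0) return(cap)
  stats::uniroot(f, c(0, cap), tol = 1e-3)$root
}

solve_arc <- function(chord, target) {
  # circular arc: t = theta / sin(theta), sagitta = chord * tan(theta/2) / 2
  f <- function(th) th / sin(th) - target
  th <- if (f(pi / 2) < 0) pi / 2 else stats::uniroot(f, c(1e-6, pi / 2),
                                                      tol = 1e-8)$root
  chord * tan(th / 2) / 2
}

solve_bezier <- function(p0, p1, target, cap) {
  f <- function(o) {
    crv <- curve_bezier(p0, p1, o, -o)   # S-shaped, bounded envelope
    crv$arc / crv$chord - target
  }
  if (f(cap) < 0) return(cap)
  stats::uniroot(f, c(0, cap), tol = 1e-3)$root
}

# Automatic radial layout. Vessels radiate from the disc band to the
# periphery; each is assigned an analytic tortuosity target drawn from its
# class distribution (veins systematically more tortuous than arteries, as
# in healthy fundus photographs) and the curve parameter is solved to meet
# it. Returns the vessel list with the designated crossing pairs recorded
# in attr(, "crossing_pairs").
layout_vessels <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ctr <- spec$od_center
  n <- spec$n_vessels
  ang <- 2 * pi * (seq_len(n) - 1) / n + runif(n, -0.25, 0.25) * 2 * pi / n
  cls <- rep(c("artery", "vein"), length.out = n)
  cross_slots <- integer(0)
  if (spec$n_crossings > 0 && n >= 2L) {
    cross_slots <- seq_len(min(spec$n_crossings, floor(n / 2))) * 2L - 1L
  }
  border_r <- function(dir, margin) {
    tx <- if (dir[1] > 0) (W - margin - ctr[1]) / dir[1]
          else if (dir[1] < 0) (margin - ctr[1]) / dir[1] else Inf
    ty <- if (dir[2] > 0) (H - margin - ctr[2]) / dir[2]
          else if (dir[2] < 0) (margin - ctr[2]) / dir[2] else Inf
    min(tx, ty)
  }
  draw_target <- function(class) {
    mu <- if (class == "artery") spec$t_artery[1] else spec$t_vein[1]
    sdv <- if (class == "artery") spec$t_artery[2] else spec$t_vein[2]
    repeat {
      t <- rnorm(1, mu, sdv)
      if (t >= 1.002 && t <= 1.45) return(t)
    }
  }
  vessels <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- ang[i]
    dir <- c(cos(theta), sin(theta))
    r0 <- spec$od_radius + runif(1, 1.5, spec$delta - 1)
    r1 <- border_r(dir, 28) * runif(1, 0.85, 0.97)
    p0 <- ctr + r0 * dir; p1 <- ctr + r1 * dir
    chord <- r1 - r0
    target <- draw_target(cls[i])
    amp_cap <- max(3, min(24, 0.14 * chord))
    kind <- if (target > 1.10) {
      sample(intersect(spec$kinds, c("sinusoid", "bezier")), 1)
    } else if (target > 1.015) {
      sample(setdiff(spec$kinds, "line"), 1)
    } else {
      sample(spec$kinds, 1)
    }
    params <- switch(kind,
      line = list(),
      arc = list(sagitta = min(solve_arc(chord, target), chord / 2)),
      sinusoid = list(amplitude = solve_sinusoid(p0, p1, 3L, target, amp_cap),
                      k = 3L),
      bezier = list(o1 = solve_bezier(p0, p1, target, 3 * amp_cap),
                    o2 = -solve_bezier(p0, p1, target, 3 * amp_cap))
    )
    vessels[[i]] <- list(class = cls[i], kind = kind, params = params,
                         width_px = spec$width_px, p0 = p0, p1 = p1)
  }
  # crossing pairs: pull a vein close to the preceding artery with a
  # sinusoid wide enough to cross it (exercises green overlap labels)
  pairs <- matrix(integer(0), ncol = 2)
  for (s in cross_slots) {
    a <- s; v <- s + 1L
    theta <- ang[a] + 0.10
    dir <- c(cos(theta), sin(theta))
    r0 <- spec$od_radius + runif(1, 1.5, spec$delta - 1)
    r1 <- border_r(dir, 28) * 0.85
    vessels[[v]] <- list(class = "vein", kind = "sinusoid",
                         params = list(amplitude = min(16, r1 * 0.10), k = 3L),
                         width_px = spec$width_px,
                         p0 = ctr + r0 * dir, p1 = ctr + r1 * dir)
    pairs <- rbind(pairs, c(a, v))
  }
  attr(vessels, "crossing_pairs") <- pairs
  vessels
}

# Shrink a vessel's displacement parameter (collision-avoidance retries).
shrink_params <- function(vs, factor = 0.7) {
  p <- vs$params
  if (!is.null(p$amplitude)) p$amplitude <- p$amplitude * factor
  if (!is.null(p$sagitta)) p$sagitta <- p$sagitta * factor
  if (!is.null(p$o1)) p$o1 <- p$o1 * factor
  if (!is.null(p$o2)) p$o2 <- p$o2 * factor
  vs$params <- p
  vs
}

#' Generate a synthetic fundus phantom
#'
#' Renders the phantom described by a [phantom_spec()]: a fundus-like RGB
#' intensity image (dark vessels on a bright textured background with a
#' bright disc), a binary vessel mask, a red/blue/green label map (arteries
#' red, veins blue, artery-vein crossing pixels green), the optic disc, and
#' an analytic truth table. Fully deterministic given the spec's seed.
#'
#' @param spec A `phantom_spec`.
#' @return List with `image` (H x W x 3), `mask` (`vessel_mask`), `labels`
#'   (`av_labels`), `od` (`optic_disc`), `truth` (tibble: vessel, class,
#'   kind, arc_length, chord_length, tortuosity, start/end pixels), `chains`
#'   (list of per-vessel pixel chains), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    vessels <- if (is.null(spec$vessels)) layout_vessels(spec) else spec$vessels
    crossing_pairs <- attr(vessels, "crossing_pairs")
    allowed_cross <- function(i, j) {
      !is.null(crossing_pairs) && nrow(crossing_pairs) > 0 &&
        any((crossing_pairs[, 1] == i & crossing_pairs[, 2] == j) |
              (crossing_pairs[, 1] == j & crossing_pairs[, 2] == i))
    }
    chains <- vector("list", length(vessels))
    vmasks <- vector("list", length(vessels))
    class_masks <- list(artery = matrix(FALSE, H, W), vein = matrix(FALSE, H, W))
    truth_rows <- vector("list", length(vessels))
    for (i in seq_along(vessels)) {
      vs <- vessels[[i]]
      # retry with shrunk displacement if the curve leaves the frame or
      # collides with an earlier vessel it is not designated to cross
      for (try in 1:6) {
        crv <- make_curve(vs$kind, vs$p0, vs$p1, vs$params)
        res <- tryCatch(rasterize_curve(crv, c(H, W)), error = function(e) NULL)
        if (!is.null(res)) {
          ext <- if (is.null(spec$vessels)) {
            list(center = spec$od_center, len = vs$width_px + 2L)
          } else NULL
          vm <- chain_to_mask(res, c(H, W), vs$width_px, extend_inward = ext)
          conflict <- FALSE
          if (!is.null(spec$vessels)) {
            # explicit vessel lists are taken verbatim
          } else {
            for (j in seq_len(i - 1L)) {
              if (allowed_cross(i, j)) next
              if (any(vm & vmasks[[j]])) { conflict <- TRUE; break }
            }
          }
          if (!conflict) break
        }
        if (try == 6L || vs$kind == "line") {
          if (is.null(res)) stop("curve leaves the image bounds")
          break
        }
        vs <- shrink_params(vs)
      }
      chain <- res
      chains[[i]] <- chain
      vmasks[[i]] <- vm
      class_masks[[vs$class]] <- class_masks[[vs$class]] | vm
      truth_rows[[i]] <- tibble(
        vessel = i, class = vs$class, kind = vs$kind,
        arc_length = crv$arc, chord_length = crv$chord,
        tortuosity = crv$arc / crv$chord,
        start_x = chain[1, "x"], start_y = chain[1, "y"],
        end_x = chain[nrow(chain), "x"], end_y = chain[nrow(chain), "y"]
      )
    }
    truth <- do.call(rbind, truth_rows)
    mask <- class_masks$artery | class_masks$vein
    overlap <- class_masks$artery & class_masks$vein

    # label map: red arteries, blue veins, green crossings, black elsewhere
    rgb <- array(0, c(H, W, 3))
    r <- matrix(0, H, W); g <- matrix(0, H, W); b <- matrix(0, H, W)
    r[class_masks$artery & !overlap] <- 1
    b[class_masks$vein & !overlap] <- 1
    g[overlap] <- 1
    r[overlap] <- 0; b[overlap] <- 0
    rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b

    # intensity image: textured bright background, bright disc, dark vessels
    bg <- c(0.85, 0.55, 0.30)
    odc <- c(0.95, 0.88, 0.60)
    vv <- c(0.45, 0.15, 0.10)
    noise <- matrix(runif(H * W, -0.02, 0.02), H, W)
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    in_od <- (xs - spec$od_center[1])^2 + (ys - spec$od_center[2])^2 <=
      spec$od_radius^2
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(bg[ch], H, W) + noise
      plane[in_od] <- odc[ch]
      plane[mask] <- vv[ch]
      plane[plane < 0] <- 0; plane[plane > 1] <- 1
      img[, , ch] <- plane
    }
    od <- optic_disc(spec$od_center[1], spec$od_center[2], spec$od_radius,
                     fov_deg = spec$fov_deg)
    list(image = img, mask = new_vessel_mask(mask, "synthetic"),
         labels = classify_hsv(rgb), od = od, truth = truth,
         chains = chains, spec = spec)
  })
}

#' Degrade a vessel mask with gaps and spurs
#'
#' Stress input for the continuity-restoration stage: deletes short runs
#' (gaps) and adds 1-3 px spurs at Poisson rates expressed per 100
#' foreground pixels. Deletions can only split components, never merge them.
#' Fully reproducible given `seed`.
#'
#' @param mask A `vessel_mask`.
#' @param gap_rate,spur_rate Expected events per 100 foreground pixels, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return A degraded `vessel_mask`.
#' @export
degrade <- function(mask, gap_rate = 0, spur_rate = 0, seed = 1L) {
  stopifnot(inherits(mask, "vessel_mask"),
            gap_rate >= 0, gap_rate <= 1, spur_rate >= 0, spur_rate <= 1)
  if (gap_rate == 0 && spur_rate == 0) return(mask)
  m <- mask$mask
  with_local_seed(seed, {
    fg <- which(m)
    nfg <- length(fg)
    n_gaps <- rpois(1, gap_rate * nfg / 100)
    if (n_gaps > 0 && nfg > 0) {
      centers <- sample(fg, min(n_gaps, nfg))
      h <- nrow(m)
      for (idx in centers) {
        r <- (idx - 1L) %% h + 1L; c <- (idx - 1L) %/% h + 1L
        rad <- sample(1:2, 1)
        rr <- max(1, r - rad):min(nrow(m), r + rad)
        cc <- max(1, c - rad):min(ncol(m), c + rad)
        m[rr, cc] <- FALSE
      }
    }
    n_spurs <- rpois(1, spur_rate * nfg / 100)
    if (n_spurs > 0) {
      fg2 <- which(m)
      if (length(fg2) > 0) {
        anchors <- sample(fg2, min(n_spurs, length(fg2)))
        h <- nrow(m)
        for (idx in anchors) {
          r <- (idx - 1L) %% h + 1L; c <- (idx - 1L) %/% h + 1L
          k <- sample(seq_len(8), 1)
          len <- sample(1:3, 1)
          for (s in seq_len(len)) {
            rr <- r + s * neigh8[k, 1]; cc <- c + s * neigh8[k, 2]
            if (rr < 1 || cc < 1 || rr > nrow(m) || cc > ncol(m)) break
            m[rr, cc] <- TRUE
          }
        }
      }
    }
  })
  new_vessel_mask(m, mask$provenance)
}
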