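# Test fixtures and independent oracles, all built in code.

# Wrap a bare pixel chain (n x 2, x/y) as a 1-px skeleton.
chain_skeleton <- function(chain, h, w, vessel_class = "artery") {
  g <- matrix(FALSE, h, w)
  g[cbind(chain[, 2], chain[, 1])] <- TRUE
  structure(list(grid = g, vessel_class = vessel_class, od = NULL),
            class = "vessel_skeleton")
}

mat_skeleton <- function(m, vessel_class = "artery") {
  structure(list(grid = m, vessel_class = vessel_class, od = NULL),
            class = "vessel_skeleton")
}

pair_row <- function(sx, sy, ex, ey, cls = "artery") {
  tibble::tibble(start_x = as.integer(sx), start_y = as.integer(sy),
                 end_x = as.integer(ex), end_y = as.integer(ey),
                 vessel_class = cls)
}

# Independent ISODATA oracle: plain loop over the intermeans update at
# tighter tolerance than the implementation under test.
oracle_isodata <- function(v, tol = 1e-9, iters = 10000L) {
  v <- as.numeric(v)
  t_cur <- mean(v)
  for (i in seq_len(iters)) {
    t_new <- (mean(v[v < t_cur]) + mean(v[v >= t_cur])) / 2
    if (abs(t_new - t_cur) < tol) break
    t_cur <- t_new
  }
  t_new
}

# Independent shortest-path oracle on the 8-connected pixel graph (igraph,
# unit weights). Returns the path pixel count or NA if unreachable.
oracle_path_pixels <- function(grid, s_xy, e_xy) {
  fg <- which(grid)
  h <- nrow(grid)
  id <- match(seq_len(h * ncol(grid)), fg)  # linear index -> vertex id
  edges <- integer(0)
  for (k in seq_len(8)) {
    dr <- retort:::neigh8[k, 1]; dc <- retort:::neigh8[k, 2]
    rows <- (fg - 1L) %% h + 1L; cols <- (fg - 1L) %/% h + 1L
    nr <- rows + dr; nc <- cols + dc
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= ncol(grid)
    nb <- fg[ok] + dr + dc * h
    ok2 <- grid[nb]
    edges <- c(edges, rbind(id[fg[ok][ok2]], id[nb[ok2]]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  s <- id[(s_xy[1] - 1L) * h + s_xy[2]]
  e <- id[(e_xy[1] - 1L) * h + e_xy[2]]
  d <- igraph::distances(g, v = s, to = e)
  if (is.infinite(d[1, 1])) NA_integer_ else as.integer(d[1, 1] + 1L)
}

# Random connected skeleton via a self-avoiding-ish random walk.
random_walk_skeleton <- function(seed, h = 40L, w = 40L, steps = 150L) {
  set.seed(seed)
  g <- matrix(FALSE, h, w)
  r <- sample(5:(h - 5), 1); c <- sample(5:(w - 5), 1)
  g[r, c] <- TRUE
  for (i in seq_len(steps)) {
    k <- sample(8, 1)
    nr <- r + retort:::neigh8[k, 1]; nc <- c + retort:::neigh8[k, 2]
    if (nr < 2 || nc < 2 || nr > h - 1 || nc > w - 1) next
    r <- nr; c <- nc
    g[r, c] <- TRUE
  }
  g
}

# Rasterized chain for a parametric test curve (uses the phantom module's
# internal rasterizer so tests and generator agree on digitization).
test_chain <- function(kind, p0, p1, params = list(), dims = c(300L, 300L)) {
  crv <- retort:::make_curve(kind, p0, p1, params)
  list(chain = retort:::rasterize_curve(crv, dims), curve = crv)
}

# Trace a bare chain end-to-end and return tortuosity records.
trace_chain_records <- function(chain, dims, arc_mode, cls = "artery") {
  sk <- chain_skeleton(chain, dims[1], dims[2], cls)
  pr <- pair_row(chain[1, 1], chain[1, 2],
                 chain[nrow(chain), 1], chain[nrow(chain), 2], cls)
  tp <- curve_length(sk, pr, od = NULL)
  tortuosity_records(list(tp), image_id = "chain", arc_mode = arc_mode)
}

# Random curve parameters for property tests (assumes RNG already seeded).
random_curve_spec <- function(dims = c(300L, 300L)) {
  margin <- 30
  p0 <- c(runif(1, margin, dims[2] - margin), runif(1, margin, dims[1] - margin))
  ang <- runif(1, 0, 2 * pi)
  len <- runif(1, 60, 130)
  p1 <- p0 + len * c(cos(ang), sin(ang))
  p1 <- pmin(pmax(p1, 10), c(dims[2] - 10, dims[1] - 10))
  len <- sqrt(sum((p1 - p0)^2))
  kind <- sample(c("line", "arc", "sinusoid", "bezier"), 1)
  params <- switch(kind,
    line = list(),
    arc = list(sagitta = runif(1, 0.02, 0.3) * len),
    sinusoid = list(amplitude = runif(1, 0, 8), k = sample(1:3, 1)),
    bezier = list(o1 = runif(1, -12, 12), o2 = runif(1, -12, 12))
  )
  list(kind = kind, p0 = p0, p1 = p1, params = params)
}
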