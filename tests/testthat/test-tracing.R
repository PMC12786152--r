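test_that("skeleton pixel extraction conserves the foreground count", {
  chain <- cbind(x = 3:12, y = rep(5L, 10))
  sk <- chain_skeleton(chain, 20, 20)
  px <- extract_skeleton_pixels(sk)
  expect_equal(nrow(px), 10)
  expect_equal(nrow(px), sum(sk$grid))
  empty <- mat_skeleton(matrix(FALSE, 5, 5))
  expect_equal(nrow(extract_skeleton_pixels(empty)), 0)
})

test_that("distance to the disc centre is Euclidean and symmetric", {
  od <- optic_disc(0, 0, 1)
  expect_equal(distance_to_od(c(3, 4), od), 5)
  expect_equal(distance_to_od(c(0, 0), od), 0)
  od2 <- optic_disc(10, 10, 1)
  expect_equal(distance_to_od(c(13, 14), od2), distance_to_od(c(7, 6), od2))
})

test_that("start band uses a strict lower and inclusive upper bound", {
  od <- optic_disc(0, 0, 10)
  px <- tibble::tibble(x = c(12, 9, 16, 15, 10), y = rep(0, 5))
  out <- candidate_starts(px, od, delta = 5)
  expect_setequal(out$x, c(12, 15))  # 12 and 15 in (10, 15]; 9, 10, 16 out
})

test_that("endpoint detection finds chain extremes and branch tips", {
  chain <- cbind(x = 3:12, y = rep(5L, 10))
  sk <- chain_skeleton(chain, 20, 20)
  en <- detect_endpoints(sk)
  expect_equal(nrow(en), 2)
  expect_setequal(en$x, c(3, 12))

  # Y shape: three tips
  m <- matrix(FALSE, 20, 20)
  for (i in 0:5) m[10 - i, 10 - i] <- TRUE  # upper-left arm
  for (i in 1:5) m[10 - i, 10 + i] <- TRUE  # upper-right arm
  for (i in 0:5) m[10 + i, 10] <- TRUE      # stem
  sk <- mat_skeleton(m)
  en <- detect_endpoints(sk)
  expect_equal(nrow(en), 3)

  iso <- matrix(FALSE, 5, 5); iso[3, 3] <- TRUE
  expect_equal(nrow(detect_endpoints(mat_skeleton(iso))), 0)
})

test_that("pair validation requires a disc-avoiding path to the band", {
  # single radial line from the band to the periphery: one pair
  od <- optic_disc(50, 50, 10)
  chain <- cbind(x = 62:90, y = rep(50L, 29))
  sk <- chain_skeleton(chain, 100, 100)
  sk <- overlay_od(sk, od)
  px <- extract_skeleton_pixels(sk)
  st <- candidate_starts(px, od, 5)
  en <- detect_endpoints(sk)
  pairs <- validate_pairs(sk, st, en)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$end_x, 90)
  expect_true(pairs$start_x %in% 62:65)

  # disconnected component away from the band: no pairs, with a warning
  far <- chain_skeleton(cbind(x = 80:95, y = rep(80L, 16)), 100, 100)
  far <- overlay_od(far, od)
  fpx <- extract_skeleton_pixels(far)
  expect_warning(
    out <- validate_pairs(far, candidate_starts(fpx, od, 5),
                          detect_endpoints(far)),
    "no candidate starts"
  )
  expect_equal(nrow(out), 0)
})

test_that("endpoints whose only band connection crosses the disc are dropped", {
  # diagonal ray jumps the 1-px band; the lone band pixel connects only
  # through the disc interior
  od <- optic_disc(30, 30, 10)
  m <- matrix(FALSE, 60, 60)
  for (i in 22:45) m[i, i] <- TRUE               # diagonal through the disc
  m[27, 20] <- TRUE                              # band pixel, d ~ 10.44
  m[26, 21] <- TRUE; m[25, 22] <- TRUE; m[24, 23] <- TRUE  # interior connector
  sk <- overlay_od(mat_skeleton(m), od)
  px <- extract_skeleton_pixels(sk)
  st <- candidate_starts(px, od, 1)
  expect_equal(nrow(st), 1)                      # the band pixel exists
  en <- detect_endpoints(sk)
  pairs <- validate_pairs(sk, st, en, od)
  expect_equal(nrow(pairs), 0)
})

test_that("curve length counts pixels inclusively along the BFS path", {
  # 10-px diagonal chain
  chain <- cbind(x = 5:14, y = 5:14)
  rec <- curve_length(chain_skeleton(chain, 20, 20),
                      pair_row(5, 5, 14, 14), od = NULL)
  expect_equal(rec$l_curve, 10)

  # L-shape of two 5-px arms sharing the corner pixel: the shortest
  # 8-connected path cuts the corner diagonally, giving 8 pixels (the
  # independent oracle agrees)
  m <- matrix(FALSE, 20, 20)
  m[10, 5:9] <- TRUE
  m[10:14, 9] <- TRUE
  rec <- curve_length(mat_skeleton(m), pair_row(5, 10, 9, 14), od = NULL)
  expect_equal(rec$l_curve, oracle_path_pixels(m, c(5, 10), c(9, 14)))
  expect_equal(rec$l_curve, 8)

  expect_error(curve_length(mat_skeleton(m), pair_row(1, 1, 9, 14), od = NULL),
               "skeleton")
})

test_that("BFS curve length equals an independent unit-weight Dijkstra", {
  for (seed in 1:50) {
    g <- random_walk_skeleton(seed)
    sk <- mat_skeleton(g)
    en <- detect_endpoints(sk)
    if (nrow(en) < 2) next
    pr <- pair_row(en$x[1], en$y[1], en$x[2], en$y[2])
    mine <- curve_length(sk, pr, od = NULL)$l_curve
    oracle <- oracle_path_pixels(g, c(en$x[1], en$y[1]), c(en$x[2], en$y[2]))
    expect_equal(mine, oracle)
  }
})

test_that("tracing is deterministic and satisfies the step-length bound", {
  ph <- generate_phantom(phantom_spec(image_size = c(256L, 256L),
                                      od_radius = 25, n_vessels = 10, seed = 13))
  av <- build_av_masks(ph$mask, ph$labels)
  sk <- overlay_od(skeletonize(av$artery, "artery"), ph$od)
  t1 <- trace_vessels(sk)
  t2 <- trace_vessels(sk)
  expect_identical(t1, t2)
  expect_gt(length(t1), 0)
  for (tp in t1) {
    steps <- abs(diff(tp$pixels))
    expect_true(all(pmax(steps[, 1], steps[, 2]) == 1))  # 8-adjacent chain
    expect_equal(unname(tp$pixels[1, ]),
                 c(tp$pair$start_x, tp$pair$start_y))
    expect_equal(unname(tp$pixels[nrow(tp$pixels), ]),
                 c(tp$pair$end_x, tp$pair$end_y))
    expect_lte(tp$l_straight, ceiling(sqrt(2) * (tp$l_curve - 1)))
    # retained endpoints obey the disc-exclusion rule
    expect_gt(distance_to_od(c(tp$pair$end_x, tp$pair$end_y), ph$od),
              ph$od$radius_px)
  }
})

test_that("straight length is the rounded Euclidean chord", {
  expect_equal(straight_length(pair_row(0, 0, 3, 4)), 5L)
  expect_equal(straight_length(pair_row(0, 0, 9, 0)), 9L)
  expect_equal(straight_length(pair_row(0, 0, 1, 1)), 1L)  # round(1.414) = 1
  expect_equal(straight_length(pair_row(7, 7, 7, 7)), 0L)
})
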