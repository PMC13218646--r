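test_that("endpoint welding merges nodes exactly and within tolerance", {
  # shared endpoint exactly
  net <- build_network(list(rbind(c(0, 0), c(100, 0)),
                            rbind(c(100, 0), c(100, 100))))
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)

  # endpoints 0.005 m apart, tolerance 0.01 -> welded
  net2 <- build_network(list(rbind(c(0, 0), c(100, 0)),
                             rbind(c(100.003, 0.004), c(100, 100))),
                        weld_tolerance = 0.01)
  expect_equal(nrow(net2$nodes), 3L)

  # same gap, tolerance below it -> not welded
  net3 <- build_network(list(rbind(c(0, 0), c(100, 0)),
                             rbind(c(100.003, 0.004), c(100, 100))),
                        weld_tolerance = 0.001)
  expect_equal(nrow(net3$nodes), 4L)

  expect_error(build_network(list()), "empty network")
  expect_error(build_network(list(rbind(c(0, 0), c(NaN, 1)))), "finite")
})

test_that("a 3x3 block grid welds to 16 nodes and 24 edges", {
  net <- build_network(grid_lines(3), weld_tolerance = 1e-9)
  expect_equal(nrow(net$nodes), 16L)
  expect_equal(nrow(net$edges), 24L)
  # stored length equals geometric length of every edge
  glen <- vapply(net$edges$geometry,
                 function(m) sum(sqrt(rowSums(diff(m)^2))), numeric(1))
  expect_equal(net$edges$length, glen, tolerance = 1e-9)
  expect_true(all(net$edges$length > 0))
})

test_that("snapping returns the nearest on-edge point with a max distance", {
  net <- build_network(list(rbind(c(0, 0), c(3000, 0))))
  o <- snap_to_network(net, c(1500, 10), max_snap = 50)
  expect_equal(o$snap_distance, 10)
  expect_equal(o$offset, 1500)
  expect_equal(o$snapped, c(1500, 0))

  # point exactly on a node
  o2 <- snap_to_network(net, c(0, 0), max_snap = 50)
  expect_equal(o2$snap_distance, 0)
  expect_true(o2$offset %in% c(0, 3000))

  expect_error(snap_to_network(net, c(1500, 100), max_snap = 50),
               "no network within snapping distance")
})

test_that("snapping ties break deterministically on the smallest edge id", {
  # two parallel edges equidistant from the query point
  net <- build_network(list(rbind(c(0, 10), c(100, 10)),
                            rbind(c(0, -10), c(100, -10))))
  o <- snap_to_network(net, c(50, 0), max_snap = 50)
  expect_equal(o$edge_id, 1L)
})

test_that("reachable length handles truncation, stars and mid-edge origins", {
  # origin at midpoint of an isolated 3000 m edge, D = 1000 -> 1000 each way
  net <- build_network(list(rbind(c(0, 0), c(3000, 0))))
  o <- snap_to_network(net, c(1500, 0), max_snap = 1)
  sub <- reachable_subnetwork(net, o, 1000)
  expect_equal(sub$total_length, 2000, tolerance = 1e-9)

  # 4 arms of 600 m, D = 1000 -> all fully reachable
  star <- build_network(list(rbind(c(0, 0), c(600, 0)),
                             rbind(c(0, 0), c(-600, 0)),
                             rbind(c(0, 0), c(0, 600)),
                             rbind(c(0, 0), c(0, -600))))
  os <- snap_to_network(star, c(0, 0), max_snap = 1)
  expect_equal(reachable_subnetwork(star, os, 1000)$total_length, 2400,
               tolerance = 1e-9)

  # 4 arms of 1500 m -> each truncated at 1000
  star2 <- build_network(list(rbind(c(0, 0), c(1500, 0)),
                              rbind(c(0, 0), c(-1500, 0)),
                              rbind(c(0, 0), c(0, 1500)),
                              rbind(c(0, 0), c(0, -1500))))
  os2 <- snap_to_network(star2, c(0, 0), max_snap = 1)
  sub2 <- reachable_subnetwork(star2, os2, 1000)
  expect_equal(sub2$total_length, 4000, tolerance = 1e-9)
  # included polyline lengths match the reported total
  lens <- vapply(sub2$lines, function(m) sum(sqrt(rowSums(diff(m)^2))),
                 numeric(1))
  expect_equal(sum(lens), sub2$total_length, tolerance = 1e-9)

  expect_error(reachable_subnetwork(net, o, -5), "distance")
})

test_that("an edge reachable from both ends is never double-counted", {
  # square loop of 4 x 100 m around the origin corner
  sq <- build_network(grid_lines(1, block = 100), weld_tolerance = 1e-9)
  o <- snap_to_network(sq, c(0, 0), max_snap = 1)
  # D = 150: 150 m clockwise plus 150 m counter-clockwise, no overlap yet
  expect_equal(reachable_subnetwork(sq, o, 150)$total_length, 300,
               tolerance = 1e-9)
  # D = 250 covers every point (farthest is 200 away) exactly once
  expect_equal(reachable_subnetwork(sq, o, 250)$total_length, 400,
               tolerance = 1e-9)
  # ... and larger thresholds cannot inflate it
  expect_equal(reachable_subnetwork(sq, o, 10000)$total_length, 400,
               tolerance = 1e-9)
})

test_that("reachable length is monotone in the distance threshold", {
  rn <- random_network(n_nodes = 10, n_extra = 5, seed = 11)
  net <- build_network(rn$lines, weld_tolerance = 1e-9)
  o <- snap_to_network(net, rn$points[1, ], max_snap = 1)
  ds <- c(200, 500, 1000, 2000, 4000)
  lens <- vapply(ds, function(D) {
    reachable_subnetwork(net, o, D)$total_length
  }, numeric(1))
  expect_true(all(diff(lens) >= -1e-9))
})

test_that("reachable length agrees with the subdivision oracle", {
  for (seed in 1:8) {
    rn <- random_network(n_nodes = sample(6:12, 1), n_extra = sample(2:8, 1),
                         seed = seed)
    net <- build_network(rn$lines, weld_tolerance = 1e-9)
    o <- snap_to_network(net, rn$points[1, ], max_snap = 1)
    for (D in c(400, 900, 1600)) {
      got <- reachable_subnetwork(net, o, D)$total_length
      want <- oracle_reachable_length(rn$lines, rn$points[1, ], D)
      expect_equal(got, want, tolerance = 0.005)
    }
  }
})

test_that("intersections are nodes with 3+ legs", {
  # Y-shape: one degree-3 node
  y <- build_network(list(rbind(c(0, 0), c(0, 100)),
                          rbind(c(0, 0), c(80, -60)),
                          rbind(c(0, 0), c(-80, -60))))
  everything <- list(list(x = c(-200, 200, 200, -200),
                          y = c(-200, -200, 200, 200)))
  expect_equal(count_intersections(y, everything), 1L)

  # straight chain: all degree <= 2
  chain <- build_network(list(rbind(c(0, 0), c(100, 0)),
                              rbind(c(100, 0), c(200, 0)),
                              rbind(c(200, 0), c(300, 0))))
  expect_equal(count_intersections(chain, everything), 0L)

  # 3x3 block grid fully covered: 8 edge nodes deg 3 + 4 interior deg 4 = 12
  grid <- build_network(grid_lines(3, block = 100), weld_tolerance = 1e-9)
  cover <- list(list(x = c(-10, 310, 310, -10), y = c(-10, -10, 310, 310)))
  expect_equal(count_intersections(grid, cover), 12L)
})

test_that("intersection count is invariant under degree-2 subdivision", {
  whole <- build_network(grid_lines(2, block = 100), weld_tolerance = 1e-9)
  # subdivide every edge at its midpoint
  halves <- unlist(lapply(grid_lines(2, block = 100), function(m) {
    mid <- (m[1, ] + m[2, ]) / 2
    list(rbind(m[1, ], mid), rbind(mid, m[2, ]))
  }), recursive = FALSE)
  subdiv <- build_network(halves, weld_tolerance = 1e-9)
  cover <- list(list(x = c(-10, 210, 210, -10), y = c(-10, -10, 210, 210)))
  expect_equal(count_intersections(subdiv, cover),
               count_intersections(whole, cover))
})
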