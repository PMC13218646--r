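test_that("city generation is deterministic given the seed", {
  c1 <- generate_city(city_config(rows = 3, cols = 3, seed = 1))
  c2 <- generate_city(city_config(rows = 3, cols = 3, seed = 1))
  expect_identical(c1$parcels$land_use, c2$parcels$land_use)
  expect_identical(c1$parcels$dwelling_units, c2$parcels$dwelling_units)
  expect_identical(c1$network$nodes, c2$network$nodes)
  c3 <- generate_city(city_config(rows = 3, cols = 3, seed = 2))
  expect_false(identical(c1$parcels$land_use, c3$parcels$land_use))

  h1 <- generate_participants(c1, 20, seed = 7)
  h2 <- generate_participants(c1, 20, seed = 7)
  expect_identical(h1, h2)
})

test_that("config validation rejects degenerate cities and bad mixtures", {
  expect_error(city_config(rows = 0), "degenerate")
  expect_error(city_config(mixture = c(residential = 1)), "six land-use")
  m <- c(residential = 0.9, commercial_retail_office = 0.3,
         institutional_civic = 0, food_related = 0, entertainment = 0,
         park = 0)
  expect_error(city_config(mixture = m), "summing to 1")
})

test_that("parcels tile their blocks without overlap", {
  city <- generate_city(city_config(rows = 2, cols = 2, block = 100,
                                    parcels_per_side = 4, seed = 3))
  p <- city$parcels
  expect_equal(nrow(p), 2 * 2 * 16)
  # per-block areas add to the block area
  expect_equal(sum(p$area), 4 * 100 * 100, tolerance = 1e-9)
  # pairwise overlap is zero
  for (i in seq_len(nrow(p) - 1)) {
    bi <- dlumr:::rings_bbox(p$geometry[[i]])
    for (j in seq((i + 1), nrow(p))) {
      bj <- dlumr:::rings_bbox(p$geometry[[j]])
      if (bi[1] >= bj[3] || bi[3] <= bj[1] || bi[2] >= bj[4] ||
          bi[4] <= bj[2]) next
      ov <- dlumr:::rings_area(
        dlumr:::rings_intersection(p$geometry[[i]], p$geometry[[j]])
      )
      expect_lt(ov, 1e-9)
    }
  }
  # all parcels inside the city bounds
  bb <- dlumr:::rings_bbox(do.call(c, p$geometry))
  expect_gte(bb[1], 0); expect_lte(bb[3], 200)
  expect_gte(bb[2], 0); expect_lte(bb[4], 200)
})

test_that("land-use frequencies converge to the mixture", {
  mix <- c(residential = 0.5, commercial_retail_office = 0.2,
           institutional_civic = 0.1, food_related = 0.1,
           entertainment = 0.05, park = 0.05)
  city <- generate_city(city_config(rows = 25, cols = 25, block = 100,
                                    parcels_per_side = 4, mixture = mix,
                                    seed = 11))
  counts <- table(factor(city$parcels$land_use, levels = names(mix)))
  expect_equal(sum(counts), 10000)
  gof <- stats::chisq.test(counts, p = mix)
  expect_gt(gof$p.value, 0.01)
})

test_that("an all-residential mixture produces buffers with no destinations", {
  mix <- c(residential = 1, commercial_retail_office = 0,
           institutional_civic = 0, food_related = 0, entertainment = 0,
           park = 0)
  city <- generate_city(city_config(rows = 3, cols = 3, block = 120,
                                    parcels_per_side = 2, mixture = mix,
                                    seed = 5))
  expect_true(all(city$parcels$land_use == "residential"))
  expect_true(all(city$parcels$dwelling_units >= 1))
  homes <- generate_participants(city, 3, seed = 1)
  ind <- compute_dlum(city$parcels, city$network, homes, distance = 250)
  expect_true(all(ind$dlum3a == 0))
})

test_that("home points fall inside residential parcels and sites partition", {
  city <- generate_city(city_config(rows = 3, cols = 3, seed = 8))
  homes <- generate_participants(city, 100, seed = 2)
  res <- city$parcels[city$parcels$land_use == "residential", ]
  inside <- vapply(seq_len(nrow(homes)), function(i) {
    any(vapply(res$geometry, function(g) {
      dlumr:::point_in_rings(g, homes$x[i], homes$y[i])
    }, logical(1)))
  }, logical(1))
  expect_true(all(inside))

  cityB <- generate_city(city_config(rows = 3, cols = 3, seed = 9))
  hA <- generate_participants(city, 10, seed = 1, site = "A")
  hB <- generate_participants(cityB, 10, seed = 1, site = "B")
  both <- dplyr::bind_rows(hA, hB)
  expect_equal(unname(table(both$site)["A"]), 10)

  no_res <- generate_city(city_config(
    rows = 2, cols = 2, seed = 1,
    mixture = c(residential = 0, commercial_retail_office = 1,
                institutional_civic = 0, food_related = 0,
                entertainment = 0, park = 0)
  ))
  expect_error(generate_participants(no_res, 5), "no residential parcels")
})

test_that("perception scores band walking minutes as specified", {
  cfg <- behavior_config(misclassification = 0, walking_speed = 80)
  d <- tibble::tibble(
    shop = c(200, 3000, 700, 1300, 2300),
    park = c(400, 400, 400, 400, 400)
  )
  sc <- simulate_perception(d, cfg)
  expect_equal(sc$score_shop, c(5L, 1L, 4L, 3L, 2L))
  expect_equal(sc$score_park, rep(5L, 5))

  # composite is the mean of item scores
  expect_equal(sc$composite, (sc$score_shop + sc$score_park) / 2)
  all3 <- simulate_perception(
    tibble::tibble(a = 1000, b = 1000, c = 1000), cfg
  )
  expect_equal(all3$composite, 3)

  expect_error(simulate_perception(tibble::tibble(a = -5), cfg),
               "non-negative")
  # noise stays within the 1..5 scale
  noisy <- simulate_perception(
    tibble::tibble(a = runif(500, 0, 4000)),
    behavior_config(misclassification = 0.5, seed = 3)
  )
  expect_true(all(noisy$score_a >= 1 & noisy$score_a <= 5))
})

test_that("nearest-destination distances are exact on a simple strip", {
  # one street, destination parcel centred at x = 1000
  net <- build_network(list(rbind(c(0, 0), c(2000, 0))))
  city <- list(
    network = net,
    parcels = parcels(
      list(
        rbind(c(950, 5), c(1050, 5), c(1050, 55), c(950, 55)),
        rbind(c(0, -55), c(100, -55), c(100, -5), c(0, -5))
      ),
      c("food_related", "residential"), c(0L, 10L)
    ),
    config = city_config()
  )
  class(city) <- "synthetic_city"
  homes <- tibble::tibble(x = c(100, 1000), y = c(0, 0))
  d <- nearest_destination_distances(city, homes, types = "food_related")
  expect_equal(d$food_related, c(900, 0), tolerance = 1e-6)
})

test_that("a null behavioural slope decouples outcomes from the indicator", {
  rhos <- vapply(1:25, function(seed) {
    withr::local_seed(seed)
    z <- rnorm(400)
    pa <- simulate_pa(z, behavior_config(beta = 0, seed = seed + 1000))
    suppressWarnings(stats::cor(z, pa$nonschool_active_transport,
                                method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 / sqrt(25 * 400))
})

test_that("the Poisson intercept sets the mean weekly frequency", {
  withr::local_seed(9)
  z <- rnorm(5000)
  pa <- simulate_pa(z, behavior_config(alpha = log(5), beta = 0, seed = 77))
  expect_equal(mean(pa$nonschool_active_transport), 5, tolerance = 0.1)
})

test_that("raising the non-residential share raises mean gross density", {
  shares <- c(0.2, 0.45, 0.7)
  means <- vapply(shares, function(sh) {
    mix <- c(residential = 1 - sh,
             commercial_retail_office = sh * 0.35,
             institutional_civic = sh * 0.2,
             food_related = sh * 0.2,
             entertainment = sh * 0.1,
             park = sh * 0.15)
    city <- generate_city(city_config(rows = 4, cols = 4, block = 120,
                                      parcels_per_side = 3, mixture = mix,
                                      seed = 31))
    homes <- generate_participants(city, 8, seed = 4)
    ind <- compute_dlum(city$parcels, city$network, homes, distance = 400)
    mean(ind$dlum3b)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
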