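test_that("terrain operator reproduces analytic planes", {
  nr <- 12; nc <- 15
  cell_km <- c(2, 2)
  # plane deepening northward: depth = z0 + k * northing
  northing <- (nr - row(matrix(0, nr, nc)) + 0.5) * cell_km[2] * 1000
  k <- 0.05
  g <- grid_layer(100 + k * northing, name = "plane")
  terr <- compute_slope_aspect(g, cell_km = cell_km)
  interior <- as.matrix(expand.grid(2:(nr - 1), 2:(nc - 1)))
  expect_lt(max(abs(unclass(terr$slope)[interior] - atan(k))), 1e-10)
  expect_lt(max(abs(unclass(terr$aspect)[interior] - 0)), 1e-10)
  # oblique plane: gradient g in a known direction
  easting <- (col(matrix(0, nr, nc)) - 0.5) * cell_km[1] * 1000
  g2 <- grid_layer(10 + 0.03 * easting + 0.04 * northing, name = "plane2")
  t2 <- compute_slope_aspect(g2, cell_km = cell_km)
  expect_lt(max(abs(unclass(t2$slope)[interior] - atan(0.05))), 1e-10)
  expect_lt(max(abs(unclass(t2$aspect)[interior] -
                      (atan2(0.03, 0.04) * 180 / pi))), 1e-10)
})

test_that("constant depth is flat with aspect 0 by convention", {
  g <- grid_layer(matrix(55, 10, 12), name = "flat")
  terr <- compute_slope_aspect(g, cell_km = c(1, 1))
  expect_true(all(unclass(terr$slope) == 0))
  expect_true(all(unclass(terr$aspect) == 0))
  expect_gt(attr(terr$aspect, "n_flat"), 0)
})

test_that("distance to shore follows the half-cell convention", {
  land <- matrix(0, 10, 10)
  land[, 10] <- 1 # eastern land strip
  g <- grid_layer(land, name = "land")
  d <- distance_to_shore(g, method = "planar")
  m <- grid_meta(g)
  cc <- cell_centres(g)
  half_km <- (m$dx * 111.195 * cos(mean(range(cc$lat)) * pi / 180) +
                m$dy * 111.195) / 4
  expect_equal(unclass(d)[5, 9], half_km * 1000, tolerance = 1e-9)
  expect_true(all(unclass(d)[, 1:9] > 0))
  expect_true(all(is.na(unclass(d)[, 10])))
})

test_that("distance to shore agrees with a brute-force oracle", {
  withr::with_seed(21, {
    land <- matrix(as.numeric(runif(400) < 0.15), 20, 20)
    land[1, 1] <- 1
    g <- grid_layer(land, name = "land")
    d <- distance_to_shore(g, method = "planar")
    cc <- cell_centres(g)
    m <- grid_meta(g)
    lat0 <- mean(range(cc$lat))
    x <- cc$lon * 111.195 * cos(lat0 * pi / 180)
    y <- cc$lat * 111.195
    half <- (m$dx * 111.195 * cos(lat0 * pi / 180) + m$dy * 111.195) / 4
    # coastal land cells by 4-neighbour adjacency
    is_land <- land == 1
    coast <- c()
    for (i in 1:20) for (j in 1:20) {
      if (!is_land[i, j]) next
      nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 20 & nb[, 2] >= 1 & nb[, 2] <= 20,
               , drop = FALSE]
      if (any(!is_land[nb])) coast <- c(coast, (j - 1) * 20 + i)
    }
    for (i in 1:20) for (j in 1:20) {
      if (is_land[i, j]) next
      idx <- (j - 1) * 20 + i
      dd <- min(sqrt((x[idx] - x[coast])^2 + (y[idx] - y[coast])^2))
      expect_equal(unclass(d)[i, j], max(dd - half, half) * 1000,
                   tolerance = 1e-9)
    }
  })
})

test_that("sediment reclassification merges 17 codes into 5 classes", {
  withr::with_seed(4, {
    raw <- grid_layer(matrix(sample(1:17, 120, TRUE), 10, 12), name = "sed")
    out <- reclassify_sediment(raw)
    expect_equal(sort(unique(as.vector(unclass(out)))), 1:5)
    expect_false(attr(out, "empty_domain"))
  })
  rocky <- grid_layer(matrix(15, 10, 10), name = "sed")
  out <- reclassify_sediment(rocky)
  expect_true(attr(out, "empty_domain"))
  merged <- grid_layer(matrix(c(1, 8, 12, 15), 10, 10, byrow = TRUE),
                       name = "sed")
  map5 <- tibble::tibble(raw_code = c(1, 8, 12, 15),
                         class = c("mud_sandy_mud", "coarse", "mixed",
                                   "rock"))
  out2 <- reclassify_sediment(merged, map5)
  expect_equal(sediment_levels()[unclass(out2)[1, 1:4]],
               c("mud_sandy_mud", "coarse", "mixed", "rock"))
  expect_error(reclassify_sediment(merged, map5[1:2, ]), "unmapped")
})

test_that("bottom CTD selection keeps the deepest record per station", {
  casts <- tibble::tibble(
    station_id = c("a", "a", "a", "b"),
    lon = -7, lat = 55, year = 2011, season = "OCT_NOV",
    pressure = c(10, 50, 30, 12),
    temperature = c(11, 9, 10, 12), salinity = 34)
  out <- select_bottom_ctd(casts)
  expect_equal(nrow(out), 2)
  expect_equal(out$pressure[out$station_id == "a"], 50)
  expect_equal(out$temperature[out$station_id == "b"], 12)
  # brute-force group-by max on a random fixture, ties to last occurrence
  withr::with_seed(8, {
    rnd <- tibble::tibble(
      station_id = sample(letters[1:6], 60, TRUE),
      lon = -7, lat = 55, year = sample(2011:2012, 60, TRUE),
      season = "OCT_NOV",
      pressure = sample(c(10, 20, 30), 60, TRUE),
      temperature = rnorm(60), salinity = rnorm(60, 34))
    got <- select_bottom_ctd(rnd)
    key <- paste(rnd$station_id, rnd$year)
    for (k in unique(key)) {
      rows <- which(key == k)
      best <- rows[max(which(rnd$pressure[rows] == max(rnd$pressure[rows])))]
      gi <- which(paste(got$station_id, got$year) == k)
      expect_equal(got$temperature[gi], rnd$temperature[best])
    }
  })
})

test_that("kernel smoothing matches its definition and limits", {
  grid <- grid_layer(matrix(0, 5, 5), name = "t")
  withr::with_seed(31, {
    casts <- tibble::tibble(lon = runif(10, -9, -4), lat = runif(10, 53, 58),
                            temperature = rnorm(10, 10))
  })
  # constant field stays constant for any bandwidth
  const <- dplyr::mutate(casts, temperature = 7.5)
  for (th in c(1, 50, 400))
    expect_equal(as.vector(unclass(kernel_smooth(const, grid, th))),
                 rep(7.5, 25), tolerance = 1e-12)
  # huge bandwidth tends to the arithmetic mean
  big <- kernel_smooth(casts, grid, 1e6)
  expect_equal(as.vector(unclass(big)), rep(mean(casts$temperature), 25),
               tolerance = 1e-6)
  # brute-force double loop oracle, 10 casts x 25 cells
  th <- 80
  got <- kernel_smooth(casts, grid, th)
  cc <- cell_centres(grid)
  for (i in 1:5) for (j in 1:5) {
    w <- exp(-haversine_km(cc$lon[i, j], cc$lat[i, j], casts$lon,
                           casts$lat)^2 / (2 * th^2))
    expect_equal(unclass(got)[i, j], sum(w * casts$temperature) / sum(w),
                 tolerance = 1e-12)
  }
  # shift/scale equivariance in the response
  a <- 2.5; b <- -4
  lhs <- kernel_smooth(dplyr::mutate(casts, temperature =
                                       a * temperature + b), grid, th)
  expect_equal(unclass(lhs), a * unclass(got) + b, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("LOOCV is exact and its minimiser is the reported bandwidth", {
  withr::with_seed(32, {
    casts <- tibble::tibble(lon = runif(15, -9, -4), lat = runif(15, 53, 58),
                            temperature = rnorm(15, 10))
  })
  grid_theta <- c(5, 20, 80, 300)
  kf <- select_bandwidth_loocv(casts, grid_theta)
  expect_true(all(kf$grid$score >= kf$score - 1e-12))
  # removing cast i and predicting at x_i equals a fresh smooth without it
  th <- 20
  score <- 0
  for (i in seq_len(nrow(casts))) {
    g1 <- grid_layer(matrix(0, 1, 1), xll = casts$lon[i] - 0.005,
                     yll = casts$lat[i] - 0.005, dx = 0.01, dy = 0.01)
    pred <- unclass(kernel_smooth(casts[-i, ], g1, th))[1, 1]
    score <- score + (casts$temperature[i] - pred)^2
  }
  expect_equal(kf$grid$score[kf$grid$theta == th], score, tolerance = 1e-6)
  # degenerate co-located casts fall back to the mid-grid bandwidth
  co <- dplyr::mutate(casts, lon = -7, lat = 55)
  kf2 <- select_bandwidth_loocv(co, grid_theta)
  expect_true(kf2$degenerate)
  expect_equal(kf2$theta, 20)
})

test_that("haul covariate extraction is a nearest-cell lookup", {
  env <- fix_env()
  cc <- cell_centres(env$depth)
  sea <- which(unclass(env$land) == 0 &
                 sediment_levels()[unclass(env$sediment)] != "rock")
  pick <- sea[c(3, 10, 25)]
  hauls <- tibble::tibble(
    haul_id = paste0("x", 1:3), survey = "SWC_IBTS", gear = "GOV",
    year = 2011, season = "OCT_NOV", lon = cc$lon[pick], lat = cc$lat[pick],
    duration = 30)
  cov <- extract_at_hauls(env, hauls)
  expect_true(all(cov$valid))
  expect_equal(cov$depth, unclass(env$depth)[pick])
  expect_equal(cov$temperature,
               unclass(env$temperature[["2011_OCT_NOV"]])[pick])
  off <- dplyr::mutate(hauls[1, ], lon = -20, haul_id = "off")
  cov2 <- extract_at_hauls(env, off)
  expect_false(cov2$valid)
  expect_equal(cov2$reason, "off grid")
  # brute-force nearest-centre agreement for jittered positions
  withr::with_seed(33, {
    m <- grid_meta(env$depth)
    jit <- tibble::tibble(
      haul_id = paste0("j", 1:20), survey = "SWC_IBTS", gear = "GOV",
      year = 2011, season = "OCT_NOV",
      lon = runif(20, -9.9, -4), lat = runif(20, 52.1, 58.9),
      duration = 30)
    cov3 <- extract_at_hauls(env, jit)
    for (i in 1:20) {
      d2 <- (cc$lon - jit$lon[i])^2 + (cc$lat - jit$lat[i])^2
      nearest <- which.min(d2)
      expect_equal(is.na(cov3$depth[i]), is.na(unclass(env$depth)[nearest]))
      if (!is.na(cov3$depth[i]))
        expect_equal(cov3$depth[i], unclass(env$depth)[nearest])
    }
  })
})
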