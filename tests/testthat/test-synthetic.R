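test_that("environment generation is deterministic and shape-checked", {
  a <- generate_environment(5, c(12, 15), years_feb = 2009, years_oct = 2011)
  b <- generate_environment(5, c(12, 15), years_feb = 2009, years_oct = 2011)
  expect_identical(unclass(a$depth), unclass(b$depth))
  expect_identical(unclass(a$temperature[[1]]), unclass(b$temperature[[1]]))
  c <- generate_environment(6, c(12, 15), years_feb = 2009, years_oct = 2011)
  expect_false(identical(unclass(a$depth), unclass(c$depth)))
  expect_error(generate_environment(1, c(5, 5)), "at least 10")
})

test_that("flat bathymetry gives identically zero slope at sea", {
  env <- generate_environment(3, c(12, 15), years_feb = 2009,
                              years_oct = 2011, flat_depth = 50)
  sea <- unclass(env$land) == 0
  expect_true(all(unclass(env$slope)[sea] == 0))
})

test_that("monotone bathymetry deepens strictly westward in every row", {
  env <- generate_environment(2, c(12, 15), years_feb = 2009,
                              years_oct = 2011, monotone_lon = TRUE)
  cc <- cell_centres(env$depth)
  for (r in seq_len(nrow(env$depth))) {
    sea <- !is.na(unclass(env$depth)[r, ])
    if (sum(sea) < 3) next
    expect_equal(cor(unclass(env$depth)[r, sea], -cc$lon[r, sea],
                     method = "spearman"), 1)
  }
})

test_that("haul generation respects survey design", {
  env <- fix_env()
  h <- generate_hauls(env, 10, years = 2011:2012, season = "OCT_NOV",
                      seed = 1)
  expect_equal(nrow(h), 40) # 10 per survey per year, 2 surveys, 2 years
  expect_setequal(unique(h$duration[h$survey == "SWC_IBTS"]), 30)
  expect_setequal(unique(h$duration[h$survey == "NIGFS"]), 60)
  expect_equal(unique(gear_for_survey(h$survey)), unique(h$gear))
  idx <- grid_index(env$depth, h$lon, h$lat)
  on_sea <- unclass(env$land)[cbind(idx$row, idx$col)] == 0
  expect_true(all(on_sea))
  expect_identical(h, generate_hauls(env, 10, 2011:2012, "OCT_NOV", seed = 1))
})

test_that("haul cell usage is uniform over eligible sea cells", {
  env <- fix_env()
  h <- generate_hauls(env, c(SWC_IBTS = 5000, NIGFS = 1), years = 2011,
                      season = "OCT_NOV", seed = 2)
  h <- h[h$survey == "SWC_IBTS", ]
  idx <- grid_index(env$depth, h$lon, h$lat)
  cell <- paste(idx$row, idx$col)
  cc <- cell_centres(env$depth)
  m <- grid_meta(env$depth)
  eligible <- which(unclass(env$land) == 0 &
                      cc$lat >= 52 + 7 / 3 + m$dy / 2)
  all_cells <- paste(row(env$depth)[eligible], col(env$depth)[eligible])
  counts <- table(factor(cell, levels = all_cells))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("SMALK labels follow the true logistic schedules", {
  truth <- fix_truth()
  sm <- generate_smalks(truth, 10000, seed = 9, seasons = "OCT_NOV")
  sm <- sm[sm$region == "S-M" & sm$year == 2011 & sm$sex == "F", ]
  par <- truth$stage_par
  p0 <- par[par$stage == "AGE0" & par$region == "S-M" &
              par$year == 2011 & par$sex == "F", ]
  bins <- cut(sm$length, breaks = c(10, 15, 20, 25, 30))
  for (b in levels(bins)) {
    sel <- !is.na(bins) & bins == b
    if (sum(sel) < 50) next
    phat <- mean(sm$age[sel] == 0)
    ptrue <- mean(plogis(p0$intercept + p0$slope * sm$length[sel]))
    se <- sqrt(ptrue * (1 - ptrue) / sum(sel))
    expect_lt(abs(phat - ptrue), 4 * se + 1e-9)
  }
  expect_identical(sm, {
    s2 <- generate_smalks(truth, 10000, seed = 9, seasons = "OCT_NOV")
    s2[s2$region == "S-M" & s2$year == 2011 & s2$sex == "F", ]
  })
})

test_that("a near-step age-0 schedule splits fish exactly at L50", {
  truth <- fix_truth()
  truth$stage_par <- dplyr::mutate(
    truth$stage_par,
    slope = ifelse(.data$stage == "AGE0", -50, .data$slope),
    intercept = -.data$slope * .data$l50)
  sm <- generate_smalks(truth, 2000, seed = 11, seasons = "OCT_NOV")
  par <- truth$stage_par[truth$stage_par$stage == "AGE0", ]
  key <- paste(sm$region, sm$sex, sm$year)
  l50 <- par$l50[match(key, paste(par$region, par$sex, par$year))]
  below <- sm$length < l50 - 0.2
  above <- sm$length > l50 + 0.2
  expect_true(all(sm$age[below] == 0))
  expect_true(all(sm$age[above] != 0))
})

test_that("catches vanish when presence is impossible", {
  env <- fix_env()
  truth <- fix_truth()
  truth$hurdle <- lapply(truth$hurdle, function(h) {
    h$presence["b0"] <- -50
    h$presence["depth"] <- 0
    h$presence["shore"] <- 0
    h
  })
  truth$gear_presence[] <- 0
  h <- generate_hauls(env, 30, 2011, "OCT_NOV", seed = 3)
  catches <- generate_catches(env, h, truth, seed = 4)
  expect_equal(nrow(catches), 0)
  expect_true(all(attr(catches, "true_totals")$total == 0))
})

test_that("zero-truncated draws match the closed-form mean", {
  withr::with_seed(10, {
    lam <- 2
    x <- rztpois(10000, lam)
    expect_true(all(x >= 1))
    mu <- lam / (1 - exp(-lam))
    v <- mu * (1 + lam - mu)
    expect_lt(abs(mean(x) - mu), 3 * sqrt(v / 10000))
  })
})

test_that("simulated zero fraction matches the presence process", {
  env <- fix_env()
  truth <- fix_truth()
  h <- generate_hauls(env, c(SWC_IBTS = 400, NIGFS = 1), 2011, "OCT_NOV",
                      seed = 6)
  catches <- generate_catches(env, h, truth, seed = 7)
  tt <- attr(catches, "true_totals")
  tt <- tt[tt$stage == "AGE0" & grepl("SWC", tt$haul_id), ]
  p_true <- plogis(tt$eta_presence)
  expected_zero <- mean(1 - p_true)
  se <- sqrt(sum(p_true * (1 - p_true))) / nrow(tt)
  expect_lt(abs(mean(tt$total == 0) - expected_zero), 3 * se + 1e-9)
})

test_that("exported truth matches its analytic definitions", {
  env <- fix_env()
  truth <- fix_truth()
  tr <- export_truth(truth, env)
  expect_equal(tr$l50$l50, -tr$l50$intercept / tr$l50$slope)
  g <- tr$grids[["AGE0_2011"]]
  expect_true(same_extent(g$p, env$depth))
  p <- unclass(g$p); lam <- unclass(g$lambda); comb <- unclass(g$combined)
  ok <- is.finite(p)
  expect_equal(comb[ok], (p * lam / (1 - exp(-lam)))[ok], tolerance = 1e-12)
  expect_true(all(comb[ok] >= (p * lam)[ok] - 1e-12))
})

test_that("generated survey data satisfy the io invariants", {
  tabs <- fix_tables()
  expect_equal(nrow(tabs$rejected), 0)
  expect_true(all(tabs$lengths$count >= 0))
  expect_true(all(tabs$smalks$age[tabs$smalks$mature] >= 1))
  expect_true(all(tabs$hauls$duration %in% c(30, 60)))
})
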