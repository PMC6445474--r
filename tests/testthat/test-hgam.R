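make_cov <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    depth = runif(n, 10, 150),
    prox_shore = runif(n, 500, 60000),
    temperature = runif(n, 8, 14),
    aspect = runif(n, 0, 360),
    lon = runif(n, -10, -3),
    survey = sample(survey_levels(), n, replace = TRUE)))
}

test_that("ZTP log-likelihood matches closed forms and brute force", {
  expect_equal(ztp_loglik(1, 1), -1 - log(1 - exp(-1)), tolerance = 1e-12)
  # lambda -> 0 with y = 1: the truncated mass concentrates at 1
  expect_equal(ztp_loglik(1, 1e-9), 0, tolerance = 1e-6)
  # brute-force normalisation over y = 1..1000 at lambda = 3
  lam <- 3
  ys <- 1:1000
  pmf <- stats::dpois(ys, lam) / (1 - stats::dpois(0, lam))
  for (y in c(1, 2, 5, 11))
    expect_equal(ztp_loglik(y, lam), log(pmf[y]), tolerance = 1e-10)
  expect_error(ztp_loglik(0, 1), "presence")
  expect_error(ztp_loglik(2, -1), "positive")
})

test_that("binomial component recovers a smooth depth effect", {
  d <- make_cov(1000, seed = 61)
  eta <- 1.5 - 0.05 * (d$depth - 70)
  withr::with_seed(62, y <- rbinom(1000, 1, plogis(eta)))
  fit <- fit_presence_gam(d, y, c("s(depth)", "re(survey)"))
  grid <- tibble::tibble(depth = seq(15, 145, length.out = 50),
                         prox_shore = 2e4, temperature = 10, aspect = 0,
                         lon = -6, survey = "SWC_IBTS")
  fhat <- predict(fit, grid)
  ftrue <- 1.5 - 0.05 * (grid$depth - 70)
  expect_gte(cor(fhat, ftrue, method = "spearman"), 0.9)
  # agrees with an independent penalized-GAM implementation
  dd <- dplyr::mutate(d, survey = factor(survey))
  g <- mgcv::gam(y ~ s(depth, bs = "cr", k = 10) + s(survey, bs = "re"),
                 family = binomial(), data = dd)
  expect_gt(cor(fitted(g), fit$fitted), 0.999)
})

test_that("smooth terms shrink towards their null space on noise labels", {
  hits <- 0
  for (s in 1:20) {
    d <- make_cov(300, seed = 600 + s)
    withr::with_seed(700 + s, y <- rbinom(300, 1, 0.5))
    fit <- fit_presence_gam(d, y, "s(depth)")
    if (fit$edf_by_term[["s(depth)"]] <= 1.5) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("a null gear contrast is estimated within 3 SE of zero", {
  d <- make_cov(800, seed = 63)
  eta <- 0.5 - 0.03 * (d$depth - 70) # no survey effect in truth
  withr::with_seed(64, y <- rbinom(800, 1, plogis(eta)))
  fit <- fit_presence_gam(d, y, c("s(depth)", "re(survey)"))
  ct <- re_contrast(fit)
  expect_lt(abs(ct$contrast), 3 * ct$se)
})

test_that("ZTP component recovers rates and matches an external fit", {
  d <- make_cov(1000, seed = 65)
  lam <- exp(1.8 - 0.02 * (d$depth - 70))
  withr::with_seed(66, y <- rztpois(1000, lam))
  fit <- fit_ztp_gam(d, y, "s(depth)")
  expect_gte(cor(exp(predict(fit, d)), lam, method = "spearman"), 0.95)
  expect_gte(fit$deviance, 0)
  # linear-predictor cross-check against glmmTMB's truncated Poisson
  skip_if_not_installed("glmmTMB")
  d$x <- (d$depth - 70) / 40
  mine <- fit_ztp_gam(d, y, "x")
  tmb <- glmmTMB::glmmTMB(y ~ x, family = glmmTMB::truncated_poisson(),
                          data = d)
  expect_equal(unname(mine$beta),
               unname(unlist(glmmTMB::fixef(tmb)$cond)), tolerance = 1e-4)
})

test_that("intercept-only ZTP fit recovers a constant rate", {
  withr::with_seed(67, y <- rztpois(2000, 3))
  d <- tibble::tibble(dummy = rep(1, 2000))
  fit <- fit_ztp_gam(d, y, character(0))
  lam_hat <- exp(fit$beta[[1]])
  se_lam <- lam_hat * sqrt(fit$Vb[1, 1])
  expect_lt(abs(lam_hat - 3), 3 * se_lam)
})

test_that("the aspect smooth is exactly periodic", {
  d <- make_cov(500, seed = 68)
  withr::with_seed(69,
                   y <- rbinom(500, 1, plogis(0.8 * cos(d$aspect * pi / 180))))
  fit <- fit_presence_gam(d, y, "s(aspect)")
  at <- function(a) predict(fit, tibble::tibble(aspect = a))
  expect_identical(at(0), at(360))
})

test_that("tensor-product terms fit a two-covariate interaction", {
  d <- make_cov(800, seed = 70)
  eta <- 0.8 * sin(d$depth / 40) * (d$lon + 6.5)
  withr::with_seed(71, y <- rbinom(800, 1, plogis(eta)))
  fit <- fit_presence_gam(d, y, "te(depth,lon)", control = hgam_control())
  expect_gt(cor(predict(fit, d), eta, method = "spearman"), 0.7)
  expect_lte(fit$edf_by_term[["te(depth,lon)"]],
             hgam_control()$k_te^2)
})

test_that("deviance decreases when an informative term is added", {
  d <- make_cov(600, seed = 72)
  eta <- 0.5 - 0.03 * (d$depth - 70) + 0.05 * (d$temperature - 11)
  withr::with_seed(73, y <- rbinom(600, 1, plogis(eta)))
  d$zd <- (d$depth - 70) / 40
  d$zt <- d$temperature - 11
  f1 <- fit_presence_gam(d, y, "zd")
  f2 <- fit_presence_gam(d, y, c("zd", "zt"))
  expect_lte(f2$deviance, f1$deviance + 1e-8)
})

test_that("combined prediction uses the truncated-Poisson mean", {
  expect_equal(combined_cpue(1, 1), 1 / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(combined_cpue(0, 5), 0)
  p <- runif(20); lam <- runif(20, 0.1, 10)
  expect_true(all(combined_cpue(p, lam) >= p * lam))
  expect_equal(combined_cpue(p, lam, truncated = FALSE), p * lam)
})

test_that("single-term deletion importance flags the signal term", {
  d <- make_cov(500, seed = 74)
  eta <- 1.2 - 0.05 * (d$depth - 70)
  withr::with_seed(75, y <- rbinom(500, 1, plogis(eta)))
  fit <- fit_presence_gam(d, y, c("s(depth)", "s(temperature)"))
  imp <- delta_deviance(fit)
  expect_gt(imp$delta_deviance[imp$term == "s(depth)"],
            imp$delta_deviance[imp$term == "s(temperature)"])
  expect_lt(imp$p_value[imp$term == "s(depth)"], 0.001)
})

test_that("stepwise AIC keeps signal terms and tracks the reference GAM", {
  # AIC retains a null 1-edf smooth with probability ~0.16 by construction,
  # so the null term is dropped in the clear majority of replicates but not
  # near-always; the decisions should agree with mgcv's AIC on the same
  # data, and the signal term must survive every replicate.
  my_drop <- 0
  mgcv_drop <- 0
  agree <- 0
  kept_signal <- 0
  for (s in 1:20) {
    d <- make_cov(250, seed = 800 + s)
    eta <- 1.2 - 0.05 * (d$depth - 70)
    withr::with_seed(900 + s, y <- rbinom(250, 1, plogis(eta)))
    sel <- stepwise_aic(d, y, c("s(depth)", "s(temperature)"),
                        family = "binomial")
    mine <- !"s(temperature)" %in% sel$terms
    if (mine) my_drop <- my_drop + 1
    if ("s(depth)" %in% sel$terms) kept_signal <- kept_signal + 1
    g2 <- mgcv::gam(y ~ s(depth, bs = "cr", k = 10) +
                      s(temperature, bs = "cr", k = 10),
                    family = binomial(), data = d, gamma = 1.4)
    g1 <- mgcv::gam(y ~ s(depth, bs = "cr", k = 10), family = binomial(),
                    data = d, gamma = 1.4)
    ref <- AIC(g1) <= AIC(g2)
    if (ref) mgcv_drop <- mgcv_drop + 1
    if (ref == mine) agree <- agree + 1
  }
  expect_equal(kept_signal, 20)
  expect_gte(my_drop, 12)
  expect_gte(agree, 16)
  expect_gte(my_drop, mgcv_drop - 2)
})

test_that("duplicating a covariate cannot improve AIC materially", {
  d <- make_cov(400, seed = 76)
  eta <- 1 - 0.04 * (d$depth - 70)
  withr::with_seed(77, y <- rbinom(400, 1, plogis(eta)))
  d$depth_copy <- d$depth
  f1 <- fit_presence_gam(d, y, "s(depth)")
  f2 <- fit_presence_gam(d, y, c("s(depth)", "s(depth_copy)"))
  expect_gte(f2$aic, f1$aic - 2)
})

test_that("VIF screening matches the auxiliary-regression definition", {
  withr::with_seed(78, {
    d <- tibble::tibble(x1 = rnorm(1000), x2 = rnorm(1000),
                        x3 = rnorm(1000))
    out <- vif_screen(d, c("x1", "x2", "x3"))
    expect_setequal(out$retained, c("x1", "x2", "x3"))
    expect_true(all(out$report$vif < 1.1))
    # near-collinear: x4 = x1 + x2 + tiny noise
    d$x4 <- d$x1 + d$x2 + rnorm(1000, sd = 0.01)
    r2 <- summary(stats::lm(x4 ~ x1 + x2 + x3, data = d))$r.squared
    out2 <- vif_screen(d, c("x1", "x2", "x3", "x4"))
    expect_equal(out2$report$vif[out2$report$iteration == 1 &
                                   out2$report$variable == "x4"],
                 1 / (1 - r2), tolerance = 1e-8)
    expect_false("x4" %in% out2$retained && "x1" %in% out2$retained &&
                   "x2" %in% out2$retained)
    expect_equal(length(out2$retained), 3)
    # exact duplicate: one copy dropped first
    d$x5 <- d$x1
    out3 <- vif_screen(d[, c("x1", "x5", "x2")], c("x1", "x5", "x2"))
    expect_equal(length(out3$retained), 2)
    expect_true("x2" %in% out3$retained)
  })
})

test_that("hurdle predictions over the stack respect the domain", {
  env <- fix_env()
  tabs <- fix_tables()
  models <- fix_stage_models()
  cp <- decompose_cpue(tabs, models)
  cov <- dplyr::filter(extract_at_hauls(env, tabs$hauls), valid)
  dat <- dplyr::inner_join(
    dplyr::select(cp, haul_id, dplyr::starts_with("cpue_")), cov,
    by = "haul_id")
  dat <- dplyr::filter(dat, season == "OCT_NOV")
  hm <- fit_hurdle(dat, dat$cpue_age0,
                   c("s(depth)", "re(survey)"),
                   c("s(depth)", "re(survey)"), stage = "AGE0",
                   control = hgam_control(k_s = 6))
  pg <- predict_combined(hm, env, 2011)
  p <- unclass(pg$p); lam <- unclass(pg$lambda); comb <- unclass(pg$combined)
  ok <- is.finite(p)
  expect_true(all(p[ok] >= 0 & p[ok] <= 1))
  expect_true(all(lam[ok] > 0))
  expect_true(all(comb[ok] >= (p * lam)[ok] - 1e-10))
  expect_equal(comb[ok], (p * lam / (1 - exp(-lam)))[ok], tolerance = 1e-12)
  # rock and land cells carry nodata
  rock <- unclass(env$sediment) == match("rock", sediment_levels())
  expect_true(all(is.na(comb[rock])))
  expect_true(all(is.na(comb[unclass(env$land) == 1])))
})
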