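# Poisson driver models, AIC selection, forest importance, dependence
# surfaces and threshold detection.

sim_poisson_table <- function(n, seed, beta_temp = 0.5, offset = TRUE) {
  set.seed(seed)
  temp <- runif(n, -2, 2)
  off <- if (offset) runif(n, 0, 1.5) else rep(0, n)
  data.frame(lat_bin = seq_len(n), depth_bin = 0,
             temperature = temp, noise = rnorm(n),
             richness = rpois(n, exp(1 + beta_temp * temp + off)),
             effort_offset = off)
}

test_that("Poisson fits recover known coefficients and closed forms", {
  tab <- sim_poisson_table(2000, 1)
  fit <- fit_poisson(tab, "temperature")
  est <- fit$coefficients$estimate[fit$coefficients$term == "temperature"]
  expect_equal(est, 0.5, tolerance = 0.1 / 0.5)
  # intercept-only: fitted mean equals the sample mean (offset-free table)
  tab0 <- sim_poisson_table(200, 2, beta_temp = 0, offset = FALSE)
  fit0 <- fit_poisson(tab0, character(0))
  expect_equal(exp(fit0$coefficients$estimate[1]), mean(tab0$richness),
               tolerance = 1e-6)
  # an all-zero offset column equals a no-offset fit
  tabz <- tab0
  tabz$effort_offset <- 0
  fitz <- fit_poisson(tabz, "temperature")
  direct <- glm(richness ~ temperature, poisson(), tabz)
  expect_equal(fitz$coefficients$estimate, unname(coef(direct)),
               tolerance = 1e-8)
  expect_equal(fitz$aic, AIC(direct))
  expect_error(fit_poisson(transform(tab0, temperature = NA), "temperature"),
               "missing")
})

test_that("AR(1) correction inflates standard errors under autocorrelation", {
  set.seed(3)
  n <- 300
  e <- as.numeric(arima.sim(list(ar = 0.7), n))
  tab <- data.frame(lat_bin = seq_len(n), depth_bin = 0,
                    temperature = rnorm(n),
                    richness = rpois(n, exp(1 + 0.3 * e)),
                    effort_offset = 0)
  plain <- fit_poisson(tab, "temperature")
  corr <- fit_poisson(tab, "temperature", ar1 = TRUE)
  expect_gte(corr$rho, 0)
  expect_true(all(corr$coefficients$se >= plain$coefficients$se - 1e-12))
})

test_that("all-subsets selection fits every subset and finds the signal", {
  tab <- sim_poisson_table(800, 5)
  tab$junk1 <- rnorm(800)
  tab$junk2 <- rnorm(800)
  sel <- all_subsets_select(tab, c("temperature", "junk1", "junk2"))
  expect_equal(nrow(sel), 8)
  expect_match(sel$terms[1], "temperature")
  expect_equal(sel$delta_aic[1], 0)
  expect_true(all(diff(sel$aic[sel$converged]) >= -1e-9))
  # the true model beats its underspecified nests at large n
  big <- sim_poisson_table(2000, 6)
  big$junk1 <- rnorm(2000)
  sel2 <- all_subsets_select(big, c("temperature", "junk1"))
  expect_match(sel2$terms[1], "temperature")
  # the model without the true driver trails far behind
  no_temp <- sel2$delta_aic[sel2$terms == "junk1"]
  expect_gt(no_temp, 10)
})

test_that("forest importance ranks the generating variable first", {
  set.seed(7)
  n <- 400
  tab <- data.frame(temperature = runif(n, 0, 25), poc = runif(n, 1, 30),
                    noise = rnorm(n))
  tab$richness <- 5 + 2 * tab$temperature + rnorm(n, 0, 2)
  hits <- vapply(1:5, function(s) {
    imp <- random_forest_importance(tab, predictors = c("temperature",
                                                        "poc", "noise"),
                                    n_trees = 200, seed = s)
    imp$predictor[imp$rank == 1] == "temperature"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # a pure-noise predictor has near-zero importance
  imp1 <- random_forest_importance(tab, predictors = c("temperature",
                                                       "poc", "noise"),
                                   n_trees = 200, seed = 1)
  expect_lt(imp1$inc_mse[imp1$predictor == "noise"], 5)
  # deterministic under seed
  imp2 <- random_forest_importance(tab, predictors = c("temperature",
                                                       "poc", "noise"),
                                   n_trees = 200, seed = 1)
  expect_identical(imp1$inc_mse, imp2$inc_mse)
  expect_warning(
    random_forest_importance(tab, predictors = c("temperature", "poc"),
                             n_trees = 50, seed = 1),
    "mtry")
})

test_that("a duplicated predictor shares importance with its copy", {
  set.seed(13)
  n <- 300
  tab <- data.frame(temperature = runif(n, 0, 25))
  tab$richness <- 3 + 1.5 * tab$temperature + rnorm(n)
  tab$noise <- rnorm(n)
  solo <- random_forest_importance(tab, predictors = c("temperature",
                                                       "noise"),
                                   n_trees = 300, mtry = 2, seed = 2)
  tab$temperature2 <- tab$temperature
  dup <- random_forest_importance(tab, predictors = c("temperature",
                                                      "temperature2",
                                                      "noise"),
                                  n_trees = 300, mtry = 2, seed = 2)
  solo_imp <- solo$inc_mse[solo$predictor == "temperature"]
  expect_lt(dup$inc_mse[dup$predictor == "temperature"], solo_imp)
  expect_lt(dup$inc_mse[dup$predictor == "temperature2"], solo_imp)
})

test_that("partial dependence reproduces closed forms and a direct oracle", {
  set.seed(17)
  n <- 80
  dat <- data.frame(x = runif(n, 0, 10), z = runif(n, -3, 3))
  dat$y <- 2 + 3 * dat$x - 1.5 * dat$z + rnorm(n, 0, 0.1)
  lin <- lm(y ~ x + z, dat)
  pd <- partial_dependence(lin, dat[, c("x", "z")], "x", grid = 0:10)
  slope <- coef(lm(pd$pd ~ pd$x))[2]
  expect_equal(unname(slope), coef(lin)["x"], ignore_attr = TRUE,
               tolerance = 1e-6)
  # constant model is flat
  konst <- lm(y ~ 1, dat)
  pdk <- partial_dependence(konst, dat[, c("x", "z")], "x", grid = 0:10)
  expect_equal(diff(range(pdk$pd)), 0)
  # forest PD equals the brute-force clamp-and-average oracle
  small <- dat[1:50, ]
  rf <- randomForest::randomForest(y ~ x + z, small, ntree = 100)
  pdf <- partial_dependence(rf, small[, c("x", "z")], "x", grid = c(2, 5, 8))
  for (i in 1:3) {
    clamped <- small
    clamped$x <- c(2, 5, 8)[i]
    expect_equal(pdf$pd[i], mean(predict(rf, clamped)), tolerance = 1e-10)
  }
  expect_true(attr(partial_dependence(lin, dat[, c("x", "z")], "x",
                                      grid = c(-5, 5)), "extrapolated"))
})

test_that("pairwise interaction surfaces separate additive from joint effects", {
  set.seed(19)
  n <- 200
  dat <- data.frame(a = runif(n, 0, 1), b = runif(n, 0, 1))
  dat$y_add <- 2 * dat$a + 3 * dat$b
  add <- lm(y_add ~ a + b, dat)
  s <- pairwise_interaction(add, dat[, c("a", "b")], "a", "b",
                            grid1 = seq(0, 1, 0.25),
                            grid2 = seq(0, 1, 0.25))
  pda <- partial_dependence(add, dat[, c("a", "b")], "a",
                            grid = seq(0, 1, 0.25))
  pdb <- partial_dependence(add, dat[, c("a", "b")], "b",
                            grid = seq(0, 1, 0.25))
  recon <- outer(pda$pd, pdb$pd, "+") - mean(predict(add, dat))
  expect_equal(s$values, recon, tolerance = 1e-8)
  # multiplicative response: corners differ from what additivity predicts
  dat$y_mul <- 10 * dat$a * dat$b
  mul <- lm(y_mul ~ a * b, dat)
  sm <- pairwise_interaction(mul, dat[, c("a", "b")], "a", "b",
                             grid1 = c(0, 1), grid2 = c(0, 1))
  expect_gt(sm$values[2, 2] - sm$values[2, 1] -
              (sm$values[1, 2] - sm$values[1, 1]), 5)
})

test_that("threshold detection recovers hinges, steps, and flags lines", {
  x <- seq(-2, 6, by = 0.05)
  hinge <- data.frame(temperature = x, pd = pmax(x - 1.5, 0) * 4)
  class(hinge) <- c("dependence_surface", "data.frame")
  th <- threshold_estimate(hinge, n_boot = 0)
  expect_true(th$identified)
  expect_lt(abs(th$breakpoint - 1.5), 0.11)

  step <- data.frame(temperature = x, pd = ifelse(x < 1.2, 0, 30))
  class(step) <- c("dependence_surface", "data.frame")
  ts <- threshold_estimate(step, n_boot = 50)
  expect_lt(abs(ts$breakpoint - 1.2), 0.11)
  expect_true(ts$ci[1] <= ts$breakpoint && ts$breakpoint <= ts$ci[2])

  lin <- data.frame(temperature = x, pd = 2 * x + 1)
  class(lin) <- c("dependence_surface", "data.frame")
  tl <- threshold_estimate(lin, n_boot = 0)
  expect_false(tl$identified)
  expect_true(is.na(tl$breakpoint))
})

test_that("threshold worlds show flat-then-rising POC response across the break", {
  cfg <- lean_config(71, archetype_mix = c(abyssal_cosmopolitan = 1))
  w <- simulate_world(cfg, threshold_temp = 1.5, thermal_clip = TRUE,
                      placement_bias = list(deep = "poc"))
  st <- world_stratum_table(w, "abyssal")
  rf <- randomForest::randomForest(richness ~ temperature + poc_flux,
                                   st, ntree = 300)
  s <- pairwise_interaction(rf, st[, c("temperature", "poc_flux")],
                            "temperature", "poc_flux",
                            grid1 = c(0, 3.5),
                            grid2 = quantile(st$poc_flux, c(0.1, 0.9)))
  below_range <- s$values[1, 2] - s$values[1, 1]
  above_range <- s$values[2, 2] - s$values[2, 1]
  expect_gt(s$values[2, 1], s$values[1, 1])  # warm rows are richer
  expect_gt(abs(above_range) + 1, abs(below_range))  # cold rows ~flat in POC
})
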