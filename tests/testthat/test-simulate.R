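test_that("simulation configs are validated", {
  expect_error(simulationConfig(shape = -1), "shape")
  expect_error(simulationConfig(shape = 2, scale = 0), "scale")
  expect_error(simulationConfig(shape = 2, corr = 1), "corr")
  expect_error(simulationConfig(shape = 2, eps = -0.1), "eps")
  expect_error(simulationConfig(shape = Inf), "explicit scale")
  cfg <- simulationConfig(shape = 2)
  expect_equal(cfg$scale, sqrt(2) - 1)    # calibrated so that Lambda = 1
  expect_equal(eulerLotkaRate(cfg$shape, cfg$scale), 1)
  for (k in c(0.5, 1, 2, 5, 10))
    expect_equal(eulerLotkaRate(k, 2^(1 / k) - 1), 1)
})

test_that("unconditional generation times are Gamma(shape, scale)", {
  set.seed(2)
  x <- drawGenerationTime(20000, shape = 3, scale = 0.5)
  expect_equal(mean(x), 1.5, tolerance = 0.02)
  expect_equal(var(x), 0.75, tolerance = 0.05)
  expect_equal(drawGenerationTime(4, Inf, 3), rep(3, 4))
})

test_that("correlated kernel preserves the stationary gamma moments", {
  set.seed(3)
  k <- 2; th <- sqrt(2) - 1; r <- 0.5
  n <- 6000
  t <- numeric(n); t[1] <- k * th
  for (i in 2:n)
    t[i] <- drawGenerationTime(1, k, th, corr = r, motherTime = t[i - 1])
  burn <- t[-(1:500)]
  expect_equal(mean(burn), k * th, tolerance = 0.08)
  expect_equal(var(burn), k * th^2, tolerance = 0.15)
  lag1 <- cor(burn[-1], burn[-length(burn)])
  expect_equal(lag1, r, tolerance = 0.12)
  # corr = 0 kernel is the unconditional gamma regardless of motherTime
  set.seed(4)
  a <- drawGenerationTime(5, k, th, corr = 0, motherTime = 100)
  set.seed(4)
  b <- drawGenerationTime(5, k, th)
  expect_identical(a, b)
})

test_that("deterministic mode reproduces the doubling cascade exactly", {
  cfg <- simulationConfig(shape = Inf, scale = 3, tMax = 8, nPrerun = 4,
                          nMain = 5, seed = 1)
  pool <- prerunFirstDivisionTimes(cfg)
  # single newborn: divisions at 3, 6; next at 9 > 8 -> 4 lineages, residual 1
  expect_equal(nrow(pool), 4 * 4)
  expect_equal(unique(pool$time), 1)
  expect_equal(unique(pool$gen), 3)
  res <- simulateMain(cfg, pool = data.frame(time = 1, gen = 3))
  # first divisions at 1, then 4, 7; next at 10 -> D = 3, 8 lineages each
  expect_equal(res$N, 5 * 8)
  expect_equal(unique(res$lineages$D), 3L)
  g <- simGrowthAndFitness(res)
  expect_equal(g$Lambda, 3 * log(2) / 8)
  expect_equal(g$tauLambda, log(8))
  expect_equal(g$meanHcl, 3 * log(2))   # homogeneous: <h>_cl = <h>_rs
  expect_equal(g$meanHrs, 3 * log(2))
})

test_that("exponential clocks give memoryless residual first-division times", {
  cfg <- simulationConfig(shape = 1, tMax = 3, nPrerun = 400, seed = 9)
  set.seed(cfg$seed)
  pool <- prerunFirstDivisionTimes(cfg)
  expect_gt(nrow(pool), 2000)
  # scale = 2^1 - 1 = 1; residuals of exponential clocks are Exp(1)
  expect_equal(mean(pool$time), 1, tolerance = 0.08)
  expect_equal(sd(pool$time), 1, tolerance = 0.12)
})

test_that("unperturbed growth rate approaches the Euler-Lotka calibration", {
  cfg <- simulationConfig(shape = 2, tMax = 6, nPrerun = 150, nMain = 250,
                          seed = 42)
  res <- simulateMain(cfg)
  g <- simGrowthAndFitness(res)
  expect_equal(g$Lambda, 1, tolerance = 0.15)
  expect_gt(g$meanHrs, g$meanHcl)   # selection raises the mean fitness
})

test_that("simulations are bit-reproducible under a fixed seed", {
  cfg <- simulationConfig(shape = 2, tMax = 4, nPrerun = 50, nMain = 50,
                          seed = 7)
  r1 <- simulateMain(cfg)
  r2 <- simulateMain(cfg)
  expect_identical(r1$lineages, r2$lineages)
  cfg2 <- cfg; cfg2$seed <- 8
  expect_false(identical(simulateMain(cfg2)$lineages, r1$lineages))
})

test_that("unperturbed results export as exactly conservative tree ensembles", {
  cfg <- simulationConfig(shape = 1, tMax = 4, nPrerun = 60, nMain = 80,
                          seed = 5)
  res <- simulateMain(cfg)
  ens <- asLineageEnsemble(res, "tree")
  expect_identical(sum(2^(-divisionCounts(ens))), as.numeric(res$nMain))
  expect_equal(finalCount(ens), res$N)
  expect_equal(obsDuration(ens), 4)

  cfgp <- simulationConfig(shape = 1, eps = 0.3, tMax = 3, nPrerun = 40,
                           nMain = 40, seed = 6)
  resp <- simulateMain(cfgp)
  expect_error(asLineageEnsemble(resp, "tree"), "eps = 0")
  expect_warning(asLineageEnsemble(resp, "chronological"), "approximate")
})

test_that("strong removal perturbations empty the pre-run pool", {
  cfg <- simulationConfig(shape = Inf, scale = 1, eps = 20, tMax = 8,
                          nPrerun = 5, seed = 3)
  set.seed(cfg$seed)
  expect_warning(pool <- prerunFirstDivisionTimes(cfg), "extinct")
  expect_equal(nrow(pool), 0)
  expect_error(simulateMain(cfg, pool = pool), "empty")
})

test_that("epsilon sweep reports decreasing growth and a slope below -1", {
  cfg <- simulationConfig(shape = 1, tMax = 5, nPrerun = 80, nMain = 150,
                          seed = 11)
  sw <- epsilonSweep(cfg, epsGrid = c(0, 0.1, 0.2))
  expect_equal(names(sw$table), c("eps", "N", "Lambda", "dLL"))
  expect_equal(sw$table$dLL[sw$table$eps == 0], 0)
  expect_lt(sw$table$Lambda[3], sw$table$Lambda[1])
  expect_lt(sw$theory$relativeSlope, -1)   # heterogeneity steepens the loss
  expect_equal(sw$theory$relativeSlope,
               -(1 + sw$theory$S_KL2 / sw$theory$tauLambda))
  expect_error(epsilonSweep(cfg, epsGrid = c(0.1, 0.2)), "include 0")
})
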