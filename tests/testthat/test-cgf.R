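test_that("cgf endpoints and derivatives tie the two statistics together", {
  set.seed(61)
  for (rep in 1:8) {
    ens <- randomLineageEnsemble(sample(1:4, 1), runif(1, 0.3, 0.7), 8)
    pair <- traitDistributions(ens, "D")
    o <- oracle_selection(divisionCounts(ens), "tree")
    expect_equal(cgf(pair, 0), 0, tolerance = 1e-12)
    expect_equal(cgf(pair, 1), o$tauLambda, tolerance = 1e-10)
    d <- cgfDerivatives(pair, c(0, 1))
    expect_equal(d$Kprime, c(o$meanHcl, o$meanHrs), tolerance = 1e-10)
    expect_equal(d$Kdoubleprime, c(o$varHcl, o$varHrs), tolerance = 1e-10)
  }
})

test_that("the cgf is convex and matches central finite differences", {
  pair <- t1_pair()
  xi <- seq(0.1, 0.9, by = 0.2)
  eps <- 1e-5
  d <- cgfDerivatives(pair, xi)
  fd1 <- (cgf(pair, xi + eps) - cgf(pair, xi - eps)) / (2 * eps)
  fd2 <- (cgf(pair, xi + eps) - 2 * cgf(pair, xi) + cgf(pair, xi - eps)) / eps^2
  expect_equal(d$Kprime, fd1, tolerance = 1e-7)
  expect_equal(d$Kdoubleprime, fd2, tolerance = 1e-4)
  expect_true(all(d$Kdoubleprime >= 0))
  cur <- kprimeCurve(pair, step = 0.05)
  expect_true(all(diff(cur$Kprime) >= -1e-12))     # K' nondecreasing
  expect_equal(cur$xi[c(1, nrow(cur))], c(0, 1))
  # hand value at xi = 1/2: K = log(0.5*sqrt(2) + 0.5*2) = log(sqrt(2)/2 + 1)
  expect_equal(cgf(pair, 0.5), log(sqrt(2) / 2 + 1))
})

test_that("cgf evaluation is numerically stable for extreme landscapes", {
  ens <- LineageEnsemble(c(rep(0, 400), 40), mode = "chronological")
  pair <- traitDistributions(ens, "D")
  k <- cgf(pair, c(0, 0.5, 1, 2))
  expect_true(all(is.finite(k)))
  expect_true(all(diff(k) > 0))
})

test_that("series cumulants match the independent raw-moment recursion", {
  set.seed(71)
  for (rep in 1:8) {
    ens <- growing_ensemble(sample(1:3, 1), runif(1, 0.3, 0.7), 7)
    pair <- traitDistributions(ens, "D")
    s <- lineagestats:::.pair_support(pair)
    kap <- cumulantValues(fitnessCumulants(pair, nMax = 8))
    oracle <- oracle_cumulants(s$h, s$Qcl, 8)
    expect_equal(kap, oracle, tolerance = 1e-9)
    # first two cumulants are mean and variance under Qcl
    expect_equal(kap[1], sum(s$Qcl * s$h), tolerance = 1e-12)
    expect_equal(kap[2], sum(s$Qcl * (s$h - kap[1])^2), tolerance = 1e-10)
  }
})

test_that("micro-tree cumulants and W_n match the hand values", {
  cs <- fitnessCumulants(t1_pair())
  kap <- cumulantValues(cs)
  expect_equal(kap[1], T1$meanHcl)
  expect_equal(kap[2], T1$kappa2)
  expect_equal(kap[3], 0, tolerance = 1e-12)       # symmetric two-point h
  W <- cumulativeContributions(cs)
  expect_equal(W[1], T1$meanHcl / T1$tauLambda)
  expect_equal(W[length(W)], 1, tolerance = 1e-9)
  expect_true(cs@converged)
})

test_that("W_n converges to 1 and the measure gap is carried by kappa_3+", {
  skewed <- fixtureEnsemble("skewed_regrowth")
  pair <- traitDistributions(skewed, "D")
  # wide, strongly skewed landscape: truncation error shrinks with the order
  w20 <- abs(cumulativeContributions(fitnessCumulants(pair, nMax = 20))[20] - 1)
  cs <- fitnessCumulants(pair, nMax = 40)
  W <- cumulativeContributions(cs)
  expect_lt(abs(W[40] - 1), w20)
  expect_equal(W[40], 1, tolerance = 5e-4)
  md <- measureDifference(pair, nMax = 40)
  expect_lt(abs(md$truncationGap), 0.05 * abs(md$exact))
  # right-skewed division counts: S_KL2 > S_KL1, kappa_3 > 0
  expect_gt(md$exact, 0)
  expect_gt(md$kappa3, 0)
  expect_identical(md$varianceEffect, "increase")
  expect_gt(cs@skewness, 0)

  mdsym <- measureDifference(t1_pair())
  expect_equal(mdsym$exact, T1$SKL2 - T1$SKL1)
})

test_that("left-skewed landscapes reverse the sign of the measure gap", {
  # mostly deep dividers plus a tail of non-dividers: kappa_3 < 0
  ens <- LineageEnsemble(c(rep(4, 180), rep(0, 20)), mode = "chronological")
  pair <- traitDistributions(ens, "D")
  md <- measureDifference(pair, nMax = 40)
  expect_lt(md$kappa3, 0)
  expect_lt(md$exact, 0)
  expect_lt(abs(md$truncationGap), 1e-5)
  expect_identical(md$varianceEffect, "decrease")
  expect_true(fitnessCumulants(pair, nMax = 40)@converged)
})

test_that("zero-growth pairs are rejected for W_n", {
  ens <- LineageEnsemble(c(0, 0, 0), mode = "chronological")
  pair <- traitDistributions(ens, "D")
  expect_error(fitnessCumulants(pair), "undefined")
})

test_that("perturbed growth interpolates between Lambda and 0", {
  pair <- t1_pair()
  expect_equal(perturbedGrowth(pair, 0), log(3))       # tau = 1
  expect_equal(perturbedGrowth(pair, 1), 0)            # K(0) = 0
  lam <- perturbedGrowth(pair, seq(0, 1, 0.1))
  expect_true(all(diff(lam) < 0))                      # monotone loss
  ens <- randomLineageEnsemble(2, 0.5, 5, trait = TRUE)
  expect_error(perturbedGrowth(traitDistributions(ens, "x"), 0.1),
               "division count")
})

test_that("response slope matches a finite difference of Lambda(eps)", {
  pair <- t1_pair()
  rs <- responseSlope(pair)
  expect_equal(rs$relativeSlope, T1$relSlope)
  expect_equal(rs$slope, -T1$meanHrs)                  # tau = 1
  eps <- 1e-4
  fd <- (perturbedGrowth(pair, eps) - perturbedGrowth(pair, -eps)) / (2 * eps)
  expect_equal(rs$slope, fd, tolerance = 1e-3)
  expect_equal(rs$relativeSlope, fd / log(3), tolerance = 1e-3)
  # homogeneous population: relative slope is exactly -1
  unif <- traitDistributions(fixtureEnsemble("uniform", d = 3, N0 = 2), "D")
  expect_equal(responseSlope(unif)$relativeSlope, -1)
})

test_that("curve and cumulant tables are written as TSV", {
  dir <- withr::local_tempdir()
  pair <- t1_pair()
  writeKprimeCurve(pair, file.path(dir, "k.tsv"), step = 0.25)
  k <- read.delim(file.path(dir, "k.tsv"))
  expect_equal(names(k), c("xi", "K", "Kprime", "Kdoubleprime"))
  expect_equal(k$K[1], 0)
  writeCumulantSeries(fitnessCumulants(pair), file.path(dir, "c.tsv"))
  cc <- read.delim(file.path(dir, "c.tsv"))
  expect_equal(cc$kappa_n[1], T1$meanHcl)
  expect_equal(cc$n, seq_len(nrow(cc)))
})
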