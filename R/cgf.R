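#' @include AllClasses.R selection.R
NULL

# log(sum(w * exp(a))) with max-shift for numerical stability
.logsumexp <- function(a, logw) {
  m <- max(a + logw)
  m + log(sum(exp(a + logw - m)))
}

#' Cumulant generating function of the fitness landscape
#'
#' `K_X(xi) = log sum_x exp(xi * h(x)) * Qcl(x)`, the cgf of the fitness
#' landscape under the chronological distribution, evaluated with a
#' log-sum-exp shift. Endpoints tie the two statistics together:
#' `K_X(0) = 0` and `K_X(1) = tau * Lambda`.
#'
#' @param pair a [TraitDistributionPair-class].
#' @param xi evaluation points (vectorized).
#' @return `K_X(xi)` in nats.
#' @export
cgf <- function(pair, xi) {
  s <- .pair_support(pair)
  logw <- log(s$Qcl)
  vapply(xi, function(z) .logsumexp(z * s$h, logw), numeric(1))
}

#' First and second derivatives of the cgf
#'
#' `K'(xi)` is the mean of `h` under the exponentially tilted chronological
#' distribution and `K''(xi)` its variance, so `K'(0) = <h>_cl`,
#' `K'(1) = <h>_rs`, `K''(0) = Var[h]_cl`, `K''(1) = Var[h]_rs` and `K` is
#' convex. For the division count on complete trees `K'` reduces to
#' `sum (d log2) 2^(xi d) Qcl(d) / sum 2^(xi d) Qcl(d)`.
#'
#' @inheritParams cgf
#' @return list of vectors `Kprime` (nats) and `Kdoubleprime` (nats^2).
#' @export
cgfDerivatives <- function(pair, xi) {
  s <- .pair_support(pair)
  logw <- log(s$Qcl)
  kp <- numeric(length(xi)); kpp <- numeric(length(xi))
  for (j in seq_along(xi)) {
    a <- xi[j] * s$h + logw
    a <- a - max(a)
    w <- exp(a); w <- w / sum(w)      # tilted distribution
    m <- sum(w * s$h)
    kp[j] <- m
    kpp[j] <- sum(w * (s$h - m)^2)
  }
  list(Kprime = kp, Kdoubleprime = kpp)
}

#' Grid evaluation of K, K' and K'' on [0, 1]
#'
#' The `K'(xi)` plot makes the selection measures visible as areas: the area
#' under the curve on `[0, 1]` is `tau * Lambda`, the area above `<h>_cl` is
#' `S_KL1`, and the area up to `<h>_rs` is `S_KL2`. Convexity of `K'` tracks
#' the sign of the third fitness cumulant.
#'
#' @param pair a [TraitDistributionPair-class].
#' @param step grid step (default 0.01).
#' @return data.frame `xi`, `K`, `Kprime`, `Kdoubleprime`.
#' @export
kprimeCurve <- function(pair, step = 0.01) {
  xi <- seq(0, 1, by = step)
  if (xi[length(xi)] < 1) xi <- c(xi, 1)
  d <- cgfDerivatives(pair, xi)
  data.frame(xi = xi, K = cgf(pair, xi),
             Kprime = d$Kprime, Kdoubleprime = d$Kdoubleprime)
}

#' Plot the K'(xi) curve
#'
#' Base-graphics rendering of [kprimeCurve()] with the chronological and
#' retrospective mean-fitness levels marked.
#'
#' @inheritParams kprimeCurve
#' @param ... passed to [plot()].
#' @export
plotKprime <- function(pair, step = 0.01, ...) {
  cur <- kprimeCurve(pair, step)
  plot(cur$xi, cur$Kprime, type = "l", xlab = expression(xi),
       ylab = expression(K * minute(xi)), ...)
  graphics::abline(h = cur$Kprime[c(1, nrow(cur))], lty = 3, col = "grey40")
  invisible(cur)
}

# Taylor coefficients c_n of K(xi) = log M(xi) from the coefficients
# a_n = E[h^n]/n! of the mgf, by the series-log recursion
# c_n = a_n - (1/n) * sum_{j=1}^{n-1} j * c_j * a_{n-j};  kappa_n = n! c_n.
.cumulants_series <- function(h, q, nMax) {
  a <- numeric(nMax + 1L); a[1] <- 1
  hk <- rep(1, length(h))
  factk <- 1
  for (n in seq_len(nMax)) {
    hk <- hk * h
    factk <- factk * n
    a[n + 1L] <- sum(q * hk) / factk
  }
  cc <- numeric(nMax)
  for (n in seq_len(nMax)) {
    acc <- a[n + 1L]
    if (n > 1L) {
      j <- seq_len(n - 1L)
      acc <- acc - sum(j * cc[j] * a[n - j + 1L]) / n
    }
    cc[n] <- acc
  }
  cc * cumprod(seq_len(nMax))
}

#' Cumulant expansion of the population growth rate
#'
#' Computes the cumulants `kappa_1..kappa_nMax` of the fitness landscape under
#' the chronological distribution by power-series arithmetic on the exact
#' finite-support moment generating function, and the cumulative contributions
#' `W_n = (1/(tau*Lambda)) * sum_{k<=n} kappa_k / k!`. When the expansion
#' converges, `W_n -> 1`: the growth rate is fully decomposed into fitness
#' cumulants (`kappa_1` the chronological mean fitness, `kappa_2` its
#' variance, `kappa_3` its skew, ...).
#'
#' Convergence is declared when `|W_nMax - 1|` is below `tol` (relative) and
#' the partial-sum error decreased over the last three orders; a
#' non-convergent series is returned flagged, never silently truncated.
#'
#' @param pair a [TraitDistributionPair-class].
#' @param nMax expansion order (default 20, comfortably above the ~10 orders
#'   needed even for strongly right-skewed division-count distributions).
#' @param tol relative tolerance on `W_nMax - 1`.
#' @return A [CumulantSeries-class].
#' @examples
#' pair <- traitDistributions(LineageEnsemble(c(1, 2, 2), mode = "tree"))
#' cumulantValues(fitnessCumulants(pair))[1:3]  # 1.5*log(2), 0.25*log(2)^2, 0
#' @export
fitnessCumulants <- function(pair, nMax = 20, tol = 1e-6) {
  if (nMax < 2) stop("nMax must be >= 2")
  s <- .pair_support(pair)
  tl <- s$tauLambda
  if (abs(tl) < 1e-14)
    stop("tau*Lambda = 0: cumulative contributions W_n are undefined")
  kap <- .cumulants_series(s$h, s$Qcl, nMax)
  terms <- kap / cumprod(seq_len(nMax))   # kappa_n / n!
  W <- cumsum(terms) / tl
  tail_err <- abs(tl - cumsum(terms))
  last3 <- tail_err[(nMax - 2L):nMax]
  converged <- abs(W[nMax] - 1) < tol &&
    all(diff(last3) <= .IDENT_TOL * max(1, abs(tl)))
  skew <- if (kap[2] > 0) kap[3] / kap[2]^1.5 else NA_real_
  methods::new("CumulantSeries", trait = pair@trait, kappa = kap, W = W,
               skewness = skew, tauLambda = tl, converged = converged)
}

#' Difference of the two KL selection strengths via the cumulant series
#'
#' `S_KL2[X] - S_KL1[X] = sum_{n>=3} kappa_n * (n - 2) / n!`: the gap between
#' the two selection strength measures is carried entirely by third and
#' higher fitness cumulants. Returns both the exact difference (from the
#' divergences) and its series reconstruction, with the truncation gap as a
#' diagnostic. The sign of the difference indicates the effect of selection
#' on fitness variance: when fourth and higher cumulants are negligible,
#' `kappa_3 > 0` (right-skewed fitness, `K'` convex downward) makes selection
#' increase the retrospective fitness variance, and conversely.
#'
#' @inheritParams fitnessCumulants
#' @return list `exact`, `series`, `truncationGap`, `kappa3`,
#'   `varianceEffect` (`"increase"`, `"decrease"` or `"none"`).
#' @export
measureDifference <- function(pair, nMax = 20) {
  st <- selectionStrengths(pair)
  exact <- st$S_KL2 - st$S_KL1
  cs <- fitnessCumulants(pair, nMax)
  kap <- cs@kappa
  n <- seq_len(nMax)
  series <- sum(kap[n >= 3] * (n[n >= 3] - 2) / factorial(n[n >= 3]))
  list(exact = exact, series = series,
       truncationGap = exact - series,
       kappa3 = kap[3],
       varianceEffect = if (abs(exact) < 1e-12) "none"
                        else if (exact > 0) "increase" else "decrease")
}

#' Population growth rate under a fitness perturbation
#'
#' For perturbations scaling lineage fitness from `d log2` to
#' `(1 - eps) d log2` -- e.g. removing each newborn daughter with probability
#' `1 - 2^-eps` -- the perturbed growth rate is
#' `Lambda(eps) = K_D(1 - eps) / tau`.
#'
#' @param pair the division-count [TraitDistributionPair-class].
#' @param eps perturbation strengths (vectorized).
#' @param tau observation duration (default: the pair's).
#' @return `Lambda(eps)` per hour.
#' @export
perturbedGrowth <- function(pair, eps, tau = pair@tau) {
  if (!identical(pair@trait, "D"))
    stop("the perturbation response is defined for the division count")
  cgf(pair, 1 - eps) / tau
}

#' Linear response of growth rate to a fitness perturbation
#'
#' `dLambda/deps` at `eps = 0` equals `-<h~(D)>_rs / tau`: the initial growth
#' rate loss is proportional to the retrospective mean fitness. Relative to
#' `Lambda`, the slope is `-(1 + S_KL2[D] / (tau*Lambda))` -- heterogeneous
#' populations (large `S_KL2[D]`) lose growth rate faster than the
#' homogeneous-reference line `-eps`.
#'
#' @inheritParams perturbedGrowth
#' @return list `slope` (per hour) and `relativeSlope` (dimensionless).
#' @export
responseSlope <- function(pair, tau = pair@tau) {
  if (!identical(pair@trait, "D"))
    stop("the perturbation response is defined for the division count")
  st <- selectionStrengths(pair)
  tl <- log(pair@Ntau / pair@N0)
  if (abs(tl) < 1e-14) stop("Lambda = 0: relative slope undefined")
  list(slope = -st$meanHrs / tau,
       relativeSlope = -(1 + st$S_KL2 / tl))
}

#' Export curve and cumulant tables
#'
#' `writeKprimeCurve` writes `xi  K  Kprime  Kdoubleprime`;
#' `writeCumulantSeries` writes `n  kappa_n  W_n`.
#'
#' @param pair a [TraitDistributionPair-class].
#' @param path output TSV path.
#' @param step grid step for the curve.
#' @export
writeKprimeCurve <- function(pair, path, step = 0.01) {
  utils::write.table(kprimeCurve(pair, step), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKprimeCurve
#' @param series a [CumulantSeries-class].
#' @export
writeCumulantSeries <- function(series, path) {
  utils::write.table(
    data.frame(n = seq_along(series@kappa), kappa_n = series@kappa,
               W_n = series@W),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
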