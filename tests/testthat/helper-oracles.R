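# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own computation paths: everything is a direct sum over
# the lineage list or a textbook recursion.

# Brute-force selection statistics from a lineage list.
oracle_selection <- function(D, mode = "tree") {
  n <- length(D)
  if (mode == "tree") {
    N0 <- sum(2^(-D)); Ntau <- n
    Pcl <- 2^(-D) / N0; Prs <- rep(1 / Ntau, n)
  } else {
    N0 <- n; Ntau <- sum(2^D)
    Pcl <- rep(1 / N0, n); Prs <- 2^D / sum(2^D)
  }
  tl <- log(Ntau / N0)
  ds <- sort(unique(D))
  Qcl <- vapply(ds, function(d) sum(Pcl[D == d]), numeric(1))
  Qrs <- vapply(ds, function(d) sum(Prs[D == d]), numeric(1))
  h <- tl + log(Qrs / Qcl)
  list(tauLambda = tl, d = ds, Qcl = Qcl, Qrs = Qrs, h = h,
       meanHcl = sum(Qcl * h), meanHrs = sum(Qrs * h),
       varHcl = sum(Qcl * h^2) - sum(Qcl * h)^2,
       varHrs = sum(Qrs * h^2) - sum(Qrs * h)^2,
       SKL1 = sum(Qcl * log(Qcl / Qrs)),
       SKL2 = sum(Qrs * log(Qrs / Qcl)))
}

# Cumulants via the raw-moment recursion
# kappa_n = m_n - sum_{j=1}^{n-1} choose(n-1, j-1) kappa_j m_{n-j}.
oracle_cumulants <- function(h, q, nMax) {
  m <- vapply(seq_len(nMax), function(n) sum(q * h^n), numeric(1))
  kap <- numeric(nMax)
  for (n in seq_len(nMax)) {
    acc <- m[n]
    if (n > 1L) for (j in seq_len(n - 1L))
      acc <- acc - choose(n - 1L, j - 1L) * kap[j] * m[n - j]
    kap[n] <- acc
  }
  kap
}

# Exhaustive enumeration of all weighted resamples of a small lineage set:
# returns every statistic value with its probability.
oracle_resample_enum <- function(D, scheme, statFun) {
  n <- length(D)
  if (scheme == "colony") {
    ndraw <- n
    w <- rep(1 / n, n)                      # P_rs on a tree
  } else {
    ndraw <- n
    w <- rep(1 / n, n)                      # uniform over lineages
  }
  idx <- do.call(expand.grid, rep(list(seq_len(n)), ndraw))
  vals <- apply(idx, 1L, function(ii) statFun(D[ii]))
  probs <- apply(idx, 1L, function(ii) prod(w[ii]))
  agg <- tapply(probs, round(vals, 12), sum)
  list(value = as.numeric(names(agg)), prob = as.numeric(agg))
}

# Random tree-mode ensemble conditioned on nonzero growth (tau*Lambda > 0),
# for tests of quantities that are undefined for a population that never
# divided.
growing_ensemble <- function(nRoots = 3, splitProb = 0.6, maxDepth = 8,
                             trait = FALSE, traitRho = 0) {
  repeat {
    ens <- randomLineageEnsemble(nRoots, splitProb, maxDepth, trait, traitRho)
    if (sum(divisionCounts(ens)) > 0) return(ens)
  }
}

# The worked three-lineage micro-tree as a cell edge list.
t1_cells <- function() {
  data.frame(
    cell_id = c("r", "a", "b", "b1", "b2"),
    parent_id = c(NA, "r", "r", "b", "b"),
    birth_time = c(0, 0.3, 0.3, 0.6, 0.6),
    end_time = c(0.3, 1.2, 0.6, 1.1, 1.3),
    fate = c("divided", "alive_at_end", "divided", "alive_at_end", "alive_at_end"),
    stringsAsFactors = FALSE)
}

t1_pair <- function() traitDistributions(fixtureEnsemble("T1"), "D")

# Frozen hand/oracle values for the micro-tree (D = 1, 2, 2).
T1 <- list(
  tauLambda = log(3),
  h = c(log(2), 2 * log(2)),
  SKL1 = log(3) - 1.5 * log(2),            # 0.05889152
  SKL2 = 5 / 3 * log(2) - log(3),          # 0.05663301
  meanHcl = 1.5 * log(2),
  meanHrs = 5 / 3 * log(2),
  kappa2 = 0.25 * log(2)^2,                # 0.12011326
  relSlope = -(1 + (5 / 3 * log(2) - log(3)) / log(3)))  # -1.0515495
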