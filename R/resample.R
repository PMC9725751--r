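#' @include AllClasses.R distributions.R
NULL

.resample_core <- function(ensemble, statistic, B, seed, scheme,
                           statName) {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rec <- ensemble@records
  n <- nrow(rec)
  D <- rec$D
  point <- statistic(ensemble)
  if (scheme == "colony") {
    prob <- lineageWeights(ensemble)$P_rs
    ndraw <- as.integer(round(finalCount(ensemble)))
  } else {
    prob <- NULL
    ndraw <- as.integer(round(initialCount(ensemble)))
  }
  vals <- numeric(B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, ndraw, replace = TRUE, prob = prob)
    v <- tryCatch({
      boot <- LineageEnsemble(
        D[idx], mode = ensembleMode(ensemble),
        traits = {
          extra <- setdiff(names(rec), c("lineage_id", "D"))
          if (length(extra)) rec[idx, extra, drop = FALSE] else NULL
        },
        # colony scheme: N0 is the replicate estimate sum(2^-D), which also
        # makes the tree-mode conservation identity hold by construction
        N0 = if (scheme == "colony") sum(2^(-D[idx])) else NULL,
        tStart = ensemble@tStart, tEnd = ensemble@tEnd)
      statistic(boot)
    }, error = function(e) NA_real_)
    if (is.na(v)) failed <- failed + 1L
    vals[b] <- v
  }
  if (failed > 0L) {
    if (failed > 0.01 * B)
      stop(failed, " of ", B, " replicates failed (> 1%)")
    message(failed, " replicate(s) failed and were dropped")
    vals <- vals[!is.na(vals)]
  }
  m <- mean(vals); s <- stats::sd(vals)
  if (B == 1L) s <- 0
  structure(list(statistic = statName, point = point, boot_mean = m,
                 boot_sd = s, lo = m - 2 * s, hi = m + 2 * s,
                 B = B, seed = seed, scheme = scheme,
                 replicates = vals),
            class = "uncertainty_summary")
}

#' Bootstrap uncertainty for lineage statistics (colony scheme)
#'
#' For complete-tree (colony) data: each replicate draws `Ntau` lineages with
#' replacement with retrospective weights `P_rs`, re-estimates the initial
#' cell number as `N0_hat = sum(2^-D)` over the resample (fractional values
#' allowed), and recomputes the statistic. Reported interval is the replicate
#' mean plus/minus two replicate standard deviations.
#'
#' @param ensemble a tree-mode [LineageEnsemble-class].
#' @param statistic function mapping a [LineageEnsemble-class] to a scalar
#'   (e.g. `function(e) tauLambda(e)`).
#' @param B replicate count (default 20000; use a few hundred for quick
#'   exploration).
#' @param seed RNG seed; fixes all replicates bit-identically.
#' @param statName label stored in the summary.
#' @return list of class `uncertainty_summary`: `statistic`, `point`,
#'   `boot_mean`, `boot_sd`, `lo`, `hi` (mean +/- 2 SD), `B`, `seed`,
#'   `scheme`, and the raw `replicates`.
#' @export
resampleColony <- function(ensemble, statistic, B = 20000, seed = NULL,
                           statName = deparse(substitute(statistic))) {
  if (ensembleMode(ensemble) != "tree")
    stop("colony resampling requires a tree-mode ensemble")
  .resample_core(ensemble, statistic, B, seed, "colony", statName)
}

#' Bootstrap uncertainty for lineage statistics (chronological scheme)
#'
#' For isolated-lineage (mother machine) data: each replicate draws `N0`
#' lineages uniformly with replacement and re-estimates the final cell
#' number as `Ntau_hat = sum(2^D)`.
#'
#' @inheritParams resampleColony
#' @export
resampleChronological <- function(ensemble, statistic, B = 20000, seed = NULL,
                                  statName = deparse(substitute(statistic))) {
  if (ensembleMode(ensemble) != "chronological")
    stop("chronological resampling requires a chronological-mode ensemble")
  .resample_core(ensemble, statistic, B, seed, "chronological", statName)
}

#' @export
print.uncertainty_summary <- function(x, ...) {
  cat(sprintf("Bootstrap (%s scheme, B = %d) for %s\n",
              x$scheme, x$B, x$statistic))
  cat(sprintf("  point = %.6g; replicates %.6g +/- 2 x %.3g -> [%.6g, %.6g]\n",
              x$point, x$boot_mean, x$boot_sd, x$lo, x$hi))
  invisible(x)
}

#' Write an uncertainty summary as JSON
#'
#' @param x an `uncertainty_summary`.
#' @param path output path.
#' @export
writeUncertaintySummary <- function(x, path) {
  jsonlite::write_json(
    list(name = x$statistic, point = x$point, boot_mean = x$boot_mean,
         boot_sd = x$boot_sd, lo = x$lo, hi = x$hi, B = x$B,
         seed = x$seed, scheme = x$scheme),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
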