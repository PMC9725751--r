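#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn LineageEnsemble per-lineage division counts
#' @param x a LineageEnsemble
#' @export
setMethod("divisionCounts", "LineageEnsemble", function(x) x@records$D)

#' @describeIn LineageEnsemble values of one lineage trait (`"D"` returns the
#'   division counts)
#' @param trait trait name
#' @export
setMethod("traitValues", "LineageEnsemble", function(x, trait) {
  if (identical(trait, "D")) return(x@records$D)
  if (!trait %in% names(x@records))
    stop("unknown lineage trait: ", trait)
  x@records[[trait]]
})

#' @describeIn LineageEnsemble names of the available lineage traits
#'   (always includes the reserved division-count trait `"D"`)
#' @export
setMethod("traitNames", "LineageEnsemble", function(x) {
  c("D", setdiff(names(x@records), c("lineage_id", "D")))
})

#' @describeIn LineageEnsemble number of lineages
#' @export
setMethod("nLineages", "LineageEnsemble", function(x) nrow(x@records))

#' @describeIn LineageEnsemble initial cell count N0
#' @export
setMethod("initialCount", "LineageEnsemble", function(x) x@N0)

#' @describeIn LineageEnsemble final cell count Ntau (estimated as
#'   `sum(2^D)` in chronological mode)
#' @export
setMethod("finalCount", "LineageEnsemble", function(x) x@Ntau)

#' @describeIn LineageEnsemble window duration tau = tEnd - tStart (hours)
#' @export
setMethod("obsDuration", "LineageEnsemble", function(x) x@tEnd - x@tStart)

#' @describeIn LineageEnsemble `"tree"` or `"chronological"`
#' @export
setMethod("ensembleMode", "LineageEnsemble", function(x) x@mode)

#' @describeIn LineageEnsemble log population fold-growth
#'   `tau * Lambda = log(Ntau / N0)`
#' @export
setMethod("tauLambda", "LineageEnsemble", function(x) log(x@Ntau / x@N0))

#' @describeIn LineageEnsemble population growth rate Lambda (per hour)
#' @export
setMethod("growthRate", "LineageEnsemble", function(x) {
  log(x@Ntau / x@N0) / (x@tEnd - x@tStart)
})

setMethod("show", "LineageEnsemble", function(object) {
  cat(sprintf("LineageEnsemble (%s mode): %d lineages over [%g, %g] h\n",
              object@mode, nrow(object@records), object@tStart, object@tEnd))
  cat(sprintf("  N0 = %.6g, Ntau = %.6g, tau*Lambda = %.4f\n",
              object@N0, object@Ntau, log(object@Ntau / object@N0)))
  dtab <- table(object@records$D)
  cat("  division counts:",
      paste(sprintf("D=%s:%d", names(dtab), as.integer(dtab)), collapse = " "), "\n")
  extra <- setdiff(names(object@records), c("lineage_id", "D"))
  if (length(extra)) cat("  traits:", paste(extra, collapse = ", "), "\n")
})

#' @describeIn TraitDistributionPair bin centre positions
#' @param x a TraitDistributionPair
#' @export
setMethod("binCenters", "TraitDistributionPair", function(x) x@binCenters)

#' @describeIn TraitDistributionPair chronological probabilities Qcl
#' @export
setMethod("chronologicalQ", "TraitDistributionPair", function(x) x@Qcl)

#' @describeIn TraitDistributionPair retrospective probabilities Qrs
#' @export
setMethod("retrospectiveQ", "TraitDistributionPair", function(x) x@Qrs)

#' @describeIn TraitDistributionPair log population fold-growth
#' @export
setMethod("tauLambda", "TraitDistributionPair", function(x) log(x@Ntau / x@N0))

#' @describeIn TraitDistributionPair window duration (hours)
#' @export
setMethod("obsDuration", "TraitDistributionPair", function(x) x@tau)

setMethod("show", "TraitDistributionPair", function(object) {
  cat(sprintf("TraitDistributionPair for trait '%s': %d bins (%s binning)\n",
              object@trait, length(object@binCenters),
              if (length(object@binning)) object@binning$kind else "?"))
  cat(sprintf("  tau = %g h, N0 = %.6g, Ntau = %.6g, tau*Lambda = %.4f\n",
              object@tau, object@N0, object@Ntau, log(object@Ntau / object@N0)))
  occ <- object@Qcl > 0
  cat(sprintf("  occupied support: %d bins on [%g, %g]\n",
              sum(occ), min(object@binCenters[occ]), max(object@binCenters[occ])))
})

#' @describeIn SelectionSummary log population fold-growth
#' @param x a SelectionSummary
#' @export
setMethod("tauLambda", "SelectionSummary", function(x) x@tauLambda)

#' @describeIn SelectionSummary growth rate Lambda (per hour)
#' @export
setMethod("growthRate", "SelectionSummary", function(x) x@Lambda)

#' @describeIn SelectionSummary the fitness landscape as a data.frame
#'   `bin_center`, `h`
#' @export
setMethod("fitnessLandscape", "SelectionSummary", function(x) x@landscape)

setMethod("show", "SelectionSummary", function(object) {
  cat(sprintf("SelectionSummary for trait '%s'\n", object@trait))
  cat(sprintf("  tau*Lambda = %.5f  (Lambda = %.5f / h)\n",
              object@tauLambda, object@Lambda))
  cat(sprintf("  <h>_cl = %.5f  <h>_rs = %.5f  Var[h]_cl = %.5f  Var[h]_rs = %.5f\n",
              object@meanHcl, object@meanHrs, object@varHcl, object@varHrs))
  cat(sprintf("  S_KL1 = %.5f  S_KL2 = %.5f  S_JF = %.5f",
              object@SKL1, object@SKL2, object@SJF))
  if (!is.na(object@Srel)) cat(sprintf("  S_rel = %.4f", object@Srel))
  cat("\n")
})

#' @describeIn CumulantSeries the cumulants kappa_1..kappa_nmax
#' @param x a CumulantSeries
#' @export
setMethod("cumulantValues", "CumulantSeries", function(x) x@kappa)

#' @describeIn CumulantSeries the cumulative contributions W_1..W_nmax
#' @export
setMethod("cumulativeContributions", "CumulantSeries", function(x) x@W)

#' @describeIn CumulantSeries log fold-growth the series expands
#' @export
setMethod("tauLambda", "CumulantSeries", function(x) x@tauLambda)

setMethod("show", "CumulantSeries", function(object) {
  n <- length(object@kappa)
  cat(sprintf("CumulantSeries for trait '%s' (n_max = %d, %s)\n",
              object@trait, n,
              if (object@converged) "converged" else "NOT converged"))
  k <- seq_len(min(4L, n))
  cat("  kappa:", paste(sprintf("%.5g", object@kappa[k]), collapse = ", "),
      if (n > 4L) "...", "\n")
  cat("  W:    ", paste(sprintf("%.4f", object@W[k]), collapse = ", "),
      if (n > 4L) "...", "\n")
  cat(sprintf("  skewness = %.4g\n", object@skewness))
})
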