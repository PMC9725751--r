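#' @include AllClasses.R AllGenerics.R distributions.R
NULL

.IDENT_TOL <- 1e-10

#' Population growth from a lineage ensemble
#'
#' `tau * Lambda = log(Ntau / N0)`. In tree mode `Ntau` is the observed final
#' cell count; in chronological mode it is the reproductive-output estimate
#' `sum(2^D)`, so `tau * Lambda = log(mean(2^D))`.
#'
#' @param ensemble a [LineageEnsemble-class].
#' @return list with `tauLambda` (nats) and `Lambda` (per hour).
#' @examples
#' populationGrowth(LineageEnsemble(c(1, 2, 2), mode = "tree"))$tauLambda # log(3)
#' @export
populationGrowth <- function(ensemble) {
  stopifnot(is(ensemble, "LineageEnsemble"))
  tl <- tauLambda(ensemble)
  list(tauLambda = tl, Lambda = tl / obsDuration(ensemble))
}

# occupied support of a pair, with h(x) = tauLambda + log(Qrs/Qcl)
.pair_support <- function(pair) {
  occ <- pair@Qcl > 0
  if (any((pair@Qrs > 0) != occ))
    stop("support mismatch between chronological and retrospective distributions")
  tl <- log(pair@Ntau / pair@N0)
  list(x = pair@binCenters[occ], Qcl = pair@Qcl[occ], Qrs = pair@Qrs[occ],
       tauLambda = tl, h = tl + log(pair@Qrs[occ] / pair@Qcl[occ]))
}

#' @describeIn TraitDistributionPair the fitness landscape
#'   `h(x) = tau*Lambda + log(Qrs(x)/Qcl(x))` over the occupied bins, as a
#'   data.frame `bin_center`, `h`. For the division count on complete trees
#'   this equals `d * log(2)` exactly.
#' @export
setMethod("fitnessLandscape", "TraitDistributionPair", function(x) {
  s <- .pair_support(x)
  data.frame(bin_center = s$x, h = s$h)
})

#' Selection strength measures from a distribution pair
#'
#' Computes the two Kullback-Leibler selection strengths and their sum, the
#' Jeffreys selection strength, by both defining routes -- the divergence form
#' (`S_KL1 = sum Qcl log(Qcl/Qrs)`, `S_KL2 = sum Qrs log(Qrs/Qcl)`) and the
#' mean-fitness form (`S_KL1 = tau*Lambda - <h>_cl`,
#' `S_KL2 = <h>_rs - tau*Lambda`) -- and cross-checks them.
#'
#' @param pair a [TraitDistributionPair-class].
#' @return list `S_JF`, `S_KL1`, `S_KL2`, `meanHcl`, `meanHrs` (all in nats).
#' @export
selectionStrengths <- function(pair) {
  s <- .pair_support(pair)
  SKL1 <- sum(s$Qcl * log(s$Qcl / s$Qrs))
  SKL2 <- sum(s$Qrs * log(s$Qrs / s$Qcl))
  meanHcl <- sum(s$Qcl * s$h)
  meanHrs <- sum(s$Qrs * s$h)
  alt1 <- s$tauLambda - meanHcl
  alt2 <- meanHrs - s$tauLambda
  scale <- max(1, abs(s$tauLambda))
  if (abs(SKL1 - alt1) > 1e-8 * scale || abs(SKL2 - alt2) > 1e-8 * scale)
    stop("internal inconsistency: divergence and mean-fitness routes disagree")
  list(S_JF = SKL1 + SKL2, S_KL1 = SKL1, S_KL2 = SKL2,
       meanHcl = meanHcl, meanHrs = meanHrs)
}

#' Decompose population growth into chronological mean fitness and selection
#'
#' The identity `tau*Lambda = <h(X)>_cl + S_KL1[X]`. For the division count,
#' `<h~(D)>_cl / tau` is the mean division rate of lineages without selection
#' and `S_KL1[D] / tau` is the growth rate gain caused by growth
#' heterogeneity; the returned `gainFraction` is `S_KL1[D] / (tau*Lambda)`.
#'
#' @param pair a [TraitDistributionPair-class]; must be for trait `"D"` unless
#'   `allowGeneric = TRUE` (the identity holds for any trait, but the
#'   growth-rate-gain reading is specific to the division count).
#' @param allowGeneric permit non-division traits.
#' @return list `meanHcl`, `S_KL1`, `gainFraction`, `tauLambda`.
#' @export
decomposeGrowth <- function(pair, allowGeneric = FALSE) {
  if (!identical(pair@trait, "D") && !allowGeneric)
    stop("growth decomposition is interpreted for trait 'D'; ",
         "set allowGeneric = TRUE for other traits")
  s <- selectionStrengths(pair)
  tl <- log(pair@Ntau / pair@N0)
  if (abs(tl - (s$meanHcl + s$S_KL1)) > .IDENT_TOL * max(1, abs(tl)))
    stop("decomposition identity violated beyond tolerance")
  list(meanHcl = s$meanHcl, S_KL1 = s$S_KL1,
       gainFraction = s$S_KL1 / tl, tauLambda = tl)
}

#' Relative selection strength
#'
#' `S_rel[X] = S_KL1[X] / S_KL1[D]`. Because the division count bounds the
#' selection strength of every lineage trait measured on the same ensemble
#' (a data-processing inequality: any trait distribution is a coarse-graining
#' of the lineage-level weights), the ratio lies in `[0, 1]`.
#'
#' @param sX `S_KL1` of the trait of interest.
#' @param sD `S_KL1` of the division count, from the same ensemble.
#' @return the ratio; `NA` when both strengths are zero (no selection at all).
#' @export
relativeSelectionStrength <- function(sX, sD) {
  if (sX < -1e-12 || sD < -1e-12) stop("selection strengths must be non-negative")
  if (sD <= 0) {
    if (sX <= 1e-12) return(NA_real_)
    stop("S_KL1[D] = 0 but S_KL1[X] > 0: inputs are not from the same ensemble")
  }
  r <- sX / sD
  if (r > 1 + 1e-9)
    stop(sprintf("S_rel = %.6g > 1: inconsistent inputs (trait selection cannot exceed division-count selection)", r))
  min(r, 1)
}

#' Full selection summary for one lineage trait
#'
#' Builds the trait's distribution pair, the fitness landscape, mean and
#' variance of fitness under both statistics, and the three selection
#' strengths. For traits other than the division count the relative selection
#' strength `S_KL1[X] / S_KL1[D]` is included.
#'
#' @param ensemble a [LineageEnsemble-class].
#' @param trait trait name (default `"D"`).
#' @param spec optional [binning()] specification.
#' @return A [SelectionSummary-class].
#' @examples
#' summary <- selectionSummary(LineageEnsemble(c(1, 2, 2), mode = "tree"))
#' fitnessLandscape(summary)   # h(1) = log(2), h(2) = 2 log(2)
#' @export
selectionSummary <- function(ensemble, trait = "D", spec = NULL) {
  pair <- traitDistributions(ensemble, trait, spec)
  s <- .pair_support(pair)
  str <- selectionStrengths(pair)
  varHcl <- sum(s$Qcl * s$h^2) - str$meanHcl^2
  varHrs <- sum(s$Qrs * s$h^2) - str$meanHrs^2
  srel <- NA_real_
  if (!identical(trait, "D")) {
    sD <- selectionStrengths(traitDistributions(ensemble, "D"))
    srel <- relativeSelectionStrength(str$S_KL1, sD$S_KL1)
  }
  tau <- obsDuration(ensemble)
  methods::new("SelectionSummary",
               trait = trait, tauLambda = s$tauLambda,
               Lambda = s$tauLambda / tau,
               landscape = data.frame(bin_center = s$x, h = s$h),
               meanHcl = str$meanHcl, meanHrs = str$meanHrs,
               varHcl = varHcl, varHrs = varHrs,
               SJF = str$S_JF, SKL1 = str$S_KL1, SKL2 = str$S_KL2,
               Srel = srel)
}

#' Randomization null for the relative selection strength
#'
#' Finite data always give positive relative selection strengths; this null
#' assesses significance by shuffling the correspondence between division
#' counts and trait values across lineages and recomputing
#' `S_rel = S_KL1[X] / S_KL1[D]` for each permutation.
#'
#' @param ensemble a [LineageEnsemble-class] carrying `trait`.
#' @param trait trait name (not `"D"`).
#' @param spec optional [binning()] spec, shared by observed and null.
#' @param nPerm number of permutations.
#' @param seed RNG seed (optional).
#' @return list `observed`, `null` (length `nPerm`), `rank` (of the observed
#'   value within `c(null, observed)`), and the upper-tail permutation
#'   p-value `pUpper = (1 + #\{null >= observed\}) / (nPerm + 1)`.
#' @export
randomizationNull <- function(ensemble, trait, spec = NULL, nPerm = 1000,
                              seed = NULL) {
  if (identical(trait, "D")) stop("randomize a non-division trait against D")
  if (!is.null(seed)) set.seed(seed)
  if (nPerm < 1) stop("nPerm must be >= 1")
  x <- traitValues(ensemble, trait)
  if (is.null(spec)) {
    spec <- binning("fixed_width", width = autoBinWidth(x))
  }
  sD <- selectionStrengths(traitDistributions(ensemble, "D"))$S_KL1
  sObs <- selectionStrengths(traitDistributions(ensemble, trait, spec))$S_KL1
  observed <- relativeSelectionStrength(sObs, sD)
  n <- nLineages(ensemble)
  D <- divisionCounts(ensemble)
  mode <- ensembleMode(ensemble)
  null <- vapply(seq_len(nPerm), function(b) {
    perm <- LineageEnsemble(D, mode = mode, traits = stats::setNames(
      data.frame(sample(x, n)), trait),
      N0 = initialCount(ensemble),
      tStart = ensemble@tStart, tEnd = ensemble@tEnd)
    sP <- selectionStrengths(traitDistributions(perm, trait, spec))$S_KL1
    relativeSelectionStrength(sP, sD)
  }, numeric(1))
  list(observed = observed, null = null,
       rank = sum(null < observed) + 1L,
       pUpper = (1 + sum(null >= observed)) / (nPerm + 1))
}

#' Export a selection summary as JSON and its landscape as TSV
#'
#' @param summary a [SelectionSummary-class].
#' @param jsonPath path for the JSON summary; the landscape TSV
#'   (`bin_center  h  h_over_tau`) is written next to it with suffix
#'   `_landscape.tsv`.
#' @param tau observation duration used for the `h_over_tau` column.
#' @export
writeSelectionSummary <- function(summary, jsonPath,
                                  tau = summary@tauLambda / summary@Lambda) {
  jsonlite::write_json(
    list(trait = summary@trait, tau_lambda = summary@tauLambda,
         lambda = summary@Lambda,
         mean_h_cl = summary@meanHcl, mean_h_rs = summary@meanHrs,
         var_h_cl = summary@varHcl, var_h_rs = summary@varHrs,
         S_JF = summary@SJF, S_KL1 = summary@SKL1, S_KL2 = summary@SKL2,
         S_rel = if (is.na(summary@Srel)) NULL else summary@Srel),
    jsonPath, auto_unbox = TRUE, digits = NA, null = "null")
  land <- summary@landscape
  land$h_over_tau <- land$h / tau
  utils::write.table(land,
                     sub("\\.json$", "_landscape.tsv", jsonPath),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(jsonPath)
}
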