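# S4 containers for cell-lineage statistics.
#
# A "lineage" is the history of one cell present at the final observation
# time, traced back to its ancestor at the initial time. Its division count D
# determines the chronological weight 2^-D / N0 (probability of reaching the
# lineage by descending the tree, picking a random branch at each division)
# and the retrospective weight 1 / Ntau (uniform over surviving lineages).

.CONSERVATION_TOL <- 1e-9

#' LineageEnsemble: a set of cell lineages over an observation window
#'
#' Container for per-lineage division counts and scalar lineage traits over a
#' window `[tStart, tEnd]`. Two modes are supported:
#' \describe{
#'   \item{`tree`}{lineages come from complete genealogical trees (time-lapse
#'     colony data): `Ntau` equals the number of lineages and the dyadic
#'     conservation identity `sum(2^-D) == N0` must hold exactly.}
#'   \item{`chronological`}{isolated lineages (mother-machine data) sampled
#'     under chronological statistics: `N0` equals the number of lineages and
#'     the final cell number is estimated as `Ntau = sum(2^D)`.}
#' }
#'
#' @slot records data.frame with columns `lineage_id`, `D` (non-negative
#'   integer division counts) and one numeric column per lineage trait.
#' @slot mode `"tree"` or `"chronological"`.
#' @slot N0 numeric(1), number of cells spanning `tStart`. May be fractional
#'   for bootstrap replicates of colony data, where it is estimated as
#'   `sum(2^-D)` over the resampled lineages.
#' @slot Ntau numeric(1), number (tree mode) or estimate (chronological mode)
#'   of cells at `tEnd`.
#' @slot tStart,tEnd numeric(1), window limits in hours.
#' @exportClass LineageEnsemble
setClass("LineageEnsemble",
  representation(
    records = "data.frame",
    mode = "character",
    N0 = "numeric",
    Ntau = "numeric",
    tStart = "numeric",
    tEnd = "numeric"
  )
)

setValidity("LineageEnsemble", function(object) {
  msg <- character()
  rec <- object@records
  if (!all(c("lineage_id", "D") %in% names(rec)))
    msg <- c(msg, "records must have columns 'lineage_id' and 'D'")
  else {
    D <- rec$D
    if (length(D) == 0L) msg <- c(msg, "ensemble has no lineages")
    if (any(!is.finite(D)) || any(D < 0) || any(D != round(D)))
      msg <- c(msg, "division counts D must be non-negative integers")
  }
  if (!(length(object@mode) == 1L && object@mode %in% c("tree", "chronological")))
    msg <- c(msg, "mode must be 'tree' or 'chronological'")
  if (!(object@tEnd > object@tStart))
    msg <- c(msg, "observation window must have positive duration")
  if (length(msg) == 0L && "D" %in% names(rec)) {
    n <- nrow(rec)
    if (object@mode == "tree") {
      if (object@Ntau != n)
        msg <- c(msg, sprintf("tree mode: Ntau (%g) must equal the number of lineages (%d)", object@Ntau, n))
      kraft <- sum(2^(-rec$D))
      if (abs(kraft - object@N0) > .CONSERVATION_TOL * max(1, object@N0))
        msg <- c(msg, sprintf(
          "tree mode conservation violated: sum(2^-D) = %.12g but N0 = %.12g (lost or censored cells?)",
          kraft, object@N0))
    } else {
      if (object@N0 != n)
        msg <- c(msg, sprintf("chronological mode: N0 (%g) must equal the number of lineages (%d)", object@N0, n))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LineageEnsemble from division counts and traits
#'
#' @param D integer vector of per-lineage division counts.
#' @param mode `"tree"` (complete genealogy) or `"chronological"` (isolated
#'   lineages).
#' @param traits optional data.frame (or named list) of numeric lineage traits,
#'   one value per lineage. `"D"` and `"lineage_id"` are reserved names.
#' @param N0 initial cell count. Tree mode default: `sum(2^-D)` (which the
#'   validity check then confirms is the conserved value); chronological mode
#'   default and requirement: `length(D)`.
#' @param tStart,tEnd observation window in hours.
#' @param lineageId optional lineage identifiers (default `L1..Ln`).
#' @return A validated [LineageEnsemble-class] object.
#' @examples
#' # the three-lineage micro-tree with D = (1, 2, 2)
#' ens <- LineageEnsemble(c(1, 2, 2), mode = "tree")
#' tauLambda(ens)  # log(3)
#' @export
LineageEnsemble <- function(D, mode = c("tree", "chronological"), traits = NULL,
                            N0 = NULL, tStart = 0, tEnd = 1, lineageId = NULL) {
  mode <- match.arg(mode)
  D <- as.numeric(D)
  n <- length(D)
  if (n == 0L) stop("ensemble has no lineages")
  if (is.null(lineageId)) lineageId <- paste0("L", seq_len(n))
  rec <- data.frame(lineage_id = as.character(lineageId), D = D,
                    stringsAsFactors = FALSE)
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    if (nrow(traits) != n)
      stop("traits must provide one value per lineage")
    bad <- intersect(names(traits), c("D", "lineage_id"))
    if (length(bad)) stop("reserved trait name(s): ", paste(bad, collapse = ", "))
    rec <- cbind(rec, traits)
  }
  if (mode == "tree") {
    if (is.null(N0)) N0 <- sum(2^(-D))
    Ntau <- n
  } else {
    if (is.null(N0)) N0 <- n
    Ntau <- sum(2^D)
  }
  methods::new("LineageEnsemble", records = rec, mode = mode, N0 = N0,
               Ntau = Ntau, tStart = as.numeric(tStart), tEnd = as.numeric(tEnd))
}

#' TraitDistributionPair: binned chronological and retrospective distributions
#'
#' Chronological `Qcl(x)` and retrospective `Qrs(x)` probabilities of a lineage
#' trait on a common binned support, together with the window duration and the
#' initial/final cell counts needed to form `tau * Lambda = log(Ntau / N0)`.
#' Both distributions are built from the same lineage set, so every occupied
#' bin is occupied in both (common support).
#'
#' @slot trait trait name (the division count is the reserved trait `"D"`).
#' @slot binCenters bin centre positions; bin `x` covers
#'   `[x - width/2, x + width/2)`.
#' @slot Qcl,Qrs probability vectors summing to one.
#' @slot tau observation duration (hours).
#' @slot N0,Ntau initial and final cell counts (Ntau estimated in
#'   chronological mode).
#' @slot binning list of binning metadata (kind, width, origin, quartile
#'   convention used by the 0.4 IQR rule).
#' @exportClass TraitDistributionPair
setClass("TraitDistributionPair",
  representation(
    trait = "character",
    binCenters = "numeric",
    Qcl = "numeric",
    Qrs = "numeric",
    tau = "numeric",
    N0 = "numeric",
    Ntau = "numeric",
    binning = "list"
  )
)

setValidity("TraitDistributionPair", function(object) {
  msg <- character()
  L <- length(object@binCenters)
  if (length(object@Qcl) != L || length(object@Qrs) != L)
    msg <- c(msg, "Qcl, Qrs and binCenters must have equal length")
  if (abs(sum(object@Qcl) - 1) > 1e-12) msg <- c(msg, "Qcl does not sum to 1")
  if (abs(sum(object@Qrs) - 1) > 1e-12) msg <- c(msg, "Qrs does not sum to 1")
  if (any(object@Qcl < 0) || any(object@Qrs < 0))
    msg <- c(msg, "negative bin mass")
  if (any((object@Qcl > 0) != (object@Qrs > 0)))
    msg <- c(msg, "support mismatch: a bin has mass under only one statistic")
  if (!(object@tau > 0)) msg <- c(msg, "tau must be positive")
  if (!(object@N0 > 0) || !(object@Ntau > 0)) msg <- c(msg, "N0 and Ntau must be positive")
  if (length(msg)) msg else TRUE
})

#' SelectionSummary: growth, fitness landscape and selection strength
#'
#' Holds the population growth `tau * Lambda`, the fitness landscape `h(x)`,
#' mean and variance of fitness under chronological and retrospective
#' statistics, the three selection strength measures and, when the trait is
#' compared against the division count, the relative selection strength.
#' All fitness quantities are in nats.
#'
#' @slot trait trait name.
#' @slot tauLambda,Lambda log fold-growth (nats) and growth rate (per hour).
#' @slot landscape data.frame `bin_center`, `h` over the occupied support.
#' @slot meanHcl,meanHrs chronological / retrospective mean fitness.
#' @slot varHcl,varHrs chronological / retrospective fitness variance.
#' @slot SJF,SKL1,SKL2 Jeffreys and the two Kullback-Leibler selection
#'   strengths; `SJF == SKL1 + SKL2`.
#' @slot Srel relative selection strength `SKL1[X] / SKL1[D]` in `[0, 1]`
#'   (NA when not computed against D).
#' @exportClass SelectionSummary
setClass("SelectionSummary",
  representation(
    trait = "character",
    tauLambda = "numeric",
    Lambda = "numeric",
    landscape = "data.frame",
    meanHcl = "numeric", meanHrs = "numeric",
    varHcl = "numeric", varHrs = "numeric",
    SJF = "numeric", SKL1 = "numeric", SKL2 = "numeric",
    Srel = "numeric"
  )
)

#' CumulantSeries: cumulant expansion of population growth
#'
#' Cumulants `kappa_1..kappa_nmax` of the fitness landscape under the
#' chronological distribution, and the cumulative contributions
#' `W_n = (1 / tauLambda) * sum_{k<=n} kappa_k / k!`, which converge to 1 when
#' the expansion converges.
#'
#' @slot trait trait name.
#' @slot kappa cumulants (nats^n).
#' @slot W cumulative contributions (dimensionless).
#' @slot skewness `kappa_3 / kappa_2^(3/2)` (NA when `kappa_2 == 0`).
#' @slot tauLambda log fold-growth the series expands.
#' @slot converged TRUE when `W_nmax` is within tolerance of 1 with a
#'   decreasing tail.
#' @exportClass CumulantSeries
setClass("CumulantSeries",
  representation(
    trait = "character",
    kappa = "numeric",
    W = "numeric",
    skewness = "numeric",
    tauLambda = "numeric",
    converged = "logical"
  )
)
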