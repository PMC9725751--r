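#' @include AllClasses.R simulate.R
NULL

#' Deterministic and simulated fixture ensembles
#'
#' Small, fully characterised ensembles used in examples, tests and the
#' bundled analysis reports:
#' \describe{
#'   \item{`T1`}{the worked three-lineage micro-tree with `D = (1, 2, 2)`
#'     (one founder; one daughter divides again): `tau*Lambda = log(3)`,
#'     `h(1) = log(2)`, `h(2) = 2 log(2)`, `S_KL1 = log(3) - 1.5 log(2)`.}
#'   \item{`uniform`}{`N0` founders all yielding `2^d` lineages with `D = d`:
#'     no heterogeneity, every selection strength is zero.}
#'   \item{`two_root`}{founders with lineage sets `\{0\}` and `\{1, 1\}`.}
#'   \item{`skewed_regrowth`}{chronological-mode ensemble mimicking regrowth
#'     from deep dormancy: a fraction `p0` of lineages never divide and the
#'     rest spread uniformly over `3..dmax` divisions, giving a strongly
#'     right-skewed division-count distribution with `S_KL2 > S_KL1`.}
#'   \item{`gamma_sim`}{a tree-mode ensemble simulated from the gamma
#'     branching process (see [simulateMain()]).}
#' }
#'
#' @param name fixture name.
#' @param d,N0 division count and founder count for `uniform`.
#' @param p0,dmax,n non-divider fraction, maximum division count and lineage
#'   count for `skewed_regrowth`.
#' @param shape,scale,corr,tMax,nMain gamma-simulation parameters for
#'   `gamma_sim` (defaults as in [simulationConfig()], with a reduced
#'   `nMain`).
#' @param seed RNG seed for the stochastic fixtures.
#' @return A [LineageEnsemble-class].
#' @examples
#' tauLambda(fixtureEnsemble("T1"))          # log(3)
#' @export
fixtureEnsemble <- function(name = c("T1", "uniform", "two_root",
                                     "skewed_regrowth", "gamma_sim"),
                            d = 3, N0 = 2, p0 = 0.9, dmax = 6, n = 200,
                            shape = 2, scale = 2^(1 / shape) - 1, corr = 0,
                            tMax = 8, nMain = 100, seed = 1) {
  name <- match.arg(name)
  switch(name,
    T1 = LineageEnsemble(c(1, 2, 2), mode = "tree", tStart = 0, tEnd = 1,
                         lineageId = c("A", "B1", "B2")),
    uniform = LineageEnsemble(rep(d, N0 * 2^d), mode = "tree",
                              tStart = 0, tEnd = 1),
    two_root = LineageEnsemble(c(0, 1, 1), mode = "tree", tStart = 0, tEnd = 1),
    skewed_regrowth = {
      n0 <- round(p0 * n)
      dlo <- min(3, dmax)
      Dplus <- rep(seq.int(dlo, dmax), length.out = n - n0)
      LineageEnsemble(c(rep(0, n0), sort(Dplus)), mode = "chronological",
                      tStart = 0, tEnd = 6)
    },
    gamma_sim = {
      cfg <- simulationConfig(shape = shape, scale = scale, corr = corr,
                              eps = 0, tMax = tMax, nPrerun = max(20, nMain %/% 2),
                              nMain = nMain, seed = seed)
      asLineageEnsemble(simulateMain(cfg), "tree")
    })
}

#' Random complete-tree ensembles for property testing
#'
#' Grows each founder's tree by splitting every current leaf with probability
#' `splitProb` per generation, up to `maxDepth` generations, so the dyadic
#' conservation identity `sum(2^-D) = N0` holds exactly by construction.
#' Optionally attaches a continuous trait correlated with the division count
#' (`traitRho` in `[0, 1]`; 0 gives an independent trait).
#'
#' Uses the session RNG: call `set.seed()` for reproducibility.
#'
#' @param nRoots founder count.
#' @param splitProb per-generation division probability.
#' @param maxDepth maximum divisions per lineage.
#' @param trait add a numeric trait column `"x"`?
#' @param traitRho correlation of the trait with `D`.
#' @return A tree-mode [LineageEnsemble-class].
#' @export
randomLineageEnsemble <- function(nRoots = 3, splitProb = 0.6, maxDepth = 8,
                                  trait = FALSE, traitRho = 0) {
  D <- integer(0)
  leaves <- rep(0L, nRoots)
  for (depth in seq_len(maxDepth)) {
    if (!length(leaves)) break
    split <- stats::runif(length(leaves)) < splitProb
    D <- c(D, leaves[!split])
    leaves <- rep(leaves[split] + 1L, each = 2L)
  }
  D <- c(D, leaves)
  traits <- NULL
  if (trait) {
    x <- traitRho * D + sqrt(max(0, 1 - traitRho^2)) * stats::rnorm(length(D))
    traits <- data.frame(x = x)
  }
  LineageEnsemble(D, mode = "tree", traits = traits, tStart = 0, tEnd = 1)
}

#' Write a fixture to disk with a manifest of its exact statistics
#'
#' Writes the lineage table (TSV + JSON sidecar, see [readLineageTable()])
#' and a `<name>_manifest.json` recording the statistics recomputed from the
#' ensemble by direct enumeration of the defining sums (`tau*Lambda`, the
#' landscape over the occupied support, all three selection strengths and
#' `W_1`, `W_2`), for use in documentation and as frozen test expectations.
#'
#' @inheritParams fixtureEnsemble
#' @param dir output directory (created if needed).
#' @param ... passed to [fixtureEnsemble()].
#' @return invisibly, the manifest list.
#' @export
generateFixture <- function(name, dir = ".", seed = 1, ...) {
  ens <- fixtureEnsemble(name, seed = seed, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLineageTable(ens, file.path(dir, paste0(name, ".tsv")))
  sm <- selectionSummary(ens, "D")
  cs <- fitnessCumulants(traitDistributions(ens, "D"))
  manifest <- list(
    name = name, mode = ensembleMode(ens), n_lineages = nLineages(ens),
    N0 = initialCount(ens), Ntau = finalCount(ens),
    tau_lambda = tauLambda(ens),
    landscape = fitnessLandscape(sm),
    S_JF = sm@SJF, S_KL1 = sm@SKL1, S_KL2 = sm@SKL2,
    W1 = cs@W[1], W2 = cs@W[2],
    skl2_exceeds_skl1 = sm@SKL2 > sm@SKL1)
  jsonlite::write_json(manifest, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}
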