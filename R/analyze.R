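#' @include AllClasses.R selection.R cgf.R resample.R simulate.R
NULL

#' End-to-end lineage analysis report
#'
#' Reads lineage data (or takes an ensemble directly), then for the division
#' count and each requested trait writes: the selection summary (JSON) with
#' its fitness landscape (TSV), the `K'(xi)` curve (TSV), the cumulant series
#' (TSV), and bootstrap uncertainty summaries (JSON) for `tau*Lambda`, the
#' mean fitness measures, the three selection strengths, `W_1`, `W_2` and
#' (for non-division traits) `S_rel`. All fitness quantities are reported in
#' nats; the landscape TSV also carries `h / tau`.
#'
#' @param input a [LineageEnsemble-class], or a path to a lineage table
#'   (`format = "lineage_table"`), cell edge list (`"cell_table"`) or Newick
#'   file (`"newick"`).
#' @param format input format when `input` is a path.
#' @param traits character vector of trait names to analyse in addition to
#'   the division count.
#' @param outDir output directory.
#' @param window `c(tStart, tEnd)` for cell-table input.
#' @param bootstrap replicate count for the uncertainty summaries (0 skips
#'   them).
#' @param seed RNG seed for the bootstrap.
#' @param nMax cumulant expansion order.
#' @return invisibly, a list with the per-trait summaries and the paths
#'   written.
#' @export
runAnalyze <- function(input, format = c("lineage_table", "cell_table", "newick"),
                       traits = character(), outDir = "lineage_report",
                       window = NULL, bootstrap = 1000, seed = 1, nMax = 20) {
  ens <- if (is(input, "LineageEnsemble")) input else {
    format <- match.arg(format)
    switch(format,
      lineage_table = readLineageTable(input),
      cell_table = {
        if (is.null(window)) stop("cell-table input needs window = c(tStart, tEnd)")
        parseCellTable(readCellTable(input), window[1], window[2])
      },
      newick = parseNewickLineages(file = input))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  out <- list()
  bootFun <- if (ensembleMode(ens) == "tree") resampleColony else resampleChronological

  for (tr in unique(c("D", traits))) {
    sm <- selectionSummary(ens, tr)
    pair <- traitDistributions(ens, tr)
    cs <- fitnessCumulants(pair, nMax)
    base <- file.path(outDir, paste0("trait_", tr))
    writeSelectionSummary(sm, paste0(base, "_selection.json"),
                          tau = obsDuration(ens))
    writeDistributionPair(pair, paste0(base, "_distributions.tsv"))
    writeKprimeCurve(pair, paste0(base, "_kprime.tsv"))
    writeCumulantSeries(cs, paste0(base, "_cumulants.tsv"))
    paths <- c(paths, paste0(base, c("_selection.json", "_distributions.tsv",
                                     "_kprime.tsv", "_cumulants.tsv")))
    if (bootstrap > 0) {
      stats_list <- list(
        tau_lambda = function(e) tauLambda(e),
        mean_h_cl = function(e) selectionStrengths(traitDistributions(e, tr))$meanHcl,
        mean_h_rs = function(e) selectionStrengths(traitDistributions(e, tr))$meanHrs,
        S_KL1 = function(e) selectionStrengths(traitDistributions(e, tr))$S_KL1,
        S_KL2 = function(e) selectionStrengths(traitDistributions(e, tr))$S_KL2,
        S_JF = function(e) selectionStrengths(traitDistributions(e, tr))$S_JF,
        W_1 = function(e) fitnessCumulants(traitDistributions(e, tr), 4)@W[1],
        W_2 = function(e) fitnessCumulants(traitDistributions(e, tr), 4)@W[2])
      if (tr != "D")
        stats_list$S_rel <- function(e) relativeSelectionStrength(
          selectionStrengths(traitDistributions(e, tr))$S_KL1,
          selectionStrengths(traitDistributions(e, "D"))$S_KL1)
      boots <- lapply(names(stats_list), function(nm) {
        u <- bootFun(ens, stats_list[[nm]], B = bootstrap, seed = seed,
                     statName = nm)
        writeUncertaintySummary(u, paste0(base, "_boot_", nm, ".json"))
        u
      })
      names(boots) <- names(stats_list)
      out[[tr]] <- list(summary = sm, cumulants = cs, bootstrap = boots)
    } else {
      out[[tr]] <- list(summary = sm, cumulants = cs)
    }
  }
  out$paths <- paths
  invisible(out)
}

#' Run the removal-perturbation simulation experiment end to end
#'
#' Drives [epsilonSweep()] and writes the per-strength growth table together
#' with the three theory lines (`-eps`, chronological-slope and
#' retrospective-slope predictions) for plotting, plus a JSON summary.
#'
#' @param config a [simulationConfig()].
#' @param epsGrid perturbation strengths (must include 0).
#' @param outDir output directory.
#' @return invisibly, the [epsilonSweep()] result.
#' @export
runSimulate <- function(config, epsGrid = seq(0, 0.2, by = 0.05),
                        outDir = "sim_report") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sw <- epsilonSweep(config, epsGrid)
  tab <- sw$table
  tab$line_uniform <- -tab$eps
  tab$line_chrono <- sw$theory$chronoSlope * tab$eps
  tab$line_retro <- sw$theory$relativeSlope * tab$eps
  utils::write.table(tab, file.path(outDir, "epsilon_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(shape = config$shape, scale = config$scale, corr = config$corr,
         tMax = config$tMax, nMain = config$nMain, seed = config$seed,
         relative_slope = sw$theory$relativeSlope,
         S_KL2 = sw$theory$S_KL2, tau_lambda = sw$theory$tauLambda),
    file.path(outDir, "epsilon_sweep.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(sw)
}
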