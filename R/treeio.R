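#' @include AllClasses.R
NULL

# Time comparisons tolerate small rounding in recorded division times.
.TIME_TOL <- 1e-9

.as_hours <- function(x, units) if (units == "min") x / 60 else x

#' Build a LineageEnsemble from a cell table (edge list)
#'
#' Converts the per-cell records of a time-lapse genealogy into the lineage
#' representation: one lineage per cell spanning the end of the observation
#' window, with its division count `D` counted over `tStart < t_div <= tEnd`
#' (a division at exactly `tStart` belongs to the previous window, so the
#' cells present at `tStart` are the `N0` founders).
#'
#' @param cells data.frame with columns `cell_id`, `parent_id` (NA or `""` for
#'   roots), `birth_time`, `end_time` and `fate` (one of `divided`,
#'   `alive_at_end`, `lost`). A divided cell's `end_time` is its division time
#'   and must equal its daughters' `birth_time`.
#' @param tStart,tEnd observation window.
#' @param strict if TRUE (default), a cell lost inside the window is an error,
#'   because all estimators assume complete trees. If FALSE, the tree is
#'   accepted with a warning reporting the conservation defect, and the
#'   ensemble's `N0` is set to `sum(2^-D)` of the surviving lineages so that
#'   chronological weights remain normalized; the true founder count is given
#'   in the warning.
#' @param traitSeries optional long-format trait samples (`cell_id`, `time`,
#'   `trait`, `value`); see [readTraitSeries()]. When supplied, each trait is
#'   time-averaged along every lineage at `t_i = tStart + i * deltaT`, reading
#'   the sample from whichever cell on the lineage path is alive at `t_i`.
#' @param deltaT sampling interval of `traitSeries` in hours (default 0.05 h,
#'   i.e. the 3-min frame interval typical of time-lapse acquisitions).
#' @param units `"hr"` (default) or `"min"` for all input times.
#' @return A tree-mode [LineageEnsemble-class].
#' @export
parseCellTable <- function(cells, tStart, tEnd, strict = TRUE,
                           traitSeries = NULL, deltaT = 0.05,
                           units = c("hr", "min")) {
  units <- match.arg(units)
  need <- c("cell_id", "parent_id", "birth_time", "end_time", "fate")
  if (!all(need %in% names(cells)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  cells$cell_id <- as.character(cells$cell_id)
  cells$parent_id <- as.character(cells$parent_id)
  cells$parent_id[cells$parent_id %in% c("", "NA")] <- NA_character_
  cells$birth_time <- .as_hours(as.numeric(cells$birth_time), units)
  cells$end_time <- .as_hours(as.numeric(cells$end_time), units)
  tStart <- .as_hours(tStart, units); tEnd <- .as_hours(tEnd, units)
  if (!(tStart < tEnd)) stop("empty observation window: tStart must be < tEnd")

  if (anyDuplicated(cells$cell_id))
    stop("duplicated cell_id in cell table")
  if (any(cells$end_time < cells$birth_time - .TIME_TOL))
    stop("cell with end_time < birth_time")
  if (!all(cells$fate %in% c("divided", "alive_at_end", "lost")))
    stop("fate must be one of 'divided', 'alive_at_end', 'lost'")

  idx <- seq_len(nrow(cells))
  names(idx) <- cells$cell_id
  parent <- idx[cells$parent_id]          # NA for roots
  # linkage and binary-division checks
  has_par <- !is.na(parent)
  if (any(abs(cells$birth_time[has_par] - cells$end_time[parent[has_par]]) > 1e-6))
    stop("child birth_time does not match parent end_time")
  nkid <- tabulate(parent[has_par], nbins = nrow(cells))
  bad <- which(cells$fate == "divided" & nkid != 2L &
                 cells$end_time <= tEnd + .TIME_TOL)
  if (length(bad))
    stop("divided cell(s) without exactly 2 recorded daughters: ",
         paste(utils::head(cells$cell_id[bad], 5), collapse = ", "))

  lost <- cells$fate == "lost" & cells$end_time > tStart + .TIME_TOL &
    cells$birth_time <= tEnd + .TIME_TOL
  if (any(lost)) {
    if (strict)
      stop(sum(lost), " cell(s) lost inside the window; complete trees are ",
           "required (use strict = FALSE to drop the affected subtrees)")
  }

  alive_at <- function(t) cells$birth_time <= t + .TIME_TOL & cells$end_time > t + .TIME_TOL
  n0_true <- sum(alive_at(tStart))
  terminal <- cells$birth_time <= tEnd + .TIME_TOL &
    (cells$end_time > tEnd + .TIME_TOL |
       (abs(cells$end_time - tEnd) <= .TIME_TOL & cells$fate == "alive_at_end"))
  if (!any(terminal))
    stop("no cell spans tEnd = ", tEnd, "; empty window")
  if (n0_true == 0L) stop("no cell spans tStart = ", tStart, "; empty window")

  term_idx <- which(terminal)
  D <- integer(length(term_idx))
  paths <- vector("list", length(term_idx))
  for (j in seq_along(term_idx)) {
    i <- term_idx[j]
    path <- i
    d <- 0L
    p <- parent[i]
    while (!is.na(p) && cells$end_time[p] > tStart + .TIME_TOL) {
      if (cells$fate[p] != "divided")
        stop("ancestor ", cells$cell_id[p], " of a terminal cell is not 'divided'")
      if (cells$end_time[p] <= tEnd + .TIME_TOL) d <- d + 1L
      path <- c(p, path)
      p <- parent[p]
    }
    D[j] <- d
    paths[[j]] <- path
  }

  traits <- NULL
  if (!is.null(traitSeries)) {
    traits <- .lineage_trait_averages(cells, paths, traitSeries,
                                      tStart, tEnd, deltaT, units)
  }

  kraft <- sum(2^(-D))
  if (abs(kraft - n0_true) > .CONSERVATION_TOL * max(1, n0_true)) {
    # only reachable with lost cells in lenient mode
    warning(sprintf(
      "conservation defect: sum(2^-D) = %.6g over surviving lineages but %d founders span tStart; ensemble N0 set to %.6g",
      kraft, n0_true, kraft))
  }
  LineageEnsemble(D, mode = "tree", traits = traits,
                  N0 = kraft, tStart = tStart, tEnd = tEnd,
                  lineageId = cells$cell_id[term_idx])
}

.lineage_trait_averages <- function(cells, paths, series, tStart, tEnd,
                                    deltaT, units) {
  need <- c("cell_id", "time", "trait", "value")
  if (!all(need %in% names(series)))
    stop("trait series must have columns: ", paste(need, collapse = ", "))
  series$cell_id <- as.character(series$cell_id)
  series$time <- .as_hours(as.numeric(series$time), units)
  deltaT <- .as_hours(deltaT, units)
  nS <- floor((tEnd - tStart) / deltaT + .TIME_TOL)
  ti <- tStart + (0:nS) * deltaT
  out <- list()
  for (tr in unique(series$trait)) {
    ss <- series[series$trait == tr, ]
    key <- paste(ss$cell_id, round(ss$time / deltaT))
    val <- stats::setNames(ss$value, key)
    avg <- vapply(paths, function(path) {
      xs <- numeric(length(ti))
      for (k in seq_along(ti)) {
        t <- ti[k]
        on <- path[cells$birth_time[path] <= t + .TIME_TOL &
                     (cells$end_time[path] > t + .TIME_TOL |
                        abs(cells$end_time[path] - t) <= .TIME_TOL & k == length(ti))]
        v <- NA_real_
        if (length(on)) {
          i <- on[length(on)]
          v <- val[paste(cells$cell_id[i], round(t / deltaT))]
        }
        if (is.na(v))
          stop(sprintf("trait '%s': missing sample at t = %g on lineage ending in %s",
                       tr, t, cells$cell_id[path[length(path)]]))
        xs[k] <- v
      }
      mean(xs)
    }, numeric(1))
    out[[tr]] <- avg
  }
  as.data.frame(out, check.names = FALSE)
}

#' Time-average a trait series sampled on a regular grid
#'
#' Computes `(1/(N+1)) * sum_{i=0}^{N} x(t_i)` with `t_i = tStart + i * deltaT`,
#' the time-averaged lineage trait used for e.g. mean fluorescence intensity.
#' All `N + 1` samples must be present; missing grid times are an error.
#'
#' @param times,values sample times and values (any order).
#' @param tStart grid origin.
#' @param deltaT sampling interval.
#' @param nSamples `N`: the grid is `t_0..t_N`.
#' @return the time average (scalar).
#' @examples
#' traitTimeAverage(c(0, 1, 2), c(0, 1, 2), tStart = 0, deltaT = 1, nSamples = 2)
#' @export
traitTimeAverage <- function(times, values, tStart, deltaT, nSamples) {
  ti <- tStart + (0:nSamples) * deltaT
  pick <- vapply(ti, function(t) {
    j <- which(abs(times - t) <= .TIME_TOL + 1e-9 * max(1, abs(t)))
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  if (anyNA(pick))
    stop("missing trait samples at t = ",
         paste(signif(ti[is.na(pick)], 8), collapse = ", "))
  mean(values[pick])
}

#' Read / write the cell edge-list TSV format
#'
#' Tab-separated with header `cell_id  parent_id  birth_time  end_time  fate`;
#' an empty `parent_id` marks a root cell.
#'
#' @param path file path.
#' @param units time units in the file, `"hr"` (default) or `"min"`.
#' @return `readCellTable`: a data.frame suitable for [parseCellTable()].
#' @export
readCellTable <- function(path, units = c("hr", "min")) {
  units <- match.arg(units)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(cell_id = "character",
                                        parent_id = "character"))
  x$birth_time <- .as_hours(x$birth_time, units)
  x$end_time <- .as_hours(x$end_time, units)
  x
}

#' @rdname readCellTable
#' @param cells a cell-record data.frame.
#' @export
writeCellTable <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format trait time series TSV
#'
#' Columns `cell_id  time  trait  value`, one row per sample.
#' @param path file path.
#' @export
readTraitSeries <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(cell_id = "character", trait = "character"))
}

#' Build a LineageEnsemble from a Newick tree
#'
#' Each leaf is a cell alive at the end of the window; its division count is
#' the number of internal nodes on the root-to-leaf path. All internal nodes
#' must be binary (a cell divides into exactly two daughters). Equivalent to
#' [parseCellTable()] on the same genealogy.
#'
#' @param text Newick string (alternative to `file`). A bare leaf label such
#'   as `"A;"` denotes a single never-dividing cell.
#' @param file path to a Newick file.
#' @param tEnd window end; when the tree has branch lengths (in hours) the
#'   default is the maximum root-to-leaf path length, otherwise 1.
#' @return A tree-mode [LineageEnsemble-class].
#' @examples
#' ens <- parseNewickLineages("((B1:0.4,B2:0.4):0.6,A:1);")
#' divisionCounts(ens)  # 2, 2, 1
#' @export
parseNewickLineages <- function(text = NULL, file = NULL, tEnd = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'text' or 'file'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  stripped <- trimws(sub(";\\s*$", "", text))
  if (!grepl("[(),]", stripped)) {
    # single never-dividing cell
    return(LineageEnsemble(0L, mode = "tree", tStart = 0,
                           tEnd = if (is.null(tEnd)) 1 else tEnd,
                           lineageId = stripped))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick near character ",
                        regexpr("[^(),:;0-9A-Za-z._ -]", text))
  if (!ape::is.binary(tr))
    stop("non-binary internal node: every division must produce exactly 2 daughters")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  # D = number of edges on the root-to-leaf path = number of internal nodes
  depth <- integer(ntip + tr$Nnode)
  depth[root] <- 0L
  for (e in seq_len(nrow(tr$edge))) {      # ape edges are in preorder
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + 1L
  }
  D <- depth[seq_len(ntip)]
  if (is.null(tEnd)) {
    tEnd <- if (!is.null(tr$edge.length)) max(ape::node.depth.edgelength(tr)[seq_len(ntip)]) else 1
    if (!is.finite(tEnd) || tEnd <= 0) tEnd <- 1
  }
  LineageEnsemble(D, mode = "tree", tStart = 0, tEnd = tEnd,
                  lineageId = tr$tip.label)
}

# Rebuild a binary tree topology from a complete division-count multiset.
# Exact dyadic arithmetic: masses are 2^(maxD - D) in integers.
.d_to_newick <- function(D, labels) {
  if (length(D) == 1L && D[1] == 0L) return(labels[1])
  maxD <- max(D)
  mass <- 2^(maxD - D)            # integer-valued doubles, sum = 2^maxD
  ord <- order(D)                 # largest mass first
  acc <- cumsum(mass[ord])
  half <- 2^(maxD - 1)
  cut <- match(half, acc)
  if (is.na(cut))
    stop("division counts do not form a complete binary tree (sum 2^-D != 1)")
  left <- ord[seq_len(cut)]
  right <- ord[-seq_len(cut)]
  paste0("(",
         .d_to_newick(D[left] - 1L, labels[left]), ",",
         .d_to_newick(D[right] - 1L, labels[right]), ")")
}

#' Serialize a tree-mode ensemble to Newick
#'
#' Reconstructs one binary tree topology per founder cell from the division
#' counts (any topology consistent with the complete-tree identity
#' `sum(2^-D) = 1` per founder) and writes it as Newick, one tree per line.
#' Branch lengths are not written; parsing the output with
#' [parseNewickLineages()] recovers the same division-count multiset.
#'
#' @param ensemble a tree-mode [LineageEnsemble-class] with integer `N0`.
#' @param file optional path; when given the strings are written there.
#' @return character vector of Newick strings (invisibly when `file` is set).
#' @export
ensembleToNewick <- function(ensemble, file = NULL) {
  stopifnot(is(ensemble, "LineageEnsemble"))
  if (ensembleMode(ensemble) != "tree")
    stop("Newick export requires a tree-mode ensemble")
  N0 <- initialCount(ensemble)
  if (abs(N0 - round(N0)) > 1e-9)
    stop("Newick export requires an integer founder count")
  N0 <- as.integer(round(N0))
  D <- as.integer(divisionCounts(ensemble))
  labels <- ensemble@records$lineage_id
  # partition lineages into founder groups, each with sum(2^-D) = 1
  maxD <- max(D, 1L)
  ord <- order(D)
  acc <- cumsum(2^(maxD - D[ord]))
  cuts <- match((2^maxD) * seq_len(N0), acc)
  if (anyNA(cuts)) stop("division counts do not partition into complete trees")
  start <- c(1L, utils::head(cuts, -1L) + 1L)
  out <- vapply(seq_len(N0), function(g) {
    i <- ord[start[g]:cuts[g]]
    paste0(.d_to_newick(D[i], labels[i]), ";")
  }, character(1))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read / write the lineage table TSV + JSON sidecar format
#'
#' The table is tab-separated with header
#' `lineage_id  division_count  <trait columns...>`; ensemble metadata
#' (`mode`, `N0`, `Ntau`, `t_start`, `t_end`) live in a JSON sidecar next to
#' the table (same path with extension `.json`).
#'
#' @param path path of the `.tsv` table.
#' @return `readLineageTable`: a [LineageEnsemble-class].
#' @export
readLineageTable <- function(path) {
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(lineage_id = "character"))
  traits <- tab[setdiff(names(tab), c("lineage_id", "division_count"))]
  if (ncol(traits) == 0L) traits <- NULL
  LineageEnsemble(tab$division_count, mode = meta$mode, traits = traits,
                  N0 = meta$N0, tStart = meta$t_start, tEnd = meta$t_end,
                  lineageId = tab$lineage_id)
}

#' @rdname readLineageTable
#' @param ensemble a [LineageEnsemble-class].
#' @export
writeLineageTable <- function(ensemble, path) {
  rec <- ensemble@records
  tab <- data.frame(lineage_id = rec$lineage_id, division_count = rec$D,
                    check.names = FALSE)
  extra <- setdiff(names(rec), c("lineage_id", "D"))
  if (length(extra)) tab <- cbind(tab, rec[extra])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(mode = ensemble@mode, N0 = ensemble@N0, Ntau = ensemble@Ntau,
         t_start = ensemble@tStart, t_end = ensemble@tEnd),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
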