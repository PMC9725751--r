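test_that("cell tables yield lineages with correct division counts and counts", {
  ens <- parseCellTable(t1_cells(), 0, 1)
  expect_s4_class(ens, "LineageEnsemble")
  expect_equal(sort(divisionCounts(ens)), c(1, 2, 2))
  expect_equal(initialCount(ens), 1)
  expect_equal(finalCount(ens), 3)
  expect_equal(obsDuration(ens), 1)

  solo <- data.frame(cell_id = "c", parent_id = NA, birth_time = 0,
                     end_time = 2, fate = "alive_at_end")
  e1 <- parseCellTable(solo, 0, 1)
  expect_equal(divisionCounts(e1), 0)
  expect_equal(initialCount(e1), 1)
  expect_equal(finalCount(e1), 1)
})

test_that("window conventions: divisions at tStart excluded, at tEnd included", {
  cells <- data.frame(
    cell_id = c("p", "c1", "c2"),
    parent_id = c(NA, "p", "p"),
    birth_time = c(0, 0.5, 0.5),
    end_time = c(0.5, 2, 2),
    fate = c("divided", "alive_at_end", "alive_at_end"))
  # division at exactly tStart: daughters are the two founders
  e_start <- parseCellTable(cells, 0.5, 1.5)
  expect_equal(divisionCounts(e_start), c(0, 0))
  expect_equal(initialCount(e_start), 2)
  # division at exactly tEnd: counted, daughters terminal
  e_end <- parseCellTable(cells, 0, 0.5)
  expect_equal(divisionCounts(e_end), c(1, 1))
  expect_equal(initialCount(e_end), 1)
})

test_that("window enlargement never decreases any lineage's division count", {
  d_narrow <- sort(divisionCounts(parseCellTable(t1_cells(), 0.4, 0.9)))
  d_wide <- sort(divisionCounts(parseCellTable(t1_cells(), 0.2, 1.0)))
  expect_true(sum(d_wide) >= sum(d_narrow))
  expect_equal(d_narrow, c(0, 1, 1))
  expect_equal(d_wide, c(1, 2, 2))
})

test_that("lost cells are rejected in strict mode and flagged in lenient mode", {
  cells <- t1_cells()
  cells$fate[cells$cell_id == "b1"] <- "lost"
  cells$end_time[cells$cell_id == "b1"] <- 0.9
  expect_error(parseCellTable(cells, 0, 1), "lost")
  expect_warning(ens <- parseCellTable(cells, 0, 1, strict = FALSE),
                 "conservation defect")
  expect_equal(sort(divisionCounts(ens)), c(1, 2))
  expect_lt(initialCount(ens), 1)      # sum(2^-D) = 3/4 < true founder count
})

test_that("Newick parsing counts internal nodes on root-to-leaf paths", {
  ens <- parseNewickLineages("((B1:0.4,B2:0.4):0.6,A:1);")
  got <- divisionCounts(ens)
  names(got) <- ens@records$lineage_id
  expect_equal(got[c("A", "B1", "B2")], c(A = 1, B1 = 2, B2 = 2))
  expect_equal(obsDuration(ens), 1)    # branch lengths give the window
  expect_equal(divisionCounts(parseNewickLineages("A;")), 0)
  expect_error(parseNewickLineages("((A,B,C),D);"), "non-binary")
  expect_error(parseNewickLineages("((A,B);"), "[Mm]alformed|parenthes")
})

test_that("Newick round-trip preserves the division-count multiset", {
  set.seed(42)
  for (rep in 1:10) {
    ens <- randomLineageEnsemble(nRoots = sample(1:4, 1),
                                 splitProb = runif(1, 0.3, 0.7), maxDepth = 7)
    nw <- ensembleToNewick(ens)
    expect_length(nw, as.integer(initialCount(ens)))
    back <- unlist(lapply(nw, function(s) divisionCounts(parseNewickLineages(s))))
    expect_equal(sort(back), sort(divisionCounts(ens)))
  }
})

test_that("lineage table round-trips through TSV + JSON sidecar", {
  set.seed(5)
  ens <- randomLineageEnsemble(3, 0.5, 6, trait = TRUE, traitRho = 0.4)
  path <- file.path(withr::local_tempdir(), "ens.tsv")
  writeLineageTable(ens, path)
  back <- readLineageTable(path)
  expect_equal(ensembleMode(back), ensembleMode(ens))
  expect_equal(initialCount(back), initialCount(ens))
  expect_equal(finalCount(back), finalCount(ens))
  expect_equal(obsDuration(back), obsDuration(ens))
  o1 <- order(divisionCounts(ens), traitValues(ens, "x"))
  o2 <- order(divisionCounts(back), traitValues(back, "x"))
  expect_equal(divisionCounts(back)[o2], divisionCounts(ens)[o1])
  expect_equal(traitValues(back, "x")[o2], traitValues(ens, "x")[o1])

  cpath <- file.path(withr::local_tempdir(), "cells.tsv")
  writeCellTable(t1_cells(), cpath)
  expect_equal(sort(divisionCounts(parseCellTable(readCellTable(cpath), 0, 1))),
               c(1, 2, 2))
})

test_that("trait time averages follow the (N+1)-sample grid rule", {
  expect_equal(traitTimeAverage(0:5, rep(7, 6), 0, 1, 5), 7)
  expect_equal(traitTimeAverage(c(0, 1, 2), c(0, 1, 2), 0, 1, 2), 1)
  # 3-min sampling of the ramp x(t) = t over [0, 6] min averages to 3 min
  tmin <- c(0, 3, 6) / 60
  expect_equal(traitTimeAverage(tmin, tmin, 0, 3 / 60, 2), 3 / 60)
  expect_error(traitTimeAverage(c(0, 2), c(1, 1), 0, 1, 2), "missing")
})

test_that("trait series are averaged along the lineage path across divisions", {
  cells <- t1_cells()
  grid <- seq(0, 1, by = 0.05)
  series <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    tt <- grid[grid >= cells$birth_time[i] - 1e-9 &
                 (grid < cells$end_time[i] - 1e-9 |
                    (abs(grid - 1) < 1e-9 & cells$end_time[i] >= 1))]
    if (!length(tt)) return(NULL)
    data.frame(cell_id = cells$cell_id[i], time = tt, trait = "gfp",
               value = ifelse(cells$cell_id[i] %in% c("a"), 10, 2))
  }))
  ens <- parseCellTable(cells, 0, 1, traitSeries = series, deltaT = 0.05)
  x <- traitValues(ens, "gfp")
  names(x) <- ens@records$lineage_id
  # lineage through 'a' sees 10 after t = 0.3 only; b-branch lineages see 2
  expect_equal(unname(x[c("b1", "b2")]), c(2, 2))
  expect_gt(x[["a"]], 2)

  series_missing <- series[series$time != 0.5, ]
  expect_error(parseCellTable(cells, 0, 1, traitSeries = series_missing),
               "missing sample")
})

test_that("minute-unit input is converted to hours", {
  cells <- t1_cells()
  cells$birth_time <- cells$birth_time * 60
  cells$end_time <- cells$end_time * 60
  ens <- parseCellTable(cells, 0, 60, units = "min")
  expect_equal(sort(divisionCounts(ens)), c(1, 2, 2))
  expect_equal(obsDuration(ens), 1)
})
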