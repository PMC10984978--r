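# RT correlation of bioactivity peaks with features, in-source relation
# annotation (the printed neutral deltas), and bioactive node marking.

mk_peaks <- function(starts, ends) {
  data.frame(peak_id = seq_along(starts), start_time = starts,
             apex_time = (starts + ends) / 2, end_time = ends,
             depth = 0.7, n_fractions = 3L)
}

mk_feats <- function(id, mz, rt, height = 1e6) {
  data.frame(id = id, mz = mz, rt = rt, height = height)
}

test_that("features are assigned to peaks by RT window", {
  peaks <- mk_peaks(16.2, 16.5)
  # the validation chemistry: a feature at 16.32 min inside the window
  f <- mk_feats(1:2, c(1029.5404, 900.0), c(16.32, 18.0))
  asg <- map_bioactive_features(f, peaks, rt_tolerance = 0.1)
  expect_equal(asg$table$feature_id, 1L)
  expect_equal(asg$table$mz, 1029.5404)
  # a feature 0.5 min outside every window stays unassigned
  f2 <- mk_feats(3, 555.5, 17.0)
  expect_equal(nrow(map_bioactive_features(f2, peaks, 0.1)$table), 0L)
  # window widening is inclusive on both sides
  edge <- mk_feats(4, 500, 16.6)
  expect_equal(nrow(map_bioactive_features(edge, peaks, 0.1)$table), 1L)
  expect_equal(nrow(map_bioactive_features(edge, peaks, 0.05)$table), 0L)
})

test_that("assignments sort by peak then descending height and keep empty peaks", {
  peaks <- mk_peaks(c(5, 10), c(5.5, 10.5))
  f <- mk_feats(1:4, c(600, 500, 400, 300), c(5.2, 5.3, 10.2, 99),
                height = c(1e5, 9e5, 5e5, 1e6))
  asg <- map_bioactive_features(f, peaks, 0.1)
  expect_equal(asg$table$feature_id, c(2L, 1L, 3L))
  expect_equal(asg$table$peak_id, c(1L, 1L, 2L))
  # an overlapping feature can map to two peaks
  over <- map_bioactive_features(mk_feats(9, 450, 5.45),
                                 mk_peaks(c(5, 5.4), c(5.5, 6)), 0.1)
  expect_equal(over$table$peak_id, c(1L, 2L))
  # a peak with no features is still reported
  empty <- map_bioactive_features(mk_feats(1, 500, 99), mk_peaks(5, 5.5), 0.1)
  expect_equal(nrow(empty$table), 0L)
  expect_equal(nrow(empty$peaks), 1L)
})

test_that("assignment is monotone in rt_tolerance", {
  peaks <- mk_peaks(c(5, 20), c(5.5, 20.5))
  set.seed(5)
  f <- mk_feats(1:30, runif(30, 100, 1000), runif(30, 0, 30))
  prev <- data.frame(peak_id = integer(0), feature_id = integer(0))
  for (tol in c(0.02, 0.1, 0.5, 2)) {
    cur <- map_bioactive_features(f, peaks, tol)$table
    key <- paste(cur$peak_id, cur$feature_id)
    expect_true(all(paste(prev$peak_id, prev$feature_id) %in% key))
    prev <- cur
  }
})

test_that("the neutral delta table carries the printed exact masses", {
  d <- neutral_delta_table()
  expect_equal(unname(d["H2O"]), 18.010565, tolerance = 1e-6)
  expect_equal(unname(d["C6H10O2"]), 114.068080, tolerance = 1e-6)
  expect_equal(unname(d["C6H10O3"]), 130.062995, tolerance = 1e-6)
  expect_equal(unname(d["MeCN"]), 41.026549, tolerance = 1e-6)
  ext <- neutral_delta_table(CH2 = 14.01565)
  expect_equal(unname(ext["CH2"]), 14.01565)
})

test_that("in-source relations reproduce the printed deltas", {
  # printed pairs: sugar loss, water loss, solvent adduct, and a chain
  peaks <- mk_peaks(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))
  f <- rbind(
    mk_feats(1:3, c(601.2280, 487.1601, 469.1515), c(1.2, 1.2, 1.2)),
    mk_feats(4:5, c(487.1606, 469.1492), c(2.2, 2.2)),
    mk_feats(6:7, c(638.2234, 597.1988), c(3.2, 3.2)))
  asg <- map_bioactive_features(f, peaks, 0.1)
  rel <- annotate_insource_relations(asg)
  get <- function(a, b) rel$relation[rel$parent_id == a & rel$child_id == b]
  expect_equal(get(1, 2), "C6H10O2")         # 601.228 -> 487.1601
  expect_equal(get(4, 5), "H2O")             # 487.1606 -> 469.1492
  expect_equal(get(6, 7), "MeCN")            # 638.2234 -> 597.1988
  expect_equal(get(1, 3), "H2O+C6H10O2")     # chained loss
  # peaks with fewer than two features contribute nothing
  expect_false(4L %in% rel$peak_id)
})

test_that("relation labeling is deterministic and direction-normalized", {
  peaks <- mk_peaks(1, 1.5)
  f <- mk_feats(1:2, c(469.1492, 487.1606), c(1.2, 1.2))  # child listed first
  rel <- annotate_insource_relations(map_bioactive_features(f, peaks, 0.1))
  expect_equal(rel$parent_id, 2L)
  expect_equal(rel$child_id, 1L)
  expect_gt(rel$delta, 0)
})

test_that("network marking flags exactly the assigned nodes, idempotently", {
  tri <- lapply(1:3, function(k)
    mk_spec(k, 500, c(100, 150, 200, 250), c(10, 20, 100, 40), rt = k))
  net <- build_network(tri)
  # empty assignments leave the network unchanged
  expect_equal(mark_network(net, integer(0)), net)
  m1 <- mark_network(net, c(1L, 3L))
  expect_equal(m1$nodes$bioactive, c(TRUE, FALSE, TRUE))
  expect_equal(mark_network(m1, c(1L, 3L)), m1)
  expect_warning(m2 <- mark_network(net, c(1L, 99L)), "unknown node")
  expect_equal(m2$nodes$bioactive, c(TRUE, FALSE, FALSE))
})

test_that("assignment report CSV includes empty peaks and relation labels", {
  peaks <- mk_peaks(c(1, 2), c(1.5, 2.5))
  f <- mk_feats(1:2, c(487.1606, 469.1492), c(1.2, 1.2))
  asg <- map_bioactive_features(f, peaks, 0.1)
  rel <- annotate_insource_relations(asg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_assignment_csv(asg, path, rel)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), 3L)                  # 2 features + 1 empty peak
  expect_true(any(got$peak_id == 2 & is.na(got$feature_id)))
  expect_true(any(grepl("H2O", got$relation_labels)))
})
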