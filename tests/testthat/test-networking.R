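# Modified cosine (against the brute-force assignment oracle), network
# construction with the published edge filters, spectral families and
# library annotation.

test_that("modified cosine basics: self-similarity, disjoint, empty", {
  s <- mk_spec(1, 500, c(100, 200, 300), c(10, 40, 90))
  self <- modified_cosine(s, s)
  expect_equal(self$cosine, 1, tolerance = 1e-12)
  expect_equal(self$matched_peaks, 3L)
  # disjoint peaks, identical precursor: nothing matches
  a <- mk_spec(1, 500, c(100, 200), c(10, 10))
  b <- mk_spec(2, 500, c(150, 250), c(10, 10))
  d <- modified_cosine(a, b)
  expect_equal(d$cosine, 0)
  expect_equal(d$matched_peaks, 0L)
  # empty spectrum scores 0 without error
  e <- mk_spec(3, 500, numeric(0), numeric(0))
  expect_equal(modified_cosine(a, e)$cosine, 0)
  # symmetry and bounds
  x <- mk_spec(4, 520, c(100.2, 199.8, 320), c(5, 80, 30))
  expect_equal(modified_cosine(a, x)$cosine, modified_cosine(x, a)$cosine,
               tolerance = 1e-12)
  expect_gte(modified_cosine(a, x)$cosine, 0)
  expect_lte(modified_cosine(a, x)$cosine, 1)
})

test_that("shifted matches link precursor-offset fragments", {
  # b's second fragment carries the precursor offset of +14.01565
  a <- mk_spec(1, 500, c(120, 350.10), c(100, 80))
  b <- mk_spec(2, 514.01565, c(120, 364.11565), c(100, 80))
  got <- modified_cosine(a, b)
  expect_equal(got$matched_peaks, 2L)
  expect_equal(got$cosine, 1, tolerance = 1e-9)
  # direct-only scoring would miss the shifted fragment
  direct_only <- modified_cosine(a, mk_spec(3, 500, c(120, 364.11565), c(100, 80)))
  expect_equal(direct_only$matched_peaks, 1L)
})

test_that("assignment equals the brute-force oracle on toy and random pairs", {
  # 3-peak toy with one direct and one shifted match
  a <- mk_spec(1, 600, c(100, 250, 430), c(50, 100, 20))
  b <- mk_spec(2, 618, c(100.3, 268.2, 380), c(60, 90, 10))
  got <- modified_cosine(a, b)
  want <- oracle_modified_cosine(a, b)
  expect_equal(got$cosine, want$cosine, tolerance = 1e-12)
  expect_equal(got$matched_peaks, want$matched_peaks)
  # randomized small-spectrum suite
  set.seed(271)
  for (i in 1:120) {
    pr <- random_spectrum_pair()
    got <- modified_cosine(pr$a, pr$b)
    want <- oracle_modified_cosine(pr$a, pr$b)
    expect_equal(got$cosine, want$cosine, tolerance = 1e-9)
  }
})

test_that("network edges honor cosine and matched-peak thresholds", {
  s1 <- mk_spec(1, 500, c(100, 150, 200, 250, 300), c(10, 20, 100, 40, 5))
  s2 <- mk_spec(2, 500, c(100, 150, 200, 250, 300), c(10, 20, 100, 40, 5))
  s3 <- mk_spec(3, 500, c(100, 150, 200, 250, 300), c(10, 20, 100, 40, 5))
  net <- build_network(list(s1, s2, s3))
  expect_equal(nrow(net$edges), 3L)   # triangle
  expect_true(all(net$edges$cosine == 1))
  # low-cosine pair: no edge
  lo <- mk_spec(4, 500, c(100, 150, 420, 480, 333), c(100, 5, 90, 80, 70))
  net2 <- build_network(list(s1, lo))
  expect_equal(nrow(net2$edges), 0L)
  # high cosine but only 3 matched peaks fails "more than three"
  t1 <- mk_spec(5, 500, c(100, 200, 300), c(50, 100, 80))
  t2 <- mk_spec(6, 500, c(100, 200, 300), c(50, 100, 80))
  expect_equal(nrow(build_network(list(t1, t2))$edges), 0L)
  expect_equal(nrow(build_network(list(t1, t2), min_matched = 3L)$edges), 1L)
  # permutation invariance of the edge set
  s4 <- mk_spec(7, 514.0157, c(100, 150, 214.0157, 264.0157, 300),
                c(10, 20, 100, 40, 5))
  e_fwd <- build_network(list(s1, s2, s3, s4))$edges
  e_rev <- build_network(list(s4, s3, s2, s1))$edges
  expect_equal(e_fwd, e_rev)
  # raising thresholds never adds edges
  loose <- build_network(list(s1, s2, s3, s4), cosine_threshold = 0.5,
                         min_matched = 2L)$edges
  tight <- build_network(list(s1, s2, s3, s4), cosine_threshold = 0.9,
                         min_matched = 5L)$edges
  key <- function(e) paste(e$node_a, e$node_b)
  expect_true(all(key(tight) %in% key(loose)))
  expect_error(build_network(list(s1, s1)), "distinct feature ids")
})

test_that("spectral families are the >=2-node components", {
  iso <- lapply(1:5, function(k)
    mk_spec(k, 300 + 50 * k, c(100 + 10 * k, 111 * k), c(10, 20)))
  net0 <- build_network(iso)
  fam0 <- spectral_families(net0)
  expect_equal(length(fam0$families), 0L)
  expect_equal(fam0$singletons, 5L)
  # one triangle plus two isolated nodes
  tri <- lapply(1:3, function(k)
    mk_spec(k, 500, c(100, 150, 200, 250), c(10, 20, 100, 40)))
  net1 <- build_network(c(tri, iso[4:5]))
  fam1 <- spectral_families(net1)
  expect_equal(length(fam1$families), 1L)
  expect_equal(fam1$families[[1]], 1:3)
  expect_equal(fam1$singletons, 2L)
})

test_that("a CH2 homolog series with shared fragments forms one family", {
  spec <- synthetic_run_spec(seed = 42L)
  comp <- demo_compounds("bacillus")[1:4]   # the CH2 ladder congeners
  run <- simulate_run(spec, comp)$run
  feats <- detect_features(run, ms2_only = TRUE)
  expect_equal(nrow(feats), 4L)
  spectra <- feats$ms2
  for (k in seq_along(spectra)) spectra[[k]]$feature_id <- feats$id[k]
  fam <- spectral_families(build_network(spectra))
  expect_equal(length(fam$families), 1L)
  expect_equal(length(fam$families[[1]]), 4L)
  expect_equal(fam$singletons, 0L)
})

test_that("library search annotates only above both thresholds", {
  q1 <- mk_spec(1, 500, c(100, 150, 200, 250), c(10, 20, 100, 40))
  q2 <- mk_spec(2, 777, c(111, 222, 333, 444), c(5, 5, 5, 5))
  lib <- list("compound X" = mk_spec(100, 500, c(100, 150, 200, 250),
                                     c(10, 20, 100, 40)),
              "compound Y" = mk_spec(101, 600, c(90, 190, 290, 390),
                                     c(50, 50, 50, 50)))
  ann <- library_search(list(q1, q2), lib)
  expect_equal(ann$annotation, c("compound X", NA))
  expect_equal(ann$score[1], 1, tolerance = 1e-12)
  expect_error(library_search(list(q1), list()), "empty")
  # decoys: shuffling library peak positions kills the match in >=95% of trials
  set.seed(99)
  hits <- 0L
  for (i in 1:60) {
    decoy_mz <- sort(runif(4, 50, 480))
    decoy <- list(decoy = mk_spec(200, 500, decoy_mz, c(10, 20, 100, 40)))
    a <- library_search(list(q1), decoy)
    if (!is.na(a$annotation[1])) hits <- hits + 1L
  }
  expect_lte(hits, 3L)
})

test_that("GraphML round-trips nodes, edges and bioactive flags", {
  tri <- lapply(1:3, function(k)
    mk_spec(k, 500, c(100, 150, 200, 250), c(10, 20, 100, 40), rt = k))
  net <- build_network(tri)
  net <- mark_network(net, c(1L, 3L))
  net$nodes$annotation[2] <- "compound X"
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  back <- read_graphml(f)
  expect_equal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$bioactive, net$nodes$bioactive)
  expect_equal(back$nodes$annotation, net$nodes$annotation)
  expect_equal(back$edges$cosine, net$edges$cosine, tolerance = 1e-9)
  expect_equal(back$edges[, c("node_a", "node_b")],
               net$edges[, c("node_a", "node_b")])
})
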