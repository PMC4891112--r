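cfg <- caller_config()

test_that("pair classification covers orientation and distance rules", {
  expect_identical(classify_read_pair(
    make_pair("c1", 1000, "+", "c1", 1300, "-"), cfg), "PROPER")
  expect_identical(classify_read_pair(
    make_pair("chr5", 1000, "+", "chr20", 1000, "-"), cfg), "CT")
  # RR folded into the FF class
  expect_identical(classify_read_pair(
    make_pair("c1", 1000, "-", "c1", 1400, "-"), cfg), "FF_TYPE")
  expect_identical(classify_read_pair(
    make_pair("c1", 1000, "+", "c1", 51000, "-"), cfg), "LD")
  expect_identical(classify_read_pair(
    make_pair("c1", 1000, "-", "c1", 5000, "+"), cfg), "RF_TYPE")
  # canonicalization: mates arrive in either order
  expect_identical(classify_read_pair(
    make_pair("c1", 51000, "-", "c1", 1000, "+"), cfg), "LD")
})

test_that("clustering groups pairs within the window under single linkage", {
  p <- rbind(make_pair("c1", 100, "+", "c2", 1000, "-", id = "a"),
             make_pair("c1", 250, "+", "c2", 1100, "-", id = "b"),
             make_pair("c1", 400, "+", "c2", 1200, "-", id = "c"))
  cl <- cluster_inconsistent_pairs(classify_read_pairs(p, cfg), cfg)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$support, 3L)
  expect_identical(cl[[1]]$rtype, "CT")

  # boundary: 501 apart with no intermediate -> two clusters; 500 -> one
  p2 <- rbind(make_pair("c1", 100, "+", "c2", 1000, "-", id = "a"),
              make_pair("c1", 601, "+", "c2", 1000, "-", id = "b"))
  expect_length(cluster_inconsistent_pairs(classify_read_pairs(p2, cfg), cfg), 2)
  p3 <- rbind(make_pair("c1", 100, "+", "c2", 1000, "-", id = "a"),
              make_pair("c1", 600, "+", "c2", 1000, "-", id = "b"))
  expect_length(cluster_inconsistent_pairs(classify_read_pairs(p3, cfg), cfg), 1)

  expect_length(cluster_inconsistent_pairs(
    classify_read_pairs(p[0, ], cfg), cfg), 0)
})

test_that("clustering equals brute-force single linkage on random inputs", {
  for (seed in 1:5) {
    n <- withr::with_seed(seed, sample(10:50, 1))
    p <- random_ct_pairs(n, span = 3000, seed = seed)
    q <- classify_read_pairs(p, cfg)
    got <- cluster_partition(cluster_inconsistent_pairs(q, cfg))
    comp <- bf_components(q$pos1, q$pos2, cfg$cluster_window)
    expect_identical(got, partition_from_components(q$id, comp))
  }
})

test_that("consensus breakpoints take the innermost base toward the junction", {
  p <- rbind(make_pair("c1", 100, "+", "c2", 1000, "-", id = "a"),
             make_pair("c1", 250, "+", "c2", 1100, "-", id = "b"))
  cl <- cluster_inconsistent_pairs(classify_read_pairs(p, cfg), cfg)[[1]]
  expect_identical(cl$bp1, 250 + 125 - 1)   # forward side: max read end
  expect_identical(cl$bp2, 1000)            # reverse side: min read start
})

test_that("support filter keeps >= min_support and is monotone", {
  p <- random_ct_pairs(40, span = 20000, seed = 3)
  cl <- cluster_inconsistent_pairs(classify_read_pairs(p, cfg), cfg)
  counts <- vapply(1:6, function(k) {
    length(filter_by_support(cl, caller_config(min_support = k)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], length(cl))

  one <- cluster_inconsistent_pairs(classify_read_pairs(
    random_ct_pairs(3, span = 100, seed = 1), cfg), cfg)
  expect_length(filter_by_support(one, cfg), 1)            # support 3 kept
  two <- cluster_inconsistent_pairs(classify_read_pairs(
    random_ct_pairs(2, span = 100, seed = 1), cfg), cfg)
  expect_length(filter_by_support(two, cfg), 0)            # support 2 removed
  expect_length(filter_by_support(list(), cfg), 0)
})

test_that("widening the cluster window never increases cluster count", {
  p <- classify_read_pairs(random_ct_pairs(50, span = 5000, seed = 4), cfg)
  counts <- vapply(c(100, 250, 500, 1000, 2000), function(w) {
    length(cluster_inconsistent_pairs(p, caller_config(cluster_window = w)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("parental subtraction removes shared rearrangements only", {
  sample_cl <- cluster_inconsistent_pairs(classify_read_pairs(
    random_ct_pairs(6, span = 100, seed = 5), cfg), cfg)
  shifted <- random_ct_pairs(6, span = 100, seed = 5)
  shifted$pos1 <- shifted$pos1 + 120   # same event within the match window
  par_cl <- cluster_inconsistent_pairs(classify_read_pairs(shifted, cfg), cfg)
  expect_length(subtract_parental(sample_cl, list(par_cl)), 0)
  expect_length(subtract_parental(sample_cl, list(sample_cl)), 0)

  far <- random_ct_pairs(6, span = 100, seed = 5)
  far$pos1 <- far$pos1 + 5000
  far_cl <- cluster_inconsistent_pairs(classify_read_pairs(far, cfg), cfg)
  expect_length(subtract_parental(sample_cl, list(far_cl)), 1)
  expect_length(subtract_parental(sample_cl, list()), 1)
})

test_that("mismatch and perfect-pair filter enforces both rules", {
  mk <- function(nms) {
    p <- do.call(rbind, lapply(seq_along(nms), function(i) {
      make_pair("c1", 100 + i, "+", "c2", 1000, "-", nm1 = nms[i],
                id = paste0("p", i))
    }))
    cluster_inconsistent_pairs(classify_read_pairs(p, cfg), cfg)[[1]]
  }
  # a 3-mismatch read discards its pair; remaining 3 perfect pairs survive
  out <- mismatch_and_perfect_filter(mk(c(0, 0, 0, 3)), cfg)
  expect_identical(out$support, 3L)
  # support 4 but no perfect pair -> removed
  expect_null(mismatch_and_perfect_filter(mk(c(1, 1, 2, 2)), cfg))
  # all perfect, support 3 -> kept unchanged
  expect_identical(mismatch_and_perfect_filter(mk(c(0, 0, 0)), cfg)$support, 3L)
  # dropping mismatched pairs can push support below threshold
  expect_null(mismatch_and_perfect_filter(mk(c(0, 0, 3, 3)), cfg))
})

test_that("realignment filter drops concordantly re-mappable pairs only", {
  ref <- generate_reference(c(chrA = 20000, chrB = 20000), 0.41, seed = 42)
  idx <- realign_index(ref)
  mk_cluster <- function(seq1, seq2, strand1 = "+", strand2 = "-") {
    p <- make_pair("chrA", 2000, strand1, "chrB", 5000, strand2,
                   seq1 = seq1, seq2 = seq2)
    cluster_inconsistent_pairs(classify_read_pairs(p, cfg), cfg)[[1]]
  }
  # pair whose reads re-map in FR orientation within 500 bp -> excluded
  conc <- mk_cluster(seq_extract(ref, "chrA", 2000, 2124),
                     seq_extract(ref, "chrA", 2200, 2324))
  r <- realignment_filter(conc, ref, cfg, index = idx)
  expect_true(r$verdicts$dropped)
  expect_null(r$cluster)

  # reads from loci 4 kb apart: no concordant placement -> retained
  junc <- mk_cluster(seq_extract(ref, "chrA", 1000, 1124),
                     seq_extract(ref, "chrA", 5000, 5124))
  r2 <- realignment_filter(junc, ref, cfg, index = idx)
  expect_false(r2$verdicts$dropped)
  expect_identical(r2$cluster$support, 1L)

  # random non-reference sequence: nothing seeds, cluster unchanged
  rnd <- withr::with_seed(99, paste(sample(c("A", "C", "G", "T"), 125,
                                           replace = TRUE), collapse = ""))
  rnd2 <- withr::with_seed(98, paste(sample(c("A", "C", "G", "T"), 125,
                                            replace = TRUE), collapse = ""))
  r3 <- realignment_filter(mk_cluster(rnd, rnd2), ref, cfg, index = idx)
  expect_false(r3$verdicts$dropped)
})

test_that("realignment and mismatch filters commute", {
  ref <- generate_reference(c(chrA = 20000, chrB = 20000), 0.41, seed = 43)
  lenient <- caller_config(min_support = 1, require_perfect_pair = FALSE)
  p <- rbind(
    make_pair("chrA", 2000, "+", "chrB", 5000, "-",
              seq1 = seq_extract(ref, "chrA", 2000, 2124),
              seq2 = seq_extract(ref, "chrA", 2200, 2324), id = "conc"),
    make_pair("chrA", 2010, "+", "chrB", 5010, "-", nm2 = 5,
              seq1 = seq_extract(ref, "chrA", 1000, 1124),
              seq2 = seq_extract(ref, "chrA", 9000, 9124), id = "mm"),
    make_pair("chrA", 2020, "+", "chrB", 5020, "-",
              seq1 = seq_extract(ref, "chrA", 1200, 1324),
              seq2 = seq_extract(ref, "chrA", 9200, 9324), id = "ok"))
  cl <- cluster_inconsistent_pairs(classify_read_pairs(p, lenient), lenient)[[1]]
  a <- realignment_filter(cl, ref, lenient)$cluster
  a <- mismatch_and_perfect_filter(a, lenient)
  b <- mismatch_and_perfect_filter(cl, lenient)
  b <- realignment_filter(b, ref, lenient)$cluster
  expect_identical(sort(a$pairs$id), sort(b$pairs$id))
  expect_identical(sort(a$pairs$id), "ok")
})

test_that("full cascade recovers planted events and subtracts parental ones", {
  ref <- generate_reference(c(cA = 40000, cB = 40000, cC = 40000), 0.41,
                            seed = 21)
  denovo <- rearrangement_events(c("n1", "n2"), c("cA", "cB"), c(12000, 18000),
                                 c("cA", "cC"), c(20000, 22000), c("LD", "CT"),
                                 "blunt", "")
  shared <- rearrangement_events(c("s1", "s2"), c("cA", "cC"), c(28000, 9000),
                                 c("cA", "cC"), c(33000, 14000), c("LD", "RF"),
                                 "blunt", "")
  both <- rbind(shared, denovo)
  class(both) <- c("sv_events", "data.frame")
  sample_g <- plant_rearrangements(ref, both, on_conflict = "new_copy")
  par_g <- plant_rearrangements(sample_g$reference, shared,
                                on_conflict = "new_copy")
  sp <- simulate_read_pairs(sample_g$genome, read_sim_params(seed = 31))
  p1 <- simulate_read_pairs(par_g$genome, read_sim_params(seed = 32))
  p2 <- simulate_read_pairs(par_g$genome, read_sim_params(seed = 33))

  calls <- call_rearrangements(sp, list(p1, p2), sample_g$reference, cfg)
  m <- match_calls_to_truth(calls, denovo)
  expect_identical(nrow(calls), 2L)
  expect_setequal(m$truth_id, c("n1", "n2"))

  # with the sample's own pairs as parental, everything is subtracted
  none <- call_rearrangements(sp, list(sp), sample_g$reference, cfg)
  expect_identical(nrow(none), 0L)
  audit <- attr(none, "audit")
  expect_identical(audit$clusters[audit$stage == "parental_subtracted"], 0L)
})
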