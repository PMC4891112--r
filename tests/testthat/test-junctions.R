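test_that("planted chemistry round-trips through classification", {
  ref <- generate_reference(c(cA = 60000, cB = 60000), 0.41, seed = 17)
  ev <- rearrangement_events(
    id = c("mh4", "blunt", "ins"),
    chrom1 = c("cA", "cA", "cA"), pos1 = c(12000, 25000, 40000),
    chrom2 = c("cA", "cA", "cB"), pos2 = c(15000, 30000, 20000),
    rtype = c("LD", "LD", "CT"),
    jclass = c("microhomology", "blunt", "insertion"),
    jseq = c("TGGA", "", "CTGAA"))
  planted <- plant_rearrangements(ref, ev)
  jc <- classify_planted_junctions(planted)
  expect_identical(jc$jclass, c("MICROHOMOLOGY", "BLUNT", "INSERTION"))
  expect_identical(jc$mh_seq[1], "TGGA")
  expect_identical(jc$mh_len[1], 4L)
  expect_identical(jc$ins_seq[3], "CTGAA")
  expect_identical(jc$ins_len[3], 5L)
})

test_that("random chemistry cases round-trip for every junction type", {
  for (seed in 1:6) {
    case <- random_chemistry_case(seed)
    planted <- case$planted
    jc <- classify_planted_junctions(planted)
    truth <- planted$truth
    expect_identical(jc$jclass,
                     c(microhomology = "MICROHOMOLOGY", blunt = "BLUNT",
                       insertion = "INSERTION")[truth$jclass],
                     ignore_attr = TRUE)
    mh <- truth$jclass == "microhomology"
    expect_identical(jc$mh_seq[mh], truth$jseq[mh])
    ins <- truth$jclass == "insertion"
    expect_identical(jc$ins_seq[ins], truth$jseq[ins])
  }
})

test_that("reported microhomology is maximal (exhaustive overlap oracle)", {
  resc <- rescale_breakpoints(example_events())
  ref <- generate_reference(resc$chrom_lengths, 0.41, seed = 2)
  planted <- plant_rearrangements(ref, resc$events, on_conflict = "new_copy")
  flank <- 50
  for (i in seq_len(nrow(planted$truth))) {
    tr <- planted$truth[i, ]
    be <- junction_breakends(tr)
    jseq <- junction_sequence(planted$genome, tr, flank)
    jc <- classify_junction(jseq, planted$reference, be$side1, be$side2, flank)
    # independent extension strings, assembled with raw substring ops
    s1 <- be$side1; s2 <- be$side2
    e1 <- paste0(seq_extract(planted$reference, s1$chrom, s1$pos - flank + 1,
                             s1$pos + flank))
    e2 <- if (s2$strand == "+") {
      seq_extract(planted$reference, s2$chrom, s2$pos - flank, s2$pos + flank - 1)
    } else {
      revcomp(seq_extract(planted$reference, s2$chrom, s2$pos - flank + 1,
                          s2$pos + flank))
    }
    expect_identical(jc$mh_len, oracle_mh_len(jseq, e1, e2),
                     info = tr$id)
  }
})

test_that("classify_junction rejects short or non-anchoring input", {
  ref <- generate_reference(c(cA = 20000), 0.41, seed = 18)
  b1 <- list(chrom = "cA", pos = 10000, strand = "+")
  b2 <- list(chrom = "cA", pos = 12000, strand = "+")
  expect_error(classify_junction("ACGT", ref, b1, b2, flank = 20), "shorter")
  junk <- strrep("ACGT", 25)
  expect_error(classify_junction(junk, ref, b1, b2, flank = 20), "anchor")
  expect_error(classify_junction(junk, ref, b1, b2, flank = 10), "flank")
})

test_that("insertion origins are found in either orientation or reported absent", {
  base <- generate_reference(c(cA = 30000), 0.41, seed = 19)
  seqs <- unclass(base)
  b2 <- 20000
  ins_rev <- withr::with_seed(7, paste(sample(c("A", "C", "G", "T"), 33,
                                              replace = TRUE), collapse = ""))
  # plant the reverse-complement template ending 79 bp upstream of break2
  substr(seqs[["cA"]], b2 - 79 - 32, b2 - 79) <- revcomp(ins_rev)
  ins_fwd <- withr::with_seed(8, paste(sample(c("A", "C", "G", "T"), 10,
                                              replace = TRUE), collapse = ""))
  b1 <- 10000
  substr(seqs[["cA"]], b1 - 10, b1 - 1) <- ins_fwd
  ref <- ref_genome(seqs)
  anchors <- data.frame(name = c("break1", "break2"), chrom = "cA",
                        pos = c(b1, b2), stringsAsFactors = FALSE)

  hit <- find_insertion_origin(ins_rev, ref, anchors, search_window = 500)
  expect_identical(hit$anchor, "break2")
  expect_identical(hit$offset, -79)
  expect_identical(hit$orientation, "reverse")

  fwd <- find_insertion_origin(ins_fwd, ref, anchors, search_window = 500)
  expect_identical(fwd$anchor, "break1")
  expect_identical(fwd$offset, -10)
  expect_identical(fwd$orientation, "forward")

  absent <- withr::with_seed(9, paste(sample(c("A", "C", "G", "T"), 25,
                                             replace = TRUE), collapse = ""))
  expect_null(find_insertion_origin(absent, ref, anchors, search_window = 500))
  expect_error(find_insertion_origin("ACGTACGT", ref, anchors,
                                     search_window = 4))
})

test_that("planted templated insertion is recovered end to end", {
  resc <- rescale_breakpoints(example_events())
  ref <- generate_reference(resc$chrom_lengths, 0.41, seed = 2)
  planted <- plant_rearrangements(ref, resc$events, on_conflict = "new_copy")
  tr <- planted$truth[planted$truth$id == "ID167", ]
  anchors <- data.frame(name = c("break1", "break2"),
                        chrom = c(tr$chrom1, tr$chrom2),
                        pos = c(tr$pos1, tr$pos2), stringsAsFactors = FALSE)
  hit <- find_insertion_origin(tr$jseq, planted$reference, anchors)
  expect_identical(hit$anchor, "break2")
  expect_identical(hit$offset, -79)
  expect_identical(hit$orientation, "reverse")
})

test_that("breakpoint distances are symmetric and reproduce the known pairs", {
  d <- breakpoint_distances(example_events(), max_report = 1000)
  expect_true(any(d$event_a == "ID119" & d$event_b == "ID120" &
                  d$break_a == "break1" & d$break_b == "break1" &
                  d$distance == 5))
  expect_true(any(d$event_a == "ID80" & d$event_b == "ID91" &
                  d$break_a == "break2" & d$break_b == "break1" &
                  d$distance == 377))

  ev <- rearrangement_events(c("x", "y"), c("c1", "c1"), c(500, 500),
                             c("c2", "c2"), c(900, 900), c("CT", "CT"),
                             "blunt", "")
  dd <- breakpoint_distances(ev, max_report = 10)
  expect_true(all(dd$distance == 0))
  # symmetry: reversing the event order gives the same distance multiset
  ev2 <- ev[2:1, ]
  expect_identical(sort(breakpoint_distances(ev2, 10)$distance),
                   sort(dd$distance))
  # triangle inequality on a same-chromosome triple
  ev3 <- rearrangement_events(c("a", "b", "c"), "c1", c(100, 250, 600),
                              "c2", c(1, 2, 3) * 1000, "CT", "blunt", "")
  d3 <- breakpoint_distances(ev3, max_report = 1e6)
  d3 <- d3[d3$chrom == "c1", ]
  expect_lte(max(d3$distance), sum(sort(d3$distance)[1:2]))
})

test_that("junction census counts classes and maximal homology", {
  empty <- summarize_junction_classes(
    data.frame(jclass = character(0), mh_len = integer(0)))
  expect_identical(unname(empty$counts), c(0L, 0L, 0L))
  expect_identical(empty$max_mh_len, 0L)

  ref <- generate_reference(c(cA = 80000), 0.41, seed = 23)
  ev <- rearrangement_events(paste0("b", 1:5), "cA",
                             seq(12000, 60000, by = 12000), "cA",
                             seq(14000, 62000, by = 12000), "LD", "blunt", "")
  planted <- plant_rearrangements(ref, ev)
  cs <- summarize_junction_classes(classify_planted_junctions(planted))
  expect_identical(unname(cs$counts["BLUNT"]), 5L)
  expect_identical(unname(cs$counts["MICROHOMOLOGY"]), 0L)
})
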