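test_that("generate_reference forces lengths, composition and determinism", {
  g <- generate_reference(c(chr1 = 100000), 0.41, seed = 1)
  expect_s3_class(g, "ref_genome")
  expect_identical(unname(chrom_lengths(g)), 100000L)

  g2 <- generate_reference(c(chr1 = 100000), 0.41, seed = 1)
  expect_identical(unclass(g), unclass(g2))

  big <- generate_reference(c(chr1 = 1000000), 0.50, seed = 7)
  gc <- sum(strsplit(big[["chr1"]], "")[[1]] %in% c("G", "C")) / 1000000
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)

  expect_error(generate_reference(c(a = 0), 0.41, 1), "positive")
  expect_error(generate_reference(c(a = -5), 0.41, 1), "positive")
  expect_error(generate_reference(c(a = 5000), 0.41, 1), "10 kb")
})

test_that("ref_genome validates names and alphabet", {
  expect_error(ref_genome(c("ACGT")), "unique")
  expect_error(ref_genome(c(a = "ACGT", a = "ACGT")), "unique")
  expect_error(ref_genome(c(a = "ACBT")), "alphabet")
  expect_warning(g <- ref_genome(character(0)), "empty")
  expect_length(g, 0)
})

test_that("plant_rearrangements: deletion conserves sequence", {
  ref <- generate_reference(c(chrA = 100000), 0.41, seed = 3)
  ev <- rearrangement_events("del1", "chrA", 20000, "chrA", 30000, "LD",
                             "blunt", "")
  planted <- plant_rearrangements(ref, ev)
  expect_identical(unname(chrom_lengths(planted$genome)), 90000L)
  expect_identical(nrow(planted$truth), 1L)
  # splice: prefix and suffix of the edited reference
  expect_identical(planted$genome[["chrA"]],
                   paste0(substr(planted$reference[["chrA"]], 1, 20000),
                          substr(planted$reference[["chrA"]], 30001, 100000)))
})

test_that("plant_rearrangements: translocation fuses prefix to suffix", {
  ref <- generate_reference(c(chr5 = 30000, chr20 = 30000), 0.41, seed = 4)
  ev <- rearrangement_events("t1", "chr5", 12000, "chr20", 15000, "CT",
                             "blunt", "")
  planted <- plant_rearrangements(ref, ev)
  manual <- paste0(substr(planted$reference[["chr5"]], 1, 12000),
                   substr(planted$reference[["chr20"]], 15001, 30000))
  expect_identical(planted$genome[["fus_t1"]], manual)
  # originals retained
  expect_true(all(c("chr5", "chr20") %in% names(planted$genome)))
})

test_that("plant_rearrangements: sequence length ledger holds per event type", {
  ref <- generate_reference(c(cA = 60000, cB = 60000), 0.41, seed = 9)
  ev <- rearrangement_events(
    c("d", "r", "i"), c("cA", "cA", "cA"), c(12000, 30000, 45000),
    c("cA", "cA", "cA"), c(15000, 33000, 47000), c("LD", "RF", "LD"),
    c("blunt", "microhomology", "insertion"), c("", "AG", "CTGAA"))
  planted <- plant_rearrangements(ref, ev)
  expected <- 60000 - (15000 - 12000) +      # LD removes (pos1, pos2]
    (33000 - 30000 + 1) +                    # RF duplicates [pos1, pos2]
    - (47000 - 45000) + nchar("CTGAA")       # second LD + inserted bases
  expect_identical(unname(chrom_lengths(planted$genome)["cA"]),
                   as.integer(expected))
})

test_that("overlapping events error by default, are copy-split on request", {
  ref <- generate_reference(c(cA = 60000), 0.41, seed = 5)
  ev <- rearrangement_events(c("a", "b"), c("cA", "cA"), c(20000, 25000),
                             c("cA", "cA"), c(40000, 30000), c("LD", "LD"),
                             "blunt", "")
  expect_error(plant_rearrangements(ref, ev), "overlap")
  planted <- plant_rearrangements(ref, ev, on_conflict = "new_copy")
  expect_true("cA_copy2" %in% names(planted$genome))
  expect_identical(nrow(planted$truth), 2L)
})

test_that("breakpoints outside the reference are rejected", {
  ref <- generate_reference(c(cA = 60000), 0.41, seed = 5)
  ev <- rearrangement_events("a", "cA", 20000, "cA", 70000, "LD", "blunt", "")
  expect_error(plant_rearrangements(ref, ev), "out of bounds")
  ev2 <- rearrangement_events("a", "cZ", 200, "cZ", 700, "LD", "blunt", "")
  expect_error(plant_rearrangements(ref, ev2), "not in reference")
})

test_that("the bundled event set plants fourteen junctions", {
  resc <- rescale_breakpoints(example_events())
  ref <- generate_reference(resc$chrom_lengths, 0.41, seed = 2)
  planted <- plant_rearrangements(ref, resc$events, on_conflict = "new_copy")
  expect_identical(nrow(planted$truth), 14L)
  expect_setequal(planted$truth$id, example_events()$id)
})

test_that("rescaling preserves order and close proximities exactly", {
  resc <- rescale_breakpoints(example_events())
  ev <- resc$events
  d119_120 <- abs(ev$pos1[ev$id == "ID119"] - ev$pos1[ev$id == "ID120"])
  expect_identical(d119_120, 5)
  d80_91 <- abs(ev$pos2[ev$id == "ID80"] - ev$pos1[ev$id == "ID91"])
  expect_identical(d80_91, 377)
  # order preserved per chromosome
  for (ch in unique(resc$map$chrom)) {
    m <- resc$map[resc$map$chrom == ch, ]
    expect_identical(order(m$old), order(m$new))
  }
})

test_that("simulate_probe_track matches its stated means and BAF states", {
  lens <- c(c1 = 100000)
  t0 <- simulate_probe_track(lens, NULL, noise_sd = 0, seed = 1)
  expect_true(all(t0$signal == 2.0))

  seg <- data.frame(chrom = "c1", start = 30000, end = 60000, copy = 1.0)
  t1 <- simulate_probe_track(lens, seg, noise_sd = 0, seed = 1, baf_noise_sd = 0)
  inside <- t1$pos >= 30000 & t1$pos <= 60000
  expect_true(all(t1$signal[inside] == 1.0))
  expect_true(all(t1$signal[!inside] == 2.0))
  # LOH inside the deletion, balanced heterozygosity outside
  expect_true(all(t1$baf[inside & t1$is_het] %in% c(0, 1)))
  expect_true(all(t1$baf[!inside & t1$is_het] == 0.5))

  amp <- data.frame(chrom = "c1", start = 30000, end = 60000, copy = 3.0,
                    loh = FALSE)
  t3 <- simulate_probe_track(lens, amp, noise_sd = 0, seed = 1, baf_noise_sd = 0)
  in3 <- t3$pos >= 30000 & t3$pos <= 60000 & t3$is_het
  expect_true(all(abs(t3$baf[in3] - 0.5) < 0.34))   # 1/3 or 2/3
  expect_true(all(t3$baf[in3] %in% c(1 / 3, 2 / 3)))

  expect_error(simulate_probe_track(lens, NULL, noise_sd = -1), "noise_sd")
  expect_error(simulate_probe_track(lens, NULL, probe_spacing = 0), "spacing")
})

test_that("rescaled segment set yields sixteen shifted probe runs", {
  cp <- rescale_cna_segments(example_cna_segments())
  tr <- simulate_probe_track(cp$chrom_lengths, cp$segments, noise_sd = 0,
                             seed = 1)
  runs <- 0L
  for (ch in unique(tr$chrom)) {
    x <- tr$signal[tr$chrom == ch] != 2
    runs <- runs + sum(x & !c(FALSE, x[-length(x)]))
  }
  expect_identical(runs, 16L)
  # every rescaled segment holds at least 30 probes
  for (i in seq_len(nrow(cp$segments))) {
    s <- cp$segments[i, ]
    expect_gte(sum(tr$chrom == s$chrom & tr$pos >= s$start & tr$pos <= s$end), 30)
  }
})

test_that("absorbed dose follows thin-slab dosimetry and is linear", {
  cfg100 <- irradiation_config(100)
  # independent arithmetic: 11.7 keV deposited over 1 um in a 3.14 um^2 spot
  expected <- 100 * (11.7 * 1.602176634e-16) / (1000 * pi * (1e-6)^2 * 1e-6)
  expect_equal(compute_absorbed_dose(cfg100), expected, tolerance = 1e-12)
  expect_equal(compute_absorbed_dose(cfg100), 59.67, tolerance = 0.01)

  cfg200 <- irradiation_config(200)
  expect_equal(compute_absorbed_dose(cfg200), 2 * compute_absorbed_dose(cfg100),
               tolerance = 0)
  expect_identical(compute_absorbed_dose(irradiation_config(0)), 0)
  expect_error(irradiation_config(10, spot_diameter_um = 0))
  expect_error(irradiation_config(-1))
})
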