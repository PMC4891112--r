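# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no stored data.

# one-row read-pair table
make_pair <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                      nm1 = 0L, nm2 = 0L, seq1 = strrep("A", 125),
                      seq2 = strrep("A", 125), id = "p1") {
  data.frame(id = id, chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             nm1 = nm1, seq1 = seq1, chrom2 = chrom2, pos2 = pos2,
             strand2 = strand2, nm2 = nm2, seq2 = seq2,
             stringsAsFactors = FALSE)
}

# n random CT-like pairs on a fixed chromosome pair, positions in [1, span]
random_ct_pairs <- function(n, span = 3000, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      make_pair("c1", sample.int(span, 1), "+", "c2", sample.int(span, 1), "-",
                id = paste0("p", i))
    }))
  })
}

# independent single-linkage oracle: connected components of the
# "both footprints within window" graph, by breadth-first search
bf_components <- function(p1, p2, window) {
  n <- length(p1)
  adj <- outer(p1, p1, function(a, b) abs(a - b) <= window) &
         outer(p2, p2, function(a, b) abs(a - b) <= window)
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# partition of ids induced by clusters (canonical form for comparison)
cluster_partition <- function(clusters) {
  parts <- lapply(clusters, function(cl) sort(cl$pairs$id))
  parts[order(vapply(parts, `[`, character(1), 1))]
}

partition_from_components <- function(ids, comp) {
  parts <- lapply(split(ids, comp), sort)
  names(parts) <- NULL
  parts[order(vapply(parts, `[`, character(1), 1))]
}

# independent maximal-overlap oracle for junction classification: given the
# two reference extensions of a junction, the true microhomology length is
# the largest k whose shared bases match both sides (simple loops, no reuse
# of package internals beyond sequence extraction)
oracle_mh_len <- function(junction_seq, e1, e2) {
  n <- nchar(junction_seq)
  a <- 0L
  while (a < min(n, nchar(e1)) &&
         substr(junction_seq, a + 1, a + 1) == substr(e1, a + 1, a + 1)) {
    a <- a + 1L
  }
  b <- 0L
  while (b < min(n, nchar(e2)) &&
         substr(junction_seq, n - b, n - b) ==
         substr(e2, nchar(e2) - b, nchar(e2) - b)) {
    b <- b + 1L
  }
  max(0L, a + b - n)
}

# small flat probe track
flat_track <- function(n = 200, spacing = 1000, value = 2, chrom = "c1") {
  data.frame(chrom = chrom, pos = seq_len(n) * spacing, signal = value,
             baf = 0.5, is_het = TRUE, stringsAsFactors = FALSE)
}

# random event set with known chemistry on a fresh two-chromosome genome
random_chemistry_case <- function(seed) {
  withr::with_seed(seed, {
    types <- sample(c("LD", "RF", "FF", "CT"), 4, replace = TRUE)
    chems <- sample(c("microhomology", "blunt", "insertion"), 4, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    jseq <- vapply(chems, function(ch) {
      switch(ch,
             microhomology = paste(sample(bases, sample(1:4, 1), replace = TRUE),
                                   collapse = ""),
             blunt = "",
             insertion = paste(sample(bases, sample(3:40, 1), replace = TRUE),
                               collapse = ""))
    }, character(1))
    pos1 <- c(12000, 24000, 36000, 48000)
    pos2 <- pos1 + sample(2000:4000, 4)
    ev <- rearrangement_events(
      id = paste0("E", 1:4),
      chrom1 = "cA", pos1 = pos1,
      chrom2 = ifelse(types == "CT", "cB", "cA"),
      pos2 = ifelse(types == "CT", pos1 + 5000, pos2),
      rtype = types, jclass = chems, jseq = jseq)
    ref <- generate_reference(c(cA = 60000, cB = 60000), 0.41,
                              seed = seed + 1000)
    list(events = ev,
         planted = plant_rearrangements(ref, ev, on_conflict = "new_copy"))
  })
}
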