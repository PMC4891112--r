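#' Read-pair simulation parameters
#'
#' Defaults model the sequencing layout used throughout the package:
#' 125 bp paired-end reads in FR orientation (forward read at the fragment
#' start, reverse read at the end), fragments of 300 +/- 30 bp, 30-fold
#' base coverage per sequence, error-free.
#'
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment (insert) size distribution, bp.
#' @param coverage fold base coverage per simulated sequence.
#' @param error_rate per-base substitution error rate in `[0, 1)`.
#' @param seed integer seed.
#' @return list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 125, insert_mean = 300,
                            insert_sd = 30, coverage = 30,
                            error_rate = 0, seed = 1L) {
  stopifnot(read_length >= 20, insert_sd >= 0, coverage > 0,
            error_rate >= 0, error_rate < 1)
  if (read_length >= insert_mean) {
    stop("read_length must be smaller than insert_mean", call. = FALSE)
  }
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

## majority-overlap block choice for a derivative interval [a1, a2];
## returns the row index in `b` (never an insertion block)
pick_block <- function(b, a1, a2) {
  i1 <- findInterval(a1, b$der_start)
  i2 <- findInterval(a2, b$der_start)
  if (i1 == i2) return(i1)
  idx <- i1:i2
  ov <- pmin(b$der_end[idx], a2) - pmax(b$der_start[idx], a1) + 1
  ov[is.na(b$chrom[idx])] <- -1   # never assign to an insertion block
  idx[which.max(ov)]
}

#' Simulate paired-end read pairs from a (derivative) genome
#'
#' Fragments are drawn uniformly along each sequence with Gaussian insert
#' sizes; the forward mate sits at the fragment start, the reverse mate at
#' the end. Mapping is emulated by coordinate lifting through the genome's
#' block map — no real aligner is run. A read overlapping a junction is
#' assigned to the block covering at least half of it and its position is
#' extrapolated linearly through that block (a stated simplification of
#' BWA-style mapping); pairs whose fragment straddles a junction therefore
#' surface with the discordant chromosome / position / strand combination
#' the junction implies. Sequences are stored aligned to the reference
#' forward strand (SAM convention). The per-read mismatch count records
#' injected sequencing errors; bases overhanging a junction are treated as
#' soft-clipped (as a real aligner would) and do not count as mismatches,
#' so error-free simulations report `nm = 0` throughout.
#'
#' @param genome derivative or plain `ref_genome` (block map taken from
#'   [genome_blocks()]).
#' @param params a [read_sim_params()] object.
#' @return data.frame of read pairs: `id`, then `chrom/pos/strand/nm/seq`
#'   for mate 1 and mate 2 (`pos` is the leftmost aligned base, 1-based).
#' @export
simulate_read_pairs <- function(genome, params) {
  if (length(genome) == 0) stop("genome is empty", call. = FALSE)
  stopifnot(inherits(params, "read_sim_params"))
  blocks <- genome_blocks(genome)
  rl <- params$read_length
  lens <- chrom_lengths(genome)
  out <- with_seed(params$seed, {
    lapply(names(lens), function(nm) {
      len <- lens[[nm]]
      n <- max(0L, as.integer(round(len * params$coverage / (2 * rl))))
      if (n == 0L || len < rl + 1) return(NULL)
      L <- pmin(len, pmax(rl + 1, as.integer(round(
        stats::rnorm(n, params$insert_mean, params$insert_sd)))))
      s <- 1L + floor(stats::runif(n) * (len - L + 1))
      simulate_pairs_one(genome[[nm]], blocks[[nm]], s, L, rl,
                         params$error_rate)
    })
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    stop("genome too short for the requested read layout", call. = FALSE)
  }
  out$id <- sprintf("rp%07d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("id", "chrom1", "pos1", "strand1", "nm1", "seq1",
          "chrom2", "pos2", "strand2", "nm2", "seq2")]
}

## one derivative sequence; s = fragment starts, L = fragment lengths
simulate_pairs_one <- function(derseq, b, s, L, rl, error_rate) {
  n <- length(s)
  ## mate derivative intervals (mate1 fwd at start, mate2 rev at end)
  a1s <- s;           a1e <- s + rl - 1L
  a2s <- s + L - rl;  a2e <- s + L - 1L

  lift <- function(astart, aend, der_orient) {
    if (nrow(b) == 1L) {
      k <- rep(1L, n)
    } else {
      k <- findInterval(astart, b$der_start)
      k2 <- findInterval(aend, b$der_start)
      for (i in which(k != k2)) k[i] <- pick_block(b, astart[i], aend[i])
    }
    plus <- b$strand[k] == "+"
    pos <- ifelse(plus,
                  b$ref_start[k] + (astart - b$der_start[k]),
                  b$ref_end[k] - (aend - b$der_start[k]))
    chrom <- b$chrom[k]
    pos <- pmax(pos, 1)     # junction-edge extrapolation never goes below 1
    ## strand of the mate on the reference
    strand <- ifelse(plus == (der_orient == "+"), "+", "-")
    dseq <- substring(derseq, astart, aend)
    ## store sequence aligned to the reference forward strand
    seq <- dseq
    flip <- !plus
    if (any(flip)) seq[flip] <- vapply(dseq[flip], revcomp, character(1), USE.NAMES = FALSE)
    list(chrom = chrom, pos = as.numeric(pos), strand = strand, seq = seq)
  }
  m1 <- lift(a1s, a1e, "+")
  m2 <- lift(a2s, a2e, "-")

  nm1 <- integer(n); nm2 <- integer(n)
  if (error_rate > 0) {
    for (mt in 1:2) {
      m <- if (mt == 1) m1 else m2
      ne <- stats::rbinom(n, rl, error_rate)
      for (i in which(ne > 0)) {
        posn <- sample.int(rl, ne[i])
        sq <- m$seq[i]
        for (p in posn) {
          old <- substr(sq, p, p)
          substr(sq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
        m$seq[i] <- sq
      }
      if (mt == 1) { m1 <- m; nm1 <- ne } else { m2 <- m; nm2 <- ne }
    }
  }
  data.frame(chrom1 = m1$chrom, pos1 = m1$pos, strand1 = m1$strand,
             nm1 = nm1, seq1 = m1$seq,
             chrom2 = m2$chrom, pos2 = m2$pos, strand2 = m2$strand,
             nm2 = nm2, seq2 = m2$seq,
             stringsAsFactors = FALSE)
}
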