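## Self-contained blastn-like surrogate: exact word seeding plus ungapped
## diagonal extension, scored +1 match / -2 mismatch, with Karlin-Altschul
## E-values. Used only to re-examine the reads supporting a candidate
## rearrangement, mirroring a BLAST remap of supporting pairs.

#' Build a realignment index over a reference genome
#'
#' Concatenates all chromosomes (separated by N runs) into one
#' `Biostrings::DNAString` subject for exact word matching.
#'
#' @param ref a `ref_genome`.
#' @param spacer number of N bases between chromosomes.
#' @return list with the subject, per-chromosome offsets, and search-space
#'   size; class `realign_index`.
#' @export
realign_index <- function(ref, spacer = 200L) {
  if (length(ref) == 0) stop("empty reference", call. = FALSE)
  lens <- chrom_lengths(ref)
  gap <- strrep("N", spacer)
  subject <- paste(unclass(ref), collapse = gap)
  starts <- cumsum(c(1, utils::head(lens + spacer, -1)))
  structure(list(subject = Biostrings::DNAString(subject),
                 subject_chars = subject,
                 chrom = names(lens), starts = as.numeric(starts),
                 lens = as.numeric(lens),
                 space = 2 * sum(as.numeric(lens))),
            class = "realign_index")
}

## best contiguous segment score along one diagonal (Kadane)
diag_best_score <- function(qchars, wchars) {
  x <- ifelse(qchars == wchars & qchars != utf8ToInt("N"), 1, -2)
  cs <- cumsum(x)
  max(cs - cummin(c(0, cs[-length(cs)])))
}

#' Best ungapped local placements of reads in a reference
#'
#' For each query sequence, exact `word_size`-mers sampled every
#' `seed_step` bases (both orientations) are matched against the indexed
#' reference; each seeded diagonal is extended without gaps and scored
#' (+1/-2). The best-scoring placements (ties included) are returned with
#' their Karlin-Altschul E-values over a search space of twice the genome
#' length.
#'
#' @param seqs character vector of read sequences.
#' @param index a [realign_index()].
#' @param cfg a [caller_config()] (lambda, K, word size, step).
#' @return list (one element per read) of data.frames with columns
#'   `chrom`, `pos` (leftmost base of the implied full-read placement),
#'   `strand`, `score`, `evalue`; zero rows when nothing seeds.
#' @export
best_local_hits <- function(seqs, index, cfg = caller_config()) {
  stopifnot(inherits(index, "realign_index"))
  w <- cfg$word_size
  queries <- list(); qmeta <- list()
  for (i in seq_along(seqs)) {
    for (orient in c("+", "-")) {
      q <- if (orient == "+") seqs[i] else revcomp(seqs[i])
      n <- nchar(q)
      if (n < w) next
      offs <- unique(c(seq(1L, n - w + 1L, by = cfg$seed_step), n - w + 1L))
      for (o in offs) {
        queries[[length(queries) + 1]] <- substr(q, o, o + w - 1L)
        qmeta[[length(qmeta) + 1]] <- c(i, o, orient)
      }
    }
  }
  out <- replicate(length(seqs),
                   data.frame(chrom = character(0), pos = numeric(0),
                              strand = character(0), score = numeric(0),
                              evalue = numeric(0)),
                   simplify = FALSE)
  if (length(queries) == 0) return(out)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unlist(queries)))
  mi <- Biostrings::matchPDict(pd, index$subject)
  starts <- Biostrings::startIndex(mi)

  ## collect candidate diagonals per (read, orientation)
  diag_map <- new.env(parent = emptyenv())
  for (qi in seq_along(queries)) {
    st <- starts[[qi]]
    if (is.null(st) || length(st) == 0) next
    meta <- qmeta[[qi]]
    read_i <- as.integer(meta[1]); seed_off <- as.integer(meta[2])
    key <- paste0(read_i, meta[3])
    diag_map[[key]] <- unique(c(diag_map[[key]], st - seed_off + 1))
  }
  subj_n <- nchar(index$subject_chars)
  for (key in ls(diag_map)) {
    read_i <- as.integer(sub("[+-]$", "", key))
    orient <- substring(key, nchar(key))
    q <- if (orient == "+") seqs[read_i] else revcomp(seqs[read_i])
    qn <- nchar(q)
    qchars <- utf8ToInt(q)
    hits <- lapply(diag_map[[key]], function(d) {
      a <- max(1, d); b <- min(subj_n, d + qn - 1)
      wch <- utf8ToInt(substr(index$subject_chars, a, b))
      qch <- qchars[(a - d + 1):(b - d + 1)]
      data.frame(diag = d, score = diag_best_score(qch, wch))
    })
    hits <- do.call(rbind, hits)
    ## map subject diagonal to chromosome coordinates; placement position is
    ## where the full read would start on that diagonal
    ci <- findInterval(hits$diag, index$starts)
    ci[ci < 1] <- 1
    hits$chrom <- index$chrom[ci]
    refpos <- hits$diag - index$starts[ci] + 1
    ## a "-" orientation hit means the reverse complement matched the
    ## forward reference: the read maps to the minus strand there
    hits$pos <- refpos
    hits$strand <- orient
    hits$evalue <- cfg$karlin_k * qn * index$space * exp(-cfg$lambda * hits$score)
    prev <- out[[read_i]]
    out[[read_i]] <- rbind(prev, hits[, c("chrom", "pos", "strand", "score", "evalue")])
  }
  ## keep only the best-scoring placements per read
  lapply(out, function(h) {
    if (nrow(h) == 0) return(h)
    h[h$score == max(h$score), , drop = FALSE]
  })
}

#' Realignment (E-value) filter for one cluster
#'
#' Each supporting pair's reads are locally re-aligned to the reference;
#' the pair is discarded when its best placements form a concordant pair —
#' FR orientation within `proper_max_distance` bp on one chromosome — with
#' both E-values below `evalue_threshold` (a mapping-error signature:
#' the pair has a perfectly ordinary home in the reference). Pairs
#' straddling a genuine junction have no such placement and are retained.
#'
#' @param cluster an `sv_cluster`.
#' @param ref the reference `ref_genome`.
#' @param cfg a [caller_config()].
#' @param index optional prebuilt [realign_index()].
#' @return list with `cluster` (support recomputed; `NULL` if no pair
#'   survives) and `verdicts` (per-pair data.frame: id, dropped).
#' @export
realignment_filter <- function(cluster, ref, cfg = caller_config(), index = NULL) {
  stopifnot(inherits(cluster, "sv_cluster"))
  if (is.null(index)) index <- realign_index(ref)
  df <- cluster$pairs
  ## sequences are stored aligned to the forward reference strand (SAM
  ## convention); recover the physical reads so orientation is meaningful
  phys <- function(seq, strand) {
    flip <- strand == "-"
    seq[flip] <- vapply(seq[flip], revcomp, character(1), USE.NAMES = FALSE)
    seq
  }
  h1 <- best_local_hits(phys(df$seq1, df$strand1), index, cfg)
  h2 <- best_local_hits(phys(df$seq2, df$strand2), index, cfg)
  dropped <- vapply(seq_len(nrow(df)), function(i) {
    a <- h1[[i]]; b <- h2[[i]]
    a <- a[a$evalue < cfg$evalue_threshold, , drop = FALSE]
    b <- b[b$evalue < cfg$evalue_threshold, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
    for (ia in seq_len(nrow(a))) {
      bb <- b[b$chrom == a$chrom[ia] &
              abs(b$pos - a$pos[ia]) <= cfg$proper_max_distance, , drop = FALSE]
      if (nrow(bb) == 0) next
      left_is_a <- a$pos[ia] <= bb$pos
      fr <- (left_is_a & a$strand[ia] == "+" & bb$strand == "-") |
            (!left_is_a & bb$strand == "+" & a$strand[ia] == "-")
      if (any(fr)) return(TRUE)
    }
    FALSE
  }, logical(1))
  verdicts <- data.frame(id = df$id, dropped = dropped, stringsAsFactors = FALSE)
  kept <- df[!dropped, , drop = FALSE]
  cl <- if (nrow(kept) == 0) NULL else build_cluster(kept)
  list(cluster = cl, verdicts = verdicts)
}
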