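#' Reference genome container
#'
#' A reference genome is stored as a named character vector of A/C/G/T
#' sequences (one element per chromosome) with S3 class `ref_genome`.
#' A derivative (rearranged) genome uses the same container plus a
#' `blocks` attribute describing, per derivative sequence, which reference
#' intervals it is composed of and in which orientation (the coordinate
#' "lift" used to emulate read mapping).
#'
#' @param sequences named character vector of chromosome sequences.
#' @return A `ref_genome` object.
#' @export
ref_genome <- function(sequences) {
  if (length(sequences) == 0) {
    warning("empty genome")
    x <- character(0)
    class(x) <- "ref_genome"
    return(x)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("chromosome names must be unique and non-empty", call. = FALSE)
  }
  sequences <- toupper(unlist(sequences))
  if (any(!nzchar(sequences))) stop("all sequences must be non-empty", call. = FALSE)
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("alphabet restricted to A/C/G/T (N allowed as padding)", call. = FALSE)
  }
  class(sequences) <- "ref_genome"
  sequences
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(unclass(x))), big.mark = ",")))
  for (nm in names(x)) {
    cat(sprintf("  %-12s %10s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `ref_genome`.
#' @return named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  vapply(unclass(genome), nchar, integer(1))
}

#' Generate a random reference genome
#'
#' Draws i.i.d. bases at a target GC fraction. Reproducible for a fixed
#' seed; for chromosomes of at least 100 kb the realized GC content is
#' within about two percentage points of `gc_fraction` (binomial bound).
#'
#' @param chrom_lengths named numeric vector, chromosome name -> length (bp),
#'   each at least 10 kb.
#' @param gc_fraction target G+C proportion in (0, 1).
#' @param seed integer seed.
#' @return A `ref_genome`.
#' @export
generate_reference <- function(chrom_lengths, gc_fraction = 0.41, seed = 1L) {
  if (length(chrom_lengths) == 0) stop("no chromosomes requested", call. = FALSE)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (any(chrom_lengths < 10000)) {
    stop("chromosome lengths must be >= 10 kb", call. = FALSE)
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0,1)", call. = FALSE)
  base_prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                 G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- with_seed(seed, {
    vapply(as.integer(chrom_lengths), function(n) {
      paste(sample(names(base_prob), n, replace = TRUE, prob = base_prob),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- names(chrom_lengths)
  ref_genome(seqs)
}

## --- sequence helpers -----------------------------------------------------

#' Extract a reference subsequence, 1-based inclusive
#'
#' Coordinates outside the chromosome are padded with `N` so junction
#' classification near sequence ends degrades gracefully (N matches nothing).
#'
#' @param genome a `ref_genome`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates (may exceed bounds).
#' @return character scalar of length `end - start + 1`.
#' @export
seq_extract <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' not in genome", chrom), call. = FALSE)
  }
  s <- genome[[chrom]]
  n <- nchar(s)
  if (end < start) return("")
  left_pad <- max(0L, 1L - start)
  right_pad <- max(0L, end - n)
  core <- substr(s, max(1L, start), min(n, end))
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' Reverse complement of a DNA string
#' @param x character scalar (A/C/G/T/N).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## seeded evaluation that does not clobber the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## derive a distinct 31-bit sub-seed from a base seed and a stage label
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
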