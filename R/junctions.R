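## Junction chemistry: classification of fusion sequences into
## microhomology / blunt / insertion, templated-origin search, and
## breakpoint proximity statistics — the NHEJ / Alt-NHEJ evidence layer.

common_prefix_len <- function(x, y) {
  a <- utf8ToInt(x); b <- utf8ToInt(y)
  n <- min(length(a), length(b))
  if (n == 0) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0) n else neq[1] - 1L
}

common_suffix_len <- function(x, y) {
  common_prefix_len(paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                    paste(rev(strsplit(y, "")[[1]]), collapse = ""))
}

#' Classify a junction sequence
#'
#' `junction_seq` must carry exactly `flank` bases on the left of the
#' fusion point (more are allowed in the middle for insertions). The left
#' flank is extended along the side-1 reference and the right flank along
#' the side-2 reference (maximal exact extents); their overlap is the
#' microhomology, a gap is an insertion, exact abutment is blunt. The
#' maximal-extent rule means a k-bp microhomology always beats a
#' (k-1)-bp-homology-plus-1-bp-insertion reading.
#'
#' Breakends are `list(chrom, pos, strand)`: side 1 approaches the junction
#' and ends at `pos` (`"+"` ascending reference, `"-"` descending, i.e.
#' reverse-complemented); side 2 leaves the junction starting at `pos`
#' (`"+"` ascending; `"-"` descending).
#'
#' @param junction_seq fusion sequence spanning the junction.
#' @param ref a `ref_genome`.
#' @param break1,break2 side-1 / side-2 breakends (see Details).
#' @param flank bases of genuine flank on each side (>= 20).
#' @param event_id optional label carried into the result.
#' @return one-row data.frame: `event_id`, `jclass`
#'   (`MICROHOMOLOGY`/`BLUNT`/`INSERTION`), `mh_seq`, `mh_len`, `ins_seq`,
#'   `ins_len`.
#' @export
classify_junction <- function(junction_seq, ref, break1, break2, flank = 50,
                              event_id = NA_character_) {
  stopifnot(flank >= 20)
  junction_seq <- toupper(junction_seq)
  n <- nchar(junction_seq)
  if (n < 2 * flank) {
    stop("junction_seq shorter than 2*flank", call. = FALSE)
  }
  e1 <- paste0(side1_flank(ref, break1, flank), side1_cont(ref, break1, flank))
  e2 <- paste0(side2_cont(ref, break2, flank), side2_flank(ref, break2, flank))
  a <- common_prefix_len(junction_seq, e1)
  b <- common_suffix_len(junction_seq, e2)
  if (a < flank || b < flank) {
    stop("junction flanks do not anchor to the reference at the stated breakpoints",
         call. = FALSE)
  }
  overlap <- a + b - n
  if (overlap > 0) {
    data.frame(event_id = event_id, jclass = "MICROHOMOLOGY",
               mh_seq = substr(junction_seq, n - b + 1, a), mh_len = overlap,
               ins_seq = "", ins_len = 0L, stringsAsFactors = FALSE)
  } else if (overlap == 0) {
    data.frame(event_id = event_id, jclass = "BLUNT", mh_seq = "", mh_len = 0L,
               ins_seq = "", ins_len = 0L, stringsAsFactors = FALSE)
  } else {
    ins <- substr(junction_seq, a + 1, n - b)
    data.frame(event_id = event_id, jclass = "INSERTION", mh_seq = "",
               mh_len = 0L, ins_seq = ins, ins_len = nchar(ins),
               stringsAsFactors = FALSE)
  }
}

#' Breakends of a planted junction
#'
#' Maps an event row (or truth row) to the side-1 / side-2 breakends used
#' by [classify_junction()], following the package's single-junction
#' constructions (LD splice, RF duplication joint, FF fold-back, CT fusion).
#'
#' @param event one-row `sv_events` / truth data.frame.
#' @return list with elements `side1` and `side2`.
#' @export
junction_breakends <- function(event) {
  list(side1 = breakend_side1(event), side2 = breakend_side2(event))
}

#' Extract a planted junction's fusion sequence from a derivative genome
#'
#' @param genome derivative genome from [plant_rearrangements()].
#' @param truth_row one row of the planting truth table.
#' @param flank flank size in bp.
#' @return character scalar with `flank` bases each side of the junction
#'   (insertions included in the middle).
#' @export
junction_sequence <- function(genome, truth_row, flank = 50) {
  substr(genome[[truth_row$der_chrom]],
         truth_row$der_jpos - flank + 1,
         truth_row$der_jpos2 + flank - 1)
}

#' Classify every planted junction of a planting result
#'
#' Round-trip helper: extracts each truth junction's fusion sequence from
#' the derivative genome and classifies it against the edited reference.
#'
#' @param planted result of [plant_rearrangements()].
#' @param flank flank size in bp.
#' @return data.frame of junction calls, one row per truth junction.
#' @export
classify_planted_junctions <- function(planted, flank = 50) {
  rows <- lapply(seq_len(nrow(planted$truth)), function(i) {
    tr <- planted$truth[i, ]
    be <- junction_breakends(tr)
    classify_junction(junction_sequence(planted$genome, tr, flank),
                      planted$reference, be$side1, be$side2, flank,
                      event_id = tr$id)
  })
  do.call(rbind, rows)
}

#' Search for the templated origin of an inserted sequence
#'
#' Exact-match search of `ins_seq` and its reverse complement within
#' `search_window` bp of each anchor breakpoint. The reported offset is
#' from the anchor to the template's reading start: the forward-strand
#' start for forward templates and the forward-strand end for reverse
#' ones; negative = upstream.
#'
#' @param ins_seq inserted sequence (non-empty).
#' @param ref a `ref_genome`.
#' @param anchors data.frame with columns `name`, `chrom`, `pos`.
#' @param search_window bp to search on each side of an anchor.
#' @return list `(anchor, offset, orientation)` for the nearest hit, or
#'   `NULL` when the sequence is absent from every window.
#' @export
find_insertion_origin <- function(ins_seq, ref, anchors, search_window = 500) {
  stopifnot(nzchar(ins_seq), search_window >= nchar(ins_seq))
  ins_seq <- toupper(ins_seq)
  L <- nchar(ins_seq)
  hits <- list()
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]; pos <- anchors$pos[i]
    lo <- max(1, pos - search_window)
    hi <- min(chrom_lengths(ref)[[chrom]], pos + search_window)
    window <- Biostrings::DNAString(seq_extract(ref, chrom, lo, hi))
    for (orientation in c("forward", "reverse")) {
      patt <- if (orientation == "forward") ins_seq else revcomp(ins_seq)
      m <- Biostrings::matchPattern(Biostrings::DNAString(patt), window)
      for (st in Biostrings::start(m)) {
        h_start <- lo + st - 1
        h_end <- h_start + L - 1
        read_start <- if (orientation == "forward") h_start else h_end
        hits[[length(hits) + 1]] <- list(anchor = anchors$name[i],
                                         offset = read_start - pos,
                                         orientation = orientation)
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  hits[[order(vapply(hits, function(h) abs(h$offset), numeric(1)))[1]]]
}

#' Pairwise proximity of breakpoints across events
#'
#' All same-chromosome distances between breakpoints of *different*
#' events, up to `max_report` bp.
#'
#' @param events an `sv_events`-style data.frame.
#' @param max_report largest distance to report (bp).
#' @return data.frame: `event_a`, `break_a`, `event_b`, `break_b`, `chrom`,
#'   `distance`, sorted by distance.
#' @export
breakpoint_distances <- function(events, max_report = 1000) {
  bp <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    data.frame(id = events$id[i], brk = c("break1", "break2"),
               chrom = c(events$chrom1[i], events$chrom2[i]),
               pos = c(events$pos1[i], events$pos2[i]),
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (i in seq_len(nrow(bp) - 1)) {
    for (j in (i + 1):nrow(bp)) {
      if (bp$id[i] == bp$id[j] || bp$chrom[i] != bp$chrom[j]) next
      d <- abs(bp$pos[i] - bp$pos[j])
      if (d <= max_report) {
        out[[length(out) + 1]] <- data.frame(
          event_a = bp$id[i], break_a = bp$brk[i],
          event_b = bp$id[j], break_b = bp$brk[j],
          chrom = bp$chrom[i], distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(event_a = character(0), break_a = character(0),
                      event_b = character(0), break_b = character(0),
                      chrom = character(0), distance = numeric(0)))
  }
  out <- do.call(rbind, out)
  out[order(out$distance), ]
}

#' Census of junction classes
#'
#' @param calls data.frame of junction calls ([classify_junction()] rows).
#' @return list with `counts` (named vector over
#'   MICROHOMOLOGY/BLUNT/INSERTION) and `max_mh_len`.
#' @export
summarize_junction_classes <- function(calls) {
  classes <- c("MICROHOMOLOGY", "BLUNT", "INSERTION")
  counts <- vapply(classes, function(cl) sum(calls$jclass == cl), integer(1))
  list(counts = counts,
       max_mh_len = if (nrow(calls) == 0) 0L else max(c(0L, calls$mh_len)))
}
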