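#' Construct a rearrangement event table
#'
#' Events are the package's exchange format for both planted truth and
#' caller output. Types follow read-pair orientation vocabulary:
#' `CT` inter-chromosomal translocation, `LD` long deletion (FR pairs at
#' excessive distance), `FF` forward-forward (head-to-head fold-back),
#' `RF` reverse-forward (tandem-duplication-type joint). Junction
#' chemistry is one of `microhomology`, `blunt`, `insertion`.
#'
#' @param id event labels (unique).
#' @param chrom1,pos1 first breakpoint (1-based).
#' @param chrom2,pos2 second breakpoint (1-based).
#' @param rtype one of `"CT"`, `"LD"`, `"FF"`, `"RF"`.
#' @param jclass junction class (`"microhomology"`, `"blunt"`, `"insertion"`),
#'   or `NA` when unknown.
#' @param jseq microhomology or insertion sequence (`""` for blunt).
#' @param origin_anchor,origin_offset,origin_orientation optional templated
#'   origin of an insertion: anchor is `"break1"` or `"break2"`, offset in bp
#'   (negative = upstream on the reference forward strand), orientation
#'   `"forward"` or `"reverse"`.
#' @return data.frame with class `sv_events`.
#' @export
rearrangement_events <- function(id, chrom1, pos1, chrom2, pos2, rtype,
                                 jclass = NA_character_, jseq = "",
                                 origin_anchor = NA_character_,
                                 origin_offset = NA_integer_,
                                 origin_orientation = NA_character_) {
  ev <- data.frame(
    id = as.character(id), chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
    chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
    rtype = as.character(rtype),
    jclass = rep_len(as.character(jclass), length(id)),
    jseq = toupper(rep_len(as.character(jseq), length(id))),
    origin_anchor = rep_len(as.character(origin_anchor), length(id)),
    origin_offset = rep_len(as.integer(origin_offset), length(id)),
    origin_orientation = rep_len(as.character(origin_orientation), length(id)),
    stringsAsFactors = FALSE
  )
  validate_events(ev)
  class(ev) <- c("sv_events", "data.frame")
  ev
}

validate_events <- function(ev) {
  if (anyDuplicated(ev$id)) stop("event ids must be unique", call. = FALSE)
  if (!all(ev$rtype %in% c("CT", "LD", "FF", "RF"))) {
    stop("rtype must be one of CT/LD/FF/RF", call. = FALSE)
  }
  intra <- ev$rtype != "CT"
  if (any(ev$chrom1[!intra] == ev$chrom2[!intra])) {
    stop("CT requires break1 and break2 on different chromosomes", call. = FALSE)
  }
  if (any(ev$chrom1[intra] != ev$chrom2[intra])) {
    stop("LD/FF/RF require both breakpoints on one chromosome", call. = FALSE)
  }
  if (any(ev$pos1[intra] >= ev$pos2[intra])) {
    stop("LD/FF/RF require pos1 < pos2", call. = FALSE)
  }
  mh <- !is.na(ev$jclass) & ev$jclass == "microhomology"
  if (any(mh & nchar(ev$jseq) < 1)) {
    stop("microhomology events need a sequence of length >= 1", call. = FALSE)
  }
  ins <- !is.na(ev$jclass) & ev$jclass == "insertion"
  if (any(ins & nchar(ev$jseq) < 1)) {
    stop("insertion events need a non-empty inserted sequence", call. = FALSE)
  }
  invisible(ev)
}

#' Bundled demonstration rearrangement set
#'
#' The fourteen de novo junctions recovered by whole-genome sequencing from
#' a proton-microbeam-irradiated oral squamous cell carcinoma subline, used
#' throughout the package as the worked example: hg19-style coordinates,
#' orientation types, and the Sanger-determined junction chemistry
#' (nine microhomologies of 1-4 bp, three blunt joints, two insertions,
#' one of them templated 79 bp upstream of breakpoint 2 in reverse
#' orientation). Rows with no junction sequence are carried as blunt.
#'
#' @return An `sv_events` data.frame of 14 rows.
#' @export
example_events <- function() {
  rearrangement_events(
    id     = c("ID23", "ID29", "ID30", "ID50", "ID76", "ID80", "ID91",
               "ID93", "ID108", "ID109", "ID119", "ID120", "ID143", "ID167"),
    chrom1 = c("chr2", "chr2", "chr2", "chr3", "chr5", "chr5", "chr5",
               "chr5", "chr7", "chr7", "chr7", "chr7", "chr12", "chr20"),
    pos1   = c(15742392, 48937454, 53106380, 144705944, 6330710, 19854137,
               89613939, 95994652, 26274055, 51228098, 127757875, 127757880,
               53845481, 57562329),
    chrom2 = c("chr2", "chr2", "chr2", "chr12", "chr5", "chr5", "chr20",
               "chr5", "chr7", "chr7", "chr7", "chr11", "chr20", "chr20"),
    pos2   = c(16708640, 81807507, 53252037, 28795184, 6378473, 89613562,
               14453942, 96157380, 123601513, 51281802, 127820864, 23404604,
               5707700, 57708236),
    rtype  = c("RF", "RF", "LD", "CT", "RF", "LD", "CT", "RF", "LD", "RF",
               "FF", "CT", "CT", "LD"),
    jclass = c("insertion", "microhomology", "microhomology", "microhomology",
               "microhomology", "blunt", "microhomology", "microhomology",
               "blunt", "microhomology", "microhomology", "blunt",
               "microhomology", "insertion"),
    jseq   = c("CTGAA", "C", "AA", "TT", "TG", "", "TGGA", "GAT", "", "TT",
               "TTT", "", "G", "GCTCTGGTCCTGCATGACGTCCGTAGGATCACTT"),
    origin_anchor      = c(rep(NA, 13), "break2"),
    origin_offset      = c(rep(NA, 13), -79L),
    origin_orientation = c(rep(NA, 13), "reverse")
  )
}

#' Bundled demonstration copy-number alteration set
#'
#' The sixteen de novo copy-number segments called by SNP array in the same
#' irradiated subline as [example_events()]: chromosome, Amp/Del state,
#' cytoband, hg19-style start/end and length in bp (length = end - start).
#'
#' @return data.frame with columns chrom, call, band, start, end, length.
#' @export
example_cna_segments <- function() {
  seg <- data.frame(
    chrom = c("chr2", "chr2", "chr5", "chr5", "chr7", "chr7", "chr7", "chr7",
              "chr8", "chr12", "chr12", "chr13", "chr14", "chr16", "chr17",
              "chr21"),
    call = c("AMP", "AMP", "DEL", "DEL", "DEL", "DEL", "DEL", "DEL", "DEL",
             "DEL", "DEL", "DEL", "AMP", "DEL", "DEL", "DEL"),
    band = c("2p24.3", "2p16.3 - 2p11.2", "5q12.1 - 5q15", "5q15 - 5q35.3",
             "7p15.2 - 7p11.2", "7q21.13 - 7q21.2", "7q21.3 - 7q31.31",
             "7q32.1 - 7q36.3", "8p23.3 - 8q24.3", "12p13.33 - 12p11.22",
             "12p11.22 - 12p11.1", "13q11 - 13q34", "14q31.1", "16q23.1",
             "17p13.3 - 17q25.3", "21q22.3"),
    start = c(16112059, 48874201, 60181452, 96133485, 26267811, 90400492,
              93403513, 127700973, 164984, 191619, 30194870, 19058717,
              82396465, 78925534, 8547, 43557092),
    end = c(16374530, 83960470, 95997250, 180693128, 56070567, 91667757,
            117737887, 159119487, 146293415, 28788116, 34823250, 115103530,
            82542289, 79054884, 81051008, 43634574),
    stringsAsFactors = FALSE
  )
  seg$length <- seg$end - seg$start
  seg
}

#' Rescale breakpoint coordinates onto small synthetic chromosomes
#'
#' Compresses real-genome coordinates to desk scale with an
#' order-preserving piecewise-linear map per chromosome: gaps between
#' consecutive breakpoint anchors at most `keep_within` bp are kept
#' exactly (so 5 bp / 377 bp proximities survive), larger gaps collapse
#' to `pad` bp; `margin` bp flank each chromosome end.
#'
#' @param events an `sv_events` table in original coordinates.
#' @param margin bp before the first and after the last anchor.
#' @param pad replacement length for gaps larger than `keep_within`.
#' @param keep_within gaps at or below this size are preserved exactly.
#' @return list with `events` (rescaled `sv_events`), `chrom_lengths`
#'   (named vector), and `map` (data.frame chrom/old/new, one row per anchor).
#' @export
rescale_breakpoints <- function(events, margin = 10000, pad = 5000,
                                keep_within = 1000) {
  anchors <- rbind(
    data.frame(chrom = events$chrom1, old = events$pos1),
    data.frame(chrom = events$chrom2, old = events$pos2)
  )
  anchors <- unique(anchors[order(anchors$chrom, anchors$old), ])
  maps <- lapply(split(anchors, anchors$chrom), function(a) {
    a <- a[order(a$old), ]
    gaps <- diff(a$old)
    newgaps <- ifelse(gaps <= keep_within, gaps, pad)
    a$new <- margin + cumsum(c(0, newgaps))
    a
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  lens <- vapply(maps, function(a) max(a$new) + margin, numeric(1))
  lift <- function(chrom, pos) {
    m <- maps[[chrom]]
    m$new[match(pos, m$old)]
  }
  out <- events
  out$pos1 <- mapply(lift, events$chrom1, events$pos1)
  out$pos2 <- mapply(lift, events$chrom2, events$pos2)
  validate_events(out)
  list(events = out, chrom_lengths = lens, map = map)
}

#' Rescale copy-number segments onto a synthetic probe grid
#'
#' Each segment becomes a run of `seg_probes` probes; gaps between
#' segments, and chromosome margins, become `gap_probes` probes, at
#' uniform `spacing` bp. Truth copy numbers default to 3.0 for AMP and
#' 1.0 for DEL.
#'
#' @param segments data.frame as from [example_cna_segments()].
#' @param seg_probes probes per rescaled segment.
#' @param gap_probes probes per neutral gap / margin.
#' @param spacing probe spacing in bp.
#' @return list with `segments` (chrom/start/end/copy/call/loh in synthetic
#'   coordinates) and `chrom_lengths`.
#' @export
rescale_cna_segments <- function(segments, seg_probes = 60, gap_probes = 45,
                                 spacing = 1000) {
  stopifnot(seg_probes >= 1, gap_probes >= 1, spacing > 0)
  out <- list()
  lens <- c()
  for (chrom in unique(segments$chrom)) {
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    pos <- gap_probes * spacing   # left margin
    for (i in seq_len(nrow(seg))) {
      start <- pos + spacing
      end <- pos + seg_probes * spacing
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = start, end = end,
        copy = if (seg$call[i] == "AMP") 3.0 else 1.0,
        call = seg$call[i],
        loh = seg$call[i] == "DEL",
        stringsAsFactors = FALSE
      )
      pos <- end + gap_probes * spacing
    }
    lens[chrom] <- pos
  }
  list(segments = do.call(rbind, out), chrom_lengths = lens)
}
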