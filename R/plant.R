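## Planting rearrangements into a reference genome.
##
## Each event plants exactly ONE novel junction:
##   LD  splice-out of (pos1, pos2]            side1 = (chrom, pos1, +), side2 = (chrom, pos2+1, +)
##   RF  tandem-duplication joint              side1 = (chrom, pos2, +), side2 = (chrom, pos1, +)
##   FF  head-to-head fold-back, tail dropped  side1 = (chrom, pos1, +), side2 = (chrom, pos2, -)
##   CT  unbalanced fusion chromosome          side1 = (chrom1, pos1, +), side2 = (chrom2, pos2+1, +)
## side1 approaches the junction, side2 leaves it; strand "-" means the
## retained side2 sequence is the reverse complement of the reference.
##
## Junction chemistry is realized by editing the reference BEFORE the
## derivative is assembled: for a microhomology the shared bases are copied
## onto the partner side's pre-junction reference, and accidental terminal
## identities that would lengthen (or create) a homology are broken by
## single-base edits. All samples are then simulated from the same edited
## reference, so the edits are junction-neutral for parental genomes.

breakend_side1 <- function(ev) {
  switch(ev$rtype,
    LD = list(chrom = ev$chrom1, pos = ev$pos1, strand = "+"),
    RF = list(chrom = ev$chrom1, pos = ev$pos2, strand = "+"),
    FF = list(chrom = ev$chrom1, pos = ev$pos1, strand = "+"),
    CT = list(chrom = ev$chrom1, pos = ev$pos1, strand = "+")
  )
}

breakend_side2 <- function(ev) {
  switch(ev$rtype,
    LD = list(chrom = ev$chrom2, pos = ev$pos2 + 1, strand = "+"),
    RF = list(chrom = ev$chrom1, pos = ev$pos1, strand = "+"),
    FF = list(chrom = ev$chrom2, pos = ev$pos2, strand = "-"),
    CT = list(chrom = ev$chrom2, pos = ev$pos2 + 1, strand = "+")
  )
}

## value of side1 flank / continuation in derivative orientation
side1_flank <- function(ref, be, k) seq_extract(ref, be$chrom, be$pos - k + 1, be$pos)
side1_cont  <- function(ref, be, k) seq_extract(ref, be$chrom, be$pos + 1, be$pos + k)

side2_flank <- function(ref, be, k) {
  if (be$strand == "+") seq_extract(ref, be$chrom, be$pos, be$pos + k - 1)
  else revcomp(seq_extract(ref, be$chrom, be$pos - k + 1, be$pos))
}
side2_cont <- function(ref, be, k) {   # k bases "before" side2 along junction orientation
  if (be$strand == "+") seq_extract(ref, be$chrom, be$pos - k, be$pos - 1)
  else revcomp(seq_extract(ref, be$chrom, be$pos + 1, be$pos + k))
}

comp1 <- function(b) chartr("ACGTN", "TGCAN", b)

## --- reference editor with claim tracking ---------------------------------

new_editor <- function(ref) {
  env <- new.env(parent = emptyenv())
  env$ref <- unclass(ref)
  env$claims <- character(0)
  env
}

ed_claim_keys <- function(chrom, positions) paste0(chrom, ":", positions)

ed_write <- function(ed, chrom, start, bases, claim = TRUE) {
  n <- nchar(bases)
  if (start < 1 || start + n - 1 > nchar(ed$ref[[chrom]])) {
    stop("junction chemistry edit out of chromosome bounds", call. = FALSE)
  }
  keys <- ed_claim_keys(chrom, start:(start + n - 1))
  if (claim) {
    if (any(keys %in% ed$claims)) {
      stop("conflicting junction chemistry edits: events too close", call. = FALSE)
    }
    ed$claims <- c(ed$claims, keys)
  }
  substr(ed$ref[[chrom]], start, start + n - 1) <- bases
  invisible(ed)
}

ed_base <- function(ed, chrom, pos) substr(ed$ref[[chrom]], pos, pos)

## make the derivative-orientation values at two single-base sites differ;
## each site is list(chrom, pos, comp = TRUE/FALSE). Prefers editing site b.
ed_ensure_diff <- function(ed, a, b) {
  va <- ed_base(ed, a$chrom, a$pos); if (isTRUE(a$comp)) va <- comp1(va)
  vb <- ed_base(ed, b$chrom, b$pos); if (isTRUE(b$comp)) vb <- comp1(vb)
  if (va != vb) return(invisible(ed))
  target <- b
  if (ed_claim_keys(b$chrom, b$pos) %in% ed$claims) {
    target <- a
    if (ed_claim_keys(a$chrom, a$pos) %in% ed$claims) {
      stop("cannot break accidental homology: both sites already claimed",
           call. = FALSE)
    }
  }
  newval <- setdiff(c("A", "C", "G", "T"), va)[1]
  if (isTRUE(target$comp)) newval <- comp1(newval)
  ed_write(ed, target$chrom, target$pos, newval)
}

## apply one event's chemistry edits
retrofit_event <- function(ed, ev) {
  s1 <- breakend_side1(ev); s2 <- breakend_side2(ev)
  ref <- ed$ref
  ## site of C1(1): one past side1 end
  c1_site <- list(chrom = s1$chrom, pos = s1$pos + 1, comp = FALSE)
  ## site of S2(1): first retained base of side2
  s2_site <- if (s2$strand == "+") list(chrom = s2$chrom, pos = s2$pos, comp = FALSE)
             else list(chrom = s2$chrom, pos = s2$pos, comp = TRUE)
  ## site of C2(k)-th base before side2 (k = 1 is immediately before)
  c2_site <- function(k) {
    if (s2$strand == "+") list(chrom = s2$chrom, pos = s2$pos - k, comp = FALSE)
    else list(chrom = s2$chrom, pos = s2$pos + k, comp = TRUE)
  }
  jclass <- if (is.na(ev$jclass)) "blunt" else ev$jclass
  if (jclass == "microhomology") {
    mh <- ev$jseq; m <- nchar(mh)
    ed_write(ed, s1$chrom, s1$pos - m + 1, mh)                    # S1 tail := mh
    if (s2$strand == "+") ed_write(ed, s2$chrom, s2$pos - m, mh)  # C2 tail := mh
    else ed_write(ed, s2$chrom, s2$pos + 1, revcomp(mh))
    ## no backward extension past the homology
    ed_ensure_diff(ed, list(chrom = s1$chrom, pos = s1$pos - m, comp = FALSE),
                   c2_site(m + 1))
    ## no forward extension into side2
    ed_ensure_diff(ed, s2_site, c1_site)
  } else if (jclass == "blunt") {
    ed_ensure_diff(ed, list(chrom = s1$chrom, pos = s1$pos, comp = FALSE),
                   c2_site(1))
    ed_ensure_diff(ed, s2_site, c1_site)
  } else if (jclass == "insertion") {
    ins <- ev$jseq
    ## optional templated origin: write ins (or its revcomp) near an anchor
    if (!is.na(ev$origin_anchor)) {
      apos <- if (ev$origin_anchor == "break1") ev$pos1 else ev$pos2
      achr <- if (ev$origin_anchor == "break1") ev$chrom1 else ev$chrom2
      L <- nchar(ins)
      off <- ev$origin_offset
      ## the offset names the template's reading start: the forward-strand
      ## start for forward templates, the forward-strand end for reverse ones
      if (identical(ev$origin_orientation, "reverse")) {
        o_end <- apos + off; o_start <- o_end - L + 1
        tmpl <- revcomp(ins)
      } else {
        o_start <- apos + off; o_end <- o_start + L - 1
        tmpl <- ins
      }
      ed_write(ed, achr, o_start, tmpl)
    }
    ## insertion must extend neither flank
    first_ins <- substr(ins, 1, 1); last_ins <- substr(ins, nchar(ins), nchar(ins))
    if (ed_base_oriented(ed, c1_site) == first_ins) ed_flip(ed, c1_site, first_ins)
    if (ed_base_oriented(ed, c2_site(1)) == last_ins) ed_flip(ed, c2_site(1), last_ins)
  } else {
    stop(sprintf("unknown junction class '%s'", jclass), call. = FALSE)
  }
  invisible(ed)
}

ed_base_oriented <- function(ed, site) {
  v <- ed_base(ed, site$chrom, site$pos)
  if (isTRUE(site$comp)) comp1(v) else v
}

ed_flip <- function(ed, site, avoid) {
  newval <- setdiff(c("A", "C", "G", "T"), avoid)[1]
  if (isTRUE(site$comp)) newval <- comp1(newval)
  ed_write(ed, site$chrom, site$pos, newval)
}

## --- copy assignment -------------------------------------------------------

## interval an intra-chromosomal event occupies on its chromosome (FF
## truncates the tail, so it occupies through the chromosome end)
event_footprint <- function(ev, chrom_len, min_sep) {
  lo <- ev$pos1 - min_sep
  hi <- if (ev$rtype == "FF") chrom_len else ev$pos2 + min_sep
  c(lo, hi)
}

assign_copies <- function(events, lens, min_sep, on_conflict) {
  intra <- events[events$rtype != "CT", , drop = FALSE]
  assignment <- list()
  for (chrom in unique(intra$chrom1)) {
    evs <- intra[intra$chrom1 == chrom, , drop = FALSE]
    evs <- evs[order(evs$pos1), , drop = FALSE]
    copies <- list()
    foot <- list()
    for (i in seq_len(nrow(evs))) {
      fp <- event_footprint(evs[i, ], lens[[chrom]], min_sep)
      placed <- FALSE
      for (k in seq_along(copies)) {
        clash <- any(vapply(foot[[k]], function(f) fp[1] <= f[2] && f[1] <= fp[2],
                            logical(1)))
        if (!clash) {
          copies[[k]] <- rbind(copies[[k]], evs[i, ])
          foot[[k]] <- c(foot[[k]], list(fp))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        if (length(copies) > 0 && on_conflict == "error") {
          stop(sprintf("events overlap within the separation window on %s (%s); use on_conflict = \"new_copy\"",
                       chrom, evs$id[i]), call. = FALSE)
        }
        copies[[length(copies) + 1]] <- evs[i, , drop = FALSE]
        foot[[length(foot) + 1]] <- list(fp)
      }
    }
    assignment[[chrom]] <- copies
  }
  assignment
}

## --- derivative assembly ---------------------------------------------------

blk <- function(chrom, ref_start, ref_end, strand, ins = NA_character_) {
  data.frame(chrom = chrom, ref_start = ref_start, ref_end = ref_end,
             strand = strand, ins = ins, stringsAsFactors = FALSE)
}

blk_len <- function(b) ifelse(is.na(b$chrom), nchar(b$ins), b$ref_end - b$ref_start + 1)

build_copy <- function(chrom, chrom_len, evs, der_name) {
  blocks <- list(); truth <- list()
  cur <- 1
  for (i in seq_len(nrow(evs))) {
    ev <- evs[i, ]
    ins <- if (!is.na(ev$jclass) && ev$jclass == "insertion") ev$jseq else NULL
    if (ev$rtype == "LD") {
      blocks[[length(blocks) + 1]] <- blk(chrom, cur, ev$pos1, "+")
    } else if (ev$rtype == "RF") {
      blocks[[length(blocks) + 1]] <- blk(chrom, cur, ev$pos2, "+")
    } else if (ev$rtype == "FF") {
      blocks[[length(blocks) + 1]] <- blk(chrom, cur, ev$pos1, "+")
    }
    jpos <- sum(vapply(blocks, blk_len, numeric(1)))
    if (!is.null(ins)) blocks[[length(blocks) + 1]] <- blk(NA, NA, NA, "+", ins)
    if (ev$rtype == "LD") {
      cur <- ev$pos2 + 1
    } else if (ev$rtype == "RF") {
      cur <- ev$pos1
    } else if (ev$rtype == "FF") {
      blocks[[length(blocks) + 1]] <- blk(chrom, ev$pos1 + 1, ev$pos2, "-")
      cur <- NA
    }
    truth[[length(truth) + 1]] <- cbind(
      ev[, c("id", "chrom1", "pos1", "chrom2", "pos2", "rtype", "jclass", "jseq",
             "origin_anchor", "origin_offset", "origin_orientation")],
      data.frame(der_chrom = der_name, der_jpos = jpos,
                 der_jpos2 = jpos + (if (is.null(ins)) 0 else nchar(ins)) + 1,
                 stringsAsFactors = FALSE)
    )
  }
  if (!is.na(cur)) blocks[[length(blocks) + 1]] <- blk(chrom, cur, chrom_len, "+")
  list(blocks = do.call(rbind, blocks), truth = do.call(rbind, truth))
}

build_fusion <- function(ev, lens) {
  ins <- if (!is.na(ev$jclass) && ev$jclass == "insertion") ev$jseq else NULL
  der_name <- paste0("fus_", ev$id)
  blocks <- list(blk(ev$chrom1, 1, ev$pos1, "+"))
  if (!is.null(ins)) blocks[[2]] <- blk(NA, NA, NA, "+", ins)
  blocks[[length(blocks) + 1]] <- blk(ev$chrom2, ev$pos2 + 1, lens[[ev$chrom2]], "+")
  truth <- cbind(
    ev[, c("id", "chrom1", "pos1", "chrom2", "pos2", "rtype", "jclass", "jseq",
           "origin_anchor", "origin_offset", "origin_orientation")],
    data.frame(der_chrom = der_name, der_jpos = ev$pos1,
               der_jpos2 = ev$pos1 + (if (is.null(ins)) 0 else nchar(ins)) + 1,
               stringsAsFactors = FALSE)
  )
  list(name = der_name, blocks = do.call(rbind, blocks), truth = truth)
}

derivative_sequence <- function(ref, blocks) {
  pieces <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    if (is.na(b$chrom)) return(b$ins)
    s <- seq_extract(ref, b$chrom, b$ref_start, b$ref_end)
    if (b$strand == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Plant rearrangements into a reference genome
#'
#' Edits the reference so each event's junction chemistry is realized
#' exactly (microhomology shared across the junction, blunt abutment, or
#' inserted sequence with optional templated origin), then assembles a
#' derivative genome in which every event contributes exactly one novel
#' junction. Events whose footprints collide within `min_sep` bp raise a
#' conflict error by default; with `on_conflict = "new_copy"` colliding
#' events are placed on additional copies of the chromosome, mimicking the
#' extra chromosome copies of an aneuploid cell line. Inter-chromosomal
#' (CT) events each produce an unbalanced fusion chromosome named
#' `fus_<id>`; the partner chromosomes are retained unrearranged.
#'
#' @param ref a `ref_genome`.
#' @param events an `sv_events` table with junction chemistry columns.
#' @param on_conflict `"error"` (default) or `"new_copy"`.
#' @param min_sep minimum separation between event footprints on one copy,
#'   default 250 bp (twice the default read length).
#' @return list with `reference` (the chemistry-edited reference — simulate
#'   parental samples from this), `genome` (derivative `ref_genome` carrying
#'   a `blocks` coordinate-lift attribute), and `truth` (one row per
#'   junction: reference breakpoints, type, chemistry, derivative chromosome
#'   and junction coordinates `der_jpos`/`der_jpos2`, the last side1 base
#'   and first side2 base in derivative coordinates).
#' @export
plant_rearrangements <- function(ref, events, on_conflict = c("error", "new_copy"),
                                 min_sep = 250) {
  on_conflict <- match.arg(on_conflict)
  validate_events(events)
  lens <- chrom_lengths(ref)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    for (side in list(c(ev$chrom1, ev$pos1), c(ev$chrom2, ev$pos2))) {
      if (!side[1] %in% names(ref)) {
        stop(sprintf("event %s: chromosome %s not in reference", ev$id, side[1]),
             call. = FALSE)
      }
      p <- as.numeric(side[2])
      if (p < 1 || p > lens[[side[1]]]) {
        stop(sprintf("event %s: breakpoint %s:%s out of bounds", ev$id,
                     side[1], format(p, scientific = FALSE)), call. = FALSE)
      }
    }
  }
  ## 1. chemistry retrofits on the reference
  ed <- new_editor(ref)
  for (i in seq_len(nrow(events))) retrofit_event(ed, events[i, ])
  ref2 <- ref_genome(ed$ref)

  ## 2. assign intra-chromosomal events to chromosome copies
  assignment <- assign_copies(events, lens, min_sep, on_conflict)

  ## 3. assemble derivative sequences + block maps + truth
  der_seqs <- character(0); der_blocks <- list(); truth <- list()
  for (chrom in names(ref2)) {
    copies <- assignment[[chrom]]
    if (is.null(copies) || length(copies) == 0) {
      der_seqs[chrom] <- ref2[[chrom]]
      der_blocks[[chrom]] <- blk(chrom, 1, lens[[chrom]], "+")
    } else {
      for (k in seq_along(copies)) {
        nm <- if (k == 1) chrom else paste0(chrom, "_copy", k)
        built <- build_copy(chrom, lens[[chrom]], copies[[k]], nm)
        der_seqs[nm] <- derivative_sequence(ref2, built$blocks)
        der_blocks[[nm]] <- built$blocks
        truth[[length(truth) + 1]] <- built$truth
      }
    }
  }
  ct <- events[events$rtype == "CT", , drop = FALSE]
  for (i in seq_len(nrow(ct))) {
    fus <- build_fusion(ct[i, ], lens)
    der_seqs[fus$name] <- derivative_sequence(ref2, fus$blocks)
    der_blocks[[fus$name]] <- fus$blocks
    truth[[length(truth) + 1]] <- fus$truth
  }
  genome <- ref_genome(der_seqs)
  ## annotate derivative coordinates on the blocks
  for (nm in names(der_blocks)) {
    b <- der_blocks[[nm]]
    ln <- blk_len(b)
    b$der_end <- cumsum(ln)
    b$der_start <- b$der_end - ln + 1
    der_blocks[[nm]] <- b
  }
  attr(genome, "blocks") <- der_blocks
  truth <- do.call(rbind, truth)
  truth <- truth[order(match(truth$id, events$id)), ]
  rownames(truth) <- NULL
  list(reference = ref2, genome = genome, truth = truth)
}

#' Coordinate-lift block map of a genome
#'
#' For a derivative genome built by [plant_rearrangements()] this is the
#' stored block map; for a plain reference it is the identity map.
#' @param genome a `ref_genome`.
#' @return named list of block data.frames.
#' @export
genome_blocks <- function(genome) {
  b <- attr(genome, "blocks")
  if (!is.null(b)) return(b)
  lens <- chrom_lengths(genome)
  out <- lapply(names(lens), function(nm) {
    x <- blk(nm, 1, lens[[nm]], "+")
    x$der_end <- lens[[nm]]; x$der_start <- 1
    x
  })
  names(out) <- names(lens)
  out
}
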