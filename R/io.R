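## Readers/writers for the plain-text formats the pipeline touches.
## Internal coordinates are 1-based inclusive everywhere; conversion to
## 0-based half-open happens only at the BEDPE boundary.

#' Read / write FASTA
#'
#' Lowercase input is uppercased (with a message); sequences wrap at 80
#' columns on write. An empty file yields an empty genome with a warning.
#'
#' @param path file path.
#' @return [read_fasta()] returns a `ref_genome`.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(suppressWarnings(ref_genome(character(0))))
  }
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    message("read_fasta: lowercase bases uppercased in ", path)
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ref_genome(seqs)
}

#' @rdname read_fasta
#' @param genome a `ref_genome`.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read / write rearrangement calls as BEDPE
#'
#' Standard 0-based half-open BEDPE; internal 1-based positions map to
#' `start = pos - 1`, `end = pos`. Columns: chrom1, start1, end1, chrom2,
#' start2, end2, name, score (support), strand1, strand2, rtype.
#'
#' @param path file path.
#' @return [read_bedpe()] returns a data.frame with internal coordinates.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2", "rtype")
  names(df) <- cols[seq_len(ncol(df))]
  bad <- df$start1 > df$end1 | df$start2 > df$end2
  if (any(bad)) {
    stop(sprintf("BEDPE record '%s': start exceeds end", df$name[which(bad)[1]]),
         call. = FALSE)
  }
  data.frame(id = df$name, chrom1 = df$chrom1, pos1 = df$end1,
             chrom2 = df$chrom2, pos2 = df$end2,
             rtype = if ("rtype" %in% names(df)) df$rtype else NA_character_,
             support = suppressWarnings(as.integer(df$score)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bedpe
#' @param events events data.frame (`id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `rtype`, optional `support`).
#' @export
write_bedpe <- function(events, path) {
  support <- if ("support" %in% names(events)) events$support else 0L
  df <- data.frame(events$chrom1, events$pos1 - 1, events$pos1,
                   events$chrom2, events$pos2 - 1, events$pos2,
                   events$id, support, "+", "+", events$rtype)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write copy-number segments as SEG
#'
#' Tab-separated SEG with a header line; the mean column stores copy
#' number (not log2 ratio), as noted in the file's comment header.
#'
#' @param path file path.
#' @return [read_seg()] returns a segments data.frame (with `length`
#'   recomputed as `end - start`).
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- c("sample", "chrom", "start", "end", "n_probes", "mean_copy",
                 "call")[seq_len(ncol(df))]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start > df$end)) stop("SEG record with start > end", call. = FALSE)
  df$length <- df$end - df$start
  df
}

#' @rdname read_seg
#' @param segments data.frame with `chrom`, `start`, `end`, `n_probes`,
#'   `mean_copy`, optional `call`.
#' @param sample sample identifier written in the first column.
#' @export
write_seg <- function(segments, path, sample = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# seg.mean is in copy-number units (diploid = 2), not log2 ratio", con)
  df <- data.frame(ID = sample, chrom = segments$chrom,
                   loc.start = segments$start, loc.end = segments$end,
                   num.mark = segments$n_probes, seg.mean = segments$mean_copy)
  if ("call" %in% names(segments)) df$call <- segments$call
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read / write read pairs as TSV
#'
#' Columns: id, chrom1, pos1, strand1, nm1, seq1, chrom2, pos2, strand2,
#' nm2, seq2 (1-based leftmost positions).
#'
#' @param path file path.
#' @return [read_pairs_tsv()] returns a read-pair data.frame.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(id = "character", seq1 = "character",
                                         seq2 = "character", pos1 = "numeric",
                                         pos2 = "numeric", nm1 = "integer",
                                         nm2 = "integer"))
  need <- c("id", "chrom1", "pos1", "strand1", "nm1", "seq1",
            "chrom2", "pos2", "strand2", "nm2", "seq2")
  if (!all(need %in% names(df))) {
    stop("read-pair TSV lacks required columns", call. = FALSE)
  }
  df[, need]
}

#' @rdname read_pairs_tsv
#' @param pairs read-pair data.frame.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit simulated read pairs as SAM
#'
#' Minimal SAM emission (header + one line per read) for interoperability
#' with samtools-style tooling; mapping quality is fixed at 60 and CIGAR
#' at full-length match, mirroring the simulator's lifted coordinates.
#'
#' @param pairs read-pair data.frame.
#' @param lens named chromosome lengths for the `@SQ` header.
#' @param path file path.
#' @export
write_pairs_sam <- function(pairs, lens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)), con)
  emit <- function(id, chrom, pos, strand, seq, mate_chrom, mate_pos,
                   mate_strand, first) {
    flag <- 1L + 64L * first + 128L * (1 - first) +
      16L * (strand == "-") + 32L * (mate_strand == "-")
    rnext <- ifelse(mate_chrom == chrom, "=", mate_chrom)
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t%s\t%d\t0\t%s\t*", id, flag, chrom,
            as.integer(pos), nchar(seq), rnext, as.integer(mate_pos), seq)
  }
  writeLines(emit(pairs$id, pairs$chrom1, pairs$pos1, pairs$strand1, pairs$seq1,
                  pairs$chrom2, pairs$pos2, pairs$strand2, 1L), con)
  writeLines(emit(pairs$id, pairs$chrom2, pairs$pos2, pairs$strand2, pairs$seq2,
                  pairs$chrom1, pairs$pos1, pairs$strand1, 0L), con)
  invisible(path)
}

#' Read / write a pipeline configuration
#'
#' JSON with nested sections (`synthetic_data`, `sv_calling`,
#' `cna_calling`, `chromothripsis_report`) plus global `seed` and
#' `outdir`. Unknown top-level keys are rejected; round trips are
#' lossless.
#'
#' @param path file path.
#' @return [read_config()] returns the configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config configuration list (see [demo_config()]).
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

validate_config <- function(config) {
  known <- c("seed", "outdir", "synthetic_data", "sv_calling", "cna_calling",
             "chromothripsis_report")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$seed)) stop("configuration lacks a seed", call. = FALSE)
  invisible(config)
}
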