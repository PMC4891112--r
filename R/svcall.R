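#' Caller configuration
#'
#' Holds the rearrangement-identification thresholds: pairs are clustered
#' when both breakpoint footprints fall within `cluster_window` bp under
#' single linkage; candidates need at least `min_support` pairs; a pair is
#' concordant (proper) when FR-oriented within `proper_max_distance` bp;
#' the realignment filter discards pairs with a concordant local placement
#' at E-value below `evalue_threshold`; reads with more than
#' `max_mismatches` mismatches are dropped; accepted calls need at least
#' one perfect (0-mismatch) pair when `require_perfect_pair` is set.
#' `lambda` and `karlin_k` are the ungapped Karlin-Altschul parameters of
#' the blastn-like surrogate search (match +1, mismatch -2);
#' `word_size`/`seed_step` control its exact seeding.
#'
#' @param cluster_window bp, single-linkage window per breakpoint footprint.
#' @param min_support minimum supporting pairs (applied before and after
#'   the filter cascade).
#' @param proper_max_distance bp, maximum start distance of a proper pair.
#' @param evalue_threshold E-value below which a concordant re-alignment
#'   disqualifies a pair.
#' @param max_mismatches per-read mismatch tolerance.
#' @param require_perfect_pair logical.
#' @param lambda,karlin_k Karlin-Altschul statistics for E-values.
#' @param word_size,seed_step exact-seed length and stride of the
#'   realignment search.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(cluster_window = 500, min_support = 3,
                          proper_max_distance = 500, evalue_threshold = 1e-7,
                          max_mismatches = 2, require_perfect_pair = TRUE,
                          lambda = 1.33, karlin_k = 0.621,
                          word_size = 31, seed_step = 16) {
  stopifnot(cluster_window > 0, min_support >= 1, proper_max_distance > 0,
            evalue_threshold > 0, max_mismatches >= 0,
            lambda > 0, karlin_k > 0, word_size >= 8, seed_step >= 1)
  structure(list(cluster_window = cluster_window, min_support = min_support,
                 proper_max_distance = proper_max_distance,
                 evalue_threshold = evalue_threshold,
                 max_mismatches = max_mismatches,
                 require_perfect_pair = isTRUE(require_perfect_pair),
                 lambda = lambda, karlin_k = karlin_k,
                 word_size = word_size, seed_step = seed_step),
            class = "caller_config")
}

#' Classify read pairs by orientation and distance
#'
#' Mates are first put in canonical order (lower chromosome/position
#' first). A pair is `PROPER` when both mates share a chromosome in FR
#' orientation (leftmost mate forward, rightmost reverse) within
#' `proper_max_distance` bp; inter-chromosomal pairs are `CT`; FR pairs at
#' excessive distance are `LD` (long-deletion signature); RF pairs are
#' `RF_TYPE` (duplication-type); FF and RR pairs are folded into `FF_TYPE`
#' (fold-back/inversion-type, RR being the mirror of FF).
#'
#' @param pairs read-pair data.frame as from [simulate_read_pairs()] or
#'   [read_pairs_tsv()].
#' @param cfg a [caller_config()].
#' @return `pairs`, canonicalized, with a `class` column.
#' @export
classify_read_pairs <- function(pairs, cfg = caller_config()) {
  stopifnot(is.data.frame(pairs))
  chroms <- sort(unique(c(pairs$chrom1, pairs$chrom2)))
  r1 <- match(pairs$chrom1, chroms); r2 <- match(pairs$chrom2, chroms)
  swap <- r1 > r2 | (r1 == r2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    for (col in c("chrom", "pos", "strand", "nm", "seq")) {
      c1 <- paste0(col, "1"); c2 <- paste0(col, "2")
      if (!c1 %in% names(pairs)) next
      tmp <- pairs[[c1]][swap]
      pairs[[c1]][swap] <- pairs[[c2]][swap]
      pairs[[c2]][swap] <- tmp
    }
  }
  inter <- pairs$chrom1 != pairs$chrom2
  dist <- pairs$pos2 - pairs$pos1
  fr <- pairs$strand1 == "+" & pairs$strand2 == "-"
  rf <- pairs$strand1 == "-" & pairs$strand2 == "+"
  cls <- character(nrow(pairs))
  cls[inter] <- "CT"
  cls[!inter & fr & dist <= cfg$proper_max_distance] <- "PROPER"
  cls[!inter & fr & dist > cfg$proper_max_distance] <- "LD"
  cls[!inter & rf] <- "RF_TYPE"
  cls[!inter & !fr & !rf] <- "FF_TYPE"
  pairs$class <- cls
  pairs
}

#' @rdname classify_read_pairs
#' @param pair single-row data.frame.
#' @return `classify_read_pair()` returns the class string.
#' @export
classify_read_pair <- function(pair, cfg = caller_config()) {
  classify_read_pairs(pair, cfg)$class
}

## single linkage connected components over the "both footprints close"
## graph, brute force within a (class, chrom pair) group — groups are small
linkage_components <- function(p1, p2, window) {
  n <- length(p1)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    close <- abs(p1[(i + 1):n] - p1[i]) <= window &
             abs(p2[(i + 1):n] - p2[i]) <= window
    for (j in which(close) + i) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

majority <- function(x) names(sort(table(x), decreasing = TRUE))[1]

read_span <- function(seq) ifelse(!is.na(seq) & nzchar(seq), nchar(seq), 1L)

## consensus breakpoint of one footprint: innermost aligned base toward the
## junction — forward reads approach from the left (max end), reverse reads
## from the right (min start)
consensus_bp <- function(pos, strand, seq) {
  if (majority(strand) == "+") max(pos + read_span(seq) - 1) else min(pos)
}

build_cluster <- function(df) {
  structure(list(
    rtype = df$class[1], chrom1 = df$chrom1[1], chrom2 = df$chrom2[1],
    bp1 = consensus_bp(df$pos1, df$strand1, df$seq1),
    bp2 = consensus_bp(df$pos2, df$strand2, df$seq2),
    strand1 = majority(df$strand1), strand2 = majority(df$strand2),
    support = nrow(df),
    has_perfect = any(!is.na(df$nm1) & !is.na(df$nm2) & df$nm1 == 0 & df$nm2 == 0),
    pairs = df), class = "sv_cluster")
}

#' @export
print.sv_cluster <- function(x, ...) {
  cat(sprintf("<sv_cluster> %s %s:%d %s / %s:%d %s support=%d perfect=%s\n",
              x$rtype, x$chrom1, x$bp1, x$strand1, x$chrom2, x$bp2, x$strand2,
              x$support, x$has_perfect))
  invisible(x)
}

#' Cluster inconsistent (discordant) read pairs
#'
#' Pairs of identical class and chromosome assignment support the same
#' rearrangement when both breakpoint footprints lie within
#' `cluster_window` bp of each other under single linkage. Consensus
#' breakpoints take the innermost aligned base toward the junction on each
#' side.
#'
#' @param pairs classified pairs ([classify_read_pairs()]); `PROPER` rows
#'   are ignored.
#' @param cfg a [caller_config()].
#' @return list of `sv_cluster` objects, ordered by breakpoints.
#' @export
cluster_inconsistent_pairs <- function(pairs, cfg = caller_config()) {
  if (!"class" %in% names(pairs)) {
    stop("pairs must be classified first (classify_read_pairs)", call. = FALSE)
  }
  pairs <- pairs[pairs$class != "PROPER", , drop = FALSE]
  if (nrow(pairs) == 0) return(list())
  key <- paste(pairs$class, pairs$chrom1, pairs$chrom2, sep = "\r")
  clusters <- list()
  for (grp in split(pairs, key)) {
    comp <- linkage_components(grp$pos1, grp$pos2, cfg$cluster_window)
    for (sub in split(grp, comp)) {
      clusters[[length(clusters) + 1]] <- build_cluster(sub)
    }
  }
  ord <- order(vapply(clusters, `[[`, character(1), "chrom1"),
               vapply(clusters, `[[`, numeric(1), "bp1"),
               vapply(clusters, `[[`, character(1), "chrom2"),
               vapply(clusters, `[[`, numeric(1), "bp2"))
  clusters[ord]
}

#' Keep clusters with sufficient read-pair support
#' @param clusters list of `sv_cluster`.
#' @param cfg a [caller_config()]; threshold is `min_support`.
#' @return filtered list.
#' @export
filter_by_support <- function(clusters, cfg = caller_config()) {
  Filter(function(cl) cl$support >= cfg$min_support, clusters)
}

#' Remove rearrangements also present in parental samples
#'
#' A sample cluster is dropped when any parental cluster shares its class
#' and chromosome pair and has both consensus breakpoints within
#' `match_window` bp.
#'
#' @param sample list of `sv_cluster` from the sample of interest.
#' @param parental list of cluster lists, one per parental sample.
#' @param match_window bp tolerance (defaults to the cluster window).
#' @return filtered sample list; removed ids recorded in attribute
#'   `"removed"`.
#' @export
subtract_parental <- function(sample, parental, match_window = 500) {
  par <- unlist(parental, recursive = FALSE)
  keep <- vapply(sample, function(cl) {
    !any(vapply(par, function(p) {
      p$rtype == cl$rtype && p$chrom1 == cl$chrom1 && p$chrom2 == cl$chrom2 &&
        abs(p$bp1 - cl$bp1) <= match_window && abs(p$bp2 - cl$bp2) <= match_window
    }, logical(1)))
  }, logical(1))
  out <- sample[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Discard high-mismatch pairs and require a perfect pair
#'
#' Pairs in which either read carries more than `max_mismatches`
#' mismatches are removed; the cluster survives only if the remaining
#' support reaches `min_support` and (when `require_perfect_pair`) at
#' least one remaining pair is mismatch-free on both reads.
#'
#' @param cluster an `sv_cluster`.
#' @param cfg a [caller_config()].
#' @return the updated cluster, or `NULL` if it fails.
#' @export
mismatch_and_perfect_filter <- function(cluster, cfg = caller_config()) {
  df <- cluster$pairs
  ok <- !is.na(df$nm1) & !is.na(df$nm2) &
        df$nm1 <= cfg$max_mismatches & df$nm2 <= cfg$max_mismatches
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < cfg$min_support) return(NULL)
  cl <- build_cluster(df)
  if (cfg$require_perfect_pair && !cl$has_perfect) return(NULL)
  cl
}

#' Full rearrangement-identification cascade
#'
#' classify -> cluster -> support filter -> parental subtraction ->
#' realignment E-value filter -> mismatch / perfect-pair filter ->
#' typed calls with consensus breakpoints. Parental pair sets are clustered
#' without a support threshold (any parental evidence subtracts).
#' A per-stage tally is attached as attribute `"audit"`.
#'
#' @param pairs sample read pairs.
#' @param parental_pair_sets list of parental read-pair data.frames
#'   (possibly empty).
#' @param ref the reference `ref_genome` for realignment.
#' @param cfg a [caller_config()].
#' @return `sv_events`-style data.frame of calls (id, breakpoints, rtype,
#'   support), sorted by chromosome and position.
#' @export
call_rearrangements <- function(pairs, parental_pair_sets = list(), ref,
                                cfg = caller_config()) {
  audit <- list()
  cl <- cluster_inconsistent_pairs(classify_read_pairs(pairs, cfg), cfg)
  audit$clustered <- length(cl)
  cl <- filter_by_support(cl, cfg)
  audit$support <- length(cl)

  par_cl <- lapply(parental_pair_sets, function(pp) {
    cluster_inconsistent_pairs(classify_read_pairs(pp, cfg), cfg)
  })
  cl <- subtract_parental(cl, par_cl, cfg$cluster_window)
  audit$parental_subtracted <- length(cl)

  idx <- realign_index(ref)
  cl <- Filter(Negate(is.null), lapply(cl, function(x) {
    realignment_filter(x, ref, cfg, index = idx)$cluster
  }))
  audit$realignment <- length(cl)

  cl <- Filter(Negate(is.null), lapply(cl, mismatch_and_perfect_filter, cfg = cfg))
  audit$mismatch_perfect <- length(cl)

  if (length(cl) == 0) {
    out <- data.frame(id = character(0), chrom1 = character(0), pos1 = numeric(0),
                      chrom2 = character(0), pos2 = numeric(0),
                      rtype = character(0), support = integer(0))
  } else {
    out <- data.frame(
      chrom1 = vapply(cl, `[[`, character(1), "chrom1"),
      pos1 = vapply(cl, `[[`, numeric(1), "bp1"),
      chrom2 = vapply(cl, `[[`, character(1), "chrom2"),
      pos2 = vapply(cl, `[[`, numeric(1), "bp2"),
      rtype = sub("_TYPE$", "", vapply(cl, `[[`, character(1), "rtype")),
      support = vapply(cl, `[[`, integer(1), "support"),
      stringsAsFactors = FALSE)
    out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), ]
    out <- cbind(id = sprintf("SV%03d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "audit") <- data.frame(stage = names(audit),
                                   clusters = unlist(audit, use.names = FALSE))
  out
}
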