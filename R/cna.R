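#' Segmentation configuration
#'
#' Parameters of the copy-number segmentation and thresholding: a split
#' must leave at least `min_probes` probes on each side, reach two-sample
#' significance `p_threshold`, and move the mean by at least `snr` times
#' the track's robust noise SD. Segment means at or below `del_threshold`
#' are deletions, at or above `amp_threshold` amplifications.
#'
#' @param min_probes minimum probes per segment (>= 2), default 30.
#' @param p_threshold split significance, default 0.001.
#' @param snr signal-to-noise gate, default 0.3.
#' @param del_threshold,amp_threshold copy-number call thresholds,
#'   defaults 1.8 and 2.6 (inclusive).
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(min_probes = 30, p_threshold = 0.001,
                                snr = 0.3, del_threshold = 1.8,
                                amp_threshold = 2.6) {
  stopifnot(min_probes >= 2, p_threshold > 0, p_threshold < 1, snr >= 0,
            del_threshold < 2, amp_threshold > 2)
  structure(list(min_probes = as.integer(min_probes),
                 p_threshold = p_threshold, snr = snr,
                 del_threshold = del_threshold, amp_threshold = amp_threshold),
            class = "segmentation_config")
}

#' Subtract a baseline (parental) probe track
#'
#' Per-probe differential signal re-centered at two copies:
#' `sample - baseline + 2`, so alterations shared with the parental line
#' cancel and an unchanged probe reads 2.0. BAF and heterozygosity flags
#' are carried over from the sample.
#'
#' @param sample,baseline probe tracks on identical grids.
#' @return differential probe track.
#' @export
subtract_baseline <- function(sample, baseline) {
  if (nrow(sample) != nrow(baseline) ||
      !all(sample$chrom == baseline$chrom) || !all(sample$pos == baseline$pos)) {
    stop("sample and baseline probe grids differ", call. = FALSE)
  }
  out <- sample
  out$signal <- sample$signal - baseline$signal + 2
  out
}

## Segment-vs-rest Welch scan of one numeric vector: the inner segment
## [i..j] (2 <= length <= n-2) maximizing |t| against the remainder of the
## interval. Returns NULL when the interval is too short to scan.
best_inner_segment <- function(x) {
  n <- length(x)
  if (n < 4) return(NULL)
  cs <- c(0, cumsum(x)); css <- c(0, cumsum(x^2))
  best <- NULL; best_t <- -Inf
  for (i in 1:(n - 1)) {
    j <- seq.int(i + 1, n)
    L <- j - i + 1
    keep <- (n - L) >= 2
    if (!any(keep)) next
    j <- j[keep]; L <- L[keep]
    s_in <- cs[j + 1] - cs[i]; ss_in <- css[j + 1] - css[i]
    rn <- n - L
    m_in <- s_in / L; m_r <- (cs[n + 1] - s_in) / rn
    v_in <- pmax(0, (ss_in - s_in^2 / L) / (L - 1))
    v_r <- pmax(0, ((css[n + 1] - ss_in) - (cs[n + 1] - s_in)^2 / rn) / (rn - 1))
    ## pooled-variance t: with the configured minimum segment sizes it
    ## coincides with Welch, and it keeps tiny low-variance windows from
    ## dominating the unconstrained scan
    sp2 <- ((L - 1) * v_in + (rn - 1) * v_r) / (n - 2)
    se2 <- sp2 * (1 / L + 1 / rn)
    tt <- ifelse(se2 > 0, abs(m_in - m_r) / sqrt(se2),
                 ifelse(m_in != m_r, Inf, 0))
    k <- which.max(tt)
    if (tt[k] > best_t) {
      best_t <- tt[k]
      best <- list(i = i, j = j[k], t = tt[k], delta = abs(m_in[k] - m_r[k]),
                   L = L[k], rn = rn[k])
    }
  }
  if (is.null(best)) return(NULL)
  best$p <- if (is.infinite(best$t)) 0 else if (best$t == 0) 1 else {
    2 * stats::pt(-best$t, n - 2)
  }
  best
}

#' Segment a probe track
#'
#' Deterministic recursive segmentation per chromosome, a functional
#' surrogate for a proprietary genomic-segmentation method (not a clone).
#' Within each interval the inner segment maximizing the Welch two-sample
#' t statistic against the rest of the interval is located without any
#' length constraint; the interval is split (into the segment and its
#' flanks, each recursed) only when that most significant region spans at
#' least `min_probes` probes, reaches `p_threshold` significance, and
#' moves the mean by at least `snr` times the robust noise SD of the
#' track (median absolute deviation of first differences divided by
#' sqrt(2)). A dominant region shorter than `min_probes` stops the
#' recursion — a sub-minimal region is not identifiable as an alteration,
#' and no blurred larger surrogate is reported in its place. When the
#' best region abuts an interval edge this reduces to a plain binary
#' split with both sides at least `min_probes`. Chromosomes with fewer
#' than `2 * min_probes` probes come back as a single segment.
#'
#' @param track a probe track ([simulate_probe_track()] /
#'   [subtract_baseline()]).
#' @param cfg a [segmentation_config()].
#' @return data.frame of segments: `chrom`, `start`, `end` (positions of
#'   the first and last probe), `mean_copy`, `n_probes`.
#' @export
segment_probe_track <- function(track, cfg = segmentation_config()) {
  stopifnot(all(c("chrom", "pos", "signal") %in% names(track)))
  diffs <- unlist(lapply(split(track$signal, track$chrom), diff), use.names = FALSE)
  sigma <- if (length(diffs) > 0) stats::mad(diffs) / sqrt(2) else 0
  out <- list()
  for (chrom in unique(track$chrom)) {
    tr <- track[track$chrom == chrom, , drop = FALSE]
    tr <- tr[order(tr$pos), , drop = FALSE]
    x <- tr$signal
    stack <- list(c(1L, length(x)))
    bounds <- list()
    while (length(stack) > 0) {
      iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      lo <- iv[1]; hi <- iv[2]
      bs <- if (hi - lo + 1 >= 2 * cfg$min_probes) best_inner_segment(x[lo:hi]) else NULL
      accept <- !is.null(bs) && bs$p < cfg$p_threshold &&
        bs$delta >= cfg$snr * sigma && bs$L >= cfg$min_probes
      if (accept) {
        i <- lo + bs$i - 1L; j <- lo + bs$j - 1L
        if (i > lo) stack[[length(stack) + 1]] <- c(lo, i - 1L)
        stack[[length(stack) + 1]] <- c(i, j)
        if (j < hi) stack[[length(stack) + 1]] <- c(j + 1L, hi)
      } else {
        bounds[[length(bounds) + 1]] <- c(lo, hi)
      }
    }
    bounds <- bounds[order(vapply(bounds, `[`, integer(1), 1))]
    for (bv in bounds) {
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = tr$pos[bv[1]], end = tr$pos[bv[2]],
        mean_copy = mean(x[bv[1]:bv[2]]), n_probes = bv[2] - bv[1] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Threshold segments into Amp/Del calls
#'
#' `DEL` at or below `del_threshold`, `AMP` at or above `amp_threshold`,
#' otherwise `NEUTRAL`; adjacent same-call segments are merged (probe-count
#' weighted mean). Lengths follow the `end - start` convention.
#'
#' @param segments output of [segment_probe_track()].
#' @param cfg a [segmentation_config()].
#' @return data.frame: `chrom`, `start`, `end`, `mean_copy`, `call`,
#'   `n_probes`, `length`.
#' @export
call_cnas <- function(segments, cfg = segmentation_config()) {
  merge_runs <- function(seg) {
    out <- list()
    for (chrom in unique(seg$chrom)) {
      s <- seg[seg$chrom == chrom, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      grp <- cumsum(c(TRUE, s$call[-1] != s$call[-nrow(s)]))
      for (g in split(s, grp)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, start = min(g$start), end = max(g$end),
          mean_copy = sum(g$mean_copy * g$n_probes) / sum(g$n_probes),
          call = g$call[1], n_probes = sum(g$n_probes),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  seg <- segments
  seg$call <- ifelse(seg$mean_copy <= cfg$del_threshold, "DEL",
                     ifelse(seg$mean_copy >= cfg$amp_threshold, "AMP", "NEUTRAL"))
  out <- merge_runs(seg)
  ## an alteration needs at least min_probes probes to be identified
  short <- out$call != "NEUTRAL" & out$n_probes < cfg$min_probes
  if (any(short)) {
    out$call[short] <- "NEUTRAL"
    out <- merge_runs(out)
  }
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Summarize CNA burden across sublines
#'
#' @param per_subline_calls named list: subline -> [call_cnas()] output.
#' @return list: `n_with_cna`, `n_total`, `fraction`, `percent` (rounded),
#'   and `per_chromosome` counts of non-neutral calls.
#' @export
summarize_cna_burden <- function(per_subline_calls) {
  has <- vapply(per_subline_calls, function(x) {
    !is.null(x) && nrow(x) > 0 && any(x$call != "NEUTRAL")
  }, logical(1))
  nonneutral <- lapply(per_subline_calls, function(x) {
    if (is.null(x)) return(character(0))
    x$chrom[x$call != "NEUTRAL"]
  })
  per_chrom <- table(unlist(nonneutral))
  n <- length(per_subline_calls)
  frac <- if (n == 0) 0 else mean(has)
  list(n_with_cna = sum(has), n_total = n, fraction = frac,
       percent = round(100 * frac),
       per_chromosome = per_chrom)
}
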