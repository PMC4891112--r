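#' Simulate an SNP-probe copy-number / BAF track
#'
#' Probes are placed every `probe_spacing` bp along each chromosome. The
#' copy-number signal is 2.0 outside truth segments and the segment's
#' `copy` inside, plus Gaussian noise. A `het_fraction` of probes is
#' heterozygous in the germline: their BAF sits near 0.5 in balanced
#' two-copy regions, near 1/3 or 2/3 in three-copy regions that retain
#' both parental alleles, and collapses to {0, 1} in LOH regions
#' (truth segments with `loh = TRUE`, by default deletions). Homozygous
#' probes read near 0 or 1 everywhere.
#'
#' @param ref a `ref_genome` or a named vector of chromosome lengths (the
#'   probe model needs coordinates only).
#' @param cna_truth data.frame with columns `chrom`, `start`, `end`,
#'   `copy`, optional `loh`; may have zero rows.
#' @param probe_spacing probe spacing in bp (> 0).
#' @param noise_sd Gaussian noise SD of the copy-number signal, copy units.
#' @param het_fraction proportion of heterozygous (informative) probes.
#' @param seed integer seed.
#' @param baf_noise_sd Gaussian noise SD of the BAF (clamped to `[0, 1]`).
#' @return data.frame: `chrom`, `pos`, `signal`, `baf`, `is_het`.
#' @export
simulate_probe_track <- function(ref, cna_truth = NULL, probe_spacing = 1000,
                                 noise_sd = 0.3, het_fraction = 0.3, seed = 1L,
                                 baf_noise_sd = 0.02) {
  lens <- if (inherits(ref, "ref_genome")) chrom_lengths(ref) else ref
  stopifnot(is.numeric(lens), !is.null(names(lens)))
  if (probe_spacing <= 0) stop("probe_spacing must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (het_fraction < 0 || het_fraction > 1) stop("het_fraction must be in [0,1]", call. = FALSE)
  if (is.null(cna_truth)) {
    cna_truth <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), copy = numeric(0))
  }
  if (nrow(cna_truth) > 0) {
    if (is.null(cna_truth$loh)) cna_truth$loh <- cna_truth$copy < 2
    bad <- !cna_truth$chrom %in% names(lens) |
      cna_truth$start < 1 | cna_truth$end > lens[cna_truth$chrom]
    if (any(bad)) stop("truth segments outside chromosome bounds", call. = FALSE)
  }
  with_seed(seed, {
    tracks <- lapply(names(lens), function(chrom) {
      pos <- seq(probe_spacing, lens[[chrom]], by = probe_spacing)
      n <- length(pos)
      if (n == 0) return(NULL)
      copy <- rep(2.0, n)
      loh <- rep(FALSE, n)
      seg <- cna_truth[cna_truth$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(seg))) {
        inside <- pos >= seg$start[i] & pos <= seg$end[i]
        copy[inside] <- seg$copy[i]
        loh[inside] <- seg$loh[i]
      }
      is_het <- stats::runif(n) < het_fraction
      baf_center <- numeric(n)
      hom_allele <- stats::runif(n) < 0.5
      baf_center[!is_het] <- ifelse(hom_allele[!is_het], 1, 0)
      het_allele <- stats::runif(n) < 0.5
      centers <- ifelse(loh, ifelse(het_allele, 1, 0),
                        ifelse(copy >= 2.5, ifelse(het_allele, 2 / 3, 1 / 3), 0.5))
      baf_center[is_het] <- centers[is_het]
      signal <- copy + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
      baf <- baf_center + if (baf_noise_sd > 0) stats::rnorm(n, 0, baf_noise_sd) else 0
      data.frame(chrom = chrom, pos = pos, signal = signal,
                 baf = pmin(1, pmax(0, baf)), is_het = is_het,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tracks)
    rownames(out) <- NULL
    out
  })
}
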