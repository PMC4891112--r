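#' Default pipeline configuration
#'
#' The stated demonstration world: the bundled 14-event / 16-segment case
#' rescaled to desk scale, 125 bp error-free pairs at 30x with
#' 300 +/- 30 bp inserts, probe tracks at 1 kb spacing with 0.3-copy
#' noise, and the published caller / segmentation thresholds.
#'
#' @param seed global seed.
#' @param outdir output directory.
#' @return nested configuration list (see [read_config()]).
#' @export
demo_config <- function(seed = 1L, outdir = file.path(tempdir(), "chromoshatter_run")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic_data = list(
      coverage = 30, read_length = 125, insert_mean = 300, insert_sd = 30,
      error_rate = 0, decoy_length = 25000, gc_fraction = 0.41,
      probe_spacing = 1000, probe_noise_sd = 0.3, het_fraction = 0.3,
      seg_probes = 60, gap_probes = 45
    ),
    sv_calling = list(
      cluster_window = 500, min_support = 3, proper_max_distance = 500,
      evalue_threshold = 1e-7, max_mismatches = 2, require_perfect_pair = TRUE
    ),
    cna_calling = list(
      min_probes = 30, p_threshold = 0.001, snr = 0.3,
      del_threshold = 1.8, amp_threshold = 2.6
    ),
    chromothripsis_report = list(
      n_perm = 2000, flag_min_breakpoints = 3, p_threshold = 0.05,
      min_oscillations = 2, baf_low = 0.15
    )
  )
}

#' Simulate the full demonstration case
#'
#' Builds everything the downstream stages consume, truth-known: the
#' bundled 14 rearrangements rescaled onto synthetic chromosomes (decoy
#' chromosomes fill out the karyotype so breakpoint localization has a
#' meaningful universe), a chemistry-retrofitted reference, the derivative
#' genome of the irradiated sample, reads for the sample and two parental
#' samples, and probe tracks (sample with the bundled 16 segments planted,
#' flat parental baseline). `parental_shared_events` are additionally
#' planted in both the sample and the parentals (to exercise parental
#' subtraction).
#'
#' @param seed integer seed; every stage derives its own stream from it.
#' @param coverage fold coverage (30 is the stated world; lower it for
#'   quick structural tests).
#' @param read_length,insert_mean,insert_sd,error_rate read simulation.
#' @param decoy_length bp length of breakpoint-free karyotype filler.
#' @param gc_fraction base composition.
#' @param probe_spacing,probe_noise_sd,het_fraction,seg_probes,gap_probes
#'   probe-track world.
#' @param parental_shared_events optional `sv_events` in rescaled
#'   coordinates, planted in sample and parentals alike.
#' @return list with `events`, `truth`, `chrom_lengths`, `reference`,
#'   `genome`, `reads` (sample / parental1 / parental2), `probe`
#'   (chrom_lengths, segments, track, baseline), `params`.
#' @export
simulate_case <- function(seed = 1L, coverage = 30, read_length = 125,
                          insert_mean = 300, insert_sd = 30, error_rate = 0,
                          decoy_length = 25000, gc_fraction = 0.41,
                          probe_spacing = 1000, probe_noise_sd = 0.3,
                          het_fraction = 0.3, seg_probes = 60, gap_probes = 45,
                          parental_shared_events = NULL) {
  resc <- rescale_breakpoints(example_events())
  karyotype <- paste0("chr", c(1:22, "X"))
  decoys <- setdiff(karyotype, names(resc$chrom_lengths))
  lens <- c(resc$chrom_lengths,
            stats::setNames(rep(decoy_length, length(decoys)), decoys))
  lens <- lens[order(match(names(lens), karyotype))]
  ref0 <- generate_reference(lens, gc_fraction, sub_seed(seed, "reference"))

  all_events <- resc$events
  if (!is.null(parental_shared_events)) {
    all_events <- rbind(parental_shared_events, resc$events)
    class(all_events) <- c("sv_events", "data.frame")
  }
  planted <- plant_rearrangements(ref0, all_events, on_conflict = "new_copy")
  parental_genome <- if (is.null(parental_shared_events)) {
    planted$reference
  } else {
    plant_rearrangements(planted$reference, parental_shared_events,
                         on_conflict = "new_copy")$genome
  }
  pp <- function(label) {
    read_sim_params(read_length, insert_mean, insert_sd, coverage, error_rate,
                    seed = sub_seed(seed, label))
  }
  reads <- list(
    sample = simulate_read_pairs(planted$genome, pp("sample")),
    parental1 = simulate_read_pairs(parental_genome, pp("parental1")),
    parental2 = simulate_read_pairs(parental_genome, pp("parental2"))
  )
  cresc <- rescale_cna_segments(example_cna_segments(), seg_probes, gap_probes,
                                probe_spacing)
  probe <- list(
    chrom_lengths = cresc$chrom_lengths,
    segments = cresc$segments,
    track = simulate_probe_track(cresc$chrom_lengths, cresc$segments,
                                 probe_spacing, probe_noise_sd, het_fraction,
                                 seed = sub_seed(seed, "probes")),
    baseline = simulate_probe_track(cresc$chrom_lengths, NULL, probe_spacing,
                                    probe_noise_sd, het_fraction,
                                    seed = sub_seed(seed, "baseline"))
  )
  denovo <- planted$truth[planted$truth$id %in% resc$events$id, , drop = FALSE]
  list(seed = seed, events = resc$events, rescale_map = resc$map,
       shared_events = parental_shared_events,
       chrom_lengths = lens, reference = planted$reference,
       genome = planted$genome, truth = planted$truth, truth_denovo = denovo,
       reads = reads, probe = probe)
}

#' Match rearrangement calls to a truth table
#'
#' A call matches a truth event when class and (canonically ordered)
#' chromosome pair agree and both breakpoints fall within `window` bp.
#'
#' @param calls caller output ([call_rearrangements()]).
#' @param truth `sv_events`-style truth.
#' @param window matching tolerance, bp.
#' @return `calls` with a `truth_id` column (`NA` = false positive).
#' @export
match_calls_to_truth <- function(calls, truth, window = 500) {
  canon <- truth
  swap <- canon$chrom1 > canon$chrom2
  tmpc <- canon$chrom1[swap]; canon$chrom1[swap] <- canon$chrom2[swap]
  canon$chrom2[swap] <- tmpc
  tmpp <- canon$pos1[swap]; canon$pos1[swap] <- canon$pos2[swap]
  canon$pos2[swap] <- tmpp
  calls$truth_id <- NA_character_
  for (i in seq_len(nrow(calls))) {
    hit <- which(canon$rtype == calls$rtype[i] &
                 canon$chrom1 == calls$chrom1[i] &
                 canon$chrom2 == calls$chrom2[i] &
                 abs(canon$pos1 - calls$pos1[i]) <= window &
                 abs(canon$pos2 - calls$pos2[i]) <= window)
    if (length(hit) > 0) calls$truth_id[i] <- canon$id[hit[1]]
  }
  calls
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' simulate -> call-cna -> call-sv -> junctions -> assess, writing every
#' artifact under `config$outdir` plus a provenance manifest (seed, config
#' hash, package version, per-stage outputs). Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param config configuration list (see [demo_config()] / [read_config()]).
#' @return invisible list with in-memory results (`case`, `cna_calls`,
#'   `sv_calls`, `junction_report`, `report`, `manifest`).
#' @export
run_pipeline <- function(config = demo_config()) {
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.json")
  write_config(config, cfg_path)
  manifest <- list(
    package = "chromoshatter",
    version = as.character(utils::packageVersion("chromoshatter")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = list()
  )
  sd <- config$synthetic_data
  case <- run_stage("simulate", do.call(simulate_case, c(list(seed = config$seed), sd)))
  files <- c(reference = "reference.fa", derivative = "derivative.fa",
             truth = "truth.bedpe", sample_pairs = "sample_pairs.tsv",
             probe_track = "probe_track.tsv", probe_baseline = "probe_baseline.tsv")
  run_stage("simulate", {
    write_fasta(case$reference, file.path(outdir, files["reference"]))
    write_fasta(case$genome, file.path(outdir, files["derivative"]))
    write_bedpe(case$truth, file.path(outdir, files["truth"]))
    write_pairs_tsv(case$reads$sample, file.path(outdir, files["sample_pairs"]))
    write_probe_tsv(case$probe$track, file.path(outdir, files["probe_track"]))
    write_probe_tsv(case$probe$baseline, file.path(outdir, files["probe_baseline"]))
  })
  manifest$stages$simulate <- unname(files)

  ccfg <- do.call(segmentation_config, config$cna_calling)
  cna <- run_stage("call-cna", {
    diff <- subtract_baseline(case$probe$track, case$probe$baseline)
    calls <- call_cnas(segment_probe_track(diff, ccfg), ccfg)
    write_seg(calls, file.path(outdir, "cna_calls.seg"), sample = "sample")
    list(diff = diff, calls = calls)
  })
  manifest$stages$`call-cna` <- "cna_calls.seg"

  scfg <- do.call(caller_config, config$sv_calling)
  sv <- run_stage("call-sv", {
    calls <- call_rearrangements(case$reads$sample,
                                 case$reads[c("parental1", "parental2")],
                                 case$reference, scfg)
    write_bedpe(calls, file.path(outdir, "sv_calls.bedpe"))
    utils::write.table(attr(calls, "audit"), file.path(outdir, "sv_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })
  manifest$stages$`call-sv` <- c("sv_calls.bedpe", "sv_audit.tsv")

  jrep <- run_stage("junctions", {
    matched <- match_calls_to_truth(sv, case$truth, scfg$cluster_window)
    jc <- classify_planted_junctions(list(genome = case$genome,
                                          reference = case$reference,
                                          truth = case$truth))
    jc <- jc[jc$event_id %in% matched$truth_id, , drop = FALSE]
    utils::write.table(jc, file.path(outdir, "junctions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jc
  })
  manifest$stages$junctions <- "junctions.tsv"

  rcfg <- config$chromothripsis_report
  report <- run_stage("assess", {
    rep <- assess_chromothripsis(
      sv, cna$calls, cna$diff, case$chrom_lengths,
      n_perm = rcfg$n_perm, seed = sub_seed(config$seed, "assess"),
      flag_min_breakpoints = rcfg$flag_min_breakpoints,
      p_threshold = rcfg$p_threshold,
      min_oscillations = rcfg$min_oscillations, baf_low = rcfg$baf_low)
    utils::write.table(rep, file.path(outdir, "chromothripsis_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    links <- sv[, c("chrom1", "pos1", "chrom2", "pos2", "rtype")]
    utils::write.table(links, file.path(outdir, "links.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rep
  })
  manifest$stages$assess <- c("chromothripsis_report.tsv", "links.tsv")

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(case = case, cna_calls = cna$calls, sv_calls = sv,
                 junction_report = jrep, report = report, manifest = manifest,
                 outdir = outdir))
}

#' Read / write probe tracks as TSV
#' @param path file path.
#' @return [read_probe_tsv()] returns a probe-track data.frame.
#' @export
read_probe_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "signal", "baf", "is_het")
  if (!all(need %in% names(df))) stop("probe TSV lacks required columns", call. = FALSE)
  df[, need]
}

#' @rdname read_probe_tsv
#' @param track probe-track data.frame.
#' @export
write_probe_tsv <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (full pipeline), `simulate`, `call-cna`,
#' `call-sv`, `junctions`, `assess`. Invoke as
#' `Rscript -e 'chromoshatter::cli_main()' run-all --seed 1 --outdir out`.
#'
#' @param args character vector of arguments (default: command line).
#' @return invisibly, the subcommand's result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: <run-all|simulate|call-cna|call-sv|junctions|assess> [options]")
    return(invisible(NULL))
  }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(...) {
    optparse::parse_args(optparse::OptionParser(option_list = list(...)),
                         args = rest)
  }
  o <- function(flag, type = "character", default = NULL) {
    optparse::make_option(flag, type = type, default = default)
  }
  res <- switch(cmd,
    "run-all" = ,
    "simulate" = {
      op <- opt(o("--config"), o("--seed", "integer", 1L),
                o("--outdir", default = "chromoshatter_run"),
                o("--coverage", "double", NA))
      config <- if (!is.null(op$config)) read_config(op$config) else demo_config()
      config$seed <- op$seed
      config$outdir <- op$outdir
      if (!is.na(op$coverage)) config$synthetic_data$coverage <- op$coverage
      run_pipeline(config)
    },
    "call-cna" = {
      op <- opt(o("--track"), o("--baseline"), o("--out", default = "cna_calls.seg"))
      track <- read_probe_tsv(op$track)
      if (!is.null(op$baseline)) {
        track <- subtract_baseline(track, read_probe_tsv(op$baseline))
      }
      calls <- call_cnas(segment_probe_track(track))
      write_seg(calls, op$out)
      calls
    },
    "call-sv" = {
      op <- opt(o("--pairs"), o("--parental"), o("--ref"),
                o("--out", default = "sv_calls.bedpe"))
      parental <- if (is.null(op$parental)) list() else {
        lapply(strsplit(op$parental, ",")[[1]], read_pairs_tsv)
      }
      calls <- call_rearrangements(read_pairs_tsv(op$pairs), parental,
                                   read_fasta(op$ref))
      write_bedpe(calls, op$out)
      calls
    },
    "junctions" = {
      op <- opt(o("--calls"), o("--ref"), o("--seqs"),
                o("--out", default = "junctions.tsv"))
      calls <- read_bedpe(op$calls)
      ref <- read_fasta(op$ref)
      amplicons <- read_fasta(op$seqs)
      rows <- lapply(intersect(calls$id, names(amplicons)), function(id) {
        ev <- calls[calls$id == id, ]
        be <- junction_breakends(ev)
        classify_junction(amplicons[[id]], ref, be$side1, be$side2,
                          event_id = id)
      })
      out <- do.call(rbind, rows)
      utils::write.table(out, op$out, sep = "\t", quote = FALSE, row.names = FALSE)
      out
    },
    "assess" = {
      op <- opt(o("--calls"), o("--cna"), o("--track"), o("--ref"),
                o("--out", default = "chromothripsis_report.tsv"),
                o("--seed", "integer", 1L))
      rep <- assess_chromothripsis(
        read_bedpe(op$calls),
        if (is.null(op$cna)) NULL else read_seg(op$cna),
        if (is.null(op$track)) NULL else read_probe_tsv(op$track),
        chrom_lengths(read_fasta(op$ref)), seed = op$seed)
      utils::write.table(rep, op$out, sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(res)
}
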