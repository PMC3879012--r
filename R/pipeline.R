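# End-to-end orchestration: configuration, the simulate -> quantify ->
# discover -> stress-compare -> motifs composition, output manifest.

#' Default pipeline configuration
#'
#' A single declarative list driving [run_pipeline()]. Every stage parameter
#' has an explicit default here and is echoed into the run report so a run is
#' self-documenting.
#'
#' @param outdir Output directory.
#' @param seed RNG seed (mandatory in simulate mode).
#' @param mode `"simulate"` (generate data, then analyze) or `"analyze"`
#'   (consume files named under `paths`).
#' @return Nested configuration list.
#' @export
default_config <- function(outdir, seed = 1, mode = "simulate") {
  list(
    mode = mode, outdir = outdir, seed = seed,
    paths = list(annotation = NULL, genome = NULL, reads_dir = NULL,
                 design = NULL),
    simulate = list(n_operons = 48, n_srnas = 20, n_decoys = 10, n_known = 5,
                    n_structural = 4, gc = 0.29, contig_length = 120000,
                    hfq_fraction = 0.5, replicates = 2,
                    times = c(15, 30, 60, 75), depth = 50000,
                    dispersion = 0.05, noise_rate = 0.005, write_reads = FALSE),
    quantify = list(min_overlap_frac = 0.5),
    discover = list(min_count = 50, min_library_fraction = NULL, flank = 50,
                    dominance = 0.8, neighbor_min = 50),
    de = list(alpha = 0.05, pseudocount = 1, fdr = FALSE, min_disp = 0.01),
    cluster = list(distance = "pearson", linkage = "average", k = 4),
    motifs = list(stem_min = 6, stem_max = 12, loop_min = 3, loop_max = 10,
                  max_mismatch = 1, allow_wobble = TRUE, tail_gap = 3,
                  score_min = 8, tail_min_u = 5, tail_window = 10,
                  up_window = 25, u_rich_min = 0.40, au_rich_min = 0.70,
                  spacer_min = 15, spacer_max = 19, upstream_scan = 60))
}

#' Read a configuration file (YAML)
#'
#' Values in the file override the defaults from [default_config()]; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$outdir)) .stopf("config must set 'outdir'")
  cfg <- default_config(user$outdir,
                        seed = if (!is.null(user$seed)) user$seed else 1,
                        mode = if (!is.null(user$mode)) user$mode else "simulate")
  merge_into <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!(k %in% names(base)))
        .stopf("unknown config key: %s%s", prefix, k)
      if (is.list(base[[k]]) && is.list(upd[[k]]))
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(prefix, k, "."))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  merge_into(cfg, user)
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  if (!config$mode %in% c("simulate", "analyze"))
    .stopf("mode must be 'simulate' or 'analyze'")
  if (config$mode == "simulate" &&
      (is.null(config$seed) || !.is_count(config$seed)))
    .stopf("seed is mandatory in simulate mode")
  d <- config$discover
  if (d$min_count < 0 || d$dominance < 0 || d$dominance > 1 || d$flank < 1)
    .stopf("discover thresholds out of bounds")
  if (config$de$alpha <= 0 || config$de$alpha > 1)
    .stopf("de$alpha out of bounds")
  invisible(config)
}

# Extract planted/candidate sRNA sequences from the contig sequence.
.extract_seqs <- function(sequence, df) {
  stats::setNames(substring(sequence, df$start + 1L, df$end), df$id)
}

#' Run the full pipeline
#'
#' Executes (optionally) the synthetic-data generator, then quantification,
#' candidate discovery, differential expression and clustering, and
#' sequence-level motif characterization, writing all tables plus a manifest
#' of MD5 content hashes under `config$outdir`. With identical configuration
#' and seed the manifest is identical.
#'
#' @param config Configuration list from [default_config()]/[read_config()].
#' @return Invisibly, a `run_report`: `summary` (headline counts), `manifest`
#'   (file, md5), `config`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path) written <<- c(written, path)

  if (config$mode == "simulate") {
    .msgf("[simulate] generating genome and counts (seed %d)", config$seed)
    sp <- config$simulate
    gen <- simulate_genome(n_operons = sp$n_operons, n_srnas = sp$n_srnas,
                           n_decoys = sp$n_decoys, n_known = sp$n_known,
                           n_structural = sp$n_structural, gc = sp$gc,
                           contig_length = sp$contig_length,
                           hfq_fraction = sp$hfq_fraction, seed = config$seed)
    annotation <- gen$annotation
    truth <- gen$truth
    design <- study_design(replicates = sp$replicates, times = sp$times,
                           depth = sp$depth)
    sim <- simulate_counts(design, annotation, truth,
                           dispersion = sp$dispersion, depth = sp$depth,
                           noise_rate = sp$noise_rate, seed = config$seed + 1L)
    readsets <- sim$readsets
    emit(write_genome_fasta(annotation, file.path(outdir, "genome.fa")))
    emit(write_annotation_gff3(annotation, file.path(outdir, "annotation.gff3")))
    emit(.write_tsv(truth, file.path(outdir, "truth.tsv")))
    emit(.write_tsv(design, file.path(outdir, "design.tsv")))
    emit(write_bed_track(annotation$predicted_srnas, annotation$contig_id,
                         file.path(outdir, "predictions.bed")))
    if (isTRUE(sp$write_reads)) {
      write_readsets_bed(readsets, annotation$contig_id,
                         file.path(outdir, "reads"))
      for (f in list.files(file.path(outdir, "reads"), full.names = TRUE)) emit(f)
    }
  } else {
    .msgf("[load] reading inputs")
    p <- config$paths
    if (is.null(p$annotation) || is.null(p$reads_dir) || is.null(p$design))
      .stopf("analyze mode needs paths: annotation, reads_dir, design")
    sequence <- if (!is.null(p$genome)) unname(read_genome_fasta(p$genome)[1]) else NULL
    annotation <- read_annotation_gff3(p$annotation, sequence = sequence)
    design <- .read_tsv(p$design)
    readsets <- read_readsets_bed(p$reads_dir)
    if (!all(design$library_id %in% names(readsets)))
      .stopf("design lists libraries with no read BED file")
    readsets <- readsets[design$library_id]
    truth <- NULL
  }

  .msgf("[quantify] counting %d libraries", length(readsets))
  iors <- derive_iors(annotation)
  emit(write_ior_table(iors, file.path(outdir, "iors.tsv")))
  cm <- build_count_matrix(readsets, annotation, iors,
                           config$quantify$min_overlap_frac)
  emit(write_count_matrix(cm, file.path(outdir, "counts.tsv")))

  .msgf("[discover] calling candidates")
  preds <- annotation$predicted_srnas
  excl <- character()
  if (nrow(annotation$known_srnas) > 0L && nrow(preds) > 0L) {
    ov <- IRanges::findOverlaps(
      .as_iranges(preds$start, preds$end),
      .as_iranges(annotation$known_srnas$start, annotation$known_srnas$end))
    excl <- unique(preds$id[S4Vectors::queryHits(ov)])
  }
  dg <- config$discover
  ledger <- discover_candidates(cm, iors, readsets, preds, exclude_ids = excl,
                                min_count = dg$min_count,
                                min_library_fraction = dg$min_library_fraction,
                                w = dg$flank, dominance = dg$dominance,
                                neighbor_min = dg$neighbor_min,
                                orfs = annotation$orfs)
  emit(.write_tsv(ledger, file.path(outdir, "candidates.tsv")))
  novel <- ledger[ledger$status == "novel_srna", , drop = FALSE]
  if (nrow(novel) > 0L) {
    emit(write_bed_track(
      data.frame(id = novel$assigned_name, start = novel$start,
                 end = novel$end, strand = "."),
      annotation$contig_id, file.path(outdir, "novel_srnas.bed")))
  }

  # the expression set: known sRNAs + novel candidates (counted on their IORs)
  srna_ids <- c(annotation$known_srnas$id, novel$id)
  display <- c(annotation$known_srnas$id, novel$assigned_name)
  de <- NULL; desum <- NULL; clres <- NULL
  if (length(srna_ids) > 0L) {
    .msgf("[stresscompare] %d sRNA features", length(srna_ids))
    sf <- size_factors(cm)
    de <- call_de(cm, design, features = srna_ids, alpha = config$de$alpha,
                  sf = sf, pseudocount = config$de$pseudocount,
                  fdr = config$de$fdr)
    de$display_id <- display[match(de$feature_id, srna_ids)]
    emit(.write_tsv(de, file.path(outdir, "de.tsv")))
    desum <- de_summary(de)
    emit(.write_tsv(desum, file.path(outdir, "de_summary.tsv")))
    rm_ <- ratio_matrix(cm, design, features = srna_ids, sf = sf,
                        pseudocount = config$de$pseudocount)
    rdf <- data.frame(feature_id = srna_ids, display_id = display,
                      rm_$ratios, check.names = FALSE)
    emit(.write_tsv(rdf, file.path(outdir, "ratios.tsv")))
    if (length(srna_ids) >= 2L) {
      clres <- hcluster(rm_, distance = config$cluster$distance,
                        linkage = config$cluster$linkage, k = config$cluster$k)
      emit(.write_tsv(data.frame(feature_id = srna_ids, display_id = display,
                                 cluster = clres$labels),
                      file.path(outdir, "clusters.tsv")))
      phy <- ape::as.phylo(clres$tree)
      ape::write.tree(phy, file.path(outdir, "tree.nwk"))
      emit(file.path(outdir, "tree.nwk"))
    }
    pr <- percentile_rank(cm$counts[srna_ids, , drop = FALSE], sf = sf)
    emit(.write_tsv(data.frame(feature_id = srna_ids, display_id = display,
                               pr, check.names = FALSE),
                    file.path(outdir, "percentiles.tsv")))
  }

  # sequence-level characterization (needs the contig sequence)
  hfq <- NULL; proms <- NULL; terms <- NULL
  if (!is.null(annotation$sequence) && length(srna_ids) > 0L) {
    .msgf("[motifs] characterizing %d sRNA sequences", length(srna_ids))
    mo <- config$motifs
    sr_iv <- rbind(
      annotation$known_srnas[, c("id", "start", "end")],
      if (nrow(novel) > 0L) {
        # novel sRNA boundaries = the overlapping prediction's interval
        first_pred <- vapply(strsplit(novel$predictions_in_ior, ","), `[`,
                             character(1), 1)
        pi <- match(first_pred, preds$id)
        data.frame(id = novel$id, start = preds$start[pi], end = preds$end[pi])
      })
    seqs <- .extract_seqs(annotation$sequence, sr_iv)
    names(seqs) <- display
    term_par <- mo[c("stem_min", "stem_max", "loop_min", "loop_max",
                     "max_mismatch", "allow_wobble", "tail_gap", "score_min")]
    terms <- do.call(rbind, lapply(names(seqs), function(id) {
      h <- tryCatch(do.call(find_terminators, c(list(seqs[[id]]), term_par)),
                    error = function(e) NULL)
      if (is.null(h) || nrow(h) == 0L) return(NULL)
      cbind(srna_id = id, h[1, , drop = FALSE])
    }))
    if (!is.null(terms)) emit(.write_tsv(terms, file.path(outdir, "terminators.tsv")))
    hfq <- do.call(classify_hfq_set,
                   c(list(seqs), mo[c("tail_min_u", "tail_window", "up_window",
                                      "u_rich_min", "au_rich_min")], term_par))
    emit(.write_tsv(hfq, file.path(outdir, "hfq.tsv")))
    ps <- sigma_a_pssms()
    up <- data.frame(id = names(seqs),
                     start = pmax(0L, sr_iv$start - mo$upstream_scan),
                     end = sr_iv$start)
    up <- up[up$end - up$start >= ncol(ps$p35$mat) + mo$spacer_min + ncol(ps$p10$mat), ,
             drop = FALSE]
    proms <- do.call(rbind, lapply(seq_len(nrow(up)), function(i) {
      h <- scan_promoter(substring(annotation$sequence, up$start[i] + 1L, up$end[i]),
                         ps$p35, ps$p10, mo$spacer_min, mo$spacer_max)
      if (nrow(h) == 0L) return(NULL)
      cbind(srna_id = up$id[i], h[1, , drop = FALSE])
    }))
    if (!is.null(proms)) emit(.write_tsv(proms, file.path(outdir, "promoters.tsv")))
  }

  manifest <- data.frame(file = basename(sort(unique(written))),
                         md5 = unname(tools::md5sum(sort(unique(written)))),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  summary <- list(
    n_libraries = length(readsets),
    n_iors = nrow(iors),
    n_expressed_iors = sum(ledger$passed_threshold),
    n_candidates = sum(ledger$passed_threshold & nzchar(ledger$predictions_in_ior)),
    n_fp_utr = sum(ledger$status == "fp_utr"),
    n_novel_srnas = sum(ledger$status == "novel_srna"),
    n_srnas_profiled = length(srna_ids),
    n_de_calls = if (!is.null(de)) sum(de$significant) else 0L,
    n_hfq_targets = if (!is.null(hfq)) sum(hfq$is_hfq_target) else 0L)
  report <- structure(list(summary = summary, manifest = manifest,
                           config = config, truth = truth, ledger = ledger,
                           de_summary = desum),
                      class = "run_report")
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (k in names(x$summary)) cat(sprintf("  %-18s %s\n", k, x$summary[[k]]))
  invisible(x)
}
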