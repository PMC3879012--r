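# File interchange: GFF3 / BED / FASTA / TSV.
#
# Internally all intervals are 0-based half-open. rtracklayer's GRanges are
# 1-based inclusive, so conversion happens at the boundary (BED files are
# themselves 0-based half-open; rtracklayer handles that conversion).

.df_to_granges <- function(df, contig_id, contig_length, type) {
  gr <- GenomicRanges::GRanges(
    seqnames = contig_id,
    ranges = .as_iranges(df$start, df$end),
    strand = if (!is.null(df$strand)) ifelse(df$strand %in% c("+", "-"), df$strand, "*") else "*")
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- df$id
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(contig_length, contig_id)
  gr
}

#' Write a genome annotation to GFF3
#'
#' Emits `gene` rows for ORFs (with `Parent` pointing at their operon),
#' `operon` rows, and `ncRNA` rows for known sRNAs, predicted sRNAs and
#' structural RNAs (distinguished by an `ncrna_class` attribute).
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  a <- annotation
  decorate <- function(g, parent = NA_character_, ncls = NA_character_) {
    S4Vectors::mcols(g)$Parent <- parent
    S4Vectors::mcols(g)$ncrna_class <- ncls
    g
  }
  grl <- list()
  if (nrow(a$operons) > 0L)
    grl$operon <- decorate(.df_to_granges(a$operons, a$contig_id,
                                          a$contig_length, "operon"))
  if (nrow(a$orfs) > 0L) {
    parent <- rep(NA_character_, nrow(a$orfs))
    if (nrow(a$operons) > 0L)
      for (i in seq_len(nrow(a$operons)))
        parent[match(a$operons$members[[i]], a$orfs$id)] <- a$operons$id[i]
    grl$gene <- decorate(.df_to_granges(a$orfs, a$contig_id, a$contig_length,
                                        "gene"), parent = parent)
  }
  for (tr in c("known_srnas", "predicted_srnas", "structural_rnas")) {
    df <- a[[tr]]
    if (nrow(df) > 0L)
      grl[[tr]] <- decorate(.df_to_granges(df, a$contig_id, a$contig_length,
                                           "ncRNA"), ncls = sub("s$", "", tr))
  }
  gr <- do.call(c, unname(grl))
  rtracklayer::export(gr, path, format = "gff3")
  # add the sequence-region pragma; drop the date line so identical
  # annotations yield byte-identical files
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##date")]
  hdr <- which(startsWith(lines, "##gff-version"))[1]
  lines <- append(lines, sprintf("##sequence-region %s 1 %d", a$contig_id,
                                 a$contig_length), after = hdr)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome annotation from GFF3
#'
#' Inverse of [write_annotation_gff3()]. Contig length is taken from the GFF3
#' sequence-region pragma when present, else from `contig_length`.
#'
#' @param path GFF3 file.
#' @param contig_length Fallback contig length.
#' @param sequence Optional contig sequence string.
#' @return A [genome_annotation()].
#' @export
read_annotation_gff3 <- function(path, contig_length = NULL, sequence = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  contig_id <- as.character(GenomicRanges::seqnames(gr)[1])
  sl <- GenomeInfoDb::seqlengths(gr)[contig_id]
  if (is.na(sl)) {
    pragma <- grep("^##sequence-region", readLines(path, n = 50), value = TRUE)
    if (length(pragma))
      sl <- as.integer(strsplit(pragma[1], "\\s+")[[1]][4])
  }
  if (is.na(sl)) {
    if (is.null(contig_length))
      .stopf("GFF3 lacks a sequence-region pragma; supply contig_length")
    sl <- contig_length
  }
  md <- S4Vectors::mcols(gr)
  grab <- function(idx) {
    data.frame(id = as.character(md$ID[idx]),
               start = GenomicRanges::start(gr)[idx] - 1L,
               end = GenomicRanges::end(gr)[idx],
               strand = as.character(GenomicRanges::strand(gr)[idx]),
               stringsAsFactors = FALSE)
  }
  is_gene <- md$type == "gene"
  is_operon <- md$type == "operon"
  orfs <- grab(which(is_gene))
  operons <- grab(which(is_operon))
  if (nrow(operons) > 0L) {
    parent <- md$Parent[is_gene]
    parent <- vapply(as.list(parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
    operons$members <- lapply(operons$id, function(op) orfs$id[which(parent == op)])
  } else {
    operons$members <- list()
  }
  ncls <- if (!is.null(md$ncrna_class)) as.character(md$ncrna_class) else rep(NA, length(gr))
  pick_nc <- function(cls) grab(which(md$type == "ncRNA" & ncls == cls))
  genome_annotation(contig_id, as.integer(sl), orfs, operons,
                    known_srnas = pick_nc("known_srna"),
                    predicted_srnas = pick_nc("predicted_srna"),
                    structural_rnas = pick_nc("structural_rna"),
                    sequence = sequence)
}

#' Read/write interval tracks as BED
#'
#' BED6 with the feature id in the name column. BED is natively 0-based
#' half-open, matching the package's internal convention.
#'
#' @param df Data frame with `id`, `start`, `end` and optional `strand`.
#' @param contig_id Contig name for the first BED column.
#' @param path File path.
#' @return `read_bed_track` returns a feature data frame.
#' @export
write_bed_track <- function(df, contig_id, path) {
  strand <- if (!is.null(df$strand)) ifelse(df$strand %in% c("+", "-"), df$strand, ".") else "."
  bed <- data.frame(chrom = contig_id, start = df$start, end = df$end,
                    name = df$id, score = 0L, strand = strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_track
#' @export
read_bed_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(id = if (!is.null(gr$name)) as.character(gr$name) else
               sprintf("feat%04d", seq_along(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read/write per-library read intervals
#'
#' Each library's mapped reads are stored as a BED3+name file of read
#' intervals; a readset in memory is a data frame with `start` and `end`.
#'
#' @param readsets Named list of read data frames (`start`, `end`).
#' @param contig_id Contig name.
#' @param dir Directory for one BED file per library.
#' @return `read_readsets_bed` returns a named list of read data frames.
#' @export
write_readsets_bed <- function(readsets, contig_id, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in names(readsets)) {
    r <- readsets[[lib]]
    bed <- data.frame(chrom = contig_id, start = r$start, end = r$end,
                      name = ".")
    utils::write.table(bed, file.path(dir, paste0(lib, ".bed")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_readsets_bed
#' @export
read_readsets_bed <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  if (length(files) == 0L) .stopf("no .bed files found under %s", dir)
  out <- lapply(files, function(f) {
    b <- utils::read.table(f, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    data.frame(start = as.integer(b[[2]]), end = as.integer(b[[3]]))
  })
  names(out) <- sub("\\.bed$", "", basename(files))
  out
}

#' Write the IOR table as TSV
#' @param iors Output of [derive_iors()].
#' @param path Output file.
#' @export
write_ior_table <- function(iors, path) .write_tsv(iors, path)

#' Write/read a genome FASTA
#' @param annotation A [genome_annotation()] carrying a sequence.
#' @param path FASTA path.
#' @export
write_genome_fasta <- function(annotation, path) {
  if (is.null(annotation$sequence)) .stopf("annotation carries no sequence")
  x <- Biostrings::DNAStringSet(annotation$sequence)
  names(x) <- annotation$contig_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read/write a feature x library count matrix as TSV
#'
#' First two columns are `feature_id` and `class`, remaining columns are
#' libraries.
#'
#' @param cm A `count_matrix` (see [build_count_matrix()]).
#' @param path File path.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), class = cm$class,
                   cm$counts, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- .read_tsv(path)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$feature_id
  structure(list(counts = counts, class = df$class,
                 libraries = colnames(counts)),
            class = "count_matrix")
}
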