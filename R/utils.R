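# Internal helpers shared across modules.

# Convert 0-based half-open [start, end) intervals to IRanges (1-based closed).
.as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.msgf <- function(...) message(sprintf(...))

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# Validate an interval data frame with columns id/start/end (0-based half-open).
.check_intervals <- function(df, what, contig_length = NULL) {
  need <- c("id", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("%s must have columns %s", what, paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$end <= df$start))
    .stopf("%s contains empty or reversed intervals (end <= start)", what)
  if (anyDuplicated(df$id))
    .stopf("%s ids are not unique", what)
  if (!is.null(contig_length) && (any(df$start < 0) || any(df$end > contig_length)))
    .stopf("%s contains intervals outside [0, %d)", what, contig_length)
  invisible(df)
}

.empty_features <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

# Deterministic TSV writer used for all pipeline outputs (no row names, no
# quoting, fixed NA representation) so that output manifests are reproducible.
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
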