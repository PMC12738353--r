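#' Write / read an isomiR count table as tab-separated text
#'
#' The on-disk dialect has columns `mirna`, `offset5`, `offset3` followed by
#' one column per sample id. The sample annotation travels in the clinical
#' table (see [write_clinical()]), which is why [read_isomir_counts()] needs
#' both files.
#'
#' @param x an [isomir_counts()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_isomir_counts <- function(x, path) {
  stopifnot(inherits(x, "isomir_counts"))
  tab <- cbind(x$ids[, c("mirna", "offset5", "offset3")],
               as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param counts_path TSV written by [write_isomir_counts()].
#' @param samples data.frame with at least `sample_id` and `tissue` (e.g. a
#'   clinical table from [read_clinical()]).
#' @rdname write_isomir_counts
#' @export
read_isomir_counts <- function(counts_path, samples) {
  tab <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  id_cols <- c("mirna", "offset5", "offset3")
  if (!all(id_cols %in% names(tab)))
    stop("count table must have columns mirna, offset5, offset3")
  sample_ids <- setdiff(names(tab), id_cols)
  missing <- setdiff(sample_ids, samples$sample_id)
  if (length(missing))
    stop("samples absent from the annotation: ", paste(missing, collapse = ", "))
  ann <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  isomir_counts(as.matrix(tab[, sample_ids, drop = FALSE]), tab[, id_cols], ann)
}

#' Write / read a clinical table as tab-separated text
#'
#' Columns: `sample_id`, `time_days`, `event`, `histology`, `gender`,
#' `tissue`, plus any derived group labels.
#'
#' @param clinical a clinical data.frame (see [simulate_clinical()]).
#' @param path TSV path.
#' @return `path` invisibly / the data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of RNA/DNA sequences.
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- chartr("tT", "uU", toupper(as.character(x)))
  names(out) <- sub(" .*", "", names(x))
  out
}

#' Write / read the mature-arm annotation table
#'
#' TSV with columns `precursor_id`, `mirna`, `start`, `end` (1-based
#' inclusive coordinates on the precursor).
#'
#' @param annotations data.frame as produced by [simulate_sequences()].
#' @param path TSV path.
#' @return `path` invisibly / the data.frame.
#' @export
write_mature_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mature_annotations
#' @export
read_mature_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a planted-site manifest as structured key-value text
#'
#' One `key=value` header line per summary quantity, followed by one
#' `site=<mirna>\t<utr_id>\t<position>\t<mismatches>` line per planted site.
#'
#' @param manifest manifest data.frame from [simulate_sequences()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  lines <- c(
    sprintf("n_sites=%d", nrow(manifest)),
    sprintf("n_exact=%d", sum(manifest$mismatches == 0)),
    sprintf("n_mismatch1=%d", sum(manifest$mismatches == 1)),
    sprintf("site=%s\t%s\t%d\t%d", manifest$mirna, manifest$utr_id,
            manifest$position, manifest$mismatches)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  sites <- lines[startsWith(lines, "site=")]
  if (!length(sites))
    return(data.frame(mirna = character(0), utr_id = character(0),
                      position = integer(0), mismatches = integer(0)))
  parts <- do.call(rbind, strsplit(sub("^site=", "", sites), "\t", fixed = TRUE))
  data.frame(mirna = parts[, 1], utr_id = parts[, 2],
             position = as.integer(parts[, 3]), mismatches = as.integer(parts[, 4]),
             stringsAsFactors = FALSE)
}
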