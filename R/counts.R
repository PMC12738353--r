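#' IsomiR read-count table
#'
#' The central container of the package: a matrix of raw read counts with one
#' row per isomiR (a miRNA name plus 5'/3' terminal offsets) and one column
#' per sample, together with a per-sample annotation giving tissue and, for
#' tumors, histology.
#'
#' @param counts non-negative integer matrix, isomiRs in rows, samples in
#'   columns. Column names are sample ids.
#' @param ids data.frame with columns `mirna`, `offset5`, `offset3`, one row
#'   per row of `counts`.
#' @param samples data.frame with columns `sample_id`,
#'   `tissue` (`"tumor"`/`"normal"`) and optionally `histology`
#'   (`"favorable"`/`"unfavorable"`/`NA`). Row order must match the columns
#'   of `counts`.
#' @return An object of class `isomir_counts`.
#' @export
isomir_counts <- function(counts, ids, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  storage.mode(counts) <- "integer"
  stopifnot(is.data.frame(ids),
            all(c("mirna", "offset5", "offset3") %in% names(ids)),
            nrow(ids) == nrow(counts))
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "tissue") %in% names(samples)),
            nrow(samples) == ncol(counts))
  if (!"histology" %in% names(samples)) samples$histology <- NA_character_
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  key <- paste(ids$mirna, ids$offset5, ids$offset3)
  if (anyDuplicated(key))
    stop("duplicate isomiR rows: ", paste(unique(key[duplicated(key)])[1:3], collapse = ", "))
  bad <- setdiff(unique(samples$tissue), c("tumor", "normal"))
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  rownames(counts) <- sprintf("%s %d|%d", ids$mirna, ids$offset5, ids$offset3)
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, ids = ids, samples = samples),
            class = "isomir_counts")
}

#' @export
print.isomir_counts <- function(x, ...) {
  cat(sprintf("isomiR count table: %d isomiRs of %d miRNAs x %d samples (%d tumor, %d normal)\n",
              nrow(x$counts), length(unique(x$ids$mirna)), ncol(x$counts),
              sum(x$samples$tissue == "tumor"), sum(x$samples$tissue == "normal")))
  invisible(x)
}

#' @export
dim.isomir_counts <- function(x) dim(x$counts)

#' Subset an isomiR count table by row and/or sample
#'
#' @param x an [isomir_counts()] object.
#' @param i row (isomiR) index; @param j column (sample) index.
#' @param ... unused.
#' @return An [isomir_counts()] object.
#' @export
`[.isomir_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  out <- isomir_counts(x$counts[i, j, drop = FALSE],
                       x$ids[i, , drop = FALSE],
                       x$samples[j, , drop = FALSE])
  # provenance attached by the simulator survives subsetting
  attr(out, "signal_mirnas") <- attr(x, "signal_mirnas")
  if (!is.null(attr(x, "depths")))
    attr(out, "depths") <- attr(x, "depths")[colnames(out$counts)]
  out
}
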