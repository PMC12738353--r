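#' IsomiR identifiers: miRNA name plus signed terminal offsets
#'
#' An isomiR is identified by the name of its parent miRNA together with the
#' signed distances (in nucleotides) of its 5' and 3' termini from the
#' corresponding termini of the archetype (canonical) mature sequence.
#' Positive offsets point downstream on the precursor (toward its 3' end),
#' negative offsets upstream. The archetype itself is `0|0`.
#'
#' @param mirna_name miRNA name, e.g. `"miR-455-5p"`.
#' @param offset5,offset3 signed integer offsets of the 5' and 3' terminus.
#' @return An object of class `isomir_id`: a list with elements `mirna_name`,
#'   `offset5`, `offset3`.
#' @examples
#' isomir_id("miR-455-5p", 0, 1)
#' @export
isomir_id <- function(mirna_name, offset5, offset3) {
  if (!is.character(mirna_name) || length(mirna_name) != 1L || !nzchar(mirna_name))
    stop("'mirna_name' must be a single non-empty string")
  for (o in list(offset5, offset3)) {
    if (length(o) != 1L || !is.numeric(o) || is.na(o) || o != round(o))
      stop("offsets must be single integers")
  }
  structure(
    list(mirna_name = mirna_name,
         offset5 = as.integer(offset5),
         offset3 = as.integer(offset3)),
    class = "isomir_id"
  )
}

#' @export
print.isomir_id <- function(x, ...) {
  cat(format_isomir(x), "\n")
  invisible(x)
}

#' Format an isomiR identifier as canonical text
#'
#' The canonical form is `<mirna_name> <offset5>|<offset3>`: a single space,
#' a vertical bar between the two offsets, a `-` sign on negative offsets and
#' no sign on positive ones.
#'
#' @param id an [isomir_id()], or its components given separately.
#' @return A single string, e.g. `"miR-455-5p 0|1"`.
#' @seealso [parse_isomir()] for the inverse.
#' @export
format_isomir <- function(id) {
  stopifnot(inherits(id, "isomir_id"))
  sprintf("%s %d|%d", id$mirna_name, id$offset5, id$offset3)
}

#' Parse canonical isomiR text into an identifier
#'
#' @param text a single string in the canonical grammar
#'   `<name> <int>|<int>`.
#' @return An [isomir_id()].
#' @examples
#' parse_isomir("miR-582-5p -1|0")
#' @export
parse_isomir <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single string")
  m <- regexec("^(.*\\S) (-?[0-9]+)\\|(-?[0-9]+)$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 4L) {
    # locate the first position where the tail of the grammar fails, for the
    # error message
    sp <- regexpr(" -?[0-9]+\\|", text)
    pos <- if (sp > 0) attr(sp, "match.length") + sp else nchar(text) + 1L
    stop(sprintf("malformed isomiR name %s: expected '<name> <int>|<int>' (error near position %d)",
                 dQuote(text), pos))
  }
  isomir_id(parts[2], as.integer(parts[3]), as.integer(parts[4]))
}

#' Mature-arm annotation on a precursor
#'
#' Records where the archetype mature sequence sits on its precursor hairpin,
#' in 1-based inclusive coordinates (the miRBase hairpin-relative convention).
#'
#' @param precursor_id precursor identifier, e.g. `"hsa-mir-455"`.
#' @param mirna_name mature miRNA name, e.g. `"miR-455-5p"`.
#' @param start,end 1-based inclusive positions of the archetype 5' and 3'
#'   ends on the precursor.
#' @return An object of class `mature_annotation`.
#' @export
mature_annotation <- function(precursor_id, mirna_name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("need 1 <= start <= end")
  structure(
    list(precursor_id = precursor_id, mirna_name = mirna_name,
         start = start, end = end),
    class = "mature_annotation"
  )
}

#' Terminal offsets of a read relative to the archetype
#'
#' Converts precursor-relative read coordinates into the signed 5'/3'
#' terminal offsets that identify the isomiR: `offset5 = read_start - start`
#' and `offset3 = read_end - end`, so positive means the terminus lies
#' downstream (toward the precursor 3' end) of the archetype terminus and
#' negative upstream.
#'
#' @param read_start,read_end 1-based inclusive coordinates of the read on
#'   the precursor.
#' @param ann a [mature_annotation()].
#' @param precursor_length optional precursor length; when given, coordinates
#'   outside `[1, precursor_length]` are an error.
#' @return An [isomir_id()] carrying the annotation's miRNA name.
#' @examples
#' ann <- mature_annotation("hsa-mir-455", "miR-455-5p", 6, 27)
#' isomir_offsets(6, 28, ann)   # miR-455-5p 0|1
#' @export
isomir_offsets <- function(read_start, read_end, ann, precursor_length = NULL) {
  stopifnot(inherits(ann, "mature_annotation"))
  read_start <- as.integer(read_start); read_end <- as.integer(read_end)
  if (is.na(read_start) || is.na(read_end) || read_start > read_end)
    stop("need read_start <= read_end")
  if (read_start < 1L)
    stop(sprintf("read_start %d is outside the precursor", read_start))
  if (!is.null(precursor_length) && read_end > precursor_length)
    stop(sprintf("read_end %d is outside the precursor (length %d)",
                 read_end, as.integer(precursor_length)))
  isomir_id(ann$mirna_name, read_start - ann$start, read_end - ann$end)
}

.normalize_rna <- function(seq, what = "sequence") {
  if (inherits(seq, "XString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L)
    stop(sprintf("'%s' must be a single string", what))
  s <- chartr("tT", "uU", toupper(seq))
  bad <- regmatches(s, regexpr("[^ACGU]", s))
  if (length(bad) && nzchar(bad))
    stop(sprintf("invalid symbol %s in %s (alphabet is A/C/G/U, T accepted as U)",
                 dQuote(bad), what))
  s
}

#' Reconstruct an isomiR sequence from the precursor
#'
#' Templated isomiRs are subsequences of the precursor: the isomiR with
#' offsets `(o5, o3)` runs from `start + o5` to `end + o3` (1-based
#' inclusive) on the precursor, so its length is the archetype length
#' `- o5 + o3`. Offsets that would extend past either end of the precursor
#' are rejected: non-templated additions are not modelled.
#'
#' @param precursor_seq precursor sequence (RNA or DNA letters; a string or a
#'   `Biostrings` `XString`). Internally normalised to RNA.
#' @param ann a [mature_annotation()].
#' @param id an [isomir_id()].
#' @return The isomiR sequence as an RNA string (with `U`).
#' @examples
#' fx <- mir455_fixture()
#' isomir_sequence(fx$precursor, fx$annotation, isomir_id("miR-455-5p", 0, 1))
#' @export
isomir_sequence <- function(precursor_seq, ann, id) {
  stopifnot(inherits(ann, "mature_annotation"), inherits(id, "isomir_id"))
  s <- .normalize_rna(precursor_seq, "precursor_seq")
  n <- nchar(s)
  if (ann$end > n)
    stop(sprintf("annotation end %d exceeds precursor length %d", ann$end, n))
  from <- ann$start + id$offset5
  to <- ann$end + id$offset3
  if (from < 1L || to > n)
    stop(sprintf("offsets (%d,%d) extend outside the precursor [1,%d]; non-templated variants are not modelled",
                 id$offset5, id$offset3, n))
  if (from > to)
    stop("offsets collapse the sequence to zero or negative length")
  substr(s, from, to)
}

#' The miR-455-5p worked-example fixture
#'
#' Returns the precursor record shipped with the package: the genuine mature
#' miR-455-5p sequence (`UAUGUGCCUUUGGACUACAUCG`) embedded at annotated
#' coordinates in a synthetic hairpin context, with the first base 3' of the
#' mature arm a `U` so that the highly expressed `0|1` isoform carries a
#' single templated 3' uridine extension. The flanking and 3p-arm context is
#' synthetic (see the FASTA header); only the 5p arm and its +1 base are
#' real.
#'
#' @return A list with `precursor` (RNA string), `annotation` (a
#'   [mature_annotation()] for miR-455-5p) and `path` (the FASTA file).
#' @export
mir455_fixture <- function() {
  path <- system.file("extdata", "hsa-mir-455_synthetic.fa",
                      package = "isomirdiv", mustWork = TRUE)
  fa <- Biostrings::readRNAStringSet(path)
  ann_path <- system.file("extdata", "hsa-mir-455_mature.tsv",
                          package = "isomirdiv", mustWork = TRUE)
  tab <- utils::read.delim(ann_path, stringsAsFactors = FALSE)
  i <- match("miR-455-5p", tab$mirna)
  list(
    precursor = as.character(fa[[1]]),
    annotation = mature_annotation(tab$precursor_id[i], tab$mirna[i],
                                   tab$start[i], tab$end[i]),
    path = path
  )
}
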