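#' Construct a locus annotation
#'
#' A locus annotation maps each locus tag (the unit of quantification: an
#' annotated mRNA or CDS) to its length in bases.
#'
#' @param locus_tag character vector of unique locus identifiers.
#' @param length integer vector of locus lengths in bases (mRNA or CDS
#'   length), all >= 1.
#' @return A `data.frame` with columns `locus_tag` and `length`, of class
#'   `locus_annotation`.
#' @export
locus_annotation <- function(locus_tag, length) {
  locus_tag <- as.character(locus_tag)
  length <- as.integer(length)
  if (length(locus_tag) != length(length))
    stop("locus_tag and length must have equal length")
  if (anyDuplicated(locus_tag))
    stop("duplicate locus_tag in annotation: ",
         paste(unique(locus_tag[duplicated(locus_tag)]), collapse = ", "))
  if (any(is.na(length)) || any(length < 1L))
    stop("all locus lengths must be integers >= 1")
  structure(data.frame(locus_tag = locus_tag, length = length,
                       stringsAsFactors = FALSE),
            class = c("locus_annotation", "data.frame"))
}

#' Read a locus annotation from FASTA or TSV
#'
#' FASTA input gives locus lengths as sequence lengths (the per-locus
#' reference sequences reads were mapped against); the locus tag is the
#' first whitespace-delimited token of each header. TSV input is two
#' columns, `locus_tag` and `length`, with an optional header line.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @return A [locus_annotation()].
#' @export
read_locus_annotation <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna|ffn)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    tags <- sub("\\s.*$", "", names(seqs))
    locus_annotation(tags, Biostrings::width(seqs))
  } else {
    df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                     colClasses = "character", stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("annotation TSV needs two columns: locus_tag, length")
    if (suppressWarnings(is.na(as.integer(df[1L, 2L])))) df <- df[-1L, , drop = FALSE]
    locus_annotation(df[[1L]], as.integer(df[[2L]]))
  }
}
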