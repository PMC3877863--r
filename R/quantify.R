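#' Read alignment records from SAM
#'
#' Parses SAM alignment lines into one record per (read, target locus) pair,
#' the unit the downstream filter operates on. For each read the number of
#' distinct locus tags it aligns to (`n_loci_hit`) is aggregated across all
#' of its alignment lines, including secondary/supplementary ones, so a read
#' with any alignment to a second locus is identifiable (and will be
#' discarded by [filter_full_single_locus()]). Multiple alignment lines of
#' one read to the *same* locus collapse to a single record, so a retained
#' read is counted once. Paired-end mates are treated as independent reads
#' (read ids get `/1`, `/2` suffixes). Unmapped records are dropped.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @param annotation optional [locus_annotation()]; if given, an alignment to
#'   a reference absent from it is a hard error.
#' @return `data.frame` with columns `read_id`, `target_locus`,
#'   `read_length`, `aligned_span`, `n_loci_hit`, `is_clipped`.
#'   `read_length` is the full query length including soft- and hard-clipped
#'   bases; `aligned_span` is the number of read bases actually matched to
#'   the reference (CIGAR M/=/X).
#' @export
read_alignments <- function(sam, annotation = NULL) {
  lines <- if (length(sam) == 1L && !grepl("\n", sam) && file.exists(sam))
    readLines(sam) else sam
  lineno <- seq_along(lines)
  body <- !startsWith(lines, "@") & nzchar(lines)
  lines <- lines[body]
  lineno <- lineno[body]
  if (length(lines) == 0L) return(empty_alignments())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM line (fewer than 11 fields) at line ",
         lineno[which(nf < 11L)[1L]])
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  rname <- vapply(fields, `[[`, "", 3L)
  cigar <- vapply(fields, `[[`, "", 6L)
  if (any(is.na(flag)))
    stop("malformed SAM line (non-numeric FLAG) at line ",
         lineno[which(is.na(flag))[1L]])

  mapped <- bitwAnd(flag, 4L) == 0L
  lines_at <- lineno[mapped]
  qname <- qname[mapped]; flag <- flag[mapped]
  rname <- rname[mapped]; cigar <- cigar[mapped]
  if (length(qname) == 0L) return(empty_alignments())
  if (any(cigar == "*" | rname == "*"))
    stop("malformed SAM line (mapped record without CIGAR/RNAME) at line ",
         lines_at[which(cigar == "*" | rname == "*")[1L]])
  if (!is.null(annotation)) {
    missing <- setdiff(rname, annotation$locus_tag)
    if (length(missing) > 0L)
      stop("read aligned to reference absent from annotation: ",
           paste(missing, collapse = ", "))
  }

  ops <- GenomicAlignments::explodeCigarOps(cigar)
  oplen <- GenomicAlignments::explodeCigarOpLengths(cigar)
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = FALSE)
  hard <- mapply(function(o, l) sum(l[o == "H"]), ops, oplen)
  read_length <- qlen + as.integer(hard)
  aligned_span <- as.integer(
    mapply(function(o, l) sum(l[o %in% c("M", "=", "X")]), ops, oplen))
  is_clipped <- vapply(ops, function(o) any(o %in% c("S", "H")), logical(1))

  # mates of a pair are independent reads
  paired <- bitwAnd(flag, 1L) != 0L
  mate <- ifelse(paired & bitwAnd(flag, 128L) != 0L, "/2",
                 ifelse(paired, "/1", ""))
  read_id <- paste0(qname, mate)
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L

  n_loci <- tapply(rname, read_id, function(r) length(unique(r)))
  rec <- data.frame(read_id, target_locus = rname, read_length, aligned_span,
                    is_clipped, secondary, stringsAsFactors = FALSE)
  # collapse duplicate lines of one read to one locus, primary line preferred
  rec <- rec[order(rec$read_id, rec$target_locus, rec$secondary), ]
  rec <- rec[!duplicated(rec[c("read_id", "target_locus")]), ]
  rec$n_loci_hit <- as.integer(n_loci[rec$read_id])
  rec$secondary <- NULL
  rownames(rec) <- NULL
  rec[c("read_id", "target_locus", "read_length", "aligned_span",
        "n_loci_hit", "is_clipped")]
}

empty_alignments <- function() {
  data.frame(read_id = character(), target_locus = character(),
             read_length = integer(), aligned_span = integer(),
             n_loci_hit = integer(), is_clipped = logical(),
             stringsAsFactors = FALSE)
}

#' Keep reads mapped in their entire length to a single locus tag
#'
#' Retains exactly the records with `n_loci_hit == 1`, `aligned_span ==
#' read_length` and no clipping. This is the strictest reading of "mapped
#' completely to a single locus tag": any soft/hard clipping, insertion or
#' deletion, or a hit to a second locus, disqualifies the read.
#'
#' @param records output of [read_alignments()].
#' @return the retained subset, same columns.
#' @export
filter_full_single_locus <- function(records) {
  keep <- records$n_loci_hit == 1L &
    records$aligned_span == records$read_length &
    !records$is_clipped
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count mapped bases per locus (coverage)
#'
#' Each base of every retained read is counted toward its target locus:
#' `raw_bases(locus)` is the sum of read lengths over retained reads on that
#' locus. Every annotated locus appears, with zero allowed.
#'
#' @param records retained records from [filter_full_single_locus()].
#' @param annotation a [locus_annotation()].
#' @return A `coverage_table`: `data.frame(locus_tag, raw_bases, length)`
#'   with attribute `total_bases` (the experiment-wide sum).
#' @export
count_base_coverage <- function(records, annotation) {
  missing <- setdiff(records$target_locus, annotation$locus_tag)
  if (length(missing) > 0L)
    stop("read aligned to reference absent from annotation: ",
         paste(missing, collapse = ", "))
  raw <- tapply(records$read_length, records$target_locus, sum)
  bases <- setNames(rep(0, nrow(annotation)), annotation$locus_tag)
  bases[names(raw)] <- raw
  tab <- data.frame(locus_tag = annotation$locus_tag,
                    raw_bases = as.numeric(bases),
                    length = annotation$length,
                    stringsAsFactors = FALSE)
  structure(tab, total_bases = sum(tab$raw_bases),
            class = c("coverage_table", "data.frame"))
}

#' Total mapped bases of a coverage table
#' @param table a `coverage_table`.
#' @return numeric scalar, the sum of `raw_bases`.
#' @export
total_bases <- function(table) attr(table, "total_bases")

#' Normalize coverage by locus length and library base total
#'
#' `norm(locus) = raw_bases / (length * total_bases) * scale_constant`.
#' The scale constant is a pure presentation choice: under log2 it is an
#' additive shift and cannot change the peak structure of the distribution.
#' The default 1e9 makes values a per-base, per-kilobase-per-gigabase
#' analogue of RPKM. Conservation: `sum(norm * length) == scale_constant`.
#'
#' @param table a `coverage_table` from [count_base_coverage()].
#' @param scale_constant positive scale, default `1e9`.
#' @return named numeric vector of normalized values for all loci
#'   (zeros included).
#' @export
normalize_coverage <- function(table, scale_constant = 1e9) {
  tb <- attr(table, "total_bases")
  if (is.null(tb)) tb <- sum(table$raw_bases)
  if (tb <= 0) stop("empty experiment: total mapped bases is zero")
  setNames(table$raw_bases / (table$length * tb) * scale_constant,
           table$locus_tag)
}

#' Log2-transform normalized coverage into an expression vector
#'
#' Loci without coverage are dropped (they have no defined log2 value and
#' are excluded from all downstream clustering and rank analysis); the rest
#' are log2-transformed.
#'
#' @param normalized named numeric vector of normalized values, all >= 0.
#' @return named numeric vector of log2 values; `attr(, "n_genes")` is the
#'   number of retained loci.
#' @export
to_expression_vector <- function(normalized) {
  if (any(normalized < 0)) stop("normalized values must be non-negative")
  v <- log2(normalized[normalized > 0])
  attr(v, "n_genes") <- length(v)
  v
}

#' Compute RPKM per locus
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm = reads * 1e9 / (length * total_reads)`. Provided as the
#' alternative expression measurement for the shape-robustness check
#' (modality classification should agree between coverage-based and
#' RPKM-based quantification).
#'
#' @param read_counts named numeric vector of read counts per locus (names
#'   are locus tags present in `annotation`).
#' @param annotation a [locus_annotation()].
#' @param total_reads total mapped reads in the experiment; if `NULL`, the
#'   sum of `read_counts`.
#' @return named numeric vector of RPKM values for all annotated loci.
#' @export
compute_rpkm <- function(read_counts, annotation, total_reads = NULL) {
  if (is.null(total_reads)) total_reads <- sum(read_counts)
  if (total_reads <= 0) stop("empty experiment: total mapped reads is zero")
  missing <- setdiff(names(read_counts), annotation$locus_tag)
  if (length(missing) > 0L)
    stop("read counts for loci absent from annotation: ",
         paste(missing, collapse = ", "))
  counts <- setNames(rep(0, nrow(annotation)), annotation$locus_tag)
  counts[names(read_counts)] <- read_counts
  len <- setNames(annotation$length, annotation$locus_tag)
  counts * 1e9 / (len * total_reads)
}

#' Full quantification: SAM + annotation to expression vector
#'
#' Runs read ingestion, the entire-length single-locus filter, base
#' counting, normalization and log2 transformation in one call.
#'
#' @inheritParams read_alignments
#' @param annotation a [locus_annotation()] (or path readable by
#'   [read_locus_annotation()]).
#' @param scale_constant see [normalize_coverage()].
#' @return list with `records` (all parsed), `retained`, `coverage`
#'   (coverage_table), `normalized`, `expression` (log2 vector), and
#'   `table`: a `data.frame(locus_tag, raw_bases, length, norm, log2_norm)`
#'   (`log2_norm` is `NA` for zero-coverage loci).
#' @export
quantify_sam <- function(sam, annotation, scale_constant = 1e9) {
  if (is.character(annotation) && length(annotation) == 1L &&
      file.exists(annotation))
    annotation <- read_locus_annotation(annotation)
  records <- read_alignments(sam, annotation)
  retained <- filter_full_single_locus(records)
  coverage <- count_base_coverage(retained, annotation)
  normalized <- normalize_coverage(coverage, scale_constant)
  expression <- to_expression_vector(normalized)
  tab <- data.frame(coverage, norm = as.numeric(normalized),
                    log2_norm = ifelse(normalized > 0, log2(normalized), NA),
                    stringsAsFactors = FALSE)
  list(records = records, retained = retained, coverage = coverage,
       normalized = normalized, expression = expression, table = tab)
}

#' Write an expression table as TSV
#'
#' @param table the `table` element of [quantify_sam()] output (columns
#'   `locus_tag`, `raw_bases`, `length`, `norm`, `log2_norm`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table written by [write_expression_tsv()]
#'
#' Also accepts any TSV with a `locus_tag` column and a `log2_norm` (or
#' `log2_value`) column.
#'
#' @param path TSV file.
#' @return named numeric vector of log2 expression values (zero-coverage
#'   loci, i.e. `NA` rows, dropped).
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  col <- intersect(c("log2_norm", "log2_value", "value"), names(df))
  if (length(col) == 0L || !"locus_tag" %in% names(df))
    stop("expression TSV needs columns locus_tag and log2_norm")
  v <- setNames(df[[col[1L]]], df$locus_tag)
  v <- v[!is.na(v)]
  attr(v, "n_genes") <- length(v)
  v
}
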