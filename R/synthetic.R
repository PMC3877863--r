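#' Specify a finite normal mixture for simulation
#'
#' @param weights mixing proportions, summing to 1.
#' @param means component means (log2 expression units).
#' @param variances component variances (> 0).
#' @param n_genes number of genes to draw.
#' @param seed RNG seed; the generator is a pure function of the spec
#'   including the seed.
#' @return list of class `mixture_spec`.
#' @export
mixture_spec <- function(weights, means, variances, n_genes = 10000L,
                         seed = 1L) {
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(weights <= 0)) stop("mixture weights must be positive")
  if (any(variances <= 0)) stop("variances must be positive")
  if (length(means) != length(weights) || length(variances) != length(weights))
    stop("weights, means, variances must have equal length")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  structure(list(weights = as.numeric(weights), means = as.numeric(means),
                 variances = as.numeric(variances),
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Draw a log2 expression vector from a mixture spec
#'
#' Each gene's component is drawn by the mixing weights, then its value from
#' that component's normal. True component labels are returned for recovery
#' tests. Same spec (including seed) always yields identical output.
#'
#' @param spec a [mixture_spec()].
#' @return list with `values` (named numeric, genes `g0001...`) and
#'   `components` (integer true labels).
#' @export
simulate_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  K <- length(spec$weights)
  n <- spec$n_genes
  out <- with_local_rng(spec$seed, {
    comp <- sample.int(K, n, replace = TRUE, prob = spec$weights)
    vals <- rnorm(n, spec$means[comp], sqrt(spec$variances[comp]))
    list(comp = comp, vals = vals)
  })
  values <- setNames(out$vals, sprintf("g%0*d", nchar(n), seq_len(n)))
  list(values = values, components = out$comp)
}

#' Specify an exact power-law (Zipf) expression vector
#'
#' @param exponent power-law exponent s (> 0); s = 1 is Zipf's law proper.
#' @param constant leading constant C (> 0), the expression of the rank-1
#'   gene.
#' @param n_genes number of genes (>= 3).
#' @param noise_sd Gaussian noise sd added on the log2 scale (0 = exact).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return list of class `zipf_spec`.
#' @export
zipf_spec <- function(exponent, constant = 2^20, n_genes = 5000L,
                      noise_sd = 0, seed = 1L) {
  if (exponent <= 0) stop("exponent must be > 0")
  if (constant <= 0) stop("constant must be > 0")
  if (n_genes < 3L) stop("n_genes must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(exponent = exponent, constant = constant,
                 n_genes = as.integer(n_genes), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "zipf_spec")
}

#' Generate a power-law log2 expression vector
#'
#' The gene of rank r gets `log2(C) - s * log2(r)` (the log2 of
#' `C * r^(-s)`), plus N(0, noise_sd^2) if noise is requested. Genes are
#' labeled `g0001..gN` in rank order.
#'
#' @param spec a [zipf_spec()].
#' @return named numeric vector of log2 expression values.
#' @export
simulate_zipf <- function(spec) {
  stopifnot(inherits(spec, "zipf_spec"))
  n <- spec$n_genes
  v <- log2(spec$constant) - spec$exponent * log2(seq_len(n))
  if (spec$noise_sd > 0)
    v <- v + with_local_rng(spec$seed, rnorm(n, 0, spec$noise_sd))
  setNames(v, sprintf("g%0*d", nchar(n), seq_len(n)))
}

#' Specify a SAM+FASTA fixture with known coverage
#'
#' @param loci `data.frame(locus_tag, length)`.
#' @param reads `data.frame(read_id, target, read_length)` plus optional
#'   columns `secondary_target` (`NA` or a second locus tag: the read also
#'   aligns there, so it fails the single-locus filter) and `clip` (number
#'   of soft-clipped bases, 0 = mapped in its entire length).
#' @param seed RNG seed for sequence content and read placement.
#' @return list of class `sam_fixture_spec`.
#' @export
sam_fixture_spec <- function(loci, reads, seed = 1L) {
  stopifnot(all(c("locus_tag", "length") %in% names(loci)),
            all(c("read_id", "target", "read_length") %in% names(reads)))
  if (is.null(reads$secondary_target))
    reads$secondary_target <- rep(NA_character_, nrow(reads))
  if (is.null(reads$clip)) reads$clip <- rep(0L, nrow(reads))
  lens <- setNames(loci$length, loci$locus_tag)
  if (nrow(reads) > 0L) {
    bad <- !(reads$target %in% loci$locus_tag) |
      (!is.na(reads$secondary_target) &
         !(reads$secondary_target %in% loci$locus_tag))
    if (any(bad)) stop("read targets a locus absent from the fixture's loci")
    span <- reads$read_length - reads$clip
    if (any(span > lens[reads$target]))
      stop("read longer than its locus: ",
           paste(reads$read_id[span > lens[reads$target]], collapse = ", "))
  }
  structure(list(loci = loci, reads = reads, seed = as.integer(seed)),
            class = "sam_fixture_spec")
}

#' Default 6-read fixture
#'
#' Three clean single-locus reads, two reads that also hit a second locus,
#' one soft-clipped read. Exactly the three clean reads pass the
#' entire-length single-locus filter, so the expected coverage is
#' locA = 100, locB = 40, locC = 0 bases.
#'
#' @param seed RNG seed.
#' @return a [sam_fixture_spec()].
#' @export
default_sam_fixture_spec <- function(seed = 1L) {
  loci <- data.frame(locus_tag = c("locA", "locB", "locC"),
                     length = c(300L, 200L, 150L),
                     stringsAsFactors = FALSE)
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    target = c("locA", "locA", "locB", "locA", "locB", "locC"),
    read_length = c(50L, 50L, 40L, 50L, 45L, 50L),
    secondary_target = c(NA, NA, NA, "locB", "locC", NA),
    clip = c(0L, 0L, 0L, 0L, 0L, 5L),
    stringsAsFactors = FALSE)
  sam_fixture_spec(loci, reads, seed = seed)
}

#' Generate a SAM+FASTA fixture with its expected coverage table
#'
#' Emits syntactically valid FASTA (random sequence content from the seed)
#' and SAM text. Reads with a `secondary_target` get a secondary alignment
#' line (FLAG 256) on that locus; clipped reads get an `xM yS` CIGAR. The
#' manifest declares, per read, whether the entire-length single-locus
#' filter retains it; the expected coverage table sums retained read lengths
#' per locus.
#'
#' @param spec a [sam_fixture_spec()].
#' @param dir optional directory; if given, `fixture.fasta`, `fixture.sam`
#'   and `manifest.tsv` are written there.
#' @return list with `fasta` and `sam` (character vectors of lines),
#'   `annotation` (a [locus_annotation()]), `expected_coverage` (a
#'   `coverage_table`), `manifest` (per-read data frame with `retained` and
#'   `reason`), `read_counts` (retained reads per locus, for RPKM), and,
#'   when `dir` is given, `paths`.
#' @export
generate_sam_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "sam_fixture_spec"))
  loci <- spec$loci
  reads <- spec$reads
  annotation <- locus_annotation(loci$locus_tag, loci$length)

  gen <- with_local_rng(spec$seed, {
    seqs <- vapply(loci$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    starts <- if (nrow(reads) > 0L) {
      span <- reads$read_length - reads$clip
      maxs <- setNames(loci$length, loci$locus_tag)[reads$target] - span + 1L
      vapply(maxs, function(m) sample.int(m, 1L), integer(1))
    } else integer(0)
    list(seqs = setNames(seqs, loci$locus_tag), starts = starts)
  })

  fasta <- as.vector(rbind(paste0(">", loci$locus_tag), gen$seqs))
  sam <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", loci$locus_tag, loci$length))
  manifest <- NULL
  if (nrow(reads) > 0L) {
    for (i in seq_len(nrow(reads))) {
      rd <- reads[i, ]
      span <- rd$read_length - rd$clip
      cigar <- if (rd$clip > 0L) sprintf("%dM%dS", span, rd$clip)
               else sprintf("%dM", span)
      seq_match <- substr(gen$seqs[[rd$target]], gen$starts[i],
                          gen$starts[i] + span - 1L)
      seq_full <- if (rd$clip > 0L)
        paste0(seq_match, strrep("N", rd$clip)) else seq_match
      sam <- c(sam, paste(rd$read_id, 0L, rd$target, gen$starts[i], 60L,
                          cigar, "*", 0L, 0L, seq_full, "*", sep = "\t"))
      if (!is.na(rd$secondary_target))
        sam <- c(sam, paste(rd$read_id, 256L, rd$secondary_target, 1L, 0L,
                            cigar, "*", 0L, 0L, "*", "*", sep = "\t"))
    }
    multi <- !is.na(reads$secondary_target)
    clipped <- reads$clip > 0L
    retained <- !multi & !clipped
    reason <- ifelse(multi, "multi_locus",
                     ifelse(clipped, "clipped", "retained"))
    manifest <- data.frame(reads[c("read_id", "target", "read_length")],
                           n_loci = 1L + as.integer(multi),
                           clipped = clipped, retained = retained,
                           reason = reason, stringsAsFactors = FALSE)
  } else {
    manifest <- data.frame(read_id = character(), target = character(),
                           read_length = integer(), n_loci = integer(),
                           clipped = logical(), retained = logical(),
                           reason = character(), stringsAsFactors = FALSE)
  }

  kept <- manifest[manifest$retained, , drop = FALSE]
  raw <- setNames(rep(0, nrow(loci)), loci$locus_tag)
  cnt <- setNames(rep(0, nrow(loci)), loci$locus_tag)
  if (nrow(kept) > 0L) {
    agg <- tapply(kept$read_length, kept$target, sum)
    raw[names(agg)] <- agg
    nrd <- table(kept$target)
    cnt[names(nrd)] <- as.numeric(nrd)
  }
  expected <- structure(
    data.frame(locus_tag = loci$locus_tag, raw_bases = as.numeric(raw),
               length = loci$length, stringsAsFactors = FALSE),
    total_bases = sum(raw), class = c("coverage_table", "data.frame"))

  out <- list(fasta = fasta, sam = sam, annotation = annotation,
              expected_coverage = expected, manifest = manifest,
              read_counts = cnt, spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "fixture.fasta"),
                  sam = file.path(dir, "fixture.sam"),
                  manifest = file.path(dir, "manifest.tsv"))
    writeLines(fasta, paths$fasta)
    writeLines(sam, paths$sam)
    write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Named preset simulation scenarios
#'
#' Templates for the transcriptome shapes the pipeline is meant to
#' distinguish, each with its documented ground truth for end-to-end tests:
#'
#' * `unimodal` — one component.
#' * `yeast_like` — two components with a dominant (85%) peak, the yeast
#'   shape whose main peak holds at least 70% of expressed genes.
#' * `bimodal_metazoan` — two balanced components, the classic
#'   high/low-expression bimodal shape; not Zipf-consistent.
#' * `ncrassa_like` — five components of which three hold at least 15%.
#' * `zipf_s1` — exact Zipf's law, exponent 1.
#'
#' Component means are separated by at least 3 standard deviations so that
#' recovery at n = 10,000 is comfortable rather than borderline.
#'
#' @param n_genes genes per mixture scenario (default 10000).
#' @param seed base RNG seed; each scenario derives its own from it.
#' @return named list; each element has `spec` (a [mixture_spec()] or
#'   [zipf_spec()]), `type`, and `expected` (ground truth: `n_peaks`,
#'   `n_main_peaks`, and scenario-specific entries).
#' @export
preset_scenarios <- function(n_genes = 10000L, seed = 1L) {
  list(
    unimodal = list(
      type = "mixture",
      spec = mixture_spec(1, 5, 1, n_genes, seed = seed + 10L),
      expected = list(n_peaks = 1L, n_main_peaks = 1L)),
    yeast_like = list(
      type = "mixture",
      spec = mixture_spec(c(0.15, 0.85), c(5, 10), c(1, 1), n_genes,
                          seed = seed + 20L),
      expected = list(n_peaks = 2L, n_main_peaks = 2L,
                      dominant_min = 0.70)),
    bimodal_metazoan = list(
      type = "mixture",
      spec = mixture_spec(c(0.5, 0.5), c(3, 9), c(1, 1), n_genes,
                          seed = seed + 30L),
      expected = list(n_peaks = 2L, n_main_peaks = 2L,
                      zipf_consistent = FALSE)),
    ncrassa_like = list(
      type = "mixture",
      spec = mixture_spec(c(0.08, 0.20, 0.35, 0.25, 0.12),
                          c(2, 6, 10, 14, 18), rep(1, 5), n_genes,
                          seed = seed + 40L),
      expected = list(n_peaks = 5L, n_main_peaks = 3L)),
    zipf_s1 = list(
      type = "zipf",
      spec = zipf_spec(1, 2^20, max(3L, n_genes %/% 2L), 0,
                       seed = seed + 50L),
      expected = list(gradient = -1, zipf_consistent = TRUE)))
}
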