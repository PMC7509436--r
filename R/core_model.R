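#' Declare the amplicon segments of a genotyping panel
#'
#' Each segment is a short PCR amplicon containing several SNPs and treated
#' downstream as one multi-allelic locus. Duplicated segments
#' (`copy_number = 2`, two near-identical adjacent genomic copies amplified by
#' one primer pair) are genotyped as a single composite diploid locus; their
#' only special treatment is a laxer secondary-peak ratio threshold when
#' calling heterozygotes, because each allele contributes proportionally less
#' signal.
#'
#' @param segment_id Character vector of unique short labels, e.g. `"SEG1"`.
#' @param amplicon_length Positive integer vector of amplicon lengths (bp).
#' @param copy_number Integer vector, 1 or 2 per segment.
#' @param chrom Optional chromosome labels.
#' @param het_ratio_threshold Secondary/primary peak ratio above which a
#'   position is called heterozygous. Defaults to 0.50 for single-copy and
#'   0.30 for duplicated segments.
#' @return A `data.frame` with one row per segment.
#' @export
segment_table <- function(segment_id, amplicon_length, copy_number = 1L,
                          chrom = NA_character_, het_ratio_threshold = NULL) {
  n <- length(segment_id)
  if (anyDuplicated(segment_id)) stop("duplicate segment_id")
  copy_number <- as.integer(rep_len(copy_number, n))
  if (!all(copy_number %in% c(1L, 2L))) stop("copy_number must be 1 or 2")
  amplicon_length <- as.integer(rep_len(amplicon_length, n))
  if (any(amplicon_length <= 0L)) stop("amplicon_length must be positive")
  if (is.null(het_ratio_threshold)) {
    het_ratio_threshold <- ifelse(copy_number == 2L, 0.30, 0.50)
  } else {
    het_ratio_threshold <- rep_len(het_ratio_threshold, n)
    if (any(het_ratio_threshold <= 0 | het_ratio_threshold > 1)) {
      stop("het_ratio_threshold must lie in (0, 1]")
    }
  }
  data.frame(
    segment_id = as.character(segment_id),
    chrom = rep_len(as.character(chrom), n),
    amplicon_length = amplicon_length,
    copy_number = copy_number,
    het_ratio_threshold = het_ratio_threshold,
    stringsAsFactors = FALSE
  )
}

#' Construct a haplotype genotype panel
#'
#' The central container: for every accession and every segment, the unordered
#' pair of haplotype IDs carried at that segment. Pairs are stored in
#' canonical (sorted) order; phase between segments is never used by any
#' downstream statistic. Missing data is segment-level (the whole amplicon
#' failed): both IDs are `NA` or neither is.
#'
#' @param hap_a,hap_b Integer matrices (accessions x segments) of haplotype
#'   IDs; `NA` marks a missing segment genotype.
#' @param accessions Character vector of accession IDs (row names).
#' @param segments Character vector of segment IDs (column names).
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(hap_a, hap_b, accessions = rownames(hap_a),
                      segments = colnames(hap_a)) {
  hap_a <- as.matrix(hap_a); hap_b <- as.matrix(hap_b)
  storage.mode(hap_a) <- "integer"; storage.mode(hap_b) <- "integer"
  if (!identical(dim(hap_a), dim(hap_b))) stop("hap_a/hap_b dimension mismatch")
  if (is.null(accessions)) accessions <- paste0("acc", seq_len(nrow(hap_a)))
  if (is.null(segments)) segments <- paste0("SEG", seq_len(ncol(hap_a)))
  if (anyDuplicated(accessions)) stop("duplicate accession ids")
  if (any(xor(is.na(hap_a), is.na(hap_b)))) {
    stop("half-missing pair: a segment genotype must be fully typed or fully missing")
  }
  swap <- !is.na(hap_a) & hap_a > hap_b
  if (any(swap)) {
    tmp <- hap_a[swap]; hap_a[swap] <- hap_b[swap]; hap_b[swap] <- tmp
  }
  dimnames(hap_a) <- dimnames(hap_b) <- list(accessions, segments)
  structure(list(hap_a = hap_a, hap_b = hap_b), class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d accessions x %d segments; %d missing genotype(s)\n",
              nrow(x$hap_a), ncol(x$hap_a), sum(is.na(x$hap_a))))
  invisible(x)
}

#' @rdname hap_panel
#' @param x A `hap_panel`.
#' @export
n_accessions <- function(x) nrow(x$hap_a)

#' @rdname hap_panel
#' @export
n_segments <- function(x) ncol(x$hap_a)

#' @rdname hap_panel
#' @export
panel_segments <- function(x) colnames(x$hap_a)

#' @rdname hap_panel
#' @export
panel_accessions <- function(x) rownames(x$hap_a)

#' Subset a panel
#'
#' @param x A `hap_panel`.
#' @param accessions,segments Indices or names; `NULL` keeps all.
#' @export
panel_subset <- function(x, accessions = NULL, segments = NULL) {
  i <- if (is.null(accessions)) seq_len(n_accessions(x)) else accessions
  j <- if (is.null(segments)) seq_len(n_segments(x)) else segments
  hap_panel(x$hap_a[i, j, drop = FALSE], x$hap_b[i, j, drop = FALSE])
}

#' Extract one accession's genotype profile as a long table
#'
#' @param x A `hap_panel`.
#' @param accession Accession ID or row index.
#' @return `data.frame` with columns segment_id, hap_a, hap_b.
#' @export
profile_table <- function(x, accession) {
  i <- if (is.character(accession)) match(accession, panel_accessions(x)) else accession
  if (is.na(i)) stop("unknown accession")
  data.frame(segment_id = panel_segments(x),
             hap_a = unname(x$hap_a[i, ]), hap_b = unname(x$hap_b[i, ]),
             stringsAsFactors = FALSE)
}

#' Validate a single genotype profile against a declared segment set
#'
#' Violations are data, not exceptions: the return value is a character
#' vector, empty when the profile is well-formed. A pair stored in
#' non-canonical order is normalised, not reported.
#'
#' @param profile A `data.frame` with columns `segment_id`, `hap_a`, `hap_b`
#'   (as returned by [profile_table()]).
#' @param segments Character vector of declared segment IDs.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_profile <- function(profile, segments) {
  out <- character(0)
  absent <- setdiff(segments, profile$segment_id)
  if (length(absent)) out <- c(out, paste("segment", absent, "absent"))
  extra <- setdiff(profile$segment_id, segments)
  if (length(extra)) out <- c(out, paste("segment", extra, "not declared"))
  dup <- unique(profile$segment_id[duplicated(profile$segment_id)])
  if (length(dup)) out <- c(out, paste("segment", dup, "duplicated"))
  half <- xor(is.na(profile$hap_a), is.na(profile$hap_b))
  if (any(half)) {
    out <- c(out, paste("segment", profile$segment_id[half], "half-missing pair"))
  }
  ok <- !is.na(profile$hap_a)
  if (any(ok & (profile$hap_a < 1 | profile$hap_b < 1))) {
    out <- c(out, "non-positive haplotype id")
  }
  out
}

# ---- genotype table I/O ---------------------------------------------------

#' Read a long-format genotype table
#'
#' Expects a TSV with header `accession_id`, `segment_id`, `hap_a`, `hap_b`;
#' `"."` denotes a missing value (a whole amplicon that failed: both IDs must
#' then be `"."`). Every accession must cover the same segment set.
#'
#' @param path Path to the TSV file.
#' @return A [hap_panel()]; segment order follows first appearance.
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("accession_id", "segment_id", "hap_a", "hap_b")
  if (!all(need %in% names(tab))) stop("genotype table must have columns ",
                                       paste(need, collapse = ", "))
  accs <- unique(tab$accession_id)
  segs <- unique(tab$segment_id)
  if (nrow(tab) != length(accs) * length(segs) ||
      any(table(tab$accession_id, tab$segment_id) != 1L)) {
    stop("ragged table: all accessions must cover the same segment set exactly once")
  }
  parse_hap <- function(v, other) {
    miss <- v == "."
    if (any(miss != (other == "."))) stop("half-missing pair")
    out <- rep(NA_integer_, length(v))
    num <- suppressWarnings(as.numeric(v[!miss]))
    if (anyNA(num) || any(num != floor(num))) stop("non-integer haplotype id")
    out[!miss] <- as.integer(num)
    out
  }
  a <- parse_hap(tab$hap_a, tab$hap_b)
  b <- parse_hap(tab$hap_b, tab$hap_a)
  ia <- match(tab$accession_id, accs); js <- match(tab$segment_id, segs)
  ha <- matrix(NA_integer_, length(accs), length(segs))
  hb <- ha
  ha[cbind(ia, js)] <- a
  hb[cbind(ia, js)] <- b
  hap_panel(ha, hb, accessions = accs, segments = segs)
}

#' Write a panel as a long-format genotype table
#'
#' @param x A `hap_panel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path) {
  fmt <- function(v) ifelse(is.na(v), ".", as.character(v))
  accs <- panel_accessions(x); segs <- panel_segments(x)
  tab <- data.frame(
    accession_id = rep(accs, each = length(segs)),
    segment_id = rep(segs, times = length(accs)),
    hap_a = fmt(as.vector(t(x$hap_a))),
    hap_b = fmt(as.vector(t(x$hap_b))),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- distance matrix I/O --------------------------------------------------

#' Read / write a labelled square distance matrix
#'
#' Tab-delimited with a header row of labels and the label repeated as the
#' first column; symmetry (1e-12) and a zero diagonal are enforced on read.
#'
#' @param path File path.
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  check_distance_matrix(m)
  m
}

#' @rdname read_distance_matrix
#' @param m Square symmetric matrix with zero diagonal.
#' @export
write_distance_matrix <- function(m, path) {
  check_distance_matrix(m)
  utils::write.table(cbind(id = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_distance_matrix <- function(m) {
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (!identical(rownames(m), colnames(m))) stop("row/column labels differ")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("distances must be non-negative")
  invisible(TRUE)
}

# ---- published reference-panel summary ------------------------------------

#' Per-segment summary of the red bayberry reference panel
#'
#' Loads the published per-segment summary of the 19-amplicon red bayberry
#' (*Morella rubra*) genotyping panel shipped with the package: amplicon
#' length and genomic copy number, SNP and haplotype counts, haplotype
#' diversity over all 141 accessions and over the 72 distinct genotypes, and
#' PIC. These printed values are inputs for panel-level aggregation; the raw
#' accession genotypes behind them are not redistributed.
#'
#' @return A `data.frame`, one row per segment.
#' @seealso [aggregate_segment_summary()]
#' @export
reference_segment_summary <- function() {
  path <- system.file("extdata", "segment_summary.tsv", package = "haplofinger",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Aggregate a per-segment summary table panel-wide
#'
#' Totals count duplicated amplicons (`copy_number = 2`) twice in the
#' amplified length, since two genomic copies are sequenced by one primer
#' pair; column means are plain unweighted means across segments.
#'
#' @param summary A `data.frame` in the layout of
#'   [reference_segment_summary()].
#' @return A list with `n_segments`, `total_snps`, `total_haplotypes`,
#'   `mean_haplotypes`, `mean_hd_all`, `mean_hd_distinct`, `mean_pic`, and
#'   `total_amplified_bp`.
#' @export
aggregate_segment_summary <- function(summary) {
  list(
    n_segments = nrow(summary),
    total_snps = sum(summary$n_snps),
    total_haplotypes = sum(summary$n_haplotypes),
    mean_haplotypes = mean(summary$n_haplotypes),
    mean_hd_all = mean(summary$hd_all),
    mean_hd_distinct = mean(summary$hd_distinct),
    mean_pic = mean(summary$pic),
    total_amplified_bp = sum(summary$amplicon_length * summary$copy_number)
  )
}
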