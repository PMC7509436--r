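# Per-segment diversity statistics on haplotype-based genotypes: allele
# (haplotype) frequencies, Nei gene diversity (haplotype diversity Hd),
# observed heterozygosity, and polymorphic information content (PIC,
# Botstein et al.).

#' Haplotype frequencies at one segment
#'
#' Every non-missing diploid genotype contributes two gene copies.
#'
#' @param panel A [hap_panel()].
#' @param segment Segment ID or column index.
#' @return A list with `freq` (named frequencies, names = haplotype IDs,
#'   sorted by ID) and `n_copies` (gene copies counted).
#' @export
allele_frequencies <- function(panel, segment) {
  j <- if (is.character(segment)) match(segment, panel_segments(panel)) else segment
  if (is.na(j)) stop("unknown segment")
  v <- c(panel$hap_a[, j], panel$hap_b[, j])
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("all genotypes missing at segment")
  tab <- table(v)
  list(freq = stats::setNames(as.numeric(tab) / length(v),
                              names(tab))[order(as.integer(names(tab)))],
       n_copies = length(v))
}

#' Frequency tables for every segment
#'
#' @param panel A [hap_panel()].
#' @return Named list (per segment) of [allele_frequencies()] entries;
#'   class `freq_table`.
#' @export
frequency_table <- function(panel) {
  segs <- panel_segments(panel)
  out <- lapply(segs, function(s) allele_frequencies(panel, s))
  names(out) <- segs
  structure(out, class = "freq_table")
}

#' Read / write per-segment haplotype frequency tables
#'
#' Long TSV with columns `segment_id`, `hap_id`, `freq`, `n_copies`;
#' frequencies of each segment must sum to 1 within 1e-9.
#'
#' @param x A [frequency_table()].
#' @param path File path.
#' @return `write_frequency_table` returns `path` invisibly;
#'   `read_frequency_table` returns a `freq_table` object.
#' @export
write_frequency_table <- function(x, path) {
  rows <- lapply(names(x), function(s) {
    data.frame(segment_id = s, hap_id = names(x[[s]]$freq),
               freq = unname(x[[s]]$freq), n_copies = x[[s]]$n_copies,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  out <- lapply(split(tab, factor(tab$segment_id, unique(tab$segment_id))),
                function(d) {
    check_freqs(d$freq)
    list(freq = stats::setNames(d$freq, d$hap_id),
         n_copies = d$n_copies[1])
  })
  structure(out[unique(tab$segment_id)], class = "freq_table")
}

check_freqs <- function(p) {
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-9) {
    stop("frequencies must be positive and sum to 1")
  }
  invisible(TRUE)
}

#' Haplotype (gene) diversity
#'
#' The probability that two randomly drawn gene copies carry different
#' haplotypes. The biased form is `1 - sum(p^2)`; the unbiased (default)
#' form rescales by `n/(n-1)` where `n` is the number of gene copies
#' counted.
#'
#' @param freqs Numeric frequency vector (positive, summing to 1).
#' @param n_copies Number of gene copies behind `freqs` (needed for the
#'   unbiased form; must be >= 2).
#' @param unbiased Logical, default `TRUE`.
#' @return Haplotype diversity in `[0, 1]` (unbiased can reach 1 exactly).
#' @export
haplotype_diversity <- function(freqs, n_copies = NULL, unbiased = TRUE) {
  check_freqs(freqs)
  h <- 1 - sum(freqs^2)
  if (!unbiased) return(h)
  if (is.null(n_copies) || n_copies < 2) {
    stop("unbiased haplotype diversity needs n_copies >= 2")
  }
  n_copies / (n_copies - 1) * h
}

#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` (Botstein-style): gene
#' diversity penalised by matings between identical heterozygotes, which are
#' uninformative for linkage.
#'
#' @param freqs Numeric frequency vector (positive, summing to 1).
#' @return PIC in `[0, 1)`.
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)
}

#' Observed heterozygosity at one segment
#'
#' Fraction of non-missing diploid genotypes carrying two distinct
#' haplotype IDs.
#'
#' @inheritParams allele_frequencies
#' @return Value in `[0, 1]`.
#' @export
observed_heterozygosity <- function(panel, segment) {
  j <- if (is.character(segment)) match(segment, panel_segments(panel)) else segment
  if (is.na(j)) stop("unknown segment")
  a <- panel$hap_a[, j]; b <- panel$hap_b[, j]
  ok <- !is.na(a)
  if (!any(ok)) stop("all genotypes missing at segment")
  mean(a[ok] != b[ok])
}

#' Per-segment diversity summary
#'
#' One row per segment: allele count `k`, gene copies, haplotype diversity
#' (biased and unbiased), observed heterozygosity, PIC, and the minor allele
#' frequency (smallest haplotype frequency). With `on_collapsed = TRUE` the
#' frequencies are computed over distinct genotypes only (one copy per
#' clone group), the convention under which PIC tracks the
#' distinct-genotype diversity.
#'
#' @param panel A [hap_panel()].
#' @param on_collapsed Collapse clones to distinct genotypes first?
#' @return `data.frame` with one row per segment plus attributes `means`
#'   and `sds` (unweighted column means/SDs across segments).
#' @export
summarize_segments <- function(panel, on_collapsed = FALSE) {
  if (on_collapsed) panel <- collapse_genotypes(panel)$representatives
  segs <- panel_segments(panel)
  rows <- lapply(segs, function(s) {
    fq <- allele_frequencies(panel, s)
    data.frame(segment_id = s, k = length(fq$freq), n_copies = fq$n_copies,
               hd = haplotype_diversity(fq$freq, fq$n_copies, unbiased = TRUE),
               hd_biased = haplotype_diversity(fq$freq, unbiased = FALSE),
               ho = observed_heterozygosity(panel, s),
               pic = pic(fq$freq), maf = min(fq$freq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  attr(out, "means") <- colMeans(out[num])
  attr(out, "sds") <- vapply(out[num], stats::sd, 0)
  out
}
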