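# SNP-site extraction from a multiple alignment of diploid IUPAC consensus
# sequences. Each aligned symbol expands to an unordered allele pair
# (A -> A/A, R -> A/G, ...); a column is a SNP site when at least two
# distinct bases occur among the non-missing expanded calls.

#' Read an aligned FASTA of IUPAC consensus sequences
#'
#' Thin wrapper returning a named character vector of equal-length upper-case
#' sequences. Uses Biostrings when available, otherwise a minimal reader
#' (plain multi-line FASTA).
#'
#' @param path FASTA file path.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(x))
    names(seqs) <- sub("\\s.*$", "", names(x))
    return(seqs)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file")
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  stats::setNames(toupper(seqs), id)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Write per-segment haplotype sequences as FASTA
#'
#' Record IDs follow the `SEGk_HAPj` convention.
#'
#' @param haplotypes Named list (per segment) of `data.frame`s with columns
#'   `hap_id` and `sequence` (the layout of a `sim_study()`'s `haplotypes`
#'   element or of [assign_hap_ids()] output).
#' @param path Output FASTA path.
#' @export
write_haplotype_fasta <- function(haplotypes, path) {
  seqs <- unlist(lapply(names(haplotypes), function(s) {
    h <- haplotypes[[s]]
    stats::setNames(h$sequence, paste0(s, "_HAP", h$hap_id))
  }))
  write_fasta(seqs, path)
}

#' Extract SNP sites from an aligned set of diploid consensus sequences
#'
#' Each sample's symbol at a column is expanded to its allele pair
#' ([iupac_expand()]); `N`, gaps and three-base ambiguity codes are missing.
#' A column is a SNP site iff at least two distinct bases occur among
#' non-missing samples. Columns with a gap in more than half the samples are
#' skipped outright (a guard against degenerate alignments; the intended
#' amplicons are indel-free).
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   over `A/C/G/T/N/-` and two-base IUPAC codes.
#' @return Object of class `snp_sites`: a list with `columns` (1-based
#'   alignment indices), `alleles` (list of character vectors), and
#'   `genotypes`, a samples x sites character matrix of `"X/Y"` unordered
#'   base pairs (`NA` = missing).
#' @export
extract_snps <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  len <- unique(nchar(alignment))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  n <- length(alignment)
  mat <- matrix(unlist(strsplit(alignment, ""), use.names = FALSE),
                nrow = n, byrow = TRUE,
                dimnames = list(names(alignment), NULL))
  cols <- integer(0); alleles <- list(); geno <- list()
  for (j in seq_len(len)) {
    sym <- mat[, j]
    if (sum(sym %in% c("-", ".")) > n / 2) next
    pairs <- lapply(sym, function(s) {
      if (s %in% c("-", ".")) return(NA_character_)
      iupac_expand(s)
    })
    miss <- vapply(pairs, function(p) anyNA(p), logical(1))
    obs <- unique(unlist(pairs[!miss]))
    if (length(obs) < 2L) next
    cols <- c(cols, j)
    alleles[[length(alleles) + 1L]] <- sort(obs)
    geno[[length(geno) + 1L]] <- vapply(pairs, function(p) {
      if (anyNA(p)) NA_character_ else paste(sort(p), collapse = "/")
    }, character(1))
  }
  gmat <- if (length(cols)) do.call(cbind, geno) else
    matrix(character(0), nrow = n, ncol = 0)
  rownames(gmat) <- names(alignment)
  colnames(gmat) <- as.character(cols)
  structure(list(columns = cols, alleles = alleles, genotypes = gmat),
            class = "snp_sites")
}

#' @export
print.snp_sites <- function(x, ...) {
  cat(sprintf("<snp_sites> %d site(s), %d sample(s)\n",
              length(x$columns), nrow(x$genotypes)))
  invisible(x)
}

#' Fraction of predicted variants later confirmed
#'
#' Simple bookkeeping for wet-lab verification of in-silico variant calls.
#'
#' @param n_predicted Number of predicted variants (> 0).
#' @param n_confirmed Number confirmed, `0 <= n_confirmed <= n_predicted`.
#' @return `n_confirmed / n_predicted`.
#' @examples
#' verification_rate(37, 36)  # 0.972973
#' @export
verification_rate <- function(n_predicted, n_confirmed) {
  if (n_predicted <= 0) stop("n_predicted must be positive")
  if (n_confirmed < 0 || n_confirmed > n_predicted) {
    stop("n_confirmed must lie in [0, n_predicted]")
  }
  n_confirmed / n_predicted
}
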