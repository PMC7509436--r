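# Probability-of-identity statistics and the fingerprinting marker set.
# All formulas assume Hardy-Weinberg genotype frequencies at each segment
# and independence across segments (segments are unlinked by design), so
# multi-locus probabilities are products of per-segment values.

#' Probability of identity between two random individuals (one locus)
#'
#' `PI = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`: the probability that two
#' independent Hardy-Weinberg genotypes coincide.
#'
#' @param freqs Numeric allele-frequency vector (positive, sum 1).
#' @return PI in `(0, 1]`.
#' @export
pi_random <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2); s4 <- sum(freqs^4)
  # sum p^4 + 4 * sum_{i<j} p_i^2 p_j^2  ==  2*S2^2 - S4
  s4 + 2 * (s2^2 - s4)
}

#' Probability of identity between two full siblings (one locus)
#'
#' `PI_sib = 0.25 + 0.5*S2 + 0.5*S2^2 - 0.25*S4` with `S2 = sum(p^2)`,
#' `S4 = sum(p^4)` (Evett & Weir sibling identity).
#'
#' @inheritParams pi_random
#' @return PI_sib in `(0, 1]`; always `>= pi_random(freqs)`.
#' @export
pi_sib <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2); s4 <- sum(freqs^4)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
}

#' Match probabilities for one observed genotype
#'
#' For a genotype at one segment, the probability that (a) a random
#' Hardy-Weinberg individual, (b) a parent or offspring, (c) a full sibling
#' carries the identical genotype. Homozygote `(i,i)`: `p_i^2`, `p_i`,
#' `((1+p_i)/2)^2`. Heterozygote `(i,j)`: `2 p_i p_j`, `(p_i+p_j)/2`,
#' `(1 + p_i + p_j + 2 p_i p_j)/4`. Multi-locus values are products across
#' segments.
#'
#' @param pair Length-2 vector of allele IDs (character or integer).
#' @param freqs Named allele-frequency vector containing both alleles.
#' @return Named numeric: `random`, `par_off`, `sib`.
#' @export
genotype_match_probs <- function(pair, freqs) {
  check_freqs(freqs)
  pair <- as.character(pair)
  if (anyNA(match(pair, names(freqs)))) stop("allele absent from frequency table")
  pi_ <- unname(freqs[pair[1]]); pj <- unname(freqs[pair[2]])
  if (pair[1] == pair[2]) {
    c(random = pi_^2, par_off = pi_, sib = ((1 + pi_) / 2)^2)
  } else {
    c(random = 2 * pi_ * pj, par_off = (pi_ + pj) / 2,
      sib = (1 + pi_ + pj + 2 * pi_ * pj) / 4)
  }
}

#' Per-genotype multi-locus match probabilities
#'
#' Applies [genotype_match_probs()] at every segment of every profile and
#' multiplies across segments (missing segments are skipped).
#'
#' @param panel A [hap_panel()].
#' @param freqs A [frequency_table()] (defaults to frequencies of `panel`).
#' @return `data.frame`: `accession`, `pi_random`, `pi_par_off`, `pi_sib`.
#' @export
profile_match_probs <- function(panel, freqs = frequency_table(panel)) {
  segs <- panel_segments(panel)
  out <- lapply(seq_len(n_accessions(panel)), function(i) {
    v <- c(random = 1, par_off = 1, sib = 1)
    for (j in seq_along(segs)) {
      a <- panel$hap_a[i, j]
      if (is.na(a)) next
      v <- v * genotype_match_probs(c(a, panel$hap_b[i, j]),
                                    freqs[[segs[j]]]$freq)
    }
    v
  })
  m <- do.call(rbind, out)
  data.frame(accession = panel_accessions(panel), pi_random = m[, "random"],
             pi_par_off = m[, "par_off"], pi_sib = m[, "sib"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Discrimination capacity under the pairwise-collision bound
#'
#' The largest population size `n` for which the expected number of
#' identical pairs, `n (n-1) / 2 * pi_value`, stays at or below `alpha`
#' (a birthday-problem bound). With `pi_value = 1` no pair is safe and the
#' capacity is 1.
#'
#' @param pi_value Multi-locus probability of identity, in `(0, 1]`.
#' @param alpha Tolerated expected number of collisions (default 0.05).
#' @return Integer capacity (>= 1).
#' @examples
#' discrimination_capacity(6.4e-10)  # 12500
#' discrimination_capacity(1.5e-4)   # 26
#' @export
discrimination_capacity <- function(pi_value, alpha = 0.05) {
  if (!(pi_value > 0 && pi_value <= 1)) stop("pi_value must lie in (0, 1]")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  n <- floor((1 + sqrt(1 + 8 * alpha / pi_value)) / 2)
  while (n * (n - 1) / 2 * pi_value > alpha) n <- n - 1
  while ((n + 1) * n / 2 * pi_value <= alpha) n <- n + 1
  max(as.integer(n), 1L)
}

#' Cumulative discrimination along an ordered segment list
#'
#' Adds segments one at a time (typically in descending PIC order) and
#' tracks the running product of PI and PI_sib together with the number of
#' distinct genotypes separable by the prefix.
#'
#' @param panel A [hap_panel()].
#' @param segment_order Permutation of the panel's segments (IDs); default
#'   descending PIC.
#' @param freqs Frequencies used for PI (default from `panel`).
#' @return `data.frame`: `segment_id`, `pi`, `pi_sib` (per segment),
#'   `cum_pi`, `cum_pi_sib`, `n_distinct`.
#' @export
cumulative_discrimination <- function(panel, segment_order = NULL,
                                      freqs = frequency_table(panel)) {
  segs <- panel_segments(panel)
  if (is.null(segment_order)) {
    pics <- vapply(segs, function(s) pic(freqs[[s]]$freq), 0)
    segment_order <- segs[order(-pics, seq_along(segs))]
  }
  if (!setequal(segment_order, segs) || length(segment_order) != length(segs)) {
    stop("segment_order must be a permutation of the panel's segments")
  }
  pis <- vapply(segment_order, function(s) pi_random(freqs[[s]]$freq), 0)
  sibs <- vapply(segment_order, function(s) pi_sib(freqs[[s]]$freq), 0)
  nd <- vapply(seq_along(segment_order), function(m) {
    collapse_genotypes(panel_subset(panel, segments = segment_order[seq_len(m)]))$n_groups
  }, 0L)
  data.frame(segment_id = segment_order, pi = pis, pi_sib = sibs,
             cum_pi = cumprod(pis), cum_pi_sib = cumprod(sibs),
             n_distinct = nd, row.names = NULL, stringsAsFactors = FALSE)
}

#' All minimum-cardinality segment subsets separating every profile
#'
#' Exact search: subset sizes are tried in increasing order; within a size,
#' subsets are enumerated in combination order over segments pre-sorted by
#' descending PIC (so informative subsets are met early), with an upper
#' bound prune: a subset whose per-segment distinct-genotype counts
#' multiply to fewer than the number of profiles cannot separate them.
#' Every subset of the first succeeding size is returned.
#'
#' @param panel A [hap_panel()] of distinct profiles (collapse clones
#'   first); an error is raised if the full segment set cannot separate
#'   them.
#' @return List with `size` (minimal cardinality) and `subsets` (list of
#'   character vectors of segment IDs, in deterministic order).
#' @export
minimal_marker_set <- function(panel) {
  n <- n_accessions(panel)
  segs <- panel_segments(panel)
  if (collapse_genotypes(panel)$n_groups < n) {
    stop("indistinguishable profiles present")
  }
  fq <- frequency_table(panel)
  pics <- vapply(segs, function(s) pic(fq[[s]]$freq), 0)
  segs <- segs[order(-pics, seq_along(segs))]
  kdist <- vapply(segs, function(s) {
    collapse_genotypes(panel_subset(panel, segments = s))$n_groups
  }, 0L)
  separates <- function(sub) {
    collapse_genotypes(panel_subset(panel, segments = sub))$n_groups == n
  }
  for (s in seq_along(segs)) {
    hits <- list()
    cmb <- utils::combn(length(segs), s)
    for (c_i in seq_len(ncol(cmb))) {
      idx <- cmb[, c_i]
      if (prod(kdist[idx]) < n) next
      sub <- segs[idx]
      if (separates(sub)) hits[[length(hits) + 1L]] <- sub
    }
    if (length(hits)) return(list(size = s, subsets = hits))
  }
  stop("unreachable: full set separates by precondition")
}

#' Barcode string for a profile over a segment subset
#'
#' `"SEGk:i/j"` tokens joined by `";"`, segments in subset order, pairs in
#' canonical order. Identical profiles yield identical codes.
#'
#' @param panel A [hap_panel()].
#' @param accession Accession ID or index.
#' @param subset Character vector of segment IDs (default: all).
#' @return A single barcode string.
#' @export
fingerprint_code <- function(panel, accession, subset = panel_segments(panel)) {
  prof <- profile_table(panel, accession)
  idx <- match(subset, prof$segment_id)
  if (anyNA(idx)) stop("unknown segment in subset")
  a <- prof$hap_a[idx]; b <- prof$hap_b[idx]
  if (anyNA(a)) stop("missing segment genotype in subset")
  paste(sprintf("%s:%d/%d", subset, a, b), collapse = ";")
}
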