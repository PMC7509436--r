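# Clone / somatic-mutant / parentage analysis. The differential segment
# number (DSN) between two profiles is the count of segments at which their
# canonical haplotype pairs differ: 0 marks a clone or synonym, a small DSN
# a somatic variant (e.g. a single loss-of-heterozygosity event), larger
# DSNs distinct lineages to be screened for parent-offspring sharing.

#' Differential segment number between two profiles
#'
#' Segments missing in either profile are skipped; the number skipped is
#' attached as attribute `n_skipped`.
#'
#' @param a,b Profile tables ([profile_table()] layout) over the same
#'   segment set.
#' @return Integer DSN with attribute `n_skipped`.
#' @export
dsn <- function(a, b) {
  idx <- match(a$segment_id, b$segment_id)
  if (anyNA(idx)) stop("profiles cover different segment sets")
  ok <- !is.na(a$hap_a) & !is.na(b$hap_a[idx])
  d <- sum(a$hap_a[ok] != b$hap_a[idx][ok] | a$hap_b[ok] != b$hap_b[idx][ok])
  structure(as.integer(d), n_skipped = sum(!ok))
}

#' Pairwise DSN matrix
#'
#' @param panel A [hap_panel()].
#' @return Symmetric integer matrix (zero diagonal) with attribute
#'   `n_skipped`, the matching matrix of pairwise skipped-segment counts.
#' @export
dsn_matrix <- function(panel) {
  n <- n_accessions(panel)
  ha <- panel$hap_a; hb <- panel$hap_b
  d <- matrix(0L, n, n, dimnames = list(panel_accessions(panel),
                                        panel_accessions(panel)))
  sk <- d
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ok <- !is.na(ha[i, ]) & !is.na(ha[j, ])
      d[i, j] <- d[j, i] <-
        sum(ha[i, ok] != ha[j, ok] | hb[i, ok] != hb[j, ok])
      sk[i, j] <- sk[j, i] <- sum(!ok)
    }
  }
  attr(d, "n_skipped") <- sk
  d
}

#' Classify profile pairs by DSN
#'
#' `dsn = 0`: identical (clone or synonym); `1 <= dsn <= somatic_threshold`:
#' somatic variant tier; above the threshold: distinct lineages (candidates
#' for parentage screening). The default threshold of 3 reflects panels
#' where observed somatic variants differ at a single segment while
#' unrelated genotypes differ at four or more.
#'
#' @param d A DSN matrix from [dsn_matrix()].
#' @param somatic_threshold Highest DSN still classed as somatic variant.
#' @return `data.frame`: `id_a`, `id_b`, `dsn`, `label`.
#' @export
classify_pairs <- function(d, somatic_threshold = 3L) {
  idx <- which(upper.tri(d), arr.ind = TRUE)
  v <- d[idx]
  lab <- ifelse(v == 0L, "identical",
         ifelse(v <= somatic_threshold, "somatic_variant", "distinct"))
  data.frame(id_a = rownames(d)[idx[, 1]], id_b = colnames(d)[idx[, 2]],
             dsn = as.integer(v), label = lab, stringsAsFactors = FALSE)
}

#' Candidate parent-offspring pairs and the pedigree network
#'
#' A pair of distinct genotypes is a candidate parent-offspring pair when it
#' is not in the somatic tier (`dsn > somatic_threshold`) and the two
#' haplotype pairs share at least one haplotype at every segment (a true
#' parent transmits one haplotype per unlinked segment; segments missing in
#' either profile are compatible by default). Direction is unknown, so the
#' pedigree network is an undirected graph.
#'
#' @param panel A [hap_panel()] of collapsed (distinct) profiles.
#' @param somatic_threshold Passed to the DSN tier rule (default 3).
#' @param multiplicity Optional named vector of clone-group sizes used as a
#'   node attribute.
#' @return List: `pairs` (data.frame `id_a`, `id_b`, `dsn`), `graph`
#'   (igraph, all profiles as nodes), `degree` (named link counts).
#' @export
candidate_parent_offspring <- function(panel, somatic_threshold = 3L,
                                       multiplicity = NULL) {
  n <- n_accessions(panel)
  ha <- panel$hap_a; hb <- panel$hap_b
  d <- dsn_matrix(panel)
  res <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (d[i, j] <= somatic_threshold) next
      ok <- !is.na(ha[i, ]) & !is.na(ha[j, ])
      share <- ha[i, ok] == ha[j, ok] | ha[i, ok] == hb[j, ok] |
               hb[i, ok] == ha[j, ok] | hb[i, ok] == hb[j, ok]
      if (all(share)) res[[length(res) + 1L]] <- c(i, j)
    }
  }
  accs <- panel_accessions(panel)
  pairs <- if (length(res)) {
    m <- do.call(rbind, res)
    data.frame(id_a = accs[m[, 1]], id_b = accs[m[, 2]],
               dsn = d[m], stringsAsFactors = FALSE)
  } else {
    data.frame(id_a = character(0), id_b = character(0), dsn = integer(0))
  }
  g <- igraph::graph_from_data_frame(pairs[, c("id_a", "id_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = accs))
  if (!is.null(multiplicity)) {
    igraph::V(g)$multiplicity <- unname(multiplicity[accs])
  }
  deg <- igraph::degree(g)
  list(pairs = pairs, graph = g, degree = deg)
}

#' Is a candidate parent Mendelian-incompatible with an offspring?
#'
#' One locus. With no other parent known, the candidate is excluded iff it
#' shares no allele with the offspring. With the other (true) parent known,
#' it is excluded iff the offspring's pair cannot be split into one allele
#' from the known parent and one from the candidate.
#'
#' @param offspring,candidate,known Length-2 allele vectors (`known` may be
#'   `NULL`).
#' @return `TRUE` if the candidate is excluded at this locus.
#' @export
parent_excluded <- function(offspring, candidate, known = NULL) {
  o <- as.character(offspring); cnd <- as.character(candidate)
  if (is.null(known)) {
    return(!any(o %in% cnd))
  }
  kn <- as.character(known)
  for (perm in list(o, rev(o))) {
    if (perm[1] %in% kn && perm[2] %in% cnd) return(FALSE)
  }
  TRUE
}

# HWE genotype classes for k alleles: rows (i, j) with i <= j, weights
# p_i^2 / 2 p_i p_j, and the carrier incidence matrix.
hwe_classes <- function(p) {
  k <- length(p)
  ij <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  w <- ifelse(ij[, 1] == ij[, 2], p[ij[, 1]]^2, 2 * p[ij[, 1]] * p[ij[, 2]])
  carrier <- matrix(FALSE, nrow(ij), k)
  carrier[cbind(seq_len(nrow(ij)), ij[, 1])] <- TRUE
  carrier[cbind(seq_len(nrow(ij)), ij[, 2])] <- TRUE
  list(i = ij[, 1], j = ij[, 2], w = w, carrier = carrier)
}

#' Per-locus parentage non-exclusion probability
#'
#' Probability that a random unrelated Hardy-Weinberg candidate is NOT
#' excluded as a parent of a random offspring, computed by exact
#' enumeration over HWE genotype classes and Mendelian transmissions
#' (no transcription of literature closed forms). Scenarios:
#' `one_parent_known` (the other true parent's genotype is available),
#' `no_parent_known`, and `parent_pair` (a candidate pair is tested
#' jointly). Cumulative non-exclusion across independent loci is the
#' product of per-locus values ([cumulative_nonexclusion()]).
#'
#' @param freqs Allele-frequency vector (positive, sum 1).
#' @param scenario One of `"one_parent_known"`, `"no_parent_known"`,
#'   `"parent_pair"`.
#' @return Non-exclusion probability in `(0, 1]`.
#' @export
nonexclusion <- function(freqs, scenario = c("one_parent_known",
                                             "no_parent_known",
                                             "parent_pair")) {
  scenario <- match.arg(scenario)
  check_freqs(freqs)
  p <- unname(freqs)
  k <- length(p)
  if (scenario == "parent_pair" && k > 40L) stop("enumeration too large")
  cl <- hwe_classes(p)
  # enumerated candidate carrier probabilities
  carry <- as.numeric(crossprod(cl$carrier, cl$w))          # P(C carries a)
  carry_both <- crossprod(cl$carrier * cl$w, cl$carrier)    # P(C carries a & b)
  carry_either <- outer(carry, carry, `+`) - as.matrix(carry_both)
  if (scenario == "no_parent_known") {
    # offspring marginal under random mating is HWE
    ne <- vapply(seq_along(cl$w), function(g) {
      a <- cl$i[g]; b <- cl$j[g]
      if (a == b) carry[a] else carry_either[a, b]
    }, 0)
    return(unname(sum(cl$w * ne)))
  }
  if (scenario == "parent_pair") {
    ne <- vapply(seq_along(cl$w), function(g) {
      a <- cl$i[g]; b <- cl$j[g]
      if (a == b) return(carry[a]^2)
      # one candidate transmits a, the other b (either order)
      2 * carry[a] * carry[b] - carry_both[a, b]^2
    }, 0)
    return(unname(sum(cl$w * ne)))
  }
  # one_parent_known: enumerate known mother M, maternal allele m (1/2 each),
  # paternal allele f ~ p; offspring O = {m, f}. The candidate escapes
  # exclusion iff it carries some allele of O that can be paternal given M.
  total <- 0
  for (g in seq_along(cl$w)) {
    m_alleles <- c(cl$i[g], cl$j[g])
    in_m <- logical(k); in_m[m_alleles] <- TRUE
    for (m in unique(m_alleles)) {
      wm <- cl$w[g] * (if (cl$i[g] == cl$j[g]) 1 else 0.5)
      for (f in seq_len(k)) {
        o <- c(m, f)
        # possible paternal alleles of O given mother M
        pa <- unique(o[c(in_m[o[2]], in_m[o[1]])])
        ne <- if (length(pa) == 1L) carry[pa] else carry_either[pa[1], pa[2]]
        total <- total + wm * p[f] * ne
      }
    }
  }
  unname(total)
}

#' Cumulative non-exclusion across segments
#'
#' @param freqs A [frequency_table()] (or list of frequency vectors).
#' @param scenario As in [nonexclusion()].
#' @return Product of per-locus non-exclusion probabilities, with the
#'   per-locus values as attribute `per_locus`.
#' @export
cumulative_nonexclusion <- function(freqs, scenario = "one_parent_known") {
  per <- vapply(freqs, function(f) {
    v <- if (is.list(f)) f$freq else f
    nonexclusion(v, scenario)
  }, 0)
  structure(prod(per), per_locus = per)
}
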