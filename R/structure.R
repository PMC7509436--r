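# Distance-based structure analysis: simple-matching genetic distance over
# multi-allelic diploid segments, UPGMA/NJ trees with segment-resampling
# bootstrap support, principal coordinates, and allele-coverage core-set
# selection by greedy seeding plus steepest-ascent exchange.

#' Simple-matching genetic distance between diploid profiles
#'
#' Per segment the two unordered haplotype pairs share `m` in {0, 1, 2}
#' haplotypes counted with multiplicity; the per-segment similarity is
#' `m/2` and the distance is one minus the mean similarity over segments
#' comparable in both profiles (missing segments are skipped pairwise).
#'
#' @param panel A [hap_panel()].
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal.
#' @export
simple_matching_distance <- function(panel) {
  n <- n_accessions(panel)
  ha <- panel$hap_a; hb <- panel$hap_b
  d <- matrix(0, n, n, dimnames = list(panel_accessions(panel),
                                       panel_accessions(panel)))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ok <- !is.na(ha[i, ]) & !is.na(ha[j, ])
      if (!any(ok)) stop("no comparable segment between profiles ",
                         rownames(ha)[i], " and ", rownames(ha)[j])
      m <- shared_allele_count(ha[i, ok], hb[i, ok], ha[j, ok], hb[j, ok])
      d[i, j] <- d[j, i] <- 1 - mean(m / 2)
    }
  }
  d
}

# multiset intersection size of {a1,b1} and {a2,b2}, vectorised over segments
shared_allele_count <- function(a1, b1, a2, b2) {
  # both pairs canonical (a <= b)
  full <- (a1 == a2 & b1 == b2)
  m <- integer(length(a1))
  m[full] <- 2L
  part <- !full & (a1 == a2 | a1 == b2 | b1 == a2 | b1 == b2)
  # one shared allele unless the only overlap is via a doubled allele that
  # the other pair carries once -- multiset logic below
  m[part] <- 1L
  # special case: pairs like (1,1) vs (1,1) handled by `full`; (1,1) vs (1,2)
  # share one; (1,2) vs (1,2) full; (1,2) vs (2,1) impossible (canonical)
  m
}

#' Build a clustering tree from a distance matrix
#'
#' UPGMA is average-linkage agglomeration (ultrametric heights); NJ is
#' Saitou-Nei neighbour joining. Negative NJ branch lengths are clamped to
#' zero with the deficit moved to the sister edge, a standard repair that
#' preserves path lengths through the parent node.
#'
#' @param d Symmetric distance matrix with labels and zero diagonal.
#' @param method `"upgma"` or `"nj"`.
#' @return An [ape::phylo] tree.
#' @export
build_tree <- function(d, method = c("upgma", "nj")) {
  method <- match.arg(method)
  check_distance_matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 leaves")
  if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    return(ape::as.phylo(hc))
  }
  if (nrow(d) == 2L) {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    return(ape::as.phylo(hc))
  }
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sisters <- setdiff(which(tr$edge[, 1L] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sisters)) {
      s <- sisters[1L]
      tr$edge.length[s] <- max(tr$edge.length[s] + deficit, 0)
    }
  }
  tr
}

#' Bootstrap support by segment resampling
#'
#' Segments are resampled with replacement `B` times; the simple-matching
#' distance and tree are recomputed on each replicate and the support of an
#' internal edge is the percentage of replicates containing the same leaf
#' bipartition. Loci (segments) are the resampling unit, consistent with
#' segments being the unit of the distance. Deterministic for a fixed seed.
#'
#' @param panel A [hap_panel()].
#' @param method `"upgma"` or `"nj"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return The tree on the full data with `node.label` set to the support
#'   percentages (root label empty).
#' @export
bootstrap_support <- function(panel, method = "nj", B = 1000L, seed = NULL) {
  if (B < 1L) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ref <- build_tree(simple_matching_distance(panel), method)
  m <- n_segments(panel)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(m, m, replace = TRUE)
    boots[[b]] <- build_tree(simple_matching_distance(
      panel_subset(panel, segments = idx)), method)
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / B)
  lab <- as.character(supp)
  lab[1L] <- ""  # root bipartition is trivial
  ref$node.label <- lab
  attr(ref, "support") <- supp
  ref
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition
#' (via [stats::cmdscale()]); axes are ordered by eigenvalue, and negative
#' eigenvalues are dropped from the explained-variance denominator.
#'
#' @param d Symmetric distance matrix.
#' @return List: `coords` (rows = samples, columns = axes with positive
#'   eigenvalues), `eig` (all eigenvalues), `explained` (fraction per
#'   retained axis).
#' @export
pcoa <- function(d) {
  check_distance_matrix(d)
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; the axis
  # count is decided from the eigenvalues below, so the warning is moot
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-9 * max(abs(eig), 1))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coords = coords, eig = eig,
       explained = eig[pos] / sum(eig[pos]))
}

# incidence matrix: accessions x (segment, haplotype) indicator
allele_incidence <- function(panel) {
  n <- n_accessions(panel)
  cols <- list()
  for (j in seq_len(n_segments(panel))) {
    ids <- sort(unique(stats::na.omit(c(panel$hap_a[, j], panel$hap_b[, j]))))
    for (h in ids) {
      cols[[paste0(panel_segments(panel)[j], ":", h)]] <-
        !is.na(panel$hap_a[, j]) &
          (panel$hap_a[, j] == h | panel$hap_b[, j] == h)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- panel_accessions(panel)
  m
}

coverage_of <- function(incidence, subset) {
  sum(colSums(incidence[subset, , drop = FALSE]) > 0L) / ncol(incidence)
}

#' Allele-coverage core-set selection
#'
#' For each requested size, selects genotypes maximising the fraction of
#' distinct (segment, haplotype) alleles covered. The optimiser is greedy
#' seeding (add the genotype with the largest coverage gain, first-index
#' tie-break) followed by steepest-ascent single-swap exchange until no
#' swap improves, repeated from `n_restarts` seeded random starts; the best
#' subset found is kept. Deterministic for a fixed seed.
#'
#' @param panel A [hap_panel()] of distinct genotypes.
#' @param sizes Integer vector of core sizes, within `[1, n]`.
#' @param n_restarts Random restarts in addition to the greedy start
#'   (default 200).
#' @param seed Optional integer seed.
#' @return `data.frame` with `size`, `coverage`, and `members` (list
#'   column of accession IDs).
#' @export
core_select <- function(panel, sizes, n_restarts = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inc <- allele_incidence(panel)
  n <- nrow(inc)
  if (any(sizes < 1L | sizes > n)) stop("sizes must lie in [1, n]")
  counts_of <- function(sub) colSums(inc[sub, , drop = FALSE])
  improve <- function(sub) {
    # steepest-ascent single swap
    repeat {
      cnt <- counts_of(sub)
      cov0 <- sum(cnt > 0L)
      best_gain <- 0L; best_swap <- NULL
      outside <- setdiff(seq_len(n), sub)
      for (s in sub) {
        cnt_wo <- cnt - inc[s, ]
        lost <- sum(cnt > 0L & cnt_wo == 0L)
        for (u in outside) {
          gained <- sum(cnt_wo == 0L & inc[u, ])
          gain <- gained - lost
          if (gain > best_gain) { best_gain <- gain; best_swap <- c(s, u) }
        }
      }
      if (is.null(best_swap)) return(sub)
      sub <- c(setdiff(sub, best_swap[1L]), best_swap[2L])
    }
  }
  greedy <- function(size) {
    sub <- integer(0)
    cnt <- numeric(ncol(inc))
    for (step in seq_len(size)) {
      gains <- vapply(seq_len(n), function(u) {
        if (u %in% sub) return(-1L)
        sum(cnt == 0L & inc[u, ])
      }, 0L)
      sub <- c(sub, which.max(gains))
      cnt <- counts_of(sub)
    }
    sub
  }
  out <- lapply(sort(unique(sizes)), function(size) {
    best <- improve(greedy(size))
    best_cov <- coverage_of(inc, best)
    for (r in seq_len(n_restarts)) {
      cand <- improve(sample.int(n, size))
      cc <- coverage_of(inc, cand)
      if (cc > best_cov) { best <- cand; best_cov <- cc }
    }
    data.frame(size = size, coverage = best_cov,
               members = I(list(rownames(inc)[sort(best)])))
  })
  do.call(rbind, out)
}
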