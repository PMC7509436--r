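# Haplotype reconstruction for one amplicon segment from unphased multi-SNP
# diploid genotypes, by gene-counting expectation-maximisation on haplotype
# frequencies (Excoffier-Slatkin style). Segments are short and unlinked, so
# each is phased independently; no recombination model is needed.

split_site_pair <- function(g) {
  # "A/G" -> c("A","G"); NA passes through
  if (is.na(g)) return(c(NA_character_, NA_character_))
  strsplit(g, "/", fixed = TRUE)[[1]]
}

#' Enumerate haplotype pairs compatible with one diploid genotype vector
#'
#' A vector with `h` heterozygous sites admits `max(1, 2^(h-1))` unordered
#' haplotype pairs (orientations modulo swapping the two haplotypes); a
#' fully homozygous vector admits its single trivial pair.
#'
#' @param v Character vector of unordered per-site base pairs (`"X/Y"`),
#'   one per SNP site; no missing entries.
#' @return List of length-2 character vectors (sorted haplotype pairs).
#' @export
enumerate_compatible_pairs <- function(v) {
  if (anyNA(v)) stop("genotype vector contains missing sites")
  alle <- vapply(v, split_site_pair, character(2))
  het <- which(alle[1, ] != alle[2, ])
  h <- length(het)
  if (h > 20L) stop("too many heterozygous sites for enumeration")
  base <- alle[1, ]
  if (h == 0L) {
    s <- paste(base, collapse = "")
    return(list(c(s, s)))
  }
  # fix the orientation of the first het site; vary the remaining h-1
  n_cfg <- 2^(h - 1L)
  out <- vector("list", n_cfg)
  for (cfg in seq_len(n_cfg) - 1L) {
    bits <- c(0L, as.integer(intToBits(cfg))[seq_len(max(h - 1L, 0L))])
    h1 <- base; h2 <- alle[2, ]
    flip <- het[bits == 1L]
    h1[flip] <- alle[2, flip]; h2[flip] <- alle[1, flip]
    s1 <- paste(h1, collapse = ""); s2 <- paste(h2, collapse = "")
    out[[cfg + 1L]] <- sort(c(s1, s2))
  }
  out
}

#' Phase one segment by expectation-maximisation
#'
#' Gene-counting EM on haplotype frequencies: the E-step weights each
#' compatible unordered pair (h1, h2) of each individual by
#' `c * p(h1) * p(h2)` with `c = 2` when `h1 != h2`, normalised per
#' individual; the M-step sets frequencies to the expected haplotype counts
#' over `2N` gene copies. The first run is initialised uniformly over all
#' haplotypes compatible with at least one individual; because a perfectly
#' symmetric start can be a stationary saddle of the likelihood (tied pair
#' weights that gene counting never breaks), a few additional runs from
#' seeded Dirichlet-jittered starts are performed and the best likelihood
#' kept, so the whole procedure stays deterministic. The log-likelihood is
#' checked to be non-decreasing at every iteration of every run.
#'
#' Individuals with any missing site are excluded from the frequency
#' estimation (and receive no phased pair).
#'
#' @param genotypes Character matrix, samples x sites, of `"X/Y"` unordered
#'   base pairs (`NA` = missing site), or a list of such vectors.
#' @param tol Convergence tolerance on the maximum absolute frequency
#'   change (default `1e-8`).
#' @param max_iter Iteration cap per run (default `1000`).
#' @param restarts Number of jittered restarts after the uniform-start run
#'   (default 10; 0 reproduces plain uniform-start EM).
#' @param seed Integer seed for the restart jitter (default 1; the RNG
#'   state of the session is left untouched).
#' @return Object of class `phasing_result`: `freq` (named haplotype
#'   frequencies, summing to 1), `pairs` (data.frame `sample`, `hap1`,
#'   `hap2`, `posterior` with the maximum-probability pair per phased
#'   sample; equally likely pairs are resolved to the lexicographically
#'   smallest), `loglik`, `loglik_trace` (best run), `n_iter`, `converged`,
#'   `excluded` (samples left unphased for missingness).
#' @export
em_phase <- function(genotypes, tol = 1e-8, max_iter = 1000L,
                     restarts = 10L, seed = 1L) {
  if (is.list(genotypes) && !is.data.frame(genotypes)) {
    genotypes <- do.call(rbind, genotypes)
  }
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) == 0L) stop("empty input: no genotype vectors")
  if (tol <= 0) stop("tol must be positive")
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(genotypes)))
  usable <- !apply(genotypes, 1L, anyNA)
  if (!any(usable)) stop("empty input: all samples have missing sites")
  cand <- lapply(which(usable), function(i) {
    enumerate_compatible_pairs(genotypes[i, ])
  })
  haps <- sort(unique(unlist(cand)))
  k <- length(haps)
  # per-individual pair index matrices and het multiplier
  p1 <- lapply(cand, function(ps) match(vapply(ps, `[`, "", 1L), haps))
  p2 <- lapply(cand, function(ps) match(vapply(ps, `[`, "", 2L), haps))
  mult <- lapply(cand, function(ps) {
    ifelse(vapply(ps, function(p) p[1] != p[2], logical(1)), 2, 1)
  })
  n_ind <- length(cand)

  em_run <- function(p) {
    loglik_trace <- numeric(0)
    prev_ll <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      counts <- numeric(k)
      ll <- 0
      for (i in seq_len(n_ind)) {
        w <- mult[[i]] * p[p1[[i]]] * p[p2[[i]]]
        tot <- sum(w)
        ll <- ll + log(tot)
        w <- w / tot
        cnt <- numeric(k)
        for (j in seq_along(w)) {
          cnt[p1[[i]][j]] <- cnt[p1[[i]][j]] + w[j]
          cnt[p2[[i]][j]] <- cnt[p2[[i]][j]] + w[j]
        }
        counts <- counts + cnt
      }
      if (ll < prev_ll - 1e-9) {
        stop("internal error: EM log-likelihood decreased")
      }
      loglik_trace <- c(loglik_trace, ll)
      newp <- counts / (2 * n_ind)
      delta <- max(abs(newp - p))
      p <- newp
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
      prev_ll <- ll
    }
    list(p = p, loglik = ll, loglik_trace = loglik_trace,
         iter = iter, converged = converged)
  }

  best <- em_run(rep(1 / k, k))
  if (restarts > 0L && k > 1L) {
    # draw all jittered starts from a private RNG stream, leaving the
    # session RNG state untouched
    rng <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    inits <- lapply(seq_len(restarts), function(r) {
      g <- stats::rgamma(k, shape = 1)
      g / sum(g)
    })
    if (is.null(rng)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", rng, globalenv())
    }
    for (init in inits) {
      run <- em_run(init)
      if (run$loglik > best$loglik + 1e-12) best <- run
    }
  }
  p <- best$p
  loglik_trace <- best$loglik_trace
  iter <- best$iter
  converged <- best$converged
  names(p) <- haps
  # MAP pair per individual; ties -> lexicographically smallest pair
  map <- lapply(seq_len(n_ind), function(i) {
    w <- mult[[i]] * p[p1[[i]]] * p[p2[[i]]]
    tot <- sum(w)
    post <- if (tot > 0) w / tot else rep(1 / length(w), length(w))
    best <- which(post >= max(post) - 1e-12)
    key <- paste(haps[p1[[i]][best]], haps[p2[[i]][best]])
    pick <- best[order(key)][1L]
    c(haps[p1[[i]][pick]], haps[p2[[i]][pick]], post[pick])
  })
  pairs <- data.frame(
    sample = ids[usable],
    hap1 = vapply(map, `[`, "", 1L),
    hap2 = vapply(map, `[`, "", 2L),
    posterior = as.numeric(vapply(map, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  # drop haplotypes whose estimated frequency collapsed to ~0
  keep <- p > 1e-12 | haps %in% c(pairs$hap1, pairs$hap2)
  p <- p[keep] / sum(p[keep])
  structure(list(freq = p, pairs = pairs,
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace, n_iter = iter,
                 converged = converged, excluded = ids[!usable]),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf("<phasing_result> %d haplotype(s), %d sample(s), loglik %.4f (%d iter%s)\n",
              length(x$freq), nrow(x$pairs), x$loglik, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Assign numeric haplotype IDs in descending frequency order
#'
#' IDs run 1..k, most frequent first; frequency ties are broken by
#' lexicographic sequence order, so the assignment is deterministic.
#'
#' @param result A [em_phase()] result (or a named frequency vector).
#' @return `data.frame` with `hap_id`, `sequence`, `freq`.
#' @export
assign_hap_ids <- function(result) {
  p <- if (inherits(result, "phasing_result")) result$freq else result
  ord <- order(-p, names(p))
  data.frame(hap_id = seq_along(p), sequence = names(p)[ord],
             freq = unname(p[ord]), stringsAsFactors = FALSE)
}

#' Convert a phasing result to numeric haplotype-ID genotypes
#'
#' @param result A [em_phase()] result.
#' @param ids Optional ID table from [assign_hap_ids()] (computed if absent).
#' @return `data.frame` with `sample`, `hap_a`, `hap_b` (canonical order).
#' @export
phased_genotypes <- function(result, ids = assign_hap_ids(result)) {
  a <- ids$hap_id[match(result$pairs$hap1, ids$sequence)]
  b <- ids$hap_id[match(result$pairs$hap2, ids$sequence)]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(sample = result$pairs$sample, hap_a = a, hap_b = b,
             stringsAsFactors = FALSE)
}

#' Collapse accessions into distinct genotypes
#'
#' Accessions are grouped by exact equality of the canonical haplotype pair
#' at every segment (missing matches only missing). Groups are numbered in
#' descending size, ties by first-accession order; the representative is the
#' first accession of the group.
#'
#' @param panel A [hap_panel()].
#' @return A list: `groups` (data.frame `group_id`, `size`,
#'   `representative`), `membership` (named vector accession -> group_id),
#'   `representatives` (a `hap_panel` of one representative per group, rows
#'   in group order), `n_groups`.
#' @export
collapse_genotypes <- function(panel) {
  fmt <- function(v) ifelse(is.na(v), ".", as.character(v))
  keys <- apply(matrix(paste(fmt(panel$hap_a), fmt(panel$hap_b), sep = "/"),
                       nrow = n_accessions(panel)), 1L, paste, collapse = ";")
  first <- !duplicated(keys)
  uk <- keys[first]
  size <- as.integer(table(factor(keys, levels = uk)))
  ord <- order(-size, seq_along(uk))
  uk <- uk[ord]; size <- size[ord]
  gid <- match(keys, uk)
  accs <- panel_accessions(panel)
  rep_acc <- accs[vapply(seq_along(uk), function(g) which(gid == g)[1L], 0L)]
  membership <- stats::setNames(gid, accs)
  reps <- panel_subset(panel, accessions = match(rep_acc, accs))
  list(groups = data.frame(group_id = seq_along(uk), size = size,
                           representative = rep_acc, stringsAsFactors = FALSE),
       membership = membership, representatives = reps,
       n_groups = length(uk))
}
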