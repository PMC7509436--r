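# Shared fixtures and independent oracles used across the test files.
# The oracles enumerate Hardy-Weinberg genotypes and Mendelian
# transmissions directly; they share no code with the implementation paths
# they check.

make_panel <- function(a, b, accessions = NULL, segments = NULL) {
  a <- rbind(a); b <- rbind(b)
  hap_panel(a, b,
            accessions = if (is.null(accessions)) paste0("acc", seq_len(nrow(a))) else accessions,
            segments = if (is.null(segments)) paste0("SEG", seq_len(ncol(a))) else segments)
}

rdirichlet1 <- function(k, conc = 1) {
  g <- pmax(stats::rgamma(k, shape = conc), 1e-12)
  g / sum(g)
}

# all HWE genotype classes for allele frequencies p: data.frame i, j, prob
hwe_geno_enum <- function(p) {
  k <- length(p)
  out <- expand.grid(i = seq_len(k), j = seq_len(k))
  out <- out[out$i <= out$j, ]
  out$prob <- ifelse(out$i == out$j, p[out$i]^2, 2 * p[out$i] * p[out$j])
  out
}

# P(two independent HWE individuals have identical genotypes)
oracle_pi_random <- function(p) {
  g <- hwe_geno_enum(p)
  sum(g$prob^2)
}

# genotype distribution of a child of parents (i1,j1) x (i2,j2)
child_dist <- function(i1, j1, i2, j2, k) {
  m <- matrix(0, k, k)
  for (x in c(i1, j1)) for (y in c(i2, j2)) {
    a <- min(x, y); b <- max(x, y)
    m[a, b] <- m[a, b] + 0.25
  }
  m
}

# P(two full sibs share a genotype), by enumeration over parent pairs
oracle_pi_sib <- function(p) {
  g <- hwe_geno_enum(p)
  k <- length(p)
  total <- 0
  for (a in seq_len(nrow(g))) for (b in seq_len(nrow(g))) {
    cd <- child_dist(g$i[a], g$j[a], g$i[b], g$j[b], k)
    total <- total + g$prob[a] * g$prob[b] * sum(cd^2)
  }
  total
}

# P(a full sib of an individual with genotype (gi,gj) has that same genotype)
oracle_sib_match <- function(gi, gj, p) {
  g <- hwe_geno_enum(p)
  k <- length(p)
  num <- 0; den <- 0
  for (a in seq_len(nrow(g))) for (b in seq_len(nrow(g))) {
    cd <- child_dist(g$i[a], g$j[a], g$i[b], g$j[b], k)
    pg <- cd[min(gi, gj), max(gi, gj)]
    den <- den + g$prob[a] * g$prob[b] * pg
    num <- num + g$prob[a] * g$prob[b] * pg * pg
  }
  num / den
}

# P(a parent of an individual with genotype (gi,gj) has that same genotype)
oracle_par_off_match <- function(gi, gj, p) {
  g <- hwe_geno_enum(p)
  k <- length(p)
  num <- 0; den <- 0
  for (a in seq_len(nrow(g))) for (b in seq_len(nrow(g))) {
    cd <- child_dist(g$i[a], g$j[a], g$i[b], g$j[b], k)
    pg <- cd[min(gi, gj), max(gi, gj)]
    w <- g$prob[a] * g$prob[b] * pg
    den <- den + w
    if (g$i[a] == min(gi, gj) && g$j[a] == max(gi, gj)) num <- num + w
  }
  num / den
}

# Jamieson & Taylor closed-form NON-exclusion probabilities (test oracle
# only; the package ships an enumeration).
jt_nonexclusion <- function(p, scenario) {
  a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
  a5 <- sum(p^5); a6 <- sum(p^6)
  excl <- switch(scenario,
    no_parent_known  = 1 - 4 * a2 + 2 * a2^2 + 4 * a3 - 3 * a4,
    one_parent_known = 1 - 2 * a2 + a3 + 3 * (a2 * a3 - a5) - 2 * (a2^2 - a4),
    parent_pair      = 1 + 4 * a4 - 4 * a5 - 3 * a6 - 8 * a2^2 +
                       8 * a2 * a3 + 2 * a3^2)
  1 - excl
}

# maximum mixture log-likelihood of unphased genotypes over haplotype
# frequencies, by multi-start Nelder-Mead on a softmax parameterisation
# (independent of the EM code path)
ml_phase_loglik <- function(genotypes, n_starts = 40L) {
  cand <- lapply(seq_len(nrow(genotypes)), function(i) {
    enumerate_compatible_pairs(genotypes[i, ])
  })
  haps <- sort(unique(unlist(cand)))
  k <- length(haps)
  ll_of <- function(theta) {
    p <- exp(theta - max(theta)); p <- p / sum(p)
    tot <- 0
    for (ps in cand) {
      s <- 0
      for (pr in ps) {
        c_ <- if (pr[1] == pr[2]) 1 else 2
        s <- s + c_ * p[match(pr[1], haps)] * p[match(pr[2], haps)]
      }
      tot <- tot + log(s)
    }
    -tot
  }
  if (k == 1L) return(0)
  best <- Inf
  for (s in seq_len(n_starts)) {
    th0 <- stats::rnorm(k, 0, 2)
    fit <- stats::optim(th0, ll_of, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (fit$value < best) best <- fit$value
  }
  -best
}

# exhaustive minimal separating subsets by scanning every subset size
brute_minimal_sets <- function(panel) {
  segs <- panel_segments(panel)
  n <- n_accessions(panel)
  for (s in seq_along(segs)) {
    hits <- list()
    cmb <- utils::combn(segs, s, simplify = FALSE)
    for (sub in cmb) {
      if (collapse_genotypes(panel_subset(panel, segments = sub))$n_groups == n) {
        hits[[length(hits) + 1L]] <- sub
      }
    }
    if (length(hits)) return(list(size = s, subsets = hits))
  }
  NULL
}

# exhaustive best allele coverage over all subsets of a given size
brute_best_coverage <- function(panel, size) {
  inc <- haplofinger:::allele_incidence(panel)
  best <- 0
  for (sub in utils::combn(nrow(inc), size, simplify = FALSE)) {
    cov <- sum(colSums(inc[sub, , drop = FALSE]) > 0L) / ncol(inc)
    if (cov > best) best <- cov
  }
  best
}
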