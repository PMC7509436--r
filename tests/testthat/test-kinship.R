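test_that("DSN counts differing segments and reports skipped ones", {
  a <- data.frame(segment_id = c("SEG1", "SEG2", "SEG3"),
                  hap_a = c(1L, 1L, NA), hap_b = c(2L, 1L, NA))
  expect_equal(as.integer(dsn(a, a)), 0L)
  b <- a; b$hap_a <- c(1L, 2L, NA); b$hap_b <- c(1L, 2L, NA)
  d <- dsn(a, b)
  expect_equal(as.integer(d), 2L)
  expect_equal(attr(d, "n_skipped"), 1L)
  # loss of heterozygosity at one segment gives DSN 1
  loh <- a; loh$hap_a[1] <- 1L; loh$hap_b[1] <- 1L
  expect_equal(as.integer(dsn(a, loh)), 1L)
})

test_that("DSN over all segments behaves as a count pseudo-metric", {
  set.seed(55)
  a <- matrix(sample.int(4L, 19L * 6L, TRUE), 6, 19)
  b <- pmax(a, matrix(sample.int(4L, 19L * 6L, TRUE), 6, 19))
  panel <- make_panel(pmin(a, b), b)
  d <- dsn_matrix(panel)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0L))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j])
  }
  # full disagreement across all 19 segments
  lo <- make_panel(matrix(1L, 1, 19), matrix(1L, 1, 19))
  hi <- make_panel(matrix(2L, 1, 19), matrix(2L, 1, 19))
  both <- hap_panel(rbind(lo$hap_a, hi$hap_a), rbind(lo$hap_b, hi$hap_b),
                    accessions = c("x", "y"))
  expect_equal(dsn_matrix(both)["x", "y"], 19L)
})

test_that("pairs are classified into clone / somatic / distinct tiers", {
  d <- matrix(c(0L, 0L, 1L, 11L,
                0L, 0L, 1L, 11L,
                1L, 1L, 0L, 12L,
                11L, 11L, 12L, 0L), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  cls <- classify_pairs(d)
  get <- function(x, y) cls$label[cls$id_a == x & cls$id_b == y]
  expect_equal(get("a", "b"), "identical")
  expect_equal(get("a", "c"), "somatic_variant")
  expect_equal(get("a", "d"), "distinct")
  strict <- classify_pairs(d, somatic_threshold = 0L)
  expect_equal(strict$label[strict$dsn == 1L][1], "distinct")
})

test_that("Mendelian offspring are always candidate pairs with each parent", {
  set.seed(61)
  st <- sim_study(sim_config(n_segments = 8L, alleles_per_segment = 6L,
                             snps_per_segment = 4L, copy_number = 1L,
                             n_base_genotypes = 12L,
                             clone_multiplicities = rep(1L, 12L),
                             n_somatic_pairs = 0L, n_trios = 0L, seed = 61L))
  pa <- profile_table(st$panel, 1); pb <- profile_table(st$panel, 2)
  off <- sim_offspring(pa, pb, seed = 62L)
  share_all <- function(x, y) {
    all(x$hap_a == y$hap_a | x$hap_a == y$hap_b |
        x$hap_b == y$hap_a | x$hap_b == y$hap_b)
  }
  expect_true(share_all(off, pa))
  expect_true(share_all(off, pb))

  # a pair disjoint at one segment is never a candidate
  a <- matrix(c(1L, 1L, 1L), 1, 3); b <- a
  x <- matrix(c(1L, 1L, 2L), 1, 3); y <- x
  panel <- hap_panel(rbind(a, x), rbind(b, y), accessions = c("p", "q"))
  out <- candidate_parent_offspring(panel, somatic_threshold = 0L)
  expect_equal(nrow(out$pairs), 0L)
})

test_that("planted pedigree links are recovered in the candidate network", {
  st <- sim_study(sim_config(seed = 29L))
  reps <- st$truth$templates
  out <- candidate_parent_offspring(reps, somatic_threshold = 3L)
  found <- paste(pmin(out$pairs$id_a, out$pairs$id_b),
                 pmax(out$pairs$id_a, out$pairs$id_b))
  tr <- st$truth$trios
  planted <- c(paste(pmin(tr$offspring, tr$parent_a),
                     pmax(tr$offspring, tr$parent_a)),
               paste(pmin(tr$offspring, tr$parent_b),
                     pmax(tr$offspring, tr$parent_b)))
  d <- dsn_matrix(reps)
  for (i in seq_along(planted)) {
    pair <- strsplit(planted[i], " ")[[1]]
    if (d[pair[1], pair[2]] > 3L) expect_true(planted[i] %in% found)
  }
  # every reported candidate really shares a haplotype at every segment
  for (r in seq_len(nrow(out$pairs))) {
    pa <- profile_table(reps, out$pairs$id_a[r])
    pb <- profile_table(reps, out$pairs$id_b[r])
    expect_true(all(pa$hap_a == pb$hap_a | pa$hap_a == pb$hap_b |
                    pa$hap_b == pb$hap_a | pa$hap_b == pb$hap_b))
  }
  expect_equal(unname(out$degree[out$pairs$id_a[1]]),
               sum(out$pairs$id_a == out$pairs$id_a[1] |
                   out$pairs$id_b == out$pairs$id_a[1]))
})

test_that("enumeration non-exclusion matches closed forms and ordering", {
  expect_equal(nonexclusion(c(a = 1), "one_parent_known"), 1)
  expect_equal(nonexclusion(c(a = 1), "no_parent_known"), 1)
  expect_equal(nonexclusion(c(a = 1), "parent_pair"), 1)
  set.seed(41)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    p <- rdirichlet1(k, runif(1, 0.3, 2))
    for (sc in c("one_parent_known", "no_parent_known", "parent_pair")) {
      expect_equal(nonexclusion(p, sc), jt_nonexclusion(p, sc),
                   tolerance = 1e-10)
    }
  }
  # P3 <= P1 <= P2 ordering over random frequency vectors
  for (rep in 1:100) {
    p <- rdirichlet1(sample(2:8, 1), runif(1, 0.2, 2))
    ne1 <- nonexclusion(p, "one_parent_known")
    ne2 <- nonexclusion(p, "no_parent_known")
    ne3 <- nonexclusion(p, "parent_pair")
    expect_lte(ne3, ne1 + 1e-12)
    expect_lte(ne1, ne2 + 1e-12)
  }
})

test_that("cumulative non-exclusion multiplies across independent loci", {
  p <- c(.5, .5)
  one <- nonexclusion(p, "no_parent_known")
  expect_equal(one, 0.875)
  cum <- cumulative_nonexclusion(list(p, p), "no_parent_known")
  expect_equal(as.numeric(cum), 0.765625)
  expect_equal(unname(attr(cum, "per_locus")), c(one, one))
})

test_that("a true parent is never Mendelian-excluded across 10^4 trios", {
  set.seed(4242)
  n_excl_duo <- 0L; n_excl_trio <- 0L
  for (t in seq_len(10000L)) {
    k <- sample(2:6, 1)
    p <- rdirichlet1(k, 0.5)
    m <- sample.int(k, 2, TRUE, prob = p)
    f <- sample.int(k, 2, TRUE, prob = p)
    o <- c(sample(m, 1), sample(f, 1))
    if (parent_excluded(o, f)) n_excl_duo <- n_excl_duo + 1L
    if (parent_excluded(o, f, known = m)) n_excl_trio <- n_excl_trio + 1L
  }
  expect_identical(n_excl_duo, 0L)
  expect_identical(n_excl_trio, 0L)
  # sanity: exclusion does happen for incompatible candidates
  expect_true(parent_excluded(c(1, 1), c(2, 2)))
  expect_true(parent_excluded(c(1, 2), c(2, 2), known = c(2, 2)))
})
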