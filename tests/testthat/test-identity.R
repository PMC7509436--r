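test_that("PI and PI_sib match direct evaluation and enumeration oracles", {
  expect_equal(pi_random(c(m = 1)), 1)
  expect_equal(pi_sib(c(m = 1)), 1)
  expect_equal(pi_random(c(.5, .5)), 0.375)
  expect_equal(pi_sib(c(.5, .5)), 0.59375)
  set.seed(17)
  for (k in 2:5) {
    p <- rdirichlet1(k, 0.7)
    expect_equal(pi_random(p), oracle_pi_random(p), tolerance = 1e-12)
    expect_equal(pi_sib(p), oracle_pi_sib(p), tolerance = 1e-12)
    expect_gte(pi_sib(p), pi_random(p))
  }
})

test_that("per-genotype match probabilities agree with Mendelian oracles", {
  expect_equal(genotype_match_probs(c("a", "a"), c(a = 1)),
               c(random = 1, par_off = 1, sib = 1))
  expect_equal(genotype_match_probs(c("a", "b"), c(a = .5, b = .5)),
               c(random = .5, par_off = .5, sib = .625))
  set.seed(23)
  for (k in 2:4) {
    p <- stats::setNames(rdirichlet1(k, 0.9), seq_len(k))
    # expectation of the sib match prob over HWE genotypes equals PI_sib
    g <- hwe_geno_enum(p)
    sib_probs <- vapply(seq_len(nrow(g)), function(r) {
      genotype_match_probs(c(g$i[r], g$j[r]), p)[["sib"]]
    }, 0)
    expect_equal(sum(g$prob * sib_probs), pi_sib(p), tolerance = 1e-12)
    rnd_probs <- vapply(seq_len(nrow(g)), function(r) {
      genotype_match_probs(c(g$i[r], g$j[r]), p)[["random"]]
    }, 0)
    expect_equal(sum(g$prob * rnd_probs), pi_random(p), tolerance = 1e-12)
    # spot-check sib and parent-offspring formulas against trio enumeration
    expect_equal(genotype_match_probs(c(1, min(2, k)), p)[["sib"]],
                 oracle_sib_match(1, min(2, k), p), tolerance = 1e-10)
    expect_equal(genotype_match_probs(c(1, min(2, k)), p)[["par_off"]],
                 oracle_par_off_match(1, min(2, k), p), tolerance = 1e-10)
  }
  expect_error(genotype_match_probs(c("z", "z"), c(a = 1)), "absent")
})

test_that("discrimination capacity implements the pairwise-collision bound", {
  expect_identical(discrimination_capacity(6.4e-10), 12500L)
  expect_identical(discrimination_capacity(1.5e-4), 26L)
  expect_identical(discrimination_capacity(1), 1L)
  # monotone: larger PI -> smaller capacity; larger alpha -> larger capacity
  pis <- 10^seq(-10, -1, by = 1)
  caps <- vapply(pis, discrimination_capacity, 0L)
  expect_true(all(diff(caps) <= 0))
  expect_gte(discrimination_capacity(1e-6, alpha = 0.10),
             discrimination_capacity(1e-6, alpha = 0.05))
  # the returned n satisfies the bound and n+1 does not
  for (pi_v in c(6.4e-10, 1.5e-4, 0.037)) {
    n <- discrimination_capacity(pi_v)
    expect_lte(n * (n - 1) / 2 * pi_v, 0.05)
    expect_gt((n + 1) * n / 2 * pi_v, 0.05)
  }
})

test_that("cumulative discrimination shrinks PI and grows distinct counts", {
  st <- sim_study(sim_config(n_segments = 6L,
                             alleles_per_segment = c(8L, 6L, 5L, 4L, 3L, 2L),
                             snps_per_segment = c(5L, 4L, 4L, 3L, 2L, 1L),
                             copy_number = 1L,
                             n_base_genotypes = 30L,
                             clone_multiplicities = rep(1L, 30L),
                             n_somatic_pairs = 0L, n_trios = 0L, seed = 9L))
  cum <- cumulative_discrimination(st$panel)
  expect_true(all(diff(cum$cum_pi) <= 1e-15))
  expect_true(all(diff(cum$cum_pi_sib) <= 1e-15))
  expect_true(all(diff(cum$n_distinct) >= 0L))
  expect_equal(cum$n_distinct[6], collapse_genotypes(st$panel)$n_groups)
  # PIC-descending default dominates a deliberately reversed order
  rev_cum <- cumulative_discrimination(st$panel, rev(cum$segment_id))
  expect_true(all(cum$cum_pi <= rev_cum$cum_pi + 1e-15))
  # a single monomorphic segment distinguishes nothing
  mono <- make_panel(matrix(1L, 4, 1), matrix(1L, 4, 1))
  expect_equal(cumulative_discrimination(mono, "SEG1")$n_distinct, 1L)
  expect_error(cumulative_discrimination(st$panel, c("SEG1", "SEG2")),
               "permutation")
})

test_that("minimal marker sets are exactly the brute-force minimal subsets", {
  # one segment already separates all four profiles
  p1 <- make_panel(matrix(c(1L, 2L, 3L, 4L, rep(1L, 4)), 4, 2),
                   matrix(c(1L, 2L, 3L, 4L, rep(1L, 4)), 4, 2))
  ms1 <- minimal_marker_set(p1)
  expect_equal(ms1$size, 1L)
  expect_equal(ms1$subsets, list("SEG1"))

  # constructed instance with two alternative minimal sets
  a <- matrix(c(1L, 1L, 2L, 2L,   # SEG1 splits {12}{34}
                1L, 2L, 1L, 2L,   # SEG2 splits {13}{24}
                1L, 2L, 1L, 2L),  # SEG3 duplicates SEG2
              4, 3)
  p2 <- make_panel(a, a)
  ms2 <- minimal_marker_set(p2)
  expect_equal(ms2$size, 2L)
  expect_setequal(lapply(ms2$subsets, sort),
                  list(c("SEG1", "SEG2"), c("SEG1", "SEG3")))

  # random panels agree with exhaustive search on size and subset list
  set.seed(77)
  for (rep in 1:5) {
    a <- matrix(sample.int(3L, 8L * 5L, TRUE), 8, 5)
    b <- pmax(a, matrix(sample.int(3L, 8L * 5L, TRUE), 8, 5))
    a2 <- pmin(a, b)
    panel <- make_panel(a2, b)
    cg <- collapse_genotypes(panel)
    panel <- cg$representatives
    if (n_accessions(panel) < 3) next
    got <- minimal_marker_set(panel)
    want <- brute_minimal_sets(panel)
    expect_equal(got$size, want$size)
    expect_setequal(lapply(got$subsets, sort), lapply(want$subsets, sort))
  }
})

test_that("profiles emit deterministic barcodes on a subset", {
  panel <- make_panel(matrix(c(2L, 1L), 1, 2), matrix(c(5L, 1L), 1, 2),
                      segments = c("SEG6", "SEG9"))
  expect_equal(fingerprint_code(panel, 1, "SEG6"), "SEG6:2/5")
  expect_equal(fingerprint_code(panel, 1), "SEG6:2/5;SEG9:1/1")
  expect_error(fingerprint_code(panel, 1, "SEG7"), "unknown segment")
  miss <- make_panel(matrix(NA_integer_), matrix(NA_integer_))
  expect_error(fingerprint_code(miss, 1, "SEG1"), "missing")
})

test_that("minimal-subset barcodes separate a synthetic panel", {
  st <- sim_study(sim_config(seed = 13L))
  reps <- collapse_genotypes(st$panel)$representatives
  ms <- minimal_marker_set(reps)
  sub <- ms$subsets[[1]]
  codes <- vapply(panel_accessions(reps), function(acc) {
    fingerprint_code(reps, acc, sub)
  }, "")
  expect_equal(anyDuplicated(codes), 0L)
})
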