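test_that("simple matching distance counts shared alleles with multiplicity", {
  p <- make_panel(matrix(c(1L, 1L), 2, 1), matrix(c(2L, 1L), 2, 1))
  d <- simple_matching_distance(p)
  expect_equal(d[1, 2], 0.5)  # (1,2) vs (1,1): one shared of two
  ident <- make_panel(matrix(c(1L, 1L, 2L, 2L), 2, 2),
                      matrix(c(3L, 3L, 2L, 2L), 2, 2))
  expect_equal(simple_matching_distance(ident)[1, 2], 0)
  disj <- make_panel(matrix(c(1L, 3L, 1L, 3L), 2, 2),
                     matrix(c(2L, 4L, 2L, 4L), 2, 2))
  expect_equal(simple_matching_distance(disj)[1, 2], 1)
  set.seed(8)
  a <- matrix(sample.int(3L, 40L, TRUE), 8, 5)
  b <- pmax(a, matrix(sample.int(3L, 40L, TRUE), 8, 5))
  rp <- make_panel(pmin(a, b), b)
  d <- simple_matching_distance(rp)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(d >= 0 & d <= 1))
  # zero distance iff identical profiles
  key <- apply(cbind(rp$hap_a, rp$hap_b), 1, paste, collapse = ",")
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(unname(d[i, j] == 0), unname(key[i] == key[j]))
  }
})

test_that("UPGMA agglomerates by average linkage with ultrametric heights", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(d, "upgma")
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(d), colnames(d)], d, tolerance = 1e-12)
  bt <- sort(ape::branching.times(tr))  # heights: (A,B) at 1, root at 3
  expect_equal(unname(bt), c(1, 3))
  # 2 leaves: a single split of height d/2
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- build_tree(d2, "upgma")
  expect_equal(sort(t2$edge.length), c(2, 2))
  expect_error(build_tree(matrix(c(0, 1, 2, 0), 2, 2,
                                 dimnames = list(c("x", "y"), c("x", "y"))),
                          "upgma"),
               "symmetric")
})

test_that("NJ is exact on additive distances", {
  # distances generated from a known 4-leaf tree ((A:1,B:2):1.5,(C:3,D:1))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5.5
  d["A", "D"] <- d["D", "A"] <- 3.5
  d["B", "C"] <- d["C", "B"] <- 6.5
  d["B", "D"] <- d["D", "B"] <- 4.5
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- build_tree(d, "nj")
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(d), colnames(d)], d, tolerance = 1e-9)
  expect_true(all(tr$edge.length >= 0))
})

test_that("negative NJ branches are clamped without breaking path lengths", {
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0),
              4, 4, dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(stats::as.dist(d))
  tr <- build_tree(d, "nj")
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})

test_that("bootstrap support is 100% for clone bipartitions, reproducible", {
  a <- matrix(c(1L, 1L, 5L, 6L,
                2L, 2L, 5L, 6L,
                3L, 3L, 5L, 6L,
                4L, 4L, 5L, 6L,
                2L, 2L, 7L, 8L), 4, 5)
  panel <- make_panel(a, a, accessions = c("c1", "c2", "far1", "far2"))
  tr <- bootstrap_support(panel, method = "nj", B = 50L, seed = 99L)
  supp <- attr(tr, "support")
  expect_true(any(supp == 100))
  tr2 <- bootstrap_support(panel, method = "nj", B = 50L, seed = 99L)
  expect_identical(attr(tr2, "support"), supp)
  one <- bootstrap_support(panel, method = "upgma", B = 1L, seed = 3L)
  expect_true(all(attr(one, "support") %in% c(0L, 100L)))
  expect_error(bootstrap_support(panel, B = 0L), "B must be")
})

test_that("PCoA double-centers distances and orders axes by eigenvalue", {
  # three equidistant points: two equal positive eigenvalues, 50% each
  d <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d) <- 0
  fit <- pcoa(d)
  expect_equal(ncol(fit$coords), 2L)
  expect_equal(fit$explained, c(0.5, 0.5), tolerance = 1e-9)
  # Euclidean input round-trips exactly
  set.seed(12)
  xy <- matrix(rnorm(10), 5, 2)
  de <- as.matrix(stats::dist(xy))
  fit2 <- pcoa(de)
  back <- as.matrix(stats::dist(fit2$coords))
  expect_equal(unname(back), unname(de), tolerance = 1e-9)
  # duplicated profiles get coincident coordinates
  p <- make_panel(matrix(c(1L, 1L, 2L), 3, 1), matrix(c(1L, 1L, 2L), 3, 1))
  f3 <- pcoa(simple_matching_distance(p))
  expect_equal(f3$coords[1, ], f3$coords[2, ], tolerance = 1e-12)
})

test_that("core selection maximises allele coverage", {
  # one locus, genotypes {A/B, A/A, B/B}: the het covers everything alone
  p <- make_panel(matrix(c(1L, 1L, 2L), 3, 1), matrix(c(2L, 1L, 2L), 3, 1))
  res <- core_select(p, sizes = 1L, n_restarts = 5L, seed = 1L)
  expect_equal(res$coverage, 1)
  expect_equal(res$members[[1]], "acc1")
  # full panel always covers everything
  st <- sim_study(sim_config(n_segments = 5L, alleles_per_segment = 5L,
                             snps_per_segment = 4L, copy_number = 1L,
                             n_base_genotypes = 20L,
                             clone_multiplicities = rep(1L, 20L),
                             n_somatic_pairs = 0L, n_trios = 0L, seed = 21L))
  full <- core_select(st$panel, sizes = 20L, n_restarts = 0L)
  expect_equal(full$coverage, 1)
  # optimizer matches brute force for small subset sizes
  res <- core_select(st$panel, sizes = 2:4, n_restarts = 30L, seed = 2L)
  for (r in seq_len(nrow(res))) {
    expect_equal(res$coverage[r], brute_best_coverage(st$panel, res$size[r]),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(res$coverage) >= -1e-12))
})
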