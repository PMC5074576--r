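# The overlap statistic, its matrix-randomization null, and the test
# variants, checked against brute-force oracles and analytic expectations.

test_that("observed statistic matches the brute-force oracle", {
  sizes <- chrom_sizes()
  pref <- partner_preference(sizes)
  set.seed(41)
  for (rep in 1:10) {
    m <- random_matrix()
    for (k in list(c(3, 3), c(5, 3), c(3, 5), c(1, 1), c(15, 15))) {
      expect_equal(
        observed_statistic(m, pref, k[1], k[2]),
        oracle_statistic(m, oracle_pref_sets(sizes, k[2]), k[1]))
    }
    # avoidance form
    dpref <- partner_preference(sizes, "size_dissimilarity")
    expect_equal(
      observed_statistic(m, dpref, 3, 3, lowest = TRUE),
      oracle_statistic(m, oracle_pref_sets(sizes, 3, dissimilar = TRUE), 3,
                       lowest = TRUE))
    # subset restriction
    sub <- sample(chroms16, 4)
    expect_equal(
      observed_statistic(m, pref, 3, 3, subset = sub),
      oracle_statistic(m, oracle_pref_sets(sizes, 3), 3, subset = sub))
  }
})

test_that("observed statistic on a 4-chromosome toy matches enumeration", {
  # 4 chromosomes, k = 1: T counts rows whose strongest partner is also
  # the size-closest partner; verified by exhaustive hand enumeration
  st <- size_table(c(chr1 = 100, chr2 = 120, chr3 = 200, chr4 = 500))
  pref <- partner_preference(st)
  m <- matrix(c(NA, 10, 8, 1,
                10, NA, 6, 2,
                8, 6, NA, 4,
                1, 2, 4, NA), 4, 4,
              dimnames = list(st$chrom, st$chrom))
  # closest in size: chr1->chr2, chr2->chr1, chr3->chr2, chr4->chr3;
  # strongest: chr1->chr2, chr2->chr1, chr3->chr1, chr4->chr3
  # => overlaps 1, 1, 0, 1
  expect_equal(observed_statistic(m, pref, 1, 1), 3L)
  expect_equal(observed_statistic(m, pref, 3, 3), 4 * 3L) # all of 3 partners
})

test_that("monotone size-ordered matrices attain the extreme statistics", {
  sizes <- chrom_sizes()
  pref <- partner_preference(sizes)
  dec <- monotone_size_matrix(sizes)            # IF falls with |dL|
  inc <- monotone_size_matrix(sizes, TRUE)      # IF rises with |dL|
  expect_equal(observed_statistic(dec, pref, 3, 3), 48L)
  expect_equal(observed_statistic(inc, pref, 3, 3), 0L)
  # avoidance: bottom-3 are the 3 most dissimilar
  expect_equal(observed_statistic(
    dec, partner_preference(sizes, "size_dissimilarity"), 3, 3,
    lowest = TRUE), 48L)
  res <- null_distribution(dec, pref, iterations = 2000, seed = 5)
  expect_lte(res$p.value, 1 / 2000 + 1e-12)
  # subset variant maximal too
  short4 <- names(sort(size_column(sizes)))[1:4]
  expect_equal(observed_statistic(dec, pref, 3, 3, subset = short4), 12L)
})

test_that("null distribution mean matches the analytic overlap expectation", {
  set.seed(43)
  m <- random_matrix()
  pref <- partner_preference(chrom_sizes())
  for (k in list(c(3, 3), c(5, 5))) {
    res <- null_distribution(m, pref, k[1], k[2], iterations = 20000,
                             seed = 44, keep_null = TRUE)
    expect_gt(res$p.value, 0.0) # sanity: a random matrix is not extreme
    exp_mean <- 16 * k[1] * k[2] / 15
    se <- res$null_sd / sqrt(res$iterations)
    expect_lt(abs(res$null_mean - exp_mean), 3 * se + 1e-9)
  }
  # subset analogue: 4 rows -> 4 * 9/15
  sub <- chroms16[1:4]
  rs <- null_distribution(m, pref, 3, 3, subset = sub, iterations = 20000,
                          seed = 45)
  expect_lt(abs(rs$null_mean - 4 * 0.6), 3 * rs$null_sd / sqrt(20000) + 1e-9)
})

test_that("null p-values are bit-reproducible under a fixed seed", {
  m <- random_matrix()
  pref <- partner_preference(chrom_sizes())
  a <- null_distribution(m, pref, iterations = 3000, seed = 99,
                         keep_null = TRUE)
  b <- null_distribution(m, pref, iterations = 3000, seed = 99,
                         keep_null = TRUE)
  expect_identical(attr(a, "null"), attr(b, "null"))
  expect_identical(a$p.value, b$p.value)
  # label-permutation mode runs and is reproducible as well
  l1 <- null_distribution(m, pref, iterations = 3000, seed = 7,
                          method = "labels")
  l2 <- null_distribution(m, pref, iterations = 3000, seed = 7,
                          method = "labels")
  expect_identical(l1$p.value, l2$p.value)
  expect_warning(null_distribution(m, pref, iterations = 500, seed = 1),
                 "resolution")
})

test_that("subset test with all chromosomes reduces to the full test", {
  m <- random_matrix()
  pref <- partner_preference(chrom_sizes())
  full <- null_distribution(m, pref, iterations = 2000, seed = 12)
  sub <- subset_test(m, pref, subset = chroms16, iterations = 2000,
                     seed = 12)
  expect_identical(full$statistic, sub$statistic)
  expect_identical(full$p.value, sub$p.value)
})

test_that("sensitivity suite covers the four k combinations", {
  m <- monotone_size_matrix(chrom_sizes())
  suite <- sensitivity_suite(m, partner_preference(chrom_sizes()),
                             iterations = 1000, seed = 3)
  expect_named(suite, c("k3_3", "k3_5", "k5_3", "k5_5"))
  # monotone matrix attains the maximum in every variant
  expect_equal(suite$k3_3$statistic, 48L)
  expect_equal(suite$k5_5$statistic, 80L)
  expect_equal(suite$k3_5$statistic, 48L)
  expect_equal(suite$k5_3$statistic, 48L)
  for (s in suite) expect_lte(s$p.value, 0.001 + 1e-12)
})

test_that("cluster-mode preference uses same-cluster partner sets", {
  clusters <- setNames(rep(1:4, each = 4), chroms16)
  pref <- cluster_preference(clusters)
  m <- random_matrix()
  m[!is.na(m)] <- 0.1
  # make each chromosome's top-3 its cluster mates
  for (g in 1:4) {
    mem <- chroms16[clusters == g]
    for (a in mem) for (b in setdiff(mem, a)) m[a, b] <- m[b, a] <- 5
  }
  expect_equal(observed_statistic(m, pref, 3), 48L)
  res <- null_distribution(m, pref, k_if = 3, iterations = 2000, seed = 8,
                           variant = "telomere_cluster")
  expect_lt(res$p.value, 0.01)
})

test_that("homology preference orders partners by decreasing homology", {
  set.seed(50)
  hom <- matrix(runif(256), 16, 16, dimnames = list(chroms16, chroms16))
  hom <- (hom + t(hom)) / 2
  pref <- homology_preference(hom)
  for (ci in sample(chroms16, 3)) {
    top <- pref$order[[ci]][1]
    others <- setdiff(chroms16, ci)
    expect_equal(top, others[which.max(hom[ci, others])])
  }
})

test_that("overlap test matches its analytic null and detects identity", {
  set.seed(51)
  ma <- random_matrix()
  ident <- overlap_test(ma, ma, k = 5, iterations = 5000, seed = 2)
  expect_equal(ident$statistic, 80L)
  expect_equal(ident$params$overlap_fraction, 1)
  expect_lte(ident$p.value, 1 / 5000 + 1e-12)
  mb <- random_matrix()
  indep <- overlap_test(ma, mb, k = 5, iterations = 20000, seed = 3)
  se <- indep$null_sd / sqrt(indep$iterations)
  expect_lt(abs(indep$null_mean - 16 * 25 / 15), 3 * se + 1e-9)
})

test_that("profile agreement is exact on identical and monotone profiles", {
  set.seed(52)
  ma <- random_matrix()
  same <- profile_agreement(ma, ma)
  expect_equal(same$r_squared, 1)
  expect_equal(same$spearman_rho, 1)
  mono <- ma
  mono[!is.na(mono)] <- mono[!is.na(mono)]^3 # strictly monotone transform
  tr <- profile_agreement(ma, mono)
  expect_equal(tr$spearman_rho, 1)
  expect_lt(tr$r_squared, 1)
  flat <- ma
  flat[!is.na(flat)] <- 1
  expect_true(profile_agreement(ma, flat)$flagged)
})
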