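# Rank analyses, binned size-similarity scores, difference matrices,
# ancestral checks, size groups and matrix I/O.

test_that("partner and global ranks agree with a direct sort oracle", {
  set.seed(21)
  for (rep in 1:5) {
    m <- random_matrix()
    for (ci in sample(chroms16, 4)) {
      pr <- partner_ranks(m, ci)
      v <- m[ci, setdiff(chroms16, ci)]
      expect_equal(unname(pr[order(-v)]), seq_len(15))
      expect_equal(names(sort(pr))[1], names(which.max(v)))
    }
    gr <- global_ranks(m)
    expect_setequal(gr$rank, 1:120)
    expect_equal(gr$value[gr$rank == 1], max(gr$value))
  }
  # ties get average ranks
  mt <- random_matrix()
  mt["chr1", c("chr2", "chr3")] <- mt[c("chr2", "chr3"), "chr1"] <- 99
  expect_equal(unname(sort(partner_ranks(mt, "chr1"))[1:2]), c(1.5, 1.5))
  mc <- random_matrix()
  mc[!is.na(mc)] <- 5
  expect_equal(unname(partner_ranks(mc, "chr4")), rep(8, 15))
  expect_equal(global_ranks(mc)$rank, rep(60.5, 120))
})

test_that("rank operations reject incomplete matrices", {
  m <- random_matrix()
  m["chr1", "chr2"] <- m["chr2", "chr1"] <- NA
  expect_error(global_ranks(m), "complete")
  expect_error(partner_ranks(m, "chr1"), "complete")
  expect_error(observed_statistic(m, partner_preference(chrom_sizes())),
               "complete")
})

test_that("average couple ranks cover the attainable range and average 60.5", {
  set.seed(22)
  m <- random_matrix()
  # force chr1 to hold the 15 strongest couples
  m["chr1", -1] <- m[-1, "chr1"] <- 1000 + 1:15
  expect_equal(average_couple_rank(m, "chr1")$mean, 8)
  # over all chromosomes the mean is 60.5 exactly (each couple counted twice)
  m2 <- random_matrix()
  means <- vapply(chroms16, function(ci) average_couple_rank(m2, ci)$mean,
                  numeric(1))
  expect_equal(mean(means), 60.5)
})

test_that("binned score is zero for flat matrices and flags size preference", {
  sizes <- chrom_sizes()
  flat <- random_matrix()
  flat[!is.na(flat)] <- 3
  bs <- binned_score(flat, sizes)
  expect_equal(nrow(bs), 5)
  expect_equal(bs$score, rep(0, 5))
  # planted signal: each chromosome's 3 closest partners at 2*mu0
  m <- random_matrix()
  m[!is.na(m)] <- 1
  pref <- oracle_pref_sets(sizes, 3)
  for (ci in chroms16)
    for (cj in pref[[ci]]) m[ci, cj] <- m[cj, ci] <- 2
  bs2 <- binned_score(m, sizes)
  expect_gt(bs2$score[1], 0)
  expect_lt(bs2$score[5], bs2$score[1])
  # direct-computation oracle for bin 1 score
  mu <- mean(m[upper.tri(m)])
  per <- vapply(chroms16, function(ci)
    (mean(m[ci, pref[[ci]]]) - mu) / mu, numeric(1))
  expect_equal(bs2$score[1], mean(per))
  # scale invariance of (x - mu)/mu
  expect_equal(binned_score(m * 7.3, sizes)$score, bs2$score)
  # log2 variant is monotone-consistent
  expect_gt(binned_score(m, sizes, scale = "log2")$score[1], 0)
})

test_that("per-chromosome bin scores sum to the row-balance identity", {
  set.seed(31)
  m <- random_matrix()
  sizes <- chrom_sizes()
  per <- attr(binned_score(m, sizes), "per_chromosome")
  mu <- mean(m[upper.tri(m)])
  row_means <- vapply(chroms16, function(ci)
    mean(m[ci, setdiff(chroms16, ci)]), numeric(1))
  # each row's five bin scores average to (row mean - mu)/mu, so the grand
  # total is 5 * 16 * (mean-of-row-means - mu)/mu; zero for balanced rows
  expect_equal(sum(per), 5 * 16 * (mean(row_means) - mu) / mu)
  balanced <- random_matrix()
  balanced[!is.na(balanced)] <- 2
  expect_equal(sum(attr(binned_score(balanced, sizes), "per_chromosome")), 0)
})

test_that("difference matrices are antisymmetric under operand swap", {
  set.seed(23)
  ma <- random_matrix()
  mb <- random_matrix()
  expect_equal(difference_matrix(ma, ma)[upper.tri(ma)], rep(0, 120))
  d <- difference_matrix(ma, mb)
  expect_equal(d, -difference_matrix(mb, ma))
  dl <- difference_matrix(ma, 2 * ma, scale = "log2")
  expect_equal(unname(dl[upper.tri(dl)]), rep(1, 120))
  neg <- ma
  neg["chr1", "chr2"] <- neg["chr2", "chr1"] <- -1
  expect_error(difference_matrix(neg, mb, scale = "log2"), "positive")
})

test_that("ancestral sisters are detected when and only when planted", {
  pairs <- ancestral_pairs()
  m <- random_matrix()
  m[!is.na(m)] <- runif(sum(!is.na(m))) # symmetric noise then overwrite
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  for (r in seq_len(nrow(pairs)))
    m[pairs$a[r], pairs$b[r]] <- m[pairs$b[r], pairs$a[r]] <- 100 + r
  chk <- ancestral_check(m)
  expect_equal(chk$n_strongest_is_sister, 16)
  expect_true(all(chk$pairs$rank_in_a_row == 1))
  # planted minimal -> never the strongest
  m2 <- random_matrix()
  for (r in seq_len(nrow(pairs)))
    m2[pairs$a[r], pairs$b[r]] <- m2[pairs$b[r], pairs$a[r]] <- 1e-6
  expect_equal(ancestral_check(m2)$n_strongest_is_sister, 0)
  expect_error(ancestral_check(random_matrix(),
                               data.frame(a = "chr1", b = "chr99")),
               "unknown")
})

test_that("mean enrichment contrast is antisymmetric and exact on planted rows", {
  m <- random_matrix()
  m["chr1", -1] <- m[-1, "chr1"] <- 8
  m["chr12", -12] <- m[-12, "chr12"] <- 1
  m["chr1", "chr12"] <- m["chr12", "chr1"] <- 8 # keep chr1 row at 8
  ctr <- mean_enrichment_contrast(m, "chr1", "chr12")
  expect_equal(mean_enrichment_contrast(m, "chr5", "chr5")$log2, 0)
  expect_equal(ctr$log2, -mean_enrichment_contrast(m, "chr12", "chr1")$log2)
  # chr12 row mean is (14*1 + 8)/15
  expect_equal(ctr$log2, log2(8) - log2((14 + 8) / 15))
})

test_that("size groups split well-separated sizes and are order-contiguous", {
  st <- size_table(c(a = 1, b = 2, c = 3, d = 100, e = 101, f = 1000))
  g <- size_groups(st, 3)
  expect_equal(unname(g), c(1, 1, 1, 2, 2, 3))
  expect_equal(length(unique(size_groups(st, 1))), 1)
  eq <- size_table(setNames(rep(5, 6), letters[1:6]))
  expect_equal(size_groups(eq, 3), size_groups(eq, 3)) # deterministic
  yeast <- size_groups(chrom_sizes(), 3)
  ord <- names(sort(size_column(chrom_sizes())))
  expect_true(all(diff(yeast[ord]) >= 0)) # contiguous in size order
})

test_that("matrix TSV round-trips bit-exactly and heatmaps order by size", {
  set.seed(24)
  m <- random_matrix()
  tsv <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, tsv)
  back <- read_matrix_tsv(tsv)
  expect_identical(back, m[rownames(back), colnames(back)])
  sizes <- chrom_sizes()
  out <- heatmap_export(m, sizes, tsv_path = tsv)
  expect_equal(rownames(out), names(sort(size_column(sizes))))
  expect_equal(rownames(out)[1], "chr1")  # shortest chromosome first
  expect_equal(rownames(out)[16], "chr12") # physical table: longest
  png <- tempfile(fileext = ".png")
  heatmap_export(difference_matrix(m, m), sizes, tsv_path = tsv,
                 png_path = png, scale = "diverging")
  expect_true(file.size(png) > 0)
})
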