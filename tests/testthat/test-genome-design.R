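# In-silico digestion, CEN fragment definition and design-rule validation.

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("find_sites locates motif starts on the forward strand", {
  expect_equal(find_sites("AACAATTGA", "MfeI"),
               data.frame(pos = 2L, enzyme = "MfeI"))
  expect_equal(find_sites("GAATTC", "EcoRI"),
               data.frame(pos = 0L, enzyme = "EcoRI"))
  both <- find_sites("GAATTCAACAATTG", c("EcoRI", "MfeI"))
  expect_equal(both$pos, c(0L, 8L))
  expect_equal(both$enzyme, c("EcoRI", "MfeI"))
  # N never matches; other characters are warned about and treated as N
  expect_equal(nrow(find_sites("GANTTC", "EcoRI")), 0)
  expect_warning(res <- find_sites("GAATTCXX", "EcoRI"), "non-ACGTN")
  expect_equal(res$pos, 0L)
})

test_that("palindromic motifs give mirror-image sites on the reverse strand", {
  set.seed(42)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    fwd <- find_sites(s)$pos
    rev <- find_sites(revcomp(s))$pos
    expect_setequal(rev, nchar(s) - 6 - fwd)
  }
})

test_that("cen_fragment recovers flanking sites and distances", {
  map <- data.frame(pos = c(10, 500, 1200), enzyme = "EcoRI")
  fr <- cen_fragment(map, 520, 640, chrom = "chrT")
  expect_equal(fr$left_site, 500)
  expect_equal(fr$right_site, 1200)
  expect_equal(fr$left_dist, 80)   # from CEN midpoint 580
  expect_equal(fr$right_dist, 620)
  expect_equal(fr$length, 700)
  expect_error(cen_fragment(data.frame(pos = 10), 520, 640), "unbounded")
  expect_error(cen_fragment(data.frame(pos = c(10, 550, 1200)), 520, 640),
               "CEN split")
})

test_that("distance_stats counts flanking distances beyond the threshold", {
  near <- data.frame(left_dist = rep(1000, 16), right_dist = rep(1000, 16))
  far <- data.frame(left_dist = rep(3000, 16), right_dist = rep(3000, 16))
  expect_equal(distance_stats(near, 2000)$count, 0)
  expect_equal(distance_stats(near, 2000)$total, 32)
  expect_equal(distance_stats(far, 2000)$count, 32)
  # monotone non-increasing in the threshold
  set.seed(7)
  frags <- data.frame(left_dist = runif(16, 0, 5000),
                      right_dist = runif(16, 0, 5000))
  counts <- vapply(seq(0, 6000, by = 500),
                   function(t) distance_stats(frags, t)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fragment size histogram uses half-open 2 kb bins", {
  h1 <- fragment_size_histogram(data.frame(length = 700))
  expect_equal(h1, data.frame(bin_start = 0L, bin_end = 2000L, count = 1L))
  h2 <- fragment_size_histogram(data.frame(length = c(1999, 2000)))
  expect_equal(h2$count, c(1L, 1L))
  expect_equal(h2$bin_start, c(0L, 2000L))
  h3 <- fragment_size_histogram(data.frame(length = rep(4100, 16)))
  expect_equal(sum(h3$count), 16)
  expect_equal(nrow(h3), 1)
  # counts always sum to the input count, any width
  set.seed(11)
  lens <- data.frame(length = sample.int(50000, 40))
  for (w in c(500, 2000, 7777))
    expect_equal(sum(fragment_size_histogram(lens, w)$count), 40)
})

test_that("primer rules are each enforced and all violations reported", {
  good <- oligo_design("primer", strrep("AC", 10), side = "L", strand = "+",
                       distance_bp = 120, tm = 57)
  expect_true(validate_primer(good)$pass)
  far <- oligo_design("primer", strrep("AC", 10), side = "L", strand = "+",
                      distance_bp = 300, tm = 57)
  expect_match(validate_primer(far)$violations, "distance")
  short <- oligo_design("primer", strrep("AC", 8), side = "L", strand = "+",
                        distance_bp = 120, tm = 57)
  expect_match(validate_primer(short)$violations, "length")
  away <- oligo_design("primer", strrep("AC", 10), side = "R", strand = "+",
                       distance_bp = 300, tm = 40)
  v <- validate_primer(away)$violations
  expect_length(v, 3) # distance, tm and orientation all reported
})

test_that("probe rules are each enforced", {
  base <- function(seq, ...) oligo_design("probe", seq, side = "L",
                                          strand = "-", distance_bp = 30,
                                          tm = 66, ...)
  expect_true(validate_probe(base(paste0(strrep("CAT", 7), "CAA")))$pass)
  expect_match(validate_probe(base(paste0("TCC", strrep("GGGG", 5))))$violations,
               "homopolymer", all = FALSE)
  expect_match(validate_probe(base(paste0("G", strrep("CAT", 7))))$violations,
               "5' end", all = FALSE)
  eq <- validate_probe(base(strrep("GCAT", 6)))  # count(C) == count(G)
  expect_match(eq$violations, "more Cs than Gs", all = FALSE)
  gc3 <- validate_probe(base(paste0(strrep("CAT", 6), "TCCGCA")))
  expect_match(gc3$violations, "3' end", all = FALSE)
  opp <- base(paste0(strrep("CAT", 7), "CAA"))
  expect_false(validate_probe(opp, primer_strand = "-")$pass)
  expect_true(validate_probe(opp, primer_strand = "+")$pass)
})

test_that("validate_oligo_table validates mixed tables row-wise", {
  tab <- data.frame(
    role = c("primer", "probe"),
    sequence = c(strrep("AC", 10), paste0(strrep("CAT", 7), "CAA")),
    side = c("L", "L"), strand = c("+", "-"),
    distance_bp = c(120, 30), tm = c(57, 66),
    stringsAsFactors = FALSE)
  out <- validate_oligo_table(tab)
  expect_true(all(out$pass))
  tab$distance_bp <- c(300, 5)
  out <- validate_oligo_table(tab)
  expect_false(any(out$pass))
})

test_that("nearest-neighbor Tm is plausible and alternatives are exact", {
  expect_equal(oligo_tm("ACGTACGTACGTACGTACGT", method = "wallace"),
               2 * 10 + 4 * 10)
  tm <- oligo_tm("ACCTGGATTTCAGAATCGCA")
  expect_true(tm > 40 && tm < 70)
  # longer GC-rich oligos melt higher
  expect_gt(oligo_tm(strrep("GC", 12)), oligo_tm(strrep("AT", 12)))
})

test_that("planted synthetic genomes round-trip through digestion", {
  set.seed(5)
  lengths <- setNames(rep(12000L, 16), chroms16)
  cen <- data.frame(chrom = chroms16, cen_start = 5940L, cen_end = 6060L)
  plant <- function(offsets) {
    do.call(rbind, lapply(chroms16, function(ch) data.frame(
      chrom = ch, pos = 6000L + offsets,
      enzyme = c("EcoRI", "MfeI"), stringsAsFactors = FALSE)))
  }
  g <- synthetic_genome(lengths, cen, plant(c(-1000L, 1000L)))
  for (ch in chroms16) {
    found <- find_sites(g$genome[[ch]])
    expect_equal(found$pos, c(5000L, 7000L))
  }
  frs <- cen_fragments(g$genome, cen)
  expect_equal(nrow(frs), 16)
  expect_equal(distance_stats(frs, 2000)$count, 0)

  g3 <- synthetic_genome(lengths, cen, plant(c(-3000L, 3000L)))
  frs3 <- cen_fragments(g3$genome, cen)
  expect_equal(distance_stats(frs3, 2000)$count, 32)
  expect_equal(unique(frs3$length), 6000L)
  # FASTA round-trip through the standard reader
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(g$genome), "\n",
                    unlist(g$genome)), fa)
  back <- read_genome_fasta(fa)
  expect_identical(unname(back), unname(g$genome))
  # infeasible placements error
  expect_error(synthetic_genome(lengths, cen, data.frame(
    chrom = "chr1", pos = 5990L, enzyme = "EcoRI")), "inside the CEN")
})
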