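# Descriptive analyses of the 16x16 normalized interaction matrix:
# partner and global couple ranks, binned size-similarity scores,
# difference matrices, ancestral-partner checks, size groupings, and
# TSV/heatmap export. Matrices are plain symmetric numeric matrices with
# chromosome dimnames; the diagonal is undefined and always NA.

#' Construct / validate an interaction matrix
#'
#' @param values 16x16 (or n x n) symmetric numeric matrix of normalized
#'   interaction frequencies with chromosome dimnames; off-diagonal values
#'   must be positive where present. The diagonal is set to `NA`.
#' @param label Genotype / timepoint label stored as an attribute.
#' @return The validated matrix.
#' @export
interaction_matrix <- function(values, label = "") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)),
            identical(rownames(values), colnames(values)))
  diag(values) <- NA_real_
  off <- values[upper.tri(values)]
  if (!isTRUE(all.equal(values, t(values))))
    stop("interaction matrix must be symmetric")
  if (any(!is.na(off) & off <= 0))
    stop("interaction frequencies must be positive")
  attr(values, "label") <- label
  values
}

# stop unless every off-diagonal cell is present
check_complete <- function(m, what = "analysis") {
  off <- m[row(m) != col(m)]
  if (anyNA(off))
    stop(what, " requires a complete matrix; ", sum(is.na(off)) / 2,
         " of ", length(off) / 2, " unique couples are missing ",
         "(missing cells are never imputed)")
  invisible(TRUE)
}

# unique couples (i < j by chromosome index) as a data frame with values
unique_couples <- function(m) {
  chroms <- rownames(m)
  ord <- order(chrom_index(chroms))
  chroms <- chroms[ord]
  idx <- which(upper.tri(diag(length(chroms))), arr.ind = TRUE)
  data.frame(cen_i = chroms[idx[, 1]], cen_j = chroms[idx[, 2]],
             value = m[cbind(chroms[idx[, 1]], chroms[idx[, 2]])],
             stringsAsFactors = FALSE)
}

#' Rank the 15 partners of a chromosome by interaction strength
#'
#' Rank 1 is the strongest partner; ties receive average ranks.
#'
#' @param m Interaction matrix.
#' @param chrom Chromosome id.
#' @return Named numeric vector of ranks over the partners.
#' @export
partner_ranks <- function(m, chrom) {
  v <- m[chrom, setdiff(colnames(m), chrom)]
  if (anyNA(v)) stop("partner_ranks requires a complete row")
  rank(-v, ties.method = "average")
}

#' Rank all unique couples globally
#'
#' Rank 1 is the most interacting of the `n(n-1)/2` unique couples; ties
#' receive average ranks.
#'
#' @param m Complete interaction matrix.
#' @return Data frame `cen_i`, `cen_j`, `value`, `rank`.
#' @export
global_ranks <- function(m) {
  check_complete(m, "global_ranks")
  uc <- unique_couples(m)
  uc$rank <- rank(-uc$value, ties.method = "average")
  uc
}

#' Mean global rank of the couples involving one chromosome
#'
#' @param m Complete interaction matrix.
#' @param chrom Chromosome id.
#' @return List with `mean` and `sd` of the 15 global ranks (out of 120)
#'   involving `chrom`.
#' @export
average_couple_rank <- function(m, chrom) {
  gr <- global_ranks(m)
  sel <- gr$cen_i == chrom | gr$cen_j == chrom
  list(mean = mean(gr$rank[sel]), sd = sd(gr$rank[sel]))
}

#' Binned size-similarity interaction score
#'
#' For each chromosome its 15 partners are ordered by chromosome size
#' similarity (|delta length| ascending, ties to the smaller index) and cut
#' into 5 bins of 3 (bin 1-3 = most similar ... bin 13-15 = most
#' dissimilar). With `mu` the mean of all unique interaction frequencies,
#' the per-chromosome bin score is the relative deviation
#' `(mean IF in bin - mu) / mu`; the reported score is its mean over the 16
#' chromosomes. Positive scores mean more interaction than the
#' genotype-average level. The score is invariant to uniform scaling of the
#' matrix. A log2 variant (`log2(mean IF in bin / mu)`) is available.
#'
#' @param m Complete interaction matrix.
#' @param sizes A [size_table()].
#' @param scale `"relative"` (default) or `"log2"`.
#' @param column Size column used for the partner ordering (swap in
#'   `"short_arm_bp"` for the short-arm analysis).
#' @return Data frame with `bin` and `score`; the 16 x 5 per-chromosome
#'   score matrix is attached as attribute `per_chromosome`.
#' @export
binned_score <- function(m, sizes, scale = c("relative", "log2"),
                         column = "length_bp") {
  scale <- match.arg(scale)
  check_complete(m, "binned_score")
  lengths <- size_column(sizes, column)
  stopifnot(setequal(names(lengths), rownames(m)))
  porder <- partner_order_by_size(lengths)
  mu <- mean(unique_couples(m)$value)
  n_bins <- (length(lengths) - 1) %/% 3
  per <- matrix(NA_real_, length(lengths), n_bins,
                dimnames = list(names(lengths), NULL))
  for (ci in names(lengths)) {
    partners <- porder[[ci]]
    for (b in seq_len(n_bins)) {
      sel <- partners[(3 * b - 2):(3 * b)]
      mb <- mean(m[ci, sel])
      per[ci, b] <- if (scale == "relative") (mb - mu) / mu else log2(mb / mu)
    }
  }
  labels <- paste(seq(1, by = 3, length.out = n_bins),
                  seq(3, by = 3, length.out = n_bins), sep = "-")
  out <- data.frame(bin = labels, score = colMeans(per))
  attr(out, "per_chromosome") <- per
  out
}

#' Difference between two interaction matrices
#'
#' @param m_a,m_b Complete interaction matrices over the same chromosomes.
#' @param scale `"linear"` (`m_b - m_a`) or `"log2"`
#'   (`log2(m_b) - log2(m_a)`).
#' @return Signed symmetric matrix; antisymmetric under operand swap.
#' @export
difference_matrix <- function(m_a, m_b, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(identical(dimnames(m_a), dimnames(m_b)))
  check_complete(m_a, "difference_matrix")
  check_complete(m_b, "difference_matrix")
  if (scale == "log2") {
    off_ok <- function(m) all(m[row(m) != col(m)] > 0)
    if (!off_ok(m_a) || !off_ok(m_b))
      stop("log2 difference requires strictly positive matrices")
    return(log2(m_b) - log2(m_a))
  }
  m_b - m_a
}

#' Check interaction ranks of ancestral centromere pairs
#'
#' For each post-duplication ancestral pair, reports the global couple rank
#' and the within-row rank of each member's ancestral sister, and counts
#' how many chromosomes have their ancestral sister as their single
#' strongest partner.
#'
#' @param m Complete interaction matrix.
#' @param pairs Data frame of pairs (`a`, `b`); default [ancestral_pairs()].
#' @return List: `pairs` (with `global_rank`, `rank_in_a_row`,
#'   `rank_in_b_row`), `n_strongest_is_sister` (0-16).
#' @export
ancestral_check <- function(m, pairs = ancestral_pairs()) {
  check_complete(m, "ancestral_check")
  if (!all(c(pairs$a, pairs$b) %in% rownames(m)))
    stop("ancestral pair references unknown chromosome")
  gr <- global_ranks(m)
  key <- paste(gr$cen_i, gr$cen_j)
  grank <- setNames(gr$rank, key)
  pk <- paste(canonical_pair(pairs$a, pairs$b)$cen_i,
              canonical_pair(pairs$a, pairs$b)$cen_j)
  pairs$global_rank <- unname(grank[pk])
  pairs$rank_in_a_row <- mapply(function(a, b) partner_ranks(m, a)[[b]],
                                pairs$a, pairs$b)
  pairs$rank_in_b_row <- mapply(function(a, b) partner_ranks(m, b)[[a]],
                                pairs$a, pairs$b)
  sister <- c(setNames(pairs$b, pairs$a), setNames(pairs$a, pairs$b))
  n_first <- sum(vapply(names(sister), function(ci) {
    pr <- partner_ranks(m, ci)
    names(pr)[which.min(pr)] == sister[[ci]]
  }, logical(1)))
  list(pairs = pairs, n_strongest_is_sister = n_first)
}

#' Contrast of mean interaction levels between two chromosomes
#'
#' `log2(mean IF over A's couples) - log2(mean over B's couples)`;
#' antisymmetric in (A, B).
#'
#' @param m Complete interaction matrix.
#' @param chrom_a,chrom_b Chromosome ids.
#' @return List with `log2` and `fold`.
#' @export
mean_enrichment_contrast <- function(m, chrom_a, chrom_b) {
  check_complete(m, "mean_enrichment_contrast")
  ma <- mean(m[chrom_a, setdiff(colnames(m), chrom_a)])
  mb <- mean(m[chrom_b, setdiff(colnames(m), chrom_b)])
  l2 <- log2(ma) - log2(mb)
  list(log2 = l2, fold = 2^l2)
}

#' Group chromosomes by size with 1-D k-means
#'
#' Deterministic quantile initialization; groups are labelled 1 (smallest)
#' to k (largest) and are contiguous in size order.
#'
#' @param sizes A [size_table()].
#' @param k Number of groups (default 3).
#' @param column Size column.
#' @return Named integer vector of group labels per chromosome.
#' @export
size_groups <- function(sizes, k = 3, column = "length_bp") {
  x <- size_column(sizes, column)
  stopifnot(k >= 1, k < length(x))
  ux <- sort(unique(x))
  if (k == 1) {
    g <- rep(1L, length(x))
  } else if (length(ux) <= k) {
    g <- match(x, ux)
  } else {
    centers <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k))
    centers <- centers + seq_along(centers) * 1e-9 # distinct init centers
    km <- kmeans(x, centers = matrix(centers, ncol = 1))
    relab <- rank(km$centers[, 1], ties.method = "first")
    g <- relab[km$cluster]
  }
  setNames(as.integer(g), names(x))
}

#' Write an interaction matrix as TSV
#'
#' Values are written with 17 significant digits so a re-import reproduces
#' the matrix bit-exactly.
#'
#' @param m Matrix with dimnames.
#' @param path Output TSV.
#' @export
write_matrix_tsv <- function(m, path) {
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  chr[is.na(m)] <- "NA"
  tab <- cbind(chrom = rownames(m), as.data.frame(chr, stringsAsFactors = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction matrix from TSV
#' @param path TSV written by [write_matrix_tsv()].
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  m
}

#' Export a heatmap of an interaction or difference matrix
#'
#' Rows and columns are ordered shortest to longest chromosome. Normalized
#' matrices are drawn on a log2 color scale (white to dark red); difference
#' matrices on a symmetric blue-white-red diverging scale centered at 0.
#' The displayed (ordered) matrix is always written as TSV; a PNG is drawn
#' when `png_path` is given.
#'
#' @param m Matrix (interaction or difference).
#' @param sizes A [size_table()] providing the ordering.
#' @param tsv_path Output TSV path.
#' @param png_path Optional PNG path.
#' @param scale `"log2"` for normalized matrices, `"diverging"` for
#'   difference matrices, `"linear"` for neither transform.
#' @return Invisibly, the ordered matrix that was exported.
#' @export
heatmap_export <- function(m, sizes, tsv_path, png_path = NULL,
                           scale = c("log2", "diverging", "linear")) {
  scale <- match.arg(scale)
  lengths <- size_column(sizes)
  ord <- names(sort(lengths))
  ord <- ord[ord %in% rownames(m)]
  mo <- m[ord, ord]
  write_matrix_tsv(mo, tsv_path)
  if (!is.null(png_path)) {
    disp <- mo
    if (scale == "log2") disp <- log2(mo)
    if (scale == "diverging") {
      lim <- max(abs(disp), na.rm = TRUE)
      if (lim == 0) lim <- 1
      breaks <- seq(-lim, lim, length.out = 101)
      pal <- colorRampPalette(c("#2166AC", "white", "#B2182B"))(100)
    } else {
      breaks <- NA
      pal <- colorRampPalette(c("white", "#FEE090", "#D73027", "#67000D"))(100)
    }
    png(png_path, width = 900, height = 800)
    pheatmap::pheatmap(disp, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = pal,
                       breaks = if (identical(breaks, NA)) NA else breaks,
                       main = if (is.null(attr(m, "label"))) "" else
                         attr(m, "label"),
                       na_col = "grey85")
    dev.off()
  }
  invisible(mo)
}
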