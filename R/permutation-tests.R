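# Permutation tests for partner-preference structure in the interaction
# matrix. The statistic T counts, summed over chromosomes, how many of the
# top-k_if interacting partners are also among the top-k_size preferred
# partners (most similar in size, most dissimilar, most arm homology, or
# same telomere cluster). The null distribution randomizes the matrix by
# permuting its unique off-diagonal values uniformly and mirroring to
# symmetry, which preserves the value multiset; permuting the chromosome
# labels is available as an alternative randomization for robustness
# checks. The p-value is the plain fraction of null iterations with
# T* >= T_obs; the conservative (r + 1) / (n + 1) estimate is also
# reported so that p = 0 never appears silently.

#' Build a partner-preference ordering
#'
#' @param sizes A [size_table()].
#' @param mode `"size_similarity"` (partners ordered by |delta length|
#'   ascending), `"size_dissimilarity"` (descending), or `"short_arm"`
#'   (similarity of short-arm lengths).
#' @return A `partner_preference` object.
#' @export
partner_preference <- function(sizes, mode = c("size_similarity",
                                               "size_dissimilarity",
                                               "short_arm")) {
  mode <- match.arg(mode)
  column <- if (mode == "short_arm") "short_arm_bp" else "length_bp"
  lengths <- size_column(sizes, column)
  ord <- partner_order_by_size(lengths,
                               decreasing = mode == "size_dissimilarity")
  structure(list(mode = mode, chrom = names(lengths), order = ord,
                 clusters = NULL), class = "partner_preference")
}

#' Partner preference from a pairwise homology matrix
#'
#' Partners are ordered by decreasing homology (e.g. shared ORF content on
#' chromosome arms); ties break to the smaller chromosome index.
#'
#' @param hom Symmetric numeric matrix with chromosome dimnames.
#' @return A `partner_preference` object with mode `"arm_homology"`.
#' @export
homology_preference <- function(hom) {
  stopifnot(is.matrix(hom), identical(rownames(hom), colnames(hom)))
  chroms <- rownames(hom)
  ord <- lapply(chroms, function(ci) {
    others <- setdiff(chroms, ci)
    others[order(-hom[ci, others], chrom_index(others))]
  })
  names(ord) <- chroms
  structure(list(mode = "arm_homology", chrom = chroms, order = ord,
                 clusters = NULL), class = "partner_preference")
}

#' Partner preference from telomere-cluster membership
#'
#' The preferred set of a chromosome is its same-cluster partners
#' (`k_size` is ignored in this mode). Cluster assignments come from
#' external literature and are user-supplied.
#'
#' @param clusters Named vector assigning every chromosome to one cluster.
#' @return A `partner_preference` object with mode `"telomere_cluster"`.
#' @export
cluster_preference <- function(clusters) {
  stopifnot(!is.null(names(clusters)))
  structure(list(mode = "telomere_cluster", chrom = names(clusters),
                 order = NULL, clusters = clusters),
            class = "partner_preference")
}

# 16x16 logical mask: is j in the preferred top-k_size set of i?
preference_mask <- function(pref, k_size, chroms) {
  stopifnot(setequal(pref$chrom, chroms))
  mask <- matrix(FALSE, length(chroms), length(chroms),
                 dimnames = list(chroms, chroms))
  if (pref$mode == "telomere_cluster") {
    for (ci in chroms) {
      same <- setdiff(names(pref$clusters)[pref$clusters ==
                                             pref$clusters[[ci]]], ci)
      mask[ci, same] <- TRUE
    }
  } else {
    stopifnot(k_size >= 1, k_size <= length(chroms) - 1)
    for (ci in chroms) mask[ci, pref$order[[ci]][seq_len(k_size)]] <- TRUE
  }
  mask
}

#' Observed partner-preference overlap statistic
#'
#' `T = sum over chromosomes of |top-k_if partners by interaction frequency
#' intersected with the top-k_size preferred partners|`. With
#' `lowest = TRUE` the bottom-k_if partners are used instead (avoidance
#' variant). Ties in the observed top-k selection break to the smaller
#' chromosome index (deterministic).
#'
#' @param m Complete interaction matrix.
#' @param pref A `partner_preference`.
#' @param k_if,k_size Top-list sizes (1-15). `k_size` is ignored for
#'   cluster-mode preferences.
#' @param subset Optional chromosome subset restricting the outer sum
#'   (candidate partners remain all 15).
#' @param lowest Use the least-interacting partners instead.
#' @return Integer statistic T.
#' @export
observed_statistic <- function(m, pref, k_if = 3, k_size = 3, subset = NULL,
                               lowest = FALSE) {
  check_complete(m, "observed_statistic")
  chroms <- rownames(m)
  stopifnot(k_if >= 1, k_if <= length(chroms) - 1)
  if (is.null(subset)) subset <- chroms
  stopifnot(all(subset %in% chroms))
  mask <- preference_mask(pref, k_size, chroms)
  total <- 0L
  for (ci in subset) {
    others <- setdiff(chroms, ci)
    v <- m[ci, others]
    ord <- order(if (lowest) v else -v, chrom_index(others))
    top <- others[ord][seq_len(k_if)]
    total <- total + sum(mask[ci, top])
  }
  as.integer(total)
}

new_coupling_test <- function(variant, statistic, null, iterations, seed,
                              params) {
  ge <- sum(null >= statistic)
  structure(list(
    variant = variant, statistic = statistic, iterations = iterations,
    null_mean = mean(null), null_sd = sd(null),
    p.value = ge / iterations,
    p_conservative = (ge + 1) / (iterations + 1),
    seed = seed, params = params), class = "coupling_test")
}

#' @export
print.coupling_test <- function(x, ...) {
  cat("Matrix-randomization permutation test:", x$variant, "\n")
  prm <- x$params[!vapply(x$params, is.null, logical(1))]
  if (length(prm))
    cat("  ", paste(names(prm), unlist(lapply(prm, paste, collapse = ",")),
                    sep = " = ", collapse = "; "), "\n", sep = "")
  cat(sprintf("  T = %d, null %.2f +/- %.2f (%d iterations)\n",
              x$statistic, x$null_mean, x$null_sd, x$iterations))
  cat(sprintf("  p = %.5g (conservative %.5g)\n", x$p.value,
              x$p_conservative))
  if (!is.null(x$seed)) cat("  seed =", x$seed, "\n")
  invisible(x)
}

#' Permutation null distribution for the overlap statistic
#'
#' @inheritParams observed_statistic
#' @param iterations Number of randomizations (default 100000; fewer than
#'   1000 triggers a warning about p-value resolution).
#' @param seed Optional integer seed; recorded in the result.
#' @param method `"values"` permutes the unique off-diagonal values
#'   (default); `"labels"` permutes chromosome labels.
#' @param variant Label stored in the result.
#' @return A `coupling_test` object; the null statistics are attached as
#'   attribute `null` when `keep_null = TRUE`.
#' @param keep_null Keep the vector of null statistics.
#' @export
null_distribution <- function(m, pref, k_if = 3, k_size = 3,
                              iterations = 1e5, seed = NULL, subset = NULL,
                              lowest = FALSE,
                              method = c("values", "labels"),
                              variant = "size_similarity",
                              keep_null = FALSE) {
  method <- match.arg(method)
  if (iterations < 1000)
    warning("fewer than 1000 iterations: poor p-value resolution")
  check_complete(m, "null_distribution")
  chroms <- rownames(m)
  if (!is.null(seed)) set.seed(seed)
  t_obs <- observed_statistic(m, pref, k_if, k_size, subset, lowest)
  mask <- preference_mask(pref, k_size, chroms)
  rows <- if (is.null(subset)) seq_along(chroms) else
    match(subset, chroms)
  if (method == "values") {
    null <- cpp_null_stats(m, mask, as.integer(k_if), lowest,
                           as.integer(rows - 1L), as.integer(iterations))
  } else {
    topk <- t(vapply(chroms, function(ci) {
      others <- setdiff(chroms, ci)
      v <- m[ci, others]
      ord <- order(if (lowest) v else -v, chrom_index(others))
      match(others[ord][seq_len(k_if)], chroms)
    }, integer(k_if)))
    null <- cpp_label_null_stats(topk - 1L, mask, as.integer(rows - 1L),
                                 as.integer(iterations))
  }
  out <- new_coupling_test(variant, t_obs, null, iterations, seed,
                           list(k_if = k_if,
                                k_size = if (pref$mode == "telomere_cluster")
                                  NULL else k_size,
                                mode = pref$mode, subset = subset,
                                lowest = lowest, method = method))
  if (keep_null) attr(out, "null") <- null
  out
}

#' Sensitivity suite over (k_if, k_size) combinations
#'
#' Runs the size-preference test for (3,3), (3,5), (5,3) and (5,5).
#'
#' @inheritParams null_distribution
#' @return Named list of `coupling_test` objects.
#' @export
sensitivity_suite <- function(m, pref, iterations = 1e5, seed = NULL, ...) {
  ks <- list(c(3, 3), c(3, 5), c(5, 3), c(5, 5))
  out <- lapply(seq_along(ks), function(i) {
    null_distribution(m, pref, k_if = ks[[i]][1], k_size = ks[[i]][2],
                      iterations = iterations,
                      seed = if (is.null(seed)) NULL else seed + i - 1,
                      variant = sprintf("size_similarity_k%d_%d",
                                        ks[[i]][1], ks[[i]][2]), ...)
  })
  names(out) <- vapply(ks, function(k) paste0("k", k[1], "_", k[2]), "")
  out
}

#' Subset variant of the preference test
#'
#' The outer sum of T is restricted to `subset` (e.g. the four shortest
#' chromosomes); candidate partners remain all 15 and the randomization
#' still permutes the full matrix.
#'
#' @inheritParams null_distribution
#' @param subset Chromosome ids.
#' @export
subset_test <- function(m, pref, subset, k_if = 3, k_size = 3,
                        iterations = 1e5, seed = NULL, ...) {
  stopifnot(length(subset) >= 1)
  null_distribution(m, pref, k_if, k_size, iterations, seed,
                    subset = subset, variant = "size_similarity_subset", ...)
}

#' Size-dissimilarity avoidance test
#'
#' Do the bottom-k least-interacting partners coincide with the most
#' size-dissimilar chromosomes more often than chance?
#'
#' @param m Complete interaction matrix.
#' @param sizes A [size_table()].
#' @inheritParams null_distribution
#' @export
avoidance_test <- function(m, sizes, k_if = 3, k_size = 3, iterations = 1e5,
                           seed = NULL, ...) {
  pref <- partner_preference(sizes, "size_dissimilarity")
  null_distribution(m, pref, k_if, k_size, iterations, seed, lowest = TRUE,
                    variant = "size_dissimilarity_avoidance", ...)
}

#' Cross-strain top-k overlap resampling test
#'
#' For each chromosome, the top-k partners in matrix A are intersected with
#' the top-k partners in matrix B and the overlaps summed. The null draws
#' independent uniform k-subsets of the 15 partners for each strain and
#' chromosome (a sum of hypergeometric overlaps).
#'
#' @param m_a,m_b Complete interaction matrices over the same chromosomes.
#' @param k Top-list size (default 5).
#' @inheritParams null_distribution
#' @return A `coupling_test`; `params$overlap_fraction` gives the observed
#'   overlap as a fraction of `16 * k`.
#' @export
overlap_test <- function(m_a, m_b, k = 5, iterations = 1e5, seed = NULL) {
  stopifnot(identical(dimnames(m_a), dimnames(m_b)))
  check_complete(m_a, "overlap_test")
  check_complete(m_b, "overlap_test")
  if (!is.null(seed)) set.seed(seed)
  chroms <- rownames(m_a)
  n_part <- length(chroms) - 1
  topk <- function(m, ci) {
    others <- setdiff(chroms, ci)
    v <- m[ci, others]
    others[order(-v, chrom_index(others))][seq_len(k)]
  }
  obs <- sum(vapply(chroms, function(ci)
    length(intersect(topk(m_a, ci), topk(m_b, ci))), integer(1)))
  null <- rowSums(matrix(rhyper(iterations * length(chroms), k, n_part - k,
                                k), ncol = length(chroms)))
  out <- new_coupling_test("top_k_overlap", as.integer(obs), null,
                           iterations, seed,
                           list(k = k,
                                overlap_fraction = obs / (length(chroms) * k)))
  out
}

#' Agreement between two interaction profiles
#'
#' Pearson R-squared on the raw paired values of the unique couples and
#' Spearman rho on their ranks, with p-values.
#'
#' @param m_a,m_b Complete interaction matrices over the same chromosomes.
#' @return List: `r_squared`, `r_squared_p`, `spearman_rho`, `spearman_p`,
#'   `n`, `flagged` (TRUE when a zero-variance profile leaves the
#'   correlation undefined).
#' @export
profile_agreement <- function(m_a, m_b) {
  stopifnot(identical(dimnames(m_a), dimnames(m_b)))
  check_complete(m_a, "profile_agreement")
  check_complete(m_b, "profile_agreement")
  x <- unique_couples(m_a)$value
  y <- unique_couples(m_b)$value
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r_squared = NA_real_, r_squared_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                n = length(x), flagged = TRUE))
  pe <- cor.test(x, y)
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(r_squared = unname(pe$estimate)^2, r_squared_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x), flagged = FALSE)
}
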