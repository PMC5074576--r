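# Fixtures and independent brute-force oracles used across the suite.

chroms16 <- chrom_ids()

# random positive symmetric interaction matrix
random_matrix <- function(n = 16, chroms = paste0("chr", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(chroms, chroms))
  vals <- exp(rnorm(n * (n - 1) / 2))
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- NA_real_
  m
}

# matrix whose IF is strictly decreasing (or increasing) in |delta length|
monotone_size_matrix <- function(sizes, increasing = FALSE) {
  lengths <- size_column(sizes)
  chroms <- names(lengths)
  d <- abs(outer(lengths, lengths, "-"))
  # strictly monotone in |dL|; tiny index term breaks exact |dL| ties
  tie <- outer(chrom_index(chroms), chrom_index(chroms), function(a, b)
    1e-9 * (a + b))
  m <- if (increasing) 1e-7 + d / max(d) + tie else 1 / (1 + d / 1e4) + tie
  dimnames(m) <- list(chroms, chroms)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- NA_real_
  m
}

# brute-force top-k overlap statistic: materializes top-k sets by repeated
# max (or min) extraction, never by vectorized ranking
oracle_statistic <- function(m, pref_sets, k_if, subset = rownames(m),
                             lowest = FALSE) {
  total <- 0
  for (ci in subset) {
    v <- m[ci, setdiff(colnames(m), ci)]
    picked <- character(0)
    for (s in seq_len(k_if)) {
      rem <- v[setdiff(names(v), picked)]
      best <- if (lowest) min(rem) else max(rem)
      cand <- names(rem)[rem == best]
      picked <- c(picked, cand[order(chrom_index(cand))][1])
    }
    total <- total + length(intersect(picked, pref_sets[[ci]]))
  }
  total
}

# preference sets (top-k_size) from a size table, built independently
oracle_pref_sets <- function(sizes, k_size, dissimilar = FALSE) {
  lengths <- size_column(sizes)
  sets <- lapply(names(lengths), function(ci) {
    others <- setdiff(names(lengths), ci)
    d <- abs(lengths[others] - lengths[ci])
    if (dissimilar) d <- -d
    others[order(d, chrom_index(others))][seq_len(k_size)]
  })
  names(sets) <- names(lengths)
  sets
}

# two-tailed Fisher p by exhaustive hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - m2):min(m1, c1)
  probs <- dhyper(support, m1, m2, c1)
  p_obs <- dhyper(a, m1, m2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# a complete 120-pair Cp record table with given underlying pair Cp
full_cp_records <- function(pair_cp, dilutions = c(2, 4, 8), reps = 1) {
  uc <- expand.grid(i = 1:16, j = 1:16)
  uc <- uc[uc$i < uc$j, ]
  rows <- list()
  for (r in seq_len(nrow(uc))) {
    ci <- paste0("chr", uc$i[r]); cj <- paste0("chr", uc$j[r])
    base <- pair_cp[[paste(ci, cj)]]
    for (si in c("L", "R")) for (sj in c("L", "R"))
      for (d in dilutions) for (rep in seq_len(reps))
        rows[[length(rows) + 1]] <- data.frame(
          cen_i = ci, side_i = si, cen_j = cj, side_j = sj,
          dilution = d, replicate = rep, cp = base + log2(d),
          stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# matching per-side-combination control table with constant Cp
full_control <- function(cp = 30) {
  uc <- expand.grid(i = 1:16, j = 1:16)
  uc <- uc[uc$i < uc$j, ]
  sc <- merge(uc, expand.grid(side_i = c("L", "R"), side_j = c("L", "R"),
                              stringsAsFactors = FALSE))
  data.frame(cen_i = paste0("chr", sc$i), side_i = sc$side_i,
             cen_j = paste0("chr", sc$j), side_j = sc$side_j, cp = cp,
             stringsAsFactors = FALSE)
}
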