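# Statistics over chromosome-spread coupling counts: per-strain summaries,
# Fisher's exact comparison of pooled counts, and fold contrasts.

#' Summarize spread coupling counts for one strain
#'
#' @param counts Data frame with columns `coupled` and `scored`, one row
#'   per replicate experiment.
#' @return List: `mean_percent` (mean of per-replicate percentages),
#'   `range_percent`, `pooled_proportion`, `pooled_coupled`,
#'   `pooled_scored`.
#' @export
coupling_summary <- function(counts) {
  stopifnot(nrow(counts) >= 1, all(counts$scored > 0),
            all(counts$coupled >= 0), all(counts$coupled <= counts$scored))
  pct <- 100 * counts$coupled / counts$scored
  list(mean_percent = mean(pct), range_percent = range(pct),
       pooled_proportion = sum(counts$coupled) / sum(counts$scored),
       pooled_coupled = sum(counts$coupled),
       pooled_scored = sum(counts$scored))
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Rows are strains, columns coupled / not coupled. The two-tailed p-value
#' sums the hypergeometric probabilities of all tables with the same
#' margins whose point probability does not exceed the observed table's
#' (the most common convention). A zero margin makes the test degenerate;
#' p = 1 is returned with a flag.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return List: `p.value`, `flagged`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p.value = 1, flagged = TRUE))
  list(p.value = fisher.test(tab, alternative = "two.sided")$p.value,
       flagged = FALSE)
}

#' Fold contrast between two coupling percentages
#'
#' @param p_a,p_b Percentages (or proportions on a shared scale).
#' @return List: `ratio` (`p_a / p_b`), `flagged` (TRUE when `p_b` is 0
#'   and the ratio is undefined).
#' @export
fold_contrast <- function(p_a, p_b) {
  if (p_b == 0) return(list(ratio = NA_real_, flagged = TRUE))
  list(ratio = p_a / p_b, flagged = FALSE)
}

#' Reconstruct integer counts from a printed percentage
#'
#' Rounds `percent / 100 * scored` to the nearest integer and verifies the
#' rounded count re-prints as the same percentage at the given precision;
#' a mismatch is an error, never silent.
#'
#' @param percent Printed percentage.
#' @param scored Number of spreads scored.
#' @param digits Decimal places at which the printed percentage was
#'   reported (default 1).
#' @return Integer count of coupled spreads.
#' @export
counts_from_percent <- function(percent, scored, digits = 1) {
  k <- round(percent / 100 * scored)
  if (round(100 * k / scored, digits) != round(percent, digits))
    stop("count ", k, "/", scored, " does not reproduce the printed ",
         percent, "% at ", digits, " decimal place(s)")
  as.integer(k)
}
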