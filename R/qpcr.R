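# Processing of raw Taqman crossing-point (Cp) records into a normalized
# interaction matrix. Cp values live on a log2 abundance scale: one cycle is
# a twofold difference at perfect amplification efficiency. Averaging is
# done on the Cp scale (geometric mean of abundances) throughout.

# canonical unordered pair: smaller chromosome index first
canonical_pair <- function(cen_i, cen_j, side_i = NULL, side_j = NULL) {
  swap <- chrom_index(cen_i) > chrom_index(cen_j)
  out <- data.frame(cen_i = ifelse(swap, cen_j, cen_i),
                    cen_j = ifelse(swap, cen_i, cen_j),
                    stringsAsFactors = FALSE)
  if (!is.null(side_i)) {
    out$side_i <- ifelse(swap, side_j, side_i)
    out$side_j <- ifelse(swap, side_i, side_j)
  }
  out
}

#' Read a Cp record table
#'
#' Expected columns: `cen_i`, `side_i`, `cen_j`, `side_j`, `dilution`,
#' `replicate`, `cp`. An empty or `"failed"` `cp` field marks a reaction
#' that failed to amplify within the instrument's cycle cap.
#'
#' @param path TSV file.
#' @return Data frame with `cp` numeric (`NA` = failed).
#' @export
read_cp_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(cp = "character"))
  tab$cp[tab$cp %in% c("", "failed", "NA")] <- NA
  tab$cp <- as.numeric(tab$cp)
  tab
}

#' Dilution-adjust Cp values
#'
#' Back-corrects a Cp measured on diluted template to the undiluted scale
#' assuming perfect (twofold per cycle) amplification efficiency:
#' `adjusted = cp - log2(dilution)`.
#'
#' @param cp Numeric Cp values (`NA` = failed, propagated).
#' @param dilution Dilution factors (1, 2, 4, 8, ...).
#' @param efficiency Per-cycle amplification factor; default 2. A fitted
#'   efficiency from [loading_concentration()] may be supplied instead.
#' @return Adjusted Cp on the undiluted scale.
#' @export
adjust_cp <- function(cp, dilution, efficiency = 2) {
  stopifnot(all(dilution > 0), efficiency > 1)
  cp - log(dilution, base = efficiency)
}

#' Average Cp records per chromosome pair
#'
#' Adjusted Cp values are averaged per side-combination first, then the
#' side-combination means are averaged with equal weight (the four ligation
#' geometries of a pair count equally). Failed reactions are handled by
#' `policy`: `"exclude"` drops them (default; unbiased when failures are
#' dilution-driven), `"censor"` imputes the instrument cycle cap as a
#' censoring bound before dilution adjustment.
#'
#' @param records Cp record data frame (see [read_cp_table()]).
#' @param policy `"exclude"` or `"censor"`.
#' @param min_side_combos Minimum side-combinations with data required for a
#'   pair mean (default 2); pairs below it are flagged missing.
#' @param max_cycles Instrument cycle cap used by the censor policy.
#' @param efficiency Amplification efficiency for dilution adjustment.
#' @return Data frame (one row per pair): `cen_i`, `cen_j`, `mean_cp`,
#'   `n_success`, `n_failed`, `n_side_combos`, `missing`. The per-side-
#'   combination means are attached as attribute `side_combos`.
#' @export
aggregate_combinations <- function(records, policy = c("exclude", "censor"),
                                   min_side_combos = 2, max_cycles = 55,
                                   efficiency = 2) {
  policy <- match.arg(policy)
  cp <- records$cp
  failed <- is.na(cp)
  if (policy == "censor") cp[failed] <- max_cycles
  adj <- adjust_cp(cp, records$dilution, efficiency)
  cano <- canonical_pair(records$cen_i, records$cen_j,
                         records$side_i, records$side_j)
  key_pair <- paste(cano$cen_i, cano$cen_j)
  key_sc <- paste(key_pair, cano$side_i, cano$side_j)
  use <- if (policy == "exclude") !failed else rep(TRUE, length(adj))
  sc_mean <- tapply(adj[use], key_sc[use], mean)
  sc_tab <- data.frame(
    key_sc = names(sc_mean),
    key_pair = sub("^((\\S+) (\\S+)).*", "\\1", names(sc_mean)),
    mean_cp = as.numeric(sc_mean), stringsAsFactors = FALSE)
  pairs <- unique(data.frame(key_pair, cen_i = cano$cen_i, cen_j = cano$cen_j,
                             stringsAsFactors = FALSE))
  pair_mean <- tapply(sc_tab$mean_cp, sc_tab$key_pair, mean)
  n_sc <- tapply(sc_tab$mean_cp, sc_tab$key_pair, length)
  out <- data.frame(
    cen_i = pairs$cen_i, cen_j = pairs$cen_j,
    mean_cp = as.numeric(pair_mean[pairs$key_pair]),
    n_success = as.integer(tapply(!failed, key_pair, sum)[pairs$key_pair]),
    n_failed = as.integer(tapply(failed, key_pair, sum)[pairs$key_pair]),
    n_side_combos = as.integer(ifelse(is.na(n_sc[pairs$key_pair]), 0,
                                      n_sc[pairs$key_pair])),
    stringsAsFactors = FALSE)
  out$missing <- out$n_side_combos < min_side_combos
  out$mean_cp[out$missing] <- NA_real_
  ord <- order(chrom_index(out$cen_i), chrom_index(out$cen_j))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "side_combos") <- sc_tab
  attr(out, "policy") <- policy
  out
}

#' Fit a loading-control dilution series
#'
#' Least-squares line of Cp against log2(relative dilution). At perfect
#' efficiency the slope is -1 (one extra cycle per twofold dilution); the
#' fitted amplification efficiency is `2^(-1/slope)` (the usual
#' standard-curve formula in log2 units). The library concentration is
#' expressed as the Cp interpolated at a fixed reference dilution; relative
#' to a reference library, the concentration factor is
#' `2^(cp_reference - cp_library)` at that dilution.
#'
#' @param lc Data frame with columns `dilution` (relative, e.g. 1/12.5 ...
#'   1/200) and `cp`.
#' @param reference Optional second loading-control data frame; when given,
#'   `concentration_factor` is this library's DNA concentration relative to
#'   the reference.
#' @param ref_dilution Dilution at which the series are compared
#'   (default 1/50).
#' @return List: `slope`, `efficiency`, `cp_at_reference`,
#'   `concentration_factor` (1 when no reference is given).
#' @export
loading_concentration <- function(lc, reference = NULL, ref_dilution = 1 / 50) {
  stopifnot(nrow(lc) >= 3)
  if (length(unique(lc$dilution)) < 2)
    stop("degenerate dilution series: no variance in dilution")
  fit <- lm(cp ~ I(log2(dilution)), data = lc)
  slope <- unname(coef(fit)[2])
  eff <- 2^(-1 / slope)
  cp_at <- unname(coef(fit)[1] + slope * log2(ref_dilution))
  factor <- 1
  if (!is.null(reference)) {
    ref <- loading_concentration(reference, ref_dilution = ref_dilution)
    factor <- 2^(ref$cp_at_reference - cp_at)
  }
  list(slope = slope, efficiency = eff, cp_at_reference = cp_at,
       concentration_factor = factor)
}

#' Normalize pair means into an interaction matrix
#'
#' Interaction frequencies are `2^(cp_control - cp_sample) / loading`.
#' By default the control subtraction happens per side-combination before
#' pair averaging (on the log2 scale), so primer/probe efficiency
#' differences between the four ligation geometries cancel; the alternative
#' order subtracts pair-level control means from pair-level sample means.
#' Missing pairs propagate as `NA` cells; they are never imputed.
#'
#' @param raw Output of [aggregate_combinations()] for the 3C sample.
#' @param control Data frame of per-side-combination mean control Cp with
#'   columns `cen_i`, `side_i`, `cen_j`, `side_j`, `cp` (a ControlLibrary),
#'   or a pair-level table with `cen_i`, `cen_j`, `cp`.
#' @param loading Scalar loading factor (relative DNA concentration of the
#'   3C library; see [loading_concentration()]).
#' @param order `"per_side_combination"` (default) or `"pair_mean"`.
#' @return 16x16 symmetric numeric matrix (diagonal `NA`), rows/columns
#'   named by chromosome in numeric order.
#' @export
normalize_matrix <- function(raw, control, loading = 1,
                             order = c("per_side_combination", "pair_mean")) {
  order <- match.arg(order)
  stopifnot(loading > 0)
  has_sides <- all(c("side_i", "side_j") %in% names(control))
  cano <- canonical_pair(control$cen_i, control$cen_j,
                         if (has_sides) control$side_i else NULL,
                         if (has_sides) control$side_j else NULL)
  ctl_pair_key <- paste(cano$cen_i, cano$cen_j)
  if (order == "per_side_combination") {
    if (!has_sides)
      stop("per-side-combination normalization needs side columns in control")
    sc <- attr(raw, "side_combos")
    if (is.null(sc))
      stop("raw table lacks side-combination means; rerun aggregate_combinations")
    ctl_key <- paste(ctl_pair_key, cano$side_i, cano$side_j)
    ctl_cp <- setNames(control$cp, ctl_key)
    log2if_sc <- ctl_cp[sc$key_sc] - sc$mean_cp
    log2if <- tapply(log2if_sc, sc$key_pair, mean, na.rm = FALSE)
  } else {
    ctl_pair <- tapply(control$cp, ctl_pair_key, mean)
    raw_key <- paste(raw$cen_i, raw$cen_j)
    log2if <- setNames(ctl_pair[raw_key] - raw$mean_cp, raw_key)
  }
  chroms <- chrom_ids()
  m <- matrix(NA_real_, 16, 16, dimnames = list(chroms, chroms))
  raw_key <- paste(raw$cen_i, raw$cen_j)
  vals <- 2^as.numeric(log2if[raw_key]) / loading
  vals[raw$missing] <- NA_real_
  for (r in seq_len(nrow(raw))) {
    m[raw$cen_i[r], raw$cen_j[r]] <- vals[r]
    m[raw$cen_j[r], raw$cen_i[r]] <- vals[r]
  }
  m
}

#' Raw-cycle enrichment contrast between two libraries
#'
#' Compares mean raw qPCR cycle numbers: a lower mean Cp means more
#' ligation products. The log2 enrichment of A over B is `B - A` cycles and
#' the fold change `2^(B - A)`.
#'
#' @param mean_a,mean_b Mean raw cycle numbers of libraries A and B, on the
#'   same (unnormalized) cycle scale.
#' @return List: `log2` (= `mean_b - mean_a`), `fold`, `fold_rounded`.
#' @export
enrichment_difference <- function(mean_a, mean_b) {
  l2 <- mean_b - mean_a
  list(log2 = l2, fold = 2^l2, fold_rounded = round(2^l2))
}

#' Concordance between two control libraries
#'
#' @param a,b Per-side-combination control tables (`cen_i`, `side_i`,
#'   `cen_j`, `side_j`, `cp`).
#' @param window Cycle window for the "within" fractions (default 1 cycle,
#'   about twofold).
#' @return List: `frac_within_own` (per library, fraction of combinations
#'   within `window` of that library's own mean), `frac_within_cross`
#'   (fraction with |A - B| <= window), `median_diff`, `pearson_r`,
#'   `pearson_p`, `n_shared`, `flagged` (TRUE when fewer than 3 shared
#'   combinations make the correlation undefined).
#' @export
control_concordance <- function(a, b, window = 1) {
  key <- function(x) {
    cano <- canonical_pair(x$cen_i, x$cen_j, x$side_i, x$side_j)
    paste(cano$cen_i, cano$cen_j, cano$side_i, cano$side_j)
  }
  ka <- key(a); kb <- key(b)
  shared <- intersect(ka, kb)
  va <- setNames(a$cp, ka)[shared]
  vb <- setNames(b$cp, kb)[shared]
  diffs <- abs(va - vb)
  flagged <- length(shared) < 3
  r <- p <- NA_real_
  if (!flagged) {
    ct <- cor.test(va, vb)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(
    frac_within_own = c(a = mean(abs(va - mean(va)) <= window),
                        b = mean(abs(vb - mean(vb)) <= window)),
    frac_within_cross = mean(diffs <= window),
    median_diff = unname(median(diffs)),
    pearson_r = r, pearson_p = p,
    n_shared = length(shared), flagged = flagged)
}

#' Proximal/distal crosslinking QC
#'
#' A crosslinked 3C library must show enrichment of intra-chromosomal
#' proximal over distal fragments; a random-ligation control must not.
#' Libraries failing this check are discarded upstream of any analysis.
#'
#' @param proximal,distal Nonnegative signal intensities (or `2^(-cp)`
#'   abundances).
#' @param crosslinked Logical: is this a crosslinked 3C library (TRUE) or a
#'   random-ligation control (FALSE)?
#' @param threshold Enrichment threshold (default 1.5).
#' @return List: `ratio`, `pass`, `flagged` (TRUE for an infinite ratio).
#' @export
qc_proximal_distal <- function(proximal, distal, crosslinked,
                               threshold = 1.5) {
  stopifnot(proximal >= 0, distal >= 0)
  ratio <- proximal / distal
  flagged <- !is.finite(ratio)
  pass <- if (crosslinked) isTRUE(ratio > threshold)
  else isTRUE(ratio >= 1 / threshold && ratio <= threshold)
  list(ratio = ratio, pass = pass, flagged = flagged)
}
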