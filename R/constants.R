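# Bundled S. cerevisiae (R64 nominal assembly) chromosome lengths and
# centromere coordinates (0-based half-open, BED convention), plus the eight
# post-whole-genome-duplication ancestral centromere pairs.

.sc_lengths_r64 <- c(
  chr1  = 230218,  chr2  = 813184,  chr3  = 316620,  chr4  = 1531933,
  chr5  = 576874,  chr6  = 270161,  chr7  = 1090940, chr8  = 562643,
  chr9  = 439888,  chr10 = 745751,  chr11 = 666816,  chr12 = 1078177,
  chr13 = 924431,  chr14 = 784333,  chr15 = 1091291, chr16 = 948066
)

# CEN intervals, 0-based half-open (SGD annotations, 1-based start - 1).
.sc_cen_r64 <- data.frame(
  chrom = paste0("chr", 1:16),
  cen_start = c(151464, 238206, 114384, 449710, 151986, 148509, 496919,
                105585, 355628, 436306, 440128, 150827, 268030, 628757,
                326583, 555956),
  cen_end   = c(151582, 238323, 114501, 449821, 152104, 148627, 497038,
                105703, 355745, 436425, 440246, 150947, 268149, 628875,
                326702, 556073),
  stringsAsFactors = FALSE
)

#' Ancestral centromere pairs from the pre-duplication yeast ancestor
#'
#' The eight pairs of S. cerevisiae centromeres descended from single
#' centromeres of the budding-yeast ancestor prior to whole-genome
#' duplication (CEN1-CEN7, CEN2-CEN4, CEN3-CEN14, CEN5-CEN9, CEN6-CEN16,
#' CEN8-CEN11, CEN10-CEN12, CEN13-CEN15).
#'
#' @return A two-column data frame of chromosome ids (`a`, `b`).
#' @export
ancestral_pairs <- function() {
  data.frame(
    a = paste0("chr", c(1, 2, 3, 5, 6, 8, 10, 13)),
    b = paste0("chr", c(7, 4, 14, 9, 16, 11, 12, 15)),
    stringsAsFactors = FALSE
  )
}

#' Chromosome labels in numeric order
#' @return Character vector `chr1` ... `chr16`.
#' @export
chrom_ids <- function() paste0("chr", 1:16)

# numeric index of a "chrN" label; used as the deterministic tie-break
chrom_index <- function(x) as.integer(sub("^chr", "", x))

#' Chromosome size table for S. cerevisiae
#'
#' Builds the bundled size table used for size-similarity analyses. Two
#' variants are available: `"assembly"` uses the nominal R64 assembly
#' lengths (in which the rDNA repeat array on chromosome 12 collapses to
#' roughly two copies, so chromosome 4 is the longest); `"physical"`
#' (default) adds a configurable rDNA-array term to chromosome 12 so that it
#' ranks as the longest chromosome, reflecting its size in vivo
#' (approximately 150 rDNA repeats of 9.1 kb).
#'
#' @param variant `"physical"` (default) or `"assembly"`.
#' @param rdna_bp Extra length (bp) added to chromosome 12 under the
#'   physical variant. Default 1.5e6.
#' @return A `size_table` data frame with columns `chrom`, `length_bp`,
#'   `short_arm_bp` (centromere midpoint to nearest telomere).
#' @export
chrom_sizes <- function(variant = c("physical", "assembly"), rdna_bp = 1.5e6) {
  variant <- match.arg(variant)
  len <- .sc_lengths_r64
  if (variant == "physical") len["chr12"] <- len["chr12"] + rdna_bp
  mid <- floor((.sc_cen_r64$cen_start + .sc_cen_r64$cen_end) / 2)
  names(mid) <- .sc_cen_r64$chrom
  mid <- mid[names(len)]
  short_arm <- pmin(mid, len - mid)
  size_table(len, short_arm = short_arm, variant = variant)
}

#' Construct a chromosome size table
#'
#' @param lengths Named numeric vector of chromosome lengths (bp).
#' @param short_arm Optional named numeric vector of short-arm lengths (bp).
#' @param variant Label recorded on the table.
#' @return A `size_table` data frame.
#' @export
size_table <- function(lengths, short_arm = NULL, variant = "custom") {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  out <- data.frame(
    chrom = names(lengths),
    length_bp = as.numeric(lengths),
    short_arm_bp = if (is.null(short_arm)) NA_real_ else
      as.numeric(short_arm[names(lengths)]),
    stringsAsFactors = FALSE
  )
  attr(out, "variant") <- variant
  class(out) <- c("size_table", "data.frame")
  out
}

# named length vector from a size table, choosing the ranking column
size_column <- function(sizes, column = c("length_bp", "short_arm_bp")) {
  column <- match.arg(column)
  v <- sizes[[column]]
  if (anyNA(v)) stop("size table column '", column, "' has missing values")
  setNames(v, sizes$chrom)
}

# for each chromosome, its partners ordered by |delta length| ascending
# (or descending); ties broken by smaller chromosome index
partner_order_by_size <- function(lengths, decreasing = FALSE) {
  chroms <- names(lengths)
  out <- lapply(chroms, function(ci) {
    others <- setdiff(chroms, ci)
    d <- abs(lengths[others] - lengths[ci])
    if (decreasing) d <- -d
    others[order(d, chrom_index(others))]
  })
  names(out) <- chroms
  out
}
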