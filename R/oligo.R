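# Primer and Taqman-probe rule validation for the 3C2D assay. Validation is
# geometric and compositional only; no secondary-structure prediction.
# "Oriented towards the restriction site" is encoded as side + strand
# metadata: a left-side (L) primer points rightwards (+ strand), a
# right-side (R) primer points leftwards (- strand).

# SantaLucia (1998) unified nearest-neighbor parameters.
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
            GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Oligonucleotide melting temperature
#'
#' Nearest-neighbor thermodynamic estimate (unified parameter set, 1998)
#' with a Schildkraut-style monovalent-salt entropy correction; simpler
#' Wallace (2+4) and GC-fraction formulas are available as alternatives
#' since no single convention is universal.
#'
#' @param sequence Nucleotide string (A/C/G/T).
#' @param method `"nn"` (default), `"wallace"` or `"gc"`.
#' @param oligo_conc Oligo concentration, mol/L (default 5e-7).
#' @param na_conc Monovalent cation concentration, mol/L (default 0.05).
#' @return Melting temperature in degrees Celsius.
#' @export
oligo_tm <- function(sequence, method = c("nn", "wallace", "gc"),
                     oligo_conc = 5e-7, na_conc = 0.05) {
  method <- match.arg(method)
  s <- toupper(sequence)
  stopifnot(grepl("^[ACGT]+$", s))
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  gc <- sum(b %in% c("G", "C"))
  if (method == "wallace") return(2 * (n - gc) + 4 * gc)
  if (method == "gc") return(64.9 + 41 * (gc - 16.4) / n)
  steps <- paste0(b[-n], b[-1])
  dh <- sum(.nn_dh[steps])
  ds <- sum(.nn_ds[steps])
  for (end in c(b[1], b[n])) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_conc)
  1000 * dh / (ds + 1.987 * log(oligo_conc / 4)) - 273.15
}

#' Describe an oligo for validation
#'
#' @param role `"primer"` or `"probe"`.
#' @param sequence Nucleotide string.
#' @param side Which side of the CEN fragment the oligo sits on (`"L"` or
#'   `"R"`).
#' @param strand `"+"` or `"-"`.
#' @param distance_bp Distance to the nearest CEN-proximal restriction site.
#' @param tm Melting temperature in Celsius; computed with [oligo_tm()] when
#'   `NA`.
#' @return An `oligo_design` list.
#' @export
oligo_design <- function(role = c("primer", "probe"), sequence, side = "L",
                         strand = "+", distance_bp, tm = NA_real_) {
  role <- match.arg(role)
  stopifnot(grepl("^[ACGTacgt]+$", sequence), side %in% c("L", "R"),
            strand %in% c("+", "-"), distance_bp >= 0)
  if (is.na(tm)) tm <- oligo_tm(sequence)
  structure(list(role = role, sequence = toupper(sequence), side = side,
                 strand = strand, distance_bp = distance_bp, tm = tm),
            class = "oligo_design")
}

#' Validate a 3C2D primer against the design rules
#'
#' Rules: distance to the CEN-proximal restriction site within 100-150 bp,
#' length 18-24 bp, Tm 56-58 C, oriented towards the restriction site
#' (left-side primers on the + strand, right-side primers on the - strand).
#' All violated rules are returned, not just the first.
#'
#' @param oligo An [oligo_design()] with role `"primer"`.
#' @return List with `pass` (logical) and `violations` (character vector).
#' @export
validate_primer <- function(oligo) {
  stopifnot(inherits(oligo, "oligo_design"), oligo$role == "primer")
  v <- character(0)
  if (oligo$distance_bp < 100 || oligo$distance_bp > 150)
    v <- c(v, "distance: must be 100-150 bp from the CEN-proximal site")
  n <- nchar(oligo$sequence)
  if (n < 18 || n > 24) v <- c(v, "length: must be 18-24 bp")
  if (oligo$tm < 56 || oligo$tm > 58) v <- c(v, "tm: must be 56-58 C")
  toward <- (oligo$side == "L" && oligo$strand == "+") ||
    (oligo$side == "R" && oligo$strand == "-")
  if (!toward) v <- c(v, "orientation: must point towards the restriction site")
  list(pass = length(v) == 0, violations = v)
}

#' Validate a Taqman probe against the design rules
#'
#' Rules: length 20-36 bp, more Cs than Gs, no G at the 5' end (quenching),
#' no homopolymer run of 4 or more, at most two C/G among the last five 3'
#' bases, Tm 65-68 C, 10-60 bp from the restriction site, and on the
#' opposite strand from its primer when the primer strand is supplied.
#'
#' @param oligo An [oligo_design()] with role `"probe"`.
#' @param primer_strand Optional strand of the matching primer.
#' @return List with `pass` and `violations`.
#' @export
validate_probe <- function(oligo, primer_strand = NULL) {
  stopifnot(inherits(oligo, "oligo_design"), oligo$role == "probe")
  s <- oligo$sequence
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  v <- character(0)
  if (n < 20 || n > 36) v <- c(v, "length: must be 20-36 bp")
  if (sum(b == "C") <= sum(b == "G")) v <- c(v, "composition: must have more Cs than Gs")
  if (b[1] == "G") v <- c(v, "5' end: no G at the 5' end")
  if (grepl("AAAA|CCCC|GGGG|TTTT", s))
    v <- c(v, "homopolymer: no stretch of 4 identical nucleotides")
  if (sum(b[(n - 4):n] %in% c("C", "G")) > 2)
    v <- c(v, "3' end: at most 2 C/G in the last 5 nucleotides")
  if (oligo$tm < 65 || oligo$tm > 68) v <- c(v, "tm: must be 65-68 C")
  if (oligo$distance_bp < 10 || oligo$distance_bp > 60)
    v <- c(v, "distance: must be 10-60 bp from the restriction site")
  if (!is.null(primer_strand) && oligo$strand == primer_strand)
    v <- c(v, "strand: must be on the opposite strand from its primer")
  list(pass = length(v) == 0, violations = v)
}

#' Validate a table of oligos
#'
#' @param table Data frame with columns `role`, `sequence`, `side`,
#'   `strand`, `distance_bp` and optionally `tm` and `primer_strand`.
#' @return The table with `pass` and `violations` columns appended.
#' @export
validate_oligo_table <- function(table) {
  res <- lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    o <- oligo_design(row$role, row$sequence, row$side, row$strand,
                      row$distance_bp,
                      if ("tm" %in% names(table)) row$tm else NA_real_)
    if (o$role == "primer") validate_primer(o)
    else validate_probe(o, if ("primer_strand" %in% names(table))
      row$primer_strand else NULL)
  })
  table$pass <- vapply(res, `[[`, logical(1), "pass")
  table$violations <- vapply(res, function(r)
    paste(r$violations, collapse = "; "), character(1))
  table
}
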