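# In-silico restriction digestion and centromere-fragment statistics for the
# double-digest (EcoRI + MfeI) 3C assay design. Coordinates are 0-based
# half-open throughout (BED convention); a site's coordinate is the motif
# start, not the cut position (the <= 5 bp difference is immaterial at the
# multi-kb distances of interest).

.enzyme_motifs <- c(EcoRI = "GAATTC", MfeI = "CAATTG")

#' Find restriction sites in a sequence
#'
#' Scans the forward strand for EcoRI (GAATTC) and/or MfeI (CAATTG)
#' recognition motifs. Both motifs are palindromic, so one strand suffices.
#' N bases never match; characters outside A/C/G/T/N are replaced by N with
#' a warning.
#'
#' @param sequence Nucleotide string.
#' @param enzymes Character vector, subset of `c("EcoRI", "MfeI")`.
#' @return Data frame with columns `pos` (0-based motif start, sorted) and
#'   `enzyme`.
#' @export
find_sites <- function(sequence, enzymes = c("EcoRI", "MfeI")) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  enzymes <- match.arg(enzymes, several.ok = TRUE)
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    warning("sequence contains non-ACGTN characters; treated as N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  subject <- Biostrings::DNAString(sequence)
  hits <- lapply(enzymes, function(e) {
    m <- Biostrings::matchPattern(.enzyme_motifs[[e]], subject, fixed = TRUE)
    pos <- Biostrings::start(m) - 1L
    data.frame(pos = pos, enzyme = rep(e, length(pos)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the restriction fragment containing a centromere
#'
#' The CEN fragment is delimited by the greatest site position strictly
#' below the CEN start and the least site position at or beyond the CEN
#' end. Flanking distances are measured from the CEN midpoint (integer
#' floor of (start + end) / 2).
#'
#' @param map Data frame of sites as returned by [find_sites()].
#' @param cen_start,cen_end CEN interval, 0-based half-open.
#' @param chrom Optional chromosome id recorded on the result.
#' @return One-row data frame: `chrom`, `left_site`, `right_site`,
#'   `left_dist`, `right_dist`, `length`.
#' @export
cen_fragment <- function(map, cen_start, cen_end, chrom = NA_character_) {
  stopifnot(cen_start <= cen_end)
  pos <- sort(map$pos)
  if (any(pos >= cen_start & pos < cen_end))
    stop("CEN split by digestion: restriction site inside the CEN interval")
  left <- pos[pos < cen_start]
  right <- pos[pos >= cen_end]
  if (length(left) == 0 || length(right) == 0)
    stop("unbounded fragment: no flanking site on one side of the CEN")
  left <- max(left)
  right <- min(right)
  mid <- floor((cen_start + cen_end) / 2)
  data.frame(chrom = chrom, left_site = left, right_site = right,
             left_dist = mid - left, right_dist = right - mid,
             length = right - left, stringsAsFactors = FALSE)
}

#' Digest a genome and locate every CEN fragment
#'
#' @param genome Named character vector of chromosome sequences.
#' @param cen Data frame with columns `chrom`, `cen_start`, `cen_end`
#'   (0-based half-open), e.g. from [read_cen_bed()].
#' @param enzymes Enzymes for the digest.
#' @return Data frame of CEN fragments, one row per chromosome.
#' @export
cen_fragments <- function(genome, cen, enzymes = c("EcoRI", "MfeI")) {
  stopifnot(all(cen$chrom %in% names(genome)))
  rows <- lapply(seq_len(nrow(cen)), function(i) {
    ch <- cen$chrom[i]
    map <- find_sites(genome[[ch]], enzymes)
    cen_fragment(map, cen$cen_start[i], cen$cen_end[i], chrom = ch)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count CEN-flanking site distances beyond a threshold
#'
#' Each chromosome contributes two flanking sites (left and right of the
#' CEN); the count tallies distances strictly greater than `threshold`.
#'
#' @param fragments Data frame from [cen_fragments()].
#' @param threshold Distance threshold in bp (default 2000).
#' @return List with `count`, `total` (2 x number of chromosomes) and the
#'   individual distances.
#' @export
distance_stats <- function(fragments, threshold = 2000) {
  d <- c(fragments$left_dist, fragments$right_dist)
  list(count = sum(d > threshold), total = length(d), distances = d,
       threshold = threshold)
}

#' Histogram of CEN fragment sizes
#'
#' Bins are half-open `[k*w, (k+1)*w)`.
#'
#' @param fragments Data frame with a `length` column.
#' @param bin_width Bin width in bp (default 2000).
#' @return Data frame with `bin_start`, `bin_end`, `count`; counts sum to
#'   the number of fragments.
#' @export
fragment_size_histogram <- function(fragments, bin_width = 2000) {
  stopifnot(nrow(fragments) > 0, bin_width > 0)
  k <- floor(fragments$length / bin_width)
  tab <- table(k)
  data.frame(bin_start = as.integer(names(tab)) * bin_width,
             bin_end = (as.integer(names(tab)) + 1) * bin_width,
             count = as.integer(tab))
}

#' Read a genome FASTA file
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read centromere annotations from a BED file
#'
#' BED is 0-based half-open; coordinates are kept as-is.
#'
#' @param path BED3(+) file.
#' @return Data frame with `chrom`, `cen_start`, `cen_end`.
#' @export
read_cen_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    out <- data.frame(chrom = as.character(gr$seqnames),
                      cen_start = gr$start - 1L, cen_end = gr$end,
                      stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(chrom = tab[[1]], cen_start = as.integer(tab[[2]]),
                      cen_end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
  }
  out
}
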