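# Synthetic-data generator. Centromere coupling is simulated per cell as a
# perfect matching of the chromosome set drawn by iterative weighted
# pairing; couple counts are then converted into Taqman Cp records (480
# side-combinations, three dilutions, triplicates), a random-ligation
# control library with per-combination efficiency scatter, and a loading-
# control dilution series -- exactly the input dialects the processing
# module reads. A planted-site genome builder supports the digestion
# module's tests.

#' Describe a coupling model
#'
#' Pairing weights between chromosomes i and j: 1 under the null; under
#' the similarity mode `exp(-|L_i - L_j| / tau)`; under the avoidance mode
#' `exp(-max(0, |L_i - L_j| - d0) / tau)` with `d0` the `avoid_quantile`
#' quantile of the pairwise size gaps, so pairings between like-sized
#' chromosomes stay uniform while the most dissimilar pairings are
#' suppressed (a deficit of dissimilar couples without a specific surplus
#' of the most similar ones); under cluster mode, a multiplier for
#' same-cluster partners. Homologous pairings always have weight 0 (they
#' are forbidden couples in diploid mode).
#'
#' @param mode One of `"null"`, `"size_similarity"`, `"size_avoidance"`,
#'   `"telomere_cluster"`.
#' @param sizes A [size_table()] (default the bundled physical yeast table).
#' @param tau Size-similarity scale in bp (default 1e5); as `tau` grows the
#'   size modes approach the null.
#' @param clusters Named cluster assignment (cluster mode only).
#' @param cluster_weight Within-cluster weight multiplier (default 5).
#' @param avoid_quantile Quantile of pairwise size gaps above which
#'   avoidance-mode suppression starts (default 0.7).
#' @return A `coupling_model` with the 16x16 weight matrix.
#' @export
coupling_model <- function(mode = c("null", "size_similarity",
                                    "size_avoidance", "telomere_cluster"),
                           sizes = chrom_sizes(), tau = 1e5,
                           clusters = NULL, cluster_weight = 5,
                           avoid_quantile = 0.7) {
  mode <- match.arg(mode)
  stopifnot(tau > 0)
  lengths <- size_column(sizes)
  chroms <- names(lengths)
  n <- length(chroms)
  w <- matrix(1, n, n, dimnames = list(chroms, chroms))
  if (mode %in% c("size_similarity", "size_avoidance")) {
    d <- abs(outer(lengths, lengths, "-"))
    if (mode == "size_similarity") {
      w <- exp(-d / tau)
    } else {
      d0 <- unname(quantile(d[upper.tri(d)], avoid_quantile))
      w <- exp(-pmax(d - d0, 0) / tau)
    }
  }
  if (mode == "telomere_cluster") {
    stopifnot(!is.null(clusters), setequal(names(clusters), chroms))
    same <- outer(clusters[chroms], clusters[chroms], "==")
    w[same] <- cluster_weight
  }
  diag(w) <- 0
  structure(list(mode = mode, weights = w, tau = tau, clusters = clusters,
                 chrom = chroms), class = "coupling_model")
}

#' Simulation parameters
#'
#' @param n_cells Cells per library (default 5000).
#' @param ploidy `"haploid"` (8 couples per cell from 16 chromosomes) or
#'   `"diploid"` (16 couples from 32 chromosomes, homolog pairing
#'   forbidden).
#' @param c0 Cp offset in cycles: the underlying Cp of a couple is
#'   `c0 - log2(count + pseudo)` (default 38, placing typical Cps near the
#'   low 30s as in real 3C libraries).
#' @param sigma Per-reaction Gaussian Cp noise sd in cycles (default 0.3).
#' @param control_sd Per-side-combination efficiency offset sd in cycles
#'   (default 1.3, reproducing the observed scatter where roughly half of
#'   control combinations sit within one cycle of the library mean).
#' @param pseudo Pseudo-count added to couple counts before the log
#'   (default 0.5) so never-observed couples stay finite.
#' @param max_cycles Instrument cycle cap; reactions whose Cp would exceed
#'   it are emitted as failed (default 55).
#' @param dilutions Dilution factors per side-combination (default 2, 4, 8).
#' @param replicates Replicates per dilution (default 3).
#' @param control_c0 Mean control-library Cp (default 30).
#' @param loading_c0 Loading-control Cp at undiluted template (default 18).
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_cells = 5000, ploidy = c("haploid", "diploid"),
                       c0 = 38, sigma = 0.3, control_sd = 1.3, pseudo = 0.5,
                       max_cycles = 55, dilutions = c(2, 4, 8),
                       replicates = 3, control_c0 = 30, loading_c0 = 18) {
  ploidy <- match.arg(ploidy)
  stopifnot(n_cells >= 1, sigma >= 0, control_sd >= 0, pseudo >= 0)
  structure(list(n_cells = n_cells, ploidy = ploidy, c0 = c0, sigma = sigma,
                 control_sd = control_sd, pseudo = pseudo,
                 max_cycles = max_cycles, dilutions = dilutions,
                 replicates = replicates, control_c0 = control_c0,
                 loading_c0 = loading_c0), class = "sim_params")
}

#' Simulate couple counts over cells
#'
#' Per cell a perfect matching of the chromosome set is sampled: a random
#' unmatched chromosome is drawn and its partner chosen among the unmatched
#' with probability proportional to the model weight. In diploid mode each
#' chromosome contributes two copies and homolog pairing is forbidden; an
#' unordered chromosome pair is counted once per cell regardless of which
#' copies coupled (3C primers cannot distinguish copies). The sequential
#' sampler is not exactly the Gibbs distribution over weighted perfect
#' matchings; a Metropolis swap-chain sampler targeting it exactly is
#' available as a slower option.
#'
#' @param model A [coupling_model()].
#' @param params A [sim_params()].
#' @param sampler `"sequential"` (default) or `"mcmc"`.
#' @param mcmc_sweeps Swap sweeps per cell for the MCMC sampler.
#' @return Symmetric integer count matrix (diagonal 0).
#' @export
simulate_cells <- function(model, params, sampler = c("sequential", "mcmc"),
                           mcmc_sweeps = 50) {
  sampler <- match.arg(sampler)
  w <- model$weights
  n <- nrow(w)
  if (any(rowSums(w) == 0))
    stop("all pairing weights are zero for some chromosome")
  copies <- if (params$ploidy == "diploid") 2L else 1L
  chrom_of <- rep(seq_len(n), each = copies)
  if (sampler == "sequential") {
    counts <- cpp_simulate_cells(w, as.integer(chrom_of - 1L), n,
                                 as.integer(params$n_cells))
  } else {
    counts <- mcmc_simulate_cells(w, chrom_of, n, params$n_cells,
                                  mcmc_sweeps)
  }
  dimnames(counts) <- dimnames(w)
  counts
}

# Metropolis swap chain over perfect matchings with stationary
# distribution proportional to the product of couple weights.
mcmc_simulate_cells <- function(w, chrom_of, n, n_cells, sweeps) {
  ne <- length(chrom_of)
  counts <- matrix(0L, n, n)
  for (cell in seq_len(n_cells)) {
    repeat { # random valid initial matching (uniform proposal)
      perm <- sample(ne)
      a <- perm[seq(1, ne, by = 2)]
      b <- perm[seq(2, ne, by = 2)]
      if (all(w[cbind(chrom_of[a], chrom_of[b])] > 0)) break
    }
    nc <- ne / 2
    for (step in seq_len(sweeps * nc)) {
      ij <- sample(nc, 2)
      i <- ij[1]; j <- ij[2]
      cur <- w[chrom_of[a[i]], chrom_of[b[i]]] *
        w[chrom_of[a[j]], chrom_of[b[j]]]
      if (runif(1) < 0.5) { # swap partners one of two ways
        new <- w[chrom_of[a[i]], chrom_of[b[j]]] *
          w[chrom_of[a[j]], chrom_of[b[i]]]
        if (runif(1) < new / cur) {
          tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp
        }
      } else {
        new <- w[chrom_of[a[i]], chrom_of[a[j]]] *
          w[chrom_of[b[i]], chrom_of[b[j]]]
        if (runif(1) < new / cur) {
          tmp <- b[i]; b[i] <- a[j]; a[j] <- tmp
        }
      }
    }
    pairs <- unique(t(apply(cbind(chrom_of[a], chrom_of[b]), 1, sort)))
    counts[pairs] <- counts[pairs] + 1L
    counts[pairs[, c(2, 1), drop = FALSE]] <-
      counts[pairs[, c(2, 1), drop = FALSE]] + 1L
  }
  counts
}

#' Convert couple counts into a synthetic Cp dataset
#'
#' The underlying Cp of a pair is `c0 - log2(count + pseudo)`. Each of the
#' four side-combinations of a pair carries a fixed efficiency offset drawn
#' from `N(0, control_sd)` shared between sample and control library (this
#' is what per-side-combination normalization cancels); each reaction adds
#' `log2(dilution)` and `N(0, sigma)` noise. Reactions whose Cp would
#' exceed the cycle cap are emitted as failed. The control library reports
#' the per-side-combination mean Cp (`control_c0` + offset) and the loading
#' control is a five-point dilution series consistent with efficiency 2.
#'
#' @param counts Count matrix from [simulate_cells()].
#' @param params A [sim_params()].
#' @return List: `cp` (record table), `control`, `loading`.
#' @export
counts_to_cp <- function(counts, params) {
  chroms <- rownames(counts)
  idx <- which(upper.tri(counts), arr.ind = TRUE)
  pairs <- data.frame(cen_i = chroms[idx[, 1]], cen_j = chroms[idx[, 2]],
                      count = counts[idx], stringsAsFactors = FALSE)
  pairs <- pairs[order(chrom_index(pairs$cen_i), chrom_index(pairs$cen_j)), ]
  under <- params$c0 - log2(pairs$count + params$pseudo)
  sides <- expand.grid(side_i = c("L", "R"), side_j = c("L", "R"),
                       stringsAsFactors = FALSE)
  sc <- merge(cbind(pairs, under = under), sides)
  sc <- sc[order(chrom_index(sc$cen_i), chrom_index(sc$cen_j),
                 sc$side_i, sc$side_j), ]
  sc$offset <- rnorm(nrow(sc), 0, params$control_sd)
  reac <- merge(sc,
                expand.grid(dilution = params$dilutions,
                            replicate = seq_len(params$replicates)))
  reac <- reac[order(chrom_index(reac$cen_i), chrom_index(reac$cen_j),
                     reac$side_i, reac$side_j, reac$dilution,
                     reac$replicate), ]
  cp <- reac$under + reac$offset + log2(reac$dilution) +
    rnorm(nrow(reac), 0, params$sigma)
  cp[cp > params$max_cycles] <- NA
  cp_tab <- data.frame(cen_i = reac$cen_i, side_i = reac$side_i,
                       cen_j = reac$cen_j, side_j = reac$side_j,
                       dilution = reac$dilution, replicate = reac$replicate,
                       cp = cp, stringsAsFactors = FALSE)
  control <- data.frame(cen_i = sc$cen_i, side_i = sc$side_i,
                        cen_j = sc$cen_j, side_j = sc$side_j,
                        cp = params$control_c0 + sc$offset,
                        stringsAsFactors = FALSE)
  dil <- c(1 / 12.5, 1 / 25, 1 / 50, 1 / 100, 1 / 200)
  loading <- data.frame(dilution = dil, cp = params$loading_c0 - log2(dil))
  rownames(cp_tab) <- rownames(control) <- NULL
  list(cp = cp_tab, control = control, loading = loading)
}

#' Simulate a normalized interaction matrix end-to-end
#'
#' Convenience wrapper: simulate couple counts, emit Cp records, aggregate
#' and normalize. The planted count matrix is attached as attribute
#' `planted`.
#'
#' @inheritParams simulate_cells
#' @return Normalized interaction matrix.
#' @export
simulate_matrix <- function(model, params, sampler = "sequential") {
  counts <- simulate_cells(model, params, sampler)
  dat <- counts_to_cp(counts, params)
  raw <- aggregate_combinations(dat$cp)
  m <- normalize_matrix(raw, dat$control)
  attr(m, "planted") <- counts
  m
}

#' Simulate cytological spread counts
#'
#' @param p_couple Coupling probability per nucleus.
#' @param n_experiments Replicate experiments (default 3).
#' @param nuclei Nuclei scored per experiment (default 50).
#' @return Data frame with `coupled`, `scored` per experiment.
#' @export
simulate_spreads <- function(p_couple, n_experiments = 3, nuclei = 50) {
  stopifnot(p_couple >= 0, p_couple <= 1)
  data.frame(coupled = rbinom(n_experiments, nuclei, p_couple),
             scored = rep(nuclei, n_experiments))
}

#' Build a synthetic genome with planted restriction sites
#'
#' Generates random background sequence, disrupts every spurious
#' EcoRI/MfeI motif occurrence, then plants motifs at the requested
#' positions, so that digesting the output recovers exactly the planted
#' map.
#'
#' @param lengths Named chromosome lengths (bp).
#' @param cen Data frame `chrom`, `cen_start`, `cen_end` (0-based
#'   half-open).
#' @param sites Data frame `chrom`, `pos` (0-based motif start), `enzyme`.
#'   Sites must not fall inside CEN intervals and must be at least 6 bp
#'   apart.
#' @return List: `genome` (named character vector), `cen`, `sites`.
#' @export
synthetic_genome <- function(lengths, cen, sites) {
  stopifnot(!is.null(names(lengths)))
  for (r in seq_len(nrow(sites))) {
    ch <- sites$chrom[r]
    p <- sites$pos[r]
    if (p < 0 || p + 6 > lengths[[ch]])
      stop("infeasible placement: site outside chromosome ", ch)
    ci <- cen[cen$chrom == ch, ]
    if (nrow(ci) && p >= ci$cen_start && p < ci$cen_end)
      stop("infeasible placement: site inside the CEN interval of ", ch)
  }
  genome <- vapply(names(lengths), function(ch) {
    len <- lengths[[ch]]
    b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    pl <- sites[sites$chrom == ch, , drop = FALSE]
    pl <- pl[order(pl$pos), , drop = FALSE]
    if (nrow(pl) > 1 && any(diff(pl$pos) < 6))
      stop("infeasible placement: planted sites closer than 6 bp on ", ch)
    for (r in seq_len(nrow(pl)))
      b[(pl$pos[r] + 1):(pl$pos[r] + 6)] <-
        strsplit(.enzyme_motifs[[pl$enzyme[r]]], "")[[1]]
    protected <- unlist(lapply(pl$pos, function(p) (p + 1):(p + 6)))
    for (iter in 1:100) {
      s <- paste(b, collapse = "")
      occ <- sort(unique(c(
        as.integer(gregexpr("GAATTC", s)[[1]]),
        as.integer(gregexpr("CAATTG", s)[[1]])))) # 1-based starts
      occ <- occ[occ > 0]
      spurious <- setdiff(occ - 1L, pl$pos)
      if (length(spurious) == 0) return(s)
      for (p in spurious) {
        cand <- setdiff((p + 1):(p + 6), protected)
        if (length(cand) == 0)
          stop("infeasible placement: spurious motif overlaps planted sites")
        at <- cand[3 %% length(cand) + 1]
        b[at] <- sample(setdiff(c("A", "C", "G", "T"), b[at]), 1)
      }
    }
    stop("failed to scrub spurious motifs on ", ch)
  }, character(1))
  list(genome = genome, cen = cen, sites = sites)
}

#' Write a complete synthetic fixture set
#'
#' Emits the TSV/FASTA/BED files the rest of the pipeline reads: Cp
#' records, control library, loading control, sizes, spread counts, and
#' the planted couple counts for reference.
#'
#' @param dir Output directory (created if needed).
#' @param model A [coupling_model()].
#' @param params A [sim_params()].
#' @param seed Integer seed (all generator randomness flows from it).
#' @param p_couple Spread coupling probabilities (named per strain) for the
#'   cytology fixture.
#' @return Invisibly, a named list of file paths.
#' @export
simulate_dataset <- function(dir, model = coupling_model("size_similarity"),
                             params = sim_params(), seed = 1,
                             p_couple = c(similar = 0.4, dissimilar = 0.127)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  counts <- simulate_cells(model, params)
  dat <- counts_to_cp(counts, params)
  sizes <- chrom_sizes()
  spreads <- do.call(rbind, lapply(names(p_couple), function(s) {
    sp <- simulate_spreads(p_couple[[s]])
    cbind(strain = s, replicate = seq_len(nrow(sp)), sp)
  }))
  paths <- list(
    cp = file.path(dir, "cp.tsv"), control = file.path(dir, "control.tsv"),
    loading = file.path(dir, "loading.tsv"),
    sizes = file.path(dir, "sizes.tsv"),
    spreads = file.path(dir, "spreads.tsv"),
    counts = file.path(dir, "planted_counts.tsv"))
  wt <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(dat$cp, paths$cp)
  wt(dat$control, paths$control)
  wt(dat$loading, paths$loading)
  wt(as.data.frame(sizes), paths$sizes)
  wt(spreads, paths$spreads)
  write_matrix_tsv(counts, paths$counts)
  invisible(paths)
}
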