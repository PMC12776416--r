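# Screen simulator: library sampling, a position-weight selection model,
# bead-capture selection, and paired-read FASTQ emission with a ground-truth
# table, so every downstream stage is testable without external data.

#' Ground-truth position-weight specificity model
#'
#' The simulator's kinase: a log-preference weight per (residue, position),
#' including the amber row `*` for non-canonical residues, plus a baseline
#' phosphorylation rate and an exposure time. Phosphorylation probability of
#' a peptide follows first-order reaction-extent kinetics, see
#' [phosphorylation_probability()].
#'
#' @param weights 21 x L numeric matrix (rows [AA_ORDER]: 20 canonical
#'   residues then `*`) of log-preferences; or `NULL` for an all-zero model.
#' @param peptide_length required when `weights` is `NULL`.
#' @param baseline_rate positive rate constant (arbitrary time^-1).
#' @param exposure_time positive reaction time.
#' @return a `specificity_model`.
#' @export
specificity_model <- function(weights = NULL, peptide_length = NULL,
                              baseline_rate = 1, exposure_time = 1) {
  if (is.null(weights)) {
    stopifnot(!is.null(peptide_length))
    weights <- matrix(0, nrow = length(AA_ORDER), ncol = peptide_length,
                      dimnames = list(AA_ORDER,
                                      as.character(seq_len(peptide_length))))
  }
  stopifnot(is.matrix(weights), nrow(weights) == length(AA_ORDER),
            all(is.finite(weights)), baseline_rate > 0, exposure_time >= 0)
  rownames(weights) <- AA_ORDER
  structure(list(weights = weights, baseline_rate = baseline_rate,
                 exposure_time = exposure_time),
            class = "specificity_model")
}

#' Random specificity model for simulation studies
#'
#' Gaussian log-preference weights for canonical residues at non-fixed
#' positions; the fixed central column and the amber row are zero unless an
#' amber bonus is requested (e.g. a non-canonical residue preferred at one
#' position).
#'
#' @param design a degenerate [library_design()].
#' @param sd standard deviation of the canonical weights.
#' @param amber_bonus named numeric vector: position index -> log-weight for
#'   the amber row at that position (e.g. `c("7" = log(3))`).
#' @param baseline_rate,exposure_time see [specificity_model()].
#' @param seed RNG seed.
#' @return a `specificity_model`.
#' @export
random_specificity_model <- function(design, sd = 0.4, amber_bonus = NULL,
                                     baseline_rate = 1, exposure_time = 1,
                                     seed = NULL) {
  L <- design$peptide_length
  w <- with_local_seed(seed, {
    m <- matrix(rnorm(length(AA_ORDER) * L, sd = sd),
                nrow = length(AA_ORDER), ncol = L,
                dimnames = list(AA_ORDER, as.character(seq_len(L))))
    m["*", ] <- 0
    if (!is.null(design$central_fixed)) m[, design$central_fixed$position] <- 0
    if (!is.null(amber_bonus))
      m["*", as.integer(names(amber_bonus))] <- amber_bonus
    m
  })
  specificity_model(w, baseline_rate = baseline_rate,
                    exposure_time = exposure_time)
}

#' Simulation configuration
#'
#' Bundles the design and the knobs of one simulated screen. Identical
#' configuration (including `seed`) gives byte-identical outputs.
#'
#' Capture defaults (0.9 efficiency, 0.01 background) are plumbing values for
#' testing, not biological estimates.
#'
#' @param design a [library_design()].
#' @param n_cells cells in the displayed population.
#' @param reads_per_sample reads sequenced per sample.
#' @param capture_efficiency probability a phosphorylated cell is captured.
#' @param background_capture probability an unphosphorylated cell is captured.
#' @param sequencing_error_rate per-base substitution probability.
#' @param abundance_dispersion sdlog of the multiplicative log-normal
#'   abundance skew (0 = even representation).
#' @param read_length paired-read length (default 75, as in 75x75 bp runs).
#' @param seed integer RNG seed.
#' @return a `sim_config`.
#' @export
simulation_config <- function(design, n_cells = 1e5, reads_per_sample = 1e5,
                              capture_efficiency = 0.9,
                              background_capture = 0.01,
                              sequencing_error_rate = 0,
                              abundance_dispersion = 0,
                              read_length = 75L, seed = 1L) {
  stopifnot(inherits(design, "library_design"),
            n_cells >= 1, reads_per_sample >= 1,
            capture_efficiency >= 0, capture_efficiency <= 1,
            background_capture >= 0, background_capture <= 1,
            sequencing_error_rate >= 0, sequencing_error_rate <= 1,
            abundance_dispersion >= 0, read_length >= 20L)
  structure(list(design = design, n_cells = as.integer(n_cells),
                 reads_per_sample = as.integer(reads_per_sample),
                 capture_efficiency = capture_efficiency,
                 background_capture = background_capture,
                 sequencing_error_rate = sequencing_error_rate,
                 abundance_dispersion = abundance_dispersion,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw n random NNS-consistent peptides for a degenerate design (codons drawn
# uniformly from the 32 NNS codons; amber translates to `*`).
sample_degenerate_peptides <- function(design, n) {
  gc <- codon_lookup()
  nns_aa <- ifelse(NNS_CODONS == "TAG", "*", gc[NNS_CODONS])
  L <- design$peptide_length
  cf <- design$central_fixed
  cols <- lapply(seq_len(L), function(j) {
    if (j == cf$position) rep(cf$residue, n)
    else nns_aa[sample.int(32L, n, replace = TRUE)]
  })
  do.call(paste0, cols)
}

#' Sample a displayed cell population from a design
#'
#' Defined designs draw cells across all members; degenerate designs draw
#' NNS-consistent random peptides; scanning designs draw from the reference
#' plus all single mutants (including the amber variant at each position).
#' A multiplicative log-normal abundance skew of the configured dispersion is
#' applied. Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return named integer vector: peptide -> cell count (the population).
#' @export
sample_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  with_local_seed(config$seed, {
    if (design$kind == "degenerate") {
      pep <- sample_degenerate_peptides(design, config$n_cells)
      tab <- table(pep)
      pop0 <- setNames(as.integer(tab), names(tab))
      if (config$abundance_dispersion > 0) {
        w <- exp(rnorm(length(pop0), sd = config$abundance_dispersion))
        pop0 <- setNames(as.integer(
          rmultinom(1L, config$n_cells, prob = pop0 * w)[, 1L]), names(pop0))
        pop0 <- pop0[pop0 > 0L]
      }
      return(pop0)
    }
    members <- if (design$kind == "defined") {
      design$members
    } else {
      ref <- strsplit(design$reference_peptide, "")[[1]]
      alts <- unlist(lapply(seq_along(ref), function(j) {
        subs <- setdiff(AA_ORDER, ref[j])
        vapply(subs, function(r) {
          x <- ref; x[j] <- r; paste(x, collapse = "")
        }, character(1))
      }))
      c(design$reference_peptide, alts)
    }
    w <- rep(1, length(members))
    if (config$abundance_dispersion > 0)
      w <- exp(rnorm(length(members), sd = config$abundance_dispersion))
    counts <- as.integer(rmultinom(1L, config$n_cells, prob = w)[, 1L])
    pop <- setNames(counts, members)
    pop[pop > 0L]
  })
}

#' Phosphorylation probability of one peptide under the model
#'
#' First-order reaction-extent kinetics:
#' `p = 1 - exp(-baseline_rate * exposure_time * exp(sum of position weights))`,
#' monotone increasing in every weight.
#'
#' @param peptide peptide string (amber as `*`).
#' @param model a [specificity_model()].
#' @param exposure_time optional override of the model's exposure time.
#' @return probability in [0, 1].
#' @export
phosphorylation_probability <- function(peptide, model,
                                        exposure_time = model$exposure_time) {
  p <- phospho_prob_bulk(peptide, model, exposure_time)
  if (length(peptide) == 1L) unname(p) else p
}

phospho_prob_bulk <- function(peptides, model, exposure_time) {
  L <- ncol(model$weights)
  if (any(nchar(peptides) != L))
    stop("peptide length does not match the model (", L, " positions)")
  n <- length(peptides)
  if (n == 0L) return(numeric(0))
  chars <- matrix(unlist(strsplit(peptides, "")), ncol = L, byrow = TRUE)
  ridx <- match(chars, AA_ORDER)
  if (anyNA(ridx)) stop("peptides contain residues outside the model alphabet")
  wsum <- rowSums(matrix(model$weights[cbind(as.vector(ridx),
                                             rep(seq_len(L), each = n))],
                         nrow = n))
  1 - exp(-model$baseline_rate * exposure_time * exp(wsum))
}

#' Calibrate exposure time for a target phosphorylation extent
#'
#' Finds the exposure time at which the population-weighted mean
#' phosphorylation probability equals the target (the protocol tunes reaction
#' conditions so the library is 25-50% phosphorylated; 0.375 is the midpoint
#' of that window). Monotone root search.
#'
#' @param model a [specificity_model()].
#' @param population named vector peptide -> cell count.
#' @param target_fraction target mean extent, in (0, 1); default 0.375.
#' @param tol absolute tolerance on the achieved mean (default 0.005).
#' @return the exposure time.
#' @export
calibrate_exposure <- function(model, population, target_fraction = 0.375,
                               tol = 0.005) {
  stopifnot(target_fraction > 0, target_fraction < 1, length(population) > 0)
  peps <- names(population)
  w <- as.numeric(population) / sum(population)
  mean_extent <- function(t) sum(w * phospho_prob_bulk(peps, model, t))
  hi <- 1 / model$baseline_rate
  it <- 0L
  while (mean_extent(hi) < target_fraction) {
    hi <- hi * 2; it <- it + 1L
    if (it > 200L) stop("target extent unattainable for this model")
  }
  r <- uniroot(function(t) mean_extent(t) - target_fraction,
               lower = 0, upper = hi, tol = hi * 1e-10)
  if (abs(mean_extent(r$root) - target_fraction) > tol)
    stop("root search did not reach the target extent")
  r$root
}

#' Simulate one round of phosphorylation and bead selection
#'
#' Each cell is phosphorylated with the peptide's model probability; captured
#' with probability `capture_efficiency` if phosphorylated, else
#' `background_capture`. The sorted population is the captured cells; the
#' unsorted population is the input. Deterministic under the config seed.
#'
#' @param population named vector peptide -> cell count.
#' @param model a [specificity_model()].
#' @param config a [simulation_config()].
#' @return list with `sorted` and `unsorted` populations and the per-peptide
#'   `p_phos` used.
#' @export
simulate_selection <- function(population, model, config) {
  stopifnot(length(population) > 0)
  p <- phospho_prob_bulk(names(population), model, model$exposure_time)
  with_local_seed(config$seed + 1L, {
    n <- as.integer(population)
    nphos <- rbinom(length(n), n, p)
    captured <- rbinom(length(n), nphos, config$capture_efficiency) +
      rbinom(length(n), n - nphos, config$background_capture)
    sorted <- setNames(captured, names(population))
    sorted <- sorted[sorted > 0L]
    list(sorted = sorted, unsorted = population,
         p_phos = setNames(p, names(population)))
  })
}

# Reverse-translate peptides with the default codon table (amber -> tag).
peptides_to_coding <- function(peptides, design) {
  L <- design$peptide_length
  n <- length(peptides)
  chars <- matrix(unlist(strsplit(peptides, "")), ncol = L, byrow = TRUE)
  codons <- matrix(DEFAULT_CODONS[chars], ncol = L)
  if (design$kind == "degenerate" && !is.null(design$central_fixed))
    codons[, design$central_fixed$position] <- tolower(design$central_fixed$codon)
  if (design$kind == "scanning") {
    # keep reference codons at unmutated positions
    ref <- strsplit(design$reference_peptide, "")[[1]]
    for (j in seq_len(L)) {
      same <- chars[, j] == ref[j]
      codons[same, j] <- design$reference_codons[j]
    }
  }
  do.call(paste0, as.data.frame(codons, stringsAsFactors = FALSE))
}

random_bases <- function(n, k) {
  m <- matrix(c("A", "C", "G", "T")[sample.int(4L, n * k, replace = TRUE)],
              ncol = k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  L <- nchar(seqs[1L])
  n <- length(seqs)
  nerr <- rbinom(n, L, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L, nerr[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Emit paired FASTQ reads for a population, with a truth table
#'
#' Reads are drawn multinomially from the population. Each read's amplicon is
#' assembled with fresh random 6-mers at the N positions, the constant
#' flanks, and the peptide coding sequence from the design's codon policy;
#' the pair covers the amplicon from both ends at the configured read length,
#' with substitution errors injected at the configured rate. Writes R1/R2
#' FASTQ (gzipped by default) plus a truth TSV of the sampled read counts per
#' peptide.
#'
#' @param population named vector peptide -> cell count.
#' @param config a [simulation_config()].
#' @param out_prefix path prefix; writes `<prefix>_R1.fastq[.gz]`,
#'   `<prefix>_R2.fastq[.gz]`, `<prefix>_truth.tsv`.
#' @param gzip compress the FASTQ output (default TRUE).
#' @param seed_offset offset added to the config seed so sorted/unsorted
#'   samples of one screen get distinct read noise.
#' @return list with the file paths and the truth counts.
#' @export
emit_fastq <- function(population, config, out_prefix, gzip = TRUE,
                       seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"), config$reads_per_sample >= 1)
  design <- config$design
  with_local_seed(config$seed + 10L + seed_offset, {
    draw <- rmultinom(1L, config$reads_per_sample,
                      prob = as.numeric(population))[, 1L]
    truth <- setNames(as.integer(draw), names(population))
    truth <- truth[truth > 0L]
    peps <- rep(names(truth), truth)
    # shuffle so the file is not ordered by peptide
    peps <- peps[sample.int(length(peps))]
    coding <- peptides_to_coding(peps, design)
    n <- length(peps)
    amplicon <- toupper(paste0(random_bases(n, 6L), AMPLICON_PRE, FLANK5,
                               coding, FLANK3, AMPLICON_POST,
                               random_bases(n, 6L)))
    alen <- nchar(amplicon[1L])
    rl <- min(config$read_length, alen)
    r1 <- substr(amplicon, 1L, rl)
    r2 <- reverse_complement(substr(amplicon, alen - rl + 1L, alen))
    r1 <- inject_errors(r1, config$sequencing_error_rate)
    r2 <- inject_errors(r2, config$sequencing_error_rate)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    f1 <- paste0(out_prefix, "_R1", ext)
    f2 <- paste0(out_prefix, "_R2", ext)
    ids <- sprintf("read%06d", seq_len(n))
    write_fastq(r1, ids, f1)
    write_fastq(r2, ids, f2)
    truth_path <- paste0(out_prefix, "_truth.tsv")
    utils::write.table(
      data.frame(peptide = names(truth), reads = as.integer(truth)),
      truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(r1 = f1, r2 = f2, truth = truth_path, truth_counts = truth)
  })
}

write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              compress = endsWith(path, ".gz"),
                              qualities = q)
  invisible(path)
}

#' Expected enrichment of each peptide under the selection model
#'
#' The capture probability of a cell displaying peptide i is
#' `p_i * c + (1 - p_i) * b`; the expected enrichment score is that capture
#' probability divided by the population-mean capture probability.
#'
#' @param population named vector peptide -> cell count.
#' @param model a [specificity_model()].
#' @param config a [simulation_config()].
#' @return named numeric vector of expected enrichment ratios.
#' @export
expected_enrichment <- function(population, model, config) {
  p <- phospho_prob_bulk(names(population), model, model$exposure_time)
  cap <- p * config$capture_efficiency +
    (1 - p) * config$background_capture
  wmean <- sum(cap * population) / sum(population)
  setNames(cap / wmean, names(population))
}
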