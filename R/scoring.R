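# Scoring: the three enrichment-score schemes computed from matched
# sorted/unsorted count structures.
#
# All schemes share the same core: counts -> frequencies within each sample,
# then the sorted frequency divided by the matched unsorted frequency. The
# schemes differ in the counting unit (whole peptides, residues per position,
# or point mutants with the wild-type repeat correction).

#' Per-peptide frequencies of a counts table
#'
#' Counts divided by the table total; values sum to 1.
#'
#' @param table a `counts_table`.
#' @return named numeric vector of frequencies.
#' @export
frequencies <- function(table) {
  stopifnot(inherits(table, "counts_table"))
  if (table$total <= 0L) stop("counts table is empty")
  table$entries / table$total
}

#' Per-peptide enrichment scores (discrete libraries)
#'
#' For each peptide, its frequency in the sorted (phosphorylated and
#' bead-enriched) sample divided by its frequency in the matched unsorted
#' sample. These ratios correlate with relative phosphorylation rates and can
#' be compared head-to-head across the library.
#'
#' Peptides absent from the unsorted sample have no defined ratio: with
#' `pseudocount = 0` (default) their enrichment is `NA` and they are flagged
#' `undefined`; a positive `pseudocount` is added to both counts of every
#' peptide instead.
#'
#' @param sorted_table,unsorted_table matched `counts_table`s.
#' @param pseudocount additive pseudocount (default 0; 0.5 is the
#'   conventional choice when enabled).
#' @return an `enrichment_table` data.frame: peptide, count_sorted,
#'   count_unsorted, freq_sorted, freq_unsorted, enrichment,
#'   log2_enrichment, log10_enrichment, undefined.
#' @export
enrichment_scores <- function(sorted_table, unsorted_table, pseudocount = 0) {
  stopifnot(inherits(sorted_table, "counts_table"),
            inherits(unsorted_table, "counts_table"))
  if (sorted_table$total <= 0L || unsorted_table$total <= 0L)
    stop("both samples must have positive totals")
  peps_s <- names(sorted_table$entries)
  peps_u <- names(unsorted_table$entries)
  if (length(peps_s) && length(peps_u) &&
      nchar(peps_s[1L]) != nchar(peps_u[1L]))
    stop("sorted and unsorted tables hold peptides of different lengths")
  peptide <- sort(union(peps_s, peps_u))
  cs <- unname(ifelse(peptide %in% peps_s, sorted_table$entries[peptide], 0L))
  cu <- unname(ifelse(peptide %in% peps_u, unsorted_table$entries[peptide], 0L))
  cs[is.na(cs)] <- 0L; cu[is.na(cu)] <- 0L
  fs <- (cs + pseudocount) / (sorted_table$total + pseudocount * length(peptide))
  fu <- (cu + pseudocount) / (unsorted_table$total + pseudocount * length(peptide))
  enr <- ifelse(fu > 0, fs / fu, NA_real_)
  out <- data.frame(peptide = peptide,
                    count_sorted = cs, count_unsorted = cu,
                    freq_sorted = fs, freq_unsorted = fu,
                    enrichment = enr,
                    log2_enrichment = log2(enr),
                    log10_enrichment = log10(enr),
                    undefined = is.na(enr),
                    stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "samples") <- c(sorted = sorted_table$sample_id,
                            unsorted = unsorted_table$sample_id)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Position-specific residue enrichment (degenerate libraries)
#'
#' For degenerate libraries individual peptides are too rare to score, but
#' residue preferences at each position are well determined. Column totals
#' are summed per position, each cell is converted to a within-column
#' frequency, and the sorted frequency is divided by the matched unsorted
#' frequency; log2 and log10 transforms are provided for visualization
#' (negative = disfavored, ~0 = neutral, positive = favored).
#'
#' The fixed central column is masked (`NA`) because the design does not
#' encode meaningful variation there.
#'
#' @param sorted_matrix,unsorted_matrix matched `residue_matrix` objects with
#'   the same shape and filter mode.
#' @param mask_center mask the central fixed column recorded on the matrices
#'   (default TRUE when a center is set).
#' @param pseudocount additive per-cell pseudocount (default 0: cells with a
#'   zero unsorted count score `NA`).
#' @return a `position_enrichment`: list with matrices `ratio`, `log2`,
#'   `log10`, plus `mask`, `filter_mode`, and per-position `totals`.
#' @export
position_enrichment <- function(sorted_matrix, unsorted_matrix,
                                mask_center = TRUE, pseudocount = 0) {
  stopifnot(inherits(sorted_matrix, "residue_matrix"),
            inherits(unsorted_matrix, "residue_matrix"))
  ms <- sorted_matrix$counts; mu <- unsorted_matrix$counts
  if (!identical(dim(ms), dim(mu)) || !identical(dimnames(ms), dimnames(mu)))
    stop("sorted and unsorted matrices have different shapes")
  if (!identical(sorted_matrix$filter_mode, unsorted_matrix$filter_mode))
    stop("sorted and unsorted matrices use different filter modes")
  tot_s <- colSums(ms) + pseudocount * nrow(ms)
  tot_u <- colSums(mu) + pseudocount * nrow(mu)
  if (any(tot_s == 0) || any(tot_u == 0))
    stop("a position has zero total counts; cannot form frequencies")
  fs <- sweep(ms + pseudocount, 2L, tot_s, "/")
  fu <- sweep(mu + pseudocount, 2L, tot_u, "/")
  ratio <- ifelse(fu > 0, fs / fu, NA_real_)
  dimnames(ratio) <- dimnames(ms)
  mask <- integer(0)
  center <- sorted_matrix$center
  if (mask_center && !is.null(center)) {
    mask <- center
    ratio[, mask] <- NA_real_
  }
  structure(list(ratio = ratio, log2 = log2(ratio), log10 = log10(ratio),
                 mask = mask, filter_mode = sorted_matrix$filter_mode,
                 totals = list(sorted = colSums(ms), unsorted = colSums(mu))),
            class = "position_enrichment")
}

#' @export
print.position_enrichment <- function(x, ...) {
  cat("<position_enrichment>", nrow(x$ratio), "residues x", ncol(x$ratio),
      "positions | filter:", x$filter_mode,
      if (length(x$mask)) paste("| masked column", x$mask), "\n")
  invisible(x)
}

#' Wild-type-normalized scanning-mutagenesis enrichment
#'
#' Sample totals use the wild-type repeat correction (raw matrix sum minus
#' `wt_count * (L - 1)`), cells become frequencies, the sorted/unsorted ratio
#' is log-transformed, and the reference sequence's log score is subtracted,
#' so the reference scores exactly 0 in every column. Negative values mark
#' mutations that reduce phosphorylation; mutations of the central Tyr to a
#' stop should be strongly negative and serve as an internal negative
#' control.
#'
#' @param sorted,unsorted matched `scanning_counts` with the same reference.
#' @param pseudocount additive per-cell pseudocount (default 0: cells absent
#'   from either sample score `NA`).
#' @return a `scanning_enrichment`: list with `ratio`, `log2`, `log10`
#'   (normalized so the reference is 0 on both log scales), `reference`,
#'   `wt_enrichment`.
#' @export
scanning_enrichment <- function(sorted, unsorted, pseudocount = 0) {
  stopifnot(inherits(sorted, "scanning_counts"),
            inherits(unsorted, "scanning_counts"))
  if (!identical(sorted$reference, unsorted$reference))
    stop("sorted and unsorted matrices have different references")
  tot_s <- scanning_corrected_total(sorted)
  tot_u <- scanning_corrected_total(unsorted)
  if (tot_s <= 0 || tot_u <= 0) stop("zero corrected total")
  fs <- (sorted$counts + pseudocount) / tot_s
  fu <- (unsorted$counts + pseudocount) / tot_u
  ratio <- ifelse(fu > 0 & fs > 0, fs / fu, NA_real_)
  dimnames(ratio) <- dimnames(sorted$counts)
  if (sorted$wt_count <= 0 || unsorted$wt_count <= 0)
    stop("reference peptide absent from a sample; cannot normalize")
  wt_ratio <- (sorted$wt_count / tot_s) / (unsorted$wt_count / tot_u)
  l2 <- log2(ratio) - log2(wt_ratio)
  l10 <- log10(ratio) - log10(wt_ratio)
  # reference cells are the wild type itself: exactly 0 after normalization
  ref_chars <- strsplit(sorted$reference, "")[[1]]
  for (j in seq_along(ref_chars)) {
    l2[ref_chars[j], j] <- 0
    l10[ref_chars[j], j] <- 0
  }
  structure(list(ratio = ratio, log2 = l2, log10 = l10,
                 reference = sorted$reference, wt_enrichment = wt_ratio),
            class = "scanning_enrichment")
}

#' @export
print.scanning_enrichment <- function(x, ...) {
  cat("<scanning_enrichment> reference", x$reference,
      "| wt enrichment", signif(x$wt_enrichment, 4), "\n")
  invisible(x)
}

#' Amber (one-stop) position enrichment
#'
#' Analysis mode for amber-suppression screens: sequences without an internal
#' amber codon are expressed more efficiently than amber-containing ones, so
#' amber-containing peptides look artificially depleted unless the comparison
#' is restricted to the one-amber subset. This builds `onestop`-filtered
#' residue matrices for both samples and applies [position_enrichment()];
#' the `*` row then reports the positional enrichment of the non-canonical
#' residue.
#'
#' @param sorted_records,unsorted_records record sets as accepted by
#'   [position_residue_counts()].
#' @param design the degenerate [library_design()] (gives length and center).
#' @param pseudocount see [position_enrichment()].
#' @return a `position_enrichment` with `filter_mode == "onestop"`.
#' @export
amber_position_enrichment <- function(sorted_records, unsorted_records,
                                      design, pseudocount = 0) {
  stopifnot(inherits(design, "library_design"))
  center <- if (!is.null(design$central_fixed)) design$central_fixed$position
  ms <- position_residue_counts(sorted_records, design$peptide_length,
                                filter_mode = "onestop", center = center)
  mu <- position_residue_counts(unsorted_records, design$peptide_length,
                                filter_mode = "onestop", center = center)
  if (ms$n_retained == 0L || mu$n_retained == 0L)
    stop("no one-amber records in the ",
         if (ms$n_retained == 0L) "sorted" else "unsorted", " sample")
  position_enrichment(ms, mu, pseudocount = pseudocount)
}

#' Select peptides for probability-logo rendering
#'
#' Splits an enrichment table into the foreground (peptides with exactly one
#' tyrosine and enrichment above the cutoff; the conventional cutoff is 3)
#' and background (all single-tyrosine peptides), and emits position
#' frequency tables suitable for logo tools.
#'
#' @param table an `enrichment_table`.
#' @param cutoff enrichment cutoff (> 0), default 3.
#' @param single_tyrosine_only restrict both sets to peptides with exactly
#'   one Tyr (default TRUE).
#' @return list with `foreground`, `background` (peptide vectors) and
#'   `foreground_pfm`, `background_pfm` (residue x position frequency
#'   matrices; `NULL` when the set is empty).
#' @export
select_for_logo <- function(table, cutoff = 3, single_tyrosine_only = TRUE) {
  stopifnot(inherits(table, "enrichment_table"), cutoff > 0)
  n_tyr <- vapply(gregexpr("Y", table$peptide, fixed = TRUE),
                  function(g) sum(g > 0L), integer(1))
  in_bg <- if (single_tyrosine_only) n_tyr == 1L else rep(TRUE, nrow(table))
  background <- table$peptide[in_bg]
  foreground <- table$peptide[in_bg & !table$undefined &
                                table$enrichment > cutoff]
  if (length(foreground) == 0L)
    warning("no peptides above the enrichment cutoff; empty foreground")
  pfm <- function(peps) {
    if (length(peps) == 0L) return(NULL)
    L <- nchar(peps[1L])
    chars <- matrix(unlist(strsplit(peps, "")), ncol = L, byrow = TRUE)
    m <- vapply(seq_len(L), function(j)
      as.vector(table(factor(chars[, j], levels = AA_ORDER))) / length(peps),
      numeric(length(AA_ORDER)))
    dimnames(m) <- list(AA_ORDER, as.character(seq_len(L)))
    m
  }
  list(foreground = foreground, background = background,
       foreground_pfm = pfm(foreground), background_pfm = pfm(background))
}

#' Average log enrichment across replicates
#'
#' Each sorted sample is scored only against its matched unsorted sample;
#' replicate combination is an explicit post-step: the mean of the log
#' scores, cell-wise or peptide-wise.
#'
#' @param scores a list of `position_enrichment` or `scanning_enrichment`
#'   objects (same shape), or of `enrichment_table`s (joined on peptide).
#' @param log_base 2 or 10.
#' @return a matrix of mean log scores, or for enrichment tables a data.frame
#'   of peptide and mean log score.
#' @export
average_replicates <- function(scores, log_base = 2) {
  slot <- if (log_base == 2) "log2" else "log10"
  if (inherits(scores[[1L]], "enrichment_table")) {
    col <- paste0("log", log_base, "_enrichment")
    peps <- sort(Reduce(union, lapply(scores, `[[`, "peptide")))
    vals <- vapply(scores, function(s) {
      v <- setNames(s[[col]], s$peptide)[peps]
      unname(v)
    }, numeric(length(peps)))
    return(data.frame(peptide = peps,
                      mean_log = rowMeans(as.matrix(vals)),
                      stringsAsFactors = FALSE))
  }
  mats <- lapply(scores, `[[`, slot)
  Reduce(`+`, mats) / length(mats)
}

#' Heatmap of a log-enrichment matrix
#'
#' ggplot2 tile heatmap on the conventional diverging blue-white-red scale
#' (blue disfavored, white neutral, red favored). Masked cells are grey.
#'
#' @param x a `position_enrichment` or `scanning_enrichment`.
#' @param log_base 2 (degenerate convention) or 10 (scanning convention).
#' @return a ggplot object.
#' @export
plot_enrichment_heatmap <- function(x,
                                    log_base = if (inherits(x, "scanning_enrichment")) 10 else 2) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  m <- if (log_base == 2) x$log2 else x$log10
  df <- data.frame(residue = factor(rep(rownames(m), ncol(m)),
                                    levels = rev(AA_ORDER)),
                   position = factor(rep(colnames(m), each = nrow(m)),
                                     levels = colnames(m)),
                   score = as.vector(m))
  lim <- max(abs(df$score), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = residue, fill = score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-lim, lim), na.value = "grey30",
                                  name = bquote(log[.(log_base)] ~ "enrichment")) +
    ggplot2::labs(x = "position", y = "residue") +
    ggplot2::theme_minimal()
}

#' Write an enrichment table to TSV
#'
#' @param table an `enrichment_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_enrichment_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
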