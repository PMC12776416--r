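# Counting: aggregate translated peptides into the count structures that the
# three scoring schemes consume, with the stop-codon filter modes used for
# amber-suppression data.

ok_peptides <- function(records) {
  if (is.data.frame(records)) {
    keep <- records$status == "ok"
    list(peptide = records$peptide[keep],
         n_amber = records$n_amber[keep])
  } else {
    # plain character vector of peptides
    list(peptide = records,
         n_amber = vapply(gregexpr("*", records, fixed = TRUE),
                          function(g) sum(g > 0L), integer(1)))
  }
}

#' Tally peptides into a counts table
#'
#' Exact-match tally of `ok` peptide records. With a whitelist (defined
#' libraries), peptides outside it are excluded and reported.
#'
#' @param records a data.frame from [process_sample()] (rows with
#'   `status == "ok"` are used) or a character vector of peptides.
#' @param whitelist optional character vector of admissible peptides.
#' @param sample_id,sorted_flag provenance carried on the table.
#' @return a `counts_table`: list with `entries` (named integer vector),
#'   `total`, `sample_id`, `sorted_flag`, `n_excluded`.
#' @export
count_peptides <- function(records, whitelist = NULL, sample_id = "sample",
                           sorted_flag = FALSE) {
  pep <- ok_peptides(records)$peptide
  n_excluded <- 0L
  if (!is.null(whitelist)) {
    out <- !(pep %in% whitelist)
    n_excluded <- sum(out)
    pep <- pep[!out]
  }
  tab <- table(pep)
  entries <- setNames(as.integer(tab), names(tab))
  structure(list(entries = entries, total = sum(entries),
                 sample_id = sample_id, sorted_flag = sorted_flag,
                 n_excluded = n_excluded),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat("<counts_table>", x$sample_id,
      if (x$sorted_flag) "(sorted)" else "(unsorted)",
      "|", length(x$entries), "peptides,", x$total, "reads")
  if (x$n_excluded) cat(",", x$n_excluded, "excluded")
  cat("\n")
  invisible(x)
}

apply_stop_filter <- function(peptide, n_amber, filter_mode) {
  switch(filter_mode,
         full = rep(TRUE, length(peptide)),
         nostop = n_amber == 0L,
         onestop = n_amber == 1L,
         stop("unknown filter_mode: ", filter_mode))
}

#' Residue-by-position counts matrix
#'
#' Tallies each retained record once per position into a 21-row matrix (20
#' canonical residues plus the amber row `*`, always last). The stop-codon
#' filter modes follow the amber-suppression analysis: `full` keeps all
#' records, `nostop` keeps records without amber codons, `onestop` keeps
#' records with exactly one amber codon (one non-canonical residue).
#'
#' @param records as in [count_peptides()].
#' @param length expected peptide length; records of any other length are
#'   excluded and reported in the `n_excluded` attribute.
#' @param filter_mode `"full"`, `"nostop"` or `"onestop"`.
#' @param center optional 1-based index of the fixed central residue; when
#'   given, columns are labelled by signed offsets (-k..+k, center 0) as in
#'   degenerate-library displays, otherwise 1..L.
#' @return a `residue_matrix`: list with `counts` (21 x L matrix),
#'   `filter_mode`, `center`, `n_retained`, `n_excluded`.
#' @export
position_residue_counts <- function(records, length, filter_mode = "full",
                                    center = NULL) {
  ok <- ok_peptides(records)
  right_len <- nchar(ok$peptide) == length
  n_excluded <- sum(!right_len)
  pep <- ok$peptide[right_len]
  na <- ok$n_amber[right_len]
  keep <- apply_stop_filter(pep, na, filter_mode)
  pep <- pep[keep]
  cols <- if (!is.null(center)) {
    labs <- seq_len(length) - center
    ifelse(labs > 0, paste0("+", labs), as.character(labs))
  } else as.character(seq_len(length))
  m <- matrix(0L, nrow = base::length(AA_ORDER), ncol = length,
              dimnames = list(AA_ORDER, cols))
  if (base::length(pep)) {
    chars <- matrix(unlist(strsplit(pep, "")), ncol = length, byrow = TRUE)
    for (j in seq_len(length)) {
      tab <- table(factor(chars[, j], levels = AA_ORDER))
      m[, j] <- m[, j] + as.integer(tab)
    }
  }
  structure(list(counts = m, filter_mode = filter_mode, center = center,
                 n_retained = base::length(pep), n_excluded = n_excluded),
            class = "residue_matrix")
}

#' @export
print.residue_matrix <- function(x, ...) {
  cat("<residue_matrix>", nrow(x$counts), "residues x", ncol(x$counts),
      "positions | filter:", x$filter_mode, "|", x$n_retained, "records\n")
  invisible(x)
}

#' Scanning-mutagenesis counts matrix
#'
#' Builds the point-mutant matrix for a scanning library: peptides differing
#' from the reference at exactly one position contribute their count to the
#' (mutant residue, position) cell; the exact reference's count is written
#' into the reference-residue cell of *every* column (the repeated wild type,
#' which scoring must correct for); peptides differing at two or more
#' positions are excluded and reported.
#'
#' @param table a `counts_table` from [count_peptides()].
#' @param reference the reference (wild-type) peptide.
#' @return a `scanning_counts`: list with `counts` (21 x L), `reference`,
#'   `wt_count`, `n_excluded_reads` (reads on multi-mutant peptides).
#' @export
scanning_matrix_counts <- function(table, reference) {
  stopifnot(inherits(table, "counts_table"))
  L <- nchar(reference)
  pep <- names(table$entries)
  if (length(pep) && any(nchar(pep) != L))
    stop("counts table contains peptides of a different length than the reference")
  ref_chars <- strsplit(reference, "")[[1]]
  m <- matrix(0L, nrow = length(AA_ORDER), ncol = L,
              dimnames = list(AA_ORDER, as.character(seq_len(L))))
  wt_count <- 0L
  n_excluded <- 0L
  if (length(pep)) {
    chars <- matrix(unlist(strsplit(pep, "")), ncol = L, byrow = TRUE)
    diffs <- chars != matrix(ref_chars, nrow = length(pep), ncol = L,
                             byrow = TRUE)
    ndiff <- rowSums(diffs)
    wt_count <- sum(table$entries[ndiff == 0L])
    singles <- which(ndiff == 1L)
    for (i in singles) {
      j <- which(diffs[i, ])
      r <- chars[i, j]
      if (r %in% AA_ORDER) m[r, j] <- m[r, j] + table$entries[i]
      else n_excluded <- n_excluded + table$entries[i]
    }
    n_excluded <- n_excluded + sum(table$entries[ndiff >= 2L])
  }
  # the wild type is repeat-counted in every column
  for (j in seq_len(L)) m[ref_chars[j], j] <- wt_count
  structure(list(counts = m, reference = reference, wt_count = wt_count,
                 n_excluded_reads = n_excluded),
            class = "scanning_counts")
}

#' @export
print.scanning_counts <- function(x, ...) {
  cat("<scanning_counts> reference", x$reference, "| wt reads", x$wt_count,
      "| corrected total", scanning_corrected_total(x), "\n")
  invisible(x)
}

#' Wild-type-corrected total of a scanning counts matrix
#'
#' The matrix repeats the wild-type count in every column, so the raw sum
#' overcounts it `L - 1` times. The corrected total
#' `sum(counts) - wt_count * (L - 1)` equals the number of contributing reads
#' (single mutants plus the wild type); for an 11-residue peptide the
#' correction multiplier is 10.
#'
#' @param scm a `scanning_counts` object.
#' @return the corrected read total.
#' @export
scanning_corrected_total <- function(scm) {
  stopifnot(inherits(scm, "scanning_counts"))
  sum(scm$counts) - scm$wt_count * (ncol(scm$counts) - 1L)
}

#' Serialize a counts matrix as TSV with a provenance header
#'
#' @param x a `residue_matrix` or `scanning_counts`.
#' @param path output path.
#' @param sample_id provenance recorded in the header comment.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path, sample_id = "") {
  m <- x$counts
  mode <- if (inherits(x, "residue_matrix")) x$filter_mode else "scanning"
  hdr <- sprintf("# sample_id=%s filter_mode=%s", sample_id, mode)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(residue = rownames(m), m, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
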