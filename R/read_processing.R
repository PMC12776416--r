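# Read processing: merge paired reads, extract the peptide-coding insert
# between the constant amplicon flanks, and translate with amber annotation.

TERMINATOR_MARK <- "#"  # internal marker for TAA/TGA before policy is applied

# Vectorized translation of DNA strings. Returns a data.frame with peptide
# (amber as `*`, untranslatable codons as `X`, terminators as `#`), n_amber,
# n_terminator and frame_ok. Lengths may vary; strings are grouped by length.
translate_many <- function(dna) {
  n <- length(dna)
  out <- data.frame(peptide = character(n), n_amber = integer(n),
                    n_terminator = integer(n), frame_ok = logical(n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  gc <- codon_lookup()
  trans <- gc
  trans["TAG"] <- "*"
  trans["TAA"] <- TERMINATOR_MARK
  trans["TGA"] <- TERMINATOR_MARK
  len <- nchar(dna)
  out$frame_ok <- len %% 3L == 0L & len > 0L
  for (L in unique(len[out$frame_ok])) {
    idx <- which(len == L & out$frame_ok)
    s <- toupper(dna[idx])
    starts <- seq(1L, L, 3L)
    cod <- vapply(starts, function(i) substring(s, i, i + 2L),
                  character(length(idx)))
    if (length(idx) == 1L) cod <- matrix(cod, nrow = 1L)
    aa <- trans[cod]
    aa[is.na(aa)] <- "X"
    aa <- matrix(aa, nrow = length(idx))
    out$peptide[idx] <- do.call(paste0, as.data.frame(aa, stringsAsFactors = FALSE))
    out$n_amber[idx] <- rowSums(aa == "*")
    out$n_terminator[idx] <- rowSums(aa == TERMINATOR_MARK)
  }
  out
}

#' Translate a DNA string to a peptide
#'
#' Standard genetic code, reading frame starting at the first base. The amber
#' codon TAG translates to `*` (a candidate non-canonical residue under amber
#' suppression); TAA/TGA translate to `#` here and are handled by
#' [translate_insert()]'s terminator policy; codons containing non-ACGT
#' characters give `X`.
#'
#' @param dna a DNA string whose length is a multiple of 3.
#' @return the peptide string.
#' @export
translate_dna <- function(dna) {
  tr <- translate_many(dna)
  if (!all(tr$frame_ok)) stop("DNA length is not a multiple of 3")
  tr$peptide
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# mismatches between two equal-length raw vectors
.mism <- function(a, b) sum(a != b)

#' Merge a read pair by best suffix-prefix overlap
#'
#' The reverse read is reverse-complemented, then every overlap length `k`
#' from `min_overlap` up to the shorter read length is scored as
#' `matches - mismatches`; overlaps whose mismatch fraction exceeds
#' `max_mismatch_fraction` are inadmissible. The best-scoring admissible
#' overlap (ties to the longer one) defines the consensus; at mismatched
#' overlap positions the base with the higher quality wins (ties to the
#' forward read).
#'
#' @param forward,reverse read sequences (the reverse read as sequenced, i.e.
#'   it will be reverse-complemented here).
#' @param qual_forward,qual_reverse optional integer Phred vectors, one per
#'   base; defaults to a constant 30.
#' @param min_overlap minimum admissible overlap length (default 10).
#' @param max_mismatch_fraction maximum fraction of mismatched overlap
#'   positions (default 0.25).
#' @return the merged sequence, or `NULL` if no admissible overlap exists.
#' @export
merge_pair <- function(forward, reverse, qual_forward = NULL,
                       qual_reverse = NULL, min_overlap = 10L,
                       max_mismatch_fraction = 0.25) {
  stopifnot(min_overlap >= 1L, max_mismatch_fraction >= 0,
            max_mismatch_fraction < 0.5)
  n1 <- nchar(forward); n2 <- nchar(reverse)
  rc2 <- reverse_complement(reverse)
  q1 <- qual_forward %||% rep(30L, n1)
  q2 <- rev(qual_reverse %||% rep(30L, n2))  # follow the reverse complement
  a <- charToRaw(toupper(forward)); b <- charToRaw(toupper(rc2))
  best_k <- NA_integer_; best_score <- -Inf; best_mism <- NA_integer_
  for (k in seq.int(min_overlap, min(n1, n2))) {
    m <- .mism(a[(n1 - k + 1L):n1], b[1:k])
    if (m / k > max_mismatch_fraction) next
    score <- k - 2L * m
    if (score > best_score || (score == best_score && k > best_k)) {
      best_score <- score; best_k <- k; best_mism <- m
    }
  }
  if (is.na(best_k)) return(NULL)
  k <- best_k
  ov_a <- (n1 - k + 1L):n1
  ov <- substring(rc2, 1L, k)
  if (best_mism > 0L) {
    ca <- a[ov_a]; cb <- b[1:k]
    diff <- which(ca != cb)
    cons <- ca
    use_b <- q2[diff] > q1[ov_a[diff]]
    cons[diff[use_b]] <- cb[diff[use_b]]
    ov <- rawToChar(cons)
  } else {
    ov <- substr(forward, n1 - k + 1L, n1)
  }
  paste0(substr(forward, 1L, n1 - k), ov, substr(rc2, k + 1L, n2))
}

# leftmost occurrence of `anchor` in `seq` with at most `mm` mismatches,
# starting the search at `from`; returns the 1-based start or NA
.find_anchor <- function(seq, anchor, mm, from = 1L) {
  if (mm == 0L) {
    p <- regexpr(anchor, substr(seq, from, nchar(seq)), fixed = TRUE)
    return(if (p > 0L) from + as.integer(p) - 1L else NA_integer_)
  }
  n <- nchar(seq); k <- nchar(anchor)
  if (n - from + 1L < k) return(NA_integer_)
  a <- charToRaw(toupper(anchor)); s <- charToRaw(toupper(seq))
  for (i in from:(n - k + 1L)) {
    if (.mism(s[i:(i + k - 1L)], a) <= mm) return(i)
  }
  NA_integer_
}

#' Extract the peptide-coding insert from a merged read
#'
#' Locates the constant 36-nt 5' anchor and 37-nt 3' anchor (the non-N
#' portions of the amplicon flanking sequences) and returns the substring
#' strictly between them. The leftmost 5' match and the nearest subsequent 3'
#' match are used; each anchor tolerates up to `max_flank_mismatches`
#' substitutions. If both anchors are missing, the reverse-complement
#' orientation is tried.
#'
#' @param merged merged read sequence.
#' @param design a [library_design()] (carried for interface symmetry; the
#'   anchors are constants of the amplicon architecture).
#' @param max_flank_mismatches substitutions tolerated per anchor (default 1).
#' @return a list with `insert`, `orientation` (`"forward"` or `"reverse"`),
#'   or `NULL` if either anchor is missing or the insert has negative length.
#' @export
extract_insert <- function(merged, design = NULL, max_flank_mismatches = 1L) {
  for (orient in c("forward", "reverse")) {
    s <- if (orient == "forward") merged else reverse_complement(merged)
    p5 <- .find_anchor(s, READ_ANCHOR5, max_flank_mismatches)
    if (is.na(p5)) next
    start <- p5 + nchar(READ_ANCHOR5)
    p3 <- .find_anchor(s, READ_ANCHOR3, max_flank_mismatches, from = start)
    if (is.na(p3)) next
    if (p3 < start) return(NULL)
    return(list(insert = substr(s, start, p3 - 1L), orientation = orient))
  }
  NULL
}

#' Translate an extracted insert into a peptide record
#'
#' @param insert_dna the insert DNA string.
#' @param design the [library_design()] giving the expected peptide length.
#' @param terminator_to_x map TAA/TGA codons to `X` instead of rejecting the
#'   read (default FALSE: such reads get status `terminator_fail` because they
#'   cannot encode a displayed peptide).
#' @return a list (one peptide record) with `insert_dna`, `peptide`,
#'   `n_amber`, `n_terminator`, `status` in
#'   `ok | frame_fail | length_fail | terminator_fail`.
#' @export
translate_insert <- function(insert_dna, design, terminator_to_x = FALSE) {
  tr <- translate_many(insert_dna)
  rec <- list(insert_dna = insert_dna, peptide = tr$peptide,
              n_amber = tr$n_amber, n_terminator = tr$n_terminator)
  if (!tr$frame_ok) {
    rec$status <- "frame_fail"; rec$peptide <- ""
  } else if (nchar(tr$peptide) != design$peptide_length) {
    rec$status <- "length_fail"
  } else if (tr$n_terminator > 0L && !terminator_to_x) {
    rec$status <- "terminator_fail"
  } else {
    if (tr$n_terminator > 0L)
      rec$peptide <- gsub(TERMINATOR_MARK, "X", rec$peptide, fixed = TRUE)
    rec$status <- "ok"
  }
  rec
}

read_fastq <- function(path) {
  # suppressWarnings: the reader warns when it drops per-read metadata
  # columns, which we never use
  x <- tryCatch(suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) NULL)
  if (is.null(x) || length(x) == 0L)
    return(list(seq = character(0), qual = character(0), id = character(0)))
  list(seq = as.character(x),
       qual = as.character(Biostrings::quality(x)),
       id = names(x) %||% as.character(seq_along(x)))
}

# Vectorized merge over many pairs: exact-overlap fast path (longest exact
# suffix-prefix overlap), scalar merge_pair fallback for the remainder.
merge_pairs_bulk <- function(s1, s2, q1, q2, min_overlap, max_mismatch_fraction) {
  n <- length(s1)
  merged <- rep(NA_character_, n)
  if (n == 0L) return(merged)
  rc2 <- reverse_complement(s2)
  l1 <- nchar(s1); l2 <- nchar(s2)
  uniform <- length(unique(l1)) == 1L && length(unique(l2)) == 1L
  todo <- seq_len(n)
  if (uniform) {
    L1 <- l1[1L]; L2 <- l2[1L]
    for (k in seq.int(min(L1, L2), min_overlap)) {
      if (length(todo) == 0L) break
      hit <- substring(s1[todo], L1 - k + 1L, L1) == substring(rc2[todo], 1L, k)
      if (any(hit)) {
        idx <- todo[hit]
        merged[idx] <- paste0(substr(s1[idx], 1L, L1 - k), rc2[idx])
        todo <- todo[!hit]
      }
    }
  }
  if (length(todo)) {
    phred <- function(q) utf8ToInt(q) - 33L
    for (i in todo) {
      m <- merge_pair(s1[i], s2[i],
                      qual_forward = phred(q1[i]), qual_reverse = phred(q2[i]),
                      min_overlap = min_overlap,
                      max_mismatch_fraction = max_mismatch_fraction)
      if (!is.null(m)) merged[i] <- m
    }
  }
  merged
}

# Vectorized insert extraction: exact regexpr fast path for both anchors,
# scalar mismatch-tolerant fallback for misses.
extract_inserts_bulk <- function(merged, max_flank_mismatches) {
  n <- length(merged)
  insert <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(insert = insert, orientation = orientation,
                                 stringsAsFactors = FALSE))
  p5 <- regexpr(READ_ANCHOR5, merged, fixed = TRUE)
  p3 <- regexpr(READ_ANCHOR3, merged, fixed = TRUE)
  fast <- p5 > 0L & p3 > 0L & p3 >= p5 + nchar(READ_ANCHOR5)
  if (any(fast)) {
    insert[fast] <- substr(merged[fast], p5[fast] + nchar(READ_ANCHOR5),
                           p3[fast] - 1L)
    orientation[fast] <- "forward"
  }
  for (i in which(!fast & !is.na(merged))) {
    r <- extract_insert(merged[i], max_flank_mismatches = max_flank_mismatches)
    if (!is.null(r)) {
      insert[i] <- r$insert
      orientation[i] <- r$orientation
    }
  }
  data.frame(insert = insert, orientation = orientation,
             stringsAsFactors = FALSE)
}

#' Process one sequencing sample into peptide records
#'
#' Streams read pairs through merge, flank-anchored insert extraction and
#' translation, with per-status QC accounting. Accepts either a paired FASTQ
#' sample (`fastq_forward` + `fastq_reverse`) or pre-merged reads
#' (`premerged`, FASTQ; merging is skipped).
#'
#' @param fastq_forward,fastq_reverse paths to the paired FASTQ files (plain
#'   or gzipped).
#' @param design the [library_design()] sequenced.
#' @param sample_id label carried into the QC stats.
#' @param premerged optional path to pre-merged reads (FASTQ).
#' @param min_overlap,max_mismatch_fraction merge parameters, see
#'   [merge_pair()].
#' @param max_flank_mismatches see [extract_insert()].
#' @param terminator_to_x see [translate_insert()].
#' @return a list with `records` (data.frame: read_id, insert_dna, peptide,
#'   n_amber, n_terminator, status, orientation) and `qc` (status totals;
#'   the status counts sum to the number of input pairs).
#' @export
process_sample <- function(fastq_forward = NULL, fastq_reverse = NULL,
                           design, sample_id = "sample",
                           premerged = NULL,
                           min_overlap = 10L, max_mismatch_fraction = 0.25,
                           max_flank_mismatches = 1L,
                           terminator_to_x = FALSE) {
  stopifnot(inherits(design, "library_design"))
  if (is.null(premerged)) {
    if (is.null(fastq_forward) || is.null(fastq_reverse))
      stop("need fastq_forward and fastq_reverse (or premerged)")
    if (!file.exists(fastq_forward)) stop("missing file: ", fastq_forward)
    if (!file.exists(fastq_reverse)) stop("missing file: ", fastq_reverse)
    r1 <- read_fastq(fastq_forward)
    r2 <- read_fastq(fastq_reverse)
    if (length(r1$seq) != length(r2$seq))
      stop("unpaired files: ", length(r1$seq), " forward vs ",
           length(r2$seq), " reverse reads")
    ids <- sub(" .*", "", r1$id)
    merged <- merge_pairs_bulk(r1$seq, r2$seq, r1$qual, r2$qual,
                               min_overlap, max_mismatch_fraction)
  } else {
    if (!file.exists(premerged)) stop("missing file: ", premerged)
    pm <- read_fastq(premerged)
    ids <- sub(" .*", "", pm$id)
    merged <- pm$seq
  }
  n <- length(merged)
  status <- rep("merge_fail", n)
  ex <- extract_inserts_bulk(merged, max_flank_mismatches)
  has_merge <- !is.na(merged)
  status[has_merge] <- ifelse(is.na(ex$insert[has_merge]),
                              "flank_fail", "pending")
  tr <- translate_many(ifelse(is.na(ex$insert), "", ex$insert))
  pend <- status == "pending"
  status[pend & !tr$frame_ok] <- "frame_fail"
  good_frame <- pend & tr$frame_ok
  status[good_frame & nchar(tr$peptide) != design$peptide_length] <- "length_fail"
  still <- status == "pending"
  if (terminator_to_x) {
    tr$peptide[still & tr$n_terminator > 0L] <-
      gsub(TERMINATOR_MARK, "X", tr$peptide[still & tr$n_terminator > 0L],
           fixed = TRUE)
  } else {
    status[still & tr$n_terminator > 0L] <- "terminator_fail"
  }
  status[status == "pending"] <- "ok"
  records <- data.frame(read_id = if (n) ids else character(0),
                        insert_dna = ex$insert,
                        peptide = ifelse(status == "ok", tr$peptide, NA_character_),
                        n_amber = ifelse(status == "ok", tr$n_amber, NA_integer_),
                        n_terminator = tr$n_terminator,
                        status = status,
                        orientation = ex$orientation,
                        stringsAsFactors = FALSE)
  statuses <- c("ok", "merge_fail", "flank_fail", "frame_fail",
                "length_fail", "terminator_fail")
  qc <- list(sample_id = sample_id,
             reads_in = n,
             reads_ok = sum(status == "ok"),
             status_counts = as.list(setNames(
               vapply(statuses, function(s) sum(status == s), integer(1)),
               statuses)),
             orientation_counts = as.list(table(ex$orientation[status == "ok"])))
  list(records = records, qc = qc)
}

#' Write processed peptide records and QC to disk
#'
#' @param result a list from [process_sample()].
#' @param tsv path for the per-read peptide table (TSV).
#' @param qc_json optional path for the QC stats (JSON).
#' @return invisibly, `result`.
#' @export
write_sample_output <- function(result, tsv, qc_json = NULL) {
  utils::write.table(result$records, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(qc_json))
    jsonlite::write_json(result$qc, qc_json, auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}
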