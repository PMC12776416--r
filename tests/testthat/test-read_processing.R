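rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# independent brute-force overlap merger used as the oracle: same admissibility
# rule, scoring matches - mismatches, ties to the longer overlap
oracle_merge <- function(f, r, min_overlap, max_mm_frac) {
  rc2 <- rc(r)
  a <- strsplit(f, "")[[1]]; b <- strsplit(rc2, "")[[1]]
  n1 <- length(a); n2 <- length(b)
  best <- NULL; best_score <- -Inf
  for (k in min_overlap:min(n1, n2)) {
    m <- sum(a[(n1 - k + 1):n1] != b[1:k])
    if (m / k > max_mm_frac) next
    score <- k - 2 * m
    if (score > best_score || (score == best_score && k > best$k)) {
      best <- list(k = k, m = m); best_score <- score
    }
  }
  if (is.null(best)) return(NULL)
  # qualities equal everywhere, so the forward base wins at mismatches
  paste0(substr(f, 1, n1 - best$k), substr(f, n1 - best$k + 1, n1),
         substr(rc2, best$k + 1, n2))
}

test_that("merge_pair finds hand-constructed overlaps and rejects disjoint reads", {
  f <- "ACGTACGTACGT"
  r <- rc("TACGTACGTTTT")
  expect_identical(merge_pair(f, r, min_overlap = 5L), "ACGTACGTACGTTTT")

  # complete overlap identity
  s <- "GATTACAGATTACAGATTACA"
  expect_identical(merge_pair(s, rc(s)), s)

  # disjoint sequences cannot merge
  expect_null(merge_pair("AAAAAAAAAAAAAAA", rc("GGGGGGGGGGGGGGG"),
                         min_overlap = 10L))
})

test_that("quality decides the consensus base at mismatched overlap positions", {
  f <- "AAAAAAAAAACCCCCCCCCC"
  ov <- "CCCCCCCCCC"
  tail3 <- "GGG"
  r_true <- paste0(ov, tail3)              # overlap CCCCCCCCCC then GGG
  # put one mismatch in the reverse copy of the overlap, with higher quality
  r_mut <- paste0("CCCCACCCCC", tail3)
  m <- merge_pair(f, rc(r_mut),
                  qual_forward = rep(10L, nchar(f)),
                  qual_reverse = rep(40L, nchar(r_mut)),
                  min_overlap = 8L)
  expect_identical(m, paste0("AAAAAAAAAA", "CCCCACCCCC", tail3))
  # and the forward base wins when its quality is higher
  m2 <- merge_pair(f, rc(r_mut),
                   qual_forward = rep(40L, nchar(f)),
                   qual_reverse = rep(10L, nchar(r_mut)),
                   min_overlap = 8L)
  expect_identical(m2, paste0(f, tail3))
})

test_that("merge_pair agrees with the brute-force oracle on random pairs", {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    tmpl <- paste(sample(bases, 60, replace = TRUE), collapse = "")
    k <- sample(12:35, 1)
    f <- substr(tmpl, 1, 40)
    r_seq <- substr(tmpl, 41 - k, 60)     # overlap of length k
    # occasionally inject a substitution into the forward read's overlap
    if (i %% 5 == 0) {
      pos <- sample(seq(41 - k, 40), 1)
      ch <- substr(f, pos, pos)
      substr(f, pos, pos) <- sample(setdiff(bases, ch), 1)
    }
    got <- merge_pair(f, rc(r_seq), min_overlap = 10L,
                      max_mismatch_fraction = 0.25)
    want <- oracle_merge(f, rc(r_seq), 10L, 0.25)
    expect_identical(got, want)
  }
})

amplicon_for <- function(insert) {
  paste0("ACGTGC", "ACCGCAGGTACTTCCGTA", "GCTGGCCAGTCTGGCCAG", insert,
         "GGAGGGCAGTCTGGGCAGTCTG", "GTGACTACAACAAAA", "TTGCAT")
}

test_that("insert extraction is anchored, mismatch-tolerant and orientation-aware", {
  d <- x5yx5_design()
  insert <- toupper("tatgatatgcatgcatgcatgcatgcatgcatg")  # 33 nt
  merged <- amplicon_for(insert)
  expect_identical(extract_insert(merged, d, max_flank_mismatches = 0L)$insert,
                   insert)

  # one substitution inside the 5' anchor is absorbed at tolerance 1
  mut <- merged
  substr(mut, 10, 10) <- "T"  # inside the 36-nt anchor region
  expect_null(extract_insert(mut, d, max_flank_mismatches = 0L))
  expect_identical(extract_insert(mut, d, max_flank_mismatches = 1L)$insert,
                   insert)

  # missing 3' anchor
  broken <- substr(merged, 1, nchar(merged) - 45)
  expect_null(extract_insert(broken, d))

  # reverse-complement orientation is found and reported
  flipped <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(merged)))
  r <- extract_insert(flipped, d)
  expect_identical(r$insert, insert)
  expect_identical(r$orientation, "reverse")
})

test_that("translation handles the standard code, amber and terminators", {
  d3 <- library_design("degenerate", peptide_length = 1L)
  expect_identical(translate_insert("tat", d3)$peptide, "Y")
  expect_identical(translate_dna("ccggatgaatgcatttatgatatgtttccgttt"),
                   "PDECIYDMFPF")

  d2 <- library_design("degenerate", peptide_length = 3L)
  rec <- translate_insert("tagtattat", d2)
  expect_identical(rec$peptide, "*YY")
  expect_equal(rec$n_amber, 1L)
  expect_identical(rec$status, "ok")

  # TAA/TGA cannot encode displayed peptide: rejected by default
  recT <- translate_insert("taatattat", d2)
  expect_identical(recT$status, "terminator_fail")
  recX <- translate_insert("taatattat", d2, terminator_to_x = TRUE)
  expect_identical(recX$status, "ok")
  expect_identical(recX$peptide, "XYY")

  expect_identical(translate_insert("tatg", d2)$status, "frame_fail")
  expect_identical(translate_insert("tattat", d2)$status, "length_fail")
})

test_that("process_sample round-trips simulator output and accounts for every pair", {
  d <- x5yx5_design()
  cfg <- simulation_config(d, n_cells = 2000, reads_per_sample = 1000,
                           sequencing_error_rate = 0, seed = 5L)
  pop <- sample_library(cfg)
  out <- emit_fastq(pop, cfg, file.path(tempdir(), "rt"), gzip = TRUE)
  res <- process_sample(out$r1, out$r2, d, sample_id = "rt")
  expect_equal(res$qc$reads_ok, 1000L)
  expect_equal(sum(unlist(res$qc$status_counts)), res$qc$reads_in)
  ct <- count_peptides(res$records)
  tru <- out$truth_counts
  expect_identical(ct$entries[sort(names(ct$entries))],
                   tru[sort(names(tru))])
})

test_that("reads lacking the 3' anchor are tallied as flank failures", {
  d <- x5yx5_design()
  set.seed(11)
  # NNS codons only, so no TAA/TGA terminators arise in frame
  nns <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"), paste0)),
                         c("G", "C"), paste0))
  inserts <- vapply(1:30, function(i)
    paste(sample(nns, 11, replace = TRUE), collapse = ""), character(1))
  amps <- vapply(inserts, amplicon_for, character(1))
  # break the 3' anchor in the last 10
  amps[21:30] <- sub("GGAGGGCAGTCTGGGCAGTCTG", "GGAGGGCAGTCTAAAAAGTCTG",
                     amps[21:30], fixed = TRUE)
  # emit as overlapping 80-nt pairs
  L <- nchar(amps[1])
  r1 <- substr(amps, 1, 80)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(amps, L - 79, L))))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  pepdisplay:::write_fastq(r1, sprintf("r%02d", 1:30), f1)
  pepdisplay:::write_fastq(r2, sprintf("r%02d", 1:30), f2)
  res <- process_sample(f1, f2, d)
  expect_equal(res$qc$status_counts$ok, 20L)
  expect_equal(res$qc$status_counts$flank_fail, 10L)
})

test_that("an empty FASTQ yields zero records and zeroed QC stats", {
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  file.create(f1); file.create(f2)
  res <- process_sample(f1, f2, x5yx5_design())
  expect_equal(nrow(res$records), 0L)
  expect_equal(res$qc$reads_in, 0L)
  expect_equal(sum(unlist(res$qc$status_counts)), 0L)
})

test_that("pre-merged input skips merging", {
  d <- x5yx5_design()
  insert <- toupper("tatgatatgcatgcatgcatgcatgcatgcatg")
  merged <- amplicon_for(insert)
  f <- tempfile(fileext = ".fastq")
  pepdisplay:::write_fastq(c(merged, merged), c("m1", "m2"), f)
  res <- process_sample(design = d, premerged = f)
  expect_equal(res$qc$reads_ok, 2L)
})
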