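# Shared fixtures built in code.

SRC_REF <- "PDECIYDMFPF"
SRC_CODONS <- c("ccg", "gat", "gaa", "tgc", "att", "tat",
                "gat", "atg", "ttt", "ccg", "ttt")

src_scanning_design <- function() {
  library_design("scanning", peptide_length = 11L,
                 reference_peptide = SRC_REF, reference_codons = SRC_CODONS)
}

x5yx5_design <- function() library_design("degenerate", peptide_length = 11L)

# minimal records data.frame from a peptide vector (all status ok)
make_records <- function(peptides) {
  data.frame(peptide = peptides,
             n_amber = vapply(gregexpr("*", peptides, fixed = TRUE),
                              function(g) sum(g > 0L), integer(1)),
             status = rep("ok", length(peptides)),
             stringsAsFactors = FALSE)
}

counts_from <- function(entries, sample_id = "s", sorted_flag = FALSE) {
  count_peptides(rep(names(entries), entries), sample_id = sample_id,
                 sorted_flag = sorted_flag)
}

random_peptide <- function(n, len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

distinct_peptides <- function(n, len) {
  out <- unique(random_peptide(2L * n, len))
  while (length(out) < n) out <- unique(c(out, random_peptide(n, len)))
  out[seq_len(n)]
}
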