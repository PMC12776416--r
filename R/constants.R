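#' @importFrom stats rbinom rmultinom rnorm runif setNames uniroot cor
#' @importFrom utils read.delim write.table head
NULL

# Constant flanks of the library-coding cassette (uppercase by convention;
# the coding region between them is emitted lowercase).
FLANK5 <- "GCTGGCCAGTCTGGCCAG"
FLANK3 <- "GGAGGGCAGTCTGGGCAGTCTG"

# Constant (non-N) portions of the amplicon flanks used to anchor insert
# extraction from merged reads.  The full amplicon carries six randomized
# bases outside each anchor.
READ_ANCHOR5 <- "ACCGCAGGTACTTCCGTAGCTGGCCAGTCTGGCCAG"    # 36 nt, ends in FLANK5
READ_ANCHOR3 <- "GGAGGGCAGTCTGGGCAGTCTGGTGACTACAACAAAA"   # 37 nt, starts with FLANK3
AMPLICON_PRE  <- "ACCGCAGGTACTTCCGTA"   # between 5' N6 and FLANK5
AMPLICON_POST <- "GTGACTACAACAAAA"      # between FLANK3 and 3' N6

# Canonical residue ordering used for all residue-by-position matrices;
# the amber/stop row `*` is always last so serialized outputs are stable.
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ORDER <- c(AA_CANONICAL, "*")

# The 32 NNS codons (any base at positions 1-2, G or C at position 3).
# Together they encode all 20 canonical amino acids plus the amber stop TAG.
NNS_CODONS <- as.vector(outer(
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("G", "C"), paste0))

# Default reverse-translation table: for each amino acid, the most frequently
# used E. coli codon whose third base is G or C (i.e. NNS-compatible), so that
# defined members are drawn from the same codon space as degenerate libraries.
# The amber `*` maps to TAG.
DEFAULT_CODONS <- c(
  A = "gcg", C = "tgc", D = "gac", E = "gag", F = "ttc",
  G = "ggc", H = "cac", I = "atc", K = "aag", L = "ctg",
  M = "atg", N = "aac", P = "ccg", Q = "cag", R = "cgc",
  S = "agc", T = "acc", V = "gtg", W = "tgg", Y = "tac",
  "*" = "tag")

# Fixed central phospho-acceptor Tyr codon in the degenerate X5-Y-X5 design.
CENTER_TYR_CODON <- "tat"

# codon -> residue lookup: standard genetic code with TAG kept distinct as the
# amber `*` (candidate non-canonical site under suppression).  TAA/TGA are the
# hard terminators and are handled by the caller.
codon_lookup <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc
}

# Run an expression with a private RNG stream, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
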