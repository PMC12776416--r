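#' Describe a displayed peptide library
#'
#' A `library_design` is a declarative description of one of the three library
#' architectures used on the eCPX display scaffold: a *defined* pool of known
#' peptides (e.g. a phosphosite library), a *degenerate* library with NNS
#' codons at randomized positions around a fixed central phospho-acceptor
#' tyrosine (the X5-Y-X5 design), or a *scanning* mutagenesis library in which
#' every position of a reference peptide is randomized in turn.
#'
#' All three share the same constant DNA flanks around the peptide-coding
#' cassette, which downstream read processing uses to locate the insert.
#'
#' @param kind one of `"defined"`, `"degenerate"`, `"scanning"`.
#' @param peptide_length number of residues encoded (default 11).
#' @param central_fixed for degenerate designs, a list with `position`
#'   (1-based residue index), `residue` and `codon` of the fixed central
#'   residue. Defaults to Tyr (`tat`) at the center of an odd-length peptide.
#' @param degenerate_codon degenerate codon pattern, default `"NNS"`. Other
#'   IUPAC patterns are accepted but flagged with a warning because the
#'   amber-suppression logic assumes NNS.
#' @param reference_peptide for scanning designs, the wild-type peptide.
#' @param reference_codons for scanning designs, one codon per reference
#'   residue (lowercase), e.g. the printed Src-consensus codons.
#' @param members for defined designs, a character vector of peptides over the
#'   20 canonical one-letter codes.
#' @return an object of class `library_design`.
#' @export
library_design <- function(kind = c("defined", "degenerate", "scanning"),
                           peptide_length = 11L,
                           central_fixed = NULL,
                           degenerate_codon = "NNS",
                           reference_peptide = NULL,
                           reference_codons = NULL,
                           members = NULL) {
  kind <- match.arg(kind)
  peptide_length <- as.integer(peptide_length)
  if (peptide_length < 1L) stop("peptide_length must be >= 1")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", degenerate_codon, ignore.case = TRUE) ||
      nchar(degenerate_codon) != 3L)
    stop("degenerate_codon must be a 3-letter IUPAC codon pattern")
  if (toupper(degenerate_codon) != "NNS")
    warning("degenerate codon is not NNS; amber-suppression handling assumes NNS")

  if (kind == "degenerate") {
    if (is.null(central_fixed)) {
      if (peptide_length %% 2L == 0L)
        stop("a centered fixed residue requires an odd peptide_length")
      central_fixed <- list(position = (peptide_length + 1L) %/% 2L,
                            residue = "Y", codon = CENTER_TYR_CODON)
    }
    if (!is.null(central_fixed$position) &&
        (central_fixed$position < 1L || central_fixed$position > peptide_length))
      stop("central_fixed$position outside the peptide")
  }

  if (kind == "scanning") {
    if (is.null(reference_peptide) || is.null(reference_codons))
      stop("scanning designs need reference_peptide and reference_codons")
    reference_codons <- tolower(reference_codons)
    if (nchar(reference_peptide) != peptide_length ||
        length(reference_codons) != peptide_length)
      stop("reference_peptide and reference_codons must match peptide_length")
    tr <- translate_dna(paste(reference_codons, collapse = ""))
    if (!identical(tr, reference_peptide))
      stop("reference_codons translate to '", tr,
           "', not reference_peptide '", reference_peptide, "'")
  }

  if (kind == "defined") {
    if (!is.null(members)) {
      if (length(members) == 0L) stop("members must be nonempty")
      bad <- !grepl(paste0("^[", paste(AA_CANONICAL, collapse = ""), "]+$"),
                    members)
      if (any(bad))
        stop("members contain non-canonical letters: ",
             paste(utils::head(members[bad], 3L), collapse = ", "))
      if (any(nchar(members) != peptide_length))
        stop("all members must have length peptide_length (", peptide_length, ")")
    }
  }

  structure(list(kind = kind,
                 peptide_length = peptide_length,
                 five_flank = FLANK5,
                 three_flank = FLANK3,
                 degenerate_codon = toupper(degenerate_codon),
                 central_fixed = central_fixed,
                 reference_peptide = reference_peptide,
                 reference_codons = reference_codons,
                 members = members),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design>", x$kind, "| peptide length", x$peptide_length, "\n")
  if (x$kind == "degenerate")
    cat("  fixed", x$central_fixed$residue, "(", x$central_fixed$codon,
        ") at position", x$central_fixed$position, "\n")
  if (x$kind == "scanning")
    cat("  reference:", x$reference_peptide, "\n")
  if (x$kind == "defined")
    cat("  members:", length(x$members), "\n")
  invisible(x)
}

oligo_template <- function(sequence, design_id, varied_position = NA_integer_) {
  structure(list(sequence = sequence,
                 varied_position = varied_position,
                 design_id = design_id),
            class = "oligo_template")
}

#' @export
print.oligo_template <- function(x, ...) {
  cat("<oligo_template>", x$design_id,
      if (!is.na(x$varied_position)) paste0("(varied position ", x$varied_position, ")"),
      "\n  ", x$sequence, "\n")
  invisible(x)
}

#' Build the degenerate-library oligo template
#'
#' Assembles the flanked degenerate oligo: the degenerate codon pattern at
#' every randomized position and the fixed codon (Tyr `tat` by default) at the
#' central position, matching the printed X5-Y-X5 oligo.
#'
#' @param design a degenerate [library_design()].
#' @return an `oligo_template`; flanks uppercase, coding region lowercase with
#'   the degenerate pattern uppercase.
#' @export
build_degenerate_oligo <- function(design) {
  stopifnot(inherits(design, "library_design"))
  if (design$kind != "degenerate") stop("design$kind must be 'degenerate'")
  cf <- design$central_fixed
  codons <- rep(design$degenerate_codon, design$peptide_length)
  codons[cf$position] <- tolower(cf$codon)
  oligo_template(paste0(design$five_flank, paste(codons, collapse = ""),
                        design$three_flank),
                 design_id = sprintf("degenerate_X%d-%s-X%d",
                                     cf$position - 1L, cf$residue,
                                     design$peptide_length - cf$position))
}

#' Build the scanning-mutagenesis oligo templates
#'
#' One template per residue position: the degenerate codon at that position
#' and the reference codons everywhere else, in position order.
#'
#' @param design a scanning [library_design()].
#' @return a list of `oligo_template`s, one per position (`varied_position`
#'   is the 1-based randomized residue index).
#' @export
build_scanning_oligos <- function(design) {
  stopifnot(inherits(design, "library_design"))
  if (design$kind != "scanning") stop("design$kind must be 'scanning'")
  lapply(seq_len(design$peptide_length), function(i) {
    codons <- design$reference_codons
    codons[i] <- design$degenerate_codon
    oligo_template(paste0(design$five_flank, paste(codons, collapse = ""),
                          design$three_flank),
                   design_id = sprintf("scanning_pos%02d", i),
                   varied_position = i)
  })
}

#' Build defined-library oligos by reverse translation
#'
#' One fully fixed flanked oligo per member peptide. Reverse translation uses
#' a fixed per-amino-acid codon table (most frequent NNS-compatible E. coli
#' codon) unless explicit codons are supplied for a member.
#'
#' @param design a defined [library_design()] with nonempty `members`.
#' @param codon_table named character vector mapping residues to codons;
#'   defaults to the package table.
#' @param member_codons optional named list: member peptide -> character
#'   vector of codons overriding the table for that member.
#' @return list of `oligo_template`s in member order.
#' @export
build_defined_oligos <- function(design, codon_table = DEFAULT_CODONS,
                                 member_codons = NULL) {
  stopifnot(inherits(design, "library_design"))
  if (design$kind != "defined") stop("design$kind must be 'defined'")
  if (is.null(design$members) || length(design$members) == 0L)
    stop("defined design has no members")
  lapply(seq_along(design$members), function(k) {
    pep <- design$members[[k]]
    res <- strsplit(pep, "")[[1]]
    codons <- if (!is.null(member_codons) && !is.null(member_codons[[pep]])) {
      tolower(member_codons[[pep]])
    } else {
      unname(codon_table[res])
    }
    if (anyNA(codons) || length(codons) != length(res))
      stop("no codon available for some residue of member ", pep)
    oligo_template(paste0(design$five_flank, paste(codons, collapse = ""),
                          design$three_flank),
                   design_id = sprintf("defined_%03d_%s", k, pep))
  })
}

#' Theoretical diversity of a library design
#'
#' Number of distinct peptides the design can encode. For the degenerate
#' design this is `alphabet^randomized_positions` with alphabet 20 (canonical)
#' or 21 (amber included); for scanning it is `positions * 19 + 1` distinct
#' peptides, plus one amber variant per position when amber is included.
#'
#' @param design a [library_design()].
#' @param include_amber count the amber (TAG-encoded) variant as a 21st letter.
#' @return a numeric count (can exceed integer range, e.g. 20^10).
#' @export
theoretical_diversity <- function(design, include_amber = FALSE) {
  stopifnot(inherits(design, "library_design"))
  if (design$kind == "defined") {
    if (is.null(design$members))
      stop("defined design: diversity is the number of members, but members are unset")
    message("defined design: returning the number of members")
    return(length(design$members))
  }
  alpha <- if (include_amber) 21 else 20
  if (design$kind == "degenerate") {
    n_random <- design$peptide_length - 1L
    return(alpha^n_random)
  }
  # scanning: reference + 19 substitutions per position (+ amber per position)
  L <- design$peptide_length
  L * 19 + 1 + if (include_amber) L else 0
}

#' Validate an oligo template against its design
#'
#' Produces a report (never throws) listing flank presence, reading frame,
#' degenerate-pattern conformity, and — for scanning designs — identity of the
#' translated fixed positions with the reference peptide.
#'
#' @param oligo an `oligo_template`.
#' @param design the [library_design()] it should conform to.
#' @return a list of logical checks plus an overall `ok` flag.
#' @export
validate_oligo <- function(oligo, design) {
  seqU <- toupper(oligo$sequence)
  f5 <- toupper(design$five_flank); f3 <- toupper(design$three_flank)
  has5 <- startsWith(seqU, f5)
  has3 <- endsWith(seqU, f3)
  coding <- if (has5 && has3)
    substr(oligo$sequence, nchar(f5) + 1L, nchar(oligo$sequence) - nchar(f3))
  else ""
  in_frame <- has5 && has3 && nchar(coding) %% 3L == 0L
  length_ok <- in_frame && nchar(coding) == 3L * design$peptide_length
  pattern_ok <- TRUE
  reference_ok <- TRUE
  if (length_ok) {
    codons <- substring(toupper(coding),
                        seq(1L, nchar(coding), 3L), seq(3L, nchar(coding), 3L))
    if (design$kind == "scanning" && !is.na(oligo$varied_position)) {
      i <- oligo$varied_position
      pattern_ok <- codons[i] == design$degenerate_codon
      fixed <- codons[-i]
      ref <- toupper(design$reference_codons)[-i]
      reference_ok <- all(fixed == ref)
    } else if (design$kind == "degenerate") {
      cf <- design$central_fixed
      pattern_ok <- all(codons[-cf$position] == design$degenerate_codon) &&
        codons[cf$position] == toupper(cf$codon)
    }
  }
  checks <- list(five_flank = has5, three_flank = has3, frame = in_frame,
                 coding_length = length_ok, degenerate_pattern = pattern_ok,
                 reference_identity = reference_ok)
  c(checks, list(ok = all(unlist(checks))))
}

#' Enumerate the peptides one NNS cassette can encode
#'
#' Expands the 32 NNS codons at the varied position of a scanning template and
#' translates; used to verify that a cassette yields the reference residue,
#' the 19 substitutions, and the amber variant.
#'
#' @param oligo a scanning `oligo_template` with a `varied_position`.
#' @param design the scanning [library_design()].
#' @return character vector of distinct peptides (amber as `*`).
#' @export
expand_scanning_position <- function(oligo, design) {
  i <- oligo$varied_position
  if (is.na(i)) stop("oligo has no varied position")
  gc <- codon_lookup()
  res <- strsplit(design$reference_peptide, "")[[1]]
  unique(vapply(NNS_CODONS, function(cod) {
    r <- res
    r[i] <- if (cod == "TAG") "*" else gc[[cod]]
    paste(r, collapse = "")
  }, character(1)))
}

#' Write an oligo pool to FASTA and CSV
#'
#' @param oligos list of `oligo_template`s.
#' @param fasta,csv output paths (either may be `NULL` to skip).
#' @return invisibly, the data frame written to CSV.
#' @export
write_oligo_pool <- function(oligos, fasta = NULL, csv = NULL) {
  df <- data.frame(design_id = vapply(oligos, `[[`, "", "design_id"),
                   varied_position = vapply(oligos, `[[`, NA_integer_,
                                            "varied_position"),
                   sequence = vapply(oligos, `[[`, "", "sequence"),
                   stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    writeLines(as.vector(rbind(paste0(">", df$design_id), df$sequence)), fasta)
  }
  if (!is.null(csv)) {
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}
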