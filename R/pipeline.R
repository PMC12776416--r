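# Pipeline: tie design -> process -> count -> score into one reproducible
# run with explicit sorted/unsorted pairing, a run manifest, and desk-scale
# fixture generation.

#' Build and validate a run configuration
#'
#' @param design a [library_design()].
#' @param samples data.frame with columns `sample_id`, `role` (`"sorted"` /
#'   `"unsorted"`), `r1`, `r2` (FASTQ paths), and `match` (for sorted
#'   samples, the `sample_id` of the matched unsorted sample; pairing is
#'   explicit, never positional).
#' @param pseudocount,log_base,filter_mode,logo_cutoff scoring options.
#' @param seed integer seed echoed into the manifest.
#' @return a validated `run_config`.
#' @export
run_config <- function(design, samples, pseudocount = 0, log_base = NULL,
                       filter_mode = "full", logo_cutoff = 3, seed = 1L) {
  stopifnot(inherits(design, "library_design"), is.data.frame(samples))
  need <- c("sample_id", "role", "r1", "r2", "match")
  if (!all(need %in% names(samples)))
    stop("samples needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in manifest")
  sorted <- samples[samples$role == "sorted", ]
  if (nrow(sorted) == 0L) stop("no sorted samples in manifest")
  for (i in seq_len(nrow(sorted))) {
    m <- sorted$match[i]
    if (is.na(m) || !nzchar(m))
      stop("sorted sample ", sorted$sample_id[i], " has no matched unsorted sample")
    hit <- samples$sample_id == m & samples$role == "unsorted"
    if (sum(hit) != 1L)
      stop("sorted sample ", sorted$sample_id[i],
           " must name exactly one unsorted sample (got ", sum(hit), ")")
  }
  for (f in c(samples$r1, samples$r2))
    if (!is.na(f) && !file.exists(f)) stop("unresolvable path: ", f)
  log_base <- log_base %||% if (design$kind == "scanning") 10 else 2
  structure(list(design = design, samples = samples,
                 pseudocount = pseudocount, log_base = log_base,
                 filter_mode = filter_mode, logo_cutoff = logo_cutoff,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file holds the design (kind, peptide_length, and kind-specific
#' fields), the sample manifest, and the scoring options; relative FASTQ
#' paths are resolved against the file's directory.
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  d <- y$design
  design <- library_design(
    kind = d$kind,
    peptide_length = d$peptide_length %||% 11L,
    reference_peptide = d$reference_peptide,
    reference_codons = unlist(d$reference_codons),
    members = unlist(d$members))
  samples <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(sample_id = s$sample_id, role = s$role,
               r1 = file.path(base, s$r1), r2 = file.path(base, s$r2),
               match = s$match %||% NA_character_,
               stringsAsFactors = FALSE)))
  run_config(design, samples,
             pseudocount = y$scoring$pseudocount %||% 0,
             log_base = y$scoring$log_base,
             filter_mode = y$scoring$filter_mode %||% "full",
             logo_cutoff = y$scoring$logo_cutoff %||% 3,
             seed = y$seed %||% 1L)
}

#' Run the full screen-analysis pipeline
#'
#' Processes every referenced sample once (merge, extract, translate),
#' counts, and scores each sorted/unsorted pair with the scheme matching the
#' design kind: per-peptide enrichment tables for defined libraries (plus
#' logo input tables), position-residue enrichment matrices for degenerate
#' libraries, and wild-type-normalized matrices for scanning libraries.
#' All tables, QC stats and a manifest with content digests are written
#' under `out_dir`.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed).
#' @param figures also write heatmap PNGs (requires ggplot2; default FALSE).
#' @return invisibly, the result bundle: per-pair scores, QC, manifest.
#' @export
run_pipeline <- function(config, out_dir, figures = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design
  samples <- config$samples
  processed <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    res <- tryCatch(
      process_sample(samples$r1[i], samples$r2[i], design, sample_id = sid),
      error = function(e) stop("stage process failed for sample ", sid, ": ",
                               conditionMessage(e)))
    processed[[sid]] <- res
    write_sample_output(res,
                        tsv = file.path(out_dir, paste0(sid, "_peptides.tsv")),
                        qc_json = file.path(out_dir, paste0(sid, "_qc.json")))
  }
  sorted_rows <- which(samples$role == "sorted")
  pairs <- list()
  for (i in sorted_rows) {
    sid <- samples$sample_id[i]; uid <- samples$match[i]
    rs <- processed[[sid]]$records; ru <- processed[[uid]]$records
    pair_id <- paste0(sid, "_vs_", uid)
    out <- list(sorted = sid, unsorted = uid)
    if (design$kind == "defined") {
      ts <- count_peptides(rs, whitelist = design$members, sample_id = sid,
                           sorted_flag = TRUE)
      tu <- count_peptides(ru, whitelist = design$members, sample_id = uid)
      et <- enrichment_scores(ts, tu, pseudocount = config$pseudocount)
      write_enrichment_tsv(et, file.path(out_dir, paste0(pair_id, "_enrichment.tsv")))
      logo <- select_for_logo(et, cutoff = config$logo_cutoff)
      if (!is.null(logo$foreground_pfm))
        utils::write.table(logo$foreground_pfm,
                           file.path(out_dir, paste0(pair_id, "_logo_fg.tsv")),
                           sep = "\t", quote = FALSE)
      out$enrichment <- et
      out$logo <- logo
    } else if (design$kind == "degenerate") {
      center <- design$central_fixed$position
      ms <- position_residue_counts(rs, design$peptide_length,
                                    filter_mode = config$filter_mode,
                                    center = center)
      mu <- position_residue_counts(ru, design$peptide_length,
                                    filter_mode = config$filter_mode,
                                    center = center)
      pe <- position_enrichment(ms, mu, pseudocount = config$pseudocount)
      write_matrix_tsv(ms, file.path(out_dir, paste0(sid, "_counts.tsv")), sid)
      write_matrix_tsv(mu, file.path(out_dir, paste0(uid, "_counts.tsv")), uid)
      utils::write.table(pe$log2,
                         file.path(out_dir, paste0(pair_id, "_log2_enrichment.tsv")),
                         sep = "\t", quote = FALSE)
      out$position_enrichment <- pe
      if (figures) save_heatmap(pe, file.path(out_dir, paste0(pair_id, "_heatmap.png")), 2)
    } else {
      ts <- count_peptides(rs, sample_id = sid, sorted_flag = TRUE)
      tu <- count_peptides(ru, sample_id = uid)
      ss <- scanning_matrix_counts(ts, design$reference_peptide)
      su <- scanning_matrix_counts(tu, design$reference_peptide)
      se <- scanning_enrichment(ss, su, pseudocount = config$pseudocount)
      write_matrix_tsv(ss, file.path(out_dir, paste0(sid, "_counts.tsv")), sid)
      write_matrix_tsv(su, file.path(out_dir, paste0(uid, "_counts.tsv")), uid)
      utils::write.table(se$log10,
                         file.path(out_dir, paste0(pair_id, "_log10_normalized.tsv")),
                         sep = "\t", quote = FALSE)
      out$scanning_enrichment <- se
      if (figures) save_heatmap(se, file.path(out_dir, paste0(pair_id, "_heatmap.png")), 10)
    }
    pairs[[pair_id]] <- out
  }
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pepdisplay")),
    seed = config$seed,
    design_kind = design$kind,
    peptide_length = design$peptide_length,
    options = list(pseudocount = config$pseudocount,
                   log_base = config$log_base,
                   filter_mode = config$filter_mode,
                   logo_cutoff = config$logo_cutoff),
    inputs = lapply(seq_len(nrow(samples)), function(i) list(
      sample_id = samples$sample_id[i], role = samples$role[i],
      r1 = samples$r1[i], r1_md5 = unname(tools::md5sum(samples$r1[i])),
      r2 = samples$r2[i], r2_md5 = unname(tools::md5sum(samples$r2[i])))),
    outputs = lapply(files, function(f) list(
      file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pairs = pairs,
                 qc = lapply(processed, `[[`, "qc"),
                 manifest = manifest,
                 out_dir = out_dir))
}

save_heatmap <- function(x, path, log_base) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible(NULL))
  p <- plot_enrichment_heatmap(x, log_base = log_base)
  try(ggplot2::ggsave(path, p, width = 8, height = 6, dpi = 150),
      silent = TRUE)
  invisible(path)
}

fixture_scenarios <- c("defined-10", "degenerate-small", "scanning-11mer",
                       "amber")

#' Generate a desk-scale simulated screen fixture
#'
#' Builds a design, a ground-truth specificity model, sorted/unsorted FASTQ
#' sample pairs and truth tables under `dir` via the screen simulator.
#' Scenarios: `defined-10` (ten defined 11-mers), `degenerate-small`
#' (X5-Y-X5), `scanning-11mer` (Src-consensus scanning), `amber` (degenerate
#' with a 3x non-canonical preference at +1). Identical seed and scenario
#' give identical directories.
#'
#' @param scenario one of `"defined-10"`, `"degenerate-small"`,
#'   `"scanning-11mer"`, `"amber"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @param reads_per_sample,n_cells optional size overrides.
#' @return list with design, model, config, file paths and truth counts.
#' @export
make_fixtures <- function(scenario, seed = 1L, dir = tempfile("fixture"),
                          reads_per_sample = NULL, n_cells = NULL) {
  if (!scenario %in% fixture_scenarios)
    stop("unknown scenario: ", scenario, " (use one of ",
         paste(fixture_scenarios, collapse = ", "), ")")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  src_ref <- "PDECIYDMFPF"
  src_codons <- c("ccg", "gat", "gaa", "tgc", "att", "tat",
                  "gat", "atg", "ttt", "ccg", "ttt")
  amber_bonus <- NULL
  if (scenario == "defined-10") {
    members <- c("PDECIYDMFPF", "AAAAAYAAAAA", "GGGGGYGGGGG", "PDECIFDMFPF",
                 "EEEIIYGEFEA", "KKKKKYKKKKK", "DEDEDYDEDED", "LPQRSYTVWCA",
                 "MNHFAYSPGIK", "AAAAAAAAAAA")
    design <- library_design("defined", peptide_length = 11L, members = members)
    model_seed <- seed + 100L
  } else if (scenario == "scanning-11mer") {
    design <- library_design("scanning", peptide_length = 11L,
                             reference_peptide = src_ref,
                             reference_codons = src_codons)
    model_seed <- seed + 200L
  } else {
    design <- library_design("degenerate", peptide_length = 11L)
    model_seed <- seed + 300L
    if (scenario == "amber") {
      center <- design$central_fixed$position
      amber_bonus <- setNames(log(3), as.character(center + 1L))
    }
  }
  model <- random_specificity_model(design, sd = 0.4,
                                    amber_bonus = amber_bonus,
                                    seed = model_seed)
  config <- simulation_config(
    design,
    n_cells = n_cells %||% switch(scenario,
                                  "defined-10" = 5e3, "scanning-11mer" = 1e4,
                                  2e4),
    reads_per_sample = reads_per_sample %||% 2e4,
    sequencing_error_rate = 0, seed = seed)
  pop <- sample_library(config)
  model$exposure_time <- calibrate_exposure(model, pop)
  sel <- simulate_selection(pop, model, config)
  sorted_files <- emit_fastq(sel$sorted, config,
                             file.path(dir, "sorted"), seed_offset = 0L)
  unsorted_files <- emit_fastq(sel$unsorted, config,
                               file.path(dir, "unsorted"), seed_offset = 1L)
  jsonlite::write_json(list(scenario = scenario, seed = seed,
                            weights = model$weights,
                            baseline_rate = model$baseline_rate,
                            exposure_time = model$exposure_time),
                       file.path(dir, "model.json"), digits = NA)
  yaml::write_yaml(list(kind = design$kind,
                        peptide_length = design$peptide_length,
                        reference_peptide = design$reference_peptide,
                        reference_codons = design$reference_codons,
                        members = design$members),
                   file.path(dir, "design.yaml"))
  list(design = design, model = model, config = config, dir = dir,
       sorted = sorted_files, unsorted = unsorted_files,
       population = pop, selection = sel)
}
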