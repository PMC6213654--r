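# Stage runners over a validated run configuration. Each stage reads its
# inputs from disk, writes its outputs to disk (so stages can be re-run
# and chained), logs parameter values and summary counts to stderr, and
# is byte-identical across re-runs at a fixed seed.

#' Build and validate a run configuration
#'
#' @param outdir Output directory (created if needed); inputs are read
#'   from / written to `<outdir>/inputs`.
#' @param seed Integer seed used by every stochastic stage.
#' @param preset Scenario preset for [run_simulate()] (see
#'   [simulate_experiment()]).
#' @param cutoff Duplex penalty cutoff for target prediction.
#' @param weights A [duplex_weights()] configuration.
#' @param window Degradome validation half-window (nt).
#' @param median_include_zeros Median convention for
#'   [classify_category()].
#' @param gene_thresholds,mirna_thresholds Lists with `min_abs_log2fc`
#'   and `max_p` (defaults from [de_thresholds()]).
#' @param comparisons List of `c(numerator, denominator)` condition
#'   pairs.
#' @param count_convention Tag-count header dialect for
#'   [read_tag_fasta()].
#' @param sim Named list forwarded to [simulate_experiment()]'s `params`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L,
                       preset = c("baseline", "noisy", "null"),
                       cutoff = 4, weights = duplex_weights(),
                       window = 1L, median_include_zeros = FALSE,
                       gene_thresholds = de_thresholds("gene"),
                       mirna_thresholds = de_thresholds("mirna"),
                       comparisons = default_comparisons(),
                       count_convention = "suffix_xN", sim = list()) {
  preset <- match.arg(preset)
  assert_string(outdir, "outdir")
  seed <- assert_count(seed, "seed", min = 0)
  if (cutoff <= 0) stopf("cutoff must be > 0")
  if (window < 0) stopf("window must be >= 0")
  for (th in list(gene_thresholds, mirna_thresholds)) {
    if (!all(c("min_abs_log2fc", "max_p") %in% names(th))) {
      stopf("thresholds need min_abs_log2fc and max_p")
    }
  }
  cfg <- list(outdir = outdir, seed = seed, preset = preset,
              cutoff = cutoff, weights = unclass(weights),
              window = as.integer(window),
              median_include_zeros = isTRUE(median_include_zeros),
              gene_thresholds = gene_thresholds,
              mirna_thresholds = mirna_thresholds,
              comparisons = comparisons,
              count_convention = count_convention, sim = sim)
  class(cfg) <- "run_config"
  cfg
}

cfg_path <- function(cfg, ...) file.path(cfg$outdir, ...)

log_msg <- function(...) message("[paretarget] ", sprintf(...))

write_config <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), cfg_path(cfg, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run pipeline stages
#'
#' `run_simulate()` generates a synthetic experiment and writes every
#' pipeline input under `<outdir>/inputs` (FASTA transcriptome, miRNA
#' and tag sets, two count matrices, design table, ground-truth JSON).
#' `run_predict()` scans the transcriptome and writes `predictions.tsv`;
#' `run_degradome()` maps tags, validates predicted sites and writes
#' `cleavage_calls.tsv` + `mapping_stats.tsv`; `run_de()` writes one DE
#' table per layer and comparison; `run_integrate()` joins everything
#' into `pairs.tsv` and a run summary; `run_all()` chains the five
#' stages.
#'
#' @param cfg A [run_config()].
#' @return Each stage returns its main result invisibly; `run_all()`
#'   returns a summary list (pair table, category tally, mapping report,
#'   precision/recall against ground truth when available).
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg_path(cfg, "inputs"), recursive = TRUE,
              showWarnings = FALSE)
  write_config(cfg)
  exp <- do.call(simulate_experiment,
                 c(list(preset = cfg$preset, seed = cfg$seed),
                   cfg$sim))
  inp <- function(f) cfg_path(cfg, "inputs", f)
  write_fasta(exp$transcripts, inp("transcripts.fa"))
  write_fasta(exp$mirnas, inp("mirnas.fa"))
  tag_rec <- data.frame(
    id = sprintf("tag%05d_x%d", seq_len(nrow(exp$tags)), exp$tags$count),
    sequence = exp$tags$sequence)
  write_fasta(tag_rec, inp("tags.fa"))
  write_count_matrix(exp$gene_counts, inp("gene_counts.tsv"))
  write_count_matrix(exp$mirna_counts, inp("mirna_counts.tsv"))
  write_tsv(data.frame(sample = names(exp$design),
                       condition = unname(exp$design)),
            inp("design.tsv"))
  write_ground_truth(exp$truth, inp("ground_truth.json"))
  log_msg("simulate[%s]: %d transcripts, %d miRNAs, %d distinct tags, %d planted pairs",
          cfg$preset, nrow(exp$transcripts), nrow(exp$mirnas),
          nrow(exp$tags), nrow(exp$truth$planted_pairs))
  invisible(exp)
}

read_inputs <- function(cfg) {
  inp <- function(f) cfg_path(cfg, "inputs", f)
  for (f in c("transcripts.fa", "mirnas.fa", "tags.fa", "gene_counts.tsv",
              "mirna_counts.tsv", "design.tsv")) {
    if (!file.exists(inp(f))) {
      stopf("missing input %s (run run_simulate() or provide inputs)",
            inp(f))
    }
  }
  transcripts <- read_transcript_fasta(inp("transcripts.fa"))
  design_df <- utils::read.delim(inp("design.tsv"),
                                 stringsAsFactors = FALSE)
  list(transcripts = transcripts,
       mirnas = read_mirna_fasta(inp("mirnas.fa")),
       tags = read_tag_fasta(inp("tags.fa"), cfg$count_convention),
       gene_counts = read_count_matrix(
         inp("gene_counts.tsv"),
         setNames(transcripts$length, transcripts$id)),
       mirna_counts = read_count_matrix(inp("mirna_counts.tsv")),
       design = setNames(design_df$condition, design_df$sample))
}

#' @rdname run_simulate
#' @export
run_predict <- function(cfg) {
  x <- read_inputs(cfg)
  w <- do.call(duplex_weights, cfg$weights)
  hits <- predict_targets(x$mirnas, x$transcripts, cfg$cutoff, w)
  write_tsv(hits, cfg_path(cfg, "predictions.tsv"))
  log_msg("predict: %d candidate sites at cutoff %.2f", nrow(hits),
          cfg$cutoff)
  invisible(hits)
}

#' @rdname run_simulate
#' @export
run_degradome <- function(cfg) {
  x <- read_inputs(cfg)
  pred_path <- cfg_path(cfg, "predictions.tsv")
  if (!file.exists(pred_path)) stopf("run run_predict() first")
  hits <- utils::read.delim(pred_path, stringsAsFactors = FALSE)
  mapped <- map_tags(x$tags, x$transcripts)
  calls <- validate_targets(hits, mapped$profiles, cfg$window,
                            cfg$median_include_zeros)
  write_tsv(calls, cfg_path(cfg, "cleavage_calls.tsv"))
  mrep <- mapping_report(mapped$stats, nrow(x$transcripts),
                         mapped$stats$total_reads)
  write_tsv(data.frame(metric = names(unlist(mrep)),
                       value = unname(unlist(mrep))),
            cfg_path(cfg, "mapping_stats.tsv"))
  tally <- summarize_categories(calls)
  log_msg("degradome: %d/%d reads mapped; %d validated sites (categories %s)",
          mapped$stats$mapped_reads, mapped$stats$total_reads,
          tally$total, paste(tally$counts, collapse = "/"))
  invisible(list(calls = calls, stats = mapped$stats, report = mrep))
}

#' @rdname run_simulate
#' @export
run_de <- function(cfg) {
  x <- read_inputs(cfg)
  for (comp in cfg$comparisons) {
    for (lbl in comp) {
      if (!any(x$design == lbl)) {
        stopf("comparison condition '%s' absent from design", lbl)
      }
    }
  }
  out <- list()
  for (comp in cfg$comparisons) {
    lbl <- paste(comp, collapse = "_vs_")
    genes <- call_de(x$gene_counts, x$design, comp, mode = "gene",
                     thresholds = cfg$gene_thresholds)
    mirs <- call_de(x$mirna_counts, x$design, comp, mode = "mirna",
                    thresholds = cfg$mirna_thresholds)
    write_tsv(genes, cfg_path(cfg, sprintf("de_gene_%s.tsv", lbl)))
    write_tsv(mirs, cfg_path(cfg, sprintf("de_mirna_%s.tsv", lbl)))
    out[[lbl]] <- list(genes = genes, mirnas = mirs)
    log_msg("de[%s]: %d DEGs, %d DEmiRs", lbl, sum(genes$significant),
            sum(mirs$significant))
  }
  invisible(out)
}

#' @rdname run_simulate
#' @export
run_integrate <- function(cfg) {
  calls_path <- cfg_path(cfg, "cleavage_calls.tsv")
  if (!file.exists(calls_path)) stopf("run run_degradome() first")
  calls <- utils::read.delim(calls_path, stringsAsFactors = FALSE)
  pairs <- list()
  for (comp in cfg$comparisons) {
    lbl <- paste(comp, collapse = "_vs_")
    genes <- utils::read.delim(
      cfg_path(cfg, sprintf("de_gene_%s.tsv", lbl)),
      stringsAsFactors = FALSE)
    mirs <- utils::read.delim(
      cfg_path(cfg, sprintf("de_mirna_%s.tsv", lbl)),
      stringsAsFactors = FALSE)
    pairs[[lbl]] <- join_pairs(mirs, genes, calls, comp)
  }
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  parts <- flag_reversed(pairs)
  write_pairs_table(pairs, cfg_path(cfg, "pairs.tsv"))
  summary_lines <- c(
    sprintf("integrated pairs: %d", nrow(pairs)),
    sprintf("reversed pairs: %d", nrow(parts$reversed)),
    sprintf("same-direction pairs: %d", nrow(parts$same_direction)))
  writeLines(summary_lines, cfg_path(cfg, "summary.txt"))
  log_msg("integrate: %d pairs (%d reversed)", nrow(pairs),
          nrow(parts$reversed))
  invisible(pairs)
}

#' @rdname run_simulate
#' @export
run_all <- function(cfg) {
  exp <- run_simulate(cfg)
  run_predict(cfg)
  deg <- run_degradome(cfg)
  run_de(cfg)
  pairs <- run_integrate(cfg)
  pr <- pair_precision_recall(pairs, exp$truth$planted_pairs)
  log_msg("closed loop: precision %.3f, recall %.3f (%d/%d pairs)",
          pr$precision, pr$recall, pr$n_correct, pr$n_planted)
  invisible(list(pairs = pairs,
                 categories = summarize_categories(deg$calls),
                 mapping = deg$report,
                 truth = exp$truth,
                 precision_recall = pr))
}
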