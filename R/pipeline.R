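# End-to-end screen: segregation filter -> coding-effect annotation ->
# severity/conservation/domain prioritization, with a funnel summary and
# reproducible on-disk outputs.

#' Run the full candidate-gene screen
#'
#' Executes the pipeline on a variant table: (1) classify every variant's
#' three-pool segregation signature and keep the candidates, (2) annotate
#' candidate substitutions against the CDS catalogue (candidates without a
#' CDS mapping pass through flagged `noncoding`), (3) score severity,
#' conservation and domain overlap, and rank. Given identical inputs the
#' output files are byte-identical across runs; timestamps appear only in
#' the run manifest.
#'
#' @param variants A pooled variant data frame, a path to a TSV/VCF, or a
#'   [simulate_dataset()] result (in which case `cds`, `alignments` and
#'   `domains` default to the simulated ones).
#' @param cds CDS catalogue (named character vector, list of
#'   [cds_model()], `DNAStringSet`, or FASTA path). `NULL` skips
#'   annotation, leaving all candidates `noncoding`.
#' @param alignments Named list of per-gene ortholog alignments, or a
#'   directory containing `aln_<gene>.fasta` files, or `NULL`.
#' @param domains Domain data frame, path to a domain TSV, or `NULL`.
#' @param thresholds A [filter_thresholds()].
#' @param conservative_below,radical_above Severity boundaries.
#' @param out_dir If non-`NULL`, write `calls.tsv`, `effects.tsv`,
#'   `report.tsv`, `funnel.json` and `manifest.jsonl` there.
#' @return Object of class `selfseg_pipeline`: list with `report` (ranked
#'   candidates), `calls`, `effects`, `funnel` (named counts) and
#'   `thresholds`.
#' @export
run_pipeline <- function(variants, cds = NULL, alignments = NULL,
                         domains = NULL,
                         thresholds = filter_thresholds(),
                         conservative_below = 100, radical_above = 150,
                         out_dir = NULL) {
  if (inherits(variants, "selfing_simulation")) {
    sim <- variants
    variants <- sim$variants
    if (is.null(cds)) cds <- sim$cds
    if (is.null(alignments)) alignments <- sim$alignments
    if (is.null(domains)) domains <- sim$domains
  }
  if (is.character(variants) && length(variants) == 1)
    variants <- read_variants(variants)
  if (is.character(domains) && length(domains) == 1)
    domains <- read_domains(domains)
  if (is.character(alignments) && length(alignments) == 1 &&
      dir.exists(alignments)) {
    files <- list.files(alignments, pattern = "^aln_.*\\.fasta$",
                        full.names = TRUE)
    alignments <- stats::setNames(
      lapply(files, read_alignment),
      sub("^aln_(.*)\\.fasta$", "\\1", basename(files)))
  }

  screened <- tryCatch(filter_candidates(variants, thresholds),
                       error = function(e)
                         stop(sprintf("segregation stage failed: %s",
                                      conditionMessage(e)), call. = FALSE))
  cand <- screened$candidates

  if (!is.null(cds) && nrow(cand) > 0) {
    parts <- tryCatch(partition_by_coding(cand, cds),
                      error = function(e)
                        stop(sprintf("annotation stage failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  } else {
    parts <- list(effects = data.frame(), noncoding = cand,
                  class_counts = stats::setNames(
                    c(0L, 0L, 0L, 0L, nrow(cand)), .EFFECT_CLASSES))
    if (nrow(cand) > 0)
      parts$effects <- partition_by_coding(
        cand[0, , drop = FALSE],
        stats::setNames(character(0), character(0)))$effects
  }

  report <- tryCatch(
    prioritize_candidates(parts, alignments = alignments,
                          domains = domains,
                          conservative_below = conservative_below,
                          radical_above = radical_above),
    error = function(e)
      stop(sprintf("prioritization stage failed: %s",
                   conditionMessage(e)), call. = FALSE))

  funnel <- c(screened$funnel,
              coding = sum(parts$class_counts[
                setdiff(.EFFECT_CLASSES, "noncoding")]),
              parts$class_counts,
              ranked = nrow(report))
  funnel <- stats::setNames(as.integer(funnel), names(funnel))

  out <- structure(list(report = report, calls = screened$calls,
                        effects = parts$effects, funnel = funnel,
                        thresholds = thresholds),
                   class = "selfseg_pipeline")
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

.write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x$calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(x$effects, file.path(out_dir, "effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(x$report, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(as.list(x$funnel),
                       file.path(out_dir, "funnel.json"),
                       auto_unbox = TRUE)
  manifest <- list(tool = "selfseg",
                   version = as.character(utils::packageVersion("selfseg")),
                   time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   thresholds = unclass(x$thresholds))
  cat(jsonlite::toJSON(manifest, auto_unbox = TRUE), "\n", sep = "",
      file = file.path(out_dir, "manifest.jsonl"), append = TRUE)
  invisible(out_dir)
}

#' @export
print.selfseg_pipeline <- function(x, ...) {
  cat("selfseg screen\n")
  for (k in names(x$funnel))
    cat(sprintf("  %-28s %d\n", k, x$funnel[[k]]))
  if (nrow(x$report) > 0) {
    top <- x$report[1, ]
    cat(sprintf("  top candidate: %s (%s, %s%s%s, rank 1)\n",
                top$variant_id,
                ifelse(is.na(top$gene_id), "noncoding", top$gene_id),
                ifelse(is.na(top$ref_aa), "", top$ref_aa),
                ifelse(is.na(top$codon_index), "", top$codon_index),
                ifelse(is.na(top$alt_aa), "", top$alt_aa)))
  }
  invisible(x)
}

#' Load a pipeline configuration from YAML
#'
#' Schema (all keys optional unless a stage needs them):
#' \preformatted{
#' variants: path.tsv | path.vcf
#' cds: cds.fasta
#' alignments: dir/            # containing aln_<gene>.fasta files
#' domains: domains.tsv
#' out_dir: out/
#' seed: 1
#' thresholds:
#'   min_mutant_freq: 0.95
#'   max_wt_freq: 0.05
#'   min_depth: 10
#'   sibling_alpha: 0.01
#'   sibling_expected_freq: 0.3333333
#'   sibling_pool_size: 12
#' severity:
#'   conservative_below: 100
#'   radical_above: 150
#' simulate:                   # pedigree_config() arguments
#'   n_background_variants: 500
#' }
#'
#' @param path YAML file.
#' @return Named list with `thresholds` realised as
#'   [filter_thresholds()] and `simulate` as [pedigree_config()] (when
#'   present).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$thresholds))
    cfg$thresholds <- do.call(filter_thresholds, cfg$thresholds)
  if (!is.null(cfg$simulate)) {
    if (!is.null(cfg$seed) && is.null(cfg$simulate$seed))
      cfg$simulate$seed <- cfg$seed
    cfg$simulate <- do.call(pedigree_config, cfg$simulate)
  }
  cfg
}
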