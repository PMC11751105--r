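# Codon-level coding-effect annotation of point substitutions on a CDS.
# Coordinates are 1-based CDS positions counted from the A of the start
# codon, so nucleotide 574 is the first base of codon 192. Annotation
# operates on the coding strand only: variants reported on the genomic
# minus strand must be reverse-complemented upstream.

.EFFECT_CLASSES <- c("synonymous", "missense", "nonsense", "stop_loss",
                     "noncoding")

#' Build a CDS model
#'
#' @param gene_id Gene identifier.
#' @param sequence In-frame coding sequence (A/C/G/T only; ambiguity codes
#'   are rejected). Length must be divisible by 3; a missing ATG start
#'   raises a warning, not an error.
#' @return Object of class `cds_model` with `gene_id`, `sequence`,
#'   `n_codons`.
#' @export
cds_model <- function(gene_id, sequence) {
  if (!is.character(gene_id) || length(gene_id) != 1 || !nzchar(gene_id))
    stop("'gene_id' must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1)
    stop("'sequence' must be a single string")
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop(sprintf("CDS of %s contains characters other than A/C/G/T (ambiguity codes are not supported)",
                 gene_id))
  if (nchar(sequence) %% 3 != 0)
    stop(sprintf("CDS of %s has length %d, not divisible by 3",
                 gene_id, nchar(sequence)))
  if (substr(sequence, 1, 3) != "ATG")
    warning(sprintf("CDS of %s does not begin with ATG", gene_id))
  structure(list(gene_id = gene_id, sequence = sequence,
                 n_codons = nchar(sequence) %/% 3L),
            class = "cds_model")
}

#' Map a CDS nucleotide position to its codon
#'
#' @param cds_pos 1-based CDS position(s).
#' @param cds Optional [cds_model()] used for range checking.
#' @return List with integer vectors `codon_index` (`ceiling(cds_pos / 3)`)
#'   and `pos_in_codon` (1..3).
#' @examples
#' cds_position_to_codon(574)  # codon 192, first base
#' @export
cds_position_to_codon <- function(cds_pos, cds = NULL) {
  if (!is.numeric(cds_pos) || length(cds_pos) < 1 || anyNA(cds_pos) ||
      any(cds_pos != round(cds_pos)) || any(cds_pos < 1))
    stop("'cds_pos' must be positive integers")
  cds_pos <- as.integer(cds_pos)
  if (!is.null(cds)) {
    if (!inherits(cds, "cds_model")) stop("'cds' must be a cds_model")
    bad <- cds_pos > nchar(cds$sequence)
    if (any(bad))
      stop(sprintf("CDS position %d is beyond the end of %s (%d nt)",
                   cds_pos[bad][1], cds$gene_id, nchar(cds$sequence)))
  }
  list(codon_index = (cds_pos - 1L) %/% 3L + 1L,
       pos_in_codon = (cds_pos - 1L) %% 3L + 1L)
}

#' Translate codons under the standard genetic code
#'
#' @param codon Character vector of unambiguous trinucleotides.
#' @return One-letter amino-acid codes; `"*"` for stop codons.
#' @export
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) < 1 || anyNA(codon))
    stop("'codon' must be a character vector")
  codon <- toupper(codon)
  if (any(nchar(codon) != 3) || any(grepl("[^ACGT]", codon)))
    stop("codons must be exactly 3 unambiguous bases (A/C/G/T)")
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Translate a full CDS codon by codon
#'
#' @param sequence In-frame nucleotide string (length divisible by 3).
#' @param strip_stop Drop a single trailing stop symbol if present.
#' @return Amino-acid string.
#' @export
translate_cds <- function(sequence, strip_stop = TRUE) {
  if (nchar(sequence) %% 3 != 0) stop("sequence length not divisible by 3")
  codons <- substring(sequence, seq(1, nchar(sequence), 3),
                      seq(3, nchar(sequence), 3))
  aa <- paste(translate_codon(codons), collapse = "")
  if (strip_stop) aa <- sub("\\*$", "", aa)
  aa
}

#' Annotate a single-nucleotide substitution on a CDS
#'
#' Substitutes `alt_base` at `cds_pos`, translates the affected codon and
#' classifies the consequence: `synonymous` (amino acid unchanged),
#' `nonsense` (gain of stop), `stop_loss` (loss of stop) or `missense`.
#' A mismatch between `ref_base` and the CDS is a hard error — silent
#' strand or offset bugs are the dominant failure mode in effect
#' annotation, so no attempt is made to continue.
#'
#' @param cds A [cds_model()] (a plain sequence string is accepted and
#'   wrapped).
#' @param cds_pos 1-based CDS position of the substitution.
#' @param ref_base,alt_base Single reference/alternate bases; indels and
#'   multi-nucleotide variants are rejected.
#' @return Object of class `coding_effect` with fields `gene_id`,
#'   `cds_pos`, `ref_base`, `alt_base`, `codon_index`, `pos_in_codon`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect_class`.
#' @examples
#' cds <- cds_model("demo", paste0("ATG", strrep("CGT", 3)))
#' annotate_substitution(cds, 4, "C", "T")  # arginine -> cysteine
#' @export
annotate_substitution <- function(cds, cds_pos, ref_base, alt_base) {
  if (is.character(cds)) cds <- cds_model("cds", cds)
  if (!inherits(cds, "cds_model")) stop("'cds' must be a cds_model")
  for (b in list(ref_base, alt_base))
    if (!is.character(b) || length(b) != 1 || !nzchar(b))
      stop("'ref_base' and 'alt_base' must be single bases")
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (nchar(ref_base) != 1 || nchar(alt_base) != 1)
    stop("only single-nucleotide substitutions are supported (no indels or MNVs)")
  if (grepl("[^ACGT]", ref_base) || grepl("[^ACGT]", alt_base))
    stop("'ref_base' and 'alt_base' must be A, C, G or T")
  if (ref_base == alt_base)
    stop("'ref_base' and 'alt_base' must differ")
  loc <- cds_position_to_codon(cds_pos, cds)
  found <- substr(cds$sequence, cds_pos, cds_pos)
  if (found != ref_base)
    stop(sprintf("reference mismatch at CDS position %d of %s: CDS has %s, variant claims %s",
                 cds_pos, cds$gene_id, found, ref_base))
  start <- (loc$codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds$sequence, start, start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, loc$pos_in_codon, loc$pos_in_codon) <- alt_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "nonsense"
  else if (ref_aa == "*") "stop_loss"
  else "missense"
  structure(list(gene_id = cds$gene_id, cds_pos = as.integer(cds_pos),
                 ref_base = ref_base, alt_base = alt_base,
                 codon_index = loc$codon_index,
                 pos_in_codon = loc$pos_in_codon,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 effect_class = effect),
            class = "coding_effect")
}

#' @export
print.coding_effect <- function(x, ...) {
  cat(sprintf("%s c.%d%s>%s  %s%d%s (%s)\n", x$gene_id, x$cds_pos,
              x$ref_base, x$alt_base, x$ref_aa, x$codon_index, x$alt_aa,
              x$effect_class))
  invisible(x)
}

# Coerce a CDS catalogue (named character vector, DNAStringSet, list of
# cds_model, or FASTA path) to a named list of cds_model.
as_cds_catalogue <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(read_cds_fasta(x))
  if (methods::is(x, "DNAStringSet"))
    x <- stats::setNames(as.character(x), names(x))
  if (is.character(x)) {
    if (is.null(names(x))) stop("CDS catalogue must be named by gene_id")
    return(stats::setNames(
      lapply(names(x), function(g) cds_model(g, x[[g]])), names(x)))
  }
  if (is.list(x)) {
    if (!all(vapply(x, inherits, logical(1), "cds_model")))
      stop("CDS catalogue list must contain cds_model objects")
    return(x)
  }
  stop("unsupported CDS catalogue")
}

#' Partition variants into coding effects and noncoding pass-through
#'
#' Variants with a `gene_id`/`cds_pos` mapping are annotated against the
#' CDS catalogue; the rest pass through with `effect_class = "noncoding"`.
#' A variant mapped to more than one CDS record (repeated `variant_id`
#' rows) is annotated against each and flagged with its multiplicity.
#'
#' @param variants Data frame with at least `variant_id`, `ref`, `alt` and
#'   the mapping columns `gene_id`, `cds_pos` (`NA` for noncoding).
#' @param cds_catalogue Named character vector, `DNAStringSet`, list of
#'   [cds_model()] or FASTA path.
#' @return List with `effects` (one row per coding annotation), `noncoding`
#'   (pass-through rows) and `class_counts` (named integer vector over all
#'   effect classes, including `noncoding`).
#' @export
partition_by_coding <- function(variants, cds_catalogue) {
  catalogue <- as_cds_catalogue(cds_catalogue)
  has_map <- !is.na(variants$gene_id) & !is.na(variants$cds_pos)
  coding <- variants[has_map, , drop = FALSE]
  noncoding <- variants[!has_map, , drop = FALSE]
  mult <- table(coding$variant_id)
  eff <- vector("list", nrow(coding))
  for (i in seq_len(nrow(coding))) {
    v <- coding[i, ]
    if (is.null(catalogue[[v$gene_id]]))
      stop(sprintf("variant %s maps to gene %s, absent from the CDS catalogue",
                   v$variant_id, v$gene_id))
    e <- annotate_substitution(catalogue[[v$gene_id]], v$cds_pos,
                               v$ref, v$alt)
    eff[[i]] <- data.frame(
      variant_id = v$variant_id, gene_id = v$gene_id,
      cds_pos = e$cds_pos, codon_index = e$codon_index,
      pos_in_codon = e$pos_in_codon,
      ref_aa = e$ref_aa, alt_aa = e$alt_aa,
      effect_class = e$effect_class,
      multiplicity = as.integer(mult[[v$variant_id]]),
      stringsAsFactors = FALSE)
  }
  effects <- if (length(eff)) do.call(rbind, eff) else
    data.frame(variant_id = character(0), gene_id = character(0),
               cds_pos = integer(0), codon_index = integer(0),
               pos_in_codon = integer(0), ref_aa = character(0),
               alt_aa = character(0), effect_class = character(0),
               multiplicity = integer(0), stringsAsFactors = FALSE)
  counts <- stats::setNames(
    c(vapply(setdiff(.EFFECT_CLASSES, "noncoding"),
             function(k) sum(effects$effect_class == k), integer(1)),
      nrow(noncoding)),
    .EFFECT_CLASSES)
  list(effects = effects, noncoding = noncoding, class_counts = counts)
}
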