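# Candidate prioritization: substitution severity (Grantham), residue
# conservation across an ortholog protein alignment, and overlap with
# annotated functional domains, combined into a deterministic ranking.

#' Per-column conservation profile of an ortholog protein alignment
#'
#' For each alignment column, the score is the fraction of non-reference
#' sequences whose residue is identical to the reference residue; a gap on
#' either side counts as a mismatch. With the small ortholog sets this
#' screen is built for (a handful of species), match-to-reference is
#' informative where column entropy is not.
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   lengths, `-` for gaps) or a `Biostrings::AAStringSet`.
#' @param reference_id Name of the reference record; must occur exactly
#'   once.
#' @return Object of class `conservation_profile` with `gene_id`,
#'   `scores` (one per column), `ref_columns` (alignment column of each
#'   ungapped reference residue) and `n_orthologs`.
#' @export
conservation_profile <- function(alignment, reference_id) {
  if (methods::is(alignment, "AAStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  if (!is.character(alignment) || is.null(names(alignment)))
    stop("'alignment' must be a named character vector or AAStringSet")
  if (length(alignment) < 2)
    stop("alignment needs the reference and at least one ortholog")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1)
    stop("aligned sequences must all have the same length")
  hits <- which(names(alignment) == reference_id)
  if (length(hits) != 1)
    stop(sprintf("reference '%s' must occur exactly once in the alignment (found %d)",
                 reference_id, length(hits)))
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  ref <- mat[hits, ]
  others <- mat[-hits, , drop = FALSE]
  match <- sweep(others, 2, ref, "==") & others != "-" &
    matrix(ref != "-", nrow(others), ncol(others), byrow = TRUE)
  scores <- colMeans(match)
  structure(list(gene_id = reference_id, scores = scores,
                 ref_columns = which(ref != "-"),
                 n_orthologs = nrow(others)),
            class = "conservation_profile")
}

#' Conservation score at a reference residue
#'
#' Maps an ungapped reference residue index to its alignment column
#' (skipping reference gap columns) and returns the fraction of orthologs
#' matching the reference there.
#'
#' @param profile A [conservation_profile()].
#' @param residue_index 1-based index into the ungapped reference protein.
#' @return Fraction in `[0, 1]`.
#' @export
conservation_at_residue <- function(profile, residue_index) {
  if (!inherits(profile, "conservation_profile"))
    stop("'profile' must be a conservation_profile")
  .check_count(residue_index, "residue_index", min = 1)
  if (residue_index > length(profile$ref_columns))
    stop(sprintf("residue %d is beyond the reference protein (%d residues)",
                 residue_index, length(profile$ref_columns)))
  unname(profile$scores[profile$ref_columns[[residue_index]]])
}

#' Does a residue fall inside an annotated domain?
#'
#' @param residue_index 1-based residue index.
#' @param domains Data frame with columns `name`, `start`, `end` (1-based,
#'   inclusive at both ends); an optional `gene_id` column is ignored here.
#'   An empty data frame (or `NULL`) means no domain annotation.
#' @return List with `in_domain` flag and the `names` of overlapped
#'   domains.
#' @export
domain_overlap <- function(residue_index, domains) {
  .check_count(residue_index, "residue_index", min = 1)
  if (is.null(domains) || nrow(as.data.frame(domains)) == 0)
    return(list(in_domain = FALSE, names = character(0)))
  domains <- as.data.frame(domains)
  if (!all(c("name", "start", "end") %in% names(domains)))
    stop("'domains' needs columns name, start, end")
  if (!is.numeric(domains$start) || !is.numeric(domains$end) ||
      anyNA(domains$start) || anyNA(domains$end) ||
      any(domains$start < 1) || any(domains$start > domains$end))
    stop("malformed domain interval: need 1 <= start <= end")
  hit <- domains$start <= residue_index & residue_index <= domains$end
  list(in_domain = any(hit), names = as.character(domains$name[hit]))
}

.EFFECT_RANK <- c(nonsense = 5, stop_loss = 4, missense = 3,
                  synonymous = 2, noncoding = 1)
.SEVERITY_RANK <- c(radical = 3, moderate = 2, conservative = 1)

#' Rank candidate variants by evidence strength
#'
#' Lexicographic ordering: effect class (nonsense > stop-loss > missense >
#' synonymous > noncoding), then severity class (radical > moderate >
#' conservative; unavailable last), then conservation score descending
#' (unavailable last), then in-domain first, then `variant_id` ascending
#' so the order is total and reproducible.
#'
#' @param reports Data frame with columns `variant_id`, `effect_class`,
#'   and optionally `grantham`, `severity_class`, `conservation_score`,
#'   `in_domain` (missing columns are treated as unavailable evidence).
#' @return The same data frame ordered by decreasing evidence, with a
#'   `rank` column (1 = best).
#' @export
rank_candidates <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) == 0) {
    reports$rank <- integer(0)
    return(reports)
  }
  if (!all(c("variant_id", "effect_class") %in% names(reports)))
    stop("'reports' needs at least variant_id and effect_class columns")
  if (!all(reports$effect_class %in% names(.EFFECT_RANK)))
    stop("unknown effect_class in reports")
  sev <- if ("severity_class" %in% names(reports))
    .SEVERITY_RANK[reports$severity_class] else rep(NA_real_, nrow(reports))
  sev[is.na(sev)] <- 0
  cons <- if ("conservation_score" %in% names(reports))
    reports$conservation_score else rep(NA_real_, nrow(reports))
  cons[is.na(cons)] <- -1
  dom <- if ("in_domain" %in% names(reports))
    reports$in_domain else rep(FALSE, nrow(reports))
  dom[is.na(dom)] <- FALSE
  o <- order(-.EFFECT_RANK[reports$effect_class], -sev, -cons, -dom,
             reports$variant_id, method = "radix")
  reports <- reports[o, , drop = FALSE]
  reports$rank <- seq_len(nrow(reports))
  rownames(reports) <- NULL
  reports
}

#' Build and rank candidate evidence reports
#'
#' Joins segregation candidates with their coding effects, scores missense
#' substitutions with the Grantham scale, looks up residue conservation in
#' per-gene ortholog alignments and domain overlap in a domain table, and
#' ranks the result with [rank_candidates()].
#'
#' @param effects Output of [partition_by_coding()] run on the candidate
#'   variants (list with `effects` and `noncoding`).
#' @param alignments Named list of per-gene alignments (each as accepted by
#'   [conservation_profile()]; the reference record must be named after
#'   the gene). `NULL` disables conservation scoring.
#' @param domains Data frame with `gene_id`, `name`, `start`, `end`, or
#'   `NULL`.
#' @param conservative_below,radical_above Severity boundaries, see
#'   [severity_class()].
#' @return Ranked data frame: one row per candidate with effect, severity,
#'   conservation, domain evidence and `rank`.
#' @export
prioritize_candidates <- function(effects, alignments = NULL, domains = NULL,
                                  conservative_below = 100,
                                  radical_above = 150) {
  profiles <- list()
  if (!is.null(alignments))
    for (g in names(alignments))
      profiles[[g]] <- conservation_profile(alignments[[g]], g)
  rows <- vector("list", nrow(effects$effects))
  for (i in seq_len(nrow(effects$effects))) {
    e <- effects$effects[i, ]
    gr <- NA_real_; sev <- NA_character_
    if (e$effect_class == "missense") {
      gr <- grantham_distance(e$ref_aa, e$alt_aa)
      sev <- severity_class(gr, conservative_below, radical_above)
    }
    cons <- NA_real_
    if (!is.null(profiles[[e$gene_id]])) {
      prof <- profiles[[e$gene_id]]
      if (e$codon_index <= length(prof$ref_columns))
        cons <- conservation_at_residue(prof, e$codon_index)
    }
    gd <- if (is.null(domains)) NULL else
      domains[!is.na(domains$gene_id) & domains$gene_id == e$gene_id, ,
              drop = FALSE]
    ov <- domain_overlap(e$codon_index, gd)
    rows[[i]] <- data.frame(
      variant_id = e$variant_id, gene_id = e$gene_id,
      cds_pos = e$cds_pos, codon_index = e$codon_index,
      ref_aa = e$ref_aa, alt_aa = e$alt_aa,
      effect_class = e$effect_class,
      grantham = gr, severity_class = sev,
      conservation_score = cons,
      in_domain = ov$in_domain,
      domain = if (length(ov$names)) paste(ov$names, collapse = ",")
               else NA_character_,
      stringsAsFactors = FALSE)
  }
  nc <- effects$noncoding
  if (!is.null(nc) && nrow(nc) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = nc$variant_id, gene_id = NA_character_,
      cds_pos = NA_integer_, codon_index = NA_integer_,
      ref_aa = NA_character_, alt_aa = NA_character_,
      effect_class = "noncoding",
      grantham = NA_real_, severity_class = NA_character_,
      conservation_score = NA_real_, in_domain = FALSE,
      domain = NA_character_, stringsAsFactors = FALSE)
  }
  reports <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(0), gene_id = character(0),
               cds_pos = integer(0), codon_index = integer(0),
               ref_aa = character(0), alt_aa = character(0),
               effect_class = character(0), grantham = numeric(0),
               severity_class = character(0),
               conservation_score = numeric(0), in_domain = logical(0),
               domain = character(0), stringsAsFactors = FALSE)
  rank_candidates(reports)
}
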