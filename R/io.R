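# Readers and writers for the formats the pipeline touches: the pooled
# variant TSV dialect, a minimal VCFv4.2 dialect with per-pool AD fields,
# CDS FASTA, aligned protein FASTA and the domain TSV.

.VARIANT_COLS <- c("variant_id", "contig", "pos", "ref", "alt",
                   "mut_alt", "mut_depth", "sib_alt", "sib_depth",
                   "wt_alt", "wt_depth")
.VCF_SAMPLES <- c(mut = "MUT", sib = "SIB", wt = "WT")

# Invariant checks shared by both readers; `where` names the source file.
.validate_variants <- function(v, where = "variant table") {
  missing_cols <- setdiff(.VARIANT_COLS, names(v))
  if (length(missing_cols))
    stop(sprintf("%s is missing required column(s): %s", where,
                 paste(missing_cols, collapse = ", ")))
  for (col in c("gene_id", "cds_pos"))
    if (is.null(v[[col]])) v[[col]] <- NA
  v$gene_id <- as.character(v$gene_id)
  v$gene_id[!is.na(v$gene_id) & v$gene_id == ""] <- NA_character_
  v$cds_pos <- suppressWarnings(as.integer(v$cds_pos))
  num <- c("pos", "mut_alt", "mut_depth", "sib_alt", "sib_depth",
           "wt_alt", "wt_depth")
  for (col in num) v[[col]] <- suppressWarnings(as.integer(v[[col]]))
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("%s: %s in row(s) %s", where, what,
                   paste(utils::head(rows, 5), collapse = ", ")))
  }
  bad(apply(is.na(v[num]), 1, any), "non-numeric or missing count")
  bad(v$pos < 1, "position < 1")
  bad(v$ref == v$alt, "ref equals alt")
  bad(v$mut_alt > v$mut_depth | v$sib_alt > v$sib_depth |
        v$wt_alt > v$wt_depth, "alt count exceeds depth")
  bad(v$mut_alt < 0 | v$sib_alt < 0 | v$wt_alt < 0 |
        v$mut_depth < 0 | v$sib_depth < 0 | v$wt_depth < 0,
      "negative count")
  v
}

#' Read a pooled variant table
#'
#' Two dialects are supported. TSV: columns `variant_id`, `contig`, `pos`
#' (1-based), `ref`, `alt`, `mut_alt`, `mut_depth`, `sib_alt`,
#' `sib_depth`, `wt_alt`, `wt_depth`, plus optional `gene_id`, `cds_pos`
#' mapping columns for coding variants. VCFv4.2: samples `MUT`, `SIB`,
#' `WT`, each carrying an `AD` (allele depth) FORMAT field; pool depth is
#' taken as ref + alt reads, ignoring any further alleles, and
#' multi-allelic records are reduced to the first listed alternate with a
#' warning. The optional `GENE`/`CDSPOS` INFO keys carry the CDS mapping.
#'
#' @param path File to read.
#' @param format `"tsv"`, `"vcf"`, or `"auto"` (by file extension).
#' @return Data frame of pooled variants; rows violating the invariants
#'   (alt count above depth, ref equal to alt, ...) raise an error naming
#'   the offending rows.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "tsv") {
    v <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    return(.validate_variants(v, basename(path)))
  }
  .read_variants_vcf(path)
}

.read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  missing_s <- setdiff(unname(.VCF_SAMPLES), samples)
  if (length(missing_s))
    stop(sprintf("%s: expected sample column(s) %s not found (samples present: %s)",
                 basename(path), paste(missing_s, collapse = ", "),
                 paste(samples, collapse = ", ")))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stop(sprintf("%s: no AD (allele depth) FORMAT field", basename(path)))
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("%d multi-allelic record(s) reduced to their first alternate allele",
                    sum(multi)))
    fix$ALT <- sub(",.*$", "", fix$ALT)
  }
  ad_field <- function(sample, slot) {
    x <- strsplit(ad[, sample], ",", fixed = TRUE)
    vapply(x, function(p) {
      if (length(p) < 2 || anyNA(p)) NA_integer_
      else as.integer(p[[slot]])
    }, integer(1))
  }
  info_key <- function(key) {
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[hit] <- sub(paste0("^.*?", key, "=([^;]*).*$"), "\\1",
                    fix$INFO[hit])
    out
  }
  ids <- fix$ID
  if (any(is.na(ids) | ids == "."))
    ids <- ifelse(is.na(ids) | ids == ".",
                  sprintf("%s_%s", fix$CHROM, fix$POS), ids)
  mk <- function(s) list(alt = ad_field(.VCF_SAMPLES[[s]], 2L),
                         ref = ad_field(.VCF_SAMPLES[[s]], 1L))
  mut <- mk("mut"); sib <- mk("sib"); wt <- mk("wt")
  v <- data.frame(
    variant_id = ids, contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    mut_alt = mut$alt, mut_depth = mut$ref + mut$alt,
    sib_alt = sib$alt, sib_depth = sib$ref + sib$alt,
    wt_alt = wt$alt, wt_depth = wt$ref + wt$alt,
    gene_id = info_key("GENE"),
    cds_pos = suppressWarnings(as.integer(info_key("CDSPOS"))),
    stringsAsFactors = FALSE)
  .validate_variants(v, basename(path))
}

#' Write a pooled variant table as TSV
#'
#' @param variants Data frame in the pooled-variant dialect.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a pooled variant table as VCFv4.2
#'
#' Emits one record per variant with samples `MUT`, `SIB`, `WT` carrying
#' `AD` = (reference reads, alternate reads), and the `GENE`/`CDSPOS`
#' INFO keys where a CDS mapping is present. The TSV and VCF dialects
#' round-trip losslessly through [read_variants()].
#'
#' @param variants Data frame in the pooled-variant dialect.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  variants <- .validate_variants(variants, "variant table")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=selfseg",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene of the CDS mapping\">",
    "##INFO=<ID=CDSPOS,Number=1,Type=Integer,Description=\"1-based CDS position\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "MUT", "SIB", "WT"), collapse = "\t")),
    con)
  info <- ifelse(is.na(variants$gene_id), ".",
                 sprintf("GENE=%s;CDSPOS=%d", variants$gene_id,
                         variants$cds_pos))
  ad <- function(alt, depth) sprintf("%d,%d", depth - alt, alt)
  writeLines(paste(variants$contig, variants$pos, variants$variant_id,
                   variants$ref, variants$alt, ".", "PASS", info, "AD",
                   ad(variants$mut_alt, variants$mut_depth),
                   ad(variants$sib_alt, variants$sib_depth),
                   ad(variants$wt_alt, variants$wt_depth),
                   sep = "\t"),
             con)
  invisible(path)
}

#' Read a CDS catalogue from FASTA
#'
#' Record identifiers (first whitespace-separated token) become gene ids.
#'
#' @param path FASTA file.
#' @return Named list of [cds_model()] objects.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  stats::setNames(lapply(seq_along(seqs), function(i)
    cds_model(ids[[i]], as.character(seqs[[i]]))), ids)
}

#' Write a CDS catalogue to FASTA
#'
#' @param cds Named character vector of sequences or list of
#'   [cds_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  if (is.list(cds) && all(vapply(cds, inherits, logical(1), "cds_model")))
    cds <- vapply(cds, function(x) x$sequence, character(1))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(cds)), path)
  invisible(path)
}

#' Read an aligned protein FASTA
#'
#' @param path Aligned FASTA (equal-length records, `-` for gaps).
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  if (length(unique(nchar(out))) > 1)
    stop(sprintf("%s: records have unequal lengths; not an alignment",
                 basename(path)))
  out
}

#' Write an alignment to FASTA
#' @param alignment Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment), path)
  invisible(path)
}

#' Read a domain annotation table
#'
#' @param path 4-column TSV: `gene_id`, `name`, `start`, `end` (1-based
#'   inclusive residue intervals).
#' @return Data frame.
#' @export
read_domains <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "name", "start", "end")
  if (!all(need %in% names(d)))
    stop(sprintf("%s must have columns %s", basename(path),
                 paste(need, collapse = ", ")))
  d
}

#' Write a simulated dataset to a directory
#'
#' Writes `variants.tsv` (and optionally `variants.vcf`), `truth.tsv`,
#' `cds.fasta`, `domains.tsv` and one `aln_<gene>.fasta` per gene.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param vcf Also write the VCF twin of the variant table.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, vcf = FALSE) {
  if (!inherits(sim, "selfing_simulation"))
    stop("'sim' must be a selfing_simulation")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_variants_tsv(sim$variants, file.path(dir, "variants.tsv"))
  if (vcf) write_variants_vcf(sim$variants, file.path(dir, "variants.vcf"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  write_cds_fasta(sim$cds, file.path(dir, "cds.fasta"))
  utils::write.table(sim$domains, file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(sim$alignments))
    write_alignment(sim$alignments[[g]],
                    file.path(dir, sprintf("aln_%s.fasta", g)))
  invisible(dir)
}
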