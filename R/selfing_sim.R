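# Synthetic selfing-pedigree simulator: pooled allele counts for a
# mutant / sibling / wild-type three-pool design with known ground truth.

#' Configuration for the synthetic selfing pedigree
#'
#' Parameters of the simulated forward-genetic screen: an ENU-mutagenized
#' hermaphrodite founder, heterozygous for one fully penetrant recessive
#' causal substitution and a load of phenotype-independent background
#' variants, is propagated by self-fertilisation; embryo pools (homozygous
#' mutants, phenotypically normal siblings, and the parental wild-type
#' strain) are then sequenced as equal-mass RNA pools.
#'
#' @param n_background_variants Number of non-causal variants in the table.
#'   May be 0 (causal variant only).
#' @param residual_het_fraction Probability that a background variant is
#'   heterozygous in the founder (still segregating in the lineage); with
#'   probability `1 - residual_het_fraction` the variant is instead a fixed
#'   strain-vs-reference difference shared with the parental wild-type
#'   strain, so it appears at frequency 1 in all three pools.
#' @param selfing_generations Number of selfed generations separating the
#'   founder from the pooled embryos (the embryos' parent has been selfed
#'   `selfing_generations - 1` times). Must be at least 1.
#' @param n_mutant_embryos,n_sibling_embryos,n_wt_embryos Embryos pooled per
#'   group.
#' @param mean_depth Mean sequencing depth per variant per pool; realised
#'   depths are Poisson around this mean.
#' @param error_rate Per-read miscall probability.
#' @param causal_cds_position 1-based CDS coordinate of the planted causal
#'   substitution within the causal gene.
#' @param coding_fraction Fraction of background variants placed inside a
#'   CDS (the rest are intergenic/noncoding).
#' @param seed Integer seed; the same seed reproduces the same dataset.
#'
#' @return An object of class `pedigree_config`.
#' @seealso [simulate_dataset()]
#' @export
pedigree_config <- function(n_background_variants = 500,
                            residual_het_fraction = 0.8,
                            selfing_generations = 2,
                            n_mutant_embryos = 12,
                            n_sibling_embryos = 12,
                            n_wt_embryos = 12,
                            mean_depth = 100,
                            error_rate = 0.001,
                            causal_cds_position = 574,
                            coding_fraction = 0.35,
                            seed = 1L) {
  .check_count(n_background_variants, "n_background_variants", min = 0)
  .check_prob(residual_het_fraction, "residual_het_fraction")
  .check_count(selfing_generations, "selfing_generations", min = 1)
  .check_count(n_mutant_embryos, "n_mutant_embryos", min = 1)
  .check_count(n_sibling_embryos, "n_sibling_embryos", min = 1)
  .check_count(n_wt_embryos, "n_wt_embryos", min = 1)
  if (!is.numeric(mean_depth) || length(mean_depth) != 1 || mean_depth < 1)
    stop("'mean_depth' must be a single number >= 1")
  .check_prob(error_rate, "error_rate")
  .check_count(causal_cds_position, "causal_cds_position", min = 1)
  .check_prob(coding_fraction, "coding_fraction")
  .check_count(seed, "seed", min = 0)
  structure(list(
    n_background_variants = as.integer(n_background_variants),
    residual_het_fraction = residual_het_fraction,
    selfing_generations = as.integer(selfing_generations),
    n_mutant_embryos = as.integer(n_mutant_embryos),
    n_sibling_embryos = as.integer(n_sibling_embryos),
    n_wt_embryos = as.integer(n_wt_embryos),
    mean_depth = mean_depth,
    error_rate = error_rate,
    causal_cds_position = as.integer(causal_cds_position),
    coding_fraction = coding_fraction,
    seed = as.integer(seed)
  ), class = "pedigree_config")
}

#' @export
print.pedigree_config <- function(x, ...) {
  cat("Selfing-pedigree configuration\n")
  cat(sprintf("  background variants : %d (%.0f%% coding)\n",
              x$n_background_variants, 100 * x$coding_fraction))
  cat(sprintf("  founder heterozygous fraction: %.2f; selfed generations: %d\n",
              x$residual_het_fraction, x$selfing_generations))
  cat(sprintf("  embryos per pool    : mutant %d, sibling %d, wild-type %d\n",
              x$n_mutant_embryos, x$n_sibling_embryos, x$n_wt_embryos))
  cat(sprintf("  mean depth %g, error rate %g, causal CDS position %d, seed %d\n",
              x$mean_depth, x$error_rate, x$causal_cds_position, x$seed))
  invisible(x)
}

#' Genotype distribution at a biallelic locus
#'
#' @param p_hom_ref,p_het,p_hom_alt Probabilities of the three genotypes;
#'   must sum to 1 (tolerance 1e-12).
#' @return Named numeric vector of class `genotype_distribution`.
#' @export
genotype_distribution <- function(p_hom_ref, p_het, p_hom_alt) {
  p <- c(hom_ref = p_hom_ref, het = p_het, hom_alt = p_hom_alt)
  if (!is.numeric(p) || length(p) != 3 || anyNA(p))
    stop("genotype probabilities must be three numbers")
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("genotype probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12)
    stop("genotype probabilities must sum to 1")
  structure(pmin(pmax(p, 0), 1), class = "genotype_distribution")
}

#' Genotype distribution after generations of self-fertilisation
#'
#' One round of selfing halves the heterozygote class; the lost mass splits
#' equally between the two homozygote classes, so the allele frequency is
#' preserved exactly while heterozygosity decays as 2^-g.
#'
#' @param parent A [genotype_distribution()].
#' @param generations Non-negative integer number of selfed generations.
#' @return A `genotype_distribution`.
#' @examples
#' genotype_distribution_after_selfing(genotype_distribution(0, 1, 0), 1)
#' @export
genotype_distribution_after_selfing <- function(parent, generations) {
  if (!inherits(parent, "genotype_distribution"))
    parent <- genotype_distribution(parent[[1]], parent[[2]], parent[[3]])
  .check_count(generations, "generations", min = 0)
  p <- unclass(parent)
  for (i in seq_len(generations)) {
    h <- p[["het"]]
    p <- c(hom_ref = p[["hom_ref"]] + h / 4,
           het = h / 2,
           hom_alt = p[["hom_alt"]] + h / 4)
  }
  genotype_distribution(p[["hom_ref"]], p[["het"]], p[["hom_alt"]])
}

#' Residual heterozygosity of a selfed line
#'
#' Closed form for the heterozygosity left after `generations` rounds of
#' selfing: `h0 * 2^-generations`.
#'
#' @param h0 Initial heterozygosity, in `[0, 1]`.
#' @param generations Non-negative integer.
#' @return A probability.
#' @export
residual_heterozygosity <- function(h0, generations) {
  .check_prob(h0, "h0")
  .check_count(generations, "generations", min = 0)
  h0 * 2^(-generations)
}

#' Sample offspring genotypes from a selfed parent
#'
#' Mendelian segregation under self-fertilisation: a heterozygous parent
#' yields offspring in 1:2:1 proportions; homozygous parents breed true.
#'
#' @param parent_genotype One of `"hom_ref"`, `"het"`, `"hom_alt"`.
#' @param n Number of offspring to draw.
#' @return Character vector of offspring genotypes.
#' @export
simulate_selfed_offspring <- function(parent_genotype, n) {
  parent_genotype <- match.arg(parent_genotype, .GENOTYPES)
  .check_count(n, "n", min = 1)
  if (parent_genotype == "het")
    sample(.GENOTYPES, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  else
    rep(parent_genotype, n)
}

#' Sample pooled read counts at a variant
#'
#' Reads supporting the alternate allele are drawn binomially with success
#' probability `f * (1 - error_rate) + (1 - f) * error_rate`, i.e. a true
#' alternate read survives miscalling and a reference read may be miscalled
#' to the alternate.
#'
#' @param true_frequency True alternate-allele frequency `f` of the pool.
#' @param depth Total reads at the site (>= 0).
#' @param error_rate Per-read miscall probability.
#' @param seed Optional integer seed for this single draw.
#' @return Named integer vector `c(alt_count, total_depth)`.
#' @export
sample_pool_counts <- function(true_frequency, depth, error_rate = 0,
                               seed = NULL) {
  .check_prob(true_frequency, "true_frequency")
  .check_count(depth, "depth", min = 0)
  .check_prob(error_rate, "error_rate")
  if (!is.null(seed)) set.seed(seed)
  p <- true_frequency * (1 - error_rate) + (1 - true_frequency) * error_rate
  alt <- rbinom(1L, size = depth, prob = p)
  c(alt_count = alt, total_depth = as.integer(depth))
}

# Deterministic per-variant substream seed (31-bit, LCG-style mixing).
.substream <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807 + 1) %%
               2147483647)
}

# Random in-frame CDS: ATG start, non-stop internal codons, one stop codon.
# `fixed` is a named list mapping codon index -> forced codon.
.random_cds <- function(n_codons, fixed = NULL) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  codons <- c("ATG",
              sample(sense, n_codons - 2, replace = TRUE),
              sample(stops, 1))
  for (idx in names(fixed)) codons[[as.integer(idx)]] <- fixed[[idx]]
  paste(codons, collapse = "")
}

# Planted causal substitution: ref codon and base change chosen so the
# substitution is a radical missense at the requested position in the codon.
# Position 1 gives the arginine-to-cysteine CGT->TGT change.
.causal_plan <- function(pos_in_codon) {
  switch(pos_in_codon,
         list(codon = "CGT", ref = "C", alt = "T"),   # R -> C
         list(codon = "TGT", ref = "G", alt = "A"),   # C -> Y
         list(codon = "TGT", ref = "T", alt = "G"))   # C -> W
}

# Mutate a protein sequence at random positions, keeping `keep` fixed.
.mutated_ortholog <- function(protein, keep = integer(0), rate = 0.1) {
  aa <- strsplit(protein, "")[[1]]
  alphabet <- rownames(grantham_matrix())
  hit <- which(runif(length(aa)) < rate)
  hit <- setdiff(hit, keep)
  for (i in hit) aa[[i]] <- sample(setdiff(alphabet, aa[[i]]), 1)
  paste(aa, collapse = "")
}

#' Simulate a pooled-sequencing variant dataset with known truth
#'
#' Generates the full three-pool design: one fully penetrant recessive
#' causal substitution (mutant pool fixed for the alternate allele,
#' wild-type strain without it, phenotypically normal siblings composed of
#' 1/3 homozygous-reference and 2/3 heterozygous embryos so the expected
#' mutant-allele frequency is 1/3), plus phenotype-independent background
#' variants. Background variants are either still segregating in the
#' lineage (founder heterozygous; the embryos' parent genotype is drawn
#' from the selfing distribution conditioned on the variant not having been
#' lost) or fixed strain differences present in every pool. Pool allele
#' frequencies are the mean genotype dosage of the pooled embryos; read
#' counts add Poisson depth and binomial miscall noise.
#'
#' Alongside the variant table the simulator emits the ground truth, the
#' CDS catalogue, a small synthetic ortholog protein alignment per gene
#' (the causal residue is kept conserved) and a synthetic functional-domain
#' annotation covering the causal residue, so the downstream annotation and
#' prioritization stages can run end to end.
#'
#' @param config A [pedigree_config()].
#' @return Object of class `selfing_simulation`: list with elements
#'   `variants` (data frame in the pooled-variant TSV dialect), `truth`,
#'   `cds` (named character vector of CDS sequences), `alignments` (named
#'   list of named character vectors, reference record named after the
#'   gene), `domains` (data frame), and `config`.
#' @export
simulate_dataset <- function(config = pedigree_config()) {
  if (!inherits(config, "pedigree_config"))
    stop("'config' must be a pedigree_config")
  set.seed(config$seed)

  causal_codon <- (config$causal_cds_position - 1) %/% 3 + 1
  causal_offset <- (config$causal_cds_position - 1) %% 3 + 1
  plan <- .causal_plan(causal_offset)

  n_bg_genes <- 5L
  gene_ids <- sprintf("g%03d", seq_len(n_bg_genes + 1L))
  causal_gene <- gene_ids[[1]]
  lens <- c(max(causal_codon + 41L, 240L),
            sample(120:320, n_bg_genes, replace = TRUE))
  cds <- character(0)
  cds[causal_gene] <- .random_cds(lens[[1]],
                                  fixed = stats::setNames(list(plan$codon),
                                                          causal_codon))
  for (i in seq_len(n_bg_genes))
    cds[gene_ids[[i + 1L]]] <- .random_cds(lens[[i + 1L]])

  # --- causal variant ------------------------------------------------------
  sib_geno <- sample(c("hom_ref", "het"), config$n_sibling_embryos,
                     replace = TRUE, prob = c(1 / 3, 2 / 3))
  causal <- list(
    contig = causal_gene, pos = config$causal_cds_position,
    ref = plan$ref, alt = plan$alt,
    gene_id = causal_gene, cds_pos = config$causal_cds_position,
    f_mut = 1, f_sib = mean(.DOSAGE[sib_geno]), f_wt = 0,
    coding = TRUE, is_causal = TRUE
  )

  # --- background variants -------------------------------------------------
  m <- config$selfing_generations - 1L
  parent_dist <- genotype_distribution_after_selfing(
    genotype_distribution(0, 1, 0), m)
  # condition on the variant not having been lost from the lineage
  seg_prob <- unclass(parent_dist)[c("het", "hom_alt")]
  seg_prob <- seg_prob / sum(seg_prob)
  acgt <- c("A", "C", "G", "T")

  bg <- vector("list", config$n_background_variants)
  for (i in seq_len(config$n_background_variants)) {
    set.seed(.substream(config$seed, i))
    coding <- runif(1) < config$coding_fraction
    if (coding) {
      gene <- sample(gene_ids[-1], 1)
      len_nt <- nchar(cds[[gene]])
      cpos <- sample(4:(len_nt - 3L), 1)
      ref <- substr(cds[[gene]], cpos, cpos)
      alt <- sample(setdiff(acgt, ref), 1)
      contig <- gene; pos <- cpos
    } else {
      gene <- NA_character_; cpos <- NA_integer_
      contig <- sprintf("scaffold_%02d", sample(20, 1))
      pos <- sample(1e6, 1)
      ref <- sample(acgt, 1)
      alt <- sample(setdiff(acgt, ref), 1)
    }
    if (runif(1) < config$residual_het_fraction) {
      parent <- sample(c("het", "hom_alt"), 1, prob = seg_prob)
      f_mut <- mean(.DOSAGE[simulate_selfed_offspring(parent,
                                                      config$n_mutant_embryos)])
      f_sib <- mean(.DOSAGE[simulate_selfed_offspring(parent,
                                                      config$n_sibling_embryos)])
      f_wt <- 0          # the wild-type strain never carries the founder allele
    } else {
      f_mut <- 1; f_sib <- 1; f_wt <- 1   # shared fixed strain difference
    }
    bg[[i]] <- list(contig = contig, pos = pos, ref = ref, alt = alt,
                    gene_id = gene, cds_pos = cpos,
                    f_mut = f_mut, f_sib = f_sib, f_wt = f_wt,
                    coding = coding, is_causal = FALSE)
  }

  recs <- c(list(causal), bg)
  set.seed(.substream(config$seed, length(recs) + 1L))
  recs <- recs[sample(length(recs))]

  n <- length(recs)
  field <- function(f, mode) vapply(recs, `[[`, vector(mode, 1), f)
  f_mut <- field("f_mut", "numeric")
  f_sib <- field("f_sib", "numeric")
  f_wt <- field("f_wt", "numeric")
  e <- config$error_rate
  depth3 <- matrix(rpois(3L * n, config$mean_depth), nrow = n)
  alt_of <- function(f, depth) rbinom(n, depth, f * (1 - e) + (1 - f) * e)
  mut_alt <- alt_of(f_mut, depth3[, 1])
  sib_alt <- alt_of(f_sib, depth3[, 2])
  wt_alt <- alt_of(f_wt, depth3[, 3])
  ids <- sprintf("v%05d", seq_len(n))
  variants <- data.frame(
    variant_id = ids,
    contig = field("contig", "character"),
    pos = field("pos", "integer"),
    ref = field("ref", "character"),
    alt = field("alt", "character"),
    mut_alt = mut_alt, mut_depth = depth3[, 1],
    sib_alt = sib_alt, sib_depth = depth3[, 2],
    wt_alt = wt_alt, wt_depth = depth3[, 3],
    gene_id = field("gene_id", "character"),
    cds_pos = field("cds_pos", "integer"),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    variant_id = ids,
    is_causal = field("is_causal", "logical"),
    true_freq_mut = f_mut, true_freq_sib = f_sib, true_freq_wt = f_wt,
    coding_status = ifelse(field("coding", "logical"),
                           "coding", "noncoding"),
    gene_id = variants$gene_id, cds_pos = variants$cds_pos,
    planted_effect = ifelse(field("is_causal", "logical"),
                            "missense", NA_character_),
    stringsAsFactors = FALSE)

  # --- ortholog alignments and domain annotation ---------------------------
  set.seed(.substream(config$seed, n + 2L))
  alignments <- list()
  for (g in names(cds)) {
    prot <- translate_cds(cds[[g]])
    keep <- if (g == causal_gene) causal_codon else integer(0)
    alignments[[g]] <- stats::setNames(
      c(prot,
        .mutated_ortholog(prot, keep = keep),
        .mutated_ortholog(prot, keep = keep)),
      c(g, paste0("human_", g), paste0("mouse_", g)))
  }
  domains <- data.frame(
    gene_id = causal_gene, name = "death_domain",
    start = max(2L, causal_codon - 39L),
    end = min(nchar(cds[[causal_gene]]) %/% 3 - 1L, causal_codon + 16L),
    stringsAsFactors = FALSE)

  structure(list(variants = variants, truth = truth, cds = cds,
                 alignments = alignments, domains = domains,
                 config = config),
            class = "selfing_simulation")
}

#' @export
print.selfing_simulation <- function(x, ...) {
  cat(sprintf("Synthetic selfing-pedigree dataset: %d variants (%d coding), seed %d\n",
              nrow(x$variants), sum(x$truth$coding_status == "coding"),
              x$config$seed))
  cat(sprintf("  causal variant: %s (%s, CDS position %d)\n",
              x$truth$variant_id[x$truth$is_causal],
              x$truth$gene_id[x$truth$is_causal],
              x$truth$cds_pos[x$truth$is_causal]))
  invisible(x)
}

# ---- shared argument checks ------------------------------------------------

.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(x)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}
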