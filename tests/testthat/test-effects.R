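test_that("CDS position maps to codon index and offset", {
  loc <- cds_position_to_codon(574)
  expect_equal(loc$codon_index, 192L)
  expect_equal(loc$pos_in_codon, 1L)
  expect_equal(cds_position_to_codon(1)$codon_index, 1L)
  expect_equal(cds_position_to_codon(1)$pos_in_codon, 1L)
  expect_equal(cds_position_to_codon(6)$codon_index, 2L)
  expect_equal(cds_position_to_codon(6)$pos_in_codon, 3L)
  expect_error(cds_position_to_codon(0), "positive")
  cds <- cds_with_codon(5, "CGT", n_codons = 6)
  expect_error(cds_position_to_codon(19, cds), "beyond")
})

test_that("codon/position round-trip is exact", {
  pos <- 1:300
  loc <- cds_position_to_codon(pos)
  expect_equal((loc$codon_index - 1L) * 3L + loc$pos_in_codon, pos)
  expect_true(all(loc$pos_in_codon %in% 1:3))
})

test_that("codon translation follows the standard genetic code", {
  expect_equal(translate_codon("CGT"), "R")
  expect_equal(translate_codon("TGT"), "C")
  expect_equal(translate_codon("TGA"), "*")
  expect_equal(translate_codon(c("ATG", "AAA")), c("M", "K"))
  expect_error(translate_codon("CG"), "3")
  expect_error(translate_codon("CGN"), "unambiguous")
})

test_that("the arginine-192 substitution annotates as a radical missense", {
  cds <- cds_with_codon(192, "CGT", n_codons = 200)
  eff <- annotate_substitution(cds, 574, "C", "T")
  expect_equal(eff$codon_index, 192L)
  expect_equal(eff$pos_in_codon, 1L)
  expect_equal(eff$ref_codon, "CGT")
  expect_equal(eff$alt_codon, "TGT")
  expect_equal(eff$ref_aa, "R")
  expect_equal(eff$alt_aa, "C")
  expect_equal(eff$effect_class, "missense")
})

test_that("synonymous, nonsense and stop-loss changes classify correctly", {
  cds <- cds_with_codon(192, "CGT", n_codons = 200)
  syn <- annotate_substitution(cds, 576, "T", "C")   # CGT -> CGC, both R
  expect_equal(syn$effect_class, "synonymous")
  expect_equal(syn$ref_aa, syn$alt_aa)

  cds2 <- cds_with_codon(10, "CGA", n_codons = 20)
  non <- annotate_substitution(cds2, 28, "C", "T")   # CGA -> TGA
  expect_equal(non$effect_class, "nonsense")
  expect_equal(non$alt_aa, "*")

  cds3 <- cds_with_codon(5, "AAA", n_codons = 6)     # terminal codon TAA
  sl <- annotate_substitution(cds3, 16, "T", "C")    # TAA -> CAA
  expect_equal(sl$effect_class, "stop_loss")
  expect_equal(sl$ref_aa, "*")
  expect_equal(sl$alt_aa, "Q")
})

test_that("reference mismatches and malformed substitutions are hard errors", {
  cds <- cds_with_codon(10, "CGT", n_codons = 20)
  expect_error(annotate_substitution(cds, 28, "A", "T"),
               "reference mismatch at CDS position 28")
  expect_error(annotate_substitution(cds, 28, "CT", "T"),
               "single-nucleotide")
  expect_error(annotate_substitution(cds, 28, "C", "C"), "differ")
  expect_error(annotate_substitution(cds, 28, "C", "N"), "A, C, G or T")
  expect_error(annotate_substitution(cds, 5000, "C", "T"), "beyond")
})

test_that("CDS validation rejects ambiguity and frame problems", {
  expect_error(cds_model("g", "ATGNNNTAA"), "A/C/G/T")
  expect_error(cds_model("g", "ATGCC"), "divisible by 3")
  expect_warning(cds_model("g", "CCCAAATAA"), "ATG")
})

test_that("annotation agrees with whole-CDS translation everywhere", {
  set.seed(77)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  seq <- paste(c("ATG", sample(sense, 331, TRUE), "TAA"), collapse = "")
  cds <- cds_model("oracle", seq)
  ref_protein <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(seq))), "")[[1]]
  for (pos in sample(nchar(seq), 160)) {
    ref <- substr(seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- annotate_substitution(cds, pos, ref, alt)
    expect_equal(eff$ref_aa, ref_protein[eff$codon_index])
    mutated <- seq
    substr(mutated, pos, pos) <- alt
    alt_protein <- strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(mutated),
                            if.fuzzy.codon = "X")), "")[[1]]
    expect_equal(eff$alt_aa, alt_protein[eff$codon_index])
  }
})

test_that("minus-strand input must be reverse-complemented upstream", {
  cds <- cds_with_codon(192, "CGT", n_codons = 200)
  minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds$sequence)))
  # the documented contract: recover the coding strand, then annotate
  plus_again <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(minus)))
  eff <- annotate_substitution(cds_model("rc", plus_again), 574, "C", "T")
  expect_equal(eff$effect_class, "missense")
  expect_equal(c(eff$ref_aa, eff$alt_aa), c("R", "C"))
  # feeding minus-strand coordinates/alleles directly fails loudly
  minus_model <- suppressWarnings(cds_model("rc", minus))
  expect_error(annotate_substitution(minus_model, 574, "C", "T"),
               "reference mismatch")
})

test_that("coding/noncoding partition conserves records and counts classes", {
  cds <- list(gA = cds_with_codon(10, "CGT", n_codons = 20),
              gB = cds_with_codon(5, "CGA", n_codons = 12))
  v <- rbind(
    variant_row("c1", 100, 33, 0, gene_id = "gA", cds_pos = 28),  # R->C
    variant_row("c2", 100, 33, 0, gene_id = "gA", cds_pos = 30),  # CGT->CGC
    variant_row("c3", 100, 33, 0, gene_id = "gB", cds_pos = 13),  # CGA->TGA
    variant_row("n1", 100, 33, 0),
    variant_row("n2", 100, 33, 0))
  v$ref <- c("C", "T", "C", "C", "C")
  v$alt <- c("T", "C", "T", "T", "T")
  parts <- partition_by_coding(v, cds)
  expect_equal(nrow(parts$effects), 3)
  expect_equal(nrow(parts$noncoding), 2)
  expect_equal(unname(parts$class_counts[c("missense", "synonymous",
                                           "nonsense", "noncoding")]),
               c(1L, 1L, 1L, 2L))
  expect_equal(sum(parts$class_counts[c("synonymous", "missense",
                                        "nonsense", "stop_loss")]),
               nrow(parts$effects))
  expect_error(partition_by_coding(
    variant_row("x", 1, 1, 0, gene_id = "missing", cds_pos = 4), cds),
    "absent from the CDS catalogue")
})

test_that("a variant mapping to two CDS records is annotated twice and flagged", {
  cds <- list(gA = cds_with_codon(10, "CGT", n_codons = 20),
              gB = cds_with_codon(10, "CGT", n_codons = 20))
  v <- rbind(variant_row("dup", 100, 33, 0, gene_id = "gA", cds_pos = 28),
             variant_row("dup", 100, 33, 0, gene_id = "gB", cds_pos = 28))
  parts <- partition_by_coding(v, cds)
  expect_equal(nrow(parts$effects), 2)
  expect_true(all(parts$effects$multiplicity == 2L))
})

test_that("the simulator's planted substitution annotates as the intended missense", {
  sim <- simulate_dataset(pedigree_config(n_background_variants = 40,
                                          seed = 19))
  parts <- partition_by_coding(sim$variants, sim$cds)
  causal_id <- sim$truth$variant_id[sim$truth$is_causal]
  eff <- parts$effects[parts$effects$variant_id == causal_id, ]
  expect_equal(nrow(eff), 1)
  expect_equal(eff$effect_class, "missense")
  expect_equal(eff$codon_index, 192L)
  expect_equal(c(eff$ref_aa, eff$alt_aa), c("R", "C"))
})
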