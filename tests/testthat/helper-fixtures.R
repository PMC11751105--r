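# Fixtures built in code: a CDS with a chosen codon planted at a chosen
# index, and an independent enumeration oracle for the exact binomial
# two-sided p-value (sum of all outcomes whose point probability does not
# exceed the observed one).

cds_with_codon <- function(codon_index, codon, n_codons = codon_index + 8,
                           gene_id = "fixture") {
  stopifnot(codon_index >= 2, codon_index < n_codons)
  codons <- c("ATG", rep("GGC", n_codons - 2), "TAA")
  codons[codon_index] <- codon
  cds_model(gene_id, paste(codons, collapse = ""))
}

binom_p_oracle <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# A variant-table row in the pooled dialect.
variant_row <- function(id, mut, sib, wt, depth = 100, gene_id = NA,
                        cds_pos = NA) {
  data.frame(variant_id = id, contig = "chr1", pos = 1L, ref = "C",
             alt = "T", mut_alt = mut, mut_depth = depth, sib_alt = sib,
             sib_depth = depth, wt_alt = wt, wt_depth = depth,
             gene_id = gene_id, cds_pos = cds_pos,
             stringsAsFactors = FALSE)
}
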