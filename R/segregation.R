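# Three-pool segregation-signature filter for a fully penetrant recessive
# allele: fixed in the mutant pool, absent from the parental wild-type
# strain, and at the Mendelian 1/3 mutant-allele frequency among
# phenotypically normal siblings of a selfed carrier.

#' Filter thresholds for the segregation screen
#'
#' The idealised signature (100% mutant pool, 0% wild-type pool) is only
#' attainable at infinite depth with no sequencing error; these thresholds
#' make the screen robust to finite depth.
#'
#' `sibling_pool_size` sets the null model of the sibling consistency test:
#' with a finite pool size the test integrates over the multinomial
#' composition of the embryo pool (see [sibling_ratio_test()]), which is
#' the exact null for a pool of that many phenotypically normal selfed
#' offspring; `Inf` gives the plain binomial test. `sibling_alpha` is the
#' per-variant rejection rate of the screen; because the pool-aware null is
#' exact, `sibling_alpha` is also the probability of discarding the true
#' causal variant, so the default is deliberately stringent (0.01) —
#' genuinely inconsistent signatures reject at p-values below 1e-20.
#'
#' @param min_mutant_freq Minimum mutant-pool alternate-allele frequency.
#' @param max_wt_freq Maximum wild-type-pool alternate-allele frequency.
#' @param min_depth Minimum per-pool depth; below it a variant is
#'   classified `low_depth`.
#' @param sibling_alpha Significance level of the sibling consistency test.
#' @param sibling_expected_freq Expected sibling-pool mutant-allele
#'   frequency (1/3 for a recessive allele under selfing).
#' @param sibling_pool_size Number of embryos in the sibling pool, or `Inf`
#'   for the plain binomial null.
#' @return Object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_mutant_freq = 0.95,
                              max_wt_freq = 0.05,
                              min_depth = 10,
                              sibling_alpha = 0.01,
                              sibling_expected_freq = 1 / 3,
                              sibling_pool_size = 12) {
  .check_prob(min_mutant_freq, "min_mutant_freq")
  .check_prob(max_wt_freq, "max_wt_freq")
  .check_count(min_depth, "min_depth", min = 1)
  .check_prob(sibling_alpha, "sibling_alpha")
  .check_prob(sibling_expected_freq, "sibling_expected_freq")
  if (min_mutant_freq <= max_wt_freq)
    stop("'min_mutant_freq' must exceed 'max_wt_freq'")
  if (sibling_expected_freq <= max_wt_freq ||
      sibling_expected_freq >= min_mutant_freq)
    stop("'sibling_expected_freq' must lie strictly between 'max_wt_freq' and 'min_mutant_freq'")
  if (!(is.infinite(sibling_pool_size) && sibling_pool_size > 0))
    .check_count(sibling_pool_size, "sibling_pool_size", min = 1)
  structure(list(min_mutant_freq = min_mutant_freq,
                 max_wt_freq = max_wt_freq,
                 min_depth = as.integer(min_depth),
                 sibling_alpha = sibling_alpha,
                 sibling_expected_freq = sibling_expected_freq,
                 sibling_pool_size = sibling_pool_size),
            class = "filter_thresholds")
}

#' Expected pool allele frequency under the recessive selfing model
#'
#' The mutant pool is fixed for the causal allele, the parental wild-type
#' strain lacks it, and among phenotypically normal offspring of a selfed
#' heterozygous carrier the genotypes are 1/3 homozygous reference and 2/3
#' heterozygous, so the wild-type allele is twice as abundant as the mutant
#' allele (mutant-allele frequency 1/3).
#'
#' @param pool One of `"mutant"`, `"sibling"`, `"wt"`.
#' @return Expected alternate-allele frequency.
#' @export
expected_pool_frequency <- function(pool) {
  pool <- match.arg(pool, c("mutant", "sibling", "wt"))
  switch(pool, mutant = 1, sibling = 1 / 3, wt = 0)
}

# Null pmf of the alternate read count for a pool of `m` phenotypically
# normal selfed offspring sequenced to `depth` reads: the pool allele
# frequency is the mean dosage of m embryos drawn iid with P(het) = 2*p0,
# P(hom ref) = 1 - 2*p0 (valid for p0 <= 1/2), and reads are binomial given
# the composition.
.pool_null_pmf <- function(depth, m, p0) {
  if (p0 > 0.5)
    stop("the pool-aware null requires expected_freq <= 1/2")
  j <- 0:m
  w <- dbinom(j, m, 2 * p0)
  f <- j / (2 * m)
  M <- vapply(f, function(ff) dbinom(0:depth, depth, ff),
              numeric(depth + 1L))
  as.numeric(M %*% w)
}

# cache of pool-null pmfs keyed by depth/m/p0 (hot loop in filter_candidates)
.pmf_cache <- new.env(parent = emptyenv())

.pool_null_pmf_cached <- function(depth, m, p0) {
  key <- sprintf("%d_%d_%.12g", depth, m, p0)
  got <- .pmf_cache[[key]]
  if (is.null(got)) {
    got <- .pool_null_pmf(depth, m, p0)
    if (length(ls(.pmf_cache)) > 4096) rm(list = ls(.pmf_cache),
                                          envir = .pmf_cache)
    .pmf_cache[[key]] <- got
  }
  got
}

#' Exact sibling-ratio consistency test
#'
#' Tests whether the sibling pool's alternate read count is consistent with
#' the Mendelian expectation (mutant-allele frequency `expected_freq`,
#' 1/3 for a recessive allele). The two-sided p-value sums the
#' probabilities of all outcomes whose point probability does not exceed
#' that of the observed outcome.
#'
#' With `pool_size = Inf` the null is binomial(`depth`, `expected_freq`)
#' and the test is the classical exact binomial test. With a finite
#' `pool_size` m the null additionally integrates over the multinomial
#' composition of the embryo pool (m embryos iid heterozygous with
#' probability `2 * expected_freq`), which is the exact null for pooled
#' sequencing of m phenotypically normal selfed offspring; ignoring this
#' overdispersion makes the binomial test reject the true causal variant
#' far more often than its nominal level once pools are small.
#'
#' @param alt_count Alternate reads observed in the sibling pool.
#' @param depth Total reads in the sibling pool.
#' @param expected_freq Null mutant-allele frequency (default 1/3).
#' @param alpha Significance level used for the `consistent` flag.
#' @param pool_size Embryos in the pool, or `Inf` for the binomial null.
#' @return List of class `sibling_test`: `p_value`, `consistent`
#'   (`p_value >= alpha`), `low_depth`. At depth 0 no p-value is defined
#'   and `low_depth` is `TRUE`.
#' @export
sibling_ratio_test <- function(alt_count, depth, expected_freq = 1 / 3,
                               alpha = 0.05, pool_size = Inf) {
  .check_count(alt_count, "alt_count", min = 0)
  .check_count(depth, "depth", min = 0)
  .check_prob(expected_freq, "expected_freq")
  .check_prob(alpha, "alpha")
  if (alt_count > depth) stop("'alt_count' cannot exceed 'depth'")
  if (depth == 0)
    return(structure(list(p_value = NA_real_, consistent = NA,
                          low_depth = TRUE), class = "sibling_test"))
  if (is.infinite(pool_size)) {
    p <- binom.test(alt_count, depth, expected_freq)$p.value
  } else {
    .check_count(pool_size, "pool_size", min = 1)
    pmf <- .pool_null_pmf_cached(as.integer(depth), as.integer(pool_size),
                                 expected_freq)
    obs <- pmf[[alt_count + 1L]]
    p <- sum(pmf[pmf <= obs * (1 + 1e-7)])  # fuzz guards ties in doubles
  }
  p <- min(p, 1)
  structure(list(p_value = p, consistent = p >= alpha, low_depth = FALSE),
            class = "sibling_test")
}

#' @export
print.sibling_test <- function(x, ...) {
  if (isTRUE(x$low_depth)) cat("sibling ratio test: no coverage (depth 0)\n")
  else cat(sprintf("sibling ratio test: p = %.4g (%s)\n", x$p_value,
                   if (x$consistent) "consistent" else "inconsistent"))
  invisible(x)
}

.SEG_CLASSES <- c("candidate", "strain_fixed", "wt_contaminated",
                  "non_segregating", "sibling_ratio_inconsistent",
                  "low_depth")

#' Classify the three-pool segregation signature of one variant
#'
#' Decision cascade: `low_depth` if any pool is below `min_depth`;
#' `strain_fixed` if all three pools are at or above `min_mutant_freq`
#' (a strain-vs-reference difference, uninformative for the phenotype);
#' `wt_contaminated` if the wild-type pool exceeds `max_wt_freq`;
#' `non_segregating` if the mutant pool falls below `min_mutant_freq`;
#' `sibling_ratio_inconsistent` if the sibling consistency test rejects;
#' otherwise `candidate`.
#'
#' @param variant A single-row data frame (or list) with elements
#'   `variant_id`, `mut_alt`, `mut_depth`, `sib_alt`, `sib_depth`,
#'   `wt_alt`, `wt_depth`.
#' @param thresholds A [filter_thresholds()].
#' @return List of class `segregation_call`: `variant_id`,
#'   `classification`, `observed_frequencies` (named numeric vector),
#'   `sibling_test_p` (`NA` when the variant is `low_depth`).
#' @export
classify_segregation <- function(variant, thresholds = filter_thresholds()) {
  if (!inherits(thresholds, "filter_thresholds"))
    stop("'thresholds' must be a filter_thresholds object")
  v <- as.list(variant)
  counts <- vapply(c("mut_alt", "mut_depth", "sib_alt", "sib_depth",
                     "wt_alt", "wt_depth"),
                   function(f) {
                     if (is.null(v[[f]]) || is.na(v[[f]]))
                       stop(sprintf("variant is missing field '%s'", f))
                     as.numeric(v[[f]])
                   }, numeric(1))
  if (any(counts[c(1, 3, 5)] > counts[c(2, 4, 6)]))
    stop("alt count exceeds depth")
  freqs <- c(mutant = unname(counts[["mut_alt"]] / counts[["mut_depth"]]),
             sibling = unname(counts[["sib_alt"]] / counts[["sib_depth"]]),
             wt = unname(counts[["wt_alt"]] / counts[["wt_depth"]]))
  t <- thresholds
  sib_p <- NA_real_
  if (any(counts[c(2, 4, 6)] < t$min_depth)) {
    cls <- "low_depth"
  } else {
    st <- sibling_ratio_test(counts[["sib_alt"]], counts[["sib_depth"]],
                             expected_freq = t$sibling_expected_freq,
                             alpha = t$sibling_alpha,
                             pool_size = t$sibling_pool_size)
    sib_p <- st$p_value
    cls <- if (all(freqs >= t$min_mutant_freq)) "strain_fixed"
    else if (freqs[["wt"]] > t$max_wt_freq) "wt_contaminated"
    else if (freqs[["mutant"]] < t$min_mutant_freq) "non_segregating"
    else if (!st$consistent) "sibling_ratio_inconsistent"
    else "candidate"
  }
  structure(list(variant_id = as.character(v$variant_id),
                 classification = cls,
                 observed_frequencies = freqs,
                 sibling_test_p = sib_p),
            class = "segregation_call")
}

#' Apply the segregation filter to a variant table
#'
#' Classifies every variant (see [classify_segregation()]) and returns the
#' candidates in input order together with the full call table and a
#' funnel summary of counts per class.
#'
#' @param variants Data frame in the pooled-variant dialect (see
#'   [read_variants()]).
#' @param thresholds A [filter_thresholds()].
#' @return Object of class `segregation_result`: list with `candidates`
#'   (the candidate rows of `variants`, call columns appended), `calls`
#'   (data frame with `variant_id`, `classification`, `freq_mut`,
#'   `freq_sib`, `freq_wt`, `sibling_p`), and `funnel` (named integer
#'   vector, including `total` and `n_tested`).
#' @export
filter_candidates <- function(variants, thresholds = filter_thresholds()) {
  if (is.null(variants) || nrow(variants) == 0) {
    warning("empty variant table: no candidates")
    calls <- data.frame(variant_id = character(0),
                        classification = character(0),
                        freq_mut = numeric(0), freq_sib = numeric(0),
                        freq_wt = numeric(0), sibling_p = numeric(0),
                        stringsAsFactors = FALSE)
    funnel <- stats::setNames(integer(length(.SEG_CLASSES) + 2),
                              c("total", .SEG_CLASSES, "n_tested"))
    return(structure(list(candidates = variants, calls = calls,
                          funnel = funnel),
                     class = "segregation_result"))
  }
  n <- nrow(variants)
  vid <- as.character(variants$variant_id)
  ma <- variants$mut_alt; md <- variants$mut_depth
  sa <- variants$sib_alt; sd_ <- variants$sib_depth
  wa <- variants$wt_alt; wd <- variants$wt_depth
  cls <- character(n)
  fm <- fs <- fw <- sp <- numeric(n)
  for (i in seq_len(n)) {
    cl <- classify_segregation(
      list(variant_id = vid[[i]],
           mut_alt = ma[[i]], mut_depth = md[[i]],
           sib_alt = sa[[i]], sib_depth = sd_[[i]],
           wt_alt = wa[[i]], wt_depth = wd[[i]]),
      thresholds)
    cls[[i]] <- cl$classification
    fm[[i]] <- cl$observed_frequencies[["mutant"]]
    fs[[i]] <- cl$observed_frequencies[["sibling"]]
    fw[[i]] <- cl$observed_frequencies[["wt"]]
    sp[[i]] <- cl$sibling_test_p
  }
  calls <- data.frame(variant_id = vid, classification = cls,
                      freq_mut = fm, freq_sib = fs, freq_wt = fw,
                      sibling_p = sp, stringsAsFactors = FALSE)
  funnel <- stats::setNames(
    c(n, vapply(.SEG_CLASSES,
                function(k) sum(calls$classification == k), integer(1)),
      sum(!is.na(calls$sibling_p))),
    c("total", .SEG_CLASSES, "n_tested"))
  keep <- calls$classification == "candidate"
  candidates <- cbind(variants[keep, , drop = FALSE],
                      calls[keep, c("freq_mut", "freq_sib", "freq_wt",
                                    "sibling_p"), drop = FALSE])
  rownames(candidates) <- NULL
  structure(list(candidates = candidates, calls = calls, funnel = funnel),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("Segregation screen funnel\n")
  for (k in names(x$funnel))
    cat(sprintf("  %-28s %d\n", k, x$funnel[[k]]))
  invisible(x)
}
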