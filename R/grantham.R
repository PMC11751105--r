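# Grantham (1974) physicochemical distance between amino acids, used to
# grade substitution severity: low distances are conservative exchanges
# (Ser<->Thr = 58), high distances radical ones (Arg<->Cys = 180).

.GRANTHAM_AA <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                  "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

# Upper triangle, row by row, in the order above.
.GRANTHAM_UPPER <- c(
  110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46, 121,  65,  80, 135, 177,
       102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,  96,  54,  91, 101,
             98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172, 138,  15,  61,
                  38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,  87, 147,
                       58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81, 128,
                            64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148,
                                109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88,
                                     135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184,
                                           21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61,
                                                22, 205, 100, 116, 158, 102, 177, 140,  28,  40,
                                                    194,  83,  99, 143,  85, 160, 122,  36,  37,
                                                         174, 154, 139, 202, 154, 170, 196, 215,
                                                               24,  68,  32,  81,  40,  87, 115,
                                                                    46,  53,  61,  29, 101, 130,
                                                                         94,  23,  42, 142, 174,
                                                                             101,  56,  95, 110,
                                                                                   45, 160, 181,
                                                                                       126, 152,
                                                                                             67)

.grantham_env <- new.env(parent = emptyenv())

#' The Grantham amino-acid distance matrix
#'
#' Symmetric 20x20 matrix of Grantham distances with a zero diagonal,
#' indexed by one-letter amino-acid codes.
#'
#' @return Numeric matrix.
#' @export
grantham_matrix <- function() {
  m <- .grantham_env$matrix
  if (is.null(m)) {
    n <- length(.GRANTHAM_AA)
    m <- matrix(0, n, n, dimnames = list(.GRANTHAM_AA, .GRANTHAM_AA))
    m[upper.tri(m)] <- 0
    k <- 1L
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- .GRANTHAM_UPPER[[k]]
        m[j, i] <- .GRANTHAM_UPPER[[k]]
        k <- k + 1L
      }
    }
    .grantham_env$matrix <- m
  }
  m
}

#' Grantham distance between two amino acids
#'
#' @param aa1,aa2 One-letter amino-acid codes (vectorised). Stop symbols
#'   and nonstandard letters are rejected.
#' @return Numeric distances; 0 for identical residues.
#' @examples
#' grantham_distance("S", "T")  # 58, a conservative exchange
#' grantham_distance("R", "C")  # 180, a radical one
#' @export
grantham_distance <- function(aa1, aa2) {
  aa1 <- toupper(aa1); aa2 <- toupper(aa2)
  bad <- !(aa1 %in% .GRANTHAM_AA) | !(aa2 %in% .GRANTHAM_AA)
  if (any(bad))
    stop(sprintf("no Grantham distance for '%s'/'%s' (stop codons and nonstandard residues are excluded)",
                 aa1[bad][1], aa2[bad][1]))
  m <- grantham_matrix()
  m[cbind(aa1, aa2)]
}

#' Severity class of a substitution distance
#'
#' Bins a Grantham distance into `conservative` (below
#' `conservative_below`), `radical` (above `radical_above`) or `moderate`
#' (in between, boundaries inclusive). The defaults reproduce the two
#' published judgments this scale operationalises: Ser->Thr (58) is a
#' substitution common in natural variation, Arg->Cys (180) a severe one.
#'
#' @param distance Non-negative Grantham distance(s).
#' @param conservative_below,radical_above Class boundaries.
#' @return Character vector of classes.
#' @export
severity_class <- function(distance, conservative_below = 100,
                           radical_above = 150) {
  if (!is.numeric(distance) || anyNA(distance) || any(distance < 0))
    stop("'distance' must be non-negative")
  if (conservative_below > radical_above)
    stop("'conservative_below' cannot exceed 'radical_above'")
  ifelse(distance < conservative_below, "conservative",
         ifelse(distance > radical_above, "radical", "moderate"))
}
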