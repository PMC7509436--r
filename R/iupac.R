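#' @keywords internal
"_PACKAGE"

# Two-base IUPAC ambiguity codes; three/four-base codes (B/D/H/V, N) are not
# valid diploid calls and are handled as missing by the callers.
.IUPAC2 <- c(R = "AG", Y = "CT", M = "AC", K = "GT", W = "AT", S = "CG")

#' Merge two bases into a diploid IUPAC symbol
#'
#' A homozygous pair collapses to the base itself; a heterozygous pair maps to
#' the two-base ambiguity code (A/G -> R, C/T -> Y, A/C -> M, G/T -> K,
#' A/T -> W, C/G -> S).
#'
#' @param a,b Single upper-case bases, each one of `A`, `C`, `G`, `T`.
#' @return A single character: a base or a two-base IUPAC code.
#' @examples
#' iupac_merge("A", "G")  # "R"
#' iupac_merge("C", "C")  # "C"
#' @export
iupac_merge <- function(a, b) {
  stopifnot(length(a) == length(b))
  bad <- !(a %in% c("A", "C", "G", "T")) | !(b %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("iupac_merge: bases must be one of A/C/G/T")
  key <- ifelse(a <= b, paste0(a, b), paste0(b, a))
  out <- ifelse(a == b, a, names(.IUPAC2)[match(key, .IUPAC2)])
  if (anyNA(out)) stop("iupac_merge: unmergeable base pair")
  out
}

#' Expand an IUPAC symbol to its unordered allele pair
#'
#' Plain bases expand to a homozygous pair; two-base ambiguity codes to their
#' heterozygous pair. `N`, gap characters and three-base codes (`B`, `D`,
#' `H`, `V`) yield `NA`: a diploid cannot carry three alleles, so such
#' symbols are treated as missing upstream noise.
#'
#' @param sym A single character symbol.
#' @return A character vector of length 2 (sorted), or `NA` if missing.
#' @export
iupac_expand <- function(sym) {
  if (sym %in% c("A", "C", "G", "T")) return(c(sym, sym))
  if (sym %in% names(.IUPAC2)) {
    p <- .IUPAC2[[sym]]
    return(c(substr(p, 1, 1), substr(p, 2, 2)))
  }
  NA_character_
}
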