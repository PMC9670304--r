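# Bitmask encoding of the IUPAC nucleotide alphabet: A=1, C=2, G=4, T=8.
# The gap "-" is mask 0; N covers all four bases.
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L,
  `-` = 0L
)

# mask -> symbol, indexed mask + 1
.IUPAC_SYM <- {
  s <- character(16L)
  s[.IUPAC_MASK + 1L] <- names(.IUPAC_MASK)
  s
}

.BASES <- c("A", "C", "G", "T")

#' IUPAC alphabet of aligned sequences
#'
#' The 16 symbols accepted everywhere in the package: the four bases, the
#' eleven ambiguity codes, and the gap character `-`.
#'
#' @return Character vector of the 16 symbols.
#' @export
iupac_alphabet <- function() names(.IUPAC_MASK)

# vectorized symbol -> mask; NA for unknown symbols
.mask_of <- function(sym) unname(.IUPAC_MASK[sym])

.sym_of <- function(mask) .IUPAC_SYM[mask + 1L]

.check_symbols <- function(sym, what = "symbol") {
  bad <- is.na(.mask_of(sym))
  if (any(bad)) {
    stop("unknown IUPAC ", what, ": ",
         paste(unique(sym[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(sym)
}

#' Base set of an IUPAC symbol
#'
#' @param code A single IUPAC symbol (one of [iupac_alphabet()]).
#' @return Character vector of bases the symbol stands for; the gap `-`
#'   returns an empty set, `N` returns all four bases.
#' @examples
#' iupac_set("R") # A G
#' iupac_set("-") # character(0)
#' @export
iupac_set <- function(code) {
  stopifnot(length(code) == 1L)
  .check_symbols(code)
  m <- .mask_of(code)
  .BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Merge two IUPAC symbols (character additivity)
#'
#' Returns the unique symbol whose base set is the union of the operands'
#' base sets. This is the additive signal expected in a direct sequence of a
#' hybrid at a site where the parental copies differ: a parent with A and a
#' parent with G yield R in the superimposed electropherogram.
#'
#' Gaps cannot be merged: a site where one parent is gapped and the other
#' carries a base is not expressible in IUPAC and is handled by callers as an
#' indel-polymorphic site.
#'
#' @param a,b IUPAC symbols (vectorized, recycled); gaps are an error.
#' @return The merged symbol(s).
#' @examples
#' iupac_merge("A", "G") # "R"
#' iupac_merge("R", "C") # "V"
#' @export
iupac_merge <- function(a, b) {
  .check_symbols(a)
  .check_symbols(b)
  ma <- .mask_of(a)
  mb <- .mask_of(b)
  if (any(ma == 0L) || any(mb == 0L)) {
    stop("cannot merge a gap with a base; indel additivity is handled ",
         "at the classification layer", call. = FALSE)
  }
  .sym_of(bitwOr(ma, mb))
}

#' Subtract one IUPAC symbol from another (peak subtraction)
#'
#' Removes the known parent's base set from an observed (possibly ambiguous)
#' symbol, yielding the inferred second parental state. When the difference
#' is empty the two copies agree at the site and the subtracted symbol itself
#' is returned.
#'
#' @param code Observed symbol; its base set must contain `base_sym`'s.
#' @param base_sym The known parent's symbol at the site.
#' @return The symbol for `set(code) \ set(base_sym)`, or `base_sym` when the
#'   difference is empty.
#' @examples
#' iupac_subtract("W", "T") # "A"
#' iupac_subtract("A", "A") # "A"
#' @export
iupac_subtract <- function(code, base_sym) {
  .check_symbols(code)
  .check_symbols(base_sym)
  mc <- .mask_of(code)
  mb <- .mask_of(base_sym)
  if (any(bitwAnd(mc, mb) != mb)) {
    stop("base symbol not contained in code at ",
         sum(bitwAnd(mc, mb) != mb), " position(s)", call. = FALSE)
  }
  diff <- bitwAnd(mc, bitwXor(15L, mb))
  out <- .sym_of(diff)
  empty <- diff == 0L
  if (any(empty)) out[empty] <- .sym_of(mb)[empty]
  out
}

# internal: masks for a character matrix of residues (rows = sequences)
.mask_matrix <- function(chr) {
  m <- .IUPAC_MASK[chr]
  if (anyNA(m)) {
    stop("illegal residue symbol(s): ",
         paste(unique(chr[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  matrix(unname(m), nrow = nrow(chr), dimnames = dimnames(chr))
}

# internal: mask vector for one residue string
.mask_string <- function(s) {
  chr <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- unname(.IUPAC_MASK[chr])
  if (anyNA(m)) {
    stop("illegal residue symbol(s): ",
         paste(unique(chr[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  m
}

.string_of_masks <- function(m) paste(.IUPAC_SYM[m + 1L], collapse = "")

# popcount over 4-bit masks (number of bases in the set)
.mask_size <- function(m) {
  bitwAnd(m, 1L) + bitwAnd(bitwShiftR(m, 1L), 1L) +
    bitwAnd(bitwShiftR(m, 2L), 1L) + bitwAnd(bitwShiftR(m, 3L), 1L)
}
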