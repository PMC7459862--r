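# IUPAC nucleotide ambiguity-code algebra: the 15 one-letter codes map
# bijectively onto the 15 non-empty subsets of {A,C,G,T}.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.BASE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# mask -> letter lookup (index = bitwise OR of base bits)
.LETTER_BY_MASK <- local({
  out <- character(15L)
  for (l in names(.IUPAC_SETS)) out[sum(.BASE_BIT[.IUPAC_SETS[[l]]])] <- l
  out
})

.IUPAC_COMP <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N"
)

.iupac_chars <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, names(.IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC letter(s): ", paste(unique(bad), collapse = ", "))
  }
  ch
}

#' IUPAC ambiguity-code base set
#'
#' @param letter A single IUPAC nucleotide code (e.g. `"R"`).
#' @return Character vector of the plain bases the code denotes.
#' @examples
#' iupac_base_set("Y")  # C, T
#' @export
iupac_base_set <- function(letter) {
  letter <- toupper(letter)
  if (!letter %in% names(.IUPAC_SETS)) stop("unknown IUPAC code: ", letter)
  .IUPAC_SETS[[letter]]
}

#' IUPAC code for a set of bases
#'
#' Inverse of [iupac_base_set()]: the unique one-letter code denoting exactly
#' the given non-empty subset of A, C, G, T.
#'
#' @param bases Character vector of plain bases.
#' @return A single IUPAC letter.
#' @examples
#' iupac_code(c("A", "C", "T"))  # "H"
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L || !all(bases %in% names(.BASE_BIT))) {
    stop("bases must be a non-empty subset of {A,C,G,T}")
  }
  .LETTER_BY_MASK[sum(.BASE_BIT[bases])]
}

#' Degeneracy of an IUPAC string
#'
#' The number of distinct non-degenerate sequences a degenerate oligo
#' represents: the product over positions of the ambiguity-set sizes.
#'
#' @param x An IUPAC string or a [`degenerate_primer`][combine_variants]
#'   object.
#' @return Integer-valued numeric.
#' @examples
#' degeneracy("TTYTAYGACTGGTAYKSYGA")  # 64
#' @export
degeneracy <- function(x) {
  ch <- .iupac_chars(as_iupac(x))
  prod(lengths(.IUPAC_SETS[ch]))
}

#' Expand a degenerate oligo into all concrete sequences
#'
#' @param x IUPAC string or degenerate primer object.
#' @param max_degeneracy Refuse to expand beyond this many sequences.
#' @return Character vector of all distinct expansions, lexicographic order;
#'   its length equals [degeneracy()].
#' @examples
#' expand_iupac("AY")  # "AC" "AT"
#' @export
expand_iupac <- function(x, max_degeneracy = 65536) {
  ch <- .iupac_chars(as_iupac(x))
  d <- prod(lengths(.IUPAC_SETS[ch]))
  if (d > max_degeneracy) {
    stop("degeneracy ", d, " exceeds max_degeneracy = ", max_degeneracy,
         "; use the set-membership range functions instead")
  }
  out <- ""
  for (set in .IUPAC_SETS[ch]) {
    out <- paste0(rep(out, each = length(set)), sort(set))
  }
  out
}

#' Reverse complement of an IUPAC string
#'
#' Complements every position's base set (R<->Y, S<->S, ...) and reverses the
#' string, so the result denotes exactly the reverse complements of the
#' original expansions.
#'
#' @param x IUPAC string or degenerate primer object.
#' @return IUPAC string.
#' @examples
#' revcomp_iupac("AYG")  # "CRT"
#' @export
revcomp_iupac <- function(x) {
  ch <- .iupac_chars(as_iupac(x))
  paste(rev(unname(.IUPAC_COMP[ch])), collapse = "")
}

# all 3k strings at Hamming distance exactly 1 from an ACGT k-mer
.hamming1_neighbors <- function(kmer) {
  ch <- strsplit(kmer, "", fixed = TRUE)[[1]]
  out <- character(3L * length(ch))
  i <- 0L
  for (pos in seq_along(ch)) {
    for (alt in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      v <- ch
      v[pos] <- alt
      i <- i + 1L
      out[i] <- paste(v, collapse = "")
    }
  }
  out
}

#' @rdname combine_variants
#' @param x Object to coerce.
#' @export
as_iupac <- function(x) {
  if (inherits(x, "degenerate_primer")) x$iupac_seq else as.character(x)
}
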