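# IUPAC nucleotide alphabet.
#
# Each symbol denotes a set of the four bases, encoded internally as a
# 4-bit mask (A=1, C=2, G=4, T=8). Ambiguity symbols arise in this package
# when aligned reads disagree at a query-anchored site.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

# mask -> symbol, index = mask value 1..15
IUPAC_FROM_MASK <- c("A", "C", "M", "G", "R", "S", "V", "T",
                     "W", "Y", "H", "K", "D", "B", "N")

IUPAC_MASK <- setNames(match(IUPAC_LETTERS, IUPAC_FROM_MASK), IUPAC_LETTERS)

# complement: swap the A<->T and C<->G bits of the base set
IUPAC_COMPLEMENT_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_COMPLEMENT_TO   <- "TGCAYRSWMKVHDBN"

# multi-base (ambiguity) symbols, i.e. everything denoting >= 2 bases
AMBIGUITY_CODES <- c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N")
TWOPLUS_CODES <- setdiff(AMBIGUITY_CODES, "N")

#' IUPAC symbol for a set of bases
#'
#' @param bases character vector of bases from `A`, `C`, `G`, `T`.
#' @return Single IUPAC symbol denoting exactly that base set.
#' @examples
#' iupac_code(c("C", "T"))  # "Y"
#' @export
iupac_code <- function(bases) {
  bases <- toupper(bases)
  if (!length(bases) || !all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be a non-empty subset of {A,C,G,T}")
  mask <- sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[unique(bases)])
  IUPAC_FROM_MASK[mask]
}

#' Base set denoted by an IUPAC symbol
#'
#' @param code single IUPAC symbol.
#' @return Character vector of the bases the symbol denotes.
#' @examples
#' iupac_bases("H")  # A C T
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  if (!code %in% IUPAC_LETTERS) stop("not an IUPAC symbol: ", code)
  mask <- IUPAC_MASK[[code]]
  c("A", "C", "G", "T")[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
}

# Canonicalize a residue string: uppercase, U -> T, validate alphabet.
# Errors name the 1-based position of the first illegal character.
canonicalize_residues <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x)) stop(what, " must be a single string")
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")), x)
  if (bad > 0L)
    stop(sprintf("illegal character '%s' in %s at position %d",
                 substr(x, bad, bad), what, bad))
  x
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity symbols complement as base sets: Y<->R, M<->K, B<->V, D<->H,
#' while S, W and N are self-complementary. The operation is an involution.
#'
#' @param residues IUPAC nucleotide string (case-insensitive; U accepted and
#'   treated as T).
#' @return Upper-case reverse-complemented string.
#' @examples
#' reverse_complement("AYGN")  # "NCRT"
#' @export
reverse_complement <- function(residues) {
  residues <- canonicalize_residues(residues)
  comp <- chartr(IUPAC_COMPLEMENT_FROM, IUPAC_COMPLEMENT_TO, residues)
  if (nchar(comp) <= 1L) return(comp)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# fast vectorised reverse-complement for plain ACGT fragments (simulator path)
rc_acgt <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# circular substring: 0-based start, wraps around the origin as needed
circ_substr <- function(seq, start0, len) {
  L <- nchar(seq)
  start0 <- ((start0 %% L) + L) %% L
  if (start0 + len <= L) return(substr(seq, start0 + 1L, start0 + len))
  n_rep <- ceiling((start0 + len) / L)
  ext <- paste(rep(seq, n_rep), collapse = "")
  substr(ext, start0 + 1L, start0 + len)
}
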