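# IUPAC nucleotide code utilities shared across modules.

# Constituent-base sets for every IUPAC code accepted in alignments.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

VALID_RESIDUES <- c(names(IUPAC_SETS), "-")

#' IUPAC code covering a set of bases
#'
#' @param bases character vector drawn from A, C, G, T.
#' @return single IUPAC letter whose constituent set equals `unique(bases)`.
#' @examples
#' iupac_code(c("C", "T")) # "Y"
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  stopifnot(all(bases %in% c("A", "C", "G", "T")), length(bases) >= 1)
  key <- paste(bases, collapse = "")
  hit <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = "") == key,
                logical(1))
  names(IUPAC_SETS)[hit][1]
}

#' Constituent bases of an IUPAC code
#'
#' @param code single IUPAC letter (gap not allowed).
#' @return character vector of A/C/G/T constituents.
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  if (is.null(IUPAC_SETS[[code]])) {
    stop("not an IUPAC nucleotide code: '", code, "'", call. = FALSE)
  }
  IUPAC_SETS[[code]]
}

#' Do two IUPAC codes share at least one constituent base?
#'
#' Gaps never match anything (including another gap).
#' @param a,b single characters (IUPAC or "-").
#' @return logical.
#' @export
iupac_compatible <- function(a, b) {
  if (a == "-" || b == "-") return(FALSE)
  length(intersect(iupac_bases(a), iupac_bases(b))) > 0
}

#' Complement / reverse-complement of an IUPAC string
#'
#' Gap characters are preserved.
#' @param x character string of IUPAC residues.
#' @return complemented (same order) or reverse-complemented string.
#' @export
complement_seq <- function(x) {
  chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
         "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
}

#' @rdname complement_seq
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_seq(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Expand a degenerate IUPAC string into all concrete sequences
#'
#' @param bases IUPAC string (no gaps).
#' @param cap maximum number of expansions allowed before erroring.
#' @return character vector of A/C/G/T strings, in deterministic order.
#' @export
expand_degenerate <- function(bases, cap = 256L) {
  chars <- strsplit(toupper(bases), "", fixed = TRUE)[[1]]
  sets <- lapply(chars, iupac_bases)
  n <- prod(vapply(sets, length, integer(1)))
  if (n > cap) {
    stop("degenerate expansion count ", n, " exceeds cap ", cap,
         "; resolve ambiguities first", call. = FALSE)
  }
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

n_expansions <- function(bases) {
  chars <- strsplit(toupper(bases), "", fixed = TRUE)[[1]]
  prod(vapply(chars, function(ch) length(iupac_bases(ch)), numeric(1)))
}
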