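# Oligonucleotide representation shared by the design and thermo modules.

#' Construct an oligonucleotide
#'
#' An oligo is a 5'->3' IUPAC base string with a parallel per-position
#' chemistry vector (`"DNA"` or `"LNA"`), an optional 3' modification and an
#' optional 5' extension (e.g. a GC clamp for DGGE). LNA chemistry is never
#' allowed on a degenerate position: the thermodynamic increments for a
#' locked degenerate base are undefined.
#'
#' @param bases 5'->3' IUPAC string (no gaps).
#' @param name oligo name.
#' @param chemistry character vector over `{"DNA","LNA"}` of the same length
#'   as `bases`, or NULL for all-DNA.
#' @param three_prime_mod `"none"` or `"phosphate"` (a 3' phosphate blocks
#'   polymerase extension, turning the oligo into a pure clamp).
#' @param five_prime_extension plain DNA string prepended at the 5' end
#'   (empty by default); excluded from Tm computations, which concern the
#'   annealing portion only.
#' @return object of class `lna_oligo`.
#' @export
oligo <- function(bases, name = "oligo", chemistry = NULL,
                  three_prime_mod = c("none", "phosphate"),
                  five_prime_extension = "") {
  three_prime_mod <- match.arg(three_prime_mod)
  bases <- normalize_residues(bases)
  if (grepl("-", bases, fixed = TRUE)) {
    stop("oligo bases may not contain gaps", call. = FALSE)
  }
  n <- nchar(bases)
  if (is.null(chemistry)) chemistry <- rep("DNA", n)
  if (length(chemistry) != n) {
    stop("chemistry vector length (", length(chemistry),
         ") does not match oligo length (", n, ")", call. = FALSE)
  }
  if (!all(chemistry %in% c("DNA", "LNA"))) {
    stop("chemistry entries must be 'DNA' or 'LNA'", call. = FALSE)
  }
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  degen <- !(chars %in% c("A", "C", "G", "T"))
  if (any(degen & chemistry == "LNA")) {
    stop("LNA chemistry on degenerate position(s) ",
         paste(which(degen & chemistry == "LNA"), collapse = ", "),
         call. = FALSE)
  }
  if (nzchar(five_prime_extension)) {
    five_prime_extension <- normalize_residues(five_prime_extension)
  }
  structure(list(name = name, bases = bases, chemistry = chemistry,
                 three_prime_mod = three_prime_mod,
                 five_prime_extension = five_prime_extension),
            class = "lna_oligo")
}

#' LNA positions of an oligo
#' @param x an `lna_oligo`.
#' @return 1-based integer vector.
#' @export
lna_positions <- function(x) which(x$chemistry == "LNA")

#' Full synthesis string of an oligo (extension + annealing bases)
#' @param x an `lna_oligo`.
#' @export
oligo_sequence <- function(x) paste0(x$five_prime_extension, x$bases)

#' @export
print.lna_oligo <- function(x, ...) {
  cat("<lna_oligo> ", x$name, "\n", sep = "")
  disp <- x$bases
  if (nzchar(x$five_prime_extension)) {
    disp <- paste0("[", x$five_prime_extension, "]", disp)
  }
  cat("  5'-", disp,
      if (x$three_prime_mod == "phosphate") "p" else "", "-3'  (",
      nchar(x$bases), " nt", if (nzchar(x$five_prime_extension))
        paste0(" + ", nchar(x$five_prime_extension), " nt 5' extension"),
      ")\n", sep = "")
  lp <- lna_positions(x)
  if (length(lp)) cat("  LNA positions (1-based):",
                      paste(lp, collapse = ", "), "\n")
  invisible(x)
}

#' Lowercase-DNA / uppercase-LNA text rendering of an oligo
#'
#' @param x an `lna_oligo`.
#' @return single character string; DNA bases lowercase, LNA bases uppercase.
#' @export
format_chemistry <- function(x) {
  chars <- strsplit(x$bases, "", fixed = TRUE)[[1]]
  chars <- ifelse(x$chemistry == "LNA", toupper(chars), tolower(chars))
  paste(chars, collapse = "")
}
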