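# Clamped-PCR protocol emission: thermal program with the extra
# clamp-annealing step, clamp-concentration titration series, and DGGE-ready
# nested primers (GC-clamp attachment).

#' 40-base GC clamp used for DGGE forward primers
#' @export
GC_CLAMP_40 <- "CGCCCGCCGCGCGCGGCGGGCGGGGCGGGGGCACGGGGGG"

#' Build the clamped-PCR thermal program and titration plan
#'
#' The clamp-annealing step sits between denaturation and the primer
#' annealing step of every cycle, at the temperature recommended by
#' [recommend_clamp_annealing()]: hot enough that the amplification primers
#' are non-functional, cool enough that the clamp still hybridizes.
#'
#' @param primer_tms list of `tm_estimate`s for the amplification primers.
#' @param clamp_tm `tm_estimate` for the clamp oligonucleotide.
#' @param cycles number of PCR cycles.
#' @param primer_anneal_C primer annealing temperature, degC.
#' @param primer_concentration_uM per-primer concentration, micromolar.
#' @param extended_titration also include the high-concentration points used
#'   for recalcitrant (plant-DNA-rich) samples.
#' @param primer_ceiling_offset see [recommend_clamp_annealing()].
#' @return list of class `protocol_spec` with fields `steps` (data.frame:
#'   label, temperature_C, duration_s, cycled), `cycles`,
#'   `primer_concentration_uM`, `clamp_concentrations_uM`, `notes`.
#' @export
build_clamping_program <- function(primer_tms, clamp_tm, cycles = 40L,
                                   primer_anneal_C = 54,
                                   primer_concentration_uM = 0.8,
                                   extended_titration = FALSE,
                                   primer_ceiling_offset = 4) {
  if (cycles < 1) stop("cycle count must be at least 1", call. = FALSE)
  clamp_anneal <- recommend_clamp_annealing(primer_tms, clamp_tm,
                                            primer_ceiling_offset)
  steps <- data.frame(
    label = c("initial denaturation", "denaturation", "clamp annealing",
              "primer annealing", "extension", "final extension"),
    temperature_C = c(94, 94, clamp_anneal, primer_anneal_C, 72, 72),
    duration_s = c(180L, 60L, 60L, 60L, 120L, 600L),
    cycled = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  titration <- c(0, 0.5, 1.0, 2.0, 3.0, 4.0)
  if (extended_titration) titration <- c(titration, 6.0, 8.0)
  validate_protocol(structure(list(
    steps = steps, cycles = as.integer(cycles),
    primer_concentration_uM = primer_concentration_uM,
    clamp_concentrations_uM = titration,
    notes = paste("Clamp annealing step added between denaturation and the",
                  "primer annealing step of each cycle.")),
    class = "protocol_spec"))
}

validate_protocol <- function(p) {
  stopifnot(all(p$steps$temperature_C >= 4), all(p$steps$temperature_C <= 99),
            all(p$steps$duration_s > 0))
  r <- rle(p$steps$cycled)
  if (sum(r$values) != 1) {
    stop("protocol must contain exactly one contiguous cycled block",
         call. = FALSE)
  }
  p
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec>\n")
  for (i in seq_len(nrow(x$steps))) {
    s <- x$steps[i, ]
    cat(sprintf("  %s%-22s %2d degC  %4d s\n",
                if (s$cycled) sprintf("[x%d] ", x$cycles) else "     ",
                s$label, as.integer(s$temperature_C), s$duration_s))
  }
  cat("  primers:", x$primer_concentration_uM, "uM each; clamp titration:",
      paste(x$clamp_concentrations_uM, collapse = ", "), "uM\n")
  invisible(x)
}

#' Serialize a protocol to YAML-format text
#' @param p a `protocol_spec`.
#' @param path output file, or NULL to return the text.
#' @export
write_protocol_yaml <- function(p, path = NULL) {
  obj <- list(steps = lapply(seq_len(nrow(p$steps)), function(i)
                as.list(p$steps[i, ])),
              cycles = p$cycles,
              primer_concentration_uM = p$primer_concentration_uM,
              clamp_concentrations_uM = p$clamp_concentrations_uM,
              notes = p$notes)
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read back a YAML protocol
#' @param path file written by [write_protocol_yaml()].
#' @return a `protocol_spec`.
#' @export
read_protocol_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  steps <- do.call(rbind, lapply(obj$steps, as.data.frame))
  validate_protocol(structure(list(
    steps = steps, cycles = as.integer(obj$cycles),
    primer_concentration_uM = obj$primer_concentration_uM,
    clamp_concentrations_uM = as.numeric(obj$clamp_concentrations_uM),
    notes = obj$notes), class = "protocol_spec"))
}

#' Serialize a protocol's thermal steps as TSV
#' @param p a `protocol_spec`.
#' @param path output file.
#' @export
write_protocol_tsv <- function(p, path) {
  utils::write.table(cbind(p$steps, cycles = ifelse(p$steps$cycled,
                                                    p$cycles, 1L)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a 5' GC clamp to a primer for DGGE
#'
#' @param primer an [oligo()] with an empty 5' extension.
#' @param clamp_seq GC-rich extension (default the standard 40-mer).
#' @return the primer with `five_prime_extension` set (extension chemistry is
#'   plain DNA).
#' @export
attach_gc_clamp <- function(primer, clamp_seq = GC_CLAMP_40) {
  if (nzchar(primer$five_prime_extension)) {
    stop("primer already carries a 5' extension", call. = FALSE)
  }
  clamp_seq <- gsub("\\s", "", clamp_seq)
  oligo(primer$bases, name = paste0(primer$name, "-GC"),
        chemistry = primer$chemistry, three_prime_mod = primer$three_prime_mod,
        five_prime_extension = clamp_seq)
}

#' Two-stage nested amplification plan for DGGE
#'
#' Stage 1 amplifies the whole ITS region with the LNA forward primer, the
#' universal reverse primer, and the host-specific clamp; the product is
#' diluted 1e3- to 1e4-fold and re-amplified with the GC-clamped forward
#' primer and the internal reverse primer for DGGE.
#'
#' @param forward_lna,reverse_primer,clamp,nested_forward_gc,nested_reverse
#'   oligo names or [oligo()]s included for the bench sheet.
#' @return character vector of plan lines.
#' @export
nested_pcr_plan <- function(forward_lna, reverse_primer, clamp,
                            nested_forward_gc, nested_reverse) {
  nm <- function(x) if (inherits(x, "lna_oligo")) x$name else as.character(x)
  c(paste0("Round 1: ", nm(forward_lna), " + ", nm(reverse_primer),
           " with clamp ", nm(clamp), " (clamped program)"),
    "Dilute round-1 product 1e3- to 1e4-fold before nested amplification.",
    paste0("Round 2 (DGGE): ", nm(nested_forward_gc), " + ",
           nm(nested_reverse)))
}
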