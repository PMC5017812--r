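# End-to-end convenience wrappers over the design modules.

#' Design the fungus-specific degenerate LNA forward primer from an alignment
#'
#' Profiles the target and each non-target host group over the forward primer
#' window, builds the degenerate consensus, finds fungus-discriminating
#' positions, and plans LNA substitutions there.
#'
#' @param aln forward-window `lna_alignment` (targets labelled `target:*`,
#'   hosts `nontarget:*`).
#' @param config a [design_config()].
#' @param cond a [conditions()] object.
#' @param name primer base name.
#' @return list of class `primer_design`: `dna_primer`, `lna_primer`,
#'   `discriminating`, `tm_dna`, `tm_lna`.
#' @export
design_forward_primer <- function(aln, config = design_config(),
                                  cond = conditions(), name = "fwd_KU") {
  tprof <- column_profiles(aln, "target:")
  host_groups <- unique(grep("^nontarget:", aln$groups, value = TRUE))
  if (length(host_groups) == 0) stop("no non-target rows in alignment",
                                     call. = FALSE)
  nprof <- lapply(host_groups, function(g) column_profiles(aln, g))
  names(nprof) <- host_groups
  dna <- degenerate_consensus(tprof, config$minor_freq_threshold,
                              name = paste(name, "DNA"))
  disc <- discriminating_positions(tprof, nprof,
                                   target_purity = config$target_purity,
                                   nontarget_purity = config$nontarget_purity)
  lna <- plan_lna(dna, disc, config)
  lna$name <- paste(name, "LNA")
  structure(list(dna_primer = dna, lna_primer = lna, discriminating = disc,
                 tm_dna = tm_oligo(dna, cond), tm_lna = tm_oligo(lna, cond)),
            class = "primer_design")
}

#' @export
print.primer_design <- function(x, ...) {
  cat("<primer_design>\n")
  cat("  DNA primer:", x$dna_primer$bases, "\n")
  cat("  LNA primer:", format_chemistry(x$lna_primer),
      "(uppercase = LNA)\n")
  cat("  discriminating positions:",
      paste(x$discriminating$column, collapse = ", "), "\n")
  cat(sprintf("  Tm (LNA primer): %.1f degC (range %.1f-%.1f over %d expansions)\n",
              x$tm_lna$tm, x$tm_lna$tm_min, x$tm_lna$tm_max,
              x$tm_lna$n_expansions))
  invisible(x)
}

#' Design one clamp per host type from a reverse-side alignment
#'
#' Partitions the non-target rows into identical-sequence types over the
#' clamp design region, then designs a blocking clamp for each type.
#'
#' @param aln reverse-side `lna_alignment`.
#' @param anchor reverse-primer 3'-terminal annealing column (defaults to the
#'   alignment's `anchor` attribute when present).
#' @param config a [design_config()].
#' @param cond a [conditions()] object.
#' @param screen logical; run [screen_cross_reactivity()] against the target
#'   rows and store the result on each design.
#' @return named list of `clamp_design`s (one per host type, names are the
#'   representative host labels).
#' @export
design_host_clamps <- function(aln, anchor = attr(aln, "anchor"),
                               config = design_config(), cond = conditions(),
                               screen = TRUE) {
  if (is.null(anchor)) stop("reverse primer anchor must be given",
                            call. = FALSE)
  hosts <- subset_records(aln, groups = "nontarget:")
  targets <- subset_records(aln, groups = "target:")
  tprof <- column_profiles(targets)
  types <- group_by_identity(hosts, max(1L, anchor - 25L),
                             min(aln$n_cols, anchor + 1L))
  out <- list()
  for (tp in unique(types$type)) {
    member_ids <- types$id[types$type == tp]
    win <- subset_records(hosts, ids = member_ids)
    cd <- design_clamp(win, anchor, tprof, config, cond)
    if (screen) cd$screen <- screen_cross_reactivity(cd, targets)
    out[[cd$host_type]] <- cd
  }
  out
}
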