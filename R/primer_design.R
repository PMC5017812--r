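# Degenerate target-specific primer construction and LNA substitution
# planning (the ITS1F KU DNA -> ITS1F KU LNA pathway).

#' Design configuration
#'
#' Aggregates the tunable thresholds of the design pipeline. Defaults:
#' a minor variant earns a degeneracy at >= 5% frequency (the source designs
#' added degeneracies for variants present "at a certain percentage" without
#' quantifying); purity thresholds for calling a base specific are 0.95;
#' clamp Tm is tuned to 70 degC within +/- 2.5 degC (the accepted reference
#' clamps span 68-72 degC around the ~70 degC working point).
#'
#' @param minor_freq_threshold minimum frequency for a minor base to enter
#'   the degenerate consensus.
#' @param target_purity,nontarget_purity purity thresholds for
#'   [discriminating_positions()].
#' @param max_lna maximum LNA substitutions in a primer.
#' @param max_lna_clamp maximum LNA substitutions in a clamp.
#' @param lna_min_spacing minimum column spacing hint for primer LNA picks.
#' @param tm_target clamp melting-temperature target, degC.
#' @param tm_tolerance acceptance half-width around `tm_target`, degC.
#' @param overlap_range allowed clamp/reverse-primer overlaps (bases).
#' @param clamp_length_range candidate clamp lengths, nt.
#' @return list of class `design_config`.
#' @export
design_config <- function(minor_freq_threshold = 0.05,
                          target_purity = 0.95, nontarget_purity = 0.95,
                          max_lna = 4L, max_lna_clamp = 6L,
                          lna_min_spacing = 1L,
                          tm_target = 70, tm_tolerance = 2.5,
                          overlap_range = c(1L, 2L),
                          clamp_length_range = c(20L, 25L)) {
  stopifnot(minor_freq_threshold >= 0, minor_freq_threshold <= 1,
            target_purity >= 0, target_purity <= 1,
            nontarget_purity >= 0, nontarget_purity <= 1,
            max_lna >= 1, max_lna_clamp >= 1,
            tm_tolerance >= 0,
            all(overlap_range %in% 1:2),
            clamp_length_range[1] <= clamp_length_range[2])
  structure(list(minor_freq_threshold = minor_freq_threshold,
                 target_purity = target_purity,
                 nontarget_purity = nontarget_purity,
                 max_lna = as.integer(max_lna),
                 max_lna_clamp = as.integer(max_lna_clamp),
                 lna_min_spacing = as.integer(lna_min_spacing),
                 tm_target = tm_target, tm_tolerance = tm_tolerance,
                 overlap_range = as.integer(sort(unique(overlap_range))),
                 clamp_length_range = as.integer(clamp_length_range)),
            class = "design_config")
}

#' Read a design configuration from a key:value file
#'
#' Accepts a flat YAML / `key: value` text file; unknown keys are rejected.
#'
#' @param path config file.
#' @return a [design_config()].
#' @export
read_design_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(design_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(design_config, vals)
}

#' Degenerate consensus of target column profiles
#'
#' Per column, emits the IUPAC code covering the modal base plus every base
#' whose frequency reaches `minor_freq_threshold`. A column needing all four
#' bases emits `N` with a warning.
#'
#' @param target_profiles `column_profiles` for the target rows.
#' @param minor_freq_threshold see [design_config()].
#' @param name name for the resulting oligo.
#' @return an all-DNA [oligo()].
#' @export
degenerate_consensus <- function(target_profiles,
                                 minor_freq_threshold = 0.05,
                                 name = "consensus") {
  if (nrow(target_profiles) == 0) stop("empty profile set", call. = FALSE)
  codes <- vapply(seq_len(nrow(target_profiles)), function(k) {
    f <- unlist(target_profiles[k, c("A", "C", "G", "T")])
    if (max(f) <= 0) stop("column ", target_profiles$col[k],
                          " has no observed bases", call. = FALSE)
    keep <- union(names(f)[which.max(f)],
                  names(f)[f >= minor_freq_threshold])
    if (length(keep) == 4) {
      warning("column ", target_profiles$col[k],
              " requires all four bases; emitting N", call. = FALSE)
    }
    iupac_code(keep)
  }, character(1))
  oligo(paste(codes, collapse = ""), name = name)
}

#' Plan LNA substitutions at target-discriminating positions
#'
#' Marks chemistry LNA at discriminating, non-degenerate primer positions.
#' When more eligible positions exist than `max_lna`, positions mismatching
#' more non-target groups are preferred, then positions nearer the 3' end
#' (a 3'-terminal LNA is permitted). Base letters are never altered; with no
#' eligible position the primer is returned unchanged with a warning.
#'
#' @param primer an [oligo()]; any existing LNA flags are recomputed.
#' @param discriminating data.frame from [discriminating_positions()], whose
#'   `column` values are positions within the primer window (1-based).
#' @param config a [design_config()].
#' @return the primer with updated chemistry.
#' @export
plan_lna <- function(primer, discriminating, config = design_config()) {
  # chemistry is recomputed from scratch, so the operation is idempotent
  n <- nchar(primer$bases)
  cols <- discriminating$column
  if (any(cols < 1 | cols > n)) {
    stop("discriminating positions fall outside the primer window",
         call. = FALSE)
  }
  chars <- strsplit(primer$bases, "", fixed = TRUE)[[1]]
  degen <- !(chars %in% c("A", "C", "G", "T"))
  skip <- cols[degen[cols]]
  if (length(skip) > 0) {
    warning("skipping degenerate position(s) ", paste(skip, collapse = ", "),
            ": LNA is not planned on degenerate bases", call. = FALSE)
  }
  elig <- discriminating[!degen[cols], , drop = FALSE]
  if (nrow(elig) == 0) {
    warning("no eligible positions for LNA substitution; primer unchanged",
            call. = FALSE)
    return(primer)
  }
  strength <- vapply(strsplit(elig$nontarget_bases, ","), length, integer(1))
  ord <- order(-strength, -elig$column)
  chosen <- sort(elig$column[ord][seq_len(min(config$max_lna, nrow(elig)))])
  chem <- rep("DNA", n)
  chem[chosen] <- "LNA"
  oligo(primer$bases, name = sub(" DNA$", "", primer$name),
        chemistry = chem, three_prime_mod = primer$three_prime_mod,
        five_prime_extension = primer$five_prime_extension)
}
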