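# Nearest-neighbor melting-temperature prediction for DNA and
# LNA-substituted oligonucleotides.
#
# Duplex enthalpy/entropy are summed over dinucleotide stacks using the
# unified DNA parameter set (SantaLucia 1998), with per-position LNA
# modification increments added to each stack flanking a locked base
# (McTigue-style accounting; the shipped increment table is the package's
# own calibrated set, see inst/extdata/lna_increments_calibrated.tsv).
# Entropy is salt-corrected, and Tm follows from dH / (dS + R ln(CT/x)).

.thermo_env <- new.env(parent = emptyenv())

load_param_table <- function(file) {
  key <- file
  if (is.null(.thermo_env[[key]])) {
    path <- system.file("extdata", file, package = "lnaclamp")
    if (!nzchar(path)) stop("parameter table not found: ", file,
                            call. = FALSE)
    .thermo_env[[key]] <- utils::read.table(path, sep = "\t", header = TRUE,
                                            comment.char = "#",
                                            stringsAsFactors = FALSE)
  }
  .thermo_env[[key]]
}

#' Reaction conditions for Tm prediction
#'
#' Defaults are the package's frozen calibration: they were fitted once
#' against the printed melting temperatures of the reference clamp
#' oligonucleotides (~68-72 degC) and the degenerate LNA forward primer range
#' (59-62 degC), because the vendor calculator the original designs used does
#' not disclose its salt/concentration assumptions. Divalent cations enter
#' through the von Ahsen equivalence `Na_eq = Na + 120 * sqrt(Mg)` (mM).
#'
#' @param monovalent_mM monovalent cation concentration, mM.
#' @param divalent_mM divalent cation concentration, mM.
#' @param oligo_uM total oligonucleotide strand concentration, micromolar.
#' @param parameter_set identifiers of the shipped parameter tables.
#' @return list of class `tm_conditions`.
#' @export
conditions <- function(monovalent_mM = 240, divalent_mM = 0,
                       oligo_uM = 0.8,
                       parameter_set = c(dna_nn = "nn_dna_santalucia1998.tsv",
                                         lna_increment =
                                           "lna_increments_calibrated.tsv")) {
  if (monovalent_mM <= 0 || oligo_uM <= 0 || divalent_mM < 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 oligo_uM = oligo_uM, parameter_set = parameter_set),
            class = "tm_conditions")
}

R_GAS <- 1.9872  # cal / (mol K)

dimer_params <- function(tab) {
  p <- tab[!startsWith(tab$param, "init") & tab$param != "sym", ]
  dh <- stats::setNames(p$dH, p$param)
  ds <- stats::setNames(p$dS, p$param)
  # fill the 6 dimers stored via their reverse complements
  all16 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  for (d in all16) {
    if (is.na(dh[d])) {
      rcd <- revcomp(d)
      dh[d] <- dh[rcd]
      ds[d] <- ds[rcd]
    }
  }
  list(dH = dh, dS = ds,
       init = list(
         GC = c(dH = tab$dH[tab$param == "init_GC"],
                dS = tab$dS[tab$param == "init_GC"]),
         AT = c(dH = tab$dH[tab$param == "init_AT"],
                dS = tab$dS[tab$param == "init_AT"])),
       sym = c(dH = tab$dH[tab$param == "sym"],
               dS = tab$dS[tab$param == "sym"]))
}

# dH (kcal/mol) and dS (cal/mol/K) for one concrete A/C/G/T sequence with a
# given set of LNA positions, before salt correction.
nn_sums <- function(seq_chars, lna_pos, dna_tab, lna_tab) {
  p <- dimer_params(dna_tab)
  n <- length(seq_chars)
  dH <- 0
  dS <- 0
  for (i in seq_len(n - 1L)) {
    d <- paste0(seq_chars[i], seq_chars[i + 1L])
    dH <- dH + p$dH[[d]]
    dS <- dS + p$dS[[d]]
  }
  for (term in c(1L, n)) {
    cls <- if (seq_chars[term] %in% c("G", "C")) "GC" else "AT"
    dH <- dH + p$init[[cls]][["dH"]]
    dS <- dS + p$init[[cls]][["dS"]]
  }
  s <- paste(seq_chars, collapse = "")
  if (identical(s, revcomp(s))) {
    dH <- dH + p$sym[["dH"]]
    dS <- dS + p$sym[["dS"]]
  }
  # Each locked base adds its increment to every stack it participates in
  # (two for an internal LNA, one at a terminus); a stack flanked by two
  # locked bases therefore receives both contributions.
  for (pos in lna_pos) {
    base <- seq_chars[pos]
    row <- lna_tab[lna_tab$base == base, ]
    n_stacks <- sum(c(pos > 1L, pos < n))
    dH <- dH + n_stacks * row$dH_inc
    dS <- dS + n_stacks * row$dS_inc
  }
  c(dH = dH, dS = dS)
}

tm_from_sums <- function(dH, dS, cond, n_bases, self_comp = FALSE) {
  na_eq <- (cond$monovalent_mM +
              120 * sqrt(max(cond$divalent_mM, 0))) / 1000
  dS_salt <- dS + 0.368 * (n_bases - 1L) * log(na_eq)
  ct <- cond$oligo_uM * 1e-6
  x <- if (self_comp) 1 else 4
  dH * 1000 / (dS_salt + R_GAS * log(ct / x)) - 273.15
}

#' Predict the melting temperature of a (possibly LNA-substituted) oligo
#'
#' For degenerate oligos every IUPAC expansion (capped at `cap`) is evaluated
#' and the median is reported as the headline `tm`, with `tm_min`/`tm_max`
#' always surfaced. LNA chemistry on a degenerate position is rejected at
#' [oligo()] construction.
#'
#' @param x an [oligo()] or an IUPAC string.
#' @param cond a [conditions()] object.
#' @param lna 1-based LNA positions, used only when `x` is a plain string.
#' @param cap maximum number of degenerate expansions.
#' @return list of class `tm_estimate`: `tm`, `tm_min`, `tm_max`,
#'   `n_expansions`, `conditions`.
#' @export
tm_oligo <- function(x, cond = conditions(), lna = NULL, cap = 256L) {
  if (!inherits(x, "lna_oligo")) {
    chem <- NULL
    if (!is.null(lna)) {
      chem <- rep("DNA", nchar(x))
      chem[lna] <- "LNA"
    }
    x <- oligo(x, chemistry = chem)
  }
  n <- nchar(x$bases)
  if (n < 8) stop("oligo too short for nearest-neighbor prediction (", n,
                  " < 8 nt)", call. = FALSE)
  dna_tab <- load_param_table(cond$parameter_set[["dna_nn"]])
  lna_tab <- load_param_table(cond$parameter_set[["lna_increment"]])
  expansions <- expand_degenerate(x$bases, cap = cap)
  lna_pos <- lna_positions(x)
  tms <- vapply(expansions, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sums <- nn_sums(chars, lna_pos, dna_tab, lna_tab)
    tm_from_sums(sums[["dH"]], sums[["dS"]], cond, n,
                 self_comp = identical(s, revcomp(s)))
  }, numeric(1), USE.NAMES = FALSE)
  structure(list(tm = stats::median(tms), tm_min = min(tms),
                 tm_max = max(tms), n_expansions = length(tms),
                 conditions = cond),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  if (x$n_expansions > 1) {
    cat(sprintf("<tm_estimate> %.1f degC (median of %d expansions; range %.1f-%.1f)\n",
                x$tm, x$n_expansions, x$tm_min, x$tm_max))
  } else {
    cat(sprintf("<tm_estimate> %.1f degC\n", x$tm))
  }
  invisible(x)
}

#' Recommend the clamp annealing temperature for a clamped-PCR program
#'
#' The clamp-annealing step must be hot enough that the amplification primers
#' are non-functional (their functional ceiling is `tm_max` plus
#' `primer_ceiling_offset`), yet no hotter than the clamp can tolerate
#' (at most 1 degC above the clamp's own Tm, or hybridization efficiency is
#' lost).
#'
#' @param primer_tms list of one or more `tm_estimate`s for the
#'   amplification primers.
#' @param clamp_tm a `tm_estimate` for the clamp.
#' @param primer_ceiling_offset degC added to the hottest primer tm_max to
#'   obtain the temperature at which primers stop priming (default 4,
#'   matching primers with Tm up to 62 degC being functional to ~66 degC).
#' @return recommended annealing temperature, integer degC.
#' @export
recommend_clamp_annealing <- function(primer_tms, clamp_tm,
                                      primer_ceiling_offset = 4) {
  if (inherits(primer_tms, "tm_estimate")) primer_tms <- list(primer_tms)
  primer_max <- max(vapply(primer_tms, function(t) t$tm_max, numeric(1)))
  if (clamp_tm$tm <= primer_max) {
    stop("design infeasible: clamp Tm (", round(clamp_tm$tm, 1),
         " degC) does not exceed the hottest primer Tm (",
         round(primer_max, 1), " degC)", call. = FALSE)
  }
  ceiling_t <- primer_max + primer_ceiling_offset
  rec <- max(ceiling_t, round(clamp_tm$tm))
  if (rec > clamp_tm$tm + 1) {
    stop("design infeasible: primers remain functional up to ",
         round(ceiling_t, 1), " degC, above the clamp's usable range (Tm ",
         round(clamp_tm$tm, 1), " + 1 degC)", call. = FALSE)
  }
  as.integer(round(rec))
}
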