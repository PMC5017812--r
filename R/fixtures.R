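# Seeded synthetic alignment generator.
#
# The generator emulates the statistical structure of the published
# forward-side (fungal ITS1F window) and reverse-side (ITS4-competition
# window) alignments at reduced scale, so every design stage is testable
# without database downloads. All randomness is fixed by the spec seed.

# Canonical sequence constants for the fungal ITS primer system.
ITS1F_SEQ <- "CTTGGTCATTTAGAGGAAGTAA"
ITS4_SEQ <- "TCCTCCGCTTATTGATATGC"
ITS2_SEQ <- "GCTGCGTTCTTCATCGATGC"

# Reverse-side template layout (coding strand, 5'->3'): a 4-column conserved
# flank, the 22-column clamp-design region, then the 19 remaining columns of
# the reverse-primer annealing site. The fungal row is the canonical 5'-28S
# flank; host windows are the reverse complements of the three host-blocking
# clamp sites and differ from the fungal row at 3-4 aligned positions.
REV_FLANK <- "GGTA"
REV_FUNGAL_CORE <- "AGGACTACCCGCTGAACTTAAG"
REV_TAIL <- "CATATCAATAAGCGGAGGA"
REV_HOST_CORES <- c(
  wheat   = "GGGACTACCCGCTGAGTTTAAG",
  soybean = "GGGGCTACCCGCTGAGTTTAAG",
  potato  = "GGGATTACCCGCTGAGTTTAAG")
HOST_TYPE_MEMBERS <- list(
  wheat   = c("wheat", "rice", "maize", "melon", "carrot"),
  soybean = c("soybean", "spinach", "peanut", "banana"),
  potato  = c("potato", "thale_cress", "tomato", "sweet_potato",
              "coffee", "orange", "cotton", "jute"))

#' Specification for the synthetic alignment generator
#'
#' Defaults encode the study conditions at reduced scale: three target phyla
#' at 200 rows each (the published alignments used thousands of rows, which
#' add nothing to design correctness), minor C variants in Ascomycota at
#' forward-window columns 3 and 19 at 30% within-phylum frequency (about 10%
#' overall, comfortably above the 5% degeneracy threshold), host plants
#' carrying their diagnostic bases, and a low background substitution rate on
#' the forward side emulating incidental database variation.
#'
#' @param seed integer; fixes all randomness.
#' @param n_per_phylum named counts for Ascomycota, Basidiomycota,
#'   Glomeromycota target rows.
#' @param minor_variant_freqs named list: forward-window column ->
#'   `list(base=, freq=, phylum=)`.
#' @param noise_rate background substitution probability per base applied to
#'   forward-side fungal rows outside the structured columns.
#' @param n_outgroup optional count of protozoa-like outgroup rows (coverage
#'   contrast), default 0.
#' @param planted_match plant one fungal row identical to the wheat-type
#'   reverse window, for cross-reactivity screen testing.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_per_phylum = c(Ascomycota = 200L,
                                          Basidiomycota = 200L,
                                          Glomeromycota = 200L),
                         minor_variant_freqs = list(
                           `3` = list(base = "C", freq = 0.30,
                                      phylum = "Ascomycota"),
                           `19` = list(base = "C", freq = 0.30,
                                       phylum = "Ascomycota")),
                         noise_rate = 0.005,
                         n_outgroup = 0L,
                         planted_match = FALSE) {
  stopifnot(length(seed) == 1, is.finite(seed),
            all(n_per_phylum >= 1),
            noise_rate >= 0, noise_rate < 1, n_outgroup >= 0)
  for (v in minor_variant_freqs) {
    stopifnot(v$base %in% c("A", "C", "G", "T"), v$freq > 0, v$freq < 1)
  }
  structure(list(seed = as.integer(seed), n_per_phylum = n_per_phylum,
                 minor_variant_freqs = minor_variant_freqs,
                 noise_rate = noise_rate, n_outgroup = as.integer(n_outgroup),
                 planted_match = isTRUE(planted_match)),
            class = "fixture_spec")
}

fungal_row_ids <- function(spec) {
  unlist(lapply(names(spec$n_per_phylum), function(ph) {
    sprintf("%s_%04d", ph, seq_len(spec$n_per_phylum[[ph]]))
  }), use.names = FALSE)
}

apply_noise <- function(rows, cols_allowed, rate) {
  if (rate <= 0 || length(cols_allowed) == 0) return(rows)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(rows)) {
    chars <- strsplit(rows[i], "", fixed = TRUE)[[1]]
    hit <- cols_allowed[stats::runif(length(cols_allowed)) < rate]
    for (j in hit) chars[j] <- sample(setdiff(bases, chars[j]), 1)
    rows[i] <- paste(chars, collapse = "")
  }
  rows
}

#' Forward-side fixture: the fungal ITS1F design window
#'
#' Generates the 22-column forward-primer window: fungal rows drawn from the
#' canonical fungal consensus with minor C variants at columns 3 and 19
#' (Ascomycota), invariant fungus-diagnostic G/T/A at columns 5/20/22, and
#' host rows carrying A/C/G at those columns. Deterministic under the spec
#' seed.
#'
#' @param spec a [fixture_spec()].
#' @return an `lna_alignment` with group labels set.
#' @export
make_forward_fixture <- function(spec = fixture_spec()) {
  withr::with_seed(spec$seed, {
    consensus <- strsplit(ITS1F_SEQ, "", fixed = TRUE)[[1]]
    diag_cols <- c(5L, 20L, 22L)
    minor_cols <- as.integer(names(spec$minor_variant_freqs))
    ids <- groups <- rows <- character(0)
    for (ph in names(spec$n_per_phylum)) {
      n <- spec$n_per_phylum[[ph]]
      block <- vapply(seq_len(n), function(i) {
        chars <- consensus
        for (cn in names(spec$minor_variant_freqs)) {
          v <- spec$minor_variant_freqs[[cn]]
          if (!is.null(v$phylum) && !identical(v$phylum, ph)) next
          if (stats::runif(1) < v$freq) chars[as.integer(cn)] <- v$base
        }
        paste(chars, collapse = "")
      }, character(1))
      free_cols <- setdiff(seq_along(consensus), c(diag_cols, minor_cols))
      block <- apply_noise(block, free_cols, spec$noise_rate)
      ids <- c(ids, sprintf("%s_%04d", ph, seq_len(n)))
      groups <- c(groups, rep(paste0("target:", ph), n))
      rows <- c(rows, block)
    }
    plant <- consensus
    plant[diag_cols] <- c("A", "C", "G")
    for (host in c("wheat", "soybean", "potato")) {
      ids <- c(ids, host)
      groups <- c(groups, paste0("nontarget:", host))
      rows <- c(rows, paste(plant, collapse = ""))
    }
    if (spec$n_outgroup > 0) {
      out <- consensus
      out[c(5L, 20L)] <- c("A", "C")   # protozoa-like partial mismatch
      ids <- c(ids, sprintf("outgroup_%03d", seq_len(spec$n_outgroup)))
      groups <- c(groups, rep("unknown", spec$n_outgroup))
      rows <- c(rows, rep(paste(out, collapse = ""), spec$n_outgroup))
    }
    alignment(ids, rows, groups)
  })
}

#' Reverse-side fixture: the ITS4-competition clamp design window
#'
#' Generates a 45-column coding-strand alignment: conserved 4-column flank,
#' the 22-column clamp region, and the 19 remaining reverse-primer columns.
#' Host rows fall into exactly three types (wheat-, soybean-, potato-like)
#' whose clamp regions are the reverse complements of the three reference
#' blocking oligonucleotides; fungal rows carry the canonical fungal 28S
#' flank, differing from each host type at 3-4 positions inside the clamp
#' window. The reverse-primer anchor (3'-terminal annealing column of the
#' universal reverse primer) is column 26, recorded in attribute `anchor`.
#'
#' @param spec a [fixture_spec()].
#' @return an `lna_alignment` with attribute `anchor`.
#' @export
make_reverse_fixture <- function(spec = fixture_spec()) {
  withr::with_seed(spec$seed, {
    fungal_row <- paste0(REV_FLANK, REV_FUNGAL_CORE, REV_TAIL)
    ids <- fungal_row_ids(spec)
    groups <- paste0("target:", rep(names(spec$n_per_phylum),
                                    spec$n_per_phylum))
    rows <- rep(fungal_row, length(ids))
    # conserved-region noise is confined to the flank: the 28S flank the
    # clamp and primer read is essentially invariant across fungi
    rows <- apply_noise(rows, seq_len(nchar(REV_FLANK)), spec$noise_rate)
    for (type in names(REV_HOST_CORES)) {
      host_row <- paste0(REV_FLANK, REV_HOST_CORES[[type]], REV_TAIL)
      members <- HOST_TYPE_MEMBERS[[type]]
      ids <- c(ids, members)
      groups <- c(groups, paste0("nontarget:", rep(type, length(members))))
      rows <- c(rows, rep(host_row, length(members)))
    }
    if (spec$planted_match) {
      ids <- c(ids, "Ascomycota_planted")
      groups <- c(groups, "target:Ascomycota")
      rows <- c(rows, paste0(REV_FLANK, REV_HOST_CORES[["wheat"]], REV_TAIL))
    }
    aln <- alignment(ids, rows, groups)
    attr(aln, "anchor") <- nchar(REV_FLANK) + nchar(REV_FUNGAL_CORE)
    aln
  })
}

#' Write a fixture to FASTA plus group sidecar
#'
#' @param aln fixture alignment.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.groups.tsv`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_fixture <- function(aln, prefix) {
  fa <- paste0(prefix, ".fasta")
  gm <- paste0(prefix, ".groups.tsv")
  write_fasta(aln, fa)
  write_group_map(aln, gm)
  invisible(c(fasta = fa, groups = gm))
}
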