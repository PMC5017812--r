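# Host-blocking LNA clamp design: overlap selection, LNA distribution over
# host-specific positions, 3' phosphorylation, Tm tuning, and exact-match
# cross-reactivity screening.
#
# The clamp binds the same template strand as the reverse primer, shifted
# toward the extension side, and overlaps the primer's 3'-terminal annealing
# positions by one or two bases. It is stored 5'->3' on its own strand, i.e.
# as the reverse complement of the host sequence it covers.

#' Design a host-blocking clamp oligonucleotide
#'
#' Candidates are enumerated per overlap (smallest first) and length: each
#' covers alignment columns `[anchor - length + overlap, anchor + overlap - 1]`
#' of the host sequence and is its reverse complement. A candidate is
#' eligible when its 3'-terminal base is host-specific (extending past the
#' last discriminating base would only add fungal-complementary sequence) and
#' it contains at least two non-overlap host-specific positions. Every
#' eligible host-specific position becomes LNA (the source designs replace
#' all plant-specific bases), capped at `max_lna_clamp` by the
#' even-distribution rule (the subset maximizing its minimum pairwise
#' spacing). Within an overlap level, the candidate whose Tm is closest to
#' `tm_target` and within `tm_tolerance` is returned; larger overlaps are
#' tried only when the current level has no candidate in the acceptance
#' band, because overlapped bases are conserved between hosts and targets
#' and dilute the clamp's specificity.
#'
#' @param host_window `lna_alignment` of rows for ONE host type (all rows
#'   identical over the design region), on the same column coordinates as
#'   `target_profiles`.
#' @param reverse_primer_anchor column of the reverse primer's 3'-terminal
#'   annealing position.
#' @param target_profiles `column_profiles` of the target (fungal) rows over
#'   the same columns.
#' @param config a [design_config()].
#' @param cond a [conditions()] object for Tm prediction.
#' @return object of class `clamp_design`: fields `oligo` (3'-phosphorylated
#'   [oligo()]), `host_type`, `overlap_length`, `overlap_columns`,
#'   `lna_positions`, `tm` (`tm_estimate`), `span` (covered columns),
#'   `screen` (NULL until [screen_cross_reactivity()] is run); attribute
#'   `candidates` holds the full evaluation table.
#' @export
design_clamp <- function(host_window, reverse_primer_anchor, target_profiles,
                         config = design_config(), cond = conditions()) {
  anchor <- as.integer(reverse_primer_anchor)
  if (anchor < 1 || anchor > host_window$n_cols) {
    stop("reverse primer anchor out of bounds", call. = FALSE)
  }
  if (anchor - 1L < 25L) {
    stop("host window must extend at least 25 columns toward the primer's ",
         "extension side of the anchor", call. = FALSE)
  }
  if (length(unique(host_window$residues)) != 1) {
    stop("host window rows are not identical; group rows into types first ",
         "(see group_by_identity)", call. = FALSE)
  }
  if (!identical(target_profiles$col, seq_len(host_window$n_cols))) {
    stop("target profiles do not cover the host window columns",
         call. = FALSE)
  }
  host_type <- sub("^nontarget:", "", unique(host_window$groups)[1])
  host <- strsplit(host_window$residues[1], "", fixed = TRUE)[[1]]

  # host-specific columns: host base differs from a well-conserved target base
  tmodal <- vapply(seq_len(nrow(target_profiles)), function(k) {
    f <- unlist(target_profiles[k, c("A", "C", "G", "T")])
    if (max(f) >= config$target_purity && target_profiles$n_effective[k] > 0)
      names(f)[which.max(f)] else NA_character_
  }, character(1))
  specific <- which(!is.na(tmodal) & host != "-" & host != tmodal)

  lengths <- seq(config$clamp_length_range[1], config$clamp_length_range[2])
  cand_rows <- list()
  best_overall <- NULL
  any_specific_ok <- FALSE

  for (k in config$overlap_range) {
    level <- list()
    for (L in lengths) {
      right <- anchor + k - 1L
      left <- right - L + 1L
      if (left < 1L || right > host_window$n_cols) next
      span <- left:right
      if (any(host[span] == "-")) next
      overlap_cols <- span[span >= anchor]
      spec_in <- setdiff(intersect(specific, span), overlap_cols)
      if (!(left %in% specific)) next   # 3' terminus must discriminate
      if (length(spec_in) < 2) next
      any_specific_ok <- TRUE
      site <- paste(host[span], collapse = "")
      bases <- revcomp(site)
      # column -> clamp position (clamp position 1 pairs with column `right`)
      lna_all <- sort(right - spec_in + 1L)
      lna_sel <- if (length(lna_all) > config$max_lna_clamp) {
        distribute_positions(lna_all, config$max_lna_clamp)
      } else lna_all
      chem <- rep("DNA", L)
      chem[lna_sel] <- "LNA"
      og <- oligo(bases, name = paste0("clamp_", host_type),
                  chemistry = chem, three_prime_mod = "phosphate")
      tm <- tm_oligo(og, cond)
      level[[length(level) + 1L]] <- list(
        oligo = og, overlap = k, overlap_cols = overlap_cols,
        span = span, lna = lna_sel, tm = tm,
        dev = abs(tm$tm - config$tm_target), length = L)
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        host_type = host_type, overlap = k, length = L, bases = bases,
        lna_positions = paste(lna_sel, collapse = ","),
        tm = round(tm$tm, 2),
        within_tolerance = abs(tm$tm - config$tm_target) <=
          config$tm_tolerance)
    }
    if (length(level) > 0) {
      devs <- vapply(level, `[[`, numeric(1), "dev")
      lens <- vapply(level, `[[`, numeric(1), "length")
      ord <- order(devs, lens)
      lvl_best <- level[[ord[1]]]
      if (is.null(best_overall) || lvl_best$dev < best_overall$dev) {
        best_overall <- lvl_best
      }
      if (lvl_best$dev <= config$tm_tolerance) {
        return(finish_clamp(lvl_best, host_type, cand_rows))
      }
    }
  }
  if (!any_specific_ok) {
    stop("insufficient specificity: fewer than two host-specific positions ",
         "available for host type '", host_type, "'", call. = FALSE)
  }
  near <- if (!is.null(best_overall)) {
    sprintf(" best near-miss: %s (overlap %d, %d nt, Tm %.1f degC)",
            best_overall$oligo$bases, best_overall$overlap,
            best_overall$length, best_overall$tm$tm)
  } else ""
  stop("no clamp candidate within ", config$tm_tolerance, " degC of ",
       config$tm_target, " degC for host type '", host_type, "';", near,
       call. = FALSE)
}

finish_clamp <- function(cand, host_type, cand_rows) {
  structure(list(oligo = cand$oligo, host_type = host_type,
                 overlap_length = cand$overlap,
                 overlap_columns = cand$overlap_cols,
                 lna_positions = cand$lna, tm = cand$tm,
                 span = cand$span, screen = NULL),
            class = "clamp_design",
            candidates = do.call(rbind, cand_rows))
}

# Subset of size k maximizing the minimum pairwise distance ("equal
# distribution"); ties broken by larger total spread, then by preferring
# 3'-proximal (larger) positions. Exhaustive: position sets here are small.
distribute_positions <- function(positions, k) {
  positions <- sort(positions)
  if (length(positions) <= k) return(positions)
  combos <- utils::combn(positions, k, simplify = FALSE)
  score <- function(s) {
    d <- diff(s)
    c(min(d), sum(d), sum(s))
  }
  best <- combos[[1]]
  bs <- score(best)
  for (s in combos[-1]) {
    sc <- score(s)
    if (sc[1] > bs[1] ||
        (sc[1] == bs[1] && sc[2] > bs[2]) ||
        (sc[1] == bs[1] && sc[2] == bs[2] && sc[3] > bs[3])) {
      best <- s
      bs <- sc
    }
  }
  best
}

#' @export
print.clamp_design <- function(x, ...) {
  cat("<clamp_design> host type:", x$host_type, "\n")
  cat("  5'-", x$oligo$bases, "p-3'  (", nchar(x$oligo$bases), " nt, ",
      "overlap ", x$overlap_length, " with reverse primer)\n", sep = "")
  cat("  chemistry:", format_chemistry(x$oligo),
      " (uppercase = LNA)\n")
  cat(sprintf("  Tm: %.1f degC; LNA positions: %s\n", x$tm$tm,
              paste(x$lna_positions, collapse = ", ")))
  if (!is.null(x$screen)) {
    cat("  cross-reactivity: ", x$screen$n_target_hits, " target hit(s)\n",
        sep = "")
  }
  invisible(x)
}

#' Write the full clamp candidate table as TSV
#' @param clamp a `clamp_design`.
#' @param path output file.
#' @export
write_clamp_candidates <- function(clamp, path) {
  utils::write.table(attr(clamp, "candidates"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exact-match cross-reactivity screen of a clamp against target sequences
#'
#' Counts target records whose residues over the clamp's covered columns are
#' exactly base-complementary to the clamp over its full length (both
#' orientations are checked). Non-zero counts produce a warning rather than
#' an error: a handful of database hits is the accepted regime for clamping.
#'
#' @param clamp a `clamp_design`.
#' @param target_aln `lna_alignment` of target sequences on the same column
#'   coordinates used at design time.
#' @return list of class `screen_result` with `n_target_hits`, `hit_ids`.
#' @export
screen_cross_reactivity <- function(clamp, target_aln) {
  span <- clamp$span
  hits <- character(0)
  if (n_records(target_aln) > 0) {
    if (max(span) > target_aln$n_cols) {
      stop("target sequences do not cover the clamp's annealing window",
           call. = FALSE)
    }
    m <- as.matrix(target_aln)
    for (i in seq_len(nrow(m))) {
      site <- paste(m[i, span], collapse = "")
      if (grepl("-", site, fixed = TRUE)) next
      if (identical(revcomp(site), clamp$oligo$bases) ||
          identical(site, clamp$oligo$bases)) {
        hits <- c(hits, target_aln$ids[i])
      }
    }
  }
  if (length(hits) > 0) {
    warning(length(hits), " target sequence(s) exactly complementary to ",
            "clamp '", clamp$oligo$name, "': amplification of these targets ",
            "may be suppressed", call. = FALSE)
  }
  structure(list(n_target_hits = length(hits), hit_ids = hits),
            class = "screen_result")
}
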