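# Column composition profiles, primer coverage, discriminating positions,
# host-type grouping, and identity-percent utilities.

#' Per-column base-frequency profiles
#'
#' Ambiguous input bases contribute fractionally and equally to each of their
#' constituent bases (an R adds 1/2 to A and 1/2 to G), so columns rich in Ns
#' do not lose effective depth. Gaps are excluded from the frequency
#' denominator and reported separately as `gap_fraction`.
#'
#' @param aln an `lna_alignment`.
#' @param group_filter `"all"`, an exact group label, or a prefix ending in
#'   `":"` (e.g. `"target:"`).
#' @return data.frame of class `column_profiles` with columns `col`, `A`,
#'   `C`, `G`, `T`, `gap_fraction`, `n_effective`.
#' @export
column_profiles <- function(aln, group_filter = "all") {
  sub <- if (identical(group_filter, "all")) aln else {
    tryCatch(subset_records(aln, groups = group_filter),
             error = function(e) stop("group filter '", group_filter,
                                      "' matches no records", call. = FALSE))
  }
  m <- as.matrix(sub)
  n <- nrow(m)
  prof <- lapply(seq_len(ncol(m)), function(j) {
    colv <- m[, j]
    gaps <- sum(colv == "-")
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    for (ch in colv[colv != "-"]) {
      b <- iupac_bases(ch)
      counts[b] <- counts[b] + 1 / length(b)
    }
    n_eff <- n - gaps
    freqs <- if (n_eff > 0) counts / n_eff else counts * 0
    data.frame(col = j, A = freqs[["A"]], C = freqs[["C"]], G = freqs[["G"]],
               T = freqs[["T"]], gap_fraction = gaps / n,
               n_effective = n_eff)
  })
  out <- do.call(rbind, prof)
  class(out) <- c("column_profiles", "data.frame")
  out
}

#' Long-format export of column profiles
#'
#' @param profiles a `column_profiles` data.frame.
#' @return data.frame with columns `col`, `base`, `freq`.
#' @export
profiles_long <- function(profiles) {
  do.call(rbind, lapply(c("A", "C", "G", "T"), function(b) {
    data.frame(col = profiles$col, base = b, freq = profiles[[b]])
  }))
}

modal_base <- function(profile_row) {
  f <- unlist(profile_row[c("A", "C", "G", "T")])
  names(f)[which.max(f)]
}

#' Primer coverage over an aligned sequence set
#'
#' A record is covered when at most `max_mismatch` primer positions fail
#' IUPAC compatibility against the record's residues at the primer's
#' annealing window (already-aligned coordinates). A degenerate primer base
#' matches any of its constituent bases; sequence ambiguity matches when the
#' constituent sets intersect; gaps never match.
#'
#' @param primer an [oligo()] or plain IUPAC string.
#' @param aln an `lna_alignment` whose columns `window_start` onward hold the
#'   annealing window.
#' @param max_mismatch mismatch allowance (default 0).
#' @param window_start first alignment column of the annealing window.
#' @return list of class `coverage_report`: `primer_name`, `per_group`
#'   (data.frame group/matched/total/fraction, plus an `overall` row),
#'   `mismatches` (data.frame id/column/primer_base/sequence_base).
#' @export
coverage <- function(primer, aln, max_mismatch = 0L, window_start = 1L) {
  bases <- if (inherits(primer, "lna_oligo")) primer$bases else
    normalize_residues(primer)
  pname <- if (inherits(primer, "lna_oligo")) primer$name else "primer"
  if (n_records(aln) == 0) stop("empty sequence set", call. = FALSE)
  plen <- nchar(bases)
  if (window_start + plen - 1L > aln$n_cols) {
    stop("primer window exceeds alignment width", call. = FALSE)
  }
  pchars <- strsplit(bases, "", fixed = TRUE)[[1]]
  m <- as.matrix(aln)[, window_start:(window_start + plen - 1L),
                      drop = FALSE]
  mm_list <- list()
  n_mm <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    ok <- vapply(seq_len(plen),
                 function(j) iupac_compatible(pchars[j], m[i, j]), logical(1))
    n_mm[i] <- sum(!ok)
    if (n_mm[i] > 0) {
      mm_list[[length(mm_list) + 1L]] <- data.frame(
        id = aln$ids[i], column = which(!ok) + window_start - 1L,
        primer_base = pchars[!ok], sequence_base = m[i, !ok])
    }
  }
  covered <- n_mm <= max_mismatch
  per_group <- do.call(rbind, lapply(unique(aln$groups), function(g) {
    sel <- aln$groups == g
    data.frame(group = g, matched = sum(covered[sel]), total = sum(sel),
               fraction = sum(covered[sel]) / sum(sel))
  }))
  per_group <- rbind(per_group,
                     data.frame(group = "overall", matched = sum(covered),
                                total = length(covered),
                                fraction = mean(covered)))
  structure(list(primer_name = pname, per_group = per_group,
                 mismatches = if (length(mm_list)) do.call(rbind, mm_list)
                              else data.frame(id = character(),
                                              column = integer(),
                                              primer_base = character(),
                                              sequence_base = character())),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> primer:", x$primer_name, "\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Write a coverage report as TSV
#' @param report a `coverage_report`.
#' @param path output file.
#' @export
write_coverage <- function(report, path) {
  utils::write.table(report$per_group, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Columns that discriminate targets from every non-target group
#'
#' A column is reported when a single base reaches at least `target_purity`
#' among targets and, in every non-target group, the modal base both differs
#' from the target base and reaches at least `nontarget_purity`.
#'
#' @param target_profiles `column_profiles` for the target rows.
#' @param nontarget_profiles a `column_profiles` data.frame, or a named list
#'   of them (one per non-target group).
#' @param target_purity,nontarget_purity thresholds in `[0, 1]`; the paper
#'   calls such bases "specific" without quantifying, so 0.95 is the
#'   documented default.
#' @return data.frame with columns `column`, `target_base`,
#'   `nontarget_bases` (comma-joined modal bases across groups), sorted by
#'   column.
#' @export
discriminating_positions <- function(target_profiles, nontarget_profiles,
                                     target_purity = 0.95,
                                     nontarget_purity = 0.95) {
  if (is.data.frame(nontarget_profiles)) {
    nontarget_profiles <- list(nontarget = nontarget_profiles)
  }
  for (np in nontarget_profiles) {
    if (!identical(np$col, target_profiles$col)) {
      stop("target and non-target profiles cover different column sets",
           call. = FALSE)
    }
  }
  rows <- list()
  for (k in seq_len(nrow(target_profiles))) {
    tp <- target_profiles[k, ]
    tf <- unlist(tp[c("A", "C", "G", "T")])
    tb <- names(tf)[which.max(tf)]
    if (tf[[tb]] < target_purity) next
    nb <- character(0)
    ok <- TRUE
    for (np in nontarget_profiles) {
      nf <- unlist(np[k, c("A", "C", "G", "T")])
      mb <- names(nf)[which.max(nf)]
      if (mb == tb || nf[[mb]] < nontarget_purity) { ok <- FALSE; break }
      nb <- c(nb, mb)
    }
    if (!ok) next
    rows[[length(rows) + 1L]] <- data.frame(
      column = tp$col, target_base = tb,
      nontarget_bases = paste(unique(nb), collapse = ","))
  }
  if (length(rows) == 0) {
    return(data.frame(column = integer(), target_base = character(),
                      nontarget_bases = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$column), , drop = FALSE]
}

#' Group records into identical-sequence types over a window
#'
#' Records whose gap-stripped window sequences are identical share a type;
#' types are labelled `a`, `b`, `c`, ... in order of first appearance.
#'
#' @param aln an `lna_alignment`.
#' @param start,end window bounds (1-based, inclusive).
#' @return data.frame with columns `id`, `group`, `type`, `window_seq`.
#' @export
group_by_identity <- function(aln, start, end) {
  win <- extract_window(aln, start, end)
  seqs <- gsub("-", "", win$residues, fixed = TRUE)
  if (any(!nzchar(seqs))) {
    stop("window is empty (all gaps) for record(s): ",
         paste(win$ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  first_seen <- unique(seqs)
  if (length(first_seen) > 26) {
    labels <- c(letters, paste0(rep(letters, each = 26), letters))
  } else {
    labels <- letters
  }
  data.frame(id = aln$ids, group = aln$groups,
             type = labels[match(seqs, first_seen)], window_seq = seqs)
}

#' Integer percent identity
#'
#' Rounds half away from zero, matching how alignment viewers report
#' similarity (204/218 gives 94, not 93).
#'
#' @param matches number of identical positions.
#' @param aligned_length alignment length (> 0).
#' @return integer percent.
#' @export
identity_percent <- function(matches, aligned_length) {
  if (any(aligned_length <= 0)) stop("aligned_length must be > 0",
                                     call. = FALSE)
  if (any(matches < 0) || any(matches > aligned_length)) {
    stop("matches must lie in [0, aligned_length]", call. = FALSE)
  }
  x <- 100 * matches / aligned_length
  as.integer(floor(x + 0.5))
}
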