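# Alignment container and sequence I/O.
#
# Coordinates are 1-based, inclusive, 5'->3' on the stored strand throughout
# the package; gap removal is anchored to a designated reference row (a primer
# row or chosen sequence), never to whole-column gap fractions.

#' Construct an alignment of gapped IUPAC sequences
#'
#' Rows are normalized (uppercase, U -> T) and validated: only IUPAC codes and
#' `-` gaps are accepted, ids must be unique and non-empty, and every row must
#' have the same number of columns.
#'
#' @param ids character vector of record identifiers.
#' @param residues character vector of residue strings (may contain `-`).
#' @param groups group labels (`target:<phylum>`, `nontarget:<host-type>` or
#'   `unknown`); recycled default `"unknown"`.
#' @return an object of class `lna_alignment` with fields `ids`, `residues`,
#'   `groups`, `n_cols`.
#' @export
alignment <- function(ids, residues, groups = "unknown") {
  ids <- as.character(ids)
  residues <- normalize_residues(as.character(residues))
  groups <- rep_len(as.character(groups), length(ids))
  if (length(ids) != length(residues)) {
    stop("ids and residues differ in length", call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("empty record id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  widths <- nchar(residues)
  if (length(unique(widths)) > 1) {
    stop("records declared as an alignment have differing lengths (",
         paste(range(widths), collapse = "-"), ")", call. = FALSE)
  }
  if (widths[1] < 1) stop("alignment must have at least one column",
                          call. = FALSE)
  structure(list(ids = ids, residues = residues, groups = groups,
                 n_cols = widths[1]),
            class = "lna_alignment")
}

normalize_residues <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- setdiff(unique(unlist(strsplit(x, "", fixed = TRUE))),
                 VALID_RESIDUES)
  if (length(bad) > 0) {
    stop("invalid residue character(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  x
}

#' @export
print.lna_alignment <- function(x, ...) {
  cat("<lna_alignment> ", length(x$ids), " records x ", x$n_cols,
      " columns\n", sep = "")
  grp <- table(x$groups)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  head_n <- min(6L, length(x$ids))
  for (i in seq_len(head_n)) {
    res <- x$residues[i]
    if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
    cat(sprintf("  %-20s %s\n", x$ids[i], res))
  }
  if (length(x$ids) > head_n) cat("  ...\n")
  invisible(x)
}

#' @export
as.matrix.lna_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$residues, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Number of records in an alignment
#' @param aln an `lna_alignment`.
#' @export
n_records <- function(aln) length(aln$ids)

#' Read sequences or an alignment from FASTA or Clustal
#'
#' Residues are normalized to uppercase with U converted to T. Group labels
#' are taken from an optional sidecar tab-separated file (columns: id, group);
#' records without a mapping default to `"unknown"`.
#'
#' @param path input file.
#' @param format `"fasta"` or `"clustal"`.
#' @param group_map optional path to a two-column TSV mapping id to group.
#' @return an `lna_alignment` (all records must share one length).
#' @export
read_sequences <- function(path, format = c("fasta", "clustal"),
                           group_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) {
                      stop("cannot parse '", path, "' as FASTA: ",
                           conditionMessage(e), call. = FALSE)
                    })
    ids <- sub("\\s.*$", "", names(set))
    residues <- as.character(set)
  } else {
    m <- tryCatch(ape::read.dna(path, format = "clustal",
                                as.character = TRUE),
                  error = function(e) {
                    stop("cannot parse '", path, "' as Clustal: ",
                         conditionMessage(e), call. = FALSE)
                  })
    ids <- rownames(m)
    residues <- apply(m, 1, paste, collapse = "")
  }
  groups <- rep("unknown", length(ids))
  if (!is.null(group_map)) {
    gm <- read_group_map(group_map)
    hit <- match(ids, gm$id)
    groups[!is.na(hit)] <- gm$group[hit[!is.na(hit)]]
  }
  alignment(ids, residues, groups)
}

#' Read an id-to-group sidecar mapping
#'
#' @param path two-column tab-separated file without header: id, group.
#' @return data.frame with columns `id`, `group`.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "group"),
                          colClasses = "character", quote = "")
  if (anyDuplicated(gm$id)) stop("duplicate ids in group map", call. = FALSE)
  gm
}

#' Write an alignment (or sequence set) as FASTA
#'
#' @param aln an `lna_alignment`.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  set <- Biostrings::BStringSet(aln$residues)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write the group sidecar for an alignment
#'
#' @param aln an `lna_alignment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(aln, path) {
  utils::write.table(data.frame(id = aln$ids, group = aln$groups),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove columns where an anchor row has gaps
#'
#' Keeps exactly the columns in which the designated anchor row (typically
#' the primer row the alignment was organized around) is not a gap. The
#' mapping from new to original column indices is retained in attribute
#' `column_map` for traceability.
#'
#' @param aln an `lna_alignment`.
#' @param anchor_id id of the anchor row.
#' @return degapped `lna_alignment` with attribute `column_map` (integer
#'   vector: new index -> old index).
#' @export
degap <- function(aln, anchor_id) {
  i <- match(anchor_id, aln$ids)
  if (is.na(i)) stop("anchor id not found: ", anchor_id, call. = FALSE)
  anchor <- strsplit(aln$residues[i], "", fixed = TRUE)[[1]]
  keep <- which(anchor != "-")
  if (length(keep) == 0) {
    stop("anchor row '", anchor_id, "' is all gaps; degapping would yield ",
         "an empty alignment", call. = FALSE)
  }
  m <- as.matrix(aln)[, keep, drop = FALSE]
  out <- alignment(aln$ids, apply(m, 1, paste, collapse = ""), aln$groups)
  attr(out, "column_map") <- keep
  out
}

#' Extract a window of alignment columns
#'
#' @param aln an `lna_alignment`.
#' @param start,end 1-based inclusive column bounds.
#' @return the sub-alignment over columns `start:end`.
#' @export
extract_window <- function(aln, start, end) {
  if (!(start >= 1 && start <= end && end <= aln$n_cols)) {
    stop("window [", start, ", ", end, "] out of bounds for ", aln$n_cols,
         " columns", call. = FALSE)
  }
  alignment(aln$ids, substr(aln$residues, start, end), aln$groups)
}

#' Subset alignment records
#'
#' @param aln an `lna_alignment`.
#' @param ids record ids to keep, or NULL.
#' @param groups group labels to keep (exact match), or a prefix such as
#'   `"target:"` to keep all groups starting with it.
#' @return the sub-alignment.
#' @export
subset_records <- function(aln, ids = NULL, groups = NULL) {
  keep <- rep(TRUE, length(aln$ids))
  if (!is.null(ids)) keep <- keep & aln$ids %in% ids
  if (!is.null(groups)) {
    hit <- aln$groups %in% groups
    pref <- endsWith(groups, ":")
    if (any(pref)) {
      for (p in groups[pref]) hit <- hit | startsWith(aln$groups, p)
    }
    keep <- keep & hit
  }
  if (!any(keep)) stop("selection matches no records", call. = FALSE)
  alignment(aln$ids[keep], aln$residues[keep], aln$groups[keep])
}
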