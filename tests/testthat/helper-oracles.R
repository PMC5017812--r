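# Independent oracles and small generators used across the suite.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# brute-force per-position set-intersection matcher
naive_covered <- function(primer, seq, max_mismatch = 0L) {
  p <- strsplit(primer, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  stopifnot(length(p) <= length(s))
  mism <- 0L
  for (j in seq_along(p)) {
    if (s[j] == "-" || p[j] == "-" ||
        length(intersect(IUPAC_ORACLE[[p[j]]], IUPAC_ORACLE[[s[j]]])) == 0) {
      mism <- mism + 1L
    }
  }
  mism <= max_mismatch
}

# independent nearest-neighbor Tm: re-reads the shipped tables and redoes the
# stack summation with its own bookkeeping (vectorized lookups rather than
# the engine's loop)
naive_tm <- function(seq, lna_pos = integer(0), na_mM = 240, ct_uM = 0.8) {
  dna <- utils::read.table(
    system.file("extdata", "nn_dna_santalucia1998.tsv", package = "lnaclamp"),
    sep = "\t", header = TRUE, comment.char = "#")
  lna <- utils::read.table(
    system.file("extdata", "lna_increments_calibrated.tsv",
                package = "lnaclamp"),
    sep = "\t", header = TRUE, comment.char = "#")
  rc1 <- function(d) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
  }
  stacks <- dna[!grepl("^(init|sym)", dna$param), ]
  rownames(stacks) <- stacks$param
  look <- function(d) {
    if (d %in% rownames(stacks)) unlist(stacks[d, c("dH", "dS")])
    else unlist(stacks[rc1(d), c("dH", "dS")])
  }
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dimers <- paste0(ch[-n], ch[-1])
  sums <- rowSums(vapply(dimers, look, numeric(2)))
  dH <- sums[["dH"]]; dS <- sums[["dS"]]
  for (term in ch[c(1, n)]) {
    key <- if (term %in% c("G", "C")) "init_GC" else "init_AT"
    dH <- dH + dna$dH[dna$param == key]
    dS <- dS + dna$dS[dna$param == key]
  }
  if (identical(seq, lnaclamp::revcomp(seq))) {
    dS <- dS + dna$dS[dna$param == "sym"]
  }
  for (p in lna_pos) {
    k <- sum(c(p > 1, p < n))
    dH <- dH + k * lna$dH_inc[lna$base == ch[p]]
    dS <- dS + k * lna$dS_inc[lna$base == ch[p]]
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  x <- if (identical(seq, lnaclamp::revcomp(seq))) 1 else 4
  dH * 1000 / (dS + 1.9872 * log(ct_uM * 1e-6 / x)) - 273.15
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# maximum over all k-subsets of the minimum pairwise spacing
oracle_best_min_spacing <- function(positions, k) {
  max(apply(utils::combn(sort(positions), k), 2,
            function(s) min(diff(s))))
}
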