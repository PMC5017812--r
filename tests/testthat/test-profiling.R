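test_that("column profiles count plain, gapped, and ambiguous bases", {
  aln <- alignment(paste0("s", 1:4),
                   c("ATR", "ATG", "AC-", "A--"))
  prof <- column_profiles(aln)
  # column of {A,A,A,A}
  expect_equal(prof$A[1], 1)
  expect_equal(prof$gap_fraction[1], 0)
  # column of {T,T,C,-}
  expect_equal(prof$T[2], 2 / 3)
  expect_equal(prof$C[2], 1 / 3)
  expect_equal(prof$gap_fraction[2], 0.25)
  expect_equal(prof$n_effective[2], 3)
  # column of {R,G} plus two gaps: R contributes 1/2 to A and 1/2 to G
  expect_equal(prof$A[3], 0.25)
  expect_equal(prof$G[3], 0.75)
  # frequencies sum to 1 wherever bases were observed
  expect_true(all(abs(rowSums(prof[, c("A", "C", "G", "T")]) - 1) < 1e-9))
  expect_error(column_profiles(aln, "target:"), "matches no records")
})

test_that("coverage matches IUPAC semantics on worked examples", {
  aln <- alignment(paste0("s", 1:3), c("ACG", "ATG", "AAG"),
                   rep("target:X", 3))
  rep1 <- coverage("AYG", aln)
  expect_equal(rep1$per_group$fraction[rep1$per_group$group == "overall"],
               2 / 3)
  expect_equal(nrow(rep1$mismatches), 1)
  expect_equal(rep1$mismatches$id, "s3")
  expect_equal(rep1$mismatches$column, 2)
  # a primer equal to every row covers everything
  same <- alignment(c("a", "b"), c("ACG", "ACG"))
  expect_equal(coverage("ACG", same)$per_group$fraction, c(1, 1))
  # N matches all
  expect_equal(
    coverage("NNN", aln)$per_group$fraction[1], 1)
  expect_error(coverage("ACGT", aln), "exceeds alignment width")
})

test_that("coverage equals the brute-force IUPAC matcher on random cases", {
  withr::with_seed(101, {
    codes <- names(IUPAC_ORACLE)
    for (rep in 1:15) {
      primer <- paste(sample(codes, 8, TRUE, prob = c(rep(4, 4), rep(1, 11))),
                      collapse = "")
      n <- sample(5:20, 1)
      rows <- vapply(seq_len(n), function(i)
        paste(sample(c(codes, "-"), 8, TRUE,
                     prob = c(rep(4, 4), rep(0.5, 11), 1)), collapse = ""),
        character(1))
      aln <- alignment(paste0("r", seq_len(n)), rows)
      for (mm in c(0L, 1L, 3L)) {
        got <- coverage(primer, aln, max_mismatch = mm)
        expected <- mean(vapply(rows, naive_covered, logical(1),
                                primer = primer, max_mismatch = mm))
        expect_equal(
          got$per_group$fraction[got$per_group$group == "overall"],
          expected)
      }
    }
  })
})

test_that("coverage is monotone in the mismatch allowance", {
  withr::with_seed(7, {
    rows <- vapply(1:12, function(i) rand_dna(10), character(1))
    aln <- alignment(paste0("r", 1:12), rows)
    primer <- rand_dna(10)
    fr <- vapply(0:10, function(mm)
      coverage(primer, aln, mm)$per_group$fraction[2], numeric(1))
    expect_true(all(diff(fr) >= 0))
    expect_equal(fr[11], 1)  # allowance = primer length covers everything
  })
})

test_that("discriminating positions require purity on both sides", {
  tgt <- alignment(paste0("t", 1:4), rep("GGAA", 4), rep("target:X", 4))
  non <- alignment(paste0("n", 1:4), rep("AGAC", 4), rep("nontarget:h", 4))
  disc <- discriminating_positions(column_profiles(tgt),
                                   column_profiles(non))
  expect_equal(disc$column, c(1, 4))
  expect_equal(disc$target_base, c("G", "A"))
  expect_equal(disc$nontarget_bases, c("A", "C"))

  # a 50/50 target split never reaches 0.95 purity
  tgt2 <- alignment(c("t1", "t2"), c("A", "G"), rep("target:X", 2))
  non2 <- alignment("n1", "C", "nontarget:h")
  expect_equal(nrow(discriminating_positions(column_profiles(tgt2),
                                             column_profiles(non2))), 0)

  # mismatched column sets are rejected
  expect_error(discriminating_positions(column_profiles(tgt),
                                        column_profiles(non2)),
               "different column sets")
})

test_that("stricter purity never adds discriminating positions", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      tgt <- alignment(paste0("t", 1:20),
                       vapply(1:20, function(i) rand_dna(12), character(1)),
                       rep("target:X", 20))
      non <- alignment(paste0("n", 1:8),
                       vapply(1:8, function(i) rand_dna(12), character(1)),
                       rep("nontarget:h", 8))
      tp <- column_profiles(tgt)
      np <- column_profiles(non)
      for (lo in c(0.5, 0.7, 0.9)) {
        strict <- discriminating_positions(tp, np, 1.0, 1.0)$column
        loose <- discriminating_positions(tp, np, lo, lo)$column
        expect_true(all(strict %in% loose))
      }
    }
  })
})

test_that("identity grouping assigns types in order of first appearance", {
  aln <- alignment(c("wheat", "rice", "maize", "soy", "odd"),
                   c("AAC-GT", "AACG-T", "A-ACGT", "AATTGT", "CCCCGT"),
                   c(rep("nontarget:x", 5)))
  types <- group_by_identity(aln, 1, 6)
  # wheat/rice/maize share the gap-stripped window sequence AACGT
  expect_equal(types$type[1:3], c("a", "a", "a"))
  expect_equal(types$type[4:5], c("b", "c"))

  distinct <- alignment(c("p", "q"), c("AC", "GT"))
  expect_equal(group_by_identity(distinct, 1, 2)$type, c("a", "b"))

  gappy <- alignment(c("p", "q"), c("A--T", "A--T"))
  expect_error(group_by_identity(gappy, 2, 3), "all gaps")
})

test_that("identity percent rounds half away from zero", {
  expect_identical(identity_percent(191, 192), 99L)
  expect_identical(identity_percent(204, 218), 94L)
  expect_identical(identity_percent(0, 100), 0L)
  expect_identical(identity_percent(185, 200), 93L)  # 92.5 rounds up
  expect_identical(identity_percent(248, 248), 100L)
  expect_error(identity_percent(1, 0), "must be > 0")
  expect_error(identity_percent(5, 4), "must lie in")
})
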