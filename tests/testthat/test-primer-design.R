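test_that("degenerate consensus adds codes for minor variants only", {
  # pure columns give the single-base string
  pure <- alignment(paste0("s", 1:10), rep("ACGT", 10), rep("target:X", 10))
  expect_equal(degenerate_consensus(column_profiles(pure))$bases, "ACGT")

  # 50/50 A/G column becomes R
  split <- alignment(paste0("s", 1:10),
                     c(rep("AC", 5), rep("GC", 5)), rep("target:X", 10))
  expect_equal(degenerate_consensus(column_profiles(split))$bases, "RC")

  # minor variant below threshold is dropped
  minor <- alignment(paste0("s", 1:100),
                     c(rep("AC", 97), rep("GC", 3)), rep("target:X", 100))
  expect_equal(degenerate_consensus(column_profiles(minor), 0.05)$bases,
               "AC")
  expect_equal(degenerate_consensus(column_profiles(minor), 0.02)$bases,
               "RC")

  # a four-way column emits N with a warning
  four <- alignment(paste0("s", 1:4), c("A", "C", "G", "T"),
                    rep("target:X", 4))
  expect_warning(cons <- degenerate_consensus(column_profiles(four), 0.05),
                 "all four bases")
  expect_equal(cons$bases, "N")
})

test_that("the forward fixture reproduces the reference degenerate primer", {
  aln <- make_forward_fixture(fixture_spec(seed = 11))
  tprof <- column_profiles(aln, "target:")
  cons <- degenerate_consensus(tprof, 0.05)
  expect_equal(cons$bases, "CTYGGTCATTTAGAGGAASTAA")
  expect_true(all(cons$chemistry == "DNA"))
})

test_that("LNA planning marks discriminating non-degenerate positions", {
  primer <- oligo("CTYGGTCATTTAGAGGAASTAA", name = "fwd KU DNA")
  disc <- data.frame(column = c(5L, 20L, 22L),
                     target_base = c("G", "T", "A"),
                     nontarget_bases = c("A", "C", "G"))
  lna <- plan_lna(primer, disc)
  expect_equal(lna_positions(lna), c(5L, 20L, 22L))
  expect_equal(lna$bases, primer$bases)  # letters never change

  # idempotent: replanning yields the same chemistry
  again <- plan_lna(lna, disc)
  expect_identical(again$chemistry, lna$chemistry)

  # empty discriminating set: unchanged primer, warning not error
  expect_warning(same <- plan_lna(primer, disc[0, ]), "no eligible")
  expect_equal(lna_positions(same), integer(0))

  # degenerate position is skipped with a warning
  disc_y <- rbind(disc, data.frame(column = 3L, target_base = "T",
                                   nontarget_bases = "A"))
  expect_warning(planned <- plan_lna(primer, disc_y), "degenerate")
  expect_equal(lna_positions(planned), c(5L, 20L, 22L))

  # out-of-window positions are an error
  expect_error(plan_lna(primer, data.frame(column = 40L, target_base = "A",
                                           nontarget_bases = "C")),
               "outside the primer window")
})

test_that("max_lna cap prefers stronger, more 3'-proximal positions", {
  primer <- oligo("ACGTACGTACGT")
  disc <- data.frame(column = c(2L, 5L, 9L, 12L),
                     target_base = "A",
                     nontarget_bases = c("C", "C,G", "C", "C,G"))
  got <- plan_lna(primer, disc, design_config(max_lna = 2))
  # both two-group mismatches win; ties broken toward the 3' end
  expect_equal(lna_positions(got), c(5L, 12L))
  got3 <- plan_lna(primer, disc, design_config(max_lna = 3))
  expect_equal(lna_positions(got3), c(5L, 9L, 12L))
})

test_that("degeneracy never lowers target coverage", {
  withr::with_seed(59, {
    for (rep in 1:8) {
      n <- 30
      rows <- vapply(seq_len(n), function(i) {
        base <- strsplit("ACGTACGTAC", "")[[1]]
        # sprinkle variant bases so some columns earn degeneracies
        j <- sample(10, 2)
        base[j] <- sample(c("A", "C", "G", "T"), 2, TRUE)
        paste(base, collapse = "")
      }, character(1))
      aln <- alignment(paste0("s", 1:n), rows, rep("target:X", n))
      prof <- column_profiles(aln)
      # random columns may legitimately need all four bases; the N warning
      # is part of that construction
      degen <- suppressWarnings(degenerate_consensus(prof, 0.05))
      modal <- degenerate_consensus(prof, 1.01)  # threshold >1: modal only
      f_deg <- coverage(degen, aln)$per_group$fraction[2]
      f_mod <- coverage(modal, aln)$per_group$fraction[2]
      expect_gte(f_deg, f_mod)
    }
  })
})

test_that("design configs read from key:value files and reject unknowns", {
  cfgf <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("minor_freq_threshold: 0.1", "max_lna: 2"), cfgf)
  cfg <- read_design_config(cfgf)
  expect_equal(cfg$minor_freq_threshold, 0.1)
  expect_equal(cfg$max_lna, 2L)
  expect_equal(cfg$tm_target, 70)

  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("frobnicate: 3", bad)
  expect_error(read_design_config(bad), "unknown config key")
})
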