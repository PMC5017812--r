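rev_fix <- make_reverse_fixture(fixture_spec(seed = 3))
anchor <- attr(rev_fix, "anchor")
targets <- subset_records(rev_fix, groups = "target:")
tprof <- column_profiles(targets)
hosts <- subset_records(rev_fix, groups = "nontarget:")

test_that("host plants partition into exactly three sequence types", {
  types <- group_by_identity(hosts, anchor - 25, anchor + 1)
  expect_equal(length(unique(types$type)), 3)
  expect_setequal(types$id[types$type == "a"],
                  c("wheat", "rice", "maize", "melon", "carrot"))
  expect_setequal(types$id[types$type == "b"],
                  c("soybean", "spinach", "peanut", "banana"))
  expect_setequal(types$id[types$type == "c"],
                  c("potato", "thale_cress", "tomato", "sweet_potato",
                    "coffee", "orange", "cotton", "jute"))
})

test_that("clamp design reproduces the three reference blocking oligos", {
  clamps <- design_host_clamps(rev_fix, screen = FALSE)
  expect_setequal(names(clamps), c("wheat", "soybean", "potato"))

  w <- clamps$wheat
  expect_equal(w$oligo$bases, "CTTAAACTCAGCGGGTAGTCCC")
  expect_equal(w$overlap_length, 1L)
  expect_equal(w$oligo$three_prime_mod, "phosphate")

  s <- clamps$soybean
  expect_equal(s$oligo$bases, "CTTAAACTCAGCGGGTAGCCCC")
  expect_equal(s$overlap_length, 1L)
  expect_equal(s$oligo$three_prime_mod, "phosphate")

  p <- clamps$potato
  expect_equal(p$oligo$bases, "GCTTAAACTCAGCGGGTAATCCC")
  expect_equal(p$overlap_length, 2L)
  expect_equal(p$oligo$three_prime_mod, "phosphate")

  # no LNA on overlap positions; LNA count at least two per design
  for (cd in clamps) {
    expect_true(all(cd$lna_positions > cd$overlap_length))
    expect_gte(length(cd$lna_positions), 2)
  }
})

test_that("accepted clamps outmelt both amplification primers by >= 6 degC", {
  clamps <- design_host_clamps(rev_fix, screen = FALSE)
  fwd <- design_forward_primer(make_forward_fixture(fixture_spec(seed = 3)))
  primer_max <- max(fwd$tm_lna$tm_max, tm_oligo(ITS4_SEQ)$tm_max)
  for (cd in clamps) {
    expect_gte(cd$tm$tm, primer_max + 6)
  }
})

test_that("hosts indistinguishable from targets are rejected", {
  # host rows identical to the fungal consensus everywhere
  fungal_row <- targets$residues[1]
  fake <- alignment(c("h1", "h2"), rep(fungal_row, 2),
                    rep("nontarget:fake", 2))
  expect_error(design_clamp(fake, anchor, tprof), "insufficient specificity")
})

test_that("clamp design validates its inputs", {
  win <- subset_records(hosts, ids = c("wheat", "rice"))
  expect_error(design_clamp(win, 10, tprof), "at least 25 columns")
  expect_error(design_clamp(win, 200, tprof), "out of bounds")
  mixed <- subset_records(hosts, ids = c("wheat", "soybean"))
  expect_error(design_clamp(mixed, anchor, tprof), "not identical")
})

test_that("infeasible Tm windows report near-misses", {
  win <- subset_records(hosts, ids = "wheat")
  tight <- design_config(tm_target = 90, tm_tolerance = 1)
  expect_error(design_clamp(win, anchor, tprof, tight), "near-miss")
})

test_that("cross-reactivity screening counts exact complements only", {
  clamps <- design_host_clamps(rev_fix, screen = FALSE)
  # clean fixture: no fungal window is complementary to any clamp
  for (cd in clamps) {
    scr <- screen_cross_reactivity(cd, targets)
    expect_equal(scr$n_target_hits, 0)
    expect_identical(scr$hit_ids, character(0))
  }

  # a planted fungal row identical to the wheat window is found, with its id
  planted_fix <- make_reverse_fixture(fixture_spec(seed = 3,
                                                   planted_match = TRUE))
  planted_targets <- subset_records(planted_fix, groups = "target:")
  wheat_clamp <- design_host_clamps(planted_fix, screen = FALSE)$wheat
  expect_warning(scr <- screen_cross_reactivity(wheat_clamp,
                                                planted_targets),
                 "exactly complementary")
  expect_equal(scr$n_target_hits, 1)
  expect_equal(scr$hit_ids, "Ascomycota_planted")

  # sanity inversion: the clamp hits every row of its own host type
  wheat_rows <- subset_records(hosts, ids = c("wheat", "rice", "maize",
                                              "melon", "carrot"))
  expect_warning(own <- screen_cross_reactivity(wheat_clamp, wheat_rows))
  expect_equal(own$n_target_hits, 5)

  # empty set: zero hits, no error
  empty <- alignment("x", strrep("A", planted_fix$n_cols))
  none <- screen_cross_reactivity(wheat_clamp,
                                  subset_records(empty, ids = "x"))
  expect_equal(none$n_target_hits, 0)
})

test_that("LNA distribution maximizes minimum pairwise spacing", {
  withr::with_seed(83, {
    for (rep in 1:25) {
      npos <- sample(4:9, 1)
      positions <- sort(sample(25, npos))
      k <- sample(2:min(6, npos - 1), 1)
      chosen <- lnaclamp:::distribute_positions(positions, k)
      expect_length(chosen, k)
      expect_true(all(chosen %in% positions))
      expect_equal(min(diff(chosen)),
                   oracle_best_min_spacing(positions, k))
    }
  })
})

test_that("candidate tables are exported with tolerance flags", {
  clamps <- design_host_clamps(rev_fix, screen = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_clamp_candidates(clamps$potato, tsv)
  tab <- utils::read.delim(tsv)
  expect_true(all(c("host_type", "overlap", "length", "bases",
                    "lna_positions", "tm", "within_tolerance") %in%
                    names(tab)))
  # potato escalated to overlap 2: its overlap-1 candidate is out of band
  o1 <- tab[tab$overlap == 1, ]
  expect_true(all(!o1$within_tolerance))
})
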