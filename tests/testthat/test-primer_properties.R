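test_that("GC ranges match hand-checked degenerate primers", {
  expect_equal(unclass(gc_range("TTYTAYGACTGGTAYKSYGA"))[1:2],
               c(min = 30.00, max = 55.00))
  expect_equal(unclass(gc_range("AADTTCTAYAAYAGYCCHG"))[1:2],
               c(min = 26.32, max = 52.63))
  expect_equal(unclass(gc_range("GGCC"))[1:2], c(min = 100, max = 100))
})

test_that("Tm uses the Wallace rule up to 20 bp and the GC formula above", {
  expect_equal(unclass(tm_range("TTYTAYGACTGGTAYKSYGA"))[1:2],
               c(min = 52.00, max = 62.00))
  expect_equal(unclass(tm_range(strrep("A", 20)))[1:2], c(min = 40, max = 40))
  # 25 bp, 15 G/C: 62.3 + 0.41 * 60 - 500/25
  p25 <- paste0(strrep("G", 15), strrep("A", 10))
  expect_equal(unclass(tm_range(p25))[1:2], c(min = 66.9, max = 66.9))
})

test_that("set-membership ranges equal brute-force extremes over expansions", {
  set.seed(41)
  for (i in 1:40) {
    L <- sample(8:22, 1)
    s <- rand_iupac(L, n_degen = sample(1:4, 1))
    cnt <- oracle_gc_counts(s)
    g <- gc_range(s)
    expect_equal(g[["min"]], kmerprimer:::round_half_up(100 * cnt[1] / L))
    expect_equal(g[["max"]], kmerprimer:::round_half_up(100 * cnt[2] / L))
    tm <- tm_range(s)
    if (L <= 20) {
      wallace <- vapply(expand_iupac(s), function(e) {
        gc <- sum(strsplit(e, "")[[1]] %in% c("G", "C"))
        4 * gc + 2 * (L - gc)
      }, 1.0)
      expect_equal(tm[["min"]], min(wallace))
      expect_equal(tm[["max"]], max(wallace))
      # Wallace identity Tm = 2L + 2(G+C)
      expect_equal(sort(unique(wallace)),
                   sort(unique(2 * L + 2 * (cnt[1]:cnt[2]))))
    } else {
      gcpct <- vapply(expand_iupac(s), function(e) {
        100 * sum(strsplit(e, "")[[1]] %in% c("G", "C")) / L
      }, 1.0)
      expect_equal(tm[["min"]],
                   kmerprimer:::round_half_up(62.3 + 0.41 * min(gcpct) - 500 / L))
      expect_equal(tm[["max"]],
                   kmerprimer:::round_half_up(62.3 + 0.41 * max(gcpct) - 500 / L))
    }
  }
})

test_that("unstructured sequences have zero folding energy", {
  expect_equal(fold_dG("AAAAAAAAAAAA"), 0.0)
  expect_message(short <- fold_dG("ACGTACG"), "shorter")
  expect_equal(short, 0.0)
})

test_that("a perfect stem-loop folds with negative energy that deepens per stack", {
  hp <- "GCGCGTTTTCGCGC"                 # 5-pair stem, 4-base loop
  g0 <- fold_dG(hp)
  expect_lt(g0, 0)
  g1 <- fold_dG(paste0("G", hp, "C"))    # one more G.C closing stack
  expect_lt(g1, g0)
})

test_that("hairpin energies agree with exhaustive stem/loop enumeration", {
  set.seed(42)
  cond <- folding_conditions()
  cases <- c(replicate(12, rand_dna(sample(10:30, 1))),
             "GCGCGTTTTCGCGC", "GGGCCCAAAGGGCCC", strrep("AT", 12))
  for (s in cases) {
    expect_equal(fold_dG(s, cond), oracle_fold_dG(s, cond), tolerance = 1e-9,
                 label = s)
  }
})

test_that("salt and temperature shift the folding energy", {
  hp <- "GCGCGTTTTCGCGC"
  # higher temperature destabilizes the stem
  expect_gt(fold_dG(hp, folding_conditions(fold_temp = 70)),
            fold_dG(hp, folding_conditions(fold_temp = 45)))
  # sub-molar salt destabilizes relative to the 1 M reference table
  expect_gt(fold_dG(hp, folding_conditions(mg = 20, na = 0)),
            fold_dG(hp, folding_conditions(mg = 0, na = 1000)))
})

test_that("dG ranges are valid intervals over expansions", {
  d1 <- dG_range("GCGCGTTTTCGCGC")
  expect_equal(d1[["min"]], d1[["max"]])
  # K expands to a stable G-closed stem or an unstable T-start
  d2 <- dG_range("KCGCGTTTTCGCGC")
  expect_lt(d2[["min"]], d2[["max"]])
  expect_true(all(is.finite(d2)))
})
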