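test_that("IUPAC window matching finds sites on both strands", {
  s <- match_sites("AYG", "ATGACG")
  fwd <- s[s$strand == "+", ]
  expect_identical(fwd$start, c(1L, 4L))
  expect_identical(fwd$end, c(3L, 6L))

  pal <- match_sites("ACGT", "ACGT")          # palindrome: both strands
  expect_identical(pal$strand, c("+", "-"))

  expect_identical(nrow(match_sites("AAAA", "CCCC")), 0L)
})

test_that("a database N matches only a primer N", {
  expect_identical(match_sites("AAA", "ANA")$start, integer(0))
  expect_identical(nrow(match_sites("ANA", "ANA")[
    match_sites("ANA", "ANA")$strand == "+", ]), 1L)
  # primer N accepts any concrete base
  expect_identical(match_sites("ANA", "ACA")$start[1], 1L)
})

test_that("matching equals brute-force expansion search", {
  set.seed(51)
  for (i in 1:40) {
    p <- rand_iupac(sample(5:10, 1), n_degen = sample(1:3, 1),
                    degen_pool = c("R", "Y", "S", "W", "K", "M"))
    s <- rand_dna(150)
    # plant one expansion so matches are not vanishingly rare
    e <- sample(expand_iupac(p), 1)
    pos <- sample(150 - nchar(p), 1)
    substr(s, pos, pos + nchar(p) - 1) <- e
    got <- match_sites(p, s)
    want <- oracle_sites(p, s)
    expect_identical(got$start[got$strand == "+"], want$fwd)
    expect_identical(got$start[got$strand == "-"], want$rev)
  }
})

test_that("sites mirror under joint reverse complementation", {
  set.seed(52)
  for (i in 1:15) {
    p <- rand_iupac(6, n_degen = 2)
    s <- rand_dna(80)
    e <- sample(expand_iupac(p), 1)
    substr(s, 20, 19 + nchar(e)) <- e
    a <- match_sites(p, s)
    b <- match_sites(revcomp_iupac(p), revcomp_iupac(s))
    mirrored_starts <- sort(nchar(s) - a$end + 1L)
    expect_identical(sort(b$start), mirrored_starts)
    # complementing both primer and template preserves the binding strand
    expect_identical(sum(a$strand == "+"), sum(b$strand == "+"))
  }
})

test_that("coverage counts matched sequences and respects the mismatch budget", {
  sim <- generate_database(10, c(200, 250),
                           list(planted_motif(FWD_MOTIF, carrier_fraction = 0.8)),
                           seed = 53)
  expect_equal(primer_coverage(degenerate_primer(FWD_MOTIF), sim$db), 0.8)
  expect_equal(primer_coverage(degenerate_primer(strrep("AC", 10)), sim$db), 0.0)

  # widening the mismatch budget can only add coverage
  set.seed(54)
  db <- make_db(replicate(15, rand_dna(100)))
  p <- degenerate_primer(rand_iupac(10, 2))
  covs <- vapply(0:3, function(mm) primer_coverage(p, db, mm), 1.0)
  expect_true(all(diff(covs) >= 0))
})

test_that("pairing reports in-range amplicons with their modal length", {
  sim <- generate_database(
    30, c(600, 700),
    list(planted_motif(FWD_MOTIF, carrier_fraction = 1,
                       paired = list(consensus = REV_PRIMER, amplicon = 421))),
    seed = 55)
  pr <- pair_and_report(list(degenerate_primer(FWD_MOTIF, "f"),
                             degenerate_primer(REV_PRIMER, "r")), sim$db)
  top <- pr[1, ]
  expect_identical(top$fwd, "f")
  expect_equal(top$pair_coverage, 1.0)
  expect_identical(top$product_length_mode, 421L)
  expect_true(all(unlist(top$product_lengths) == 421L))
  # amplicons carry both primers: never shorter than either
  expect_true(all(unlist(top$product_lengths) >= nchar(FWD_MOTIF)))

  # bounds excluding the planted spacing kill the pair
  none <- pair_and_report(list(degenerate_primer(FWD_MOTIF, "f"),
                               degenerate_primer(REV_PRIMER, "r")),
                          sim$db, product_min = 450, product_max = 500)
  expect_true(all(none$pair_coverage == 0))
  expect_true(all(is.na(none$product_length_mode)))
})

test_that("pair coverage never exceeds either single-primer coverage", {
  sim <- generate_database(
    25, c(600, 700),
    list(planted_motif(FWD_MOTIF, carrier_fraction = 0.7,
                       paired = list(consensus = REV_PRIMER, amplicon = 300))),
    seed = 56)
  f <- degenerate_primer(FWD_MOTIF, "f")
  r <- degenerate_primer(REV_PRIMER, "r")
  pr <- pair_and_report(list(f, r), sim$db)
  top <- pr[pr$fwd == "f", ]
  expect_lte(top$pair_coverage,
             min(primer_coverage(f, sim$db), primer_coverage(r, sim$db)))
  expect_equal(top$pair_coverage, round(0.7 * 25) / 25)
  expect_identical(top$n_covered, length(top$covered[[1]]))
})

test_that("specificity is coverage measured on the off-target database", {
  sim <- generate_database(20, c(150, 200),
                           list(planted_motif(FWD_MOTIF, carrier_fraction = 0.5)),
                           seed = 57)
  p <- degenerate_primer(FWD_MOTIF)
  expect_equal(specificity(p, sim$db), primer_coverage(p, sim$db))

  off <- generate_database(200, c(100, 120),
                           list(planted_motif(FWD_MOTIF, carrier_fraction = 0.005)),
                           seed = 58)
  expect_equal(specificity(p, off$db), 0.005)

  clean <- generate_database(30, c(100, 120), seed = 59)
  expect_equal(specificity(p, clean$db), 0.0)
})
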