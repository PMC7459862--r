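test_that("high-frequency selection ranks by count with lexicographic ties", {
  db <- make_db(c("AAAAA", "AAAA", "CCCC", "CCCCC"))  # AAAA x3, CCCC x3 ...
  tbl <- count_kmers(db, 4)
  expect_identical(select_high_frequency(tbl, top_n = 1)$kmer, "AAAA")

  tie <- count_kmers(make_db(c("AAAA", "CCCC")), 4)   # equal counts
  expect_identical(select_high_frequency(tie, top_n = 1)$kmer, "AAAA")

  expect_identical(nrow(select_high_frequency(tie, top_n = 5,
                                              min_fraction = 0.9)), 0L)
})

test_that("overlap length covers suffix/prefix matches and containment", {
  expect_identical(overlap_length("ACGTACGTACGT", "CGTACGTACGTA"), 11L)
  expect_identical(overlap_length("CGTACGTACGTA", "ACGTACGTACGT"), 11L)
  expect_identical(overlap_length("AAAATTTT", "TTTTGGGG"), 4L)
  expect_identical(overlap_length("ACGT", "TTACGTTT"), 4L)   # containment
  expect_identical(overlap_length("AACC", "GGTT"), 0L)
})

test_that("merging keeps the highest-count k-mer of each overlap group", {
  # two k-mers sharing a 13-base junction, counts 1218 vs 1137
  a <- "CGCGGTTGCTCGTGTGTGG"
  b <- paste0(substr(a, 7, 19), "AACTGA")
  stopifnot(overlap_length(a, b) == 13L)
  db_rows <- data.frame(kmer = c(a, b), occurrences = c(1218L, 1137L),
                        seq_hits = c(100L, 90L), seq_fraction = c(0.9, 0.8),
                        stringsAsFactors = FALSE)
  kept <- merge_overlapping(db_rows, x = 10)
  expect_identical(kept$kmer, a)

  # equal count, equal length: lexicographically smaller survives
  tie <- data.frame(kmer = c("CGTACGTACGTA", "ACGTACGTACGT"),
                    occurrences = c(5L, 5L), seq_hits = c(5L, 5L),
                    seq_fraction = c(0.5, 0.5), stringsAsFactors = FALSE)
  expect_identical(merge_overlapping(tie, x = 10)$kmer, "ACGTACGTACGT")

  # equal count, different length: longer survives
  lt <- data.frame(kmer = c("ACGTACGTACG", "ACGTACGTACGT"),
                   occurrences = c(5L, 5L), seq_hits = c(5L, 5L),
                   seq_fraction = c(0.5, 0.5), stringsAsFactors = FALSE)
  expect_identical(merge_overlapping(lt, x = 10)$kmer, "ACGTACGTACGT")

  disjoint <- data.frame(kmer = c("AAAAAAAAAAAA", "CCCCCCCCCCCC"),
                         occurrences = c(9L, 5L), seq_hits = c(3L, 2L),
                         seq_fraction = c(0.3, 0.2), stringsAsFactors = FALSE)
  expect_identical(merge_overlapping(disjoint, x = 10)$kmer, disjoint$kmer)
})

test_that("no surviving pair overlaps by more than x", {
  set.seed(31)
  for (rep in 1:5) {
    db <- make_db(replicate(6, rand_dna(40)))
    tbl <- count_kmers(db, 12)
    sel <- select_high_frequency(tbl, top_n = 20)
    out <- merge_overlapping(sel, x = 6)
    if (nrow(out) >= 2) {
      for (i in 1:(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
        expect_lte(overlap_length(out$kmer[i], out$kmer[j]), 6L)
      }
    }
  }
})

test_that("Hamming-1 variants are folded in as IUPAC unions", {
  db <- make_db(c(rep("ACGT", 6), "ACGA", "ACGA", "ACGC", "ACGC"))
  tbl <- count_kmers(db, 4)
  p <- combine_variants("ACGT", tbl)
  expect_identical(p$iupac_seq, "ACGH")     # {T} u {A} u {C} at position 4
  expect_setequal(p$absorbed_variants, c("ACGA", "ACGC"))
  expect_identical(as.integer(p$degeneracy), 3L)

  lone <- combine_variants("ACGT", count_kmers(make_db(rep("ACGT", 3)), 4))
  expect_identical(lone$iupac_seq, "ACGT")
  expect_identical(as.integer(lone$degeneracy), 1L)

  expect_error(combine_variants("TTTT", tbl), "absent")
})

test_that("absorption respects the eligibility floor and degeneracy cap", {
  db <- make_db(c(rep("ACGT", 6), "ACGA", "ACGA", "ACGC", "ACGC"))
  tbl <- count_kmers(db, 4)
  # floor above both variant fractions (0.2): nothing absorbed
  p0 <- combine_variants("ACGT", tbl, variant_min_fraction = 0.5)
  expect_identical(p0$iupac_seq, "ACGT")
  # cap 2: only the first variant (fraction tie broken lexicographically)
  p1 <- combine_variants("ACGT", tbl, max_degeneracy = 2)
  expect_identical(p1$iupac_seq, "ACGW")    # T u A
  expect_identical(p1$absorbed_variants, "ACGA")
})

test_that("the seed is always an expansion of the combined primer", {
  set.seed(32)
  for (rep in 1:6) {
    db <- make_db(replicate(8, rand_dna(30)))
    tbl <- count_kmers(db, 6)
    seed <- tbl$kmer[1]
    p <- combine_variants(seed, tbl, variant_min_fraction = 0)
    exps <- expand_iupac(p$iupac_seq)
    expect_true(seed %in% exps)
    expect_true(all(p$absorbed_variants %in% exps))
    expect_identical(length(exps), as.integer(p$degeneracy))
  }
})

test_that("a database of identical sequences yields exact full-coverage primers", {
  db <- make_db(rep("ATGACCGTTAGCTTGACCATCCGGA", 5))
  pr <- design_primers(db, pipeline_config(), prefix = "id")
  expect_gt(length(pr), 0L)
  for (p in pr) {
    expect_identical(as.integer(p$degeneracy), 1L)
    expect_equal(p$coverage, 1.0)
  }
})

test_that("design recovers a planted degenerate motif with its coverage", {
  sim <- generate_database(
    100, c(600, 800),
    list(planted_motif(FWD_MOTIF, carrier_fraction = 0.85,
                       variants = data.frame(pos = c(5, 12),
                                             alt = c("T", "A"),
                                             fraction = c(0.3, 0.15)))),
    seed = 101)
  cfg <- pipeline_config(primer_len_min = 20, primer_len_max = 20)
  pr <- design_primers(sim$db, cfg, prefix = "gene")
  expect_gt(length(pr), 0L)
  expected <- FWD_MOTIF
  substr(expected, 5, 5) <- iupac_code(c(substr(FWD_MOTIF, 5, 5), "T"))
  substr(expected, 12, 12) <- iupac_code(c(substr(FWD_MOTIF, 12, 12), "A"))
  expect_identical(pr[[1]]$iupac_seq, expected)
  expect_equal(pr[[1]]$coverage, 0.85)
  expect_identical(pr[[1]]$name, "gene_kmer1")
})

test_that("a motif below the coverage floor is not emitted", {
  sim <- generate_database(
    60, c(300, 400),
    list(planted_motif(FWD_MOTIF, carrier_fraction = 0.10)), seed = 102)
  cfg <- pipeline_config(primer_len_min = 20, primer_len_max = 20,
                         min_coverage = 0.2)
  expect_warning(pr <- design_primers(sim$db, cfg), "min_coverage")
  expect_length(pr, 0L)
})

test_that("degenerate widening never loses the seed's coverage", {
  sim <- generate_database(
    50, c(300, 400),
    list(planted_motif(FWD_MOTIF, carrier_fraction = 0.8,
                       variants = data.frame(pos = 9, alt = "C",
                                             fraction = 0.25))),
    seed = 103)
  tbl <- count_kmers(sim$db, 20)
  p <- combine_variants(FWD_MOTIF, tbl)
  expect_gte(primer_coverage(p, sim$db),
             primer_coverage(degenerate_primer(FWD_MOTIF), sim$db))
})
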