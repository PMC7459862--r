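# Degenerate-primer assembly: high-frequency k-mer selection, overlap
# merging, and folding of Hamming-distance-1 variants into IUPAC codes.
# Every tie-break is a total order (count, then length, then lexicographic)
# so the output is byte-deterministic.

#' Select high-frequency k-mers
#'
#' k-mers are ranked by occurrence count (descending, ties broken
#' lexicographically); the top `top_n` ranks are returned, dropping those
#' whose per-sequence hit fraction falls below `min_fraction`.
#'
#' @param table A [count_kmers()] table.
#' @param top_n Number of ranks to keep.
#' @param min_fraction Minimum `seq_fraction` to retain a candidate.
#' @return Subset of `table` rows, ranked; possibly empty.
#' @export
select_high_frequency <- function(table, top_n = 30, min_fraction = 0) {
  if (nrow(table) == 0L) stop("empty k-mer table")
  ord <- order(-table$occurrences, table$kmer)
  out <- table[ord, , drop = FALSE]
  out <- utils::head(out, top_n)
  out <- out[out$seq_fraction >= min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap length between two k-mers
#'
#' The maximum of: the longest exact suffix-of-`a` / prefix-of-`b` match, the
#' longest exact suffix-of-`b` / prefix-of-`a` match, and (when one string
#' contains the other) the length of the shorter.
#'
#' @param a,b Plain k-mer strings.
#' @return Integer overlap length (0 when disjoint).
#' @export
overlap_length <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na <= nb && grepl(a, b, fixed = TRUE)) return(na)
  if (nb < na && grepl(b, a, fixed = TRUE)) return(nb)
  for (o in seq.int(min(na, nb) - 1L, 1L)) {
    if (substr(a, na - o + 1L, na) == substr(b, 1L, o) ||
        substr(b, nb - o + 1L, nb) == substr(a, 1L, o)) {
      return(o)
    }
  }
  0L
}

#' Merge k-mers with large mutual overlap
#'
#' k-mers overlapping by more than `x` bases are taken to originate from the
#' same locus and are grouped transitively; within each group the k-mer with
#' the highest occurrence count survives (ties: the longer k-mer, then the
#' lexicographically smaller).
#'
#' @param candidates Rows of a [count_kmers()] table (as returned by
#'   [select_high_frequency()]).
#' @param x Overlap threshold in bases (merge when overlap > x).
#' @return Surviving rows, sorted by occurrences descending (then length
#'   descending, then k-mer).
#' @export
merge_overlapping <- function(candidates, x) {
  if (x < 1) stop("x must be >= 1")
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  km <- candidates$kmer
  # transitive grouping via union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (overlap_length(km[i], km[j]) > x) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  pick <- unlist(lapply(unique(comp), function(g) {
    idx <- which(comp == g)
    idx[order(-candidates$occurrences[idx], -nchar(km[idx]), km[idx])][1L]
  }), use.names = FALSE)
  out <- candidates[pick, , drop = FALSE]
  out <- out[order(-out$occurrences, -nchar(out$kmer), out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wrap an existing oligo as a degenerate primer
#'
#' Constructor for evaluating user-supplied primers (e.g. published primer
#' sequences) with the coverage and property tools.
#'
#' @param iupac_seq Primer sequence over the IUPAC alphabet, 5'->3' as
#'   synthesized.
#' @param name Optional primer name.
#' @return A `degenerate_primer` object.
#' @examples
#' degenerate_primer("GGGGHTTYTACTGGTGGT", "amoA_1F")
#' @export
degenerate_primer <- function(iupac_seq, name = NA_character_) {
  iupac_seq <- paste(.iupac_chars(iupac_seq), collapse = "")
  new_degenerate_primer(iupac_seq, seed_kmer = iupac_seq, name = name)
}

new_degenerate_primer <- function(iupac_seq, seed_kmer,
                                  absorbed_variants = character(0),
                                  seed_occurrences = NA_integer_,
                                  coverage = NA_real_, name = NA_character_) {
  structure(list(name = name,
                 iupac_seq = iupac_seq,
                 seed_kmer = seed_kmer,
                 absorbed_variants = absorbed_variants,
                 seed_occurrences = seed_occurrences,
                 degeneracy = degeneracy(iupac_seq),
                 coverage = coverage),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate primer%s> %s\n",
              if (is.na(x$name)) "" else paste0(" ", x$name), x$iupac_seq))
  cat(sprintf("  seed %s, %d variant(s) absorbed, degeneracy %d, coverage %s\n",
              x$seed_kmer, length(x$absorbed_variants), x$degeneracy,
              if (is.na(x$coverage)) "NA" else sprintf("%.4f", x$coverage)))
  invisible(x)
}

#' Fold Hamming-distance-1 variants into a degenerate primer
#'
#' Every k-mer in `table` at Hamming distance exactly 1 from `seed` with
#' `seq_fraction >= variant_min_fraction` is absorbed: at its differing
#' position the IUPAC base set becomes the union of the existing set and the
#' variant base. Absorption proceeds in descending `seq_fraction` order
#' (ties lexicographic) and stops before any absorption that would push the
#' degeneracy above `max_degeneracy`.
#'
#' @param seed A k-mer present in `table`.
#' @param table A [count_kmers()] table.
#' @param variant_min_fraction Minimum `seq_fraction` a variant must reach.
#' @param max_degeneracy Hard cap on the degeneracy of the result.
#' @return A `degenerate_primer` object: fields `iupac_seq`, `seed_kmer`,
#'   `absorbed_variants`, `degeneracy`, `coverage` (NA until filled by
#'   [primer_coverage()]).
#' @examples
#' db <- seq_db(paste0("s", 1:10),
#'              c(rep("ACGT", 6), "ACGA", "ACGA", "ACGC", "ACGC"))
#' combine_variants("ACGT", count_kmers(db, 4))$iupac_seq  # "ACGH"
#' @export
combine_variants <- function(seed, table, variant_min_fraction = 0.01,
                             max_degeneracy = 64) {
  frac <- stats::setNames(table$seq_fraction, table$kmer)
  if (!seed %in% names(frac)) stop("seed k-mer absent from table: ", seed)
  nbrs <- .hamming1_neighbors(seed)
  elig <- nbrs[nbrs %in% names(frac)]
  elig <- elig[frac[elig] >= variant_min_fraction]
  elig <- elig[order(-frac[elig], elig)]

  seed_ch <- strsplit(seed, "", fixed = TRUE)[[1]]
  sets <- as.list(seed_ch)
  absorbed <- character(0)
  for (v in elig) {
    v_ch <- strsplit(v, "", fixed = TRUE)[[1]]
    pos <- which(v_ch != seed_ch)
    new_sets <- sets
    new_sets[[pos]] <- union(sets[[pos]], v_ch[pos])
    if (prod(lengths(new_sets)) > max_degeneracy) break
    sets <- new_sets
    absorbed <- c(absorbed, v)
  }
  iupac <- paste(vapply(sets, iupac_code, ""), collapse = "")
  occ <- stats::setNames(table$occurrences, table$kmer)
  new_degenerate_primer(iupac, seed, absorbed,
                        seed_occurrences = unname(occ[seed]))
}

#' Design degenerate primers for a database
#'
#' For each primer length k in the configured range: count k-mers, select
#' high-frequency candidates (frequency floor `min_coverage`), merge
#' candidates overlapping by more than `overlap` bases, fold in
#' Hamming-distance-1 variants, compute database coverage, and drop primers
#' below `min_coverage`. The union across k is returned sorted by coverage
#' (descending, ties by IUPAC string) and named `<prefix>_kmer<i>` in that
#' order.
#'
#' @param db A [seq_db()] (already preprocessed).
#' @param config A [pipeline_config()].
#' @param prefix Name prefix for emitted primers (typically the gene name).
#' @return List of `degenerate_primer` objects, possibly empty.
#' @export
design_primers <- function(db, config = pipeline_config(), prefix = "primer") {
  if (nrow(db) == 0L) stop("empty database")
  primers <- list()
  for (k in seq.int(config$primer_len_min, config$primer_len_max)) {
    tbl <- count_kmers(db, k)
    if (nrow(tbl) == 0L) next
    sel <- select_high_frequency(tbl, config$top_n, config$min_coverage)
    if (nrow(sel) == 0L) next
    merged <- merge_overlapping(sel, config$overlap)
    for (seed in merged$kmer) {
      p <- combine_variants(seed, tbl, config$variant_min_fraction,
                            config$max_degeneracy)
      p$coverage <- primer_coverage(p, db, config$max_mismatches)
      if (p$coverage >= config$min_coverage) primers <- c(primers, list(p))
    }
  }
  if (length(primers) == 0L) {
    warning("no primer reached min_coverage = ", config$min_coverage)
    return(list())
  }
  # drop duplicate IUPAC strings (keep the higher-coverage instance)
  seqs <- vapply(primers, function(p) p$iupac_seq, "")
  covs <- vapply(primers, function(p) p$coverage, 1.0)
  ord <- order(-covs, seqs)
  primers <- primers[ord][!duplicated(seqs[ord])]
  for (i in seq_along(primers)) {
    primers[[i]]$name <- paste0(prefix, "_kmer", i)
  }
  primers
}

#' Tabulate a list of designed primers
#'
#' @param primers List of `degenerate_primer` objects.
#' @return Data frame with one row per primer: name, IUPAC string, length,
#'   degeneracy, coverage, seed k-mer and its occurrence count.
#' @export
primer_table <- function(primers) {
  data.frame(
    name = vapply(primers, function(p) p$name, ""),
    iupac_seq = vapply(primers, function(p) p$iupac_seq, ""),
    length = vapply(primers, function(p) nchar(p$iupac_seq), 1L),
    degeneracy = vapply(primers, function(p) as.integer(p$degeneracy), 1L),
    coverage = vapply(primers, function(p) p$coverage, 1.0),
    seed_kmer = vapply(primers, function(p) p$seed_kmer, ""),
    seed_occurrences = vapply(primers,
                              function(p) as.integer(p$seed_occurrences), 1L),
    stringsAsFactors = FALSE
  )
}
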