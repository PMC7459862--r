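# IUPAC-aware in-silico matching of primers against sequence databases:
# binding sites, coverage, amplicon prediction, off-target specificity.
# Matching is a deterministic window scan with a mismatch budget; a sequence
# base matches a primer position when it is a member of that position's
# IUPAC base set. A database N matches only a primer N.

# base -> bit encoding of a database sequence (N gets its own bit)
.encode_seq <- function(seq) {
  m <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)
  unname(m[strsplit(seq, "", fixed = TRUE)[[1]]])
}

# per-position match masks for a primer: the base-set bits, plus the N bit
# for primer N (so primer N accepts a database N, nothing else does)
.primer_masks <- function(iupac) {
  ch <- .iupac_chars(iupac)
  vapply(ch, function(l) {
    mk <- sum(.BASE_BIT[.IUPAC_SETS[[l]]])
    if (l == "N") mk <- mk + 16L
    as.integer(mk)
  }, 1L, USE.NAMES = FALSE)
}

# start positions (1-based) and mismatch counts of all windows within budget
.match_starts <- function(sbits, masks, max_mismatches) {
  L <- length(masks)
  nw <- length(sbits) - L + 1L
  if (nw < 1L) return(list(start = integer(0), mismatches = integer(0)))
  mism <- integer(nw)
  for (j in seq_len(L)) {
    mism <- mism + as.integer(bitwAnd(sbits[j:(j + nw - 1L)], masks[j]) == 0L)
  }
  keep <- which(mism <= max_mismatches)
  list(start = keep, mismatches = mism[keep])
}

#' Binding sites of a primer on a sequence
#'
#' Scans both orientations: forward sites are windows where every sequence
#' base belongs to the corresponding primer IUPAC set (allowing up to
#' `max_mismatches` violations); reverse-strand sites are found by matching
#' the primer's reverse complement against the sense strand. Coordinates are
#' 1-based inclusive.
#'
#' @param primer IUPAC string or `degenerate_primer`.
#' @param seq Sequence string (or a single-row [seq_db()]).
#' @param max_mismatches Mismatch budget per site.
#' @return Data frame with columns `start`, `end`, `strand` (`"+"`/`"-"`),
#'   `mismatches`.
#' @examples
#' match_sites("AYG", "ATGACG")  # forward sites at 1 and 4
#' @export
match_sites <- function(primer, seq, max_mismatches = 0) {
  if (inherits(seq, "seq_db")) {
    stopifnot(nrow(seq) == 1L)
    seq <- seq$seq
  }
  iupac <- as_iupac(primer)
  L <- nchar(iupac)
  sbits <- .encode_seq(seq)
  fwd <- .match_starts(sbits, .primer_masks(iupac), max_mismatches)
  rev <- .match_starts(sbits, .primer_masks(revcomp_iupac(iupac)),
                       max_mismatches)
  out <- data.frame(
    start = c(fwd$start, rev$start),
    end = c(fwd$start, rev$start) + L - 1L,
    strand = rep(c("+", "-"), c(length(fwd$start), length(rev$start))),
    mismatches = c(fwd$mismatches, rev$mismatches),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Ids of database sequences matched by a primer
#'
#' @param primer IUPAC string or `degenerate_primer`.
#' @param db A [seq_db()].
#' @param max_mismatches Mismatch budget per site.
#' @return Character vector of matched sequence ids (either strand).
#' @export
covered_ids <- function(primer, db, max_mismatches = 0) {
  iupac <- as_iupac(primer)
  fm <- .primer_masks(iupac)
  rm_ <- .primer_masks(revcomp_iupac(iupac))
  hit <- vapply(db$seq, function(s) {
    sbits <- .encode_seq(s)
    length(.match_starts(sbits, fm, max_mismatches)$start) > 0L ||
      length(.match_starts(sbits, rm_, max_mismatches)$start) > 0L
  }, TRUE, USE.NAMES = FALSE)
  db$id[hit]
}

#' Database coverage of a primer
#'
#' Fraction of database sequences containing at least one binding site for
#' the primer on either strand.
#'
#' @inheritParams covered_ids
#' @return Fraction in [0, 1].
#' @export
primer_coverage <- function(primer, db, max_mismatches = 0) {
  if (nrow(db) == 0L) stop("empty database")
  length(covered_ids(primer, db, max_mismatches)) / nrow(db)
}

# per-sequence amplicon evaluation for one (forward, reverse) primer pair;
# fstarts/rstarts are per-sequence site-start lists on the sense strand
.pair_amplicons <- function(fstarts, rstarts, Lf, Lr, product_min, product_max) {
  n <- length(fstarts)
  lens <- integer(0)
  covered <- logical(n)
  rec_len <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    fs <- fstarts[[i]]; rs <- rstarts[[i]]
    if (length(fs) == 0L || length(rs) == 0L) next
    best <- NA_integer_
    for (f in fs) {
      rs_ok <- rs[rs >= f + Lf]                 # reverse site strictly downstream
      if (length(rs_ok) == 0L) next
      alen <- rs_ok + Lr - f                    # product length, primers inclusive
      alen <- alen[alen >= product_min & alen <= product_max]
      if (length(alen) > 0L) {
        m <- min(alen)
        if (is.na(best) || m < best) best <- m  # shortest in-range product;
      }                                         # leftmost forward wins ties
    }
    if (!is.na(best)) {
      covered[i] <- TRUE
      rec_len[i] <- best
    }
  }
  list(covered = covered, lengths = rec_len)
}

#' Evaluate all primer pairs against a database
#'
#' For every ordered pair (forward, reverse) of distinct primers, each
#' database sequence is scanned for forward-strand sites of the forward
#' primer and reverse-strand sites of the reverse primer strictly
#' downstream. The product length is the span from the forward site start to
#' the reverse site end, primers inclusive. A sequence counts as covered
#' when at least one product length lies in `[product_min, product_max]`;
#' the shortest in-range product per sequence is recorded, and the reported
#' mode is the most frequent recorded length (ties: the smallest).
#'
#' @param primers List of at least two named `degenerate_primer` objects.
#' @param db A [seq_db()].
#' @param product_min,product_max Product length bounds in bp (inclusive).
#' @param max_mismatches Mismatch budget per site.
#' @param rev_sense Set `TRUE` when the primers are sense-strand k-mers as
#'   emitted by [design_primers()]: the reverse member of each pair is then
#'   taken to be the reverse complement of the listed (downstream) k-mer,
#'   its binding site located by matching the k-mer itself on the sense
#'   strand, and `rev_seq` reports the synthesized (reverse-complemented)
#'   sequence. Leave `FALSE` when reverse primers are supplied 5'->3' as
#'   synthesized.
#' @return A `pair_report` data frame sorted by `pair_coverage` descending:
#'   columns `fwd`, `rev`, `fwd_seq`, `rev_seq`, `pair_coverage`,
#'   `n_covered`, `product_length_mode`, plus list-columns
#'   `product_lengths` and `covered` (covered sequence ids).
#' @export
pair_and_report <- function(primers, db, product_min = 200, product_max = 500,
                            max_mismatches = 0, rev_sense = FALSE) {
  if (length(primers) < 2L) stop("need at least two primers to pair")
  nm <- vapply(seq_along(primers), function(i) {
    n <- primers[[i]]$name
    if (is.null(n) || is.na(n)) paste0("primer", i) else n
  }, "")
  if (anyDuplicated(nm)) stop("primer names must be unique")
  n <- nrow(db)
  sbits <- lapply(db$seq, .encode_seq)
  # precompute per-primer site starts per sequence, both orientations
  fsites <- rsites <- vector("list", length(primers))
  for (p in seq_along(primers)) {
    fm <- .primer_masks(as_iupac(primers[[p]]))
    rm_ <- .primer_masks(revcomp_iupac(as_iupac(primers[[p]])))
    fsites[[p]] <- lapply(sbits, function(sb) .match_starts(sb, fm, max_mismatches)$start)
    rsites[[p]] <- lapply(sbits, function(sb) .match_starts(sb, rm_, max_mismatches)$start)
  }
  lens_p <- vapply(primers, function(p) nchar(as_iupac(p)), 1L)

  rows <- list()
  for (fi in seq_along(primers)) {
    for (ri in seq_along(primers)) {
      if (fi == ri) next
      rsite_list <- if (rev_sense) fsites[[ri]] else rsites[[ri]]
      amp <- .pair_amplicons(fsites[[fi]], rsite_list, lens_p[fi], lens_p[ri],
                             product_min, product_max)
      rec <- amp$lengths[!is.na(amp$lengths)]
      mode_len <- if (length(rec) > 0L) {
        tab <- table(rec)
        min(as.integer(names(tab)[tab == max(tab)]))
      } else NA_integer_
      rows[[length(rows) + 1L]] <- list(
        fwd = nm[fi], rev = nm[ri],
        fwd_seq = as_iupac(primers[[fi]]),
        rev_seq = if (rev_sense) revcomp_iupac(primers[[ri]])
                  else as_iupac(primers[[ri]]),
        pair_coverage = sum(amp$covered) / n,
        n_covered = sum(amp$covered),
        product_length_mode = mode_len,
        product_lengths = rec,
        covered = db$id[amp$covered]
      )
    }
  }
  out <- data.frame(
    fwd = vapply(rows, `[[`, "", "fwd"),
    rev = vapply(rows, `[[`, "", "rev"),
    fwd_seq = vapply(rows, `[[`, "", "fwd_seq"),
    rev_seq = vapply(rows, `[[`, "", "rev_seq"),
    pair_coverage = vapply(rows, `[[`, 1.0, "pair_coverage"),
    n_covered = vapply(rows, `[[`, 1L, "n_covered"),
    product_length_mode = vapply(rows, `[[`, 1L, "product_length_mode"),
    stringsAsFactors = FALSE
  )
  out$product_lengths <- lapply(rows, `[[`, "product_lengths")
  out$covered <- lapply(rows, `[[`, "covered")
  out <- out[order(-out$pair_coverage, out$fwd, out$rev), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_report", "data.frame")
  out
}

#' Off-target coverage (specificity) of a primer or primer pair
#'
#' Identical computation to [primer_coverage()] (or the pair coverage of
#' [pair_and_report()]) but against an off-target database; lower values mean
#' better specificity.
#'
#' @param x A `degenerate_primer`/IUPAC string, or a list of two primers
#'   `list(fwd = ..., rev = ...)`.
#' @param offtarget_db A [seq_db()].
#' @param max_mismatches Mismatch budget per site.
#' @param product_min,product_max Product bounds (pair mode only).
#' @param rev_sense Passed to [pair_and_report()] (pair mode only).
#' @return Off-target coverage fraction.
#' @export
specificity <- function(x, offtarget_db, max_mismatches = 0,
                        product_min = 200, product_max = 500,
                        rev_sense = FALSE) {
  if (nrow(offtarget_db) == 0L) stop("empty off-target database")
  if (is.list(x) && !inherits(x, "degenerate_primer")) {
    if (length(x) != 2L) stop("a primer pair must be a list of two primers")
    f <- x[[1]]; r <- x[[2]]
    if (!inherits(f, "degenerate_primer")) f <- new_degenerate_primer(as_iupac(f), as_iupac(f))
    if (!inherits(r, "degenerate_primer")) r <- new_degenerate_primer(as_iupac(r), as_iupac(r))
    f$name <- "fwd"; r$name <- "rev"
    rep <- pair_and_report(list(f, r), offtarget_db, product_min, product_max,
                           max_mismatches, rev_sense)
    return(rep$pair_coverage[rep$fwd == "fwd" & rep$rev == "rev"])
  }
  primer_coverage(x, offtarget_db, max_mismatches)
}
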