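# k-mer decomposition and counting. Counting is strand-specific (a k-mer and
# its reverse complement are distinct entries); windows containing N carry no
# evidence for any concrete k-mer and are dropped.

#' Decompose a sequence into k-mers
#'
#' Sliding window of width `k`, step 1: a length-m sequence yields m - k + 1
#' windows in order. Windows containing N are excluded.
#'
#' @param seq A DNA string over A/C/G/T/N.
#' @param k Window length (>= 1).
#' @return Character vector of windows in sequence order; empty when `k`
#'   exceeds the sequence length.
#' @examples
#' kmerize("AACTGACTGA", 4)  # 7 windows
#' @export
kmerize <- function(seq, k) {
  if (k < 1) stop("k must be >= 1")
  seq <- as.character(seq)
  m <- nchar(seq)
  if (k > m) return(character(0))
  starts <- seq_len(m - k + 1L)
  w <- substring(seq, starts, starts + k - 1L)
  w[!grepl("N", w, fixed = TRUE)]
}

#' Count k-mers across a database
#'
#' Tabulates, for every N-free window of width `k`, its total occurrence
#' count (with multiplicity) and the number of distinct sequences containing
#' it at least once. `seq_fraction = seq_hits / n_sequences` is the
#' per-sequence hit fraction used downstream as a coverage proxy.
#'
#' @param db A [seq_db()].
#' @param k k-mer length.
#' @return A `kmer_table`: data frame with columns `kmer`, `occurrences`,
#'   `seq_hits`, `seq_fraction`, sorted by occurrences (descending) then
#'   k-mer; attributes `k` and `n_sequences`.
#' @examples
#' count_kmers(seq_db("s1", "AAAA"), 2)  # AA: 3 occurrences, 1 sequence
#' @export
count_kmers <- function(db, k) {
  if (nrow(db) == 0L) stop("empty database")
  wins <- lapply(db$seq, kmerize, k = k)
  occ <- table(unlist(wins, use.names = FALSE))
  hits <- table(unlist(lapply(wins, unique), use.names = FALSE))
  kmers <- names(occ)
  out <- data.frame(kmer = kmers,
                    occurrences = as.integer(occ),
                    seq_hits = as.integer(hits[kmers]),
                    stringsAsFactors = FALSE)
  out$seq_fraction <- out$seq_hits / nrow(db)
  out <- out[order(-out$occurrences, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  attr(out, "n_sequences") <- nrow(db)
  class(out) <- c("kmer_table", "data.frame")
  out
}

#' Count k-mers over a length range
#'
#' @param db A [seq_db()].
#' @param k_min,k_max Inclusive k range.
#' @return List of independent [count_kmers()] tables, one per k, named by k.
#' @export
count_kmer_range <- function(db, k_min, k_max) {
  if (k_min > k_max) stop("k_min must be <= k_max")
  ks <- seq.int(k_min, k_max)
  stats::setNames(lapply(ks, function(k) count_kmers(db, k)), ks)
}

#' Write a k-mer table to TSV
#'
#' Columns `kmer`, `occurrences`, `seq_hits`, `seq_fraction` (6-decimal
#' fixed point).
#'
#' @param table A `kmer_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  out <- data.frame(kmer = table$kmer,
                    occurrences = table$occurrences,
                    seq_hits = table$seq_hits,
                    seq_fraction = sprintf("%.6f", table$seq_fraction),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
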