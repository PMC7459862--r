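# Sequence database container and the three preprocessing tools:
# length statistics, length-based trimming, exact-duplicate removal.

#' Construct a sequence database
#'
#' A `seq_db` is a plain data frame with one row per sequence and columns
#' `id`, `description`, `seq` (upper-case DNA over A/C/G/T/N) and a `lineage`
#' list-column of ordered taxon names (domain towards species), `NULL` where
#' unannotated. Sequences are normalized on construction: upper-cased, U
#' replaced by T.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of nucleotide sequences.
#' @param description Free-text header remainders (recycled).
#' @param lineage Optional list of character vectors, one per sequence.
#' @return A `seq_db` data frame.
#' @examples
#' db <- seq_db(c("s1", "s2"), c("acgu", "AACTGACTGA"))
#' db$seq
#' @export
seq_db <- function(id, seq, description = "", lineage = NULL) {
  id <- as.character(id)
  seq <- chartr("U", "T", toupper(as.character(seq)))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (anyDuplicated(id)) stop("duplicate sequence ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(seq))) stop("empty sequence(s)")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("non-ACGTN characters in sequence(s): ",
                     paste(id[bad], collapse = ", "))
  out <- data.frame(id = id,
                    description = rep_len(as.character(description), length(id)),
                    seq = seq, stringsAsFactors = FALSE)
  out$lineage <- if (is.null(lineage)) rep(list(NULL), length(id)) else lineage
  class(out) <- c("seq_db", "data.frame")
  out
}

#' Read a FASTA database
#'
#' Loads a (multi-line) FASTA file into a [seq_db()]. Sequences are
#' upper-cased and U is replaced by T. Records containing characters outside
#' the IUPAC nucleotide alphabet are rejected with a warning; ambiguity codes
#' other than N are collapsed to N with a warning, so downstream matching
#' semantics stay well defined. A taxonomic lineage is parsed from the header
#' description when it contains the configured delimiter (default style:
#' `>id k__Bacteria;p__Proteobacteria;...`).
#'
#' @param path Path to a FASTA file.
#' @param lineage_delim Delimiter splitting lineage ranks in the description;
#'   set to `NULL` to disable lineage parsing.
#' @param strip_rank_prefix Drop `k__` / `p__`-style rank prefixes.
#' @return A [seq_db()] in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgt", ">s2", "AACTGACTGA"), f)
#' load_fasta(f)$seq
#' @export
load_fasta <- function(path, lineage_delim = ";", strip_rank_prefix = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- chartr("U", "T", toupper(as.character(x)))

  invalid <- grepl("[^ACGTNRYSWKMBDHV]", seqs) | !nzchar(seqs)
  if (any(invalid)) {
    warning("rejecting ", sum(invalid), " record(s) with non-nucleotide ",
            "characters or empty sequence: ",
            paste(ids[invalid], collapse = ", "))
    ids <- ids[!invalid]; desc <- desc[!invalid]; seqs <- seqs[!invalid]
    if (length(ids) == 0L) stop("no valid records in ", path)
  }
  amb <- grepl("[RYSWKMBDHV]", seqs)
  if (any(amb)) {
    warning("ambiguity codes other than N replaced by N in ",
            sum(amb), " record(s): ", paste(ids[amb], collapse = ", "))
    seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  }

  lineage <- rep(list(NULL), length(ids))
  if (!is.null(lineage_delim)) {
    has_lin <- grepl(lineage_delim, desc, fixed = TRUE)
    lineage[has_lin] <- lapply(strsplit(desc[has_lin], lineage_delim,
                                        fixed = TRUE), function(parts) {
      parts <- trimws(parts)
      if (strip_rank_prefix) parts <- sub("^[A-Za-z]__", "", parts)
      parts[nzchar(parts)]
    })
  }
  seq_db(ids, seqs, desc, lineage)
}

#' Write a database to FASTA
#'
#' @param db A [seq_db()].
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 80) {
  headers <- ifelse(nzchar(db$description),
                    paste0(">", db$id, " ", db$description),
                    paste0(">", db$id))
  lines <- character(0)
  for (i in seq_len(nrow(db))) {
    s <- db$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    lines <- c(lines, headers[i], substring(s, starts,
                                            pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Sequence length statistics
#'
#' Quick summary of the length distribution of a database: count, min, max,
#' mean, median, and a histogram of counts per length bin.
#'
#' @param db A [seq_db()].
#' @param bin_width Histogram bin width in bp; bins are labelled by their
#'   lower edge.
#' @return A `length_stats` list with fields `n_sequences`, `min_len`,
#'   `max_len`, `mean_len`, `median_len`, `histogram`.
#' @examples
#' length_stats(seq_db(c("a", "b"), c("ACGT", "AACTGACTGA")))
#' @export
length_stats <- function(db, bin_width = 100) {
  if (nrow(db) == 0L) stop("empty database")
  lens <- nchar(db$seq)
  bins <- (lens %/% bin_width) * bin_width
  structure(list(n_sequences = nrow(db),
                 min_len = min(lens), max_len = max(lens),
                 mean_len = mean(lens), median_len = stats::median(lens),
                 histogram = table(bins)),
            class = "length_stats")
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf("%d sequences, length %d-%d bp (mean %.1f, median %.1f)\n",
              x$n_sequences, x$min_len, x$max_len, x$mean_len, x$median_len))
  print(x$histogram)
  invisible(x)
}

#' Filter or truncate sequences by length
#'
#' Sequences shorter than `min_len` are always removed. Sequences longer than
#' `max_len` are removed (`mode = "delete"`) or cut to their first `max_len`
#' bases (`mode = "truncate"`). Record order is preserved.
#'
#' @param db A [seq_db()].
#' @param min_len,max_len Retained length bounds in bp (inclusive).
#' @param mode `"delete"` or `"truncate"`.
#' @return A filtered [seq_db()].
#' @export
trim_by_length <- function(db, min_len, max_len, mode = c("delete", "truncate")) {
  mode <- match.arg(mode)
  if (min_len <= 0 || min_len > max_len) {
    stop("need 0 < min_len <= max_len")
  }
  lens <- nchar(db$seq)
  keep <- lens >= min_len
  if (mode == "delete") {
    keep <- keep & lens <= max_len
    out <- db[keep, , drop = FALSE]
  } else {
    out <- db[keep, , drop = FALSE]
    long <- nchar(out$seq) > max_len
    out$seq[long] <- substr(out$seq[long], 1L, max_len)
  }
  rownames(out) <- NULL
  out
}

#' Remove exact duplicate sequences
#'
#' Among records with byte-identical sequence strings (after the upper-case
#' normalization applied on ingest), only the first in database order is
#' kept. Ids are untouched; reverse complements are not collapsed.
#'
#' @param db A [seq_db()].
#' @return A deduplicated [seq_db()].
#' @export
dedupe_exact <- function(db) {
  out <- db[!duplicated(db$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}
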