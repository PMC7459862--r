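# Covered-taxonomy and phenotype-group summaries: which taxa and which
# oxygen-requirement / gram classes a primer (set) reaches.

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

.OXYGEN_CLASSES <- c("aerobic", "anaerobic", "facultative_anaerobic", "unknown")
.GRAM_CLASSES <- c("positive", "negative", "unknown")

.breakdown <- function(group, covered, label) {
  tot <- table(group)
  cov <- table(group[covered])
  taxa <- names(tot)
  out <- data.frame(
    taxon = taxa,
    n_total = as.integer(tot),
    n_covered = as.integer(ifelse(is.na(cov[taxa]), 0L, cov[taxa])),
    stringsAsFactors = FALSE
  )
  out$fraction_covered <- round_half_up(100 * out$n_covered / out$n_total)
  out <- out[order(-out$n_total, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "axis") <- label
  class(out) <- c("taxon_breakdown", "data.frame")
  out
}

#' Summarize covered sequences by taxonomic rank
#'
#' Counts, per taxon at the requested rank, how many database sequences
#' exist and how many of them are covered (member of `covered_ids`).
#' Records lacking a lineage, or lacking the rank, are grouped under
#' `"unclassified"`.
#'
#' @param db A [seq_db()] with lineage annotation on at least one record.
#' @param covered_ids Character vector of covered sequence ids (e.g. from
#'   [covered_ids()] or a [pair_and_report()] row).
#' @param rank Rank name (`"domain"` ... `"species"`) or 1-based lineage
#'   index.
#' @return A `taxon_breakdown` data frame: `taxon`, `n_total`, `n_covered`,
#'   `fraction_covered` (percent, 2 decimals), sorted by `n_total`.
#' @export
breakdown_by_rank <- function(db, covered_ids, rank = "phylum") {
  if (all(vapply(db$lineage, is.null, TRUE))) {
    stop("no lineage annotation in database")
  }
  idx <- if (is.numeric(rank)) as.integer(rank) else match(tolower(rank), .TAX_RANKS)
  if (is.na(idx) || idx < 1L) stop("unknown rank: ", rank)
  group <- vapply(db$lineage, function(lin) {
    if (is.null(lin) || length(lin) < idx || !nzchar(lin[idx])) "unclassified"
    else lin[idx]
  }, "")
  .breakdown(group, db$id %in% covered_ids,
             if (is.numeric(rank)) .TAX_RANKS[idx] else tolower(rank))
}

#' Read a taxon phenotype map
#'
#' Three-column tab-separated file (with header `taxon`, `oxygen_class`,
#' `gram_class`) assigning each taxon an oxygen-requirement class
#' (aerobic / anaerobic / facultative_anaerobic / unknown) and a gram class
#' (positive / negative / unknown). Values outside these vocabularies are
#' demoted to `"unknown"` with a warning.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `taxon`, `oxygen_class`, `gram_class`.
#' @export
read_phenotype_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "oxygen_class", "gram_class")
  if (!all(need %in% names(x))) {
    stop("phenotype map must have columns: ", paste(need, collapse = ", "))
  }
  bad_o <- !x$oxygen_class %in% .OXYGEN_CLASSES
  bad_g <- !x$gram_class %in% .GRAM_CLASSES
  if (any(bad_o) || any(bad_g)) {
    warning("out-of-vocabulary phenotype classes set to 'unknown'")
    x$oxygen_class[bad_o] <- "unknown"
    x$gram_class[bad_g] <- "unknown"
  }
  x[need]
}

#' Summarize covered sequences by phenotype class
#'
#' Each record is assigned a phenotype by most-specific-wins lineage lookup:
#' the lineage is walked from species towards domain and the first taxon
#' present in the map decides the class; records with no match (or no
#' lineage) count as `"unknown"`.
#'
#' @param db A [seq_db()].
#' @param covered_ids Covered sequence ids.
#' @param phenomap A phenotype map (see [read_phenotype_map()]).
#' @param axis `"oxygen"` or `"gram"`.
#' @return A `taxon_breakdown` over the class vocabulary.
#' @export
breakdown_by_phenotype <- function(db, covered_ids, phenomap,
                                   axis = c("oxygen", "gram")) {
  axis <- match.arg(axis)
  if (nrow(phenomap) == 0L) stop("empty phenotype map")
  col <- if (axis == "oxygen") "oxygen_class" else "gram_class"
  lut <- stats::setNames(phenomap[[col]], phenomap$taxon)
  group <- vapply(db$lineage, function(lin) {
    if (!is.null(lin)) {
      for (taxon in rev(lin)) {
        if (taxon %in% names(lut)) return(unname(lut[taxon]))
      }
    }
    "unknown"
  }, "")
  .breakdown(group, db$id %in% covered_ids, axis)
}
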