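# Assembling the curated CPG table: keep only complete-level assemblies,
# attach replicon counts and seven-rank lineages, preserve source order.

# The completeness selector: the source dialect's assembly level for a
# gap-free genome, matched after whitespace-trim, case-insensitively.
COMPLETE_STATUS <- "complete genome"

is_complete_status <- function(status) {
  !is.na(status) & tolower(trimws(status)) == COMPLETE_STATUS
}

#' Curate complete prokaryotic genome metadata
#'
#' Builds the curated CPG table from parsed genome-report records: keeps
#' exactly the records whose assembly status is "Complete Genome"
#' (trimmed, case-insensitive), counts chromosomes and plasmids from the
#' replicon field, resolves the seven-rank lineage of each taxid, and
#' preserves source order. Total: records whose taxid is missing from the
#' taxonomy are kept with an all-"unclassified" lineage and reported in
#' the log, never dropped.
#'
#' @param raw Tibble of raw records, or a `genome_report` object from
#'   [read_genome_report()].
#' @param db A `tax_db` from [load_taxdump()].
#' @return A list of class `curation` with
#'   \describe{
#'     \item{records}{curated tibble, columns per [curated_columns()].}
#'     \item{log}{list: `n_input`, `n_kept`, `n_dropped`,
#'       `taxonomy_misses` (taxids not found in `db`).}
#'   }
#' @export
curate <- function(raw, db) {
  if (inherits(raw, "genome_report")) raw <- raw$records
  stopifnot(is.data.frame(raw), inherits(db, "tax_db"))

  keep <- is_complete_status(raw$status)
  kept <- raw[keep, , drop = FALSE]

  counts <- count_replicons(kept$replicons)
  lin <- resolve_lineages(db, kept$taxid)

  records <- tibble::tibble(
    organism_name = kept$organism_name,
    taxid = kept$taxid,
    size_mb = kept$size_mb,
    gc_percent = kept$gc_percent,
    replicons = kept$replicons,
    n_chromosomes = counts$n_chromosomes,
    n_plasmids = counts$n_plasmids,
    genes = kept$genes,
    proteins = kept$proteins,
    release_date = kept$release_date,
    ftp_path = kept$ftp_path
  )
  records <- dplyr::bind_cols(records, lin$lineages)

  structure(
    list(
      records = records,
      log = list(
        n_input = nrow(raw),
        n_kept = nrow(records),
        n_dropped = nrow(raw) - nrow(records),
        taxonomy_misses = lin$misses
      )
    ),
    class = "curation"
  )
}

#' @export
print.curation <- function(x, ...) {
  cat(sprintf(
    "<curation> kept %d of %d record(s) (%d dropped, %d taxonomy miss(es))\n",
    x$log$n_kept, x$log$n_input, x$log$n_dropped, length(x$log$taxonomy_misses)
  ))
  invisible(x)
}
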