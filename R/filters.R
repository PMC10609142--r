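# Declarative, composable filtering of the curated table: one optional
# taxonomic-rank selection plus inclusive numeric ranges over the six
# genomic features. Clauses combine by conjunction; records missing a value
# for a filtered numeric feature are excluded by that clause (so prevalence
# denominators match the filtered table a user sees).

RANGE_FEATURES <- c(
  size_range = "size_mb",
  gc_range = "gc_percent",
  chromosome_range = "n_chromosomes",
  plasmid_range = "n_plasmids",
  gene_range = "genes",
  protein_range = "proteins"
)

check_range <- function(x, what) {
  if (is.null(x)) {
    return(NULL)
  }
  if (!is.numeric(x) || length(x) != 2 || anyNA(x)) {
    usage_error(paste0(what, " must be a numeric [lo, hi] pair"))
  }
  if (x[[1]] > x[[2]]) {
    usage_error(paste0(what, ": lower bound exceeds upper bound"))
  }
  as.numeric(x)
}

#' Build a filter specification
#'
#' A conjunction of at most one taxonomic-rank selection and inclusive
#' numeric ranges over genomic features. `Inf` / `-Inf` express open-ended
#' bounds. An unknown rank name is rejected here, before any filtering.
#'
#' @param rank Optional rank name (one of [canonical_ranks()]).
#' @param value Taxon name to match at `rank` (case-insensitive exact
#'   match); required iff `rank` is given.
#' @param size_range,gc_range,chromosome_range,plasmid_range,gene_range,protein_range
#'   Optional inclusive numeric `[lo, hi]` pairs over genome size (Mb),
#'   GC%, chromosome count, plasmid count, gene count, protein count.
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' filter_spec(rank = "superkingdom", value = "Bacteria",
#'             chromosome_range = c(2, Inf))
filter_spec <- function(rank = NULL, value = NULL,
                        size_range = NULL, gc_range = NULL,
                        chromosome_range = NULL, plasmid_range = NULL,
                        gene_range = NULL, protein_range = NULL) {
  if (xor(is.null(rank), is.null(value))) {
    usage_error("rank and value must be given together")
  }
  if (!is.null(rank)) {
    if (!(is.character(rank) && length(rank) == 1 && rank %in% canonical_ranks())) {
      usage_error(paste0(
        "unknown rank '", paste(rank, collapse = ","),
        "'; must be one of: ", paste(canonical_ranks(), collapse = ", ")
      ))
    }
    if (!(is.character(value) && length(value) == 1)) {
      usage_error("value must be a single taxon name")
    }
  }
  structure(
    list(
      rank = rank, value = value,
      size_range = check_range(size_range, "size_range"),
      gc_range = check_range(gc_range, "gc_range"),
      chromosome_range = check_range(chromosome_range, "chromosome_range"),
      plasmid_range = check_range(plasmid_range, "plasmid_range"),
      gene_range = check_range(gene_range, "gene_range"),
      protein_range = check_range(protein_range, "protein_range")
    ),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  clauses <- character()
  if (!is.null(x$rank)) clauses <- paste0(x$rank, " = ", x$value)
  for (f in names(RANGE_FEATURES)) {
    if (!is.null(x[[f]])) {
      clauses[[length(clauses) + 1L]] <-
        paste0(RANGE_FEATURES[[f]], " in [", x[[f]][[1]], ", ", x[[f]][[2]], "]")
    }
  }
  if (length(clauses) == 0) clauses <- "(no clauses: identity)"
  cat("<filter_spec>", paste(clauses, collapse = " AND "), "\n")
  invisible(x)
}

#' Apply a filter specification to curated records
#'
#' Returns the records satisfying the conjunction of all present clauses,
#' in input order. The rank clause is a case-insensitive exact match on
#' the named lineage column. A record with a missing value for a filtered
#' numeric feature fails that clause.
#'
#' @param records Curated tibble.
#' @param spec A [filter_spec()].
#' @return Filtered tibble (same columns, input order preserved).
#' @export
apply_filters <- function(records, spec) {
  stopifnot(is.data.frame(records), inherits(spec, "filter_spec"))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(spec$rank)) {
    v <- records[[spec$rank]]
    m <- !is.na(v) & tolower(v) == tolower(spec$value)
    keep <- keep & m
  }
  for (f in names(RANGE_FEATURES)) {
    rng <- spec[[f]]
    if (is.null(rng)) next
    col <- RANGE_FEATURES[[f]]
    x <- records[[col]]
    keep <- keep & !is.na(x) & x >= rng[[1]] & x <= rng[[2]]
  }
  records[keep, , drop = FALSE]
}
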