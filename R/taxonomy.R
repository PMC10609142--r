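# Offline taxID -> lineage resolution from NCBI taxdump flat files
# (nodes.dmp / names.dmp / optional merged.dmp). Fields are separated by
# "\t|\t" and lines terminated by "\t|". Only the seven canonical ranks are
# kept in a lineage; all other ranks (strain, no rank, clade, ...) are
# skipped during the parent walk.

split_dmp <- function(lines) {
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Load an NCBI taxonomy dump
#'
#' Builds an in-memory taxonomy database from `nodes.dmp` and `names.dmp`
#' (scientific names only), with an optional `merged.dmp` mapping retired
#' taxids to their replacements. The tree is validated on load: a parent
#' taxid absent from the node set, or a cycle anywhere above a node, aborts
#' with the offending taxid.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @param merged_path Optional path to `merged.dmp`.
#' @return An object of class `tax_db` supporting [resolve_lineage()].
#' @export
load_taxdump <- function(nodes_path, names_path, merged_path = NULL) {
  for (p in c(nodes_path, names_path, merged_path)) {
    if (!file.exists(p)) input_error(paste0("no such taxdump file: ", p))
  }
  node_fields <- split_dmp(readLines(nodes_path, warn = FALSE))
  taxid <- vapply(node_fields, function(f) as.integer(f[[1]]), integer(1))
  parent <- vapply(node_fields, function(f) as.integer(f[[2]]), integer(1))
  rank <- vapply(node_fields, function(f) trimws(f[[3]]), character(1))
  if (anyNA(taxid) || anyNA(parent)) {
    parse_error("malformed nodes.dmp: non-integer taxid or parent")
  }
  if (anyDuplicated(taxid)) {
    parse_error(paste0("duplicate taxid in nodes.dmp: ", taxid[duplicated(taxid)][[1]]))
  }

  key <- as.character(taxid)
  parent_map <- stats::setNames(parent, key)
  rank_map <- stats::setNames(rank, key)

  dangling <- !(as.character(parent) %in% key)
  if (any(dangling)) {
    parse_error(paste0(
      "node ", taxid[dangling][[1]], " references absent parent ",
      parent[dangling][[1]]
    ))
  }

  # cycle check: walk every node to a root (parent == self), memoizing
  # resolved nodes; a revisit within the current path is a cycle
  state <- stats::setNames(integer(length(taxid)), key) # 0 unseen, 1 done
  for (start in key) {
    if (state[[start]] == 1L) next
    path <- character()
    cur <- start
    repeat {
      if (cur %in% path) {
        parse_error(paste0("cycle detected in taxonomy at taxid ", cur))
      }
      path[[length(path) + 1L]] <- cur
      p <- as.character(parent_map[[cur]])
      if (p == cur || state[[p]] == 1L) break
      cur <- p
    }
    state[path] <- 1L
  }

  name_fields <- split_dmp(readLines(names_path, warn = FALSE))
  is_sci <- vapply(
    name_fields,
    function(f) length(f) >= 4 && trimws(f[[4]]) == "scientific name",
    logical(1)
  )
  name_fields <- name_fields[is_sci]
  name_map <- stats::setNames(
    vapply(name_fields, function(f) trimws(f[[2]]), character(1)),
    vapply(name_fields, function(f) trimws(f[[1]]), character(1))
  )

  merged_map <- stats::setNames(integer(0), character(0))
  if (!is.null(merged_path)) {
    merged_fields <- split_dmp(readLines(merged_path, warn = FALSE))
    merged_map <- stats::setNames(
      vapply(merged_fields, function(f) as.integer(f[[2]]), integer(1)),
      vapply(merged_fields, function(f) trimws(f[[1]]), character(1))
    )
  }

  structure(
    list(
      parent = parent_map, rank = rank_map, name = name_map,
      merged = merged_map, n = length(taxid)
    ),
    class = "tax_db"
  )
}

#' @export
print.tax_db <- function(x, ...) {
  cat(sprintf(
    "<tax_db> %d node(s), %d merged id(s)\n", x$n, length(x$merged)
  ))
  invisible(x)
}

empty_lineage <- function() {
  stats::setNames(rep(UNCLASSIFIED, 7), canonical_ranks())
}

#' Resolve the seven-rank lineage of a taxid
#'
#' Walks parent pointers from `taxid` to the root, filling each canonical
#' rank slot (superkingdom to species) with the scientific name of the
#' first node of that rank on the path. Slots with no node of that rank
#' stay `"unclassified"`. The NCBI rank string `"domain"` (the newer name
#' for the top prokaryote rank) is accepted for the superkingdom slot.
#' Retired taxids are followed through the merged map if one was loaded.
#'
#' @param db A `tax_db` from [load_taxdump()].
#' @param taxid Positive integer taxid.
#' @return Named character vector of length 7 (names from
#'   [canonical_ranks()]).
#' @export
resolve_lineage <- function(db, taxid) {
  stopifnot(inherits(db, "tax_db"))
  key <- as.character(taxid)
  if (!(key %in% names(db$parent))) {
    if (key %in% names(db$merged)) {
      key <- as.character(db$merged[[key]])
    }
    if (!(key %in% names(db$parent))) {
      lookup_error(paste0("taxid not in taxonomy database: ", taxid))
    }
  }
  lineage <- empty_lineage()
  cur <- key
  repeat {
    r <- db$rank[[cur]]
    if (identical(r, "domain")) r <- "superkingdom"
    if (r %in% canonical_ranks() && lineage[[r]] == UNCLASSIFIED) {
      nm <- db$name[cur]
      if (!is.na(nm)) lineage[[r]] <- unname(nm)
    }
    p <- as.character(db$parent[[cur]])
    if (p == cur) break
    cur <- p
  }
  lineage
}

# Vectorized lineage resolution with miss tolerance: unknown taxids get an
# all-unclassified lineage and are reported, not dropped (keeps genome
# counts stable relative to the source file).
resolve_lineages <- function(db, taxids) {
  uniq <- unique(taxids)
  res <- matrix(UNCLASSIFIED,
    nrow = length(uniq), ncol = 7,
    dimnames = list(as.character(uniq), canonical_ranks())
  )
  misses <- integer()
  for (i in seq_along(uniq)) {
    lin <- tryCatch(resolve_lineage(db, uniq[[i]]),
      cpgmeta_lookup_error = function(e) NULL
    )
    if (is.null(lin)) {
      misses[[length(misses) + 1L]] <- uniq[[i]]
    } else {
      res[i, ] <- lin
    }
  }
  out <- res[as.character(taxids), , drop = FALSE]
  rownames(out) <- NULL
  list(lineages = tibble::as_tibble(out), misses = misses)
}
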