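# Parsing the raw `Replicons` field: entries are `;`-separated, each with an
# optional `descriptor:accessions` shape, accessions `/`-separated.
# Classification is by descriptor substring: "plasmid" anywhere wins (catches
# "megaplasmid", "plasmid pXO1"), else a descriptor starting with
# "chromosome" is a chromosome, else `other`. Unclassifiable entries are
# never dropped silently — they land in `other`.

#' Parse a raw replicon string
#'
#' Splits the raw `Replicons` metadata field into classified entries and
#' counts chromosomes and plasmids. Total function: missing input (`NA`,
#' empty, or the `-` sentinel) yields an empty set with all counts zero.
#'
#' @param raw A single raw replicon string, or `NA`.
#' @return An object of class `replicon_set`: a list with
#'   \describe{
#'     \item{entries}{tibble with columns `kind` (one of `chromosome`,
#'       `plasmid`, `other`), `label` (the descriptor text), and
#'       `accessions` (list column of accession vectors).}
#'     \item{n_chromosomes, n_plasmids, n_other}{entry counts by kind.}
#'   }
#' @export
#' @examples
#' rs <- parse_replicons(
#'   "chromosome:NC_003997.3/AE017225.1; plasmid pXO1:NC_007322.2; plasmid pXO2:NC_007323.3"
#' )
#' rs$n_chromosomes # 1
#' rs$n_plasmids    # 2
parse_replicons <- function(raw) {
  if (length(raw) != 1) {
    usage_error("parse_replicons() takes a single string; see count_replicons() for vectors")
  }
  kinds <- character()
  labels <- character()
  accs <- list()
  if (!is_missing_cell(raw)) {
    parts <- strsplit(raw, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[nchar(parts) > 0]
    for (p in parts) {
      colon <- regexpr(":", p, fixed = TRUE)
      if (colon > 0) {
        label <- trimws(substr(p, 1, colon - 1))
        acc_raw <- trimws(substr(p, colon + 1, nchar(p)))
        acc <- trimws(strsplit(acc_raw, "/", fixed = TRUE)[[1]])
        acc <- acc[nchar(acc) > 0]
      } else {
        label <- trimws(p)
        acc <- character()
      }
      d <- tolower(label)
      kind <- if (grepl("plasmid", d, fixed = TRUE)) {
        "plasmid"
      } else if (startsWith(d, "chromosome")) {
        "chromosome"
      } else {
        "other"
      }
      kinds[[length(kinds) + 1L]] <- kind
      labels[[length(labels) + 1L]] <- label
      accs[[length(accs) + 1L]] <- acc
    }
  }
  structure(
    list(
      entries = tibble::tibble(kind = kinds, label = labels, accessions = accs),
      n_chromosomes = sum(kinds == "chromosome"),
      n_plasmids = sum(kinds == "plasmid"),
      n_other = sum(kinds == "other")
    ),
    class = "replicon_set"
  )
}

#' @export
print.replicon_set <- function(x, ...) {
  cat(sprintf(
    "<replicon_set> %d chromosome(s), %d plasmid(s), %d other\n",
    x$n_chromosomes, x$n_plasmids, x$n_other
  ))
  invisible(x)
}

#' Serialize a replicon set back to the field dialect
#'
#' Canonical re-serialization: entries joined with `"; "`, accessions with
#' `/`. Parsing the result reproduces the same classification and counts
#' (idempotence).
#'
#' @param x A `replicon_set`.
#' @return A single string, or `NA` for an empty set.
#' @export
format_replicons <- function(x) {
  stopifnot(inherits(x, "replicon_set"))
  if (nrow(x$entries) == 0) {
    return(NA_character_)
  }
  parts <- mapply(function(label, acc) {
    if (length(acc) == 0) label else paste0(label, ":", paste(acc, collapse = "/"))
  }, x$entries$label, x$entries$accessions)
  paste(parts, collapse = "; ")
}

#' Count replicons across a vector of raw strings
#'
#' Vectorized convenience over [parse_replicons()].
#'
#' @param raw Character vector of raw replicon strings (`NA` allowed).
#' @return Tibble with columns `n_chromosomes`, `n_plasmids`, `n_other`,
#'   one row per input element.
#' @export
count_replicons <- function(raw) {
  n <- length(raw)
  nc <- integer(n)
  np <- integer(n)
  no <- integer(n)
  for (i in seq_len(n)) {
    rs <- parse_replicons(raw[[i]])
    nc[[i]] <- rs$n_chromosomes
    np[[i]] <- rs$n_plasmids
    no[[i]] <- rs$n_other
  }
  tibble::tibble(n_chromosomes = nc, n_plasmids = np, n_other = no)
}

#' Multichromosomal and plasmid-bearing predicates
#'
#' A genome is multichromosomal (multipartite) if its replicon set contains
#' two or more chromosomes, and plasmid-bearing if it contains at least one
#' plasmid. These predicates define the prevalence proportions and the 2x2
#' chi-square cross-tabulation.
#'
#' @param x A `replicon_set`, or a numeric vector of chromosome / plasmid
#'   counts.
#' @return Logical.
#' @export
is_multichromosomal <- function(x) {
  if (inherits(x, "replicon_set")) x$n_chromosomes >= 2 else x >= 2
}

#' @rdname is_multichromosomal
#' @export
has_plasmid <- function(x) {
  if (inherits(x, "replicon_set")) x$n_plasmids >= 1 else x >= 1
}
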