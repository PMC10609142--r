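# Reading and writing the two tabular dialects the package speaks:
# the NCBI genome-reports tab-delimited format (input) and the curated
# CSV (output / downstream substrate).

# Header-name -> canonical field mapping for the genome-report dialect.
# Parsing is header-name-driven, never positional; permuting source columns
# must not change the result.
REPORT_COLUMN_MAP <- c(
  "Organism/Name" = "organism_name",
  "TaxID"         = "taxid",
  "Size (Mb)"     = "size_mb",
  "GC%"           = "gc_percent",
  "Replicons"     = "replicons",
  "Genes"         = "genes",
  "Proteins"      = "proteins",
  "Release Date"  = "release_date",
  "Status"        = "status",
  "FTP Path"      = "ftp_path"
)

MANDATORY_FIELDS <- c("organism_name", "taxid", "status")

#' Read a prokaryote genome report
#'
#' Parses the tab-delimited genome-report dialect distributed under NCBI
#' GENOME_REPORTS: a single `#`-prefixed header line naming the columns,
#' then one tab-separated data line per assembly. Columns are identified by
#' header name, not position. The sentinel `-` (and the empty string) maps
#' to missing. Any source column not in the canonical set is preserved
#' verbatim as an extra character column.
#'
#' In lenient mode (the default) parsing is total: malformed numeric cells,
#' unparseable dates, and out-of-range values become missing, and rows with
#' an invalid `TaxID` are rejected; every coercion or rejection is recorded
#' in the parse log with its line number. In strict mode any malformed
#' numeric cell, invalid taxid, or missing mandatory column
#' (organism name, taxid, status) aborts with the offending line.
#'
#' @param source Path to the report file, or a connection.
#' @param strict Abort on malformed cells instead of logging? Default `FALSE`.
#' @return A list of class `genome_report` with elements
#'   \describe{
#'     \item{records}{tibble with columns `organism_name`, `taxid`,
#'       `size_mb`, `gc_percent`, `replicons`, `genes`, `proteins`,
#'       `release_date` (Date), `status`, `ftp_path`, then any extra
#'       source columns.}
#'     \item{log}{tibble of parse events: `line`, `field`, `reason`.}
#'   }
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c(
#'   "#Organism/Name\tTaxID\tSize (Mb)\tGC%\tReplicons\tGenes\tProteins\tRelease Date\tStatus\tFTP Path",
#'   "Escherichia coli\t562\t4.64\t50.8\tchromosome:U00096.3\t4321\t4140\t1997/09/05\tComplete Genome\t-"
#' ), f)
#' rep <- read_genome_report(f)
#' rep$records
read_genome_report <- function(source, strict = FALSE) {
  lines <- tryCatch(suppressWarnings(readLines(source, warn = FALSE)),
    error = function(e) input_error(paste0("cannot read genome report: ", conditionMessage(e)))
  )
  if (length(lines) == 0) {
    input_error("empty genome report: no header line")
  }
  header <- lines[[1]]
  if (!startsWith(header, "#")) {
    parse_error("genome report header must begin with '#'")
  }
  col_names <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  col_names <- trimws(col_names)

  canon <- unname(REPORT_COLUMN_MAP[col_names])
  missing_mandatory <- setdiff(
    MANDATORY_FIELDS,
    canon[!is.na(canon)]
  )
  if (length(missing_mandatory) > 0 && strict) {
    parse_error(paste0(
      "missing mandatory column(s): ",
      paste(names(REPORT_COLUMN_MAP)[REPORT_COLUMN_MAP %in% missing_mandatory], collapse = ", ")
    ))
  }

  log_lines <- integer()
  log_fields <- character()
  log_reasons <- character()
  note <- function(line, field, reason) {
    log_lines[[length(log_lines) + 1L]] <<- line
    log_fields[[length(log_fields) + 1L]] <<- field
    log_reasons[[length(log_reasons) + 1L]] <<- reason
  }

  data_lines <- lines[-1]
  keep <- nchar(trimws(data_lines)) > 0
  line_no <- which(keep) + 1L          # 1-based file line numbers
  data_lines <- data_lines[keep]
  n <- length(data_lines)

  cells <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_src <- length(col_names)
  # ragged rows: pad short, truncate long (logged)
  mat <- matrix(NA_character_, nrow = n, ncol = ncol_src)
  for (i in seq_len(n)) {
    row <- cells[[i]]
    if (length(row) > ncol_src) {
      note(line_no[[i]], "<row>", "extra cells truncated")
      row <- row[seq_len(ncol_src)]
    } else if (length(row) < ncol_src) {
      note(line_no[[i]], "<row>", "short row padded with missing")
    }
    mat[i, seq_along(row)] <- row
  }
  colnames(mat) <- col_names

  get_col <- function(field) {
    src <- names(REPORT_COLUMN_MAP)[REPORT_COLUMN_MAP == field]
    if (src %in% col_names) unname(mat[, src, drop = TRUE]) else rep(NA_character_, n)
  }

  coerce_numeric <- function(raw, field, integer = FALSE,
                             lower = -Inf, upper = Inf,
                             lower_open = FALSE) {
    out <- rep(NA_real_, n)
    miss <- is_missing_cell(raw)
    for (i in which(miss & !is.na(raw) & trimws(raw) == MISSING_SENTINEL)) {
      note(line_no[[i]], field, "missing sentinel")
    }
    idx <- which(!miss)
    if (length(idx) > 0) {
      val <- suppressWarnings(as.numeric(trimws(raw[idx])))
      bad <- is.na(val)
      for (j in which(bad)) {
        if (strict) {
          parse_error(sprintf(
            "line %d: malformed numeric cell in '%s': %s",
            line_no[[idx[j]]], field, raw[[idx[j]]]
          ))
        }
        note(line_no[[idx[j]]], field, "malformed numeric")
      }
      in_range <- !bad &
        (if (lower_open) val > lower else val >= lower) &
        val <= upper
      oor <- !bad & !in_range
      for (j in which(oor)) {
        if (strict) {
          parse_error(sprintf(
            "line %d: out-of-range value in '%s': %s",
            line_no[[idx[j]]], field, raw[[idx[j]]]
          ))
        }
        note(line_no[[idx[j]]], field, "out of range")
      }
      val[bad | oor] <- NA_real_
      out[idx] <- val
    }
    if (integer) as.integer(out) else out
  }

  organism_name <- trimws(get_col("organism_name"))
  organism_name[is_missing_cell(organism_name)] <- NA_character_

  taxid_raw <- get_col("taxid")
  taxid <- suppressWarnings(as.integer(trimws(taxid_raw)))
  bad_taxid <- is.na(taxid) | taxid <= 0
  for (i in which(bad_taxid)) {
    if (strict) {
      parse_error(sprintf(
        "line %d: invalid TaxID: %s", line_no[[i]],
        ifelse(is.na(taxid_raw[[i]]), "<missing>", taxid_raw[[i]])
      ))
    }
    note(line_no[[i]], "taxid", "invalid taxid: record rejected")
  }

  size_mb <- coerce_numeric(get_col("size_mb"), "size_mb",
    lower = 0, lower_open = TRUE
  )
  gc_percent <- coerce_numeric(get_col("gc_percent"), "gc_percent",
    lower = 0, upper = 100, lower_open = TRUE
  )
  genes <- coerce_numeric(get_col("genes"), "genes", integer = TRUE, lower = 0)
  proteins <- coerce_numeric(get_col("proteins"), "proteins", integer = TRUE, lower = 0)

  replicons <- get_col("replicons")
  replicons[is_missing_cell(replicons)] <- NA_character_

  date_raw <- get_col("release_date")
  release_date <- rep(as.Date(NA), n)
  has_date <- !is_missing_cell(date_raw)
  if (any(has_date)) {
    d <- as.Date(trimws(date_raw[has_date]), format = "%Y/%m/%d")
    d2 <- as.Date(trimws(date_raw[has_date]), format = "%Y-%m-%d")
    d[is.na(d)] <- d2[is.na(d)]
    for (j in which(is.na(d))) {
      note(line_no[which(has_date)[j]], "release_date", "unparseable date")
    }
    release_date[has_date] <- d
  }

  status <- trimws(get_col("status"))
  status[is_missing_cell(status)] <- NA_character_

  ftp_path <- trimws(get_col("ftp_path"))
  ftp_path[is_missing_cell(ftp_path)] <- NA_character_

  records <- tibble::tibble(
    organism_name = organism_name,
    taxid = taxid,
    size_mb = size_mb,
    gc_percent = gc_percent,
    replicons = replicons,
    genes = genes,
    proteins = proteins,
    release_date = release_date,
    status = status,
    ftp_path = ftp_path
  )

  extra_cols <- setdiff(col_names, names(REPORT_COLUMN_MAP))
  for (ec in extra_cols) {
    v <- unname(mat[, ec, drop = TRUE])
    v[is_missing_cell(v)] <- NA_character_
    records[[ec]] <- v
  }

  records <- records[!bad_taxid, , drop = FALSE]

  structure(
    list(
      records = records,
      log = tibble::tibble(line = log_lines, field = log_fields, reason = log_reasons)
    ),
    class = "genome_report"
  )
}

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf(
    "<genome_report> %d record(s), %d parse log entr%s\n",
    nrow(x$records), nrow(x$log), if (nrow(x$log) == 1) "y" else "ies"
  ))
  invisible(x)
}

#' Column order of the curated metadata table
#'
#' The fixed, documented schema of the curated CPG table: genomic features
#' and provenance first, then the seven lineage ranks.
#'
#' @return Character vector of the 18 column names, in output order.
#' @export
curated_columns <- function() {
  c(
    "organism_name", "taxid", "size_mb", "gc_percent", "replicons",
    "n_chromosomes", "n_plasmids", "genes", "proteins", "release_date",
    "ftp_path", canonical_ranks()
  )
}

curated_col_classes <- function() {
  c(
    organism_name = "character", taxid = "integer", size_mb = "numeric",
    gc_percent = "numeric", replicons = "character",
    n_chromosomes = "integer", n_plasmids = "integer",
    genes = "integer", proteins = "integer", release_date = "character",
    ftp_path = "character",
    superkingdom = "character", phylum = "character", class = "character",
    order = "character", family = "character", genus = "character",
    species = "character"
  )
}

#' Write the curated CPG table to CSV
#'
#' RFC-4180-style CSV with the fixed column order of [curated_columns()].
#' Missing values are written as empty cells; a header row is always
#' present (so an empty record set yields a header-only file). Dates are
#' written ISO (`YYYY-MM-DD`).
#'
#' @param records Curated tibble as produced by [curate()] (or any tibble
#'   with the curated schema).
#' @param dest Output file path.
#' @return `dest`, invisibly.
#' @export
write_curated_csv <- function(records, dest) {
  cols <- curated_columns()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    usage_error(paste0(
      "records lack curated column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  out <- as.data.frame(records[cols])
  if (inherits(out$release_date, "Date")) {
    out$release_date <- format(out$release_date, "%Y-%m-%d")
  }
  tryCatch(
    write.csv(out, dest, row.names = FALSE, na = ""),
    error = function(e) input_error(paste0("cannot write ", dest, ": ", conditionMessage(e)))
  )
  invisible(dest)
}

#' Read a curated CPG table from CSV
#'
#' Inverse of [write_curated_csv()]. The header must match the documented
#' schema exactly (same names, same order); anything else is a schema
#' error. Empty cells read back as missing — an empty string and a missing
#' character field are not distinguished by the CSV form.
#'
#' @param path CSV file path.
#' @return Curated tibble (possibly zero rows).
#' @export
read_curated_csv <- function(path) {
  if (!file.exists(path)) {
    input_error(paste0("no such file: ", path))
  }
  classes <- curated_col_classes()
  df <- tryCatch(
    suppressWarnings(read.csv(path,
      colClasses = unname(classes), check.names = FALSE,
      na.strings = "", stringsAsFactors = FALSE
    )),
    error = function(e) parse_error(paste0("cannot parse curated CSV: ", conditionMessage(e)))
  )
  if (!identical(names(df), curated_columns())) {
    parse_error(paste0(
      "curated CSV schema mismatch; expected columns: ",
      paste(curated_columns(), collapse = ", ")
    ))
  }
  df$release_date <- as.Date(df$release_date, format = "%Y-%m-%d")
  tibble::as_tibble(df)
}

#' Fetch the genome report with a local cache
#'
#' Returns a cached copy of the report if it is younger than `max_age`;
#' otherwise downloads atomically (temp file, then rename) and returns the
#' fresh copy. On network failure a stale cache is returned with a warning;
#' with no cache at all the failure aborts. Offline workflows never need
#' this: point [read_genome_report()] at a local file instead.
#'
#' @param url Report URL. Default is the NCBI GENOME_REPORTS prokaryotes
#'   report.
#' @param cache_dir Directory holding the cached copy.
#' @param max_age Maximum cache age in seconds before refresh
#'   (default 86400, i.e. daily).
#' @param quiet Suppress download progress. Default `TRUE`.
#' @return Path to the local copy.
#' @export
fetch_report <- function(url = "https://ftp.ncbi.nlm.nih.gov/genomes/GENOME_REPORTS/prokaryotes.txt",
                         cache_dir = tools::R_user_dir("cpgmeta", "cache"),
                         max_age = 86400, quiet = TRUE) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, basename(url))
  if (file.exists(dest)) {
    age <- as.numeric(difftime(Sys.time(), file.mtime(dest), units = "secs"))
    if (age < max_age) {
      message("using cached report (", round(age), "s old): ", dest)
      return(dest)
    }
  }
  tmp <- tempfile(tmpdir = cache_dir)
  ok <- tryCatch(
    {
      download.file(url, tmp, quiet = quiet, mode = "wb")
      TRUE
    },
    error = function(e) FALSE,
    warning = function(w) FALSE
  )
  if (ok && file.exists(tmp) && file.size(tmp) > 0) {
    file.rename(tmp, dest)
    message("downloaded fresh report: ", dest)
    return(dest)
  }
  unlink(tmp)
  if (file.exists(dest)) {
    warn(paste0("download failed; returning stale cache: ", dest))
    return(dest)
  }
  input_error(paste0("download failed and no cached copy exists: ", url))
}
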