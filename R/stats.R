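# Descriptive statistics over the curated table: five-number summaries,
# pairwise-complete Pearson correlations, submissions per year, per-rank
# distribution tables, reported percentages, and the 2x2 chi-square test.

#' Five-number summary plus mean
#'
#' Boxplot statistics of a numeric feature: minimum, first quartile,
#' median, third quartile, maximum, and mean. Missing values are dropped
#' first. Quartiles use linear interpolation between order statistics
#' (the default continuous quantile definition), so results are
#' reproducible bit-for-bit.
#'
#' @param values Numeric vector; must contain at least one non-missing
#'   value.
#' @return A list of class `boxplot_stats`: `n`, `minimum`, `q1`,
#'   `median`, `q3`, `maximum`, `mean`.
#' @export
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 5))
boxplot_stats <- function(values) {
  if (!is.numeric(values)) usage_error("values must be numeric")
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    usage_error("boxplot_stats() needs at least one non-missing value")
  }
  q <- unname(quantile(values, probs = c(0.25, 0.5, 0.75), type = 7))
  structure(
    list(
      n = length(values),
      minimum = min(values),
      q1 = q[[1]],
      median = q[[2]],
      q3 = q[[3]],
      maximum = max(values),
      mean = mean(values)
    ),
    class = "boxplot_stats"
  )
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf(
    "<boxplot_stats> n=%d min=%g q1=%g median=%g q3=%g max=%g mean=%g\n",
    x$n, x$minimum, x$q1, x$median, x$q3, x$maximum, x$mean
  ))
  invisible(x)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Pearson r for every pair of the named numeric features, using
#' pairwise-complete observations so one missing feature does not shrink
#' all pairs. Pairs with fewer than two complete cases or zero variance
#' are reported as `NA` (undefined — distinct from 0). The per-pair
#' number of complete cases is returned alongside for auditability.
#'
#' @param records Curated tibble (or any data frame).
#' @param features Character vector of at least two numeric column names.
#' @return An object of class `correlation_matrix`: list with `features`,
#'   `r` (symmetric matrix), and `n` (matrix of complete-case counts).
#' @export
pearson_matrix <- function(records, features) {
  stopifnot(is.data.frame(records))
  if (length(features) < 2) {
    usage_error("pearson_matrix() needs at least two features")
  }
  missing_cols <- setdiff(features, names(records))
  if (length(missing_cols) > 0) {
    usage_error(paste0("unknown feature(s): ", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(records[features])
  if (!is.numeric(m)) usage_error("all selected features must be numeric")
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs", method = "pearson"))
  n_pair <- crossprod(!is.na(m))
  r[n_pair < 2] <- NA_real_
  structure(
    list(features = features, r = r, n = n_pair),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix>\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Genome submissions per year
#'
#' Counts records per calendar year of their release date, ascending.
#' Records without a release date go to an unknown bucket, reported as a
#' final row with `year = NA`. Counts always sum to the number of input
#' records.
#'
#' @param records Curated tibble with a `release_date` column (Date).
#' @return Tibble with columns `year` (integer, `NA` = unknown) and
#'   `count`.
#' @export
submissions_by_year <- function(records) {
  stopifnot(is.data.frame(records), "release_date" %in% names(records))
  year <- as.integer(format(records$release_date, "%Y"))
  out <- dplyr::count(tibble::tibble(year = year), .data$year, name = "count")
  dplyr::arrange(out, .data$year) # NA sorts last
}

#' Distribution of records across the taxa of one rank
#'
#' Counts records per taxon at the chosen canonical rank, including the
#' `"unclassified"` bucket. Sorted by count descending, then taxon name
#' ascending; `top_n` truncates after sorting.
#'
#' @param records Curated tibble.
#' @param rank One of [canonical_ranks()].
#' @param top_n Optional: keep only the first `top_n` rows after sorting.
#' @return Tibble with columns `taxon` and `count`; attribute `rank`
#'   carries the rank name.
#' @export
distribution_by_rank <- function(records, rank, top_n = NULL) {
  stopifnot(is.data.frame(records))
  if (!(is.character(rank) && length(rank) == 1 && rank %in% canonical_ranks())) {
    usage_error(paste0(
      "unknown rank '", paste(rank, collapse = ","), "'; must be one of: ",
      paste(canonical_ranks(), collapse = ", ")
    ))
  }
  taxon <- records[[rank]]
  taxon[is.na(taxon)] <- UNCLASSIFIED
  out <- dplyr::count(tibble::tibble(taxon = taxon), .data$taxon, name = "count")
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$taxon)
  if (!is.null(top_n)) {
    stopifnot(is.numeric(top_n), top_n >= 0)
    out <- head(out, top_n)
  }
  attr(out, "rank") <- rank
  out
}

# Half-up rounding (R's round() is round-half-even, which would turn e.g.
# 0.5 at the last kept digit the wrong way for reported percentages).
round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Prevalence as a reported percentage
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places —
#' the convention used for reported prevalence figures such as the
#' fraction of complete genomes that are multichromosomal or carry a
#' plasmid.
#'
#' @param numerator Nonnegative count, at most `denominator`.
#' @param denominator Positive count.
#' @param decimals Number of decimal places (default 1).
#' @return The percentage as a plain number.
#' @export
#' @examples
#' proportion_percent(1633, 32603)  # 5.0
proportion_percent <- function(numerator, denominator, decimals = 1) {
  if (!is.numeric(numerator) || !is.numeric(denominator) ||
    length(numerator) != 1 || length(denominator) != 1) {
    usage_error("numerator and denominator must be single numbers")
  }
  if (denominator <= 0) usage_error("denominator must be positive")
  if (numerator < 0 || numerator > denominator) {
    usage_error("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Chi-square test of independence on a 2x2 table
#'
#' Pearson's chi-square statistic with one degree of freedom, optionally
#' with the Yates continuity correction, and the upper-tail p-value. All
#' four marginal sums must be positive. Used to test whether being
#' multichromosomal and carrying a plasmid are independent.
#'
#' @param table 2x2 matrix (or coercible) of nonnegative counts.
#' @param continuity_correction Apply the Yates correction? Default
#'   `FALSE`.
#' @return A list of class `chisq_2x2`: `statistic`, `df` (always 1),
#'   `p_value`, `table`, `continuity_correction`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L)) || !is.numeric(m)) {
    usage_error("table must be a 2x2 numeric matrix")
  }
  if (any(m < 0) || anyNA(m)) {
    usage_error("table must contain nonnegative counts")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    usage_error("all row and column marginal sums must be positive")
  }
  res <- suppressWarnings(chisq.test(m, correct = continuity_correction))
  structure(
    list(
      statistic = unname(res$statistic),
      df = 1L,
      p_value = unname(res$p.value),
      table = m,
      continuity_correction = continuity_correction
    ),
    class = "chisq_2x2"
  )
}

#' @export
print.chisq_2x2 <- function(x, ...) {
  cat(sprintf(
    "<chisq_2x2> X2[1, N = %d] = %.4g, p = %.5g%s\n",
    sum(x$table), x$statistic, x$p_value,
    if (x$continuity_correction) " (Yates-corrected)" else ""
  ))
  invisible(x)
}

#' Cross-tabulate chromosome multiplicity against plasmid carriage
#'
#' Builds the 2x2 contingency table behind the plasmid-prevalence
#' question: rows single-/multichromosomal (fewer than two vs two or more
#' chromosomes), columns plasmid-free vs plasmid-bearing.
#'
#' @param records Curated tibble with `n_chromosomes` and `n_plasmids`.
#' @return 2x2 integer matrix with dimnames `chromosomes` x `plasmids`.
#' @export
multichromosome_plasmid_table <- function(records) {
  multi <- is_multichromosomal(records$n_chromosomes)
  plas <- has_plasmid(records$n_plasmids)
  m <- matrix(
    c(
      sum(!multi & !plas), sum(!multi & plas),
      sum(multi & !plas), sum(multi & plas)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      chromosomes = c("single", "multi"),
      plasmids = c("none", "one_or_more")
    )
  )
  m
}
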