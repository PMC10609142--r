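test_that("boxplot stats give closed-form quartiles and degenerate cases", {
  b <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3)
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)
  expect_equal(b$n, 5)
  single <- boxplot_stats(7)
  expect_true(all(unlist(single[c("minimum", "q1", "median", "q3", "maximum", "mean")]) == 7))
  expect_error(boxplot_stats(c(NA_real_, NA_real_)), class = "cpgmeta_usage_error")
})

test_that("boxplot median matches a sort-based oracle on lognormal draws", {
  x <- withr::with_seed(10, rlnorm(1000, log(4.24), 0.45))
  b <- boxplot_stats(x)
  s <- sort(x)
  expect_identical(b$median, (s[500] + s[501]) / 2)
  expect_identical(b$minimum, s[1])
  expect_identical(b$maximum, s[1000])
  expect_true(b$minimum <= b$q1 && b$q1 <= b$median &&
    b$median <= b$q3 && b$q3 <= b$maximum)
  # missing values are dropped first
  expect_equal(boxplot_stats(c(x, NA))$n, 1000)
})

test_that("exact linearity gives r = 1 and constant features are undefined", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1, z = rep(5, 10))
  cm <- pearson_matrix(d, c("x", "y", "z"))
  expect_equal(cm$r["x", "y"], 1)
  expect_true(is.na(cm$r["x", "z"]))
  expect_true(is.na(cm$r["z", "z"]))
  expect_equal(cm$r["x", "x"], 1)
  expect_true(isSymmetric(cm$r))
})

test_that("pearson matrix equals the direct covariance-formula oracle to 1e-12", {
  d <- withr::with_seed(20, tibble::tibble(
    a = rnorm(50), b = rnorm(50) + 0.5 * rnorm(50)
  ))
  cm <- pearson_matrix(d, c("a", "b"))
  oracle_r <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  expect_equal(cm$r["a", "b"], oracle_r(d$a, d$b), tolerance = 1e-12)
  expect_equal(cm$n["a", "b"], 50)
})

test_that("pairwise-complete deletion keeps per-pair sample sizes independent", {
  d <- withr::with_seed(30, tibble::tibble(
    a = rnorm(40), b = rnorm(40), c = rnorm(40)
  ))
  d$a[1:10] <- NA
  cm <- pearson_matrix(d, c("a", "b", "c"))
  expect_equal(cm$n["b", "c"], 40)
  expect_equal(cm$n["a", "b"], 30)
  complete <- !is.na(d$a)
  direct <- cor(d$a[complete], d$b[complete])
  expect_equal(cm$r["a", "b"], direct, tolerance = 1e-12)
})

test_that("submissions per year bucket correctly, with unknown last", {
  recs <- tibble::tibble(
    release_date = as.Date(c("1995-03-01", "1995-12-31", "1996-06-15"))
  )
  by <- submissions_by_year(recs)
  expect_equal(by$year, c(1995L, 1996L))
  expect_equal(by$count, c(2L, 1L))

  all_missing <- tibble::tibble(release_date = as.Date(c(NA, NA)))
  by2 <- submissions_by_year(all_missing)
  expect_equal(nrow(by2), 1)
  expect_true(is.na(by2$year))
  expect_equal(by2$count, 2L)

  mixed <- tibble::tibble(release_date = as.Date(c("2001-01-01", NA)))
  by3 <- submissions_by_year(mixed)
  expect_equal(sum(by3$count), 2)
  expect_true(is.na(by3$year[nrow(by3)]))
})

test_that("year histogram of a generated fixture matches the manifest exactly", {
  fx <- generate_fixture(fixture_config(n_records = 500, seed = 13), tempfile("fx"))
  db <- load_taxdump(fx$paths$nodes, fx$paths$names)
  cur <- curate(read_genome_report(fx$paths$report), db)
  by <- submissions_by_year(cur$records)
  truth <- fx$summary$year_counts
  for (i in seq_len(nrow(by))) {
    key <- if (is.na(by$year[i])) "unknown" else as.character(by$year[i])
    expect_equal(by$count[i], truth[[key]])
  }
  expect_equal(sum(by$count), fx$summary$n_complete)
})

test_that("distribution by rank counts, sorts, and truncates as documented", {
  recs <- tibble::tibble(phylum = c("A", "A", "B", "unclassified"))
  d <- distribution_by_rank(recs, "phylum")
  expect_equal(d$taxon, c("A", "B", "unclassified"))
  expect_equal(d$count, c(2L, 1L, 1L))
  expect_equal(sum(d$count), nrow(recs))
  top1 <- distribution_by_rank(recs, "phylum", top_n = 1)
  expect_equal(top1$taxon, "A")
  # ties broken by name ascending
  tie <- distribution_by_rank(tibble::tibble(genus = c("Zeta", "Alpha")), "genus")
  expect_equal(tie$taxon, c("Alpha", "Zeta"))
  expect_error(distribution_by_rank(recs, "kingdom"), class = "cpgmeta_usage_error")
})

test_that("per-rank fixture distributions equal the manifest histograms", {
  fx <- generate_fixture(fixture_config(n_records = 800, seed = 23), tempfile("fx"))
  db <- load_taxdump(fx$paths$nodes, fx$paths$names)
  cur <- curate(read_genome_report(fx$paths$report), db)
  for (rank in c("phylum", "genus", "species")) {
    d <- distribution_by_rank(cur$records, rank)
    truth <- fx$summary[[paste0(rank, "_counts")]]
    expect_equal(sum(d$count), fx$summary$n_complete)
    for (i in seq_len(nrow(d))) {
      expect_equal(d$count[i], truth[[d$taxon[i]]])
    }
    expect_equal(nrow(d), length(truth))
  }
})

test_that("reported percentages use half-up rounding and validate inputs", {
  expect_equal(proportion_percent(1633, 32603, 1), 5.0)
  expect_equal(proportion_percent(14279, 32603, 1), 43.8)
  expect_equal(proportion_percent(14156, 32143, 1), 44.0)
  expect_equal(proportion_percent(5, 460, 1), 1.1)
  expect_equal(proportion_percent(123, 460, 1), 26.7)
  expect_equal(proportion_percent(0, 100, 1), 0)
  expect_equal(proportion_percent(1, 800, 1), 0.1) # 0.125 rounds half-up
  expect_error(proportion_percent(5, 0), class = "cpgmeta_usage_error")
  expect_error(proportion_percent(11, 10), class = "cpgmeta_usage_error")
  # complement sums to 100 at the chosen precision
  for (a in c(1633, 14279, 0, 32603)) {
    expect_equal(
      proportion_percent(a, 32603, 1) + proportion_percent(32603 - a, 32603, 1),
      100,
      tolerance = 0.1 + 1e-9
    )
  }
})

test_that("chi-square on a 2x2 table matches the closed-form oracle", {
  even <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_equal(even$df, 1L)

  closed_form <- function(m) {
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  tables <- list(
    matrix(c(20, 10, 10, 20), 2, byrow = TRUE),
    matrix(c(5, 95, 40, 60), 2, byrow = TRUE),
    matrix(c(1, 1, 1, 1), 2)
  )
  for (m in tables) {
    res <- chi_square_2x2(m)
    expect_equal(res$statistic, closed_form(m), tolerance = 1e-12)
    expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE), tolerance = 1e-12)
    # symmetry: swapping both rows and both columns changes nothing
    swapped <- m[2:1, 2:1]
    expect_equal(chi_square_2x2(swapped)$statistic, res$statistic, tolerance = 1e-12)
    # Yates correction only ever shrinks the statistic
    expect_lte(chi_square_2x2(m, continuity_correction = TRUE)$statistic, res$statistic)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), class = "cpgmeta_usage_error")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), class = "cpgmeta_usage_error")
})

test_that("the multichromosome-plasmid cross-tabulation covers all four cells", {
  recs <- tibble::tibble(
    n_chromosomes = c(1L, 1L, 2L, 3L),
    n_plasmids = c(0L, 2L, 0L, 1L)
  )
  tab <- multichromosome_plasmid_table(recs)
  expect_equal(unname(tab), matrix(c(1, 1, 1, 1), 2, byrow = TRUE))
  expect_equal(chi_square_2x2(tab)$statistic, 0)
})
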