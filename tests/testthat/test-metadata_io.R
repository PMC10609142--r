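test_that("a well-formed report line maps directly onto record fields", {
  path <- write_report(c(
    report_header(),
    sample_report_line(size = "4.24", gc = "50.7")
  ))
  rep <- read_genome_report(path)
  expect_equal(nrow(rep$records), 1)
  r <- rep$records
  expect_equal(r$organism_name, "Escherichia coli K-12")
  expect_equal(r$taxid, 511145L)
  expect_equal(r$size_mb, 4.24)
  expect_equal(r$gc_percent, 50.7)
  expect_equal(r$status, "Complete Genome")
  expect_equal(r$release_date, as.Date("1997-09-05"))
  expect_true(is.na(r$ftp_path)) # '-' sentinel
})

test_that("the '-' sentinel maps to missing and is logged", {
  path <- write_report(c(report_header(), sample_report_line(genes = "-")))
  rep <- read_genome_report(path)
  expect_true(is.na(rep$records$genes))
  g <- rep$log[rep$log$field == "genes", ]
  expect_equal(nrow(g), 1)
  expect_equal(g$line, 2L)
  expect_match(g$reason, "sentinel")
})

test_that("lenient parsing is total: malformed cells become missing with a log entry", {
  path <- write_report(c(
    report_header(),
    sample_report_line(size = "4.1mb", gc = "150", date = "sometime"),
    sample_report_line(organism = "Bad taxid", taxid = "xx")
  ))
  rep <- read_genome_report(path)
  expect_equal(nrow(rep$records), 1) # bad-taxid row rejected
  expect_true(is.na(rep$records$size_mb))
  expect_true(is.na(rep$records$gc_percent))
  expect_true(is.na(rep$records$release_date))
  expect_setequal(
    rep$log$reason,
    c(
      "malformed numeric", "out of range", "unparseable date",
      "invalid taxid: record rejected"
    )
  )
  expect_true(all(rep$log$line %in% c(2L, 3L)))
})

test_that("strict mode aborts on malformed numerics and missing mandatory columns", {
  bad_cell <- write_report(c(report_header(), sample_report_line(size = "four")))
  expect_error(read_genome_report(bad_cell, strict = TRUE), class = "cpgmeta_parse_error")
  expect_error(
    read_genome_report(bad_cell, strict = TRUE),
    regexp = "line 2"
  )
  no_status <- write_report(c(
    paste("#Organism/Name", "TaxID", "Size (Mb)", sep = "\t"),
    paste("Org", "1", "4.2", sep = "\t")
  ))
  expect_error(read_genome_report(no_status, strict = TRUE), class = "cpgmeta_parse_error")
})

test_that("unreadable source is an input error, distinct from a parse error", {
  expect_error(read_genome_report(tempfile("nope")), class = "cpgmeta_input_error")
  no_header <- write_report(c("Organism\t1", "x\t2"))
  expect_error(read_genome_report(no_header), class = "cpgmeta_parse_error")
})

test_that("column identification is order-independent", {
  cols <- c(
    "#Organism/Name", "TaxID", "Size (Mb)", "GC%", "Replicons", "Genes",
    "Proteins", "Release Date", "Status", "FTP Path"
  )
  vals <- c(
    "Org A", "77", "3.33", "44.4", "chromosome:X1", "3000", "2900",
    "2010/05/06", "Complete Genome", "https://x"
  )
  straight <- read_genome_report(write_report(c(
    paste(cols, collapse = "\t"), paste(vals, collapse = "\t")
  )))
  perm <- sample(length(cols))
  # keep a '#' on the first header cell, as the dialect requires
  pcols <- sub("^#", "", cols)[perm]
  pcols[1] <- paste0("#", pcols[1])
  permuted <- read_genome_report(write_report(c(
    paste(pcols, collapse = "\t"), paste(vals[perm], collapse = "\t")
  )))
  expect_identical(straight$records, permuted$records)
})

test_that("extra source columns are preserved verbatim", {
  path <- write_report(c(
    paste("#Organism/Name", "TaxID", "Status", "BioProject Accession", "Center", sep = "\t"),
    paste("Org", "9", "Complete Genome", "PRJNA123", "JGI", sep = "\t")
  ))
  rep <- read_genome_report(path)
  expect_equal(rep$records[["BioProject Accession"]], "PRJNA123")
  expect_equal(rep$records[["Center"]], "JGI")
})

test_that("a generated 1,000-line report parses with zero rejects", {
  fx <- generate_fixture(
    fixture_config(n_records = 1000, seed = 7),
    tempfile("fx")
  )
  rep <- read_genome_report(fx$paths$report)
  expect_equal(nrow(rep$records), 1000)
  expect_false(any(grepl("rejected", rep$log$reason)))
})

test_that("curated CSV writes header-only for zero records and round-trips values", {
  empty <- random_curated_records(0)
  path <- tempfile(fileext = ".csv")
  write_curated_csv(empty, path)
  expect_equal(length(readLines(path)), 1)
  back <- read_curated_csv(path)
  expect_equal(nrow(back), 0)
  expect_identical(names(back), curated_columns())

  three <- random_curated_records(3, seed = 11)
  write_curated_csv(three, path)
  rt <- read_curated_csv(path)
  expect_equal(as.data.frame(rt), as.data.frame(three))
})

test_that("curated CSV read/write is the identity on arbitrary generated records", {
  for (seed in 1:5) {
    recs <- random_curated_records(40, seed = seed)
    path <- tempfile(fileext = ".csv")
    write_curated_csv(recs, path)
    expect_equal(as.data.frame(read_curated_csv(path)), as.data.frame(recs))
  }
  big <- random_curated_records(500, seed = 99)
  path <- tempfile(fileext = ".csv")
  write_curated_csv(big, path)
  expect_equal(length(readLines(path)), 501)
  expect_equal(as.data.frame(read_curated_csv(path)), as.data.frame(big))
})

test_that("schema mismatch on read is rejected", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1, b = 2), path, row.names = FALSE)
  expect_error(read_curated_csv(path), class = "cpgmeta_parse_error")
})

test_that("fetch_report returns a fresh cache without touching the network", {
  cache <- tempfile("cache")
  dir.create(cache)
  cached <- file.path(cache, "prokaryotes.txt")
  writeLines("#header", cached)
  got <- suppressMessages(fetch_report(
    url = "file:///unreachable/prokaryotes.txt",
    cache_dir = cache, max_age = 3600
  ))
  expect_equal(got, cached)
  expect_equal(readLines(got), "#header")
})

test_that("fetch_report falls back to a stale cache with a warning", {
  cache <- tempfile("cache")
  dir.create(cache)
  cached <- file.path(cache, "prokaryotes.txt")
  writeLines("#stale", cached)
  Sys.setFileTime(cached, Sys.time() - 10 * 86400)
  expect_warning(
    got <- fetch_report(
      url = "file:///unreachable/prokaryotes.txt",
      cache_dir = cache, max_age = 3600
    ),
    regexp = "stale"
  )
  expect_equal(readLines(got), "#stale")
})

test_that("fetch_report with no cache and no network aborts", {
  expect_error(
    suppressWarnings(fetch_report(
      url = "file:///unreachable/prokaryotes.txt",
      cache_dir = tempfile("cache"), max_age = 3600
    )),
    class = "cpgmeta_input_error"
  )
})
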