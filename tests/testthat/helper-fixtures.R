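# Hand-built fixtures shared across test files. Everything is generated in
# code at test time; no stored binary data.

report_header <- function(cols = c(
                            "#Organism/Name", "TaxID", "Size (Mb)", "GC%",
                            "Replicons", "Genes", "Proteins", "Release Date",
                            "Status", "FTP Path"
                          )) {
  paste(cols, collapse = "\t")
}

write_report <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# One well-formed complete-genome line in the report dialect.
sample_report_line <- function(organism = "Escherichia coli K-12",
                               taxid = 511145,
                               size = "4.64", gc = "50.8",
                               replicons = "chromosome:U00096.3",
                               genes = "4321", proteins = "4140",
                               date = "1997/09/05",
                               status = "Complete Genome",
                               ftp = "-") {
  paste(organism, taxid, size, gc, replicons, genes, proteins, date, status, ftp,
    sep = "\t"
  )
}

# Minimal taxdump: root -> Bacteria -> Proteobacteria (phylum) ->
# Escherichia (genus) -> E. coli (species); plus Archaea.
write_mini_taxdump <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dmp <- function(...) paste0(paste(c(...), collapse = "\t|\t"), "\t|")
  writeLines(c(
    dmp(1, 1, "no rank"),
    dmp(2, 1, "superkingdom"),
    dmp(2157, 1, "superkingdom"),
    dmp(1224, 2, "phylum"),
    dmp(561, 1224, "genus"),
    dmp(562, 561, "species"),
    dmp(511145, 562, "strain")
  ), file.path(dir, "nodes.dmp"))
  writeLines(c(
    dmp(1, "root", "", "scientific name"),
    dmp(2, "Bacteria", "", "scientific name"),
    dmp(2, "eubacteria", "", "genbank common name"),
    dmp(2157, "Archaea", "", "scientific name"),
    dmp(1224, "Proteobacteria", "", "scientific name"),
    dmp(561, "Escherichia", "", "scientific name"),
    dmp(562, "Escherichia coli", "", "scientific name")
  ), file.path(dir, "names.dmp"))
  dir
}

mini_taxdb <- function(dir = write_mini_taxdump()) {
  load_taxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
}

# Random curated records for property tests (no empty-string fields: the
# CSV form cannot distinguish "" from missing).
random_curated_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      organism_name = sprintf("Organism %d", seq_len(n)),
      taxid = sample.int(1e6, n),
      size_mb = round(runif(n, 0.1, 16), 2),
      gc_percent = round(runif(n, 14, 76), 1),
      replicons = ifelse(runif(n) < 0.1, NA_character_,
        sprintf("chromosome:NC_%06d.1", seq_len(n))
      ),
      n_chromosomes = sample(0:3, n, replace = TRUE),
      n_plasmids = sample(0:4, n, replace = TRUE),
      genes = ifelse(runif(n) < 0.1, NA_integer_, sample.int(15000, n)),
      proteins = sample.int(15000, n),
      release_date = as.Date("1995-01-01") + sample.int(10000, n),
      ftp_path = sprintf("https://example.org/g/%d", seq_len(n)),
      superkingdom = sample(c("Bacteria", "Archaea"), n, replace = TRUE),
      phylum = sample(c("Proteobacteria", "Firmicutes", "unclassified"), n, replace = TRUE),
      class = "unclassified",
      order = "unclassified",
      family = "unclassified",
      genus = sample(c("Escherichia", "Bacillus"), n, replace = TRUE),
      species = sprintf("Species %d", seq_len(n))
    )
  })
}
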