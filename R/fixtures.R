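# Seeded synthetic-data generator: emits a genome report in the source
# dialect plus a matched mini taxdump, together with a ground-truth
# manifest. The manifest is the oracle every pipeline stage is checked
# against. Defaults emulate the observed conditions for complete
# prokaryotic genomes: lognormal sizes around a 4.24 Mb median spanning
# roughly 0.1-16 Mb, GC centred on 50.7% within the observed 13.5-75.6%
# extremes, ~5% multichromosomal and ~44% plasmid-bearing genomes.

#' Configuration for the synthetic fixture generator
#'
#' All distributions are configurable; the seed fixes the full output
#' byte-for-byte. Replicon strings are rendered from the ground-truth
#' counts through the descriptor vocabulary the parser understands, with
#' a configurable fraction of adversarial spelling variants
#' ("chromosome 2", "megaplasmid", stray whitespace) to exercise the
#' grammar. Complete/non-complete status is assigned by deterministic
#' allocation (the first `floor(fraction_complete * n_records)` records
#' after a seeded shuffle), so the complete count is exact, not binomial.
#'
#' @param n_records Number of report rows.
#' @param fraction_complete Fraction of rows with status
#'   "Complete Genome", allocated deterministically.
#' @param size_median_mb,size_sigma Lognormal genome-size parameters:
#'   median in Mb and sigma on the log scale.
#' @param gc_mean,gc_sd,gc_bounds Truncated-normal GC% parameters
#'   (mean, sd, inclusive bounds).
#' @param chromosome_probs Named probability vector over chromosome
#'   counts (names are the counts).
#' @param plasmid_probs Named probability vector over plasmid counts.
#' @param other_replicon_prob Probability of one extra unclassifiable
#'   replicon entry per genome.
#' @param missing_rates Named rates of missing cells per column
#'   (`size_mb`, `gc_percent`, `genes`, `proteins`, `release_date`,
#'   `replicons`, `ftp_path`).
#' @param adversarial_fraction Fraction of replicon entries rendered with
#'   adversarial spelling/whitespace variants.
#' @param n_phyla,n_genera,n_species Taxonomy shape. Class, order, and
#'   family are deliberately left unresolved so lineages exercise the
#'   "unclassified" sentinel.
#' @param year_range Inclusive release-year span.
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(n_records = 1000,
                           fraction_complete = 0.4,
                           size_median_mb = 4.24,
                           size_sigma = 0.45,
                           gc_mean = 50.7,
                           gc_sd = 8,
                           gc_bounds = c(13.5, 75.6),
                           chromosome_probs = c("1" = 0.95, "2" = 0.04, "3" = 0.01),
                           plasmid_probs = c("0" = 0.56, "1" = 0.24, "2" = 0.13, "3" = 0.07),
                           other_replicon_prob = 0.02,
                           missing_rates = c(
                             size_mb = 0.01, gc_percent = 0.01, genes = 0.02,
                             proteins = 0.02, release_date = 0.02,
                             replicons = 0.01, ftp_path = 0.05
                           ),
                           adversarial_fraction = 0.15,
                           n_phyla = 8, n_genera = 30, n_species = 90,
                           year_range = c(1995, 2023),
                           seed = 1L) {
  stopifnot(
    n_records >= 1,
    size_median_mb > 0, size_sigma > 0, gc_sd > 0,
    length(gc_bounds) == 2, gc_bounds[[1]] < gc_bounds[[2]],
    other_replicon_prob >= 0, other_replicon_prob <= 1,
    adversarial_fraction >= 0, adversarial_fraction <= 1,
    n_phyla >= 1, n_genera >= 1, n_species >= 1,
    length(year_range) == 2, year_range[[1]] <= year_range[[2]]
  )
  if (fraction_complete < 0 || fraction_complete > 1) {
    usage_error("fraction_complete must lie in [0, 1]")
  }
  for (p in list(chromosome_probs, plasmid_probs)) {
    if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p))))) {
      usage_error("count distributions must be named by integer counts")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      usage_error("count distribution probabilities must be nonnegative and sum to 1")
    }
  }
  need <- c(
    "size_mb", "gc_percent", "genes", "proteins", "release_date",
    "replicons", "ftp_path"
  )
  if (!all(need %in% names(missing_rates))) {
    usage_error(paste0("missing_rates must name: ", paste(need, collapse = ", ")))
  }
  if (any(missing_rates < 0) || any(missing_rates > 1)) {
    usage_error("missing_rates must lie in [0, 1]")
  }
  structure(
    list(
      n_records = as.integer(n_records),
      fraction_complete = fraction_complete,
      size_median_mb = size_median_mb, size_sigma = size_sigma,
      gc_mean = gc_mean, gc_sd = gc_sd, gc_bounds = gc_bounds,
      chromosome_probs = chromosome_probs, plasmid_probs = plasmid_probs,
      other_replicon_prob = other_replicon_prob,
      missing_rates = missing_rates,
      adversarial_fraction = adversarial_fraction,
      n_phyla = as.integer(n_phyla), n_genera = as.integer(n_genera),
      n_species = as.integer(n_species),
      year_range = as.integer(year_range),
      seed = as.integer(seed)
    ),
    class = "fixture_config"
  )
}

sample_counts <- function(probs, n) {
  as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

random_accession <- function(k) {
  sprintf("NZ_CP%06d.%d", sample.int(999999L, k, replace = TRUE), sample(1:3, k, replace = TRUE))
}

# Render one genome's replicon field from its ground-truth counts.
# Adversarial entries stay inside the parser's grammar (same kind), they
# just use the messier spellings seen in the wild.
render_replicons <- function(n_chr, n_plas, n_other, adversarial_fraction) {
  entries <- character()
  if (n_chr == 1) {
    adv <- runif(1) < adversarial_fraction
    lab <- if (adv) {
      sample(c("Chromosome", "chromosome circular", "chromosome 1"), 1)
    } else {
      "chromosome"
    }
    entries <- paste0(lab, ":", random_accession(1))
  } else if (n_chr > 1) {
    for (i in seq_len(n_chr)) {
      adv <- runif(1) < adversarial_fraction
      lab <- if (adv) paste0("Chromosome ", i) else paste0("chromosome ", i)
      acc <- random_accession(1)
      if (runif(1) < 0.1) acc <- paste(random_accession(2), collapse = "/")
      entries[[length(entries) + 1L]] <- paste0(lab, ":", acc)
    }
  }
  if (n_plas > 0) {
    for (i in seq_len(n_plas)) {
      adv <- runif(1) < adversarial_fraction
      pname <- paste0(
        "p", paste(sample(LETTERS, 2, replace = TRUE), collapse = ""),
        sample.int(99L, 1)
      )
      if (adv) {
        variant <- sample(3, 1)
        entries[[length(entries) + 1L]] <- switch(variant,
          paste0("megaplasmid:", random_accession(1)),
          paste0("Plasmid ", pname, " : ", random_accession(1)),
          paste0("plasmid ", pname) # descriptor only, no accession
        )
      } else {
        entries[[length(entries) + 1L]] <- paste0("plasmid ", pname, ":", random_accession(1))
      }
    }
  }
  if (n_other > 0) {
    for (i in seq_len(n_other)) {
      entries[[length(entries) + 1L]] <-
        paste0(sample(c("segment A", "linear replicon"), 1), ":", random_accession(1))
    }
  }
  if (length(entries) == 0) {
    return(MISSING_SENTINEL)
  }
  entries <- entries[sample.int(length(entries))]
  sep <- if (runif(1) < adversarial_fraction) " ;  " else "; "
  paste(entries, collapse = sep)
}

dmp_line <- function(...) {
  paste0(paste(c(...), collapse = "\t|\t"), "\t|")
}

#' Generate a synthetic genome report, taxdump, and ground-truth manifest
#'
#' Writes four artifacts to `out_dir`: `report.txt` (genome-report
#' dialect), `nodes.dmp` and `names.dmp` (taxdump dialect, covering every
#' taxid used), `manifest.csv` (per-record ground truth: status,
#' chromosome/plasmid/other counts, lineage, release year, feature
#' values), and `summary.json` (aggregate truths over the complete-level
#' records: complete count, multichromosomal count, plasmid-bearing
#' count, per-rank and per-year histograms). Identical config and seed
#' reproduce all files byte-for-byte.
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (report, nodes, names,
#'   manifest, summary), the `manifest` tibble, the `summary` list, and
#'   the `config`.
#' @export
generate_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_records

  # --- taxonomy: root -> superkingdom -> phylum -> genus -> species
  n_arch <- if (config$n_phyla >= 3) max(1L, round(0.15 * config$n_phyla)) else 0L
  phylum_ids <- 100L + seq_len(config$n_phyla)
  phylum_names <- sprintf("Phylum%02d", seq_len(config$n_phyla))
  phylum_sk <- c(
    rep("Archaea", n_arch),
    rep("Bacteria", config$n_phyla - n_arch)
  )
  genus_ids <- 10000L + seq_len(config$n_genera)
  genus_names <- sprintf("Genus%03d", seq_len(config$n_genera))
  genus_phylum <- sample.int(config$n_phyla, config$n_genera, replace = TRUE)
  species_ids <- 100000L + seq_len(config$n_species)
  species_genus <- sample.int(config$n_genera, config$n_species, replace = TRUE)
  species_names <- sprintf("%s sp%04d", genus_names[species_genus], seq_len(config$n_species))

  sk_ids <- c(Bacteria = 2L, Archaea = 2157L)
  nodes <- c(
    dmp_line(1, 1, "no rank"),
    dmp_line(sk_ids[["Bacteria"]], 1, "superkingdom"),
    dmp_line(sk_ids[["Archaea"]], 1, "superkingdom"),
    vapply(seq_len(config$n_phyla), function(i) {
      dmp_line(phylum_ids[[i]], sk_ids[[phylum_sk[[i]]]], "phylum")
    }, character(1)),
    vapply(seq_len(config$n_genera), function(i) {
      dmp_line(genus_ids[[i]], phylum_ids[[genus_phylum[[i]]]], "genus")
    }, character(1)),
    vapply(seq_len(config$n_species), function(i) {
      dmp_line(species_ids[[i]], genus_ids[[species_genus[[i]]]], "species")
    }, character(1))
  )
  names_lines <- c(
    dmp_line(1, "root", "", "scientific name"),
    dmp_line(sk_ids[["Bacteria"]], "Bacteria", "", "scientific name"),
    dmp_line(sk_ids[["Archaea"]], "Archaea", "", "scientific name"),
    vapply(seq_len(config$n_phyla), function(i) {
      dmp_line(phylum_ids[[i]], phylum_names[[i]], "", "scientific name")
    }, character(1)),
    vapply(seq_len(config$n_genera), function(i) {
      dmp_line(genus_ids[[i]], genus_names[[i]], "", "scientific name")
    }, character(1)),
    vapply(seq_len(config$n_species), function(i) {
      dmp_line(species_ids[[i]], species_names[[i]], "", "scientific name")
    }, character(1))
  )

  # --- per-record truth
  sp <- sample.int(config$n_species, n, replace = TRUE)
  taxid <- species_ids[sp]
  organism_name <- sprintf("%s strain S%05d", species_names[sp], seq_len(n))

  shuffle <- sample.int(n)
  n_complete <- floor(config$fraction_complete * n)
  is_complete <- logical(n)
  is_complete[shuffle[seq_len(n_complete)]] <- TRUE
  status <- ifelse(
    is_complete, "Complete Genome",
    sample(c("Scaffold", "Contig", "Chromosome"), n, replace = TRUE)
  )

  n_chr <- sample_counts(config$chromosome_probs, n)
  n_plas <- sample_counts(config$plasmid_probs, n)
  n_other <- as.integer(runif(n) < config$other_replicon_prob)

  miss <- lapply(config$missing_rates, function(rate) runif(n) < rate)

  # a genome whose replicon field is missing has unknown (zero) counts
  n_chr[miss$replicons] <- 0L
  n_plas[miss$replicons] <- 0L
  n_other[miss$replicons] <- 0L
  replicons <- character(n)
  for (i in seq_len(n)) {
    replicons[[i]] <- if (miss$replicons[[i]]) {
      MISSING_SENTINEL
    } else {
      render_replicons(n_chr[[i]], n_plas[[i]], n_other[[i]], config$adversarial_fraction)
    }
  }
  # rendering can also yield the sentinel when all counts are zero
  none <- replicons == MISSING_SENTINEL
  n_chr[none] <- 0L
  n_plas[none] <- 0L
  n_other[none] <- 0L

  size_mb <- round(pmin(pmax(
    rlnorm(n, log(config$size_median_mb), config$size_sigma), 0.11
  ), 16.04), 2)
  gc <- round(rtruncnorm(
    n, config$gc_mean, config$gc_sd,
    config$gc_bounds[[1]], config$gc_bounds[[2]]
  ), 1)
  genes <- as.integer(round(size_mb * 1000 * runif(n, 0.85, 1.1)))
  proteins <- as.integer(round(genes * runif(n, 0.85, 0.97)))

  d0 <- as.Date(sprintf("%d-01-01", config$year_range[[1]]))
  d1 <- as.Date(sprintf("%d-12-31", config$year_range[[2]]))
  release_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L
  ftp_path <- sprintf(
    "https://ftp.ncbi.nlm.nih.gov/genomes/all/GCA/%03d/%03d/%03d/GCA_%09d.1_ASM%dv1",
    sample.int(999L, n, replace = TRUE), sample.int(999L, n, replace = TRUE),
    sample.int(999L, n, replace = TRUE), sample.int(999999999L, n, replace = TRUE),
    seq_len(n)
  )

  size_out <- ifelse(miss$size_mb, NA_real_, size_mb)
  gc_out <- ifelse(miss$gc_percent, NA_real_, gc)
  genes_out <- ifelse(miss$genes, NA_integer_, genes)
  proteins_out <- ifelse(miss$proteins, NA_integer_, proteins)
  date_out <- release_date
  date_out[miss$release_date] <- NA
  ftp_out <- ifelse(miss$ftp_path, NA_character_, ftp_path)

  cell <- function(x) ifelse(is.na(x), MISSING_SENTINEL, as.character(x))
  header <- paste(c(
    "#Organism/Name", "TaxID", "BioProject Accession", "Group", "SubGroup",
    "Size (Mb)", "GC%", "Replicons", "Genes", "Proteins", "Release Date",
    "Status", "Center", "FTP Path"
  ), collapse = "\t")
  rows <- paste(
    organism_name, taxid,
    sprintf("PRJNA%06d", sample.int(999999L, n, replace = TRUE)),
    phylum_sk[genus_phylum[species_genus[sp]]],
    phylum_names[genus_phylum[species_genus[sp]]],
    cell(ifelse(miss$size_mb, NA, sprintf("%.2f", size_mb))),
    cell(ifelse(miss$gc_percent, NA, sprintf("%.1f", gc))),
    replicons,
    cell(genes_out), cell(proteins_out),
    cell(format(date_out, "%Y/%m/%d")),
    status, "SynthCenter", cell(ftp_out),
    sep = "\t"
  )

  manifest <- tibble::tibble(
    row_id = seq_len(n),
    organism_name = organism_name,
    taxid = taxid,
    status = status,
    is_complete = is_complete,
    n_chromosomes = n_chr,
    n_plasmids = n_plas,
    n_other = n_other,
    size_mb = size_out,
    gc_percent = gc_out,
    genes = genes_out,
    proteins = proteins_out,
    year = ifelse(is.na(date_out), NA_integer_, as.integer(format(date_out, "%Y"))),
    superkingdom = phylum_sk[genus_phylum[species_genus[sp]]],
    phylum = phylum_names[genus_phylum[species_genus[sp]]],
    class = UNCLASSIFIED, order = UNCLASSIFIED, family = UNCLASSIFIED,
    genus = genus_names[species_genus[sp]],
    species = species_names[sp]
  )

  cm <- manifest[manifest$is_complete, , drop = FALSE]
  hist_of <- function(x) {
    x[is.na(x)] <- "unknown"
    t <- table(x)
    as.list(stats::setNames(as.integer(t), names(t)))
  }
  summary <- list(
    n_records = n,
    n_complete = nrow(cm),
    n_multichromosomal_complete = sum(cm$n_chromosomes >= 2),
    n_plasmid_bearing_complete = sum(cm$n_plasmids >= 1),
    phylum_counts = hist_of(cm$phylum),
    genus_counts = hist_of(cm$genus),
    species_counts = hist_of(cm$species),
    year_counts = hist_of(as.character(cm$year)),
    seed = config$seed
  )

  paths <- list(
    report = file.path(out_dir, "report.txt"),
    nodes = file.path(out_dir, "nodes.dmp"),
    names = file.path(out_dir, "names.dmp"),
    manifest = file.path(out_dir, "manifest.csv"),
    summary = file.path(out_dir, "summary.json")
  )
  writeLines(c(header, rows), paths$report)
  writeLines(nodes, paths$nodes)
  writeLines(names_lines, paths$names)
  write.csv(as.data.frame(manifest), paths$manifest, row.names = FALSE, na = "")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    paths = paths, manifest = manifest, summary = summary, config = config
  ))
}
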