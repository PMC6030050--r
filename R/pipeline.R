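build_params <- function(config) {
  pp <- do.call(primer_pair, config$primers %||% list())
  qp <- do.call(qc_params, config$qc %||% list())
  ap <- do.call(assignment_params, config$assignment %||% list())
  mp <- do.call(mitotype_params, config$mitotype %||% list())
  list(primers = pp, qc = qp, assignment = ap, mitotype = mp,
       k = config[["k"]] %||% 11L)  # [[ avoids partial matching
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$reference_fasta))
    stop("config: reference_fasta is required")
  if (!file.exists(config$reference_fasta))
    stop("config: reference_fasta does not exist: ", config$reference_fasta)
  if (!is.null(config$known_haplotypes_fasta) &&
      !file.exists(config$known_haplotypes_fasta))
    stop("config: known_haplotypes_fasta does not exist: ",
         config$known_haplotypes_fasta)
  if (is.null(config$fastq) && is.null(config$simulate))
    stop("config: either fastq or a simulate block is required")
  if (!is.null(config$fastq) && !file.exists(config$fastq))
    stop("config: fastq does not exist: ", config$fastq)
  if (is.null(config$outdir)) stop("config: outdir is required")
  config$params <- build_params(config)  # validates all parameter blocks
  config
}

community_spec_from_config <- function(sim) {
  members <- lapply(sim$members, function(m)
    list(species = m$species, fraction = m$fraction,
         mitotypes = unlist(m$mitotypes)))
  community_spec(members, host_fraction = sim$host_fraction %||% 0)
}

#' Run the full pipeline
#'
#' Orchestrates build-db, read ingestion or simulation, QC, assignment,
#' community profiling and mitotype calling as one reproducible run. All
#' outputs land in `config$outdir` together with a machine-readable
#' manifest (parameters, seed, package version, md5 of every output);
#' rerunning with the same config and seed reproduces identical files.
#'
#' @param config list or path to a YAML file. Required: `reference_fasta`,
#'   `outdir`, and either `fastq` or a `simulate` block (`n_reads`,
#'   `host_fraction`, `members`, optional `error_model` fields);
#'   `known_haplotypes_fasta` enables mitotype calling; optional blocks
#'   `primers`, `qc`, `assignment`, `mitotype` override defaults; `seed`
#'   governs all randomness.
#' @param library_id label for the sequenced library.
#' @return invisibly, a list with the database, QC report, assignments,
#'   profile, mitotype tables, and the manifest.
#' @export
run_pipeline <- function(config, library_id = "library1") {
  config <- validate_config(config)
  p <- config$params
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  records <- read_reference_fasta(config$reference_fasta,
                                  host_species = config$host_species %||%
                                    "Apis mellifera")
  db <- build_database(records, p$primers, k = p$k)
  write_database(db, file.path(outdir, "db"))

  known <- NULL
  if (!is.null(config$known_haplotypes_fasta))
    known <- read_known_haplotypes(config$known_haplotypes_fasta)

  if (!is.null(config$fastq)) {
    reads <- read_fastq(config$fastq)
    truth <- NULL
  } else {
    sim <- config$simulate
    if (is.null(known))
      stop("simulation requires known_haplotypes_fasta to define ",
           "per-mitotype amplicons")
    sources <- do.call(rbind, lapply(seq_len(nrow(known)), function(i) {
      amp <- extract_amplicon(list(accession = known$haplotype_id[i],
                                   sequence = known$sequence[i]), p$primers)
      if (is.null(amp)) return(NULL)
      data.frame(species = known$species[i],
                 haplotype_id = known$haplotype_id[i],
                 amplicon = amp$with_primers_sequence,
                 stringsAsFactors = FALSE)
    }))
    host_amp <- NULL
    host_rec <- db$records[db$records$is_host, , drop = FALSE]
    if (nrow(host_rec) > 0)
      host_amp <- db$amplicons[[host_rec$accession[1]]]$with_primers_sequence
    model <- do.call(error_model, sim$error_model %||% list())
    spec <- community_spec_from_config(sim)
    lib <- simulate_library(sources, host_amp, spec, model,
                            n_reads = sim$n_reads, seed = seed)
    reads <- lib$reads
    truth <- lib$truth
    write_fastq(reads, file.path(outdir, "simulated.fastq"))
    write.table(truth, file.path(outdir, "truth_manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  qc <- filter_reads(reads, p$qc, p$primers)
  write.table(qc$report$dispositions, file.path(outdir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  asg <- assign_batch(qc$reads, db, p$assignment)
  write.table(asg$assignments, file.path(outdir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  profile <- profile_library(asg$assignments, library_id)
  write_profile(profile, file.path(outdir, "profile.tsv"))

  mito <- list()
  if (!is.null(known)) {
    for (sp in eligible_species(list(profile), p$mitotype)) {
      kn_sp <- known[known$species == sp, , drop = FALSE]
      if (nrow(kn_sp) == 0) next
      classes <- project_haplotypes(kn_sp, p$primers)
      sp_reads <- qc$reads[qc$reads$read_id %in%
        asg$assignments$read_id[asg$assignments$status == "assigned_species" &
                                  asg$assignments$species == sp], ,
        drop = FALSE]
      if (nrow(sp_reads) == 0) next
      acc <- db$records$accession[db$records$species == sp][1]
      collapsed <- collapse_reads(sp_reads,
                                  db$amplicons[[acc]]$with_primers_sequence,
                                  p$primers, p$mitotype)
      mito[[sp]] <- call_mitotypes(collapsed, classes, p$mitotype)
      write.table(mito[[sp]]$calls,
                  file.path(outdir, paste0("mitotypes_",
                                           gsub("[^A-Za-z0-9]+", "_", sp),
                                           ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("honeytrace")),
    seed = seed, library_id = library_id,
    qc = qc$report[c("n_input", "n_retained", "n_too_short",
                     "n_low_quality")],
    assignment_summary = asg$summary,
    files = setNames(as.list(unname(tools::md5sum(outputs))),
                     sub(paste0(outdir, "/"), "", outputs, fixed = TRUE)))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(db = db, qc_report = qc$report, assignments = asg,
                 profile = profile, mitotypes = mito, manifest = manifest))
}

#' Reproduce the published worked-example percentages
#'
#' Recomputes every per-library taxon fraction and abundance category from
#' the packaged per-species count table and compares them with the
#' percentages and category labels printed in the source study. Computed
#' percentages are rounded to the printed precision before comparison;
#' anything differing by more than 0.01 percentage points, or any category
#' mismatch, is flagged.
#'
#' @param stop_on_mismatch error out when any row fails.
#' @return list with `percentages` (computed vs printed, `match` flag),
#'   `categories` (per Table-2-style row), and `all_match`.
#' @export
worked_example_report <- function(stop_on_mismatch = FALSE) {
  counts_path <- system.file("extdata", "table2_counts.tsv",
                             package = "honeytrace", mustWork = TRUE)
  pct_path <- system.file("extdata", "results_percentages.tsv",
                          package = "honeytrace", mustWork = TRUE)
  counts <- read.delim(counts_path, stringsAsFactors = FALSE)
  if (nrow(counts) == 0) stop("empty worked-example fixture")
  profiles <- load_count_table(counts_path)
  printed <- read.delim(pct_path, stringsAsFactors = FALSE)

  computed_pct <- numeric(nrow(printed)); rounded <- numeric(nrow(printed))
  for (i in seq_len(nrow(printed))) {
    prof <- profiles[[printed$library[i]]]
    row <- as.data.frame(prof)[as.data.frame(prof)$taxon ==
                                 printed$taxon[i], ]
    if (nrow(row) != 1) stop("fixture row not found: ", printed$taxon[i])
    computed_pct[i] <- 100 * row$fraction
    dp <- nchar(sub("^[^.]*\\.?", "", as.character(printed$printed_pct[i])))
    rounded[i] <- round(computed_pct[i], dp)
  }
  pct <- data.frame(library = printed$library, taxon = printed$taxon,
                    computed_pct = computed_pct, rounded_pct = rounded,
                    printed_pct = printed$printed_pct,
                    match = abs(rounded - printed$printed_pct) <= 0.01 + 1e-9,
                    stringsAsFactors = FALSE)

  cat_rows <- lapply(unique(counts$library), function(lib) {
    prof <- as.data.frame(profiles[[lib]])
    d <- counts[counts$library == lib, ]
    m <- match(d$taxon, prof$taxon)
    data.frame(library = lib, taxon = d$taxon,
               computed_category = prof$category[m],
               printed_category = tolower(d$printed_category),
               stringsAsFactors = FALSE)
  })
  cats <- do.call(rbind, cat_rows)
  cats$match <- cats$computed_category == cats$printed_category

  all_match <- all(pct$match) && all(cats$match)
  if (stop_on_mismatch && !all_match)
    stop("worked example does not reproduce the printed values")
  list(percentages = pct, categories = cats, all_match = all_match)
}
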