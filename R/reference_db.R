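#' Degenerate Hemiptera COI primer pair
#'
#' The default primers target a 135-140 bp COI fragment conserved across the
#' main plant-sucking Hemiptera families (forward written 5'->3' on the
#' sense strand, reverse 5'->3' on the antisense strand, the usual PCR
#' convention). `W` = A/T and `R` = A/G widen the taxonomic net.
#'
#' @param forward,reverse IUPAC primer strings.
#' @param max_mismatches mismatch budget per primer site during reference
#'   extraction (Hamming, no indels).
#' @param min_amplicon_len,max_amplicon_len accepted product span in bp,
#'   primers included.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward = "TGGAWCAGGAACAGGATGAAC",
                        reverse = "AAATGAARTTGATTGCTCCTA",
                        max_mismatches = 2L,
                        min_amplicon_len = 100L,
                        max_amplicon_len = 200L) {
  stopifnot(nchar(forward) > 0, nchar(reverse) > 0,
            max_mismatches >= 0, min_amplicon_len <= max_amplicon_len)
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatches = as.integer(max_mismatches),
                 min_amplicon_len = as.integer(min_amplicon_len),
                 max_amplicon_len = as.integer(max_amplicon_len)),
            class = "primer_pair")
}

parse_reference_headers <- function(headers, host_species = "Apis mellifera") {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad)) {
    stop("malformed reference header (expected accession|order|suborder|",
         "family|genus|species): ", headers[bad][1])
  }
  m <- do.call(rbind, parts)
  df <- data.frame(accession = m[, 1], order = m[, 2], suborder = m[, 3],
                   family = m[, 4], genus = m[, 5], species = m[, 6],
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$accession))
    stop("duplicate accession in reference set: ",
         df$accession[duplicated(df$accession)][1])
  if (any(df$order == ""))
    stop("order rank must be non-empty for every reference record")
  df$is_host <- df$species == host_species
  df
}

#' Read a taxonomy-annotated COI reference FASTA
#'
#' Headers carry the lineage inline as
#' `accession|order|suborder|family|genus|species` (pipe-delimited; lower
#' ranks may be empty for records annotated at genus or family level only).
#' The honey-bee host is an ordinary record, flagged `is_host`, so host
#' reads are assigned and then excluded from Hemiptera profiles instead of
#' going silently unmatched.
#'
#' @param path FASTA file.
#' @param host_species species name marking the off-target host lineage.
#' @return data.frame of records with lineage columns, `is_host`, `sequence`.
#' @export
read_reference_fasta <- function(path, host_species = "Apis mellifera") {
  seqs <- Biostrings::readDNAStringSet(path)
  df <- parse_reference_headers(names(seqs), host_species)
  df$sequence <- toupper(as.character(seqs))
  rownames(df) <- NULL
  df
}

#' Read a known-haplotype FASTA
#'
#' Headers are `species|haplotype_id|n_db_entries`, where `n_db_entries`
#' counts how many public database entries carry that haplotype (0 for a
#' haplotype never deposited).
#'
#' @param path FASTA file.
#' @return data.frame with `species`, `haplotype_id`, `n_db_entries`,
#'   `sequence`.
#' @export
read_known_haplotypes <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed known-haplotype header (expected ",
         "species|haplotype_id|n_db_entries)")
  m <- do.call(rbind, parts)
  df <- data.frame(species = m[, 1], haplotype_id = m[, 2],
                   n_db_entries = as.integer(m[, 3]),
                   sequence = toupper(as.character(seqs)),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$n_db_entries)) || any(df$n_db_entries < 0))
    stop("n_db_entries must be a non-negative integer")
  dup <- duplicated(df[, c("species", "haplotype_id")])
  if (any(dup)) stop("duplicate haplotype_id within species")
  rownames(df) <- NULL
  df
}

# earliest (5'-most) valid product on one strand, or NULL
find_product_plus <- function(sequence, primers) {
  fwd <- find_primer_sites(sequence, primers$forward, primers$max_mismatches)
  if (nrow(fwd) == 0) return(NULL)
  rev_rc <- revcomp(primers$reverse)
  rev <- find_primer_sites(sequence, rev_rc, primers$max_mismatches)
  if (nrow(rev) == 0) return(NULL)
  lf <- nchar(primers$forward); lr <- nchar(primers$reverse)
  hits <- list()
  for (p in fwd$position) {
    for (r in rev$position) {
      span <- (r + lr) - p
      if (r >= p + lf && span >= primers$min_amplicon_len &&
          span <= primers$max_amplicon_len) {
        hits[[length(hits) + 1L]] <- c(start = p, end = p + span)
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  hm <- do.call(rbind, hits)
  hm <- hm[order(hm[, "start"], hm[, "end"]), , drop = FALSE]
  if (nrow(hm) > 1)
    warning("multiple candidate products; keeping the 5'-most",
            call. = FALSE)
  as.list(hm[1, ])
}

#' Extract the primer-delimited amplicon from a reference record
#'
#' In-silico PCR: searches both strands for a forward-primer site followed,
#' within the accepted span, by a site matching the reverse complement of
#' the reverse primer. Coordinates are 0-based half-open and always refer to
#' the stored (+) sequence; `insert_sequence` is the region between the
#' primers on the amplified strand.
#'
#' @param record list or one-row data.frame with `accession` and `sequence`.
#' @param primers a [primer_pair()].
#' @return list with `accession`, `start`, `end`, `strand`,
#'   `with_primers_sequence`, `insert_sequence`, or `NULL` when no valid
#'   product exists.
#' @export
extract_amplicon <- function(record, primers) {
  seq <- toupper(record$sequence)
  lf <- nchar(primers$forward); lr <- nchar(primers$reverse)
  hit <- find_product_plus(seq, primers)
  strand <- "+"
  if (is.null(hit)) {
    rc <- revcomp(seq)
    hit_rc <- find_product_plus(rc, primers)
    if (is.null(hit_rc)) return(NULL)
    L <- nchar(seq)
    product <- substr(rc, hit_rc$start + 1L, hit_rc$end)
    start <- L - hit_rc$end
    end <- L - hit_rc$start
    strand <- "-"
  } else {
    product <- substr(seq, hit$start + 1L, hit$end)
    start <- hit$start
    end <- hit$end
  }
  list(accession = record$accession, start = as.integer(start),
       end = as.integer(end), strand = strand,
       with_primers_sequence = product,
       insert_sequence = substr(product, lf + 1L, nchar(product) - lr))
}

build_kmer_index <- function(amplicon_seqs, k) {
  postings <- list()
  for (acc in names(amplicon_seqs)) {
    s <- amplicon_seqs[[acc]]
    n <- nchar(s) - k + 1L
    if (n < 1) next
    kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    for (i in seq_len(n)) {
      km <- kmers[i]
      postings[[km]] <- rbind(postings[[km]],
                              data.frame(accession = acc, offset = i - 1L,
                                         stringsAsFactors = FALSE))
    }
  }
  postings
}

#' Build the assignment reference database
#'
#' Extracts the amplicon from every record, drops (and logs) records with no
#' valid product, and indexes the with-primers amplicon sequences with a
#' k-mer table used to gather alignment candidates. Deterministic for a
#' fixed input.
#'
#' @param records data.frame from [read_reference_fasta()].
#' @param primers a [primer_pair()].
#' @param k k-mer size of the candidate index; 11 is sensitive enough at
#'   97 percent identity on ~140 bp queries.
#' @return object of class `reference_db`.
#' @export
build_database <- function(records, primers = primer_pair(), k = 11L) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  amplicons <- list()
  excluded <- data.frame(accession = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    amp <- extract_amplicon(records[i, ], primers)
    if (is.null(amp)) {
      excluded <- rbind(excluded,
                        data.frame(accession = records$accession[i],
                                   reason = "no_valid_amplicon",
                                   stringsAsFactors = FALSE))
    } else {
      amplicons[[records$accession[i]]] <- amp
    }
  }
  if (length(amplicons) == 0)
    stop("empty database: no record yields a valid amplicon")
  kept <- records[records$accession %in% names(amplicons), , drop = FALSE]
  rownames(kept) <- NULL
  seqs <- vapply(amplicons, `[[`, "", "with_primers_sequence")
  db <- list(records = kept, amplicons = amplicons,
             kmer_index = build_kmer_index(seqs, as.integer(k)),
             k = as.integer(k), primers = primers, excluded = excluded)
  class(db) <- "reference_db"
  db
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference_db:", nrow(x$records), "records,",
      length(x$amplicons), "amplicons, k =", x$k, "\n")
  cat("  species:", length(unique(x$records$species)), " host records:",
      sum(x$records$is_host), " excluded:", nrow(x$excluded), "\n")
  invisible(x)
}

#' Serialize a reference database to disk
#'
#' Writes a JSON manifest (taxonomy, amplicon coordinates, parameters), a
#' FASTA of with-primers amplicon sequences, and a TSV exclusion log. Output
#' bytes are a deterministic function of the database.
#'
#' @param db a `reference_db`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- order(db$records$accession)
  recs <- db$records[ord, , drop = FALSE]
  amps <- db$amplicons[recs$accession]
  manifest <- list(
    k = db$k,
    primers = unclass(db$primers),
    records = lapply(seq_len(nrow(recs)), function(i) {
      a <- amps[[i]]
      list(accession = recs$accession[i], order = recs$order[i],
           suborder = recs$suborder[i], family = recs$family[i],
           genus = recs$genus[i], species = recs$species[i],
           is_host = recs$is_host[i], start = a$start, end = a$end,
           strand = a$strand)
    }))
  manifest_path <- file.path(dir, "database.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  fasta_path <- file.path(dir, "amplicons.fasta")
  writeLines(as.vector(rbind(paste0(">", recs$accession),
                             vapply(amps, `[[`, "", "with_primers_sequence"))),
             fasta_path)
  log_path <- file.path(dir, "excluded.tsv")
  write.table(db$excluded, log_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(manifest = manifest_path, fasta = fasta_path, log = log_path))
}

#' Project full-length known haplotypes onto the amplicon region
#'
#' Haplotypes defined over a longer reference region often become
#' indistinguishable over a short amplicon. This collapses a known-haplotype
#' set into equivalence classes of identical insert sequence, unioning
#' member ids and summing database entry counts. Haplotypes with no valid
#' amplicon are excluded and reported in the `excluded` attribute.
#'
#' @param known data.frame from [read_known_haplotypes()] (one species).
#' @param primers a [primer_pair()].
#' @return data.frame with `class_sequence`, `member_ids` (comma-joined),
#'   `n_members`, `total_n_db_entries`, sorted by `total_n_db_entries`
#'   descending, ties broken by sequence.
#' @export
project_haplotypes <- function(known, primers = primer_pair()) {
  stopifnot(is.data.frame(known), nrow(known) >= 1)
  inserts <- character(nrow(known))
  ok <- logical(nrow(known))
  for (i in seq_len(nrow(known))) {
    amp <- extract_amplicon(list(accession = known$haplotype_id[i],
                                 sequence = known$sequence[i]), primers)
    if (!is.null(amp)) { inserts[i] <- amp$insert_sequence; ok[i] <- TRUE }
  }
  excluded <- known$haplotype_id[!ok]
  kn <- known[ok, , drop = FALSE]
  ins <- inserts[ok]
  if (nrow(kn) == 0) stop("no known haplotype yields a valid amplicon")
  cls <- split(seq_len(nrow(kn)), ins)
  out <- data.frame(
    class_sequence = names(cls),
    member_ids = vapply(cls, function(ix)
      paste(sort(kn$haplotype_id[ix]), collapse = ","), ""),
    n_members = lengths(cls),
    total_n_db_entries = vapply(cls, function(ix)
      sum(kn$n_db_entries[ix]), 0L),
    stringsAsFactors = FALSE)
  out <- out[order(-out$total_n_db_entries, out$class_sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Per-species primer mismatch report
#'
#' The computational analog of a primer-efficiency assay: for each species,
#' the minimum Hamming distance of each primer over its best site on either
#' strand. Species with no site within 5 mismatches are reported `NA`
#' ("no site"). Ordering this table shows which taxa the degenerate primers
#' favour (the honey-bee host is expected to sit strictly above the
#' Hemiptera targets).
#'
#' @param db a `reference_db`.
#' @param primers a [primer_pair()]; defaults to the pair stored in `db`.
#' @return data.frame with `species`, `min_forward_mismatches`,
#'   `min_reverse_mismatches` (NA = no site).
#' @export
primer_mismatch_report <- function(db, primers = db$primers) {
  stopifnot(inherits(db, "reference_db"))
  best_mm <- function(seqs, primer) {
    budget <- 5L
    mins <- vapply(seqs, function(s) {
      h1 <- find_primer_sites(s, primer, budget)
      h2 <- find_primer_sites(revcomp(s), primer, budget)
      mm <- c(h1$mismatches, h2$mismatches)
      if (length(mm) == 0) NA_integer_ else min(mm)
    }, 0L)
    if (all(is.na(mins))) NA_integer_ else min(mins, na.rm = TRUE)
  }
  species <- unique(db$records$species)
  fwd <- integer(length(species)); rev <- integer(length(species))
  for (i in seq_along(species)) {
    seqs <- db$records$sequence[db$records$species == species[i]]
    fwd[i] <- best_mm(seqs, primers$forward)
    rev[i] <- best_mm(seqs, primers$reverse)
  }
  data.frame(species = species, min_forward_mismatches = fwd,
             min_reverse_mismatches = rev, stringsAsFactors = FALSE)
}
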