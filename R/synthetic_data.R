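#' Ion-Torrent-like sequencing error model
#'
#' Substitutions are drawn per base; insertions/deletions per base with the
#' rate multiplied inside homopolymer runs of length >= 3, the dominant
#' error mode of semiconductor sequencing. Qualities are drawn per base from
#' a normal distribution and clamped to [2, 40].
#'
#' @param substitution_rate,indel_rate per-base probabilities in [0, 0.2].
#' @param homopolymer_multiplier factor (>= 1) applied to `indel_rate`
#'   inside homopolymer runs of length >= 3.
#' @param quality_mean,quality_sd per-base Phred quality distribution;
#'   `quality_mean` must lie in [10, 40].
#' @return object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.005, indel_rate = 0.005,
                        homopolymer_multiplier = 3,
                        quality_mean = 30, quality_sd = 5) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.2,
            indel_rate >= 0, indel_rate <= 0.2,
            homopolymer_multiplier >= 1,
            quality_mean >= 10, quality_mean <= 40, quality_sd >= 0)
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 homopolymer_multiplier = homopolymer_multiplier,
                 quality_mean = quality_mean, quality_sd = quality_sd),
            class = "error_model")
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Apply the error model to one sequence
#'
#' Draws from the session RNG stream, so results are deterministic after
#' `set.seed()`. Substitutions always change the base (uniform over the
#' other three); an indel event is an equal-odds single-base duplication or
#' deletion at the drawn position.
#'
#' @param sequence DNA string.
#' @param model an [error_model()].
#' @return list with `sequence` (mutated) and `n_errors` (total edits).
#' @export
mutate_sequence <- function(sequence, model) {
  v <- strsplit(sequence, "")[[1]]
  n <- length(v)
  n_err <- 0L
  if (model$substitution_rate > 0) {
    hit <- which(runif(n) < model$substitution_rate)
    if (length(hit)) {
      for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1L)
      n_err <- n_err + length(hit)
    }
  }
  if (model$indel_rate > 0) {
    rate <- rep(model$indel_rate, n)
    r <- rle(v)
    in_run <- rep(r$lengths >= 3, r$lengths)
    rate[in_run] <- rate[in_run] * model$homopolymer_multiplier
    rate <- pmin(rate, 1)
    ev <- which(runif(n) < rate)
    if (length(ev)) {
      counts <- rep(1L, n)
      ins <- runif(length(ev)) < 0.5
      counts[ev[ins]] <- 2L   # duplicate the base
      counts[ev[!ins]] <- 0L  # delete it
      v <- rep(v, counts)
      n_err <- n_err + length(ev)
    }
  }
  list(sequence = paste(v, collapse = ""), n_errors = n_err)
}

#' Specify a simulated honey community
#'
#' @param members list of member specs, each a list with `species`,
#'   `fraction`, and `mitotypes` (named numeric vector of within-species
#'   mitotype fractions, e.g. `c(Hap1 = 0.85, Hap2 = 0.15)`). Member
#'   fractions must sum to 1; so must each mitotype vector.
#' @param host_fraction fraction of reads drawn from the honey-bee host
#'   background, in [0, 1].
#' @return object of class `community_spec`.
#' @export
community_spec <- function(members, host_fraction = 0) {
  stopifnot(is.list(members), length(members) >= 1,
            host_fraction >= 0, host_fraction <= 1)
  fr <- vapply(members, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("member fractions must sum to 1 (got ", sum(fr), ")")
  for (m in members) {
    if (abs(sum(m$mitotypes) - 1) > 1e-9)
      stop("mitotype fractions for ", m$species, " must sum to 1")
    if (is.null(names(m$mitotypes)) || any(names(m$mitotypes) == ""))
      stop("mitotype fractions must be named by haplotype id")
  }
  structure(list(members = members, host_fraction = host_fraction),
            class = "community_spec")
}

encode_phred <- function(q) {
  vapply(q, function(x) intToUtf8(as.integer(x) + 33L), "")
}

#' Simulate one honey amplicon library
#'
#' Per read: the source is drawn host-first, then species, then mitotype
#' (multinomially per the community spec); the with-primers amplicon is
#' taken, reverse-complemented with probability 0.5 (fragment-ligation
#' libraries read either strand), mutated under the error model, and given
#' per-base qualities ~ Normal(quality_mean, quality_sd) clamped to [2, 40].
#' A truth manifest records every read's origin.
#'
#' @param sources data.frame with `species`, `haplotype_id`, `amplicon`
#'   (with-primers sequence) covering every member of `spec`.
#' @param host_amplicon with-primers amplicon of the host, or `NULL` when
#'   `host_fraction` is 0.
#' @param spec a [community_spec()].
#' @param model an [error_model()].
#' @param n_reads number of reads to draw.
#' @param seed optional integer; when given, seeds the RNG so the library is
#'   bit-reproducible.
#' @return list with `reads` (data.frame: read_id, sequence, quality),
#'   `truth` (per-read origin and error count) and `counts` (realized
#'   per-source tallies).
#' @export
simulate_library <- function(sources, host_amplicon, spec, model, n_reads,
                             seed = NULL) {
  stopifnot(inherits(spec, "community_spec"), inherits(model, "error_model"),
            n_reads >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  key <- paste(sources$species, sources$haplotype_id, sep = "\r")
  lookup <- setNames(sources$amplicon, key)
  pool_sp <- character(0); pool_hap <- character(0); pool_p <- numeric(0)
  for (m in spec$members) {
    for (h in names(m$mitotypes)) {
      k <- paste(m$species, h, sep = "\r")
      if (is.na(lookup[k]))
        stop("no amplicon supplied for ", m$species, " / ", h)
      pool_sp <- c(pool_sp, m$species)
      pool_hap <- c(pool_hap, h)
      pool_p <- c(pool_p, m$fraction * m$mitotypes[[h]])
    }
  }
  if (spec$host_fraction > 0) {
    if (is.null(host_amplicon)) stop("host_fraction > 0 but no host amplicon")
    pool_sp <- c(pool_sp, "host"); pool_hap <- c(pool_hap, "host")
    pool_p <- c(pool_p * (1 - spec$host_fraction), spec$host_fraction)
    lookup[paste("host", "host", sep = "\r")] <- host_amplicon
  }
  draw <- sample.int(length(pool_p), n_reads, replace = TRUE, prob = pool_p)
  flip <- runif(n_reads) < 0.5
  no_error <- model$substitution_rate == 0 && model$indel_rate == 0
  seqs <- character(n_reads); nerr <- integer(n_reads)
  quals <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- lookup[[paste(pool_sp[draw[i]], pool_hap[draw[i]], sep = "\r")]]
    if (flip[i]) s <- revcomp(s)
    if (!no_error) {
      mu <- mutate_sequence(s, model)
      s <- mu$sequence; nerr[i] <- mu$n_errors
    }
    q <- pmin(40L, pmax(2L, as.integer(round(
      rnorm(nchar(s), model$quality_mean, model$quality_sd)))))
    seqs[i] <- s
    quals[i] <- encode_phred(list(q))
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  truth <- data.frame(read_id = ids, source_species = pool_sp[draw],
                      source_haplotype = pool_hap[draw],
                      strand = ifelse(flip, "-", "+"),
                      n_errors = nerr, stringsAsFactors = FALSE)
  counts_sp <- table(truth$source_species)
  counts_hap <- table(paste(truth$source_species, truth$source_haplotype))
  list(reads = data.frame(read_id = ids, sequence = seqs, quality = quals,
                          stringsAsFactors = FALSE),
       truth = truth,
       counts = list(species = counts_sp, mitotype = counts_hap))
}

# plant a concrete realization of an IUPAC primer (degenerate positions
# resolved by the current RNG stream)
realize_primer <- function(primer) {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  v <- strsplit(primer, "")[[1]]
  paste(vapply(v, function(b) {
    e <- expand[[b]]
    if (length(e) == 1) e else sample(e, 1L)
  }, ""), collapse = "")
}

mutate_k_sites <- function(sequence, k) {
  v <- strsplit(sequence, "")[[1]]
  pos <- sample.int(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1L)
  paste(v, collapse = "")
}

#' Generate a synthetic reference set with known ground truth
#'
#' Builds full-length-like reference records (random flanks around a planted
#' exact-primer amplicon) for `n_species` Hemiptera species plus the
#' honey-bee host, with the requested number of mitotypes per species. Every
#' pair of species differs at >= 6 insert positions (amplicon identity below
#' 0.97 with or without primers) while within-species mitotypes differ at
#' 1-2 sites (identity >= 0.97), so the assignment thresholds separate
#' species but not mitotypes, as they must. Each mitotype is deposited as
#' its own reference record, mirroring public-database redundancy.
#'
#' @param n_species number of non-host species.
#' @param n_mitotypes integer vector (length `n_species`) of mitotypes per
#'   species.
#' @param divergence fraction of insert positions mutated between species;
#'   must yield >= 6 pairwise differences (error otherwise).
#' @param seed integer seed; the fixture is a deterministic function of it.
#' @param insert_len insert length between the primers (97 gives a 139 bp
#'   product with the default 21-mer primers).
#' @param flank_len random flank placed on each side of the planted
#'   amplicon.
#' @param dir optional directory; when given, writes `reference.fasta` and
#'   `known_haplotypes.fasta` there.
#' @return list with `records` (reference data.frame), `known` (known
#'   haplotypes incl. full sequences and entry counts), `amplicons`
#'   (data.frame species/haplotype_id/amplicon), `host_amplicon`, `primers`,
#'   and file `paths` when `dir` was given.
#' @export
make_reference_fixture <- function(n_species = 5,
                                   n_mitotypes = c(2, 1, 1, 1, 1),
                                   divergence = 0.10, seed = 1,
                                   insert_len = 97L, flank_len = 60L,
                                   dir = NULL) {
  stopifnot(length(n_mitotypes) == n_species, all(n_mitotypes >= 1))
  min_diff <- 6L
  if (ceiling(divergence * insert_len) < min_diff)
    stop("divergence too small: need >= ", min_diff,
         " inter-species insert differences for sub-0.97 identity")
  set.seed(as.integer(seed))
  primers <- primer_pair()
  fwd_site <- realize_primer(primers$forward)
  rev_site <- revcomp(realize_primer(primers$reverse))

  base_insert <- random_dna(insert_len)
  inserts <- character(n_species)
  for (i in seq_len(n_species)) {
    repeat {
      cand <- mutate_k_sites(base_insert, ceiling(divergence * insert_len))
      ok <- all(vapply(seq_len(i - 1L), function(j)
        hamming(cand, inserts[j]) >= min_diff, TRUE))
      if (ok && hamming(cand, base_insert) >= min_diff) {
        inserts[i] <- cand; break
      }
    }
  }
  repeat {
    host_insert <- mutate_k_sites(base_insert, ceiling(0.25 * insert_len))
    if (all(vapply(inserts, function(s)
      hamming(host_insert, s) >= min_diff, TRUE))) break
  }

  species <- sprintf("Genus%s synthetica%d", LETTERS[seq_len(n_species)],
                     seq_len(n_species))
  genera <- sprintf("Genus%s", LETTERS[seq_len(n_species)])
  families <- sprintf("Family%s", LETTERS[seq_len(n_species)])

  records <- list(); known <- list(); amps <- list()
  entry_counts <- c(10L, 3L, 2L, 2L, 1L, 1L, 1L, 1L)
  make_record_seq <- function(amplicon) {
    # flanks are regenerated until the planted product is the unique hit
    repeat {
      s <- paste0(random_dna(flank_len), amplicon, random_dna(flank_len))
      amp <- suppressWarnings(
        extract_amplicon(list(accession = "tmp", sequence = s), primers))
      if (!is.null(amp) && amp$with_primers_sequence == amplicon &&
          amp$start == flank_len) return(s)
    }
  }
  for (i in seq_len(n_species)) {
    hap_ins <- character(n_mitotypes[i])
    hap_ins[1] <- inserts[i]
    for (j in seq_len(n_mitotypes[i])[-1]) {
      repeat {
        cand <- mutate_k_sites(inserts[i], sample(1:2, 1L))
        if (!cand %in% hap_ins[seq_len(j - 1L)]) { hap_ins[j] <- cand; break }
      }
    }
    for (j in seq_len(n_mitotypes[i])) {
      amplicon <- paste0(fwd_site, hap_ins[j], rev_site)
      full <- make_record_seq(amplicon)
      acc <- sprintf("SYN%02dH%02d", i, j)
      records[[acc]] <- data.frame(
        accession = acc, order = "Hemiptera", suborder = "Synthorrhyncha",
        family = families[i], genus = genera[i], species = species[i],
        is_host = FALSE, sequence = full, stringsAsFactors = FALSE)
      known[[acc]] <- data.frame(
        species = species[i], haplotype_id = sprintf("Hap%d", j),
        n_db_entries = entry_counts[min(j, length(entry_counts))],
        sequence = full, stringsAsFactors = FALSE)
      amps[[acc]] <- data.frame(
        species = species[i], haplotype_id = sprintf("Hap%d", j),
        amplicon = amplicon, stringsAsFactors = FALSE)
    }
  }
  host_amplicon <- paste0(fwd_site, host_insert, rev_site)
  host_full <- make_record_seq(host_amplicon)
  records[["HOST01"]] <- data.frame(
    accession = "HOST01", order = "Hymenoptera", suborder = "Apocrita",
    family = "Apidae", genus = "Apis", species = "Apis mellifera",
    is_host = TRUE, sequence = host_full, stringsAsFactors = FALSE)

  records <- do.call(rbind, records); rownames(records) <- NULL
  known <- do.call(rbind, known); rownames(known) <- NULL
  amps <- do.call(rbind, amps); rownames(amps) <- NULL

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ref_path <- file.path(dir, "reference.fasta")
    writeLines(as.vector(rbind(
      paste0(">", records$accession, "|", records$order, "|",
             records$suborder, "|", records$family, "|", records$genus, "|",
             records$species),
      records$sequence)), ref_path)
    known_path <- file.path(dir, "known_haplotypes.fasta")
    writeLines(as.vector(rbind(
      paste0(">", known$species, "|", known$haplotype_id, "|",
             known$n_db_entries),
      known$sequence)), known_path)
    paths <- c(reference = ref_path, known = known_path)
  }
  list(records = records, known = known, amplicons = amps,
       host_amplicon = host_amplicon, primers = primers, paths = paths)
}

#' Long-region haplotypes that collapse over the short amplicon
#'
#' Constructs a known-haplotype set in which variant positions are planted
#' inside or outside the amplicon insert so that `n_haplotypes` distinct
#' full-length haplotypes project onto exactly `n_classes` distinct insert
#' patterns; the classic situation where a short barcode cannot resolve
#' haplotypes defined over a longer region.
#'
#' @param n_haplotypes number of full-length haplotypes (>= `n_classes`).
#' @param n_classes number of distinct insert patterns to survive
#'   projection.
#' @param seed integer seed.
#' @return data.frame in [read_known_haplotypes()] layout.
#' @export
make_projection_fixture <- function(n_haplotypes = 19, n_classes = 11,
                                    seed = 1) {
  stopifnot(n_classes >= 1, n_haplotypes >= n_classes)
  set.seed(as.integer(seed))
  primers <- primer_pair()
  fwd_site <- realize_primer(primers$forward)
  rev_site <- revcomp(realize_primer(primers$reverse))
  insert_len <- 97L; flank_len <- 60L
  base_insert <- random_dna(insert_len)
  class_inserts <- character(n_classes)
  class_inserts[1] <- base_insert
  for (i in seq_len(n_classes)[-1]) {
    repeat {
      cand <- mutate_k_sites(base_insert, sample(1:3, 1L))
      if (!cand %in% class_inserts[seq_len(i - 1L)]) {
        class_inserts[i] <- cand; break
      }
    }
  }
  flank5 <- random_dna(flank_len)
  base_flank3 <- random_dna(flank_len)
  # assign each haplotype a class; extra haplotypes differ only in the flank
  cls <- c(seq_len(n_classes),
           sample(n_classes, n_haplotypes - n_classes, replace = TRUE))
  flank_variants <- list(base_flank3)
  out <- vector("list", n_haplotypes)
  for (h in seq_len(n_haplotypes)) {
    f3 <- if (h <= n_classes) base_flank3 else {
      repeat {
        cand <- mutate_k_sites(base_flank3, sample(1:3, 1L))
        if (!cand %in% unlist(flank_variants)) break
      }
      flank_variants[[length(flank_variants) + 1L]] <- cand
      cand
    }
    seqh <- paste0(flank5, fwd_site, class_inserts[cls[h]], rev_site, f3)
    out[[h]] <- data.frame(species = "GenusA synthetica1",
                           haplotype_id = sprintf("H%d", h),
                           n_db_entries = 1L, sequence = seqh,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # metadata columns (FASTQ comment lines) are not carried through
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(x), sequence = unname(as.character(x)),
             quality = unname(as.character(Biostrings::quality(x))),
             stringsAsFactors = FALSE, row.names = NULL)
}
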