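#' Mitotype-calling parameters
#'
#' A candidate mitotype is reliable when it is supported by at least
#' `min_reads` reads AND is either already known (matches a projected
#' database haplotype exactly) or reaches `min_fraction` of the species'
#' mitotypable reads. The read-count floor is the guard against sequencing
#' errors and always applies under the default precedence; the alternative
#' reading `(count >= min_reads AND known) OR fraction >= min_fraction` is
#' available via `precedence = "alternative"`.
#'
#' @param min_reads minimum supporting reads.
#' @param min_fraction minimum fraction of the species' mitotypable reads
#'   for an unknown mitotype.
#' @param require_full_span only reads whose alignment covers the whole
#'   insert (and carry no deletion) are mitotypable; others are unplaced.
#' @param min_species_reads per-library read floor used by
#'   [eligible_species()].
#' @param precedence reliability rule precedence (see above).
#' @return object of class `mitotype_params`.
#' @export
mitotype_params <- function(min_reads = 20L, min_fraction = 0.05,
                            require_full_span = TRUE,
                            min_species_reads = 10L,
                            precedence = c("guard_first", "alternative")) {
  stopifnot(min_reads >= 1, min_fraction > 0, min_fraction < 1)
  structure(list(min_reads = as.integer(min_reads),
                 min_fraction = min_fraction,
                 require_full_span = isTRUE(require_full_span),
                 min_species_reads = as.integer(min_species_reads),
                 precedence = match.arg(precedence)),
            class = "mitotype_params")
}

# project one read onto the insert region of the species amplicon;
# NA when unplaced (incomplete span or deletion vs the reference)
read_insert_key <- function(sequence, species_amplicon, primers, params,
                            band = 16L) {
  lf <- nchar(primers$forward); lr <- nchar(primers$reverse)
  L <- nchar(species_amplicon)
  ins_lo <- lf; ins_hi <- L - lr  # 0-based half-open insert region
  best <- align_semi_global(sequence, species_amplicon, band)
  if (best$identity < 0.9) {
    # reads reach this stage oriented by QC; realign only clear mismatches
    al <- align_semi_global(revcomp(sequence), species_amplicon, band)
    if (al$score > best$score) best <- al
  }
  if (params$require_full_span &&
      (best$tstart > ins_lo || best$tend < ins_hi)) return(NA_character_)
  qa <- strsplit(best$qaln, "")[[1]]
  ta <- strsplit(best$taln, "")[[1]]
  tpos <- best$tstart
  key <- character(0)
  for (i in seq_along(ta)) {
    if (ta[i] != "-") {
      if (tpos >= ins_lo && tpos < ins_hi) {
        if (qa[i] == "-") return(NA_character_)  # deletion: reject the read
        key <- c(key, qa[i])
      }
      tpos <- tpos + 1L
    }
    # insertions relative to the reference are dropped from the key
  }
  paste(key, collapse = "")
}

#' Collapse a species' reads into candidate mitotypes
#'
#' Each read is aligned to the species amplicon; its insert-region sequence
#' (read-relative insertions removed; reads with deletions or incomplete
#' span unplaced) is the grouping key, and identical keys are counted
#' together.
#'
#' @param reads data.frame of reads already assigned to the species
#'   (`read_id`, `sequence`).
#' @param species_amplicon the species' with-primers amplicon sequence.
#' @param primers a [primer_pair()].
#' @param params a [mitotype_params()].
#' @return list with `candidates` (data.frame `sequence`, `count`, sorted
#'   by count descending), `n_unplaced`, `total`.
#' @export
collapse_reads <- function(reads, species_amplicon, primers = primer_pair(),
                           params = mitotype_params()) {
  keys <- vapply(reads$sequence, read_insert_key, "",
                 species_amplicon = species_amplicon, primers = primers,
                 params = params, USE.NAMES = FALSE)
  placed <- !is.na(keys)
  tab <- table(keys[placed])
  candidates <- data.frame(sequence = names(tab), count = as.integer(tab),
                           stringsAsFactors = FALSE)
  candidates <- candidates[order(-candidates$count, candidates$sequence), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  list(candidates = candidates, n_unplaced = sum(!placed),
       total = nrow(reads))
}

#' Call mitotypes from collapsed candidates
#'
#' Matches candidates exactly against projected known haplotype classes
#' (one short-region class may group several long-region haplotypes) and
#' applies the reliability filter. Unreliable candidates stay in the table,
#' flagged.
#'
#' @param collapsed output of [collapse_reads()].
#' @param known_classes projection from [project_haplotypes()], or `NULL`
#'   when no known haplotypes exist for the species.
#' @param params a [mitotype_params()].
#' @return object of class `mitotype_table`: list with `calls` (data.frame
#'   `sequence`, `count`, `fraction`, `known_ids`, `is_known`,
#'   `is_reliable`, sorted by count descending), `species_total`,
#'   `n_unplaced`.
#' @export
call_mitotypes <- function(collapsed, known_classes = NULL,
                           params = mitotype_params()) {
  cand <- collapsed$candidates
  n_mito <- sum(cand$count)
  if (nrow(cand) == 0) {
    calls <- data.frame(sequence = character(), count = integer(),
                        fraction = numeric(), known_ids = character(),
                        is_known = logical(), is_reliable = logical(),
                        stringsAsFactors = FALSE)
  } else {
    idx <- if (is.null(known_classes)) rep(NA_integer_, nrow(cand))
           else match(cand$sequence, known_classes$class_sequence)
    is_known <- !is.na(idx)
    known_ids <- ifelse(is_known, known_classes$member_ids[idx], "")
    fraction <- cand$count / n_mito
    is_reliable <- if (params$precedence == "guard_first") {
      cand$count >= params$min_reads &
        (is_known | fraction >= params$min_fraction)
    } else {
      (cand$count >= params$min_reads & is_known) |
        fraction >= params$min_fraction
    }
    calls <- data.frame(sequence = cand$sequence, count = cand$count,
                        fraction = fraction, known_ids = known_ids,
                        is_known = is_known, is_reliable = is_reliable,
                        stringsAsFactors = FALSE)
  }
  structure(list(calls = calls,
                 species_total = collapsed$total,
                 n_unplaced = collapsed$n_unplaced),
            class = "mitotype_table")
}

#' @export
print.mitotype_table <- function(x, ...) {
  cat("mitotype_table:", nrow(x$calls), "candidates,",
      sum(x$calls$is_reliable), "reliable;",
      x$n_unplaced, "unplaced of", x$species_total, "reads\n")
  invisible(x)
}

#' Frequencies of reliable mitotypes
#'
#' @param table a `mitotype_table`.
#' @return data.frame (`sequence`, `known_ids`, `fraction`) over reliable
#'   calls only, renormalized, sorted descending; empty (with a warning)
#'   when nothing is reliable.
#' @export
mitotype_frequencies <- function(table) {
  stopifnot(inherits(table, "mitotype_table"))
  rel <- table$calls[table$calls$is_reliable, , drop = FALSE]
  if (nrow(rel) == 0) {
    warning("no reliable mitotype calls", call. = FALSE)
    return(data.frame(sequence = character(), known_ids = character(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(sequence = rel$sequence, known_ids = rel$known_ids,
                    fraction = rel$count / sum(rel$count),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species eligible for mitotype analysis
#'
#' The species with the largest read total across all libraries, plus any
#' species reaching `min_species_reads` reads in at least two libraries.
#'
#' @param profiles list of `library_profile` objects.
#' @param params a [mitotype_params()].
#' @return character vector of species names.
#' @export
eligible_species <- function(profiles, params = mitotype_params()) {
  stopifnot(length(profiles) >= 1)
  rows <- do.call(rbind, lapply(profiles, function(p)
    as.data.frame(p)[as.data.frame(p)$rank == "species",
                     c("taxon", "count")]))
  if (nrow(rows) == 0) return(character(0))
  totals <- tapply(rows$count, rows$taxon, sum)
  top <- names(totals)[which.max(totals)]
  n_libs <- vapply(names(totals), function(sp)
    sum(vapply(profiles, function(p) {
      d <- as.data.frame(p)
      any(d$rank == "species" & d$taxon == sp &
            d$count >= params$min_species_reads)
    }, TRUE)), 0L)
  multi <- names(n_libs)[n_libs >= 2L]
  sort(unique(c(top, multi)))
}
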