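#' Assignment parameters
#'
#' Reads are assigned the taxonomy of their best alignment provided it
#' reaches `min_identity` (matching columns over all alignment columns,
#' gaps included) and `min_coverage` (query bases aligned to target bases
#' over query length; "95 percent coverage to 100" means coverage in
#' [0.95, 1], with 1 attainable). Ties within `tie_margin` score units
#' across species fall back to the lowest common ancestor rank.
#'
#' @param min_identity,min_coverage proportions in (0, 1].
#' @param tie_margin score difference within which hits count as tied.
#' @param seed_k k-mer size for candidate gathering (matches the database
#'   index).
#' @param band alignment band; must cover the expected indel count, and is
#'   widened automatically when it cannot connect the ends.
#' @return object of class `assignment_params`.
#' @export
assignment_params <- function(min_identity = 0.97, min_coverage = 0.95,
                              tie_margin = 0L, seed_k = 11L, band = 16L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1, tie_margin >= 0, band >= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 tie_margin = tie_margin, seed_k = as.integer(seed_k),
                 band = as.integer(band)),
            class = "assignment_params")
}

#' Banded semi-global alignment
#'
#' Aligns the full query within the target (leading/trailing target gaps
#' free) under +1/-1/-2 match/mismatch/gap scoring with a linear gap
#' penalty. The band restricts the dynamic program to a corridor around the
#' main diagonal; it is widened (doubled) automatically when too small to
#' connect the corners, or an error of class `band_exceeded` is signalled
#' when `widen = FALSE`. The banded score equals the unbanded score whenever
#' the band is at least the indel count of the optimal path.
#'
#' @param query,target DNA strings.
#' @param band corridor half-width; `-1` disables banding.
#' @param widen widen automatically instead of signalling.
#' @return list with `score`, `identity`, `coverage`, aligned strings
#'   `qaln`/`taln`, and target coordinates `tstart`/`tend` (0-based
#'   half-open).
#' @export
align_semi_global <- function(query, target, band = 16L, widen = TRUE) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  b <- as.integer(band)
  repeat {
    res <- cpp_align_semiglobal(query, target, b)
    if (isTRUE(res$band_ok)) return(res)
    if (!widen) {
      stop(structure(class = c("band_exceeded", "error", "condition"),
                     list(message = "band too small to connect corners",
                          call = sys.call())))
    }
    if (b < 0 || b > nchar(target) + nchar(query)) {
      stop("alignment failed even unbanded")
    }
    b <- if (b * 2L > nchar(target)) -1L else b * 2L
  }
}

# per-strand candidate accessions sharing at least one seed k-mer; a hit
# passing the identity/coverage thresholds on a ~100 bp query always shares
# an exact k-mer (pigeonhole at <= ~5 edits), so unseeded pairs need not be
# aligned
gather_candidates <- function(query, qrc, db, seed_k) {
  n <- nchar(query) - seed_k + 1L
  strand_hits <- function(s) {
    if (n < 1) return(character(0))
    kmers <- unique(substring(s, seq_len(n), seq_len(n) + seed_k - 1L))
    unique(unlist(mget(kmers, envir = db$kmer_env, ifnotfound = list(NULL)),
                  use.names = FALSE))
  }
  out <- list(`+` = strand_hits(query), `-` = strand_hits(qrc))
  if (length(out$`+`) == 0 && length(out$`-`) == 0) {
    out <- list(`+` = names(db$amplicons), `-` = names(db$amplicons))
  }
  out
}

# hashed k-mer -> accession lookup, built lazily from the postings index
db_kmer_env <- function(db) {
  if (!is.null(db$kmer_env)) return(db)
  env <- new.env(hash = TRUE, size = max(29L, 2L * length(db$kmer_index)))
  for (km in names(db$kmer_index)) {
    assign(km, unique(db$kmer_index[[km]]$accession), envir = env)
  }
  db$kmer_env <- env
  db
}

lca_rank <- function(lineages) {
  # deepest rank shared by all tied lineages below species
  g <- unique(lineages$genus); f <- unique(lineages$family)
  if (length(g) == 1 && all(g != "")) {
    list(rank = "genus", genus = g, family = lineages$family[1],
         order = lineages$order[1])
  } else if (length(f) == 1 && all(f != "")) {
    list(rank = "family", genus = "", family = f,
         order = lineages$order[1])
  } else NULL
}

#' Assign one read to a reference taxon
#'
#' Candidate references are gathered through shared k-mers on both strands
#' (all references when no seed matches); the read is aligned to each on
#' both strands and hits failing the identity or coverage threshold are
#' discarded. Among passing hits the best score wins; when two or more
#' species tie within `tie_margin` the read is assigned at the deepest
#' shared rank (genus, else family, else left unassigned). A best hit on
#' the host record yields status `host`.
#'
#' @param read list or one-row data.frame with `read_id` and `sequence`.
#' @param db a `reference_db` from [build_database()].
#' @param params an [assignment_params()].
#' @return one-row data.frame: `read_id`, `status`, `rank`, lineage
#'   columns, best-hit `accession`, `identity`, `coverage`, `score`,
#'   `strand`.
#' @export
assign_read <- function(read, db, params = assignment_params()) {
  db <- db_kmer_env(db)
  row <- assign_read_core(read, db, params)
  as.data.frame(row, stringsAsFactors = FALSE)
}

unassigned_row <- function(read_id, status = "unassigned") {
  list(read_id = read_id, status = status, rank = "none", species = "",
       genus = "", family = "", order = "", accession = "",
       identity = NA_real_, coverage = NA_real_, score = NA_integer_,
       strand = "")
}

assign_read_core <- function(read, db, params) {
  query <- read$sequence
  if (nchar(query) < params$seed_k) return(unassigned_row(read$read_id))
  qrc <- revcomp(query)
  cands <- gather_candidates(query, qrc, db, params$seed_k)
  accs <- unique(c(cands$`+`, cands$`-`))
  hits <- vector("list", length(accs))
  nh <- 0L
  for (acc in accs) {
    target <- db$amplicons[[acc]]$with_primers_sequence
    best <- NULL
    for (strand in c("+", "-")) {
      if (!acc %in% cands[[strand]]) next
      q <- if (strand == "+") query else qrc
      al <- align_semi_global(q, target, params$band)
      if (is.null(best) || al$score > best$score) {
        best <- al; best$strand <- strand
      }
    }
    if (best$identity >= params$min_identity &&
        best$coverage >= params$min_coverage) {
      nh <- nh + 1L
      hits[[nh]] <- list(accession = acc, score = best$score,
                         identity = best$identity, coverage = best$coverage,
                         strand = best$strand)
    }
  }
  if (nh == 0L) return(unassigned_row(read$read_id))
  hits <- hits[seq_len(nh)]
  scores <- vapply(hits, `[[`, 0, "score")
  ord <- order(-scores, vapply(hits, `[[`, "", "accession"))
  hits <- hits[ord]; scores <- scores[ord]
  tied <- hits[scores >= scores[1] - params$tie_margin]
  tied_acc <- vapply(tied, `[[`, "", "accession")
  recs <- db$records[match(tied_acc, db$records$accession), , drop = FALSE]
  best <- tied[[1]]
  common <- function(extra = list()) {
    c(list(read_id = read$read_id), extra,
      list(accession = best$accession, identity = best$identity,
           coverage = best$coverage, score = best$score,
           strand = best$strand))
  }
  if (all(recs$is_host)) {
    r <- recs[1, ]
    return(common(list(status = "host", rank = "species",
                       species = r$species, genus = r$genus,
                       family = r$family, order = r$order)))
  }
  if (any(recs$is_host)) {
    # host and non-host tie: no meaningful shared rank
    out <- unassigned_row(read$read_id)
    out$identity <- best$identity; out$coverage <- best$coverage
    out$score <- best$score
    return(out)
  }
  sp <- unique(recs$species)
  if (length(sp) == 1) {
    r <- recs[1, ]
    return(common(list(status = "assigned_species", rank = "species",
                       species = r$species, genus = r$genus,
                       family = r$family, order = r$order)))
  }
  lca <- lca_rank(recs)
  if (is.null(lca)) {
    out <- unassigned_row(read$read_id)
    out$identity <- best$identity; out$coverage <- best$coverage
    out$score <- best$score
    return(out)
  }
  common(list(status = "assigned_higher_rank", rank = lca$rank,
              species = "", genus = lca$genus, family = lca$family,
              order = lca$order))
}

#' Assign a batch of reads
#'
#' Order-preserving; the summary counts (`n_host`, `n_hemiptera`,
#' `n_unassigned`) partition the batch, reproducing the host-read
#' accounting in which honey-bee reads are the complement of the Hemiptera
#' reads rather than silently dropped.
#'
#' @param reads data.frame with `read_id`, `sequence`.
#' @param db a `reference_db`.
#' @param params an [assignment_params()].
#' @return list with `assignments` (one row per read) and `summary`.
#' @export
assign_batch <- function(reads, db, params = assignment_params()) {
  db <- db_kmer_env(db)
  n <- nrow(reads)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- assign_read_core(
      list(read_id = reads$read_id[i], sequence = reads$sequence[i]),
      db, params)
  }
  cols <- if (n > 0) names(rows[[1]]) else names(unassigned_row(""))
  assignments <- as.data.frame(
    lapply(setNames(cols, cols), function(cl)
      unlist(lapply(rows, `[[`, cl), use.names = FALSE)),
    stringsAsFactors = FALSE)
  if (n == 0) {
    assignments <- as.data.frame(unassigned_row(""),
                                 stringsAsFactors = FALSE)[0, ]
  }
  summary <- list(
    n_host = sum(assignments$status == "host"),
    n_hemiptera = sum(assignments$status %in%
                        c("assigned_species", "assigned_higher_rank")),
    n_unassigned = sum(assignments$status == "unassigned"))
  list(assignments = assignments, summary = summary)
}
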