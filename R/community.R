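#' Categorical abundance label
#'
#' Read proportions are not quantitative in amplicon metabarcoding, so
#' abundance is reported categorically: `high` above 30 percent, `medium`
#' from 5 to 30 percent (closed interval: both boundaries are medium),
#' `low` below 5 percent.
#'
#' @param fraction numeric vector of proportions in [0, 1].
#' @return character vector in `high`/`medium`/`low`.
#' @examples
#' categorize(c(0.6498, 0.146, 0.0376, 0.05, 0.30))
#' @export
categorize <- function(fraction) {
  if (any(is.na(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("fraction must lie in [0, 1]")
  ifelse(fraction > 0.30, "high",
         ifelse(fraction >= 0.05, "medium", "low"))
}

taxon_display <- function(rank, species, genus, family) {
  ifelse(rank == "species", species,
         ifelse(rank == "genus", paste(genus, "sp."),
                paste(family, "spp.")))
}

make_profile <- function(taxon, rank, count, library_id, n_host,
                         n_unassigned, denominator = NULL) {
  denom <- if (is.null(denominator)) sum(count) else denominator
  if (denom == 0) {
    warning("library ", library_id, ": no assigned reads; empty profile",
            call. = FALSE)
    prof <- data.frame(taxon = character(), rank = character(),
                       count = integer(), fraction = numeric(),
                       category = character(), stringsAsFactors = FALSE)
  } else {
    fraction <- count / denom
    prof <- data.frame(taxon = taxon, rank = rank, count = as.integer(count),
                       fraction = fraction, category = categorize(fraction),
                       stringsAsFactors = FALSE)
    prof <- prof[order(-prof$count, prof$taxon), , drop = FALSE]
    rownames(prof) <- NULL
  }
  structure(prof, library_id = library_id, denominator = as.integer(denom),
            n_host = as.integer(n_host), n_unassigned = as.integer(n_unassigned),
            class = c("library_profile", "data.frame"))
}

#' Profile one library from per-read assignments
#'
#' Counts reads by taxon over species- and higher-rank assignments;
#' fractions use the Hemiptera-assigned total as denominator (the printed
#' abundance categories are only consistent with that denominator; the
#' all-reads alternative is available via `denominator = "all"`). Host and
#' unassigned reads are carried separately and never enter the profile.
#'
#' @param assignments data.frame from [assign_batch()].
#' @param library_id label for the library.
#' @param denominator `"assigned"` (Hemiptera-assigned reads, default) or
#'   `"all"` (every read in the batch).
#' @return a `library_profile` data.frame (`taxon`, `rank`, `count`,
#'   `fraction`, `category`) with `denominator`, `n_host`, `n_unassigned`
#'   attributes; rows sorted by count descending.
#' @export
profile_library <- function(assignments, library_id,
                            denominator = c("assigned", "all")) {
  denominator <- match.arg(denominator)
  asg <- assignments[assignments$status %in%
                       c("assigned_species", "assigned_higher_rank"), ,
                     drop = FALSE]
  n_host <- sum(assignments$status == "host")
  n_unassigned <- sum(assignments$status == "unassigned")
  key <- paste(asg$rank,
               taxon_display(asg$rank, asg$species, asg$genus, asg$family),
               sep = "\r")
  tab <- table(key)
  parts <- strsplit(as.character(names(tab)), "\r", fixed = TRUE)
  make_profile(
    taxon = vapply(parts, `[`, "", 2),
    rank = vapply(parts, `[`, "", 1),
    count = as.integer(tab), library_id = library_id,
    n_host = n_host, n_unassigned = n_unassigned,
    denominator = if (denominator == "all") nrow(assignments) else NULL)
}

#' Load per-library count tables into profiles
#'
#' Reads a TSV of pre-made per-taxon read counts (columns `library`,
#' `taxon`, `rank`, `count`; extra columns ignored) and produces one
#' profile per library under the same contract as [profile_library()] given
#' one-read-per-count assignments.
#'
#' @param path TSV file.
#' @return named list of `library_profile` objects, in file order.
#' @export
load_count_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("library", "taxon", "rank", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) return(list())
  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop("malformed count at line ", bad[1] + 1L, " of ", path)
  profs <- lapply(split(df, factor(df$library, unique(df$library))),
                  function(d) make_profile(d$taxon, d$rank, d$count,
                                           library_id = d$library[1],
                                           n_host = 0L, n_unassigned = 0L))
  profs[unique(df$library)]
}

#' Write a library profile as TSV
#'
#' @param profile a `library_profile`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  df$fraction <- sprintf("%.6f", df$fraction)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
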