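#' QC parameters
#'
#' The retention rule keeps reads that are at least `min_length` bp after
#' trimming with a mean quality of at least `min_mean_quality` (Q20 is read
#' as mean read quality, the usual Ion Torrent convention). Window trimming
#' removes trailing/leading windows whose mean Phred falls below
#' `window_quality`, then individual low-quality end bases.
#'
#' @param min_length minimum post-trim read length in bp.
#' @param min_mean_quality minimum mean Phred quality.
#' @param window trim window size in bases.
#' @param window_quality Phred threshold for window and end-base trimming.
#' @param trim_primers remove primer sequence and orient reads to the
#'   forward strand before quality trimming.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(min_length = 50L, min_mean_quality = 20,
                      window = 10L, window_quality = 20,
                      trim_primers = TRUE) {
  stopifnot(min_length >= 1, window >= 1)
  structure(list(min_length = as.integer(min_length),
                 min_mean_quality = min_mean_quality,
                 window = as.integer(window),
                 window_quality = window_quality,
                 trim_primers = isTRUE(trim_primers)),
            class = "qc_params")
}

decode_phred <- function(q) utf8ToInt(q) - 33L

trim_one_end <- function(quals, window, threshold) {
  # number of bases to drop from the tail of `quals`: remove trailing
  # low-mean windows and trailing low bases until neither rule applies
  # (fixpoint, so trimming is idempotent)
  n <- length(quals)
  keep <- n
  repeat {
    if (keep >= window &&
        mean(quals[(keep - window + 1L):keep]) < threshold) {
      keep <- keep - window
    } else if (keep >= 1L && quals[keep] < threshold) {
      keep <- keep - 1L
    } else break
  }
  n - keep
}

#' Quality-trim one read at both ends
#'
#' From the 3' end, whole windows with mean Phred below the threshold and
#' trailing bases below the threshold are removed until neither rule
#' applies (a fixpoint, so trimming is idempotent); the same rule is applied
#' once at the 5' end. May return an empty read.
#'
#' @param read list or one-row data.frame with `sequence` and `quality`
#'   (Phred+33 string).
#' @param params a [qc_params()].
#' @return the trimmed read (same shape, `read_id` preserved if present).
#' @export
quality_trim <- function(read, params = qc_params()) {
  q <- decode_phred(read$quality)
  drop3 <- trim_one_end(q, params$window, params$window_quality)
  keep <- length(q) - drop3
  q5 <- rev(q[seq_len(keep)])
  drop5 <- trim_one_end(q5, params$window, params$window_quality)
  from <- drop5 + 1L
  list(read_id = read$read_id,
       sequence = substr(read$sequence, from, keep),
       quality = substr(read$quality, from, keep))
}

#' Locate and remove primer sequence, orienting the read forward
#'
#' Looks for the forward primer near the 5' end (first 25 bases) and the
#' reverse complement of the reverse primer near the 3' end (last 25 bases).
#' When neither is found on the stored strand but the forward primer is
#' found on the reverse complement, the read is reoriented first. Found
#' primers are removed together with any bases outside them.
#'
#' @param read list with `sequence`, `quality` (and optionally `read_id`).
#' @param primers a [primer_pair()].
#' @param max_mismatches Hamming budget per primer site.
#' @return list with the trimmed `read`, logical flags `found_forward`,
#'   `found_reverse`, and `reoriented`.
#' @export
trim_primers <- function(read, primers = primer_pair(), max_mismatches = 2L) {
  lf <- nchar(primers$forward); lr <- nchar(primers$reverse)
  rev_rc <- revcomp(primers$reverse)
  end_window <- 25L
  locate5 <- function(s) {
    hits <- find_primer_sites(s, primers$forward, max_mismatches)
    hits <- hits[hits$position < end_window, , drop = FALSE]
    if (nrow(hits)) hits$position[1] else NA_integer_
  }
  locate3 <- function(s) {
    hits <- find_primer_sites(s, rev_rc, max_mismatches)
    hits <- hits[hits$position + lr > nchar(s) - end_window, , drop = FALSE]
    if (nrow(hits)) hits$position[nrow(hits)] else NA_integer_
  }
  seq <- read$sequence; qual <- read$quality
  reoriented <- FALSE
  p5 <- locate5(seq)
  if (is.na(p5)) {
    rc <- revcomp(seq)
    if (!is.na(locate5(rc))) {
      seq <- rc
      qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
      reoriented <- TRUE
      p5 <- locate5(seq)
    }
  }
  p3 <- locate3(seq)
  from <- if (!is.na(p5)) p5 + lf + 1L else 1L
  to <- if (!is.na(p3)) p3 else nchar(seq)
  if (from > to + 1L) { from <- 1L; to <- 0L }
  list(read = list(read_id = read$read_id,
                   sequence = substr(seq, from, to),
                   quality = substr(qual, from, to)),
       found_forward = !is.na(p5), found_reverse = !is.na(p3),
       reoriented = reoriented)
}

#' Trim and filter a read batch
#'
#' Primer trimming (with forward-strand reorientation) runs first when
#' enabled, then quality trimming; reads are retained iff the post-trim
#' length and mean quality clear the thresholds. Every input read lands in
#' exactly one disposition bucket, checked length-first.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param params a [qc_params()].
#' @param primers a [primer_pair()] used when `params$trim_primers`.
#' @return list with `reads` (retained, trimmed, input order) and `report`
#'   (tallies plus per-read `dispositions`).
#' @export
filter_reads <- function(reads, params = qc_params(),
                         primers = primer_pair()) {
  n <- nrow(reads)
  out_seq <- character(n); out_qual <- character(n)
  disposition <- character(n)
  for (i in seq_len(n)) {
    rd <- list(read_id = reads$read_id[i], sequence = reads$sequence[i],
               quality = reads$quality[i])
    if (params$trim_primers) rd <- trim_primers(rd, primers)$read
    rd <- quality_trim(rd, params)
    len <- nchar(rd$sequence)
    disposition[i] <-
      if (len < params$min_length) "too_short"
      else if (mean(decode_phred(rd$quality)) < params$min_mean_quality)
        "low_quality"
      else "retained"
    out_seq[i] <- rd$sequence; out_qual[i] <- rd$quality
  }
  keep <- disposition == "retained"
  report <- list(n_input = n, n_retained = sum(keep),
                 n_too_short = sum(disposition == "too_short"),
                 n_low_quality = sum(disposition == "low_quality"),
                 dispositions = data.frame(read_id = reads$read_id,
                                           disposition = disposition,
                                           stringsAsFactors = FALSE))
  list(reads = data.frame(read_id = reads$read_id[keep],
                          sequence = out_seq[keep], quality = out_qual[keep],
                          stringsAsFactors = FALSE),
       report = report)
}
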