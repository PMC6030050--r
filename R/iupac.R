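#' IUPAC-aware base matching
#'
#' Tests whether a concrete subject base falls in the expansion of a single
#' (possibly degenerate) IUPAC pattern symbol. An `N` in the subject matches
#' nothing and is counted as a mismatch, so low-information reference
#' positions never inflate primer matches.
#'
#' @param pattern_base single IUPAC character (e.g. `"W"` = A or T).
#' @param base single subject base in `A`, `C`, `G`, `T`, `N`.
#' @return `TRUE` if `base` is in the expansion of `pattern_base`.
#' @examples
#' iupac_match("W", "A")  # TRUE
#' iupac_match("R", "C")  # FALSE
#' @export
iupac_match <- function(pattern_base, base) {
  cpp_iupac_match(as.character(pattern_base), as.character(base))
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x character vector of DNA strings; degenerate codes are
#'   complemented symbol-wise (W<->W, R<->Y, ...).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Locate degenerate-primer sites by windowed Hamming scan
#'
#' Slides the primer along the sequence and reports every window whose
#' IUPAC-aware Hamming distance is within the mismatch budget. Indels are
#' deliberately not considered: reference sequences are high quality, and
#' indel tolerance belongs to read alignment, not site finding.
#'
#' @param sequence subject DNA string (A/C/G/T/N).
#' @param primer IUPAC primer string, 5'->3'.
#' @param max_mismatches non-negative mismatch budget.
#' @return data.frame with `position` (0-based start) and `mismatches`,
#'   sorted by position.
#' @export
find_primer_sites <- function(sequence, primer, max_mismatches = 2L) {
  stopifnot(nchar(primer) > 0, max_mismatches >= 0)
  cpp_find_primer_sites(as.character(sequence), as.character(primer),
                        as.integer(max_mismatches))
}
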