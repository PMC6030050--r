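# Independent oracles and small builders used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# brute-force IUPAC window scan (independent of the compiled scanner)
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

naive_primer_scan <- function(sequence, primer, max_mm) {
  sv <- strsplit(sequence, "")[[1]]
  pv <- strsplit(primer, "")[[1]]
  k <- length(pv); n <- length(sv)
  out <- list()
  for (s in seq_len(n - k + 1L)) {
    mm <- 0L
    for (i in seq_len(k)) {
      b <- sv[s + i - 1L]
      if (b == "N" || !(b %in% IUPAC_SETS[[pv[i]]])) mm <- mm + 1L
    }
    if (mm <= max_mm) out[[length(out) + 1L]] <- c(s - 1L, mm)
  }
  if (length(out) == 0)
    return(data.frame(position = integer(), mismatches = integer()))
  m <- do.call(rbind, out)
  data.frame(position = m[, 1], mismatches = m[, 2])
}

# unbanded full-DP semi-global aligner (score only), written independently
# of the compiled implementation: free leading/trailing target gaps,
# +1/-1/-2 scoring with linear gaps
oracle_semiglobal_score <- function(query, target,
                                    match = 1, mismatch = -1, gap = -2) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  m <- length(q); n <- length(t)
  prev <- rep(0, n + 1)  # row 0: leading target gap free
  for (i in seq_len(m)) {
    cur <- numeric(n + 1)
    cur[1] <- prev[1] + gap
    for (j in seq_len(n)) {
      s <- if (q[i] == t[j]) match else mismatch
      cur[j + 1] <- max(prev[j] + s, prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  max(prev)
}

# maximal window-then-base end trimming, written as a literal search over
# prefixes: drop trailing windows while their mean is below threshold,
# then trailing bases
oracle_end_trim <- function(quals, window, threshold) {
  keep <- length(quals)
  repeat {
    if (keep >= window &&
        mean(quals[(keep - window + 1):keep]) < threshold) {
      keep <- keep - window
    } else if (keep >= 1 && quals[keep] < threshold) {
      keep <- keep - 1
    } else break
  }
  keep
}

phred_string <- function(q) {
  paste(vapply(q, function(x) rawToChar(as.raw(x + 33L)), ""), collapse = "")
}

make_read <- function(sequence, q = 30L, read_id = "r1") {
  list(read_id = read_id, sequence = sequence,
       quality = phred_string(rep(q, nchar(sequence))))
}

# small shared fixture built once per test run
shared_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_reference_fixture(
      n_species = 6, n_mitotypes = c(2, 1, 1, 1, 1, 1), seed = 7)
    fx
  }
})

shared_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- build_database(shared_fixture()$records,
                                           shared_fixture()$primers)
    db
  }
})

six_taxon_spec <- function(host_fraction = 0,
                           fractions = c(0.65, 0.15, 0.08, 0.04, 0.04, 0.04),
                           mitotypes1 = c(Hap1 = 1)) {
  sp <- unique(shared_fixture()$amplicons$species)
  members <- lapply(seq_along(sp), function(i)
    list(species = sp[i], fraction = fractions[i],
         mitotypes = if (i == 1) mitotypes1 else c(Hap1 = 1)))
  community_spec(members, host_fraction = host_fraction)
}
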