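test_that("self-alignment gives identity 1, coverage 1, length score", {
  s <- rand_dna(140)
  al <- align_semi_global(s, s, band = 16)
  expect_equal(al$score, 140L)
  expect_equal(al$identity, 1.0)
  expect_equal(al$coverage, 1.0)
  expect_equal(al$tstart, 0L)
  expect_equal(al$tend, 140L)
})

test_that("four substitutions in a 140-mer give identity 136/140", {
  set.seed(44)
  t <- rand_dna(140)
  v <- strsplit(t, "")[[1]]
  for (p in c(10, 50, 90, 130)) v[p] <- setdiff(c("A","C","G","T"), v[p])[1]
  q <- paste(v, collapse = "")
  al <- align_semi_global(q, t, band = 16)
  expect_equal(al$identity, 136 / 140)
  expect_equal(al$coverage, 1.0)
})

test_that("banded score equals the unbanded full-DP oracle", {
  set.seed(99)
  for (rep in 1:500) {
    m <- sample(10:60, 1)
    n <- sample(m:60, 1)
    q <- rand_dna(m); t <- rand_dna(n)
    al <- align_semi_global(q, t, band = 16)
    expect_equal(al$score, oracle_semiglobal_score(q, t))
  }
})

test_that("banded equals unbanded when the band covers the indels", {
  set.seed(101)
  for (rep in 1:50) {
    t <- rand_dna(150)
    # plant up to 3 indels and a few substitutions in a copy
    v <- strsplit(t, "")[[1]]
    for (p in sample(20:130, sample(0:4, 1))) v[p] <- sample(c("A","C","G","T"), 1)
    n_ind <- sample(0:3, 1)
    for (k in seq_len(n_ind)) {
      p <- sample(seq_along(v), 1)
      v <- if (runif(1) < 0.5) v[-p] else append(v, v[p], after = p)
    }
    q <- paste(v, collapse = "")
    banded <- align_semi_global(q, t, band = 16)
    full <- align_semi_global(q, t, band = -1)
    expect_equal(banded$score, full$score)
  }
})

test_that("a too-narrow band signals and auto-widening recovers", {
  q <- rand_dna(80); t <- rand_dna(40)  # query much longer than target
  expect_error(align_semi_global(q, t, band = 2, widen = FALSE),
               class = "band_exceeded")
  al <- align_semi_global(q, t, band = 2, widen = TRUE)
  expect_equal(al$score, oracle_semiglobal_score(q, t))
})

test_that("zero-error reads are assigned to their source species", {
  fx <- shared_fixture()
  db <- shared_db()
  amp <- fx$amplicons$amplicon[1]
  asg <- assign_read(list(read_id = "r1", sequence = amp), db)
  expect_equal(asg$status, "assigned_species")
  expect_equal(asg$species, fx$amplicons$species[1])
  expect_equal(asg$identity, 1.0)
  # reverse strand
  asg_rc <- assign_read(list(read_id = "r2", sequence = revcomp(amp)), db)
  expect_equal(asg_rc$species, fx$amplicons$species[1])
  expect_equal(asg_rc$strand, "-")
  # host amplicon goes to host status
  asg_h <- assign_read(list(read_id = "r3", sequence = fx$host_amplicon), db)
  expect_equal(asg_h$status, "host")
})

test_that("a read below 97 percent identity to every reference is unassigned", {
  fx <- shared_fixture()
  db <- shared_db()
  amp <- fx$amplicons$amplicon[1]
  v <- strsplit(amp, "")[[1]]
  idx <- seq(25, 115, by = 13)  # 8 substitutions in 139 bp: identity ~0.942
  for (p in idx) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  bad <- paste(v, collapse = "")
  al <- align_semi_global(bad, amp, band = 16)
  expect_lt(al$identity, 0.97)
  asg <- assign_read(list(read_id = "r", sequence = bad), db)
  expect_equal(asg$status, "unassigned")
  expect_equal(asg$rank, "none")
})

test_that("equidistant congeneric hits fall back to the genus rank", {
  # two same-genus species and a read exactly between them
  set.seed(7)
  fwd_site <- "TGGATCAGGAACAGGATGAAC"
  rev_site <- revcomp("AAATGAAATTGATTGCTCCTA")
  ins <- strsplit(rand_dna(97), "")[[1]]
  insA <- ins; insA[10] <- "A"; insA[20] <- "A"
  insB <- ins; insB[10] <- "C"; insB[20] <- "C"
  insRead <- ins; insRead[10] <- "A"; insRead[20] <- "C"  # 1 diff from each
  mk <- function(acc, species, insv) data.frame(
    accession = acc, order = "Hemiptera", suborder = "Sternorrhyncha",
    family = "Aphididae", genus = "Cinara", species = species,
    is_host = FALSE,
    sequence = paste0(strrep("G", 30), fwd_site,
                      paste(insv, collapse = ""), rev_site, strrep("C", 30)),
    stringsAsFactors = FALSE)
  records <- rbind(mk("CA1", "Cinara cedri", insA),
                   mk("CB1", "Cinara tujafilina", insB))
  db <- build_database(records, primer_pair())
  read <- paste0(fwd_site, paste(insRead, collapse = ""), rev_site)
  asg <- assign_read(list(read_id = "tie", sequence = read), db)
  expect_equal(asg$status, "assigned_higher_rank")
  expect_equal(asg$rank, "genus")
  expect_equal(asg$genus, "Cinara")
  expect_equal(asg$species, "")
})

test_that("batch summary partitions the batch and preserves order", {
  fx <- shared_fixture()
  db <- shared_db()
  spec <- six_taxon_spec(host_fraction = 0.7)
  lib <- simulate_library(fx$amplicons, fx$host_amplicon, spec,
                          error_model(0, 0), n_reads = 100, seed = 23)
  res <- assign_batch(lib$reads, db)
  s <- res$summary
  expect_equal(s$n_host + s$n_hemiptera + s$n_unassigned, 100L)
  expect_equal(res$assignments$read_id, lib$reads$read_id)
  truth_host <- sum(lib$truth$source_species == "host")
  expect_equal(s$n_host, truth_host)
  expect_equal(s$n_unassigned, 0L)

  empty <- assign_batch(lib$reads[0, ], db)
  expect_equal(unlist(empty$summary), c(n_host = 0L, n_hemiptera = 0L,
                                        n_unassigned = 0L))
})

test_that("raising the identity threshold never assigns more reads", {
  fx <- shared_fixture()
  db <- shared_db()
  spec <- six_taxon_spec()
  lib <- simulate_library(fx$amplicons, fx$host_amplicon, spec,
                          error_model(0.02, 0.01), n_reads = 150, seed = 29)
  qc <- filter_reads(lib$reads, qc_params(), fx$primers)
  n_assigned <- vapply(c(0.90, 0.97, 0.995), function(thr) {
    res <- assign_batch(qc$reads, db, assignment_params(min_identity = thr))
    res$summary$n_hemiptera + res$summary$n_host
  }, 0L)
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("species calls stay correct under 1 percent substitution error", {
  fx <- shared_fixture()
  db <- shared_db()
  spec <- six_taxon_spec()
  lib <- simulate_library(fx$amplicons, fx$host_amplicon, spec,
                          error_model(0.01, 0), n_reads = 1000, seed = 37)
  qc <- filter_reads(lib$reads, qc_params(), fx$primers)
  res <- assign_batch(qc$reads, db)
  a <- res$assignments
  tr <- lib$truth[match(a$read_id, lib$truth$read_id), ]
  sp_rows <- a$status == "assigned_species"
  expect_gt(sum(sp_rows), 0)
  expect_gte(mean(a$species[sp_rows] == tr$source_species[sp_rows]), 0.99)
})
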