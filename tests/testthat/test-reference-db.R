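test_that("degenerate IUPAC matching expands correctly and rejects junk", {
  expect_true(iupac_match("W", "A"))
  expect_true(iupac_match("W", "T"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("A", "A"))
  expect_false(iupac_match("A", "N"))  # subject N matches nothing
  expect_false(iupac_match("N", "N"))
  expect_error(iupac_match("Z", "A"))
})

test_that("primer site finding matches a planted site and respects budget", {
  fwd <- primer_pair()$forward
  x <- rand_dna(40); y <- rand_dna(40)
  site <- "TGGAACAGGAACAGGATGAAC"  # W realized as A
  s <- paste0(x, site, y)
  hits <- find_primer_sites(s, fwd, 0)
  expect_true(nrow(hits) >= 1)
  expect_true(any(hits$position == 40 & hits$mismatches == 0))

  broken <- sub("CAGGATGAAC$", "CAGGATGTAC", site)
  hits2 <- find_primer_sites(paste0(x, broken, y), fwd, 0)
  expect_false(any(hits2$position == 40))
})

test_that("primer site finding equals the brute-force window scan", {
  set.seed(42)
  fwd <- primer_pair()$forward
  for (rep in 1:40) {
    s <- rand_dna(sample(200:600, 1))
    mm <- sample(0:3, 1)
    got <- find_primer_sites(s, fwd, mm)
    want <- naive_primer_scan(s, fwd, mm)
    expect_equal(got$position, want$position)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("amplicon extraction recovers a planted 139 bp product", {
  primers <- primer_pair()
  set.seed(1)
  insert <- rand_dna(97)
  fwd_site <- "TGGATCAGGAACAGGATGAAC"      # W -> T
  rev_site <- revcomp("AAATGAAATTGATTGCTCCTA")  # R -> A
  amplicon <- paste0(fwd_site, insert, rev_site)
  rec <- list(accession = "X1", sequence = paste0(rand_dna(50), amplicon,
                                                  rand_dna(50)))
  amp <- extract_amplicon(rec, primers)
  expect_equal(nchar(amp$with_primers_sequence), 139L)
  expect_equal(amp$insert_sequence, insert)
  expect_equal(amp$end - amp$start, nchar(amp$with_primers_sequence))
  expect_equal(amp$strand, "+")

  # strand symmetry: the reverse-complemented record gives the same insert
  rec_rc <- list(accession = "X1rc", sequence = revcomp(rec$sequence))
  amp_rc <- extract_amplicon(rec_rc, primers)
  expect_equal(amp_rc$insert_sequence, insert)
  expect_equal(amp_rc$strand, "-")
  expect_equal(amp_rc$end - amp_rc$start, 139L)
})

test_that("products outside the accepted span are rejected", {
  primers <- primer_pair()
  fwd_site <- "TGGATCAGGAACAGGATGAAC"
  rev_site <- revcomp("AAATGAAATTGATTGCTCCTA")
  set.seed(2)
  rec <- list(accession = "far",
              sequence = paste0(rand_dna(20), fwd_site, rand_dna(300),
                                rev_site, rand_dna(20)))
  expect_null(extract_amplicon(rec, primers))
})

test_that("database build keeps extractable records and logs the rest", {
  fx <- shared_fixture()
  records <- fx$records
  records <- rbind(records, data.frame(
    accession = "NOPRIMER", order = "Hemiptera", suborder = "S",
    family = "F", genus = "G", species = "Ghost species", is_host = FALSE,
    sequence = rand_dna(250), stringsAsFactors = FALSE))
  db <- build_database(records, fx$primers)
  expect_equal(length(db$amplicons), nrow(fx$records))
  expect_equal(db$excluded$accession, "NOPRIMER")
  expect_equal(db$excluded$reason, "no_valid_amplicon")
  expect_error(build_database(records[records$accession == "NOPRIMER", ],
                              fx$primers), "empty database")
})

test_that("serialized database bytes are deterministic", {
  db <- shared_db()
  d1 <- file.path(tempdir(), "dbout1"); d2 <- file.path(tempdir(), "dbout2")
  write_database(db, d1); write_database(db, d2)
  for (f in c("database.json", "amplicons.fasta", "excluded.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("haplotype projection collapses identical inserts", {
  primers <- primer_pair()
  set.seed(3)
  insert <- rand_dna(97)
  fwd_site <- "TGGATCAGGAACAGGATGAAC"
  rev_site <- revcomp("AAATGAAATTGATTGCTCCTA")
  mk <- function(id, ins, flank3, n = 1L) data.frame(
    species = "Sp x", haplotype_id = id, n_db_entries = n,
    sequence = paste0(strrep("C", 30), fwd_site, ins, rev_site, flank3),
    stringsAsFactors = FALSE)
  ins2 <- paste0("T", substr(insert, 2, 97))
  known <- rbind(mk("h1", insert, strrep("A", 30), 5L),
                 mk("h2", insert, strrep("G", 30), 2L),
                 mk("h3", insert, strrep("T", 30), 1L),
                 mk("h4", ins2, strrep("A", 30), 1L))
  pr <- project_haplotypes(known, primers)
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$n_members, c(3L, 1L))
  expect_equal(pr$total_n_db_entries, c(8L, 1L))
  expect_equal(pr$member_ids[1], "h1,h2,h3")

  single <- project_haplotypes(known[1, ], primers)
  expect_equal(nrow(single), 1L)
  expect_equal(single$n_members, 1L)
})

test_that("19 planted haplotypes with 11 insert patterns give 11 classes", {
  kn <- make_projection_fixture(n_haplotypes = 19, n_classes = 11, seed = 3)
  expect_equal(length(unique(kn$sequence)), 19L)
  pr <- project_haplotypes(kn)
  expect_equal(nrow(pr), 11L)
  expect_equal(sum(pr$n_members), 19L)
})

test_that("primer mismatch report orders host above exact-site targets", {
  fx <- shared_fixture()
  db <- shared_db()
  # degrade the host's forward site by two mismatches (N matches nothing)
  fwd_site <- substr(db$amplicons[[1]]$with_primers_sequence, 1, 21)
  broken <- fwd_site
  substr(broken, 3, 3) <- "N"; substr(broken, 8, 8) <- "N"
  recs <- fx$records
  recs$sequence[recs$accession == "HOST01"] <-
    sub(fwd_site, broken, recs$sequence[recs$accession == "HOST01"],
        fixed = TRUE)
  db2 <- build_database(recs, fx$primers)
  rep <- primer_mismatch_report(db2, fx$primers)
  host_row <- rep[rep$species == "Apis mellifera", ]
  target_rows <- rep[rep$species != "Apis mellifera", ]
  expect_true(all(target_rows$min_forward_mismatches == 0))
  expect_true(all(target_rows$min_reverse_mismatches == 0))
  expect_equal(host_row$min_forward_mismatches, 2L)
  expect_true(host_row$min_forward_mismatches >
                max(target_rows$min_forward_mismatches))
})
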