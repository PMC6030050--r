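make_species_reads <- function(seqs, prefix = "m") {
  data.frame(read_id = sprintf("%s%04d", prefix, seq_along(seqs)),
             sequence = seqs, stringsAsFactors = FALSE)
}

test_that("identical zero-error reads collapse to one candidate", {
  fx <- shared_fixture()
  amp <- fx$amplicons$amplicon[1]
  insert <- substr(amp, 22, nchar(amp) - 21)
  reads <- make_species_reads(rep(insert, 100))
  col <- collapse_reads(reads, amp, fx$primers)
  expect_equal(nrow(col$candidates), 1L)
  expect_equal(col$candidates$count, 100L)
  expect_equal(col$candidates$sequence, insert)
  expect_equal(col$n_unplaced, 0L)
  expect_equal(col$total, 100L)
})

test_that("two haplotypes one SNP apart collapse to 80/20 candidates", {
  fx <- shared_fixture()
  amp <- fx$amplicons$amplicon[1]
  insert <- substr(amp, 22, nchar(amp) - 21)
  v <- strsplit(insert, "")[[1]]
  v[40] <- setdiff(c("A", "C", "G", "T"), v[40])[1]
  variant <- paste(v, collapse = "")
  reads <- make_species_reads(c(rep(insert, 80), rep(variant, 20)))
  col <- collapse_reads(reads, amp, fx$primers)
  expect_equal(col$candidates$count, c(80L, 20L))
  expect_equal(col$candidates$sequence[1], insert)
  expect_equal(col$candidates$sequence[2], variant)
  # count conservation
  expect_equal(sum(col$candidates$count) + col$n_unplaced, col$total)
})

test_that("truncated and deletion-bearing reads are unplaced", {
  fx <- shared_fixture()
  amp <- fx$amplicons$amplicon[1]
  insert <- substr(amp, 22, nchar(amp) - 21)
  truncated <- substr(insert, 1, nchar(insert) - 10)
  deleted <- paste0(substr(insert, 1, 39), substr(insert, 41, nchar(insert)))
  inserted <- paste0(substr(insert, 1, 40), "A", substr(insert, 41,
                                                        nchar(insert)))
  reads <- make_species_reads(c(rep(insert, 5), truncated, deleted,
                                inserted))
  col <- collapse_reads(reads, amp, fx$primers)
  expect_equal(col$n_unplaced, 2L)  # truncation + deletion
  # the insertion-bearing read is placed with its extra base removed
  expect_equal(col$candidates$count, 6L)
  expect_equal(col$candidates$sequence, insert)
})

test_that("the reliability rule combines the read floor with known/frequency", {
  mk_collapsed <- function(counts, seqs) {
    list(candidates = data.frame(sequence = seqs, count = counts,
                                 stringsAsFactors = FALSE),
         n_unplaced = 0L, total = sum(counts))
  }
  known <- data.frame(class_sequence = "AAAA", member_ids = "Hap1",
                      n_members = 1L, total_n_db_entries = 5L,
                      stringsAsFactors = FALSE)
  # known candidate, 25 reads, 2 percent: reliable (known overrides freq)
  col <- mk_collapsed(c(1225L, 25L), c("CCCC", "AAAA"))
  tab <- call_mitotypes(col, known)
  expect_true(tab$calls$is_reliable[tab$calls$sequence == "AAAA"])
  expect_true(tab$calls$is_known[tab$calls$sequence == "AAAA"])
  expect_equal(tab$calls$known_ids[tab$calls$sequence == "AAAA"], "Hap1")

  # unknown candidate, 25 reads, 4 percent: fails both arms
  col2 <- mk_collapsed(c(600L, 25L), c("CCCC", "GGGG"))
  tab2 <- call_mitotypes(col2, known)
  expect_false(tab2$calls$is_reliable[tab2$calls$sequence == "GGGG"])

  # known candidate at 50 percent but only 19 reads: the floor always wins
  col3 <- mk_collapsed(c(19L, 19L), c("AAAA", "CCCC"))
  tab3 <- call_mitotypes(col3, known)
  expect_false(any(tab3$calls$is_reliable))

  # alternative precedence: the 5-percent arm alone suffices
  tab3b <- call_mitotypes(col3, known,
                          mitotype_params(precedence = "alternative"))
  expect_true(all(tab3b$calls$is_reliable))

  # exact matching: one changed base breaks known status
  col4 <- mk_collapsed(25L, "AAAT")
  expect_false(call_mitotypes(col4, known)$calls$is_known)
})

test_that("reliable-call frequencies renormalize and sort", {
  col <- list(candidates = data.frame(
    sequence = c("AAAA", "CCCC", "GGGG"),
    count = c(90L, 10L, 2L), stringsAsFactors = FALSE),
    n_unplaced = 0L, total = 102L)
  known <- data.frame(class_sequence = c("AAAA", "CCCC"),
                      member_ids = c("Hap1", "Hap2"),
                      n_members = c(1L, 1L),
                      total_n_db_entries = c(4L, 1L),
                      stringsAsFactors = FALSE)
  tab <- call_mitotypes(col, known, mitotype_params(min_reads = 10))
  fr <- mitotype_frequencies(tab)
  expect_equal(fr$fraction, c(0.9, 0.1))
  expect_equal(fr$known_ids, c("Hap1", "Hap2"))

  solo <- call_mitotypes(list(candidates = data.frame(
    sequence = "AAAA", count = 30L, stringsAsFactors = FALSE),
    n_unplaced = 0L, total = 30L), known)
  expect_equal(mitotype_frequencies(solo)$fraction, 1.0)

  none <- call_mitotypes(list(candidates = data.frame(
    sequence = "GGGG", count = 3L, stringsAsFactors = FALSE),
    n_unplaced = 0L, total = 3L), known)
  expect_warning(fr0 <- mitotype_frequencies(none), "no reliable")
  expect_equal(nrow(fr0), 0L)
})

test_that("an 85/15 two-mitotype mixture is recovered from noisy reads", {
  fx <- shared_fixture()
  db <- shared_db()
  sp1 <- fx$amplicons$species[1]
  spec <- community_spec(list(
    list(species = sp1, fraction = 1,
         mitotypes = c(Hap1 = 0.85, Hap2 = 0.15))), 0)
  n <- 5000
  lib <- simulate_library(fx$amplicons, fx$host_amplicon, spec,
                          error_model(0.005, 0.005), n_reads = n, seed = 41)
  qc <- filter_reads(lib$reads, qc_params(), fx$primers)
  col <- collapse_reads(qc$reads,
                        fx$amplicons$amplicon[1], fx$primers)
  classes <- project_haplotypes(fx$known[fx$known$species == sp1, ],
                                fx$primers)
  tab <- call_mitotypes(col, classes)
  fr <- mitotype_frequencies(tab)
  expect_equal(nrow(fr), 2L)
  n_eff <- sum(tab$calls$count[tab$calls$is_reliable])
  se <- sqrt(0.85 * 0.15 / n_eff)
  expect_lt(abs(fr$fraction[1] - 0.85), 3 * se)
  expect_equal(sum(col$candidates$count) + col$n_unplaced, col$total)
})

test_that("species eligibility needs 10 reads in two libraries or the top spot", {
  path <- system.file("extdata", "table2_counts.tsv",
                      package = "honeytrace")
  profiles <- load_count_table(path)
  elig <- eligible_species(profiles)
  expect_true(all(c("Metcalfa pruinosa", "Myzus persicae",
                    "Aphis gossypii") %in% elig))
  # 9 reads in two libraries: excluded; 10 in two: included
  mk_prof <- function(lib, counts) {
    a <- data.frame(read_id = "x", status = "assigned_species",
                    rank = "species", species = names(counts),
                    genus = "G", family = "F", order = "Hemiptera",
                    stringsAsFactors = FALSE)[rep(seq_along(counts),
                                                  counts), ]
    a$read_id <- sprintf("r%d", seq_len(nrow(a)))
    profile_library(a, lib)
  }
  p1 <- mk_prof("l1", c(`Big species` = 100, `Nine reads` = 9,
                        `Ten reads` = 10))
  p2 <- mk_prof("l2", c(`Big species` = 80, `Nine reads` = 9,
                        `Ten reads` = 10))
  e <- eligible_species(list(p1, p2))
  expect_true("Ten reads" %in% e)
  expect_false("Nine reads" %in% e)
  expect_true("Big species" %in% e)
})
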