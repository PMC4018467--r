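test_that("validity thresholds: 12+ mononucleotide copies, 4+ multinucleotide copies", {
  r <- find_repeats(strrep("A", 12))
  expect_equal(nrow(r), 1L)
  expect_identical(r$motif, "A")
  expect_equal(r$copies, 12)
  expect_equal(nrow(find_repeats(strrep("A", 11))), 0L)

  r <- find_repeats(strrep("GA", 4))
  expect_equal(nrow(r), 1L)
  expect_identical(r$motif, "AG")   # canonical rotation
  expect_equal(r$unit_len, 2L)
  expect_equal(r$copies, 4)
  expect_equal(nrow(find_repeats(strrep("GA", 3))), 0L)
})

test_that("runs merge across interruptions up to max_gap with purity accounting", {
  # two (GA)4 tracts separated by a 2-nt CT interruption: one merged run
  s <- paste0(strrep("GA", 4), "CT", strrep("GA", 4))
  r <- find_repeats(s)
  expect_equal(nrow(r), 1L)
  expect_equal(r$interruptions, 1L)
  expect_equal(r$copies, 8)
  expect_equal(r$purity, 16 / 18)
  expect_equal(c(r$start, r$end), c(1L, 18L))

  # a 6-nt insert exceeds max_gap = 4: tracts stay separate
  s2 <- paste0(strrep("GA", 4), "CTCTCT", strrep("GA", 4))
  r2 <- find_repeats(s2)
  expect_equal(nrow(r2), 2L)
  expect_true(all(r2$interruptions == 0L))
})

test_that("scanner equals the exhaustive enumeration oracle on random sequences", {
  set.seed(303)
  n_checked <- 0
  for (i in 1:50) {
    # mix unbiased sequences with repeat-seeded ones so runs actually occur
    s <- if (i %% 2 == 0) {
      random_dna(200)
    } else {
      paste0(random_dna(40), strrep("GA", sample(3:12, 1)),
             random_dna(10), strrep(sample(c("A", "T"), 1), sample(10:16, 1)),
             random_dna(30), strrep("CTT", sample(3:6, 1)), random_dna(20))
    }
    got <- find_repeats(s)
    want <- oracle_repeats(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got, want, tolerance = 1e-12)
      n_checked <- n_checked + nrow(want)
    }
  }
  expect_gt(n_checked, 20)   # the corpus exercised real runs
})

test_that("N breaks runs and invalid alphabets are rejected", {
  expect_equal(nrow(find_repeats(paste0(strrep("A", 6), "N", strrep("A", 6)))),
               0L)
  expect_equal(nrow(find_repeats("")), 0L)
  expect_error(find_repeats("ACGX"), "alphabet|characters")
})

test_that("reversing the sequence mirrors run coordinates", {
  set.seed(99)
  for (i in 1:10) {
    s <- paste0(random_dna(30), strrep("GA", 6), random_dna(15),
                strrep("A", 13), random_dna(20))
    n <- nchar(s)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    f <- find_repeats(s)
    r <- find_repeats(rev_s)
    expect_equal(nrow(f), nrow(r))
    got <- r[order(r$start), ]
    mirrored <- data.frame(start = n - f$end + 1L, end = n - f$start + 1L)
    mirrored <- mirrored[order(mirrored$start), ]
    expect_equal(got$start, mirrored$start)
    expect_equal(got$end, mirrored$end)
    expect_equal(sort(got$copies), sort(f$copies))
  }
})

test_that("phase-shifted motifs share one canonical rotation", {
  a <- find_repeats(paste0("T", strrep("AG", 5), "T"))
  b <- find_repeats(paste0("T", strrep("GA", 5), "T"))
  expect_identical(a$motif, b$motif)
  expect_equal(a$purity, b$purity)
})

test_that("STR decomposition recovers flanks and the central (GA) core", {
  flank5 <- "TCTCACTCTCTGTCACTGCC"
  flank3 <- "CCTTGACCCTCACAGGACTC"
  s <- paste0(flank5, strrep("GA", 20), flank3)
  ann <- decompose_str(s, id = "toy")
  expect_equal(nchar(ann$central$sequence), 40L)
  expect_identical(ann$initial$sequence, flank5)
  expect_identical(ann$final$sequence, flank3)
  expect_false(ann$degenerate)
  expect_equal(ann$total_length,
               nchar(ann$initial$sequence) + nchar(ann$central$sequence) +
                 nchar(ann$final$sequence))

  # short-central allele: 13 pure units give the 26-nt central region
  w93 <- paste0(flank5, strrep("GA", 13), flank3)
  expect_equal(nchar(decompose_str(w93)$central$sequence), 26L)

  # interrupted core merges into a single central sector
  s2 <- paste0(flank5, strrep("GA", 6), "CT", strrep("GA", 6), flank3)
  ann2 <- decompose_str(s2)
  expect_equal(ann2$interruptions, 1L)
  expect_equal(nchar(ann2$central$sequence), 26L)

  # no valid run: degenerate annotation with empty central sector
  ann3 <- decompose_str("ACGTACTGCATG")
  expect_true(ann3$degenerate)
  expect_identical(ann3$central$sequence, "")
})

test_that("str_report is consistent with decomposition and the panel truth", {
  p <- generate_panel(panel_config(seed = 4L))
  tab <- scan_panel(p)
  expect_equal(nrow(tab), 34L)
  expect_identical(tab$total_length,
                   unname(p$truth$str_length[match(tab$id, p$truth$id)]))
  expect_equal(tab$total_length,
               tab$initial_length + tab$central_length + tab$final_length)
  expect_true(all(!tab$degenerate))
  expect_true(all(tab$central_motif == "GA"))
  # the conserved 20-nt flanks are recovered as initial/final sectors
  expect_true(all(tab$initial_length == 20L))
  expect_true(all(tab$final_length == 20L))
})
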