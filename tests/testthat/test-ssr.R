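test_that("thresholds validate their keys and defaults", {
  th <- ssr_thresholds()
  expect_equal(unname(th[as.character(2:6)]), c(6L, 5L, 5L, 4L, 4L))
  expect_error(ssr_thresholds(c(`2` = 6, `3` = 5)), "keys exactly")
  expect_error(ssr_thresholds(c(`2` = 1, `3` = 5, `4` = 5, `5` = 4, `6` = 4)),
               ">= 2")
})

test_that("planted tracts are found with MISA semantics", {
  s <- paste0("TTT", strrep("AG", 7), "CCC")
  loci <- find_ssrs(c(x = s))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$motif, "AG")
  expect_equal(loci$repeats, 7)
  expect_equal(loci$start, 4)
  expect_equal(loci$end, 17)

  # below the di-nucleotide threshold of 6
  expect_equal(nrow(find_ssrs(c(x = strrep("AG", 5)))), 0)

  # smallest-unit rule: (ATAT) x 5 is AT x 10
  loci <- find_ssrs(c(x = strrep("ATAT", 5)))
  expect_equal(loci$motif, "AT")
  expect_equal(loci$repeats, 10)

  # N interrupts a tract
  s <- paste0(strrep("AG", 3), "N", strrep("AG", 3))
  expect_equal(nrow(find_ssrs(c(x = s))), 0)

  # trailing partial repeats are not counted
  loci <- find_ssrs(c(x = paste0("CCC", strrep("GAA", 6), "GA", "CCC")))
  expect_equal(loci$repeats, 6)
  expect_equal(loci$end, 3 + 18)
})

test_that("miner agrees exactly with the shift-comparison oracle on random sequences", {
  set.seed(7)
  for (i in 1:60) {
    s <- rand_seq_with_tracts(sample(200:1500, 1), sample(0:4, 1))
    got <- find_ssrs(c(x = s))
    want <- oracle_find_ssrs(s)
    expect_equal(got[, c("motif", "unit_length", "repeats", "start", "end")],
                 want, info = paste("seq", i))
  }
})

test_that("reported loci of one sequence never overlap at nested unit sizes", {
  set.seed(11)
  for (i in 1:20) {
    loci <- find_ssrs(c(x = rand_seq_with_tracts(800, 4)))
    if (nrow(loci) < 2) next
    for (a in seq_len(nrow(loci) - 1)) {
      for (b in (a + 1):nrow(loci)) {
        ua <- loci$unit_length[a]; ub <- loci$unit_length[b]
        if (ua %% ub == 0 || ub %% ua == 0) {
          overlap <- loci$start[b] <= loci$end[a] &&
                     loci$start[a] <= loci$end[b]
          expect_false(overlap)
        }
      }
    }
  }
})

test_that("motif frequencies count loci, optionally merging rotations", {
  seqs <- c(g1 = paste0("CTTT", strrep("AG", 7), "TTTC",
                        strrep("AG", 6), "TTT"),
            g2 = paste0("CCAA", strrep("TC", 8), "AAA"))
  loci <- find_ssrs(seqs)
  tab <- motif_frequency(loci)
  expect_equal(sum(tab$locus_count), nrow(loci))
  expect_equal(tab$locus_count[tab$motif == "AG"], 2)
  expect_equal(tab$locus_count[tab$motif == "TC"], 1)
  expect_equal(tab$sequence_ids[tab$motif == "AG"], "g1")

  # rotation classes merge GA with AG but never with TC (not a rotation);
  # each class is labelled by its lexicographically smallest rotation
  loci2 <- rbind(loci,
                 within(loci[1, ], {motif <- "GA"; start <- 500; end <- 513}))
  tab2 <- motif_frequency(loci2, canonicalize = TRUE)
  expect_equal(tab2$locus_count[tab2$motif == "AG"], 3)
  expect_equal(tab2$locus_count[tab2$motif == "CT"], 1)  # class of TC

  empty <- motif_frequency(find_ssrs(c(x = "ACGTACGA")))
  expect_equal(nrow(empty), 0)
})

test_that("motif selection ranks by abundance with activity as tie-break", {
  freq <- data.frame(
    motif = c("TC", "AG", "GAA", "CCA"),
    unit_length = c(2L, 2L, 3L, 3L),
    locus_count = c(9L, 4L, 5L, 5L),
    sequence_ids = c("g1;g2", "g3", "g4", "g5"),
    stringsAsFactors = FALSE)
  sel <- select_motifs(freq, k_per_unit = 1, units = c(2, 3))
  expect_equal(sel$motif[sel$unit_length == 2], "TC")

  # tri-nucleotide tie broken by host-gene activity
  act <- c(g4 = 0.5, g5 = 3.0)
  sel <- select_motifs(freq, gene_activity = act, k_per_unit = 1,
                       units = c(2, 3))
  expect_equal(sel$motif[sel$unit_length == 3], "CCA")

  w <- testthat::capture_warnings(
    sel3 <- select_motifs(freq, k_per_unit = 3, units = c(2, 3)))
  expect_length(w, 2)           # one shortfall warning per unit length
  expect_match(w, "only 2 motif", all = TRUE)
  expect_equal(nrow(sel3), 4)   # returns everything available
  expect_error(select_motifs(freq[0, ]), "empty")
})

test_that("exclusive transcript sets partition the union", {
  r <- exclusive_transcripts(c("g1", "g2", "g3"), c("g2"))
  expect_equal(sort(r$only_a), c("g1", "g3"))
  expect_equal(r$only_b, character(0))
  expect_equal(r$shared, "g2")

  r <- exclusive_transcripts(c("a", "b"), c("c"))
  expect_equal(r$shared, character(0))
  r <- exclusive_transcripts(c("a", "b"), c("b", "a"))
  expect_equal(r$only_a, character(0))
  expect_equal(r$only_b, character(0))
})
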