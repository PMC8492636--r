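plant_template <- function(len, inserts) {
  # inserts: named list position -> sequence; returns template string
  s <- rand_dna(len)
  for (pos in names(inserts)) {
    p <- as.integer(pos)
    substr(s, p, p + nchar(inserts[[pos]]) - 1) <- inserts[[pos]]
  }
  s
}

test_that("binding sites honour strand, mismatch budget and the 3' seed", {
  set.seed(21)
  primer <- data.frame(name = "P", seq = rand_dna(20))
  tmpl <- plant_template(400, setNames(list(primer$seq), 101))
  hits <- find_binding_sites(tmpl, primer)
  expect_equal(hits$position, 101)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  # one internal mismatch: invisible at 0, reported at 1
  mut <- primer$seq
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut, 5, 5))[1]
  tmpl2 <- plant_template(400, setNames(list(mut), 101))
  expect_equal(nrow(find_binding_sites(tmpl2, primer)), 0)
  h1 <- find_binding_sites(tmpl2, primer, max_mismatch = 1)
  expect_equal(h1$mismatches, 1)

  # 3'-terminal mismatch is never tolerated
  mut3 <- primer$seq
  substr(mut3, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mut3, 20, 20))[1]
  tmpl3 <- plant_template(400, setNames(list(mut3), 101))
  expect_equal(nrow(find_binding_sites(tmpl3, primer, max_mismatch = 2)), 0)

  # minus strand: template carries the reverse complement
  tmpl4 <- plant_template(400,
                          setNames(list(reverse_complement(primer$seq)), 201))
  h4 <- find_binding_sites(tmpl4, primer)
  expect_true(any(h4$strand == "-" & h4$position == 201))

  # N in the template never matches
  tmplN <- tmpl
  substr(tmplN, 110, 110) <- "N"
  expect_equal(nrow(find_binding_sites(tmplN, primer)), 0)

  # primer longer than template: empty, not an error
  expect_equal(nrow(find_binding_sites("ACGT", primer)), 0)
})

test_that("amplicons arise from convergent site pairs with exact coordinates", {
  set.seed(22)
  A <- data.frame(name = "A", kind = "miRNA", seq = rand_dna(20))
  B <- data.frame(name = "B", kind = "miRNA", seq = rand_dna(20))
  primers <- rbind(A, B)
  pair <- data.frame(pair_name = "A + B", primer_a = "A", primer_b = "B")

  tmpl <- plant_template(800, list(`101` = A$seq,
                                   `581` = reverse_complement(B$seq)))
  amp <- predict_amplicons(tmpl, pair, primers)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 101)
  expect_equal(amp$end, 600)
  expect_equal(amp$length, 500)
  expect_equal(amp$fwd_primer, "A")
  expect_equal(amp$rev_primer, "B")

  # no convergent sites: empty result, not an error
  tmpl2 <- plant_template(800, list(`101` = A$seq, `581` = B$seq))
  expect_equal(nrow(predict_amplicons(tmpl2, pair, primers)), 0)

  # single-primer amplification: a + and a - site of the same primer
  tmpl3 <- plant_template(800, list(`101` = A$seq,
                                    `381` = reverse_complement(A$seq)))
  amp3 <- predict_amplicons(tmpl3, pair, primers)
  expect_equal(nrow(amp3), 1)
  expect_equal(amp3$fwd_primer, "A")
  expect_equal(amp3$rev_primer, "A")
  expect_equal(amp3$length, 300)

  # product window is enforced
  expect_equal(nrow(predict_amplicons(tmpl, pair, primers, min_len = 600)), 0)
  expect_equal(nrow(predict_amplicons(tmpl, pair, primers, max_len = 400)), 0)
  expect_error(predict_amplicons(tmpl, pair, primers, min_len = 500,
                                 max_len = 400), "min_len")
})

test_that("amplicon sets are invariant under primer swap and template reversal", {
  set.seed(23)
  A <- data.frame(name = "A", seq = rand_dna(18))
  B <- data.frame(name = "B", seq = rand_dna(18))
  primers <- rbind(A, B)
  pair_ab <- data.frame(pair_name = "A + B", primer_a = "A", primer_b = "B")
  pair_ba <- data.frame(pair_name = "A + B", primer_a = "B", primer_b = "A")

  for (i in 1:10) {
    gap <- sample(150:900, 1)
    pos2 <- 101 + 18 + gap
    tmpl <- plant_template(pos2 + 18 + 100,
                           setNames(list(A$seq, reverse_complement(B$seq)),
                                    c(101, pos2)))
    amp1 <- predict_amplicons(tmpl, pair_ab, primers)
    amp2 <- predict_amplicons(tmpl, pair_ba, primers)
    expect_equal(amp1, amp2)
    expect_equal(amp1$length, gap + 36)

    # reverse-complemented template: coordinates mirror
    rc <- reverse_complement(tmpl)
    amp_rc <- predict_amplicons(rc, pair_ab, primers)
    L <- nchar(tmpl)
    expect_equal(nrow(amp_rc), 1)
    expect_equal(amp_rc$start, L - amp1$end + 1)
    expect_equal(amp_rc$end, L - amp1$start + 1)
  }
})

test_that("planted site distances are recovered exactly across random panels", {
  set.seed(24)
  for (i in 1:25) {
    A <- data.frame(name = "A", seq = rand_dna(20))
    B <- data.frame(name = "B", seq = rand_dna(20))
    primers <- rbind(A, B)
    pair <- data.frame(pair_name = "A + B", primer_a = "A", primer_b = "B")
    gap <- sample(100:1000, 1)
    start <- sample(50:150, 1)
    pos2 <- start + 20 + gap
    tmpl <- plant_template(pos2 + 20 + 60,
                           setNames(list(A$seq, reverse_complement(B$seq)),
                                    c(start, pos2)))
    amp <- predict_amplicons(tmpl, pair, primers)
    expect_equal(amp$length, gap + 40)
  }
})

test_that("batch prediction matches per-template prediction and writes TSV/BED", {
  set.seed(25)
  A <- data.frame(name = "A", seq = rand_dna(20))
  B <- data.frame(name = "B", seq = rand_dna(20))
  primers <- rbind(A, B)
  pairs <- data.frame(pair_name = "A + B", primer_a = "A", primer_b = "B")
  tmpls <- c(
    g1 = plant_template(600, list(`51` = A$seq,
                                  `401` = reverse_complement(B$seq))),
    g2 = rand_dna(600))
  batch <- predict_amplicons_batch(tmpls, pairs, primers)
  single <- predict_amplicons(tmpls[["g1"]], pairs, primers,
                              template_id = "g1")
  expect_equal(batch, single)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_amplicon_tsv(batch, tsv, bed)
  bed_df <- read.delim(bed, header = FALSE)
  expect_equal(bed_df$V2, batch$start - 1)  # 0-based half-open
  expect_equal(bed_df$V3, batch$end)

  sq <- amplicon_sequence(tmpls[["g1"]], batch[1, ])
  expect_equal(nchar(sq), batch$length[1])
  expect_equal(substr(sq, 1, 20), A$seq)
})
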