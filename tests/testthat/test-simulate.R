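test_that("identical configurations give byte-identical panels", {
  p1 <- simulate_panel(demo_panel_config(seed = 7))
  p2 <- simulate_panel(demo_panel_config(seed = 7))
  expect_identical(p1$genomes, p2$genomes)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$primers, p2$primers)

  p3 <- simulate_panel(demo_panel_config(seed = 8))
  expect_false(identical(p1$genomes, p3$genomes))
})

test_that("panel generation does not disturb the caller RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_panel(demo_panel_config(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("planted SSR tracts are recovered from the synthetic transcripts", {
  panel <- simulate_panel(demo_panel_config(seed = 3))
  loci <- find_ssrs(panel$transcripts)
  for (m in panel$config$issr_motifs$motif) {
    hosts <- grep(paste0("^gene_", m, "_"), panel$transcripts$id, value = TRUE)
    found <- loci$sequence_id[loci$motif == m]
    expect_true(all(hosts %in% found),
                info = paste("motif", m, "not mined from all host genes"))
  }
})

test_that("planted primer sites sit at their truth coordinates", {
  panel <- simulate_panel(demo_panel_config(seed = 4))
  pseq <- setNames(panel$primers$seq, panel$primers$name)
  tr <- panel$truth[sample(nrow(panel$truth), 25), ]
  for (r in seq_len(nrow(tr))) {
    g <- panel$genomes[[tr$genotype[r]]]
    f <- pseq[[tr$fwd_primer[r]]]
    expect_equal(substr(g, tr$fwd_start[r], tr$fwd_start[r] + nchar(f) - 1),
                 f)
    rv <- reverse_complement(pseq[[tr$rev_primer[r]]])
    expect_equal(substr(g, tr$rev_end[r] - nchar(rv) + 1, tr$rev_end[r]), rv)
    expect_equal(tr$rev_end[r] - tr$fwd_start[r] + 1, tr$product_len[r])
  }
})

test_that("discriminative cassettes exist only in tolerant carriers", {
  panel <- simulate_panel(demo_panel_config(seed = 6))
  disc <- panel$truth[panel$truth$type == "discriminative", ]
  expect_setequal(unique(disc$genotype), c("T1", "T2"))
  expect_setequal(unique(disc$pair_name), panel$expected_candidates$pair_name)
})

test_that("panels round-trip through a directory and path-based pipeline", {
  panel <- simulate_panel(demo_panel_config(seed = 2))
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  expect_true(file.exists(file.path(dir, "mirnas.fasta")))

  res_mem <- run_pipeline(pipeline_config(), panel = panel)
  cfg <- pipeline_config(mirna_fasta = file.path(dir, "mirnas.fasta"),
                         transcript_fasta = file.path(dir, "transcripts.fasta"),
                         genome_fasta = file.path(dir, "genomes.fasta"),
                         bulk_yaml = file.path(dir, "bulks.yaml"),
                         k_per_unit = 1)
  res_path <- run_pipeline(cfg)
  expect_equal(res_path$band_matrix$values, res_mem$band_matrix$values)
  expect_equal(res_path$bsa$candidates, res_mem$bsa$candidates)
})

test_that("band dropout is reproducible and binomially calibrated", {
  vals <- matrix(1L, 25, 20)
  bm <- make_bm(vals, rep(paste0("p", 1:5), 5))
  expect_identical(degrade_bands(bm, 0, seed = 1), bm)

  d1 <- degrade_bands(bm, 0.3, seed = 9)
  d2 <- degrade_bands(bm, 0.3, seed = 9)
  expect_identical(d1$values, d2$values)

  # dropout close to 1 removes nearly everything
  d <- degrade_bands(bm, 0.99, seed = 2)
  expect_lt(sum(d$values), 25)

  # mean flipped count over 200 replicates ~ Binomial(500, 0.1)
  flips <- vapply(1:200, function(s) {
    sum(degrade_bands(bm, 0.1, seed = s)$values == 0)
  }, numeric(1))
  expect_lt(abs(mean(flips) - 50), 3)
  expect_error(degrade_bands(bm, 1, seed = 1), "dropout")
})

test_that("BSA false negatives increase monotonically with dropout", {
  panel <- simulate_panel(demo_panel_config(seed = 10))
  res <- run_pipeline(pipeline_config(), panel = panel)
  bm <- res$band_matrix
  design <- panel$bulk_design
  truth_keys <- paste(panel$expected_candidates$pair_name,
                      panel$expected_candidates$product_len)
  fn_rate <- function(dropout) {
    mean(vapply(1:30, function(s) {
      got <- select_candidate_markers(degrade_bands(bm, dropout, seed = s),
                                      design)$candidates
      keys <- paste(got$pair_name, got$size)
      sum(!truth_keys %in% keys) / length(truth_keys)
    }, numeric(1)))
  }
  rates <- vapply(c(0, 0.15, 0.45), fn_rate, numeric(1))
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})
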