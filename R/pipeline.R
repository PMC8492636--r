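#' Pipeline configuration
#'
#' Collects every stage parameter of the marker pipeline with the package
#' defaults: SSR thresholds 6/5/5/4/4 for unit 2-6, ISSR anchor length 2
#' and target primer length 18, exact-match in-silico PCR with a 3 nt
#' 3'-seed and a 100-3000 bp product window, 2 percent relative band-size
#' binning, multiallelic PIC, a 3-cluster dendrogram cut, and no scoring
#' noise.
#'
#' @param mirna_fasta,transcript_fasta,genome_fasta Input paths (ignored
#'   when `run_pipeline()` is given an in-memory panel).
#' @param bulk_yaml Bulk design YAML path (optional; pipeline skips BSA
#'   selection without a design).
#' @param out_dir Output directory (optional; no files written when NULL).
#' @param thresholds,k_per_unit,anchor_len,target_len,min_len,max_len,
#'   max_mismatch,seed_len,rel_tol,pic_mode,n_clusters,dropout,seed Stage
#'   parameters.
#' @param species Named list of related-species sample ids for
#'   transferability (optional).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_fasta = NULL, transcript_fasta = NULL,
                            genome_fasta = NULL, bulk_yaml = NULL,
                            out_dir = NULL,
                            thresholds = ssr_thresholds(),
                            k_per_unit = 2L, anchor_len = 2L,
                            target_len = 18L, min_len = 100L,
                            max_len = 3000L, max_mismatch = 0L,
                            seed_len = 3L, rel_tol = 0.02,
                            pic_mode = "multiallelic", n_clusters = 3L,
                            dropout = 0, seed = 1L, species = NULL) {
  structure(list(mirna_fasta = mirna_fasta,
                 transcript_fasta = transcript_fasta,
                 genome_fasta = genome_fasta, bulk_yaml = bulk_yaml,
                 out_dir = out_dir, thresholds = thresholds,
                 k_per_unit = as.integer(k_per_unit),
                 anchor_len = as.integer(anchor_len),
                 target_len = as.integer(target_len),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 max_mismatch = as.integer(max_mismatch),
                 seed_len = as.integer(seed_len), rel_tol = rel_tol,
                 pic_mode = pic_mode, n_clusters = as.integer(n_clusters),
                 dropout = dropout, seed = as.integer(seed),
                 species = species),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full marker pipeline
#'
#' Executes primer design, pairing, in-silico PCR, band binning, marker
#' statistics (PIC, percent polymorphism, transferability), clustering
#' (Jaccard similarity, UPGMA with Newick export, cluster cut) and
#' bulked-sample candidate selection, in that order. Inputs are either an
#' in-memory [simulate_panel()] result or FASTA/YAML paths in the
#' configuration. When `cfg$out_dir` is set, all stage outputs are written
#' there as TSV/FASTA/Newick/YAML and a machine-readable `summary.yaml`.
#'
#' @param cfg A [pipeline_config()].
#' @param panel Optional `sim_panel`; overrides the input paths.
#' @return list with elements `primers`, `pairs`, `ssr_loci`, `motif_freq`,
#'   `amplicons`, `band_matrix`, `pic`, `polymorphism`, `similarity`,
#'   `tree`, `newick`, `clusters`, `bsa` (or NULL), `transferability`
#'   (or NULL), `summary` (named list of counts).
#' @export
run_pipeline <- function(cfg, panel = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(panel)) {
    mirnas <- panel$mirnas
    transcripts <- panel$transcripts
    genomes <- panel$genomes
    design <- panel$bulk_design
    if (is.null(cfg$species) && length(panel$config$species) > 0) {
      cfg$species <- as.list(setNames(panel$config$species,
                                      panel$config$species))
    }
    if (cfg$dropout == 0) cfg$dropout <- panel$config$dropout
    # the panel records its own design conditions; re-derive with them
    cfg$k_per_unit <- panel$config$k_per_unit
    cfg$anchor_len <- panel$config$anchor_len
    cfg$target_len <- panel$config$target_len
  } else {
    if (is.null(cfg$mirna_fasta) || is.null(cfg$transcript_fasta) ||
        is.null(cfg$genome_fasta)) {
      stop("provide either a panel or mirna/transcript/genome FASTA paths")
    }
    mirnas <- stage("read_mirnas", read_mirna_fasta(cfg$mirna_fasta))
    transcripts <- stage("read_transcripts", {
      tr <- read_fasta(cfg$transcript_fasta)
      tr[, c("id", "seq")]
    })
    genomes <- stage("read_genomes", {
      fa <- read_fasta(cfg$genome_fasta)
      setNames(fa$seq, fa$id)
    })
    design <- if (!is.null(cfg$bulk_yaml)) read_bulk_design(cfg$bulk_yaml)
              else NULL
  }
  if (length(genomes) == 0) stop("pipeline stage 'read_genomes' failed: no templates")

  mirna_primers <- stage("design_mirna", design_mirna_primer(mirnas))
  ssr_loci <- stage("mine_ssr", find_ssrs(transcripts, cfg$thresholds))
  motif_freq <- stage("mine_ssr", motif_frequency(ssr_loci))
  chosen <- stage("select_motifs",
                  select_motifs(motif_freq, k_per_unit = cfg$k_per_unit))
  issr_primers <- stage("design_issr", do.call(rbind, lapply(
    chosen$motif, function(m) {
      design_issr_primer(m, transcripts, anchor_len = cfg$anchor_len,
                         target_len = cfg$target_len,
                         thresholds = cfg$thresholds)
    })))
  primers <- rbind(mirna_primers[, c("name", "kind", "seq")],
                   issr_primers[, c("name", "kind", "seq")])
  pairs_within <- stage("combine", combine_within(mirna_primers))
  pairs_across <- stage("combine", combine_across(mirna_primers, issr_primers))
  pairs <- rbind(pairs_within, pairs_across)
  pairs <- pairs[order(pairs$pair_name), , drop = FALSE]
  rownames(pairs) <- NULL

  amplicons <- stage("epcr", predict_amplicons_batch(
    genomes, pairs, primers, min_len = cfg$min_len, max_len = cfg$max_len,
    max_mismatch = cfg$max_mismatch, seed_len = cfg$seed_len))
  if (nrow(amplicons) == 0) stop("pipeline stage 'epcr' failed: no amplicons")

  bm <- stage("score", amplicons_to_band_matrix(
    amplicons, rel_tol = cfg$rel_tol, samples = sort(names(genomes))))
  if (cfg$dropout > 0) {
    bm <- degrade_bands(bm, cfg$dropout, cfg$seed)
  }

  pic_tab <- stage("stats", pic(bm, mode = cfg$pic_mode))
  poly <- stage("stats", percent_polymorphic(bm))

  sim <- stage("cluster", jaccard_similarity(bm))
  tree <- stage("cluster", upgma(sim))
  nwk <- write_newick(tree)
  clusters <- stage("cluster", cut_clusters(tree, cfg$n_clusters))

  bsa <- NULL
  if (!is.null(design)) {
    bsa <- stage("bsa_select", select_candidate_markers(bm, design))
  }

  transfer <- NULL
  if (!is.null(cfg$species)) {
    species <- lapply(cfg$species, as.character)
    focal <- setdiff(bm$samples, unlist(species))
    # transferability is assessed on the selected candidate markers when
    # BSA ran (the markers actually carried across species), else all pairs
    bm_t <- bm
    if (!is.null(bsa) && nrow(bsa$candidates) > 0) {
      bm_t <- subset_band_matrix(bm, unique(bsa$candidates$pair_name))
    }
    transfer <- stage("stats", transferability(bm_t, focal, species))
  }

  summary <- list(
    n_mirna_primers = nrow(mirna_primers),
    n_issr_primers = nrow(issr_primers),
    n_mirna_pairs = nrow(pairs_within),
    n_mirna_issr_pairs = nrow(pairs_across),
    n_pairs = nrow(pairs),
    n_samples = length(genomes),
    n_ssr_loci = nrow(ssr_loci),
    n_loci = poly$n_loci,
    n_polymorphic_loci = poly$n_polymorphic_loci,
    pct_polymorphic_loci = poly$pct_loci,
    n_polymorphic_pairs = poly$n_polymorphic_pairs,
    pct_polymorphic_pairs = poly$pct_pairs,
    mean_pic = round(mean(pic_tab$pic, na.rm = TRUE), 2),
    n_clusters = cfg$n_clusters,
    n_candidate_markers = if (is.null(bsa)) NA_integer_
                          else nrow(bsa$candidates))

  res <- list(primers = primers, pairs = pairs, ssr_loci = ssr_loci,
              motif_freq = motif_freq, amplicons = amplicons,
              band_matrix = bm, pic = pic_tab, polymorphism = poly,
              similarity = sim, tree = tree, newick = nwk,
              clusters = clusters, bsa = bsa, transferability = transfer,
              summary = summary)

  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(res, cfg$out_dir)
  }
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  w(primer_gc_report(res$primers), "primers.tsv")
  w(res$pairs, "pairs.tsv")
  write_ssr_tsv(res$ssr_loci, file.path(out_dir, "ssr_loci.tsv"))
  w(res$motif_freq, "motif_frequency.tsv")
  write_amplicon_tsv(res$amplicons, file.path(out_dir, "amplicons.tsv"),
                     bed_path = file.path(out_dir, "amplicons.bed"))
  write_band_matrix(res$band_matrix, file.path(out_dir, "band_matrix.tsv"))
  w(res$pic, "pic.tsv")
  write_similarity_tsv(res$similarity, file.path(out_dir, "similarity.tsv"))
  writeLines(res$newick, file.path(out_dir, "dendrogram.nwk"))
  w(data.frame(sample = names(res$clusters), cluster = res$clusters),
    "clusters.tsv")
  if (!is.null(res$bsa)) {
    w(res$bsa$candidates, "candidate_markers.tsv")
  }
  summary <- res$summary
  if (!is.null(res$transferability)) {
    summary$transferability <- as.list(res$transferability)
  }
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}
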