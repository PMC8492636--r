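default_genotypes <- function() {
  c("Badami_Zarand", "Ahmad_Aghaei", "Bayazy", "Sabzpesteh_Nough",
    "Fandoghi_Ghafouri", "Akbari", "Kale_Ghouchi", "Ohadi", "Italian",
    "Harati", "Fandoghi_48", "Khanjari_Ravar", "Cirizi", "Ghazvini",
    "Sarakhs", "Badami_Anar", "Bane", "Kasoor")
}

default_mirnas <- function() {
  data.frame(
    name = c("mir164h", "mir166k", "mir171g", "mir172b",
             "mir393e", "mir399a", "mir482b", "mir827"),
    arm = c("5p", "3p", "5p", "3p", "5p", "3p", "5p", "3p"),
    stringsAsFactors = FALSE)
}

default_issr_motifs <- function() {
  # selected motifs: di TC and AG, tri GAA and CCA, penta GACCA and CTACT;
  # anchors are the flank 2-mers planted in the synthetic transcripts
  data.frame(
    motif = c("TC", "AG", "GAA", "CCA", "GACCA", "CTACT"),
    anchor = c("GA", "CT", "TC", "GT", "TT", "GA"),
    n_transcripts = c(9L, 7L, 8L, 6L, 7L, 5L),
    stringsAsFactors = FALSE)
}

default_discriminative <- function() {
  data.frame(
    primer_a = c("mir171g", "mir166k", "ISSR-TC"),
    primer_b = c("mir393e", "mir172b", "mir399a"),
    product_len = c(988L, 687L, 495L),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic genotype-panel generator
#'
#' The defaults emulate the study conditions of a bulked-sample marker
#' screen in pistachio: 18 samples (16 cultivated genotypes plus two
#' related wild species), eight salt-responsive mature miRNAs (four per
#' precursor arm), six selected SSR motifs (di/tri/penta), two parallel
#' tolerant bulks against one sensitive bulk, and three planted
#' tolerance-linked presence/absence loci whose product lengths (988, 687
#' and 495 bp) match the cloned products of the three selected markers.
#'
#' @param seed Integer seed; identical configurations are byte-identical.
#' @param genotypes Sample ids of the panel.
#' @param groups Named list of genotype groups used for group-structured
#'   neutral variation (latent similarity clusters).
#' @param tolerant_bulks,sensitive_bulks Lists of sample-id vectors, one per
#'   bulk.
#' @param tolerant_carriers Genotypes carrying the planted tolerance-linked
#'   insertions (must include every tolerant-bulk sample and exclude every
#'   sensitive-bulk sample).
#' @param mirnas data.frame `name`, `arm`; mature sequences are generated.
#' @param issr_motifs data.frame `motif`, `anchor`, `n_transcripts`.
#' @param discriminative data.frame `primer_a`, `primer_b`, `product_len`:
#'   the planted bulk-differential loci.
#' @param monomorphic_fraction Fraction of neutral marker loci that are
#'   identical across all genotypes (default 0.3).
#' @param neutral_products Grid of neutral product lengths (bp); spaced
#'   > 2 percent apart so size bins never chain together.
#' @param spacer_len Inter-cassette spacer length (bp); kept above the
#'   in-silico PCR `max_len` so planted loci amplify independently.
#' @param anchor_len,target_len,k_per_unit ISSR design parameters.
#' @param dropout Per-band dropout probability applied by the pipeline
#'   (gel scoring noise); default 0.
#' @param species Sample ids belonging to related species rather than the
#'   focal species (used for transferability reporting).
#' @param nontransferable Named list: species sample id -> pair names whose
#'   loci are absent from that genome (models partial cross-species
#'   transferability).
#' @return list of class `panel_config`.
#' @export
panel_config <- function(seed = 1L,
                         genotypes = default_genotypes(),
                         groups = NULL,
                         tolerant_bulks = list("Ghazvini", "Badami_Anar"),
                         sensitive_bulks = list("Sarakhs"),
                         tolerant_carriers = NULL,
                         mirnas = default_mirnas(),
                         issr_motifs = default_issr_motifs(),
                         discriminative = default_discriminative(),
                         monomorphic_fraction = 0.3,
                         neutral_products = c(240, 300, 380, 560, 720, 900),
                         spacer_len = 3100L,
                         anchor_len = 2L,
                         target_len = 18L,
                         k_per_unit = 2L,
                         dropout = 0,
                         species = intersect(c("Bane", "Kasoor"), genotypes),
                         nontransferable = list(
                           Bane = c("mir171g + mir393e",
                                    "mir166k + mir172b"))) {
  if (is.null(groups)) {
    groups <- if (setequal(genotypes, default_genotypes())) {
      list(I = c("Badami_Zarand", "Ahmad_Aghaei", "Sabzpesteh_Nough",
                 "Fandoghi_Ghafouri", "Akbari", "Kale_Ghouchi", "Ohadi",
                 "Italian", "Fandoghi_48", "Khanjari_Ravar", "Cirizi",
                 "Ghazvini", "Badami_Anar"),
           II = c("Bayazy", "Kasoor"),
           III = c("Harati", "Bane", "Sarakhs"))
    } else {
      list(I = genotypes)
    }
  }
  if (is.null(tolerant_carriers)) {
    tolerant_carriers <- if ("I" %in% names(groups)) groups$I
                         else unlist(tolerant_bulks)
  }
  design <- bulk_design(tolerant_bulks, sensitive_bulks)
  ids <- unlist(c(design$tolerant, design$sensitive))
  if (!all(ids %in% genotypes)) stop("bulk samples must be panel genotypes")
  if (!all(unlist(design$tolerant) %in% tolerant_carriers)) {
    stop("every tolerant-bulk sample must be a tolerant carrier")
  }
  if (any(unlist(design$sensitive) %in% tolerant_carriers)) {
    stop("sensitive-bulk samples cannot be tolerant carriers")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(seed = as.integer(seed), genotypes = genotypes,
                 groups = groups, bulk_design = design,
                 tolerant_carriers = tolerant_carriers, mirnas = mirnas,
                 issr_motifs = issr_motifs, discriminative = discriminative,
                 monomorphic_fraction = monomorphic_fraction,
                 neutral_products = neutral_products,
                 spacer_len = as.integer(spacer_len),
                 anchor_len = as.integer(anchor_len),
                 target_len = as.integer(target_len),
                 k_per_unit = as.integer(k_per_unit),
                 dropout = dropout, species = intersect(species, genotypes),
                 nontransferable = nontransferable[
                   names(nontransferable) %in% genotypes]),
            class = "panel_config")
}

#' Compact demo panel configuration
#'
#' A reduced three-sample panel (two parallel tolerant bulks T1 and T2, one
#' sensitive bulk S) with six miRNAs, one selected SSR motif per unit
#' length, and the three planted bulk-differential loci. Small enough for
#' examples, repeated-simulation studies and quick end-to-end runs.
#'
#' @param seed Integer seed.
#' @param dropout Per-band dropout probability (default 0).
#' @return A [panel_config()].
#' @export
demo_panel_config <- function(seed = 1L, dropout = 0) {
  mirnas <- default_mirnas()
  mirnas <- mirnas[mirnas$name %in% c("mir166k", "mir171g", "mir172b",
                                      "mir393e", "mir399a", "mir827"), ]
  motifs <- default_issr_motifs()
  motifs <- motifs[motifs$motif %in% c("TC", "GAA", "GACCA"), ]
  panel_config(seed = seed,
               genotypes = c("T1", "T2", "S"),
               groups = list(I = c("T1", "T2", "S")),
               tolerant_bulks = list("T1", "T2"),
               sensitive_bulks = list("S"),
               tolerant_carriers = c("T1", "T2"),
               mirnas = mirnas, issr_motifs = motifs,
               k_per_unit = 1L, dropout = dropout,
               species = character(0), nontransferable = list())
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

ssr_repeat_count <- function(unit, thresholds = ssr_thresholds()) {
  thresholds[[as.character(unit)]] + 2L
}

build_transcripts <- function(cfg) {
  rows <- list()
  th <- ssr_thresholds()
  for (i in seq_len(nrow(cfg$issr_motifs))) {
    motif <- cfg$issr_motifs$motif[i]
    anchor <- cfg$issr_motifs$anchor[i]
    u <- nchar(motif)
    reps <- ssr_repeat_count(u, th)
    n_tr <- cfg$issr_motifs$n_transcripts[i]
    n_anchor <- ceiling(0.75 * n_tr)
    # alternate flank: valid (does not extend the repeat) but different
    alt <- setdiff(c("GG", "CC", "TT", "AA", "GT", "CA"), anchor)
    alt <- alt[substr(alt, 1, 1) != substr(motif, 1, 1)][1]
    for (j in seq_len(n_tr)) {
      prefix <- random_dna(60)
      # the base before the tract must not left-extend it
      guard <- setdiff(c("A", "C", "G", "T"), substr(motif, u, u))[1]
      substr(prefix, 60, 60) <- guard
      flank <- if (j <= n_anchor) anchor else alt
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("gene_%s_%02d", motif, j),
        seq = paste0(prefix, strrep(motif, reps), flank, random_dna(120)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a synthetic genotype panel
#'
#' Builds a deterministic panel of genotype genomes carrying planted marker
#' loci, together with the miRNA and transcript inputs needed to re-derive
#' the primers: (1) random mature miRNA sequences for the configured names
#' and arms; (2) synthetic salt-responsive transcripts with planted SSR
#' tracts and designated anchor flanks; (3) per-genotype genomes assembled
#' from independent marker cassettes (forward primer site + insert +
#' reverse-complemented primer site) separated by spacers longer than the
#' PCR product window, so every planted locus amplifies exactly once.
#' Neutral cassettes are monomorphic, group-structured (insert length
#' varies with the latent genotype group, with the tolerant and sensitive
#' groups sharing lengths so no neutral band mimics the bulk contrast) or
#' idiosyncratic (per-genotype lengths, with the experimental tolerant and
#' sensitive bulk genotypes constrained to share a length). Discriminative
#' cassettes exist only in tolerant-carrier genomes and produce the planted
#' bulk-differential bands. Planted coordinates are verified against the
#' assembled genomes before returning.
#'
#' @param cfg A [panel_config()].
#' @return list of class `sim_panel`: `config`, `mirnas`, `transcripts`,
#'   `primers`, `pairs`, `genomes` (named character), `truth` (data.frame of
#'   planted loci per genotype), `bulk_design`, `expected_candidates`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(cfg$seed, {
    # --- miRNAs and their primers -------------------------------------
    mirnas <- cfg$mirnas
    mirnas$seq <- vapply(seq_len(nrow(mirnas)), function(i) random_rna(21),
                         character(1))
    mirnas$precursor_id <- paste0("pre-", mirnas$name)
    mirna_primers <- design_mirna_primer(mirnas)

    # --- transcripts and ISSR primers ---------------------------------
    transcripts <- build_transcripts(cfg)
    loci <- find_ssrs(transcripts)
    freq <- motif_frequency(loci)
    chosen <- select_motifs(freq, k_per_unit = cfg$k_per_unit,
                            units = sort(unique(nchar(cfg$issr_motifs$motif))))
    if (!setequal(chosen$motif, cfg$issr_motifs$motif)) {
      stop("internal: motif selection on synthetic transcripts drifted; got ",
           paste(chosen$motif, collapse = ","))
    }
    issr_primers <- do.call(rbind, lapply(cfg$issr_motifs$motif, function(m) {
      design_issr_primer(m, transcripts, anchor_len = cfg$anchor_len,
                         target_len = cfg$target_len)
    }))
    primers <- rbind(mirna_primers[, c("name", "kind", "seq")],
                     issr_primers[, c("name", "kind", "seq")])

    # --- marker pairs -------------------------------------------------
    pairs <- rbind(combine_within(mirna_primers),
                   combine_across(mirna_primers, issr_primers))
    pairs <- pairs[order(pairs$pair_name), , drop = FALSE]
    rownames(pairs) <- NULL

    # --- cassette plan ------------------------------------------------
    plen <- setNames(nchar(primers$seq), primers$name)
    disc <- cfg$discriminative
    disc$pair_name <- canonical_pair_name(disc$primer_a, disc$primer_b)
    if (!all(disc$pair_name %in% pairs$pair_name)) {
      stop("discriminative pairs must be pairs of the design: ",
           paste(setdiff(disc$pair_name, pairs$pair_name), collapse = ", "))
    }
    genotypes <- cfg$genotypes
    group_of <- setNames(rep(names(cfg$groups),
                             lengths(cfg$groups)), unlist(cfg$groups))
    exp_bulk <- c(unlist(cfg$bulk_design$tolerant)[1],
                  unlist(cfg$bulk_design$sensitive)[1])

    n_pairs <- nrow(pairs)
    type_draw <- runif(n_pairs)
    kind_draw <- runif(n_pairs)
    cassettes <- list()
    for (i in seq_len(n_pairs)) {
      pn <- pairs$pair_name[i]
      grid <- cfg$neutral_products
      d_here <- disc$product_len[disc$pair_name == pn]
      if (length(d_here) > 0) {
        grid <- grid[abs(grid - d_here) / d_here > 0.05]
      }
      type <- if (type_draw[i] < cfg$monomorphic_fraction) "monomorphic"
              else if (kind_draw[i] < 0.5 && length(cfg$groups) > 1) "structured"
              else "idiosyncratic"
      products <- switch(type,
        monomorphic = setNames(rep(sample(grid, 1), length(genotypes)),
                               genotypes),
        structured = {
          two <- sample(grid, 2)
          # groups I and III share a length so no neutral band separates
          # the tolerant bulks from the sensitive bulk
          lens <- setNames(rep(two[1], length(genotypes)), genotypes)
          if ("II" %in% names(cfg$groups)) {
            lens[cfg$groups$II] <- two[2]
          }
          lens
        },
        idiosyncratic = {
          lens <- setNames(sample(grid, length(genotypes), replace = TRUE),
                           genotypes)
          # the experimental tolerant and sensitive bulk genotypes share
          # neutral alleles, isolating the planted tolerance loci
          lens[exp_bulk[2]] <- lens[exp_bulk[1]]
          lens
        })
      cassettes[[length(cassettes) + 1L]] <- list(
        pair_name = pn, fwd = pairs$primer_a[i], rev = pairs$primer_b[i],
        type = type, products = products)
    }
    for (i in seq_len(nrow(disc))) {
      products <- setNames(rep(disc$product_len[i], length(genotypes)),
                           genotypes)
      cassettes[[length(cassettes) + 1L]] <- list(
        pair_name = disc$pair_name[i], fwd = disc$primer_a[i],
        rev = disc$primer_b[i], type = "discriminative",
        products = products, carriers = cfg$tolerant_carriers)
    }

    # --- shared random material ---------------------------------------
    n_slots <- length(cassettes)
    spacers <- vapply(seq_len(n_slots + 1L), function(i)
      random_dna(cfg$spacer_len), character(1))
    inserts <- vapply(seq_len(n_slots), function(i) {
      cs <- cassettes[[i]]
      max_ins <- max(cs$products) - plen[[cs$fwd]] - plen[[cs$rev]]
      if (max_ins < 1) stop("product length too short for primers of ",
                            cs$pair_name)
      random_dna(max_ins)
    }, character(1))
    absent_filler <- random_dna(200)

    # --- assemble genomes ---------------------------------------------
    pseq <- setNames(primers$seq, primers$name)
    prc <- setNames(reverse_complement(primers$seq), primers$name)
    genomes <- setNames(character(length(genotypes)), genotypes)
    tr_g <- tr_pair <- tr_type <- tr_fwd <- tr_rev <- character(0)
    tr_start <- tr_end <- tr_len <- integer(0)
    for (g in genotypes) {
      parts <- character(2L * n_slots + 1L)
      cursor <- 0L
      k <- 1L
      for (slot in seq_len(n_slots)) {
        parts[k] <- spacers[slot]
        cursor <- cursor + cfg$spacer_len
        k <- k + 1L
        cs <- cassettes[[slot]]
        absent <- (cs$type == "discriminative" && !(g %in% cs$carriers)) ||
          (g %in% names(cfg$nontransferable) &&
           cs$pair_name %in% cfg$nontransferable[[g]])
        if (absent) {
          parts[k] <- absent_filler
          cursor <- cursor + nchar(absent_filler)
        } else {
          ins_len <- cs$products[[g]] - plen[[cs$fwd]] - plen[[cs$rev]]
          cass_seq <- paste0(pseq[[cs$fwd]],
                             substr(inserts[slot], 1L, ins_len),
                             prc[[cs$rev]])
          parts[k] <- cass_seq
          tr_g <- c(tr_g, g)
          tr_pair <- c(tr_pair, cs$pair_name)
          tr_type <- c(tr_type, cs$type)
          tr_fwd <- c(tr_fwd, cs$fwd)
          tr_rev <- c(tr_rev, cs$rev)
          tr_start <- c(tr_start, cursor + 1L)
          tr_end <- c(tr_end, cursor + nchar(cass_seq))
          tr_len <- c(tr_len, cs$products[[g]])
          cursor <- cursor + nchar(cass_seq)
        }
        k <- k + 1L
      }
      parts[k] <- spacers[n_slots + 1L]
      genomes[[g]] <- paste(parts, collapse = "")
    }
    truth <- data.frame(genotype = tr_g, pair_name = tr_pair,
                        type = tr_type, fwd_primer = tr_fwd,
                        rev_primer = tr_rev, fwd_start = tr_start,
                        rev_end = tr_end, product_len = tr_len,
                        stringsAsFactors = FALSE)

    # --- verify planted coordinates -----------------------------------
    for (r in seq_len(nrow(truth))) {
      g <- truth$genotype[r]
      f_seq <- primers$seq[primers$name == truth$fwd_primer[r]]
      r_seq <- primers$seq[primers$name == truth$rev_primer[r]]
      span <- truth$rev_end[r] - truth$fwd_start[r] + 1L
      fwd_ok <- substr(genomes[[g]], truth$fwd_start[r],
                       truth$fwd_start[r] + nchar(f_seq) - 1L) == f_seq
      rev_ok <- substr(genomes[[g]], truth$rev_end[r] - nchar(r_seq) + 1L,
                       truth$rev_end[r]) == reverse_complement(r_seq)
      if (!fwd_ok || !rev_ok || span != truth$product_len[r]) {
        stop("planted locus verification failed for ", truth$pair_name[r],
             " in ", g)
      }
    }

    expected <- disc[, c("pair_name", "product_len")]
    expected <- expected[order(expected$pair_name), , drop = FALSE]
    rownames(expected) <- NULL

    structure(list(config = cfg, mirnas = mirnas, transcripts = transcripts,
                   primers = primers, pairs = pairs, genomes = genomes,
                   truth = truth, bulk_design = cfg$bulk_design,
                   expected_candidates = expected),
              class = "sim_panel")
  })
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("sim_panel:", length(x$genomes), "genotypes,",
      nrow(x$primers), "primers,", nrow(x$pairs), "marker pairs,",
      nrow(x$expected_candidates), "planted bulk-differential loci\n")
  invisible(x)
}

#' Write a simulated panel to a directory
#'
#' Writes `mirnas.fasta` (arm-annotated headers), `transcripts.fasta`,
#' `genomes.fasta` (one record per genotype), `truth.tsv` and `bulks.yaml`.
#'
#' @param panel A `sim_panel`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mir <- panel$mirnas
  mir_ids <- sprintf("%s|arm=%s|precursor=%s", mir$name, mir$arm,
                     mir$precursor_id)
  write_fasta(setNames(mir$seq, mir_ids), file.path(dir, "mirnas.fasta"))
  write_fasta(panel$transcripts, file.path(dir, "transcripts.fasta"))
  write_fasta(panel$genomes, file.path(dir, "genomes.fasta"))
  write.table(panel$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bulk_design(panel$bulk_design, file.path(dir, "bulks.yaml"))
  invisible(dir)
}

#' Randomly drop presence calls from a band matrix
#'
#' Models gel scoring noise: each presence call flips to absence
#' independently with probability `dropout`; absences and NAs are
#' untouched. Reproducible under `seed`.
#'
#' @param bm A `band_matrix`.
#' @param dropout Flip probability in \[0, 1).
#' @param seed Integer seed.
#' @return The degraded `band_matrix`.
#' @export
degrade_bands <- function(bm, dropout, seed) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (dropout == 0) return(bm)
  with_seed(seed, {
    ones <- which(!is.na(bm$values) & bm$values == 1)
    flip <- ones[runif(length(ones)) < dropout]
    bm$values[flip] <- 0L
    bm
  })
}
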