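new_primer <- function(name, sequence, kind, source = NA_character_,
                       arm = NA_character_, motif = NA_character_,
                       n_repeat_units = NA_integer_, anchor = NA_character_,
                       anchor_source = NA_character_) {
  sequence <- toupper(sequence)
  if (grepl("N", sequence, fixed = TRUE)) {
    stop("primer '", name, "' contains N; primers must be fully specified")
  }
  sequence <- check_dna(sequence, paste0("primer '", name, "'"))
  if (nchar(sequence) < 15L) {
    stop("primer '", name, "' is shorter than 15 nt (", nchar(sequence), " nt)")
  }
  data.frame(name = name, kind = kind, seq = sequence, source = source,
             arm = arm, motif = motif, n_repeat_units = n_repeat_units,
             anchor = anchor, anchor_source = anchor_source,
             stringsAsFactors = FALSE)
}

#' Design a primer from a mature miRNA
#'
#' The marker primer targets the genomic mature-miRNA site so that two
#' primers amplify the region between neighbouring miRNA loci rather than a
#' single stem-loop. The rule: a mature miRNA originating from the 5' arm of
#' its precursor is converted to the reverse complement (after U->T); a
#' mature miRNA from the 3' arm is used unchanged (U->T only).
#'
#' @param mirna One-row data.frame from [mature_mirna()] (columns `name`,
#'   `seq`, `arm`), or a multi-row data.frame to design several primers.
#' @return data.frame of primers (columns `name`, `kind`, `seq`, `source`,
#'   `arm`, ...), one row per miRNA.
#' @export
design_mirna_primer <- function(mirna) {
  stopifnot(all(c("name", "seq", "arm") %in% names(mirna)))
  rows <- lapply(seq_len(nrow(mirna)), function(i) {
    dna <- rna_to_dna(mirna$seq[i])
    primer_seq <- if (mirna$arm[i] == "5p") reverse_complement(dna) else dna
    new_primer(name = mirna$name[i], sequence = primer_seq, kind = "miRNA",
               source = mirna$name[i], arm = mirna$arm[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design a semi-random anchored ISSR primer
#'
#' Builds a repeat-block primer `motif x n + anchor` where
#' `n = ceiling((target_len - anchor_len) / nchar(motif))` and the anchor is
#' the most frequent `anchor_len`-mer found immediately 3' of maximal tracts
#' of `motif` in the template transcripts ("semi-random": the anchor is
#' data-derived, not arbitrary). Candidate anchors that would extend the
#' repeat (first base equal to the first motif base) are excluded. Ties on
#' flank frequency break to the lexicographically smallest k-mer.
#'
#' @param motif Repeat motif (2-6 nt), must be present among mined motifs of
#'   the templates.
#' @param templates Template transcripts: data.frame with `id`, `seq` or
#'   named character vector.
#' @param anchor_len Anchor length, 1-4 (default 2).
#' @param target_len Approximate primer length (default 18).
#' @param name Primer name (default `"ISSR-<motif>"`).
#' @param thresholds [ssr_thresholds()] used to locate motif tracts.
#' @return One-row primer data.frame.
#' @export
design_issr_primer <- function(motif, templates, anchor_len = 2L,
                               target_len = 18L,
                               name = paste0("ISSR-", motif),
                               thresholds = ssr_thresholds()) {
  motif <- check_dna(motif, "motif")
  if (!anchor_len %in% 1:4) stop("anchor_len must be in 1..4")
  if (is.character(templates)) {
    templates <- data.frame(id = names(templates), seq = unname(templates),
                            stringsAsFactors = FALSE)
  }
  loci <- find_ssrs(templates, thresholds)
  loci <- loci[loci$motif == motif, , drop = FALSE]
  if (nrow(loci) == 0L) {
    stop("motif ", motif, " not found among mined SSR loci of the templates")
  }
  # collect the anchor_len-mer immediately 3' of each tract
  flanks <- character(0)
  hosts <- character(0)
  for (i in seq_len(nrow(loci))) {
    s <- templates$seq[match(loci$sequence_id[i], templates$id)]
    from <- loci$end[i] + 1L
    to <- loci$end[i] + anchor_len
    if (to > nchar(s)) next
    k <- toupper(substr(s, from, to))
    if (grepl("[^ACGT]", k)) next
    flanks <- c(flanks, k)
    hosts <- c(hosts, loci$sequence_id[i])
  }
  # exclude anchors that extend the repeat
  keep <- substr(flanks, 1L, 1L) != substr(motif, 1L, 1L)
  flanks_ok <- flanks[keep]
  if (length(flanks_ok) == 0L) {
    stop("no valid anchor of length ", anchor_len, " for motif ", motif,
         " (all observed flanks extend the repeat); try a longer anchor_len")
  }
  tab <- table(flanks_ok)
  best <- names(tab)[tab == max(tab)]
  anchor <- sort(best)[1]
  n_units <- as.integer(ceiling((target_len - anchor_len) / nchar(motif)))
  seq <- paste0(strrep(motif, n_units), anchor)
  new_primer(name = name, sequence = seq, kind = "ISSR",
             motif = motif, n_repeat_units = n_units, anchor = anchor,
             anchor_source = paste(unique(hosts[keep][flanks_ok == anchor]),
                                   collapse = ";"))
}

canonical_pair_name <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = " + ")
}

make_pairs <- function(a_names, b_names) {
  pn <- canonical_pair_name(a_names, b_names)
  ord <- order(pn)
  data.frame(pair_name = pn[ord],
             primer_a = pmin(a_names, b_names)[ord],
             primer_b = pmax(a_names, b_names)[ord],
             stringsAsFactors = FALSE)
}

#' All unordered pairs of primers from one set
#'
#' Combining n single primers gives n(n-1)/2 marker pairs; pair names are
#' canonical ("nameA + nameB" with names sorted) and the output is sorted by
#' pair name.
#'
#' @param primers Primer data.frame (>= 2 rows, unique names).
#' @return data.frame with columns `pair_name`, `primer_a`, `primer_b`.
#' @export
combine_within <- function(primers) {
  nm <- primers$name
  if (length(nm) < 2L) stop("need at least 2 primers")
  if (anyDuplicated(nm)) stop("duplicate primer names")
  idx <- combn(length(nm), 2L)
  make_pairs(nm[idx[1L, ]], nm[idx[2L, ]])
}

#' Cross pairs between two primer sets
#'
#' Full cross product of two disjoint primer sets (|a| x |b| pairs), with
#' optional seeded subsampling to emulate a random selection of
#' combinations.
#'
#' @param set_a,set_b Primer data.frames with disjoint names.
#' @param subsample Optional number of pairs to keep.
#' @param seed Seed for the subsample draw (required with `subsample`).
#' @return data.frame with columns `pair_name`, `primer_a`, `primer_b`.
#' @export
combine_across <- function(set_a, set_b, subsample = NULL, seed = NULL) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) stop("both sets must be non-empty")
  if (length(intersect(set_a$name, set_b$name)) > 0L) {
    stop("primer sets share names: ",
         paste(intersect(set_a$name, set_b$name), collapse = ", "))
  }
  grid <- expand.grid(a = set_a$name, b = set_b$name,
                      stringsAsFactors = FALSE)
  pairs <- make_pairs(grid$a, grid$b)
  if (!is.null(subsample)) {
    if (is.null(seed)) stop("subsampling requires a seed")
    if (subsample > nrow(pairs)) stop("subsample exceeds number of pairs")
    keep <- with_seed(seed, sample.int(nrow(pairs), subsample))
    pairs <- pairs[sort(keep), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  pairs
}

#' GC content of primer sequences (informational report)
#'
#' @param primers Primer data.frame.
#' @return The input with an extra `gc` column (fraction in 0-1).
#' @export
primer_gc_report <- function(primers) {
  gc <- vapply(primers$seq, function(s) {
    chars <- strsplit(s, "")[[1]]
    mean(chars %in% c("G", "C"))
  }, numeric(1))
  primers$gc <- unname(gc)
  primers
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
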