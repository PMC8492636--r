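count_mismatches <- function(a, b) {
  # a, b equal-length strings; N in the template never matches
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  sum(av != bv | bv == utf8ToInt("N"))
}

mismatch_positions <- function(primer, site) {
  av <- utf8ToInt(primer)
  bv <- utf8ToInt(site)
  which(av != bv | bv == utf8ToInt("N"))
}

#' Find primer binding sites on a template
#'
#' Scans both strands for positions where the primer anneals with at most
#' `max_mismatch` mismatches and a perfectly matching 3'-terminal seed of
#' `seed_len` nucleotides. N in the template never matches. The reported
#' `position` is the 1-based coordinate of the 5'-most template base covered
#' by the primer footprint, on either strand.
#'
#' @param template Template DNA sequence (character scalar).
#' @param primer One-row primer data.frame (columns `name`, `seq`) or a
#'   character scalar primer sequence.
#' @param template_id Identifier recorded in the output.
#' @param max_mismatch Maximum non-seed mismatches (default 0).
#' @param seed_len 3'-terminal bases that must match exactly (default 3).
#' @return data.frame with columns `template_id`, `position`, `strand`,
#'   `mismatches`, `primer_name`. A primer longer than the template yields
#'   zero rows.
#' @export
find_binding_sites <- function(template, primer, template_id = "template",
                               max_mismatch = 0L, seed_len = 3L) {
  if (is.data.frame(primer)) {
    primer_name <- primer$name[1]
    primer_seq <- primer$seq[1]
  } else {
    primer_name <- "primer"
    primer_seq <- primer
  }
  template <- check_dna(template, "template")
  primer_seq <- check_dna(primer_seq, "primer")
  plen <- nchar(primer_seq)
  empty <- data.frame(template_id = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      primer_name = character(), stringsAsFactors = FALSE)
  if (plen > nchar(template)) return(empty)
  subject <- Biostrings::DNAString(template)
  out <- list(empty)

  scan <- function(pattern, strand) {
    hits <- Biostrings::matchPattern(pattern, subject,
                                     max.mismatch = max_mismatch)
    if (length(hits) == 0L) return(NULL)
    starts <- Biostrings::start(hits)
    keep <- logical(length(starts))
    mm <- integer(length(starts))
    for (k in seq_along(starts)) {
      site <- substr(template, starts[k], starts[k] + plen - 1L)
      pos <- mismatch_positions(pattern, site)
      mm[k] <- length(pos)
      seed_idx <- if (strand == "+") (plen - seed_len + 1L):plen
                  else seq_len(seed_len)
      keep[k] <- mm[k] <= max_mismatch && !any(pos %in% seed_idx)
    }
    if (!any(keep)) return(NULL)
    data.frame(template_id = template_id, position = starts[keep],
               strand = strand, mismatches = mm[keep],
               primer_name = primer_name, stringsAsFactors = FALSE)
  }

  plus <- scan(primer_seq, "+")
  minus <- scan(reverse_complement(primer_seq), "-")
  res <- rbind(empty, plus, minus)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict PCR amplicons of a primer pair on a template
#'
#' Enumerates every convergent combination of binding sites: a plus-strand
#' site of either primer of the pair upstream of a minus-strand site of
#' either primer (including two sites of the same primer, i.e. single-primer
#' amplification as seen for stem-loop products), with product length within
#' `[min_len, max_len]`. Products shorter than the summed primer lengths
#' (overlapping footprints) are rejected. Coordinates are 1-based inclusive
#' over the outermost primer bases.
#'
#' @param template Template DNA (character scalar).
#' @param pair One-row data.frame with `primer_a`, `primer_b`, `pair_name`.
#' @param primers Primer data.frame holding the pair's primers.
#' @param template_id Identifier recorded in the output.
#' @param min_len,max_len Product length window (defaults 100-3000 bp).
#' @param max_mismatch,seed_len Passed to [find_binding_sites()].
#' @param sites Optional precomputed site table for this template (as
#'   returned by [find_binding_sites()], rows for both primers); when given,
#'   the template is not rescanned.
#' @return data.frame with columns `template_id`, `pair_name`, `start`,
#'   `end`, `length`, `fwd_primer`, `rev_primer`, `mismatches`, sorted by
#'   start. Zero rows when nothing amplifies.
#' @export
predict_amplicons <- function(template, pair, primers,
                              template_id = "template",
                              min_len = 100L, max_len = 3000L,
                              max_mismatch = 0L, seed_len = 3L,
                              sites = NULL) {
  if (min_len >= max_len) stop("min_len must be < max_len")
  p_names <- unique(c(pair$primer_a[1], pair$primer_b[1]))
  plens <- setNames(nchar(primers$seq), primers$name)
  if (is.null(sites)) {
    sites <- do.call(rbind, lapply(p_names, function(nm) {
      row <- primers[primers$name == nm, , drop = FALSE]
      if (nrow(row) == 0L) stop("primer '", nm, "' not found in primer table")
      find_binding_sites(template, row, template_id = template_id,
                         max_mismatch = max_mismatch, seed_len = seed_len)
    }))
  } else {
    sites <- sites[sites$primer_name %in% p_names, , drop = FALSE]
  }
  empty <- data.frame(template_id = character(), pair_name = character(),
                      start = integer(), end = integer(), length = integer(),
                      fwd_primer = character(), rev_primer = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0L) return(empty)
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty)
  out <- list(empty)
  for (i in seq_len(nrow(plus))) {
    f_len <- plens[[plus$primer_name[i]]]
    for (j in seq_len(nrow(minus))) {
      r_len <- plens[[minus$primer_name[j]]]
      start <- plus$position[i]
      end <- minus$position[j] + r_len - 1L
      len <- end - start + 1L
      if (minus$position[j] < start) next
      if (len < f_len + r_len) next          # overlapping footprints
      if (len < min_len || len > max_len) next
      out[[length(out) + 1L]] <- data.frame(
        template_id = template_id, pair_name = pair$pair_name[1],
        start = start, end = end, length = len,
        fwd_primer = plus$primer_name[i], rev_primer = minus$primer_name[j],
        mismatches = plus$mismatches[i] + minus$mismatches[j],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict amplicons for many pairs over many templates
#'
#' Efficient batch wrapper: each primer is matched against each template
#' once, and the cached sites are reused across all pairs.
#'
#' @param templates Named character vector of template sequences, or a
#'   data.frame with `id` and `seq`.
#' @param pairs Pair table from [combine_within()]/[combine_across()].
#' @param primers Primer data.frame.
#' @inheritParams predict_amplicons
#' @return Combined amplicon data.frame (possibly zero rows).
#' @export
predict_amplicons_batch <- function(templates, pairs, primers,
                                    min_len = 100L, max_len = 3000L,
                                    max_mismatch = 0L, seed_len = 3L) {
  if (is.data.frame(templates)) {
    templates <- setNames(templates$seq, templates$id)
  }
  if (length(templates) == 0L) stop("no templates supplied")
  used <- unique(c(pairs$primer_a, pairs$primer_b))
  out <- list()
  for (tid in names(templates)) {
    sites <- do.call(rbind, lapply(used, function(nm) {
      row <- primers[primers$name == nm, , drop = FALSE]
      find_binding_sites(templates[[tid]], row, template_id = tid,
                         max_mismatch = max_mismatch, seed_len = seed_len)
    }))
    for (i in seq_len(nrow(pairs))) {
      out[[length(out) + 1L]] <- predict_amplicons(
        templates[[tid]], pairs[i, , drop = FALSE], primers,
        template_id = tid, min_len = min_len, max_len = max_len,
        max_mismatch = max_mismatch, seed_len = seed_len, sites = sites)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- predict_amplicons("ACGT", pairs[0, ], primers)
  rownames(res) <- NULL
  res
}

#' Extract the sequence of a predicted amplicon
#'
#' @param template Template DNA the amplicon was predicted on.
#' @param amplicon One-row amplicon data.frame (`start`, `end`).
#' @return Character scalar, the amplified product sequence.
#' @export
amplicon_sequence <- function(template, amplicon) {
  substr(template, amplicon$start[1], amplicon$end[1])
}

#' Write amplicons as TSV and optional BED
#'
#' The BED export converts the 1-based inclusive amplicon coordinates to
#' 0-based half-open intervals.
#'
#' @param amplicons Amplicon data.frame.
#' @param path TSV output path.
#' @param bed_path Optional BED output path.
#' @return Invisibly, `path`.
#' @export
write_amplicon_tsv <- function(amplicons, path, bed_path = NULL) {
  write.table(amplicons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = amplicons$template_id,
                      chromStart = amplicons$start - 1L,
                      chromEnd = amplicons$end,
                      name = amplicons$pair_name)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
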