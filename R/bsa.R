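#' Bulk design for bulked-sample marker selection
#'
#' Describes the phenotypic-extreme contrast: one or more tolerant bulks
#' (pooled samples from the tolerant tail; using two parallel tolerant
#' bulks increases power and reduces false positives) against one or more
#' sensitive bulks. All groups must be disjoint.
#'
#' @param tolerant List of character vectors (or a single character vector)
#'   of sample ids, one element per tolerant bulk.
#' @param sensitive Same, for sensitive bulks.
#' @return list of class `bulk_design` with components `tolerant`,
#'   `sensitive`.
#' @export
bulk_design <- function(tolerant, sensitive) {
  as_groups <- function(x) {
    if (is.character(x)) x <- as.list(x)
    lapply(x, as.character)
  }
  tolerant <- as_groups(tolerant)
  sensitive <- as_groups(sensitive)
  if (length(tolerant) < 1 || length(sensitive) < 1) {
    stop("need at least one tolerant and one sensitive bulk")
  }
  ids <- unlist(c(tolerant, sensitive))
  if (anyDuplicated(ids)) {
    stop("bulk groups must be disjoint; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(tolerant = tolerant, sensitive = sensitive),
            class = "bulk_design")
}

#' Read/write a bulk design as YAML
#'
#' The YAML file has top-level keys `tolerant` and `sensitive`, each a list
#' of sample-id lists.
#'
#' @param path YAML path.
#' @return For `read_bulk_design`, a `bulk_design`.
#' @export
read_bulk_design <- function(path) {
  y <- yaml::read_yaml(path)
  bulk_design(y$tolerant, y$sensitive)
}

#' @rdname read_bulk_design
#' @param design A `bulk_design` to write.
#' @export
write_bulk_design <- function(design, path) {
  yaml::write_yaml(list(tolerant = design$tolerant,
                        sensitive = design$sensitive), path)
  invisible(path)
}

#' Select candidate trait-linked markers by bulk contrast
#'
#' A band is a candidate when it is present in every tolerant bulk and
#' absent from every sensitive bulk — the common-band rule for linking a
#' presence/absence locus to the contrasted trait. A bulk of several
#' samples presents a band when at least one member carries it (pooled-DNA
#' semantics) and lacks it only when every member lacks it. Bands with NA
#' (reaction failure) in any bulk sample are disqualified and reported
#' separately.
#'
#' @param bm A `band_matrix`.
#' @param design A [bulk_design()].
#' @return list with `candidates` (data.frame `pair_name`, `bin_id`, `size`,
#'   sorted by pair then size) and `unresolved` (same columns; bands
#'   disqualified by NA).
#' @export
select_candidate_markers <- function(bm, design) {
  stopifnot(inherits(design, "bulk_design"))
  ids <- unlist(c(design$tolerant, design$sensitive))
  missing <- setdiff(ids, bm$samples)
  if (length(missing) > 0) {
    stop("bulk samples not in matrix: ", paste(missing, collapse = ", "))
  }
  n_bands <- nrow(bm$bands)
  selected <- logical(n_bands)
  unresolved <- logical(n_bands)
  for (r in seq_len(n_bands)) {
    vals <- bm$values[r, , drop = TRUE]
    block <- vals[ids]
    if (anyNA(block)) {
      unresolved[r] <- TRUE
      next
    }
    tol_ok <- all(vapply(design$tolerant,
                         function(g) any(vals[g] == 1), logical(1)))
    sens_ok <- all(vapply(design$sensitive,
                          function(g) all(vals[g] == 0), logical(1)))
    selected[r] <- tol_ok && sens_ok
  }
  fmt <- function(keep) {
    out <- bm$bands[keep, , drop = FALSE]
    out <- out[order(out$pair_name, out$size), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(candidates = fmt(selected), unresolved = fmt(unresolved))
}

#' Verify a cloned PCR product against its primer pair
#'
#' Checks that a (cloned and sequenced) product carries its two primer
#' sites at its termini: the forward primer as an exact plus-strand site at
#' position 1 and the reverse primer as an exact minus-strand site ending at
#' the last base, with 0 mismatches.
#'
#' @param clone_seq Product DNA sequence.
#' @param pair One-row pair data.frame (`primer_a`, `primer_b`,
#'   `pair_name`).
#' @param primers Primer table holding the pair's primers.
#' @return list with `length` (bp), `ok` (logical), `fwd_primer`,
#'   `rev_primer` (primer names found at the 5' and 3' ends, NA when
#'   absent).
#' @export
verify_clone <- function(clone_seq, pair, primers) {
  clone_seq <- check_dna(clone_seq, "clone sequence")
  p_names <- unique(c(pair$primer_a[1], pair$primer_b[1]))
  len <- nchar(clone_seq)
  fwd <- NA_character_
  rev <- NA_character_
  for (nm in p_names) {
    pseq <- primers$seq[primers$name == nm]
    if (length(pseq) != 1) stop("primer '", nm, "' not found")
    if (substr(clone_seq, 1, nchar(pseq)) == pseq) fwd <- nm
    rc <- reverse_complement(pseq)
    if (substr(clone_seq, len - nchar(pseq) + 1, len) == rc) rev <- nm
  }
  list(length = len, ok = !is.na(fwd) && !is.na(rev),
       fwd_primer = fwd, rev_primer = rev)
}
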