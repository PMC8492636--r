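pair_rows <- function(bm) {
  split(seq_len(nrow(bm$bands)), bm$bands$pair_name)
}

#' Polymorphism information content per primer pair
#'
#' PIC = 1 - sum(p_i^2) over allele frequencies p_i. In the default
#' `multiallelic` mode each distinct band (size bin) of a primer pair is one
#' allele class and p_i is that band's share of all presence calls of the
#' pair — treating the pair's banding pattern as one multi-allelic locus,
#' which is how pair-level PIC values above the 0.5 dominant-marker ceiling
#' arise. In `dominant` mode each band is scored as a biallelic dominant
#' locus (p = presence frequency among non-NA samples,
#' PIC_band = 1 - p^2 - (1-p)^2) and the pair value is the mean over its
#' bands. NA samples (reaction failures) are excluded from all frequencies.
#'
#' @param bm A `band_matrix`.
#' @param mode "multiallelic" (default) or "dominant".
#' @return data.frame with columns `pair_name`, `pic`, `n_bands`, `mode`.
#'   A pair with zero presence calls gets `pic = NA` with a warning.
#' @export
pic <- function(bm, mode = c("multiallelic", "dominant")) {
  mode <- match.arg(mode)
  groups <- pair_rows(bm)
  res <- lapply(names(groups), function(pn) {
    rows <- groups[[pn]]
    vals <- bm$values[rows, , drop = FALSE]
    ok_samples <- colSums(is.na(vals)) == 0
    if (sum(ok_samples) < 2) {
      stop("pair '", pn, "' has fewer than 2 samples with non-NA data")
    }
    vals <- vals[, ok_samples, drop = FALSE]
    value <- if (mode == "multiallelic") {
      counts <- rowSums(vals == 1)
      total <- sum(counts)
      if (total == 0) {
        warning("pair '", pn, "' has zero presence calls; PIC undefined")
        NA_real_
      } else {
        p <- counts / total
        1 - sum(p^2)
      }
    } else {
      p <- rowMeans(vals == 1)
      mean(1 - p^2 - (1 - p)^2)
    }
    data.frame(pair_name = pn, pic = value, n_bands = length(rows),
               mode = mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Percent polymorphic loci and primer pairs
#'
#' A band (locus) is polymorphic when it is present in at least one and
#' absent in at least one non-NA sample; a primer pair is polymorphic when
#' at least one of its bands is. Percentages are reported rounded to one
#' decimal.
#'
#' @param bm A `band_matrix`.
#' @return list with `band_polymorphic` (logical per band),
#'   `pair_polymorphic` (named logical per pair), `n_loci`,
#'   `n_polymorphic_loci`, `pct_loci`, `n_pairs`, `n_polymorphic_pairs`,
#'   `pct_pairs`.
#' @export
percent_polymorphic <- function(bm) {
  if (nrow(bm$bands) == 0) stop("empty band matrix")
  band_poly <- apply(bm$values, 1, function(v) {
    v <- v[!is.na(v)]
    any(v == 1) && any(v == 0)
  })
  groups <- pair_rows(bm)
  pair_poly <- vapply(groups, function(rows) any(band_poly[rows]), logical(1))
  list(band_polymorphic = band_poly,
       pair_polymorphic = pair_poly,
       n_loci = length(band_poly),
       n_polymorphic_loci = sum(band_poly),
       pct_loci = round(100 * mean(band_poly), 1),
       n_pairs = length(pair_poly),
       n_polymorphic_pairs = sum(pair_poly),
       pct_pairs = round(100 * mean(pair_poly), 1))
}

#' Cross-species transferability of markers
#'
#' For each related-species sample group: 100 x (number of primer pairs
#' yielding at least one band in that species, among pairs that amplify in
#' the focal samples) / (number of pairs yielding at least one band in the
#' focal samples), rounded to the nearest integer.
#'
#' @param bm A `band_matrix`.
#' @param focal_samples Sample ids of the focal species.
#' @param species Named list of character vectors: sample ids per related
#'   species.
#' @return Named numeric vector of transferability percentages.
#' @export
transferability <- function(bm, focal_samples, species) {
  all_ids <- c(focal_samples, unlist(species))
  missing <- setdiff(all_ids, bm$samples)
  if (length(missing) > 0) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  }
  groups <- pair_rows(bm)
  amplifies <- function(rows, ids) {
    v <- bm$values[rows, ids, drop = FALSE]
    any(v == 1, na.rm = TRUE)
  }
  focal_ok <- vapply(groups, amplifies, logical(1), ids = focal_samples)
  if (!any(focal_ok)) stop("no primer pair amplifies in the focal samples")
  vapply(species, function(ids) {
    hit <- vapply(groups[focal_ok], amplifies, logical(1), ids = ids)
    round(100 * sum(hit) / sum(focal_ok))
  }, numeric(1))
}

#' Summarise a set of pair-level PIC values
#'
#' Reporting convention: mean PIC rounded to two decimals, range, and the
#' percentage of values above 0.5 rounded to one decimal.
#'
#' @param values Numeric vector of PIC values (NA dropped).
#' @return list with `n`, `mean`, `min`, `max`, `pct_above_0.5`.
#' @export
pic_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no PIC values")
  list(n = length(values),
       mean = round(mean(values), 2),
       min = min(values),
       max = max(values),
       pct_above_0.5 = round(100 * mean(values > 0.5), 1))
}
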