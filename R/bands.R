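#' Bin observed band sizes into a binary band matrix
#'
#' Gel-estimated product sizes are approximate, so sizes of one primer pair
#' are clustered by single linkage: two sizes fall in the same bin when they
#' are within `rel_tol` (relative to the smaller size) of each other,
#' directly or through a chain. Each bin becomes one scored band (locus)
#' with the median member size as its representative. Whole-reaction
#' failures (a primer pair that did not amplify at all in a sample, as
#' opposed to a genuinely absent band) are recorded as NA for every band of
#' that pair in that sample.
#'
#' @param observations data.frame with columns `pair_name`, `sample`,
#'   `size` (bp, positive).
#' @param rel_tol Relative size tolerance for binning (default 0.02).
#' @param samples Optional character vector fixing the sample universe and
#'   column order; defaults to the samples seen in `observations` and
#'   `failures`.
#' @param failures Optional data.frame with columns `pair_name`, `sample`
#'   marking whole-pair amplification failures.
#' @return A `band_matrix`: list with `values` (bands x samples matrix over
#'   1/0/NA), `bands` (data.frame `pair_name`, `bin_id`, `size`), `samples`.
#' @export
bin_bands <- function(observations, rel_tol = 0.02, samples = NULL,
                      failures = NULL) {
  if (rel_tol <= 0) stop("rel_tol must be positive")
  stopifnot(all(c("pair_name", "sample", "size") %in% names(observations)))
  if (nrow(observations) > 0 && any(observations$size <= 0)) {
    stop("band sizes must be positive")
  }
  if (is.null(samples)) {
    samples <- sort(unique(c(observations$sample, failures$sample)))
  }
  band_rows <- list()
  values <- list()
  for (pn in sort(unique(observations$pair_name))) {
    obs <- observations[observations$pair_name == pn, , drop = FALSE]
    sizes <- sort(unique(obs$size))
    gaps <- diff(sizes) / sizes[-length(sizes)]
    bin_of_size <- setNames(cumsum(c(1, gaps > rel_tol)), sizes)
    obs$bin <- bin_of_size[as.character(obs$size)]
    for (b in sort(unique(obs$bin))) {
      members <- obs[obs$bin == b, , drop = FALSE]
      rep_size <- median(members$size)
      row <- as.integer(samples %in% members$sample)
      band_rows[[length(band_rows) + 1L]] <- data.frame(
        pair_name = pn, bin_id = b, size = rep_size,
        stringsAsFactors = FALSE)
      values[[length(values) + 1L]] <- row
    }
  }
  bands <- if (length(band_rows) > 0) do.call(rbind, band_rows) else
    data.frame(pair_name = character(), bin_id = integer(),
               size = numeric(), stringsAsFactors = FALSE)
  mat <- if (length(values) > 0) do.call(rbind, values) else
    matrix(integer(0), nrow = 0, ncol = length(samples))
  colnames(mat) <- samples
  rownames(mat) <- band_label(bands)
  if (!is.null(failures) && nrow(failures) > 0) {
    for (i in seq_len(nrow(failures))) {
      rows <- bands$pair_name == failures$pair_name[i]
      col <- match(failures$sample[i], samples)
      if (is.na(col)) stop("failure sample '", failures$sample[i],
                           "' not in sample universe")
      mat[rows, col] <- NA_integer_
    }
  }
  structure(list(values = mat, bands = bands, samples = samples),
            class = "band_matrix")
}

band_label <- function(bands) {
  if (nrow(bands) == 0) return(character(0))
  paste(bands$pair_name, bands$bin_id, bands$size, sep = ":")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat("band_matrix: ", nrow(x$bands), " bands (loci) x ",
      length(x$samples), " samples, ",
      length(unique(x$bands$pair_name)), " primer pairs\n", sep = "")
  invisible(x)
}

#' Write a band matrix as TSV
#'
#' Rows are bands labelled `pair_name:bin_id:size`, columns samples, cells
#' 1/0/NA.
#'
#' @param bm A `band_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_band_matrix <- function(bm, path) {
  df <- data.frame(band = rownames(bm$values), bm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a band matrix written by [write_band_matrix()]
#'
#' @param path TSV path.
#' @return A `band_matrix`.
#' @export
read_band_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df$band
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- labels
  parts <- strsplit(labels, ":", fixed = TRUE)
  bands <- data.frame(
    pair_name = vapply(parts, function(p) paste(head(p, -2), collapse = ":"),
                       character(1)),
    bin_id = as.integer(vapply(parts, function(p) p[length(p) - 1L],
                               character(1))),
    size = as.numeric(vapply(parts, function(p) p[length(p)], character(1))),
    stringsAsFactors = FALSE)
  structure(list(values = mat, bands = bands, samples = colnames(mat)),
            class = "band_matrix")
}

#' Restrict a band matrix to a set of primer pairs
#'
#' @param bm A `band_matrix`.
#' @param pair_names Pair names to keep.
#' @return A `band_matrix` with only the bands of the named pairs.
#' @export
subset_band_matrix <- function(bm, pair_names) {
  keep <- bm$bands$pair_name %in% pair_names
  if (!any(keep)) stop("no bands for the requested pairs")
  structure(list(values = bm$values[keep, , drop = FALSE],
                 bands = bm$bands[keep, , drop = FALSE],
                 samples = bm$samples),
            class = "band_matrix")
}

#' Band matrix from predicted amplicons
#'
#' Convenience bridge from in-silico PCR output to the scoring statistics:
#' each amplicon contributes one observation (pair, template/sample,
#' length).
#'
#' @param amplicons Amplicon data.frame from [predict_amplicons_batch()].
#' @param rel_tol,samples,failures Passed to [bin_bands()].
#' @return A `band_matrix`.
#' @export
amplicons_to_band_matrix <- function(amplicons, rel_tol = 0.02,
                                     samples = NULL, failures = NULL) {
  obs <- data.frame(pair_name = amplicons$pair_name,
                    sample = amplicons$template_id,
                    size = amplicons$length, stringsAsFactors = FALSE)
  bin_bands(obs, rel_tol = rel_tol, samples = samples, failures = failures)
}
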