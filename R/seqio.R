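DNA_CHARS <- c("A", "C", "G", "T", "N")
RNA_CHARS <- c("A", "C", "G", "U", "N")

#' Read a multi-record FASTA file
#'
#' Reads DNA or RNA FASTA (wrapped or unwrapped lines). Residues are stored
#' uppercase; the alphabet of each record is auto-detected (a record is
#' flagged RNA when it contains U and no T, DNA otherwise). Record ids must
#' be unique; illegal residues are reported with record name and position.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `seq`, `alphabet` ("DNA" or
#'   "RNA") and `desc` (text after the first whitespace in the header, or
#'   `NA`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in ", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header (empty id) at record ", which(!nzchar(ids))[1])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  alphabet <- character(length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (length(chars) == 0L) {
      stop("empty sequence for record '", ids[i], "'")
    }
    bad <- which(!chars %in% union(DNA_CHARS, RNA_CHARS))
    if (length(bad) > 0L) {
      stop("illegal residue '", chars[bad[1]], "' in record '", ids[i],
           "' at position ", bad[1])
    }
    has_t <- "T" %in% chars
    has_u <- "U" %in% chars
    if (has_t && has_u) {
      stop("record '", ids[i], "' mixes T and U residues")
    }
    alphabet[i] <- if (has_u) "RNA" else "DNA"
  }
  data.frame(id = ids, seq = unname(seqs), alphabet = alphabet, desc = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x A data.frame with columns `id` and `seq` (optionally `desc`), or
#'   a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- data.frame(id = names(x), seq = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    header <- x$id[i]
    if (!is.null(x$desc) && !is.na(x$desc[i]) && nzchar(x$desc[i])) {
      header <- paste(header, x$desc[i])
    }
    writeLines(paste0(">", header), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " contains non-DNA characters: ",
         paste(unique(unlist(strsplit(gsub("[ACGTN]", "", x[bad]), ""))),
               collapse = ", "))
  }
  x
}

#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick complement of the reversed string; N maps to N.
#' Vectorised over `x`.
#'
#' @param x Character vector of DNA sequences (U must already be converted).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  x <- check_dna(x, "reverse_complement() input")
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Convert RNA residues to DNA
#'
#' Replaces every U with T; other residues are unchanged. Accepts sequences
#' already in DNA alphabet (identity).
#'
#' @param x Character vector of RNA or DNA sequences.
#' @return Character vector in DNA alphabet.
#' @export
rna_to_dna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTUN]", x)
  if (any(bad)) {
    stop("rna_to_dna() input contains illegal characters")
  }
  if (any(grepl("T", x) & grepl("U", x))) {
    stop("sequence mixes T and U residues")
  }
  chartr("U", "T", x)
}

#' Construct a validated mature miRNA record
#'
#' A mature miRNA is the ~18-24 nt product excised from one arm of a
#' pre-miRNA hairpin; the arm of origin ("5p" or "3p") determines the primer
#' design rule. Sequences shorter than 15 nt are rejected; 15-17 nt raises a
#' warning (unusually short for a mature miRNA).
#'
#' @param name miRNA name, e.g. "mir171g".
#' @param sequence RNA or DNA residues.
#' @param arm Arm of origin: "5p" or "3p".
#' @param precursor_id Optional precursor identifier.
#' @return One-row data.frame with columns `name`, `seq`, `arm`,
#'   `precursor_id`.
#' @export
mature_mirna <- function(name, sequence, arm, precursor_id = NA_character_) {
  stopifnot(is.character(name), nzchar(name))
  arm <- match.arg(arm, c("5p", "3p"))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTUN]", sequence)) {
    stop("mature miRNA '", name, "' has illegal residues")
  }
  if (nchar(sequence) < 15L) {
    stop("mature miRNA '", name, "' is shorter than 15 nt (",
         nchar(sequence), " nt); rejected")
  }
  if (nchar(sequence) < 18L) {
    warning("mature miRNA '", name, "' is shorter than 18 nt (",
            nchar(sequence), " nt)")
  }
  data.frame(name = name, seq = sequence, arm = arm,
             precursor_id = precursor_id, stringsAsFactors = FALSE)
}

#' Read mature miRNAs from FASTA with arm-annotated headers
#'
#' Headers follow the dialect `>name|arm=5p` or `>name|arm=3p`, optionally
#' with `|precursor=<id>` and a free-text description after whitespace.
#'
#' @param path FASTA path.
#' @return data.frame with columns `name`, `seq`, `arm`, `precursor_id`.
#' @export
read_mirna_fasta <- function(path) {
  fa <- read_fasta(path)
  recs <- vector("list", nrow(fa))
  for (i in seq_len(nrow(fa))) {
    fields <- strsplit(fa$id[i], "|", fixed = TRUE)[[1]]
    name <- fields[1]
    arm <- sub("^arm=", "", grep("^arm=", fields, value = TRUE))
    if (length(arm) != 1L || !arm %in% c("5p", "3p")) {
      stop("record '", name, "': header must carry |arm=5p or |arm=3p")
    }
    prec <- sub("^precursor=", "", grep("^precursor=", fields, value = TRUE))
    if (length(prec) == 0L) prec <- NA_character_
    recs[[i]] <- mature_mirna(name, fa$seq[i], arm, prec)
  }
  out <- do.call(rbind, recs)
  if (anyDuplicated(out$name)) {
    stop("duplicate miRNA names in ", path)
  }
  out
}
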