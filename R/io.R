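AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                 "S","T","V","W","Y")

VARIANT_SIGNIFICANCE <- c("pathogenic", "likely_pathogenic", "benign",
                          "likely_benign", "other")

#' Protein entry table
#'
#' Builds the canonical-sequence table the validators work against: one row
#' per protein with its UniProt-style identifier, canonical amino-acid
#' sequence, family membership and (optionally) organism.
#'
#' @param uid Character vector of protein identifiers (unique).
#' @param sequence Character vector of canonical sequences (20 standard
#'   residues plus `X`).
#' @param family_id Character vector of family identifiers.
#' @param organism Optional character vector.
#' @return A `data.frame` with class `protein_entries`.
#' @export
protein_entries <- function(uid, sequence, family_id, organism = NA_character_) {
  if (length(family_id) == 1) family_id <- rep(family_id, length(uid))
  stopifnot(length(uid) == length(sequence), length(uid) == length(family_id))
  if (anyDuplicated(uid)) {
    stop("protein uids must be unique within a dataset")
  }
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("empty canonical sequence")
  bad <- grepl(paste0("[^", paste(c(AA_STANDARD, "X"), collapse = ""), "]"),
               sequence)
  if (any(bad)) {
    stop("sequence alphabet restricted to the 20 standard residues plus X: ",
         paste(uid[bad], collapse = ", "))
  }
  out <- data.frame(uid = as.character(uid), sequence = sequence,
                    family_id = as.character(family_id),
                    organism = organism, stringsAsFactors = FALSE)
  class(out) <- c("protein_entries", "data.frame")
  out
}

#' Read a family multiple sequence alignment
#'
#' Reads an aligned multi-FASTA (gap character `-`) into a family alignment
#' object. All rows must have identical width and the file must contain at
#' least two records; record order is preserved.
#'
#' @param path Path to an aligned FASTA file.
#' @param family_id Family identifier; defaults to the file name without
#'   extension.
#' @return A `family_alignment`: list with `family_id`, `uid`, `aln` (gapped
#'   rows, upper case) and `n_columns`.
#' @export
read_alignment <- function(path, family_id = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 2) {
    stop("family-too-small: alignment must contain at least 2 records")
  }
  w <- Biostrings::width(aa)
  if (length(unique(w)) != 1) {
    stop("format error: alignment rows differ in length")
  }
  if (is.null(family_id)) {
    family_id <- sub("\\.[^.]*$", "", basename(path))
  }
  family_alignment(family_id,
                   uid = sub("\\s.*$", "", names(aa)),
                   aln = toupper(as.character(aa)))
}

#' Construct a family alignment from gapped rows
#'
#' @param family_id Family identifier.
#' @param uid Member identifiers, in alignment order.
#' @param aln Gapped sequences (equal length, `-` gaps).
#' @return A `family_alignment` object.
#' @export
family_alignment <- function(family_id, uid, aln) {
  stopifnot(length(uid) == length(aln), length(uid) >= 2)
  aln <- toupper(as.character(aln))
  w <- unique(nchar(aln))
  if (length(w) != 1) stop("format error: alignment rows differ in length")
  structure(list(family_id = as.character(family_id),
                 uid = as.character(uid),
                 aln = unname(aln),
                 n_columns = w),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("family_alignment '%s': %d members x %d columns\n",
              x$family_id, length(x$uid), x$n_columns))
  invisible(x)
}

#' Ungapped (canonical) sequences of a family alignment
#'
#' @param alignment A `family_alignment`.
#' @return Named character vector of ungapped member sequences.
#' @export
ungap_alignment <- function(alignment) {
  stats::setNames(gsub("-", "", alignment$aln, fixed = TRUE), alignment$uid)
}

#' Write a family alignment as aligned FASTA
#'
#' @param alignment A `family_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(alignment$aln, alignment$uid))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# column index of each ungapped residue for one gapped row
residue_columns <- function(gapped_row) {
  which(strsplit(gapped_row, "", fixed = TRUE)[[1]] != "-")
}

#' Read a PTM observation table
#'
#' Tab-separated with header columns `uid`, `position`, `residue`,
#' `ptm_type`, `known_function`, `source_count` and optionally `putative`.
#' Putative rows are dropped. When a `protein_entries` table is supplied,
#' each row is validated against the canonical sequence; rows whose residue
#' disagrees with the canonical sequence (or whose position is out of range)
#' are rejected with a per-row reason.
#'
#' @param path Path to the TSV.
#' @param proteins Optional `protein_entries` for validation.
#' @return List with `ptms` (accepted rows) and `rejected` (rows + `reason`).
#' @export
read_ptm_table <- function(path, proteins = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty PTM table: ", path)
    return(list(ptms = empty_ptm_table(), rejected = empty_ptm_table(reason = TRUE)))
  }
  need <- c("uid", "position", "residue", "ptm_type", "known_function",
            "source_count")
  if (!all(need %in% names(df))) {
    stop("format error: PTM table must have columns ",
         paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos)) stop("format error: malformed position column")
  df$position <- pos
  df$known_function <- as.logical(df$known_function)
  df$source_count <- as.integer(df$source_count)
  df$residue <- toupper(df$residue)
  # unknown-function observations carry no usable source count
  df$source_count[!df$known_function] <- 0L
  if ("putative" %in% names(df)) {
    df <- df[!as.logical(df$putative), , drop = FALSE]
    df$putative <- NULL
  }
  validate_ptms(df, proteins)
}

validate_ptms <- function(df, proteins = NULL) {
  reason <- rep(NA_character_, nrow(df))
  if (!is.null(proteins)) {
    idx <- match(df$uid, proteins$uid)
    reason[is.na(idx)] <- "unknown uid"
    seqs <- proteins$sequence[idx]
    ok <- !is.na(idx)
    inb <- ok & df$position >= 1 & df$position <= nchar(seqs)
    reason[ok & !inb] <- "position out of range"
    at <- rep(NA_character_, nrow(df))
    at[inb] <- substr(seqs[inb], df$position[inb], df$position[inb])
    mism <- inb & at != df$residue
    reason[mism] <- "residue mismatch with canonical sequence"
  }
  keep <- is.na(reason)
  rejected <- df[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(ptms = df[keep, , drop = FALSE], rejected = rejected)
}

empty_ptm_table <- function(reason = FALSE) {
  out <- data.frame(uid = character(), position = integer(),
                    residue = character(), ptm_type = character(),
                    known_function = logical(), source_count = integer(),
                    stringsAsFactors = FALSE)
  if (reason) out$reason <- character()
  out
}

#' Write a PTM observation table
#' @param ptms PTM data.frame as returned in `read_ptm_table()$ptms`.
#' @param path Output path.
#' @export
write_ptm_table <- function(ptms, path) {
  utils::write.table(ptms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue disorder tendencies
#'
#' TSV with columns `uid`, `position`, `tendency` (values in `[0, 1]`;
#' tendency above 0.5 means the residue is predicted disordered).
#'
#' @param path Path to the TSV.
#' @return data.frame `uid`, `position`, `tendency`.
#' @export
read_disorder_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("uid", "position", "tendency")
  if (!all(need %in% names(df))) {
    stop("format error: disorder table must have columns ",
         paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df$tendency <- as.numeric(df$tendency)
  if (any(df$tendency < 0 | df$tendency > 1, na.rm = TRUE)) {
    stop("disorder tendencies must lie in [0, 1]")
  }
  df[need]
}

#' Write a disorder-tendency table
#' @param disorder data.frame `uid`, `position`, `tendency`.
#' @param path Output path.
#' @export
write_disorder_table <- function(disorder, path) {
  utils::write.table(disorder, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a missense-variant table
#'
#' TSV with columns `uid`, `position`, `ref_aa`, `alt_aa`, `significance`.
#' Significance values outside the controlled vocabulary
#' (pathogenic / likely_pathogenic / benign / likely_benign) are coerced to
#' `"other"`. Rows where the reference equals the alternate residue are
#' rejected.
#'
#' @param path Path to the TSV.
#' @param proteins Optional `protein_entries` for position validation.
#' @return List with `variants` and `rejected` data.frames.
#' @export
read_variant_table <- function(path, proteins = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("uid", "position", "ref_aa", "alt_aa", "significance")
  if (!all(need %in% names(df))) {
    stop("format error: variant table must have columns ",
         paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df$ref_aa <- toupper(df$ref_aa)
  df$alt_aa <- toupper(df$alt_aa)
  df$significance <- tolower(df$significance)
  df$significance[!df$significance %in% VARIANT_SIGNIFICANCE] <- "other"
  reason <- rep(NA_character_, nrow(df))
  reason[df$ref_aa == df$alt_aa] <- "ref equals alt"
  if (!is.null(proteins)) {
    idx <- match(df$uid, proteins$uid)
    bad <- is.na(idx) & is.na(reason)
    reason[bad] <- "unknown uid"
    ok <- !is.na(idx) & is.na(reason)
    oob <- ok & (df$position < 1 | df$position > nchar(proteins$sequence[idx]))
    reason[oob] <- "position out of range"
  }
  keep <- is.na(reason)
  rejected <- df[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(variants = df[keep, need, drop = FALSE], rejected = rejected)
}

#' Write a variant table
#' @param variants data.frame as returned in `read_variant_table()$variants`.
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
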