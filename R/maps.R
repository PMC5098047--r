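# MAP construction: projecting per-protein PTM observations onto family
# alignment columns and deriving the alignment-side features and labels.

KFSC_BIN_LEVELS <- c("1", "2", "3", "4", "5-10", "11+", "none")

#' Project PTM observations onto alignment columns
#'
#' Every accepted PTM observation is assigned to the alignment column where
#' its 1-based native position lands after gapping of its member row. One
#' MAP (modified alignment position) is created per column holding at least
#' one observation.
#'
#' @param alignment A `family_alignment`.
#' @param ptms PTM data.frame (columns as in [read_ptm_table()]); all uids
#'   must be alignment members and all positions valid.
#' @return A `map_table`: data.frame with one row per MAP (`family_id`,
#'   `column`, `ptm_count`, `ptm_types`, plus placeholder feature/label
#'   columns), sorted by column, carrying the projected observations in
#'   `attr(, "observations")`.
#' @export
project_ptms_to_columns <- function(alignment, ptms) {
  ptms <- ptms[ptms$uid %in% alignment$uid, , drop = FALSE]
  if (nrow(ptms) == 0) {
    return(map_table(alignment$family_id, data.frame(), empty_obs_table()))
  }
  colmap <- lapply(alignment$aln, residue_columns)
  names(colmap) <- alignment$uid
  canon <- ungap_alignment(alignment)
  bad <- ptms$position > nchar(canon[ptms$uid])
  if (any(bad)) {
    stop("PTM position beyond canonical sequence for uid ",
         paste(unique(ptms$uid[bad]), collapse = ", "))
  }
  ptms$family_id <- alignment$family_id
  ptms$column <- vapply(seq_len(nrow(ptms)),
                        function(i) colmap[[ptms$uid[i]]][ptms$position[i]],
                        integer(1))
  stopifnot(!anyNA(ptms$column))  # a residue can never sit on its own gap
  cols <- sort(unique(ptms$column))
  maps <- data.frame(
    family_id = alignment$family_id,
    column = cols,
    ptm_count = as.integer(tabulate(match(ptms$column, cols), length(cols))),
    ptm_types = vapply(cols, function(co)
      paste(sort(unique(ptms$ptm_type[ptms$column == co])), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  map_table(alignment$family_id, maps, ptms)
}

map_table <- function(family_id, maps, observations) {
  if (nrow(maps) == 0) {
    maps <- data.frame(family_id = character(), column = integer(),
                       ptm_count = integer(), ptm_types = character(),
                       stringsAsFactors = FALSE)
  }
  n <- nrow(maps)
  for (col in c("conservation", "sasa", "ppi", "score")) {
    maps[[col]] <- rep(NA_real_, n)
  }
  for (col in c("nc", "nkc", "kfsc")) maps[[col]] <- rep(NA_integer_, n)
  maps$known_function <- rep(NA, n)
  maps$kfsc_bin <- rep(NA_character_, n)
  attr(maps, "observations") <- observations
  class(maps) <- c("map_table", "data.frame")
  maps
}

empty_obs_table <- function() {
  cbind(empty_ptm_table(),
        data.frame(family_id = character(), column = integer()))
}

#' Observations projected into a map table
#' @param maps A `map_table`.
#' @return The PTM observation data.frame with its `column` assignment.
#' @export
map_observations <- function(maps) attr(maps, "observations")

#' Compute PTM residue conservation per MAP
#'
#' Conservation of a MAP is the fraction of family members whose residue at
#' the MAP's column is identical to any amino-acid identity observed
#' modified at that MAP; gap rows count in the denominator. The value is
#' always positive because the modified member itself matches.
#'
#' @param alignment The `family_alignment` the maps came from.
#' @param maps A `map_table`.
#' @return The map table with `conservation` filled.
#' @export
compute_conservation <- function(alignment, maps) {
  if (nrow(maps) == 0) return(maps)
  obs <- map_observations(maps)
  chars <- do.call(rbind, strsplit(alignment$aln, "", fixed = TRUE))
  maps$conservation <- vapply(seq_len(nrow(maps)), function(i) {
    co <- maps$column[i]
    modified <- unique(obs$residue[obs$column == co])
    mean(chars[, co] %in% modified)
  }, numeric(1))
  maps
}

#' Compute neighbor count and neighbor known count
#'
#' For each MAP, `nc` is the number of other MAPs of the same family within
#' `window` alignment columns (the MAP's own column never counts), and
#' `nkc` the number of those with known biological function. Labels must be
#' assigned first (see [assign_labels()]).
#'
#' @param maps A `map_table` (single family; columns distinct).
#' @param window Column window half-width (default 2).
#' @return The map table with `nc` and `nkc` filled.
#' @export
compute_neighbor_features <- function(maps, window = 2) {
  if (nrow(maps) == 0) return(maps)
  stopifnot(!anyNA(maps$known_function))
  cols <- maps$column
  maps$nc <- vapply(seq_along(cols), function(i) {
    sum(abs(cols - cols[i]) <= window) - 1L
  }, integer(1))
  maps$nkc <- vapply(seq_along(cols), function(i) {
    near <- abs(cols - cols[i]) <= window
    near[i] <- FALSE
    sum(maps$known_function[near])
  }, integer(1))
  maps
}

#' Assign known-function labels and source-count bins
#'
#' A MAP is labeled known-function when at least one of its observations has
#' experimentally demonstrated function. The MAP-level known-function source
#' count (KFSC) is the maximum source count over its known-function
#' observations, binned into 1, 2, 3, 4, 5-10 and 11+ (unknown MAPs get
#' KFSC 0 and bin `"none"`).
#'
#' @param maps A `map_table`.
#' @return The map table with `known_function`, `kfsc`, `kfsc_bin` filled.
#' @export
assign_labels <- function(maps) {
  if (nrow(maps) == 0) return(maps)
  obs <- map_observations(maps)
  known_obs <- obs[obs$known_function, , drop = FALSE]
  mkey <- paste(maps$family_id, maps$column)
  kkey <- paste(known_obs$family_id, known_obs$column)
  maps$known_function <- mkey %in% kkey
  maps$kfsc <- vapply(mkey, function(k) {
    sc <- known_obs$source_count[kkey == k]
    if (length(sc)) max(sc) else 0L
  }, integer(1), USE.NAMES = FALSE)
  maps$kfsc_bin <- kfsc_bin(maps$kfsc, maps$known_function)
  maps
}

#' Bin known-function source counts
#' @param kfsc Integer vector of source counts.
#' @param known Logical vector; unknown MAPs bin to `"none"`.
#' @return Character vector over the levels 1, 2, 3, 4, 5-10, 11+, none.
#' @export
kfsc_bin <- function(kfsc, known = kfsc > 0) {
  out <- ifelse(!known, "none",
         ifelse(kfsc >= 11, "11+",
         ifelse(kfsc >= 5, "5-10", as.character(kfsc))))
  out[known & kfsc < 1] <- "none"
  out
}

#' Build the complete MAP table for one family
#'
#' Convenience wrapper: project, label, conservation, neighbor features.
#'
#' @param alignment A `family_alignment`.
#' @param ptms Accepted PTM observations for the family.
#' @param window Neighbor window (columns, default 2).
#' @return A fully annotated `map_table` (structure features still `NA`).
#' @export
build_maps <- function(alignment, ptms, window = 2) {
  maps <- project_ptms_to_columns(alignment, ptms)
  maps <- assign_labels(maps)
  maps <- compute_conservation(alignment, maps)
  compute_neighbor_features(maps, window = window)
}

#' Write a MAP table as TSV
#'
#' Stable column order: family_id, column, ptm_count, types, conservation,
#' sasa, ppi, nc, nkc, known, kfsc, kfsc_bin, score.
#'
#' @param maps A `map_table` (or plain data.frame with the same columns).
#' @param path Output path.
#' @export
write_map_table <- function(maps, path) {
  out <- as.data.frame(maps)[, c("family_id", "column", "ptm_count",
                                 "ptm_types", "conservation", "sasa", "ppi",
                                 "nc", "nkc", "known_function", "kfsc",
                                 "kfsc_bin", "score")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bind per-family MAP tables into one dataset table
#' @param map_list List of `map_table`s.
#' @return One `map_table` with pooled observations.
#' @export
bind_maps <- function(map_list) {
  map_list <- Filter(function(m) nrow(m) > 0, map_list)
  if (!length(map_list)) {
    return(map_table("", data.frame(), empty_obs_table()))
  }
  obs <- do.call(rbind, lapply(map_list, map_observations))
  out <- do.call(rbind, lapply(map_list, as.data.frame))
  rownames(out) <- NULL
  attr(out, "observations") <- obs
  class(out) <- c("map_table", "data.frame")
  out
}
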