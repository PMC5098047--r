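# Hotspot calling: threshold derivation from the high-confidence score
# distribution, enrichment versus random chance, and clinical-variant
# coincidence (Type-1 / Type-2).

#' Derive the function-potential hotspot threshold
#'
#' The threshold is taken from the score distribution of the
#' high-confidence MAPs (known-function source count >= `kfsc_min`): it is
#' the largest observed score `t` such that at least `coverage` of that
#' subset scores at or above `t` (conservative lower interpolation), so the
#' coverage contract always holds exactly.
#'
#' @param maps A scored `map_table` (or data.frame with `score`, `kfsc`).
#' @param kfsc_min Source-count cutoff defining the high-confidence subset
#'   (default 11).
#' @param coverage Required covered fraction (default 0.90).
#' @return The threshold score.
#' @export
derive_hotspot_threshold <- function(maps, kfsc_min = 11, coverage = 0.90) {
  s <- maps$score[!is.na(maps$kfsc) & maps$kfsc >= kfsc_min]
  s <- s[!is.na(s)]
  if (length(s) < 10) {
    stop("fewer than 10 MAPs with kfsc >= ", kfsc_min,
         "; supply an explicit threshold instead")
  }
  s <- sort(s)
  n <- length(s)
  s[n - ceiling(coverage * n) + 1L]
}

#' Call function-potential hotspots
#'
#' @param maps A scored `map_table`.
#' @param threshold Score threshold (a MAP is a hotspot iff
#'   `score >= threshold`).
#' @param category Optional ingested per-MAP annotation (e.g. known, U1-A,
#'   U1-B, U2, U3, U4); tabulated, never computed.
#' @return data.frame of calls (`family_id`, `column`, `score`,
#'   `known_function`, `is_hotspot`, `category`) with a `summary` attribute
#'   counting hotspots by label and category.
#' @export
call_hotspots <- function(maps, threshold, category = NULL) {
  stopifnot(!anyNA(maps$score))
  calls <- data.frame(family_id = maps$family_id, column = maps$column,
                      score = maps$score,
                      known_function = maps$known_function,
                      is_hotspot = maps$score >= threshold,
                      category = if (is.null(category)) NA_character_
                                 else as.character(category),
                      stringsAsFactors = FALSE)
  summary <- list(
    threshold = threshold,
    n_hotspots = sum(calls$is_hotspot),
    n_known_hotspots = sum(calls$is_hotspot & calls$known_function),
    n_unknown_hotspots = sum(calls$is_hotspot & !calls$known_function),
    by_category = if (!is.null(category)) {
      table(category[calls$is_hotspot])
    })
  attr(calls, "summary") <- summary
  calls
}

#' Enrichment of a subset above score thresholds, versus random chance
#'
#' For each threshold `t`: observed = number of subset MAPs with
#' `score >= t`; expected = `|subset| * P(score >= t)` under random
#' placement of the subset across all MAPs; the ratio observed / expected
#' is 1 in expectation for a subset independent of score.
#'
#' @param scores Score vector over all MAPs.
#' @param subset Logical vector marking the subset (non-empty).
#' @param thresholds Score thresholds (default `c(0.1, 0.196, 0.35, 0.5)`).
#' @return data.frame `threshold`, `observed`, `expected`, `ratio` (`NA`
#'   when expected is 0).
#' @export
enrichment_vs_random <- function(scores, subset,
                                 thresholds = c(0.1, 0.196, 0.35, 0.5)) {
  subset <- as.logical(subset)
  if (!any(subset)) stop("empty subset")
  n <- length(scores)
  rows <- lapply(thresholds, function(t) {
    above <- scores >= t
    observed <- sum(subset & above)
    expected <- sum(subset) * sum(above) / n
    data.frame(threshold = t, observed = observed, expected = expected,
               ratio = if (expected > 0) observed / expected else NA_real_)
  })
  do.call(rbind, rows)
}

#' Join clinical variants to MAPs (Type-1 / Type-2 coincidence)
#'
#' A variant matches a MAP when its protein is a member of the MAP's family
#' and its native position projects to the MAP's alignment column. The
#' record is Type-1 when that exact (uid, position) carries an observed PTM
#' in the MAP, Type-2 otherwise (alignment-column coincidence only); the
#' two classes are disjoint by construction. Variants matching no MAP are
#' dropped and counted.
#'
#' @param maps A `map_table` covering one or more families.
#' @param alignments Named list of `family_alignment`s (names = family_id).
#' @param variants Variant data.frame (from [read_variant_table()]).
#' @return List with `records` (one row per variant-MAP match: variant
#'   fields + `family_id`, `column`, `type`, `score`) and `dropped`
#'   (count + reasons table).
#' @export
join_variants <- function(maps, alignments, variants) {
  obs <- map_observations(maps)
  obs_key <- paste(obs$uid, obs$position)
  map_key <- paste(maps$family_id, maps$column)
  recs <- list()
  reasons <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    matched <- FALSE
    for (fam in alignments) {
      m <- match(v$uid, fam$uid)
      if (is.na(m)) next
      cols <- residue_columns(fam$aln[m])
      if (v$position > length(cols)) next
      column <- cols[v$position]
      mi <- match(paste(fam$family_id, column), map_key)
      if (is.na(mi)) next
      type <- if (paste(v$uid, v$position) %in%
                  obs_key[obs$family_id == fam$family_id &
                          obs$column == column]) 1L else 2L
      recs[[length(recs) + 1L]] <-
        cbind(v, data.frame(family_id = fam$family_id, column = column,
                            type = type, score = maps$score[mi],
                            stringsAsFactors = FALSE))
      matched <- TRUE
    }
    reasons[i] <- if (matched) "" else
      if (any(vapply(alignments, function(f) v$uid %in% f$uid, logical(1))))
        "no MAP at column" else "uid absent from all families"
  }
  records <- if (length(recs)) {
    do.call(rbind, c(recs, list(make.row.names = FALSE)))
  } else {
    cbind(variants[0, ], data.frame(family_id = character(),
                                    column = integer(), type = integer(),
                                    score = numeric()))
  }
  list(records = records,
       dropped = as.data.frame(table(reason = reasons[reasons != ""]),
                               stringsAsFactors = FALSE))
}

#' Tabulate pathogenic/benign variant coincidence at a hotspot threshold
#'
#' Pools pathogenic with likely_pathogenic and benign with likely_benign;
#' variants of other/uncertain significance are excluded from the table.
#'
#' @param records Coincidence records from [join_variants()].
#' @param threshold Hotspot score threshold.
#' @return data.frame cross-tabulating `type` (1/2) x `significance`
#'   (pathogenic/benign) x `hotspot` (above/below threshold) with counts.
#' @export
pathogenic_benign_summary <- function(records, threshold) {
  sig <- ifelse(records$significance %in% c("pathogenic", "likely_pathogenic"),
                "pathogenic",
         ifelse(records$significance %in% c("benign", "likely_benign"),
                "benign", NA_character_))
  keep <- !is.na(sig)
  grid <- expand.grid(type = c(1L, 2L),
                      significance = c("pathogenic", "benign"),
                      hotspot = c(TRUE, FALSE), stringsAsFactors = FALSE)
  grid$count <- mapply(function(ty, sg, hs) {
    sum(keep & records$type == ty & sig == sg &
          (records$score >= threshold) == hs)
  }, grid$type, grid$significance, grid$hotspot)
  grid
}
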