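# Seeded synthetic-data generators for every input the pipeline consumes:
# family alignments, PTM tables, disorder tracks, x-ray-style structures and
# clinical variant tables, with controllable statistical structure. All
# randomness flows from one seed through named per-family substreams, so
# adding families does not perturb earlier ones.

# amino-acid background frequencies (rounded UniProt-like composition)
AA_FREQS <- c(A = .083, C = .014, D = .055, E = .067, F = .039, G = .071,
              H = .023, I = .059, K = .058, L = .097, M = .024, N = .041,
              P = .047, Q = .039, R = .055, S = .066, T = .053, V = .069,
              W = .011, Y = .029)

substream_seed <- function(seed, label) {
  # deterministic 31-bit hash of (seed, label); double arithmetic is exact
  # here because every intermediate stays far below 2^53
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. Defaults describe a
#' realistic desk-scale regime: small-to-medium families, ~6% positive
#' class rate, geometric source counts supported on 1..68, moderate gap and
#' PTM densities.
#'
#' @param seed Integer seed (mandatory; all substreams derive from it).
#' @param n_families Number of families.
#' @param members_range Family size range (inclusive; generator draws
#'   within it, capped by the 2..360 membership bound).
#' @param length_range Canonical sequence length range.
#' @param gap_rate Per-member, per-column gap probability.
#' @param substitution_rate Per-site residue substitution rate between
#'   members.
#' @param ptm_density Expected PTMs per eligible residue.
#' @param ptm_type_freqs Named sampling weights over PTM types (defaults
#'   dominated by phosphorylation, then ubiquitination and acetylation).
#' @param label_coefficients Logistic coefficients over the six features
#'   (named; used by [simulate_labels()]).
#' @param label_intercept Logistic intercept (default chosen, together
#'   with the default coefficients, to give a ~6% marginal positive rate
#'   and a Bayes AUC near 0.8 — the regime of real PTM datasets).
#' @param kfsc_prob Geometric parameter of the source-count distribution
#'   (support truncated to 1..68).
#' @param structure_coverage Fraction of each covered protein's sequence
#'   resolved in its synthetic structure.
#' @param structure_fraction Fraction of proteins given a structure.
#' @param variant_density Variants per protein.
#' @param pathogenic_bias Strength of pathogenic placement bias toward
#'   high-feature MAPs (0 = uniform).
#' @param type1_fraction Fraction of pathogenic variants placed exactly on
#'   observed PTM sites (Type-1 regime; default 0.25, i.e. 1:3).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_families = 12,
                              members_range = c(3, 12),
                              length_range = c(120, 300),
                              gap_rate = 0.06,
                              substitution_rate = 0.15,
                              ptm_density = 0.05,
                              ptm_type_freqs = c(Phosphorylation = 0.61,
                                                 Ubiquitination = 0.11,
                                                 Acetylation = 0.09,
                                                 `N-linked Glycosylation` = 0.05,
                                                 Methylation = 0.05,
                                                 Sumoylation = 0.03,
                                                 `S-nitrosylation` = 0.03,
                                                 Citrullination = 0.03),
                              label_coefficients = c(ptm_count = 0.55,
                                                     sasa = 0.014,
                                                     conservation = 1.8,
                                                     ppi = 0.9,
                                                     nc = 0.15,
                                                     nkc = 0.7),
                              label_intercept = -6.2,
                              kfsc_prob = 0.45,
                              structure_coverage = 0.8,
                              structure_fraction = 0.5,
                              variant_density = 0.6,
                              pathogenic_bias = 2.0,
                              type1_fraction = 0.25) {
  if (missing(seed)) stop("simulation_config requires a seed")
  members_range <- pmin(pmax(members_range, 2L), 360L)
  cfg <- as.list(environment())
  stopifnot(gap_rate >= 0, gap_rate <= 1, ptm_density >= 0, ptm_density <= 1,
            structure_coverage >= 0, structure_coverage <= 1,
            type1_fraction >= 0, type1_fraction <= 1)
  class(cfg) <- "simulation_config"
  cfg
}

sample_sequence <- function(n) {
  paste(sample(names(AA_FREQS), n, replace = TRUE, prob = AA_FREQS),
        collapse = "")
}

#' Simulate one protein family
#'
#' Generates a root sequence, derives members by i.i.d. substitutions,
#' inserts gaps column-wise (the canonical sequence of each member is its
#' ungapped row, so the alignment invariant holds by construction), places
#' PTMs only on residues chemically compatible with their type, and writes
#' per-residue disorder as smoothed noise elevated toward both termini.
#'
#' @param config A `simulation_config`.
#' @param family_id Family identifier (also names the random substream).
#' @return List with `alignment` (`family_alignment`), `proteins`
#'   (`protein_entries`), `ptms` (observation table, labels all unknown at
#'   this stage) and `disorder` (tendency table).
#' @export
simulate_family <- function(config, family_id) {
  set.seed(substream_seed(config$seed, paste0("family:", family_id)))
  n_mem <- sample(config$members_range[1]:config$members_range[2], 1)
  L <- sample(config$length_range[1]:config$length_range[2], 1)
  root <- strsplit(sample_sequence(L), "")[[1]]
  compat <- default_ptm_compatibility()
  uids <- sprintf("%s_P%02d", family_id, seq_len(n_mem))
  rows <- character(n_mem)
  for (m in seq_len(n_mem)) {
    res <- root
    mut <- stats::runif(L) < config$substitution_rate
    res[mut] <- sample(names(AA_FREQS), sum(mut), replace = TRUE,
                       prob = AA_FREQS)
    gap <- stats::runif(L) < config$gap_rate
    # keep >= 2 residues so every member has a usable canonical sequence
    if (sum(!gap) < 2) gap[] <- FALSE
    res[gap] <- "-"
    rows[m] <- paste(res, collapse = "")
  }
  aln <- family_alignment(family_id, uids, rows)
  canon <- ungap_alignment(aln)
  proteins <- protein_entries(uids, unname(canon), family_id)

  types <- names(config$ptm_type_freqs)
  ptm_rows <- list()
  dis_rows <- list()
  for (m in seq_len(n_mem)) {
    sq <- strsplit(canon[m], "")[[1]]
    n <- length(sq)
    # disorder: smoothed block noise + terminal elevation
    base <- stats::rnorm(n, 0.35, 0.15)
    sm <- stats::filter(base, rep(1 / 9, 9), sides = 2)
    sm[is.na(sm)] <- base[is.na(sm)]
    edge <- pmax(0, 0.45 - 0.03 * pmin(seq_len(n) - 1, rev(seq_len(n)) - 1))
    tend <- pmin(1, pmax(0, as.numeric(sm) + edge))
    dis_rows[[m]] <- data.frame(uid = uids[m], position = seq_len(n),
                                tendency = tend, stringsAsFactors = FALSE)
    for (ty in types) {
      elig <- which(sq %in% compat[[ty]])
      if (!length(elig)) next
      hit <- elig[stats::runif(length(elig)) <
                    config$ptm_density * config$ptm_type_freqs[[ty]] /
                    mean(config$ptm_type_freqs)]
      if (length(hit)) {
        ptm_rows[[length(ptm_rows) + 1L]] <-
          data.frame(uid = uids[m], position = hit, residue = sq[hit],
                     ptm_type = ty, known_function = FALSE,
                     source_count = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  ptms <- if (length(ptm_rows)) {
    do.call(rbind, c(ptm_rows, list(make.row.names = FALSE)))
  } else empty_ptm_table()
  list(alignment = aln, proteins = proteins, ptms = ptms,
       disorder = do.call(rbind, c(dis_rows, list(make.row.names = FALSE))))
}

#' Simulate known-function labels and source counts on a MAP table
#'
#' Draws each MAP's known-function label Bernoulli with logit linear in the
#' six features, then draws a source count for positives from a truncated
#' geometric distribution whose mean shifts upward with the linear
#' predictor, so high-confidence (high-KFSC) MAPs sit higher on the score
#' scale. The labels are then pushed back onto one randomly chosen member
#' observation per positive MAP so the observation-level contract
#' (MAP known iff some observation known) holds.
#'
#' @param maps A `map_table` with features computed.
#' @param config A `simulation_config` (coefficients, intercept, kfsc_prob).
#' @param seed Optional override of the label substream seed.
#' @return The map table relabeled, with refreshed observations, plus the
#'   true per-MAP probabilities in `attr(, "true_prob")`.
#' @export
simulate_labels <- function(maps, config, seed = NULL) {
  set.seed(if (is.null(seed)) substream_seed(config$seed, "labels") else seed)
  fm <- map_features(maps)
  beta <- config$label_coefficients[colnames(fm)]
  eta <- config$label_intercept + drop(fm %*% beta)
  prob <- stats::plogis(eta)
  known <- stats::runif(nrow(maps)) < prob
  kfsc <- draw_kfsc(eta, known, config)
  obs <- map_observations(maps)
  obs$known_function <- FALSE
  obs$source_count <- 0L
  mkey <- paste(maps$family_id, maps$column)
  okey <- paste(obs$family_id, obs$column)
  for (i in which(known)) {
    cand <- which(okey == mkey[i])
    pick <- cand[sample.int(length(cand), 1)]
    obs$known_function[pick] <- TRUE
    obs$source_count[pick] <- kfsc[i]
  }
  attr(maps, "observations") <- obs
  maps <- assign_labels(maps)
  # neighbor known counts depend on labels; recompute per family
  maps <- refresh_neighbors(maps)
  attr(maps, "true_prob") <- prob
  maps
}

#' Draw known-function source counts for positive MAPs
#'
#' Truncated-geometric counts on 1..68 whose success probability shrinks
#' with the linear predictor, so high-feature MAPs accumulate more
#' corroborating sources — the monotone confidence pattern of curated PTM
#' databases.
#'
#' @param eta Linear predictor per MAP.
#' @param known Logical positive labels (negatives get count 0).
#' @param config A `simulation_config` (`kfsc_prob`).
#' @return Integer vector of source counts.
#' @export
draw_kfsc <- function(eta, known, config) {
  kfsc <- integer(length(known))
  if (any(known)) {
    p <- pmin(0.9, pmax(0.05, config$kfsc_prob -
                          0.08 * (eta[known] - mean(eta))))
    kfsc[known] <- pmin(1L + stats::rgeom(sum(known), p), 68L)
  }
  kfsc
}

refresh_neighbors <- function(maps, window = 2) {
  out <- lapply(split(seq_len(nrow(maps)), maps$family_id), function(idx) {
    sub <- maps[idx, , drop = FALSE]
    cols <- sub$column
    sub$nc <- vapply(seq_along(cols), function(i)
      sum(abs(cols - cols[i]) <= window) - 1L, integer(1))
    sub$nkc <- vapply(seq_along(cols), function(i) {
      near <- abs(cols - cols[i]) <= window
      near[i] <- FALSE
      sum(sub$known_function[near])
    }, integer(1))
    sub
  })
  res <- do.call(rbind, out)
  res <- res[order(res$family_id, res$column), ]
  rownames(res) <- NULL
  attr(res, "observations") <- map_observations(maps)
  attr(res, "true_prob") <- attr(maps, "true_prob")
  class(res) <- c("map_table", "data.frame")
  res
}

#' Simulate an x-ray-style structure for a protein
#'
#' Emits an idealized alpha-helical backbone (N, CA, C, O, CB) over a
#' contiguous covered subrange of the sequence; residues outside the range
#' stay unresolved, exercising the disorder fallback downstream. Optionally
#' a second, docked copy of the chain is added at a fixed offset to create
#' a protein-protein interface.
#'
#' @param sequence Canonical sequence.
#' @param uid Protein identifier (names the substream).
#' @param config A `simulation_config` (`structure_coverage`, `seed`).
#' @param structure_id Structure identifier.
#' @param docked Add a contacting second chain (default FALSE).
#' @param contact_gap Inter-chain backbone gap in Angstrom when docked
#'   (default 4).
#' @return List of `structure_chain`s (chain A, plus B when docked).
#' @export
simulate_structure <- function(sequence, uid, config, structure_id,
                               docked = FALSE, contact_gap = 4) {
  set.seed(substream_seed(config$seed, paste0("structure:", uid)))
  L <- nchar(sequence)
  n_res <- max(1L, round(config$structure_coverage * L))
  start <- if (n_res >= L) 1L else sample.int(L - n_res + 1L, 1)
  resnos <- seq(start, length.out = n_res)
  sq <- strsplit(toupper(sequence), "")[[1]]
  aa1to3 <- stats::setNames(names(AA3_TO_1), AA3_TO_1)
  atoms <- do.call(rbind, lapply(seq_along(resnos), function(i) {
    r <- resnos[i]
    theta <- (i - 1) * 100 * pi / 180
    ca <- c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
    offs <- rbind(N = c(-1.2, 0.5, -0.8), CA = c(0, 0, 0),
                  C = c(1.2, 0.4, 0.7), O = c(1.9, 1.4, 0.9),
                  CB = c(-0.5, -1.3, 0.6))
    if (sq[r] == "G") offs <- offs[rownames(offs) != "CB", , drop = FALSE]
    data.frame(resno = r, resid = unname(aa1to3[sq[r]]),
               elety = rownames(offs),
               element = substr(rownames(offs), 1, 1),
               x = ca[1] + offs[, 1], y = ca[2] + offs[, 2],
               z = ca[3] + offs[, 3], stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL
  chains <- list(structure_chain(structure_id, "A", atoms))
  if (docked) {
    b <- atoms
    # translate along +x so the closest heavy-atom pair sits at contact_gap
    b$x <- b$x + (max(atoms$x) - min(atoms$x)) + contact_gap
    chains <- c(chains, list(structure_chain(structure_id, "B", b)))
  }
  chains
}

#' Simulate a clinical-variant table over a scored MAP set
#'
#' Pathogenic (and likely_pathogenic) variants are preferentially placed on
#' the columns of high-scoring MAPs — a `type1_fraction` of them exactly on
#' observed PTM sites (Type-1 regime), the rest on other members of the
#' same column (Type-2). Benign variants are placed half uniformly over
#' residues and half on MAP columns with the inverse score weighting,
#' emulating the concentration of tolerated variation at low-constraint
#' positions.
#'
#' @param maps A scored `map_table`.
#' @param alignments Named list of `family_alignment`s.
#' @param proteins A `protein_entries` table.
#' @param config A `simulation_config`.
#' @return Variant data.frame (`uid`, `position`, `ref_aa`, `alt_aa`,
#'   `significance`).
#' @export
simulate_variants <- function(maps, alignments, proteins, config) {
  set.seed(substream_seed(config$seed, "variants"))
  n_var <- max(4L, round(config$variant_density * nrow(proteins)))
  n_path <- round(n_var / 2)
  obs <- map_observations(maps)
  score <- maps$score
  if (all(is.na(score))) score <- rep(1, nrow(maps))
  w <- exp(config$pathogenic_bias * (score - mean(score)) / max(stats::sd(score), 1e-9))
  rows <- list()
  add_row <- function(uid, pos, sig) {
    sq <- proteins$sequence[proteins$uid == uid]
    ref <- substr(sq, pos, pos)
    alt <- sample(setdiff(AA_STANDARD, ref), 1)
    rows[[length(rows) + 1L]] <<- data.frame(
      uid = uid, position = pos, ref_aa = ref, alt_aa = alt,
      significance = sig, stringsAsFactors = FALSE)
  }
  sig_path <- c("pathogenic", "likely_pathogenic")
  for (i in seq_len(n_path)) {
    mi <- sample.int(nrow(maps), 1, prob = w)
    fam <- alignments[[maps$family_id[mi]]]
    col <- maps$column[mi]
    o <- obs[obs$family_id == maps$family_id[mi] & obs$column == col, ]
    if (stats::runif(1) < config$type1_fraction && nrow(o)) {
      pick <- o[sample.int(nrow(o), 1), ]
      add_row(pick$uid, pick$position, sample(sig_path, 1))
    } else {
      # a member whose residue at this column is not an observed PTM site
      cand <- setdiff(fam$uid, o$uid)
      if (!length(cand)) cand <- fam$uid
      for (u in sample(cand)) {
        cols <- residue_columns(fam$aln[match(u, fam$uid)])
        pos <- match(col, cols)
        if (!is.na(pos) && !paste(u, pos) %in% paste(o$uid, o$position)) {
          add_row(u, pos, sample(sig_path, 1))
          break
        }
      }
    }
  }
  sig_ben <- c("benign", "likely_benign")
  for (i in seq_len(n_var - n_path)) {
    if (stats::runif(1) < 0.5) {
      # anti-biased toward low-scoring MAP columns
      mi <- sample.int(nrow(maps), 1, prob = 1 / w)
      fam <- alignments[[maps$family_id[mi]]]
      placed <- FALSE
      for (u in sample(fam$uid)) {
        cols <- residue_columns(fam$aln[match(u, fam$uid)])
        pos <- match(maps$column[mi], cols)
        if (!is.na(pos)) {
          add_row(u, pos, sample(sig_ben, 1))
          placed <- TRUE
          break
        }
      }
      if (placed) next
    }
    pi <- sample.int(nrow(proteins), 1)
    pos <- sample.int(nchar(proteins$sequence[pi]), 1)
    add_row(proteins$uid[pi], pos, sample(sig_ben, 1))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate a direct feature/label fixture for model evaluation
#'
#' Draws `n` six-feature vectors from realistic marginal distributions and
#' labels from a known logistic surface, returning the true generative
#' probabilities so a Bayes-optimal AUC can be computed for comparison.
#'
#' @param n Number of rows.
#' @param config A `simulation_config` (coefficients and intercept define
#'   the surface).
#' @param seed Optional substream override.
#' @return List `features` (matrix), `labels`, `true_prob`.
#' @export
simulate_map_features <- function(n, config, seed = NULL) {
  set.seed(if (is.null(seed)) substream_seed(config$seed, "features") else seed)
  pc <- 1 + stats::rpois(n, 0.8)
  sasa <- ifelse(stats::runif(n) < 0.15, 0, stats::rgamma(n, 2, rate = 1 / 40))
  cons <- stats::rbeta(n, 1.2, 2.5)
  ppi <- ifelse(stats::runif(n) < 0.6, 0, stats::runif(n))
  nc <- stats::rbinom(n, 4, 0.2)
  nkc <- pmin(nc, stats::rbinom(n, 2, 0.1))
  fm <- cbind(ptm_count = pc, sasa = sasa, conservation = cons, ppi = ppi,
              nc = as.numeric(nc), nkc = as.numeric(nkc))
  beta <- config$label_coefficients[colnames(fm)]
  prob <- stats::plogis(config$label_intercept + drop(fm %*% beta))
  labels <- stats::runif(n) < prob
  list(features = fm, labels = labels, true_prob = prob)
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Runs the family, structure and disorder generators for every family and
#' (optionally) writes every file format the readers consume: aligned
#' FASTA, PTM/disorder/variant TSVs and PDB files, plus a chain-to-protein
#' mapping TSV.
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (`NULL` = in-memory only).
#' @param labels Assign known-function labels and source counts to the
#'   observations via [simulate_labels()] over alignment-side features
#'   (default `TRUE`), making the emitted PTM table self-contained for a
#'   downstream pipeline run.
#' @return List `alignments`, `proteins`, `ptms`, `disorder`, `structures`
#'   (list of chain lists), `chain_uid`, and `paths` when written.
#' @export
simulate_saphire_dataset <- function(config, dir = NULL, labels = TRUE) {
  fams <- lapply(seq_len(config$n_families), function(i)
    simulate_family(config, sprintf("FAM%03d", i)))
  alignments <- lapply(fams, `[[`, "alignment")
  names(alignments) <- vapply(alignments, `[[`, "", "family_id")
  proteins <- do.call(rbind, lapply(fams, `[[`, "proteins"))
  class(proteins) <- c("protein_entries", "data.frame")
  ptms <- do.call(rbind, c(lapply(fams, `[[`, "ptms"),
                           list(make.row.names = FALSE)))
  disorder <- do.call(rbind, c(lapply(fams, `[[`, "disorder"),
                               list(make.row.names = FALSE)))
  if (labels && nrow(ptms)) {
    maps <- stage_build_maps(alignments, proteins, ptms, saphire_config())
    maps$ppi <- 0
    maps <- simulate_labels(maps, config)
    obs <- map_observations(maps)
    ptms <- obs[names(ptms)]
  }
  set.seed(substream_seed(config$seed, "structure-pick"))
  covered <- proteins$uid[stats::runif(nrow(proteins)) <
                            config$structure_fraction]
  structures <- list()
  chain_uid <- character(0)
  for (uid in covered) {
    sid <- paste0("S_", uid)
    docked <- substream_seed(config$seed, paste0("dock:", uid)) %% 2L == 0L
    ch <- simulate_structure(proteins$sequence[proteins$uid == uid], uid,
                             config, sid, docked = docked)
    structures[[sid]] <- ch
    for (c1 in ch) {
      chain_uid[paste(sid, c1$chain_id, sep = ":")] <- uid
    }
  }
  out <- list(alignments = alignments, proteins = proteins, ptms = ptms,
              disorder = disorder, structures = structures,
              chain_uid = chain_uid, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (fam in alignments) {
      write_alignment(fam, file.path(dir, paste0(fam$family_id, ".afa")))
    }
    write_ptm_table(ptms, file.path(dir, "ptms.tsv"))
    write_disorder_table(disorder, file.path(dir, "disorder.tsv"))
    for (sid in names(structures)) {
      write_pdb_file(structures[[sid]], file.path(dir, paste0(sid, ".pdb")))
    }
    utils::write.table(
      data.frame(chain = names(chain_uid), uid = unname(chain_uid)),
      file.path(dir, "chain_map.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    out$paths <- dir
  }
  out
}
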