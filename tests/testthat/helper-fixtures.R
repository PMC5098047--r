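# Small in-code fixture builders shared across the suite.

# a PTM observation data.frame with sensible defaults
ptm_rows <- function(uid, position, residue, ptm_type = "Phosphorylation",
                     known_function = FALSE, source_count = 0L) {
  n <- length(uid)
  data.frame(uid = uid, position = as.integer(position), residue = residue,
             ptm_type = rep_len(ptm_type, n),
             known_function = rep_len(known_function, n),
             source_count = rep_len(as.integer(source_count), n),
             stringsAsFactors = FALSE)
}

# a bare chain from an atom coordinate table; one atom per residue unless
# atoms_per_residue rows are supplied explicitly
toy_chain <- function(xyz, resno = seq_len(nrow(xyz)), element = "C",
                      structure_id = "TOY", chain_id = "A",
                      resid = "ALA", elety = "CA") {
  structure_chain(structure_id, chain_id,
                  data.frame(resno = as.integer(resno), resid = resid,
                             elety = elety, element = element,
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             stringsAsFactors = FALSE))
}

# an ideal-helix chain fixture of n residues (backbone + CB), poly-alanine
helix_chain <- function(n, structure_id = "HLX", chain_id = "A",
                        start_resno = 1) {
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    theta <- (i - 1) * 100 * pi / 180
    ca <- c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
    offs <- rbind(N = c(-1.2, 0.5, -0.8), CA = c(0, 0, 0),
                  C = c(1.2, 0.4, 0.7), O = c(1.9, 1.4, 0.9),
                  CB = c(-0.5, -1.3, 0.6))
    data.frame(resno = start_resno + i - 1L, resid = "ALA",
               elety = rownames(offs),
               element = substr(rownames(offs), 1, 1),
               x = ca[1] + offs[, 1], y = ca[2] + offs[, 2],
               z = ca[3] + offs[, 3], stringsAsFactors = FALSE)
  }))
  structure_chain(structure_id, chain_id, atoms)
}

# a minimal scored map table built directly (bypassing alignments) for the
# hotspot / coincidence operations
toy_map_table <- function(n, score, known = rep(FALSE, n),
                          kfsc = rep(0L, n), ptm_types = "Phosphorylation",
                          family_id = "FAM", column = seq_len(n) * 10L) {
  df <- data.frame(family_id = family_id, column = as.integer(column),
                   ptm_count = 1L, ptm_types = ptm_types,
                   conservation = 0.5, sasa = NA_real_, ppi = 0,
                   score = score, nc = 0L, nkc = 0L,
                   kfsc = as.integer(kfsc), known_function = known,
                   kfsc_bin = saphire::kfsc_bin(kfsc, known),
                   stringsAsFactors = FALSE)
  attr(df, "observations") <- cbind(
    ptm_rows(paste0("P", seq_len(n)), seq_len(n), "S",
             known_function = known, source_count = kfsc),
    data.frame(family_id = family_id, column = as.integer(column)))
  class(df) <- c("map_table", "data.frame")
  df
}

# write text lines to a temp file and return its path
tmpfile <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# exhaustive pairwise-concordance AUC oracle (ties count one half)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(conc)
}
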