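# Structure ingestion: PDB chains, resolved->canonical mapping, quality filters.
# Only x-ray style ATOM records of standard residues are used; model 1 only;
# alternate locations resolved by highest occupancy, then alphabetical altloc.

#' Read x-ray structure chains from a PDB file
#'
#' Parses ATOM records (model 1 only, standard residues only) into one
#' `structure_chain` per chain identifier. Alternate locations are resolved
#' per atom by highest occupancy, ties broken alphabetically by the altloc
#' code. HETATM-only chains (ligands, waters) are omitted.
#'
#' @param path Path to a PDB-format coordinate file.
#' @param structure_id Identifier; defaults to the file name without
#'   extension.
#' @return List of `structure_chain` objects (possibly empty, with a
#'   warning, when the file holds no usable ATOM records).
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(AA3_TO_1), , drop = FALSE]
  if (nrow(at) == 0) {
    warning("no usable ATOM records in ", path)
    return(list())
  }
  # altloc resolution: keep, per (chain, resno, atom name), the record with
  # the highest occupancy; ties by alphabetical altloc code
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$eleno), , drop = FALSE]

  lapply(split(at, at$chain), function(ch) {
    structure_chain(structure_id, ch$chain[1],
                    data.frame(resno = ch$resno,
                               resid = ch$resid,
                               elety = ch$elety,
                               element = atom_element(ch$elesy, ch$elety),
                               x = ch$x, y = ch$y, z = ch$z,
                               stringsAsFactors = FALSE))
  })
}

AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

atom_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | !nzchar(el)
  # fall back to the first alphabetic character of the atom name
  el[miss] <- substr(gsub("[^A-Za-z].*$", "",
                          sub("^[0-9]*", "", toupper(elety[miss]))), 1, 1)
  el
}

#' Construct a structure chain
#'
#' @param structure_id Structure identifier (e.g. PDB code).
#' @param chain_id Chain identifier.
#' @param atoms data.frame with columns `resno`, `resid` (3-letter),
#'   `elety` (atom name), `element`, `x`, `y`, `z` (Angstrom).
#' @return A `structure_chain`: the atom table plus `resolved_residue_count`
#'   and an initially empty `residue_map`.
#' @export
structure_chain <- function(structure_id, chain_id, atoms) {
  stopifnot(all(c("resno", "resid", "elety", "element", "x", "y", "z")
                %in% names(atoms)))
  structure(list(structure_id = as.character(structure_id),
                 chain_id = as.character(chain_id),
                 atoms = atoms,
                 resolved_residue_count = length(unique(atoms$resno)),
                 residue_map = NULL),
            class = "structure_chain")
}

#' @export
print.structure_chain <- function(x, ...) {
  cat(sprintf("structure_chain %s:%s — %d residues, %d atoms%s\n",
              x$structure_id, x$chain_id, x$resolved_residue_count,
              nrow(x$atoms),
              if (is.null(x$residue_map)) "" else " (mapped)"))
  invisible(x)
}

#' Resolved one-letter sequence of a chain
#'
#' @param chain A `structure_chain`.
#' @return data.frame `resno`, `aa` in residue-number order.
#' @export
chain_sequence <- function(chain) {
  res <- chain$atoms[!duplicated(chain$atoms$resno), c("resno", "resid")]
  res <- res[order(res$resno), ]
  data.frame(resno = res$resno, aa = unname(AA3_TO_1[res$resid]),
             stringsAsFactors = FALSE)
}

#' Map resolved residues onto the canonical sequence
#'
#' The resolved residues are split into blocks of consecutive residue
#' numbers and each block must occur verbatim in the canonical sequence,
#' downstream of the previous block (greedy left-to-right matching). Any
#' internal insertion or deletion relative to the canonical sequence — the
#' signature of a chimeric or engineered construct — rejects the chain.
#'
#' @param chain A `structure_chain`.
#' @param sequence Canonical amino-acid sequence of the chain's protein.
#' @return On success, the chain with `residue_map` filled (named integer
#'   vector: resolved residue number -> 1-based native position). On
#'   failure, a `chain_rejection` object carrying `reason = "noncanonical"`
#'   (test with [is_rejected()]).
#' @export
map_resolved_to_canonical <- function(chain, sequence) {
  stopifnot(nzchar(sequence), nrow(chain$atoms) > 0)
  sequence <- toupper(sequence)
  res <- chain_sequence(chain)
  if (anyNA(res$aa)) return(rejection("noncanonical"))
  blocks <- split(seq_len(nrow(res)), cumsum(c(1L, diff(res$resno) != 1L)))
  map <- integer(nrow(res))
  from <- 1L
  for (b in blocks) {
    pat <- paste(res$aa[b], collapse = "")
    hit <- regexpr(pat, substr(sequence, from, nchar(sequence)), fixed = TRUE)
    if (hit < 0) return(rejection("noncanonical"))
    start <- from + as.integer(hit) - 1L
    map[b] <- seq(start, length.out = length(b))
    from <- start + length(b)
  }
  chain$residue_map <- stats::setNames(map, res$resno)
  chain
}

rejection <- function(reason) {
  structure(list(reason = reason), class = "chain_rejection")
}

#' Was a chain mapping rejected?
#' @param x Result of [map_resolved_to_canonical()].
#' @return `TRUE` for a rejection, `FALSE` for an accepted chain.
#' @export
is_rejected <- function(x) inherits(x, "chain_rejection")

#' Apply structure quality filters
#'
#' Retains chains with strictly more than `min_resolved` resolved residues
#' and an accepted resolved-to-canonical mapping; everything else is listed
#' in the rejection report with its reason.
#'
#' @param chains List of `structure_chain` objects.
#' @param proteins A `protein_entries` table (canonical sequences).
#' @param chain_uid Named character vector mapping `"structure_id:chain_id"`
#'   to protein uid.
#' @param min_resolved Minimum resolved-residue count (exclusive bound;
#'   default 50).
#' @return List with `chains` (qualifying, with `residue_map` and `uid`
#'   attached) and `report` (per-chain `kept` flag and `reason`).
#' @export
filter_structures <- function(chains, proteins, chain_uid, min_resolved = 50) {
  kept <- list()
  rows <- lapply(chains, function(ch) {
    key <- paste(ch$structure_id, ch$chain_id, sep = ":")
    uid <- unname(chain_uid[key])
    reason <- NA_character_
    if (is.na(uid) || !uid %in% proteins$uid) {
      reason <- "no protein mapping"
    } else if (ch$resolved_residue_count <= min_resolved) {
      reason <- sprintf("resolved residues <= %d", min_resolved)
    } else {
      mapped <- map_resolved_to_canonical(
        ch, proteins$sequence[proteins$uid == uid])
      if (is_rejected(mapped)) {
        reason <- mapped$reason
      } else {
        mapped$uid <- uid
        kept[[key]] <<- mapped
      }
    }
    data.frame(structure_id = ch$structure_id, chain_id = ch$chain_id,
               kept = is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
  })
  list(chains = kept, report = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Write chains to a PDB-format file
#'
#' Minimal fixed-width writer (ATOM records, single model) for the chains
#' produced by the synthetic-structure generator.
#'
#' @param chains List of `structure_chain` objects (one structure).
#' @param path Output path.
#' @export
write_pdb_file <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in chains) {
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      name <- a$elety[i]
      # PDB column convention: 1-3 char atom names start in column 14
      name <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name, a$resid[i], ch$chain_id, a$resno[i],
        a$x[i], a$y[i], a$z[i], 1, 0, a$element[i]), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}
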