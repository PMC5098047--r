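# Solvent accessible surface area (Shrake-Rupley), the intrinsic-disorder
# fallback for unresolved residues, geometric interface detection, and
# aggregation of both to MAP level.

# van der Waals radii (Angstrom), Bondi-style values for the elements seen
# in protein heavy atoms; hydrogens included for completeness.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90)

vdw_radius <- function(elements, default = 1.70) {
  r <- VDW_RADII[toupper(elements)]
  if (anyNA(r)) {
    warning("unknown element(s) ",
            paste(unique(elements[is.na(r)]), collapse = ", "),
            "; using fallback radius ", default)
    r[is.na(r)] <- default
  }
  unname(r)
}

# rotation-covariant local frame for one atom, built from the directions to
# its nearest and nearest non-collinear neighbours; under any rigid motion
# of the molecule the frame co-rotates, so the test-point sphere buries
# identically and SASA is invariant to floating-point precision
local_frame <- function(i, xyz, d2) {
  ord <- order(d2)
  ord <- ord[d2[ord] > 0]
  if (!length(ord)) return(diag(3))
  e1 <- xyz[ord[1], ] - xyz[i, ]
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- NULL
  for (j in ord[-1]) {
    v <- xyz[j, ] - xyz[i, ]
    v <- v - sum(v * e1) * e1
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) { e2 <- v / nv; break }
  }
  if (is.null(e2)) {
    # collinear cluster: any completion (burial is axially symmetric)
    ref <- diag(3)[, which.min(abs(e1))]
    e2 <- ref - sum(ref * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
  }
  cbind(e1, e2, c(e1[2] * e2[3] - e1[3] * e2[2],
                  e1[3] * e2[1] - e1[1] * e2[3],
                  e1[1] * e2[2] - e1[2] * e2[1]))
}

# deterministic quasi-uniform unit-sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius `probe_radius` over every atom of the chain: each
#' atom is surrounded by a fixed deterministic set of test points on its
#' solvent-expanded sphere, points falling inside any neighbouring atom's
#' expanded sphere are buried, and the accessible area is the exposed
#' fraction times the full sphere area `4*pi*(r_vdw + probe)^2`. Per-atom
#' areas are summed per residue. SASA is computed for the chain in
#' isolation, i.e. per computationally segregated chain. Each atom's
#' test-point sphere is oriented by a local frame built from its nearest
#' neighbours, making the result invariant under rigid motion of the input
#' (to floating-point precision).
#'
#' @param chain A `structure_chain`.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points Test points per atom (default 960).
#' @return data.frame `resno`, `sasa` (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(chain, probe_radius = 1.4,
                               n_sphere_points = 960) {
  a <- chain$atoms
  stopifnot(nrow(a) >= 1)
  xyz <- cbind(a$x, a$y, a$z)
  rad <- vdw_radius(a$element) + probe_radius
  pts <- sphere_points(n_sphere_points)
  n <- nrow(a)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad + rad[i])^2 & d2 > 0)
    exposed <- rep(TRUE, n_sphere_points)
    if (length(nb)) {
      p <- (pts %*% t(local_frame(i, xyz, d2))) * rad[i]
      p[, 1] <- p[, 1] + xyz[i, 1]
      p[, 2] <- p[, 2] + xyz[i, 2]
      p[, 3] <- p[, 3] + xyz[i, 3]
      for (j in nb) {
        if (!any(exposed)) break
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
               (p[, 3] - xyz[j, 3])^2
        exposed <- exposed & dj2 >= rad[j]^2
      }
    }
    area[i] <- mean(exposed) * 4 * pi * rad[i]^2
  }
  resno <- sort(unique(a$resno))
  data.frame(resno = resno,
             sasa = vapply(resno, function(r) sum(area[a$resno == r]),
                           numeric(1)))
}

#' Effective SASA with the intrinsic-disorder fallback
#'
#' A residue resolved in at least one qualifying chain gets the mean of its
#' per-chain SASA values. A residue resolved nowhere but predicted
#' disordered (tendency > 0.5) is assigned the maximal per-residue SASA
#' observed across the protein's qualifying structures; an unresolved
#' residue predicted ordered gets no SASA at all (`NA`).
#'
#' @param sasa_values Numeric vector of per-chain SASA values for the
#'   residue (length 0 when unresolved).
#' @param disorder Disorder tendency in `[0, 1]` (default 0 when absent).
#' @param chain_max_sasa Maximum per-residue SASA over the protein's
#'   qualifying structures.
#' @return Effective SASA in Angstrom^2, or `NA_real_`.
#' @export
effective_sasa <- function(sasa_values, disorder = 0, chain_max_sasa = NA_real_) {
  if (length(sasa_values)) return(mean(sasa_values))
  if (!is.na(disorder) && disorder > 0.5) return(chain_max_sasa)
  NA_real_
}

#' Detect protein-protein interface residues
#'
#' A residue is interface-flagged iff any of its heavy atoms lies within
#' `contact_cutoff` of any heavy atom of a *different* chain of the same
#' structure. Single-chain structures yield all-false flags.
#'
#' @param chains List of `structure_chain`s belonging to one structure.
#' @param contact_cutoff Heavy-atom contact distance in Angstrom (default 5).
#' @return data.frame `structure_id`, `chain_id`, `resno`, `interface`.
#' @export
detect_interface_residues <- function(chains, contact_cutoff = 5.0) {
  flags <- lapply(chains, function(ch) {
    heavy <- ch$atoms[ch$atoms$element != "H", , drop = FALSE]
    data.frame(structure_id = ch$structure_id, chain_id = ch$chain_id,
               resno = sort(unique(heavy$resno)), interface = FALSE,
               stringsAsFactors = FALSE)
  })
  if (length(chains) >= 2) {
    heavies <- lapply(chains, function(ch)
      ch$atoms[ch$atoms$element != "H", , drop = FALSE])
    cut2 <- contact_cutoff^2
    for (i in seq_along(chains)) for (j in seq_along(chains)) {
      if (i == j) next
      ai <- heavies[[i]]; aj <- heavies[[j]]
      if (!nrow(ai) || !nrow(aj)) next
      # all-pairs squared distances chain i vs chain j
      d2 <- outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
            outer(ai$z, aj$z, "-")^2
      touching <- unique(ai$resno[rowSums(d2 <= cut2) > 0])
      flags[[i]]$interface <- flags[[i]]$interface |
        flags[[i]]$resno %in% touching
    }
  }
  do.call(rbind, c(flags, list(make.row.names = FALSE)))
}

#' Per-residue structure annotations for a protein set
#'
#' Runs SASA and interface detection over the qualifying chains, maps
#' everything onto canonical positions via each chain's `residue_map`, and
#' applies the disorder fallback, yielding one annotation row per
#' (uid, native position).
#'
#' @param proteins A `protein_entries` table.
#' @param chains Qualifying mapped chains (output of [filter_structures()]).
#' @param disorder Optional disorder data.frame (`uid`, `position`,
#'   `tendency`).
#' @param probe_radius,n_sphere_points Passed to [shrake_rupley_sasa()].
#' @param contact_cutoff Passed to [detect_interface_residues()].
#' @return data.frame `uid`, `position`, `resolved`, `sasa` (effective,
#'   `NA` when unavailable), `interface` (fraction of covering chains
#'   flagged), `disorder`.
#' @export
annotate_residue_structure <- function(proteins, chains, disorder = NULL,
                                       probe_radius = 1.4,
                                       n_sphere_points = 960,
                                       contact_cutoff = 5.0) {
  per_res <- list()
  if (length(chains)) {
    by_structure <- split(chains, vapply(chains, `[[`, "", "structure_id"))
    iface <- do.call(rbind, c(unname(lapply(by_structure,
      detect_interface_residues, contact_cutoff = contact_cutoff)),
      list(make.row.names = FALSE)))
    per_res <- lapply(chains, function(ch) {
      s <- shrake_rupley_sasa(ch, probe_radius, n_sphere_points)
      key <- paste(ch$structure_id, ch$chain_id, sep = ":")
      fl <- iface[iface$structure_id == ch$structure_id &
                  iface$chain_id == ch$chain_id, ]
      data.frame(uid = ch$uid,
                 position = unname(ch$residue_map[as.character(s$resno)]),
                 sasa = s$sasa,
                 interface = fl$interface[match(s$resno, fl$resno)],
                 stringsAsFactors = FALSE)
    })
  }
  obs <- if (length(per_res)) {
    do.call(rbind, c(per_res, list(make.row.names = FALSE)))
  } else {
    data.frame(uid = character(), position = integer(), sasa = numeric(),
               interface = logical())
  }
  out <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    uid <- proteins$uid[i]
    L <- nchar(proteins$sequence[i])
    rows <- obs[obs$uid == uid, , drop = FALSE]
    dis <- rep(0, L)
    if (!is.null(disorder)) {
      d <- disorder[disorder$uid == uid, , drop = FALSE]
      dis[d$position] <- d$tendency
    }
    chain_max <- if (nrow(rows)) max(rows$sasa) else NA_real_
    pos <- seq_len(L)
    eff <- numeric(L); ifr <- numeric(L); resolved <- logical(L)
    for (p in pos) {
      v <- rows$sasa[rows$position == p]
      resolved[p] <- length(v) > 0
      eff[p] <- effective_sasa(v, dis[p], chain_max)
      ifr[p] <- if (resolved[p]) mean(rows$interface[rows$position == p]) else 0
    }
    data.frame(uid = uid, position = pos, resolved = resolved, sasa = eff,
               interface = ifr, disorder = dis, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate structural annotations to MAP level
#'
#' `sasa` of a MAP is the mean effective SASA over its member observations
#' with a non-missing value (missing when none have one); `ppi` is the
#' fraction of members with structural coverage whose residue is
#' interface-flagged (0 when no member is covered).
#'
#' @param maps A `map_table`.
#' @param annotations Output of [annotate_residue_structure()].
#' @return The map table with `sasa` and `ppi` filled.
#' @export
aggregate_map_structure_features <- function(maps, annotations) {
  if (nrow(maps) == 0) return(maps)
  obs <- map_observations(maps)
  akey <- paste(annotations$uid, annotations$position)
  idx <- match(paste(obs$uid, obs$position), akey)
  obs_sasa <- annotations$sasa[idx]
  obs_iface <- annotations$interface[idx]
  obs_res <- annotations$resolved[idx]
  mkey <- paste(obs$family_id, obs$column)
  for (i in seq_len(nrow(maps))) {
    sel <- mkey == paste(maps$family_id[i], maps$column[i])
    sv <- obs_sasa[sel]
    maps$sasa[i] <- if (any(!is.na(sv))) mean(sv, na.rm = TRUE) else NA_real_
    covered <- which(sel & !is.na(obs_res) & obs_res)
    maps$ppi[i] <- if (length(covered)) mean(obs_iface[covered] > 0) else 0
  }
  maps
}
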