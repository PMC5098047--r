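# PTM-type coincidence: the network over mixed-type MAPs, relative edge
# counts, typical/atypical classification by residue chemistry, Tukey
# outlier edges, and disorder stratification of coincident positions.

#' Default PTM-type residue-compatibility table
#'
#' Maps each PTM type to the residues it can chemically modify; used to
#' classify coincidence edges as typical (the two types can modify the same
#' residue) or atypical. User-overridable.
#'
#' @return Named list: PTM type -> character vector of one-letter residues.
#' @export
default_ptm_compatibility <- function() {
  list(
    Phosphorylation = c("S", "T", "Y"),
    Ubiquitination = "K",
    Sumoylation = "K",
    Neddylation = "K",
    Acetylation = "K",
    Methylation = c("K", "R"),
    Citrullination = "R",
    `N-linked Glycosylation` = "N",
    `O-linked Glycosylation` = c("S", "T"),
    Hydroxylation = c("P", "K"),
    `S-nitrosylation` = "C",
    Disulfide = "C",
    Palmitoylation = "C",
    Glutathionylation = "C",
    Prenylation = "C",
    Myristoylation = "G",
    `Gamma-carboxyglutamic acid` = "E",
    `Pyrrolidone carboxylic acid` = "Q"
  )
}

map_type_sets <- function(maps) {
  strsplit(maps$ptm_types, ";", fixed = TRUE)
}

#' Build the PTM-type coincidence network
#'
#' Restricts to mixed-type MAPs (two or more distinct PTM types). Each
#' unordered pair of types present in a MAP increments that pair's edge
#' count; a node's occurrence is the number of coincident MAPs containing
#' the type. When `total_type_counts` is given (type occurrences in the
#' full dataset), each node also carries its percentage of that total.
#'
#' @param maps A `map_table`.
#' @param total_type_counts Optional named vector of dataset-wide type
#'   occurrence counts.
#' @return A `coincidence_network`: list with `nodes` (`type`,
#'   `occurrence`, `pct_of_total`), `edges` (`type_a`, `type_b`, `count`),
#'   and `type_count_distribution` (mixed-type MAPs by number of types).
#' @export
build_coincidence_network <- function(maps, total_type_counts = NULL) {
  sets <- map_type_sets(maps)
  k <- lengths(sets)
  mixed <- sets[k >= 2]
  if (!length(mixed)) {
    warning("no mixed-type MAPs; empty coincidence network")
  }
  nodes_tab <- table(unlist(lapply(mixed, unique)))
  pairs <- do.call(rbind, lapply(mixed, function(s) {
    s <- sort(unique(s))
    t(utils::combn(s, 2))
  }))
  edges <- if (is.null(pairs)) {
    data.frame(type_a = character(), type_b = character(), count = integer())
  } else {
    agg <- table(paste(pairs[, 1], pairs[, 2], sep = "\r"))
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    data.frame(type_a = vapply(parts, `[`, "", 1),
               type_b = vapply(parts, `[`, "", 2),
               count = as.integer(agg), stringsAsFactors = FALSE)
  }
  nodes <- data.frame(type = names(nodes_tab),
                      occurrence = as.integer(nodes_tab),
                      stringsAsFactors = FALSE)
  nodes$pct_of_total <- if (!is.null(total_type_counts)) {
    100 * nodes$occurrence / as.numeric(total_type_counts[nodes$type])
  } else rep(NA_real_, nrow(nodes))
  dist <- table(factor(pmin(k[k >= 2], 5), levels = 2:5,
                       labels = c("2", "3", "4", "5+")))
  structure(list(nodes = nodes, edges = edges,
                 type_count_distribution = dist,
                 n_mixed_maps = sum(k >= 2), n_maps = length(k)),
            class = "coincidence_network")
}

#' @export
print.coincidence_network <- function(x, ...) {
  cat(sprintf("coincidence_network: %d nodes, %d edges, %d/%d mixed-type MAPs\n",
              nrow(x$nodes), nrow(x$edges), x$n_mixed_maps, x$n_maps))
  invisible(x)
}

#' Relative edge count
#'
#' For an edge (a, b): `count(a, b) / (occurrence(a) + occurrence(b))`,
#' times a display scale (analysis uses scale 1). The normalization removes
#' the bias toward frequently observed PTM types.
#'
#' @param network A `coincidence_network`.
#' @param scale Display multiplier (default 1).
#' @return The network with `relative_edge_count` added to the edge table.
#' @export
relative_edge_count <- function(network, scale = 1) {
  occ <- stats::setNames(network$nodes$occurrence, network$nodes$type)
  e <- network$edges
  network$edges$relative_edge_count <-
    scale * e$count / (occ[e$type_a] + occ[e$type_b])
  network
}

#' Classify edges as typical or atypical
#'
#' An edge is typical iff the two PTM types can modify at least one common
#' residue according to the compatibility table; otherwise atypical.
#'
#' @param network A `coincidence_network`.
#' @param compatibility Named list, type -> residues
#'   (default [default_ptm_compatibility()]); every network type must be
#'   covered.
#' @return The network with a logical `typical` flag per edge.
#' @export
classify_edges_typical <- function(network,
                                   compatibility = default_ptm_compatibility()) {
  types <- network$nodes$type
  missing <- setdiff(types, names(compatibility))
  if (length(missing)) {
    stop("no residue compatibility entry for type(s): ",
         paste(missing, collapse = ", "))
  }
  e <- network$edges
  network$edges$typical <- mapply(function(a, b) {
    length(intersect(compatibility[[a]], compatibility[[b]])) > 0
  }, e$type_a, e$type_b, USE.NAMES = FALSE)
  network
}

#' Tukey-fence outlier edges per typicality group
#'
#' Within each group (typical / atypical), an edge is an outlier when its
#' value exceeds `Q3 + 1.5 * IQR`, quartiles by linear interpolation.
#' Groups with fewer than 4 values are undefined (warning, no flags).
#'
#' @param values Numeric values (e.g. relative edge counts).
#' @param groups Grouping vector aligned with `values`.
#' @return Logical outlier flags aligned with `values`.
#' @export
detect_outlier_edges <- function(values, groups) {
  out <- rep(FALSE, length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 4) {
      warning("group '", g, "' has fewer than 4 values; outliers undefined")
      out[idx] <- NA
      next
    }
    q <- stats::quantile(values[idx], c(0.25, 0.75), type = 7, names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    out[idx] <- values[idx] > fence
  }
  out
}

#' Disorder distribution of coincident modified residues
#'
#' For each mixed-type class (2, 3, 4, 5+ PTM types per MAP), collects the
#' disorder tendencies of the member modified residues and the ordered
#' fraction (tendency <= 0.5). Classes with no MAPs are omitted.
#'
#' @param maps A `map_table`.
#' @param disorder Disorder data.frame (`uid`, `position`, `tendency`).
#' @return data.frame `n_types`, `n_residues`, `ordered_fraction`, with the
#'   raw tendency vectors in `attr(, "tendencies")`.
#' @export
coincident_disorder_distribution <- function(maps, disorder) {
  sets <- map_type_sets(maps)
  k <- lengths(sets)
  obs <- map_observations(maps)
  dkey <- paste(disorder$uid, disorder$position)
  classes <- c("2", "3", "4", "5+")
  keep <- list()
  rows <- lapply(classes, function(cl) {
    sel <- if (cl == "5+") k >= 5 else k == as.integer(cl)
    if (!any(sel)) return(NULL)
    mk <- paste(maps$family_id[sel], maps$column[sel])
    o <- obs[paste(obs$family_id, obs$column) %in% mk, , drop = FALSE]
    tend <- disorder$tendency[match(paste(o$uid, o$position), dkey)]
    tend <- tend[!is.na(tend)]
    keep[[cl]] <<- tend
    data.frame(n_types = cl, n_residues = length(tend),
               ordered_fraction = if (length(tend)) mean(tend <= 0.5)
                                  else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tendencies") <- keep
  out
}

#' Export the coincidence network as node/edge TSVs
#'
#' @param network A `coincidence_network` (after [relative_edge_count()]
#'   and [classify_edges_typical()] for the full column set).
#' @param node_path,edge_path Output paths.
#' @export
write_network <- function(network, node_path, edge_path) {
  utils::write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  e <- network$edges
  names(e)[names(e) == "type_a"] <- "source"
  names(e)[names(e) == "type_b"] <- "target"
  utils::write.table(e, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_path, edge_path))
}
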