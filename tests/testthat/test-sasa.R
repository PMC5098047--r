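# Shrake-Rupley SASA, the disorder fallback, interface detection and MAP
# aggregation.

# closed-form accessible area of two intersecting solvent-expanded spheres:
# the buried part of sphere 1 is a spherical cap of height
# h1 = R1 - (d^2 + R1^2 - R2^2) / (2 d), area 2 pi R1 h1
two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * c(R1^2, R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * h1,
    4 * pi * R2^2 - 2 * pi * R2 * h2)
}

test_that("a single isolated atom has the analytic sphere area", {
  ch <- toy_chain(cbind(1.3, -2.1, 0.7), element = "C")
  s <- shrake_rupley_sasa(ch, probe_radius = 1.4)
  expect_equal(s$sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)

  # nitrogen radius differs
  sn <- shrake_rupley_sasa(toy_chain(cbind(0, 0, 0), element = "N"))
  expect_equal(sn$sasa, 4 * pi * (1.55 + 1.4)^2, tolerance = 0.01)
})

test_that("far-separated atoms are additive full spheres", {
  ch <- toy_chain(rbind(c(0, 0, 0), c(100, 0, 0)), resno = c(1, 2))
  s <- shrake_rupley_sasa(ch)
  expect_equal(s$sasa, rep(4 * pi * (1.70 + 1.4)^2, 2), tolerance = 0.01)
})

test_that("two overlapping atoms match the closed-form cap oracle within 2%", {
  R <- 1.70 + 1.4
  for (d in c(1.5, 2.5, 4.0, 5.5)) {
    ch <- toy_chain(rbind(c(0, 0, 0), c(d, 0, 0)), resno = c(1, 2))
    s <- shrake_rupley_sasa(ch)
    oracle <- two_sphere_sasa(R, R, d)
    expect_equal(s$sasa, oracle, tolerance = 0.02,
                 info = paste("separation", d))
  }
})

test_that("SASA is rotation- and translation-invariant", {
  ch <- helix_chain(20)
  base <- shrake_rupley_sasa(ch)
  th <- 0.83
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(ch$atoms[, c("x", "y", "z")]) %*% rot
  moved <- ch
  moved$atoms$x <- xyz[, 1] + 11.2
  moved$atoms$y <- xyz[, 2] - 3.7
  moved$atoms$z <- xyz[, 3] + 0.5
  s2 <- shrake_rupley_sasa(moved)
  expect_equal(s2$sasa, base$sasa, tolerance = 1e-6)
})

test_that("SASA converges with sphere-point density", {
  ch <- helix_chain(10)   # 50 atoms
  s960 <- shrake_rupley_sasa(ch, n_sphere_points = 960)
  s3840 <- shrake_rupley_sasa(ch, n_sphere_points = 3840)
  expect_lt(abs(sum(s960$sasa) - sum(s3840$sasa)) / sum(s3840$sasa), 0.01)
  # per-residue agreement stays within discretization noise
  expect_lt(max(abs(s960$sasa - s3840$sasa) / s3840$sasa), 0.05)
})

test_that("unknown elements fall back to the default radius with a warning", {
  ch <- toy_chain(cbind(0, 0, 0), element = "Q")
  expect_warning(s <- shrake_rupley_sasa(ch), "unknown element")
  expect_equal(s$sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
})

test_that("effective SASA applies the disorder fallback rule", {
  # resolved in two chains -> mean
  expect_equal(effective_sasa(c(30, 50), disorder = 0.9), 40)
  # unresolved + disordered -> maximal observed per-residue SASA
  expect_equal(effective_sasa(numeric(0), disorder = 0.8,
                              chain_max_sasa = 123.4), 123.4)
  # unresolved + ordered -> no value at all
  expect_true(is.na(effective_sasa(numeric(0), disorder = 0.3,
                                   chain_max_sasa = 123.4)))
  # boundary: 0.5 is not disordered
  expect_true(is.na(effective_sasa(numeric(0), disorder = 0.5,
                                   chain_max_sasa = 99)))
})

test_that("interface detection respects the contact cutoff exactly", {
  mk2 <- function(d) {
    list(toy_chain(cbind(0, 0, 0), structure_id = "S", chain_id = "A"),
         toy_chain(cbind(d, 0, 0), structure_id = "S", chain_id = "B"))
  }
  near <- detect_interface_residues(mk2(4.9), contact_cutoff = 5)
  expect_true(all(near$interface))
  far <- detect_interface_residues(mk2(5.1), contact_cutoff = 5)
  expect_false(any(far$interface))

  # single chain -> no partner, no interface
  solo <- detect_interface_residues(list(helix_chain(5)))
  expect_false(any(solo$interface))

  # a residue far from the partner chain is not flagged
  chA <- toy_chain(rbind(c(0, 0, 0), c(30, 0, 0)), resno = c(1, 2),
                   structure_id = "S", chain_id = "A")
  chB <- toy_chain(cbind(3, 0, 0), structure_id = "S", chain_id = "B")
  res <- detect_interface_residues(list(chA, chB))
  expect_equal(res$interface[res$chain_id == "A"], c(TRUE, FALSE))
})

test_that("interface flags agree with a brute-force all-pairs oracle and are symmetric", {
  set.seed(31)
  chA <- helix_chain(8, "S", "A")
  chB <- helix_chain(8, "S", "B")
  chB$atoms$x <- chB$atoms$x + 9
  res <- detect_interface_residues(list(chA, chB), contact_cutoff = 5)
  oracle_flag <- function(me, other) {
    vapply(sort(unique(me$atoms$resno)), function(r) {
      a <- me$atoms[me$atoms$resno == r, ]
      any(vapply(seq_len(nrow(a)), function(i) {
        d2 <- (other$atoms$x - a$x[i])^2 + (other$atoms$y - a$y[i])^2 +
              (other$atoms$z - a$z[i])^2
        any(d2 <= 25)
      }, logical(1)))
    }, logical(1))
  }
  expect_equal(res$interface[res$chain_id == "A"], oracle_flag(chA, chB))
  expect_equal(res$interface[res$chain_id == "B"], oracle_flag(chB, chA))
  expect_equal(any(res$interface[res$chain_id == "A"]),
               any(res$interface[res$chain_id == "B"]))
})

test_that("residue annotations aggregate correctly to MAP level", {
  pe <- protein_entries(c("P1", "P2", "P3"), c("SSS", "SSS", "SSS"), "F")
  ann <- data.frame(uid = rep(c("P1", "P2", "P3"), each = 3),
                    position = rep(1:3, 3),
                    resolved = c(TRUE, TRUE, FALSE,
                                 TRUE, FALSE, FALSE,
                                 TRUE, TRUE, TRUE),
                    sasa = c(20, 30, NA, 40, NA, NA, 10, 50, 60),
                    interface = c(1, 0, 0, 1, 0, 0, 0, 0, 1),
                    disorder = 0.2)
  aln <- family_alignment("F", c("P1", "P2", "P3"), c("SSS", "SSS", "SSS"))
  maps <- build_maps(aln, ptm_rows(c("P1", "P2", "P3"), c(1, 1, 1), "S"))
  maps <- aggregate_map_structure_features(maps, ann)
  expect_equal(maps$sasa, mean(c(20, 40, 10)))
  # one of three covered members is interface-flagged... P1 yes, P2 yes, P3 no
  expect_equal(maps$ppi, 2 / 3)

  # a MAP with no coverage at all: sasa missing, ppi 0
  maps2 <- build_maps(aln, ptm_rows("P2", 3, "S"))
  maps2 <- aggregate_map_structure_features(maps2, ann)
  expect_true(is.na(maps2$sasa))
  expect_equal(maps2$ppi, 0)
})

test_that("the full annotation path never invents SASA for ordered unresolved residues", {
  pe <- protein_entries("P1", paste(rep("A", 80), collapse = ""), "F")
  ch <- helix_chain(60, "S1", "A")
  ch <- map_resolved_to_canonical(ch, pe$sequence)
  ch$uid <- "P1"
  dis <- data.frame(uid = "P1", position = 1:80,
                    tendency = rep(c(0.2, 0.9), each = 40))
  ann <- annotate_residue_structure(pe, list(ch), dis,
                                    n_sphere_points = 240)
  unresolved <- ann[!ann$resolved, ]
  ordered <- unresolved[unresolved$disorder <= 0.5, ]
  disordered <- unresolved[unresolved$disorder > 0.5, ]
  expect_true(all(is.na(ordered$sasa)))
  expect_true(all(!is.na(disordered$sasa)))
  expect_equal(unique(disordered$sasa), max(ann$sasa[ann$resolved]))
})
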