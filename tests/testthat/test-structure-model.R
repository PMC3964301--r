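# Structure reading and Go-model construction: PDB round trips, bead
# extraction, contact detection against a brute-force oracle, hydrogen-bond
# terms, topology combinatorics and serialization.

test_that("PDB round trip preserves coordinates to writing precision", {
  h <- fh_hairpin()
  path <- tempfile(fileext = ".pdb")
  write_structure(h, path)
  h2 <- read_structure(path)
  expect_equal(n_residues(h2), 31L)
  expect_lt(max(abs(calpha_coords(h2) - calpha_coords(h))), 1e-3)
  expect_equal(residue_names(h2), residue_names(h))
})

test_that("toy PDB parses and error paths identify the offender", {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2      12.967   8.110  -5.000  1.00  0.00           C",
    "ATOM      4  CB  GLY A   2      13.500   8.500  -4.000  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- read_structure(path)
  expect_equal(n_residues(s), 2L)
  expect_equal(nrow(s$atoms), 4L)

  # residue 2 without a Calpha must be named in the error
  writeLines(lines[c(1, 2, 4, 5)], path)
  expect_error(read_structure(path), "CA")

  # mangled coordinate field reported with its line number
  bad <- lines
  bad[3] <- sub("12.967", "12.9x7", bad[3])
  writeLines(bad, path)
  expect_error(read_structure(path), "line 3")
})

test_that("beads carry Calpha positions and tabulated residue masses", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  b <- extract_beads(read_structure(path))
  expect_equal(nrow(b), 1L)
  expect_equal(b$mass, unname(residue_masses["GLY"]))

  hb <- extract_beads(fh_hairpin())
  expect_equal(nrow(hb), 31L)         # fibroin-H fragment size
  expect_equal(hb$index, 1:31)

  s <- fh_hairpin()
  s$atoms$res_name[s$atoms$res_index == 5L] <- "XXX"
  expect_error(extract_beads(s), "XXX")
})

test_that("contact detection matches the brute-force all-pairs oracle", {
  h <- make_beta_hairpin(5L)
  got <- native_contacts(h, scheme = "calpha")
  want <- brute_force_contacts(h, 6.5, calpha_only = TRUE)
  expect_equal(got[, c("i", "j")], want, ignore_attr = TRUE)

  # same oracle at a different cutoff and on a sandwich
  spec <- fold_spec(n_strands = 3L, residues_per_strand = 4L,
                    strands_per_sheet = 2L)
  sw <- make_beta_sandwich(spec)
  for (cut in c(5, 6.5, 8)) {
    got <- native_contacts(sw, cutoff = cut, scheme = "calpha")
    want <- brute_force_contacts(sw, cut, calpha_only = TRUE)
    expect_equal(got[, c("i", "j")], want, ignore_attr = TRUE)
  }

  # sigma anchors the native distance
  ca <- calpha_coords(h)
  got <- native_contacts(h, scheme = "calpha")
  d <- sqrt(rowSums((ca[got$i, , drop = FALSE] - ca[got$j, , drop = FALSE])^2))
  expect_equal(got$sigma, d)
})

test_that("short-range pairs are excluded regardless of distance", {
  # residues i and i+2 nearly on top of each other: still no contact
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(0.5, 0.5, 0), c(4.0, 0.5, 0),
              c(0.6, 1.0, 0))
  at <- data.frame(res_index = 1:5, res_name = "GLY", res_seq = 1:5,
                   atom_name = "CA", element = "C",
                   x = ca[, 1], y = ca[, 2], z = ca[, 3])
  s <- aastructure(at)
  con <- native_contacts(s, scheme = "calpha")
  expect_true(all(con$j - con$i >= 4))
  # far pair with a generous cutoff is still not a contact
  expect_false(any(con$sigma > 6.5))
  # a structure too short to host any admissible pair gives an empty set
  expect_equal(nrow(native_contacts(make_extended_chain(4), scheme = "calpha")),
               0L)
})

test_that("contact energy schemes set and renormalize well depths", {
  con <- data.frame(i = c(1L, 1L, 2L, 3L, 5L), j = c(5L, 6L, 7L, 8L, 9L),
                    sigma = 5, epsilon = NA_real_, is_hbond = FALSE)
  seqn <- rep(c("ILE", "GLY", "SER"), 3)
  uni <- assign_contact_energies(con, seqn, "uniform", epsilon = 1.0)
  expect_true(all(uni$epsilon == 1.0))
  stat <- assign_contact_energies(con, seqn, "statistical", epsilon = 1.3)
  expect_equal(mean(stat$epsilon), 1.3, tolerance = 1e-12)
  expect_gt(var(stat$epsilon), 0)
  expect_equal(nrow(assign_contact_energies(con[0, ], seqn, "uniform")), 0L)
  expect_error(assign_contact_energies(con, seqn, "uniform", epsilon = -1),
               "positive")
})

test_that("hydrogen-bond detection counts ideal cross-strand geometries", {
  all_pairs <- make_beta_hairpin(14L, backbone = TRUE, skip_turn_pair = FALSE)
  hb <- detect_native_hbonds(all_pairs)
  expect_equal(nrow(hb), 14L)          # every registered pair
  expect_true(all(hb$is_hbond))

  fh <- fh_hairpin()                   # turn-adjacent pair left out
  expect_equal(nrow(detect_native_hbonds(fh)), 13L)

  expect_message(hb0 <- detect_native_hbonds(make_beta_hairpin(6L)),
                 "skipped")
  expect_equal(nrow(hb0), 0L)
})

test_that("model topology has chain combinatorics and is deterministic", {
  ch <- make_extended_chain(3L)
  m3 <- suppressMessages(build_go_model(ch))
  expect_equal(nrow(m3$bonds), 2L)
  expect_equal(nrow(m3$angles), 1L)
  expect_equal(nrow(m3$dihedrals), 0L)
  expect_equal(nrow(m3$contacts), 0L)

  m <- fh_model()
  n <- nrow(m$beads)
  expect_equal(nrow(m$bonds), n - 1L)
  expect_equal(nrow(m$angles), n - 2L)
  expect_equal(m$bonds$r0,
               sqrt(rowSums(diff(as.matrix(m$beads[, c("x", "y", "z")]))^2)))
  expect_equal(sum(m$contacts$is_hbond), 13L)
  # H-bond contacts carry the energy bonus
  expect_true(all(m$contacts$epsilon[m$contacts$is_hbond] == 1.5))

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_topology(build_go_model(fh_hairpin()), f1)
  write_topology(build_go_model(fh_hairpin()), f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical builds

  m2 <- read_topology(f1)
  expect_equal(m2$contacts, m$contacts, tolerance = 1e-12)
  expect_equal(m2$bonds, m$bonds, tolerance = 1e-12)
})

test_that("chain breaks are flagged unless overridden", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(9.0, 0, 0))
  at <- data.frame(res_index = 1:3, res_name = "GLY", res_seq = 1:3,
                   atom_name = "CA", element = "C",
                   x = ca[, 1], y = ca[, 2], z = ca[, 3])
  s <- aastructure(at)
  expect_error(suppressMessages(build_go_model(s)), "chain break")
  expect_s3_class(
    suppressMessages(build_go_model(s, allow_chain_breaks = TRUE)),
    "go_model")
})

test_that("native end distance is in nm and rigid-transform invariant", {
  m2 <- suppressMessages(build_go_model(make_extended_chain(2L)))
  expect_equal(native_end_distance(m2), 0.38)

  m <- fh_model()
  d0 <- native_end_distance(m)
  for (sd in 1:5) {
    mt <- m
    xyz <- rigid_transform(as.matrix(m$beads[, c("x", "y", "z")]), seed = sd)
    mt$beads$x <- xyz[, 1]; mt$beads$y <- xyz[, 2]; mt$beads$z <- xyz[, 3]
    expect_equal(native_end_distance(mt), d0, tolerance = 1e-9)
  }
})
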