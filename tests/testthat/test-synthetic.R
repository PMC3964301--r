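# Synthetic beta-fold generators: sizes, lattice geometry, strand-count
# recovery, topology permutations, determinism.

test_that("hairpin has the fibroin-H-like size and registered geometry", {
  h <- make_beta_hairpin(14L, loop_length = 3L)
  expect_equal(n_residues(h), 31L)

  ca <- calpha_coords(h)
  n <- 14L
  partners <- (2L * n + 4L) - (1:n) # antiparallel register (loop = 3)
  d <- sqrt(rowSums((ca[1:n, ] - ca[partners, ])^2))
  expect_equal(d, rep(4.8, n), tolerance = 1e-6)

  # every registered cross-strand pair appears in the Calpha contact set
  con <- native_contacts(h, scheme = "calpha")
  key <- paste(con$i, con$j)
  reg <- paste(pmin(1:n, partners), pmax(1:n, partners))
  in_range <- abs(partners - (1:n)) > 3   # all but turn-adjacent pairs
  expect_true(all(reg[in_range] %in% key))

  expect_error(make_beta_hairpin(14L, spacing = 2.0), "spacing")
  # strand arithmetic: rise fixes the strand end-to-end length
  h10 <- make_beta_hairpin(10L, rise = 3.4)
  ca10 <- calpha_coords(h10)
  expect_equal(sqrt(sum((ca10[10, ] - ca10[1, ])^2)), 9 * 3.4,
               tolerance = 1e-6)
})

test_that("sandwich generator recovers the requested strand counts", {
  cnt_like <- fold_spec(n_strands = 7L, residues_per_strand = 12L,
                        strands_per_sheet = 4L)
  sw <- make_beta_sandwich(cnt_like)
  expect_equal(n_residues(sw), fold_spec_n_residues(cnt_like))
  expect_equal(count_strands(sw, min_run = 8L), 7L)

  nrx_like <- fold_spec(n_strands = 13L, residues_per_strand = 10L,
                        strands_per_sheet = 7L)
  expect_equal(count_strands(make_beta_sandwich(nrx_like), min_run = 7L), 13L)

  # same-strand residues collinear to tight tolerance
  ca <- calpha_coords(sw)
  strand_of <- attr(sw, "strand_of")
  for (s in unique(strand_of[strand_of > 0])) {
    seg <- ca[strand_of == s, ]
    b <- diff(seg); b <- b / sqrt(rowSums(b^2))
    expect_lt(max(abs(sweep(b, 2, b[1, ]) )), 1e-6)
  }
})

test_that("topology order permutes the contact map, not the size", {
  base <- fold_spec(n_strands = 7L, residues_per_strand = 8L,
                    strands_per_sheet = 4L)
  greek <- fold_spec(n_strands = 7L, residues_per_strand = 8L,
                     strands_per_sheet = 4L,
                     topology_order = c(2L, 1L, 4L, 3L, 6L, 5L, 7L))
  s1 <- make_beta_sandwich(base)
  s2 <- make_beta_sandwich(greek)
  expect_equal(n_residues(s1), n_residues(s2))
  c1 <- native_contacts(s1, scheme = "calpha")
  c2 <- native_contacts(s2, scheme = "calpha")
  expect_false(identical(paste(c1$i, c1$j), paste(c2$i, c2$j)))

  expect_error(fold_spec(n_strands = 4L, strands_per_sheet = 2L,
                         topology_order = c(1L, 2L, 3L, 3L)),
               "permutation")
})

test_that("extended chain is the contour-length reference", {
  ch2 <- make_extended_chain(2L)
  expect_equal(sqrt(sum((calpha_coords(ch2)[2, ] - calpha_coords(ch2)[1, ])^2)),
               3.8)
  ch <- make_extended_chain(31L)
  m <- suppressMessages(build_go_model(ch))
  expect_equal(native_end_distance(m), 11.4)   # 30 * 3.8 A in nm
  expect_equal(contour_length(m), 11.4)
  expect_equal(nrow(m$contacts), 0L)
})

test_that("generators are deterministic", {
  expect_identical(make_beta_hairpin(9L, backbone = TRUE),
                   make_beta_hairpin(9L, backbone = TRUE))
  spec <- fold_spec(n_strands = 5L, residues_per_strand = 6L,
                    strands_per_sheet = 3L)
  expect_identical(make_beta_sandwich(spec), make_beta_sandwich(spec))
})
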