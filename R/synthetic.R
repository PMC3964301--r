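## Deterministic generators of idealized beta-fold Calpha geometries:
## a two-strand antiparallel hairpin (fibroin-H-like), flat two-sheet
## beta-sandwiches with configurable strand topology (FnIII / LNS-like), and
## a fully extended chain used as the contour-length reference state.
## Geometry uses textbook beta-strand parameters; no randomness anywhere.

.default_residue <- "GLY"

#' Specification of a two-sheet beta-sandwich fold
#'
#' @param n_strands Number of beta strands.
#' @param residues_per_strand Residues in each strand.
#' @param strands_per_sheet Strands placed in the first sheet; the remainder
#'   forms the second sheet.
#' @param strand_spacing Inter-strand Calpha spacing within a sheet, Angstrom.
#' @param residue_rise Per-residue rise along a strand, Angstrom.
#' @param sheet_separation Distance between the two sheet planes, Angstrom.
#' @param loop_length Residues in each connecting loop.
#' @param topology_order Permutation of `1:n_strands`: spatial slot occupied
#'   by each sequence-consecutive strand. The default meanders — up the first
#'   sheet, across at the adjacent edge, back down the second sheet — so
#'   every loop connects nearby strand ends; other permutations give
#'   Greek-key-like topologies.
#' @return A `fold_spec` list.
#' @export
fold_spec <- function(n_strands = 7L, residues_per_strand = 12L,
                      strands_per_sheet = 4L, strand_spacing = 4.8,
                      residue_rise = 3.4, sheet_separation = 10,
                      loop_length = 3L,
                      topology_order = c(seq_len(strands_per_sheet),
                                         rev(seq(strands_per_sheet + 1L,
                                                 n_strands)))) {
  stopifnot(n_strands >= 2L, residues_per_strand >= 3L,
            strands_per_sheet >= 1L, strands_per_sheet < n_strands,
            strand_spacing > 0, residue_rise > 0, sheet_separation > 0,
            loop_length >= 1L)
  if (length(topology_order) != n_strands ||
      !setequal(topology_order, seq_len(n_strands))) {
    stop("topology_order must be a permutation of 1:n_strands")
  }
  structure(list(
    n_strands = as.integer(n_strands),
    residues_per_strand = as.integer(residues_per_strand),
    strands_per_sheet = as.integer(strands_per_sheet),
    strand_spacing = strand_spacing,
    residue_rise = residue_rise,
    sheet_separation = sheet_separation,
    loop_length = as.integer(loop_length),
    topology_order = as.integer(topology_order)
  ), class = "fold_spec")
}

#' Total residue count implied by a fold spec
#' @param spec A [fold_spec()].
#' @return Integer.
#' @export
fold_spec_n_residues <- function(spec) {
  spec$n_strands * spec$residues_per_strand +
    (spec$n_strands - 1L) * spec$loop_length
}

.atoms_from_ca <- function(ca, res_names, extra = NULL) {
  n <- nrow(ca)
  atoms <- data.frame(
    res_index = seq_len(n), res_name = res_names, res_seq = seq_len(n),
    atom_name = "CA", element = "C",
    x = ca[, 1], y = ca[, 2], z = ca[, 3],
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    atoms <- rbind(atoms, extra)
    atoms <- atoms[order(atoms$res_index,
                         match(atoms$atom_name, c("N", "CA", "O"))), ]
    rownames(atoms) <- NULL
  }
  atoms
}

#' Idealized antiparallel beta-hairpin
#'
#' Two antiparallel strands joined by a short turn, built on a flat lattice:
#' residue `k` of strand one faces residue `2n + loop - 1 - k` of strand two
#' at the configured inter-strand spacing. With `backbone = TRUE`, carbonyl O
#' and amide N pseudo-atoms are placed across the strand gap so that every
#' registered cross-strand pair carries one O...N geometry at `hbond_length`;
#' with `skip_turn_pair = TRUE` the pair adjacent to the turn donates its
#' carbonyl to the turn instead, as in real hairpins, so a hairpin with `n`
#' residues per strand carries `n - 1` hydrogen-bond geometries (13 for the
#' 14 + 3 + 14 fibroin-H-like default).
#'
#' @param residues_per_strand Residues per strand (>= 3); default 14 gives the
#'   31-residue fibroin-H-like fragment.
#' @param spacing Inter-strand Calpha spacing, Angstrom (>= 3).
#' @param rise Per-residue rise along the strand, Angstrom.
#' @param loop_length Turn residues between the strands.
#' @param backbone Place ideal backbone N/O pseudo-atoms for hydrogen-bond
#'   detection.
#' @param hbond_length N...O distance of the ideal cross-strand hydrogen bond,
#'   Angstrom.
#' @param skip_turn_pair Leave the turn-adjacent registered pair without a
#'   hydrogen-bond geometry.
#' @param res_names Residue names recycled over the chain (default polyglycine).
#' @return An [aastructure()].
#' @export
make_beta_hairpin <- function(residues_per_strand = 14L, spacing = 4.8,
                              rise = 3.4, loop_length = 3L, backbone = FALSE,
                              hbond_length = 2.9, skip_turn_pair = TRUE,
                              res_names = .default_residue) {
  n <- as.integer(residues_per_strand)
  if (n < 3L) stop("residues_per_strand must be >= 3")
  if (spacing < 3) stop("non-physical inter-strand spacing (< 3 Angstrom)")
  stopifnot(rise > 0, loop_length >= 1L)
  n_total <- 2L * n + loop_length
  ca <- matrix(NA_real_, n_total, 3)
  # strand 1 along +z at x = 0, strand 2 antiparallel at x = spacing
  ca[1:n, ] <- cbind(0, 0, (0:(n - 1)) * rise)
  s2 <- (n + loop_length + 1L):n_total
  ca[s2, ] <- cbind(spacing, 0, ((n - 1):0) * rise)
  # turn: arched in the x-z plane above the strand tops
  z_top <- (n - 1) * rise
  l <- seq_len(loop_length)
  frac <- l / (loop_length + 1)
  arch <- sqrt(max(0, (0.9 * rise)^2 * (loop_length + 1)^2 - spacing^2)) / 2
  ca[n + l, ] <- cbind(spacing * frac, 0, z_top + arch * sinpi(frac))
  res_names <- toupper(rep_len(res_names, n_total))
  extra <- NULL
  if (backbone) {
    delta <- (spacing - hbond_length) / 2
    rows <- list()
    for (k in 1:n) {                 # strand 1: carbonyl O toward strand 2
      if (!(skip_turn_pair && k == n)) {
        rows[[length(rows) + 1L]] <- data.frame(
          res_index = k, res_name = res_names[k], res_seq = k,
          atom_name = "O", element = "O",
          x = delta, y = 0, z = ca[k, 3], stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(   # amide N points away
        res_index = k, res_name = res_names[k], res_seq = k,
        atom_name = "N", element = "N",
        x = -delta, y = 0, z = ca[k, 3], stringsAsFactors = FALSE)
    }
    for (k in s2) {                  # strand 2: amide N toward strand 1
      rows[[length(rows) + 1L]] <- data.frame(
        res_index = k, res_name = res_names[k], res_seq = k,
        atom_name = "N", element = "N",
        x = spacing - delta, y = 0, z = ca[k, 3], stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        res_index = k, res_name = res_names[k], res_seq = k,
        atom_name = "O", element = "O",
        x = spacing + delta, y = 0, z = ca[k, 3], stringsAsFactors = FALSE)
    }
    extra <- do.call(rbind, rows)
  }
  aastructure(.atoms_from_ca(ca, res_names, extra), chain = "A")
}

#' Idealized two-sheet beta-sandwich
#'
#' Strands are laid out on two flat sheets separated by
#' `spec$sheet_separation`; spatial slot `topology_order[s]` receives the
#' `s`-th strand of the sequence, strand direction alternates along the
#' sequence so loops connect adjacent ends, and loops bulge outward away from
#' the sandwich core.
#'
#' @param spec A [fold_spec()].
#' @param res_names Residue names recycled over the chain.
#' @return An [aastructure()].
#' @export
make_beta_sandwich <- function(spec, res_names = .default_residue) {
  stopifnot(inherits(spec, "fold_spec"))
  n_res <- fold_spec_n_residues(spec)
  nps <- spec$residues_per_strand
  ca <- matrix(NA_real_, n_res, 3)
  strand_of <- integer(0)
  z <- (0:(nps - 1)) * spec$residue_rise
  y_mid <- spec$sheet_separation / 2
  pos <- 1L
  anchors <- matrix(NA_real_, spec$n_strands, 3)  # start of each strand
  for (s in seq_len(spec$n_strands)) {
    slot <- spec$topology_order[s] - 1L
    in_sheet2 <- slot >= spec$strands_per_sheet
    x <- if (in_sheet2) {
      (slot - spec$strands_per_sheet) * spec$strand_spacing +
        spec$strand_spacing / 2           # staggered second sheet
    } else {
      slot * spec$strand_spacing
    }
    y <- if (in_sheet2) spec$sheet_separation else 0
    zz <- if (s %% 2L == 1L) z else rev(z) # antiparallel along sequence
    rows <- pos:(pos + nps - 1L)
    ca[rows, ] <- cbind(x, y, zz)
    strand_of <- c(strand_of, rep(s, nps))
    anchors[s, ] <- ca[rows[1L], ]
    if (s < spec$n_strands) {             # loop to the next strand
      a <- ca[rows[nps], ]
      pos <- pos + nps
      # peek next strand start
      slot_n <- spec$topology_order[s + 1L] - 1L
      in2 <- slot_n >= spec$strands_per_sheet
      xn <- if (in2) (slot_n - spec$strands_per_sheet) * spec$strand_spacing +
              spec$strand_spacing / 2 else slot_n * spec$strand_spacing
      yn <- if (in2) spec$sheet_separation else 0
      zn <- if ((s + 1L) %% 2L == 1L) z[1L] else rev(z)[1L]
      b <- c(xn, yn, zn)
      frac <- seq_len(spec$loop_length) / (spec$loop_length + 1)
      # bulge away from the slab midplane and beyond the strand ends;
      # shrink the bulge if it would stretch a virtual bond past 4.2 A
      out_y <- if (a[2] + b[2] > spec$sheet_separation) 1 else -1
      out_z <- if (a[3] > max(z) / 2) 1 else -1
      bulge <- 2.5
      repeat {
        lp <- cbind(a[1] + (b[1] - a[1]) * frac,
                    a[2] + (b[2] - a[2]) * frac + out_y * bulge * sinpi(frac),
                    a[3] + (b[3] - a[3]) * frac + out_z * bulge * sinpi(frac))
        seg <- diff(rbind(a, lp, b))
        if (max(sqrt(rowSums(seg^2))) <= 4.2 || bulge < 0.1) break
        bulge <- bulge * 0.7
      }
      rows_l <- pos:(pos + spec$loop_length - 1L)
      ca[rows_l, ] <- lp
      strand_of <- c(strand_of, rep(0L, spec$loop_length))
      pos <- pos + spec$loop_length
    }
  }
  res_names <- toupper(rep_len(res_names, n_res))
  out <- aastructure(.atoms_from_ca(ca, res_names), chain = "A")
  attr(out, "strand_of") <- strand_of
  out
}

#' Fully extended Calpha chain
#'
#' Collinear trace with constant consecutive spacing; its end-to-end distance
#' `(N - 1) * rise` is the contour length used as the full-stretch reference.
#'
#' @param n_residues Number of residues (>= 2).
#' @param rise Consecutive Calpha spacing, Angstrom (default 3.8, the virtual
#'   Calpha-Calpha bond length).
#' @param res_names Residue names recycled over the chain.
#' @return An [aastructure()].
#' @export
make_extended_chain <- function(n_residues, rise = 3.8,
                                res_names = .default_residue) {
  n <- as.integer(n_residues)
  stopifnot(n >= 2L, rise > 0)
  ca <- cbind(0, 0, (0:(n - 1)) * rise)
  aastructure(.atoms_from_ca(ca, toupper(rep_len(res_names, n))), chain = "A")
}

#' Count beta strands of a Calpha trace by bond-direction runs
#'
#' Diagnostic used to verify generated sandwich topologies: consecutive
#' Calpha-Calpha bond vectors that stay (anti)parallel to the first bond of a
#' run (|cos| > `tol_cos`) are grouped, and runs of at least `min_run` bonds
#' count as strands. Loop regions change direction and break runs.
#'
#' @param x An [aastructure()].
#' @param min_run Minimum number of collinear bonds per strand.
#' @param tol_cos Collinearity threshold on |cos(angle)|.
#' @return Integer strand count.
#' @export
count_strands <- function(x, min_run = 4L, tol_cos = 0.995) {
  ca <- calpha_coords(x)
  b <- diff(ca)
  b <- b / sqrt(rowSums(b^2))
  n_strand <- 0L
  run <- 1L
  ref <- b[1L, ]
  for (i in 2:nrow(b)) {
    if (abs(sum(b[i, ] * ref)) > tol_cos) {
      run <- run + 1L
    } else {
      if (run >= min_run) n_strand <- n_strand + 1L
      run <- 1L
      ref <- b[i, ]
    }
  }
  if (run >= min_run) n_strand <- n_strand + 1L
  n_strand
}
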