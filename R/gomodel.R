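## Building the Calpha Go-like model: beads with residue masses, bonded
## topology from native geometry (bonds treated downstream as holonomic
## constraints, harmonic angles, single-cosine torsions), native contacts
## with the 13/18/4 modified Lennard-Jones well anchored at the native pair
## distance, and native hydrogen-bond terms flagged for an energy bonus.

#' Extract coarse-grained beads from a structure
#'
#' One bead per residue at the Calpha position, carrying the average residue
#' mass of its amino-acid type. Unknown residue names are an error (no silent
#' default mass).
#'
#' @param structure An [aastructure()].
#' @return Data frame with columns `index`, `res_name`, `mass` (Da), `x`, `y`,
#'   `z` (Angstrom).
#' @export
extract_beads <- function(structure) {
  stopifnot(inherits(structure, "aastructure"))
  ca <- calpha_coords(structure)
  res <- residue_names(structure)
  data.frame(
    index = seq_along(res), res_name = res,
    mass = lookup_residue_mass(res),
    x = ca[, 1], y = ca[, 2], z = ca[, 3],
    stringsAsFactors = FALSE
  )
}

#' Detect native contacts
#'
#' A residue pair (i, j) is a native contact when it is separated in sequence
#' by more than `min_seq_sep` bonds (default 3, so the closest admissible pair
#' is (i, i+4); shorter-range geometry is handled by the angle and torsion
#' terms) and the residues are within `cutoff` in the native structure. Two
#' distance schemes are supported: `"heavy"` tests every heavy-atom pair
#' across the two residues (all-atom input, default cutoff 4.5 Angstrom);
#' `"calpha"` tests the Calpha-Calpha distance (Calpha-only input, default
#' cutoff 6.5 Angstrom). With `scheme = "auto"` the Calpha scheme is chosen
#' when the structure carries no atoms beyond CA and pseudo-backbone N/O.
#' The contact's `sigma` is the native Calpha-Calpha distance, so the native
#' pair distance sits at the minimum of the contact potential.
#'
#' @param structure An [aastructure()].
#' @param cutoff Distance cutoff in Angstrom; `NULL` picks the scheme default.
#' @param min_seq_sep Minimum sequence separation in bonds; pairs with
#'   `j - i <= min_seq_sep` are excluded.
#' @param scheme `"auto"`, `"heavy"` or `"calpha"`.
#' @return Data frame with columns `i`, `j` (`i < j`, each pair once), `sigma`
#'   (Angstrom), `epsilon` (NA until assigned), `is_hbond` (FALSE).
#' @export
native_contacts <- function(structure, cutoff = NULL, min_seq_sep = 3L,
                            scheme = c("auto", "heavy", "calpha")) {
  stopifnot(inherits(structure, "aastructure"), min_seq_sep >= 0L)
  scheme <- match.arg(scheme)
  if (scheme == "auto") {
    scheme <- if (all(structure$atoms$atom_name %in% c("CA", "N", "O")))
      "calpha" else "heavy"
  }
  if (is.null(cutoff)) cutoff <- if (scheme == "heavy") 4.5 else 6.5
  stopifnot(cutoff > 0)
  ca <- calpha_coords(structure)
  n <- nrow(ca)
  empty <- data.frame(i = integer(0), j = integer(0), sigma = numeric(0),
                      epsilon = numeric(0), is_hbond = logical(0))
  if (n < min_seq_sep + 2L) return(empty)
  if (scheme == "calpha") {
    d <- as.matrix(stats::dist(ca))
    pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    keep <- (pairs[, 2] - pairs[, 1]) > min_seq_sep
    pairs <- pairs[keep, , drop = FALSE]
    ii <- pairs[, 1]; jj <- pairs[, 2]
  } else {
    at <- structure$atoms[toupper(structure$atoms$element) != "H", ,
                          drop = FALSE]
    xyz <- as.matrix(at[, c("x", "y", "z")])
    idx_by_res <- split(seq_len(nrow(at)), at$res_index)
    ii <- integer(0); jj <- integer(0)
    for (i in seq_len(n)) {
      j_first <- i + min_seq_sep + 1L
      if (j_first > n) break
      da <- xyz[idx_by_res[[i]], , drop = FALSE]
      for (j in j_first:n) {
        db <- xyz[idx_by_res[[j]], , drop = FALSE]
        d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * tcrossprod(da, db)
        if (min(d2) <= cutoff^2) { ii <- c(ii, i); jj <- c(jj, j) }
      }
    }
  }
  if (length(ii) == 0L) return(empty)
  sigma <- sqrt(rowSums((ca[ii, , drop = FALSE] - ca[jj, , drop = FALSE])^2))
  out <- data.frame(i = as.integer(ii), j = as.integer(jj), sigma = sigma,
                    epsilon = NA_real_, is_hbond = FALSE)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Assign contact well depths
#'
#' `"uniform"` sets every `epsilon` to the configured value. `"statistical"`
#' weights pairs by the product of shifted Kyte-Doolittle hydropathies of the
#' two residues and renormalizes so that the mean `epsilon` over the contact
#' set equals the configured value (hydrophobic pairs get deeper wells at
#' constant total cohesion).
#'
#' @param contacts Contact table from [native_contacts()].
#' @param sequence Character vector of three-letter residue codes, one per
#'   bead (needed by the statistical scheme).
#' @param scheme `"uniform"` or `"statistical"`.
#' @param epsilon Configured well depth (uniform value / statistical mean),
#'   kcal/mol, > 0.
#' @return `contacts` with `epsilon` filled in.
#' @export
assign_contact_energies <- function(contacts, sequence = NULL,
                                    scheme = c("uniform", "statistical"),
                                    epsilon = 1.0) {
  scheme <- match.arg(scheme)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("configured epsilon must be a positive scalar (kcal/mol)")
  }
  if (nrow(contacts) == 0L) return(contacts)
  if (scheme == "uniform") {
    contacts$epsilon <- epsilon
  } else {
    if (is.null(sequence)) stop("statistical scheme needs the residue sequence")
    h <- kyte_doolittle[toupper(sequence)]
    if (anyNA(h)) {
      stop("unknown residue name(s) in sequence: ",
           paste(unique(toupper(sequence)[is.na(h)]), collapse = ", "))
    }
    w <- (h + 5) / 9.5                      # shift to (0, 1]
    pw <- w[contacts$i] * w[contacts$j]
    contacts$epsilon <- unname(epsilon * pw / mean(pw))
  }
  contacts
}

#' Detect native hydrogen-bond pairs
#'
#' Flags residue pairs whose backbone N(i)...O(j) or O(i)...N(j) distance is
#' within `cutoff` and whose sequence separation exceeds `min_seq_sep` bonds.
#' For Calpha-only input (no backbone N/O atoms) the operation degrades
#' gracefully: it returns zero terms and emits a notice.
#'
#' @param structure An [aastructure()].
#' @param cutoff Donor-acceptor N...O cutoff, Angstrom (default 3.5).
#' @param min_seq_sep Minimum sequence separation in bonds.
#' @return Contact table (as [native_contacts()]) with `is_hbond = TRUE`.
#' @export
detect_native_hbonds <- function(structure, cutoff = 3.5, min_seq_sep = 3L) {
  stopifnot(inherits(structure, "aastructure"), cutoff > 0)
  at <- structure$atoms
  empty <- data.frame(i = integer(0), j = integer(0), sigma = numeric(0),
                      epsilon = numeric(0), is_hbond = logical(0))
  nn <- at[at$atom_name == "N", , drop = FALSE]
  oo <- at[at$atom_name == "O", , drop = FALSE]
  if (nrow(nn) == 0L || nrow(oo) == 0L) {
    message("no backbone N/O atoms: hydrogen-bond detection skipped")
    return(empty)
  }
  ca <- calpha_coords(structure)
  dx <- outer(nn$x, oo$x, "-"); dy <- outer(nn$y, oo$y, "-")
  dz <- outer(nn$z, oo$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  ri <- nn$res_index[hit[, 1]]; rj <- oo$res_index[hit[, 2]]
  keep <- abs(rj - ri) > min_seq_sep
  ri <- ri[keep]; rj <- rj[keep]
  if (length(ri) == 0L) return(empty)
  i <- pmin(ri, rj); j <- pmax(ri, rj)
  key <- unique(paste(i, j))
  i <- as.integer(sub(" .*", "", key)); j <- as.integer(sub(".* ", "", key))
  sigma <- sqrt(rowSums((ca[i, , drop = FALSE] - ca[j, , drop = FALSE])^2))
  out <- data.frame(i = i, j = j, sigma = sigma, epsilon = NA_real_,
                    is_hbond = TRUE)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Build the full Calpha Go-like model
#'
#' Assembles beads, bonds (native consecutive Calpha distances, treated as
#' holonomic constraints by the engine), harmonic angles and single-cosine
#' torsions referenced to the native geometry, and the merged contact set:
#' native contacts from [native_contacts()] plus hydrogen-bond pairs from
#' [detect_native_hbonds()]. Hydrogen-bonded contacts have their well depth
#' multiplied by `hbond_factor`; hydrogen-bond pairs not already in the
#' contact set are added. The build is deterministic: identical input and
#' options give an identical model.
#'
#' @param structure An [aastructure()].
#' @param contact_cutoff Cutoff passed to [native_contacts()] (`NULL` = scheme
#'   default).
#' @param contact_scheme Scheme passed to [native_contacts()].
#' @param min_seq_sep Minimum sequence separation in bonds for contacts.
#' @param energy_scheme `"uniform"` or `"statistical"` (see
#'   [assign_contact_energies()]).
#' @param epsilon Contact well depth (uniform value / statistical mean),
#'   kcal/mol.
#' @param hbond_factor Multiplier on `epsilon` for hydrogen-bonded contacts.
#' @param hbonds Detect native hydrogen bonds (needs backbone N/O atoms;
#'   skipped with a notice otherwise).
#' @param k_theta Harmonic angle constant, kcal mol^-1 rad^-2
#'   (V = k_theta/2 (theta - theta0)^2).
#' @param k_phi Torsion amplitude, kcal/mol (V = k_phi (1 - cos(phi - phi0))).
#' @param sigma_rep,epsilon_rep Excluded-volume repulsion
#'   `epsilon_rep (sigma_rep / r)^12` acting between non-contact pairs with
#'   sequence separation > `min_seq_sep`.
#' @param allow_chain_breaks Accept consecutive Calpha distances > 4.5
#'   Angstrom instead of raising an error.
#' @return An object of class `go_model`.
#' @export
build_go_model <- function(structure, contact_cutoff = NULL,
                           contact_scheme = "auto", min_seq_sep = 3L,
                           energy_scheme = "uniform", epsilon = 1.0,
                           hbond_factor = 1.5, hbonds = TRUE,
                           k_theta = 40, k_phi = 1.0,
                           sigma_rep = 4.0, epsilon_rep = 0.01,
                           allow_chain_breaks = FALSE) {
  beads <- extract_beads(structure)
  n <- nrow(beads)
  if (n < 2L) stop("need at least 2 residues")
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  d_con <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  if (!allow_chain_breaks && any(d_con > 4.5)) {
    g <- which(d_con > 4.5)[1L]
    stop(sprintf("chain break between residues %d and %d (%.2f Angstrom)",
                 g, g + 1L, d_con[g]), call. = FALSE)
  }
  bonds <- data.frame(i = 1:(n - 1), j = 2:n, r0 = d_con)
  angles <- if (n >= 3L) {
    data.frame(i = 1:(n - 2), j = 2:(n - 1), k = 3:n,
               theta0 = vapply(1:(n - 2), function(a)
                 .angle3(xyz[a, ], xyz[a + 1, ], xyz[a + 2, ]), 0),
               k_theta = k_theta)
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    theta0 = numeric(0), k_theta = numeric(0))
  dihedrals <- if (n >= 4L) {
    dh <- data.frame(i = 1:(n - 3), j = 2:(n - 2), k = 3:(n - 1), l = 4:n,
                     phi0 = vapply(1:(n - 3), function(a)
                       .dihedral4(xyz[a, ], xyz[a + 1, ], xyz[a + 2, ],
                                  xyz[a + 3, ]), 0),
                     k_phi = k_phi)
    # torsions with a near-collinear native flank (idealized straight
    # strands) are degenerate: no meaningful reference angle, singular
    # gradient; they are excluded from the force field
    th <- angles$theta0
    keep <- sin(th[dh$i]) > 0.2 & sin(th[dh$j]) > 0.2
    dh[keep, , drop = FALSE]
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    l = integer(0), phi0 = numeric(0), k_phi = numeric(0))
  contacts <- native_contacts(structure, cutoff = contact_cutoff,
                              min_seq_sep = min_seq_sep,
                              scheme = contact_scheme)
  contacts <- assign_contact_energies(contacts, beads$res_name,
                                      scheme = energy_scheme,
                                      epsilon = epsilon)
  if (hbonds) {
    hb <- detect_native_hbonds(structure, min_seq_sep = min_seq_sep)
    if (nrow(hb) > 0L) {
      key_c <- paste(contacts$i, contacts$j)
      key_h <- paste(hb$i, hb$j)
      flag <- key_c %in% key_h
      contacts$is_hbond[flag] <- TRUE
      contacts$epsilon[flag] <- contacts$epsilon[flag] * hbond_factor
      new <- hb[!(key_h %in% key_c), , drop = FALSE]
      if (nrow(new) > 0L) {
        new <- assign_contact_energies(new, beads$res_name,
                                       scheme = energy_scheme,
                                       epsilon = epsilon)
        new$epsilon <- new$epsilon * hbond_factor
        new$is_hbond <- TRUE
        contacts <- rbind(contacts, new)
        contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
      }
    }
  }
  rownames(contacts) <- NULL
  structure(list(
    beads = beads, bonds = bonds, angles = angles, dihedrals = dihedrals,
    contacts = contacts, sequence = beads$res_name,
    params = list(min_seq_sep = as.integer(min_seq_sep),
                  sigma_rep = sigma_rep, epsilon_rep = epsilon_rep,
                  hbond_factor = hbond_factor, epsilon = epsilon,
                  energy_scheme = energy_scheme)
  ), class = "go_model")
}

#' @export
print.go_model <- function(x, ...) {
  cat(sprintf(paste0("go_model: %d beads, %d bonds (constrained), ",
                     "%d angles, %d dihedrals, %d contacts (%d H-bond)\n"),
              nrow(x$beads), nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals), nrow(x$contacts), sum(x$contacts$is_hbond)))
  invisible(x)
}

#' Native end-to-end distance
#'
#' Euclidean distance between the first and last bead in the native
#' structure, in nm. This is the folded-state value of the pulling coordinate
#' (the fixed-to-pulled bead distance).
#'
#' @param model A `go_model`.
#' @return Distance in nm.
#' @export
native_end_distance <- function(model) {
  stopifnot(inherits(model, "go_model"), nrow(model$beads) >= 2L)
  xyz <- as.matrix(model$beads[, c("x", "y", "z")])
  sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2)) / 10
}

#' Contour length of a model
#'
#' Full stretch length `(N - 1) * bond_length` in nm, the reference
#' denominator of relative extensions.
#'
#' @param model A `go_model`.
#' @param bond_length Virtual Calpha-Calpha bond length, Angstrom.
#' @return Length in nm.
#' @export
contour_length <- function(model, bond_length = 3.8) {
  stopifnot(inherits(model, "go_model"))
  (nrow(model$beads) - 1L) * bond_length / 10
}

.angle3 <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

.dihedral4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Serialize a model to JSON
#'
#' Writes the complete topology (beads with masses and native coordinates,
#' bonds, angles, dihedrals, contacts with `sigma` in Angstrom and `epsilon`
#' in kcal/mol, and the repulsion/H-bond parameters) as a plain-text JSON
#' document. Bead indices are 1-based. [read_topology()] restores the model.
#'
#' @param model A `go_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(model, path) {
  stopifnot(inherits(model, "go_model"))
  payload <- list(
    format = "gopull-topology-1",
    sequence = model$sequence,
    beads = model$beads, bonds = model$bonds, angles = model$angles,
    dihedrals = model$dihedrals, contacts = model$contacts,
    params = model$params
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", digits = NA,
                           auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a serialized model
#' @param path Path written by [write_topology()].
#' @return A `go_model`.
#' @export
read_topology <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (is.null(p$format) || p$format != "gopull-topology-1") {
    stop("not a gopull topology file: ", path)
  }
  structure(list(
    beads = as.data.frame(p$beads), bonds = as.data.frame(p$bonds),
    angles = as.data.frame(p$angles), dihedrals = as.data.frame(p$dihedrals),
    contacts = as.data.frame(p$contacts), sequence = p$sequence,
    params = p$params
  ), class = "go_model")
}
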