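## R-facing layer over the compiled engine: parameter containers, pair
## potential helpers, the Langevin/constant-velocity-pulling drivers and the
## force-trace container.

#' Simulation parameters
#'
#' @param timestep Integration step, ps (default 0.01 = 10 fs).
#' @param temperature Thermostat target, K (default 300).
#' @param friction Langevin collision frequency, ps^-1 (default 0.5; the
#'   coupling strength is a sensitivity knob, not a physical observable).
#' @param constraint_tolerance Relative tolerance of the iterative bond
#'   constraint solver.
#' @param seed Integer seed for velocity assignment and thermostat noise.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(timestep = 0.01, temperature = 300,
                              friction = 0.5, constraint_tolerance = 1e-8,
                              seed = 1L) {
  stopifnot(timestep > 0, temperature >= 0, friction >= 0,
            constraint_tolerance > 0)
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction,
                 constraint_tolerance = constraint_tolerance,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Constant-velocity pulling protocol
#'
#' The last bead is tethered to a dummy anchor moving at constant speed along
#' the native N-to-C direction while the first bead is held fixed; the spring
#' constant is given in pN/A as in force-spectroscopy practice.
#'
#' @param model A `go_model` (supplies defaults for the bead choices and the
#'   pulling direction).
#' @param speed Anchor speed, A/ps (default 0.025).
#' @param spring_constant Spring constant, pN/A (default 100).
#' @param pulled_bead Index of the pulled bead (default: last).
#' @param fixed_bead Index of the immobilized bead (default: first); `NA`
#'   leaves all beads free.
#' @param direction Unit pulling vector; default the native N-to-C vector.
#' @param D0 Initial anchor-to-bead distance, A (default 0: anchor starts on
#'   the pulled bead).
#' @return A `pulling_protocol` list.
#' @export
pulling_protocol <- function(model, speed = 0.025, spring_constant = 100,
                             pulled_bead = NULL, fixed_bead = NULL,
                             direction = NULL, D0 = 0) {
  stopifnot(inherits(model, "go_model"), speed >= 0, spring_constant > 0)
  n <- nrow(model$beads)
  if (is.null(pulled_bead)) pulled_bead <- n
  if (is.null(fixed_bead)) fixed_bead <- 1L
  if (is.null(direction)) {
    xyz <- as.matrix(model$beads[, c("x", "y", "z")])
    direction <- xyz[n, ] - xyz[1, ]
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("degenerate pulling direction")
  structure(list(pulled_bead = as.integer(pulled_bead),
                 fixed_bead = if (is.na(fixed_bead)) NA_integer_
                              else as.integer(fixed_bead),
                 direction = direction / nrm, speed = speed,
                 spring_constant = spring_constant, D0 = D0),
            class = "pulling_protocol")
}

#' Contact pair energy (13/18/4 modified Lennard-Jones)
#'
#' `V(r) = epsilon * (13 (sigma/r)^12 - 18 (sigma/r)^10 + 4 (sigma/r)^6)`:
#' minimum of depth `-epsilon` exactly at `r = sigma`, plus a small
#' desolvation-like barrier outside the well before the tail decays.
#'
#' @param r Pair distance, Angstrom (> 0).
#' @param sigma Native pair distance, Angstrom.
#' @param epsilon Well depth, kcal/mol.
#' @return Energy in kcal/mol (vectorized over `r`).
#' @export
contact_pair_energy <- function(r, sigma, epsilon) {
  if (any(r <= 0)) stop("pair distance must be positive")
  q <- sigma / r
  epsilon * (13 * q^12 - 18 * q^10 + 4 * q^6)
}

#' Radial force of the contact potential
#'
#' Returns `-dV/dr` of [contact_pair_energy()]: positive when the pair is
#' pushed apart (repulsive), negative when pulled together (attractive),
#' zero at `r = sigma`.
#'
#' @inheritParams contact_pair_energy
#' @return Force in kcal mol^-1 A^-1 (vectorized over `r`).
#' @export
contact_pair_force <- function(r, sigma, epsilon) {
  if (any(r <= 0)) stop("pair distance must be positive")
  q <- sigma / r
  -epsilon * (-156 * q^12 + 180 * q^10 - 24 * q^6) / r
}

#' Maxwell-Boltzmann velocity assignment
#'
#' Draws each velocity component from a normal with variance `kB T / m`,
#' reproducibly for a fixed seed. This random assignment is the only noise
#' source distinguishing replicas of a pulling ensemble.
#'
#' @param masses Bead masses, Da.
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @return N x 3 matrix of velocities, A/ps.
#' @export
maxwell_boltzmann_velocities <- function(masses, temperature, seed = 1L) {
  stopifnot(all(masses > 0), temperature >= 0)
  mass_e <- masses * go_constants$Da_to_kcalps
  cpp_mb_velocities(mass_e, go_constants$kB * temperature, as.double(seed))
}

.topo_list <- function(model) {
  list(
    mass = model$beads$mass * go_constants$Da_to_kcalps,
    bond_i = model$bonds$i - 1L, bond_j = model$bonds$j - 1L,
    bond_r0 = model$bonds$r0,
    angle_i = model$angles$i - 1L, angle_j = model$angles$j - 1L,
    angle_k = model$angles$k - 1L, angle_theta0 = model$angles$theta0,
    angle_kf = model$angles$k_theta,
    dih_i = model$dihedrals$i - 1L, dih_j = model$dihedrals$j - 1L,
    dih_k = model$dihedrals$k - 1L, dih_l = model$dihedrals$l - 1L,
    dih_phi0 = model$dihedrals$phi0, dih_kf = model$dihedrals$k_phi,
    con_i = model$contacts$i - 1L, con_j = model$contacts$j - 1L,
    con_sigma = model$contacts$sigma, con_eps = model$contacts$epsilon,
    sigma_rep = model$params$sigma_rep, eps_rep = model$params$epsilon_rep,
    min_seq_sep = model$params$min_seq_sep
  )
}

#' Forces and energy decomposition of a configuration
#'
#' Analytic per-bead forces of the full coarse-grained force field (angles,
#' torsions, native contacts, excluded-volume repulsion; bonds appear either
#' as holonomic constraints, contributing no force here, or optionally as
#' stiff harmonic springs). The energy decomposition sums to the total
#' potential energy, and internal forces sum to the zero vector.
#'
#' @param model A `go_model`.
#' @param positions N x 3 matrix, Angstrom; default the native coordinates.
#' @param include_bonds Add harmonic bond terms with constant `k_bond`
#'   (used when running without constraints, e.g. for gradient checks).
#' @param k_bond Harmonic bond constant, kcal mol^-1 A^-2.
#' @return List with `force` (N x 3, kcal mol^-1 A^-1) and named `energy`
#'   vector (`bond`, `angle`, `dihedral`, `contact`, `repulsion`, kcal/mol).
#' @export
total_forces <- function(model, positions = NULL, include_bonds = FALSE,
                         k_bond = 200) {
  stopifnot(inherits(model, "go_model"))
  if (is.null(positions)) {
    positions <- as.matrix(model$beads[, c("x", "y", "z")])
  }
  if (!all(is.finite(positions))) stop("non-finite positions")
  cpp_forces(positions, .topo_list(model), include_bonds, k_bond)
}

.as_force_trace <- function(raw, model, protocol, params, record_every,
                            equil_steps) {
  K_pN <- protocol$spring_constant
  structure(list(
    time = raw$time,                                  # ps since pulling start
    extension = raw$rnc / 10,                         # nm
    force = raw$force_int * go_constants$pN_per_kcalmolA, # pN (K (D - D0))
    D = raw$D,                                        # anchor distance, A
    kinetic = raw$kinetic, potential = raw$potential, # kcal/mol
    contact_intact = raw$intact,
    contacts = model$contacts[, c("i", "j")],
    n_beads = nrow(model$beads),
    seed = params$seed,
    speed = protocol$speed, spring_constant = K_pN,
    record_every = record_every, timestep = params$timestep,
    equil_steps = equil_steps,
    pos_final = raw$pos_final, steps_done = raw$steps_done
  ), class = "force_trace")
}

#' Construct a force trace from series
#'
#' Builds a `force_trace` from externally supplied series (e.g. imported
#' spectra or synthetic test cases); the engine produces the same structure
#' from [run_cv_smd()].
#'
#' @param time Time series, ps (strictly increasing).
#' @param extension End-to-end extension series, nm (> 0).
#' @param force Spring force series, pN.
#' @param contact_intact Optional frames x contacts logical matrix of contact
#'   intactness.
#' @param contacts Optional data frame with bead columns `i`, `j`, one row
#'   per contact (required with `contact_intact`).
#' @param n_beads Number of beads of the underlying model.
#' @param seed Seed tag carried through summaries.
#' @return A `force_trace`.
#' @export
force_trace <- function(time, extension, force, contact_intact = NULL,
                        contacts = NULL, n_beads = NULL, seed = NA_integer_) {
  n <- length(time)
  stopifnot(length(extension) == n, length(force) == n, n >= 1,
            all(diff(time) > 0), all(extension > 0))
  if (!is.null(contact_intact)) {
    contact_intact <- as.matrix(contact_intact)
    stopifnot(nrow(contact_intact) == n, !is.null(contacts),
              nrow(contacts) == ncol(contact_intact))
  }
  structure(list(time = time, extension = extension, force = force,
                 contact_intact = contact_intact, contacts = contacts,
                 n_beads = n_beads, seed = seed),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(
    "force_trace: %d frames, %.3g ns, extension %.2f -> %.2f nm, seed %d\n",
    length(x$time), max(x$time) / 1000, x$extension[1],
    x$extension[length(x$extension)], x$seed))
  invisible(x)
}

#' Unbiased Langevin run (no pulling)
#'
#' Thermostated dynamics of the model with bond constraints and no external
#' force; used for equilibration studies and thermostat validation. All beads
#' are free.
#'
#' @param model A `go_model`.
#' @param params [simulation_params()].
#' @param n_steps Number of integration steps.
#' @param record_every Recording cadence in steps.
#' @param init_temperature Temperature of the initial velocity draw; defaults
#'   to the thermostat target.
#' @return A `force_trace` (with zero force series).
#' @export
run_langevin <- function(model, params = simulation_params(), n_steps,
                         record_every = 100L, init_temperature = NULL) {
  stopifnot(inherits(model, "go_model"))
  if (is.null(init_temperature)) init_temperature <- params$temperature
  pos0 <- as.matrix(model$beads[, c("x", "y", "z")])
  raw <- cpp_run(pos0, .topo_list(model), params$timestep,
                 params$temperature, params$friction, go_constants$kB,
                 params$constraint_tolerance, as.double(params$seed),
                 0L, as.integer(n_steps), as.integer(record_every),
                 -1L, -1L, c(1, 0, 0), 0, 0, 0, -1, 1.5,
                 init_temperature)
  protocol <- list(speed = 0, spring_constant = 1e-12)
  trace <- .as_force_trace(raw, model, protocol, params, record_every, 0L)
  trace$force <- rep(0, length(trace$time))
  trace
}

#' Constant-velocity steered run
#'
#' Equilibrates the model for `equil_steps` without pulling, anchors the
#' dummy atom `D0` ahead of the pulled bead along the pulling direction, then
#' advances the anchor at constant speed until the end-to-end extension
#' reaches `target_extension` (default 80% of the contour length) or
#' `max_steps` elapse. The trace is sampled every `record_every` steps and
#' carries, per frame, the intactness of every native contact (a contact
#' counts as broken while its pair distance exceeds
#' `rupture_factor * sigma`).
#'
#' @param model A `go_model`.
#' @param protocol [pulling_protocol()].
#' @param params [simulation_params()].
#' @param record_every Recording cadence in steps (default 100 = 1 ps at the
#'   default timestep).
#' @param equil_steps Unbiased equilibration steps before pulling.
#' @param target_extension Stop when the extension reaches this many nm;
#'   `NULL` = 80% of the contour length (pulling further probes taut-backbone
#'   elasticity rather than unfolding: every contact has long ruptured and the
#'   spring force rises steeply and uninformatively).
#' @param max_steps Hard cap on pulling steps; `NULL` sizes the cap from the
#'   pulling speed and travel distance (plus 50% slack).
#' @param rupture_factor Contact bookkeeping threshold on `r / sigma`.
#' @return A `force_trace`.
#' @export
run_cv_smd <- function(model, protocol = pulling_protocol(model),
                       params = simulation_params(), record_every = 100L,
                       equil_steps = 10000L, target_extension = NULL,
                       max_steps = NULL, rupture_factor = 1.5) {
  stopifnot(inherits(model, "go_model"), inherits(protocol, "pulling_protocol"))
  if (is.null(target_extension)) {
    target_extension <- 0.80 * contour_length(model)
  }
  target_A <- target_extension * 10
  if (is.null(max_steps)) {
    if (protocol$speed > 0) {
      travel <- max(target_A - native_end_distance(model) * 10, 10)
      max_steps <- ceiling(1.5 * travel / (protocol$speed * params$timestep))
    } else {
      stop("max_steps must be given when the pulling speed is zero")
    }
  }
  pos0 <- as.matrix(model$beads[, c("x", "y", "z")])
  K_int <- protocol$spring_constant / go_constants$pN_per_kcalmolA
  fixed <- if (is.na(protocol$fixed_bead)) -1L else protocol$fixed_bead - 1L
  raw <- cpp_run(pos0, .topo_list(model), params$timestep,
                 params$temperature, params$friction, go_constants$kB,
                 params$constraint_tolerance, as.double(params$seed),
                 as.integer(equil_steps), as.integer(max_steps),
                 as.integer(record_every),
                 protocol$pulled_bead - 1L, fixed,
                 protocol$direction, protocol$speed, K_int, protocol$D0,
                 target_A, rupture_factor, params$temperature)
  .as_force_trace(raw, model, protocol, params, record_every, equil_steps)
}

#' Write a trace to CSV
#'
#' Plain-text export of the sampled series: `time_ps`, `extension_nm`,
#' `force_pN`.
#'
#' @param trace A `force_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(
    data.frame(time_ps = trace$time, extension_nm = trace$extension,
               force_pN = trace$force),
    path, row.names = FALSE)
  invisible(path)
}
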