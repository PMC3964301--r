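# Engine physics: pair potential analytics, unit conversions, velocity
# assignment, force/energy consistency, constraint satisfaction,
# reproducibility, thermostat and drag behavior.

test_that("contact potential has the 13/18/4 analytic structure", {
  expect_equal(contact_pair_energy(5, 5, 2), -2)         # V(sigma) = -eps
  expect_equal(contact_pair_force(5, 5, 2), 0)           # minimum
  expect_lt(abs(contact_pair_energy(50, 5, 1)), 1e-5)    # tail decay

  # desolvation-like barrier located by a dense scan of the bare formula
  r <- seq(1.01, 3, by = 1e-5)
  v <- 13 * (1 / r)^12 - 18 * (1 / r)^10 + 4 * (1 / r)^6
  i <- which.max(v[r > 1.1]) + sum(r <= 1.1)
  expect_equal(r[i], 1.4485, tolerance = 1e-3)
  expect_equal(v[i], 0.1428, tolerance = 1e-3)
  expect_equal(contact_pair_energy(r[i] * 7, 7, 1.0), v[i], tolerance = 1e-6)

  # attraction flips to repulsion across the barrier
  expect_lt(contact_pair_force(1.40 * 7, 7, 1), 0)  # pulled inward
  expect_gt(contact_pair_force(1.50 * 7, 7, 1), 0)  # pushed outward

  expect_error(contact_pair_energy(0, 5, 1), "positive")
})

test_that("contact force matches finite differences of the energy", {
  set.seed(7)
  for (k in 1:200) {
    sg <- runif(1, 4, 8); ep <- runif(1, 0.5, 2); r <- runif(1, 0.7, 2.5) * sg
    fd <- -(contact_pair_energy(r + 1e-6, sg, ep) -
            contact_pair_energy(r - 1e-6, sg, ep)) / 2e-6
    expect_equal(contact_pair_force(r, sg, ep), fd, tolerance = 1e-5)
  }
})

test_that("spring force and unit conversions are linear and invertible", {
  expect_equal(spring_force(10, 10, 100), 0)
  expect_equal(spring_force(11, 10, 278), 278)
  expect_equal(spring_force(9.5, 10, 100), -50)   # anchor lagging: negative
  expect_equal(convert_spring_constant(4), 278, tolerance = 0.1)
  expect_equal(convert_spring_constant(0), 0)
  for (k in c(0.1, 1, 4, 50)) {
    expect_equal(convert_spring_constant_inverse(convert_spring_constant(k)),
                 k, tolerance = 1e-12)
  }
})

test_that("velocity assignment is thermal, seeded, and zero at T = 0", {
  masses <- rep(110, 3)
  expect_true(all(maxwell_boltzmann_velocities(masses, 0, 1) == 0))
  expect_identical(maxwell_boltzmann_velocities(masses, 300, 42),
                   maxwell_boltzmann_velocities(masses, 300, 42))
  expect_false(identical(maxwell_boltzmann_velocities(masses, 300, 1),
                         maxwell_boltzmann_velocities(masses, 300, 2)))

  # equipartition: mean kinetic energy per DOF = kT/2 within 3 SE
  n <- 33334L
  v <- maxwell_boltzmann_velocities(rep(110, n), 300, 7)
  ke_dof <- 0.5 * 110 * (10 / 4184) * as.vector(v)^2
  half_kT <- 0.0019872 * 300 / 2
  se <- sd(ke_dof) / sqrt(length(ke_dof))
  expect_lt(abs(mean(ke_dof) - half_kT), 3 * se)
})

test_that("total forces are consistent gradients with zero net force", {
  m <- fh_model()
  tf0 <- total_forces(m)
  # native state: contacts at their minima, angles/dihedrals at reference
  expect_lt(max(abs(tf0$force)), 0.05)
  expect_equal(sum(tf0$energy[c("bond", "angle", "dihedral")]), 0,
               tolerance = 1e-9)

  set.seed(3)
  for (rep in 1:3) {
    x <- as.matrix(m$beads[, c("x", "y", "z")]) +
      matrix(rnorm(93, sd = 0.3), ncol = 3)
    tf <- total_forces(m, x, include_bonds = TRUE)
    expect_lt(max(abs(colSums(tf$force))), 1e-9)  # Newton's third law
    idx <- sample(93, 12)
    for (q in idx) {
      xp <- x; xp[q] <- xp[q] + 1e-5
      xm <- x; xm[q] <- xm[q] - 1e-5
      fd <- -(sum(total_forces(m, xp, include_bonds = TRUE)$energy) -
              sum(total_forces(m, xm, include_bonds = TRUE)$energy)) / 2e-5
      expect_equal(tf$force[q], fd, tolerance = 1e-4)
    }
  }
  expect_error(total_forces(m, matrix(NaN, nrow(m$beads), 3)), "finite")
})

test_that("constraints hold and trajectories are seed-reproducible", {
  m <- fh_model()
  tr1 <- run_cv_smd(m, params = simulation_params(seed = 5),
                    equil_steps = 200L, max_steps = 3000L,
                    target_extension = 20)
  tr2 <- run_cv_smd(m, params = simulation_params(seed = 5),
                    equil_steps = 200L, max_steps = 3000L,
                    target_extension = 20)
  expect_identical(tr1$force, tr2$force)     # bit-reproducible
  expect_identical(tr1$pos_final, tr2$pos_final)

  tr3 <- run_cv_smd(m, params = simulation_params(seed = 6),
                    equil_steps = 200L, max_steps = 3000L,
                    target_extension = 20)
  expect_false(identical(tr1$force, tr3$force))

  # constrained bonds at their native lengths after the run
  d <- sqrt(rowSums(diff(tr1$pos_final)^2))
  expect_lt(max(abs(d - m$bonds$r0) / m$bonds$r0), 1e-7)

  # fixed bead immobile
  expect_equal(tr1$pos_final[1, ], unlist(m$beads[1, c("x", "y", "z")]),
               ignore_attr = TRUE)

  # trace series well-formed
  expect_true(all(diff(tr1$time) > 0))
  expect_true(all(tr1$extension > 0))
  expect_equal(length(tr1$time), length(tr1$force))
  expect_equal(nrow(tr1$contact_intact), length(tr1$time))
})

test_that("native fold is stable in an unbiased thermostated run", {
  m <- fh_model()
  tr <- run_langevin(m, simulation_params(seed = 11), n_steps = 30000L,
                     record_every = 300L)
  r0 <- native_end_distance(m)
  expect_true(all(abs(tr$extension - r0) / r0 < 0.5))
  expect_gt(min(rowSums(tr$contact_intact)), 0.8 * nrow(m$contacts))
})

test_that("a dragged dimer settles at the Stokes-like mean spring force", {
  # fast, heavy, high-friction regime so the axial spring stretch dominates
  # the (always positive) lateral thermal contribution to the anchor distance
  ch <- make_extended_chain(2L, res_names = "TRP")
  m <- suppressMessages(build_go_model(ch))
  gamma <- 10; v <- 2
  prot <- pulling_protocol(m, speed = v, spring_constant = 100,
                           fixed_bead = NA)
  tr <- run_cv_smd(m, prot,
                   simulation_params(seed = 2, friction = gamma),
                   equil_steps = 0L, max_steps = 300000L,
                   target_extension = 1e6, record_every = 100L)
  drag_int <- sum(m$beads$mass) * (10 / 4184) * gamma * v  # kcal/mol/A
  drag_pN <- drag_int * 69.477
  mean_F <- mean(tr$force[-seq_len(100)])
  expect_equal(mean_F, drag_pN, tolerance = 0.02)
})
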