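# Replica ensembles: seeding contract, reproducibility, failure handling,
# output round trips, speed-scan bookkeeping. Dynamics-heavy statistical
# assertions live in the acceptance suite; here the replica counts are small.

short_run_args <- function(model) {
  list(equil_steps = 500L, target_extension = 0.25 * contour_length(model),
       record_every = 100L)
}

test_that("a one-replica ensemble equals the corresponding single run", {
  m <- small_sandwich_model()
  args <- short_run_args(m)
  es <- do.call(ensemble_spec,
                c(list(model = m, n_replicas = 1L, base_seed = 9L), args))
  ens <- run_ensemble(es)
  expect_equal(nrow(ens$summaries), 1L)

  tr <- do.call(run_cv_smd,
                c(list(model = m, protocol = pulling_protocol(m),
                       params = simulation_params(seed = 9L)), args))
  s <- summarize_trace(tr)
  expect_equal(ens$summaries$F_max_pN, s$F_max)
  expect_equal(ens$summaries$rNC_nm, s$r_NC_at_max)
  expect_equal(ens$summaries$seed, 9L)
})

test_that("ensembles are reproducible and seeded by base_seed + index", {
  m <- small_sandwich_model()
  args <- short_run_args(m)
  es <- do.call(ensemble_spec,
                c(list(model = m, n_replicas = 3L, base_seed = 20L), args))
  e1 <- run_ensemble(es)
  e2 <- run_ensemble(es)
  expect_identical(e1$summaries, e2$summaries)
  expect_equal(e1$summaries$seed, 20:22)
  expect_gt(sd(e1$summaries$F_max_pN), 0)  # replicas genuinely differ

  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_ensemble_summary(e1, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$F_max_pN, e1$summaries$F_max_pN)
  rep <- jsonlite::fromJSON(js)
  expect_equal(rep$n_success, 3L)
})

test_that("failing replicas are recorded and the ensemble continues", {
  m <- small_sandwich_model()
  # impossible protocol: zero speed with no step cap errors inside run_cv_smd
  es <- ensemble_spec(m, protocol = pulling_protocol(m, speed = 0),
                      n_replicas = 2L, base_seed = 1L)
  ens <- run_ensemble(es)
  expect_equal(nrow(ens$failures), 2L)
  expect_match(ens$failures$reason[1], "max_steps")
  expect_null(ens$summaries)
})

test_that("speed scan reports controls and undefined errors honestly", {
  m <- small_sandwich_model()
  sc <- speed_scan(m, speeds = c(0, 0.05, 0.1), n_replicas = 1L,
                   base_seed = 3L, equil_steps = 200L,
                   target_extension = 0.25 * contour_length(m))
  expect_equal(nrow(sc), 3L)
  expect_true(sc$is_control[sc$speed_A_ps == 0])
  expect_true(is.na(sc$mean_F_max_pN[sc$speed_A_ps == 0]))
  # single replica: SE undefined, not zero
  expect_true(all(is.na(sc$se_F_max_pN[!sc$is_control])))
  expect_true(all(is.finite(sc$mean_F_max_pN[!sc$is_control])))
})
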