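# Shared fixtures, built once per test run and memoised; everything is a
# deterministic function of the seeds fixed here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

# Small cohort WITH time series: DFA / block-level / pipeline tests.
small_ts_cohort <- function() {
  fixture("small_ts", function() {
    simulate_cohort(cohort_config(n_subjects = 60, n_parcels = 24,
                                  seed = 101))
  })
}

# Larger cohort WITHOUT time series: PLS / pattern recovery tests on true H.
truth_cohort <- function() {
  fixture("truth500", function() {
    simulate_cohort(cohort_config(n_subjects = 500, n_parcels = 40,
                                  seed = 202),
                    generate_timeseries = FALSE)
  })
}

# Fitted PLS (with inference) on the truth cohort.
truth_model <- function() {
  fixture("truth500_model", function() {
    coh <- truth_cohort()
    pls_analysis(coh$truth$true_h, coh$factors, n_perm = 300, n_boot = 300,
                 seed = 7)
  })
}

# Fixed geometry for surrogate / axis tests.
test_geometry <- function(n_parcels = 80, seed = 11) {
  fixture(paste0("geom", n_parcels, "_", seed), function() {
    set.seed(seed)
    parcel_geometry(cbind(runif(n_parcels, 0, 140),
                          runif(n_parcels, 0, 170),
                          runif(n_parcels, 0, 120)))
  })
}

expect_tbl_names <- function(tbl, nms) {
  expect_true(all(nms %in% names(tbl)))
}
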