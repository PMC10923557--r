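test_that("the same seed reproduces the register byte for byte", {
  cfg <- small_cfg()
  s1 <- simulate_parish(cfg)
  s2 <- simulate_parish(cfg)
  expect_identical(s1$text, s2$text)
  expect_identical(s1$truth$events, s2$truth$events)
  s3 <- simulate_parish(small_cfg(seed = 43L))
  expect_false(identical(s1$text, s3$text))
})

test_that("degenerate configurations behave as their parameters dictate", {
  # zero fecundability: universally childless, all true rates zero
  cfg <- small_cfg(fecundability_base = 0)
  sim <- simulate_parish(cfg)
  expect_equal(nrow(sim$truth$events), 0L)
  tr <- true_rates(sim)
  expect_true(all(tr$births == 0))

  # invalid probabilities and windows are rejected
  expect_error(synth_config(twin_prob = 1.5), "probabilities")
  expect_error(synth_config(adult_mortality_hazard = -1), "hazards")
  expect_error(synth_config(window = c(1700L, 1730L)), "50 years")
})

test_that("no registered event postdates the couple's migration", {
  sim <- simulate_parish(small_cfg(migration_hazard = 0.1, seed = 7L))
  recs <- read_frf(text = sim$text)
  b <- records_to_bundle(recs, "SIM")
  mig <- sim$truth$unions$migration
  frf <- sim$truth$unions$frf
  date_cols <- function(t) t[, grep("_date$", names(t)), drop = FALSE]
  for (tab in c("marriages", "husbands", "wives", "children")) {
    t <- b[[tab]]
    m <- mig[match(as.integer(sub("^SIM0*", "", t$parfrf)), frf)]
    for (col in names(date_cols(t))) {
      d <- as.numeric(t[[col]])
      # remarriage-proxy death dates are bounds, not observed events
      if (col %in% c("burial_date", "death_date") &&
          "burial_weighting" %in% names(t)) {
        w <- t[[sub("_date$", "_weighting", col)]]
        d[!is.na(w) & w %% 1000L == 150L] <- NA
      }
      expect_true(all(d <= m | is.na(d)),
                  label = paste("passive registration in", tab, col))
    }
  }
})

test_that("with no migration or under-registration, in-window births are all registered", {
  cfg <- small_cfg(migration_hazard = 0, under_registration_prob = 0)
  sim <- simulate_parish(cfg)
  b <- records_to_bundle(read_frf(text = sim$text), "SIM")
  w1 <- as.numeric(as.Date(sprintf("%d-12-31", cfg$window[2])))
  # every truth baby whose baptism or burial could fall in the window has
  # a child row; count a conservative subset: babies born 200+ days before
  # the window end
  babies <- sim$truth$babies
  expectable <- sum(babies$birth < w1 - 200)
  expect_gte(nrow(b$children), expectable)
})

test_that("simulated registers round-trip through the full pipeline", {
  sim <- simulate_parish(small_cfg())
  recs <- read_frf(text = sim$text)
  txt2 <- write_frf(recs)
  expect_identical(txt2, sim$text)
  prep <- prepare_parish(text = sim$text, parish_code = "SIM",
                         parish_meta = sim$parish_meta)
  chk <- run_consistency_checks(prep$ids)
  expect_equal(unname(chk$counts["ordering"]), 0L)
})

test_that("true rates match the renewal-theory birth interval", {
  # constant fecundability, no decline in range, no mortality or twins:
  # mean birth interval = waiting (1-f)/f + gestation + 1 + non-susceptible
  # months; the annual rate is 12 over that
  f <- 0.2
  cfg <- synth_config(n_couples = 600L, seed = 99L,
                      fecundability_base = f,
                      fecundability_decline_start = 49,
                      fecundability_zero_age = 50,
                      adult_mortality_hazard = 0,
                      migration_hazard = 0,
                      stillbirth_prob = 0, twin_prob = 0,
                      infant_death_prob = 0, child_death_prob = 0,
                      remarriage_prob = 0, daughter_marriage_prob = 0)
  sim <- simulate_parish(cfg)
  tr <- true_rates(sim)
  cycle_months <- (1 - f) / f + cfg$gestation_months + 1 +
    cfg$nonsusceptible_months
  expected <- 12 / cycle_months
  ba <- rates_by_age(tr)
  mid <- ba$rate[ba$age_group %in% c("25-29", "30-34", "35-39")]
  expect_equal(mean(mid), expected, tolerance = 0.05)

  # truth is invariant to the registration parameters
  cfg2 <- cfg
  cfg2$under_registration_prob <- 0.5
  tr2 <- true_rates(simulate_parish(cfg2))
  expect_equal(rates_by_age(tr2)$rate, rates_by_age(tr)$rate)
})

test_that("estimates converge to truth as the parish grows", {
  err <- vapply(c(250L, 1000L), function(n) {
    cfg <- synth_config(n_couples = n, migration_hazard = 0,
                        under_registration_prob = 0, seed = 5L)
    sim <- simulate_parish(cfg)
    prep <- prepare_parish(text = sim$text, parish_code = "SIM",
                           parish_meta = sim$parish_meta)
    res <- fertility_rates_for(prep, reference_criteria())
    abs(res$tmfr - tmfr(true_rates(sim)))
  }, 0)
  expect_lt(err[2], max(err[1], 0.25))
})
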