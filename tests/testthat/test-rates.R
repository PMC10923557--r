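episode_row <- function(age_group = "20-24", period = "1700-1724",
                        duration = 5, event = 0L, weight = 1,
                        id = "w1") {
  data.frame(id = id, union = id, start = as.Date("1700-01-01"),
             end = as.Date("1700-01-01") + duration * 365.25,
             start_age = 20, end_age = 20 + duration,
             age_group = age_group, period = period,
             parity = 0L, lactation = 0L, prev_child_dead = 0L,
             event = event, duration_years = duration, weight = weight,
             stringsAsFactors = FALSE)
}

test_that("cells accumulate weighted person-years and births", {
  eps <- rbind(episode_row(duration = 4),
               episode_row(duration = 1, event = 1L))
  rt <- person_years_and_births(eps)
  expect_equal(rt$person_years, 5)
  expect_equal(rt$births, 1)
  expect_equal(rt$rate, 0.2)

  # a single stratum reweighted: totals scale, the rate is invariant
  eps$weight <- 0.5
  rt2 <- person_years_and_births(eps)
  expect_equal(rt2$person_years, 2.5)
  expect_equal(rt2$births, 0.5)
  expect_equal(rt2$rate, 0.2)

  empty <- person_years_and_births(eps[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("weighted totals equal weight times unweighted contributions", {
  sim <- simulate_parish(small_cfg())
  prep <- prepare_parish(text = sim$text, parish_code = "SIM",
                         parish_meta = sim$parish_meta)
  res <- fertility_rates_for(prep, reference_criteria())
  eps <- res$episodes
  eps$weight <- 0.5
  rt_half <- person_years_and_births(eps)
  expect_equal(rt_half$person_years, res$rates$person_years * 0.5)
  expect_equal(rt_half$births, res$rates$births * 0.5)
})

test_that("TMFR is five times the age-group rate sum over 20-49", {
  mk <- function(rates) {
    lo <- seq(20L, 45L, 5L)
    do.call(rbind, lapply(seq_along(lo), function(i)
      episode_row(age_group = sprintf("%d-%d", lo[i], lo[i] + 4),
                  duration = 1,
                  event = 0L)))
  }
  eps <- mk()
  eps$event <- NULL; eps$event <- 0L
  # fabricate one birth per 5 person-years in every group: rate 0.2 each
  eps <- do.call(rbind, lapply(seq_len(nrow(eps)), function(i) {
    rbind(transform(eps[i, ], duration_years = 5),
          transform(eps[i, ], duration_years = 0, event = 1L))
  }))
  eps$duration_years[eps$event == 1L] <- 1e-9
  rt <- person_years_and_births(eps)
  expect_equal(tmfr(rt), 6, tolerance = 1e-6)

  # the worked arithmetic example
  rates <- c(0.4, 0.35, 0.3, 0.2, 0.1, 0.02)
  lo <- seq(20L, 45L, 5L)
  eps2 <- do.call(rbind, lapply(seq_along(lo), function(i) {
    base <- episode_row(age_group = sprintf("%d-%d", lo[i], lo[i] + 4),
                        duration = 100)
    ev <- base; ev$duration_years <- 1e-9; ev$event <- 1L
    rbind(base, ev[rep(1, round(rates[i] * 100)), ])
  }))
  rt2 <- person_years_and_births(eps2)
  expect_equal(tmfr(rt2), 5 * sum(rates), tolerance = 1e-4)
  expect_equal(5 * sum(rates), 6.85)

  # any missing age group leaves TMFR undefined
  rt3 <- person_years_and_births(episode_row())
  expect_message(v <- tmfr(rt3), "undefined")
  expect_true(is.na(v))
})

test_that("TMFR is linear in the rates", {
  eps <- do.call(rbind, lapply(seq(20L, 45L, 5L), function(a) {
    base <- episode_row(age_group = sprintf("%d-%d", a, a + 4),
                        duration = 5)
    ev <- base; ev$duration_years <- 1e-9; ev$event <- 1L
    rbind(base, ev)
  }))
  rt <- person_years_and_births(eps)
  infl <- inflate_for_multiplicity(rt, 0.1)
  expect_equal(tmfr(infl), tmfr(rt) * 1.1)
})

test_that("multiplicity inflation is explicit, bounded, and exact", {
  eps <- rbind(episode_row(duration = 4),
               episode_row(duration = 1, event = 1L))
  rt <- person_years_and_births(eps)
  expect_equal(inflate_for_multiplicity(rt, 0.015)$rate, 0.203)
  expect_equal(inflate_for_multiplicity(rt, 0)$rate, rt$rate)
  expect_error(inflate_for_multiplicity(rt, 0.5), "0.1")
})

test_that("criteria comparisons align profiles and ratios", {
  sim <- simulate_parish(small_cfg())
  prep <- prepare_parish(text = sim$text, parish_code = "SIM",
                         parish_meta = sim$parish_meta)
  ref <- fertility_rates_for(prep, reference_criteria())
  cmp <- compare_criteria(list(reference = ref$episodes,
                               same = ref$episodes))
  expect_true(all(abs(cmp$age_profiles$same_ratio - 1) < 1e-12,
                  na.rm = TRUE))
  expect_true(all(abs(cmp$period_series$same_ratio - 1) < 1e-12,
                  na.rm = TRUE))
})

test_that("undefined cells carry no rate", {
  eps <- episode_row(duration = 0)
  eps$duration_years <- 0
  rt <- person_years_and_births(eps)
  expect_true(is.na(rt$rate[rt$person_years == 0]))
})
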