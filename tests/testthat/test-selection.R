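meta_tst <- function()
  parish_metadata("Testfield", "TST",
                  quality_years = data.frame(start = 1500L, end = 1900L),
                  sample_groups = data.frame(group = 1L, start = 1500L,
                                             end = 1900L))

test_that("pre-requisites exclude families without wife birthdate or marriage", {
  fam <- rbind(family_row("TST000001"),
               family_row("TST000002", wife_birth = as.Date(NA),
                          wife_birth_est = NA),
               family_row("TST000003", marriage = as.Date(NA),
                          marriage_est = NA))
  d <- select_families(fam, empty_children(), reference_criteria(),
                       meta_tst())
  expect_true(d$included[1])
  expect_match(d$reasons[2], "NO_WIFE_BIRTHDATE")
  expect_match(d$reasons[3], "NO_MARRIAGE_DATE")
})

test_that("the observation window follows the Henry rules", {
  # husband buried 1730, wife 50 in 1728: exit at the earlier (age 50)
  fam <- family_row("TST000001", wife_birth = as.Date("1678-03-15"),
                    husband_death = as.Date("1730-01-10"))
  d <- select_families(fam, empty_children(), reference_criteria(),
                       meta_tst())
  expect_true(d$included)
  expect_equal(d$entry, fam$marriage_date)
  expect_equal(d$exit, reconkit:::.age_boundary(fam$wife_birth, 50))

  # spouse death before 50 marks the exit instead
  fam2 <- family_row("TST000002", husband_death = as.Date("1710-05-05"))
  d2 <- select_families(fam2, empty_children(), reference_criteria(),
                        meta_tst())
  expect_equal(d2$exit, as.Date("1710-05-05"))

  # no spouse death at all: excluded from the reference sample
  fam3 <- family_row("TST000003", husband_death = as.Date(NA),
                     husband_death_est = NA)
  d3 <- select_families(fam3, empty_children(), reference_criteria(),
                        meta_tst())
  expect_false(d3$included)
  expect_match(d3$reasons, "NO_SPOUSE_DEATH")
})

test_that("Henry variant modes partition the reference sample", {
  died_late <- family_row("TST000001",
                          husband_death = as.Date("1730-01-10"))
  died_early <- family_row("TST000002",
                           husband_death = as.Date("1710-05-05"))
  both <- family_row("TST000003", husband_death = as.Date("1730-01-10"),
                     wife_death = as.Date("1735-01-01"),
                     wife_death_est = "Exact")
  fam <- rbind(died_late, died_early, both)
  kids <- empty_children()
  d50 <- select_families(fam, kids, ends_age_50_criteria(), meta_tst())
  expect_equal(d50$included, c(TRUE, FALSE, TRUE))
  dlt <- select_families(fam, kids, spouse_died_lt50_criteria(), meta_tst())
  expect_equal(dlt$included, c(FALSE, TRUE, FALSE))
  d2d <- select_families(fam, kids, two_spouse_deaths_criteria(),
                         meta_tst())
  expect_equal(d2d$included, c(FALSE, FALSE, TRUE))
})

test_that("child-end windows include exactly the families the reference drops", {
  # no spouse death; last dated child event ends the diagnostic window
  fam <- family_row("TST000001", husband_death = as.Date(NA),
                    husband_death_est = NA, n_children = 1L)
  kids <- child_row("TST000001", as.Date("1705-04-01"))
  dref <- select_families(fam, kids, reference_criteria(), meta_tst())
  dvio <- select_families(fam, kids, violating_criteria(), meta_tst())
  expect_false(dref$included)
  expect_true(dvio$included)
  expect_equal(dvio$exit, as.Date("1705-04-01"))

  # under-15 child death after the last birth extends the violating window
  kids2 <- child_row("TST000001", as.Date("1705-04-01"),
                     death = as.Date("1712-09-01"))
  dvio2 <- select_families(fam, kids2, violating_criteria(), meta_tst())
  expect_equal(dvio2$exit, as.Date("1712-09-01"))

  # with a spouse death the family is excluded from the diagnostic subset
  fam3 <- family_row("TST000003", n_children = 1L)
  dvio3 <- select_families(fam3, child_row("TST000003",
                                           as.Date("1705-04-01")),
                           violating_criteria(), meta_tst())
  expect_false(dvio3$included)
  expect_match(dvio3$reasons, "HAS_SPOUSE_DEATH")
})

test_that("date-precision rules exclude estimated months", {
  fam <- rbind(
    family_row("TST000001"),
    family_row("TST000002", marriage_est = "Estimated (dd/mm)"),
    family_row("TST000003", husband_death_est = "Before this date"),
    family_row("TST000004", wife_birth_est = "Estimated (dd/mm)"),
    family_row("TST000005", marriage_est = "Estimated (dd)"))
  d <- select_families(fam, empty_children(), reference_criteria(),
                       meta_tst())
  expect_equal(d$included, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_match(d$reasons[2], "MARRIAGE_DATE_ESTIMATED")
  expect_match(d$reasons[3], "SPOUSE_DEATH_ESTIMATED")

  # child birth months: estimated excluded, dummy births allowed
  fam2 <- family_row("TST000006", n_children = 1L)
  kids_est <- child_row("TST000006", as.Date("1705-04-01"),
                        est = "Estimated (dd/mm)")
  kids_dummy <- child_row("TST000006", as.Date("1705-04-01"),
                          est = "Dummy birth (burial date)")
  expect_false(select_families(fam2, kids_est, reference_criteria(),
                               meta_tst())$included)
  expect_true(select_families(fam2, kids_dummy, reference_criteria(),
                              meta_tst())$included)
  no_dummy <- criteria_set(name = "strict", allow_dummy_births = FALSE)
  expect_false(select_families(fam2, kids_dummy, no_dummy,
                               meta_tst())$included)
})

test_that("remarriages are excluded from the reference sample", {
  fam <- rbind(family_row("TST000001"),
               family_row("TST000002", wife_remarriage = TRUE),
               family_row("TST000003", husband_remarriage = TRUE))
  d <- select_families(fam, empty_children(), reference_criteria(),
                       meta_tst())
  expect_equal(d$included, c(TRUE, FALSE, FALSE))
  expect_match(d$reasons[2], "WIFE_REMARRIAGE")
})

test_that("parish weights and quality years apply", {
  metas <- list(
    BIR = parish_metadata("Birstall", "BIR"),
    SHP = parish_metadata("Shepshed", "SHP"),
    TST = meta_tst(),
    NAR = parish_metadata("Narrowfield", "NAR",
                          quality_years = data.frame(start = 1690L,
                                                     end = 1720L)))
  fam <- rbind(family_row("BIR000001", parish = "BIR"),
               family_row("SHP000001", parish = "SHP"),
               family_row("TST000001", parish = "TST"),
               family_row("NAR000001", parish = "NAR"))
  d <- select_families(fam, empty_children(), reference_criteria(), metas)
  expect_false(d$included[1])          # Birstall omitted from fertility
  expect_match(d$reasons[1], "PARISH_EXCLUDED")
  expect_true(d$included[2])
  expect_equal(d$weight[2], 0.5)       # Shepshed half weight
  expect_equal(d$weight[3], 1)
  # window 1700-1728 ends outside the 1690-1720 quality years
  expect_false(d$included[4])
  expect_match(d$reasons[4], "OUTSIDE_QUALITY_YEARS")
})

test_that("occupation availability can be required", {
  fam <- rbind(family_row("TST000001", husband_occupation = TRUE),
               family_row("TST000002", husband_occupation = FALSE))
  d <- select_families(fam, empty_children(), occupation_criteria(),
                       meta_tst())
  expect_equal(d$included, c(TRUE, FALSE))
})

test_that("the funnel is monotone and decisions ignore input order", {
  sim <- simulate_parish(small_cfg())
  prep <- prepare_parish(text = sim$text, parish_code = "SIM",
                         parish_meta = sim$parish_meta)
  d <- select_families(prep$families, prep$children,
                       reference_criteria(), prep$parish_meta)
  funnel <- attr(d, "funnel")
  expect_true(all(diff(funnel$families) <= 0))
  expect_true(all(diff(funnel$person_years) <= 1e-9))

  perm <- sample(nrow(prep$families))
  d2 <- select_families(prep$families[perm, ], prep$children,
                        reference_criteria(), prep$parish_meta)
  expect_setequal(d2$union[d2$included], d$union[d$included])
})

test_that("diagnostic subsets are disjoint from the reference sample", {
  sim <- simulate_parish(small_cfg())
  prep <- prepare_parish(text = sim$text, parish_code = "SIM",
                         parish_meta = sim$parish_meta)
  dref <- select_families(prep$families, prep$children,
                          reference_criteria(), prep$parish_meta)
  dvio <- select_families(prep$families, prep$children,
                          violating_criteria(), prep$parish_meta)
  expect_length(intersect(dref$union[dref$included],
                          dvio$union[dvio$included]), 0L)
})
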