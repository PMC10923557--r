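test_that("individual IDs follow the role-suffix grammar", {
  expect_identical(make_individual_id("P", "wife"), "PW")
  expect_identical(make_individual_id("P", "husband"), "PH")
  expect_identical(make_individual_id("P", "child", 2), "PC02")
  expect_identical(make_individual_id("P", "husband_father"), "PHF")
  expect_error(make_individual_id("P", "child"), "child_number")
  expect_error(make_individual_id("P", "uncle"), "unknown role")
  # distinct roles give distinct ids
  roles <- c("wife", "husband", "wife_father", "wife_mother",
             "husband_father", "husband_mother")
  expect_length(unique(vapply(roles, function(r)
    make_individual_id("P", r), "")), length(roles))
})

test_that("weightings map to estimation labels", {
  expect_identical(map_weighting_to_estimation(NA), "Exact")
  # year only recorded: day and month ambiguity offsets
  expect_identical(map_weighting_to_estimation(3000, as.Date("1700-01-01")),
                   "Estimated (dd/mm)")
  # day unknown (code 101, plus its day-ambiguity offset)
  expect_identical(map_weighting_to_estimation(1101, as.Date("1780-07-01")),
                   "Estimated (dd)")
  # spouse death proxied by remarriage
  expect_identical(map_weighting_to_estimation(150, as.Date("1750-01-01")),
                   "Before this date")
  # leap-day adjustment alone leaves the date fully known
  expect_identical(map_weighting_to_estimation(4000, as.Date("1700-02-28")),
                   "Exact")
  # unknown base codes: conservative default, with a warning
  expect_warning(lab <- map_weighting_to_estimation(777),
                 "unknown weighting")
  expect_identical(lab, "Estimated")
})

test_that("IDS build emits unions, memberships, and mirrored kinship", {
  b <- records_to_bundle(fixture_records(), "TST")
  ids <- build_ids(b, fixture_meta())

  un <- ids$CONTEXT[ids$CONTEXT$type == "Union", ]
  expect_equal(nrow(un), 2L)
  expect_equal(un$date[1], as.Date("1741-06-15"))

  # FRF 17: husband, wife, 2 children
  ic <- ids$INDIV_CONTEXT[ids$INDIV_CONTEXT$id_c == "TST000017", ]
  expect_equal(nrow(ic), 4L)
  expect_setequal(ic$relation, c("Husband", "Wife", "Child"))

  # mirrored pairs: even count, involution
  ii <- ids$INDIV_INDIV
  expect_equal(nrow(ii) %% 2L, 0L)
  key <- paste(ii$id_i_1, ii$id_i_2)
  rev <- paste(ii$id_i_2, ii$id_i_1)
  expect_setequal(key, rev)
  # mother-child given in both directions
  expect_true(any(ii$id_i_1 == "TST000017W" & ii$id_i_2 == "TST000017C01" &
                    ii$relation == "mother of"))
  expect_true(any(ii$id_i_1 == "TST000017C01" & ii$id_i_2 == "TST000017W" &
                    ii$relation == "child of"))

  # no empty datum rows
  ind <- ids$INDIVIDUAL
  expect_true(all(!is.na(ind$value) | !is.na(ind$date)))
  # birth kept distinct from baptism for the paired child date
  c1 <- ind[ind$id_i == "TST000017C01", ]
  expect_equal(c1$date[c1$type == "BAPTISM_DATE"], as.Date("1742-07-15"))
  expect_equal(c1$date[c1$type == "BIRTH_DATE"], as.Date("1742-06-21"))
  # widowhood flag is NOT imported as a Type
  expect_false(any(grepl("^Widow", ind$type, ignore.case = TRUE)))
  # stillbirth flags arrive as Types
  expect_true(any(ind$type == "Stillbirth"))
})

test_that("a burial-only child gets a dummy birth record", {
  txt <- c("M/1/1-1-1700/-", "W/a/2-2-1680/-/-/-/-/-",
           "C/x/f/-/10-5-1701/-/-", "$")
  b <- records_to_bundle(read_frf(text = txt), "TST")
  ids <- build_ids(b, fixture_meta())
  ind <- ids$INDIVIDUAL
  db <- ind[ind$id_i == "TST000001C01" & ind$type == "BIRTH_DATE", ]
  expect_equal(nrow(db), 1L)
  expect_equal(db$date, as.Date("1701-05-10"))
  expect_identical(db$estimation, "Dummy birth (burial date)")
})

test_that("harmonization rewrites linked individuals to the earliest ID", {
  # child C01 of FRF 1 (baptised 1701) marries into FRF 2 as wife
  txt <- c("M/1/1-1-1700/-", "W/a/2-2-1680/-/-/-/-/-",
           "C/x/f/3-3-1701/-/1-6-1725/2", "$",
           "M/2/1-6-1725/-", "H/h/-/-/-/-/-/-",
           "W/x/3-3-1701/-/-/-/-/-", "$")
  b <- records_to_bundle(read_frf(text = txt), "TST")
  ids <- harmonize_ids(build_ids(b, fixture_meta()), resolve_links(b))
  map <- attr(ids, "id_map")
  expect_equal(map$original, "TST000002W")
  expect_equal(map$canonical, "TST000001C01")
  expect_false("TST000002W" %in% ids$INDIVIDUAL$id_i)
  # the canonical id is now the wife of union 2
  ic <- ids$INDIV_CONTEXT
  expect_true(any(ic$id_i == "TST000001C01" & ic$id_c == "TST000002" &
                    ic$relation == "Wife"))
})

test_that("a widower keeps one ID across his two unions", {
  txt <- c("M/1/1-1-1700/-", "H/h/-/-/-/-/-/2",
           "W/w1/5-5-1680/1-1-1710/-/-/-/-", "$",
           "M/2/1-1-1712/-", "H/h/-/-/-/-/1/-",
           "W/w2/6-6-1690/-/-/-/-/-", "$")
  b <- records_to_bundle(read_frf(text = txt), "TST")
  ids <- harmonize_ids(build_ids(b, fixture_meta()), resolve_links(b))
  ic <- ids$INDIV_CONTEXT[ids$INDIV_CONTEXT$relation == "Husband", ]
  expect_equal(unique(ic$id_i), "TST000001H")
  expect_equal(nrow(ic), 2L)  # two union memberships, one person
})

test_that("harmonization with no links is the identity", {
  b <- records_to_bundle(read_frf(
    text = c("M/1/1-1-1700/-", "W/a/-/-/-/-/-/-", "$")), "TST")
  ids0 <- build_ids(b, fixture_meta())
  ids1 <- harmonize_ids(ids0, resolve_links(b))
  expect_equal(nrow(attr(ids1, "id_map")), 0L)
  expect_equal(ids1$INDIVIDUAL, ids0$INDIVIDUAL)
})

test_that("consistency checks flag constructed violations and pass clean data", {
  # death before birth (no marriage date, so exactly one issue)
  txt <- c("M/1/-/-", "W/a/2-2-1680/1-1-1670/-/-/-/-", "$")
  b <- records_to_bundle(read_frf(text = txt), "TST")
  chk <- run_consistency_checks(build_ids(b, fixture_meta()))
  expect_equal(unname(chk$counts["ordering"]), 1L)

  # mother aged 14 at a child's birth
  txt <- c("M/1/1-1-1700/-", "W/a/2-2-1686/-/-/-/-/-",
           "C/x/f/1-3-1700/-/-/-", "$")
  b <- records_to_bundle(read_frf(text = txt), "TST")
  chk <- run_consistency_checks(build_ids(b, fixture_meta()))
  expect_equal(unname(chk$counts["mother_age"]), 1L)
  expect_lt(chk$mother_age_issues$age, 15)

  # clean synthetic parish: no ordering violations
  sim <- simulate_parish(small_cfg())
  b <- records_to_bundle(read_frf(text = sim$text), "SIM")
  ids <- harmonize_ids(build_ids(b, sim$parish_meta), resolve_links(b))
  chk <- run_consistency_checks(ids)
  expect_equal(unname(chk$counts["ordering"]), 0L)
})
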