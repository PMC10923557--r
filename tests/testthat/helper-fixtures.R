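# Hand-built FRF fixture: two families with the format features the parser
# must handle — paired dates, weightings, flags with compound values,
# missing markers, literacy and parent lines, cross-family links.
fixture_frf_text <- function() {
  c(
    "M/17/15-6-1741/chapel",
    "H/John/-/3-2-1780 (1-2-1780)/-/lab/-/-",
    "W/Mary/0-7-1720*101/12-9-1785/-/-/-/44",
    "C/Ann/f/15-7-1742 (21-6-1742)/-/-/-",
    "C/Tom/m/10-8-1742/20-8-1742/-/-",
    "HM/Jane",
    "WF/Giles/moor/husb",
    "L/y/n",
    "F/H/W/C1/Z2/C2/Z2",
    "$",
    "M/44/2-5-1786/-",
    "H/Peter/-/-/-/-/-/-",
    "W/Mary/0-7-1720*101/12-9-1785/-/-/17/-",
    "$")
}

fixture_records <- function() read_frf(text = fixture_frf_text())

# a minimal single-parish metadata covering all dates in the fixtures
fixture_meta <- function()
  parish_metadata("Testfield", "TST",
                  quality_years = data.frame(start = 1500L, end = 1900L),
                  sample_groups = data.frame(group = 1L, start = 1500L,
                                             end = 1900L))

# small, fast simulator configuration for property tests
small_cfg <- function(...) {
  do.call(synth_config,
          utils::modifyList(list(n_couples = 120L, seed = 42L),
                            list(...)))
}

# hand-built family/children tables for selection-rule unit tests;
# every date Exact unless overridden
family_row <- function(union = "TST000001",
                       marriage = as.Date("1700-06-01"),
                       wife_birth = as.Date("1678-03-15"),
                       wife_death = as.Date(NA),
                       husband_death = as.Date("1730-01-10"),
                       marriage_est = "Exact",
                       wife_birth_est = "Exact",
                       wife_death_est = NA_character_,
                       husband_death_est = "Exact",
                       wife_remarriage = FALSE,
                       husband_remarriage = FALSE,
                       husband_occupation = TRUE,
                       parish = "TST", n_children = 0L) {
  data.frame(
    union = union, marriage_date = marriage,
    marriage_estimation = marriage_est,
    wife_id = paste0(union, "W"), husband_id = paste0(union, "H"),
    wife_birth = wife_birth, wife_birth_estimation = wife_birth_est,
    wife_death = wife_death, wife_death_estimation = wife_death_est,
    husband_birth = as.Date(NA), husband_birth_estimation = NA_character_,
    husband_death = husband_death,
    husband_death_estimation = husband_death_est,
    husband_occupation = husband_occupation,
    wife_remarriage = wife_remarriage,
    husband_remarriage = husband_remarriage,
    parish = parish, n_children = n_children,
    stringsAsFactors = FALSE)
}

empty_children <- function() {
  data.frame(id_i = character(), union = character(),
             birth_date = as.Date(character()),
             birth_estimation = character(),
             death_date = as.Date(character()),
             stringsAsFactors = FALSE)
}

child_row <- function(union, birth, est = "Exact", death = as.Date(NA)) {
  data.frame(id_i = paste0(union, "C01"), union = union,
             birth_date = birth, birth_estimation = est,
             death_date = death, stringsAsFactors = FALSE)
}

# day-by-day enumeration oracle for person-years per (age group x period)
# cell: slow but independent of the episode algebra
brute_force_person_years <- function(windows,
                                     age_breaks = seq(15L, 50L, 5L),
                                     period_breaks = seq(1575L, 1900L,
                                                         25L)) {
  acc <- list()
  for (i in seq_len(nrow(windows))) {
    days <- seq(as.numeric(windows$entry[i]),
                as.numeric(windows$exit[i]) - 1)
    if (!length(days)) next
    age <- (days - as.numeric(windows$birth_date[i])) / 365.25
    ag <- reconkit:::.age_group_label(age, age_breaks)
    yr <- reconkit:::.num_date_parts(days)$year
    pe <- reconkit:::.period_label(yr, period_breaks)
    key <- paste(ag, pe, sep = "|")
    tab <- tapply(rep(windows$weight[i] / 365.25, length(days)), key, sum)
    acc[[i]] <- data.frame(key = names(tab), py = as.numeric(tab),
                           stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, acc)
  out <- tapply(a$py, a$key, sum)
  data.frame(key = names(out), person_years = as.numeric(out),
             stringsAsFactors = FALSE)
}
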