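test_that("baptisms within 60 days collapse to one event", {
  cl <- collapse_multiple_births(as.Date(c("1780-07-15", "1780-08-10")))
  expect_equal(cl$events, as.Date("1780-07-15"))  # 26 days apart
  expect_equal(cl$sizes, 2L)
  expect_equal(cl$n_collapsed, 1L)

  cl <- collapse_multiple_births(as.Date(c("1780-07-15", "1782-01-01")))
  expect_length(cl$events, 2L)
  expect_equal(cl$n_collapsed, 0L)

  d <- as.Date("1700-03-01")
  cl <- collapse_multiple_births(c(d, d, d))  # same-day triplets
  expect_equal(cl$events, d)
  expect_equal(cl$sizes, 3L)

  expect_length(collapse_multiple_births(as.Date(character()))$events, 0L)
})

test_that("the chronicle tracks parity, lactation, and marital status", {
  txt <- c("M/1/1-1-1700/-", "H/h/-/1-1-1730/-/-/-/-",
           "W/a/2-2-1680/-/-/-/-/-",
           "C/x/f/1-3-1702/-/-/-",
           "C/y/m/1-6-1704/1-9-1704/-/-", "$")
  b <- records_to_bundle(read_frf(text = txt), "TST")
  ids <- build_ids(b, fixture_meta())
  ch <- build_chronicle(ids)
  w <- ch[ch$id == "TST000001W", ]

  par <- w[w$attribute == "parity", ]
  expect_equal(par$value[order(par$date)], c("0", "1", "2"))
  expect_equal(sum(w$is_event), 2L)
  expect_equal(w$date[w$is_event], as.Date(c("1702-03-01", "1704-06-01")))

  ms <- w[w$attribute == "marital_status", ]
  expect_equal(ms$value[order(ms$date)], c("single", "married", "widowed"))

  # second child dies while nursing: lactation closes at the death, and
  # the previous-child-death indicator turns on
  lac <- w[w$attribute == "lactation", ]
  expect_true(any(lac$value == "0" & lac$date == as.Date("1704-09-01")))
  pcd <- w[w$attribute == "prev_child_dead", ]
  expect_true(any(pcd$value == "1" & pcd$date == as.Date("1704-09-01")))
})

test_that("twin baptisms produce a single parity increment", {
  txt <- c("M/1/1-1-1700/-", "W/a/2-2-1680/-/-/-/-/-",
           "C/x/f/1-3-1702/-/-/-",
           "C/y/m/20-3-1702/-/-/-",
           "F/C1/2/C2/2", "$")
  b <- records_to_bundle(read_frf(text = txt), "TST")
  ch <- build_chronicle(build_ids(b, fixture_meta()))
  w <- ch[ch$id == "TST000001W", ]
  expect_equal(sum(w$is_event), 1L)
  expect_equal(max(as.integer(w$value[w$attribute == "parity"])), 1L)
})

test_that("a never-married woman contributes no fertility chronicle", {
  # a parish of one family with no wife line yields no chronicle rows
  txt <- c("M/1/1-1-1700/-", "H/h/-/-/-/-/-/-", "$")
  ch <- build_chronicle(build_ids(
    records_to_bundle(read_frf(text = txt), "TST"), fixture_meta()))
  expect_equal(nrow(ch), 0L)
})

simple_window <- function(entry, exit, birth = as.Date("1680-01-01"),
                          id = "w1") {
  data.frame(id = id, union = "u1", birth_date = birth,
             entry = as.Date(entry), exit = as.Date(exit), weight = 1,
             stringsAsFactors = FALSE)
}

empty_chronicle <- function() {
  data.frame(id = character(), union = character(),
             attribute = character(), value = character(),
             date = as.Date(character()), is_event = logical(),
             stringsAsFactors = FALSE)
}

test_that("a 10-year window with no births splits only at age bounds", {
  birth <- as.Date("1680-01-01")
  entry <- reconkit:::.age_boundary(birth, 20)
  exit <- reconkit:::.age_boundary(birth, 30)
  eps <- make_episodes(empty_chronicle(),
                       simple_window(entry, exit, birth),
                       period_breaks = c(1575L, 1850L))  # unbroken period
  expect_equal(nrow(eps), 2L)
  expect_equal(eps$age_group, c("20-24", "25-29"))
  expect_equal(eps$event, c(0L, 0L))
  expect_equal(eps$duration_years, c(5, 5), tolerance = 2 / 365.25)
  expect_equal(sum(eps$duration_years),
               as.numeric(exit - entry) / 365.25)
})

test_that("a birth splits the window and flags exactly that episode", {
  birth <- as.Date("1680-01-01")
  entry <- reconkit:::.age_boundary(birth, 20)
  exit <- reconkit:::.age_boundary(birth, 30)
  bdate <- birth + ceiling(22.5 * 365.25)
  ch <- data.frame(id = "w1", union = "u1", attribute = "birth",
                   value = "1", date = bdate, is_event = TRUE,
                   stringsAsFactors = FALSE)
  eps <- make_episodes(ch, simple_window(entry, exit, birth),
                       period_breaks = c(1575L, 1850L))
  expect_equal(nrow(eps), 3L)
  expect_equal(eps$event, c(1L, 0L, 0L))
  expect_equal(eps$end[1], bdate)
  expect_equal(eps$start_age[2], 22.5, tolerance = 0.01)
})

test_that("zero-length windows yield no episodes", {
  d <- as.Date("1700-01-01")
  eps <- make_episodes(empty_chronicle(), simple_window(d, d))
  expect_equal(nrow(eps), 0L)
})

test_that("a birth on the window-closing day still counts", {
  birth <- as.Date("1680-01-01")
  entry <- reconkit:::.age_boundary(birth, 20)
  exit <- entry + 365L
  ch <- data.frame(id = "w1", union = "u1", attribute = "birth",
                   value = "1", date = exit, is_event = TRUE,
                   stringsAsFactors = FALSE)
  eps <- make_episodes(ch, simple_window(entry, exit, birth))
  expect_equal(sum(eps$event), 1L)
  expect_equal(eps$end[which(eps$event == 1L)], exit)
})

test_that("episode durations conserve each woman's window exactly", {
  sim <- simulate_parish(small_cfg())
  prep <- prepare_parish(text = sim$text, parish_code = "SIM",
                         parish_meta = sim$parish_meta)
  res <- fertility_rates_for(prep, reference_criteria())
  eps <- res$episodes
  win <- res$windows
  per_woman <- tapply(eps$duration_years, eps$union, sum)
  expected <- as.numeric(win$exit - win$entry) / 365.25
  names(expected) <- win$union
  expect_equal(per_woman[names(expected)], expected,
               tolerance = 1e-8, ignore_attr = TRUE)
  # event flags conserve collapsed births inside windows
  ev <- prep$chronicle[prep$chronicle$is_event, ]
  inside <- mapply(function(u, id, en, ex)
    sum(ev$id == id & ev$date > en & ev$date <= ex),
    win$union, win$id, win$entry, win$exit)
  expect_equal(sum(eps$event), sum(inside))
})

test_that("episode person-years match the day-enumeration oracle", {
  sim <- simulate_parish(small_cfg())
  prep <- prepare_parish(text = sim$text, parish_code = "SIM",
                         parish_meta = sim$parish_meta)
  res <- fertility_rates_for(prep, reference_criteria())
  oracle <- brute_force_person_years(res$windows)
  got <- res$rates
  gkey <- paste(got$age_group, got$period, sep = "|")
  for (k in seq_len(nrow(oracle))) {
    g <- got$person_years[gkey == oracle$key[k]]
    if (!length(g)) g <- 0
    expect_lt(abs(g - oracle$person_years[k]),
              nrow(res$windows) / 365.25)
  }
})
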