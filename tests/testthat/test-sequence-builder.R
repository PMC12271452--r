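mk_events <- function(pid, dates, source, code) {
  data.frame(patient_id = pid, date = as.Date(dates), source = source,
             code = code, stringsAsFactors = FALSE)
}

test_that("unmapped codes are dropped and order preserved", {
  ev <- mk_events("p1",
                  c("2010-01-01", "2010-02-01", "2010-03-01", "2010-04-01",
                    "2010-05-01"),
                  "diagnosis",
                  c("I10", "XXX1", "E11", "XXX2", "J45"))
  out <- map_events(ev, default_code_map())
  expect_equal(out$token, c("I10", "E11", "J45"))
  expect_equal(out$date, as.Date(c("2010-01-01", "2010-03-01", "2010-05-01")))
  expect_equal(nrow(map_events(ev[0, ], default_code_map())), 0)
})

test_that("monthly refill deduplication follows the 6-month gap rule", {
  cm <- default_code_map()
  # continuous monthly refills collapse to the first
  ev <- map_events(mk_events("p1", c("2015-01-05", "2015-02-03", "2015-03-02"),
                             "medication", "statins"), cm)
  out <- dedup_medications(ev)
  expect_equal(out$date, as.Date("2015-01-05"))
  # a gap above the threshold re-admits the medication
  ev2 <- map_events(mk_events("p1", c("2015-01-05", "2015-02-03", "2015-11-10"),
                              "medication", "statins"), cm)
  out2 <- dedup_medications(ev2)
  expect_equal(out2$date, as.Date(c("2015-01-05", "2015-11-10")))
  # non-monthly medications are all kept
  ev3 <- map_events(mk_events("p1", c("2015-01-05", "2015-01-20", "2015-02-03",
                                      "2015-02-20"),
                              "medication", "antibiotics"), cm)
  expect_equal(nrow(dedup_medications(ev3)), 4)
  # unsorted input is a contract violation
  ev4 <- ev2[c(3, 1, 2), ]
  expect_error(dedup_medications(ev4), "chronological")
})

test_that("deduplication is idempotent on random refill streams", {
  cm <- default_code_map()
  withr::with_seed(42, {
    for (i in 1:20) {
      dates <- sort(as.Date("2010-01-01") + sample.int(2000, 30))
      ev <- map_events(mk_events("p1", format(dates), "medication", "SSRIs"), cm)
      once <- dedup_medications(ev)
      twice <- dedup_medications(once)
      expect_identical(as.data.frame(once), as.data.frame(twice))
    }
  })
})

test_that("vocabulary pruning counts distinct patients against the threshold", {
  counts <- c(tokA = 150, tokB = 100, tokC = 99, tokD = 3, tokE = 1)
  rows <- do.call(rbind, lapply(names(counts), function(tk) {
    data.frame(patient_id = sprintf("%s_p%d", tk, seq_len(counts[[tk]])),
               date = as.Date("2010-01-01"), source = "diagnosis",
               token = tk, cadence = NA_character_)
  }))
  v <- build_vocabulary(rows, min_patient_count = 100)
  expect_setequal(setdiff(v$tokens, names(v$special)), c("tokA", "tokB"))
  # repeat occurrences in one patient count once
  one <- data.frame(patient_id = "p1", date = as.Date("2010-01-01"),
                    source = "diagnosis", token = rep("tokZ", 500),
                    cadence = NA_character_)
  v1 <- build_vocabulary(one, min_patient_count = 2)
  expect_false("tokZ" %in% v1$tokens)
  expect_equal(unname(v1$patient_counts["tokZ"]), 1L)
  # empty cohort leaves only the special tokens
  v0 <- build_vocabulary(rows[0, ], min_patient_count = 100)
  expect_equal(v0$tokens, names(v0$special))
})

test_that("raising the pruning threshold never adds tokens", {
  co <- generate_cohort(cohort_config(n_patients = 200, seed = 6))
  mapped <- map_events(co$events, default_code_map())
  sizes <- vapply(c(1, 5, 20, 50), function(th) {
    length(build_vocabulary(mapped, min_patient_count = th)$tokens)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  vs <- lapply(c(5, 20), function(th)
    build_vocabulary(mapped, min_patient_count = th)$tokens)
  expect_true(all(vs[[2]] %in% vs[[1]]))
})

test_that("visit numbers pool events by calendar month", {
  expect_equal(assign_visits(as.Date(c("2010-01-03", "2010-01-20", "2010-03-05"))),
               c(1, 1, 2))
  expect_equal(assign_visits(as.Date("2010-06-15")), 1)
  months <- as.Date(sprintf("2010-%02d-10", 1:12))
  expect_equal(assign_visits(months), 1:12)
  expect_equal(assign_visits(as.Date(character())), integer())
})

test_that("sequences align channels, truncate to the most recent events and map OOV to UNK", {
  n <- 100
  dates <- as.Date("1995-06-01") + round(seq(0, 9000, length.out = n))
  ev <- data.frame(patient_id = "p1", date = dates, source = "diagnosis",
                   token = rep(c("I10", "E11", "J45", "ZZZ"), 25),
                   cadence = NA_character_)
  dm <- data.frame(patient_id = "p1", gender = "female",
                   year_of_birth = 1940L)
  vocab <- build_vocabulary(ev[ev$token != "ZZZ", ], min_patient_count = 1)
  ss <- build_sequences(ev, dm, vocab, max_len = 64)
  s <- ss[[1]]
  expect_length(s$token_ids, 64)
  expect_equal(length(s$age_years), length(s$token_ids))
  expect_equal(length(s$calendar_year), length(s$token_ids))
  expect_equal(length(s$visit_number), length(s$token_ids))
  # most recent events kept
  expect_equal(s$tokens, ev$token[(n - 63):n])
  expect_true(!is.unsorted(s$age_years))
  expect_true(!is.unsorted(s$visit_number))
  expect_equal(s$visit_number[1], 1)
  # OOV token becomes UNK
  expect_true(all(s$token_ids[s$tokens == "ZZZ"] == vocab$special[["[UNK]"]]))
})

test_that("a 24-event history yields a length-24 sequence", {
  dates <- as.Date("2000-01-15") + seq(0, by = 45, length.out = 24)
  ev <- data.frame(patient_id = "p1", date = dates, source = "diagnosis",
                   token = "I10", cadence = NA_character_)
  dm <- data.frame(patient_id = "p1", gender = "male", year_of_birth = 1945L)
  vocab <- build_vocabulary(ev, min_patient_count = 1)
  s <- build_sequences(ev, dm, vocab, max_len = 64)[[1]]
  expect_length(s$token_ids, 24)
})

test_that("sequences round-trip through delimited text", {
  co <- generate_cohort(cohort_config(n_patients = 25, seed = 14))
  sq <- cohort_to_sequences(co, min_patient_count = 2)
  p <- tempfile(fileext = ".csv")
  write_sequences(sq$sequences, p)
  back <- read_sequences(p)
  expect_equal(length(back), length(sq$sequences))
  i <- which(vapply(back, `[[`, character(1), "patient_id") ==
               sq$sequences[[1]]$patient_id)
  expect_equal(back[[i]]$token_ids, sq$sequences[[1]]$token_ids)
  expect_equal(back[[i]]$age_years, sq$sequences[[1]]$age_years)
  unlink(p)
})
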