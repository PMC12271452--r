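# From raw coded event streams to model-ready token sequences: code mapping,
# monthly-medication deduplication, patient-count vocabulary pruning,
# visit numbering by pooled 1-month intervals, and channel-aligned sequences.

#' Construct a code map
#'
#' Maps raw source codes to sequence tokens. Diagnosis codes map to ICD-10
#' three-character categories, medication product codes to medication groups
#' with a refill-cadence flag (monthly medications are subject to
#' deduplication), lab codes to abnormality tokens. Events whose code has no
#' mapping are dropped by [map_events()].
#'
#' @param map Data frame with columns `raw_code`, `token`, `domain`
#'   (`diagnosis`, `medication`, `lab`, `symptom`) and `cadence`
#'   (`monthly` / `adhoc`; only meaningful for medications).
#' @return An object of class `code_map`.
#' @export
code_map <- function(map) {
  need <- c("raw_code", "token", "domain", "cadence")
  assert_that(all(need %in% names(map)),
              "code map needs columns raw_code, token, domain, cadence")
  assert_that(!anyDuplicated(map$raw_code), "raw codes must map uniquely")
  assert_that(all(nzchar(map$token)), "target tokens must be non-empty")
  structure(list(map = data.table::as.data.table(map)), class = "code_map")
}

#' Identity code map for a synthetic cohort
#'
#' Synthetic cohorts already emit target-level codes, so the default map is
#' the identity over the condition list, medication groups and background
#' codes, carrying each medication group's cadence.
#'
#' @param extra_unmapped Optional character vector of raw codes to leave
#'   unmapped (they will be dropped), emulating codes with no ICD-10 map.
#' @return A `code_map`.
#' @export
default_code_map <- function(extra_unmapped = character()) {
  ltc <- default_ltc_list()
  med <- default_medications()
  bk <- default_background_codes()
  m <- rbind(
    data.frame(raw_code = ltc$code, token = ltc$code, domain = "diagnosis",
               cadence = NA_character_, stringsAsFactors = FALSE),
    data.frame(raw_code = med$code, token = med$code, domain = "medication",
               cadence = med$cadence, stringsAsFactors = FALSE),
    data.frame(raw_code = bk$code, token = bk$code, domain = bk$source,
               cadence = NA_character_, stringsAsFactors = FALSE)
  )
  m <- m[!(m$raw_code %in% extra_unmapped), ]
  code_map(m)
}

#' Map raw events to sequence tokens
#'
#' Applies the code map to an events table; events with no mapping are
#' dropped, chronological order is preserved.
#'
#' @param events Data frame with columns `patient_id`, `date`, `source`,
#'   `code` (as written by [generate_cohort()]).
#' @param codemap A [code_map()].
#' @return A data.table with columns `patient_id`, `date`, `source`,
#'   `token`, `cadence`.
#' @export
map_events <- function(events, codemap) {
  assert_that(inherits(codemap, "code_map"), "codemap must be a code_map")
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0) {
    return(data.table::data.table(patient_id = character(),
                                  date = as.Date(character()),
                                  source = character(), token = character(),
                                  cadence = character()))
  }
  ev$.ord <- seq_len(nrow(ev))
  m <- codemap$map[, c("raw_code", "token", "cadence")]
  out <- merge(ev, m, by.x = "code", by.y = "raw_code", sort = FALSE)
  out <- out[order(out$.ord), ]
  res <- out[, c("patient_id", "date", "source", "token", "cadence")]
  data.table::setattr(res, "class", c("data.table", "data.frame"))
  res[]
}

#' Deduplicate monthly medication refills
#'
#' For medication groups flagged as monthly, only the first prescription
#' enters the sequence; later prescriptions of the same group are suppressed
#' until a gap of at least `gap_days` between consecutive raw prescriptions
#' occurs, after which the next prescription is kept and the rule restarts.
#' Non-monthly medications and non-medication events pass through untouched.
#'
#' @param events Mapped events (output of [map_events()]), chronological
#'   within patient.
#' @param gap_days Gap threshold in days; default 183 (~6 months).
#' @return The events table with suppressed refills removed.
#' @export
dedup_medications <- function(events, gap_days = 183) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0) return(ev)
  chk <- ev[, list(ok = !is.unsorted(date)), by = "patient_id"]
  assert_that(all(chk$ok), "events must be chronological within patient")
  is_monthly <- ev$source == "medication" & !is.na(ev$cadence) &
    ev$cadence == "monthly"
  keep <- rep(TRUE, nrow(ev))
  if (any(is_monthly)) {
    sub <- ev[is_monthly, ]
    sub$.row <- which(is_monthly)
    grp <- paste(sub$patient_id, sub$token, sep = "\r")
    for (g in split(seq_len(nrow(sub)), grp)) {
      d <- as.numeric(sub$date[g])
      k <- c(TRUE, diff(d) >= gap_days)
      keep[sub$.row[g][!k]] <- FALSE
    }
  }
  ev[keep, ]
}

#' Build the token vocabulary
#'
#' Tokens are counted per distinct patient; tokens seen in fewer than
#' `min_patient_count` patients are excluded. Special tokens (PAD, MASK,
#' CLS, SEP, UNK) occupy the first indices and are never pruned; remaining
#' tokens are indexed in lexicographic order.
#'
#' @param events Mapped events for the whole cohort.
#' @param min_patient_count Patient-count threshold (default 100).
#' @return An object of class `ehr_vocabulary` with `tokens` (index ->
#'   token), `index` (named lookup), `special` and `patient_counts`.
#' @export
build_vocabulary <- function(events, min_patient_count = 100) {
  special <- c("[PAD]", "[MASK]", "[CLS]", "[SEP]", "[UNK]")
  ev <- data.table::as.data.table(events)
  if (nrow(ev) > 0) {
    cnt <- ev[, list(n_patients = data.table::uniqueN(patient_id)), by = "token"]
    kept <- sort(cnt$token[cnt$n_patients >= min_patient_count])
    counts <- setNames(cnt$n_patients, cnt$token)
  } else {
    kept <- character()
    counts <- integer()
  }
  tokens <- c(special, kept)
  structure(list(tokens = tokens,
                 index = setNames(seq_along(tokens), tokens),
                 special = setNames(seq_along(special), special),
                 patient_counts = counts,
                 min_patient_count = min_patient_count),
            class = "ehr_vocabulary")
}

#' @export
print.ehr_vocabulary <- function(x, ...) {
  cat(sprintf("<ehr_vocabulary> %d tokens (%d special), min patient count %d\n",
              length(x$tokens), length(x$special), x$min_patient_count))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens)

token_to_id <- function(vocab, tokens) {
  id <- unname(vocab$index[tokens])
  id[is.na(id)] <- vocab$special[["[UNK]"]]
  id
}

#' Assign visit numbers
#'
#' Events in the same pooled 1-month interval (calendar month) share a visit
#' number; the counter starts at 1 and increments at each new occupied
#' month.
#'
#' @param dates Chronological Date vector for one patient.
#' @return Integer vector of visit numbers, non-decreasing from 1.
#' @export
assign_visits <- function(dates) {
  if (length(dates) == 0) return(integer())
  key <- format(dates, "%Y-%m")
  cumsum(c(TRUE, key[-1] != key[-length(key)]))
}

#' Build channel-aligned token sequences
#'
#' Converts mapped, deduplicated events into per-patient token sequences
#' with parallel age (completed years at event), calendar year and visit
#' channels. Out-of-vocabulary tokens become UNK. If a patient has more than
#' `max_len` events the most recent `max_len` are kept.
#'
#' @param events Mapped (and typically deduplicated) events.
#' @param demographics Demographics table (`patient_id`, `gender`,
#'   `year_of_birth`).
#' @param vocab An [build_vocabulary()] result.
#' @param max_len Maximum sequence length (default 64).
#' @return An object of class `sequence_set`: a list of per-patient
#'   sequences, each with `patient_id`, `token_ids`, `tokens`, `age_years`,
#'   `calendar_year`, `visit_number`, `gender`.
#' @export
build_sequences <- function(events, demographics, vocab, max_len = 64) {
  ev <- data.table::as.data.table(events)
  dm <- data.table::as.data.table(demographics)
  ev <- merge(ev, dm[, c("patient_id", "gender", "year_of_birth")],
              by = "patient_id", sort = FALSE)
  data.table::setorderv(ev, c("patient_id", "date"))
  out <- lapply(split(seq_len(nrow(ev)), ev$patient_id), function(ix) {
    d <- ev[ix, ]
    visits <- assign_visits(d$date)
    yr <- as.integer(format(d$date, "%Y"))
    age <- yr - d$year_of_birth[1]
    n <- nrow(d)
    if (n > max_len) {
      sel <- (n - max_len + 1):n
      d <- d[sel, ]; visits <- visits[sel]; yr <- yr[sel]; age <- age[sel]
      visits <- visits - visits[1] + 1L   # counter restarts at 1
    }
    list(patient_id = d$patient_id[1],
         token_ids = token_to_id(vocab, d$token),
         tokens = d$token,
         age_years = as.integer(age),
         calendar_year = yr,
         visit_number = as.integer(visits),
         gender = d$gender[1])
  })
  # patients with no events are simply absent (ineligible downstream)
  structure(unname(out), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  lens <- vapply(x, function(s) length(s$token_ids), integer(1))
  cat(sprintf("<sequence_set> %d patients, median length %s\n",
              length(x), if (length(lens)) median(lens) else NA))
  invisible(x)
}

#' Write / read sequences as delimited text
#'
#' One row per patient; channels are pipe-delimited integer lists.
#'
#' @param sequences A `sequence_set`.
#' @param path Output file (CSV).
#' @return `write_sequences` the path invisibly; `read_sequences` a
#'   `sequence_set`.
#' @export
write_sequences <- function(sequences, path) {
  rows <- data.table::rbindlist(lapply(sequences, function(s) {
    data.table::data.table(
      patient_id = s$patient_id, gender = s$gender,
      token_ids = paste(s$token_ids, collapse = "|"),
      tokens = paste(s$tokens, collapse = "|"),
      age_years = paste(s$age_years, collapse = "|"),
      calendar_year = paste(s$calendar_year, collapse = "|"),
      visit_number = paste(s$visit_number, collapse = "|"))
  }))
  data.table::fwrite(rows, path)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  rows <- data.table::fread(path, colClasses = "character")
  out <- lapply(seq_len(nrow(rows)), function(i) {
    sp <- function(col, f) f(strsplit(rows[[col]][i], "|", fixed = TRUE)[[1]])
    list(patient_id = rows$patient_id[i],
         token_ids = sp("token_ids", as.integer),
         tokens = sp("tokens", identity),
         age_years = sp("age_years", as.integer),
         calendar_year = sp("calendar_year", as.integer),
         visit_number = sp("visit_number", as.integer),
         gender = rows$gender[i])
  })
  structure(out, class = "sequence_set")
}

#' End-to-end sequence construction from a cohort
#'
#' Convenience wrapper: map, deduplicate, build vocabulary, build sequences.
#'
#' @param cohort An `ehr_cohort`.
#' @param codemap A `code_map` (default identity map for synthetic cohorts).
#' @param min_patient_count Vocabulary pruning threshold.
#' @param max_len Maximum sequence length.
#' @param gap_days Medication deduplication gap.
#' @return List with `sequences` (`sequence_set`), `vocab`, `events`
#'   (mapped, deduplicated).
#' @export
cohort_to_sequences <- function(cohort, codemap = default_code_map(),
                                min_patient_count = 100, max_len = 64,
                                gap_days = 183) {
  mapped <- map_events(cohort$events, codemap)
  dd <- dedup_medications(mapped, gap_days = gap_days)
  vocab <- build_vocabulary(dd, min_patient_count = min_patient_count)
  seqs <- build_sequences(dd, cohort$demographics, vocab, max_len = max_len)
  list(sequences = seqs, vocab = vocab, events = dd)
}
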