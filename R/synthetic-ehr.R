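# Synthetic primary-care cohort generator.
#
# Real UK primary-care data of the kind this pipeline targets are access
# restricted, so the package ships a generator that emulates their structure
# with known ground truth: each patient is drawn from one morbidity archetype
# (hard assignment), conditions are sampled per-archetype with odds uplift on
# planted comorbidity pairs, linked medications are emitted as monthly refill
# streams from condition onset, and demographic marginals follow configurable
# targets (defaults mirror the published cohort's Table-1-style margins).

#' Default long-term condition list
#'
#' 54 chronic conditions plus 3 risk factors (hypertension, smoking status,
#' obesity), coded as ICD-10 three-character categories. The list is a
#' plausible stand-in for published multimorbidity condition lists; any
#' data frame with `code` and `name` columns can replace it.
#'
#' @return A data.frame with columns `code`, `name`, `class`.
#' @export
default_ltc_list <- function() {
  x <- rbind(
    c("I10", "hypertension",            "risk_factor"),
    c("F17", "smoking",                 "risk_factor"),
    c("E66", "obesity",                 "risk_factor"),
    c("E11", "type 2 diabetes",         "cardiometabolic"),
    c("E78", "hyperlipidaemia",         "cardiometabolic"),
    c("I25", "coronary heart disease",  "cardiometabolic"),
    c("I21", "myocardial infarction",   "cardiometabolic"),
    c("I50", "heart failure",           "cardiometabolic"),
    c("I48", "atrial fibrillation",     "cardiometabolic"),
    c("I63", "stroke",                  "cardiometabolic"),
    c("G45", "TIA",                     "cardiometabolic"),
    c("I73", "peripheral vascular disease", "cardiometabolic"),
    c("I80", "venous thromboembolism",  "cardiometabolic"),
    c("I26", "pulmonary embolism",      "cardiometabolic"),
    c("I35", "valve disease",           "cardiometabolic"),
    c("N18", "chronic kidney disease",  "other"),
    c("F32", "depression",              "mental_health"),
    c("F41", "anxiety",                 "mental_health"),
    c("F31", "bipolar disorder",        "mental_health"),
    c("F20", "schizophrenia",           "mental_health"),
    c("F10", "alcohol misuse",          "mental_health"),
    c("F19", "drug misuse",             "mental_health"),
    c("F51", "insomnia",                "mental_health"),
    c("F03", "dementia",                "mental_health"),
    c("J45", "asthma",                  "respiratory"),
    c("J44", "COPD",                    "respiratory"),
    c("J47", "bronchiectasis",          "respiratory"),
    c("J84", "interstitial lung disease", "respiratory"),
    c("G47", "sleep apnoea",            "respiratory"),
    c("M19", "osteoarthritis",          "musculoskeletal"),
    c("M06", "rheumatoid arthritis",    "musculoskeletal"),
    c("M81", "osteoporosis",            "musculoskeletal"),
    c("M10", "gout",                    "musculoskeletal"),
    c("M54", "chronic back pain",       "musculoskeletal"),
    c("G40", "epilepsy",                "neurological"),
    c("G20", "Parkinson disease",       "neurological"),
    c("G43", "migraine",                "neurological"),
    c("G35", "multiple sclerosis",      "neurological"),
    c("K58", "irritable bowel syndrome", "digestive"),
    c("K50", "inflammatory bowel disease", "digestive"),
    c("K21", "reflux disease",          "digestive"),
    c("K27", "peptic ulcer",            "digestive"),
    c("K76", "chronic liver disease",   "digestive"),
    c("K80", "gallstone disease",       "digestive"),
    c("C18", "colorectal cancer",       "cancer"),
    c("C50", "breast cancer",           "cancer"),
    c("C61", "prostate cancer",         "cancer"),
    c("C34", "lung cancer",             "cancer"),
    c("D64", "anaemia",                 "other"),
    c("E03", "hypothyroidism",          "other"),
    c("E27", "adrenal insufficiency",   "other"),
    c("L40", "psoriasis",               "other"),
    c("L20", "eczema",                  "other"),
    c("H40", "glaucoma",                "other"),
    c("H25", "cataract",                "other"),
    c("H90", "hearing loss",            "other"),
    c("N39", "urinary incontinence",    "other")
  )
  data.frame(code = x[, 1], name = x[, 2], class = x[, 3],
             stringsAsFactors = FALSE)
}

# Symptom / lab-abnormality tokens (ICD-10 R-chapter categories).
default_background_codes <- function() {
  data.frame(
    code = c("R05", "R06", "R51", "R53", "R42", "R03", "R73", "R79", "R94"),
    source = c(rep("symptom", 5), rep("lab", 4)),
    stringsAsFactors = FALSE
  )
}

# Medication groups with refill cadence. Monthly groups are emitted as
# monthly refill streams; ad-hoc groups as a small number of one-off scripts.
default_medications <- function() {
  data.frame(
    code = c("ACE_inhibitors", "statins", "metformin", "beta_blockers",
             "SSRIs", "antipsychotics", "hypnotics",
             "inhaled_corticosteroids", "bronchodilators",
             "analgesics", "NSAIDs", "antibiotics", "PPIs"),
    cadence = c("monthly", "monthly", "monthly", "monthly",
                "monthly", "monthly", "monthly",
                "monthly", "monthly",
                "adhoc", "adhoc", "adhoc", "monthly"),
    stringsAsFactors = FALSE
  )
}

#' Construct an archetype definition
#'
#' An archetype is a latent morbidity profile: per-condition prevalence,
#' age-at-onset distribution (truncated normal within the observation
#' window) and condition-linked medication groups.
#'
#' @param name Archetype label.
#' @param weight Mixing proportion within its gender stratum.
#' @param prevalence Named numeric vector, condition code -> probability.
#' @param onset_mean,onset_sd Named numeric vectors (or scalars recycled over
#'   conditions) giving the age-at-onset distribution in years.
#' @param medication_links Data frame with columns `condition`, `medication`,
#'   `cadence` ("monthly" or "adhoc").
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, weight, prevalence,
                           onset_mean = 60, onset_sd = 12,
                           medication_links = NULL) {
  assert_that(all(prevalence >= 0 & prevalence <= 1),
              "archetype prevalences must lie in [0, 1]")
  assert_that(weight >= 0, "archetype weight must be non-negative")
  conds <- names(prevalence)
  if (length(onset_mean) == 1) onset_mean <- setNames(rep(onset_mean, length(conds)), conds)
  if (length(onset_sd) == 1) onset_sd <- setNames(rep(onset_sd, length(conds)), conds)
  if (is.null(medication_links)) {
    medication_links <- data.frame(condition = character(), medication = character(),
                                   cadence = character(), stringsAsFactors = FALSE)
  }
  structure(list(name = name, weight = weight, prevalence = prevalence,
                 onset_mean = onset_mean, onset_sd = onset_sd,
                 medication_links = medication_links),
            class = "archetype_spec")
}

#' Default archetype set
#'
#' Five archetypes per gender stratum: low disease burden, cardiometabolic,
#' mental health, respiratory and mixed morbidity, with block-structured
#' condition prevalences and condition-linked medication groups.
#'
#' @return A list of [archetype_spec()] objects whose weights sum to 1.
#' @export
default_archetypes <- function() {
  list(
    archetype_spec("low_burden", 0.30,
      prevalence = c(I10 = 0.08, E03 = 0.05, K21 = 0.05, H25 = 0.05,
                     M19 = 0.05, L20 = 0.04),
      onset_mean = 60, onset_sd = 12),
    archetype_spec("cardiometabolic", 0.25,
      prevalence = c(I10 = 0.88, E11 = 0.62, E78 = 0.60, I25 = 0.40,
                     I21 = 0.15, I50 = 0.18, I48 = 0.22, I63 = 0.10,
                     E66 = 0.50, N18 = 0.18),
      onset_mean = c(I10 = 55, E11 = 58, E78 = 56, I25 = 63, I21 = 65,
                     I50 = 70, I48 = 68, I63 = 70, E66 = 50, N18 = 68),
      onset_sd = 9,
      medication_links = data.frame(
        condition = c("I10", "E11", "E78", "I25"),
        medication = c("ACE_inhibitors", "metformin", "statins", "beta_blockers"),
        cadence = "monthly", stringsAsFactors = FALSE)),
    archetype_spec("mental_health", 0.18,
      prevalence = c(F32 = 0.82, F41 = 0.68, F51 = 0.35, F10 = 0.30,
                     F19 = 0.18, F31 = 0.10, F20 = 0.06, F17 = 0.50),
      onset_mean = c(F32 = 42, F41 = 40, F51 = 48, F10 = 45, F19 = 38,
                     F31 = 35, F20 = 30, F17 = 35),
      onset_sd = 11,
      medication_links = data.frame(
        condition = c("F32", "F51", "F20"),
        medication = c("SSRIs", "hypnotics", "antipsychotics"),
        cadence = "monthly", stringsAsFactors = FALSE)),
    archetype_spec("respiratory", 0.12,
      prevalence = c(J45 = 0.72, J44 = 0.48, J47 = 0.12, J84 = 0.05,
                     G47 = 0.20, F17 = 0.55),
      onset_mean = c(J45 = 42, J44 = 62, J47 = 58, J84 = 66, G47 = 55,
                     F17 = 35),
      onset_sd = 12,
      medication_links = data.frame(
        condition = c("J45", "J44"),
        medication = c("inhaled_corticosteroids", "bronchodilators"),
        cadence = "monthly", stringsAsFactors = FALSE)),
    archetype_spec("mixed", 0.15,
      prevalence = c(M19 = 0.62, M54 = 0.45, M81 = 0.28, K21 = 0.42,
                     K58 = 0.25, D64 = 0.25, N39 = 0.22, H90 = 0.20,
                     C18 = 0.08, G43 = 0.20),
      onset_mean = c(M19 = 62, M54 = 50, M81 = 70, K21 = 52, K58 = 45,
                     D64 = 60, N39 = 66, H90 = 68, C18 = 68, G43 = 38),
      onset_sd = 10,
      medication_links = data.frame(
        condition = c("M19", "K21"),
        medication = c("analgesics", "PPIs"),
        cadence = c("adhoc", "monthly"), stringsAsFactors = FALSE))
  )
}

#' Default planted comorbidity pairs
#'
#' Clinically established disease pairs planted with an odds-ratio uplift so
#' that embedding validation has a known ground truth.
#'
#' @return Data frame with columns `a`, `b`, `odds_multiplier`.
#' @export
default_comorbidity_pairs <- function() {
  data.frame(
    a = c("I10", "E78", "E66", "F32", "J44", "I25", "I10", "M19"),
    b = c("E11", "I25", "E11", "F41", "F17", "I50", "I63", "M54"),
    odds_multiplier = c(2.5, 2.0, 2.0, 3.0, 2.5, 2.5, 2.0, 2.0),
    stringsAsFactors = FALSE
  )
}

#' Cohort generator configuration
#'
#' Demographic targets default to the published cohort margins the simulator
#' emulates: 54.8% female, ethnicity recorded for 37.7% (93.4% White among
#' recorded), IMD linkage for 51.3% with 22.6% in the least deprived
#' quintile.
#'
#' @param n_patients Number of patients (>= 0).
#' @param prop_female Proportion of female patients.
#' @param ethnicity_dist Named probabilities over ethnicity categories.
#' @param ethnicity_recorded_prob Probability ethnicity is recorded at all.
#' @param imd_dist Probabilities over IMD quintiles 1 (least deprived) to 5.
#' @param imd_linked_prob Probability a patient has IMD linkage.
#' @param archetypes_female,archetypes_male Lists of [archetype_spec()];
#'   weights are normalised to sum to 1 within each gender.
#' @param comorbidity_pairs Data frame (`a`, `b`, `odds_multiplier` > 0).
#' @param study_start,study_end Observation window (ISO dates).
#' @param age_range Age at `study_end`, sampled uniformly.
#' @param background_event_rate Mean number of symptom/lab background events
#'   per patient (Poisson).
#' @param seed Integer seed; fixed seed gives a byte-identical cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          prop_female = 0.548,
                          ethnicity_dist = c(White = 0.934, `South Asian` = 0.029,
                                             Black = 0.020, Mixed = 0.005,
                                             Other = 0.012),
                          ethnicity_recorded_prob = 0.377,
                          imd_dist = c(0.226, 0.222, 0.211, 0.183, 0.158),
                          imd_linked_prob = 0.513,
                          archetypes_female = default_archetypes(),
                          archetypes_male = default_archetypes(),
                          comorbidity_pairs = default_comorbidity_pairs(),
                          study_start = "1990-01-01",
                          study_end = "2020-12-31",
                          age_range = c(50, 100),
                          background_event_rate = 6,
                          seed = 1L) {
  assert_that(is.numeric(n_patients) && length(n_patients) == 1 && n_patients >= 0,
              "n_patients must be a single non-negative number")
  assert_that(prop_female >= 0 && prop_female <= 1, "prop_female must be in [0, 1]")
  assert_that(all(comorbidity_pairs$odds_multiplier > 0),
              "comorbidity odds multipliers must be > 0")
  norm_w <- function(arcs) {
    w <- vapply(arcs, `[[`, numeric(1), "weight")
    assert_that(sum(w) > 0, "archetype weights must sum to a positive value")
    for (i in seq_along(arcs)) arcs[[i]]$weight <- w[i] / sum(w)
    arcs
  }
  structure(list(
    n_patients = as.integer(n_patients), prop_female = prop_female,
    ethnicity_dist = ethnicity_dist / sum(ethnicity_dist),
    ethnicity_recorded_prob = ethnicity_recorded_prob,
    imd_dist = imd_dist / sum(imd_dist), imd_linked_prob = imd_linked_prob,
    archetypes_female = norm_w(archetypes_female),
    archetypes_male = norm_w(archetypes_male),
    comorbidity_pairs = comorbidity_pairs,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    age_range = age_range,
    background_event_rate = background_event_rate,
    seed = as.integer(seed)), class = "cohort_config")
}

# Truncated-normal sampler via inverse-CDF (vectorised).
rtruncnorm_vec <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  bad <- phi <= plo  # distribution mass entirely outside window
  u <- runif(n, plo, phi)
  x <- qnorm(u, mean, sd)
  x[bad] <- runif(sum(bad), lo[bad], hi[bad])
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort
#'
#' Draws each patient from one archetype of their gender stratum, samples
#' conditions at the archetype prevalences with odds uplift on planted
#' comorbidity pairs (the uplift preserves the marginal prevalence of the
#' second pair member), places age at onset with a truncated normal inside
#' the observation window, and emits diagnosis events, monthly medication
#' refill streams from onset, and background symptom/lab events.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ehr_cohort`: a list with data.tables
#'   `demographics`, `events`, `truth`, plus the `config`.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  n <- config$n_patients
  if (n == 0) {
    return(structure(list(
      demographics = data.table::data.table(
        patient_id = character(), gender = character(),
        year_of_birth = integer(), ethnicity = character(),
        imd_quintile = integer(), registration_start = as.Date(character()),
        registration_end = as.Date(character())),
      events = data.table::data.table(
        patient_id = character(), date = as.Date(character()),
        source = character(), code = character()),
      truth = data.table::data.table(patient_id = character(),
                                     gender = character(),
                                     archetype = character()),
      config = config), class = "ehr_cohort"))
  }
  with_seed(config$seed, {
    pid <- sprintf("p%07d", seq_len(n))
    gender <- ifelse(runif(n) < config$prop_female, "female", "male")
    age_end <- runif(n, config$age_range[1], config$age_range[2])
    end_year <- as.integer(format(config$study_end, "%Y"))
    yob <- end_year - floor(age_end)
    rec <- runif(n) < config$ethnicity_recorded_prob
    eth <- rep(NA_character_, n)
    eth[rec] <- sample(names(config$ethnicity_dist), sum(rec), replace = TRUE,
                       prob = config$ethnicity_dist)
    lnk <- runif(n) < config$imd_linked_prob
    imd <- rep(NA_integer_, n)
    imd[lnk] <- sample(seq_along(config$imd_dist), sum(lnk), replace = TRUE,
                       prob = config$imd_dist)
    demographics <- data.table::data.table(
      patient_id = pid, gender = gender, year_of_birth = as.integer(yob),
      ethnicity = eth, imd_quintile = imd,
      registration_start = config$study_start,
      registration_end = config$study_end)

    window_years <- as.numeric(config$study_end - config$study_start) / 365.25
    age_start <- pmax(age_end - window_years, 0)
    birth_date <- config$study_end - round(age_end * 365.25)

    # archetype assignment per gender stratum
    archetype <- character(n)
    for (g in c("female", "male")) {
      arcs <- if (g == "female") config$archetypes_female else config$archetypes_male
      idx <- which(gender == g)
      if (!length(idx)) next
      nm <- vapply(arcs, `[[`, character(1), "name")
      w <- vapply(arcs, `[[`, numeric(1), "weight")
      archetype[idx] <- sample(nm, length(idx), replace = TRUE, prob = w)
    }
    truth <- data.table::data.table(patient_id = pid, gender = gender,
                                    archetype = archetype)

    ev_list <- list()
    for (g in c("female", "male")) {
      arcs <- if (g == "female") config$archetypes_female else config$archetypes_male
      for (spec in arcs) {
        idx <- which(gender == g & archetype == spec$name)
        if (!length(idx)) next
        conds <- names(spec$prevalence)
        m <- length(idx)
        pres <- matrix(runif(m * length(conds)) <
                         rep(spec$prevalence, each = m),
                       nrow = m, dimnames = list(NULL, conds))
        # planted comorbidity pairs: redraw second member conditionally so
        # that the pair odds ratio exceeds 1 while the marginal prevalence
        # of the second member is preserved
        cp <- config$comorbidity_pairs
        for (r in seq_len(nrow(cp))) {
          a <- cp$a[r]; b <- cp$b[r]
          if (!(a %in% conds) || !(b %in% conds)) next
          pa <- spec$prevalence[[a]]; pb <- spec$prevalence[[b]]
          if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) next
          ob <- pb / (1 - pb)
          p1 <- cp$odds_multiplier[r] * ob / (1 + cp$odds_multiplier[r] * ob)
          p0 <- max(0, (pb - p1 * pa) / (1 - pa))
          pcond <- ifelse(pres[, a], p1, p0)
          pres[, b] <- runif(m) < pcond
        }
        wh <- which(pres, arr.ind = TRUE)
        if (nrow(wh)) {
          ci <- idx[wh[, 1]]
          cc <- conds[wh[, 2]]
          mu <- spec$onset_mean[cc]; sdv <- spec$onset_sd[cc]
          onset <- rtruncnorm_vec(length(ci), mu, sdv,
                                  lo = age_start[ci], hi = age_end[ci])
          dxdate <- birth_date[ci] + round(onset * 365.25)
          dxdate <- pmin(pmax(dxdate, config$study_start), config$study_end)
          ev_list[[length(ev_list) + 1]] <- data.table::data.table(
            patient_id = pid[ci], date = dxdate, source = "diagnosis", code = cc)
          # linked medication refills from onset
          ml <- spec$medication_links
          for (r in seq_len(nrow(ml))) {
            sel <- which(cc == ml$condition[r])
            if (!length(sel)) next
            if (ml$cadence[r] == "monthly") {
              nref <- pmax(1L, as.integer(floor(
                as.numeric(config$study_end - dxdate[sel]) / 30.44)) + 1L)
              rep_i <- rep(seq_along(sel), nref)
              off <- sequence(nref) - 1L
              mdate <- dxdate[sel][rep_i] + round(off * 30.44)
              mdate <- pmin(mdate, config$study_end)
              ev_list[[length(ev_list) + 1]] <- data.table::data.table(
                patient_id = pid[ci[sel]][rep_i], date = mdate,
                source = "medication", code = ml$medication[r])
            } else {
              nscr <- rpois(length(sel), 2) + 1L
              rep_i <- rep(seq_along(sel), nscr)
              span <- as.numeric(config$study_end - dxdate[sel])[rep_i]
              mdate <- dxdate[sel][rep_i] + round(runif(length(rep_i)) * span)
              ev_list[[length(ev_list) + 1]] <- data.table::data.table(
                patient_id = pid[ci[sel]][rep_i], date = mdate,
                source = "medication", code = ml$medication[r])
            }
          }
        }
      }
    }

    # background symptom / lab-abnormality events
    if (config$background_event_rate > 0) {
      bk <- default_background_codes()
      nb <- rpois(n, config$background_event_rate)
      if (sum(nb) > 0) {
        rep_i <- rep(seq_len(n), nb)
        span <- as.numeric(config$study_end - config$study_start)
        bdate <- config$study_start + round(runif(length(rep_i)) * span)
        # background events only after the patient plausibly enters care
        lo <- birth_date[rep_i] + round(pmax(age_start[rep_i], 18) * 365.25)
        bdate <- pmax(bdate, pmin(lo, config$study_end))
        ksel <- sample.int(nrow(bk), length(rep_i), replace = TRUE)
        ev_list[[length(ev_list) + 1]] <- data.table::data.table(
          patient_id = pid[rep_i], date = bdate,
          source = bk$source[ksel], code = bk$code[ksel])
      }
    }

    events <- if (length(ev_list)) data.table::rbindlist(ev_list) else
      data.table::data.table(patient_id = character(), date = as.Date(character()),
                             source = character(), code = character())
    data.table::setorderv(events, c("patient_id", "date", "source", "code"))
    structure(list(demographics = demographics, events = events,
                   truth = truth, config = config), class = "ehr_cohort")
  })
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d patients, %d events, %d archetype labels\n",
              nrow(x$demographics), nrow(x$events), nrow(x$truth)))
  invisible(x)
}

#' Restrict a cohort to eligible patients
#'
#' Applies the eligibility rule used for the clustering cohort: age at the
#' last recorded event must reach `min_age`.
#'
#' @param cohort An `ehr_cohort`.
#' @param min_age Minimum age (years) at last event; default 50.
#' @return A filtered `ehr_cohort`.
#' @export
filter_eligible <- function(cohort, min_age = 50) {
  ev <- cohort$events
  dm <- cohort$demographics
  last <- ev[, list(last_date = max(date)), by = "patient_id"]
  last <- merge(last, dm[, c("patient_id", "year_of_birth")], by = "patient_id")
  last$age_last <- as.integer(format(last$last_date, "%Y")) - last$year_of_birth
  keep <- last$patient_id[last$age_last >= min_age]
  cohort$demographics <- dm[dm$patient_id %in% keep, ]
  cohort$events <- ev[ev$patient_id %in% keep, ]
  cohort$truth <- cohort$truth[cohort$truth$patient_id %in% keep, ]
  cohort
}

#' Summarise cohort demographics
#'
#' Counts and percentages by gender, ethnicity and IMD quintile, computed on
#' the reporting denominators used for such cohort tables: gender
#' percentages over all patients, ethnicity percentages among patients with
#' recorded ethnicity, IMD percentages among patients with IMD linkage.
#'
#' Also accepts an externally supplied count table (columns `variable`,
#' `level`, `n`) so that published counts can be summarised directly.
#'
#' @param x An `ehr_cohort`, a demographics data frame, or a count table
#'   with columns `variable`, `level`, `n`.
#' @return A data.frame with columns `variable`, `level`, `n`,
#'   `denominator`, `pct`.
#' @export
summarize_demographics <- function(x) {
  if (inherits(x, "ehr_cohort")) x <- x$demographics
  x <- as.data.frame(x)
  if (all(c("variable", "level", "n") %in% names(x))) {
    out <- do.call(rbind, lapply(split(x, x$variable), function(d) {
      den <- sum(d$n)
      data.frame(variable = d$variable, level = as.character(d$level),
                 n = d$n, denominator = den,
                 pct = if (den > 0) 100 * d$n / den else 0,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  blocks <- list()
  if (nrow(x) == 0) {
    return(data.frame(variable = character(), level = character(),
                      n = integer(), denominator = integer(), pct = numeric()))
  }
  tab <- function(v, variable) {
    v <- v[!is.na(v)]
    den <- length(v)
    if (den == 0) return(NULL)
    tt <- table(v)
    data.frame(variable = variable, level = names(tt),
               n = as.integer(tt), denominator = den,
               pct = 100 * as.integer(tt) / den, stringsAsFactors = FALSE)
  }
  blocks$gender <- tab(x$gender, "gender")
  blocks$ethnicity <- tab(x$ethnicity, "ethnicity")
  blocks$imd <- tab(x$imd_quintile, "imd")
  out <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write / read a cohort as delimited text
#'
#' Events, demographics and ground-truth tables as CSV; the configuration as
#' JSON.
#'
#' @param cohort An `ehr_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns the file paths invisibly; `read_cohort`
#'   an `ehr_cohort` (without archetype specs in the config echo).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.csv"),
             demographics = file.path(dir, "demographics.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.json"))
  data.table::fwrite(cohort$events, paths["events"])
  data.table::fwrite(cohort$demographics, paths["demographics"])
  data.table::fwrite(cohort$truth, paths["truth"])
  cfg <- cohort$config
  cfg$archetypes_female <- lapply(cfg$archetypes_female, unclass)
  cfg$archetypes_male <- lapply(cfg$archetypes_male, unclass)
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ev <- data.table::fread(file.path(dir, "events.csv"))
  ev$date <- as.Date(ev$date)
  dm <- data.table::fread(file.path(dir, "demographics.csv"))
  dm$registration_start <- as.Date(dm$registration_start)
  dm$registration_end <- as.Date(dm$registration_end)
  tr <- data.table::fread(file.path(dir, "truth.csv"))
  structure(list(demographics = dm, events = ev, truth = tr, config = NULL),
            class = "ehr_cohort")
}
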