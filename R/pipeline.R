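# End-to-end orchestration: runs the pipeline stages in order with one
# global seed deterministically split into per-stage seeds, and writes a
# manifest of produced files into a versioned output directory.

pipeline_stages <- function() {
  c("simulate", "build-sequences", "pretrain", "finetune", "embed",
    "select-k", "cluster", "stability", "temporal", "evaluate", "lca")
}

stage_dependencies <- function() {
  list("build-sequences" = "simulate",
       "pretrain" = "build-sequences",
       "finetune" = "pretrain",
       "embed" = "finetune",
       "select-k" = "embed",
       "cluster" = "select-k",
       "stability" = "cluster",
       "temporal" = "cluster",
       "evaluate" = "cluster",
       "lca" = "simulate")
}

#' Pipeline run configuration
#'
#' @param cohort A [cohort_config()] for the `simulate` stage.
#' @param model A [model_config()]; defaults to [desk_model_config()].
#' @param min_patient_count,max_len Sequence-building parameters.
#' @param k_range,kselect_replicates,kselect_fraction,precluster_k
#'   k-selection parameters.
#' @param stability_replicates,stability_fraction Stability parameters.
#' @param splice_ages Ages for temporal splicing (default 50:100, thinned
#'   for desk-scale runs via `splice_step`).
#' @param splice_step Step between splice ages.
#' @param lca_range Candidate LCA class counts.
#' @param seed Global seed; split deterministically into stage seeds.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort, model = desk_model_config(),
                       min_patient_count = 5, max_len = 64,
                       k_range = 2:10, kselect_replicates = 25,
                       kselect_fraction = 0.1, precluster_k = 50,
                       stability_replicates = 20, stability_fraction = 0.25,
                       splice_ages = seq(50, 100, by = 10),
                       splice_step = NULL, lca_range = 1:6,
                       seed = 1L) {
  structure(list(cohort = cohort, model = model,
                 min_patient_count = min_patient_count, max_len = max_len,
                 k_range = k_range, kselect_replicates = kselect_replicates,
                 kselect_fraction = kselect_fraction,
                 precluster_k = precluster_k,
                 stability_replicates = stability_replicates,
                 stability_fraction = stability_fraction,
                 splice_ages = splice_ages, lca_range = lca_range,
                 seed = as.integer(seed)), class = "run_config")
}

next_run_dir <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  existing <- list.dirs(out_dir, recursive = FALSE, full.names = FALSE)
  runs <- suppressWarnings(as.integer(sub("^run-", "", existing)))
  nxt <- if (length(runs) && any(!is.na(runs))) max(runs, na.rm = TRUE) + 1L else 1L
  file.path(out_dir, sprintf("run-%03d", nxt))
}

#' Run the pipeline
#'
#' Executes the requested stages in order inside a fresh versioned run
#' directory (`<out_dir>/run-NNN`, never overwriting previous runs), with
#' per-stage seeds derived deterministically from the global seed, and
#' writes a JSON manifest recording stage outputs, seeds and file hashes.
#'
#' @param config A [run_config()].
#' @param stages Ordered subset of the stage names
#'   (`r paste(pipeline_stages(), collapse = ", ")`).
#' @param out_dir Output root directory.
#' @param state Optional state list from a previous call (supplies
#'   dependency outputs when running later stages alone).
#' @return Invisibly, a list with `manifest`, `state` (in-memory stage
#'   outputs) and `run_dir`.
#' @export
run_pipeline <- function(config, stages = pipeline_stages(),
                         out_dir = tempfile("mltcseq-run-"), state = NULL) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  unknown <- setdiff(stages, pipeline_stages())
  assert_that(length(unknown) == 0,
              paste("unknown stage(s):", paste(unknown, collapse = ", ")))
  deps <- stage_dependencies()
  st <- state %||% list()
  run_dir <- next_run_dir(out_dir)
  dir.create(run_dir, recursive = TRUE)
  seeds <- derive_seeds(config$seed, length(pipeline_stages()),
                        labels = pipeline_stages())
  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   stages = list(), files = list())
  need <- function(stage, key) {
    dep <- deps[[stage]]
    assert_that(!is.null(st[[key]]),
                sprintf("stage '%s' requires output of stage '%s'", stage, dep))
    st[[key]]
  }
  out_file <- function(name) file.path(run_dir, name)
  log_files <- function(stage, paths) {
    manifest$stages[[stage]] <<- list(outputs = unname(paths))
    for (p in paths) manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      cfg <- config$cohort; cfg$seed <- unname(seeds[["simulate"]])
      st$cohort <- generate_cohort(cfg)
      paths <- write_cohort(st$cohort, file.path(run_dir, "cohort"))
      log_files(stage, paths)
    } else if (stage == "build-sequences") {
      cohort <- need(stage, "cohort")
      st$seqdata <- cohort_to_sequences(cohort,
                                        min_patient_count = config$min_patient_count,
                                        max_len = config$max_len)
      p <- out_file("sequences.csv")
      write_sequences(st$seqdata$sequences, p)
      log_files(stage, p)
    } else if (stage == "pretrain") {
      sq <- need(stage, "seqdata")
      st$pretrained <- rtd_pretrain(sq$sequences, sq$vocab, config$model,
                                    seed = unname(seeds[["pretrain"]]))
      p <- out_file("pretrain_history.csv")
      data.table::fwrite(st$pretrained$history, p)
      log_files(stage, p)
    } else if (stage == "finetune") {
      pt <- need(stage, "pretrained")
      sq <- st$seqdata
      ft <- diffcse_finetune(pt$generator, sq$sequences, sq$vocab,
                             seed = unname(seeds[["finetune"]]))
      st$encoder <- ft$encoder
      p <- out_file("finetune_history.csv")
      data.table::fwrite(ft$history, p)
      log_files(stage, p)
    } else if (stage == "embed") {
      enc <- need(stage, "encoder")
      sq <- st$seqdata
      st$embeddings <- embed_patients(enc, sq$sequences, sq$vocab)
      p <- out_file("embeddings.csv")
      data.table::fwrite(data.table::data.table(patient_id = rownames(st$embeddings),
                                                st$embeddings), p)
      log_files(stage, p)
    } else if (stage == "select-k") {
      emb <- need(stage, "embeddings")
      st$kreport <- select_optimal_k(emb, k_range = config$k_range,
                                     replicates = config$kselect_replicates,
                                     fraction = config$kselect_fraction,
                                     precluster_k = config$precluster_k,
                                     seed = unname(seeds[["select-k"]]))
      p <- out_file("k_selection.csv")
      data.table::fwrite(st$kreport$metrics, p)
      log_files(stage, p)
    } else if (stage == "cluster") {
      emb <- st$embeddings
      kr <- need(stage, "kreport")
      st$model <- fit_final_kmeans(emb, kr$chosen_k,
                                   seed = unname(seeds[["cluster"]]))
      p <- out_file("assignments.csv")
      data.table::fwrite(data.table::data.table(patient_id = rownames(emb),
                                                cluster = st$model$cluster), p)
      log_files(stage, p)
    } else if (stage == "stability") {
      mod <- need(stage, "model")
      st$stability <- bootstrap_stability(st$embeddings, mod,
                                          replicates = config$stability_replicates,
                                          fraction = config$stability_fraction,
                                          seed = unname(seeds[["stability"]]))
      p <- out_file("stability.csv")
      data.table::fwrite(st$stability$per_cluster, p)
      log_files(stage, p)
    } else if (stage == "temporal") {
      mod <- need(stage, "model")
      age_emb <- list()
      for (a in config$splice_ages) {
        spl <- splice_records(st$cohort, a)
        if (nrow(spl$demographics) == 0) next
        sq <- cohort_to_sequences(spl,
                                  min_patient_count = config$min_patient_count,
                                  max_len = config$max_len)
        # reuse the final vocabulary so token ids match the encoder
        sq2 <- build_sequences(sq$events, spl$demographics,
                               st$seqdata$vocab, max_len = config$max_len)
        age_emb[[as.character(a)]] <-
          embed_patients(st$encoder, sq2, st$seqdata$vocab)
      }
      st$temporal <- temporal_cohesion(age_emb, mod, st$embeddings)
      p <- out_file("temporal_cohesion.csv")
      data.table::fwrite(st$temporal$by_age, p)
      log_files(stage, p)
    } else if (stage == "evaluate") {
      mod <- need(stage, "model")
      X <- disease_matrix(st$cohort$events,
                          patient_ids = rownames(st$embeddings))
      w <- suppressMessages(dfipf(X))
      cw <- suppressMessages(cdfipf(w, mod$cluster))
      st$cdfipf <- cw
      p <- out_file("cdfipf.csv")
      data.table::fwrite(data.table::data.table(cluster = rownames(cw),
                                                as.data.frame(unclass(cw))), p)
      log_files(stage, p)
    } else if (stage == "lca") {
      cohort <- need(stage, "cohort")
      X <- disease_matrix(cohort$events)
      st$lca <- select_classes(X, C_range = config$lca_range,
                               seed = unname(seeds[["lca"]]))
      p <- out_file("lca_selection.csv")
      data.table::fwrite(st$lca$table, p)
      log_files(stage, p)
    }
  }
  mp <- file.path(run_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, state = st, run_dir = run_dir))
}
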