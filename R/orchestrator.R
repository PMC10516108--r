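# Orchestration of the active-learning loop: configuration profiles, run
# setup (corpus preprocessing, pretraining, the one-time projection), the
# per-iteration cycle in three modes, and a resumable loop driver.

#' Run configuration
#'
#' Bundles every knob of the loop.  `run_config()` carries the full-scale
#' defaults (100,000 generated molecules per iteration, k = 100 clusters,
#' 1000-molecule scored subsets, 5000/5000 replica floor and sampling
#' budget); [tiny_run_config()] is a desk-scale profile that preserves all
#' of those ratios (2000 generated, k = 20, cap 5, 100 scored, 250/250)
#' and exercises identical code paths.
#'
#' @param generation_size Unique molecules generated per iteration.
#' @param scored_subset Number of molecules selected for scoring per
#'   iteration.
#' @param k Number of k-means clusters.
#' @param n_restarts k-means restarts per clustering.
#' @param per_cluster_cap First-pass cap of [select_for_scoring()].
#' @param n_components Principal components of the chemical-space proxy.
#' @param score_threshold Score threshold of the AL set construction.
#' @param replica_floor,sampling_budget See [al_config()].
#' @param min_count,coverage,train_fraction Corpus preprocessing knobs.
#' @param model [generator_config()] template (context length is set from
#'   the corpus at setup time).
#' @param pretrain,finetune [train_schedule()]s.
#' @param temperature Sampling temperature.
#' @param max_attempt_factor Cap on raw samples per generation stage, as a
#'   multiple of `generation_size`; when the model's unique yield is low the
#'   stage stops at the cap and reports a shortfall.
#' @param provider Descriptor provider (`"fast"`, `"chemistry"`, or a
#'   function).
#' @param weights [interaction_weights()].
#' @param filters Optional [filter_set()] applied to generated molecules
#'   (`NULL` = no filtering, the filter-free evaluation setting).
#' @param references Optional character vector of reference ligands for
#'   similarity metrics.
#' @return A `run_config` list.
#' @export
run_config <- function(generation_size = 100000L, scored_subset = 1000L,
                       k = 100L, n_restarts = 100L, per_cluster_cap = 10L,
                       n_components = 120L, score_threshold = 11,
                       replica_floor = 5000L, sampling_budget = 5000L,
                       min_count = 1000L, coverage = 0.9999,
                       train_fraction = 0.95,
                       model = generator_config(),
                       pretrain = pretrain_schedule(),
                       finetune = finetune_schedule(),
                       temperature = 1.0,
                       max_attempt_factor = 10L,
                       provider = "chemistry",
                       weights = interaction_weights(),
                       filters = NULL,
                       references = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @export
tiny_run_config <- function(score_threshold = 11, ...) {
  run_config(
    generation_size = 2000L, scored_subset = 100L, k = 20L,
    n_restarts = 25L, per_cluster_cap = 5L, n_components = 10L,
    score_threshold = score_threshold,
    replica_floor = 250L, sampling_budget = 250L,
    min_count = 1L, coverage = 1.0, train_fraction = 0.95,
    model = tiny_generator_config(),
    pretrain = train_schedule(batch_size = 16L, epochs = 18L,
                              peak_lr = 2e-3, final_lr = 2e-4),
    finetune = train_schedule(batch_size = 16L, epochs = 10L,
                              peak_lr = 2e-4, final_lr = 2e-5,
                              warmup_token_fraction = 0),
    temperature = 1.0,
    max_attempt_factor = 10L,
    provider = "fast",
    ...
  )
}

resolve_provider <- function(provider) {
  if (is.function(provider)) return(provider)
  switch(provider,
         fast = descriptor_provider_fast(),
         chemistry = descriptor_provider_chemistry(),
         rlang::abort(paste0("unknown descriptor provider: ", provider)))
}

#' Set up an active-learning run
#'
#' Preprocesses the corpus, builds and pretrains the model, computes the
#' pretraining-set descriptors and fits the one-time chemical-space
#' projection that every later iteration reuses.
#'
#' @param corpus Character vector of raw SMILES (or tibble with `smiles`,
#'   or a file path readable by [read_smiles()]).
#' @param config A [run_config()].
#' @param master_seed Master seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @return An `al_run_state` carrying the model, vocabulary, projection,
#'   config, metrics table and seed ledger.
#' @export
al_setup <- function(corpus, config = tiny_run_config(), master_seed = 1L) {
  if (is.character(corpus) && length(corpus) == 1 && file.exists(corpus)) {
    corpus <- read_smiles(corpus)
  }
  prep <- preprocess_corpus(corpus, min_count = config$min_count,
                            coverage = config$coverage,
                            train_fraction = config$train_fraction,
                            seed = derive_seed(master_seed, "split"))
  cfg <- config$model
  cfg$context_length <- prep$max_len + 2L
  model <- build_model(cfg, prep$vocabulary,
                       seed = derive_seed(master_seed, "init"))
  model <- pretrain(model, prep$train, config$pretrain,
                    seed = derive_seed(master_seed, "pretrain"),
                    validation = prep$validation)
  provider <- resolve_provider(config$provider)
  desc <- compute_descriptors(prep$corpus, provider)
  projection <- fit_projection(desc, n_components = config$n_components)
  structure(
    list(model = model, vocabulary = prep$vocabulary,
         projection = projection, provider = provider,
         config = config, corpus = prep$corpus,
         preprocess_report = prep$report,
         master_seed = as.integer(master_seed),
         iteration = 0L,
         metrics = tibble(),
         seed_ledger = tibble(stage = c("split", "init", "pretrain"),
                              iteration = NA_integer_,
                              seed = c(derive_seed(master_seed, "split"),
                                       derive_seed(master_seed, "init"),
                                       derive_seed(master_seed, "pretrain")))),
    class = "al_run_state"
  )
}

#' @export
print.al_run_state <- function(x, ...) {
  cat(sprintf("<al_run_state: iteration %d, %d metric row(s), master seed %d>\n",
              x$iteration, nrow(x$metrics), x$master_seed))
  invisible(x)
}

log_seed <- function(state, stage, it) {
  s <- derive_seed(state$master_seed, stage, it)
  state$seed_ledger <- bind_rows(state$seed_ledger,
                                 tibble(stage = stage, iteration = it, seed = s))
  list(state = state, seed = s)
}

#' Run one iteration of the loop
#'
#' One cycle of generate -> (optional filters) -> descriptors -> project ->
#' cluster -> select -> score -> metrics -> build AL set -> fine-tune.
#' Modes:
#'
#' * `"complete"` — cluster-stratified scoring subset; AL set = replicas of
#'   passing molecules + cluster samples with softmax fractions of mean
#'   cluster scores;
#' * `"uniform"` — identical except every cluster gets the same sampling
#'   fraction (the diffusion-effect control);
#' * `"naive"` — no proxy/clustering: a random scored subset, AL set =
#'   replicas only.
#'
#' @param state An `al_run_state` from [al_setup()].
#' @param pose_provider A [pose_provider()] used to score the selected
#'   subset.
#' @param mode `"complete"`, `"uniform"` or `"naive"`.
#' @param finetune Whether to build the AL set and fine-tune (the final
#'   metrics-only generation of a loop passes `FALSE`).
#' @return The updated state, with one row appended to `state$metrics`.
#' @export
run_iteration <- function(state, pose_provider,
                          mode = c("complete", "uniform", "naive"),
                          finetune = TRUE) {
  mode <- match.arg(mode)
  cfg <- state$config
  it <- state$iteration

  r <- log_seed(state, "generate", it); state <- r$state
  gen <- generate_unique(state$model, cfg$generation_size,
                         temperature = cfg$temperature,
                         max_attempts = cfg$max_attempt_factor * cfg$generation_size,
                         seed = r$seed)
  if (!is.null(cfg$filters)) gen <- apply_filters(gen, cfg$filters)
  assert_that(nrow(gen) >= 1, "no valid molecules generated")

  if (mode == "naive") {
    r <- log_seed(state, "select", it); state <- r$state
    take <- with_seed(r$seed,
                      sample.int(nrow(gen), min(cfg$scored_subset, nrow(gen))))
    selected <- tibble(smiles = gen$smiles[take], cluster = 1L)
    ensemble <- tibble(smiles = gen$smiles, cluster = 1L)
  } else {
    desc <- compute_descriptors(gen, state$provider)
    coords <- project(state$projection, desc)
    r <- log_seed(state, "cluster", it); state <- r$state
    clustering <- cluster_molecules(coords, k = cfg$k,
                                    n_restarts = cfg$n_restarts,
                                    seed = r$seed)
    r <- log_seed(state, "select", it); state <- r$state
    selected <- select_for_scoring(clustering,
                                   per_cluster_cap = cfg$per_cluster_cap,
                                   total = cfg$scored_subset, seed = r$seed)
    ensemble <- cluster_members(clustering)
  }

  scored <- score_molecules(selected, pose_provider, cfg$weights)
  # cluster-stratified subsets over-represent small clusters; weight each
  # scored molecule by its inverse inclusion probability (cluster size /
  # number scored there) so subset statistics estimate ensemble statistics
  # comparably across selection schemes
  weights <- NULL
  if (mode != "naive") {
    sizes <- table(ensemble$cluster)
    n_scored <- table(scored$cluster)
    weights <- as.numeric(sizes[as.character(scored$cluster)]) /
      as.numeric(n_scored[as.character(scored$cluster)])
  }
  state$metrics <- bind_rows(
    state$metrics,
    iteration_metrics_row(it, scored$score, cfg$score_threshold,
                          n_generated = nrow(gen), weights = weights,
                          references = cfg$references,
                          generated = gen$smiles))

  if (finetune) {
    r <- log_seed(state, "alset", it); state <- r$state
    acfg <- al_config(cfg$score_threshold, cfg$replica_floor,
                      cfg$sampling_budget,
                      fraction_method = if (mode == "uniform") "uniform" else "softmax")
    training <- if (mode == "naive") {
      passing <- scored %>% filter(.data$score >= cfg$score_threshold)
      if (nrow(passing) == 0) {
        rlang::warn("naive iteration: nothing passes the threshold; skipping fine-tune")
        NULL
      } else {
        rep(passing$smiles,
            each = replica_multiplicity(nrow(passing), cfg$replica_floor))
      }
    } else {
      al_set_smiles(build_al_set(scored, ensemble, acfg, seed = r$seed))
    }
    if (!is.null(training) && length(training) > 0) {
      r <- log_seed(state, "finetune", it); state <- r$state
      state$model <- fine_tune(state$model, training, cfg$finetune,
                               seed = r$seed)
    }
    state$iteration <- it + 1L
  }
  state
}

#' Run the full loop
#'
#' Executes the setup (or resumes from a checkpoint), then
#' `n_iterations + 1` generation/scoring cycles: metric rows are recorded
#' for iterations `0..n_iterations`, with a fine-tune after every row but
#' the last.  Iteration 0 is the post-pretraining generation.
#'
#' @param corpus Raw SMILES corpus (vector, tibble or path); ignored when
#'   resuming.
#' @param pose_provider A [pose_provider()], or a factory
#'   `function(state) -> pose_provider` called once after setup (useful
#'   when the scorer depends on the fitted projection).
#' @param config A [run_config()].
#' @param mode Loop mode; see [run_iteration()].
#' @param n_iterations Number of fine-tuning iterations (metric rows are
#'   `0..n_iterations`).
#' @param master_seed Master seed.
#' @param workdir Optional directory for per-iteration checkpoints, the
#'   metrics CSV and the run manifest.
#' @param resume Resume from the newest checkpoint in `workdir`.
#' @param setup Optional precomputed [al_setup()] state (lets several modes
#'   share one pretrained model).
#' @return The final `al_run_state`; `state$metrics` holds one row per
#'   iteration.
#' @export
run_loop <- function(corpus = NULL, pose_provider, config = tiny_run_config(),
                     mode = c("complete", "uniform", "naive"),
                     n_iterations = 5L, master_seed = 1L, workdir = NULL,
                     resume = FALSE, setup = NULL) {
  mode <- match.arg(mode)
  state <- NULL
  if (resume && !is.null(workdir)) {
    cks <- sort(list.files(workdir, pattern = "^state_iter\\d+\\.rds$",
                           full.names = TRUE))
    if (length(cks) > 0) state <- readRDS(cks[length(cks)])
  }
  if (is.null(state)) {
    state <- if (!is.null(setup)) setup else {
      assert_that(!is.null(corpus), "need a corpus (or a setup/resume state)")
      al_setup(corpus, config, master_seed)
    }
  }
  if (is.function(pose_provider) && !inherits(pose_provider, "pose_provider")) {
    pose_provider <- pose_provider(state)
  }
  while (nrow(state$metrics) <= n_iterations) {
    state <- run_iteration(state, pose_provider, mode,
                           finetune = nrow(state$metrics) < n_iterations)
    if (!is.null(workdir)) {
      dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(state, file.path(workdir,
                               sprintf("state_iter%03d.rds", nrow(state$metrics) - 1L)))
      readr::write_csv(state$metrics, file.path(workdir, "metrics.csv"))
      write_manifest(state, mode, file.path(workdir, "manifest.json"))
    }
  }
  state$mode <- mode
  state
}

write_manifest <- function(state, mode, path) {
  cfg <- state$config
  manifest <- list(
    mode = mode,
    master_seed = state$master_seed,
    iteration = state$iteration,
    optimizer = state$model$optimizer,
    config = list(
      generation_size = cfg$generation_size, scored_subset = cfg$scored_subset,
      k = cfg$k, n_restarts = cfg$n_restarts,
      per_cluster_cap = cfg$per_cluster_cap,
      n_components = cfg$n_components, score_threshold = cfg$score_threshold,
      replica_floor = cfg$replica_floor, sampling_budget = cfg$sampling_budget,
      temperature = cfg$temperature,
      provider = if (is.function(cfg$provider)) "custom" else cfg$provider,
      standardize_descriptors = TRUE
    ),
    model = list(embed_dim = cfg$model$embed_dim, n_blocks = cfg$model$n_blocks,
                 n_heads = cfg$model$n_heads, dropout = cfg$model$dropout),
    toolkit = toolkit_versions(),
    seed_ledger = state$seed_ledger
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname run_loop
#' @param x An `al_run_state`.
#' @param ... Unused.
#' @method tidy al_run_state
#' @export
tidy.al_run_state <- function(x, ...) x$metrics
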