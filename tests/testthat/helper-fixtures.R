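# Shared fixtures, built once per test run.  Everything is generated in
# code; sizes are kept small so the whole suite stays fast.

micro_corpus <- make_corpus(120, seed = 7)

micro_prep <- preprocess_corpus(micro_corpus, min_count = 1, coverage = 1,
                                train_fraction = 0.9, seed = 5)

# a small trained model shared by generator/orchestrator tests
micro_model <- local({
  cfg <- tiny_generator_config(context_length = micro_prep$max_len + 2L)
  m <- build_model(cfg, micro_prep$vocabulary, seed = 11)
  sch <- train_schedule(batch_size = 16, epochs = 8,
                        peak_lr = 2e-3, final_lr = 2e-4)
  pretrain(m, micro_prep$train, sch, seed = 13,
           validation = micro_prep$validation)
})

# a model overfit on a single molecule (memorisation fixture)
overfit_model <- local({
  vocab <- token_vocabulary(c("CCOCC", "CCNCC", "CCCCC"))
  cfg <- tiny_generator_config(context_length = 8L)
  m <- build_model(cfg, vocab, seed = 3)
  enc <- encode_corpus(rep("CCOCC", 8), vocab, 6L)
  sch <- train_schedule(batch_size = 8, epochs = 60,
                        peak_lr = 3e-3, final_lr = 3e-4)
  pretrain(m, enc, sch, seed = 5)
})

# micro run profile for orchestrator tests (much smaller than the tiny
# acceptance profile)
micro_run_config <- function(...) {
  run_config(
    generation_size = 250L, scored_subset = 40L, k = 5L, n_restarts = 5L,
    per_cluster_cap = 8L, n_components = 6L, score_threshold = 11,
    replica_floor = 40L, sampling_budget = 40L,
    min_count = 1L, coverage = 1.0, train_fraction = 0.9,
    model = tiny_generator_config(),
    pretrain = train_schedule(batch_size = 16L, epochs = 6L,
                              peak_lr = 2e-3, final_lr = 2e-4),
    finetune = train_schedule(batch_size = 16L, epochs = 3L,
                              peak_lr = 2e-4, final_lr = 2e-5,
                              warmup_token_fraction = 0),
    max_attempt_factor = 6L,
    provider = "fast",
    ...
  )
}

make_micro_setup <- function(master_seed = 1L, n = 100L) {
  corp <- make_corpus(n, seed = derive_seed(master_seed, "corpus"))
  suppressWarnings(al_setup(corp, micro_run_config(), master_seed))
}

make_surrogate_for <- function(setup, threshold = 11, seed = 1L) {
  co <- project(setup$projection,
                compute_descriptors(setup$corpus, setup$provider))
  scorer <- calibrate_surrogate(co, threshold = threshold,
                                top_fraction = 0.25,
                                seed = derive_seed(seed, "scorer"))
  surrogate_pose_provider(scorer, setup$projection, setup$provider)
}

random_profile <- function() {
  counts <- sample(0:6, length(INTERACTION_TYPES), replace = TRUE)
  do.call(interaction_profile, as.list(setNames(counts, INTERACTION_TYPES)))
}
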