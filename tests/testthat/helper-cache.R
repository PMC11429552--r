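# Shared heavy fixtures, generated once per test run and memoized.
.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# full-size strong-preset run (15 participants x 100 trials/class, seed 42):
# the synthetic analog of the study's dataset
strong_table <- function() {
  cache_get("strong_table", function() {
    cfg <- generator_config(preset = "strong", seed = 42)
    run <- generate_epochs(cfg)
    bands <- band_decompose(run$epochs)
    tab <- extract_feature_table(bands)
    rm(bands, run)
    gc(verbose = FALSE)
    tab
  })
}

# same size, no planted effects
null_table <- function() {
  cache_get("null_table", function() {
    cfg <- generator_config(seed = 99)
    run <- generate_epochs(cfg)
    bands <- band_decompose(run$epochs)
    tab <- extract_feature_table(bands)
    rm(bands, run)
    gc(verbose = FALSE)
    tab
  })
}

planted_feature_names <- function(preset = "strong") {
  vapply(preset_effects(preset), `[[`, "", "feature_name")
}

# small-grid model specs for structural classifier tests
tiny_model_specs <- function() {
  list(SGD = model_spec("SGD", list(loss = "hinge", alpha = 1e-3)),
       SVC = model_spec("SVC", list(kernel = "linear", C = 1, gamma = "scale")),
       DT = model_spec("DT", list(max_depth = 5, min_samples_leaf = 5)),
       GNB = model_spec("GNB", list(var_smoothing = 1e-9)),
       KNN = model_spec("KNN", list(k = 5, metric = "euclidean")),
       RF = model_spec("RF", list(num_trees = 50, max_depth = 10)),
       MLP = model_spec("MLP", list(hidden = 10, alpha = 1e-3, max_iter = 200)))
}
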