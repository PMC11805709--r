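# Shared fixtures, built lazily and memoized so expensive fits run once per
# test session.
fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# Small well-separated two-cluster cohort and its K=2 fit.
two_cluster_data <- function() {
  memo("two_cluster", function() {
    generate_cohort(sim_config(n_children = 200, k_true = 2, seed = 19))
  })
}

two_cluster_fit <- function() {
  memo("two_cluster_fit", function() {
    gpm_fit(two_cluster_data()$cohort, K = 2,
            control = gpm_control(seed = 19, max_iter = 40))
  })
}

# Moderate preset cohort with weight/height columns, split into train/test,
# with the K=5 model and the Jenss-Bayley population fits.
preset_split <- function() {
  memo("preset_split", function() {
    g <- generate_cohort(sim_config(n_children = 220, seed = 29,
                                    emit_wh = TRUE))
    s <- split_train_test(g$cohort, 150, seed = 29)
    list(truth = g$truth, train = s$train, test = s$test)
  })
}

preset_model <- function() {
  memo("preset_model", function() {
    gpm_fit(preset_split()$train, K = 5,
            control = gpm_control(seed = 29, max_iter = 50))
  })
}

preset_jb <- function() {
  memo("preset_jb", function() {
    s <- preset_split()
    list(weight = fit_jb_mixed(s$train, trait = "weight"),
         height = fit_jb_mixed(s$train, trait = "height"))
  })
}
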