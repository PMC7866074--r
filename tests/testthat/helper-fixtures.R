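# Shared fixtures, all built in code.

# Tiny deterministic record table in the internal layout (2 systems).
tiny_records <- function() {
  data.frame(
    solvent = c("n-hexane", "n-hexane", "n-hexane", "ethanol"),
    solute = c("benzene", "benzene", "benzene", "benzene"),
    T = c(298.15, 313.15, 333.15, 298.15),
    rho1 = c(0.655, 0.641, 0.622, 0.789),
    mu1 = c(0.300, 0.263, 0.224, 1.074),
    D12 = c(4.7e-5, 5.4e-5, 6.4e-5, 1.8e-5),
    polarity = c("nonpolar", "nonpolar", "nonpolar", "polar"),
    source = "fixture",
    stringsAsFactors = FALSE
  )
}

# Fast single-point grids used where the test exercises the pipeline, not
# the breadth of the grid.
fast_grids <- list(
  mlr = list(),
  knn = list(k = c(1L, 3L)),
  dtree = list(max_depth = c(4L, 0L), min_leaf = 1L),
  rforest = list(num_trees = 100L, max_depth = 0L, feature_subset = "sqrt"),
  gboost = list(n_stages = 150L, learning_rate = 0.1, max_depth = 3L)
)

nonpolar_variables <- c("T", "mu1", "M2", "Pc2", "M1")
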