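# planted-feature benchmark shared by the recovery and reduction-scan
# acceptance checks: 1000 synthetic graphs, the 2 planted fingerprint
# columns plus 480 iid noise columns, noise sd = 10% of the signal sd.
# Built once per test run (memoized).

.benchmark_env <- new.env(parent = emptyenv())

planted_benchmark <- function() {
  if (!is.null(.benchmark_env$data)) return(.benchmark_env$data)
  graphs <- generate_graphs(synth_config(n_graphs = 1000, seed = 2024))
  recipe <- synth_recipe()
  targets <- generate_targets(graphs, recipe, noise_frac = 0.1, seed = 2025)
  F <- aabba:::features_by_label(graphs, recipe$label)
  noise <- aabba:::with_seed(2026, matrix(rnorm(1000 * 480), 1000, 480))
  colnames(noise) <- sprintf("noise%03d", seq_len(480))
  X <- cbind(F, noise)
  .benchmark_env$data <- list(X = X, y = targets$y,
                              signal = targets$signal,
                              noise_sd = attr(targets, "noise_sd"),
                              planted = recipe$label)
  .benchmark_env$data
}
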