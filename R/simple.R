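#' Simplified interface: top-k predictions from a file
#'
#' Loads and assembles an edge-list network, runs the named predictor, and
#' returns the `min(k, #non-edges)` highest-scored non-edges, sorted by
#' score descending then lexicographic edge order.
#'
#' @param net_file Path to an edge-list file (see [read_edge_list()]).
#' @param algorithm A registered predictor name (see [lp_predictor()]).
#' @param k Number of top candidates.
#' @param seed Integer seed for stochastic predictors.
#' @param ... Passed to [lp_predictor()].
#' @return A tibble `label_i`, `label_j`, `score`.
#' @export
simple_top <- function(net_file, algorithm, k, seed = 1L, ...) {
  net <- read_edge_list(net_file)
  fit <- lp_learn(lp_predictor(algorithm, ...), net, seed = seed)
  lp_top(fit, k)[, c("label_i", "label_j", "score")]
}

#' Simplified interface: evaluate predictors on a file
#'
#' Delegates to [run_experiment()] with the standard protocol (by default
#' 10% of the links are removed per run) and returns the per-(algorithm,
#' measure) summary.
#'
#' @param net_file Path to an edge-list file.
#' @param algorithms Character vector of predictor names.
#' @param measures Subset of `"roc"`, `"pr"`, `"prdg"`, `"tpr"`.
#' @param remove_ratio Fraction of links removed per run.
#' @param runs Number of runs.
#' @param seed Master seed.
#' @param ... Passed to [run_experiment()].
#' @return A tibble `algorithm`, `measure`, `mean`, `sd`, `runs`.
#' @export
simple_evaluate <- function(net_file, algorithms, measures = c("roc", "tpr"),
                            remove_ratio = 0.1, runs = 1L, seed = 1L, ...) {
  net <- read_edge_list(net_file)
  exp_ <- run_experiment(net, algorithms, measures = measures,
                         remove_ratio = remove_ratio, runs = runs,
                         seed = seed, ...)
  sm <- glance(exp_)
  names(sm)[names(sm) == "predictor"] <- "algorithm"
  sm
}
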