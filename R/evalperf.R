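#' Build a test split from a ground-truth network
#'
#' Uniformly removes `round(remove_ratio * m)` edges from the ground truth;
#' the remaining edges form the *observed* network (same node set, so IDs
#' and labels are preserved). `add_ratio > 0` additionally injects that
#' fraction of false edges (sampled from the ground-truth non-edges) into
#' the observed network. The evaluation negatives are the ground-truth
#' non-edges: all of them, or a seeded uniform sample. Removal does not
#' enforce connectivity unless `keep_largest_component = TRUE`, in which
#' case removed edges that disconnect the graph are still allowed but the
#' split records component membership of the observed network.
#'
#' @param net Assembled ground-truth [network()].
#' @param remove_ratio Fraction of edges to remove (0 < ratio < 1).
#' @param add_ratio Fraction of false edges to inject (default 0).
#' @param seed Integer seed; identical seeds give identical splits.
#' @param negatives `"all"` or a positive count of sampled negatives.
#' @return An `lp_split`: list with `observed` (assembled network),
#'   `removed` and `negatives` (tibbles `i`, `j`), `added`, and the
#'   parameters.
#' @export
make_test_split <- function(net, remove_ratio = 0.1, add_ratio = 0,
                            seed = 1L, negatives = "all") {
  check_network(net, assembled = TRUE)
  if (remove_ratio <= 0 || remove_ratio >= 1) {
    abort("`remove_ratio` must be strictly between 0 and 1.")
  }
  n_remove <- round(remove_ratio * net$m)
  if (n_remove >= net$m) abort("requested removal leaves no observed edges.")
  removed_idx <- withr::with_seed(seed, sample.int(net$m, n_remove))
  removed <- tibble(i = net$ei[removed_idx], j = net$ej[removed_idx])
  removed <- removed[order(removed$i, removed$j), ]
  keep <- setdiff(seq_len(net$m), removed_idx)

  added <- tibble(i = integer(0), j = integer(0))
  if (add_ratio > 0) {
    n_add <- min(round(add_ratio * net$m), nonedge_count(net))
    added <- sample_nonedges(net, n_add, seed = cpp_mix_seed(seed, 101L))
  }

  observed <- network()
  for (lab in net$labels) add_node_lax(observed, lab)
  for (idx in keep) add_edge(observed, net$ei[idx], net$ej[idx])
  if (nrow(added)) {
    for (r in seq_len(nrow(added))) add_edge(observed, added$i[r], added$j[r])
  }
  assemble(observed)

  negs <- if (identical(negatives, "all")) {
    non_edges(net)
  } else {
    if (!is.numeric(negatives) || negatives < 1) {
      abort('`negatives` must be "all" or a positive count.')
    }
    sample_nonedges(net, min(negatives, nonedge_count(net)),
                    seed = cpp_mix_seed(seed, 102L))
  }

  structure(
    list(
      observed = observed, removed = removed, negatives = negs,
      added = added, remove_ratio = remove_ratio, add_ratio = add_ratio,
      seed = seed, ground_m = net$m
    ),
    class = "lp_split"
  )
}

#' @export
print.lp_split <- function(x, ...) {
  cat(sprintf(
    "<lp_split: observed m = %d, removed = %d, negatives = %d, seed = %d>\n",
    x$observed$m, nrow(x$removed), nrow(x$negatives), x$seed
  ))
  invisible(x)
}

new_curve <- function(points, area, kind) {
  structure(list(points = points, area = area, kind = kind),
            class = "lp_curve")
}

#' @export
print.lp_curve <- function(x, ...) {
  cat(sprintf("<lp_curve %s: %d points, area = %.6f>\n",
              x$kind, nrow(x$points), x$area))
  invisible(x)
}

#' @export
tidy.lp_curve <- function(x, ...) x$points

#' @export
glance.lp_curve <- function(x, ...) {
  tibble(kind = x$kind, area = x$area, n_points = nrow(x$points))
}

#' @export
autoplot.lp_curve <- function(object, ...) {
  labs <- switch(object$kind,
    roc = c("false positive rate", "true positive rate"),
    pr = c("recall", "precision"),
    c("x", "y")
  )
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = labs[1], y = labs[2],
      title = sprintf("%s curve (area = %.4f)", toupper(object$kind), object$area)
    )
}

# cumulative confusion counts per distinct threshold, descending.
# Equal scores enter atomically (tie groups).
confusion_sweep <- function(pos, neg) {
  scores <- c(pos, neg)
  labels <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
  thr <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, thr)
  tp_by <- tapply(labels, grp, sum)
  all_by <- tabulate(grp, nbins = length(thr))
  tp_g <- numeric(length(thr))
  tp_g[as.integer(names(tp_by))] <- tp_by
  tp <- cumsum(tp_g)
  fp <- cumsum(all_by) - tp
  list(tp = tp, fp = fp, P = length(pos), N = length(neg), thr = thr)
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney statistic: the mean over all
#' (positive, negative) score pairs of 1 if the positive ranks higher,
#' 0.5 on ties. `mode = "batch"` holds both score sets and also returns the
#' ROC step curve (with the empty-prediction origin). `mode = "stream"`
#' stores only one class sorted (by default the positives) and consumes the
#' other in bounded-size chunks, accumulating pair counts by binary search;
#' it returns the identical AUC but no curve.
#'
#' @param pos,neg Numeric score vectors for true (removed) links and
#'   negatives; both must be non-empty.
#' @param mode `"batch"` or `"stream"`.
#' @param stream_class Which class is streamed in stream mode (the other is
#'   stored sorted): `"neg"` (default) or `"pos"`.
#' @param chunk_size Streamed scores consumed per step.
#' @return A list with `auc` and `curve` (an `lp_curve`, `NULL` in stream
#'   mode).
#' @examples
#' roc_auc(c(0.9, 0.8), c(0.1, 0.2))$auc # 1
#' @export
roc_auc <- function(pos, neg, mode = c("batch", "stream"),
                    stream_class = c("neg", "pos"), chunk_size = 4096L) {
  mode <- match.arg(mode)
  stream_class <- match.arg(stream_class)
  if (!length(pos) || !length(neg)) abort("both score classes must be non-empty.")
  np <- length(pos)
  nn <- length(neg)
  if (mode == "stream") {
    if (stream_class == "neg") {
      stored <- sort(pos)
      streamed <- neg
    } else {
      stored <- sort(neg)
      streamed <- pos
    }
    wins <- 0.0
    posn <- 0L
    while (posn < length(streamed)) {
      hi <- min(posn + chunk_size, length(streamed))
      v <- streamed[(posn + 1L):hi]
      le <- findInterval(v, stored) # stored values <= v
      lt <- findInterval(v, stored, left.open = TRUE) # stored values < v
      if (stream_class == "neg") {
        # per negative v: positives above + half the ties
        wins <- wins + sum((np - le) + 0.5 * (le - lt))
      } else {
        # per positive v: negatives below + half the ties
        wins <- wins + sum(lt + 0.5 * (le - lt))
      }
      posn <- hi
    }
    return(list(auc = wins / (as.numeric(np) * nn), curve = NULL))
  }
  r <- rank(c(pos, neg)) # midranks handle ties
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (as.numeric(np) * nn)
  sw <- confusion_sweep(pos, neg)
  pts <- tibble(
    x = c(0, sw$fp / sw$N),
    y = c(0, sw$tp / sw$P),
    threshold = c(Inf, sw$thr)
  )
  curve <- new_curve(pts, auc, "roc")
  list(auc = auc, curve = curve)
}

#' Davis-Goadrich interpolation of one PR segment
#'
#' Between two PR curve points with `tp_a < tp_b` true positives, the
#' achievable operating points at each unit TP step `x` in between carry
#' `fp_a + (x - tp_a) * (fp_b - fp_a) / (tp_b - tp_a)` false positives;
#' their precision is `x / (x + fp)`. These are the points inserted before
#' integrating the PR curve under `interpolation = "davis_goadrich"`.
#'
#' @param tp_a,fp_a,tp_b,fp_b Confusion counts at the two segment ends.
#' @return A tibble `tp`, `fp`, `precision` of the interior interpolated
#'   points (empty if `tp_b - tp_a < 2`).
#' @examples
#' dg_interpolate(5, 5, 10, 30) # precision at TP = 7 is 7/22
#' @export
dg_interpolate <- function(tp_a, fp_a, tp_b, fp_b) {
  rf <- dg_refine(tp_a, fp_a, tp_b, fp_b)
  tibble(tp = rf$tp, fp = rf$fp, precision = rf$tp / (rf$tp + rf$fp))
}

# interior unit-TP-step refinement of one PR segment, FP linear in TP
dg_refine <- function(tp_a, fp_a, tp_b, fp_b) {
  if (tp_b - tp_a < 2) {
    return(list(tp = numeric(0), fp = numeric(0)))
  }
  x <- seq(tp_a + 1, tp_b - 1)
  s <- (fp_b - fp_a) / (tp_b - tp_a)
  list(tp = x, fp = fp_a + (x - tp_a) * s)
}

#' Precision-recall curve and area
#'
#' Sweeps thresholds descending (tie groups atomically); each distinct
#' threshold yields a point `(recall, precision) = (TP/P, TP/(TP+FP))`.
#' The area spans recall 0 to 1: the segment below the first attainable
#' recall is interpolated from the empty-prediction corner (TP = FP = 0),
#' which keeps that point's own precision constant — a perfect ranking thus
#' has area exactly 1 under both rules. `interpolation = "trapezoid"`
#' connects consecutive points linearly; `"davis_goadrich"` inserts a point
#' at every unit TP step with linearly interpolated FP (the achievable
#' curve), which never lies above the chord while precision is falling.
#'
#' @param pos,neg Numeric score vectors; `pos` must be non-empty.
#' @param interpolation `"trapezoid"` or `"davis_goadrich"`.
#' @return A list with `aupr` and `curve` (points at the distinct
#'   thresholds; the refinement is used only for integration).
#' @export
pr_auc <- function(pos, neg, interpolation = c("trapezoid", "davis_goadrich")) {
  interpolation <- match.arg(interpolation)
  if (!length(pos)) abort("positive score set must be non-empty.")
  sw <- confusion_sweep(pos, neg)
  P <- sw$P
  tp <- sw$tp
  fp <- sw$fp
  prec <- tp / (tp + fp)
  rec <- tp / P
  keep <- tp > 0 # points before the first true positive have no precision
  tp_pts <- tp[keep]
  fp_pts <- fp[keep]
  if (!length(tp_pts)) abort("no true positive is ever retrieved.")
  pts <- tibble(x = rec[keep], y = prec[keep], threshold = sw$thr[keep])

  # integration grid in TP space, anchored at the empty-prediction corner
  grid_tp <- tp_pts[1]
  grid_prec <- tp_pts[1] / (tp_pts[1] + fp_pts[1])
  # leading segment [0, tp_1]: DG interpolation from (0, 0) gives constant
  # precision; both rules integrate it as a rectangle
  area <- (tp_pts[1] / P) * grid_prec
  if (length(tp_pts) > 1) {
    for (k in seq_len(length(tp_pts) - 1)) {
      a_tp <- tp_pts[k]; a_fp <- fp_pts[k]
      b_tp <- tp_pts[k + 1]; b_fp <- fp_pts[k + 1]
      if (b_tp == a_tp) next # recall unchanged: zero width
      if (interpolation == "davis_goadrich") {
        rf <- dg_refine(a_tp, a_fp, b_tp, b_fp)
        seg_tp <- c(a_tp, rf$tp, b_tp)
        seg_fp <- c(a_fp, rf$fp, b_fp)
      } else {
        seg_tp <- c(a_tp, b_tp)
        seg_fp <- c(a_fp, b_fp)
      }
      seg_prec <- seg_tp / (seg_tp + seg_fp)
      area <- area + sum(diff(seg_tp / P) *
                           (head(seg_prec, -1) + seg_prec[-1]) / 2)
    }
  }
  curve <- new_curve(pts, area, "pr")
  list(aupr = area, curve = curve)
}

#' General threshold-sweep performance curve
#'
#' Sweeps thresholds descending over the pooled scores and maps each
#' cumulative confusion state `(TP, FP, P, N)` through user coordinate
#' functions; the curve always starts from the empty-prediction state
#' `TP = FP = 0`. The area is computed by the trapezoidal rule and requires
#' `x` to be nondecreasing. With `x = FP/N`, `y = TP/P` this reproduces the
#' ROC curve and its Mann-Whitney area exactly.
#'
#' @param x_fn,y_fn Functions of `(tp, fp, P, N)` returning coordinates.
#' @param pos,neg Numeric score vectors.
#' @return A list with `area` and `curve`.
#' @export
general_curve <- function(x_fn, y_fn, pos, neg) {
  if (!length(pos) || !length(neg)) abort("both score classes must be non-empty.")
  sw <- confusion_sweep(pos, neg)
  tp <- c(0, sw$tp)
  fp <- c(0, sw$fp)
  x <- vapply(seq_along(tp), function(k) x_fn(tp[k], fp[k], sw$P, sw$N), 0)
  y <- vapply(seq_along(tp), function(k) y_fn(tp[k], fp[k], sw$P, sw$N), 0)
  if (any(diff(x) < -1e-12)) {
    abort("x coordinate must be nondecreasing along the sweep; area undefined.")
  }
  area <- if (length(x) > 1) sum(diff(x) * (head(y, -1) + y[-1]) / 2) else 0
  list(area = area, curve = new_curve(tibble(x = x, y = y), area, "general"))
}

#' Top-precision
#'
#' The fraction of removed (true) edges among the `l` highest-scored
#' candidate pairs; `l` defaults to the number of removed edges. Two
#' computations are available: `method = "scores"` scores the explicit
#' candidate set (removed edges plus the split's negatives);
#' `method = "top"` asks the predictor for its top `l` non-edges of the
#' observed network (the fast path). The two agree whenever the split keeps
#' all ground-truth non-edges as negatives, making the candidate sets
#' coincide.
#'
#' @param fit An [lp_learn()] result trained on `split$observed`.
#' @param split An [make_test_split()] result.
#' @param l Depth of the ranking (default `nrow(split$removed)`).
#' @param method `"scores"` or `"top"`.
#' @return A single ratio in `[0, 1]`.
#' @export
top_precision <- function(fit, split, l = NULL, method = c("scores", "top")) {
  method <- match.arg(method)
  if (!inherits(split, "lp_split")) abort("`split` must come from make_test_split().")
  if (is.null(l)) l <- nrow(split$removed)
  if (l < 1) abort("`l` must be >= 1.")
  removed_keys <- pair_key(split$removed$i, split$removed$j,
                           length(split$observed$labels))
  if (method == "top") {
    top <- lp_top(fit, l)
    keys <- pair_key(top$i, top$j, length(split$observed$labels))
    return(sum(keys %in% removed_keys) / l)
  }
  cand <- rbind(
    cbind(split$removed$i, split$removed$j),
    cbind(split$negatives$i, split$negatives$j)
  )
  if (l > nrow(cand)) abort("`l` exceeds the candidate count.")
  truth <- c(rep(TRUE, nrow(split$removed)), rep(FALSE, nrow(split$negatives)))
  score <- lp_score(fit, cand[, 1], cand[, 2])
  ord <- order(-score, cand[, 1], cand[, 2])
  mean(truth[ord][seq_len(l)])
}

perf_measures <- c("roc", "pr", "prdg", "tpr")

# evaluate one fitted predictor on one split, all requested measures
eval_measures <- function(fit, split, measures) {
  pos <- lp_score(fit, split$removed$i, split$removed$j)
  neg <- lp_score(fit, split$negatives$i, split$negatives$j)
  vapply(measures, function(ms) {
    switch(ms,
      roc = roc_auc(pos, neg)$auc,
      pr = pr_auc(pos, neg, "trapezoid")$aupr,
      prdg = pr_auc(pos, neg, "davis_goadrich")$aupr,
      tpr = top_precision(fit, split, method = "scores")
    )
  }, 0)
}

#' Multi-run evaluation experiment
#'
#' For each run, derives an independent per-run seed from `(seed, run)`,
#' builds a fresh test split, trains every predictor on the observed
#' network, scores the removed edges and the negatives, and evaluates every
#' measure. Results come back as a long tibble; identical seeds reproduce
#' it exactly.
#'
#' @param net Assembled ground-truth [network()].
#' @param predictors Character vector of registered predictor names (see
#'   [lp_predictor()]).
#' @param measures Subset of `"roc"`, `"pr"`, `"prdg"`, `"tpr"`.
#' @param remove_ratio,add_ratio Split parameters per run.
#' @param runs Number of independent runs.
#' @param seed Master seed.
#' @param negatives Passed to [make_test_split()].
#' @param ... Extra arguments passed to [lp_predictor()] (e.g. `d`).
#' @return An `lp_experiment`: tibble with columns `run`, `predictor`,
#'   `measure`, `value` (runs x predictors x measures rows), with the
#'   per-predictor summary available via [glance()].
#' @export
run_experiment <- function(net, predictors, measures = c("roc", "tpr"),
                           remove_ratio = 0.1, add_ratio = 0, runs = 10L,
                           seed = 1L, negatives = "all", ...) {
  check_network(net, assembled = TRUE)
  if (runs < 1) abort("`runs` must be >= 1.")
  measures <- tolower(measures)
  bad <- setdiff(measures, perf_measures)
  if (length(bad)) {
    abort(paste0("unknown measures: ", paste(bad, collapse = ", "),
                 " (available: ", paste(perf_measures, collapse = ", "), ")"))
  }
  specs <- lapply(predictors, lp_predictor, ...) # validates names up front
  rows <- list()
  for (r in seq_len(runs)) {
    run_seed <- cpp_mix_seed(seed, r)
    split <- make_test_split(net, remove_ratio = remove_ratio,
                             add_ratio = add_ratio, seed = run_seed,
                             negatives = negatives)
    for (pidx in seq_along(specs)) {
      fit <- lp_learn(specs[[pidx]], split$observed,
                      seed = cpp_mix_seed(run_seed, 1000L + pidx))
      vals <- eval_measures(fit, split, measures)
      rows[[length(rows) + 1L]] <- tibble(
        run = r, predictor = predictors[pidx],
        measure = measures, value = unname(vals)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lp_experiment", class(out))
  attr(out, "seed") <- seed
  attr(out, "runs") <- runs
  out
}

#' @export
glance.lp_experiment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$predictor, .data$measure),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    runs = dplyr::n(), .groups = "drop"
  )
}

#' @export
tidy.lp_experiment <- function(x, ...) tibble::as_tibble(x)

#' @export
autoplot.lp_experiment <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$predictor, y = .data$value)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "measure value")
}

#' Write an experiment table as TSV
#'
#' The long table (`run`, `predictor`, `measure`, `value`) followed by a
#' commented summary block with per-(predictor, measure) means and standard
#' deviations.
#'
#' @param experiment An [run_experiment()] result.
#' @param path Output path.
#' @export
write_experiment <- function(experiment, path) {
  df <- tibble::as_tibble(experiment)
  lines <- c(
    "run\tpredictor\tmeasure\tvalue",
    sprintf("%d\t%s\t%s\t%.17g", df$run, df$predictor, df$measure, df$value)
  )
  sm <- glance(experiment)
  lines <- c(
    lines, "# summary",
    sprintf("# %s\t%s\tmean=%.6f\tsd=%.6f", sm$predictor, sm$measure, sm$mean, sm$sd)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
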