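test_that("test splits remove the requested fraction, reproducibly and disjointly", {
  net <- gen_er(40, 0.3, seed = 61)
  m <- n_edges(net)
  split <- make_test_split(net, remove_ratio = 0.1, seed = 5)
  expect_equal(nrow(split$removed), round(0.1 * m))
  expect_equal(n_edges(split$observed), m - round(0.1 * m))
  expect_identical(
    make_test_split(net, remove_ratio = 0.1, seed = 5)$removed,
    split$removed
  )
  expect_error(make_test_split(net, remove_ratio = 0), "between 0 and 1")

  # removed edges: absent from observed, present in ground truth; negatives
  # are ground-truth non-edges
  set.seed(62)
  for (rep in 1:25) {
    g <- gen_er(sample(10:30, 1), runif(1, 0.2, 0.5), seed = 900 + rep)
    if (n_edges(g) < 5) next
    sp <- make_test_split(g, remove_ratio = 0.25, seed = rep)
    expect_false(any(has_edge(sp$observed, sp$removed$i, sp$removed$j)))
    expect_true(all(has_edge(g, sp$removed$i, sp$removed$j)))
    expect_false(any(has_edge(g, sp$negatives$i, sp$negatives$j)))
    # same node set, same labels
    expect_equal(sp$observed$labels, g$labels)
  }

  # false-edge injection adds edges that are not in the ground truth
  sp <- make_test_split(net, remove_ratio = 0.1, add_ratio = 0.05, seed = 7)
  expect_equal(nrow(sp$added), round(0.05 * m))
  expect_false(any(has_edge(net, sp$added$i, sp$added$j)))
  expect_true(all(has_edge(sp$observed, sp$added$i, sp$added$j)))

  # sampled negatives
  sp <- make_test_split(net, remove_ratio = 0.1, seed = 8, negatives = 50)
  expect_equal(nrow(sp$negatives), 50L)
})

test_that("batch ROC AUC equals the pairwise Mann-Whitney oracle, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.1, 0.2))$auc, 1.0)
  expect_equal(roc_auc(0.5, 0.5)$auc, 0.5)
  expect_equal(roc_auc(c(0.6, 0.4), c(0.5, 0.3))$auc, 0.75)
  expect_error(roc_auc(numeric(0), 1), "non-empty")

  set.seed(63)
  for (rep in 1:300) {
    np <- sample(1:30, 1)
    nn <- sample(1:30, 1)
    pos <- sample(seq(0, 1, 0.125), np, replace = TRUE)
    neg <- sample(seq(0, 1, 0.125), nn, replace = TRUE)
    expect_equal(roc_auc(pos, neg)$auc, oracle_auc(pos, neg), tolerance = 1e-14)
  }
})

test_that("streaming ROC equals batch mode regardless of the streamed class", {
  set.seed(64)
  for (rep in 1:200) {
    np <- sample(1:40, 1)
    nn <- sample(1:40, 1)
    pos <- sample(seq(0, 1, 0.1), np, replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), nn, replace = TRUE)
    b <- roc_auc(pos, neg)$auc
    s1 <- roc_auc(pos, neg, mode = "stream", chunk_size = 7L)$auc
    s2 <- roc_auc(pos, neg, mode = "stream", stream_class = "pos", chunk_size = 7L)$auc
    expect_equal(s1, b, tolerance = 1e-12)
    expect_equal(s2, b, tolerance = 1e-12)
  }
})

test_that("AUC invariances: monotone transform, complement symmetry, random mean", {
  set.seed(65)
  for (rep in 1:50) {
    pos <- sample(seq(0, 1, 0.2), sample(2:20, 1), replace = TRUE)
    neg <- sample(seq(0, 1, 0.2), sample(2:20, 1), replace = TRUE)
    a <- roc_auc(pos, neg)$auc
    expect_equal(roc_auc(exp(3 * pos), exp(3 * neg))$auc, a, tolerance = 1e-12)
    expect_equal(roc_auc(-pos, -neg)$auc + a, 1, tolerance = 1e-12)
  }
  # random scores hover at 1/2 (3 sigma of the mean over 200 trials)
  aucs <- vapply(1:200, function(k) {
    set.seed(10000 + k)
    roc_auc(runif(25), runif(25))$auc
  }, 0)
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})

test_that("PR areas: interpolation formula, perfect separation, and DG bound", {
  # the worked interpolation example: between (TP=5,FP=5) and (TP=10,FP=30),
  # at TP=7 the interpolated FP count is 15, so precision = 7/22
  pts <- dg_interpolate(5, 5, 10, 30)
  expect_equal(pts$precision[pts$tp == 7], 7 / 22)
  expect_equal(pts$tp, 6:9)
  expect_equal(pts$fp, c(10, 15, 20, 25)) # FP = 5 + 5 * (TP - 5)
  expect_equal(nrow(dg_interpolate(3, 1, 4, 2)), 0L)

  expect_equal(pr_auc(c(0.9, 0.8), c(0.1, 0.2), "trapezoid")$aupr, 1.0)
  expect_equal(pr_auc(c(0.9, 0.8), c(0.1, 0.2), "davis_goadrich")$aupr, 1.0)
  expect_error(pr_auc(numeric(0), 1), "non-empty")

  # a strictly convex segment: DG strictly below the chord
  pos <- c(rep(3, 5), rep(1, 5))
  neg <- c(rep(3, 5), rep(1, 25))
  tr <- pr_auc(pos, neg, "trapezoid")$aupr
  dg <- pr_auc(pos, neg, "davis_goadrich")$aupr
  expect_lt(dg, tr)

  # closed-form oracle: continuous integral of the interpolated precision
  # t/(t + 5 + 5(t-5)) over the segment. The unit-TP trapezoid sum sits just
  # above it (the interpolant is convex) and below the two-point chord.
  fine <- local({
    f <- function(t) t / (t + 5 + (t - 5) * 5)
    first <- (5 / 10) * 0.5 # anchor rectangle, precision 1/2 up to recall 0.5
    first + stats::integrate(f, 5, 10)$value / 10
  })
  expect_gte(dg, fine - 1e-12)
  expect_lte(dg, tr + 1e-12)
  expect_equal(dg, fine, tolerance = 0.01)

  # monotone-precision random score sets: DG never exceeds the trapezoid
  set.seed(66)
  strict <- 0
  for (rep in 1:200) {
    sc <- rand_monotone_scores(sample(3:8, 1))
    a_tr <- pr_auc(sc$pos, sc$neg, "trapezoid")$aupr
    a_dg <- pr_auc(sc$pos, sc$neg, "davis_goadrich")$aupr
    expect_lte(a_dg, a_tr + 1e-12)
    if (a_dg < a_tr - 1e-12) strict <- strict + 1
  }
  expect_gt(strict, 20) # refinement genuinely engages
})

test_that("the general curve reproduces ROC exactly and guards monotonicity", {
  set.seed(67)
  for (rep in 1:50) {
    pos <- sample(seq(0, 1, 0.2), sample(2:25, 1), replace = TRUE)
    neg <- sample(seq(0, 1, 0.2), sample(2:25, 1), replace = TRUE)
    g <- general_curve(function(tp, fp, P, N) fp / N,
                       function(tp, fp, P, N) tp / P, pos, neg)
    expect_equal(g$area, roc_auc(pos, neg)$auc, tolerance = 1e-12)
  }
  # constant y = 1: area equals the swept x range
  g <- general_curve(function(tp, fp, P, N) (tp + fp) / (P + N),
                     function(tp, fp, P, N) 1, c(1, 2), c(0.5))
  expect_equal(g$area, 1)
  # non-monotone x is rejected
  expect_error(
    general_curve(function(tp, fp, P, N) -tp, function(tp, fp, P, N) 1,
                  c(1, 2), c(0.5)),
    "nondecreasing"
  )
})

test_that("top-precision agrees between full scoring and the predictor top path", {
  net <- gen_er(30, 0.3, seed = 68)
  split <- make_test_split(net, remove_ratio = 0.2, seed = 9)
  fit <- lp_learn(lp_predictor("RAL"), split$observed)
  tp_scores <- top_precision(fit, split, method = "scores")
  tp_top <- top_precision(fit, split, method = "top")
  expect_equal(tp_scores, tp_top)
  expect_true(tp_scores >= 0 && tp_scores <= 1)
  expect_error(top_precision(fit, split, l = 0), ">= 1")

  set.seed(69)
  for (rep in 1:20) {
    g <- gen_er(sample(12:25, 1), runif(1, 0.25, 0.5), seed = 950 + rep)
    if (n_edges(g) < 8) next
    sp <- make_test_split(g, remove_ratio = 0.25, seed = rep)
    for (nm in c("CNE", "RAL", "SDG")) {
      f <- lp_learn(lp_predictor(nm), sp$observed, seed = rep)
      expect_equal(top_precision(f, sp, method = "scores"),
                   top_precision(f, sp, method = "top"))
    }
  }
})

test_that("the experiment harness is reproducible with the documented shape", {
  net <- gen_er(30, 0.3, seed = 70)
  e1 <- run_experiment(net, c("RAL", "CNE", "RND"), c("roc", "tpr"),
                       remove_ratio = 0.2, runs = 5, seed = 11)
  expect_equal(nrow(e1), 5L * 3L * 2L)
  e2 <- run_experiment(net, c("RAL", "CNE", "RND"), c("roc", "tpr"),
                       remove_ratio = 0.2, runs = 5, seed = 11)
  expect_identical(tibble::as_tibble(e1), tibble::as_tibble(e2))

  sm <- glance(e1)
  expect_equal(nrow(sm), 6L)
  expect_true(all(c("mean", "sd") %in% names(sm)))

  # unknown names fail before any computation
  expect_error(run_experiment(net, "NOPE", "roc", runs = 1), "unknown predictor")
  expect_error(run_experiment(net, "RAL", "nope", runs = 1), "unknown measures")

  # signal recovery: a real index beats the random baseline on planted blocks
  pp <- gen_planted(60, 2, 0.35, 0.03, seed = 71)
  e <- run_experiment(pp, c("RAL", "RND"), "roc", remove_ratio = 0.1,
                      runs = 3, seed = 12)
  sm <- glance(e)
  expect_gt(sm$mean[sm$predictor == "RAL"], sm$mean[sm$predictor == "RND"])
})

test_that("experiment tables round-trip to TSV with a summary block", {
  net <- gen_er(20, 0.3, seed = 72)
  e <- run_experiment(net, "RAL", "roc", runs = 2, seed = 13)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_experiment(e, f)
  lines <- readLines(f)
  expect_equal(lines[1], "run\tpredictor\tmeasure\tvalue")
  expect_equal(sum(!startsWith(lines, "#")) - 1L, nrow(e))
  expect_true(any(startsWith(lines, "# summary")))
})
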