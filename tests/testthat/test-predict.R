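test_that("worked micro-examples of the topological indices", {
  p4 <- make_path(4)
  expect_equal(local_score(p4, "RAL", 0, 2), 0.5) # 1 / degree(1)
  expect_equal(local_score(p4, "JID", 0, 2), 0.5) # |{1}| / |{1,3}|
  expect_equal(local_score(p4, "CNE", 0, 3), 0)
  expect_equal(local_score(p4, "ADA", 0, 2), 1 / log(2))
  expect_equal(local_score(p4, "PAT", 0, 3), 1)

  # square 0-1-2-3-0 with chord 1-3: C(0,2) = {1,3}, each with one link
  # inside C and degree 3
  sq <- network_from_edges(data.frame(a = c(0, 1, 2, 3, 1), b = c(1, 2, 3, 0, 3)))
  expect_equal(local_score(sq, "CRA", 0, 2), 2 / 3)

  expect_error(local_score(p4, "XXX", 0, 1), "unknown topological index")
})

test_that("every index equals the brute-force set-arithmetic oracle on random graphs", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    net <- gen_er(n, runif(1, 0.1, 0.6), seed = 600 + rep)
    adj <- oracle_adjacency(net)
    deg <- lengths(adj)
    pairs <- t(combn(0:(n - 1), 2))
    take <- sample(nrow(pairs), min(40, nrow(pairs)))
    for (idx in c("CNE", "ADA", "RAL", "CRA", "JID", "PAT")) {
      got <- local_score(net, idx, pairs[take, 1], pairs[take, 2])
      want <- vapply(take, function(r) {
        oracle_index(adj, deg, idx, pairs[r, 1], pairs[r, 2])
      }, 0)
      expect_equal(got, want, tolerance = 1e-14)
      # symmetry in the arguments
      expect_equal(local_score(net, idx, pairs[take, 2], pairs[take, 1]), got)
    }
    got <- sum_degrees_score(net, pairs[take, 1], pairs[take, 2])
    want <- vapply(take, function(r) {
      oracle_index(adj, deg, "SDG", pairs[r, 1], pairs[r, 2])
    }, 0)
    expect_equal(got, want)
  }
})

test_that("sum-of-degrees needs no learning and handles isolated nodes", {
  p4 <- make_path(4)
  expect_equal(sum_degrees_score(p4, 0, 2), 3)
  expect_equal(sum_degrees_score(p4, 2, 0), 3)
  iso <- network()
  add_node(iso, "a")
  add_node(iso, "b")
  assemble(iso)
  expect_equal(sum_degrees_score(iso, 0, 1), 0)
})

test_that("similarity measures follow their definitions and edge conventions", {
  expect_equal(similarity("cosine", c(1, 0), c(0, 1)), 0)
  expect_equal(similarity("cosine", c(0, 0), c(1, 1)), 0) # zero-norm convention
  expect_equal(similarity("pearson", c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(similarity("pearson", c(1, 1, 1), c(1, 2, 3)), 0) # zero variance
  expect_equal(similarity("dot", c(1, 2), c(3, 4)), 11)
  expect_equal(similarity("L1", c(1, 2), c(3, 5)), -5)
  expect_equal(similarity("L2", c(0, 0), c(3, 4)), -5)
  expect_equal(similarity("Lp", c(0, 0), c(3, 4), p = 2), -5)
  expect_error(similarity("cosine", c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(similarity("nope", 1, 1), "unknown similarity")
  expect_error(similarity("Lp", 1, 2, p = 0.5), ">= 1")
})

test_that("the logistic classifier separates, stays in [0,1], and is deterministic", {
  x <- matrix(c(-1, 1), ncol = 1)
  m <- classifier_learn(x, c(0, 1))
  expect_gt(classifier_predict(m, matrix(1)), 0.5)
  expect_lt(classifier_predict(m, matrix(-1)), 0.5)

  set.seed(52)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.integer(X[, 1] + rnorm(50, sd = 0.3) > 0)
  m1 <- classifier_learn(X, y, seed = 3)
  m2 <- classifier_learn(X, y, seed = 3)
  expect_identical(m1$weights, m2$weights)
  p <- classifier_predict(m1, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(classifier_learn(X, rep(1, 50)), "both classes")
})

test_that("the encoder-classifier predictor builds the documented training set", {
  net <- gen_er(30, 0.25, seed = 53)
  m <- n_edges(net)
  spec <- lp_predictor("ECL:node2vec:logistic", d = 8,
                       walk_length = 10, walks_per_node = 3)
  fit <- lp_learn(spec, net, seed = 4)
  expect_equal(fit$n_train, m + min(m, nonedge_count(net)))

  # determinism of the whole pipeline
  fit2 <- lp_learn(spec, net, seed = 4)
  ne <- sample_nonedges(net, 20, seed = 1)
  expect_identical(lp_score(fit, ne$i, ne$j), lp_score(fit2, ne$i, ne$j))
  s <- lp_score(fit, ne$i, ne$j)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(lp_score(fit, ne$j, ne$i), s) # symmetry via canonical codes

  expect_error(lp_predictor("ECL:node2vec"), "ECL:<encoder>:<classifier>")
  expect_error(lp_predictor("ECL:node2vec:svm"), "unknown classifier")
})

test_that("the encoder-similarity predictor scores node-code similarity", {
  # two 6-cliques joined by one bridge: spectral codes separate the cliques
  cl <- rbind(t(combn(0:5, 2)), t(combn(6:11, 2)), c(0, 6))
  net <- network_from_edges(data.frame(a = cl[, 1], b = cl[, 2]))
  enc <- lem_encode(net, 2)
  within <- apply(t(combn(0:5, 2)), 1, function(r) esm_score(net, enc, "cosine", r[1], r[2]))
  cross <- apply(expand.grid(0:5, 6:11), 1, function(r) esm_score(net, enc, "cosine", r[1], r[2]))
  expect_gt(mean(within), mean(cross))

  fit <- lp_learn(lp_predictor("ESM:lem:cosine", d = 2), net)
  expect_equal(lp_score(fit, 1, 2), esm_score(net, enc, "cosine", 1, 2))
  expect_equal(lp_score(fit, 2, 1), lp_score(fit, 1, 2))
  # identical node codes give cosine 1
  fake <- structure(list(codes = rbind(c(1, 2), c(1, 2)), d = 2), class = "lp_encoding")
  expect_equal(esm_score(net, fake, "cosine", 0, 1), 1)
  expect_error(lp_predictor("ESM:lem:nope"), "unknown similarity")
})

test_that("top-k equals sort-and-truncate of the full sheet for every predictor", {
  p4 <- make_path(4)
  fit <- lp_learn(lp_predictor("RAL"), p4)
  top2 <- lp_top(fit, 2)
  expect_equal(top2$i, c(0L, 1L)) # scores 0.5, 0.5; lexicographic tie rule
  expect_equal(top2$j, c(2L, 3L))
  expect_equal(lp_top(fit, 1)$i, 0L)
  expect_equal(nrow(lp_top(fit, 99)), 3L) # capped at the non-edge count
  expect_error(lp_top(fit, 0), "positive")

  set.seed(54)
  preds <- c("CNE", "ADA", "RAL", "CRA", "JID", "PAT", "SDG", "RND")
  for (rep in 1:4) {
    net <- gen_er(sample(10:30, 1), runif(1, 0.15, 0.5), seed = 700 + rep)
    for (nm in preds) {
      fit <- lp_learn(lp_predictor(nm), net, seed = rep)
      sheet <- lp_predict_neg(fit, chunk_size = 37L)
      ord <- order(-sheet$score, sheet$i, sheet$j)
      k <- min(10, nrow(sheet))
      if (k == 0) next
      top <- lp_top(fit, k, chunk_size = 37L)
      expect_equal(top$i, sheet$i[ord][1:k])
      expect_equal(top$j, sheet$j[ord][1:k])
      expect_equal(top$score, sheet$score[ord][1:k])
    }
  }
})

test_that("predict_neg follows the enumeration order and matches pointwise scores", {
  p4 <- make_path(4)
  fit <- lp_learn(lp_predictor("RAL"), p4)
  sheet <- lp_predict_neg(fit)
  expect_equal(nrow(sheet), 3L)
  ne <- non_edges(p4)
  expect_equal(sheet$i, ne$i)
  expect_equal(sheet$j, ne$j)

  set.seed(55)
  for (rep in 1:10) {
    net <- gen_er(sample(5:25, 1), runif(1, 0.2, 0.7), seed = 800 + rep)
    fit <- lp_learn(lp_predictor(sample(c("CNE", "RAL", "JID", "SDG"), 1)), net)
    sheet <- lp_predict_neg(fit, chunk_size = 11L)
    ne <- non_edges(net)
    expect_equal(sheet$i, ne$i)
    expect_equal(sheet$j, ne$j)
    if (nrow(ne)) {
      expect_equal(sheet$score, lp_score(fit, ne$i, ne$j))
    }
  }
})

test_that("scores are invariant under node relabeling", {
  set.seed(56)
  net <- gen_er(15, 0.3, seed = 57)
  perm <- sample(15) - 1
  ed <- edges(net)
  # rebuild with permuted IDs but the same labels
  net2 <- network_from_edges(data.frame(
    a = as.character(perm[ed$i + 1]), b = as.character(perm[ed$j + 1])
  ))
  for (nm in c("CNE", "ADA", "RAL", "CRA", "JID", "PAT", "SDG")) {
    f1 <- lp_learn(lp_predictor(nm), net)
    f2 <- lp_learn(lp_predictor(nm), net2)
    s1 <- lp_predict_neg(f1)
    s2 <- lp_predict_neg(f2)
    key <- function(s) {
      k <- paste(pmin(s$label_i, s$label_j), pmax(s$label_i, s$label_j))
      s$score[order(k)]
    }
    # relabel net's sheet into net2's label space before comparing
    s1$label_i <- as.character(perm[s1$i + 1])
    s1$label_j <- as.character(perm[s1$j + 1])
    expect_equal(key(s1), key(s2), tolerance = 1e-12)
  }
})

test_that("unknown predictor names fail fast with the registry listing", {
  expect_error(lp_predictor("WAT"), "available")
  expect_s3_class(lp_predictor("ral"), "lp_predictor") # case-insensitive
  expect_s3_class(lp_predictor("ESM:LEM:COSINE"), "lp_predictor")
})
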