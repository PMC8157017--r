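#' Topological similarity scores
#'
#' Local neighborhood indices for node pairs (existing or not). With
#' `C = intersect(neighbors(i), neighbors(j))` and degree `k_z`:
#'
#' * `CNE` (common neighbors): `|C|`
#' * `ADA` (Adamic-Adar): `sum_z 1 / ln(k_z)` (natural log; a common
#'   neighbor always has `k_z >= 2`)
#' * `RAL` (resource allocation): `sum_z 1 / k_z`
#' * `CRA` (local-community resource allocation): each common neighbor is
#'   weighted by its links back into `C`: `sum_z |N(z) ∩ C| / k_z`
#' * `JID` (Jaccard): `|C| / |N(i) ∪ N(j)|` (0 when the union is empty)
#' * `PAT` (preferential attachment): `k_i * k_j`
#'
#' @param net An assembled [network()].
#' @param index One of `"CNE"`, `"ADA"`, `"RAL"`, `"CRA"`, `"JID"`, `"PAT"`
#'   (case-insensitive).
#' @param i,j Equal-length vectors of 0-based node IDs.
#' @return Numeric score vector, symmetric in `i` and `j`.
#' @examples
#' p4 <- network_from_edges(data.frame(a = c(0, 1, 2), b = c(1, 2, 3)))
#' local_score(p4, "RAL", 0, 2) # 1 / degree(1) = 0.5
#' @export
local_score <- function(net, index, i, j) {
  check_network(net, assembled = TRUE)
  index <- toupper(index)
  if (!index %in% c("CNE", "ADA", "RAL", "CRA", "JID", "PAT")) {
    abort(paste0("unknown topological index: ", index))
  }
  i <- check_ids(net, i)
  j <- check_ids(net, j)
  if (length(i) != length(j)) abort("`i` and `j` must have equal length.")
  deg <- net$deg
  adj <- net$adj
  if (index == "PAT") return(as.numeric(deg[i + 1L] * deg[j + 1L]))
  vapply(seq_along(i), function(k) {
    gi <- adj[[i[k] + 1L]]
    gj <- adj[[j[k] + 1L]]
    C <- intersect(gi, gj)
    switch(index,
      CNE = length(C),
      ADA = if (length(C)) sum(1 / log(deg[C + 1L])) else 0,
      RAL = if (length(C)) sum(1 / deg[C + 1L]) else 0,
      CRA = if (length(C)) {
        sum(vapply(C, function(z) {
          sum(adj[[z + 1L]] %in% C) / deg[z + 1L]
        }, 0))
      } else 0,
      JID = {
        u <- union(gi, gj)
        if (length(u)) length(C) / length(u) else 0
      }
    )
  }, 0)
}

#' Sum-of-degrees score
#'
#' The minimal worked example of a custom predictor: the score of a pair is
#' `k_i + k_j`. No initialization or learning is needed.
#'
#' @inheritParams local_score
#' @return Numeric score vector.
#' @export
sum_degrees_score <- function(net, i, j) {
  check_network(net, assembled = TRUE)
  i <- check_ids(net, i)
  j <- check_ids(net, j)
  as.numeric(net$deg[i + 1L] + net$deg[j + 1L])
}

local_indices <- c("CNE", "ADA", "RAL", "CRA", "JID", "PAT")

#' Link predictors
#'
#' All predictors share one lifecycle: create a specification with
#' `lp_predictor()`, bind and train it on a network with [lp_learn()], then
#' query scores with [lp_score()], [lp_predict_neg()] or [lp_top()].
#' Registered names (case-insensitive):
#'
#' * `"CNE"`, `"ADA"`, `"RAL"`, `"CRA"`, `"JID"`, `"PAT"` — topological
#'   similarity ([local_score()]);
#' * `"SDG"` — sum of degrees ([sum_degrees_score()]);
#' * `"RND"` — seeded uniform random scores (baseline);
#' * `"ECL:<encoder>:<classifier>"` — graph embedding + classifier, e.g.
#'   `"ECL:node2vec:logistic"`: the observed edges (label 1) plus
#'   `neg_ratio * m` sampled non-edges (label 0) train the classifier on
#'   concatenated edge codes;
#' * `"ESM:<encoder>:<measure>"` — graph embedding + node-code similarity,
#'   e.g. `"ESM:lem:cosine"`.
#'
#' @param name Predictor name, possibly composite as above.
#' @param d Embedding dimension for composed predictors.
#' @param neg_ratio Sampled negatives per observed edge for `ECL`.
#' @param ... Extra encoder arguments (see [lp_encoder()]).
#' @return An `lp_predictor` specification.
#' @examples
#' p4 <- network_from_edges(data.frame(a = c(0, 1, 2), b = c(1, 2, 3)))
#' fit <- lp_learn(lp_predictor("RAL"), p4)
#' lp_top(fit, 2)
#' @export
lp_predictor <- function(name, d = 16L, neg_ratio = 1, ...) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  head_ <- toupper(parts[1])
  if (head_ %in% c(local_indices, "SDG", "RND")) {
    if (length(parts) != 1L) abort(paste0("unexpected arguments in: ", name))
    kind <- if (head_ == "SDG") "sdg" else if (head_ == "RND") "random" else "local"
    return(structure(list(name = head_, kind = kind, index = head_),
                     class = "lp_predictor"))
  }
  if (head_ == "ECL") {
    if (length(parts) != 3L) abort("ECL predictors are named ECL:<encoder>:<classifier>.")
    if (tolower(parts[3]) != "logistic") {
      abort(paste0("unknown classifier: ", parts[3], " (available: logistic)"))
    }
    return(structure(
      list(name = toupper(name), kind = "ecl",
           encoder = lp_encoder(parts[2], d = d, ...),
           classifier = tolower(parts[3]), neg_ratio = neg_ratio),
      class = "lp_predictor"
    ))
  }
  if (head_ == "ESM") {
    if (length(parts) != 3L) abort("ESM predictors are named ESM:<encoder>:<measure>.")
    if (!tolower(parts[3]) %in% similarity_measures) {
      abort(paste0("unknown similarity measure: ", parts[3]))
    }
    return(structure(
      list(name = toupper(name), kind = "esm",
           encoder = lp_encoder(parts[2], d = d, ...),
           measure = tolower(parts[3])),
      class = "lp_predictor"
    ))
  }
  abort(paste0(
    "unknown predictor: ", name,
    " (available: ", paste(c(local_indices, "SDG", "RND",
                             "ECL:<encoder>:logistic", "ESM:<encoder>:<measure>"),
                           collapse = ", "), ")"
  ))
}

#' Train a predictor on a network
#'
#' Local indices need no learning; composed predictors run their encoder
#' (and, for `ECL`, build the edge/non-edge training set and fit the
#' classifier). Identical seeds give identical fitted predictors.
#'
#' @param pred An [lp_predictor()] specification.
#' @param net An assembled [network()] with at least one edge for `ECL`.
#' @param seed Integer seed used by stochastic components.
#' @return An `lp_fitted` predictor.
#' @export
lp_learn <- function(pred, net, seed = 1L) {
  if (!inherits(pred, "lp_predictor")) abort("`pred` must be an lp_predictor().")
  check_network(net, assembled = TRUE)
  fitted <- list(spec = pred, net = net, seed = seed)
  if (pred$kind == "ecl") {
    if (net$m < 1) abort("ECL training requires at least one edge.")
    enc <- lp_encode(pred$encoder, net, seed = seed)
    n_neg <- min(round(pred$neg_ratio * net$m), nonedge_count(net))
    negs <- sample_nonedges(net, n_neg, seed = cpp_mix_seed(seed, 2L))
    x_pos <- edge_code_matrix(enc, net$ei, net$ej)
    x_neg <- edge_code_matrix(enc, negs$i, negs$j)
    y <- c(rep(1L, nrow(x_pos)), rep(0L, nrow(x_neg)))
    model <- classifier_learn(rbind(x_pos, x_neg), y, seed = cpp_mix_seed(seed, 3L))
    fitted$encoding <- enc
    fitted$model <- model
    fitted$n_train <- length(y)
  } else if (pred$kind == "esm") {
    fitted$encoding <- lp_encode(pred$encoder, net, seed = seed)
  }
  structure(fitted, class = "lp_fitted")
}

# row-wise concatenated edge codes in canonical order
edge_code_matrix <- function(enc, i, j) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  cbind(enc$codes[a + 1L, , drop = FALSE], enc$codes[b + 1L, , drop = FALSE])
}

#' Score node pairs with a fitted predictor
#'
#' @param fit An [lp_learn()] result.
#' @param i,j Equal-length 0-based node ID vectors (argument order per pair
#'   is irrelevant).
#' @return Numeric scores, finite, symmetric.
#' @export
lp_score <- function(fit, i, j) {
  if (!inherits(fit, "lp_fitted")) abort("`fit` must come from lp_learn().")
  net <- fit$net
  i <- check_ids(net, i)
  j <- check_ids(net, j)
  spec <- fit$spec
  switch(spec$kind,
    local = local_score(net, spec$index, i, j),
    sdg = sum_degrees_score(net, i, j),
    random = cpp_hash_scores(pmin(i, j), pmax(i, j), fit$seed),
    ecl = classifier_predict(fit$model, edge_code_matrix(fit$encoding, i, j)),
    esm = {
      a <- pmin(i, j)
      b <- pmax(i, j)
      vapply(seq_along(a), function(k) {
        similarity(spec$measure, node_code(fit$encoding, a[k]),
                   node_code(fit$encoding, b[k]))
      }, 0)
    }
  )
}

#' Encoder-similarity score of one pair
#'
#' Similarity between the two *node* codes of the pair (not the edge code).
#'
#' @param net An assembled [network()].
#' @param enc An `lp_encoding` computed on `net`.
#' @param measure A [similarity()] measure name.
#' @param i,j 0-based node IDs.
#' @return A single numeric score.
#' @export
esm_score <- function(net, enc, measure, i, j) {
  check_network(net, assembled = TRUE)
  similarity(measure, node_code(enc, min(i, j)), node_code(enc, max(i, j)))
}

# decode a range [from, to) of non-edge indices into a scored tibble
score_nonedge_range <- function(fit, from, to) {
  idx <- seq(from, to - 1)
  pares <- nonedge_at(fit$net, idx)
  pares$score <- lp_score(fit, pares$i, pares$j)
  pares
}

#' Score all non-edges
#'
#' One score per non-edge, in canonical (lexicographic) enumeration order,
#' computed in chunks so the non-edge set is never materialized at once.
#'
#' @param fit An [lp_learn()] result.
#' @param chunk_size Number of non-edges scored per chunk.
#' @return A tibble `i`, `j`, `label_i`, `label_j`, `score`.
#' @export
lp_predict_neg <- function(fit, chunk_size = 20000L) {
  if (!inherits(fit, "lp_fitted")) abort("`fit` must come from lp_learn().")
  total <- nonedge_count(fit$net)
  out <- vector("list", max(1, ceiling(total / chunk_size)))
  pos <- 0
  k <- 0L
  while (pos < total) {
    hi <- min(pos + chunk_size, total)
    k <- k + 1L
    out[[k]] <- score_nonedge_range(fit, pos, hi)
    pos <- hi
  }
  sheet <- if (k == 0L) tibble(i = integer(0), j = integer(0), score = numeric(0))
           else dplyr::bind_rows(out[seq_len(k)])
  sheet$label_i <- fit$net$labels[sheet$i + 1L]
  sheet$label_j <- fit$net$labels[sheet$j + 1L]
  sheet[, c("i", "j", "label_i", "label_j", "score")]
}

#' Top-k non-edges by score
#'
#' Streams the non-edge enumeration in chunks, keeping only the current best
#' `k` candidates (memory O(k + chunk)), so all non-edge scores are never
#' held at once. Ties are broken by lexicographic canonical edge order, so
#' the result is deterministic and equals sorting the full score sheet and
#' truncating.
#'
#' @param fit An [lp_learn()] result.
#' @param k Number of top non-edges (positive; capped at the non-edge count).
#' @param chunk_size Non-edges scored per chunk.
#' @return A tibble `i`, `j`, `label_i`, `label_j`, `score`, sorted by score
#'   descending then `(i, j)`.
#' @export
lp_top <- function(fit, k, chunk_size = 20000L) {
  if (!inherits(fit, "lp_fitted")) abort("`fit` must come from lp_learn().")
  if (k <= 0) abort("`k` must be positive.")
  total <- nonedge_count(fit$net)
  k <- min(k, total)
  best <- NULL
  pos <- 0
  while (pos < total) {
    hi <- min(pos + chunk_size, total)
    cand <- score_nonedge_range(fit, pos, hi)
    best <- if (is.null(best)) cand else dplyr::bind_rows(best, cand)
    best <- best[order(-best$score, best$i, best$j), , drop = FALSE]
    best <- head(best, k)
    pos <- hi
  }
  if (is.null(best)) {
    best <- tibble(i = integer(0), j = integer(0), score = numeric(0))
  }
  best$label_i <- fit$net$labels[best$i + 1L]
  best$label_j <- fit$net$labels[best$j + 1L]
  tibble::as_tibble(best[, c("i", "j", "label_i", "label_j", "score")])
}

#' @export
print.lp_predictor <- function(x, ...) {
  cat(sprintf("<lp_predictor: %s>\n", x$name))
  invisible(x)
}

#' @export
print.lp_fitted <- function(x, ...) {
  cat(sprintf("<fitted %s on %d nodes / %d edges>\n",
              x$spec$name, length(x$net$labels), x$net$m))
  invisible(x)
}

#' @export
glance.lp_fitted <- function(x, ...) {
  tibble(
    predictor = x$spec$name, n = length(x$net$labels), m = x$net$m,
    seed = x$seed
  )
}
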