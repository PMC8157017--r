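#' Graph embeddings (encodings)
#'
#' An encoding assigns each node a `d`-dimensional real code vector; the
#' code of an edge is the concatenation of its two node codes in canonical
#' (`i < j`) order, hence of dimension `2d`. All encoders produce an
#' `lp_encoding` object and are interchangeable inside the
#' encoder-classifier and encoder-similarity predictors.
#'
#' @name encoding
NULL

new_encoding <- function(codes, method) {
  if (!all(is.finite(codes))) abort("encoding contains non-finite entries.")
  structure(list(codes = codes, d = ncol(codes), method = method),
            class = "lp_encoding")
}

#' @export
print.lp_encoding <- function(x, ...) {
  cat(sprintf("<lp_encoding: %d nodes x %d dims (%s)>\n",
              nrow(x$codes), x$d, x$method))
  invisible(x)
}

#' @rdname encoding
#' @param enc An `lp_encoding`.
#' @param i,j 0-based node IDs.
#' @return `node_code()`: numeric vector of length `d`; `edge_code()`:
#'   length `2d`, independent of argument order.
#' @export
node_code <- function(enc, i) enc$codes[i + 1L, ]

#' @rdname encoding
#' @export
edge_code <- function(enc, i, j) {
  a <- min(i, j)
  b <- max(i, j)
  c(enc$codes[a + 1L, ], enc$codes[b + 1L, ])
}

#' Laplacian eigenmaps encoder
#'
#' Solves the generalized eigenproblem `L y = lambda D y` (with `L = D - A`
#' the combinatorial Laplacian) and keeps the `d` eigenvectors of smallest
#' nonzero eigenvalue, dropping the constant eigenvector at `lambda = 0`.
#' Computed through the symmetric normalized Laplacian
#' `D^{-1/2} L D^{-1/2}`, mapping eigenvectors back by `y = D^{-1/2} u`.
#' Deterministic up to column sign, fixed by making the first entry of
#' magnitude above 1e-9 positive.
#'
#' @param net An assembled, connected [network()] (each node degree >= 1).
#' @param d Embedding dimension, at most `n - 1`.
#' @return An `lp_encoding`.
#' @export
lem_encode <- function(net, d) {
  check_network(net, assembled = TRUE)
  n <- length(net$labels)
  if (d < 1 || d > n - 1) abort("`d` must be in [1, n - 1].")
  if (length(bfs(net, 0)) < n) {
    abort("network is disconnected; embed each connected component separately.")
  }
  A <- matrix(0, n, n)
  A[cbind(net$ei + 1L, net$ej + 1L)] <- 1
  A[cbind(net$ej + 1L, net$ei + 1L)] <- 1
  deg <- net$deg
  s <- 1 / sqrt(deg)
  M <- diag(n) - (s %o% s) * A # normalized Laplacian, symmetric
  eig <- eigen(M, symmetric = TRUE)
  # eigenvalues descending; smallest is ~0 (constant direction)
  cols <- seq(n - 1L, n - d, by = -1L)
  Y <- (s * eig$vectors)[, cols, drop = FALSE] # back-transform D^{-1/2} u
  for (k in seq_len(ncol(Y))) {
    v <- Y[, k]
    nz <- which(abs(v) > 1e-9)
    if (length(nz) && v[nz[1L]] < 0) Y[, k] <- -v
  }
  new_encoding(Y, "lem")
}

#' Edge-wise matrix factorization encoder
#'
#' Minimizes `sum_(i,j) in E (1 - <u_i, u_j>)^2 + reg * sum_i ||u_i||^2` by
#' seeded stochastic gradient descent over the observed edges (no negative
#' sampling). Deterministic given the seed.
#'
#' @param net An assembled [network()].
#' @param d Embedding dimension.
#' @param epochs,lr,reg SGD passes, learning rate, L2 penalty.
#' @param seed Integer seed.
#' @return An `lp_encoding`, with the initial and final objective values in
#'   attributes `loss_initial` / `loss_final`.
#' @export
matfact_encode <- function(net, d = 16L, epochs = 100L, lr = 0.025,
                           reg = 1e-3, seed = 1L) {
  check_network(net, assembled = TRUE)
  if (d < 1) abort("`d` must be >= 1.")
  n <- length(net$labels)
  m <- net$m
  loss <- function(U) {
    if (m == 0) return(reg * sum(U^2))
    dots <- rowSums(U[net$ei + 1L, , drop = FALSE] * U[net$ej + 1L, , drop = FALSE])
    sum((1 - dots)^2) + reg * sum(U^2)
  }
  U <- withr::with_seed(seed, {
    U <- matrix(runif(n * d, -0.5, 0.5) / d, n, d)
    if (m > 0) {
      for (ep in seq_len(epochs)) {
        for (idx in sample.int(m)) {
          a <- net$ei[idx] + 1L
          b <- net$ej[idx] + 1L
          ua <- U[a, ]
          ub <- U[b, ]
          err <- 1 - sum(ua * ub)
          U[a, ] <- ua + lr * (err * ub - reg * ua)
          U[b, ] <- ub + lr * (err * ua - reg * ub)
        }
      }
    }
    U
  })
  enc <- new_encoding(U, "matfact")
  attr(enc, "loss_initial") <- withr::with_seed(seed, loss(matrix(runif(n * d, -0.5, 0.5) / d, n, d)))
  attr(enc, "loss_final") <- loss(U)
  enc
}

#' Second-order biased random walks (node2vec)
#'
#' Generates `walks_per_node` walks from every node (node order reshuffled
#' each pass). From current node `v` with predecessor `t`, a neighbor `x`
#' gets unnormalized weight `1/p` if `x = t`, `1` if `x` is adjacent to
#' `t`, and `1/q` otherwise; the first step is uniform. `p = q = 1` gives
#' first-order (DeepWalk) walks. Walks from isolated nodes have length 1.
#'
#' @param net An assembled [network()].
#' @param p,q Return and in-out bias parameters (positive).
#' @param walk_length Maximum walk length (nodes).
#' @param walks_per_node Walks started from each node.
#' @param seed Integer seed.
#' @return An `lp_walks` object: list of 0-based node-ID vectors with the
#'   parameters attached.
#' @export
node2vec_walks <- function(net, p = 1, q = 1, walk_length = 40L,
                           walks_per_node = 10L, seed = 1L) {
  check_network(net, assembled = TRUE)
  if (p <= 0 || q <= 0 || walk_length < 1 || walks_per_node < 1) {
    abort("walk parameters must be positive.")
  }
  walks <- withr::with_seed(
    seed,
    cpp_node2vec_walks(net$adj, p, q, as.integer(walk_length),
                       as.integer(walks_per_node))
  )
  structure(
    list(walks = walks, p = p, q = q, walk_length = walk_length,
         walks_per_node = walks_per_node, seed = seed,
         n = length(net$labels)),
    class = "lp_walks"
  )
}

#' One-step node2vec transition probabilities
#'
#' The exact distribution used by the walk sampler, exposed for analysis:
#' probabilities over the neighbors of `v` (ascending ID order) given
#' predecessor `t` (`t = NULL` for the uniform first step).
#'
#' @param net An assembled [network()].
#' @param t Predecessor node ID or `NULL`.
#' @param v Current node ID.
#' @param p,q Bias parameters.
#' @return Numeric vector aligned with `neighbors(net, v)`.
#' @export
node2vec_step_probs <- function(net, t, v, p = 1, q = 1) {
  check_network(net, assembled = TRUE)
  v <- check_ids(net, v)
  t <- if (is.null(t)) -1L else check_ids(net, t)
  cpp_node2vec_step_probs(net$adj, t, v, p, q)
}

#' Skip-gram training parameters
#'
#' @param window Context window half-width (>= 1).
#' @param negatives Negative samples per positive pair (>= 1).
#' @param epochs Passes over the corpus.
#' @param lr,lr_final Initial and final learning rate (linear decay).
#' @return An `sgns_params` list.
#' @export
sgns_params <- function(window = 5L, negatives = 5L, epochs = 5L,
                        lr = 0.025, lr_final = 1e-4) {
  if (window < 1 || negatives < 1 || lr <= 0 || lr_final <= 0) {
    abort("invalid skip-gram parameters.")
  }
  list(window = as.integer(window), negatives = as.integer(negatives),
       epochs = as.integer(epochs), lr = lr, lr_final = lr_final)
}

#' Skip-gram with negative sampling over a walk corpus
#'
#' For every (center, context) pair within the window, maximizes
#' `log sigma(u . v') + sum_neg log sigma(-u . v'_neg)` with negatives drawn
#' proportional to corpus frequency^0.75. Returns the center-vector matrix.
#' Deterministic given the seed.
#'
#' @param corpus An `lp_walks` object from [node2vec_walks()].
#' @param d Embedding dimension.
#' @param params An [sgns_params()] list.
#' @param seed Integer seed.
#' @return An `lp_encoding`.
#' @export
sgns_train <- function(corpus, d = 16L, params = sgns_params(), seed = 1L) {
  if (!inherits(corpus, "lp_walks")) abort("`corpus` must come from node2vec_walks().")
  if (d < 1) abort("`d` must be >= 1.")
  if (!length(corpus$walks)) abort("corpus is empty.")
  U <- withr::with_seed(
    seed,
    cpp_sgns_train(corpus$walks, corpus$n, as.integer(d), params$window,
                   params$negatives, params$epochs, params$lr, params$lr_final)
  )
  new_encoding(U, "node2vec")
}

#' Encoder specifications
#'
#' A light registry so encoders can be named inside composed predictors:
#' `"lem"`, `"matfact"`, `"node2vec"`, and `"deepwalk"` (node2vec with
#' `p = q = 1`). `lp_encode()` runs the named encoder on a network.
#'
#' @param name Encoder name.
#' @param d Embedding dimension.
#' @param ... Encoder-specific parameters (`p`, `q`, `walk_length`,
#'   `walks_per_node`, `params` for walk encoders; `epochs`, `lr`, `reg`
#'   for matfact).
#' @return `lp_encoder()`: an encoder spec; `lp_encode()`: an `lp_encoding`.
#' @export
lp_encoder <- function(name = c("node2vec", "deepwalk", "lem", "matfact"),
                       d = 16L, ...) {
  name <- match.arg(tolower(name), c("node2vec", "deepwalk", "lem", "matfact"))
  structure(list(name = name, d = as.integer(d), args = list(...)),
            class = "lp_encoder_spec")
}

#' @rdname lp_encoder
#' @param encoder An `lp_encoder()` spec.
#' @param net An assembled [network()].
#' @param seed Integer seed for stochastic encoders.
#' @export
lp_encode <- function(encoder, net, seed = 1L) {
  if (!inherits(encoder, "lp_encoder_spec")) abort("`encoder` must be an lp_encoder().")
  a <- encoder$args
  switch(encoder$name,
    lem = lem_encode(net, encoder$d),
    matfact = do.call(
      matfact_encode,
      c(list(net = net, d = encoder$d, seed = seed),
        a[intersect(names(a), c("epochs", "lr", "reg"))])
    ),
    node2vec = {
      walk_args <- a[intersect(names(a), c("p", "q", "walk_length", "walks_per_node"))]
      corpus <- do.call(node2vec_walks, c(list(net = net, seed = seed), walk_args))
      params <- if (!is.null(a$params)) a$params else sgns_params()
      sgns_train(corpus, d = encoder$d, params = params,
                 seed = cpp_mix_seed(seed, 1L))
    },
    deepwalk = {
      walk_args <- a[intersect(names(a), c("walk_length", "walks_per_node"))]
      corpus <- do.call(node2vec_walks,
                        c(list(net = net, p = 1, q = 1, seed = seed), walk_args))
      params <- if (!is.null(a$params)) a$params else sgns_params()
      sgns_train(corpus, d = encoder$d, params = params,
                 seed = cpp_mix_seed(seed, 1L))
    }
  )
}
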