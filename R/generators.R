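#' Seeded random-graph generators
#'
#' Standard synthetic benchmark graphs, used throughout the test suite as
#' stand-ins for real interaction networks. Node labels are the decimal IDs
#' `"0" ... "n-1"`. All generators are deterministic under `seed`.
#'
#' * `gen_er(n, p)`: Erdős–Rényi `G(n, p)` — every pair independently an
#'   edge with probability `p`.
#' * `gen_ba(n, m_attach)`: Barabási–Albert preferential attachment — each
#'   new node attaches to `m_attach` distinct existing nodes chosen
#'   proportional to degree.
#' * `gen_planted(n, blocks, p_in, p_out)`: planted partition — nodes are
#'   assigned to `blocks` contiguous, near-equal blocks; within-block pairs
#'   are edges with probability `p_in`, cross-block pairs with `p_out`.
#'   The block assignment is attached both as attribute `"blocks"` (integer
#'   vector by ID) and as a [node_map()] in attribute `"block_map"`.
#'
#' @param n Number of nodes.
#' @param p Edge probability.
#' @param m_attach Edges added per new node (`1 <= m_attach < n`).
#' @param blocks Number of planted blocks.
#' @param p_in,p_out Within/cross-block edge probabilities.
#' @param seed Integer seed.
#' @return An assembled [network()].
#' @export
gen_er <- function(n, p, seed = 1L) {
  if (n < 1 || p < 0 || p > 1) abort("invalid Erdős–Rényi parameters.")
  pairs <- all_pairs(n)
  keep <- withr::with_seed(seed, runif(nrow(pairs)) < p)
  build_generated(n, pairs[keep, , drop = FALSE])
}

#' @rdname gen_er
#' @export
gen_ba <- function(n, m_attach, seed = 1L) {
  if (m_attach < 1 || m_attach >= n) abort("`m_attach` must satisfy 1 <= m_attach < n.")
  withr::with_seed(seed, {
    ei <- integer(0)
    ej <- integer(0)
    # first new node connects to all m_attach seed nodes; afterwards targets
    # are drawn degree-proportionally (repeated-endpoint multiset), distinct
    repeated <- integer(0)
    targets <- seq_len(m_attach) - 1L
    for (src in seq(m_attach, n - 1L)) {
      ei <- c(ei, rep(src, length(targets)))
      ej <- c(ej, targets)
      repeated <- c(repeated, targets, rep(src, length(targets)))
      if (src < n - 1L) {
        tset <- integer(0)
        while (length(tset) < m_attach) {
          cand <- repeated[sample.int(length(repeated), 1L)]
          if (!cand %in% tset) tset <- c(tset, cand)
        }
        targets <- tset
      }
    }
    build_generated(n, cbind(ei, ej))
  })
}

#' @rdname gen_er
#' @export
gen_planted <- function(n, blocks, p_in, p_out, seed = 1L) {
  if (blocks < 1 || blocks > n) abort("`blocks` must be in [1, n].")
  if (any(c(p_in, p_out) < 0) || any(c(p_in, p_out) > 1)) {
    abort("probabilities must be in [0, 1].")
  }
  assign <- sort(rep_len(seq_len(blocks), n)) # contiguous blocks
  pairs <- all_pairs(n)
  same <- assign[pairs[, 1] + 1L] == assign[pairs[, 2] + 1L]
  prob <- ifelse(same, p_in, p_out)
  keep <- withr::with_seed(seed, runif(nrow(pairs)) < prob)
  net <- build_generated(n, pairs[keep, , drop = FALSE])
  attr(net, "blocks") <- assign
  bm <- node_map(net, 0L)
  bm <- map_set(bm, seq_len(n) - 1L, assign)
  attr(net, "block_map") <- bm
  net
}

# all canonical pairs (i < j) of 0..n-1 as a two-column matrix
all_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  i <- rep(seq_len(n - 1L) - 1L, times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L) - 1L, function(a) seq(a + 1L, n - 1L)))
  cbind(i, j)
}

build_generated <- function(n, pairs) {
  net <- network()
  for (id in seq_len(n) - 1L) add_node_lax(net, as.character(id))
  if (nrow(pairs)) {
    net$ei <- pmin(pairs[, 1], pairs[, 2])
    net$ej <- pmax(pairs[, 1], pairs[, 2])
  }
  assemble(net)
  net
}
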