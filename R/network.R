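#' Create an empty undirected network
#'
#' A network has a two-phase life cycle. In the *pre-assembly* phase nodes
#' and edges may be added and labels translated to IDs; edge and non-edge
#' queries are not yet available. Calling [assemble()] freezes the network:
#' afterwards it is immutable but fully queryable (edges, non-edges, degrees,
#' sampling). Node IDs are contiguous integers `0, ..., n - 1` assigned in
#' insertion order.
#'
#' The object is environment-backed, so `add_node()` and `add_edge()` modify
#' it in place and return their documented values rather than a new network.
#'
#' @return An object of class `lp_network`.
#' @examples
#' net <- network()
#' add_node(net, "A")
#' add_node(net, "B")
#' add_edge(net, 0, 1)
#' assemble(net)
#' n_nodes(net)
#' @export
network <- function() {
  env <- new.env(parent = emptyenv())
  env$labels <- character(0)
  env$id_of <- new.env(parent = emptyenv()) # label -> 0-based id
  env$ei <- integer(0) # accumulated canonical edge endpoints (i < j)
  env$ej <- integer(0)
  env$assembled <- FALSE
  class(env) <- "lp_network"
  env
}

is_network <- function(x) inherits(x, "lp_network")

check_network <- function(net, assembled = NA) {
  if (!is_network(net)) abort("`net` must be an lp_network object.")
  if (isTRUE(assembled) && !net$assembled) {
    abort("network must be assembled before edge or non-edge queries.")
  }
  if (isFALSE(assembled) && net$assembled) {
    abort("network is assembled and immutable; mutation is not allowed.")
  }
  invisible(net)
}

check_ids <- function(net, ids) {
  ids <- as.integer(ids)
  if (any(is.na(ids)) || any(ids < 0L) || any(ids >= length(net$labels))) {
    abort("node ID out of range.")
  }
  ids
}

#' Add a node by label
#'
#' Idempotent: re-adding an existing label returns its ID with
#' `is_new = FALSE`. New labels receive ID `n` (the current node count).
#'
#' @param net An unassembled [network()].
#' @param label Node label (length-1 character).
#' @return A list with `id` (0-based integer) and `is_new` (logical).
#' @export
add_node <- function(net, label) {
  check_network(net, assembled = FALSE)
  label <- as.character(label)
  if (length(label) != 1L || is.na(label)) abort("`label` must be a single string.")
  existing <- net$id_of[[label]]
  if (!is.null(existing)) {
    return(list(id = existing, is_new = FALSE))
  }
  id <- length(net$labels)
  net$labels <- c(net$labels, label)
  net$id_of[[label]] <- id
  list(id = id, is_new = TRUE)
}

#' Add an undirected edge by node IDs
#'
#' Argument order is irrelevant; duplicates are collapsed at assembly.
#' Self-loops are rejected.
#'
#' @param net An unassembled [network()].
#' @param i,j 0-based node IDs.
#' @return The network, invisibly.
#' @export
add_edge <- function(net, i, j) {
  check_network(net, assembled = FALSE)
  i <- check_ids(net, i)
  j <- check_ids(net, j)
  if (length(i) != 1L || length(j) != 1L) abort("`i` and `j` must be single IDs.")
  if (i == j) abort("self-loops are not allowed.")
  net$ei <- c(net$ei, min(i, j))
  net$ej <- c(net$ej, max(i, j))
  invisible(net)
}

# encode a canonical pair as a single double (exact for n < 2^26)
pair_key <- function(i, j, n) as.numeric(i) * n + as.numeric(j)

#' Assemble a network
#'
#' Finalizes the adjacency structure (sorted, deduplicated), computes the
#' non-edge index tables, and makes the network immutable. Only assembled
#' networks support edge and non-edge queries.
#'
#' @param net An unassembled [network()].
#' @return The network, invisibly.
#' @export
assemble <- function(net) {
  check_network(net)
  if (net$assembled) abort("network is already assembled.")
  n <- length(net$labels)
  if (length(net$ei)) {
    keys <- pair_key(net$ei, net$ej, n)
    keep <- !duplicated(keys)
    ei <- net$ei[keep]
    ej <- net$ej[keep]
    ord <- order(ei, ej)
    ei <- ei[ord]
    ej <- ej[ord]
  } else {
    ei <- integer(0)
    ej <- integer(0)
  }
  net$ei <- ei
  net$ej <- ej
  net$edge_keys <- pair_key(ei, ej, n) # sorted ascending
  net$m <- length(ei)
  adj <- vector("list", n)
  if (n > 0L) {
    for (k in seq_len(n)) adj[[k]] <- integer(0)
    if (length(ei)) {
      sp <- split(c(ej, ei), c(ei, ej) + 1L)
      for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(sp[[nm]])
    }
  }
  net$adj <- adj
  net$deg <- lengths(adj)
  # per-source counts of absent higher-ID partners, for non-edge decoding
  if (n > 0L) {
    higher_deg <- vapply(seq_len(n), function(k) sum(adj[[k]] > (k - 1L)), 0L)
    absent <- (n - 1L - (seq_len(n) - 1L)) - higher_deg
    net$nonedge_prefix <- c(0, cumsum(as.numeric(absent))) # length n + 1
  } else {
    net$nonedge_prefix <- 0
  }
  net$assembled <- TRUE
  invisible(net)
}

#' @rdname network-accessors
#' @export
n_nodes <- function(net) {
  check_network(net)
  length(net$labels)
}

#' Network accessors
#'
#' `n_nodes()` and `n_edges()` return counts, `degrees()` the per-ID degree
#' vector, `neighbors()` the ascending neighbor IDs of one node, and
#' `has_edge()` tests edge existence. All but `n_nodes()` require an
#' assembled network.
#'
#' @param net A [network()].
#' @param i,j 0-based node IDs.
#' @name network-accessors
#' @export
n_edges <- function(net) {
  check_network(net, assembled = TRUE)
  net$m
}

#' @rdname network-accessors
#' @export
degrees <- function(net) {
  check_network(net, assembled = TRUE)
  net$deg
}

#' @rdname network-accessors
#' @export
neighbors <- function(net, i) {
  check_network(net, assembled = TRUE)
  i <- check_ids(net, i)
  net$adj[[i + 1L]]
}

#' @rdname network-accessors
#' @export
has_edge <- function(net, i, j) {
  check_network(net, assembled = TRUE)
  i <- check_ids(net, i)
  j <- check_ids(net, j)
  a <- pmin(i, j)
  b <- pmax(i, j)
  keys <- pair_key(a, b, length(net$labels))
  idx <- findInterval(keys, net$edge_keys)
  idx > 0 & net$edge_keys[pmax(idx, 1L)] == keys & a != b
}

# rank (1-based) of an existing canonical edge in the sorted edge list, NA if absent
edge_rank <- function(net, i, j) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  keys <- pair_key(a, b, length(net$labels))
  idx <- findInterval(keys, net$edge_keys)
  ok <- idx > 0 & net$edge_keys[pmax(idx, 1L)] == keys
  ifelse(ok, idx, NA_integer_)
}

#' Translate between labels and IDs
#'
#' @param net A [network()].
#' @param label Character vector of labels.
#' @param id Integer vector of 0-based IDs.
#' @return `get_id()` returns 0-based IDs; `get_label()` returns labels.
#' @export
get_id <- function(net, label) {
  check_network(net)
  out <- vapply(as.character(label), function(l) {
    v <- net$id_of[[l]]
    if (is.null(v)) abort(paste0("unknown label: ", l))
    v
  }, 0L, USE.NAMES = FALSE)
  out
}

#' @rdname get_id
#' @export
get_label <- function(net, id) {
  check_network(net)
  id <- check_ids(net, id)
  net$labels[id + 1L]
}

#' Edges of an assembled network as a tibble
#'
#' @param net An assembled [network()].
#' @return A tibble with columns `i`, `j` (canonical, `i < j`, lexicographic
#'   order), `label_i`, `label_j`.
#' @export
edges <- function(net) {
  check_network(net, assembled = TRUE)
  tibble(
    i = net$ei, j = net$ej,
    label_i = net$labels[net$ei + 1L],
    label_j = net$labels[net$ej + 1L]
  )
}

#' Non-edge enumeration
#'
#' An assembled network on `n` nodes with `m` edges has
#' `n(n-1)/2 - m` absent canonical pairs ("non-edges" or negative links),
#' enumerated in lexicographic `(i, j)` order without materializing the set.
#' `nonedge_count()` returns the count, `nonedge_at()` decodes 0-based
#' enumeration indices into pairs (O(log n) each via prefix sums),
#' `nonedge_index()` is its inverse, and `non_edges()` materializes the full
#' tibble (small networks only).
#'
#' @param net An assembled [network()].
#' @param t Vector of 0-based non-edge indices.
#' @param i,j 0-based node IDs of a non-edge.
#' @return `nonedge_at()`: tibble with columns `i`, `j`; `nonedge_index()`:
#'   numeric index vector.
#' @export
nonedge_count <- function(net) {
  check_network(net, assembled = TRUE)
  n <- length(net$labels)
  n * (n - 1) / 2 - net$m
}

#' @rdname nonedge_count
#' @export
nonedge_at <- function(net, t) {
  check_network(net, assembled = TRUE)
  total <- nonedge_count(net)
  t <- as.numeric(t)
  if (any(is.na(t)) || any(t < 0) || any(t >= total)) {
    abort("non-edge index out of range.")
  }
  prefix <- net$nonedge_prefix
  # source row: largest i with prefix[i] <= t
  src <- findInterval(t, prefix, rightmost.closed = FALSE, left.open = FALSE) - 1L
  # findInterval with ties: prefix is nondecreasing with flat runs for
  # saturated rows; we need the row whose [prefix[i], prefix[i+1]) contains t
  src <- vapply(seq_along(t), function(k) {
    i <- src[k]
    while (prefix[i + 2L] <= t[k]) i <- i + 1L
    i
  }, 0L)
  r <- t - prefix[src + 1L] # 0-based rank among absent higher partners
  j <- vapply(seq_along(t), function(k) {
    i <- src[k]
    higher <- net$adj[[i + 1L]]
    higher <- higher[higher > i]
    jj <- i + 1L + as.integer(r[k])
    for (h in higher) {
      if (h <= jj) jj <- jj + 1L else break
    }
    jj
  }, 0L)
  tibble(i = src, j = j)
}

#' @rdname nonedge_count
#' @export
nonedge_index <- function(net, i, j) {
  check_network(net, assembled = TRUE)
  i <- check_ids(net, i)
  j <- check_ids(net, j)
  a <- pmin(i, j)
  b <- pmax(i, j)
  if (any(a == b)) abort("a non-edge joins two distinct nodes.")
  if (any(has_edge(net, a, b))) abort("pair is an existing edge, not a non-edge.")
  prefix <- net$nonedge_prefix
  vapply(seq_along(a), function(k) {
    higher <- net$adj[[a[k] + 1L]]
    skipped <- sum(higher > a[k] & higher < b[k])
    prefix[a[k] + 1L] + (b[k] - a[k] - 1) - skipped
  }, 0)
}

#' @rdname nonedge_count
#' @export
non_edges <- function(net) {
  check_network(net, assembled = TRUE)
  total <- nonedge_count(net)
  if (total == 0) return(tibble(i = integer(0), j = integer(0)))
  nonedge_at(net, seq_len(total) - 1)
}

#' Seeded uniform sampling of nodes, edges and non-edges
#'
#' Samples without replacement; identical seeds give identical samples.
#' Non-edges are drawn by sampling enumeration indices and decoding with
#' [nonedge_at()], so the non-edge set is never materialized.
#'
#' @param net An assembled [network()].
#' @param count Sample size (at most the population size).
#' @param seed Integer seed.
#' @return `sample_nodes()`: integer IDs; the others: a tibble `i`, `j`.
#' @export
sample_nodes <- function(net, count, seed) {
  check_network(net, assembled = TRUE)
  n <- length(net$labels)
  if (count > n) abort("sample size exceeds node count.")
  withr::with_seed(seed, sample.int(n, count) - 1L)
}

#' @rdname sample_nodes
#' @export
sample_edges <- function(net, count, seed) {
  check_network(net, assembled = TRUE)
  if (count > net$m) abort("sample size exceeds edge count.")
  idx <- withr::with_seed(seed, sample.int(net$m, count))
  tibble(i = net$ei[idx], j = net$ej[idx])
}

#' @rdname sample_nodes
#' @export
sample_nonedges <- function(net, count, seed) {
  check_network(net, assembled = TRUE)
  total <- nonedge_count(net)
  if (count > total) abort("sample size exceeds non-edge count.")
  t <- withr::with_seed(seed, sample(total, count)) - 1
  nonedge_at(net, t)
}

#' @export
print.lp_network <- function(x, ...) {
  state <- if (x$assembled) "assembled" else "under construction"
  m <- if (x$assembled) x$m else length(unique(pair_key(x$ei, x$ej, length(x$labels))))
  cat(sprintf("<lp_network: %d nodes, %d edges, %s>\n", length(x$labels), m, state))
  invisible(x)
}

#' Build an assembled network from an edge data frame
#'
#' Convenience constructor used throughout the package: nodes are created in
#' first-appearance order of the labels (or IDs coerced to labels).
#'
#' @param df Data frame whose first two columns are node labels.
#' @return An assembled [network()].
#' @export
network_from_edges <- function(df) {
  net <- network()
  a <- as.character(df[[1]])
  b <- as.character(df[[2]])
  for (k in seq_along(a)) {
    ia <- add_node_lax(net, a[k])
    ib <- add_node_lax(net, b[k])
    add_edge(net, ia, ib)
  }
  assemble(net)
  net
}

# add-or-get without the list overhead
add_node_lax <- function(net, label) {
  existing <- net$id_of[[label]]
  if (!is.null(existing)) return(existing)
  id <- length(net$labels)
  net$labels <- c(net$labels, label)
  net$id_of[[label]] <- id
  id
}
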