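#' Node and edge maps
#'
#' Maps attach values to an assembled network. A *node map* stores one value
#' per node ID with constant-time access; a *sparse node map* stores explicit
#' values for a subset of IDs and returns its default value for every other
#' node; an *edge map* is keyed by canonical existing edges and resolves keys
#' by binary search over the sorted edge list (O(log m)).
#'
#' Maps are plain functional values: setters return the modified map.
#'
#' @param net An assembled [network()].
#' @param init Initial value for every node / edge.
#' @param default Value returned by a sparse node map for unset IDs
#'   (for example `0.0`).
#' @return A map object of class `lp_node_map`, `lp_sparse_node_map` or
#'   `lp_edge_map`.
#' @examples
#' net <- network_from_edges(data.frame(a = c("A", "B"), b = c("B", "C")))
#' nm <- node_map(net, 0)
#' nm <- map_set(nm, 2, 5)
#' map_get(nm, 2)
#' @export
node_map <- function(net, init = NA_real_) {
  check_network(net, assembled = TRUE)
  structure(list(values = rep(init, length(net$labels))), class = "lp_node_map")
}

#' @rdname node_map
#' @export
sparse_node_map <- function(net, default = 0) {
  check_network(net, assembled = TRUE)
  structure(
    list(default = default, explicit = list(), n = length(net$labels)),
    class = "lp_sparse_node_map"
  )
}

#' @rdname node_map
#' @export
edge_map <- function(net, init = NA_real_) {
  check_network(net, assembled = TRUE)
  structure(
    list(
      values = rep(init, net$m),
      edge_keys = net$edge_keys,
      n = length(net$labels),
      ei = net$ei, ej = net$ej
    ),
    class = "lp_edge_map"
  )
}

#' Read and write map values
#'
#' For node maps `key` is a vector of node IDs; for edge maps it is a
#' two-column matrix/data frame of node IDs (canonicalized internally).
#'
#' @param map A map created by [node_map()], [sparse_node_map()] or
#'   [edge_map()].
#' @param key Node IDs, or edge endpoints for an edge map.
#' @param value Replacement value(s).
#' @return `map_get()` returns the stored values; `map_set()` the updated map.
#' @export
map_get <- function(map, key, ...) UseMethod("map_get")

#' @rdname map_get
#' @export
map_set <- function(map, key, value, ...) UseMethod("map_set")

#' @export
map_get.lp_node_map <- function(map, key, ...) {
  key <- as.integer(key)
  if (any(key < 0L) || any(key >= length(map$values))) abort("node ID out of range.")
  map$values[key + 1L]
}

#' @export
map_set.lp_node_map <- function(map, key, value, ...) {
  key <- as.integer(key)
  if (any(key < 0L) || any(key >= length(map$values))) abort("node ID out of range.")
  map$values[key + 1L] <- value
  map
}

#' @export
map_get.lp_sparse_node_map <- function(map, key, ...) {
  key <- as.integer(key)
  if (any(key < 0L) || any(key >= map$n)) abort("node ID out of range.")
  vapply(key, function(k) {
    v <- map$explicit[[as.character(k)]]
    if (is.null(v)) map$default else v
  }, map$default)
}

#' @export
map_set.lp_sparse_node_map <- function(map, key, value, ...) {
  key <- as.integer(key)
  if (any(key < 0L) || any(key >= map$n)) abort("node ID out of range.")
  for (idx in seq_along(key)) map$explicit[[as.character(key[idx])]] <- value[[idx]]
  map
}

edge_map_rank <- function(map, i, j) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  keys <- as.numeric(a) * map$n + as.numeric(b)
  idx <- findInterval(keys, map$edge_keys)
  ok <- idx > 0 & map$edge_keys[pmax(idx, 1L)] == keys
  if (!all(ok)) abort("edge map keys must be existing edges.")
  idx
}

#' @export
map_get.lp_edge_map <- function(map, key, ...) {
  key <- as.matrix(key)
  map$values[edge_map_rank(map, as.integer(key[, 1]), as.integer(key[, 2]))]
}

#' @export
map_set.lp_edge_map <- function(map, key, value, ...) {
  key <- as.matrix(key)
  map$values[edge_map_rank(map, as.integer(key[, 1]), as.integer(key[, 2]))] <- value
  map
}
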