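#' Breadth-first and depth-first traversal
#'
#' Visits every node reachable from `source` exactly once. Neighbors are
#' expanded in ascending ID order, so BFS delivers nodes in nondecreasing
#' hop distance with a deterministic tie rule, and DFS follows the
#' lowest-ID unvisited neighbor first.
#'
#' @param net An assembled [network()].
#' @param source 0-based source node ID.
#' @param processor Optional callback invoked as `processor(id)` on each
#'   visited node, in visit order.
#' @return Integer vector of visited node IDs in visit order, invisibly if a
#'   processor is supplied.
#' @export
bfs <- function(net, source, processor = NULL) {
  check_network(net, assembled = TRUE)
  source <- check_ids(net, source)
  n <- length(net$labels)
  seen <- logical(n)
  queue <- integer(n)
  queue[1L] <- source
  seen[source + 1L] <- TRUE
  head_ <- 1L
  tail_ <- 1L
  order_out <- integer(0)
  while (head_ <= tail_) {
    v <- queue[head_]
    head_ <- head_ + 1L
    order_out <- c(order_out, v)
    if (!is.null(processor)) processor(v)
    for (w in net$adj[[v + 1L]]) {
      if (!seen[w + 1L]) {
        seen[w + 1L] <- TRUE
        tail_ <- tail_ + 1L
        queue[tail_] <- w
      }
    }
  }
  if (is.null(processor)) order_out else invisible(order_out)
}

#' @rdname bfs
#' @export
dfs <- function(net, source, processor = NULL) {
  check_network(net, assembled = TRUE)
  source <- check_ids(net, source)
  n <- length(net$labels)
  seen <- logical(n)
  stack <- c(source)
  order_out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v + 1L]) next
    seen[v + 1L] <- TRUE
    order_out <- c(order_out, v)
    if (!is.null(processor)) processor(v)
    nb <- net$adj[[v + 1L]]
    # push in descending order so the lowest ID is expanded first
    stack <- c(stack, rev(nb[!seen[nb + 1L]]))
  }
  if (is.null(processor)) order_out else invisible(order_out)
}

# adjacency-aligned edge lengths; NULL lengths = unit (hop) metric
adjacency_lengths <- function(net, lengths = NULL) {
  n <- length(net$labels)
  if (is.null(lengths)) {
    return(lapply(net$adj, function(nb) rep(1, length(nb))))
  }
  if (!inherits(lengths, "lp_edge_map")) abort("`lengths` must be an edge map.")
  if (any(lengths$values < 0, na.rm = TRUE)) abort("edge lengths must be nonnegative.")
  lapply(seq_len(n), function(k) {
    nb <- net$adj[[k]]
    if (!length(nb)) return(numeric(0))
    map_get(lengths, cbind(rep(k - 1L, length(nb)), nb))
  })
}

#' Single-source shortest paths (Dijkstra)
#'
#' `dijkstra_all()` computes, for one source, the shortest-path length and
#' the number of edges (hops) on that path to every node. `dijkstra_path()`
#' returns one shortest path and stops as soon as the target is settled.
#' Unreachable nodes carry distance `Inf` and `NA` hops. With unit lengths
#' (the default) distances equal BFS hop counts.
#'
#' @param net An assembled [network()].
#' @param lengths Optional [edge_map()] of nonnegative edge lengths;
#'   `NULL` means every edge has length 1.
#' @param s,t 0-based source / target node IDs.
#' @return `dijkstra_all()`: a tibble with columns `node`, `dist`, `hops`.
#'   `dijkstra_path()`: a list with `path` (node IDs, or `NULL` if
#'   unreachable), `length`, `hops`.
#' @export
dijkstra_all <- function(net, lengths = NULL, s) {
  check_network(net, assembled = TRUE)
  s <- check_ids(net, s)
  lad <- adjacency_lengths(net, lengths)
  n <- length(net$labels)
  dist <- rep(Inf, n)
  hops <- rep(NA_integer_, n)
  done <- logical(n)
  dist[s + 1L] <- 0
  hops[s + 1L] <- 0L
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || done[u] || is.infinite(dist[u])) break
    done[u] <- TRUE
    nb <- net$adj[[u]]
    if (length(nb)) {
      cand <- dist[u] + lad[[u]]
      for (k in seq_along(nb)) {
        w <- nb[k] + 1L
        if (!done[w] && cand[k] < dist[w]) {
          dist[w] <- cand[k]
          hops[w] <- hops[u] + 1L
        }
      }
    }
    if (all(done | is.infinite(dist))) break
  }
  tibble(node = seq_len(n) - 1L, dist = dist, hops = hops)
}

#' @rdname dijkstra_all
#' @export
dijkstra_path <- function(net, lengths = NULL, s, t) {
  check_network(net, assembled = TRUE)
  s <- check_ids(net, s)
  t <- check_ids(net, t)
  lad <- adjacency_lengths(net, lengths)
  n <- length(net$labels)
  dist <- rep(Inf, n)
  hops <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  done <- logical(n)
  dist[s + 1L] <- 0
  hops[s + 1L] <- 0L
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || done[u] || is.infinite(dist[u])) break
    done[u] <- TRUE
    if (u == t + 1L) break
    nb <- net$adj[[u]]
    if (length(nb)) {
      cand <- dist[u] + lad[[u]]
      for (k in seq_along(nb)) {
        w <- nb[k] + 1L
        if (!done[w] && cand[k] < dist[w]) {
          dist[w] <- cand[k]
          hops[w] <- hops[u] + 1L
          parent[w] <- u - 1L
        }
      }
    }
  }
  if (is.infinite(dist[t + 1L])) {
    return(list(path = NULL, length = Inf, hops = NA_integer_))
  }
  path <- t
  while (path[1L] != s) path <- c(parent[path[1L] + 1L], path)
  list(path = path, length = dist[t + 1L], hops = hops[t + 1L])
}

#' Exact shortest-path distance calculator with caching
#'
#' Binds a network and a length map, and serves pairwise distance queries
#' from cached single-source Dijkstra rows. Strategy `"full"` keeps every
#' computed row; `"lru"` keeps at most `capacity` rows, evicting the least
#' recently used. The calculator keeps a run counter so cache behavior can
#' be observed.
#'
#' @param net An assembled [network()].
#' @param lengths Optional [edge_map()] of nonnegative lengths.
#' @param strategy `"full"` or `"lru"`.
#' @param capacity Maximum number of cached source rows for `"lru"`.
#' @return An `lp_esp` calculator object (environment).
#' @export
esp_calculator <- function(net, lengths = NULL, strategy = c("full", "lru"),
                           capacity = 16L) {
  check_network(net, assembled = TRUE)
  strategy <- match.arg(strategy)
  env <- new.env(parent = emptyenv())
  env$net <- net
  env$lengths <- lengths
  env$strategy <- strategy
  env$capacity <- as.integer(capacity)
  env$cache <- list()
  env$lru <- character(0)
  env$runs <- 0L
  class(env) <- "lp_esp"
  env
}

esp_row <- function(calc, s) {
  key <- as.character(s)
  row <- calc$cache[[key]]
  if (is.null(row)) {
    row <- dijkstra_all(calc$net, calc$lengths, s)
    calc$runs <- calc$runs + 1L
    calc$cache[[key]] <- row
    calc$lru <- c(setdiff(calc$lru, key), key)
    if (calc$strategy == "lru" && length(calc$lru) > calc$capacity) {
      evict <- calc$lru[1L]
      calc$lru <- calc$lru[-1L]
      calc$cache[[evict]] <- NULL
    }
  } else {
    calc$lru <- c(setdiff(calc$lru, key), key)
  }
  row
}

#' Pairwise exact distance through a calculator
#'
#' Serves `(i, j)` from a cached row of either endpoint if available,
#' otherwise runs Dijkstra from `i`. Symmetric in its arguments.
#'
#' @param calc An [esp_calculator()].
#' @param i,j 0-based node IDs.
#' @return A list with `dist` and `hops` (`Inf` / `NA` if unreachable).
#' @export
exact_dist <- function(calc, i, j) {
  if (!inherits(calc, "lp_esp")) abort("`calc` must be an esp_calculator().")
  i <- check_ids(calc$net, i)
  j <- check_ids(calc$net, j)
  ki <- as.character(i)
  kj <- as.character(j)
  if (!is.null(calc$cache[[ki]])) {
    row <- esp_row(calc, i)
    return(list(dist = row$dist[j + 1L], hops = row$hops[j + 1L]))
  }
  if (!is.null(calc$cache[[kj]])) {
    row <- esp_row(calc, j)
    return(list(dist = row$dist[i + 1L], hops = row$hops[i + 1L]))
  }
  row <- esp_row(calc, i)
  list(dist = row$dist[j + 1L], hops = row$hops[j + 1L])
}

#' Landmark-based approximate distances
#'
#' Precomputes exact distance tables from a set of landmark nodes; any
#' pairwise distance is then approximated by the best two-leg route through
#' a landmark: `min_k [d(i,k) + d(k,j)]`. The approximation is an upper
#' bound on the true distance and is exact whenever some landmark lies on a
#' shortest `i`-`j` path (in particular when every node is a landmark).
#'
#' By default the `k` highest-degree nodes are used (ties by lowest ID), a
#' heuristic that tends to place landmarks on many shortest paths.
#'
#' @param net An assembled [network()].
#' @param lengths Optional [edge_map()] of nonnegative lengths.
#' @param landmarks Explicit 0-based landmark IDs, overriding `k`.
#' @param k Number of top-degree landmarks when `landmarks` is `NULL`.
#' @return An `lp_landmarks` object.
#' @export
landmark_set <- function(net, lengths = NULL, landmarks = NULL, k = 4L) {
  check_network(net, assembled = TRUE)
  n <- length(net$labels)
  if (is.null(landmarks)) {
    ids <- seq_len(n) - 1L
    landmarks <- ids[order(-net$deg, ids)][seq_len(min(k, n))]
  }
  landmarks <- sort(unique(check_ids(net, landmarks)))
  if (!length(landmarks)) abort("landmark set must be non-empty.")
  rows <- lapply(landmarks, function(s) dijkstra_all(net, lengths, s))
  structure(
    list(
      landmarks = landmarks,
      dist = do.call(rbind, lapply(rows, function(r) r$dist)),
      hops = do.call(rbind, lapply(rows, function(r) r$hops))
    ),
    class = "lp_landmarks"
  )
}

#' @rdname landmark_set
#' @param lm An `lp_landmarks` object.
#' @param i,j 0-based node IDs.
#' @return `approx_dist()`: list with `dist` (upper bound, possibly `Inf`)
#'   and `hops` (leg sum at the minimizing landmark; ties resolved toward
#'   the lowest landmark ID).
#' @export
approx_dist <- function(lm, i, j) {
  if (!inherits(lm, "lp_landmarks")) abort("`lm` must be a landmark_set().")
  total <- lm$dist[, i + 1L] + lm$dist[, j + 1L]
  if (all(is.infinite(total))) return(list(dist = Inf, hops = NA_integer_))
  best <- which.min(total) # first minimum = lowest landmark ID (rows sorted)
  list(dist = total[best], hops = lm$hops[best, i + 1L] + lm$hops[best, j + 1L])
}
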