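# Independent oracles used across the suite. These deliberately avoid the
# package's own data paths: adjacency is rebuilt from the edge tibble with
# plain set arithmetic.

# path graph 0-1-2-...-(n-1)
make_path <- function(n) {
  network_from_edges(data.frame(a = 0:(n - 2), b = 1:(n - 1)))
}

# adjacency as a list of plain integer sets, straight from the edge list
oracle_adjacency <- function(net) {
  n <- n_nodes(net)
  ed <- edges(net)
  adj <- lapply(seq_len(n), function(k) integer(0))
  for (r in seq_len(nrow(ed))) {
    adj[[ed$i[r] + 1]] <- c(adj[[ed$i[r] + 1]], ed$j[r])
    adj[[ed$j[r] + 1]] <- c(adj[[ed$j[r] + 1]], ed$i[r])
  }
  lapply(adj, sort)
}

# brute-force non-edge list: every canonical pair not in the edge set
oracle_nonedges <- function(net) {
  n <- n_nodes(net)
  ed <- edges(net)
  ekeys <- paste(ed$i, ed$j)
  out <- NULL
  for (i in 0:(max(n - 2, 0))) {
    for (j in seq_len(n - 1 - i) + i) {
      if (n < 2) break
      if (!paste(i, j) %in% ekeys) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# explicit set-arithmetic implementations of every topological index
oracle_index <- function(adj, deg, index, i, j) {
  gi <- adj[[i + 1]]
  gj <- adj[[j + 1]]
  C <- gi[gi %in% gj]
  switch(index,
    CNE = length(C),
    ADA = sum(vapply(C, function(z) 1 / log(deg[z + 1]), 0)),
    RAL = sum(vapply(C, function(z) 1 / deg[z + 1], 0)),
    CRA = sum(vapply(C, function(z) {
      sum(adj[[z + 1]] %in% C) / deg[z + 1]
    }, 0)),
    JID = {
      u <- unique(c(gi, gj))
      if (length(u) == 0) 0 else length(C) / length(u)
    },
    PAT = deg[i + 1] * deg[j + 1],
    SDG = deg[i + 1] + deg[j + 1]
  )
}

# pairwise Mann-Whitney AUC by full enumeration
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) {
    wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  }
  wins / (length(pos) * length(neg))
}

# all-pairs shortest hop distances by repeated BFS over the oracle adjacency
oracle_hop_dists <- function(net) {
  n <- n_nodes(net)
  adj <- oracle_adjacency(net)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    level <- 0
    while (length(frontier)) {
      level <- level + 1
      nxt <- unique(unlist(adj[frontier])) + 1
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- level
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# random score sets whose realized PR precision is non-increasing: per-group
# FP/TP increments are nondecreasing in the sweep order, the regime in which
# linear PR interpolation overestimates the area. Returns list(pos, neg).
rand_monotone_scores <- function(n_groups = 6) {
  dtp <- sample(1:4, n_groups, replace = TRUE)
  dfp <- round(dtp * runif(n_groups, 0, 4))
  ord <- order(dfp / dtp) # realized per-group FP/TP ratio, ascending
  dtp <- dtp[ord]
  dfp <- dfp[ord]
  pos <- rep(n_groups - seq_len(n_groups), times = dtp) # descending scores
  neg <- rep(n_groups - seq_len(n_groups), times = dfp)
  if (!length(neg)) neg <- -1 # ensure both classes present
  list(pos = pos, neg = neg)
}
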