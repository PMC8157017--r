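#' Read a network from a plain-text edge list
#'
#' Each data line holds two whitespace-separated node labels, with an
#' optional third token parsed as a numeric edge weight. Lines starting with
#' `#` and blank lines are skipped. Nodes are created in first-appearance
#' order; duplicate edge lines are collapsed (for weighted files the last
#' weight wins). The returned network is assembled.
#'
#' @param path Path to a UTF-8 edge-list file.
#' @return An assembled [network()]. If any line carried a weight, an
#'   [edge_map()] of weights (default 1 elsewhere) is attached as attribute
#'   `"weights"`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  net <- network()
  wi <- integer(0)
  wj <- integer(0)
  wv <- numeric(0)
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "" || startsWith(raw, "#")) next
    tok <- strsplit(raw, "[[:space:]]+")[[1]]
    if (length(tok) < 2L) {
      abort(sprintf("malformed edge-list line %d: %s", ln, raw))
    }
    ia <- add_node_lax(net, tok[1])
    ib <- add_node_lax(net, tok[2])
    if (ia == ib) abort(sprintf("self-loop on line %d: %s", ln, raw))
    add_edge(net, ia, ib)
    if (length(tok) >= 3L) {
      w <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(w)) abort(sprintf("malformed weight on line %d: %s", ln, raw))
      wi <- c(wi, min(ia, ib))
      wj <- c(wj, max(ia, ib))
      wv <- c(wv, w)
    }
  }
  assemble(net)
  if (length(wv)) {
    wm <- edge_map(net, 1)
    wm <- map_set(wm, cbind(wi, wj), wv)
    attr(net, "weights") <- wm
  }
  net
}

#' Write a network as a plain-text edge list
#'
#' One line per canonical edge: `label_i label_j`, separated by a single
#' space; reading the file back with [read_edge_list()] reproduces an
#' isomorphic network.
#'
#' @param net An assembled [network()].
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  check_network(net, assembled = TRUE)
  df <- edges(net)
  writeLines(paste(df$label_i, df$label_j), path, useBytes = TRUE)
  invisible(path)
}

#' Write a score sheet as TSV
#'
#' Emits `label_i<TAB>label_j<TAB>score` per row, no header.
#'
#' @param sheet A tibble with columns `label_i`, `label_j`, `score` (as
#'   returned by [lp_top()] or [lp_predict_neg()]).
#' @param path Output path.
#' @export
write_scores <- function(sheet, path) {
  if (!all(c("label_i", "label_j", "score") %in% names(sheet))) {
    abort("`sheet` must have columns label_i, label_j, score.")
  }
  writeLines(
    sprintf("%s\t%s\t%.17g", sheet$label_i, sheet$label_j, sheet$score),
    path,
    useBytes = TRUE
  )
  invisible(path)
}

#' Write an encoding as TSV
#'
#' Emits `label<TAB>c1<TAB>...<TAB>cd` per node.
#'
#' @param enc An [encoding][lp_encode] object.
#' @param net The network the encoding was computed on (for labels).
#' @param path Output path.
#' @export
write_encoding <- function(enc, net, path) {
  check_network(net, assembled = TRUE)
  codes <- enc$codes
  rows <- vapply(seq_len(nrow(codes)), function(r) {
    paste(c(net$labels[r], sprintf("%.17g", codes[r, ])), collapse = "\t")
  }, "")
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
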