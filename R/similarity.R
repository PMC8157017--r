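#' Vector similarity measures
#'
#' Similarities between two equal-length numeric vectors. Distance-based
#' measures (`L1`, `L2`, `Lp`) are negated so that larger values always mean
#' more similar. `cosine` returns 0 if either vector has zero norm and
#' `pearson` returns 0 for zero-variance input.
#'
#' @param measure One of `"cosine"`, `"dot"`, `"L1"`, `"L2"`, `"Lp"`,
#'   `"pearson"` (case-insensitive).
#' @param u,v Numeric vectors of equal length.
#' @param p Order for `"Lp"` (>= 1).
#' @return A single numeric similarity.
#' @examples
#' similarity("cosine", c(1, 0), c(0, 1))
#' similarity("dot", c(1, 2), c(3, 4))
#' @export
similarity <- function(measure, u, v, p = 3) {
  if (length(u) != length(v)) abort("`u` and `v` must have equal length.")
  measure <- tolower(measure)
  if (measure == "lp" && p < 1) abort("`p` must be >= 1 for Lp similarity.")
  switch(measure,
    cosine = {
      nu <- sqrt(sum(u^2))
      nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) 0 else sum(u * v) / (nu * nv)
    },
    dot = sum(u * v),
    l1 = -sum(abs(u - v)),
    l2 = -sqrt(sum((u - v)^2)),
    lp = -sum(abs(u - v)^p)^(1 / p),
    pearson = {
      if (stats::sd(u) == 0 || stats::sd(v) == 0) 0 else stats::cor(u, v)
    },
    abort(paste0("unknown similarity measure: ", measure))
  )
}

similarity_measures <- c("cosine", "dot", "l1", "l2", "lp", "pearson")
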