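#' Diversity indices for a vector of species counts
#'
#' Classical per-sample community descriptors, all on natural logarithms:
#' species richness S (number of species with count > 0), total abundance N,
#' Shannon-Wiener H' = -sum p_i ln p_i, Simpson D = 1 - sum p_i^2, and Pielou
#' evenness J = H' / ln S.
#'
#' Empty samples (total count 0) yield `NA` for Shannon and Simpson rather
#' than 0, so that downstream averaging can skip them instead of silently
#' biasing diversity-area curves towards zero; Pielou is additionally `NA`
#' when S <= 1 (evenness of a monoculture is undefined).
#'
#' @param counts Numeric vector of non-negative per-species counts.
#' @return A single number (`richness` and `abundance` are integers).
#' @examples
#' richness(c(5, 0, 2))   # 2
#' shannon(rep(1, 4))     # log(4)
#' @export
richness <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts > 0)
}

#' @rdname richness
#' @export
abundance <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts)
}

#' @rdname richness
#' @export
shannon <- function(counts) {
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' @rdname richness
#' @export
simpson <- function(counts) {
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- counts / n
  1 - sum(p^2)
}

#' @rdname richness
#' @export
pielou <- function(counts) {
  s <- richness(counts)
  if (s <= 1) return(NA_real_)
  shannon(counts) / log(s)
}

diversity_metrics <- c("richness", "abundance", "shannon", "simpson",
                       "pielou", "density")

metric_fun <- function(metric) {
  switch(metric,
    richness = richness,
    abundance = abundance,
    shannon = shannon,
    simpson = simpson,
    pielou = pielou,
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  )
}

#' Evaluate a diversity metric on every window of a survey
#'
#' Pools quadrat counts within each square window of side `k` (see
#' [enumerate_windows()]) and evaluates the metric on the pooled counts.
#' `density` is total abundance divided by window area (individuals / m^2).
#'
#' @param x A [survey_data()] object.
#' @param k Window side in quadrat units.
#' @param metric One of `"richness"`, `"abundance"`, `"shannon"`,
#'   `"simpson"`, `"pielou"`, `"density"`.
#' @param mode Window placement, `"tiling"` (default) or `"sliding"`.
#' @return Tibble `subplot`, `window_row`, `window_col`, `k`, `area`,
#'   `metric`, `value` with one row per window per subplot.
#' @export
diversity_surface <- function(x, k, metric = "richness",
                              mode = c("tiling", "sliding")) {
  stopifnot(inherits(x, "survey"))
  metric <- match.arg(metric, diversity_metrics)
  mode <- match.arg(mode)
  wc <- window_counts(x, k, mode)
  counts <- as.matrix(wc[x$species])
  value <- if (metric == "density") {
    rowSums(counts) / wc$area
  } else {
    apply(counts, 1L, metric_fun(metric))
  }
  out <- wc[c("subplot", "window_row", "window_col", "k", "area")]
  out$metric <- metric
  out$value <- as.numeric(value)
  out
}
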