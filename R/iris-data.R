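# The classic Iris measurements of Fisher (1936), bundled as a worked
# heteroscedasticity example.

#' Fisher's (1936) Iris measurements
#'
#' The 150 original iris records (50 per species; sepal length/width and
#' petal length/width in centimeters) as printed by Fisher (1936).  Note
#' these are Fisher's original values, which differ from R's
#' `datasets::iris` in three cells of *I. setosa* (the well-known row 35
#' petal-width and row 38 sepal-width/petal-length discrepancies); group
#' standard deviations, and hence effect sizes, differ accordingly.
#'
#' @return A `data.frame` with columns `species` (factor: setosa,
#'   versicolor, virginica), `sepal_length`, `sepal_width`, `petal_length`
#'   and `petal_width`.
#' @export
iris_measurements <- function() {
  path <- system.file("extdata", "iris_fisher.csv", package = "smde",
                      mustWork = TRUE)
  tab <- utils::read.csv(path)
  tab$species <- factor(tab$species,
                        levels = c("setosa", "versicolor", "virginica"))
  tab
}

#' Pairwise effect sizes across species for every measurement
#'
#' For each measurement column and each ordered species pair (1 vs 2,
#' 1 vs 3, 2 vs 3), computes the unbiased pooled-SD effect size d, the
#' unbiased Welch-based effect size e, their ratio d/e, and the ratio of
#' the two sample SDs.  The SD ratio is the practical diagnostic: the
#' further it is from 1, the more the equal-variance assumption behind d
#' distorts the estimate relative to e.
#'
#' @param data A `data.frame` shaped like [iris_measurements()]: one factor
#'   column naming the group plus numeric measurement columns.
#' @param group_column Name of the factor column.
#' @return A `data.frame` with columns `characteristic`, `pair`, `d`, `e`,
#'   `d_over_e` and `sd_ratio`.
#' @export
#' @examples
#' head(species_contrast_table())
species_contrast_table <- function(data = iris_measurements(),
                                   group_column = "species") {
  labels <- levels(factor(data[[group_column]]))
  if (length(labels) < 2L) stop("need at least two groups")
  measures <- setdiff(names(data), group_column)
  pairs <- utils::combn(seq_along(labels), 2, simplify = FALSE)
  rows <- list()
  for (col in measures) for (pr in pairs) {
    x <- data[[col]][data[[group_column]] == labels[pr[1]]]
    y <- data[[col]][data[[group_column]] == labels[pr[2]]]
    g1 <- summarize_sample(x)
    g2 <- summarize_sample(y)
    design <- two_sample_design(g1, g2)
    d <- hedges_d(design)
    e <- e_unbiased(design)
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = col,
      pair = paste(labels[pr[1]], "vs", labels[pr[2]]),
      d = d, e = e, d_over_e = d / e,
      sd_ratio = sqrt(g1$var / g2$var)
    )
  }
  do.call(rbind, rows)
}
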