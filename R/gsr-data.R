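#' Packaged rice trial: paddy-yield cell means
#'
#' Pooled paddy-yield means (kg/ha, integer display precision) of 20 Green
#' Super Rice genotypes — 18 advanced lines plus two local check cultivars
#' (G19, G20) — evaluated in a triplicate RCBD at 12 rice-growing locations
#' across Pakistan in 2021. This is the worked example used throughout the
#' package documentation and tests.
#'
#' @return A 20 x 12 numeric matrix with genotypes `G1..G20` in rows and
#'   environments `E1..E12` in columns.
#' @examples
#' cm <- cell_means(gsr_yield_means())
#' round(percent_over_check(cm, "G1", check = "G20"), 2)
#' @export
gsr_yield_means <- function() {
  path <- system.file("extdata", "gsr_yield_means.csv", package = "metstab",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(`rownames<-`(df[, -1], df$genotype))
}

#' Packaged rice trial: combined-ANOVA mean squares for six traits
#'
#' Mean squares (GEN, ENV, GEN:ENV, ERROR with their degrees of freedom)
#' from the combined analysis of the packaged rice trial for six traits:
#' plant height, tiller number, panicle length, grains per panicle,
#' thousand-grain weight and paddy yield. Together with `r = 3` replicates
#' these drive [genetic_components()].
#'
#' The tiller-number error mean square is stored as 22.79: the published
#' ANOVA table prints 2.79, a dropped leading digit, since the trial's own
#' variance-component table (environmental variance 7.60 = 22.79/3,
#' phenotypic variance 13.65) is only consistent with 22.79.
#'
#' @return A data.frame with columns `source`, `df` and one numeric column
#'   per trait.
#' @examples
#' ms <- gsr_mean_squares()
#' gms <- unlist(ms[ms$source == "GEN", -(1:2)])
#' ems <- unlist(ms[ms$source == "ERROR", -(1:2)])
#' genetic_components(gms, ems, r = 3)
#' @export
gsr_mean_squares <- function() {
  path <- system.file("extdata", "gsr_mean_squares.csv", package = "metstab",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Packaged rice trial: published univariate stability statistics
#'
#' The published paddy-yield stability-statistics table of the packaged
#' rice trial (ASV, ASI, joint-regression slope, Wricke's ecovalence,
#' Shukla's variance, WAAS), kept for cross-checking recomputed values.
#' Two caveats, documented in the package vignette: the published ASV and
#' ASI columns are swapped relative to the statistics' defining equations
#' (the ASV column holds the \eqn{\theta^2}-weighted index of [asi()] and
#' the ASI column the SS-ratio value of [asv()]), and the WAAS column was
#' produced with BLUP-shrunken interaction effects, which this package's
#' fixed-effects [waas()] intentionally does not replicate.
#'
#' @return A data.frame with one row per genotype.
#' @export
gsr_stability_published <- function() {
  path <- system.file("extdata", "gsr_stability_published.csv",
                      package = "metstab", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
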