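#' AMMI stability value (ASV)
#'
#' Scalar stability measure built from the first two interaction principal
#' component scores,
#' \deqn{ASV_i = \sqrt{\left(\frac{SS_1}{SS_2} s_{i1}\right)^2 + s_{i2}^2},}
#' where \eqn{SS_k = \lambda_k^2} is the interaction sum of squares of axis
#' k and \eqn{s_{ik} = \gamma_{ik}\sqrt{\lambda_k}} are the symmetric-scaled
#' genotype scores. Genotypes with ASV near zero contribute little to the
#' G\eqn{\times}E interaction and are considered stable.
#'
#' When the second axis carries no interaction (\eqn{\lambda_2 = 0}) the
#' axis-weight is undefined and the statistic falls back to \eqn{|s_{i1}|}
#' with a warning.
#'
#' @param fit an [ammi_fit()] object with at least two axes.
#' @return A named numeric vector, one value per genotype.
#' @examples
#' fit <- ammi_fit(cell_means(gsr_yield_means()))
#' sort(round(asv(fit), 2))[1:3]
#' @seealso [asi()], [stability_table()]
#' @export
asv <- function(fit) {
  stopifnot(inherits(fit, "ammi"))
  if (fit$K < 2) {
    stop_metstab("metstab_error_degenerate", "ASV needs at least two interaction axes")
  }
  s <- ammi_scores(fit, "genotype", "sqrtlam", axes = 2)
  ss <- fit$lambda[1:2]^2
  # rank-1 interaction up to numerical noise: the axis-ratio weight blows up
  if (ss[2] <= .Machine$double.eps * max(ss[1], 1)) {
    warning("lambda_2 = 0: ASV axis weight undefined, falling back to |IPCA1 score|")
    return(stats::setNames(abs(s[, 1]), rownames(s)))
  }
  stats::setNames(sqrt((ss[1] / ss[2] * s[, 1])^2 + s[, 2]^2), rownames(s))
}

#' AMMI stability index (ASI)
#'
#' \deqn{ASI_i = \sqrt{(s_{i1}\,\theta_1^2)^2 + (s_{i2}\,\theta_2^2)^2},}
#' with \eqn{s_{ik}} the symmetric-scaled genotype scores and
#' \eqn{\theta_k^2} the fraction of the interaction sum of squares explained
#' by axis k (default \eqn{EP_k/100}). Lower is more stable.
#'
#' The scaling convention (`"sqrtlam"` scores, SS-fraction weights) is
#' recorded on the result as attributes `scaling` and `theta2`. Note that
#' published tables do not always label the two AMMI statistics
#' consistently: with these conventions the packaged rice trial's printed
#' "ASV" column is reproduced by this index and its printed "ASI" column by
#' [asv()] (see the package vignette).
#'
#' @param fit an [ammi_fit()] object with at least two axes.
#' @param theta2 axis weights; defaults to `fit$EP[1:2] / 100`.
#' @return A named numeric vector with attributes `theta2` and `scaling`.
#' @export
asi <- function(fit, theta2 = fit$EP[1:2] / 100) {
  stopifnot(inherits(fit, "ammi"))
  if (fit$K < 2) {
    stop_metstab("metstab_error_degenerate", "ASI needs at least two interaction axes")
  }
  stopifnot(length(theta2) == 2)
  s <- ammi_scores(fit, "genotype", "sqrtlam", axes = 2)
  out <- sqrt((s[, 1] * theta2[1])^2 + (s[, 2] * theta2[2])^2)
  structure(stats::setNames(out, rownames(s)),
            theta2 = theta2, scaling = "sqrtlam")
}

#' Eberhart-Russell joint-regression slope
#'
#' Regresses each genotype's environment means on the environmental index
#' \eqn{I_j = \bar X_{.j} - \bar X_{..}}:
#' \deqn{b_i = \sum_j (\bar X_{ij} - \bar X_{i.}) I_j \Big/ \sum_j I_j^2 .}
#' A slope of 1 is average responsiveness to environment quality; slopes
#' below (above) 1 indicate below- (above-) average responsiveness. The
#' slopes average exactly 1 over genotypes.
#'
#' @param means a [cell_means] object with at least 3 environments.
#' @return A named numeric vector of slopes, one per genotype.
#' @examples
#' b <- joint_regression(cell_means(gsr_yield_means()))
#' round(range(b), 2)
#' @export
joint_regression <- function(means) {
  stopifnot(inherits(means, "cell_means"))
  if (means$q < 3) {
    stop_metstab("metstab_error_degenerate", "joint regression needs q >= 3 environments")
  }
  I_j <- means$col_means - means$grand_mean
  denom <- sum(I_j^2)
  if (denom == 0) {
    stop_metstab("metstab_error_degenerate",
                 "no environmental spread: all environment means are equal")
  }
  centred <- sweep(means$means, 1, means$row_means)
  stats::setNames(drop(centred %*% I_j) / denom, rownames(means$means))
}

#' Wricke's ecovalence
#'
#' Each genotype's contribution to the interaction sum of squares of the
#' cell-means matrix,
#' \deqn{W_i^2 = \sum_j (\bar X_{ij} - \bar X_{i.} - \bar X_{.j} + \bar X_{..})^2 .}
#' The ecovalences sum to the total interaction SS
#' (\eqn{\sum_i W_i^2 = \sum_k \lambda_k^2}); lower is more stable.
#'
#' @param means a [cell_means] object (g >= 2, q >= 2).
#' @return A named numeric vector, one value per genotype.
#' @export
wricke_ecovalence <- function(means) {
  stopifnot(inherits(means, "cell_means"))
  if (means$g < 2 || means$q < 2) {
    stop_metstab("metstab_error_degenerate", "ecovalence needs g >= 2 and q >= 2")
  }
  Z <- sweep(sweep(means$means, 1, means$row_means), 2, means$col_means) +
    means$grand_mean
  stats::setNames(rowSums(Z^2), rownames(means$means))
}

#' Shukla's stability variance
#'
#' Unbiased per-genotype interaction variance, an affine transform of
#' Wricke's ecovalence:
#' \deqn{\sigma^2_i = \frac{p}{(p-2)(q-1)} W_i^2 -
#'       \frac{\sum_m W_m^2}{(p-1)(p-2)(q-1)},}
#' where p and q are the numbers of genotypes and environments. Because the
#' transform is affine with a positive slope, ranking genotypes by
#' \eqn{\sigma^2_i} is identical to ranking them by \eqn{W_i^2}.
#'
#' @param wi2 vector of ecovalences (from [wricke_ecovalence()] or a
#'   published table), or a [cell_means] object from which they are
#'   computed.
#' @param p,q genotype and environment counts; inferred when `wi2` is a
#'   [cell_means] object or a full-length vector.
#' @return A named numeric vector of stability variances.
#' @examples
#' cm <- cell_means(gsr_yield_means())
#' head(round(shukla_variance(cm, q = 12)))
#' @export
shukla_variance <- function(wi2, p = NULL, q = NULL) {
  if (inherits(wi2, "cell_means")) {
    if (is.null(p)) p <- wi2$g
    if (is.null(q)) q <- wi2$q
    wi2 <- wricke_ecovalence(wi2)
  }
  if (is.null(p)) p <- length(wi2)
  if (is.null(q)) {
    stop_metstab("metstab_error_config", "environment count q is required")
  }
  if (p < 3) {
    stop_metstab("metstab_error_degenerate", "Shukla's variance needs p >= 3 genotypes")
  }
  p / ((p - 2) * (q - 1)) * wi2 - sum(wi2) / ((p - 1) * (p - 2) * (q - 1))
}

#' Weighted average of absolute IPCA scores (WAAS)
#'
#' \deqn{WAAS_i = \frac{\sum_k |s_{ik}|\, EP_k}{\sum_k EP_k},}
#' the average of a genotype's absolute symmetric-scaled interaction scores
#' weighted by the variance explained by each axis. Lower is more stable.
#' All axes are used by default; a count, or `"significant"` together with
#' an [ammi_anova()] table, restricts the average to the leading axes.
#'
#' @param fit an [ammi_fit()] object.
#' @param axes `"all"` (default), a positive axis count, or
#'   `"significant"` (axes with p < 0.05 in `anova`).
#' @param anova an [ammi_anova()] table; required for
#'   `axes = "significant"`.
#' @return A named numeric vector, one value per genotype, with attribute
#'   `axes` recording the count used.
#' @export
waas <- function(fit, axes = "all", anova = NULL) {
  stopifnot(inherits(fit, "ammi"))
  n_axes <- if (identical(axes, "all")) {
    fit$K
  } else if (identical(axes, "significant")) {
    if (is.null(anova)) {
      stop_metstab("metstab_error_config",
                   "axes = \"significant\" needs an ammi_anova() table")
    }
    pc <- grepl("^PC[0-9]+$", anova$source)
    max(1L, sum(anova$p[pc] < 0.05, na.rm = TRUE))
  } else {
    stopifnot(is.numeric(axes), axes >= 1)
    min(as.integer(axes), fit$K)
  }
  s <- ammi_scores(fit, "genotype", "sqrtlam", axes = n_axes)
  w <- fit$EP[seq_len(n_axes)]
  out <- drop(abs(s) %*% w) / sum(w)
  structure(stats::setNames(out, rownames(s)), axes = n_axes)
}

#' Blend stability and yield into a superiority score (WAASY)
#'
#' Rescales pooled yield to 0-100 (higher yield, higher score) and WAAS to
#' 0-100 (lower WAAS, higher score) by min-max, then blends them:
#' \deqn{WAASY_i = \frac{w_Y\, yscore_i + (100 - w_Y)\, sscore_i}{100}.}
#' `weight_yield = 100` ranks purely on yield, `0` purely on stability.
#' Each genotype is also classified into one of four quadrants by (mean
#' above/below the grand mean) x (WAAS below/above the median WAAS):
#' `productive_stable`, `productive_unstable`, `unproductive_stable`,
#' `unproductive_unstable`.
#'
#' @param waas per-genotype WAAS values (from [waas()]).
#' @param means the [cell_means] object the WAAS was computed from.
#' @param weight_yield yield weight in percent, between 0 and 100.
#' @return A data.frame with columns `genotype`, `mean`, `waas`, `y_score`,
#'   `s_score`, `waasy`, `class` and `rank` (1 = best blended score).
#' @export
waasy_ranking <- function(waas, means, weight_yield = 50) {
  stopifnot(inherits(means, "cell_means"),
            weight_yield >= 0, weight_yield <= 100)
  y <- means$row_means[names(waas)]
  rescale <- function(x, higher_better) {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      stop_metstab("metstab_error_degenerate",
                   "min-max rescaling degenerate: all values identical")
    }
    sc <- 100 * (x - rng[1]) / (rng[2] - rng[1])
    if (higher_better) sc else 100 - sc
  }
  y_score <- rescale(y, TRUE)
  s_score <- rescale(waas, FALSE)
  score <- (weight_yield * y_score + (100 - weight_yield) * s_score) / 100
  productive <- y >= means$grand_mean
  stable <- waas <= stats::median(waas)
  cls <- ifelse(productive,
                ifelse(stable, "productive_stable", "productive_unstable"),
                ifelse(stable, "unproductive_stable", "unproductive_unstable"))
  data.frame(genotype = names(waas), mean = unname(y), waas = unname(waas),
             y_score = unname(y_score), s_score = unname(s_score),
             waasy = unname(score), class = unname(cls),
             rank = rank(-score, ties.method = "average"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate stability statistics table
#'
#' Computes all six univariate stability statistics — ASV, ASI,
#' joint-regression slope \eqn{b_i}, Wricke's ecovalence \eqn{W_i^2},
#' Shukla's \eqn{\sigma^2_i} and WAAS — plus the blended WAASY score, with a
#' rank column for each (average ranks on ties). Stability statistics rank
#' ascending (1 = most stable); the mean and WAASY rank descending (1 =
#' best).
#'
#' @param means a [cell_means] object.
#' @param fit an [ammi_fit()] of `means`; refitted when omitted.
#' @param weight_yield yield weight for WAASY, percent.
#' @param waas_axes axes specification passed to [waas()].
#' @return A `stability_table` data.frame, one row per genotype.
#' @examples
#' tab <- stability_table(cell_means(gsr_yield_means()))
#' tab[order(tab$ASV_rank)[1:3], c("genotype", "mean", "ASV", "Wi2")]
#' @export
stability_table <- function(means, fit = NULL, weight_yield = 50,
                            waas_axes = "all") {
  stopifnot(inherits(means, "cell_means"))
  if (is.null(fit)) fit <- ammi_fit(means)
  wi2 <- wricke_ecovalence(means)
  w <- waas(fit, axes = waas_axes)
  wy <- waasy_ranking(w, means, weight_yield = weight_yield)
  out <- data.frame(
    genotype = rownames(means$means),
    mean = unname(means$row_means),
    ASV = unname(asv(fit)),
    ASI = as.numeric(asi(fit)),
    bi = unname(joint_regression(means)),
    Wi2 = unname(wi2),
    shukla = unname(shukla_variance(wi2, p = means$g, q = means$q)),
    WAAS = unname(w),
    WAASY = wy$waasy,
    waasy_class = wy$class,
    row.names = NULL, stringsAsFactors = FALSE
  )
  asc <- function(x) rank(x, ties.method = "average")
  desc <- function(x) rank(-x, ties.method = "average")
  out$mean_rank <- desc(out$mean)
  out$ASV_rank <- asc(out$ASV)
  out$ASI_rank <- asc(out$ASI)
  out$bi_rank <- asc(abs(out$bi - 1))   # closeness to unit slope
  out$Wi2_rank <- asc(out$Wi2)
  out$shukla_rank <- asc(out$shukla)
  out$WAAS_rank <- asc(out$WAAS)
  out$WAASY_rank <- desc(out$WAASY)
  structure(out, class = c("stability_table", "data.frame"),
            weight_yield = weight_yield)
}

#' Write a stability table as CSV
#'
#' @param x a [stability_table()] data.frame.
#' @param path output file path.
#' @param digits significant digits.
#' @return `path`, invisibly.
#' @export
write_stability <- function(x, path, digits = 6) {
  stopifnot(inherits(x, "stability_table"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) & !grepl("_rank$", names(df))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
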