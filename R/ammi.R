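#' Fit the AMMI model to a cell-means matrix
#'
#' Decomposes the genotype-by-environment cell means as
#' \deqn{\bar X_{ij} = \mu + \alpha_i + \beta_j +
#'       \sum_{k=1}^{K} \lambda_k \gamma_{ik} \delta_{jk} + \varepsilon_{ij},}
#' the additive main effects and multiplicative interaction (AMMI) model:
#' additive genotype and environment effects by marginal means, and the
#' interaction by a singular value decomposition of the doubly-centered
#' matrix \eqn{Z_{ij} = \bar X_{ij} - \bar X_{i.} - \bar X_{.j} + \bar X_{..}}.
#' All \eqn{K = \min(g-1, q-1)} axes are retained, so the reconstruction is
#' exact and \eqn{\varepsilon_{ij} = 0}.
#'
#' Per axis, the share of the interaction sum of squares is
#' \eqn{EP_k = 100\,\lambda_k^2/\sum_m \lambda_m^2}. Because SVD signs are
#' arbitrary, each singular-vector pair is flipped so that the genotype
#' score of largest magnitude on that axis is positive; outputs are thereby
#' reproducible across platforms.
#'
#' @param means a [cell_means] object with at least 3 genotypes and 3
#'   environments.
#' @return An object of class `ammi`: list with `mu`, `genotype_effects`,
#'   `environment_effects`, `lambda` (singular values), `gamma` / `delta`
#'   (orthonormal genotype / environment eigenvectors, g x K and q x K),
#'   `EP` (percent of interaction SS per axis), `K`, and the input `means`.
#' @examples
#' fit <- ammi_fit(cell_means(gsr_yield_means()))
#' round(fit$EP[1:3], 1)
#' @seealso [ammi_scores()], [ammi_anova()], [stability_table()]
#' @export
ammi_fit <- function(means) {
  stopifnot(inherits(means, "cell_means"))
  if (means$g < 3 || means$q < 3) {
    stop_metstab("metstab_error_degenerate",
                 "AMMI needs at least 3 genotypes and 3 environments")
  }
  X <- means$means
  Z <- sweep(sweep(X, 1, means$row_means), 2, means$col_means) + means$grand_mean
  K <- min(means$g - 1L, means$q - 1L)
  sv <- svd(Z)
  lambda <- sv$d[seq_len(K)]
  gamma <- sv$u[, seq_len(K), drop = FALSE]
  delta <- sv$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    i <- which.max(abs(gamma[, k]))
    if (gamma[i, k] < 0) {
      gamma[, k] <- -gamma[, k]
      delta[, k] <- -delta[, k]
    }
  }
  dimnames(gamma) <- list(rownames(X), paste0("IPCA", seq_len(K)))
  dimnames(delta) <- list(colnames(X), paste0("IPCA", seq_len(K)))
  ss <- lambda^2
  EP <- if (sum(ss) > 0) 100 * ss / sum(ss) else rep(0, K)
  structure(
    list(mu = means$grand_mean,
         genotype_effects = means$row_means - means$grand_mean,
         environment_effects = means$col_means - means$grand_mean,
         lambda = lambda, gamma = gamma, delta = delta,
         EP = EP, K = K, interaction = Z, means = means),
    class = "ammi"
  )
}

#' Interaction principal component scores
#'
#' Genotype or environment scores on the AMMI interaction axes under a
#' chosen scaling of the singular values: `"sqrtlam"` (default; symmetric
#' scaling \eqn{\gamma_{ik}\sqrt{\lambda_k}}, the convention behind the
#' stability statistics), `"eigen"` (raw orthonormal eigenvectors) or
#' `"lam"` (full singular value on the chosen side).
#'
#' @param fit an [ammi_fit()] object.
#' @param entity `"genotype"` or `"environment"`.
#' @param scaling `"sqrtlam"`, `"eigen"` or `"lam"`.
#' @param axes number of leading axes to return (default: all).
#' @return A matrix with one row per genotype/environment and columns
#'   `IPCA1..IPCAk`.
#' @export
ammi_scores <- function(fit, entity = c("genotype", "environment"),
                        scaling = c("sqrtlam", "eigen", "lam"),
                        axes = fit$K) {
  stopifnot(inherits(fit, "ammi"))
  entity <- match.arg(entity)
  scaling <- match.arg(scaling)
  axes <- min(axes, fit$K)
  V <- if (entity == "genotype") fit$gamma else fit$delta
  V <- V[, seq_len(axes), drop = FALSE]
  scale_k <- switch(scaling,
                    sqrtlam = sqrt(fit$lambda[seq_len(axes)]),
                    eigen = rep(1, axes),
                    lam = fit$lambda[seq_len(axes)])
  sweep(V, 2, scale_k, `*`)
}

#' Reconstruct cell means from a truncated AMMI model
#'
#' @param fit an [ammi_fit()] object.
#' @param axes number of interaction axes retained (default: all, exact
#'   reconstruction).
#' @return A g x q matrix of fitted cell means.
#' @export
ammi_predict <- function(fit, axes = fit$K) {
  stopifnot(inherits(fit, "ammi"))
  axes <- min(axes, fit$K)
  add <- outer(fit$genotype_effects, fit$environment_effects, `+`) + fit$mu
  if (axes == 0) return(add)
  k <- seq_len(axes)
  add + fit$gamma[, k, drop = FALSE] %*%
    (fit$lambda[k] * t(fit$delta[, k, drop = FALSE]))
}

#' @export
print.ammi <- function(x, ...) {
  cat(sprintf("AMMI fit: %d genotypes x %d environments, %d interaction axes\n",
              x$means$g, x$means$q, x$K))
  ep <- round(x$EP, 1)
  cat("  percent of interaction SS per axis:\n   ",
      paste(sprintf("PC%d: %.1f", seq_along(ep), ep), collapse = "  "), "\n")
  cat(sprintf("  cumulative PC1+PC2: %.1f%%\n", sum(x$EP[1:min(2, x$K)])))
  invisible(x)
}

#' AMMI analysis of variance with Gollob F-tests
#'
#' Extends a [combined_anova()] table with one row per interaction
#' principal component axis. On the observation scale the axis sum of
#' squares is \eqn{r\lambda_k^2}; its Gollob degrees of freedom are
#' \eqn{g + q - 1 - 2k}; the F statistic tests the axis mean square against
#' the pooled error mean square. Per-axis interaction proportions and their
#' accumulation are reported alongside. When fewer than all axes are
#' retained, a residual interaction row absorbs the remainder.
#'
#' @param fit an [ammi_fit()] object.
#' @param anova a `met_anova` table from replicate-level data (needed for
#'   the error stratum).
#' @param r replicate count; defaults to the count recorded in `anova`.
#' @param axes number of axes to list (default: all).
#' @return A `met_anova` data.frame with the PC rows inserted between
#'   GEN:ENV and ERROR, plus columns `proportion` and `accumulated`.
#' @export
ammi_anova <- function(fit, anova, r = attr(anova, "r"), axes = fit$K) {
  stopifnot(inherits(fit, "ammi"))
  if (!inherits(anova, "met_anova") || !"ERROR" %in% anova$source) {
    stop_metstab("metstab_error_no_replicates",
                 "ammi_anova needs a combined ANOVA from replicate-level data")
  }
  if (is.null(r)) {
    stop_metstab("metstab_error_no_replicates",
                 "replicate count r is not recorded in the ANOVA table")
  }
  axes <- min(axes, fit$K)
  g <- fit$means$g; q <- fit$means$q
  ems <- anova$MS[anova$source == "ERROR"]
  edf <- anova$df[anova$source == "ERROR"]
  k <- seq_len(axes)
  ss <- r * fit$lambda[k]^2
  df <- g + q - 1 - 2 * k
  ms <- ss / df
  pc <- data.frame(source = paste0("PC", k), df = as.integer(df), SS = ss,
                   MS = ms, F = ms / ems,
                   p = stats::pf(ms / ems, df, edf, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
  if (axes < fit$K) {
    rest <- seq.int(axes + 1L, fit$K)
    rss <- r * sum(fit$lambda[rest]^2)
    rdf <- (g - 1) * (q - 1) - sum(df)
    pc <- rbind(pc, data.frame(source = "PC residual", df = as.integer(rdf),
                               SS = rss, MS = rss / rdf, F = NA_real_,
                               p = NA_real_, stringsAsFactors = FALSE))
  }
  base <- as.data.frame(anova)
  top <- base[base$source != "ERROR" & base$source != "TOTAL", , drop = FALSE]
  bottom <- base[base$source %in% c("ERROR", "TOTAL"), , drop = FALSE]
  out <- rbind(top, pc, bottom)
  out$proportion <- NA_real_
  out$accumulated <- NA_real_
  i <- grepl("^PC[0-9]+$", out$source)
  out$proportion[i] <- fit$EP[k]
  out$accumulated[i] <- cumsum(fit$EP[k])
  structure(out, class = c("met_anova", "data.frame"),
            g = attr(anova, "g"), q = attr(anova, "q"), r = r,
            trait = attr(anova, "trait"))
}
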