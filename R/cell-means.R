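#' Genotype-by-environment cell means
#'
#' Builds the genotype \eqn{\times} environment matrix of replicate means
#' \eqn{\bar X_{ij}} that every downstream stage (AMMI, GGE, the univariate
#' stability statistics) consumes, together with its margins: row means
#' \eqn{\bar X_{i.}}, column means \eqn{\bar X_{.j}} and the grand mean
#' \eqn{\bar X_{..}}.
#'
#' A bare numeric matrix (genotypes in rows, environments in columns) can be
#' supplied directly — the usual situation when only a published means table
#' is available. In that case the replicate count behind each cell is
#' recorded as 1 and operations that need a replicate-level error stratum
#' (e.g. [combined_anova()]) are unavailable.
#'
#' @param x a [trial_data] object or a numeric matrix of means with row and
#'   column names.
#' @param ... passed to methods.
#' @return An object of class `cell_means`: list with `means` (g x q
#'   matrix), `row_means`, `col_means`, `grand_mean`, counts `g`, `q`, `r`,
#'   the `trait` label and the flag `replicated` (TRUE when built from
#'   replicate-level data).
#' @examples
#' cm <- cell_means(gsr_yield_means())
#' round(cm$row_means[1:4])
#' @export
cell_means <- function(x, ...) UseMethod("cell_means")

new_cell_means <- function(X, r, trait, replicated) {
  structure(
    list(means = X,
         row_means = rowMeans(X), col_means = colMeans(X),
         grand_mean = mean(X),
         g = nrow(X), q = ncol(X), r = as.integer(r),
         trait = trait, replicated = replicated),
    class = "cell_means"
  )
}

#' @rdname cell_means
#' @export
cell_means.trial_data <- function(x, ...) {
  X <- tapply(x$records$value, list(x$records$gen, x$records$env), mean)
  X <- matrix(X, nrow = x$g, ncol = x$q,
              dimnames = list(levels(x$records$gen), levels(x$records$env)))
  new_cell_means(X, r = x$r, trait = x$trait, replicated = x$r >= 2)
}

#' @rdname cell_means
#' @param trait trait label for a directly supplied matrix.
#' @export
cell_means.matrix <- function(x, trait = "trait value", ...) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_metstab("metstab_error_values", "cell means must be finite numbers")
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("G", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("E", seq_len(ncol(x)))
  new_cell_means(x, r = 1L, trait = trait, replicated = FALSE)
}

#' @export
print.cell_means <- function(x, ...) {
  cat(sprintf("Cell means: %d genotypes x %d environments (%s)\n",
              x$g, x$q, x$trait))
  cat(sprintf("  replicates behind each cell: %d%s\n", x$r,
              if (x$replicated) "" else " (matrix supplied directly)"))
  cat(sprintf("  grand mean: %.4g\n", x$grand_mean))
  invisible(x)
}

#' Percent yield advantage over a check genotype
#'
#' Signed percent difference of a genotype's pooled mean relative to a check
#' cultivar's pooled mean, `100 * (mean_g / mean_check - 1)` — the usual
#' "percent over/under local check" column of a trial report.
#'
#' @param means a [cell_means] object.
#' @param genotype genotype label(s); `NULL` (default) computes the column
#'   for all genotypes.
#' @param check the check genotype's label.
#' @return A named numeric vector of signed percentages.
#' @examples
#' cm <- cell_means(gsr_yield_means())
#' round(percent_over_check(cm, "G1", check = "G20"), 2)
#' @export
percent_over_check <- function(means, genotype = NULL, check) {
  stopifnot(inherits(means, "cell_means"))
  rm <- means$row_means
  if (!check %in% names(rm)) {
    stop_metstab("metstab_error_label", paste0("unknown check genotype: ", check))
  }
  if (is.null(genotype)) genotype <- names(rm)
  if (!all(genotype %in% names(rm))) {
    stop_metstab("metstab_error_label",
                 paste0("unknown genotype(s): ",
                        paste(setdiff(genotype, names(rm)), collapse = ", ")))
  }
  if (rm[[check]] == 0) {
    stop_metstab("metstab_error_degenerate",
                 "check genotype has zero pooled mean; percent is undefined")
  }
  100 * (rm[genotype] / rm[[check]] - 1)
}

#' Write a cell-means matrix as CSV
#'
#' Genotypes in rows, environments in columns, with a final `mean` column
#' (genotype means) and a final `mean` row (environment means; its last cell
#' is the grand mean).
#'
#' @param means a [cell_means] object.
#' @param path output file path.
#' @param digits significant digits used for formatting.
#' @return `path`, invisibly.
#' @export
write_cell_means <- function(means, path, digits = 6) {
  stopifnot(inherits(means, "cell_means"))
  X <- cbind(means$means, mean = means$row_means)
  X <- rbind(X, mean = c(means$col_means, means$grand_mean))
  df <- data.frame(genotype = rownames(X),
                   signif(X, digits),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
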