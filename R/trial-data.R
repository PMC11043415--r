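#' Construct a validated multi-environment trial data set
#'
#' A `trial_data` object holds long-format replicated observations of one
#' trait: one row per (environment, genotype, replicate) with a numeric
#' trait value. The design must be balanced — every genotype observed in
#' every environment with the same number of replicates — because every
#' downstream estimator assumes balance. Imbalance, duplicated keys and
#' non-finite values are rejected with classed errors rather than repaired.
#'
#' @param data a data.frame containing the mapped columns.
#' @param env,gen,rep,value names of the columns holding the environment,
#'   genotype and replicate labels and the trait measurement.
#' @param trait a label for the trait (e.g. `"paddy yield (kg/ha)"`), used
#'   in printouts and reports.
#'
#' @return An object of class `trial_data`: a list with elements `records`
#'   (a data.frame with columns `env`, `gen`, `rep`, `value`), `trait`, and
#'   the design counts `g` (genotypes), `q` (environments), `r` (replicates).
#'
#' @examples
#' df <- expand.grid(env = c("E1", "E2", "E3"), gen = c("G1", "G2", "G3"),
#'                   rep = c("R1", "R2"))
#' df$value <- rnorm(nrow(df), 5000, 300)
#' td <- trial_data(df, trait = "yield (kg/ha)")
#' td$g; td$q; td$r
#' @seealso [read_trial()], [cell_means()], [simulate_trial()]
#' @export
trial_data <- function(data, env = "env", gen = "gen", rep = "rep",
                       value = "value", trait = "trait value") {
  cols <- c(env = env, gen = gen, rep = rep, value = value)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_metstab("metstab_error_columns",
                 paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  rec <- data.frame(
    env = as.character(data[[env]]),
    gen = as.character(data[[gen]]),
    rep = as.character(data[[rep]]),
    value = data[[value]],
    stringsAsFactors = FALSE
  )
  if (nrow(rec) == 0) {
    stop_metstab("metstab_error_empty", "no observations: the trial data set is empty")
  }
  if (!is.numeric(rec$value) || anyNA(rec$value) || any(!is.finite(rec$value))) {
    stop_metstab("metstab_error_values",
                 "trait values must be finite numbers (no NA/NaN/Inf/non-numeric)")
  }
  key <- paste(rec$env, rec$gen, rec$rep, sep = "\r")
  if (anyDuplicated(key)) {
    first <- rec[which(duplicated(key))[1L], ]
    stop_metstab("metstab_error_duplicate",
                 sprintf("duplicated (environment, genotype, replicate) key: (%s, %s, %s)",
                         first$env, first$gen, first$rep))
  }
  # level order = order of first appearance, so output tables follow the file
  rec$env <- factor(rec$env, levels = unique(rec$env))
  rec$gen <- factor(rec$gen, levels = unique(rec$gen))
  rec$rep <- factor(rec$rep, levels = unique(rec$rep))

  counts <- table(rec$env, rec$gen)
  r <- counts[1L, 1L]
  if (any(counts != r)) {
    bad <- which(counts != r, arr.ind = TRUE)[1L, ]
    stop_metstab("metstab_error_balance",
                 sprintf(paste0("unbalanced design: cell (%s, %s) has %d replicate(s) ",
                                "while (%s, %s) has %d"),
                         rownames(counts)[bad[1L]], colnames(counts)[bad[2L]],
                         counts[bad[1L], bad[2L]],
                         rownames(counts)[1L], colnames(counts)[1L], r))
  }
  structure(
    list(records = rec, trait = trait,
         g = nlevels(rec$gen), q = nlevels(rec$env), r = as.integer(r)),
    class = "trial_data"
  )
}

#' Read a multi-environment trial from a delimited text file
#'
#' Reads a CSV/TSV file with a header row and builds a validated
#' [trial_data] object. Column names are configurable; the defaults are
#' `env`, `gen`, `rep`, `value`. The decimal separator is `.` and the file
#' is read as UTF-8.
#'
#' @param path path to the file.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param trait trait label; defaults to the name of the value column.
#' @inheritParams trial_data
#' @return A [trial_data] object.
#' @export
read_trial <- function(path, env = "env", gen = "gen", rep = "rep",
                       value = "value", trait = value, sep = ",") {
  if (!file.exists(path)) {
    stop_metstab("metstab_error_file", paste0("file not found: ", path))
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                      stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) {
      stop_metstab("metstab_error_empty",
                   paste0("could not parse '", path, "': ", conditionMessage(e)))
    }
  )
  trial_data(df, env = env, gen = gen, rep = rep, value = value, trait = trait)
}

#' Write trial data back to a delimited text file
#'
#' Writes the long-format records with columns `env`, `gen`, `rep`, `value`
#' at full precision, so that `read_trial(write_trial(x, f))` round-trips
#' every record.
#'
#' @param x a [trial_data] object.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trial <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "trial_data"))
  rec <- x$records
  rec$value <- format(rec$value, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(rec, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.trial_data <- function(x, ...) {
  cat("Multi-environment trial data\n")
  cat(sprintf("  trait      : %s\n", x$trait))
  cat(sprintf("  genotypes  : %d\n", x$g))
  cat(sprintf("  environments: %d\n", x$q))
  cat(sprintf("  replicates : %d (balanced RCBD within each environment)\n", x$r))
  cat(sprintf("  observations: %d\n", nrow(x$records)))
  invisible(x)
}
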