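#' Combined analysis of variance across environments
#'
#' Fits the fixed-effects model for a balanced RCBD trial replicated across
#' environments,
#' \deqn{y_{ijr} = \mu + E_j + R_{r(j)} + G_i + (GE)_{ij} + \varepsilon_{ijr},}
#' with replicates (blocks) nested within environments. The degrees of
#' freedom are \eqn{q-1} (ENV), \eqn{q(r-1)} (REP(ENV)), \eqn{g-1} (GEN),
#' \eqn{(g-1)(q-1)} (GEN:ENV) and \eqn{q(g-1)(r-1)} (ERROR). The
#' environment main effect is tested against the REP(ENV) stratum; REP(ENV),
#' GEN and GEN:ENV are tested against the pooled error.
#'
#' @param data a balanced [trial_data] object with at least two replicates.
#' @return A `met_anova` object: a data.frame with columns `source`, `df`,
#'   `SS`, `MS`, `F`, `p` and rows ENV, REP(ENV), GEN, GEN:ENV, ERROR,
#'   TOTAL. The design counts are attached as attributes `g`, `q`, `r`.
#' @examples
#' sim <- simulate_trial(simulation_config(g = 5, q = 4, r = 3, seed = 1))
#' combined_anova(sim$data)
#' @seealso [variance_components()], [ammi_anova()]
#' @export
combined_anova <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  if (data$r < 2) {
    stop_metstab("metstab_error_reps",
                 "combined ANOVA needs r >= 2 replicates for an error stratum")
  }
  fit <- stats::aov(value ~ env + env:rep + gen + gen:env, data = data$records)
  tab <- summary(fit)[[1L]]
  rn <- trimws(rownames(tab))
  pick <- function(term) {
    i <- match(term, rn)
    c(df = tab[i, "Df"], SS = tab[i, "Sum Sq"])
  }
  rows <- rbind(
    ENV = pick("env"),
    `REP(ENV)` = pick("env:rep"),
    GEN = pick("gen"),
    `GEN:ENV` = pick("env:gen"),
    ERROR = pick("Residuals")
  )
  out <- data.frame(source = rownames(rows), df = as.integer(rows[, "df"]),
                    SS = rows[, "SS"], row.names = NULL,
                    stringsAsFactors = FALSE)
  out$MS <- out$SS / out$df
  ems <- out$MS[out$source == "ERROR"]
  rep_ms <- out$MS[out$source == "REP(ENV)"]
  edf <- out$df[out$source == "ERROR"]
  rdf <- out$df[out$source == "REP(ENV)"]
  out$F <- NA_real_
  out$p <- NA_real_
  # ENV tested against the block stratum, everything else against pooled error
  i <- out$source == "ENV"
  out$F[i] <- out$MS[i] / rep_ms
  out$p[i] <- stats::pf(out$F[i], out$df[i], rdf, lower.tail = FALSE)
  for (src in c("REP(ENV)", "GEN", "GEN:ENV")) {
    i <- out$source == src
    out$F[i] <- out$MS[i] / ems
    out$p[i] <- stats::pf(out$F[i], out$df[i], edf, lower.tail = FALSE)
  }
  total <- data.frame(source = "TOTAL", df = sum(out$df), SS = sum(out$SS),
                      MS = sum(out$SS) / sum(out$df), F = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  structure(out, class = c("met_anova", "data.frame"),
            g = data$g, q = data$q, r = data$r, trait = data$trait)
}

#' @export
print.met_anova <- function(x, ...) {
  cat("Combined ANOVA", if (!is.null(attr(x, "trait"))) paste0("(", attr(x, "trait"), ")"), "\n")
  y <- as.data.frame(x)
  y$SS <- signif(y$SS, 6); y$MS <- signif(y$MS, 6)
  y$F <- signif(y$F, 4); y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write an ANOVA table as CSV
#'
#' @param anova a `met_anova` object (from [combined_anova()] or
#'   [ammi_anova()]).
#' @param path output file path.
#' @param digits significant digits.
#' @return `path`, invisibly.
#' @export
write_anova <- function(anova, path, digits = 6) {
  stopifnot(inherits(anova, "met_anova"))
  df <- as.data.frame(anova)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "df"
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
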