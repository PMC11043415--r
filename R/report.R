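#' Run the full MET analysis and write a report directory
#'
#' Ties the stages together: validates the input, builds the cell means and
#' runs the requested analyses in dependency order (`anova` before
#' `genetics`, `ammi` before `stability`), writing one delimited file per
#' stage plus a checksum manifest. Outputs are deterministic for a fixed
#' input and configuration, so re-running reproduces byte-identical files.
#'
#' @param input a [trial_data] object, a [cell_means] object, a numeric
#'   means matrix, or a path to a long-format CSV readable by
#'   [read_trial()].
#' @param analyses subset of `c("anova", "genetics", "ammi", "stability",
#'   "gge")`; defaults to all that the input supports.
#' @param out_dir output directory (created if missing).
#' @param waasy_ratio yield weight (percent) for the WAASY blend.
#' @param svp singular-value partitioning mode for the GGE stage.
#' @param waas_axes axes specification for WAAS (see [waas()]).
#' @param digits significant digits for numbers in the report files.
#' @param trait trait label used when `input` is a bare matrix or path.
#' @param quiet suppress the per-stage log lines.
#' @return Invisibly, the manifest data.frame (`file`, `md5`), also written
#'   to `manifest.csv` in `out_dir`.
#' @examples
#' dir <- tempfile("report")
#' manifest <- met_run(gsr_yield_means(), out_dir = dir, quiet = TRUE)
#' manifest$file
#' @export
met_run <- function(input,
                    analyses = c("anova", "genetics", "ammi", "stability", "gge"),
                    out_dir = "met-report", waasy_ratio = 50,
                    svp = "symmetric", waas_axes = "all", digits = 6,
                    trait = "trait value", quiet = FALSE) {
  known <- c("anova", "genetics", "ammi", "stability", "gge")
  bad <- setdiff(analyses, known)
  if (length(bad) > 0) {
    stop_metstab("metstab_error_config",
                 paste0("unknown analysis name(s): ", paste(bad, collapse = ", "),
                        " (choose from ", paste(known, collapse = ", "), ")"))
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, metstab_error = function(e) {
      stop_metstab(class(e)[1L],
                   sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    say("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - s)
    out
  }

  data <- NULL
  if (is.character(input)) input <- read_trial(input, trait = trait)
  if (inherits(input, "trial_data")) {
    data <- input
    means <- cell_means(data)
  } else if (inherits(input, "cell_means")) {
    means <- input
  } else if (is.matrix(input)) {
    means <- cell_means(input, trait = trait)
  } else {
    stop_metstab("metstab_error_config",
                 "input must be trial data, cell means, a matrix, or a file path")
  }
  needs_reps <- intersect(analyses, c("anova", "genetics"))
  if (length(needs_reps) > 0 && (is.null(data) || data$r < 2)) {
    stop_metstab("metstab_error_no_replicates",
                 paste0("analyses {", paste(needs_reps, collapse = ", "),
                        "} need replicate-level data; a means matrix only supports ",
                        "ammi, stability and gge"))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(fname) files[[length(files) + 1L]] <<- fname

  write_cell_means(means, file.path(out_dir, "cell_means.csv"), digits)
  emit("cell_means.csv")

  anova <- NULL
  if ("anova" %in% analyses || "genetics" %in% analyses) {
    anova <- stage("anova", combined_anova(data))
  }
  if ("anova" %in% analyses) {
    write_anova(anova, file.path(out_dir, "anova.csv"), digits)
    emit("anova.csv")
  }
  if ("genetics" %in% analyses) {
    vc <- stage("genetics", variance_components(anova))
    df <- as.data.frame(vc)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = digits)
    utils::write.csv(df, file.path(out_dir, "genetics.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("genetics.csv")
  }
  fit <- NULL
  if ("ammi" %in% analyses || "stability" %in% analyses) {
    fit <- stage("ammi", ammi_fit(means))
  }
  if ("ammi" %in% analyses) {
    sc <- rbind(
      data.frame(entity = "genotype",
                 label = rownames(fit$gamma),
                 signif(ammi_scores(fit, "genotype"), digits)),
      data.frame(entity = "environment",
                 label = rownames(fit$delta),
                 signif(ammi_scores(fit, "environment"), digits))
    )
    utils::write.csv(sc, file.path(out_dir, "ammi_scores.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("ammi_scores.csv")
    if (!is.null(anova)) {
      write_anova(ammi_anova(fit, anova),
                  file.path(out_dir, "ammi_anova.csv"), digits)
      emit("ammi_anova.csv")
    }
  }
  if ("stability" %in% analyses) {
    tab <- stage("stability",
                 stability_table(means, fit, weight_yield = waasy_ratio,
                                 waas_axes = waas_axes))
    write_stability(tab, file.path(out_dir, "stability.csv"), digits)
    emit("stability.csv")
  }
  if ("gge" %in% analyses) {
    model <- stage("gge", gge_fit(means, svp = svp))
    write_gge(model, file.path(out_dir, "gge_coords.csv"),
              file.path(out_dir, "gge_geometry.json"), digits)
    emit("gge_coords.csv")
    emit("gge_geometry.json")
  }

  paths <- file.path(out_dir, files)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  say("wrote %d files to %s in %.2fs", length(files) + 1L, out_dir,
      proc.time()[["elapsed"]] - t0)
  invisible(manifest)
}
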