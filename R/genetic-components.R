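#' Variance components and broad-sense heritability from mean squares
#'
#' Estimates the genotypic, environmental and phenotypic variance components
#' and broad-sense heritability from the genotype mean square (GMS) and the
#' error mean square (EMS) of a combined ANOVA:
#' \deqn{\hat\sigma^2_g = (GMS - EMS)/r, \quad \hat\sigma^2_e = EMS/r,}
#' \deqn{\hat\sigma^2_p = \hat\sigma^2_g + \hat\sigma^2_e, \quad
#'       h^2_B = 100\,\hat\sigma^2_g/\hat\sigma^2_p .}
#'
#' The default divisor for \eqn{\hat\sigma^2_g} is `r` alone — the
#' convention used in many trial reports, where the "genotypic variance" is
#' on the scale of genotype means pooled over environments times the number
#' of environments. The textbook across-environment divisor `r * q` is
#' available via `divisor = "rq"`.
#'
#' Negative \eqn{\hat\sigma^2_g} estimates (GMS < EMS) are reported as-is,
#' never clamped to zero; the returned table flags them in the
#' `negative_sigma2_g` column and a warning is emitted.
#'
#' @param gms,ems genotype and error mean squares; vectors (optionally
#'   named by trait) are accepted.
#' @param r replicate count.
#' @param q environment count; only needed for `divisor = "rq"`.
#' @param divisor `"r"` (default) or `"rq"`.
#' @param trait optional trait labels (recycled against `gms`).
#' @return A `genetic_components` data.frame with columns `trait`,
#'   `sigma2_g`, `sigma2_e`, `sigma2_p`, `h2_broad` (percent) and
#'   `negative_sigma2_g`.
#' @examples
#' # plant height in the packaged rice trial: GMS = 2152.1, EMS = 30.12
#' genetic_components(2152.1, 30.12, r = 3)
#' @seealso [variance_components()] for the ANOVA-table interface.
#' @export
genetic_components <- function(gms, ems, r, q = NULL,
                               divisor = c("r", "rq"), trait = NULL) {
  divisor <- match.arg(divisor)
  stopifnot(length(gms) == length(ems), r >= 1)
  if (divisor == "rq" && is.null(q)) {
    stop_metstab("metstab_error_config", "divisor = \"rq\" needs the environment count q")
  }
  den <- if (divisor == "r") r else r * q
  sigma2_g <- (gms - ems) / den
  sigma2_e <- ems / r
  sigma2_p <- sigma2_g + sigma2_e
  if (any(sigma2_p == 0)) {
    stop_metstab("metstab_error_degenerate",
                 "phenotypic variance is zero; heritability is undefined")
  }
  h2 <- 100 * sigma2_g / sigma2_p
  neg <- sigma2_g < 0
  if (any(neg)) {
    warning("negative genotypic variance estimate (GMS < EMS); reported as-is")
  }
  if (is.null(trait)) {
    trait <- if (!is.null(names(gms))) names(gms) else
      paste0("trait", seq_along(gms))
  }
  structure(
    data.frame(trait = trait, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
               sigma2_p = sigma2_p, h2_broad = h2, negative_sigma2_g = neg,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("genetic_components", "data.frame"), r = r, divisor = divisor
  )
}

#' Variance components from a combined ANOVA table
#'
#' Convenience wrapper extracting the GEN and ERROR mean squares from a
#' [combined_anova()] table and applying [genetic_components()].
#'
#' @param anova a `met_anova` object containing GEN and ERROR rows.
#' @param r replicate count; defaults to the count recorded in `anova`.
#' @inheritParams genetic_components
#' @return A `genetic_components` data.frame (one row).
#' @export
variance_components <- function(anova, r = attr(anova, "r"),
                                divisor = c("r", "rq")) {
  stopifnot(inherits(anova, "met_anova"))
  divisor <- match.arg(divisor)
  src <- anova$source
  if (!all(c("GEN", "ERROR") %in% src)) {
    stop_metstab("metstab_error_config",
                 "ANOVA table must contain GEN and ERROR rows")
  }
  if (is.null(r)) {
    stop_metstab("metstab_error_config", "replicate count r is not available")
  }
  genetic_components(anova$MS[src == "GEN"], anova$MS[src == "ERROR"],
                     r = r, q = attr(anova, "q"), divisor = divisor,
                     trait = attr(anova, "trait"))
}
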