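#' Fit a GGE model (environment-centered SVD)
#'
#' Centers each environment column of the cell-means matrix by its mean,
#' \eqn{Y_{ij} = \bar X_{ij} - \bar X_{.j}}, so that the matrix holds the
#' genotype main effect plus the genotype-by-environment interaction (G +
#' GE), and decomposes it by SVD. Biplot coordinates for the first two axes
#' are produced under a singular-value partitioning (SVP) mode:
#'
#' * `"symmetric"` (default): \eqn{\sqrt{\lambda}} to both sides,
#' * `"genotype"`: full \eqn{\lambda} on the genotype side (genotype-metric),
#' * `"environment"`: full \eqn{\lambda} on the environment side.
#'
#' The rank-2 approximation \eqn{G E^\top} is identical under every mode.
#' No scaling by environment standard deviations is applied. Axis signs are
#' fixed by flipping each axis so the environment coordinate of largest
#' magnitude is positive.
#'
#' @param means a [cell_means] object with g >= 3 and q >= 3.
#' @param svp singular-value partitioning mode.
#' @return An object of class `gge`: list with the centered matrix `Y`,
#'   singular values `d`, full eigenvector matrices `u`, `v`, 2-column
#'   coordinate matrices `gcoord`, `ecoord`, `pc_percent` (percent of total
#'   variability per axis) and `svp`.
#' @examples
#' mod <- gge_fit(cell_means(gsr_yield_means()))
#' round(sum(mod$pc_percent[1:2]), 2)
#' @seealso [which_won_where()], [mean_vs_stability()],
#'   [discrimination_representativeness()], [rank_ideal()]
#' @export
gge_fit <- function(means, svp = c("symmetric", "genotype", "environment")) {
  stopifnot(inherits(means, "cell_means"))
  svp <- match.arg(svp)
  if (means$g < 3 || means$q < 3) {
    stop_metstab("metstab_error_degenerate",
                 "GGE needs at least 3 genotypes and 3 environments")
  }
  Y <- sweep(means$means, 2, means$col_means)
  sv <- svd(Y)
  K <- min(means$g - 1L, means$q)  # column centering removes one dimension
  d <- sv$d[seq_len(K)]
  u <- sv$u[, seq_len(K), drop = FALSE]
  v <- sv$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  rownames(u) <- rownames(Y); rownames(v) <- colnames(Y)
  ss <- d^2
  pc_percent <- if (sum(ss) > 0) 100 * ss / sum(ss) else rep(0, K)
  gs <- switch(svp, symmetric = sqrt(d[1:2]), genotype = d[1:2],
               environment = c(1, 1))
  es <- switch(svp, symmetric = sqrt(d[1:2]), genotype = c(1, 1),
               environment = d[1:2])
  gcoord <- sweep(u[, 1:2, drop = FALSE], 2, gs, `*`)
  ecoord <- sweep(v[, 1:2, drop = FALSE], 2, es, `*`)
  colnames(gcoord) <- colnames(ecoord) <- c("PC1", "PC2")
  structure(
    list(Y = Y, d = d, u = u, v = v, gcoord = gcoord, ecoord = ecoord,
         pc_percent = pc_percent, svp = svp, means = means),
    class = "gge"
  )
}

#' @export
print.gge <- function(x, ...) {
  cat(sprintf("GGE model (%s SVP): %d genotypes x %d environments\n",
              x$svp, nrow(x$gcoord), nrow(x$ecoord)))
  cat(sprintf("  PC1: %.2f%%  PC2: %.2f%%  (PC1+PC2: %.2f%%)\n",
              x$pc_percent[1], x$pc_percent[2], sum(x$pc_percent[1:2])))
  invisible(x)
}

# Unit vector of the average-environment axis (AEA): the direction of the
# mean environment vector in the rank-2 biplot plane.
aea_vector <- function(model) {
  a <- colMeans(model$ecoord)
  len <- sqrt(sum(a^2))
  if (len == 0) {
    stop_metstab("metstab_error_degenerate",
                 "zero-length average-environment vector")
  }
  a / len
}

#' Which-won-where geometry of a GGE biplot
#'
#' Builds the convex hull of the genotype points in the rank-2 biplot
#' plane, draws the sector boundary rays from the origin perpendicular to
#' each hull edge, assigns each environment to a sector by angle, and names
#' the winning (vertex) genotype of each occupied sector. An environment
#' falling exactly on a boundary ray is assigned to the counter-clockwise
#' sector.
#'
#' @param model a [gge_fit()] object.
#' @return An object of class `gge_geometry`: list with `hull` (vertex
#'   genotype labels in counter-clockwise order), `rays` (unit boundary-ray
#'   directions with their angles; ray i separates vertex i from vertex
#'   i+1), `environments` (data.frame with `environment`, `angle`, `sector`
#'   = winning vertex label), and `winners` (data.frame of occupied sectors:
#'   `winner`, `environments`). Collinear genotype points make the sector
#'   construction degenerate; this is reported via `degenerate = TRUE` and
#'   an explanatory `reason` instead of sectors.
#' @examples
#' geom <- which_won_where(gge_fit(cell_means(gsr_yield_means())))
#' subset(geom$environments, environment == "E6")
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gge"))
  P <- model$gcoord
  hull <- grDevices::chull(P)           # clockwise order
  hull <- rev(hull)                     # counter-clockwise
  if (length(hull) < 3 || qr(sweep(P, 2, colMeans(P)))$rank < 2) {
    return(structure(list(degenerate = TRUE,
                          reason = "genotype points are collinear; hull has no interior",
                          hull = rownames(P)[hull]),
                     class = "gge_geometry"))
  }
  nh <- length(hull)
  V <- P[hull, , drop = FALSE]
  # boundary ray between vertex i and vertex i+1: perpendicular from the
  # origin to the edge V_i -> V_{i+1}; equal-projection direction, pointing
  # outward (origin is the centroid of the genotype points, hence inside)
  rays <- t(vapply(seq_len(nh), function(i) {
    a <- V[i, ]; b <- V[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    n <- c(e[2], -e[1])                 # outward normal for ccw order
    if (sum(n * a) < 0) n <- -n
    n / sqrt(sum(n^2))
  }, numeric(2)))
  ray_angle <- atan2(rays[, 2], rays[, 1]) %% (2 * pi)
  env_angle <- atan2(model$ecoord[, 2], model$ecoord[, 1]) %% (2 * pi)

  # vertex i owns the sector between ray i-1 and ray i (ccw); an angle equal
  # to ray i belongs to the ccw neighbour, vertex i+1
  sector_of <- function(theta) {
    for (i in seq_len(nh)) {
      lo <- ray_angle[if (i == 1L) nh else i - 1L]
      hi <- ray_angle[i]
      inside <- if (lo < hi) theta > lo & theta <= hi else theta > lo | theta <= hi
      if (inside) {
        return(if (theta == hi) (if (i == nh) 1L else i + 1L) else i)
      }
    }
    stop("internal error: angle not covered by any sector")  # nocov
  }
  sec <- vapply(env_angle, sector_of, integer(1))
  env <- data.frame(environment = rownames(model$ecoord),
                    angle = unname(env_angle),
                    sector = rownames(V)[sec],
                    row.names = NULL, stringsAsFactors = FALSE)
  winners <- stats::aggregate(environment ~ sector, data = env,
                              FUN = function(e) paste(e, collapse = ","))
  names(winners) <- c("winner", "environments")
  structure(
    list(degenerate = FALSE, hull = rownames(V),
         rays = data.frame(ray = seq_len(nh), x = rays[, 1], y = rays[, 2],
                           angle = ray_angle),
         environments = env, winners = winners),
    class = "gge_geometry"
  )
}

#' @export
print.gge_geometry <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate which-won-where geometry:", x$reason, "\n")
    return(invisible(x))
  }
  cat("Which-won-where geometry\n")
  cat("  hull vertices (ccw):", paste(x$hull, collapse = ", "), "\n")
  cat("  sector winners:\n")
  for (i in seq_len(nrow(x$winners))) {
    cat(sprintf("    %-6s <- %s\n", x$winners$winner[i], x$winners$environments[i]))
  }
  invisible(x)
}

#' Mean performance versus stability projections
#'
#' Projects each genotype onto the average-environment axis (AEA, the unit
#' vector of the mean environment coordinate): the signed projection
#' measures mean performance, and the orthogonal deviation from the axis
#' measures instability (smaller = more stable).
#'
#' @param model a [gge_fit()] object.
#' @return A data.frame with columns `genotype`, `mean_projection` and
#'   `stability` (absolute orthogonal deviation).
#' @export
mean_vs_stability <- function(model) {
  stopifnot(inherits(model, "gge"))
  u <- aea_vector(model)
  perp <- c(-u[2], u[1])
  proj <- drop(model$gcoord %*% u)
  dev <- abs(drop(model$gcoord %*% perp))
  data.frame(genotype = rownames(model$gcoord),
             mean_projection = unname(proj), stability = unname(dev),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Environment discriminativeness and representativeness
#'
#' Per test environment, the biplot vector length (discriminating power)
#' and the cosine of its angle with the average-environment axis
#' (representativeness of the target set of environments). Environments are
#' classified into quadrants by (length above/below the median length) x
#' (cosine above/below the median cosine).
#'
#' @param model a [gge_fit()] object.
#' @return A data.frame with columns `environment`, `length`, `cosine` and
#'   `quadrant` (one of `"high_disc_high_repr"`, `"high_disc_low_repr"`,
#'   `"low_disc_high_repr"`, `"low_disc_low_repr"`).
#' @export
discrimination_representativeness <- function(model) {
  stopifnot(inherits(model, "gge"))
  u <- aea_vector(model)
  len <- sqrt(rowSums(model$ecoord^2))
  if (any(len == 0)) {
    stop_metstab("metstab_error_degenerate",
                 paste0("zero-length environment vector: ",
                        paste(rownames(model$ecoord)[len == 0], collapse = ", ")))
  }
  cosine <- drop(model$ecoord %*% u) / len
  disc_hi <- len >= stats::median(len)
  repr_hi <- cosine >= stats::median(cosine)
  quad <- paste0(ifelse(disc_hi, "high", "low"), "_disc_",
                 ifelse(repr_hi, "high", "low"), "_repr")
  data.frame(environment = rownames(model$ecoord), length = unname(len),
             cosine = unname(cosine), quadrant = quad,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genotypes or environments by distance to the ideal point
#'
#' In the average-environment coordinate frame, the ideal genotype sits on
#' the average-environment axis at the maximal genotype projection with
#' zero deviation; the ideal environment sits on the axis at the maximal
#' environment vector length. Entries are ranked by Euclidean distance to
#' the ideal point (ascending; ties share an average rank).
#'
#' @param model a [gge_fit()] object.
#' @param target `"genotypes"` or `"environments"`.
#' @return A data.frame ordered by distance, with columns `label`,
#'   `distance`, `rank`.
#' @export
rank_ideal <- function(model, target = c("genotypes", "environments")) {
  stopifnot(inherits(model, "gge"))
  target <- match.arg(target)
  u <- aea_vector(model)
  perp <- c(-u[2], u[1])
  if (target == "genotypes") {
    C <- model$gcoord
    ideal <- c(max(drop(C %*% u)), 0)
  } else {
    C <- model$ecoord
    ideal <- c(max(sqrt(rowSums(C^2))), 0)
  }
  fr <- cbind(drop(C %*% u), drop(C %*% perp))
  dist <- sqrt((fr[, 1] - ideal[1])^2 + (fr[, 2] - ideal[2])^2)
  out <- data.frame(label = rownames(C), distance = unname(dist),
                    rank = rank(dist, ties.method = "average"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Write GGE coordinates and geometry to files
#'
#' Writes the rank-2 biplot coordinates (genotypes and environments, with
#' the axis variance percents) as CSV, and optionally the which-won-where
#' geometry plus projections as JSON.
#'
#' @param model a [gge_fit()] object.
#' @param coords_path CSV output path for coordinates.
#' @param geometry_path optional JSON output path for the derived geometry.
#' @param digits significant digits for the CSV.
#' @return `coords_path`, invisibly.
#' @export
write_gge <- function(model, coords_path, geometry_path = NULL, digits = 6) {
  stopifnot(inherits(model, "gge"))
  co <- rbind(
    data.frame(entity = "genotype", label = rownames(model$gcoord),
               PC1 = model$gcoord[, 1], PC2 = model$gcoord[, 2]),
    data.frame(entity = "environment", label = rownames(model$ecoord),
               PC1 = model$ecoord[, 1], PC2 = model$ecoord[, 2])
  )
  co$PC1 <- signif(co$PC1, digits); co$PC2 <- signif(co$PC2, digits)
  utils::write.csv(co, coords_path, row.names = FALSE, quote = FALSE)
  if (!is.null(geometry_path)) {
    geom <- which_won_where(model)
    payload <- list(
      svp = model$svp,
      pc_percent = model$pc_percent[1:2],
      which_won_where = unclass(geom),
      mean_vs_stability = mean_vs_stability(model),
      discrimination_representativeness =
        discrimination_representativeness(model),
      rank_genotypes = rank_ideal(model, "genotypes"),
      rank_environments = rank_ideal(model, "environments")
    )
    jsonlite::write_json(payload, geometry_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(coords_path)
}
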