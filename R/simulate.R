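#' Configuration for a simulated multi-environment trial
#'
#' Describes a balanced RCBD trial replicated across environments with
#' additive genotype and environment effects, a low-rank bilinear
#' genotype-by-environment interaction, replicate-within-environment
#' (block) effects and i.i.d. Gaussian noise:
#' \deqn{y_{ijr} = \mu + g_i + e_j +
#'       \sum_k \lambda^*_k \gamma^*_{ik} \delta^*_{jk} + b_{r(j)} +
#'       \varepsilon_{ijr}.}
#' The interaction eigenvectors \eqn{\gamma^*, \delta^*} are drawn exactly
#' centered and orthonormal, so the generative model is a true rank-
#' \eqn{K^*} AMMI truth and the interaction weights define the exact
#' per-axis shares \eqn{EP^*_k = 100\lambda^{*2}_k/\sum\lambda^{*2}}.
#'
#' The defaults emulate a 20-genotype x 12-location x 3-replicate rice
#' yield trial (units kg/ha): grand mean 6700, genotype SD 300, environment
#' SD 1600, block-within-environment SD 1300, plot noise SD 1150, and a
#' rank-2 interaction with weights 7500 and 6300 on the cell-means scale.
#'
#' @param g,q,r genotype, environment and replicate counts.
#' @param mu grand mean (trait units).
#' @param sd_gen,sd_env,sd_rep,sd_noise standard deviations of the
#'   genotype, environment, replicate-within-environment and residual
#'   effects (trait units, all >= 0).
#' @param interaction_rank number of interaction axes \eqn{K^*}
#'   (`0 <= K* <= min(g-1, q-1)`, minus one more when
#'   `zero_interaction_genotype` is set).
#' @param interaction_weights non-increasing vector of \eqn{\lambda^*_k},
#'   length `interaction_rank`.
#' @param zero_interaction_genotype if TRUE, the first genotype is
#'   constructed with exactly zero interaction (all its \eqn{\gamma^*}
#'   entries are 0), giving a genotype with known true ecovalence 0 and
#'   true joint-regression slope 1.
#' @param seed integer seed; the same configuration always generates the
#'   identical data set.
#' @return A validated `simulation_config` object (a list).
#' @examples
#' cfg <- simulation_config(seed = 42)
#' sim <- simulate_trial(cfg)
#' sim$data
#' @export
simulation_config <- function(g = 20, q = 12, r = 3, mu = 6700,
                              sd_gen = 300, sd_env = 1600, sd_rep = 1300,
                              sd_noise = 1150, interaction_rank = 2,
                              interaction_weights = c(7500, 6300),
                              zero_interaction_genotype = FALSE,
                              seed = 1L) {
  ok <- g >= 2 && q >= 2 && r >= 1 &&
    all(c(sd_gen, sd_env, sd_rep, sd_noise) >= 0) &&
    interaction_rank >= 0 && length(seed) == 1 && is.finite(seed)
  if (!ok) {
    stop_metstab("metstab_error_config", "invalid simulation configuration")
  }
  max_rank <- min(g - 1L, q - 1L) - if (zero_interaction_genotype) 1L else 0L
  if (interaction_rank > max_rank) {
    stop_metstab("metstab_error_config",
                 sprintf("interaction_rank must be <= %d for this design", max_rank))
  }
  if (interaction_rank > 0) {
    if (length(interaction_weights) != interaction_rank ||
        any(interaction_weights < 0) ||
        is.unsorted(rev(interaction_weights))) {
      stop_metstab("metstab_error_config",
                   "interaction_weights must be non-negative, non-increasing, one per axis")
    }
  }
  structure(list(g = as.integer(g), q = as.integer(q), r = as.integer(r),
                 mu = mu, sd_gen = sd_gen, sd_env = sd_env, sd_rep = sd_rep,
                 sd_noise = sd_noise,
                 interaction_rank = as.integer(interaction_rank),
                 interaction_weights = if (interaction_rank > 0)
                   as.numeric(interaction_weights) else numeric(0),
                 zero_interaction_genotype = isTRUE(zero_interaction_genotype),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Orthonormal columns, each exactly centered (orthogonal to the constant
# vector); optionally with a leading zero row so one entry carries no
# interaction. QR of a column-centered Gaussian matrix stays inside the
# centered subspace, so orthonormality and centering hold simultaneously.
centered_orthonormal <- function(n, k, zero_first = FALSE) {
  if (k == 0) return(matrix(0, n, 0))
  m <- if (zero_first) n - 1L else n
  M <- matrix(stats::rnorm(m * k), m, k)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))[, seq_len(k), drop = FALSE]
  if (zero_first) Q <- rbind(0, Q)
  Q
}

#' Simulate a balanced replicated multi-environment trial
#'
#' Draws one trial from a [simulation_config()] and returns both the data
#' (a validated [trial_data] object) and the full truth record. The state
#' of R's random number generator is saved and restored, so simulation is a
#' pure function of the configuration.
#'
#' @param config a [simulation_config()] object.
#' @return A list with `data` (a [trial_data]) and `truth` (the drawn
#'   genotype/environment/block effects, the interaction eigenvectors and
#'   weights, the exact per-axis interaction shares `EP`, and the
#'   configuration).
#' @seealso [recovery_suite()], [write_truth()]
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  g <- config$g; q <- config$q; r <- config$r
  gen_eff <- stats::rnorm(g, 0, config$sd_gen)
  env_eff <- stats::rnorm(q, 0, config$sd_env)
  rep_eff <- matrix(stats::rnorm(q * r, 0, config$sd_rep), q, r)
  K <- config$interaction_rank
  gamma <- centered_orthonormal(g, K, config$zero_interaction_genotype)
  delta <- centered_orthonormal(q, K)
  inter <- if (K > 0) {
    gamma %*% (config$interaction_weights * t(delta))
  } else matrix(0, g, q)
  gen_lab <- sprintf("G%d", seq_len(g))
  env_lab <- sprintf("E%d", seq_len(q))
  rep_lab <- sprintf("R%d", seq_len(r))
  grid <- expand.grid(gen = seq_len(g), env = seq_len(q), rep = seq_len(r),
                      KEEP.OUT.ATTRS = FALSE)
  value <- config$mu + gen_eff[grid$gen] + env_eff[grid$env] +
    inter[cbind(grid$gen, grid$env)] +
    rep_eff[cbind(grid$env, grid$rep)] +
    stats::rnorm(nrow(grid), 0, config$sd_noise)
  df <- data.frame(env = env_lab[grid$env], gen = gen_lab[grid$gen],
                   rep = rep_lab[grid$rep], value = value,
                   stringsAsFactors = FALSE)
  truth <- list(
    config = config,
    genotype_effects = stats::setNames(gen_eff, gen_lab),
    environment_effects = stats::setNames(env_eff, env_lab),
    rep_effects = `dimnames<-`(rep_eff, list(env_lab, rep_lab)),
    gamma = gamma, delta = delta,
    interaction_weights = config$interaction_weights,
    interaction_means = inter,
    EP = if (K > 0) 100 * config$interaction_weights^2 /
      sum(config$interaction_weights^2) else numeric(0)
  )
  list(data = trial_data(df, trait = "simulated trait"), truth = truth)
}

#' Write a simulation truth record as JSON
#'
#' @param truth the `truth` element returned by [simulate_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  payload <- truth
  payload$config <- unclass(payload$config)
  payload$gamma <- as.data.frame(payload$gamma)
  payload$delta <- as.data.frame(payload$delta)
  payload$interaction_means <- as.data.frame(payload$interaction_means)
  payload$rep_effects <- as.data.frame(payload$rep_effects)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Truth-implied broad-sense heritability for a simulation design
#'
#' Applies the heritability estimator's formula to the expected mean
#' squares of the generative model: the genotype mean square has
#' expectation \eqn{\sigma^2_{noise} + qr\sigma^2_g} and the error mean
#' square \eqn{\sigma^2_{noise}}, so the divisor-`r` estimators converge to
#' \eqn{\hat\sigma^2_g \to q\sigma^2_g} and
#' \eqn{\hat\sigma^2_e \to \sigma^2_{noise}/r}, giving
#' \deqn{h^2_B \to \frac{100\, q\sigma^2_g}{q\sigma^2_g + \sigma^2_{noise}/r}.}
#'
#' @param config a [simulation_config()] object.
#' @return The implied heritability in percent.
#' @export
implied_heritability <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  s2g <- config$q * config$sd_gen^2
  s2e <- config$sd_noise^2 / config$r
  100 * s2g / (s2g + s2e)
}

#' Repeated simulate-and-analyze estimator check
#'
#' Simulates `reps` independent trials from a configuration (seeds
#' `config$seed, config$seed + 1, ...`), runs the full analysis on each and
#' summarizes the sampling distribution of the key estimators: broad-sense
#' heritability, the first interaction axis share \eqn{EP_1}, and — when
#' the configuration carries a zero-interaction genotype — that genotype's
#' joint-regression slope (truth 1) and ecovalence (truth 0; its noise-only
#' expectation on the cell-means scale is
#' \eqn{(q-1)(g-1)/g \cdot \sigma^2_{noise}/r}).
#'
#' @param config a [simulation_config()] object.
#' @param reps number of simulated trials (>= 50).
#' @return A `recovery_suite` data.frame with one row per statistic:
#'   `statistic`, `mean`, `sd`, `se`, `truth` (NA where no closed-form
#'   truth applies).
#' @export
recovery_suite <- function(config, reps = 200) {
  stopifnot(inherits(config, "simulation_config"))
  if (reps < 50) {
    stop_metstab("metstab_error_config", "recovery_suite needs reps >= 50")
  }
  h2 <- ep1 <- b1 <- w1 <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sim <- simulate_trial(cfg)
    cm <- cell_means(sim$data)
    an <- combined_anova(sim$data)
    h2[i] <- variance_components(an)$h2_broad
    ep1[i] <- ammi_fit(cm)$EP[1]
    b1[i] <- joint_regression(cm)[1]
    w1[i] <- wricke_ecovalence(cm)[1]
  }
  g <- config$g; q <- config$q; r <- config$r
  zero <- config$zero_interaction_genotype
  stats_list <- list(
    h2_broad = list(x = h2, truth = implied_heritability(config)),
    EP1 = list(x = ep1,
               truth = if (config$interaction_rank > 0 && config$sd_noise == 0)
                 100 * config$interaction_weights[1]^2 /
                   sum(config$interaction_weights^2) else NA_real_),
    b_G1 = list(x = b1, truth = if (zero) 1 else NA_real_),
    Wi2_G1 = list(x = w1, truth = if (zero)
      (q - 1) * (g - 1) / g * config$sd_noise^2 / r else NA_real_)
  )
  out <- do.call(rbind, lapply(names(stats_list), function(nm) {
    s <- stats_list[[nm]]
    data.frame(statistic = nm, mean = mean(s$x), sd = stats::sd(s$x),
               se = stats::sd(s$x) / sqrt(reps), truth = s$truth,
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("recovery_suite", "data.frame"), reps = reps)
}
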