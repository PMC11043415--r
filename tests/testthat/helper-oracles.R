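# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use explicit loops / alternative decompositions so they share
# no code path with the implementation they check.

random_means <- function(g, q, seed, scale = 1) {
  set.seed(seed)
  X <- matrix(rnorm(g * q, 10, scale), g, q,
              dimnames = list(paste0("G", 1:g), paste0("E", 1:q)))
  cell_means(X)
}

# balanced long-format data frame from explicit effects
toy_trial <- function(g, q, r, mu = 0, gen_eff = rep(0, g),
                      env_eff = rep(0, q), inter = matrix(0, g, q),
                      noise = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(gen = 1:g, env = 1:q, rep = 1:r)
  grid$value <- mu + gen_eff[grid$gen] + env_eff[grid$env] +
    inter[cbind(grid$gen, grid$env)] + rnorm(nrow(grid), 0, noise)
  data.frame(env = paste0("E", grid$env), gen = paste0("G", grid$gen),
             rep = paste0("R", grid$rep), value = grid$value)
}

oracle_ecovalence <- function(X) {
  g <- nrow(X); q <- ncol(X)
  gm <- mean(X)
  out <- numeric(g)
  for (i in 1:g) {
    for (j in 1:q) {
      out[i] <- out[i] + (X[i, j] - mean(X[i, ]) - mean(X[, j]) + gm)^2
    }
  }
  names(out) <- rownames(X)
  out
}

oracle_shukla <- function(wi2, p, q) {
  out <- numeric(length(wi2))
  for (i in seq_along(wi2)) {
    term1 <- p / ((p - 2) * (q - 1)) * wi2[i]
    term2 <- sum(wi2) / ((p - 1) * (p - 2) * (q - 1))
    out[i] <- term1 - term2
  }
  out
}

oracle_waas <- function(scores, ep) {
  out <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    num <- 0
    for (k in seq_along(ep)) num <- num + abs(scores[i, k]) * ep[k]
    out[i] <- num / sum(ep)
  }
  out
}

# per-environment winner by exhaustive projection over all genotypes
oracle_winners <- function(model) {
  proj <- model$gcoord %*% t(model$ecoord)
  rownames(model$gcoord)[apply(proj, 2, which.max)]
}

# brute-force balanced ANOVA sums of squares by explicit loops
oracle_anova_ss <- function(df) {
  y <- df$value
  gm <- mean(y)
  env <- as.character(df$env); gen <- as.character(df$gen)
  rep_ <- as.character(df$rep)
  envs <- unique(env); gens <- unique(gen); reps <- unique(rep_)
  g <- length(gens); q <- length(envs); r <- length(reps)
  m_env <- sapply(envs, function(e) mean(y[env == e]))
  m_gen <- sapply(gens, function(a) mean(y[gen == a]))
  m_cell <- outer(gens, envs, Vectorize(function(a, e) mean(y[gen == a & env == e])))
  m_blk <- outer(envs, reps, Vectorize(function(e, b) mean(y[env == e & rep_ == b])))
  ss_env <- g * r * sum((m_env - gm)^2)
  ss_gen <- q * r * sum((m_gen - gm)^2)
  ss_rep <- g * sum((sweep(m_blk, 1, m_env[envs]))^2)
  ss_int <- r * sum((m_cell - outer(m_gen, rep(1, q)) -
                       outer(rep(1, g), m_env) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_env - ss_gen - ss_rep - ss_int
  c(ENV = ss_env, `REP(ENV)` = ss_rep, GEN = ss_gen, `GEN:ENV` = ss_int,
    ERROR = ss_err, TOTAL = ss_tot)
}

# a hand-built rank-2 gge-like object for pure geometry tests
fake_gge <- function(gcoord, ecoord) {
  rownames(gcoord) <- paste0("G", seq_len(nrow(gcoord)))
  rownames(ecoord) <- paste0("E", seq_len(nrow(ecoord)))
  structure(list(gcoord = gcoord, ecoord = ecoord), class = "gge")
}
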