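test_that("ASV and ASI reduce correctly in edge geometries", {
  # rank-1 interaction: lambda_2 = 0 triggers the |IPCA1| fallback
  Z <- matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3, byrow = TRUE)
  X <- 10 + Z
  fit <- ammi_fit(cell_means(X))
  expect_warning(a <- asv(fit), "lambda_2")
  s1 <- ammi_scores(fit, "genotype")[, 1]
  expect_equal(unname(a), unname(abs(s1)), tolerance = 1e-10)

  # unit theta weights collapse ASI to the score norm
  cm <- random_means(5, 4, seed = 1)
  fit2 <- ammi_fit(cm)
  s <- ammi_scores(fit2, "genotype", axes = 2)
  expect_equal(as.numeric(asi(fit2, theta2 = c(1, 1))),
               unname(sqrt(s[, 1]^2 + s[, 2]^2)), tolerance = 1e-10)

  # a genotype with no interaction scores zero on every statistic
  cfg <- simulation_config(g = 6, q = 5, r = 2, sd_noise = 0, sd_rep = 0,
                           interaction_rank = 2,
                           interaction_weights = c(40, 20),
                           zero_interaction_genotype = TRUE, seed = 6)
  cmz <- cell_means(simulate_trial(cfg)$data)
  fitz <- ammi_fit(cmz)
  expect_lt(asi(fitz)[[1]], 1e-8)
  expect_lt(waas(fitz)[[1]], 1e-8)
  expect_lt(wricke_ecovalence(cmz)[[1]], 1e-12)
})

test_that("ASV matches its defining formula and is sign-flip invariant", {
  for (s in 1:10) {
    cm <- random_means(5, 4, seed = 200 + s)
    fit <- ammi_fit(cm)
    sc <- ammi_scores(fit, "genotype", axes = 2)
    ss <- fit$lambda[1:2]^2
    expect_equal(unname(asv(fit)),
                 unname(sqrt((ss[1] / ss[2] * sc[, 1])^2 + sc[, 2]^2)),
                 tolerance = 1e-10)
  }
  # flipping an axis pair leaves ASV unchanged
  cm <- random_means(5, 4, seed = 300)
  fit <- ammi_fit(cm)
  flipped <- fit
  flipped$gamma[, 1] <- -flipped$gamma[, 1]
  flipped$delta[, 1] <- -flipped$delta[, 1]
  expect_equal(asv(flipped), asv(fit), tolerance = 1e-12)
})

test_that("joint regression recovers forced slopes and averages to one", {
  X <- random_means(5, 6, seed = 4, scale = 4)$means
  X[2, ] <- 3                       # constant row: slope 0
  # fixed-point construction: row 1 = a + final column means, so its
  # centered deviations equal the environmental index exactly -> slope 1
  g <- nrow(X)
  X[1, ] <- (7 + colSums(X[-1, ]) / g) / (1 - 1 / g)
  b <- joint_regression(cell_means(X))
  expect_equal(unname(b[1]), 1, tolerance = 1e-9)
  expect_equal(unname(b[2]), 0, tolerance = 1e-9)
  expect_equal(mean(b), 1, tolerance = 1e-9)

  flat <- matrix(5, 4, 4)
  expect_error(joint_regression(cell_means(flat)),
               class = "metstab_error_degenerate")
})

test_that("ecovalence matches direct summation and vanishes for additive data", {
  X <- 10 + outer(1:4, 1:5, `+`)
  expect_lt(max(wricke_ecovalence(cell_means(X))), 1e-18)

  Z <- matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3, byrow = TRUE)
  w <- wricke_ecovalence(cell_means(20 + Z))
  expect_equal(unname(w), c(8, 0, 8), tolerance = 1e-10)
})

test_that("Shukla's variance is the stated affine transform of ecovalence", {
  expect_equal(shukla_variance(rep(0, 5), q = 4), rep(0, 5))
  expect_error(shukla_variance(c(1, 2), p = 2, q = 4),
               class = "metstab_error_degenerate")
  # 3x3 toy against term-by-term evaluation
  cm <- random_means(3, 3, seed = 31)
  wi2 <- wricke_ecovalence(cm)
  expect_equal(unname(shukla_variance(wi2, p = 3, q = 3)),
               unname(oracle_shukla(wi2, 3, 3)), tolerance = 1e-12)
})

test_that("WAAS equals the hand-weighted average of absolute scores", {
  cm <- random_means(6, 5, seed = 8)
  fit <- ammi_fit(cm)
  w2 <- waas(fit, axes = 2)
  expect_equal(as.numeric(w2),
               oracle_waas(ammi_scores(fit, "genotype", axes = 2),
                           fit$EP[1:2]),
               tolerance = 1e-12)
  expect_equal(attr(w2, "axes"), 2L)
  # a single axis leaves just the absolute score
  w1 <- waas(fit, axes = 1)
  expect_equal(as.numeric(w1), unname(abs(ammi_scores(fit, "genotype")[, 1])),
               tolerance = 1e-12)
  expect_error(waas(fit, axes = "significant"),
               class = "metstab_error_config")
})

test_that("WAASY blends rescaled yield and stability with the stated weights", {
  X <- rbind(G1 = c(12, 10, 8), G2 = c(9, 7, 5), G3 = c(6, 5, 7))
  cm <- cell_means(X)
  w <- c(G1 = 2, G2 = 0, G3 = 4)
  # hand computation at 50/50: y_score = (100, 25, 0); s_score = (50, 100, 0)
  out <- waasy_ranking(w, cm, weight_yield = 50)
  expect_equal(out$waasy, c(75, 62.5, 0))
  # pure yield weight reproduces the mean ranking
  out100 <- waasy_ranking(w, cm, weight_yield = 100)
  expect_equal(out100$rank, unname(rank(-cm$row_means, ties.method = "average")))
  # pure stability weight reproduces the WAAS ranking
  out0 <- waasy_ranking(w, cm, weight_yield = 0)
  expect_equal(out0$rank, unname(rank(w, ties.method = "average")))
  # degenerate rescaling is an error
  expect_error(waasy_ranking(c(G1 = 1, G2 = 1, G3 = 1), cm),
               class = "metstab_error_degenerate")
})

test_that("stability table is complete, ranked, and internally consistent", {
  cm <- cell_means(gsr_yield_means())
  tab <- stability_table(cm)
  expect_equal(nrow(tab), 20)
  for (col in grep("_rank$", names(tab), value = TRUE)) {
    expect_equal(sort(tab[[col]]), 1:20, info = col)
  }
  expect_true(all(tab$Wi2 >= 0))
  expect_true(all(tab$ASV >= 0))
  expect_true(all(tab$ASI >= 0))
  expect_true(all(tab$WAAS >= 0))
  # sigma2_i is affine in Wi2 with positive slope: identical orderings
  expect_equal(order(tab$shukla), order(tab$Wi2))
  expect_equal(tab$shukla_rank, tab$Wi2_rank)
})

test_that("brute-force oracles agree on random matrices across many seeds", {
  for (s in 1:100) {
    g <- sample(3:6, 1); q <- sample(3:6, 1)
    cm <- random_means(g, q, seed = 1000 + s, scale = 2)
    wi2 <- wricke_ecovalence(cm)
    expect_equal(unname(wi2), unname(oracle_ecovalence(cm$means)),
                 tolerance = 1e-9)
    expect_equal(unname(shukla_variance(wi2, p = g, q = q)),
                 unname(oracle_shukla(wi2, g, q)), tolerance = 1e-9)
    fit <- ammi_fit(cm)
    expect_equal(as.numeric(waas(fit)),
                 oracle_waas(ammi_scores(fit, "genotype"), fit$EP),
                 tolerance = 1e-9)
    # interaction SS conservation and slope identity
    expect_equal(sum(wi2), sum(fit$lambda^2),
                 tolerance = 1e-6 * sum(fit$lambda^2) + 1e-12)
    expect_equal(mean(joint_regression(cm)), 1, tolerance = 1e-9)
  }
})
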