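test_that("PC percents are SVP-invariant and match an eigen oracle", {
  cm <- random_means(5, 4, seed = 12, scale = 2)
  mods <- lapply(c("symmetric", "genotype", "environment"),
                 function(m) gge_fit(cm, svp = m))
  for (m in mods[-1]) expect_equal(m$pc_percent, mods[[1]]$pc_percent)
  Y <- sweep(cm$means, 2, colMeans(cm$means))
  ev <- eigen(t(Y) %*% Y, symmetric = TRUE)$values
  ev <- ev[seq_along(mods[[1]]$pc_percent)]
  expect_equal(mods[[1]]$pc_percent, 100 * ev / sum(ev), tolerance = 1e-8)
  expect_true(mods[[1]]$pc_percent[1] >= mods[[1]]$pc_percent[2])
  expect_lte(sum(mods[[1]]$pc_percent[1:2]), 100 + 1e-9)
})

test_that("the rank-2 product is identical under every partitioning mode", {
  cm <- random_means(6, 5, seed = 13, scale = 3)
  recon <- lapply(c("symmetric", "genotype", "environment"), function(m) {
    mod <- gge_fit(cm, svp = m)
    mod$gcoord %*% t(mod$ecoord)
  })
  expect_equal(recon[[2]], recon[[1]], tolerance = 1e-9)
  expect_equal(recon[[3]], recon[[1]], tolerance = 1e-9)
  # and equals the rank-2 truncation of the centered matrix
  Y <- sweep(cm$means, 2, colMeans(cm$means))
  sv <- svd(Y)
  expect_equal(unname(recon[[1]]),
               sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2]),
               tolerance = 1e-9)
})

test_that("identical genotype rows collapse to the origin", {
  X <- matrix(rep(c(4, 9, 2, 7), each = 5), 5, 4)
  mod <- gge_fit(cell_means(X))
  expect_lt(max(abs(mod$gcoord)), 1e-9)
})

test_that("centering removes every environment's mean", {
  cm <- random_means(6, 5, seed = 14)
  mod <- gge_fit(cm)
  expect_lt(max(abs(colSums(mod$Y))), 1e-9 * max(abs(cm$means)))
})

test_that("which-won-where assigns the max-projection genotype to each sector", {
  # hand geometry: three genotypes, env near the (1, 0) vertex
  mod <- fake_gge(rbind(c(1, 0), c(0, 1), c(-1, -1)),
                  rbind(c(1, 0.1)))
  geom <- which_won_where(mod)
  expect_false(geom$degenerate)
  expect_equal(geom$environments$sector, "G1")

  # boundary tie goes to the counter-clockwise sector
  # equal projection onto G1 and G2 happens along their bisector (1,1)/sqrt(2)
  modt <- fake_gge(rbind(c(1, 0), c(0, 1), c(-1, -1)),
                   rbind(c(1, 1) / sqrt(2)))
  geomt <- which_won_where(modt)
  # the ccw sector after the G1/G2 boundary ray is G2's
  expect_equal(geomt$environments$sector, "G2")

  # random matrices: sector winner equals brute-force max projection
  for (s in 1:100) {
    g <- sample(4:6, 1); q <- sample(3:6, 1)
    cm <- random_means(g, q, seed = 2000 + s, scale = 2)
    mod <- gge_fit(cm)
    geom <- which_won_where(mod)
    if (isTRUE(geom$degenerate)) next
    expect_equal(geom$environments$sector, oracle_winners(mod),
                 info = paste("seed", s))
  }
})

test_that("winners are invariant under global rotation of the frame", {
  cm <- random_means(6, 5, seed = 15, scale = 2)
  mod <- gge_fit(cm)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- fake_gge(mod$gcoord %*% R, mod$ecoord %*% R)
  w1 <- which_won_where(mod)$environments$sector
  w2 <- which_won_where(rot)$environments$sector
  expect_equal(unname(w2), unname(w1))
})

test_that("collinear genotype points are reported as degenerate", {
  mod <- fake_gge(cbind(c(-1, 0, 1, 2), c(-2, 0, 2, 4)),
                  rbind(c(1, 0), c(0, 1)))
  geom <- which_won_where(mod)
  expect_true(geom$degenerate)
  expect_match(geom$reason, "collinear")
})

test_that("the hull contains every genotype point", {
  cm <- random_means(8, 6, seed = 16, scale = 2)
  mod <- gge_fit(cm)
  geom <- which_won_where(mod)
  V <- mod$gcoord[geom$hull, , drop = FALSE]
  nh <- nrow(V)
  # each point lies left of (or on) every ccw hull edge
  for (p in seq_len(nrow(mod$gcoord))) {
    for (i in seq_len(nh)) {
      a <- V[i, ]; b <- V[if (i == nh) 1 else i + 1, ]
      cross <- (b[1] - a[1]) * (mod$gcoord[p, 2] - a[2]) -
        (b[2] - a[2]) * (mod$gcoord[p, 1] - a[1])
      expect_gte(cross, -1e-9)
    }
  }
  # every environment is assigned to exactly one sector
  expect_equal(nrow(geom$environments), mod$means$q)
  expect_true(all(geom$environments$sector %in% geom$hull))
})

test_that("mean-vs-stability projections behave geometrically", {
  # a genotype at the origin projects to zero with zero deviation
  mod <- fake_gge(rbind(c(0, 0), c(2, 1), c(-1, 2)),
                  rbind(c(1, 0), c(1, 0.5), c(0.8, -0.2)))
  ms <- mean_vs_stability(mod)
  expect_equal(ms$mean_projection[1], 0)
  expect_equal(ms$stability[1], 0)

  # identical environment coordinates: deviation is distance from that axis
  mode <- fake_gge(rbind(c(1, 1), c(2, -1), c(0, 3)),
                   rbind(c(2, 0), c(2, 0)))
  mse <- mean_vs_stability(mode)
  expect_equal(mse$stability, unname(abs(mode$gcoord[, 2])))
  expect_equal(mse$mean_projection, unname(mode$gcoord[, 1]))

  # top genotype by projection matches the top pooled mean on real data
  cm <- cell_means(gsr_yield_means())
  ms2 <- mean_vs_stability(gge_fit(cm))
  expect_equal(ms2$genotype[which.max(ms2$mean_projection)],
               names(which.max(cm$row_means)))
})

test_that("discriminativeness and representativeness follow vector arithmetic", {
  mod <- fake_gge(rbind(c(1, 0), c(0, 1), c(-1, -1)),
                  rbind(c(3, 0), c(0, 2), c(1, 1)))
  u <- colMeans(mod$ecoord); u <- u / sqrt(sum(u^2))
  dr <- discrimination_representativeness(mod)
  expect_equal(dr$length, c(3, 2, sqrt(2)), tolerance = 1e-12)
  expect_equal(dr$cosine, unname(drop(mod$ecoord %*% u) / dr$length),
               tolerance = 1e-12)

  # both environments lie on the average-environment axis: cosine 1
  mod3 <- fake_gge(rbind(c(1, 0), c(0, 1), c(-1, -1)),
                   rbind(c(2, 0), c(4, 0)))
  dr3 <- discrimination_representativeness(mod3)
  expect_equal(dr3$cosine, c(1, 1), tolerance = 1e-12)
  # mean environment vector along x, first environment on y: cosine 0
  mod4 <- fake_gge(rbind(c(1, 0), c(0, 1), c(-1, -1)),
                   rbind(c(0, 2), c(3, -1), c(3, -1)))
  dr4 <- discrimination_representativeness(mod4)
  expect_equal(dr4$cosine[1], 0, tolerance = 1e-12)

  expect_error(discrimination_representativeness(
    fake_gge(rbind(c(1, 0), c(0, 1), c(-1, -1)),
             rbind(c(0, 0), c(1, 0)))),
    class = "metstab_error_degenerate")

  cm <- random_means(6, 6, seed = 17)
  drq <- discrimination_representativeness(gge_fit(cm))
  expect_true(all(drq$quadrant %in% c("high_disc_high_repr", "high_disc_low_repr",
                                      "low_disc_high_repr", "low_disc_low_repr")))
})

test_that("ideal-point ranking sorts by brute-force distance", {
  # a point on the axis at the maximum projection IS the ideal point
  mod <- fake_gge(rbind(c(3, 0), c(1, 1), c(0, -2)),
                  rbind(c(1, 0), c(2, 0)))
  rk <- rank_ideal(mod, "genotypes")
  expect_equal(rk$label[1], "G1")
  expect_equal(rk$distance[1], 0, tolerance = 1e-12)
  # symmetric points about the axis tie
  mods <- fake_gge(rbind(c(2, 1), c(2, -1), c(0, 0)),
                   rbind(c(1, 0), c(3, 0)))
  rks <- rank_ideal(mods, "genotypes")
  expect_equal(rks$distance[rks$label == "G1"],
               rks$distance[rks$label == "G2"], tolerance = 1e-12)
  expect_equal(rks$rank[rks$label == "G1"], 1.5)

  # brute-force ordering on a random 4x3 case
  cm <- random_means(4, 3, seed = 18, scale = 2)
  mod2 <- gge_fit(cm)
  for (target in c("genotypes", "environments")) {
    rk2 <- rank_ideal(mod2, target)
    C <- if (target == "genotypes") mod2$gcoord else mod2$ecoord
    u <- colMeans(mod2$ecoord); u <- u / sqrt(sum(u^2))
    perp <- c(-u[2], u[1])
    ideal_len <- if (target == "genotypes") max(C %*% u) else
      max(sqrt(rowSums(C^2)))
    d <- sqrt((drop(C %*% u) - ideal_len)^2 + drop(C %*% perp)^2)
    expect_equal(rk2$label, rownames(C)[order(d)])
    expect_equal(rk2$distance, unname(sort(d)), tolerance = 1e-12)
  }
})
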