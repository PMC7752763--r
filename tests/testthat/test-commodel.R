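set.seed(77)

test_that("family grouping sums member series and drops unmapped features", {
  rel <- matrix(c(10, 12, 5, 6, 2, 3), 3, 2, byrow = TRUE,
                dimnames = list(c("r1", "r2", "x9"), c("t1", "t2")))
  map <- data.frame(feature = c("r1", "r2", "p1"),
                    family = c("F", "F", "F"),
                    kind = c("bacteria", "bacteria", "plasmid"))
  expect_message(g <- group_by_family(rel, map), "excluded")
  expect_equal(unname(g$series["F|bacteria", ]), c(15, 18))
  expect_false("x9" %in% g$info$group)
})

test_that("pairwise Pearson tests match the closed-form coefficient", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  m <- rbind(a = x, b = y, const = c(2, 2, 2, 2))
  colnames(m) <- paste0("t", 1:4)
  suppressWarnings(co <- correlate_groups(m))
  r_ab <- co$r[co$group1 == "a" & co$group2 == "b"]
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_ab, r_closed)
  expect_equal(co$r[co$group1 == "a" & co$group2 == "a"], numeric(0))
  expect_true(is.na(co$r[co$group2 == "const"][1]))  # constant series
  # self-correlation and anti-correlation
  m2 <- rbind(a = x, b = x, neg = -x)
  colnames(m2) <- paste0("t", 1:4)
  co2 <- correlate_groups(m2)
  expect_equal(co2$r[co2$group1 == "a" & co2$group2 == "b"], 1)
  expect_equal(co2$r[co2$group1 == "a" & co2$group2 == "neg"], -1)
})

test_that("hierarchical clustering of correlation profiles separates blocks", {
  set.seed(78)
  base1 <- sin(seq(0, 3 * pi, length.out = 20))
  base2 <- cos(seq(0, 3 * pi, length.out = 20))
  m <- rbind(a1 = base1, a2 = base1 + rnorm(20, 0, 0.01),
             b1 = -base1, b2 = -base1 + rnorm(20, 0, 0.01))
  colnames(m) <- paste0("t", 1:20)
  co <- correlate_groups(m)
  # with four groups the between-block profile distance is exactly 4, so a
  # cut below that separates the two anti-correlated blocks
  cl <- cluster_groups(co, height = 2)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_equal(cl[["b1"]], cl[["b2"]])
  expect_false(cl[["a1"]] == cl[["b1"]])
  # identical groups cluster together at any positive height
  m3 <- rbind(g1 = base1, g2 = base1, g3 = base2)
  colnames(m3) <- paste0("t", 1:20)
  cl3 <- cluster_groups(correlate_groups(m3), height = 0.001)
  expect_equal(cl3[["g1"]], cl3[["g2"]])
  # missing correlations are refused, not imputed
  m4 <- rbind(g1 = base1, konst = rep(1, 20))
  colnames(m4) <- paste0("t", 1:20)
  suppressWarnings(co4 <- correlate_groups(m4))
  expect_error(cluster_groups(co4), "refusing to impute")
})

test_that("the random search ranks an exact-copy model first with adj R2 1", {
  set.seed(79)
  n <- 30
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  y <- X[, "g3"]
  ms <- random_model_search(y, X, n_realizations = 2000, max_terms = 4,
                            seed = 5)
  expect_equal(ms$adj_r2[1], 1, tolerance = 1e-12)
  expect_true(grepl("g3", ms$predictors[1]))
  # adjusted R2 matches its closed form on every fitted model
  for (i in sample(nrow(ms), 50)) {
    expect_equal(ms$adj_r2[i],
                 1 - (1 - ms$r2[i]) * (n - 1) / (n - ms$n_terms[i] - 1))
  }
})

test_that("planted predictors are enriched, recovered and ablatable", {
  set.seed(80)
  n <- 40
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("g", 1:8)))
  y <- 1.0 * X[, "g1"] - 0.5 * X[, "g2"] + rnorm(n, 0, 0.05)
  ms <- random_model_search(y, X, n_realizations = 5000, max_terms = 5,
                            seed = 6)
  top <- strsplit(ms$predictors[1], ",")[[1]]
  expect_true(all(c("g1", "g2") %in% top))
  enr <- enrichment_in_top(ms, N = 50)
  expect_true(all(c("g1", "g2") %in% enr$group[enr$enriched]))
  mod <- global_and_reduced_model(y, X, enr$group[enr$enriched])
  expect_true(all(c("g1", "g2") %in% mod$significant))
  expect_equal(sign(unname(coef(mod$reduced)[
    names(mod$name_map)[mod$name_map == "g1"]])), 1)
  expect_equal(sign(unname(coef(mod$reduced)[
    names(mod$name_map)[mod$name_map == "g2"]])), -1)
  # removing a planted predictor hurts; removing it entirely degenerates
  ab <- ablate_predictor(mod, "g1")
  expect_gt(ab$delta_adj_r2, 0)
  expect_error(ablate_predictor(mod, "g8"), "not in the reduced model")

  # a redundant near-duplicate of a retained predictor costs ~ nothing
  X2 <- cbind(X[, c("g1", "g2")], g1dup = X[, "g1"] + rnorm(n, 0, 1e-4))
  mod2 <- global_and_reduced_model(y, X2, colnames(X2), alpha = 1)
  ab2 <- ablate_predictor(mod2, "g1dup")
  expect_lt(abs(ab2$delta_adj_r2), 0.01)

  # a single predictor equal to the response: reduced = global, adj R2 = 1
  mod3 <- suppressWarnings(global_and_reduced_model(X[, "g1"], X, "g1"))
  expect_equal(mod3$global_adj_r2, 1, tolerance = 1e-12)
  expect_equal(mod3$reduced_adj_r2, 1, tolerance = 1e-12)
  ab3 <- ablate_predictor(mod3, "g1")
  expect_equal(ab3$ablated_adj_r2, 0)  # intercept-only

  # pure-noise enriched set: reduced model likely empty at alpha 0.05
  set.seed(81)
  y_noise <- rnorm(n)
  mod4 <- global_and_reduced_model(y_noise, X, c("g4", "g5"))
  expect_true(mod4$reduced_empty || length(mod4$significant) <= 1)
})

test_that("enrichment scores behave at the extremes", {
  set.seed(82)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- X[, "g1"] + rnorm(n, 0, 0.01)
  ms <- random_model_search(y, X, n_realizations = 3000, max_terms = 3,
                            seed = 9)
  enr <- enrichment_in_top(ms, N = 25)
  expect_true(enr$enriched[enr$group == "g1"])
  expect_lt(enr$p[enr$group == "g1"], 1e-6)
  absent <- enr[enr$n_top == 0, ]
  expect_true(all(!absent$enriched))
})

test_that("searches under different seeds explore the same model space", {
  set.seed(83)
  n <- 35
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- 0.8 * X[, "g2"] + rnorm(n, 0, 0.5)
  a <- random_model_search(y, X, n_realizations = 3000, seed = 1)
  b <- random_model_search(y, X, n_realizations = 3000, seed = 2)
  ks <- suppressWarnings(stats::ks.test(a$adj_r2, b$adj_r2))
  expect_gt(ks$p.value, 0.01)
  # and the same seed reproduces the ranking exactly
  a2 <- random_model_search(y, X, n_realizations = 3000, seed = 1)
  expect_equal(a$predictors, a2$predictors)
  expect_equal(a$adj_r2, a2$adj_r2)
})
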