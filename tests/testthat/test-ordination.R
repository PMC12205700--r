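test_that("two perfectly correlated variables collapse onto one component", {
  x <- data.frame(a = 1:20, b = 2 * (1:20) + 5)
  res <- pca_environment(x)
  expect_equal(unname(res$eigenvalues), c(2, 0), tolerance = 1e-12)
  expect_equal(res$retained, 1L)
})

test_that("eigenvalues of a correlation PCA sum to the variable count", {
  set.seed(31)
  x <- as.data.frame(matrix(rnorm(60 * 7), 60, 7))
  res <- pca_environment(x)
  expect_equal(sum(res$eigenvalues), 7, tolerance = 1e-10)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
})

test_that("loadings are variable-score correlations; reconstruction is exact", {
  set.seed(32)
  x <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
  x$V2 <- x$V1 * 0.7 + x$V2 * 0.5
  res <- pca_environment(x)
  std_scores <- sweep(res$scores, 2, sqrt(res$eigenvalues), `/`)
  for (k in 1:5) {
    expect_equal(unname(cor(scale(x), res$scores[, k])[, 1]),
                 unname(res$loadings[, k]), tolerance = 1e-10)
  }
  recon <- std_scores %*% t(res$loadings)
  expect_equal(unname(recon), unname(scale(as.matrix(x))),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: strongest variable of each component loads positive
  for (k in 1:5) {
    expect_gte(res$loadings[which.max(abs(res$loadings[, k])), k], 0)
  }
})

test_that("rows with gaps and flat variables are dropped with warnings", {
  x <- data.frame(plot_id = sprintf("p%d", 1:10),
                  a = rnorm(10), b = rnorm(10), flat = 1)
  x$a[3] <- NA
  expect_warning(expect_warning(res <- pca_environment(x), "missing"),
                 "zero-variance")
  expect_equal(res$n, 9L)
  expect_equal(res$dropped_plots, "p3")
  expect_equal(res$dropped_variables, "flat")
  expect_error(pca_environment(data.frame(a = 1:5)), "2 variables")
})

test_that("loading significance follows the correlation t-test", {
  L <- matrix(c(0, 0.9, 0.2), 3, 1,
              dimnames = list(c("zero", "strong", "weak"), "PC1"))
  # r = 0.9, n = 10: t ~ 5.84, p < 0.001 -> kept
  out10 <- filter_significant_loadings(L, n = 10)
  expect_true(is.na(out10["zero", 1]))
  expect_equal(out10["strong", 1], 0.9)
  # r = 0.2, n = 20: t ~ 0.866, p ~ 0.40 -> masked
  out20 <- filter_significant_loadings(L, n = 20)
  expect_true(is.na(out20["weak", 1]))
  t_weak <- 0.2 * sqrt(18 / (1 - 0.04))
  expect_equal(t_weak, 0.866, tolerance = 1e-3)
  expect_gt(2 * pt(-t_weak, 18), 0.05)  # ~0.40, far from significance
  expect_error(filter_significant_loadings(L, n = 2), "exceed 2")
})

test_that("group summaries reduce to global stats for one group", {
  x <- data.frame(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  s <- summarize_by_group(x, rep("all", 4))
  expect_equal(s$mean, c(mean(x$a), 2))
  expect_equal(s$sd, c(sd(x$a), 0))
  s2 <- summarize_by_group(x, c("A", "A", "B", "B"))
  expect_equal(s2$group, c("A", "A", "B", "B"))
  expect_equal(s2$mean[s2$group == "A" & s2$variable == "a"], 1.5)
})

test_that("the planted moisture gradient dominates the ordination", {
  scen <- community_scenario()
  tab <- generate_indicator_table(scen, seed = 1)
  gen <- generate_releves(scen, tab, seed = 1)
  reg <- suppressWarnings(
    plot_scores(gen$releves, tab, scale_definitions("didukh")$scale_id))
  hem <- suppressWarnings(plot_hemeroby(gen$releves, tab))
  block <- merge(reg, hem[c("plot_id", "hemeroby_index",
                            "naturalness_index")], by = "plot_id")
  res <- suppressWarnings(pca_environment(block))
  expect_gt(res$explained_pct[1], max(res$explained_pct[-1]))
  hd <- reg$Hd[match(rownames(res$scores), reg$plot_id)]
  rho <- cor(res$scores[, 1], hd, method = "spearman",
             use = "complete.obs")
  expect_gt(abs(rho), 0.8)
  # moisture and hemeroby pull PC1 in opposite directions
  expect_lt(res$loadings["Hd", 1] * res$loadings["hemeroby_index", 1], 0)
  # wet-association plots are wetter than dry-association plots
  s <- summarize_by_group(block["Hd"], as.character(gen$labels))
  wet <- scen$associations$association[which.max(scen$associations$moisture)]
  dry <- scen$associations$association[which.min(scen$associations$moisture)]
  expect_gt(s$mean[s$group == wet], s$mean[s$group == dry])
})
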