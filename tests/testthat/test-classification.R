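test_that("pseudospecies expansion is nested over the cut levels", {
  rs <- releve_set(data.frame(
    plot_id = c("p1", "p2", "p3"),
    species = c("a sp", "a sp", "b sp"),
    cover = c(7, 0.5, 25)))
  psm <- make_pseudospecies(rs)
  # a sp at 7% switches on cuts 0, 2, 5 only; at 0.5% only presence
  expect_equal(colnames(psm)[attr(psm, "species") == "a sp"],
               c("a sp@0", "a sp@2", "a sp@5"))
  expect_equal(unname(psm["p1", c("a sp@0", "a sp@2", "a sp@5")]),
               c(1L, 1L, 1L))
  expect_equal(unname(psm["p2", c("a sp@0", "a sp@2", "a sp@5")]),
               c(1L, 0L, 0L))
  # b sp at 25% reaches every cut
  expect_equal(sum(attr(psm, "species") == "b sp"), 5L)
  expect_error(make_pseudospecies(rs, c(0, 5, 5)), "strictly increasing")
  expect_error(make_pseudospecies(rs, c(2, 5)), "first cut level")
})

test_that("pseudospecies column count matches a brute-force recount", {
  gen <- generate_releves(community_scenario(), seed = 4)
  rs <- gen$releves
  cuts <- c(0, 2, 5, 10, 20)
  psm <- make_pseudospecies(rs, cuts)
  m <- as.matrix(rs)
  expected <- 0L
  for (sp in colnames(m)) {
    mx <- max(m[, sp])
    expected <- expected + sum(cuts == 0 | cuts <= mx)
  }
  expect_equal(ncol(psm), expected)
  # nestedness: presence at a cut implies presence at all lower cuts
  for (sp in sample(colnames(m), 10)) {
    cols <- which(attr(psm, "species") == sp)
    sub <- psm[, cols, drop = FALSE]
    ord <- order(attr(psm, "cut")[cols])
    sub <- sub[, ord, drop = FALSE]
    if (ncol(sub) > 1) {
      expect_true(all(sub[, -ncol(sub)] - sub[, -1] >= 0))
    }
  }
})

test_that("reciprocal-averaging axis 1 matches a dense eigensolver", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(8:20, 1); m <- sample(10:30, 1)
    A <- matrix(rbinom(n * m, 1, 0.35), n, m)
    A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
    if (nrow(A) < 3 || ncol(A) < 3) next
    ca <- ca_axis1(A)
    # oracle: symmetric eigenproblem of the row-averaged operator
    Dr <- diag(1 / sqrt(rowSums(A)))
    Dc <- diag(1 / colSums(A))
    S <- Dr %*% A %*% Dc %*% t(A) %*% Dr
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(ca$eigenvalue, ev[2], tolerance = 1e-8)
    expect_gt(ca$eigenvalue, 0)
    expect_lt(ca$eigenvalue, 1)
  }
})

test_that("vegan's correspondence analysis confirms the axis-1 eigenvalue", {
  skip_if_not_installed("vegan")
  set.seed(21)
  A <- matrix(rbinom(15 * 25, 1, 0.4), 15, 25)
  A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
  ca <- ca_axis1(A)
  ref <- vegan::cca(A)
  expect_equal(ca$eigenvalue, unname(ref$CA$eig[1]), tolerance = 1e-8)
})

test_that("two disjoint species blocks are separated by the first division", {
  rs <- block_releves(n = 10)
  psm <- make_pseudospecies(rs)
  tree <- twinspan(psm, max_levels = 1)
  g <- twinspan_groups(tree)
  expect_equal(length(unique(g)), 2L)
  blocks <- substr(names(g), 1, 1)
  expect_equal(length(unique(paste(blocks, g))), 2L)  # split == blocks
  node <- tree$root
  expect_gt(node$eigenvalue, 0)
  expect_lte(node$eigenvalue, 1)  # fully disjoint blocks reach exactly 1
  expect_lte(nrow(node$indicators), 5L)
})

test_that("small or degenerate inputs yield a single leaf or an error", {
  rs <- releve_set(data.frame(plot_id = "p1", species = "a sp", cover = 10))
  tree <- twinspan(make_pseudospecies(rs))
  expect_equal(tree$n_groups, 1L)
  m <- matrix(c(1, 0, 1, 0), 2, 2,
              dimnames = list(c("p1", "p2"), c("s@0", "t@0")))
  m["p2", ] <- 0
  expect_error(twinspan(m), "degenerate")
})

test_that("plot order only relabels the partition, never changes it", {
  gen <- generate_releves(community_scenario(), seed = 6)
  rs <- gen$releves
  psm <- make_pseudospecies(rs)
  tree1 <- twinspan(psm, max_levels = 3)
  perm <- sample(nrow(psm))
  psm2 <- psm[perm, , drop = FALSE]
  attr(psm2, "species") <- attr(psm, "species")
  attr(psm2, "cut") <- attr(psm, "cut")
  tree2 <- twinspan(psm2, max_levels = 3)
  g1 <- twinspan_groups(tree1)
  g2 <- twinspan_groups(tree2)[names(g1)]
  # set-level equality of the two partitions
  split1 <- lapply(split(names(g1), g1), sort)
  split2 <- lapply(split(names(g2), g2), sort)
  expect_true(all(vapply(split1, function(s)
    any(vapply(split2, identical, logical(1), s)), logical(1))))
})

test_that("cutting the division tree yields the requested group count", {
  gen <- generate_releves(community_scenario(), seed = 1)
  tree <- twinspan(make_pseudospecies(gen$releves))
  for (k in c(2, 6, 12)) {
    g <- twinspan_groups(tree, k = k)
    expect_equal(length(unique(g)), k)
    expect_equal(sort(names(g)), sort(gen$releves$plots$plot_id))
  }
  js <- twinspan_to_json(tree)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(length(parsed$plots), tree$n_plots)
})

test_that("phi matches its closed form and symmetry properties", {
  # N=20, N_p=10, n=5, n_p=5 (equalized design is already balanced)
  expect_equal(phytoind:::phi_coefficient(20, 10, 5, 5),
               50 / sqrt(7500), tolerance = 1e-12)
  # ubiquitous species: no association
  expect_equal(phytoind:::phi_coefficient(20, 10, 20, 10), 0)
  # perfect indicator under equalization
  expect_equal(phytoind:::phi_coefficient(20, 8, 8, 8), 1)
  # swapping group and complement flips the sign
  a <- phytoind:::phi_coefficient(30, 12, 9, 7, equalize = FALSE)
  b <- phytoind:::phi_coefficient(30, 18, 9, 2, equalize = FALSE)
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("fidelity tables carry counts and Fisher p-values", {
  pres <- rbind(matrix(c(1, 1, 0), 6, 3, byrow = TRUE),
                matrix(c(0, 1, 1), 6, 3, byrow = TRUE))
  dimnames(pres) <- list(sprintf("p%02d", 1:12), c("a sp", "b sp", "c sp"))
  fid <- fidelity(pres, rep(c("G1", "G2"), each = 6))
  a_g1 <- fid[fid$species == "a sp" & fid$group == "G1", ]
  expect_equal(a_g1[, c("N", "N_p", "n", "n_p")],
               data.frame(N = 12L, N_p = 6L, n = 6L, n_p = 6L),
               ignore_attr = TRUE)
  expect_equal(a_g1$phi, 1)
  expect_equal(a_g1$p_value,
               fisher.test(matrix(c(6, 0, 0, 6), 2))$p.value)
  # b sp occurs everywhere: phi 0 for both groups
  expect_true(all(fid$phi[fid$species == "b sp"] == 0))
  expect_error(fidelity(pres, rep("G1", 12)), "2 groups")
  empty <- cbind(pres, "d sp" = 0)
  expect_warning(fidelity(empty, rep(c("G1", "G2"), each = 6)),
                 "absent everywhere")
})

test_that("synoptic table reports occurrence percentages and flags", {
  pres <- matrix(0, 10, 2, dimnames = list(sprintf("p%02d", 1:10),
                                           c("a sp", "b sp")))
  pres[1:3, "a sp"] <- 1   # 3 of 10 plots in G1
  pres[6:10, "b sp"] <- 1
  groups <- rep(c("G1", "G2"), each = 5)
  pres[1, "b sp"] <- 1     # keep every species present somewhere in G1 too
  syn <- suppressWarnings(synoptic_table(pres, groups))
  expect_equal(unname(syn$percentages["a sp", "G1"]), 60)  # 3 of 5
  expect_equal(unname(syn$percentages["a sp", "G2"]), 0)
  # diagnostic flag needs BOTH thresholds
  fid <- data.frame(species = "a sp", group = "G1", phi = 0.6,
                    p_value = 0.2, N = 10, N_p = 5, n = 3, n_p = 3)
  syn2 <- synoptic_table(pres[, "a sp", drop = FALSE], groups, fid)
  expect_false(any(syn2$diagnostics$diagnostic))
})
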