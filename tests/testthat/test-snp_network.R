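test_that("signed adjacency hits its endpoints and closed forms", {
  b <- matrix(c(0, 1, -1, 1, 0, 0, -1, 0, 0), 3, 3)
  a <- signed_adjacency(b, 1)$adjacency
  expect_equal(a[1, 2], 1)      # s = +1
  expect_equal(a[1, 3], 0)      # s = -1
  expect_equal(a[2, 3], 0.5)    # s = 0
  expect_equal(diag(a), rep(0, 3))

  a12 <- signed_adjacency(b, 12)$adjacency
  expect_equal(a12[2, 3], 0.5^12)   # = 2.44140625e-4

  expect_error(signed_adjacency(matrix(0, 3, 3), 6), "no interaction")
})

test_that("adjacency is monotone in the coefficient at fixed power", {
  set.seed(2)
  b <- matrix(rnorm(100), 10, 10); b <- (b + t(b)) / 2; diag(b) <- 0
  a <- signed_adjacency(b, 6)$adjacency
  ut <- upper.tri(b)
  ord <- order(b[ut])
  expect_true(all(diff(a[ut][ord]) >= -1e-12))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("failed-status cells get the neutral weight", {
  b <- matrix(c(0, 1, NA, 1, 0, 0.5, NA, 0.5, 0), 3, 3)
  st <- matrix("ok", 3, 3); st[1, 3] <- st[3, 1] <- "collinear"
  a <- signed_adjacency(b, 2, status = st)$adjacency
  expect_equal(a[1, 3], 0.25)   # ((1+0)/2)^2
})

test_that("TOM matches closed forms and stays in bounds", {
  # 2-node network: TOM12 = a/(a + 1 - a) = a
  a <- matrix(c(0, 0.37, 0.37, 0), 2, 2)
  expect_equal(tom_similarity(a)[1, 2], 0.37)

  # complete graph with unit weights saturates
  ones <- matrix(1, 5, 5); diag(ones) <- 0
  expect_true(all(tom_similarity(ones) == 1))

  set.seed(9)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    a <- matrix(runif(n * n), n, n); a <- (a + t(a)) / 2; diag(a) <- 0
    tt <- tom_similarity(a)
    expect_true(all(tt >= 0 & tt <= 1))
    expect_true(isSymmetric(tt))
  }
})

test_that("pick_power behaves monotonically and falls back on noise", {
  sm <- simulate_beta3_modules(150, c(30, 30), seed = 2)
  p1 <- pick_power(sm$beta3, target_r2 = 0.5)$power_beta
  p2 <- pick_power(sm$beta3, target_r2 = 0.9)$power_beta
  expect_gte(p2, p1)   # larger target never selects a smaller power

  noise <- simulate_beta3_modules(60, integer(0), seed = 3)
  expect_warning(pf <- pick_power(noise$beta3, candidates = c(2, 4)),
                 "falling back")
  expect_equal(pf$power_beta, 12)
})

test_that("cluster_and_cut recovers planted modules and greys out noise", {
  # two tight planted blocks, no background
  sm <- simulate_beta3_modules(100, c(50, 50), within_mean = 0.9,
                               within_sd = 0.02, bg_sd = 0.02, seed = 5)
  adj <- signed_adjacency(sm$beta3, 12)$adjacency
  part <- cluster_and_cut(1 - tom_similarity(adj), 30)
  expect_equal(ari(part$assignment, sm$truth), 1)
  # color convention: largest modules get the head of the palette
  expect_setequal(setdiff(unique(part$assignment), "grey"),
                  c("turquoise", "blue"))

  # pure noise: >= 90% grey at min size 30
  noise <- simulate_beta3_modules(300, integer(0), seed = 7)
  adj0 <- signed_adjacency(noise$beta3, 12)$adjacency
  p0 <- cluster_and_cut(1 - tom_similarity(adj0), 30)
  expect_gte(mean(p0$assignment == "grey"), 0.9)

  # identical interaction profiles collapse to a single module
  flat <- matrix(0.8, 40, 40); diag(flat) <- 0
  rownames(flat) <- colnames(flat) <- sprintf("s%02d", 1:40)
  pf <- cluster_and_cut(1 - tom_similarity(
    signed_adjacency(flat, 6)$adjacency), 10)
  expect_equal(unname(table(pf$assignment)[["turquoise"]]), 40)
})

test_that("module detection is deterministic", {
  sm <- simulate_beta3_modules(200, c(40, 40), seed = 31)
  adj <- signed_adjacency(sm$beta3, 12)$adjacency
  d <- 1 - tom_similarity(adj)
  p1 <- cluster_and_cut(d, 30)
  p2 <- cluster_and_cut(d, 30)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("eigen_snp matches an SVD/power-iteration oracle", {
  cfg <- sim_config(n_samples = 50, n_snps = 20, missing_rate = 0.02,
                    seed = 19)
  gm <- simulate_genotypes(cfg)$gm
  es <- eigen_snp(gm$values)
  expect_equal(mean(es$eigensnp), 0, tolerance = 1e-10)
  expect_equal(sd(es$eigensnp), 1, tolerance = 1e-10)

  # power-iteration oracle on the imputed, z-scored matrix
  X <- gm$values
  for (j in seq_len(ncol(X))) {
    mj <- is.na(X[, j]); if (any(mj)) X[mj, j] <- mean(X[, j], na.rm = TRUE)
  }
  Z <- scale(X)
  C <- tcrossprod(Z)
  v <- rnorm(nrow(Z))
  for (it in 1:500) { v <- C %*% v; v <- v / sqrt(sum(v^2)) }
  v <- drop(v) / sd(drop(v))
  if (cor(v, es$eigensnp) < 0) v <- -v
  expect_equal(abs(cor(v, es$eigensnp)), 1, tolerance = 1e-8)

  # rank-1 module: identical columns explain everything
  g <- sample(0:2, 30, replace = TRUE)
  es1 <- eigen_snp(cbind(g, g, g))
  expect_equal(es1$variance_explained, 1, tolerance = 1e-12)
  expect_equal(es1$eigensnp, as.numeric(scale(g)) / sd(as.numeric(scale(g))),
               tolerance = 1e-8)

  expect_warning(eigen_snp(cbind(g, g, rep(1, 30))), "zero-variance")
})

test_that("allele-coding flips do not change trait correlations", {
  cfg <- sim_config(n_samples = 40, n_snps = 10, missing_rate = 0,
                    seed = 29)
  gm <- simulate_genotypes(cfg)$gm
  set.seed(29); y <- rnorm(40)
  e1 <- eigen_snp(gm$values)$eigensnp
  e2 <- eigen_snp(2L - gm$values)$eigensnp
  expect_equal(abs(cor(e1, y)), abs(cor(e2, y)), tolerance = 1e-10)
})

test_that("merge_close_modules merges duplicates and respects cut height", {
  cfg <- sim_config(n_samples = 60, n_snps = 30, missing_rate = 0,
                    within_block_rho = 0.999, ld_block_size = 15,
                    n_chromosomes = 1, seed = 55)
  gm <- simulate_genotypes(cfg)$gm
  ids <- gm$snps$snp_id
  # split one LD block into two fake modules -> near-identical eigenSNPs
  asg <- setNames(c(rep("blue", 8), rep("red", 7), rep("green", 15)), ids)
  part <- structure(list(assignment = asg, hclust = NULL,
                         min_module_size = 3),
                    class = "module_partition")
  merged <- merge_close_modules(part, gm, cut_height = 0.25)
  mods <- setdiff(unique(merged$assignment), "grey")
  expect_length(mods, 2)   # blue+red collapse, green independent

  # orthogonal modules never merge even at a permissive height
  cfg2 <- sim_config(n_samples = 60, n_snps = 30, within_block_rho = 0,
                     missing_rate = 0, seed = 56)
  gm2 <- simulate_genotypes(cfg2)$gm
  part2 <- structure(list(assignment = setNames(
    rep(c("blue", "red", "green"), each = 10), gm2$snps$snp_id),
    hclust = NULL, min_module_size = 3), class = "module_partition")
  m2 <- merge_close_modules(part2, gm2, cut_height = 0.25)
  expect_length(setdiff(unique(m2$assignment), "grey"), 3)
})

test_that("soft connectivity follows the handshake identity", {
  # star: hub at weight 1 to m leaves
  m <- 6
  a <- matrix(0, m + 1, m + 1)
  a[1, 2:(m + 1)] <- a[2:(m + 1), 1] <- 1
  k <- soft_connectivity(a)
  expect_equal(max(k$connectivity), m)
  expect_equal(sort(k$connectivity), c(rep(1, m), m))

  expect_true(all(soft_connectivity(matrix(0, 4, 4))$connectivity == 0))

  set.seed(13)
  for (rep in 1:5) {
    a <- matrix(runif(64), 8, 8); a <- (a + t(a)) / 2; diag(a) <- 0
    k <- soft_connectivity(a)$connectivity
    expect_equal(sum(k), 2 * sum(a[upper.tri(a)]), tolerance = 1e-10)
  }
})
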