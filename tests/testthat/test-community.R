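test_that("Bray-Curtis matches the closed form and the naive oracle", {
  m <- rbind(a = c(1, 0), b = c(0, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 1)
  expect_equal(diag(unclass(d)), c(a = 0, b = 0))

  m2 <- rbind(a = c(2, 1, 0), b = c(1, 1, 1))
  expect_equal(bray_curtis(m2)["a", "b"], 1 / 3, tolerance = 1e-12)
  expect_equal(bray_curtis(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)

  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    m <- matrix(rexp(n * 6), n, 6,
                dimnames = list(paste0("s", 1:n), paste0("o", 1:6)))
    expect_equal(unclass(bray_curtis(m)), naive_bray(m), tolerance = 1e-12)
  }
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "zero-sum")
})

test_that("UPGMA recovers ultrametric distances exactly and ignores label order", {
  d <- matrix(0.8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.2
  d["c", "d"] <- d["d", "c"] <- 0.4
  diag(d) <- 0
  hc <- hierarchical_cluster(d)
  coph <- as.matrix(cophenetic(hc))[rownames(d), colnames(d)]
  expect_equal(coph, d, tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  hc2 <- hierarchical_cluster(d[perm, perm])
  part <- function(h) unname(lapply(split(names(cutree(h, 2)),
                                          cutree(h, 2)), sort))
  expect_setequal(part(hc), part(hc2))
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "two objects")
})

test_that("first UPGMA merge joins the closest pair", {
  d <- matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3, 3,
              dimnames = list(1:3, 1:3))
  hc <- hierarchical_cluster(d)
  expect_setequal(-hc$merge[1, ], c(1, 2))
})

test_that("NMDS embeds planar configurations at near-zero stress, deterministically", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  d <- as.matrix(dist(pts))
  ord <- nmds(d, k = 2, n_restarts = 5, seed = 3)
  expect_lt(ord$stress, 0.01)
  expect_equal(ord$stress, min(ord$stress_restarts))
  expect_true(all(ord$stress <= ord$stress_restarts))
  expect_equal(unname(colMeans(ord$points)), c(0, 0), tolerance = 1e-8)

  ord2 <- nmds(d, k = 2, n_restarts = 5, seed = 3)
  expect_identical(ord$points, ord2$points)

  # duplicated samples land on (nearly) coincident points
  m <- rbind(a = c(5, 1, 0), b = c(5, 1, 0), c = c(0, 1, 5), e = c(2, 2, 2))
  dd <- bray_curtis(m)
  o <- nmds(dd, seed = 1, n_restarts = 5)
  expect_lt(sqrt(sum((o$points["a", ] - o$points["b", ])^2)), 0.05)
})

test_that("PERMANOVA partitions R2 to unity and matches the brute-force oracle", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    m <- matrix(rexp(n * 5), n, 5,
                dimnames = list(paste0("s", 1:n), paste0("o", 1:5)))
    g <- factor(rep_len(c("x", "y"), n))
    d <- bray_curtis(m)
    fit <- permanova(d, ~ g, data.frame(g = g), n_perm = 99, seed = 1,
                     exhaustive_cap = 2)
    expect_equal(sum(fit$table$R2), 1, tolerance = 1e-9)
    expect_equal(fit$table$R2[1], oracle_permanova_r2(d, g),
                 tolerance = 1e-12)
  }
})

test_that("PERMANOVA on perfectly separated groups attains the enumerated minimum p", {
  m <- rbind(matrix(rep(c(1, 0), each = 3), 3, 2),
             matrix(rep(c(0, 1), each = 3), 3, 2))
  rownames(m) <- paste0("s", 1:6)
  d <- bray_curtis(m)   # within 0, between 1
  fit <- permanova(d, ~ g, data.frame(g = rep(c("a", "b"), each = 3)),
                   n_perm = 99, seed = 1)
  expect_true(fit$exhaustive)
  # 10 distinct 3+3 splits; only the true split separates -> p = 1/10
  expect_equal(fit$table$p[1], 0.1, tolerance = 1e-12)
  expect_equal(fit$table$R2[1], 1, tolerance = 1e-9)
})

test_that("PERMANOVA p-values are invariant to sample ordering", {
  set.seed(13)
  # n = 6 so the permutation null is enumerated exhaustively
  m <- matrix(rexp(6 * 4), 6, 4, dimnames = list(paste0("s", 1:6), NULL))
  g <- rep(c("a", "b"), each = 3)
  d <- bray_curtis(m)
  f1 <- permanova(d, ~ g, data.frame(g = g), n_perm = 99, seed = 5)
  perm <- sample(6)
  f2 <- permanova(unclass(d)[perm, perm], ~ g, data.frame(g = g[perm]),
                  n_perm = 99, seed = 5)
  expect_true(f1$exhaustive && f2$exhaustive)
  expect_equal(f1$table$R2, f2$table$R2, tolerance = 1e-9)
  expect_equal(f1$table$p[1], f2$table$p[1], tolerance = 1e-9)
})

test_that("PERMANOVA agrees with vegan::adonis2 on sequential R2 and F", {
  set.seed(17)
  m <- matrix(rexp(12 * 6), 12, 6, dimnames = list(paste0("s", 1:12), NULL))
  md <- data.frame(g = rep(c("a", "b"), each = 6),
                   t = rep(c("p", "q", "r"), 4))
  d <- bray_curtis(m)
  fit <- permanova(d, ~ g + t, md, n_perm = 999, seed = 1,
                   exhaustive_cap = 2)
  ref <- vegan::adonis2(as.dist(d) ~ g + t, data = md, permutations = 99,
                        by = "terms")
  expect_equal(fit$table$R2[1:2], ref$R2[1:2], tolerance = 1e-9)
  expect_equal(fit$table$F[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_error(permanova(d, ~ c, data.frame(c = rep("x", 12))), "constant")
})

test_that("environmental vectors recover axis-aligned variables exactly", {
  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10),
                                                  c("NMDS1", "NMDS2")))
  pts <- scale(pts, scale = FALSE)
  env <- data.frame(v1 = pts[, 1], v2 = -pts[, 2], noise = rnorm(10),
                    const = 1)
  vf <- fit_env_vectors(pts, env, n_perm = 99, seed = 1)
  v <- vf$vectors
  expect_equal(v$r2[v$variable == "v1"], 1, tolerance = 1e-9)
  expect_equal(unlist(v[v$variable == "v1", c("NMDS1", "NMDS2")]),
               c(NMDS1 = 1, NMDS2 = 0), tolerance = 1e-6)
  expect_equal(unlist(v[v$variable == "v2", c("NMDS1", "NMDS2")]),
               c(NMDS1 = 0, NMDS2 = -1), tolerance = 1e-6)
  expect_true(v$skipped[v$variable == "const"])
  # unit direction norm
  expect_equal(sum(unlist(v[v$variable == "noise",
                            c("NMDS1", "NMDS2")])^2), 1, tolerance = 1e-9)
})

test_that("vector-fit permutation test is calibrated at the nominal level", {
  set.seed(31)
  pts <- matrix(rnorm(16), 8, 2)
  rej <- replicate(400, {
    vf <- fit_env_vectors(pts, data.frame(v = rnorm(8)), n_perm = 99,
                          seed = sample.int(1e6, 1))
    vf$vectors$p[1] <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("sharing counts enumerate Venn cells exactly", {
  sets <- list(UC = c("A", "B", "C"), C = c("B", "C", "D"), SW = "C")
  sc <- sharing_counts(sets)
  get <- function(cb) sc$count[sc$combination == cb]
  expect_equal(get("UC&C&SW"), 1)   # {C}
  expect_equal(get("UC&C"), 1)      # {B}
  expect_equal(get("UC"), 1)        # {A}
  expect_equal(get("C"), 1)         # {D}
  expect_equal(sum(sc$count), 4)

  same <- sharing_counts(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same$count[same$combination == "a&b"], 2)
  disj <- sharing_counts(list(a = "x", b = "y"))
  expect_equal(disj$count[disj$combination %in% c("a", "b")], c(1, 1))
  expect_equal(disj$count[disj$combination == "a&b"], 0)
})

test_that("module detection recovers disjoint abundance blocks", {
  m <- matrix(0, 10, 6, dimnames = list(paste0("s", 1:10), paste0("o", 1:6)))
  set.seed(4)
  m[1:5, 1:3] <- runif(15, 0.5, 1)    # block 1 occupies samples 1-5
  m[6:10, 4:6] <- runif(15, 0.5, 1)   # block 2 occupies samples 6-10
  mod <- detect_modules(m, k = 2)
  expect_equal(unname(mod[paste0("o", 1:3)]), rep(1, 3))
  expect_equal(unname(mod[paste0("o", 4:6)]), rep(2, 3))

  # k = #OTUs -> singleton modules
  expect_equal(sort(unique(detect_modules(m, k = 6))), 1:6)
  # duplicated profiles always share a module
  m2 <- m; m2[, 2] <- m2[, 1]
  for (k in 2:5) {
    mm <- detect_modules(m2, k = k)
    expect_equal(unname(mm["o1"]), unname(mm["o2"]))
  }
  expect_error(detect_modules(m, k = 7), "exceeds")
})
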