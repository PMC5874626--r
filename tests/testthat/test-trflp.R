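peak_df <- function(sizes, areas, sample = "S1")
  data.frame(sample_id = sample, size_bp = sizes, area = areas)

test_that("size-window gating keeps the closed 50-550 bp interval", {
  p <- peak_df(c(45, 50, 300, 550, 551), rep(100, 5))
  kept <- filter_size_range(p)
  expect_equal(kept$size_bp, c(50, 300, 550))
  expect_equal(nrow(filter_size_range(p[0, ])), 0)
  inside <- peak_df(c(60, 100), c(1, 2))
  expect_identical(filter_size_range(inside), inside)
})

test_that("iterative noise filtration reproduces the converged hand oracle", {
  # hand-run: pass 1 sigma = sqrt(mean(1000^2,950^2,10^2,12^2,8^2)) ~ 616.9,
  # threshold 709 -> {1000, 950}; pass 2 over {10,12,8}: sigma ~ 10.13,
  # threshold 11.65 -> promotes 12; pass 3 over {10,8}: sigma ~ 9.06,
  # threshold 10.42 -> nothing. Converged signal {1000, 950, 12}.
  fn <- filter_noise(peak_df(101:105, c(1000, 950, 10, 12, 8)))
  expect_setequal(fn$signal$area, c(1000, 950, 12))
  expect_setequal(fn$noise$area, c(10, 8))
  expect_false(fn$all_noise)

  # all-equal areas: threshold 1.15 x sigma exceeds the common area
  eq <- filter_noise(peak_df(101:104, rep(20, 4)))
  expect_true(eq$all_noise)
  expect_equal(nrow(eq$signal), 0)

  # dominance: one very large peak is always signal
  dom <- filter_noise(peak_df(101:105, c(5000, 3, 2, 4, 3)))
  expect_true(5000 %in% dom$signal$area)
})

test_that("noise filtration converges in at most n promoting passes and ignores order", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    areas <- rlnorm(n, 5, 2)
    p <- peak_df(seq_len(n) + 50, areas)
    fn <- filter_noise(p)
    expect_lte(fn$iterations - 1, n)  # each pass only moves peaks one way
    perm <- sample(n)
    fn2 <- filter_noise(p[perm, ])
    expect_setequal(fn$signal$area, fn2$signal$area)
  }
})

test_that("fragment binning matches the exhaustive single-linkage oracle", {
  one <- bin_fragments(peak_df(c(100.0, 100.4, 100.9), c(1, 1, 2)))
  expect_equal(ncol(one$abundance), 1)  # gaps 0.4, 0.5 chain into one OTU
  two <- bin_fragments(peak_df(c(100.0, 101.0), c(1, 1)))
  expect_equal(ncol(two$abundance), 2)  # gap 1.0 > 0.6 splits

  single <- bin_fragments(peak_df(123.4, 50))
  expect_equal(dim(single$abundance), c(1, 1))
  expect_equal(single$otus$centroid_bp, 123.4)

  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    sizes <- runif(n, 50, 80)
    p <- peak_df(sizes, runif(n, 1, 100),
                 sample = sample(c("A", "B"), n, replace = TRUE))
    tab <- bin_fragments(p)
    oracle <- oracle_bins(sizes, 0.6)
    expect_equal(ncol(tab$abundance), length(unique(oracle)))
    # membership agrees: sizes in the same oracle cluster share a bin
    bins <- findInterval(sizes, sort(tab$otus$size_min_bp))
    expect_equal(length(unique(paste(oracle, bins))),
                 length(unique(oracle)))
  }
})

test_that("binning sums same-sample areas and uses area-weighted centroids", {
  p <- peak_df(c(100.0, 100.3, 100.1), c(10, 30, 5),
               sample = c("A", "A", "B"))
  tab <- bin_fragments(p)
  expect_equal(ncol(tab$abundance), 1)
  expect_equal(unname(tab$abundance["A", 1]), 40)
  expect_equal(unname(tab$abundance["B", 1]), 5)
  expect_equal(tab$otus$centroid_bp,
               sum(c(100, 100.3, 100.1) * c(10, 30, 5)) / 45)
  expect_true(tab$otus$centroid_bp >= tab$otus$size_min_bp &&
                tab$otus$centroid_bp <= tab$otus$size_max_bp)
})

test_that("relative standardization normalizes rows and is scale invariant", {
  p <- rbind(peak_df(c(100, 110, 120), c(2, 1, 1), "A"),
             peak_df(c(100, 110, 120), c(20, 10, 10), "B"))
  rel <- standardize_relative(bin_fragments(p))
  expect_equal(unname(rel$abundance["A", ]), c(0.5, 0.25, 0.25))
  expect_equal(unname(rel$abundance["A", ]), unname(rel$abundance["B", ]))
  expect_equal(unname(rowSums(rel$abundance)), c(1, 1), tolerance = 1e-9)

  solo <- standardize_relative(bin_fragments(peak_df(100, 7)))
  expect_equal(unname(solo$abundance[1, 1]), 1)
})

test_that("singleton and low-abundance OTUs are removed without renormalizing", {
  set.seed(3)
  # 10 samples x 4 OTUs: OTU1 abundant everywhere, OTU2 in one sample only,
  # OTU3 at ~0.5% mean, OTU4 at ~30%
  m <- matrix(0, 10, 4, dimnames = list(paste0("s", 1:10),
                                        paste0("otu", 1:4)))
  m[, 1] <- 0.695; m[5, 2] <- 0.2; m[, 3] <- 0.005; m[, 4] <- 0.3
  m[5, ] <- m[5, ] / sum(m[5, ])
  tab <- structure(list(abundance = m, state = "relative",
                        otus = data.frame(id = colnames(m)),
                        samples = rownames(m)), class = "trf_otu_table")
  filtered <- filter_otus(tab)
  expect_false(colnames(m)[2] %in% colnames(filtered$abundance))
  expect_false(colnames(m)[3] %in% colnames(filtered$abundance))
  expect_true(colnames(m)[4] %in% colnames(filtered$abundance))
  expect_setequal(filtered$removed$id, colnames(m)[2:3])
  # rows not renormalized
  expect_equal(unname(filtered$abundance["s1", "otu4"]), 0.3)

  allgone <- structure(list(abundance = m[, 3, drop = FALSE],
                            state = "relative",
                            otus = data.frame(id = colnames(m)[3]),
                            samples = rownames(m)), class = "trf_otu_table")
  expect_error(filter_otus(allgone), "degenerate")
})

test_that("log transform is ln(1 + 100x), zero-preserving and monotone", {
  m <- matrix(c(0, 0.01, 0.25, 0.74), 1, 4,
              dimnames = list("s1", paste0("o", 1:4)))
  tab <- structure(list(abundance = m, state = "relative",
                        otus = data.frame(id = colnames(m)),
                        samples = "s1"), class = "trf_otu_table")
  lg <- log_transform(tab)
  expect_equal(unname(lg$abundance[1, 1]), 0)
  expect_equal(unname(lg$abundance[1, 2]), log(2), tolerance = 1e-12)
  expect_true(all(diff(unname(lg$abundance[1, ])) > 0))
  expect_identical(lg$state, "log")
})

test_that("the pipeline is invariant to per-sample area rescaling", {
  set.seed(21)
  p <- rbind(peak_df(c(100, 110, 120, 130), runif(4, 100, 1000), "A"),
             peak_df(c(100, 110, 125, 130), runif(4, 100, 1000), "B"))
  r1 <- run_trflp(p, filter_low_abundance = FALSE)
  p2 <- p
  p2$area[p2$sample_id == "A"] <- 10 * p2$area[p2$sample_id == "A"]
  r2 <- run_trflp(p2, filter_low_abundance = FALSE)
  expect_equal(r1$relative$abundance, r2$relative$abundance,
               tolerance = 1e-12)
})
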