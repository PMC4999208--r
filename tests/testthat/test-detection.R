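# KS testing, median differences, p-value adjustment and BE-gene calls.

test_that("ks_two_sample handles the degenerate cases", {
  same <- ks_two_sample(c(0.2, 0.5, 0.7), c(0.7, 0.2, 0.5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  apart <- ks_two_sample(c(0.1, 0.15, 0.2), c(0.6, 0.7, 0.8, 0.9))
  expect_equal(apart$statistic, 1)

  expect_error(ks_two_sample(numeric(0), 1), "at least one")
  expect_error(ks_two_sample(c(0.1, NA), c(0.2, 0.3)), "finite")
})

test_that("exact KS p-value equals the split-enumeration oracle", {
  # fixed example: 3 vs 4 disjoint samples -> 2 of the C(7,3)=35 splits reach D=1
  ex <- ks_two_sample(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6, 0.7))
  expect_equal(ex$p_value, 2 / 35)
  expect_equal(ex$p_value, oracle_ks_exact_p(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6, 0.7)),
               tolerance = 1e-12)

  # random beta-valued inputs across all size pairs with n_x + n_y <= 8
  set.seed(11)
  for (rep in seq_len(60)) {
    nx <- sample(1:7, 1)
    ny <- sample(seq_len(8 - nx), 1)
    x <- round(runif(nx), 3)
    y <- round(runif(ny), 3)  # rounding provokes occasional ties
    got <- ks_two_sample(x, y)
    expect_equal(got$p_value, oracle_ks_exact_p(x, y), tolerance = 1e-12,
                 info = sprintf("nx=%d ny=%d", nx, ny))
  }
})

test_that("large samples switch to the asymptotic Kolmogorov distribution", {
  set.seed(2)
  x <- runif(150); y <- runif(150)   # 150*150 > 10000
  got <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("median_difference matches hand-computed medians", {
  expect_equal(median_difference(c(0.55, 0.65), c(0.5)), 0.1)
  expect_equal(median_difference(c(0.3, 0.1), c(0.1, 0.3)), 0)
  # medians: mid(0.2, 0.4) = 0.3 and median(0.1, 0.3, 0.9) = 0.3
  expect_equal(median_difference(c(0.2, 0.4), c(0.1, 0.3, 0.9)), 0)
  expect_equal(median_difference(c(0.2, NA), c(0.4, 0.6, NA)), 0.3)
  expect_error(median_difference(c(NA_real_), c(0.2)), "empty")
})

test_that("p-value adjustment reproduces hand-computed BH and Bonferroni values", {
  expect_equal(adjust_pvalues(0.04, "fdr"), 0.04)
  expect_equal(adjust_pvalues(0.04, "bonferroni"), 0.04)
  expect_equal(adjust_pvalues(0.04, "hommel"), 0.04)

  # BH step-up by hand: p*m/i = {.04,.04,.04,.04}; cumulative min from top
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr"),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1.0))

  # order-preserving pairing with the input, against the independent oracle
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(adjust_pvalues(p, "fdr"), oracle_bh(p))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("detect_be_genes applies both tests with a strict mdif inequality", {
  # 3 features x 12 samples, 3 batches of 4; f1 constant, f2 shifted by
  # exactly 0.05 in batch A (boundary), f3 strongly shifted in batch A.
  base <- c(0.2, 0.21, 0.19, 0.2)
  beta <- rbind(
    f1 = rep(0.5, 12),
    f2 = c(base + 0.05, base, base),
    f3 = c(base + 0.4, base, base))
  colnames(beta) <- paste0("s", 1:12)
  batches <- batch_fixture(beta, rep(c("A", "B", "C"), each = 4))

  tab <- suppressWarnings(detect_be_genes(beta, batches))
  expect_setequal(names(tab),
                  c("feature_id", "batch_id", "ks_p", "adj_p", "mdif",
                    "n_in_batch", "is_BE"))
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$adj_p >= tab$ks_p - 1e-12))

  f1 <- tab[tab$feature_id == "f1", ]
  expect_true(all(!f1$is_BE))
  expect_true(all(f1$mdif == 0))

  f2A <- tab[tab$feature_id == "f2" & tab$batch_id == "A", ]
  expect_equal(f2A$mdif, 0.05)
  expect_false(f2A$is_BE)  # "larger than 0.05" is strict

  f3A <- tab[tab$feature_id == "f3" & tab$batch_id == "A", ]
  expect_equal(f3A$mdif, 0.4)
  expect_true(f3A$is_BE)
})

test_that("detection warns on small batches and rejects single-batch input", {
  beta <- beta_fixture(runif(20, 0.3, 0.5), 4, 5)
  batches <- batch_fixture(beta, c("A", "A", "A", "A", "B"))
  expect_warning(detect_be_genes(beta, batches), "fewer than 5")

  expect_error(
    suppressWarnings(detect_be_genes(beta, batch_fixture(beta, rep("A", 5)))),
    "at least 2")
})

test_that("a strong shift in one batch is reliably detected", {
  # one feature shifted +0.3 in a 10-sample batch vs 50 samples at ~0.2
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    vals <- matrix(rnorm(5 * 60, 0.2, 0.02), 5, 60)
    vals[1, 1:10] <- vals[1, 1:10] + 0.3
    vals <- pmin(pmax(vals, 0), 1)
    dimnames(vals) <- list(paste0("f", 1:5), paste0("s", 1:60))
    batches <- batch_fixture(vals, rep(c("A", "B", "C", "D", "E", "F"), each = 10))
    tab <- detect_be_genes(vals, batches)
    hit <- tab$is_BE[tab$feature_id == "f1" & tab$batch_id == "A"]
    hits <- hits + as.integer(hit)
    # and nothing else is flagged
    expect_equal(sum(tab$is_BE), as.integer(hit))
  }
  expect_equal(hits, 10L)
})

test_that("detected BE-gene count is monotone in the injected shift", {
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(k) {
    spec <- small_bench_spec(seed = 4, k = 0)
    sim <- simulate_beta_matrix(spec)
    aff <- rownames(sim$beta)[1:150]
    # fixed absolute shift in beta units: k here acts via a constant-SD trick
    inj <- sim$beta
    cols <- which(sim$batches$batch_id == "B01")
    inj[aff, cols] <- pmin(1, inj[aff, cols] + k)
    tab <- detect_be_genes(inj, sim$batches)
    sum(tab$is_BE)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[4], counts[1])
})

test_that("per-batch and global FDR families agree on nulls and rank power sensibly", {
  spec <- small_bench_spec(seed = 9, k = 3)
  bench <- simulate_benchmark(spec)
  per_batch <- detect_be_genes(bench$beta, bench$batches, fdr_family = "per_batch")
  glob <- detect_be_genes(bench$beta, bench$batches, fdr_family = "global")
  # on this data the global family, diluted by 12 null batches, is the
  # more conservative of the two, and both concentrate calls in the
  # affected batch
  expect_lte(sum(glob$is_BE), sum(per_batch$is_BE))
  expect_gt(sum(glob$is_BE), 0)
  aff <- bench$affected_batch
  expect_gt(sum(per_batch$is_BE[per_batch$batch_id == aff]),
            0.9 * sum(per_batch$is_BE))
})
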