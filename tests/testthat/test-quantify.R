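test_that("rpkm matches hand arithmetic and is scale invariant", {
  counts <- matrix(c(0, 1000), 1, dimnames = list("s1", c("t1", "t2")))
  ab <- rpkm(counts, c(t1 = 1e6, t2 = 2e6), 1e7)
  expect_equal(ab["s1", "t1"], 0)
  expect_equal(ab["s1", "t2"], 1000 / (2000 * 10))   # 0.05
  ab2 <- rpkm(counts * 2, c(t1 = 1e6, t2 = 2e6), 2e7)
  expect_equal(ab2, ab)
  expect_error(rpkm(counts, c(t1 = 1e6, t2 = 2e6),
                    stats::setNames(0, "s1")), "s1")
})

test_that("shannon: closed forms, errors, and vegan oracle", {
  expect_equal(shannon(c(0, 5, 0)), 0)
  expect_equal(shannon(rep(2, 4)), log(4))
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "non-negative")
  skip_if_not_installed("vegan")
  set.seed(1)
  for (i in 1:10) {
    x <- stats::runif(8)
    expect_equal(shannon(x), unname(vegan::diversity(x)), tolerance = 1e-12)
  }
})

test_that("shannon is maximal iff uniform", {
  set.seed(2)
  k <- 6
  hmax <- shannon(rep(1, k))
  for (i in 1:25) {
    x <- stats::rgamma(k, 1)
    h <- shannon(x)
    expect_lte(h, hmax + 1e-12)
    if (max(abs(x / sum(x) - 1 / k)) > 1e-3) expect_lt(h, hmax)
  }
})

test_that("bray_curtis: closed forms, invariants, vegan oracle", {
  m <- rbind(a = c(6, 2), b = c(2, 2), c = c(6, 2), d = c(5, 0),
             e = c(0, 3))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["d", "e"], 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(z1 = c(0, 0), z2 = c(0, 0))), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(3)
  x <- matrix(stats::rgamma(60, 1), 6,
              dimnames = list(letters[1:6], NULL))
  expect_equal(bray_curtis(x),
               as.matrix(vegan::vegdist(x, method = "bray")),
               tolerance = 1e-12)
})

test_that("within_between_test enumerates pairs and handles ties", {
  # one 2-member family + one singleton: 1 within, 2 between
  meta <- make_meta(2, c(2, 1))
  ch <- family_cohort(meta)
  d <- dist_mat(matrix(c(0, .1, .5, .1, 0, .6, .5, .6, 0), 3),
                meta$sample_id)
  wb <- within_between_test(d, ch)
  expect_length(wb$within, 1)
  expect_length(wb$between, 2)
  expect_equal(length(wb$within) + length(wb$between), choose(3, 2))
  # identical distributions -> p = 1 under exact enumeration
  d2 <- dist_mat(matrix(.4, 3, 3) - diag(.4, 3), meta$sample_id)
  expect_equal(within_between_test(d2, ch)$wilcoxon_p, 1)
  # no within pair
  ch2 <- family_cohort(make_meta(3, 1))
  d3 <- dist_mat(matrix(.2, 3, 3) - diag(.2, 3), ch2$samples$sample_id)
  expect_error(within_between_test(d3, ch2), "within-family")
})

test_that("within/between pair count identity holds on random cohorts", {
  for (seed in 1:4) {
    set.seed(seed)
    nf <- sample(2:5, 1)
    meta <- make_meta(nf, sample(1:3, nf, replace = TRUE))
    n <- nrow(meta)
    if (sum(choose(table(meta$family_id), 2)) == 0) next
    x <- matrix(stats::runif(n * 3), n)
    d <- dist_mat(as.matrix(stats::dist(x)) / 3, meta$sample_id)
    wb <- within_between_test(d, family_cohort(meta))
    expect_equal(length(wb$within) + length(wb$between), choose(n, 2))
  }
})

test_that("planted family effect: within distances below between", {
  sc <- generate_cohort(simulation_config(
    n_families = 8, members_per_family = 3, n_species = 1,
    n_abundance_taxa = 30, genome_length = 900, family_effect_size = 1,
    seed = 10))
  wb <- within_between_test(bray_curtis(sc$abundance), sc$cohort)
  expect_lt(stats::median(wb$within), stats::median(wb$between))
  expect_lt(wb$wilcoxon_p, 0.05)
})

test_that("child_parent_trend reproduces hand-computed correlations", {
  meta <- do.call(rbind, lapply(1:4, function(f)
    data.frame(sample_id = c(sprintf("p%d", f), sprintf("c%d", f)),
               family_id = sprintf("F%d", f),
               role = c("father", "child"), ethnicity = "Daur",
               sex = "M", age = c(40, f), region = "regionA")))
  ch <- family_cohort(meta)
  ids <- meta$sample_id
  base <- matrix(0.9, 8, 8); diag(base) <- 0
  d <- dist_mat(base, ids)
  set_cp <- function(d, vals) {
    for (f in 1:4) {
      d[sprintf("c%d", f), sprintf("p%d", f)] <- vals[f]
      d[sprintf("p%d", f), sprintf("c%d", f)] <- vals[f]
    }
    d
  }
  # ages 1:4 against distances (0.4, 0.1, 0.3, 0.2): rho = -0.4 by the
  # rank formula 1 - 6*sum(d^2)/(n(n^2-1)) with d = (-3, 1, 0, 2)
  tr <- child_parent_trend(set_cp(d, c(0.4, 0.1, 0.3, 0.2)), ch)
  expect_equal(tr$rho, -0.4)
  expect_equal(tr$n_pairs, 4)
  # monotone case
  expect_equal(child_parent_trend(set_cp(d, c(0.1, 0.2, 0.3, 0.4)), ch)$rho, 1)
  # constant distances: all-tied convention rho = 0, p = 1
  tr0 <- child_parent_trend(set_cp(d, rep(0.3, 4)), ch)
  expect_equal(tr0$rho, 0)
  expect_equal(tr0$p_value, 1)
  # fewer than 3 pairs errors
  ch2 <- family_cohort(meta[1:4, ])
  expect_error(child_parent_trend(dist_mat(base[1:4, 1:4], ids[1:4]), ch2),
               "at least 3")
})

test_that("diversity_similarity_trend: monotone case and order invariance", {
  meta <- make_meta(3, 2)
  ch <- family_cohort(meta)
  ids <- meta$sample_id
  d <- matrix(0.8, 6, 6); diag(d) <- 0
  within <- rbind(c(1, 2), c(3, 4), c(5, 6))
  for (k in 1:3) {
    d[within[k, 1], within[k, 2]] <- d[within[k, 2], within[k, 1]] <-
      c(0.6, 0.4, 0.2)[k]
  }
  d <- dist_mat(d, ids)
  div <- data.frame(sample_id = ids, shannon = rep(c(1, 2, 3), each = 2))
  tr <- diversity_similarity_trend(d, div, ch)
  expect_equal(tr$rho, -1)
  expect_equal(tr$n_pairs, 3)
  # permuting sample order leaves rho unchanged
  perm <- c(4, 3, 6, 5, 1, 2)
  tr2 <- diversity_similarity_trend(d[perm, perm], div, ch)
  expect_equal(tr2$rho, tr$rho)
})

test_that("spearman_test and wilcoxon_rank_sum match stats oracles", {
  set.seed(4)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  st <- spearman_test(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(st$rho, unname(ref$estimate))
  expect_equal(st$p_value, ref$p.value, tolerance = 1e-10)
  # exact enumeration branch agrees with cor.test exact p for tie-free n=6
  x6 <- c(3, 1, 4, 1.5, 5, 9); y6 <- c(2, 7, 1, 8, 2.8, 6)
  st6 <- spearman_test(x6, y6)
  ref6 <- stats::cor.test(x6, y6, method = "spearman", exact = TRUE)
  expect_equal(st6$p_value, ref6$p.value, tolerance = 1e-12)
  # wilcoxon exact branch vs wilcox.test for tie-free samples
  a <- c(1.1, 2.3, 0.7, 5.2, 3.3); b <- c(2.2, 6.1, 4.4, 0.5, 7.7, 8.1)
  expect_equal(wilcoxon_rank_sum(a, b),
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # approximate branch vs wilcox.test with continuity correction
  set.seed(5)
  a2 <- stats::rnorm(15); b2 <- stats::rnorm(12, 0.5)
  expect_equal(wilcoxon_rank_sum(a2, b2),
               stats::wilcox.test(a2, b2, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-10)
})
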