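test_that("Wilcoxon rank-sum handles exact, tied and degenerate inputs", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p.value, 1 / 3) # full enumeration over C(4,2) assignments
  expect_equal(w$statistic, 0)

  expect_warning(w0 <- wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7) * 0 + 5),
                 NA) # not constant-identical, no warning path
  expect_warning(wc <- wilcoxon_rank_sum(c(5, 5), c(5, 5)), "identical")
  expect_equal(wc$p.value, 1)
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), "at least 2")
})

test_that("exact Wilcoxon path agrees with full rank enumeration", {
  set.seed(31)
  for (i in 1:100) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    got <- wilcoxon_rank_sum(x, y)
    want <- oracle_wilcox_exact(x, y)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks enumeration for moderate samples", {
  # deterministic sweep of every achievable 6+6 statistic; the continuity-
  # corrected approximation deviates at most ~0.0155 from enumeration (at
  # mid-range p), and under 0.01 wherever p < 0.2
  r <- 1:12
  all_u <- apply(combn(12, 6), 2, function(idx) sum(r[idx]) - 6 * 7 / 2)
  for (u in 0:36) {
    exact <- min(1, 2 * min(mean(all_u <= u), mean(all_u >= u)))
    x <- rep(0, 6)
    sig <- sqrt(6 * 6 * 13 / 12)
    z <- (u - 18 - sign(u - 18) * 0.5) / sig
    approx <- if (u == 18) 1 else 2 * pnorm(-abs(z))
    expect_lt(abs(approx - exact), 0.016)
    if (exact < 0.2) expect_lt(abs(approx - exact), 0.01)
  }
})

test_that("Benjamini-Hochberg is a capped monotone step-up adjustment", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.5), 0.5)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- adjust_bh(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone in p
  }
})

test_that("Bray-Curtis follows the normalized absolute-difference formula", {
  m <- rbind(u = c(1, 2), v = c(2, 1), w = c(0, 5), z = c(3, 0))
  d <- bray_curtis(m)
  expect_equal(d["u", "u"], 0)
  expect_equal(d["u", "v"], 1 / 3)
  expect_equal(d["w", "z"], 1) # disjoint supports
  expect_equal(d, t(d))
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "Zero-total")
})

test_that("PERMANOVA pseudo-F matches the loop oracle and vegan", {
  set.seed(34)
  m <- matrix(rpois(8 * 12, 8), 8, 12,
              dimnames = list(paste0("s", 1:8), NULL))
  labels <- rep(c("PD", "REF"), each = 4)
  d <- bray_curtis(m)
  res <- permanova(d, labels, seed = 35)
  expect_equal(res$statistic, oracle_permanova_f(d, labels),
               tolerance = 1e-10)
  ad <- vegan::adonis2(stats::as.dist(d) ~ g,
                       data = data.frame(g = labels), permutations = 99)
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-8)
})

test_that("PERMANOVA enumerates small designs exactly", {
  # two tight, well separated clusters of 3
  x <- rbind(matrix(rnorm(6, 0, 0.01), 3), matrix(rnorm(6, 10, 0.01), 3))
  d <- as.matrix(stats::dist(x))
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  labels <- rep(c("A", "B"), each = 3)
  res <- permanova(d, labels)
  expect_equal(res$method, "exact")
  expect_equal(res$n_permutations, choose(6, 3))
  # minimum achievable p over all 20 assignments (observed + complement)
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    oracle_permanova_f(d, ifelse(seq_len(6) %in% idx, "A", "B"))
  })
  p_min <- sum(f_all >= max(f_all) * (1 - 1e-9)) / ncol(combos)
  expect_equal(res$p.value, p_min)
  expect_equal(p_min, 2 / 20)
})

test_that("sampled PERMANOVA p agrees with enumeration within Monte-Carlo error", {
  set.seed(36)
  m <- matrix(rpois(6 * 10, 6) + rep(c(0, 3), each = 3), 6, 10,
              dimnames = list(paste0("s", 1:6), NULL))
  d <- bray_curtis(m)
  labels <- rep(c("A", "B"), each = 3)
  exact <- permanova(d, labels)
  sampled <- permanova(d, labels, n_permutations = 2000, seed = 37,
                       exact_limit = 1)
  se <- sqrt(exact$p.value * (1 - exact$p.value) / 2000)
  expect_lt(abs(sampled$p.value - exact$p.value), 3 * se + 2 / 2000)
})

test_that("all-zero distances are rejected as degenerate", {
  sim <- simulate_count_table(c(3, 3), n_families = 1, effect_size = 0,
                              seed = 38)
  tbl <- sim$table
  tbl$fam_001 <- 5 # identical single-family counts
  d <- bray_curtis(as.matrix(tbl[, "fam_001", drop = FALSE]) +
                     matrix(0, 6, 1, dimnames = list(tbl$genome_id, NULL)))
  expect_error(permanova(d, tbl$group_label), "Degenerate")
})

test_that("NMDS embeds easy geometries with near-zero stress", {
  d3 <- matrix(1, 3, 3) - diag(3)
  rownames(d3) <- colnames(d3) <- paste0("s", 1:3)
  r <- nmds_ordination(d3, k = 2, seed = 39, n_starts = 5)
  expect_lt(r$stress, 1e-6)

  set.seed(40)
  pts <- matrix(rnorm(20 * 2), 20, 2)
  d <- as.matrix(stats::dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:20)
  r2 <- nmds_ordination(d, k = 2, seed = 41)
  expect_lt(r2$stress, 0.05)
  r3 <- nmds_ordination(d, k = 3, seed = 41)
  expect_lte(r3$stress, r2$stress + 1e-8)
})

test_that("compare_traits flags programmed shifts and nothing for null tables", {
  tt <- simulate_trait_table(
    20, 20,
    means = setNames(rep(5, 20), paste0("aa_", letters[1:20])),
    sds = setNames(rep(0.2, 20), paste0("aa_", letters[1:20])),
    focal_shift = c(aa_a = 1), seed = 42)
  res <- compare_traits(tt)
  hit <- res[res$trait == "aa_a", ]
  expect_equal(hit$direction, "up_in_PD")
  expect_lt(hit$p_adj, 0.05)
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))

  # identical groups: everything NS
  same <- tt
  same$group_label <- rep(c("PD", "REF"), 20)
  same[paste0("aa_", letters[1:20])] <-
    same[rep(seq_len(20), each = 2), paste0("aa_", letters[1:20])]
  res0 <- suppressWarnings(compare_traits(same))
  expect_true(all(res0$stars == "NS"))

  # row permutation leaves results unchanged
  perm <- tt[sample(nrow(tt)), ]
  expect_equal(compare_traits(perm), res)
})
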