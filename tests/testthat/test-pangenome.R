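pa_matrix <- function(m) {
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("G", seq_len(ncol(m)))
  m
}

test_that("matrix validation binarizes, drops empty genes and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tG1\tG2", "a\t2\t0", "b\t1\t1", "c\t0\t0"), path)
  expect_warning(expect_warning(m <- read_pa_matrix(path), "binarizing"),
                 "absent from every genome")
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(m %in% c(0L, 1L)))

  bad <- pa_matrix(matrix(c(1, 0, 0, 0), 2, 2))
  expect_warning(expect_error(cryosig:::validate_pa_matrix(bad),
                              "at least one gene"),
                 "absent")
})

test_that("rarefaction pan/core curves behave on constructed models", {
  # two identical genomes
  ident <- pa_matrix(matrix(1L, 10, 2))
  r <- rarefy(ident, n_permutations = 10, seed = 1)
  expect_true(all(r$pan == 10) && all(r$core == 10))
  expect_equal(r$summary$median_new, c(10, 0))

  # 100 core + 50 unique per genome, G = 10: exact closed-form curves
  sim <- simulate_presence_absence(
    pangenome_sim_spec(10, core_size = 100, model = "constant_unique",
                       unique_per_genome = 50, seed = 2))
  r2 <- rarefy(sim$matrix, n_permutations = 40, seed = 3)
  expect_equal(r2$summary$median_pan, 100 + 50 * (1:10))
  # the first genome alone has all 150 of its genes "core"
  expect_equal(r2$summary$median_core, c(150, rep(100, 9)))
  expect_equal(r2$summary$median_new[-1], rep(50, 9))

  # invariants on a random matrix: monotone curves, endpoints exact
  set.seed(4)
  m <- pa_matrix(matrix(rbinom(200 * 6, 1, 0.5), 200, 6))
  m <- m[rowSums(m) > 0, ]
  r3 <- rarefy(m, n_permutations = 25, seed = 5)
  expect_true(all(apply(r3$pan, 1, function(v) all(diff(v) >= 0))))
  expect_true(all(apply(r3$core, 1, function(v) all(diff(v) <= 0))))
  expect_true(all(r3$pan[, 6] == nrow(m)))
  expect_true(all(r3$core[, 6] == sum(rowSums(m) == 6)))
})

test_that("rarefaction is seed-deterministic", {
  sim <- simulate_presence_absence(pangenome_sim_spec(8, core_size = 50,
                                                      seed = 6))
  a <- rarefy(sim$matrix, n_permutations = 30, seed = 42)
  b <- rarefy(sim$matrix, n_permutations = 30, seed = 42)
  expect_identical(a$summary, b$summary)
  expect_identical(a$pan, b$pan)
  expect_error(rarefy(sim$matrix, n_permutations = 10), "seed")
})

test_that("exhaustive rarefaction medians match a set-based oracle", {
  set.seed(8)
  m <- pa_matrix(matrix(rbinom(60 * 5, 1, 0.4), 60, 5))
  m <- m[rowSums(m) > 0, ]
  r <- rarefy(m, exhaustive = TRUE)
  expect_equal(r$n_permutations, factorial(5))
  want <- oracle_rarefaction(m)
  expect_equal(r$summary$median_pan, want$median_pan)
  expect_equal(r$summary$median_core, want$median_core)
})

test_that("Heaps fit recovers exact and noisy power laws", {
  # constant-unique: alpha = 0, kappa = 50 at fit tolerance
  sim <- simulate_presence_absence(
    pangenome_sim_spec(10, core_size = 100, model = "constant_unique",
                       unique_per_genome = 50, seed = 9))
  r <- rarefy(sim$matrix, n_permutations = 30, seed = 10)
  fit <- fit_heaps(r, "pan_new_genes")
  expect_equal(fit$alpha, 0, tolerance = 1e-6)
  expect_equal(fit$kappa, 50, tolerance = 1e-6)
  expect_true(fit$open)

  # noise-free synthetic curve: parameters back to 1e-6
  G <- 30
  exact <- structure(list(
    summary = tibble::tibble(N = 1:G),
    new = matrix(rep(500 * (1:G)^(-0.6), each = 3), 3, G, byrow = FALSE),
    core = matrix(rep(2000 * (1:G)^(-0.2), each = 3), 3, G, byrow = FALSE)),
    class = "rarefaction_result")
  f2 <- fit_heaps(exact, "pan_new_genes")
  expect_equal(f2$alpha, 0.6, tolerance = 1e-6)
  expect_equal(f2$kappa, 500, tolerance = 1e-4)
  f3 <- fit_heaps(exact, "core_decay")
  expect_equal(f3$alpha, 0.2, tolerance = 1e-6)

  # identical genomes: degenerate
  ident <- pa_matrix(matrix(1L, 20, 5))
  r0 <- rarefy(ident, n_permutations = 5, seed = 11)
  expect_error(fit_heaps(r0, "pan_new_genes"), "Degenerate")
})

test_that("predict_discovery evaluates the fitted forms", {
  sim <- simulate_presence_absence(
    pangenome_sim_spec(10, core_size = 100, model = "constant_unique",
                       unique_per_genome = 50, seed = 12))
  fit <- fit_heaps(rarefy(sim$matrix, n_permutations = 20, seed = 13),
                   "pan_new_genes")
  expect_equal(predict_discovery(fit, 11), 50, tolerance = 1e-5)
  expect_error(predict_discovery(fit, 1), ">= 2")

  manual <- structure(list(kappa = 500, alpha = 0.6,
                           curve = "pan_new_genes"), class = "heaps_fit")
  expect_equal(predict_discovery(manual, 71), 500 * 71^(-0.6))
  manual$curve <- "core_decay"
  expect_equal(predict_discovery(manual, 71),
               500 * (70^(-0.6) - 71^(-0.6)))
})

test_that("gene partition bins occupancy per the published thresholds", {
  m <- pa_matrix(rbind(c(1, rep(0, 9)), rep(1, 10)))
  p <- partition_genes(m)
  expect_equal(p$partition$count[p$partition$category == "cloud"], 1L)
  expect_equal(p$partition$count[p$partition$category == "strict_core"], 1L)

  # exactly 95% occupancy (19/20) is soft core, boundary inclusive
  m2 <- pa_matrix(rbind(c(rep(1, 19), 0), rep(1, 20)))
  p2 <- partition_genes(m2)
  expect_equal(p2$partition$count[p2$partition$category == "soft_core"], 1L)

  set.seed(14)
  m3 <- pa_matrix(matrix(rbinom(500 * 20, 1, 0.3), 500, 20))
  m3 <- m3[rowSums(m3) > 0, ]
  p3 <- partition_genes(m3)
  expect_equal(sum(p3$partition$count), nrow(m3))
  expect_equal(sum(p3$partition$percent), 100, tolerance = 0.01)
  expect_equal(sum(p3$literal$count), nrow(m3))

  # identical genomes: 100% strict core
  ident <- simulate_presence_absence(
    pangenome_sim_spec(6, core_size = 40, model = "identical", seed = 15))
  pi_ <- partition_genes(ident$matrix)
  expect_equal(pi_$partition$percent[pi_$partition$category == "strict_core"],
               100)
})
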