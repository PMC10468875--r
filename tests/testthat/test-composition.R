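test_that("gc_content excludes ambiguity codes from both terms", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("GCNN"), 100)
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content(""), "non-empty")
})

test_that("codon-position GC pools codons and matches the striding oracle", {
  expect_equal(unname(codon_position_gc("ATGGCC")), c(50, 50, 100))
  expect_equal(unname(codon_position_gc(c("ATG", "ATG"))), c(0, 0, 100))
  expect_error(codon_position_gc("ATGA"), "divisible")

  set.seed(5)
  seqs <- vapply(1:100, function(i) random_cds(sample(10:60, 1)),
                 character(1))
  expect_equal(unname(codon_position_gc(seqs)), oracle_codon_gc(seqs),
               tolerance = 1e-12)

  per <- codon_position_gc(seqs[1:5], pooled = FALSE)
  expect_equal(nrow(per), 5L)
  expect_equal(unname(unlist(per[1, c("gc1", "gc2", "gc3")])),
               oracle_codon_gc(seqs[1]))
})

test_that("aa_composition pools residues and drops non-standard letters", {
  p <- aa_composition("KK")
  expect_equal(p[["K"]], 1)
  expect_equal(sum(p), 1)
  p2 <- aa_composition(c("KR", "RK"))
  expect_equal(p2[["K"]], 0.5)
  expect_equal(p2[["R"]], 0.5)
  expect_equal(aa_composition("KXK")[["K"]], 1) # X excluded
  expect_error(aa_composition("XX"), "no standard residues")

  # invariant under concatenation order
  set.seed(9)
  prots <- vapply(1:30, function(i) random_peptide(sample(20:80, 1)),
                  character(1))
  expect_equal(aa_composition(prots), aa_composition(rev(prots)))
})

test_that("aa proportions recover multinomial sampling frequencies within 3 SE", {
  set.seed(21)
  f <- cryosig:::default_aa_freq()
  n <- 60000
  prot <- paste(sample(names(f), n, TRUE, prob = f), collapse = "")
  got <- aa_composition(prot)
  se <- sqrt(f * (1 - f) / n)
  expect_true(all(abs(got - f) <= 3 * se + 1e-12))
})

test_that("coding_density uses the interval union across contigs", {
  mk <- function(features) {
    genome_record("g", tibble::tibble(contig_id = "c", seq = strrep("A", 12)),
                  features)
  }
  one <- mk(tibble::tibble(contig_id = "c", start = 1L, end = 6L,
                           strand = "+", ftype = "CDS", product = NA,
                           locus_tag = "a"))
  expect_equal(coding_density(one), 50)
  dup <- mk(tibble::tibble(contig_id = "c", start = c(1L, 1L),
                           end = c(6L, 6L), strand = "+", ftype = "CDS",
                           product = NA, locus_tag = c("a", "b")))
  expect_equal(coding_density(dup), 50) # overlap counted once

  # random interval sets vs per-base boolean mask oracle
  set.seed(13)
  for (i in 1:20) {
    L <- 200L
    k <- sample(1:8, 1)
    s <- sample(seq_len(L - 20), k, replace = TRUE)
    e <- pmin(L, s + sample(5:30, k, replace = TRUE))
    g <- genome_record("g",
                       tibble::tibble(contig_id = "c", seq = strrep("A", L)),
                       tibble::tibble(contig_id = "c", start = as.integer(s),
                                      end = as.integer(e), strand = "+",
                                      ftype = "CDS", product = NA,
                                      locus_tag = paste0("f", seq_len(k))))
    mask <- logical(L)
    for (j in seq_len(k)) mask[s[j]:e[j]] <- TRUE
    expect_equal(coding_density(g), 100 * sum(mask) / L)
  }
})

test_that("element_gc separates genomic element classes", {
  g <- tiny_genome()
  # c1 CDS "ATGAAATAA" (hypothetical), c2 CDS -> "ATGGGCTAA";
  # tRNA "GGGG", rRNA "AAAA"
  e <- element_gc(g)
  expect_equal(e[["gc_hypothetical"]], gc_content("ATGAAATAA"))
  expect_equal(e[["gc_cds"]], cryosig:::gc_pooled(c("ATGAAATAA", "ATGGGCTAA")))
  expect_equal(e[["gc_trna"]], 100)
  expect_equal(e[["gc_rrna"]], 0)
  expect_equal(e[["gc_rna"]], 50)
  expect_equal(e[["gc_genomic"]], cryosig:::gc_pooled(g$contigs$seq))

  # a class with no members is undefined, not zero
  g2 <- g
  g2$features <- g2$features[g2$features$ftype != "rRNA", ]
  expect_true(is.na(element_gc(g2)[["gc_rrna"]]))
})

test_that("composition profile satisfies the pooled GC identity", {
  sim <- simulate_genomes(genome_sim_spec(n_pd = 2, n_ref = 2,
                                          genes_per_genome = 80,
                                          gene_len_mean = 120, seed = 5))
  prof <- suppressMessages(composition_profiles(sim$genomes))
  expect_equal(nrow(prof), 4L)
  # ambiguity-free CDS: gc_cds is exactly the mean of GC1, GC2, GC3
  expect_equal(prof$gc_cds, (prof$gc1 + prof$gc2 + prof$gc3) / 3,
               tolerance = 1e-9)
  aa_cols <- grep("^aa_", names(prof))
  expect_equal(unname(rowSums(prof[, aa_cols])), rep(1, 4),
               tolerance = 1e-9)
  expect_true(all(prof$coding_density > 0 & prof$coding_density <= 100))
})

test_that("two-group genome sets recover the programmed GC3 offset", {
  spec <- genome_sim_spec(n_pd = 20, n_ref = 20, genes_per_genome = 150,
                          gene_len_mean = 150, gene_len_sd = 40,
                          pd_gc3_offset = -3, seed = 101)
  sim <- simulate_genomes(spec)
  gc3 <- vapply(sim$genomes, function(g) {
    cds <- g$features[g$features$ftype == "CDS", ]
    codon_position_gc(extract_feature_seq(g, cds))[["gc3"]]
  }, numeric(1))
  groups <- vapply(sim$genomes, function(g) g$group_label, character(1))
  # pooled (group-mean) difference close to the programmed -3 points
  diff <- mean(gc3[groups == "PD"]) - mean(gc3[groups == "REF"])
  expect_lt(abs(diff - (-3)), 0.5)
  # and per-genome medians separate in the right direction
  expect_lt(median(gc3[groups == "PD"]), median(gc3[groups == "REF"]))
})
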