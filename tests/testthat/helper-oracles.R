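# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation (loops, string striding, exhaustive enumeration) that
# shares no code path with the package internals it checks.

oracle_n50 <- function(lengths) {
  # exhaustive scan over candidate L values, largest first: N50 is the
  # largest contig length whose at-least-L contigs cover half the assembly
  half <- sum(lengths) / 2
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= half) return(L)
  }
  stop("no candidate found")
}

oracle_codon_gc <- function(seqs) {
  # string striding, character by character
  chars <- unlist(strsplit(seqs, "", fixed = TRUE))
  pos <- rep_len(1:3, length(chars))
  vapply(1:3, function(p) {
    cc <- chars[pos == p]
    cc <- cc[cc %in% c("A", "C", "G", "T")]
    100 * sum(cc %in% c("G", "C")) / length(cc)
  }, numeric(1))
}

oracle_translate <- function(seq) {
  # dictionary lookup codon by codon
  tab <- Biostrings::getGeneticCode("11")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(unname(tab[codons]), collapse = "")
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "", fixed = TRUE)[[1]]]), collapse = "")
}

oracle_flexibility <- function(protein, scale, window) {
  # naive double loop over window positions and residues
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(v)
  if (n < window) return(NA_real_)
  scores <- numeric(n - window + 1)
  for (i in seq_len(n - window + 1)) {
    s <- 0
    for (j in i:(i + window - 1)) s <- s + scale[[v[j]]]
    scores[i] <- s / window
  }
  mean(scores)
}

oracle_pi_grid <- function(protein, pka, step = 1e-4) {
  # dense grid scan for the pH of minimal |net charge|
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  cnt <- c(K = sum(v == "K"), R = sum(v == "R"), H = sum(v == "H"),
           D = sum(v == "D"), E = sum(v == "E"), C = sum(v == "C"),
           Y = sum(v == "Y"))
  pH <- seq(0, 14, by = step)
  q <- 1 / (1 + 10^(pH - pka[["nterm"]])) +
    cnt[["K"]] / (1 + 10^(pH - pka[["K"]])) +
    cnt[["R"]] / (1 + 10^(pH - pka[["R"]])) +
    cnt[["H"]] / (1 + 10^(pH - pka[["H"]])) -
    1 / (1 + 10^(pka[["cterm"]] - pH)) -
    cnt[["D"]] / (1 + 10^(pka[["D"]] - pH)) -
    cnt[["E"]] / (1 + 10^(pka[["E"]] - pH)) -
    cnt[["C"]] / (1 + 10^(pka[["C"]] - pH)) -
    cnt[["Y"]] / (1 + 10^(pka[["Y"]] - pH))
  pH[which.min(abs(q))]
}

oracle_wilcox_exact <- function(x, y) {
  # full enumeration of rank assignments; two-sided p as twice the
  # smaller tail, capped at 1
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  all_u <- apply(combn(nx + ny, nx), 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  list(statistic = u_obs, p.value = min(1, p))
}

oracle_rarefaction <- function(m) {
  # set-based accumulation over every genome order
  G <- ncol(m)
  orders <- cryosig:::all_orders(G)
  gene_sets <- lapply(seq_len(G), function(j) which(m[, j] == 1))
  pan <- core <- matrix(0L, nrow(orders), G)
  for (p in seq_len(nrow(orders))) {
    u <- integer(0); s <- NULL
    for (k in seq_len(G)) {
      gs <- gene_sets[[orders[p, k]]]
      u <- union(u, gs)
      s <- if (is.null(s)) gs else intersect(s, gs)
      pan[p, k] <- length(u)
      core[p, k] <- length(s)
    }
  }
  list(median_pan = apply(pan, 2, median),
       median_core = apply(core, 2, median))
}

oracle_permanova_f <- function(d, labels) {
  # Anderson's pseudo-F computed with explicit loops
  n <- nrow(d)
  ss_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        s <- s + d[idx[a], idx[b]]^2
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  ((ss_total - ss_within) / 1) / (ss_within / (n - 2))
}

oracle_components <- function(adj) {
  # breadth-first search over the redundancy graph
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# small annotated genome built in code: two contigs, CDS on both strands,
# a hypothetical CDS, one tRNA and one rRNA
tiny_genome <- function(genome_id = "g1", group_label = "PD") {
  contigs <- tibble::tibble(
    contig_id = c("c1", "c2"),
    #       1 ATGAAATAA 9 | 10 GGGG 13 | 14 ... spacer ... 23
    seq = c("ATGAAATAAGGGGTTTTTTTTTT",
    # c2: revcomp CDS at 3..11 (plus-strand product ATGGGCTAA), rRNA 13..16
            "AATTAGCCCATAAAAAGG"))
  features <- tibble::tibble(
    contig_id = c("c1", "c1", "c2", "c2"),
    start = c(1L, 10L, 3L, 13L),
    end = c(9L, 13L, 11L, 16L),
    strand = c("+", "+", "-", "+"),
    ftype = c("CDS", "tRNA", "CDS", "rRNA"),
    product = c("hypothetical protein", "tRNA-Gly",
                "annotated protein", "16S ribosomal RNA"),
    locus_tag = c("t1", "t2", "t3", "t4"))
  genome_record(genome_id, contigs, features, group_label)
}

random_peptide <- function(len) {
  paste(sample(cryosig:::AA_STANDARD, len, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  tab <- Biostrings::getGeneticCode("11")
  sense <- names(tab)[tab != "*"]
  paste(c(sample(sense, n_codons, replace = TRUE), "TAA"), collapse = "")
}

hash_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  unname(tools::md5sum(files))
}
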