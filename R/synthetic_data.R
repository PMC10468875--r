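# codon sets per residue under the bacterial/archaeal code, split by
# third-position base class (S = G/C ending, W = A/T ending); every residue
# except Met and Trp offers both, which is what makes expectation-matched
# GC3 control by synonymous-codon choice feasible.
codon_sets <- function(code = "11") {
  gc_tab <- Biostrings::getGeneticCode(code)
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  keep <- aa %in% AA_STANDARD
  third <- substr(codons, 3L, 3L)
  strong <- third %in% c("G", "C")
  lapply(setNames(AA_STANDARD, AA_STANDARD), function(a) {
    list(strong = codons[keep & aa == a & strong],
         weak = codons[keep & aa == a & !strong])
  })
}

# default reference amino-acid frequencies: an acidic, haloarchaeal-style
# proteome (high Asp/Glu, low Lys)
default_aa_freq <- function() {
  f <- c(A = 0.094, C = 0.008, D = 0.082, E = 0.080, F = 0.034,
         G = 0.082, H = 0.021, I = 0.044, K = 0.028, L = 0.082,
         M = 0.020, P = 0.046, N = 0.033, Q = 0.028, R = 0.062,
         S = 0.062, T = 0.066, V = 0.078, W = 0.012, Y = 0.028)
  f <- f[AA_STANDARD]
  f / sum(f)
}

#' Specification for the two-group synthetic genome generator
#'
#' Defines the study conditions the generator emulates: two genome groups
#' (a cold-adapted "PD" group and a reference group) with programmed
#' offsets in GC3 (via synonymous-codon choice), amino-acid composition
#' and tRNA G+C, plus a null rRNA contrast. Defaults follow the study
#' design: 10 PD vs 60 reference genomes; reduced-scale genomes of 1000
#' CDS each (composition statistics depend on total residue counts, which
#' remain large).
#'
#' @param n_pd,n_ref Genomes per group.
#' @param genes_per_genome CDS per genome.
#' @param gene_len_mean,gene_len_sd Gene length distribution in codons
#'   (minimum 50).
#' @param aa_freq Reference-group amino-acid frequency vector (20 values,
#'   summing to 1).
#' @param pd_aa_shift Named per-residue offsets added to `aa_freq` for the
#'   PD group (must sum to 0). Default: Lys +1, Asn +0.5, Arg -1,
#'   Pro -0.5 percentage points (the classic psychrophile signature).
#' @param aa_jitter_sd Per-genome lognormal jitter of residue frequencies.
#' @param ref_gc3 Reference-group GC3 target (percent).
#' @param pd_gc3_offset PD-group GC3 offset in percentage points
#'   (default -3).
#' @param gc3_sd Per-genome standard deviation of the GC3 target
#'   (percentage points).
#' @param trna_n,rrna_n tRNA and rRNA genes per genome.
#' @param trna_gc,rrna_gc RNA-gene G+C targets (percent).
#' @param pd_trna_gc_offset PD offset on the tRNA target; the rRNA target
#'   is shared so the rRNA contrast is null.
#' @param hypothetical_frac Fraction of CDS annotated as "hypothetical
#'   protein".
#' @param n_contigs Contigs per genome.
#' @param intergenic_mean Mean intergenic gap (bp).
#' @param intergenic_gc G+C of intergenic sequence (percent).
#' @param seed Integer seed; every draw of the generator derives from it.
#' @return A `genome_sim_spec` list.
#' @export
genome_sim_spec <- function(n_pd = 10L, n_ref = 60L,
                            genes_per_genome = 1000L,
                            gene_len_mean = 250, gene_len_sd = 80,
                            aa_freq = default_aa_freq(),
                            pd_aa_shift = c(K = 0.01, N = 0.005,
                                            R = -0.01, P = -0.005),
                            aa_jitter_sd = 0.05,
                            ref_gc3 = 80, pd_gc3_offset = -3, gc3_sd = 1,
                            trna_n = 40L, rrna_n = 3L,
                            trna_gc = 62, rrna_gc = 58,
                            pd_trna_gc_offset = -2,
                            hypothetical_frac = 0.3,
                            n_contigs = 5L, intergenic_mean = 120,
                            intergenic_gc = 60, seed = 1L) {
  aa_freq <- aa_freq[AA_STANDARD]
  stopifnot(abs(sum(aa_freq) - 1) < 1e-9, all(aa_freq > 0))
  shift <- setNames(rep(0, 20), AA_STANDARD)
  shift[names(pd_aa_shift)] <- pd_aa_shift
  if (abs(sum(shift)) > 1e-9) abort("pd_aa_shift must sum to 0")
  if (any(aa_freq + shift <= 0)) abort("pd_aa_shift drives a frequency <= 0")
  if (ref_gc3 <= 0 || ref_gc3 >= 100 || ref_gc3 + pd_gc3_offset <= 0 ||
      ref_gc3 + pd_gc3_offset >= 100) {
    abort("GC3 targets must lie strictly inside (0, 100)")
  }
  structure(list(
    n_pd = n_pd, n_ref = n_ref, genes_per_genome = genes_per_genome,
    gene_len_mean = gene_len_mean, gene_len_sd = gene_len_sd,
    aa_freq = aa_freq, pd_aa_shift = shift, aa_jitter_sd = aa_jitter_sd,
    ref_gc3 = ref_gc3, pd_gc3_offset = pd_gc3_offset, gc3_sd = gc3_sd,
    trna_n = trna_n, rrna_n = rrna_n, trna_gc = trna_gc, rrna_gc = rrna_gc,
    pd_trna_gc_offset = pd_trna_gc_offset,
    hypothetical_frac = hypothetical_frac, n_contigs = n_contigs,
    intergenic_mean = intergenic_mean, intergenic_gc = intergenic_gc,
    seed = seed), class = "genome_sim_spec")
}

# random nucleotide string(s) at a given GC percent
random_seq <- function(lengths, gc) {
  vapply(lengths, function(L) {
    paste(sample(c("G", "C", "A", "T"), L, replace = TRUE,
                 prob = c(gc / 200, gc / 200, (100 - gc) / 200,
                          (100 - gc) / 200)), collapse = "")
  }, character(1))
}

# strong-codon choice probability hitting a pooled GC3 target in
# expectation, given residue frequencies (Met/Trp are always strong)
strong_prob_for_gc3 <- function(aa_freq, gc3_target) {
  f_fixed <- aa_freq[["M"]] + aa_freq[["W"]]
  s <- (gc3_target / 100 - f_fixed) / (1 - f_fixed)
  clamped <- s < 0 || s > 1
  list(s = min(max(s, 0), 1), clamped = clamped)
}

simulate_one_genome <- function(genome_id, group, spec, sets) {
  shift <- if (group == "PD") spec$pd_aa_shift else 0
  base <- spec$aa_freq + shift
  f <- base * exp(rnorm(20, 0, spec$aa_jitter_sd))
  f <- f / sum(f)
  gc3_group <- spec$ref_gc3 + if (group == "PD") spec$pd_gc3_offset else 0
  gc3_target <- min(max(rnorm(1, gc3_group, spec$gc3_sd), 1), 99)
  sp <- strong_prob_for_gc3(f, gc3_target)
  trna_gc <- spec$trna_gc + if (group == "PD") spec$pd_trna_gc_offset else 0

  n_genes <- spec$genes_per_genome
  lens <- pmax(50L, round(rnorm(n_genes, spec$gene_len_mean,
                                spec$gene_len_sd)))
  total <- sum(lens)
  residues <- sample(AA_STANDARD, total, replace = TRUE, prob = f)
  use_strong <- runif(total) < sp$s
  codons <- character(total)
  for (a in AA_STANDARD) {
    for (strong in c(TRUE, FALSE)) {
      set <- if (strong) sets[[a]]$strong else sets[[a]]$weak
      sel <- which(residues == a & use_strong == strong)
      if (!length(sel)) next
      if (!length(set)) set <- c(sets[[a]]$strong, sets[[a]]$weak)
      codons[sel] <- set[sample.int(length(set), length(sel),
                                    replace = TRUE)]
    }
  }
  gene_idx <- rep.int(seq_len(n_genes), lens)
  cds <- vapply(split(codons, gene_idx),
                function(co) paste(c(co, "TAA"), collapse = ""),
                character(1))

  rna_seqs <- c(random_seq(rep(76L, spec$trna_n), trna_gc),
                random_seq(rep(1500L, spec$rrna_n), spec$rrna_gc))
  rna_type <- c(rep("tRNA", spec$trna_n), rep("rRNA", spec$rrna_n))

  feat_seq <- c(cds, rna_seqs)
  feat_type <- c(rep("CDS", n_genes), rna_type)
  ord <- sample.int(length(feat_seq))
  feat_seq <- feat_seq[ord]; feat_type <- feat_type[ord]
  nf <- length(feat_seq)
  strand <- sample(c("+", "-"), nf, replace = TRUE)
  contig_of <- sort(rep_len(seq_len(spec$n_contigs), nf))
  gaps <- rpois(nf, spec$intergenic_mean) + 10L

  contigs <- vector("list", spec$n_contigs)
  starts <- ends <- integer(nf)
  contig_ids <- paste0(genome_id, "_c", seq_len(spec$n_contigs))
  for (ci in seq_len(spec$n_contigs)) {
    sel <- which(contig_of == ci)
    pos <- 1L
    parts <- character(0)
    for (j in sel) {
      gseq <- random_seq(gaps[j], spec$intergenic_gc)
      s <- feat_seq[j]
      if (strand[j] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      starts[j] <- pos + gaps[j]
      ends[j] <- starts[j] + nchar(s) - 1L
      pos <- ends[j] + 1L
      parts <- c(parts, gseq, s)
    }
    parts <- c(parts, random_seq(50L, spec$intergenic_gc))
    contigs[[ci]] <- paste(parts, collapse = "")
  }

  is_cds <- feat_type == "CDS"
  product <- rep(NA_character_, nf)
  product[is_cds] <- ifelse(runif(sum(is_cds)) < spec$hypothetical_frac,
                            "hypothetical protein", "annotated protein")
  product[feat_type == "tRNA"] <- "tRNA-Xxx"
  product[feat_type == "rRNA"] <- "16S ribosomal RNA"
  features <- tibble(
    contig_id = contig_ids[contig_of],
    start = starts, end = ends, strand = strand, ftype = feat_type,
    product = product,
    locus_tag = sprintf("%s_%05d", genome_id, seq_len(nf)))
  g <- genome_record(genome_id,
                     tibble(contig_id = contig_ids,
                            seq = unlist(contigs)),
                     features, group_label = group)
  truth <- c(list(genome_id = genome_id, group_label = group,
                  gc3_target = gc3_target, strong_prob = sp$s,
                  gc3_clamped = sp$clamped, trna_gc_target = trna_gc,
                  rrna_gc_target = spec$rrna_gc),
             as.list(setNames(f, paste0("freq_", names(f)))))
  list(genome = g, truth = as_tibble(truth))
}

#' Simulate a two-group genome set with programmed signatures
#'
#' Draws proteins residue-wise from group-specific amino-acid frequencies,
#' back-translates them choosing synonymous codons so the genome hits its
#' GC3 target in expectation (closed-form strong-codon probability, no
#' rejection sampling), adds tRNA/rRNA genes at their own G+C targets,
#' assembles contigs with random intergenic spacers and writes FASTA +
#' GFF3 files, a manifest and a truth table recording every programmed
#' parameter per genome.
#'
#' @param spec A [genome_sim_spec()].
#' @param out_dir Output directory (created if needed). If `NULL`, files
#'   are not written and only in-memory records are returned.
#' @return A list with `genomes` (named list of `genome_record`),
#'   `manifest` (tibble; `NULL` columns when `out_dir` is `NULL`) and
#'   `truth` (tibble, one row per genome).
#' @export
simulate_genomes <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  sets <- codon_sets()
  ids <- c(sprintf("PD%02d", seq_len(spec$n_pd)),
           sprintf("REF%02d", seq_len(spec$n_ref)))
  groups <- c(rep("PD", spec$n_pd), rep("REF", spec$n_ref))
  sims <- withr::with_seed(spec$seed, {
    purrr::map2(ids, groups, simulate_one_genome, spec = spec, sets = sets)
  })
  genomes <- setNames(purrr::map(sims, "genome"), ids)
  truth <- purrr::map_dfr(sims, "truth")
  manifest <- tibble(genome_id = ids, fasta_path = NA_character_,
                     gff_path = NA_character_, group_label = groups)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$fasta_path <- file.path(out_dir, paste0(ids, ".fna"))
    manifest$gff_path <- file.path(out_dir, paste0(ids, ".gff"))
    purrr::pwalk(manifest, function(genome_id, fasta_path, gff_path, ...) {
      write_genome(genomes[[genome_id]], fasta_path, gff_path)
    })
    # written paths are relative to the manifest's own directory
    readr::write_tsv(manifest |>
                       mutate(fasta_path = basename(.data$fasta_path),
                              gff_path = basename(.data$gff_path)),
                     file.path(out_dir, "manifest.tsv"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
  }
  list(genomes = genomes, manifest = manifest, truth = truth)
}

#' Specification for presence/absence matrix simulation
#'
#' The `"power_law_discovery"` model produces an exchangeable gene pool:
#' every accessory gene is present in each genome independently with its
#' own occupancy probability p, and the p values are drawn from a
#' truncated power density proportional to `p^(alpha - 2)`. Under that
#' mixture the expected number of newly discovered genes at rarefaction
#' step N falls off as `kappa * N^(-alpha)` for any genome order, which
#' is exactly the Heaps'-law structure the fitting machinery consumes.
#' `"constant_unique"` gives every genome the core plus a fixed number of
#' private genes (true alpha = 0); `"identical"` is core only.
#'
#' @param n_genomes Number of genomes G.
#' @param core_size Genes shared by all genomes.
#' @param model `"power_law_discovery"`, `"constant_unique"` or
#'   `"identical"`.
#' @param kappa,alpha Power-law discovery parameters (alpha in (0, 2) for
#'   the power-law model).
#' @param unique_per_genome Private genes per genome for
#'   `"constant_unique"`.
#' @param p_min Lower truncation of the occupancy-probability density
#'   (default 1e-5; smaller values extend the power-law regime to larger
#'   genome counts at the cost of a larger latent gene pool).
#' @param seed Integer seed.
#' @return A `pangenome_sim_spec` list.
#' @export
pangenome_sim_spec <- function(n_genomes, core_size = 1000L,
                               model = c("power_law_discovery",
                                         "constant_unique", "identical"),
                               kappa = 500, alpha = 0.6,
                               unique_per_genome = 50L, p_min = 1e-5,
                               seed = 1L) {
  model <- match.arg(model)
  stopifnot(kappa > 0, alpha >= 0, n_genomes >= 2L)
  if (model == "power_law_discovery" && (alpha <= 0 || alpha >= 2)) {
    abort("power_law_discovery requires alpha in (0, 2)")
  }
  structure(list(n_genomes = n_genomes, core_size = core_size,
                 model = model, kappa = kappa, alpha = alpha,
                 unique_per_genome = unique_per_genome, p_min = p_min,
                 seed = seed),
            class = "pangenome_sim_spec")
}

#' Simulate a gene presence/absence matrix of known openness
#'
#' @param spec A [pangenome_sim_spec()].
#' @return A list with `matrix` (binary genes x genomes) and `truth`
#'   (the spec parameters plus realized pool sizes).
#' @export
simulate_presence_absence <- function(spec) {
  stopifnot(inherits(spec, "pangenome_sim_spec"))
  G <- spec$n_genomes
  withr::with_seed(spec$seed, {
    if (spec$model == "power_law_discovery") {
      a <- spec$alpha
      eps <- spec$p_min
      # occupancy-probability density C * p^(a-2) on [eps, 1]; the latent
      # pool size is calibrated so the expected discovery curve is
      # kappa * N^(-a) (Beta-tail asymptotics)
      if (abs(a - 1) < 1e-8) {
        C <- 1 / log(1 / eps)
      } else {
        C <- (1 - a) / (eps^(a - 1) - 1)
      }
      n_latent <- max(1L, round(spec$kappa / (C * gamma(a))))
      u <- runif(n_latent)
      p <- if (abs(a - 1) < 1e-8) {
        eps^(1 - u)
      } else {
        (eps^(a - 1) - u * (eps^(a - 1) - 1))^(1 / (a - 1))
      }
      acc <- matrix(as.integer(runif(n_latent * G) < p), n_latent, G)
      acc <- acc[rowSums(acc) > 0, , drop = FALSE]
      m <- rbind(matrix(1L, spec$core_size, G), acc)
      truth_extra <- list(n_latent = n_latent,
                          n_accessory = nrow(acc),
                          total_genes = nrow(m))
    } else {
      new_counts <- switch(spec$model,
        identical = c(spec$core_size, rep(0L, G - 1L)),
        constant_unique = c(spec$core_size + spec$unique_per_genome,
                            rep(spec$unique_per_genome, G - 1L)))
      total <- sum(new_counts)
      m <- matrix(0L, total, G)
      owner <- rep.int(seq_len(G), new_counts)
      m[cbind(seq_len(total), owner)] <- 1L
      m[seq_len(spec$core_size), ] <- 1L
      truth_extra <- list(new_counts = new_counts, total_genes = total)
    }
    rownames(m) <- sprintf("gene_%06d", seq_len(nrow(m)))
    colnames(m) <- sprintf("G%03d", seq_len(G))
    list(matrix = m, truth = c(unclass(spec), truth_extra))
  })
}

#' Simulate an overdispersed functional gene-count table
#'
#' Counts follow a negative-binomial model with lognormal family means; a
#' stated fraction of families receives a group mean multiplier
#' `1 + effect_size` in the focal group. `effect_size = 0` is the
#' exchangeable null.
#'
#' @param n_per_group Length-2 vector: genomes in the focal (PD) and
#'   reference group.
#' @param n_families Number of gene families.
#' @param effect_size Relative mean shift on affected families (>= 0).
#' @param affected_frac Fraction of families shifted (default 0.3).
#' @param base_mean Median family mean count.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return A list with `table` (tibble: genome_id, group_label, one column
#'   per family) and `truth` (affected family names and multiplier).
#' @export
simulate_count_table <- function(n_per_group = c(10L, 10L),
                                 n_families = 50L, effect_size = 0,
                                 affected_frac = 0.3, base_mean = 10,
                                 dispersion = 5, seed = 1L) {
  stopifnot(effect_size >= 0, length(n_per_group) == 2L)
  withr::with_seed(seed, {
    fam <- sprintf("fam_%03d", seq_len(n_families))
    mu <- base_mean * exp(rnorm(n_families, 0, 1))
    n_aff <- round(affected_frac * n_families)
    affected <- if (effect_size > 0 && n_aff > 0) fam[seq_len(n_aff)]
                else character(0)
    mult <- ifelse(fam %in% affected, 1 + effect_size, 1)
    n_tot <- sum(n_per_group)
    groups <- rep(c("PD", "REF"), n_per_group)
    counts <- do.call(rbind, lapply(seq_len(n_tot), function(i) {
      m <- if (groups[i] == "PD") mu * mult else mu
      rnbinom(n_families, mu = m, size = dispersion)
    }))
    colnames(counts) <- fam
    tbl <- dplyr::bind_cols(
      tibble(genome_id = sprintf("%s%02d", groups,
                                 stats::ave(seq_len(n_tot), groups,
                                            FUN = seq_along)),
             group_label = groups),
      as_tibble(counts))
    list(table = tbl,
         truth = list(affected = affected, multiplier = 1 + effect_size,
                      family_means = setNames(mu, fam)))
  })
}

#' Simulate a two-group numeric trait table
#'
#' Gaussian per-genome trait draws used for statistical calibration
#' studies of the group-comparison machinery (type-I error, power). Trait
#' means can be offset in the focal group.
#'
#' @param n_focal,n_other Genomes per group (labels `"PD"` / `"REF"`).
#' @param means Named vector of trait means (reference group).
#' @param sds Named vector of per-genome trait standard deviations.
#' @param focal_shift Named vector of focal-group mean offsets (default:
#'   none, the null).
#' @param seed Integer seed.
#' @return A tibble with `genome_id`, `group_label` and one column per
#'   trait.
#' @export
simulate_trait_table <- function(n_focal, n_other, means, sds,
                                 focal_shift = NULL, seed = 1L) {
  stopifnot(identical(names(means), names(sds)))
  shift <- setNames(rep(0, length(means)), names(means))
  if (!is.null(focal_shift)) shift[names(focal_shift)] <- focal_shift
  withr::with_seed(seed, {
    n <- n_focal + n_other
    groups <- rep(c("PD", "REF"), c(n_focal, n_other))
    vals <- purrr::imap(means, function(m, tr) {
      rnorm(n, mean = m + ifelse(groups == "PD", shift[[tr]], 0),
            sd = sds[[tr]])
    })
    dplyr::bind_cols(
      tibble(genome_id = sprintf("%s%02d", groups,
                                 stats::ave(seq_len(n), groups,
                                            FUN = seq_along)),
             group_label = groups),
      as_tibble(vals))
  })
}
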