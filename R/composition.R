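#' G+C content of nucleotide sequences
#'
#' Computes 100 * (G + C) / (A + C + G + T) per sequence. IUPAC ambiguity
#' codes are excluded from both numerator and denominator; a sequence with
#' no unambiguous base yields `NA`.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of percents (NA where undefined).
#' @examples
#' gc_content(c("ATGC", "AATT", "GCNN"))
#' @export
gc_content <- function(seq) {
  if (length(seq) == 0L || any(!nzchar(seq))) {
    abort("gc_content requires non-empty sequences")
  }
  cnt <- base_counts(seq)
  gc <- cnt[, "G"] + cnt[, "C"]
  tot <- rowSums(cnt)
  ifelse(tot == 0, NA_real_, 100 * gc / tot)
}

# unambiguous base counts (A/C/G/T) per sequence
base_counts <- function(seq) {
  Biostrings::letterFrequency(Biostrings::BStringSet(seq),
                              letters = c("A", "C", "G", "T"))
}

# pooled GC over the concatenation of a set of sequences
gc_pooled <- function(seqs) {
  if (length(seqs) == 0L) return(NA_real_)
  cnt <- colSums(base_counts(seqs))
  tot <- sum(cnt)
  if (tot == 0) NA_real_ else 100 * (cnt[["G"]] + cnt[["C"]]) / tot
}

#' Codon-position G+C content (GC1, GC2, GC3)
#'
#' Pools codons across all supplied coding sequences and computes the G+C
#' percent separately at the first, second and third codon positions,
#' excluding ambiguity codes as in [gc_content()].
#'
#' @param cds_seqs Character vector of CDS nucleotide sequences, each of
#'   length divisible by 3 (apply the partial-CDS policy first).
#' @param pooled If `TRUE` (default) return one pooled `(gc1, gc2, gc3)`
#'   vector for the whole set; otherwise a tibble with one row per CDS.
#' @return Named numeric vector `c(gc1, gc2, gc3)`, or a per-CDS tibble.
#' @examples
#' codon_position_gc("ATGGCC")
#' @export
codon_position_gc <- function(cds_seqs, pooled = TRUE) {
  if (length(cds_seqs) == 0L) abort("No coding sequences supplied")
  if (any((nchar(cds_seqs) %% 3L) != 0L)) {
    abort("All CDS lengths must be divisible by 3")
  }
  if (!pooled) {
    per <- t(vapply(cds_seqs, function(s) codon_position_gc(s, pooled = TRUE),
                    numeric(3)))
    return(tibble(locus_tag = names(cds_seqs) %||%
                    paste0("cds", seq_along(cds_seqs)),
                  gc1 = per[, 1], gc2 = per[, 2], gc3 = per[, 3]))
  }
  r <- charToRaw(paste(cds_seqs, collapse = ""))
  n <- length(r)
  bases <- charToRaw("ACGT")
  pos_gc <- vapply(1:3, function(p) {
    sub <- r[seq.int(p, n, by = 3L)]
    cnt <- vapply(bases, function(b) sum(sub == b), numeric(1))
    tot <- sum(cnt)
    if (tot == 0) NA_real_ else 100 * (cnt[2L] + cnt[3L]) / tot
  }, numeric(1))
  setNames(pos_gc, c("gc1", "gc2", "gc3"))
}

#' Pooled amino-acid composition of a proteome
#'
#' Counts residues over all proteins pooled together and returns the
#' proportion of each of the 20 standard amino acids. `X` and any other
#' non-standard letters are excluded from numerator and denominator.
#'
#' @param proteins Character vector of protein sequences (stops already
#'   stripped).
#' @return Named numeric vector of 20 proportions summing to 1.
#' @examples
#' aa_composition(c("KR", "RK"))
#' @export
aa_composition <- function(proteins) {
  proteins <- proteins[!is.na(proteins)]
  if (length(proteins) == 0L) abort("No proteins supplied")
  cnt <- colSums(Biostrings::letterFrequency(Biostrings::BStringSet(proteins),
                                             letters = AA_STANDARD))
  tot <- sum(cnt)
  if (tot == 0) abort("Proteome contains no standard residues")
  setNames(as.numeric(cnt) / tot, AA_STANDARD)
}

#' Coding density of a genome
#'
#' Percent of the genome covered by the union of CDS intervals; overlapping
#' or duplicated CDS are counted once.
#'
#' @param genome A `genome_record` with at least one CDS feature.
#' @return Percent in (0, 100].
#' @export
coding_density <- function(genome) {
  cds <- genome$features |> filter(.data$ftype == "CDS")
  if (nrow(cds) == 0L) abort("Genome has no CDS features")
  covered <- sum(vapply(split(cds, cds$contig_id), function(d) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$start, d$end))))
  }, numeric(1)))
  100 * covered / sum(nchar(genome$contigs$seq))
}

#' G+C content of genomic element classes
#'
#' Pooled G+C of: the whole genome, all CDS, hypothetical-protein CDS,
#' RNA genes (tRNA and rRNA together), tRNA only and rRNA only. A class
#' with no annotated members yields `NA`.
#'
#' @param genome A `genome_record`.
#' @param hypothetical_pattern Case-insensitive regular expression applied
#'   to the CDS `product` field to identify hypothetical proteins.
#' @return Named numeric vector with elements `gc_genomic`, `gc_cds`,
#'   `gc_hypothetical`, `gc_rna`, `gc_trna`, `gc_rrna`.
#' @export
element_gc <- function(genome, hypothetical_pattern = "hypothetical protein") {
  f <- genome$features
  class_gc <- function(sel) {
    if (!any(sel)) return(NA_real_)
    gc_pooled(extract_feature_seq(genome, f[sel, ]))
  }
  is_cds <- f$ftype == "CDS"
  is_hyp <- is_cds & !is.na(f$product) &
    grepl(hypothetical_pattern, f$product, ignore.case = TRUE)
  c(gc_genomic = gc_pooled(genome$contigs$seq),
    gc_cds = class_gc(is_cds),
    gc_hypothetical = class_gc(is_hyp),
    gc_rna = class_gc(f$ftype %in% c("tRNA", "rRNA")),
    gc_trna = class_gc(f$ftype == "tRNA"),
    gc_rrna = class_gc(f$ftype == "rRNA"))
}

#' Full compositional profile of one genome
#'
#' Assembles every per-genome compositional trait that downstream group
#' comparisons consume: genome size, CDS count, coding density, element-wise
#' G+C, pooled codon-position GC1/GC2/GC3 and the 20 amino-acid proportions
#' (columns `aa_A` ... `aa_Y`). GC1/2/3 and amino-acid composition are
#' computed on retained CDS only (partial CDS and pseudogenes excluded).
#'
#' @inheritParams element_gc
#' @param code Genetic code table for translation (default `"11"`).
#' @return A one-row tibble.
#' @export
composition_profile <- function(genome, hypothetical_pattern =
                                  "hypothetical protein", code = "11") {
  f <- genome$features
  cds <- f |> filter(.data$ftype == "CDS")
  cds_seqs <- extract_feature_seq(genome, cds)
  tr <- translate_cds(cds_seqs, code = code)
  ok <- tr$status == "ok"
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    inform(sprintf("%s: excluded %d CDS from composition (%s)",
                   genome$genome_id, n_excluded,
                   paste(names(table(tr$status[!ok])), collapse = ", ")))
  }
  if (!any(ok)) abort(paste0("No retained CDS in genome ", genome$genome_id))
  gcp <- codon_position_gc(cds_seqs[ok])
  aa <- aa_composition(tr$protein[ok])
  egc <- element_gc(genome, hypothetical_pattern)
  dplyr::bind_cols(
    tibble(genome_id = genome$genome_id,
           group_label = genome$group_label,
           genome_size = sum(nchar(genome$contigs$seq)),
           n_cds = nrow(cds),
           coding_density = coding_density(genome)),
    as_tibble(as.list(egc)),
    as_tibble(as.list(gcp)),
    as_tibble(as.list(setNames(aa, paste0("aa_", names(aa))))))
}

#' Compositional profiles for a set of genomes
#'
#' @param genomes A named list of `genome_record` objects (e.g. from
#'   [load_genomes()]) or a manifest path/tibble.
#' @inheritParams composition_profile
#' @return A tibble with one row per genome.
#' @export
composition_profiles <- function(genomes, hypothetical_pattern =
                                   "hypothetical protein", code = "11") {
  if (is.character(genomes) || inherits(genomes, "data.frame")) {
    genomes <- load_genomes(genomes)
  }
  purrr::map_dfr(genomes, composition_profile,
                 hypothetical_pattern = hypothetical_pattern, code = code)
}
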