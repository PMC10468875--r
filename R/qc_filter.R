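#' Assembly N50
#'
#' The smallest contig length L such that contigs of length >= L cover at
#' least half of the total assembly.
#'
#' @param contig_lengths Numeric vector of positive contig lengths (bp).
#' @return N50 in bp.
#' @examples
#' compute_n50(c(5, 4, 3)) # 4
#' @export
compute_n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0L) abort("No contig lengths supplied")
  if (any(contig_lengths <= 0) || any(is.na(contig_lengths))) {
    abort("Contig lengths must be positive")
  }
  len <- sort(contig_lengths, decreasing = TRUE)
  len[which(cumsum(len) >= sum(len) / 2)[1L]]
}

#' Default assembly quality-control thresholds
#'
#' Genomes are removed when they have more than `max_contigs` contigs, an
#' N50 below `min_n50`, completeness below `min_completeness` or
#' contamination above `max_contamination`. All inequalities are strict, so
#' a genome sitting exactly on every threshold passes.
#'
#' @param max_contigs,min_n50,min_completeness,max_contamination Threshold
#'   values (counts, bp, percent, percent).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(max_contigs = 300, min_n50 = 20000,
                          min_completeness = 95, max_contamination = 5) {
  list(max_contigs = max_contigs, min_n50 = min_n50,
       min_completeness = min_completeness,
       max_contamination = max_contamination)
}

#' Apply assembly quality control to per-genome metrics
#'
#' @param stats A data frame with columns `genome_id`, `n_contigs`, `n50`,
#'   `completeness`, `contamination` (QUAST/CheckM-style metrics).
#' @param thresholds Threshold list from [qc_thresholds()].
#' @return The input tibble with logical `qc_pass` and a `qc_reasons`
#'   column listing every violated rule (empty string when passing).
#' @export
qc_pass <- function(stats, thresholds = qc_thresholds()) {
  stats <- as_tibble(stats)
  need <- c("genome_id", "n_contigs", "n50", "completeness", "contamination")
  if (!all(need %in% names(stats))) {
    abort(paste0("stats must have columns ", paste(need, collapse = ", ")))
  }
  if (any(stats$completeness < 0 | stats$completeness > 100) ||
      any(stats$contamination < 0 | stats$contamination > 100)) {
    abort("completeness and contamination must be percentages in [0, 100]")
  }
  th <- thresholds
  reasons <- purrr::pmap_chr(stats[need], function(genome_id, n_contigs, n50,
                                                   completeness,
                                                   contamination) {
    r <- c(
      if (n_contigs > th$max_contigs)
        sprintf("contigs %d > %d", n_contigs, th$max_contigs),
      if (n50 < th$min_n50) sprintf("N50 %d < %d", as.integer(n50),
                                    as.integer(th$min_n50)),
      if (completeness < th$min_completeness)
        sprintf("completeness %.2f%% < %.0f%%", completeness,
                th$min_completeness),
      if (contamination > th$max_contamination)
        sprintf("contamination %.2f%% > %.0f%%", contamination,
                th$max_contamination))
    paste(r, collapse = "; ")
  })
  stats |> mutate(qc_pass = !nzchar(reasons), qc_reasons = reasons)
}

#' Read a square AAI matrix
#'
#' Reads a tabular average amino-acid identity matrix whose first column
#' and header row carry genome ids, validating symmetry and the percent
#' scale (self-identity 100).
#'
#' @param path Path to a TSV/CSV matrix file.
#' @return A numeric matrix with genome ids as dimnames.
#' @export
read_aai_matrix <- function(path) {
  m <- read_table_auto(path)
  ids <- as.character(m[[1L]])
  v <- as.matrix(m[, -1L, drop = FALSE])
  mode(v) <- "numeric"
  rownames(v) <- ids
  validate_aai(v)
}

validate_aai <- function(v) {
  if (nrow(v) != ncol(v) || !identical(rownames(v), colnames(v))) {
    abort("AAI matrix must be square with matching row/column genome ids")
  }
  if (any(v < 0 | v > 100, na.rm = TRUE)) abort("AAI values must be in [0, 100]")
  if (max(abs(v - t(v))) > 1e-9) abort("AAI matrix must be symmetric")
  if (max(abs(diag(v) - 100)) > 1e-9) abort("AAI self-identity must be 100")
  v
}

#' Deduplicate genomes by average amino-acid identity
#'
#' Single-linkage clusters genomes whose pairwise AAI meets the redundancy
#' threshold and keeps one representative per cluster, preferring higher
#' completeness, then lower contamination, then higher N50, then the
#' lexicographically smallest genome id.
#'
#' @param aai Symmetric percent AAI matrix (genome ids as dimnames), e.g.
#'   from [read_aai_matrix()].
#' @param stats Per-genome metrics tibble (as for [qc_pass()]), used for
#'   the representative tiebreak.
#' @param threshold Redundancy threshold in percent AAI; pairs with
#'   AAI >= `threshold` are considered duplicates. Default 99.5.
#' @return A tibble with one row per genome: `genome_id`, `cluster`
#'   (integer cluster index), `kept` (logical) and `representative`
#'   (the kept genome of its cluster).
#' @export
dedup_by_aai <- function(aai, stats, threshold = 99.5) {
  aai <- validate_aai(aai)
  ids <- rownames(aai)
  stats <- as_tibble(stats)
  if (!all(ids %in% stats$genome_id)) {
    abort("AAI matrix contains genome ids missing from stats")
  }
  adj <- aai >= threshold
  diag(adj) <- TRUE
  # single-linkage clusters = connected components of the redundancy graph
  comp <- connected_components(adj)
  st <- stats[match(ids, stats$genome_id), ]
  ord <- order(comp,
               -st$completeness, st$contamination, -st$n50, ids)
  first <- !duplicated(comp[ord])
  rep_of <- setNames(ids[ord][first], comp[ord][first])
  tibble(genome_id = ids,
         cluster = comp,
         representative = unname(rep_of[as.character(comp)])) |>
    mutate(kept = .data$genome_id == .data$representative) |>
    select(dplyr::all_of(c("genome_id", "cluster", "kept", "representative")))
}

# connected components of a logical adjacency matrix by label propagation
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), integer(1))
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

#' Run the full genome QC and deduplication stage
#'
#' @inheritParams dedup_by_aai
#' @inheritParams qc_pass
#' @return A list with `stats` (QC-annotated tibble), `dedup` (cluster
#'   report restricted to QC-passing genomes) and `kept` (character vector
#'   of retained genome ids).
#' @export
qc_and_dedup <- function(stats, aai, thresholds = qc_thresholds(),
                         threshold = 99.5) {
  stats <- qc_pass(stats, thresholds)
  passed <- stats$genome_id[stats$qc_pass]
  keep_ids <- intersect(rownames(aai), passed)
  if (length(keep_ids) == 0L) {
    return(list(stats = stats, dedup = NULL, kept = character()))
  }
  dd <- dedup_by_aai(aai[keep_ids, keep_ids, drop = FALSE], stats, threshold)
  list(stats = stats, dedup = dd, kept = dd$genome_id[dd$kept])
}
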