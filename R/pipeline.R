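#' Pipeline run configuration
#'
#' Collects every input path, threshold and seed of a full pipeline run.
#' All randomized stages (rarefaction, PERMANOVA, NMDS) draw from the
#' explicit `seed`, so a rerun with an identical config and inputs
#' reproduces identical outputs.
#'
#' @param manifest_path Genome manifest (see [read_genome_manifest()]).
#' @param out_dir Output directory for stage tables and the summary.
#' @param seed Integer seed (mandatory).
#' @param stats_path,aai_path Optional assembly-stats table and AAI matrix
#'   enabling the QC/deduplication stage.
#' @param pa_matrix_path Optional gene presence/absence matrix enabling
#'   the pangenome stage.
#' @param count_table_paths Optional named character vector of functional
#'   count tables (genomes x families) for the multivariate stage.
#' @param qc Thresholds from [qc_thresholds()].
#' @param aai_threshold AAI redundancy threshold (percent).
#' @param n_permutations Rarefaction permutations (default 1000).
#' @param permanova_permutations PERMANOVA permutations (default 999).
#' @param scale_name,window Flexibility scale name and window.
#' @param pka_name pKa set name.
#' @param hypothetical_pattern Product pattern marking hypothetical CDS.
#' @return A `cryosig_config` list.
#' @export
run_config <- function(manifest_path, out_dir, seed,
                       stats_path = NULL, aai_path = NULL,
                       pa_matrix_path = NULL, count_table_paths = NULL,
                       qc = qc_thresholds(), aai_threshold = 99.5,
                       n_permutations = 1000L,
                       permanova_permutations = 999L,
                       scale_name = "vihinen", window = 9L,
                       pka_name = "ipc_protein",
                       hypothetical_pattern = "hypothetical protein") {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    abort("Config validation: an explicit integer seed is required")
  }
  cfg <- structure(list(
    manifest_path = manifest_path, out_dir = out_dir,
    seed = as.integer(seed), stats_path = stats_path, aai_path = aai_path,
    pa_matrix_path = pa_matrix_path,
    count_table_paths = count_table_paths, qc = qc,
    aai_threshold = aai_threshold, n_permutations = n_permutations,
    permanova_permutations = permanova_permutations,
    scale_name = scale_name, window = window, pka_name = pka_name,
    hypothetical_pattern = hypothetical_pattern), class = "cryosig_config")
  # hash covers the analysis-relevant fields; where outputs land does not
  # change what they contain
  cfg$config_hash <- rlang::hash(cfg[setdiff(names(cfg),
                                             c("config_hash", "out_dir"))])
  cfg
}

stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s\nCompleted stages: %s", name,
                  conditionMessage(e),
                  paste(log$done, collapse = ", ")))
  })
}

#' Run the full comparative-genomics pipeline
#'
#' Executes QC/deduplication (when assembly stats and an AAI matrix are
#' configured), compositional profiling, protein-property profiling,
#' two-group trait comparison, pangenome rarefaction with Heaps fits and
#' gene partitioning (when a presence/absence matrix is configured), and
#' multivariate comparison of functional count tables. Each stage writes a
#' plain TSV into the output directory; fit results and provenance go to
#' `summary.json`, stamped with the config hash.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cryosig_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- new.env(); log$done <- character()
  out <- list(); paths <- character()
  emit <- function(df, file) {
    p <- file.path(config$out_dir, file)
    readr::write_tsv(df, p)
    paths <<- c(paths, p)
  }
  mark <- function(s) log$done <- c(log$done, s)

  manifest <- stage("manifest", log, read_genome_manifest(config$manifest_path))

  if (!is.null(config$stats_path) && !is.null(config$aai_path)) {
    out$qc <- stage("qc", log, {
      qcres <- qc_and_dedup(read_table_auto(config$stats_path),
                            read_aai_matrix(config$aai_path),
                            thresholds = config$qc,
                            threshold = config$aai_threshold)
      emit(qcres$stats, "qc_report.tsv")
      if (!is.null(qcres$dedup)) emit(qcres$dedup, "dedup_report.tsv")
      manifest <- manifest |> filter(.data$genome_id %in% qcres$kept)
      qcres
    })
    mark("qc")
  }

  genomes <- stage("load_genomes", log, load_genomes(manifest))
  mark("load_genomes")

  out$composition <- stage("composition", log, {
    prof <- composition_profiles(
      genomes, hypothetical_pattern = config$hypothetical_pattern)
    emit(prof, "composition_profiles.tsv")
    prof
  })
  mark("composition")

  out$protein_props <- stage("protein_props", log, {
    pp <- protein_profiles(genomes,
                           scale = flexibility_scale(config$scale_name),
                           pka = pka_set(config$pka_name),
                           window = config$window)
    emit(pp, "protein_props.tsv")
    pp
  })
  mark("protein_props")

  labels <- manifest$group_label
  if (length(unique(labels[!is.na(labels)])) == 2L) {
    out$comparison <- stage("compare", log, {
      traits <- out$composition |>
        left_join(out$protein_props |>
                    select(dplyr::all_of(c("genome_id", "mean_flexibility",
                                           "mean_pi"))),
                  by = "genome_id")
      cmp <- compare_traits(traits)
      emit(cmp, "group_comparison.tsv")
      cmp
    })
    mark("compare")
  }

  if (!is.null(config$pa_matrix_path)) {
    out$pangenome <- stage("pangenome", log, {
      m <- read_pa_matrix(config$pa_matrix_path)
      rar <- rarefy(m, n_permutations = config$n_permutations,
                    seed = config$seed)
      emit(rar$summary, "rarefaction.tsv")
      fits <- list(pan = fit_heaps(rar, "pan_new_genes"),
                   core = fit_heaps(rar, "core_decay"))
      part <- partition_genes(m)
      emit(part$partition, "partition.tsv")
      emit(part$literal, "partition_literal.tsv")
      list(rarefaction = rar, fits = fits, partition = part)
    })
    mark("pangenome")
  }

  if (!is.null(config$count_table_paths)) {
    out$counts <- stage("functional_counts", log, {
      purrr::imap(config$count_table_paths, function(p, nm) {
        ct <- read_table_auto(p)
        if (!"group_label" %in% names(ct)) {
          ct <- ct |> left_join(manifest |>
                                  select(dplyr::all_of(c("genome_id",
                                                         "group_label"))),
                                by = "genome_id")
        }
        cc <- compare_counts(ct, seed = config$seed,
                             n_permutations = config$permanova_permutations)
        emit(cc$nmds$coordinates |>
               mutate(table = nm, stress = cc$nmds$stress),
             paste0("ordination_", nm, ".tsv"))
        cc
      })
    })
    mark("functional_counts")
  }

  summary <- list(
    config_hash = config$config_hash,
    seed = config$seed,
    n_genomes = length(genomes),
    stages = log$done,
    heaps = if (!is.null(out$pangenome)) {
      lapply(out$pangenome$fits, function(f) {
        list(curve = f$curve, kappa = f$kappa, alpha = f$alpha,
             alpha_se = f$alpha_se, open = f$open)
      })
    },
    permanova = if (!is.null(out$counts)) {
      lapply(out$counts, function(cc) {
        list(pseudo_F = cc$permanova$statistic, p = cc$permanova$p.value,
             method = cc$permanova$method, stress = cc$nmds$stress)
      })
    })
  sp <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  paths <- c(paths, sp)
  invisible(c(out, list(paths = paths, summary = summary)))
}
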