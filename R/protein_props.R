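#' Amino-acid flexibility scales
#'
#' Per-residue flexibility indices used by the sliding-window flexibility
#' score. Two scales ship with the package:
#'
#' * `"vihinen"` (default) — normalized B-factor flexibility indices of
#'   Vihinen, Torkkila and Riikonen (values around 1; larger = more
#'   flexible). Under this scale the classic psychrophile substitutions
#'   (more Lys, fewer Arg/Pro) increase the score.
#' * `"bhaskaran"` — the average-flexibility index of Bhaskaran and
#'   Ponnuswamy (0.3-0.54 range).
#'
#' @param name Scale name.
#' @return Named numeric vector over the 20 standard residues.
#' @export
flexibility_scale <- function(name = c("vihinen", "bhaskaran")) {
  name <- match.arg(name)
  sc <- switch(name,
    vihinen = c(A = 0.984, C = 0.906, D = 1.068, E = 1.094, F = 0.915,
                G = 1.031, H = 0.950, I = 0.927, K = 1.102, L = 0.935,
                M = 0.952, N = 1.048, P = 1.049, Q = 1.037, R = 1.008,
                S = 1.046, T = 0.997, V = 0.931, W = 0.904, Y = 0.929),
    bhaskaran = c(A = 0.360, C = 0.350, D = 0.510, E = 0.500, F = 0.310,
                  G = 0.540, H = 0.320, I = 0.460, K = 0.470, L = 0.370,
                  M = 0.300, N = 0.460, P = 0.510, Q = 0.490, R = 0.530,
                  S = 0.510, T = 0.440, V = 0.390, W = 0.310, Y = 0.420))
  stopifnot(identical(sort(names(sc)), AA_STANDARD))
  sc
}

#' Ionizable-group pKa sets for isoelectric-point calculation
#'
#' Named pKa sets for the protein charge model: N- and C-terminus plus the
#' side chains of C, D, E, H, K, R and Y. `"ipc_protein"` (default) holds
#' the IPC values optimized for whole proteins; `"ipc_peptide"` the
#' peptide-optimized IPC values; `"emboss"` the EMBOSS defaults.
#'
#' @param name Set name.
#' @return Named numeric vector with elements `nterm`, `cterm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y`.
#' @export
pka_set <- function(name = c("ipc_protein", "ipc_peptide", "emboss")) {
  name <- match.arg(name)
  switch(name,
    ipc_protein = c(nterm = 9.094, cterm = 2.869, C = 7.555, D = 3.872,
                    E = 4.412, H = 5.637, K = 9.052, R = 11.84, Y = 10.85),
    ipc_peptide = c(nterm = 9.564, cterm = 2.383, C = 8.297, D = 3.887,
                    E = 4.317, H = 6.018, K = 10.517, R = 12.503,
                    Y = 10.071),
    emboss = c(nterm = 8.6, cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
               H = 6.5, K = 10.8, R = 12.5, Y = 10.1))
}

#' Sliding-window protein flexibility
#'
#' Slides an unweighted window along the protein; each window scores the
#' mean of the per-residue scale values and the protein scores the mean
#' over all window positions. `X`/non-standard residues are imputed with
#' the scale mean. Proteins shorter than the window yield `NA`.
#'
#' @param proteins Character vector of protein sequences.
#' @param scale Named per-residue scale, e.g. from [flexibility_scale()].
#' @param window Odd window width (default 9).
#' @return Numeric vector of per-protein flexibility scores.
#' @examples
#' protein_flexibility(strrep("K", 9)) # equals the K scale value
#' @export
protein_flexibility <- function(proteins, scale = flexibility_scale(),
                                window = 9L) {
  if (window < 1L || window %% 2L == 0L) abort("window must be odd and >= 1")
  if (!identical(sort(names(scale)), AA_STANDARD)) {
    abort("scale must cover exactly the 20 standard residues")
  }
  imput <- mean(scale)
  vapply(proteins, function(p) {
    if (is.na(p)) return(NA_real_)
    n <- nchar(p)
    if (n < window) return(NA_real_)
    v <- scale[strsplit(p, "", fixed = TRUE)[[1L]]]
    v[is.na(v)] <- imput
    # mean over windows = mean of running window means (cumsum trick)
    cs <- cumsum(c(0, v))
    wsum <- cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]
    mean(wsum / window)
  }, numeric(1), USE.NAMES = !is.null(names(proteins)))
}

#' Protein isoelectric point
#'
#' Models the protein's net charge as the sum of Henderson-Hasselbalch
#' terms over the N-terminus, C-terminus and ionizable side chains, and
#' finds the pH of zero charge by bisection on \[0, 14\]. The charge is
#' strictly decreasing in pH, so the root is unique. Bisection runs to the
#' pH tolerance; at genome-scale protein sizes the residual charge at the
#' returned pH is far below 1e-4 elementary charges.
#'
#' @param proteins Character vector of protein sequences.
#' @param pka Named pKa vector, e.g. from [pka_set()].
#' @param tol Bisection pH tolerance (default 1e-3).
#' @return Numeric vector of pI values (pH units).
#' @examples
#' isoelectric_point("GGGG") # (pKa_Nterm + pKa_Cterm) / 2
#' @export
isoelectric_point <- function(proteins, pka = pka_set(), tol = 1e-3) {
  out <- rep(NA_real_, length(proteins))
  names(out) <- names(proteins)
  ok <- !is.na(proteins) & nzchar(proteins)
  if (!any(ok)) return(out)
  ion <- c("K", "R", "H", "D", "E", "C", "Y")
  counts <- Biostrings::letterFrequency(Biostrings::BStringSet(proteins[ok]),
                                        letters = ion)
  # all proteins bisected in lock-step; each freezes once its interval
  # is inside the pH tolerance
  n <- sum(ok)
  lo <- rep(0, n); hi <- rep(14, n)
  res <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  charge_at <- function(pH, cnt) {
    pos <- 1 / (1 + 10^(pH - pka[["nterm"]])) +
      cnt[, "K"] / (1 + 10^(pH - pka[["K"]])) +
      cnt[, "R"] / (1 + 10^(pH - pka[["R"]])) +
      cnt[, "H"] / (1 + 10^(pH - pka[["H"]]))
    neg <- 1 / (1 + 10^(pka[["cterm"]] - pH)) +
      cnt[, "D"] / (1 + 10^(pka[["D"]] - pH)) +
      cnt[, "E"] / (1 + 10^(pka[["E"]] - pH)) +
      cnt[, "C"] / (1 + 10^(pka[["C"]] - pH)) +
      cnt[, "Y"] / (1 + 10^(pka[["Y"]] - pH))
    pos - neg
  }
  while (any(active)) {
    mid <- (lo[active] + hi[active]) / 2
    q <- charge_at(mid, counts[active, , drop = FALSE])
    stop_now <- (hi[active] - lo[active]) / 2 < tol
    idx <- which(active)
    res[idx[stop_now]] <- mid[stop_now]
    go_up <- q > 0
    lo[idx[go_up & !stop_now]] <- mid[go_up & !stop_now]
    hi[idx[!go_up & !stop_now]] <- mid[!go_up & !stop_now]
    active[idx[stop_now]] <- FALSE
  }
  out[ok] <- res
  out
}

#' Genome-scale protein property profile
#'
#' Translates all retained CDS of a genome and reports per-protein and
#' genome-mean flexibility and isoelectric point. Genome means are
#' unweighted over proteins; proteins shorter than the flexibility window
#' are excluded from the flexibility mean (count reported).
#'
#' @param genome A `genome_record`.
#' @param scale Flexibility scale (see [flexibility_scale()]).
#' @param pka pKa set (see [pka_set()]).
#' @param window Flexibility window width.
#' @param code Genetic code table.
#' @return A list of class `protein_property_profile` with `genome_id`,
#'   `group_label`, `per_protein` (tibble: locus_tag, flexibility, pi),
#'   `mean_flexibility`, `mean_pi`, and exclusion counts.
#' @export
genome_protein_profile <- function(genome, scale = flexibility_scale(),
                                   pka = pka_set(), window = 9L,
                                   code = "11") {
  tr <- genome_proteins(genome, code = code)
  kept <- tr |> filter(.data$status == "ok")
  if (nrow(kept) == 0L) {
    abort(paste0("No retained proteins in genome ", genome$genome_id))
  }
  flex <- protein_flexibility(kept$protein, scale = scale, window = window)
  pi <- isoelectric_point(kept$protein, pka = pka)
  n_short <- sum(is.na(flex))
  if (n_short > 0) {
    inform(sprintf("%s: %d protein(s) shorter than window %d excluded from flexibility mean",
                   genome$genome_id, n_short, window))
  }
  structure(list(
    genome_id = genome$genome_id,
    group_label = genome$group_label,
    per_protein = tibble(locus_tag = kept$locus_tag,
                         flexibility = unname(flex), pi = unname(pi)),
    mean_flexibility = mean(flex, na.rm = TRUE),
    mean_pi = mean(pi),
    n_proteins = nrow(kept),
    n_excluded_translation = sum(tr$status != "ok"),
    n_excluded_flexibility = n_short),
    class = "protein_property_profile")
}

#' @export
print.protein_property_profile <- function(x, ...) {
  cat(sprintf("<protein_property_profile> %s: %d proteins, mean flexibility %.4f, mean pI %.3f\n",
              x$genome_id, x$n_proteins, x$mean_flexibility, x$mean_pi))
  invisible(x)
}

#' @method tidy protein_property_profile
#' @export
tidy.protein_property_profile <- function(x, ...) {
  x$per_protein |> mutate(genome_id = x$genome_id, .before = 1L)
}

#' @method glance protein_property_profile
#' @export
glance.protein_property_profile <- function(x, ...) {
  tibble(genome_id = x$genome_id, group_label = x$group_label,
         mean_flexibility = x$mean_flexibility, mean_pi = x$mean_pi,
         n_proteins = x$n_proteins,
         n_excluded_translation = x$n_excluded_translation,
         n_excluded_flexibility = x$n_excluded_flexibility)
}

#' Genome-level protein property table for a set of genomes
#'
#' @param genomes Named list of `genome_record` objects, or a manifest
#'   path/tibble.
#' @inheritParams genome_protein_profile
#' @return A tibble with one row per genome (the [glance()] of each
#'   profile).
#' @export
protein_profiles <- function(genomes, scale = flexibility_scale(),
                             pka = pka_set(), window = 9L, code = "11") {
  if (is.character(genomes) || inherits(genomes, "data.frame")) {
    genomes <- load_genomes(genomes)
  }
  purrr::map_dfr(genomes, function(g) {
    glance(genome_protein_profile(g, scale = scale, pka = pka,
                                  window = window, code = code))
  })
}
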