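#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. The null
#' distribution is enumerated exactly when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie and continuity corrections is used. Two identical constant samples
#' yield p = 1 with a warning.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list with `statistic` (Mann-Whitney U of the first sample)
#'   and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  if (length(x) < 2L || length(y) < 2L) {
    abort("Each sample needs at least 2 observations")
  }
  if (length(unique(c(x, y))) == 1L) {
    warn("All values identical in both samples; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1, input order
#' preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param counts Non-negative numeric matrix or data frame, genomes in
#'   rows (row names = genome ids), gene families in columns. Every row
#'   must have a positive total.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(counts) {
  m <- as.matrix(counts)
  mode(m) <- "numeric"
  if (any(m < 0)) abort("Counts must be non-negative")
  if (any(rowSums(m) == 0)) {
    abort(paste0("Zero-total row(s): ",
                 paste(rownames(m)[rowSums(m) == 0], collapse = ", ")))
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Two-group PERMANOVA on a distance matrix
#'
#' Computes Anderson's pseudo-F from total and within-group sums of
#' squared distances and obtains the p-value by permuting group labels.
#' When the number of distinct label assignments `choose(n, n1)` does not
#' exceed `exact_limit`, all assignments are enumerated and
#' p = #\{F >= F_obs\} / #assignments; otherwise `n_permutations` random
#' permutations give p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations).
#'
#' @param d Square distance matrix (or `dist`).
#' @param labels Two-level group label per row of `d` (each group n >= 2).
#' @param n_permutations Random permutations for the sampled mode.
#' @param seed Integer seed for the sampled mode.
#' @param exact_limit Enumerate exhaustively when the number of distinct
#'   assignments is at most this (default 10000).
#' @return A `permanova_result` with `statistic` (pseudo-F), `p.value`,
#'   `method` (`"exact"` or `"sampled"`), `n_permutations` and the
#'   permutation F distribution.
#' @export
permanova <- function(d, labels, n_permutations = 999L, seed = NULL,
                      exact_limit = 10000L) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  if (nrow(d) != length(labels)) abort("labels must match the distance matrix")
  lev <- unique(labels)
  if (length(lev) != 2L) abort("PERMANOVA here is defined for exactly 2 groups")
  if (any(table(labels) < 2L)) abort("Each group needs at least 2 samples")
  n <- nrow(d)
  if (all(d == 0)) {
    abort("Degenerate input: all pairwise distances are zero")
  }
  d2 <- d^2
  n1 <- sum(labels == lev[1L])
  pseudo_f_from_v <- function(V) {
    # V: n x K indicator matrix of group-1 membership
    R <- d2 %*% V
    vDv <- colSums(V * R)
    oneDv <- colSums(R)
    total <- sum(d2)
    wDw <- total - 2 * oneDv + vDv
    ss_within <- vDv / (2 * n1) + wDw / (2 * (n - n1))
    ss_total <- total / (2 * n)
    (ss_total - ss_within) / (ss_within / (n - 2))
  }
  v_obs <- matrix(as.numeric(labels == lev[1L]), ncol = 1L)
  f_obs <- pseudo_f_from_v(v_obs)
  n_assign <- choose(n, n1)
  if (n_assign <= exact_limit) {
    combos <- combn(n, n1)
    V <- matrix(0, n, ncol(combos))
    V[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = n1))] <- 1
    f_perm <- pseudo_f_from_v(V)
    p <- sum(f_perm >= f_obs - 1e-9 * max(1, abs(f_obs))) / n_assign
    method <- "exact"
    n_perm <- n_assign
  } else {
    if (is.null(seed)) abort("Provide a seed for sampled permutations")
    V <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(i) as.numeric(seq_len(n) %in% sample.int(n, n1)),
             numeric(n))
    })
    f_perm <- pseudo_f_from_v(V)
    p <- (1 + sum(f_perm >= f_obs - 1e-9 * max(1, abs(f_obs)))) /
      (1 + n_permutations)
    method <- "sampled"
    n_perm <- n_permutations
  }
  structure(list(statistic = f_obs, p.value = p, method = method,
                 n_permutations = n_perm, f_perm = f_perm,
                 groups = setNames(c(n1, n - n1), lev), seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> pseudo-F = %.4f, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p.value, x$method, x$n_permutations))
  invisible(x)
}

#' @method tidy permanova_result
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, method = x$method,
         n_permutations = x$n_permutations)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS via [vegan::metaMDS()] (monotone regression,
#' best of `n_starts` random starts).
#'
#' @param d Square distance matrix (or `dist`).
#' @param k Embedding dimension (default 2; must satisfy k < n - 1).
#' @param seed Integer seed for the random starts.
#' @param n_starts Number of random starts (default 20).
#' @return An `ordination_result` with `coordinates` (tibble, one row per
#'   sample), `stress` in \[0, 1\] and `converged`.
#' @export
nmds_ordination <- function(d, k = 2L, seed = 1L, n_starts = 20L) {
  dm <- stats::as.dist(as.matrix(d))
  n <- attr(dm, "Size")
  if (k > n - 1L) abort("k must be at most n - 1")
  fit <- withr::with_seed(seed, suppressWarnings({
    vegan::metaMDS(dm, k = k, try = n_starts, trymax = n_starts,
                   autotransform = FALSE, wascores = FALSE, trace = 0)
  }))
  coords <- as_tibble(vegan::scores(fit, display = "sites"),
                      .name_repair = "minimal")
  names(coords) <- paste0("NMDS", seq_len(k))
  coords <- coords |>
    mutate(sample_id = rownames(as.matrix(d)) %||%
             paste0("s", seq_len(n)), .before = 1L)
  structure(list(coordinates = coords,
                 stress = fit$stress / if (fit$stress > 1) 100 else 1,
                 converged = isTRUE(fit$converged) || fit$converged > 0,
                 k = k, seed = seed, n_starts = n_starts),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> k = %d, stress = %.4f%s\n", x$k, x$stress,
              if (!x$converged) " (no convergent solution; best kept)" else ""))
  invisible(x)
}

#' Ordination scatter plot
#'
#' @param object An `ordination_result`.
#' @param labels Optional group label per sample (in coordinate order).
#' @param ... Unused.
#' @return A ggplot of the first two ordination axes.
#' @method autoplot ordination_result
#' @export
autoplot.ordination_result <- function(object, labels = NULL, ...) {
  d <- object$coordinates
  d$group <- labels %||% "all"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# significance stars used in the comparison figures
p_stars <- function(p) {
  dplyr::case_when(p < 0.005 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "NS")
}

#' Per-trait two-group comparison with BH adjustment
#'
#' Runs one two-sided Wilcoxon rank-sum test per numeric trait column,
#' adjusts the p-values across the trait family with Benjamini-Hochberg,
#' and annotates direction (from group medians) and significance stars
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.005 on the adjusted value).
#'
#' @param trait_table Data frame with `genome_id`, a two-level
#'   `group_label` column, and numeric trait columns.
#' @param group_col Name of the label column (default `"group_label"`).
#' @param focal Level treated as the focal (e.g. cold-adapted) group;
#'   defaults to `"PD"` when present, otherwise the first level. Direction
#'   is reported relative to this group.
#' @param star_on Use `"p_adj"` (default) or `"p_raw"` for stars and
#'   direction calls.
#' @return A tibble with one row per trait: `trait`, `n_focal`, `n_other`,
#'   `median_focal`, `median_other`, `statistic`, `p_raw`, `p_adj`,
#'   `direction` (`up_in_<focal>`, `down_in_<focal>` or `ns`), `stars`.
#' @export
compare_traits <- function(trait_table, group_col = "group_label",
                           focal = NULL, star_on = c("p_adj", "p_raw")) {
  star_on <- match.arg(star_on)
  tt <- as_tibble(trait_table)
  if (!group_col %in% names(tt)) {
    abort(paste0("Missing group column '", group_col, "'"))
  }
  labels <- as.character(tt[[group_col]])
  if (any(is.na(labels))) abort("Missing group labels")
  lev <- unique(labels)
  if (length(lev) != 2L) abort("Exactly two groups required")
  focal <- focal %||% (if ("PD" %in% lev) "PD" else lev[1L])
  other <- setdiff(lev, focal)
  if (min(table(labels)) < 2L) abort("Each group needs at least 2 genomes")
  traits <- names(tt)[vapply(tt, is.numeric, logical(1))]
  traits <- setdiff(traits, c("genome_id", group_col))
  if (length(traits) == 0L) abort("No numeric trait columns found")
  res <- purrr::map_dfr(traits, function(tr) {
    x <- tt[[tr]][labels == focal]
    y <- tt[[tr]][labels == other]
    if (length(unique(c(x, y))) == 1L) {
      warn(paste0("Trait '", tr, "' constant in both groups; reported NS"))
      w <- list(statistic = length(x) * length(y) / 2, p.value = 1)
    } else {
      w <- wilcoxon_rank_sum(x, y)
    }
    tibble(trait = tr, n_focal = length(x), n_other = length(y),
           median_focal = median(x), median_other = median(y),
           statistic = w$statistic, p_raw = w$p.value)
  })
  res <- res |> mutate(p_adj = adjust_bh(.data$p_raw))
  p_call <- res[[star_on]]
  res |>
    mutate(
      direction = dplyr::case_when(
        p_call >= 0.05 ~ "ns",
        .data$median_focal > .data$median_other ~ paste0("up_in_", focal),
        .data$median_focal < .data$median_other ~ paste0("down_in_", focal),
        TRUE ~ "ns"),
      stars = p_stars(p_call))
}

#' Multivariate two-group comparison of a functional count table
#'
#' Bray-Curtis distances, two-group PERMANOVA and NMDS in one call, as
#' applied to externally produced functional gene-count tables (CAZyme
#' families, nitrogen/sulfur-cycle genes).
#'
#' @param count_table Data frame with `genome_id`, `group_label` and
#'   non-negative count columns.
#' @param seed Integer seed for permutations and NMDS starts.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param k NMDS dimension.
#' @return A list with `dist`, `permanova` and `nmds`.
#' @export
compare_counts <- function(count_table, seed, n_permutations = 999L, k = 2L) {
  ct <- as_tibble(count_table)
  num <- setdiff(names(ct)[vapply(ct, is.numeric, logical(1))], "genome_id")
  m <- as.matrix(ct[, num, drop = FALSE])
  rownames(m) <- ct$genome_id
  d <- bray_curtis(m)
  list(dist = d,
       permanova = permanova(d, ct$group_label,
                             n_permutations = n_permutations, seed = seed),
       nmds = nmds_ordination(d, k = k, seed = seed))
}
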