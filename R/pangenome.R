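#' Read a gene presence/absence matrix
#'
#' Reads a tabular gene-cluster occupancy matrix (first column gene ids,
#' remaining columns genome ids; comma- or tab-separated). Copy numbers
#' greater than 1 are binarized with a warning. Gene rows absent from
#' every genome are dropped with a warning.
#'
#' @param path Path to the matrix file.
#' @return Binary integer matrix, genes in rows, genomes in columns.
#' @export
read_pa_matrix <- function(path) {
  d <- read_table_auto(path)
  genes <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  if (any(m > 1)) {
    warn("Copy numbers > 1 found; binarizing to presence/absence")
    m[m > 1] <- 1
  }
  validate_pa_matrix(m)
}

validate_pa_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("Presence/absence matrix needs gene row names and genome column names")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("Duplicate gene or genome ids in presence/absence matrix")
  }
  if (!all(m %in% c(0, 1))) abort("Matrix cells must be 0/1")
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warn(sprintf("Dropping %d gene(s) absent from every genome", sum(empty)))
    m <- m[!empty, , drop = FALSE]
  }
  if (any(colSums(m) == 0)) abort("Every genome must carry at least one gene")
  storage.mode(m) <- "integer"
  m
}

# all permutations of 1..n as an n! x n matrix (recursive construction)
all_orders <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_orders(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Pangenome rarefaction over genome permutations
#'
#' For each permutation of genome order, accumulates the pangenome (union
#' of genes over the first N genomes), the core genome (intersection) and
#' the number of new genes discovered at each step, then takes element-wise
#' medians across permutations.
#'
#' @param m Binary gene x genome matrix (see [read_pa_matrix()]).
#' @param n_permutations Number of random genome orders (default 1000).
#' @param seed Integer seed making the permutation set reproducible.
#' @param exhaustive If `TRUE`, enumerate all `G!` genome orders instead of
#'   sampling (only sensible for G <= 8).
#' @return A `rarefaction_result`: list with `summary` (tibble of N,
#'   `median_pan`, `median_core`, `median_new`), the per-permutation
#'   `pan`, `core` and `new` matrices (permutations x N), `seed` and
#'   `n_permutations`.
#' @export
rarefy <- function(m, n_permutations = 1000L, seed = NULL,
                   exhaustive = FALSE) {
  m <- validate_pa_matrix(m)
  G <- ncol(m)
  if (G < 2L) abort("Rarefaction needs at least 2 genomes")
  if (exhaustive) {
    orders <- all_orders(G)
  } else {
    if (is.null(seed)) abort("Provide a seed for reproducible rarefaction")
    orders <- withr::with_seed(seed, t(replicate(n_permutations,
                                                 sample.int(G))))
  }
  P <- nrow(orders)
  n_genes <- nrow(m)
  all_present <- rowSums(m) == G
  pan <- core <- matrix(0L, P, G)
  for (p in seq_len(P)) {
    mp <- m[, orders[p, ], drop = FALSE]
    first_present <- max.col(mp, ties.method = "first")
    pan[p, ] <- cumsum(tabulate(first_present, nbins = G))
    first_absent <- rep.int(G + 1L, n_genes)
    if (!all(all_present)) {
      first_absent[!all_present] <-
        max.col(1L - mp[!all_present, , drop = FALSE], ties.method = "first")
    }
    core[p, ] <- n_genes - cumsum(tabulate(first_absent, nbins = G))
  }
  new <- cbind(pan[, 1L, drop = FALSE], pan[, -1L, drop = FALSE] -
                 pan[, -G, drop = FALSE])
  med <- function(x) apply(x, 2L, median)
  structure(list(
    summary = tibble(N = seq_len(G), median_pan = med(pan),
                     median_core = med(core), median_new = med(new)),
    pan = pan, core = core, new = new,
    n_permutations = P, seed = if (exhaustive) NA_integer_ else seed,
    exhaustive = exhaustive),
    class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  G <- nrow(x$summary)
  cat(sprintf("<rarefaction_result> %d genomes, %d permutation(s)%s\n",
              G, x$n_permutations, if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  median pan(%d) = %d, median core(%d) = %d\n", G,
              x$summary$median_pan[G], G, x$summary$median_core[G]))
  invisible(x)
}

#' Fit Heaps' law to a rarefaction curve
#'
#' Fits the power law `y = kappa * N^(-alpha)` by nonlinear least squares:
#' for `curve = "pan_new_genes"` to the median new-gene discovery counts
#' over N = 2..G (Tettelin-style openness fit; alpha < 1 means the
#' pangenome is open), and for `curve = "core_decay"` to the median core
#' counts over N = 1..G. The reported `alpha_se` is the across-permutation
#' variability: alpha refit on each permutation's own curve, then the
#' standard deviation taken. The asymptotic fit SE is kept as
#' `alpha_se_fit`.
#'
#' @param result A `rarefaction_result` from [rarefy()].
#' @param curve `"pan_new_genes"` or `"core_decay"`.
#' @return A `heaps_fit` object with `kappa`, `alpha`, `alpha_se`,
#'   `alpha_se_fit`, `curve`, `open` and the fitted model.
#' @export
fit_heaps <- function(result, curve = c("pan_new_genes", "core_decay")) {
  curve <- match.arg(curve)
  stopifnot(inherits(result, "rarefaction_result"))
  G <- nrow(result$summary)
  if (G < 4L) abort("Heaps fit needs at least 4 genomes")
  take <- function(mat) {
    if (curve == "pan_new_genes") {
      list(N = 2:G, Y = mat[, -1L, drop = FALSE])
    } else {
      list(N = 1:G, Y = mat)
    }
  }
  med <- take(if (curve == "pan_new_genes") result$new else result$core)
  y_med <- apply(med$Y, 2L, median)
  if (all(y_med == 0)) {
    abort("Degenerate fit: curve is identically zero (identical genomes?)")
  }
  fit <- fit_power_law(med$N, y_med)
  alphas <- apply(med$Y, 1L, function(y) {
    tryCatch(fit_power_law(med$N, y)$alpha, error = function(e) NA_real_)
  })
  structure(list(
    kappa = fit$kappa, alpha = fit$alpha,
    alpha_se = sd(alphas, na.rm = TRUE),
    alpha_se_fit = fit$alpha_se,
    n_refits = sum(!is.na(alphas)),
    curve = curve, open = fit$alpha < 1,
    model = fit$model,
    data = tibble(N = med$N, y = y_med)),
    class = "heaps_fit")
}

# kappa * N^(-alpha) least-squares fit (Levenberg-Marquardt) with log-log
# regression starting values; SE from the analytic Jacobian
fit_power_law <- function(N, y) {
  pos <- y > 0
  if (sum(pos) >= 2L) {
    ll <- stats::lm(log(y[pos]) ~ log(N[pos]))
    start <- list(kappa = exp(coef(ll)[[1L]]), alpha = -coef(ll)[[2L]])
  } else {
    start <- list(kappa = max(y, 1), alpha = 0.5)
  }
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) y - p$kappa * N^(-p$alpha),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0L || fit$info == 9L) {
    abort(paste0("Power-law fit did not converge: ", fit$message))
  }
  kappa <- fit$par$kappa; alpha <- fit$par$alpha
  if (kappa <= 0) abort("Degenerate fit: non-positive kappa")
  pred <- kappa * N^(-alpha)
  J <- cbind(N^(-alpha), -kappa * log(N) * N^(-alpha))
  dof <- length(y) - 2L
  sigma2 <- if (dof > 0) sum((y - pred)^2) / dof else 0
  se <- tryCatch(sqrt(sigma2 * diag(solve(crossprod(J))))[2L],
                 error = function(e) NA_real_)
  list(kappa = kappa, alpha = alpha, alpha_se = se, model = fit)
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("<heaps_fit> %s: kappa = %.3f, alpha = %.4f +/- %.4f (%s)\n",
              x$curve, x$kappa, x$alpha, x$alpha_se,
              if (x$open) "open, alpha < 1" else "closed, alpha >= 1"))
  invisible(x)
}

#' @method tidy heaps_fit
#' @export
tidy.heaps_fit <- function(x, ...) {
  tibble(term = c("kappa", "alpha"),
         estimate = c(x$kappa, x$alpha),
         std.error = c(NA_real_, x$alpha_se))
}

#' @method glance heaps_fit
#' @export
glance.heaps_fit <- function(x, ...) {
  tibble(curve = x$curve, kappa = x$kappa, alpha = x$alpha,
         alpha_se = x$alpha_se, alpha_se_fit = x$alpha_se_fit,
         open = x$open, n_points = nrow(x$data))
}

#' Predict gene discovery or core loss from a Heaps fit
#'
#' For a `pan_new_genes` fit, the expected number of new genes contributed
#' by the `at_N`-th genome, `kappa * at_N^(-alpha)`. For a `core_decay`
#' fit, the expected number of core genes lost when going from `at_N - 1`
#' to `at_N` genomes, `kappa * ((at_N-1)^(-alpha) - at_N^(-alpha))`.
#' Returns a rate, not an integer.
#'
#' @param fit A `heaps_fit`.
#' @param at_N Genome count at which to evaluate (>= 2).
#' @return Expected gene count (numeric).
#' @export
predict_discovery <- function(fit, at_N) {
  stopifnot(inherits(fit, "heaps_fit"))
  if (any(at_N < 2)) abort("at_N must be >= 2")
  if (fit$curve == "pan_new_genes") {
    fit$kappa * at_N^(-fit$alpha)
  } else {
    fit$kappa * ((at_N - 1)^(-fit$alpha) - at_N^(-fit$alpha))
  }
}

#' Partition genes by occupancy across genomes
#'
#' Computes each gene's occupancy fraction f (genomes carrying it / G) and
#' bins genes into cloud (f < 0.15), shell (0.15 <= f < 0.95), soft core
#' (0.95 <= f < 1) and strict core (f = 1). The published figure-caption
#' binning that stops the soft core at 99% (leaving \[0.99, 1) unassigned)
#' is reported alongside as `literal`.
#'
#' @param m Binary gene x genome matrix.
#' @param cloud_max,shell_max Upper occupancy bounds of the cloud and shell
#'   bins (defaults 0.15 and 0.95).
#' @return A `gene_partition`: list with `partition` (tibble of category,
#'   count, percent), `literal` (caption binning with `soft_core` capped at
#'   99% and a `core_95_strict_excl` remainder bin), `occupancy` (per-gene
#'   fractions) and the thresholds used.
#' @export
partition_genes <- function(m, cloud_max = 0.15, shell_max = 0.95) {
  m <- validate_pa_matrix(m)
  G <- ncol(m)
  f <- rowSums(m) / G
  cat_default <- cut(f, breaks = c(0, cloud_max, shell_max, 1 - 1e-12, 1),
                     labels = c("cloud", "shell", "soft_core", "strict_core"),
                     right = FALSE, include.lowest = TRUE)
  cat_default[f == 1] <- "strict_core"
  tab <- table(cat_default)
  partition <- tibble(category = names(tab),
                      count = as.integer(tab),
                      percent = 100 * as.integer(tab) / nrow(m))
  lit_cat <- dplyr::case_when(
    f < cloud_max ~ "cloud",
    f < shell_max ~ "shell",
    f < 0.99 ~ "soft_core",
    f < 1 ~ "unassigned_99_100",
    TRUE ~ "strict_core")
  lt <- table(factor(lit_cat, levels = c("cloud", "shell", "soft_core",
                                         "unassigned_99_100",
                                         "strict_core")))
  structure(list(
    partition = partition,
    literal = tibble(category = names(lt), count = as.integer(lt),
                     percent = 100 * as.integer(lt) / nrow(m)),
    occupancy = f,
    thresholds = c(cloud_max = cloud_max, shell_max = shell_max),
    n_genes = nrow(m), n_genomes = G),
    class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition> %d genes x %d genomes\n", x$n_genes,
              x$n_genomes))
  print(as.data.frame(x$partition), row.names = FALSE)
  invisible(x)
}

#' @method tidy gene_partition
#' @export
tidy.gene_partition <- function(x, ...) x$partition

#' Rarefaction curve plot
#'
#' @param object A `rarefaction_result`.
#' @param ... Unused.
#' @return A ggplot of the median pan and core curves with interquartile
#'   ribbons.
#' @method autoplot rarefaction_result
#' @export
autoplot.rarefaction_result <- function(object, ...) {
  q <- function(mat, p) apply(mat, 2L, quantile, probs = p)
  d <- dplyr::bind_rows(
    tibble(N = object$summary$N, curve = "pan",
           med = object$summary$median_pan,
           lo = q(object$pan, 0.025), hi = q(object$pan, 0.975)),
    tibble(N = object$summary$N, curve = "core",
           med = object$summary$median_core,
           lo = q(object$core, 0.025), hi = q(object$core, 0.975)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$N, y = .data$med,
                                  colour = .data$curve,
                                  fill = .data$curve)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Genomes sampled", y = "Gene clusters",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Gene-partition bar plot
#'
#' @param object A `gene_partition`.
#' @param ... Unused.
#' @return A ggplot bar chart of partition percentages.
#' @method autoplot gene_partition
#' @export
autoplot.gene_partition <- function(object, ...) {
  ggplot2::ggplot(object$partition,
                  ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Percent of pangenome") +
    ggplot2::theme_minimal()
}
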