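#' Per-sample diversity measures
#'
#' Richness (units with value > 0), Shannon H' in natural-log units
#' (via [vegan::diversity()]), Pielou evenness `J = H / ln(richness)`, and
#' the classic Chao1 estimator `S_obs + F1^2 / (2 F2)` (or
#' `S_obs + F1 (F1 - 1) / 2` when there are no doubletons), where F1 and F2
#' are the singleton and doubleton counts. Chao1 is only meaningful on
#' integer count data; it is `NA` for non-integer input. All-zero samples
#' get richness 0, H = 0 and undefined (NA) evenness.
#'
#' @param mat A sample-by-unit abundance matrix (samples in rows), or a long
#'   tibble with `sample_id`, a unit id column, and `value`.
#' @param base Logarithm base for Shannon H' (default `exp(1)`).
#' @return A tibble `sample_id`, `richness`, `shannon_h`, `pielou_j`,
#'   `chao1`.
#' @export
diversity_metrics <- function(mat, base = exp(1)) {
  mat <- as_sample_matrix(mat)
  rich <- rowSums(mat > 0)
  h <- vegan::diversity(mat, index = "shannon", base = base)
  j <- ifelse(rich > 1, h / log(rich, base = base),
              ifelse(rich == 1, NA_real_, NA_real_))
  chao <- apply(mat, 1, chao1_estimate)
  tibble(
    sample_id = rownames(mat),
    richness = as.integer(rich),
    shannon_h = as.numeric(h),
    pielou_j = as.numeric(j),
    chao1 = as.numeric(chao)
  )
}

chao1_estimate <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) return(0)
  if (any(abs(x - round(x)) > 1e-8)) return(NA_real_)
  s_obs <- length(x)
  f1 <- sum(round(x) == 1)
  f2 <- sum(round(x) == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

as_sample_matrix <- function(mat) {
  if (is.matrix(mat)) {
    vp_assert(!is.null(rownames(mat)), "matrix needs sample rownames")
    return(mat)
  }
  vp_assert(is.data.frame(mat), "`mat` must be a matrix or data frame")
  unit_col <- intersect(c("vc_id", "unit_id", "contig_id"), names(mat))[1]
  vp_assert(!is.na(unit_col),
            "long input needs a `vc_id`, `unit_id` or `contig_id` column")
  vp_assert_fields(mat, c("sample_id", "value"), "`mat`")
  wide <- mat |>
    select(sample_id, unit = dplyr::all_of(unit_col), value) |>
    tidyr::pivot_wider(names_from = unit, values_from = value,
                       values_fill = 0)
  out <- as.matrix(wide[, -1, drop = FALSE])
  rownames(out) <- wide$sample_id
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum(|a_i - b_i|) / sum(a_i + b_i)`, computed with
#' [vegan::vegdist()].
#'
#' @param mat Sample-by-unit abundance matrix or long tibble (see
#'   [diversity_metrics()]).
#' @return A symmetric `dist`-backed matrix with zero diagonal.
#' @export
bray_curtis <- function(mat) {
  mat <- as_sample_matrix(mat)
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns coordinates
#' `eigvec * sqrt(eigval)` for the positive eigenvalues, sorted by
#' eigenvalue. Negative eigenvalues are dropped with a warning (no Cailliez
#' correction).
#'
#' @param d A symmetric distance matrix with zero diagonal.
#' @return A list of class `virome_pcoa`: `coordinates` (tibble with
#'   `sample_id` and `axis1..axisK`), `eigenvalues`, and
#'   `variance_explained`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  vp_assert(isSymmetric(unname(d), tol = 1e-8),
            "`d` must be a symmetric distance matrix")
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # eigenvalue screen below handles that case explicitly
  sc <- suppressWarnings(cmdscale(stats::as.dist(d), k = n - 1,
                                  eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > 1e-8)
  if (any(eig < -1e-8)) {
    rlang::warn("negative eigenvalues dropped from PCoA")
  }
  coords <- sc$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("axis", seq_along(pos))
  structure(
    list(
      coordinates = bind_cols(
        tibble(sample_id = rownames(d) %||% as.character(seq_len(n))),
        as_tibble(coords)
      ),
      eigenvalues = eig[pos],
      variance_explained = eig[pos] / sum(eig[pos])
    ),
    class = "virome_pcoa"
  )
}

#' PERMANOVA with sequential covariate adjustment
#'
#' Permutational multivariate analysis of variance on a distance matrix,
#' fitted with [vegan::adonis2()] using sequential (Type I) partitioning:
#' covariates enter the model before the group term, so the group's
#' pseudo-F is conditioned on them. P-values use raw label permutation:
#' `p = (1 + #{perm F >= obs F}) / (1 + n_perm)`.
#'
#' @param d Distance matrix (samples in rows/columns, named).
#' @param metadata Data frame with `sample_id`, the group column, and any
#'   covariates.
#' @param group Name of the grouping column.
#' @param covariates Character vector of covariate column names entered
#'   before the group (default none).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A `virome_permanova` list: `pseudo_f`, `p_value`, `r2`,
#'   `n_permutations`, `term_order`, and the full `aov_table`.
#' @export
permanova <- function(d, metadata, group, covariates = character(0),
                      n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  vp_assert_fields(metadata, c("sample_id", group, covariates),
                   "`metadata`")
  idx <- match(rownames(d), metadata$sample_id)
  vp_assert(!anyNA(idx), "metadata is missing samples present in `d`")
  md <- as.data.frame(metadata[idx, , drop = FALSE])
  counts_per_group <- table(md[[group]])
  vp_assert(all(counts_per_group >= 2),
            "every group needs at least 2 samples")
  rhs <- paste(c(covariates, group), collapse = " + ")
  fml <- stats::as.formula(paste("stats::as.dist(d) ~", rhs))
  fit <- with_seed(seed, vegan::adonis2(
    fml, data = md, permutations = n_perm, by = "terms"
  ))
  grp_row <- match(group, rownames(fit))
  structure(
    list(
      pseudo_f = fit$F[grp_row],
      p_value = fit$`Pr(>F)`[grp_row],
      r2 = fit$R2[grp_row],
      n_permutations = n_perm,
      term_order = c(covariates, group),
      aov_table = as.data.frame(fit)
    ),
    class = "virome_permanova"
  )
}

#' @export
print.virome_permanova <- function(x, ...) {
  cat("<virome_permanova>\n")
  cat(sprintf("  terms: %s\n", paste(x$term_order, collapse = " + ")))
  cat(sprintf("  group pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$r2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Spearman correlations with Benjamini-Hochberg adjustment
#'
#' Computes Spearman's rank correlation (ties mid-ranked) for each requested
#' pair of columns and adjusts the p-values with the Benjamini-Hochberg
#' procedure across all tested pairs.
#'
#' @param data A data frame holding the variables.
#' @param pairs A two-column data frame (or list of 2-vectors) naming the
#'   `x` and `y` columns of each test.
#' @return A tibble `x`, `y`, `rho`, `p`, `q`.
#' @export
spearman_bh <- function(data, pairs) {
  if (!is.data.frame(pairs)) {
    pairs <- as.data.frame(do.call(rbind, pairs))
  }
  names(pairs)[1:2] <- c("x", "y")
  res <- purrr::pmap_dfr(pairs, function(x, y, ...) {
    ok <- complete.cases(data[[x]], data[[y]])
    ct <- suppressWarnings(
      cor.test(data[[x]][ok], data[[y]][ok], method = "spearman")
    )
    tibble(x = x, y = y, rho = unname(ct$estimate), p = ct$p.value)
  })
  res |> mutate(q = p.adjust(p, method = "BH"))
}
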