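#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact enumeration: with both margins fixed, the two-sided p-value is the
#' sum of hypergeometric probabilities of every admissible table whose
#' probability does not exceed the observed table's (the probability-mass
#' method, with 1e-7 relative slack against floating-point ties). One-sided
#' variants sum the corresponding hypergeometric tail.
#'
#' @param table A 2x2 matrix `rbind(c(a, b), c(c, d))` (group 1
#'   present/absent, group 2 present/absent), or the count `a` when `b`,
#'   `c`, `d` are given.
#' @param b,c_,d Optional individual counts.
#' @param sided `"two"` (default), `"greater"` or `"less"` (tail of the
#'   first group's presence count).
#' @return The p-value.
#' @export
#' @examples
#' fisher_exact(rbind(c(78, 21), c(58, 39)))  # ~0.005
fisher_exact <- function(table, b = NULL, c_ = NULL, d = NULL,
                         sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (!is.matrix(table)) {
    vp_assert(!is.null(b) && !is.null(c_) && !is.null(d),
              "supply a 2x2 matrix or all four counts")
    table <- rbind(c(table, b), c(c_, d))
  }
  vp_assert(all(dim(table) == c(2, 2)) && all(table >= 0),
            "`table` must be a 2x2 matrix of non-negative counts")
  a <- table[1, 1]
  m1 <- sum(table[1, ])          # group 1 size
  m2 <- sum(table[2, ])          # group 2 size
  k <- sum(table[, 1])           # total present
  vp_assert(m1 > 0 && m2 > 0, "zero margin: test undefined")
  # one admissible table when a column margin is zero
  if (k == 0 || k == m1 + m2) return(1)
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  support <- lo:hi
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  p <- switch(
    sided,
    two = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a])
  )
  min(1, p)
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when `min(n, m) <= exact_limit` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' The switch point of 25 keeps balanced cohorts of 24 per group on the
#' exact path.
#'
#' @param x,y Numeric samples for the two groups.
#' @param sided `"two"` (default), `"greater"` or `"less"`.
#' @param exact_limit Largest `min(n, m)` for the exact branch (default 25).
#' @return A list with `statistic` (W) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, sided = c("two", "greater", "less"),
                              exact_limit = 25) {
  sided <- match.arg(sided)
  vp_assert(length(x) > 0 && length(y) > 0, "empty group")
  alt <- switch(sided, two = "two.sided", greater = "greater",
                less = "less")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(length(x), length(y)) <= exact_limit && !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = use_exact,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}

#' Benjamini-Hochberg adjustment
#'
#' `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, returned in the
#' input order. Monotone in p-rank and idempotent.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Per-unit prevalence comparison between two groups
#'
#' Builds a 2x2 presence table per unit, applies [fisher_exact()], and
#' adjusts across units with Benjamini-Hochberg. `direction` names the
#' group with the higher presence fraction ("none" on exact ties).
#'
#' @param presence A data frame `unit_id`, `sample_id`, `present`
#'   (logical), or a layer with `value` (present = value > 0).
#' @param metadata A data frame `sample_id`, `group` with exactly two
#'   groups.
#' @return A tibble `unit_id`, per-group counts, `direction`, `p`, `q`,
#'   sorted by `q`.
#' @export
prevalence_compare <- function(presence, metadata) {
  vp_assert_fields(metadata, c("sample_id", "group"), "`metadata`")
  groups <- sort(unique(metadata$group))
  vp_assert(length(groups) == 2, "`metadata` must contain exactly 2 groups")
  unit_col <- intersect(c("vc_id", "unit_id", "contig_id", "lineage"),
                        names(presence))[1]
  vp_assert(!is.na(unit_col), "`presence` needs a unit id column")
  if (!"present" %in% names(presence)) {
    vp_assert_fields(presence, "value", "`presence`")
    presence$present <- presence$value > 0
  }
  df <- presence |>
    rename(unit_id = dplyr::all_of(unit_col)) |>
    select(unit_id, sample_id, present) |>
    left_join(metadata |> select(sample_id, group), by = "sample_id")
  n_by_group <- table(metadata$group)
  res <- df |>
    group_by(unit_id) |>
    summarise(
      present_1 = sum(present[group == groups[1]]),
      present_2 = sum(present[group == groups[2]]),
      .groups = "drop"
    ) |>
    mutate(
      n_1 = as.integer(n_by_group[[groups[1]]]),
      n_2 = as.integer(n_by_group[[groups[2]]]),
      p = purrr::map2_dbl(present_1, present_2, function(a, b) {
        fisher_exact(rbind(c(a, n_by_group[[groups[1]]] - a),
                           c(b, n_by_group[[groups[2]]] - b)))
      }),
      direction = dplyr::case_when(
        present_1 / n_1 > present_2 / n_2 ~ groups[1],
        present_1 / n_1 < present_2 / n_2 ~ groups[2],
        TRUE ~ "none"
      ),
      q = bh_adjust(p)
    ) |>
    arrange(q, p, unit_id)
  names(res)[names(res) == "present_1"] <- paste0("present_", groups[1])
  names(res)[names(res) == "present_2"] <- paste0("present_", groups[2])
  names(res)[names(res) == "n_1"] <- paste0("n_", groups[1])
  names(res)[names(res) == "n_2"] <- paste0("n_", groups[2])
  res
}

#' Ingest an externally computed compositional differential-abundance table
#'
#' The bias-corrected compositional analysis itself is performed by the
#' published external method; this adapter only validates its result table
#' (unit id, log-fold-change, standard error, BH-adjusted q) and coerces it
#' into the package's group-comparison shape.
#'
#' @param table A data frame with columns `unit_id`, `lfc`, `se`, `q`.
#' @return A tibble `unit_id`, `lfc`, `se`, `q`, `direction`.
#' @export
ancombc_adapter <- function(table) {
  required <- c("unit_id", "lfc", "se", "q")
  missing <- setdiff(required, names(table))
  vp_assert(length(missing) == 0,
            sprintf("malformed result table; missing column(s): %s",
                    paste(missing, collapse = ", ")))
  vp_assert(is.numeric(table$lfc) && is.numeric(table$se) &&
              is.numeric(table$q), "`lfc`, `se`, `q` must be numeric")
  vp_assert(all(table$q >= 0 & table$q <= 1, na.rm = TRUE),
            "`q` values must lie in [0, 1]")
  vp_assert(all(table$se >= 0, na.rm = TRUE), "`se` must be non-negative")
  as_tibble(table) |>
    select(unit_id, lfc, se, q) |>
    mutate(direction = dplyr::case_when(
      lfc > 0 ~ "group2_higher",
      lfc < 0 ~ "group1_higher",
      TRUE ~ "none"
    ))
}
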