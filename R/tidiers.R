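# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA fit
#'
#' @param x A `virome_permanova` from [permanova()].
#' @param ... Unused.
#' @return One row per model term: `term`, `df`, `sum_of_squares`, `r2`,
#'   `statistic`, `p_value`.
#' @export
tidy.virome_permanova <- function(x, ...) {
  tab <- x$aov_table
  tibble(
    term = rownames(tab),
    df = tab$Df,
    sum_of_squares = tab$SumOfSqs,
    r2 = tab$R2,
    statistic = tab$F,
    p_value = tab$`Pr(>F)`
  )
}

#' @rdname tidy.virome_permanova
#' @export
glance.virome_permanova <- function(x, ...) {
  tibble(
    pseudo_f = x$pseudo_f,
    r2 = x$r2,
    p_value = x$p_value,
    n_permutations = x$n_permutations
  )
}

#' Tidy a PCoA ordination
#'
#' @param x A `virome_pcoa` from [pcoa()].
#' @param ... Unused.
#' @return The sample coordinates tibble.
#' @export
tidy.virome_pcoa <- function(x, ...) {
  x$coordinates
}

#' @rdname tidy.virome_pcoa
#' @export
glance.virome_pcoa <- function(x, ...) {
  tibble(
    n_axes = length(x$eigenvalues),
    variance_axis1 = x$variance_explained[1],
    variance_axis2 = if (length(x$variance_explained) > 1)
      x$variance_explained[2] else NA_real_
  )
}

#' Tidy an abundance object into one long table
#'
#' @param x A `virome_abundance` from [compute_abundance()].
#' @param ... Unused.
#' @return A long tibble `vc_id`, `sample_id`, `counts`, `rpkm`,
#'   `relative`.
#' @export
tidy.virome_abundance <- function(x, ...) {
  x$vc_counts |>
    rename(counts = value) |>
    left_join(x$vc_rpkm |> rename(rpkm = value),
              by = c("vc_id", "sample_id")) |>
    left_join(x$vc_relative |> rename(relative = value),
              by = c("vc_id", "sample_id"))
}

#' @rdname tidy.virome_abundance
#' @export
glance.virome_abundance <- function(x, ...) {
  tibble(
    n_samples = dplyr::n_distinct(x$vc_relative$sample_id),
    n_vcs = dplyr::n_distinct(x$vc_relative$vc_id),
    n_zeroed = sum(x$coverage_mask$zeroed),
    min_identity = x$params$min_identity,
    min_coverage = x$params$min_coverage
  )
}
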