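# Alignment records use 0-based half-open coordinates throughout; see
# from_one_based() for converting 1-based inclusive input.

#' Remove spurious read mappings below an identity cutoff
#'
#' Keeps alignment records with `identity >= min_identity` (the boundary is
#' inclusive: mappings at *less than* the cutoff are removed).
#'
#' @param records A data frame of alignment records with at least an
#'   `identity` column (fraction in `[0, 1]`).
#' @param min_identity Minimum identity fraction (default 0.90).
#' @return The filtered records.
#' @export
filter_identity <- function(records, min_identity = 0.90) {
  vp_assert_fields(records, "identity", "`records`")
  vp_assert(all(records$identity >= 0 & records$identity <= 1),
            "`identity` must be within [0, 1]")
  records |> filter(identity >= min_identity)
}

#' Horizontal coverage of one contig in one sample
#'
#' Fraction of contig positions covered by at least one alignment interval
#' (union length / contig length).
#'
#' @param records Alignment records for a single contig and sample, with
#'   0-based half-open `start`, `end` columns.
#' @param contig_len Contig length in bp.
#' @return Coverage fraction in `[0, 1]`.
#' @export
horizontal_coverage <- function(records, contig_len) {
  if (nrow(records) == 0) return(0)
  vp_assert_fields(records, c("start", "end"), "`records`")
  vp_assert(all(records$start >= 0 & records$start < records$end),
            "intervals must satisfy 0 <= start < end")
  vp_assert(all(records$end <= contig_len),
            "alignment interval exceeds contig length")
  ir <- IRanges::reduce(IRanges::IRanges(start = records$start + 1L,
                                         end = records$end))
  sum(IRanges::width(ir)) / contig_len
}

#' Per contig-sample read counts with horizontal-coverage zeroing
#'
#' Sums `n_reads` per contig and sample, then sets counts to zero wherever
#' the contig's horizontal coverage in that sample is below `threshold`
#' (coverage of exactly the threshold is kept: counts at *less than* the
#' cutoff are zeroed). The coverage of every contig-sample combination is
#' retained as provenance.
#'
#' @param records Identity-filtered alignment records (`contig_id`,
#'   `sample_id`, `start`, `end`, `n_reads`).
#' @param contig_lengths Named vector (or data frame `contig_id`, `length`)
#'   of contig lengths.
#' @param threshold Minimum coverage fraction (default 0.75).
#' @return A list with `counts` (tibble `contig_id`, `sample_id`, `counts`)
#'   and `coverage_mask` (tibble `contig_id`, `sample_id`, `coverage`,
#'   `zeroed`).
#' @export
counts_with_coverage_zeroing <- function(records, contig_lengths,
                                         threshold = 0.75) {
  vp_assert_fields(records,
                   c("contig_id", "sample_id", "start", "end", "n_reads"),
                   "`records`")
  lens <- as_length_vector(contig_lengths)
  missing <- setdiff(unique(records$contig_id), names(lens))
  vp_assert(length(missing) == 0,
            sprintf("no length for contig(s): %s",
                    paste(missing, collapse = ", ")))
  if (nrow(records) == 0) {
    return(list(
      counts = tibble(contig_id = character(0), sample_id = character(0),
                      counts = numeric(0)),
      coverage_mask = tibble(contig_id = character(0),
                             sample_id = character(0),
                             coverage = numeric(0), zeroed = logical(0))
    ))
  }
  per <- records |>
    group_by(contig_id, sample_id) |>
    summarise(
      counts = sum(n_reads),
      coverage = horizontal_coverage(
        tibble(start = start, end = end),
        lens[[contig_id[1]]]
      ),
      .groups = "drop"
    ) |>
    mutate(zeroed = coverage < threshold,
           counts = if_else(zeroed, 0, as.numeric(counts)))
  list(
    counts = per |> select(contig_id, sample_id, counts),
    coverage_mask = per |> select(contig_id, sample_id, coverage, zeroed)
  )
}

as_length_vector <- function(contig_lengths) {
  if (is.data.frame(contig_lengths)) {
    vp_assert_fields(contig_lengths, c("contig_id", "length"),
                     "`contig_lengths`")
    setNames(contig_lengths$length, contig_lengths$contig_id)
  } else {
    vp_assert(!is.null(names(contig_lengths)),
              "`contig_lengths` must be named")
    contig_lengths
  }
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((contig_len / 1000) * (library_size / 1e6))`.
#'
#' @param counts Numeric read counts.
#' @param contig_len Contig length(s) in bp.
#' @param library_size Mapped reads in the sample's library.
#' @return RPKM values.
#' @export
rpkm <- function(counts, contig_len, library_size) {
  vp_assert(all(library_size > 0), "`library_size` must be > 0")
  counts / ((contig_len / 1000) * (library_size / 1e6))
}

#' Aggregate a per-contig abundance layer to viral clusters
#'
#' Sums values over each VC's member contigs, per sample. Totals are
#' conserved: the matrix total before and after aggregation is identical.
#'
#' @param layer A tibble `contig_id`, `sample_id`, `value`.
#' @param vcs A tibble `contig_id`, `vc_id`.
#' @return A tibble `vc_id`, `sample_id`, `value`.
#' @export
aggregate_by_vc <- function(layer, vcs) {
  vp_assert_fields(layer, c("contig_id", "sample_id", "value"), "`layer`")
  vp_assert_fields(vcs, c("contig_id", "vc_id"), "`vcs`")
  unassigned <- setdiff(unique(layer$contig_id), vcs$contig_id)
  vp_assert(length(unassigned) == 0,
            sprintf("contig(s) without VC assignment: %s",
                    paste(unassigned, collapse = ", ")))
  layer |>
    left_join(vcs |> select(contig_id, vc_id), by = "contig_id") |>
    group_by(vc_id, sample_id) |>
    summarise(value = sum(value), .groups = "drop")
}

#' Convert an abundance layer to within-sample relative abundance
#'
#' Divides each sample's values by the sample total. Samples whose total is
#' zero stay all-zero, with a warning.
#'
#' @param layer A tibble with `sample_id` and `value` columns (plus any unit
#'   id column).
#' @return The same tibble with `value` replaced by relative abundances.
#' @export
relative_abundance <- function(layer) {
  vp_assert_fields(layer, c("sample_id", "value"), "`layer`")
  totals <- tapply(layer$value, layer$sample_id, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    rlang::warn(sprintf("sample(s) with zero total abundance: %s",
                        paste(zero, collapse = ", ")))
  }
  denom <- totals[layer$sample_id]
  denom[denom == 0] <- 1
  layer |> mutate(value = value / as.numeric(denom))
}

#' Full coverage-filtered abundance pipeline
#'
#' Runs the fixed pipeline order: identity filter, coverage zeroing, RPKM,
#' VC aggregation, relative abundance. Library size defaults to the total
#' identity-filtered mapped reads per sample; pass `library_sizes` to use
#' another denominator (e.g. all quality-controlled reads).
#'
#' @param records Raw alignment records (`contig_id`, `sample_id`, `start`,
#'   `end`, `n_reads`, `identity`).
#' @param contig_lengths Named vector or data frame of contig lengths.
#' @param vcs Tibble `contig_id`, `vc_id` assigning every mapped contig.
#' @param min_identity Identity cutoff (default 0.90).
#' @param min_coverage Horizontal-coverage cutoff (default 0.75).
#' @param library_sizes Optional named vector of per-sample library sizes.
#' @return A `virome_abundance` object: list with tibbles `counts`
#'   (per contig), `vc_counts`, `vc_rpkm`, `vc_relative` (per VC),
#'   `coverage_mask`, and the `library_sizes` used.
#' @export
compute_abundance <- function(records, contig_lengths, vcs,
                              min_identity = 0.90, min_coverage = 0.75,
                              library_sizes = NULL) {
  lens <- as_length_vector(contig_lengths)
  kept <- filter_identity(records, min_identity)
  if (is.null(library_sizes)) {
    library_sizes <- tapply(kept$n_reads, kept$sample_id, sum)
    library_sizes <- setNames(as.numeric(library_sizes),
                              names(library_sizes))
  }
  cz <- counts_with_coverage_zeroing(kept, lens, threshold = min_coverage)
  counts <- cz$counts
  rpkm_layer <- counts |>
    mutate(value = rpkm(counts, lens[contig_id],
                        library_sizes[sample_id])) |>
    select(contig_id, sample_id, value)
  counts_layer <- counts |> rename(value = counts)
  vc_counts <- aggregate_by_vc(counts_layer, vcs)
  vc_rpkm <- aggregate_by_vc(rpkm_layer, vcs)
  vc_relative <- relative_abundance(vc_rpkm)
  structure(
    list(
      counts = counts,
      vc_counts = vc_counts,
      vc_rpkm = vc_rpkm,
      vc_relative = vc_relative,
      coverage_mask = cz$coverage_mask,
      library_sizes = library_sizes,
      params = list(min_identity = min_identity,
                    min_coverage = min_coverage)
    ),
    class = "virome_abundance"
  )
}

#' @export
print.virome_abundance <- function(x, ...) {
  cat("<virome_abundance>\n")
  cat("  samples:", dplyr::n_distinct(x$vc_relative$sample_id), "\n")
  cat("  VCs:", dplyr::n_distinct(x$vc_relative$vc_id), "\n")
  cat("  identity cutoff:", x$params$min_identity,
      "| coverage cutoff:", x$params$min_coverage, "\n")
  invisible(x)
}

#' Per-unit prevalence and prevalence bin
#'
#' Prevalence is the fraction of samples in which a unit has non-zero
#' (filtered) abundance. Units are binned as "individual" (prevalence below
#' `low`), "core" (above `high`) or "intermediate" otherwise.
#'
#' @param layer A tibble with a unit id column (`vc_id` or `unit_id`),
#'   `sample_id` and `value`; absent combinations count as zero.
#' @param n_samples Total number of samples (default: distinct `sample_id`
#'   in `layer`).
#' @param low,high Bin boundaries (defaults 0.10 and 0.30).
#' @return A tibble `unit_id`, `n_present`, `prevalence`, `bin`.
#' @export
prevalence_bins <- function(layer, n_samples = NULL, low = 0.10,
                            high = 0.30) {
  unit_col <- intersect(c("vc_id", "unit_id", "contig_id"), names(layer))[1]
  vp_assert(!is.na(unit_col),
            "`layer` needs a `vc_id`, `unit_id` or `contig_id` column")
  vp_assert_fields(layer, c("sample_id", "value"), "`layer`")
  n_samples <- n_samples %||% dplyr::n_distinct(layer$sample_id)
  layer |>
    group_by(unit_id = .data[[unit_col]]) |>
    summarise(n_present = sum(value > 0), .groups = "drop") |>
    mutate(
      prevalence = n_present / n_samples,
      bin = dplyr::case_when(
        prevalence < low ~ "individual",
        prevalence > high ~ "core",
        TRUE ~ "intermediate"
      )
    )
}

#' Cumulative ranked-abundance curve for one sample
#'
#' Sorts a sample's unit abundances in decreasing order (ties broken by unit
#' id) and accumulates the fractions; the curve is non-decreasing and ends
#' at 1 when the sample total is positive.
#'
#' @param values Numeric abundances.
#' @param unit_ids Optional unit ids for deterministic tie-breaks.
#' @return A tibble `abund_rank`, `unit_id`, `value`, `cum_fraction`.
#' @export
ranked_abundance_curve <- function(values, unit_ids = NULL) {
  unit_ids <- unit_ids %||% as.character(seq_along(values))
  ord <- order(-values, unit_ids)
  total <- sum(values)
  cf <- if (total > 0) cumsum(values[ord]) / total else
    rep(0, length(values))
  tibble(
    abund_rank = seq_along(values),
    unit_id = unit_ids[ord],
    value = values[ord],
    cum_fraction = cf
  )
}
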