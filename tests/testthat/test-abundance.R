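test_that("identity filter keeps the 90% boundary inclusive", {
  recs <- tibble::tibble(identity = c(0.90, 0.899, 0.95, 0.70))
  kept <- filter_identity(recs)
  expect_equal(kept$identity, c(0.90, 0.95))
  expect_equal(nrow(filter_identity(recs[0, ])), 0)
  expect_error(filter_identity(tibble::tibble(identity = 1.2)), "0, 1")
})

test_that("horizontal coverage is the union fraction", {
  recs <- tibble::tibble(start = c(0, 40), end = c(50, 80))
  expect_equal(horizontal_coverage(recs, 100), 0.8)
  expect_equal(horizontal_coverage(recs[0, ], 100), 0)
  expect_error(
    horizontal_coverage(tibble::tibble(start = 0, end = 200), 100),
    "exceeds"
  )
})

test_that("horizontal coverage matches a per-position oracle on random cases", {
  set.seed(501)
  for (i in 1:100) {
    L <- sample(50:500, 1)
    k <- sample(1:12, 1)
    starts <- sample(0:(L - 2), k, replace = TRUE)
    ends <- pmin(starts + sample(1:60, k, replace = TRUE), L)
    impl <- horizontal_coverage(tibble::tibble(start = starts, end = ends),
                                L)
    expect_equal(impl, coverage_oracle(starts, ends, L))
  }
})

test_that("coverage zeroing applies the strict less-than-75% rule", {
  lens <- c(ctg = 1000)
  # 80% coverage: kept
  r80 <- tibble::tibble(contig_id = "ctg", sample_id = "s1",
                        start = 0, end = 800, n_reads = 40)
  out <- counts_with_coverage_zeroing(r80, lens)
  expect_equal(out$counts$counts, 40)
  expect_false(out$coverage_mask$zeroed)
  # 70% coverage: zeroed, provenance retained
  r70 <- tibble::tibble(contig_id = "ctg", sample_id = "s1",
                        start = 0, end = 700, n_reads = 40)
  out <- counts_with_coverage_zeroing(r70, lens)
  expect_equal(out$counts$counts, 0)
  expect_true(out$coverage_mask$zeroed)
  expect_equal(out$coverage_mask$coverage, 0.7)
  # exactly 75%: kept
  r75 <- tibble::tibble(contig_id = "ctg", sample_id = "s1",
                        start = 0, end = 750, n_reads = 40)
  out <- counts_with_coverage_zeroing(r75, lens)
  expect_equal(out$counts$counts, 40)
})

test_that("RPKM follows its closed form and scaling law", {
  expect_equal(rpkm(10, 2000, 1e6), 5)
  expect_equal(rpkm(0, 2000, 1e6), 0)
  expect_equal(rpkm(10, 2000, 2e6), rpkm(10, 2000, 1e6) / 2)
  expect_error(rpkm(10, 2000, 0), "library_size")
})

test_that("VC aggregation sums members and conserves totals", {
  layer <- tibble::tibble(
    contig_id = c("c1", "c2", "c3"),
    sample_id = "s1",
    value = c(5, 3, 7)
  )
  vcs <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                        vc_id = c("VC1", "VC1", "VC2"))
  agg <- aggregate_by_vc(layer, vcs)
  expect_equal(agg$value[agg$vc_id == "VC1"], 8)
  expect_equal(agg$value[agg$vc_id == "VC2"], 7)   # singleton unchanged
  expect_equal(sum(agg$value), sum(layer$value))   # conservation
  expect_error(
    aggregate_by_vc(layer, vcs[1:2, ]),
    "c3"
  )
})

test_that("relative abundance closes rows to 1 and warns on zero totals", {
  layer <- tibble::tibble(
    unit_id = c("u1", "u2", "u1", "u2"),
    sample_id = c("s1", "s1", "s2", "s2"),
    value = c(4, 6, 0, 0)
  )
  expect_warning(rel <- relative_abundance(layer), "zero total")
  expect_equal(rel$value[rel$sample_id == "s1"], c(0.4, 0.6))
  expect_equal(rel$value[rel$sample_id == "s2"], c(0, 0))
  # column permutation invariance
  rel2 <- suppressWarnings(relative_abundance(layer[c(2, 4, 1, 3), ]))
  expect_equal(
    dplyr::arrange(rel2, sample_id, unit_id),
    dplyr::arrange(rel, sample_id, unit_id)
  )
})

test_that("prevalence bins follow the 10%/30% boundaries", {
  layer <- tidyr::expand_grid(
    vc_id = c("rare", "core", "everywhere"),
    sample_id = sprintf("s%03d", 1:196)
  )
  layer$value <- with(layer, dplyr::case_when(
    vc_id == "rare" & sample_id %in% sprintf("s%03d", 1:19) ~ 1,
    vc_id == "core" & sample_id %in% sprintf("s%03d", 1:60) ~ 1,
    vc_id == "everywhere" ~ 1,
    TRUE ~ 0
  ))
  bins <- prevalence_bins(layer, n_samples = 196)
  expect_equal(bins$bin[bins$unit_id == "rare"], "individual")
  expect_equal(bins$bin[bins$unit_id == "core"], "core")
  expect_equal(bins$prevalence[bins$unit_id == "everywhere"], 1)
})

test_that("ranked-abundance curves accumulate to one", {
  cur <- ranked_abundance_curve(c(0.5, 0.3, 0.2), c("a", "b", "c"))
  expect_equal(cur$cum_fraction, c(0.5, 0.8, 1.0))
  expect_equal(ranked_abundance_curve(7)$cum_fraction, 1)
  # permuting the row leaves the curve unchanged
  cur2 <- ranked_abundance_curve(c(0.2, 0.5, 0.3), c("c", "a", "b"))
  expect_equal(cur$cum_fraction, cur2$cum_fraction)
  expect_equal(cur$unit_id, cur2$unit_id)
})

test_that("the full pipeline equals a brute-force recomputation on small instances", {
  set.seed(502)
  n_contigs <- 12
  n_samples <- 6
  lens <- setNames(sample(800:2000, n_contigs), sprintf("c%02d", 1:n_contigs))
  vcs <- tibble::tibble(
    contig_id = names(lens),
    vc_id = paste0("VC", rep(1:4, each = 3))
  )
  recs <- dplyr::bind_rows(lapply(1:250, function(i) {
    cid <- sample(names(lens), 1)
    s <- sample(0:(lens[[cid]] - 100), 1)
    tibble::tibble(
      contig_id = cid,
      sample_id = sprintf("s%d", sample(n_samples, 1)),
      start = s, end = s + sample(50:600, 1),
      n_reads = sample(1:20, 1),
      identity = round(runif(1, 0.7, 1), 3)
    )
  }))
  recs$end <- pmin(recs$end, lens[recs$contig_id])
  # samples whose every contig is coverage-zeroed warn; expected here
  ab <- suppressWarnings(compute_abundance(recs, lens, vcs))

  # ---- independent brute-force recomputation -------------------------
  kept <- recs[recs$identity >= 0.90, ]
  libsz <- tapply(kept$n_reads, kept$sample_id, sum)
  combos <- unique(kept[, c("contig_id", "sample_id")])
  brute_counts <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- kept[kept$contig_id == combos$contig_id[i] &
                  kept$sample_id == combos$sample_id[i], ]
    cov <- coverage_oracle(sub$start, sub$end, lens[[combos$contig_id[i]]])
    data.frame(
      contig_id = combos$contig_id[i], sample_id = combos$sample_id[i],
      counts = if (cov < 0.75) 0 else sum(sub$n_reads)
    )
  }))
  brute_counts$rpkm <- brute_counts$counts /
    ((lens[brute_counts$contig_id] / 1000) *
       (as.numeric(libsz[brute_counts$sample_id]) / 1e6))
  brute_counts$vc_id <- vcs$vc_id[match(brute_counts$contig_id,
                                        vcs$contig_id)]
  brute_vc <- aggregate(rpkm ~ sample_id + vc_id, data = brute_counts,
                        FUN = sum)
  tot <- tapply(brute_vc$rpkm, brute_vc$sample_id, sum)
  denom <- as.numeric(tot[brute_vc$sample_id])
  brute_vc$relative <- ifelse(denom > 0, brute_vc$rpkm / denom, 0)

  impl <- ab$vc_relative |> dplyr::arrange(sample_id, vc_id)
  brute_vc <- brute_vc[order(brute_vc$sample_id, brute_vc$vc_id), ]
  expect_equal(impl$vc_id, brute_vc$vc_id)
  expect_equal(impl$value, brute_vc$relative, tolerance = 1e-12)
  # compositional closure
  sums <- tapply(ab$vc_relative$value, ab$vc_relative$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
})
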