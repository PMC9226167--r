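small_spec <- function(seed = 1, ...) {
  community_spec(n_phage_genomes = 8, n_host_genomes = 3,
                 n_samples_per_group = 4, marker_family_spec = NULL,
                 seed = seed, ...)
}

test_that("identical spec and seed give byte-identical bundles", {
  b1 <- generate_community(small_spec(seed = 11))
  b2 <- generate_community(small_spec(seed = 11))
  expect_identical(rlang::hash(b1), rlang::hash(b2))
  b3 <- generate_community(small_spec(seed = 12))
  expect_false(identical(rlang::hash(b1), rlang::hash(b3)))
})

test_that("prophage_fraction = 0 plants no prophages", {
  b <- generate_community(small_spec(seed = 2, prophage_fraction = 0))
  expect_equal(nrow(b$truth$prophages), 0)
  expect_false(any(b$truth$triage$phage & b$truth$triage$bacterial))
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(community_spec(n_phage_genomes = 0), "n_phage_genomes")
  expect_error(community_spec(prophage_fraction = 1.5),
               "prophage_fraction")
  expect_error(
    community_spec(marker_family_spec = list(
      n_per_subfamily = c(2, 2), divergence_within = 0.7,
      divergence_between = 0.3
    )),
    "divergence"
  )
  expect_error(
    community_spec(richness_differential = c(control = 0, case = 0.5)),
    "richness_differential"
  )
  expect_error(
    community_spec(crispr_spacer_plan = tibble::tibble(
      host = 1, phage = 1, n_spacers = 2, mismatches = 5
    )),
    "mismatches"
  )
})

test_that("planted prophage intervals lie within their host contigs and match the phage", {
  b <- generate_community(small_spec(seed = 3, prophage_fraction = 0.5))
  pros <- b$truth$prophages
  expect_gt(nrow(pros), 0)
  for (i in seq_len(nrow(pros))) {
    host_seq <- b$contigs$sequence[b$contigs$contig_id ==
                                     pros$host_contig_id[i]]
    phage_seq <- b$contigs$sequence[b$contigs$contig_id ==
                                      pros$phage_id[i]]
    expect_lte(pros$end[i], nchar(host_seq))
    expect_equal(substr(host_seq, pros$start[i] + 1, pros$end[i]),
                 phage_seq)
  }
})

test_that("every planted spacer occurs in its target phage within its mismatch budget", {
  spec <- small_spec(
    seed = 4,
    crispr_spacer_plan = tibble::tibble(
      host = c(1, 2, 3), phage = c(1, 2, 3),
      n_spacers = c(3, 2, 3), mismatches = c(0, 1, 2)
    )
  )
  b <- generate_community(spec)
  sp <- b$truth$spacers
  expect_equal(nrow(sp), 8)
  phages <- b$contigs[b$contigs$contig_id %in% sp$target_phage, ]
  hits <- match_protospacers(
    sp |> dplyr::select(spacer_id, spacer_seq),
    phages, max_mismatches = 3
  )
  found <- dplyr::inner_join(
    hits, sp |> dplyr::select(spacer_id, target_phage, mismatches),
    by = "spacer_id"
  ) |>
    dplyr::filter(contig_id == target_phage,
                  mismatches.x <= mismatches.y)
  expect_setequal(found$spacer_id, sp$spacer_id)
})

test_that("truth labels cover every generated contig", {
  b <- generate_community(small_spec(seed = 5))
  expect_setequal(b$truth$triage$contig_id, b$contigs$contig_id)
  phage_ids <- b$truth$triage$contig_id[b$truth$triage$phage &
                                          !b$truth$triage$bacterial]
  expect_setequal(b$truth$lineages$contig_id, phage_ids)
  expect_setequal(unique(b$proteins$contig_id), phage_ids)
  # protein ids follow the <contig>_<orf_index> convention
  expect_true(all(b$proteins$protein_id ==
                    paste0(b$proteins$contig_id, "_",
                           b$proteins$orf_index)))
})

test_that("marker family generation respects counts, length and divergence 0", {
  fam0 <- generate_marker_family(n_per_subfamily = c(2, 1),
                                 divergence_within = 0,
                                 divergence_between = 0, seed = 6)
  expect_equal(nrow(fam0$contigs), 3)
  seeds <- heliusviridae_markers()$markers
  mk <- fam0$proteins[!is.na(fam0$proteins$marker), ]
  for (i in seq_len(nrow(mk))) {
    expect_equal(mk$sequence[i], unname(seeds[[mk$marker[i]]]))
  }
  expect_error(generate_marker_family(divergence_within = 0.9),
               "divergence")
  expect_equal(nrow(generate_marker_family(c(5, 5, 5),
                                           seed = 7)$contigs), 15)
})

test_that("within-subfamily shared-PC fractions exceed between-subfamily ones", {
  fam <- generate_marker_family(n_per_subfamily = c(3, 3, 3),
                                divergence_within = 0.05,
                                divergence_between = 0.35, seed = 8)
  hits <- homology_search(fam$proteins |>
                            dplyr::select(protein_id, sequence))
  pcs <- build_protein_clusters(hits, fam$proteins$protein_id)
  pcm <- pcs |>
    dplyr::left_join(fam$proteins |>
                       dplyr::select(protein_id, contig_id),
                     by = "protein_id") |>
    dplyr::distinct(contig_id, pc_id)
  m <- shared_pc_matrix(pcm)
  subfam <- fam$truth$subfamily[match(rownames(m),
                                      fam$truth$contig_id)]
  same <- outer(subfam, subfam, "==")
  diag(same) <- NA
  within_vals <- m[which(same)]
  between_vals <- m[which(!same)]
  expect_gt(min(within_vals), max(between_vals))
})

test_that("alignment records track planted abundance and exercise the identity filter", {
  b <- generate_community(small_spec(seed = 9))
  profiles <- tidyr::expand_grid(
    sample_id = b$metadata$sample_id[1:2],
    contig_id = b$truth$lineages$contig_id
  ) |>
    dplyr::mutate(abundance = ifelse(contig_id ==
                                       b$truth$lineages$contig_id[1],
                                     0, 1))
  al <- generate_alignments(b, profiles = profiles, seed = 9)
  # abundance 0 -> no records
  expect_equal(sum(al$alignments$contig_id ==
                     b$truth$lineages$contig_id[1]), 0)
  expect_error(
    generate_alignments(
      b, profiles = tibble::tibble(sample_id = "s", contig_id = "nope",
                                   abundance = 1)
    ),
    "unknown contig"
  )
})

test_that("the contaminant fraction is realized within its binomial interval", {
  b <- generate_community(
    community_spec(n_phage_genomes = 12, n_host_genomes = 3,
                   n_samples_per_group = 4, marker_family_spec = NULL,
                   seed = 10)
  )
  al <- generate_alignments(b, contaminant_fraction = 0.2,
                            library_size = 50000, seed = 10)
  n <- nrow(al$alignments)
  expect_gt(n, 1000)
  prop <- mean(al$alignments$identity < 0.90)
  ci <- qnorm(0.995) * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(prop - 0.2), ci + 0.01)
})

test_that("depth vectors conserve aligned bases", {
  b <- generate_community(small_spec(seed = 13))
  al <- generate_alignments(b, seed = 13)
  cid <- al$alignments$contig_id[1]
  sub <- al$alignments[al$alignments$contig_id == cid, ]
  L <- b$contigs$length[b$contigs$contig_id == cid]
  depth <- depth_from_alignments(sub, L)
  expect_equal(sum(depth),
               sum(sub$n_reads * (sub$end - sub$start)))
})

test_that("a planted prevalence differential is rejected by Fisher in nearly all seeds", {
  hits <- vapply(1:100, function(s) {
    sim <- simulate_presence_matrix(1, 24, 0.9, 0.1, seed = s)
    counts <- sim$presence |>
      dplyr::left_join(sim$metadata, by = "sample_id") |>
      dplyr::group_by(group) |>
      dplyr::summarise(n_present = sum(present))
    a <- counts$n_present[counts$group == "control"]
    b <- counts$n_present[counts$group == "case"]
    fisher_exact(rbind(c(a, 24 - a), c(b, 24 - b))) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("recovered VC relative abundance tracks planted abundance", {
  spec <- community_spec(n_phage_genomes = 20, n_host_genomes = 2,
                         n_samples_per_group = 6, vc_group_size = 1,
                         marker_family_spec = NULL,
                         planted_effects = NULL,
                         richness_differential = c(control = 0.95,
                                                   case = 0.95),
                         seed = 7)
  b <- generate_community(spec)
  al <- generate_alignments(b, seed = 7)
  vcs <- tibble::tibble(contig_id = b$truth$lineages$contig_id,
                        vc_id = b$truth$lineages$lineage)
  ab <- compute_abundance(al$alignments,
                          b$contigs |> dplyr::select(contig_id, length),
                          vcs)
  planted <- al$abundance_truth |>
    dplyr::left_join(b$truth$lineages, by = "contig_id") |>
    dplyr::group_by(sample_id, lineage) |>
    dplyr::summarise(planted = sum(abundance), .groups = "drop") |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(planted_rel = planted / sum(planted)) |>
    dplyr::ungroup()
  j <- planted |>
    dplyr::left_join(ab$vc_relative |> dplyr::rename(lineage = vc_id),
                     by = c("sample_id", "lineage")) |>
    dplyr::mutate(value = ifelse(is.na(value), 0, value))
  expect_gte(cor(j$planted_rel, j$value, method = "spearman"), 0.9)
})
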