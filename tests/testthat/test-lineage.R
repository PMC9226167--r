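test_that("the marker loop closes: generated genomes are classified family members", {
  fam <- generate_marker_family(n_per_subfamily = c(2), seed = 31,
                                divergence_within = 0.1,
                                divergence_between = 0.1)
  cf <- classify_family(fam$proteins, fam$contigs)
  expect_true(all(cf$family_member))
  expect_true(all(fam$contigs$length > 30000))
})

test_that("membership needs every required marker and the length rule", {
  fam <- generate_marker_family(n_per_subfamily = c(1), seed = 32,
                                divergence_within = 0.1,
                                divergence_between = 0.1)
  prots <- fam$proteins
  no_term <- prots[is.na(prots$marker) |
                     prots$marker != "terminase_large_subunit", ]
  # strict mode: deleting the terminase removes membership
  strict <- classify_family(no_term, fam$contigs)
  expect_false(any(strict$family_member))
  # terminase is a required structural gene in relaxed mode too
  relaxed <- classify_family(no_term, fam$contigs,
                             markers = heliusviridae_markers(relaxed = TRUE))
  expect_false(any(relaxed$family_member))
  # deleting a non-structural marker: fails strict, passes relaxed
  no_pol <- prots[is.na(prots$marker) |
                    prots$marker != "dna_polymerase_I", ]
  expect_false(any(classify_family(no_pol, fam$contigs)$family_member))
  expect_true(all(classify_family(
    no_pol, fam$contigs,
    markers = heliusviridae_markers(relaxed = TRUE)
  )$family_member))
  # all nine markers on a short contig: not a member
  short <- fam$contigs |> dplyr::mutate(length = 20000)
  expect_false(any(classify_family(prots, short)$family_member))
})

test_that("classification is monotone in the protein set", {
  fam <- generate_marker_family(n_per_subfamily = c(1), seed = 33,
                                divergence_within = 0.05,
                                divergence_between = 0.2)
  extra <- fam$proteins |>
    dplyr::bind_rows(tibble::tibble(
      contig_id = fam$contigs$contig_id[1], orf_index = 99L,
      protein_id = paste0(fam$contigs$contig_id[1], "_99"),
      sequence = rand_protein(150), marker = NA_character_
    ))
  base <- classify_family(fam$proteins, fam$contigs)
  more <- classify_family(extra, fam$contigs)
  expect_true(all(more$family_member >= base$family_member))
})

test_that("subfamily assignment is deterministic and order invariant", {
  set.seed(706)
  pcm <- planted_pc_membership(n_groups = 3, group_size = 4, pool = 15,
                               carry = 14)
  ids <- unique(pcm$contig_id)
  s1 <- assign_subfamilies(ids, pcm, k = 3)
  s2 <- assign_subfamilies(rev(ids), pcm, k = 3)
  expect_identical(s1, s2)
  truth <- sub("_[0-9]+$", "", s1$contig_id)
  expect_equal(ari(s1$subfamily, truth), 1)
  # k = 1: everything in one subfamily
  s3 <- assign_subfamilies(ids, pcm, k = 1)
  expect_equal(unique(s3$subfamily), "alpha")
  expect_error(assign_subfamilies(ids[1:2], pcm, k = 3), "at least k")
})

test_that("duplicate PC profiles land in the same subfamily", {
  pcm <- dplyr::bind_rows(
    tidyr::expand_grid(contig_id = c("a1", "a2"),
                       pc_id = paste0("A", 1:10)),
    tidyr::expand_grid(contig_id = c("b1", "b2"),
                       pc_id = paste0("B", 1:10))
  )
  s <- assign_subfamilies(c("a1", "a2", "b1", "b2"), pcm, k = 2)
  expect_equal(s$subfamily[s$contig_id == "a1"],
               s$subfamily[s$contig_id == "a2"])
  expect_equal(s$subfamily[s$contig_id == "b1"],
               s$subfamily[s$contig_id == "b2"])
})

test_that("Crassvirales calls need both markers, 350 columns and 70 kb", {
  set.seed(707)
  q <- crassvirales_queries()
  mk <- function(cid, both = TRUE, div = 0.2) {
    seqs <- c(mutate_protein_for_test(q[["crass_terminase"]], div),
              if (both) mutate_protein_for_test(q[["crass_polymerase"]], div),
              rand_protein(200))
    tibble::tibble(contig_id = cid, orf_index = seq_along(seqs),
                   protein_id = paste0(cid, "_", seq_along(seqs)),
                   sequence = seqs)
  }
  prots <- dplyr::bind_rows(mk("big"), mk("small"),
                            mk("term_only", both = FALSE))
  contigs <- tibble::tibble(contig_id = c("big", "small", "term_only"),
                            length = c(80000, 60000, 80000))
  res <- classify_crassvirales(prots, contigs)
  expect_true(res$crassvirales[res$contig_id == "big"])
  expect_false(res$crassvirales[res$contig_id == "small"])   # length rule
  expect_false(res$crassvirales[res$contig_id == "term_only"])
  expect_gte(res$aln_terminase[res$contig_id == "big"], 350)
  # nt unit interpretation scales the threshold by codon length
  res_nt <- classify_crassvirales(prots, contigs, unit = "nt")
  expect_true(res_nt$crassvirales[res_nt$contig_id == "big"])
})

test_that("prophage boundaries are exact on noise-free step profiles", {
  L <- 100000
  d <- matrix(20, nrow = 3, ncol = L)
  d[, 10001:78665] <- 0
  pr <- depth_profile("ctg", d,
                      flanks = list(left = c(0, 10000),
                                    right = c(78665, L)))
  res <- extract_prophage_boundaries(pr)
  expect_equal(res$start, 10000)
  expect_equal(res$end, 78665)
  expect_equal(res$length, 68665)
  expect_equal(res$n_informative, 3)

  # uniform depth in every sample: no discriminating sample
  flat <- depth_profile("ctg", matrix(20, nrow = 2, ncol = 1000),
                        flanks = list(left = c(0, 200),
                                      right = c(800, 1000)))
  expect_error(extract_prophage_boundaries(flat), "no discriminating")
})

test_that("boundaries stay within 50 bp of the insertion under Poisson noise", {
  L <- 30000
  true_start <- 8000
  true_end <- 24000
  for (s in 1:20) {
    set.seed(800 + s)
    lam <- matrix(12, nrow = 2, ncol = L)
    lam[, (true_start + 1):true_end] <- 0.2
    d <- matrix(rpois(length(lam), lam), nrow = 2)
    pr <- depth_profile("ctg", d,
                        flanks = list(left = c(0, true_start),
                                      right = c(true_end, L)))
    res <- extract_prophage_boundaries(pr)
    expect_lte(abs(res$start - true_start), 50)
    expect_lte(abs(res$end - true_end), 50)
  }
})

test_that("lineage prevalence counts presence per group", {
  assignments <- tibble::tibble(unit_id = c("VC1", "VC2", "VC9"),
                                lineage = c("fam", "fam", "ghost"))
  layer <- tibble::tibble(
    vc_id = rep(c("VC1", "VC2"), each = 4),
    sample_id = rep(c("c1", "c2", "m1", "m2"), 2),
    value = c(1, 0, 0, 0, 0, 1, 0, 0.5)
  )
  md <- tibble::tibble(sample_id = c("c1", "c2", "m1", "m2"),
                       group = c("ctrl", "ctrl", "mets", "mets"))
  prev <- lineage_prevalence(assignments, layer, md)
  fam <- prev[prev$lineage == "fam", ]
  expect_equal(fam$n_present[fam$group == "ctrl"], 2)
  expect_equal(fam$n_present[fam$group == "mets"], 1)
  expect_true(all(prev$n_present <= prev$n_samples))
  ghost <- prev[prev$lineage == "ghost", ]
  expect_true(all(ghost$n_present == 0))
})
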