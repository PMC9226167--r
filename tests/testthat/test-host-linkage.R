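build_test_array <- function(repeat_seq, spacers, pad_left, pad_right) {
  paste0(pad_left,
         paste0(repeat_seq, spacers, collapse = ""), repeat_seq,
         pad_right)
}

test_that("a constructed array yields exactly its spacers; two copies do not", {
  set.seed(701)
  rep30 <- rand_dna(30)
  spacers <- c(rand_dna(32), rand_dna(32), rand_dna(32))
  seq4 <- build_test_array(rep30, spacers, rand_dna(500), rand_dna(500))
  res <- detect_crispr_arrays(tibble::tibble(contig_id = "h1",
                                             sequence = seq4))
  expect_setequal(res$spacer_seq, spacers)
  expect_equal(nrow(res), 3)
  expect_equal(unique(res$repeat_seq), rep30)

  seq2 <- build_test_array(rep30, spacers[1], rand_dna(500), rand_dna(500))
  res2 <- detect_crispr_arrays(tibble::tibble(contig_id = "h2",
                                              sequence = seq2))
  expect_equal(nrow(res2), 0)
})

test_that("planted arrays in synthetic bundles are recovered exactly (truth closure)", {
  for (s in c(5, 23)) {
    spec <- community_spec(n_phage_genomes = 8, n_host_genomes = 4,
                           n_samples_per_group = 4,
                           marker_family_spec = NULL, seed = s)
    b <- generate_community(spec)
    hosts <- b$contigs[grepl("^host", b$contigs$contig_id), ]
    found <- detect_crispr_arrays(hosts)
    expect_setequal(found$spacer_seq, b$truth$spacers$spacer_seq)
  }
})

test_that("protospacer matching finds planted spacers at the planted site", {
  set.seed(702)
  contig <- rand_dna(2000)
  proto <- substr(contig, 501, 532)
  spacers <- tibble::tibble(
    spacer_id = c("exact", "rc", "two_mm"),
    spacer_seq = c(
      proto,
      revcomp(proto),
      { ch <- strsplit(proto, "")[[1]]
        ch[c(3, 20)] <- vapply(ch[c(3, 20)],
                               function(x) setdiff(NT4, x)[1], "")
        paste(ch, collapse = "") }
    )
  )
  hits <- match_protospacers(spacers,
                             tibble::tibble(contig_id = "p1",
                                            sequence = contig))
  exact <- hits[hits$spacer_id == "exact", ]
  expect_equal(exact$start, 500)
  expect_equal(exact$end, 532)
  expect_equal(exact$strand, "+")
  rc <- hits[hits$spacer_id == "rc", ]
  expect_equal(rc$start, 500)
  expect_equal(rc$strand, "-")
  # two substitutions exceed the <2-mismatch rule at the default tolerance
  expect_equal(nrow(hits[hits$spacer_id == "two_mm", ]), 0)
  # ...but are found when the tolerance is raised
  hits2 <- match_protospacers(spacers,
                              tibble::tibble(contig_id = "p1",
                                             sequence = contig),
                              max_mismatches = 2)
  expect_equal(nrow(hits2[hits2$spacer_id == "two_mm", ]), 1)
})

test_that("protospacer matching equals the brute-force Hamming oracle", {
  set.seed(703)
  contigs <- tibble::tibble(
    contig_id = sprintf("p%02d", 1:6),
    sequence = vapply(1:6, function(i) rand_dna(400), "")
  )
  # half random spacers, half lifted from the contigs with 0-2 edits
  spacers <- dplyr::bind_rows(lapply(1:30, function(i) {
    if (i %% 2 == 0) {
      tibble::tibble(spacer_id = paste0("sp", i),
                     spacer_seq = rand_dna(sample(20:35, 1)))
    } else {
      src <- sample(6, 1)
      w <- sample(20:35, 1)
      s <- sample(400 - w, 1)
      sq <- substr(contigs$sequence[src], s, s + w - 1)
      n_mut <- sample(0:2, 1)
      if (n_mut > 0) {
        ch <- strsplit(sq, "")[[1]]
        at <- sample(w, n_mut)
        ch[at] <- vapply(ch[at], function(x) setdiff(NT4, x)[1], "")
        sq <- paste(ch, collapse = "")
      }
      if (sample(2, 1) == 1) sq <- revcomp(sq)
      tibble::tibble(spacer_id = paste0("sp", i), spacer_seq = sq)
    }
  }))
  impl <- match_protospacers(spacers, contigs, max_mismatches = 1)
  for (i in seq_len(nrow(spacers))) {
    for (j in seq_len(nrow(contigs))) {
      orc <- protospacer_oracle(spacers$spacer_seq[i],
                                contigs$sequence[j], max_mm = 1)
      sub <- impl[impl$spacer_id == spacers$spacer_id[i] &
                    impl$contig_id == contigs$contig_id[j], ]
      expect_equal(nrow(sub), nrow(orc))
      if (nrow(orc) > 0) {
        orc <- orc[order(orc$start, orc$strand), ]
        sub <- sub[order(sub$start, sub$strand), ]
        expect_equal(sub$start, orc$start)
        expect_equal(sub$strand, orc$strand)
        expect_equal(sub$mismatches, orc$mismatches)
      }
    }
  }
})

test_that("matching is strand symmetric", {
  set.seed(704)
  contig <- rand_dna(600)
  sp <- tibble::tibble(spacer_id = "s", spacer_seq = substr(contig, 101, 130))
  fwd <- match_protospacers(sp, tibble::tibble(contig_id = "c",
                                               sequence = contig))
  # reverse-complement both spacer and target: same hit set, strands swap
  rc <- match_protospacers(
    sp |> dplyr::mutate(spacer_seq = revcomp(spacer_seq)),
    tibble::tibble(contig_id = "c", sequence = revcomp(contig))
  )
  expect_equal(nrow(fwd), nrow(rc))
  expect_setequal(fwd$mismatches, rc$mismatches)
})

test_that("short spacers warn but are still searched", {
  expect_warning(
    hits <- match_protospacers(
      tibble::tibble(spacer_id = "tiny", spacer_seq = "ACGTACGTACGT"),
      tibble::tibble(contig_id = "c",
                     sequence = paste0(rand_dna(50), "ACGTACGTACGT",
                                       rand_dna(50)))
    ),
    "18"
  )
  expect_gte(nrow(hits), 1)
})

test_that("prophage VC links propagate the carrier's taxon", {
  vcs <- tibble::tibble(contig_id = c("pro1", "c2", "c3"),
                        vc_id = c("VC1", "VC1", "VC2"))
  taxa <- tibble::tibble(contig_id = "pro1", taxon = "Bacteroides fragilis",
                         rank = "species", phylum = "Bacteroidetes")
  links <- prophage_vc_links(vcs, taxa)
  expect_equal(links$vc_id, "VC1")
  expect_equal(links$taxon, "Bacteroides fragilis")
  expect_equal(links$route, "prophage")
  # VC without prophage members yields nothing
  expect_equal(nrow(prophage_vc_links(vcs, taxa[0, ])), 0)
})

test_that("reference co-clustering requires unanimity at family rank", {
  vcs <- tibble::tibble(
    contig_id = c("r1", "r2", "r3", "r4", "c1"),
    vc_id = c("VC1", "VC1", "VC2", "VC2", "VC3")
  )
  refs <- tibble::tibble(
    contig_id = c("r1", "r2", "r3", "r4"),
    host_family = c("Streptococcaceae", "Streptococcaceae",
                    "Lactobacillaceae", "Streptococcaceae"),
    phylum = "Firmicutes"
  )
  links <- refseq_cocluster_links(vcs, refs)
  expect_equal(links$vc_id, "VC1")          # VC2 split: no link
  expect_equal(links$rank, "family")
  expect_equal(nrow(refseq_cocluster_links(vcs, refs[0, ])), 0)
})

test_that("merged predictions deduplicate and flag multi-phylum VCs", {
  sp <- tibble::tibble(vc_id = c("VC1", "VC2"), taxon = c("A", "B"),
                       rank = "genus",
                       phylum = c("Firmicutes", "Firmicutes"),
                       route = "spacer", evidence_ids = c("s1", "s2"))
  pro <- tibble::tibble(vc_id = c("VC1", "VC2"), taxon = c("A", "C"),
                        rank = c("genus", "genus"),
                        phylum = c("Firmicutes", "Bacteroidetes"),
                        route = "prophage", evidence_ids = c("p1", "p2"))
  merged <- merge_host_predictions(sp, pro)
  vc1 <- merged[merged$vc_id == "VC1", ]
  expect_equal(nrow(vc1), 1)                 # deduplicated by taxon+rank
  expect_equal(vc1$route, "prophage;spacer")
  expect_false(vc1$multi_phylum)
  vc2 <- merged[merged$vc_id == "VC2", ]
  expect_true(all(vc2$multi_phylum))         # Firmicutes + Bacteroidetes
  expect_equal(nrow(merge_host_predictions()), 0)
})
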