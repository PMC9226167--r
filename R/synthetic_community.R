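# Deterministic synthetic communities with planted ground truth.
#
# Reads are never simulated: all in-scope computation consumes alignment
# records, so the generator emits alignment records and depth vectors
# directly. Every stochastic draw flows from one integer seed through named
# substreams (substream_seed), so bundles are byte-identical across runs.

#' Specification of a synthetic virome community
#'
#' The defaults emulate the structure of a balanced two-group case/control
#' gut-virome cohort: 24 samples per group (the balanced subset design),
#' background phages organised in relatable groups of four plus singletons,
#' a marker-gene family with three subfamilies, prophages integrated in
#' bacterial contigs, CRISPR arrays targeting planted protospacers, a
#' log-normal abundance model, one planted prevalence differential
#' (0.9 versus 0.1) and a modest case-group richness deficit.
#'
#' @param n_phage_genomes Background phage genomes (marker-family genomes
#'   are generated in addition).
#' @param n_host_genomes Bacterial genomes.
#' @param n_samples_per_group Samples per group; groups are labelled
#'   "control" and "case".
#' @param phage_length_range Background phage genome length bounds in bp.
#' @param vc_group_size Size of each planted relatedness group (genomes
#'   sharing a protein pool); remaining genomes are singletons.
#' @param marker_family_spec List with `n_per_subfamily` (integer vector),
#'   `divergence_within` and `divergence_between` (substitutions/site), or
#'   `NULL` to skip the marker family.
#' @param prophage_fraction Fraction of phage genomes also inserted into a
#'   host contig as a prophage.
#' @param crispr_spacer_plan Data frame `host` (host index), `phage` (phage
#'   index), `n_spacers`, `mismatches` (0-3 substitutions between each
#'   planted spacer and its protospacer), or `NULL` for the default plan.
#' @param abundance_model List with `meanlog` and `sdlog`, each a named
#'   vector over groups, for the log-normal per-genome abundance draws.
#' @param planted_effects Data frame `lineage`, `prevalence_control`,
#'   `prevalence_case` of per-lineage presence differentials; lineages are
#'   named `group_01`, `group_02`, ... for the planted VC groups,
#'   `singleton_<i>` for singletons and `subfam_1`, `subfam_2`, ... for
#'   marker subfamilies.
#' @param richness_differential Named vector of per-group inclusion
#'   probabilities for non-effect genomes.
#' @param seed Master integer seed.
#' @return A validated `community_spec` list.
#' @export
community_spec <- function(n_phage_genomes = 24,
                           n_host_genomes = 8,
                           n_samples_per_group = 24,
                           phage_length_range = c(15000, 60000),
                           vc_group_size = 4,
                           marker_family_spec = list(
                             n_per_subfamily = c(5, 5, 5),
                             divergence_within = 0.05,
                             divergence_between = 0.35
                           ),
                           prophage_fraction = 0.2,
                           crispr_spacer_plan = NULL,
                           abundance_model = list(
                             meanlog = c(control = 0, case = 0),
                             sdlog = c(control = 1.5, case = 1.5)
                           ),
                           planted_effects = tibble(
                             lineage = "group_01",
                             prevalence_control = 0.9,
                             prevalence_case = 0.1
                           ),
                           richness_differential = c(control = 0.9,
                                                     case = 0.7),
                           seed = 1) {
  spec <- structure(
    list(
      n_phage_genomes = n_phage_genomes,
      n_host_genomes = n_host_genomes,
      n_samples_per_group = n_samples_per_group,
      phage_length_range = phage_length_range,
      vc_group_size = vc_group_size,
      marker_family_spec = marker_family_spec,
      prophage_fraction = prophage_fraction,
      crispr_spacer_plan = crispr_spacer_plan,
      abundance_model = abundance_model,
      planted_effects = planted_effects,
      richness_differential = richness_differential,
      seed = seed
    ),
    class = "community_spec"
  )
  validate_community_spec(spec)
  spec
}

validate_community_spec <- function(spec) {
  check_count <- function(x, field) {
    vp_assert(is.numeric(x) && length(x) == 1 && x >= 1 &&
                x == round(x),
              sprintf("invalid `%s`: must be a count >= 1", field))
  }
  check_count(spec$n_phage_genomes, "n_phage_genomes")
  check_count(spec$n_host_genomes, "n_host_genomes")
  check_count(spec$n_samples_per_group, "n_samples_per_group")
  vp_assert(length(spec$phage_length_range) == 2 &&
              spec$phage_length_range[1] <= spec$phage_length_range[2],
            "invalid `phage_length_range`")
  check_count(spec$vc_group_size, "vc_group_size")
  if (!is.null(spec$marker_family_spec)) {
    mf <- spec$marker_family_spec
    vp_assert(all(mf$n_per_subfamily >= 1),
              "invalid `marker_family_spec`: counts must be >= 1")
    vp_assert(mf$divergence_within >= 0 && mf$divergence_within <= 0.5 &&
                mf$divergence_between >= 0 &&
                mf$divergence_between <= 0.5,
              "invalid `marker_family_spec`: divergence must be in [0, 0.5]")
  }
  vp_assert(spec$prophage_fraction >= 0 && spec$prophage_fraction <= 1,
            "invalid `prophage_fraction`: must be in [0, 1]")
  if (!is.null(spec$crispr_spacer_plan)) {
    vp_assert_fields(spec$crispr_spacer_plan,
                     c("host", "phage", "n_spacers", "mismatches"),
                     "`crispr_spacer_plan`")
    vp_assert(all(spec$crispr_spacer_plan$mismatches %in% 0:3),
              "invalid `crispr_spacer_plan`: mismatches must be in 0..3")
  }
  vp_assert(all(c("control", "case") %in%
                  names(spec$richness_differential)) &&
              all(spec$richness_differential > 0 &
                    spec$richness_differential <= 1),
            "invalid `richness_differential`: probabilities in (0, 1]")
  vp_assert(all(c("meanlog", "sdlog") %in% names(spec$abundance_model)),
            "invalid `abundance_model`: needs meanlog and sdlog")
  if (!is.null(spec$planted_effects) && nrow(spec$planted_effects) > 0) {
    vp_assert_fields(spec$planted_effects,
                     c("lineage", "prevalence_control", "prevalence_case"),
                     "`planted_effects`")
    pv <- c(spec$planted_effects$prevalence_control,
            spec$planted_effects$prevalence_case)
    vp_assert(all(pv > 0 & pv <= 1),
              "invalid `planted_effects`: prevalences must be in (0, 1]")
  }
  vp_assert(is.numeric(spec$seed) && length(spec$seed) == 1,
            "invalid `seed`")
  invisible(spec)
}

#' Generate a marker-family genome set
#'
#' Plants diverged homologs of the nine seed marker proteins in every
#' generated genome: each subfamily descends from an ancestor diverged from
#' the seeds at `divergence_between` substitutions/site, and each member
#' diverges from its subfamily ancestor at `divergence_within`. Members of
#' a subfamily additionally share a subfamily-private accessory protein
#' pool, so shared-protein-cluster fractions are higher within than between
#' subfamilies. All genomes exceed 30,000 bp.
#'
#' @param n_per_subfamily Integer vector of genomes per subfamily.
#' @param divergence_within,divergence_between Substitution rates per site,
#'   both in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param markers Named character vector of seed marker proteins (default:
#'   the package's nine synthetic fixtures).
#' @param n_accessory Accessory proteins private to each subfamily.
#' @param length_range Genome length bounds in bp (min kept above 30 kb).
#' @return A list with `contigs`, `proteins` tibbles and a `truth` tibble
#'   (`contig_id`, `subfamily`).
#' @export
generate_marker_family <- function(n_per_subfamily = c(5, 5, 5),
                                   divergence_within = 0.05,
                                   divergence_between = 0.35,
                                   seed = 1,
                                   markers = NULL,
                                   n_accessory = 8,
                                   length_range = c(31000, 60000)) {
  vp_assert(divergence_within >= 0 && divergence_within <= 0.5 &&
              divergence_between >= 0 && divergence_between <= 0.5,
            "divergence must be in [0, 0.5]")
  vp_assert(length_range[1] > 30000,
            "marker-family genomes must exceed 30,000 bp")
  markers <- markers %||%
    read_fixture_fasta("heliusviridae_marker_seeds_synthetic.faa")
  with_seed(substream_seed(seed, "marker_family"), {
    n_sub <- length(n_per_subfamily)
    contigs <- list()
    proteins <- list()
    truth <- list()
    for (s in seq_len(n_sub)) {
      ancestors <- vapply(markers, mutate_protein,
                          character(1), rate = divergence_between)
      accessory <- vapply(seq_len(n_accessory), function(i) {
        random_protein(sample(150:350, 1))
      }, character(1))
      sub_label <- paste0("subfam_", s)
      for (g in seq_len(n_per_subfamily[s])) {
        cid <- sprintf("mk_s%d_g%02d", s, g)
        glen <- sample(length_range[1]:length_range[2], 1)
        contigs[[cid]] <- tibble(
          contig_id = cid,
          sequence = random_dna(glen),
          length = glen
        )
        prot_seqs <- c(
          vapply(ancestors, mutate_protein, character(1),
                 rate = divergence_within),
          vapply(accessory, mutate_protein, character(1),
                 rate = divergence_within),
          vapply(1:3, function(i) random_protein(sample(150:300, 1)),
                 character(1))
        )
        proteins[[cid]] <- tibble(
          contig_id = cid,
          orf_index = seq_along(prot_seqs),
          protein_id = paste0(cid, "_", seq_along(prot_seqs)),
          sequence = unname(prot_seqs),
          marker = c(names(markers), rep(NA, length(prot_seqs) -
                                           length(markers)))
        )
        truth[[cid]] <- tibble(contig_id = cid, subfamily = sub_label)
      }
    }
    list(
      contigs = bind_rows(contigs),
      proteins = bind_rows(proteins),
      truth = bind_rows(truth)
    )
  })
}

#' Generate a deterministic synthetic community bundle
#'
#' Builds phage and bacterial contigs with planted structure: background
#' phage genomes organised into relatedness groups sharing diverged protein
#' pools (plus singletons), an optional marker-gene family with subfamily
#' structure, prophages inserted into host contigs, CRISPR arrays whose
#' spacers match planted protospacers within their planned mismatch count,
#' per-contig triage evidence consistent with the truth labels, sample
#' metadata for two groups, and a `truth` list every downstream recovery
#' test can be scored against.
#'
#' @param spec A [community_spec()].
#' @return A `community_bundle` list: `contigs`, `proteins`,
#'   `triage_features`, `crispr_truth`, `metadata`, `spec` and `truth`
#'   (with `triage`, `lineages`, `subfamilies`, `prophages`, `spacers`,
#'   `effects` elements).
#' @export
generate_community <- function(spec = community_spec()) {
  validate_community_spec(spec)
  seed <- spec$seed

  # --- background phage genomes in relatedness groups + singletons ------
  n_bg <- spec$n_phage_genomes
  gsize <- spec$vc_group_size
  n_groups <- n_bg %/% gsize
  group_of <- c(rep(seq_len(n_groups), each = gsize),
                rep(NA, n_bg - n_groups * gsize))
  phage <- with_seed(substream_seed(seed, "background_phages"), {
    contigs <- list(); proteins <- list(); lineage <- list()
    pools <- lapply(seq_len(n_groups), function(g) {
      vapply(1:16, function(i) random_protein(sample(150:350, 1)),
             character(1))
    })
    for (i in seq_len(n_bg)) {
      cid <- sprintf("phage_%03d", i)
      glen <- sample(spec$phage_length_range[1]:spec$phage_length_range[2],
                     1)
      contigs[[cid]] <- tibble(contig_id = cid,
                               sequence = random_dna(glen),
                               length = glen)
      g <- group_of[i]
      if (!is.na(g)) {
        pool <- pools[[g]]
        carried <- sort(sample(seq_along(pool),
                               round(0.8 * length(pool))))
        prot_seqs <- c(
          vapply(pool[carried], mutate_protein, character(1),
                 rate = 0.02),
          vapply(1:2, function(x) random_protein(sample(150:300, 1)),
                 character(1))
        )
        lin <- sprintf("group_%02d", g)
      } else {
        prot_seqs <- vapply(1:15, function(x) {
          random_protein(sample(150:350, 1))
        }, character(1))
        lin <- sprintf("singleton_%03d", i)
      }
      proteins[[cid]] <- tibble(
        contig_id = cid,
        orf_index = seq_along(prot_seqs),
        protein_id = paste0(cid, "_", seq_along(prot_seqs)),
        sequence = unname(prot_seqs),
        marker = NA_character_
      )
      lineage[[cid]] <- tibble(contig_id = cid, lineage = lin)
    }
    list(contigs = bind_rows(contigs), proteins = bind_rows(proteins),
         lineage = bind_rows(lineage))
  })

  # --- marker family ----------------------------------------------------
  subfam_truth <- tibble(contig_id = character(0),
                         subfamily = character(0))
  if (!is.null(spec$marker_family_spec)) {
    mf <- spec$marker_family_spec
    fam <- generate_marker_family(
      n_per_subfamily = mf$n_per_subfamily,
      divergence_within = mf$divergence_within,
      divergence_between = mf$divergence_between,
      seed = substream_seed(seed, "family_seed")
    )
    subfam_truth <- fam$truth
    phage$contigs <- bind_rows(phage$contigs, fam$contigs)
    phage$proteins <- bind_rows(phage$proteins, fam$proteins)
    phage$lineage <- bind_rows(
      phage$lineage,
      fam$truth |> mutate(lineage = subfamily) |>
        select(contig_id, lineage)
    )
  }
  phage_ids <- phage$contigs$contig_id

  # --- prophage selection and host genomes ------------------------------
  n_pro <- round(spec$prophage_fraction * length(phage_ids))
  prophage_ids <- with_seed(substream_seed(seed, "prophage_pick"), {
    if (n_pro > 0) sort(sample(phage_ids, n_pro)) else character(0)
  })

  plan <- spec$crispr_spacer_plan %||% default_spacer_plan(spec)
  vp_assert(all(plan$host <= spec$n_host_genomes),
            "`crispr_spacer_plan` references an unknown host index")
  vp_assert(all(plan$phage <= length(phage_ids)),
            "`crispr_spacer_plan` references an unknown phage index")

  hosts <- with_seed(substream_seed(seed, "hosts"), {
    build_hosts(spec, phage$contigs, phage_ids, prophage_ids, plan)
  })

  contigs <- bind_rows(
    phage$contigs |> mutate(sample_id = "assembly", circular = FALSE),
    hosts$contigs |> mutate(sample_id = "assembly", circular = FALSE)
  )

  # --- triage features consistent with truth ----------------------------
  triage <- with_seed(substream_seed(seed, "triage"), {
    build_triage(phage_ids, hosts)
  })

  truth_triage <- bind_rows(
    tibble(contig_id = phage_ids, phage = TRUE, bacterial = FALSE),
    tibble(contig_id = hosts$contigs$contig_id, phage = FALSE,
           bacterial = TRUE) |>
      mutate(phage = contig_id %in% hosts$prophages$host_contig_id)
  )

  metadata <- tibble(
    sample_id = c(sprintf("control_%02d", seq_len(spec$n_samples_per_group)),
                  sprintf("case_%02d", seq_len(spec$n_samples_per_group))),
    group = rep(c("control", "case"), each = spec$n_samples_per_group)
  )
  metadata <- with_seed(substream_seed(seed, "covariates"), {
    metadata |>
      mutate(age = round(runif(dplyr::n(), 35, 70)),
             sex = sample(c("F", "M"), dplyr::n(), replace = TRUE))
  })

  structure(
    list(
      contigs = contigs,
      proteins = phage$proteins,
      triage_features = triage,
      crispr_truth = hosts$spacers,
      metadata = metadata,
      spec = spec,
      truth = list(
        triage = truth_triage,
        lineages = phage$lineage,
        subfamilies = subfam_truth,
        prophages = hosts$prophages,
        spacers = hosts$spacers,
        effects = spec$planted_effects
      )
    ),
    class = "community_bundle"
  )
}

default_spacer_plan <- function(spec) {
  n <- min(3, spec$n_host_genomes, spec$n_phage_genomes)
  tibble(host = seq_len(n), phage = seq_len(n), n_spacers = 3,
         mismatches = 0)
}

# hosts carry (optionally) a CRISPR array and/or an inserted prophage;
# sequences are assembled left-to-right so planted intervals are exact
build_hosts <- function(spec, phage_contigs, phage_ids, prophage_ids,
                        plan) {
  phage_seq <- setNames(phage_contigs$sequence, phage_contigs$contig_id)
  contigs <- list(); prophages <- list(); spacers <- list()
  pro_host <- if (length(prophage_ids) > 0) {
    setNames(rep(seq_len(spec$n_host_genomes),
                 length.out = length(prophage_ids)), prophage_ids)
  } else integer(0)
  for (h in seq_len(spec$n_host_genomes)) {
    hid <- sprintf("host_%03d", h)
    base_len <- sample(20000:40000, 1)
    left <- random_dna(round(base_len * 0.4))
    mid <- random_dna(round(base_len * 0.3))
    right <- random_dna(base_len - nchar(left) - nchar(mid))
    # CRISPR array between left and mid
    array_part <- ""
    plan_rows <- plan[plan$host == h, , drop = FALSE]
    arr <- NULL
    if (nrow(plan_rows) > 0) {
      arr <- build_array(plan_rows, phage_seq, phage_ids, hid,
                         left_char = substr(left, nchar(left), nchar(left)),
                         right_char = substr(mid, 1, 1))
      array_part <- arr$array_seq
    }
    # prophage between mid and right
    pro_part <- ""
    my_pro <- names(pro_host)[pro_host == h]
    pro_rows <- NULL
    if (length(my_pro) > 0) {
      pid <- my_pro[1]                      # one prophage per host contig
      pro_part <- phage_seq[[pid]]
      pro_start <- nchar(left) + nchar(array_part) + nchar(mid)
      pro_rows <- tibble(
        host_contig_id = hid, phage_id = pid,
        start = pro_start, end = pro_start + nchar(pro_part)
      )
    }
    seqs <- paste0(left, array_part, mid, pro_part, right)
    contigs[[hid]] <- tibble(contig_id = hid, sequence = seqs,
                             length = nchar(seqs))
    if (!is.null(pro_rows)) prophages[[hid]] <- pro_rows
    if (!is.null(arr)) {
      spacers[[hid]] <- arr$spacers |>
        mutate(host_contig_id = hid,
               array_offset = nchar(left))
    }
  }
  list(
    contigs = bind_rows(contigs),
    prophages = if (length(prophages)) bind_rows(prophages) else
      tibble(host_contig_id = character(0), phage_id = character(0),
             start = integer(0), end = integer(0)),
    spacers = if (length(spacers)) bind_rows(spacers) else
      tibble(spacer_id = character(0), spacer_seq = character(0),
             target_phage = character(0), mismatches = integer(0),
             protospacer_start = integer(0), strand = character(0),
             host_contig_id = character(0), array_offset = integer(0))
  )
}

# one array per host: a 30-bp repeat interleaved with spacers lifted from
# the target phages; boundary characters are rejection-sampled so the
# repeat cannot be extended into the spacers by the array detector
build_array <- function(plan_rows, phage_seq, phage_ids, hid,
                        left_char, right_char) {
  spacer_len <- 32L
  repeat_len <- 30L
  for (attempt in 1:50) {
    rep_seq <- random_dna(repeat_len)
    sp <- list()
    for (r in seq_len(nrow(plan_rows))) {
      pid <- phage_ids[plan_rows$phage[r]]
      target <- phage_seq[[pid]]
      for (k in seq_len(plan_rows$n_spacers[r])) {
        pos <- sample(nchar(target) - spacer_len, 1)
        proto <- substr(target, pos, pos + spacer_len - 1L)
        strand <- sample(c("+", "-"), 1)
        sp_seq <- if (strand == "+") proto else revcomp(proto)
        mm <- plan_rows$mismatches[r]
        if (mm > 0) {
          chars <- strsplit(sp_seq, "")[[1]]
          at <- sample(spacer_len, mm)
          chars[at] <- vapply(chars[at], function(ch) {
            sample(setdiff(DNA_ALPHABET, ch), 1)
          }, character(1))
          sp_seq <- paste(chars, collapse = "")
        }
        sp[[length(sp) + 1L]] <- tibble(
          spacer_seq = sp_seq, target_phage = pid,
          mismatches = plan_rows$mismatches[r],
          protospacer_start = pos - 1L, strand = strand
        )
      }
    }
    sp <- bind_rows(sp)
    if (anyDuplicated(sp$spacer_seq)) next
    # every repeat copy is preceded by the previous spacer's last base (the
    # first by the host base) and followed by the next spacer's first base;
    # three consecutive equal boundary bases would let the array detector
    # extend the repeat into the spacers and report a shifted sub-array
    prec <- c(left_char, substr(sp$spacer_seq, spacer_len, spacer_len))
    foll <- c(substr(sp$spacer_seq, 1, 1), right_char)
    if (max(rle(prec)$lengths) >= 3 || max(rle(foll)$lengths) >= 3) next
    array_seq <- paste0(
      paste0(rep_seq, sp$spacer_seq, collapse = ""), rep_seq
    )
    sp$spacer_id <- paste0(hid, "_planted_sp", seq_len(nrow(sp)))
    return(list(array_seq = array_seq, repeat_seq = rep_seq,
                spacers = sp))
  }
  rlang::abort("could not construct a CRISPR array within 50 attempts")
}

build_triage <- function(phage_ids, hosts) {
  n <- length(phage_ids)
  route <- sample(c("sorter", "finder", "joint"), n, replace = TRUE,
                  prob = c(0.7, 0.15, 0.15))
  phage_feats <- tibble(
    contig_id = phage_ids,
    sorter_category = dplyr::case_when(
      route == "sorter" ~ sample(c(1L, 2L), n, replace = TRUE),
      route == "joint" ~ sample(c(3L, 6L), n, replace = TRUE),
      TRUE ~ NA_integer_
    ),
    finder_score = dplyr::case_when(
      route == "finder" ~ runif(n, 0.91, 0.99),
      route == "joint" ~ runif(n, 0.71, 0.89),
      TRUE ~ NA_real_
    ),
    finder_p = if_else(route %in% c("finder", "joint"),
                       runif(n, 0.001, 0.04), NA_real_),
    annotation_superkingdom = dplyr::case_when(
      route == "joint" ~ sample(c("Viruses", "unclassified"), n,
                                replace = TRUE),
      TRUE ~ NA_character_
    ),
    annotation_is_eukaryotic_virus = FALSE
  )
  pro_hosts <- hosts$prophages$host_contig_id
  host_ids <- hosts$contigs$contig_id
  host_feats <- tibble(
    contig_id = host_ids,
    sorter_category = if_else(
      host_ids %in% pro_hosts,
      sample(c(4L, 5L), length(host_ids), replace = TRUE),
      NA_integer_
    ),
    finder_score = NA_real_,
    finder_p = NA_real_,
    annotation_superkingdom = "Bacteria",
    annotation_is_eukaryotic_virus = FALSE
  )
  bind_rows(phage_feats, host_feats)
}

#' @export
print.community_bundle <- function(x, ...) {
  cat("<community_bundle>\n")
  cat("  contigs:", nrow(x$contigs),
      sprintf("(%d phage, %d bacterial)\n",
              sum(x$truth$triage$phage & !x$truth$triage$bacterial),
              sum(x$truth$triage$bacterial)))
  cat("  samples:", nrow(x$metadata), "\n")
  cat("  planted prophages:", nrow(x$truth$prophages),
      "| planted spacers:", nrow(x$truth$spacers), "\n")
  invisible(x)
}

#' Realize per-sample presence and abundance for a bundle
#'
#' For each sample, each phage genome is present with its group's inclusion
#' probability (`richness_differential`), except genomes in planted-effect
#' lineages, which are present (as a lineage) with the planted per-group
#' prevalence. Present genomes draw a log-normal abundance.
#'
#' @param bundle A `community_bundle`.
#' @param seed Integer seed for the realization stream.
#' @return A tibble `sample_id`, `contig_id`, `abundance` (0 when absent).
#' @keywords internal
realize_abundance <- function(bundle, seed) {
  spec <- bundle$spec
  lineages <- bundle$truth$lineages
  effects <- bundle$truth$effects
  md <- bundle$metadata
  with_seed(substream_seed(seed, "abundance_realization"), {
    rows <- lapply(seq_len(nrow(md)), function(i) {
      grp <- md$group[i]
      incl <- spec$richness_differential[[grp]]
      # lineage-level presence for planted effects
      eff_present <- if (!is.null(effects) && nrow(effects) > 0) {
        setNames(
          runif(nrow(effects)) <
            if (grp == "control") effects$prevalence_control else
              effects$prevalence_case,
          effects$lineage
        )
      } else logical(0)
      present <- vapply(lineages$lineage, function(lin) {
        if (lin %in% names(eff_present)) eff_present[[lin]] else
          runif(1) < incl
      }, logical(1))
      ab <- ifelse(
        present,
        rlnorm(nrow(lineages),
               meanlog = spec$abundance_model$meanlog[[grp]],
               sdlog = spec$abundance_model$sdlog[[grp]]),
        0
      )
      tibble(sample_id = md$sample_id[i],
             contig_id = lineages$contig_id, abundance = ab)
    })
    bind_rows(rows)
  })
}

#' Generate alignment records for a community bundle
#'
#' Emits the PAF-like alignment records (and, on request, per-base depth
#' vectors via [depth_from_alignments()]) that stand in for the output of a
#' read mapper. Per-contig summed reads are proportional to the planted
#' abundance times contig length, with Poisson noise; present contigs are
#' tiled by fixed-size chunks so their horizontal coverage is complete; a
#' configured fraction of records receives identity below 0.90 to exercise
#' the identity filter.
#'
#' @param bundle A `community_bundle`.
#' @param profiles Optional abundance profile tibble `sample_id`,
#'   `contig_id`, `abundance` overriding the built-in realization; contig
#'   ids must exist in the bundle.
#' @param library_size Expected mapped reads per sample (default 50,000).
#' @param contaminant_fraction Fraction of records with identity below 0.90
#'   (default 0.05).
#' @param chunk Tiling chunk size in bp (default 2,000).
#' @param seed Integer seed.
#' @return A list with `alignments` (tibble `query_id`, `contig_id`,
#'   `start`, `end`, `n_reads`, `identity`, `sample_id`) and
#'   `abundance_truth`.
#' @export
generate_alignments <- function(bundle, profiles = NULL,
                                library_size = 50000,
                                contaminant_fraction = 0.05,
                                chunk = 2000, seed = NULL) {
  vp_assert(inherits(bundle, "community_bundle"),
            "`bundle` must come from generate_community()")
  seed <- seed %||% bundle$spec$seed
  phage_ids <- bundle$truth$lineages$contig_id
  lens <- setNames(bundle$contigs$length, bundle$contigs$contig_id)
  if (is.null(profiles)) {
    profiles <- realize_abundance(bundle, seed)
  } else {
    vp_assert_fields(profiles, c("sample_id", "contig_id", "abundance"),
                     "`profiles`")
    unknown <- setdiff(unique(profiles$contig_id), names(lens))
    vp_assert(length(unknown) == 0,
              sprintf("unknown contig id(s) in profile: %s",
                      paste(unknown, collapse = ", ")))
  }
  recs <- with_seed(substream_seed(seed, "alignments"), {
    active <- profiles[profiles$abundance > 0, , drop = FALSE]
    out <- vector("list", nrow(active))
    if (nrow(active) > 0) {
      # per-sample normalisation: expected reads proportional to
      # abundance * length, scaled to the library size
      weight <- active$abundance * lens[active$contig_id]
      totals <- tapply(weight, active$sample_id, sum)
      exp_reads <- library_size * weight /
        as.numeric(totals[active$sample_id])
      for (i in seq_len(nrow(active))) {
        cid <- active$contig_id[i]
        L <- lens[[cid]]
        starts <- seq.int(0L, L - 1L, by = chunk)
        ends <- pmin(starts + chunk, L)
        n_chunks <- length(starts)
        reads <- rpois(n_chunks, exp_reads[i] / n_chunks)
        contam <- runif(n_chunks) < contaminant_fraction
        ident <- ifelse(contam, runif(n_chunks, 0.70, 0.895),
                        runif(n_chunks, 0.95, 1.0))
        keep <- reads > 0
        if (!any(keep)) next
        out[[i]] <- tibble(
          query_id = paste0(active$sample_id[i], "_", cid, "_r",
                            seq_len(sum(keep))),
          contig_id = cid,
          start = starts[keep], end = ends[keep],
          n_reads = reads[keep], identity = round(ident[keep], 4),
          sample_id = active$sample_id[i]
        )
      }
    }
    bind_rows(out)
  })
  if (nrow(recs) == 0) {
    recs <- tibble(query_id = character(0), contig_id = character(0),
                   start = integer(0), end = integer(0),
                   n_reads = integer(0), identity = numeric(0),
                   sample_id = character(0))
  }
  list(alignments = recs, abundance_truth = profiles)
}

#' Per-base depth vector from alignment records
#'
#' Each record contributes its `n_reads` to every position of its interval,
#' so the depth-vector sum equals the total aligned bases
#' (`sum(n_reads * (end - start))`).
#'
#' @param records Alignment records for one contig (any sample subset).
#' @param contig_len Contig length in bp.
#' @return Numeric depth vector of length `contig_len`.
#' @export
depth_from_alignments <- function(records, contig_len) {
  depth <- numeric(contig_len)
  for (i in seq_len(nrow(records))) {
    idx <- (records$start[i] + 1L):records$end[i]
    depth[idx] <- depth[idx] + records$n_reads[i]
  }
  depth
}

#' Simulate a two-group presence/absence matrix
#'
#' Light-weight companion to the full generator for power calculations:
#' units are present in a sample with their group's inclusion probability.
#'
#' @param n_units Number of units (e.g. VCs).
#' @param n_per_group Samples per group.
#' @param p_control,p_case Inclusion probabilities.
#' @param seed Integer seed.
#' @return A list with `presence` (long tibble `unit_id`, `sample_id`,
#'   `present`) and `metadata`.
#' @export
simulate_presence_matrix <- function(n_units, n_per_group, p_control,
                                     p_case, seed = 1) {
  with_seed(substream_seed(seed, "presence_sim"), {
    md <- tibble(
      sample_id = c(sprintf("control_%02d", seq_len(n_per_group)),
                    sprintf("case_%02d", seq_len(n_per_group))),
      group = rep(c("control", "case"), each = n_per_group)
    )
    pres <- tidyr::expand_grid(
      unit_id = sprintf("unit_%04d", seq_len(n_units)),
      sample_id = md$sample_id
    ) |>
      left_join(md, by = "sample_id") |>
      mutate(present = runif(dplyr::n()) <
               if_else(group == "control", p_control, p_case)) |>
      select(unit_id, sample_id, present)
    list(presence = pres, metadata = md)
  })
}
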