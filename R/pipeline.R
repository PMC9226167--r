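# End-to-end orchestration from a config list/file, with a run manifest.

PIPELINE_STAGES <- c("synth", "triage", "cluster", "abundance", "ecology",
                     "host", "lineage", "compare")

STAGE_DEPS <- list(
  triage = "synth", cluster = "triage", abundance = "cluster",
  ecology = "abundance", host = "cluster", lineage = "cluster",
  compare = "abundance"
)

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A config list accepted by [run_pipeline()].
#' @export
default_config <- function(out_dir = tempfile("viromeprofiler_run_"),
                           seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = as.list(setNames(rep(TRUE, length(PIPELINE_STAGES)),
                              PIPELINE_STAGES)),
    synth = list(n_phage_genomes = 16, n_host_genomes = 6,
                 n_samples_per_group = 12),
    triage = list(min_identity = 90),
    cluster = list(bit_threshold = 50, vc_threshold = 1, inflation = 1.5),
    abundance = list(min_identity = 0.90, min_coverage = 0.75,
                     library_size = 50000),
    ecology = list(n_perm = 199),
    host = list(max_mismatches = 1),
    lineage = list(k = 3),
    compare = list(alpha = 0.05),
    log_level = "info"
  )
}

validate_config <- function(config) {
  known <- c("out_dir", "seed", "stages", PIPELINE_STAGES[-1], "synth",
             "log_level")
  unknown <- setdiff(names(config), known)
  vp_assert(length(unknown) == 0,
            sprintf("unknown config key(s): %s",
                    paste(unknown, collapse = ", ")))
  stages <- config$stages
  unknown_stage <- setdiff(names(stages), PIPELINE_STAGES)
  vp_assert(length(unknown_stage) == 0,
            sprintf("unknown stage(s): %s",
                    paste(unknown_stage, collapse = ", ")))
  enabled <- PIPELINE_STAGES[vapply(PIPELINE_STAGES, function(s) {
    isTRUE(stages[[s]])
  }, logical(1))]
  for (s in enabled) {
    dep <- STAGE_DEPS[[s]]
    if (!is.null(dep) && !dep %in% enabled) {
      rlang::abort(sprintf(
        "stage '%s' is enabled but its dependency '%s' is not", s, dep))
    }
  }
  enabled
}

#' Read a pipeline config from YAML or JSON
#'
#' Keys absent from the file fall back to [default_config()] values.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A config list.
#' @export
read_config <- function(path) {
  vp_assert(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modifyList(base[[nm]], cfg[[nm]])
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' Run the full profiling pipeline on a synthetic community
#'
#' Executes the enabled stages in fixed order (synth, triage, cluster,
#' abundance, then ecology / host / lineage in any order, then compare),
#' writes every stage's tabular outputs as TSV under `config$out_dir`, and
#' returns a run manifest with the config snapshot, per-file MD5 hashes and
#' wall-clock timings. Re-running with an identical config reproduces
#' identical hashes.
#'
#' @param config A config list (see [default_config()]) or a path to a
#'   YAML/JSON config file.
#' @return A `run_manifest` list: `config`, `files` (tibble `file`, `md5`),
#'   `timings` (tibble `stage`, `seconds`), `results` (in-memory stage
#'   outputs).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  enabled <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  timings <- list()
  say <- function(...) {
    if (identical(config$log_level, "info")) {
      message(sprintf("[viromeprofiler] %s", sprintf(...)))
    }
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% enabled) return(invisible(NULL))
    say("stage %s", stage)
    t0 <- Sys.time()
    tryCatch(fn(), error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(e)), parent = e)
    })
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
  }

  run_stage("synth", function() {
    spec_args <- config$synth %||% list()
    spec_args$seed <- config$seed
    spec <- do.call(community_spec, spec_args)
    bundle <- generate_community(spec)
    aln <- generate_alignments(
      bundle,
      library_size = config$abundance$library_size %||% 50000,
      seed = config$seed
    )
    res$bundle <<- bundle
    res$alignments <<- aln$alignments
    write_contigs_fasta(bundle$contigs, file.path(out_dir, "contigs.fasta"))
    write_proteins_fasta(bundle$proteins,
                         file.path(out_dir, "proteins.fasta"))
    write_tsv_file(bundle$triage_features,
                   file.path(out_dir, "triage_features.tsv"))
    write_tsv_file(aln$alignments, file.path(out_dir, "alignments.tsv"))
    write_tsv_file(bundle$metadata, file.path(out_dir, "metadata.tsv"))
    jsonlite::write_json(
      lapply(bundle$truth, function(x) if (is.data.frame(x)) x else x),
      file.path(out_dir, "truth.json")
    )
  })

  run_stage("triage", function() {
    bundle <- res$bundle
    tri <- classify_viral(bundle$triage_features)
    circ <- detect_circular(bundle$contigs)
    res$triage <<- tri |>
      left_join(circ |> select(contig_id, circular), by = "contig_id")
    write_tsv_file(res$triage, file.path(out_dir, "triage_calls.tsv"))
  })

  run_stage("cluster", function() {
    bundle <- res$bundle
    phage_ids <- res$triage$contig_id[res$triage$phage &
                                        !res$triage$bacterial]
    prots <- bundle$proteins |> filter(contig_id %in% phage_ids)
    params <- scoring_params(
      bit_threshold = config$cluster$bit_threshold %||% 50)
    hits <- homology_search(prots |> select(protein_id, sequence), params)
    pcs <- build_protein_clusters(hits, protein_ids = prots$protein_id)
    pc_membership <- pcs |>
      left_join(prots |> select(protein_id, contig_id),
                by = "protein_id") |>
      distinct(contig_id, pc_id)
    vcs <- build_viral_clusters(
      pc_membership,
      universe = dplyr::n_distinct(pcs$pc_id),
      contig_ids = phage_ids,
      threshold = config$cluster$vc_threshold %||% 1,
      inflation = config$cluster$inflation %||% 1.5
    )
    res$hits <<- hits
    res$pcs <<- pcs
    res$pc_membership <<- pc_membership
    res$vcs <<- vcs
    write_tsv_file(hits, file.path(out_dir, "hits.tsv"))
    write_tsv_file(pcs, file.path(out_dir, "pcs.tsv"))
    write_tsv_file(vcs, file.path(out_dir, "vcs.tsv"))
  })

  run_stage("abundance", function() {
    bundle <- res$bundle
    ab <- compute_abundance(
      res$alignments |> filter(contig_id %in% res$vcs$contig_id),
      bundle$contigs |> select(contig_id, length),
      res$vcs,
      min_identity = config$abundance$min_identity %||% 0.90,
      min_coverage = config$abundance$min_coverage %||% 0.75
    )
    res$abundance <<- ab
    write_tsv_file(ab$vc_counts, file.path(out_dir, "abundance_counts.tsv"))
    write_tsv_file(ab$vc_rpkm, file.path(out_dir, "abundance_rpkm.tsv"))
    write_tsv_file(ab$vc_relative,
                   file.path(out_dir, "abundance_relative.tsv"))
    write_tsv_file(ab$coverage_mask,
                   file.path(out_dir, "coverage_mask.tsv"))
    write_tsv_file(
      prevalence_bins(ab$vc_relative,
                      n_samples = nrow(bundle$metadata)),
      file.path(out_dir, "prevalence.tsv")
    )
  })

  run_stage("ecology", function() {
    bundle <- res$bundle
    ab <- res$abundance
    div <- diversity_metrics(ab$vc_counts)
    d <- bray_curtis(ab$vc_relative)
    ord <- pcoa(d)
    md <- bundle$metadata |>
      filter(sample_id %in% rownames(d))
    perm <- permanova(d, md, group = "group",
                      covariates = intersect("age", names(md)),
                      n_perm = config$ecology$n_perm %||% 199,
                      seed = config$seed)
    res$diversity <<- div
    res$pcoa <<- ord
    res$permanova <<- perm
    write_tsv_file(div, file.path(out_dir, "diversity.tsv"))
    write_tsv_file(ord$coordinates, file.path(out_dir, "pcoa_coords.tsv"))
    writeLines(utils::capture.output(print(perm)),
               file.path(out_dir, "permanova.txt"))
  })

  run_stage("host", function() {
    bundle <- res$bundle
    bact_ids <- res$triage$contig_id[res$triage$bacterial]
    bact <- bundle$contigs |> filter(contig_id %in% bact_ids)
    spacers <- detect_crispr_arrays(bact)
    phage_contigs <- bundle$contigs |>
      filter(contig_id %in% res$vcs$contig_id)
    hits <- match_protospacers(
      spacers, phage_contigs,
      max_mismatches = config$host$max_mismatches %||% 1
    )
    spacer_taxa <- spacers |>
      distinct(spacer_id, host_contig_id) |>
      mutate(taxon = host_contig_id, rank = "genome",
             phylum = "synthetic_phylum") |>
      select(spacer_id, taxon, rank, phylum)
    sp_links <- spacer_vc_links(hits, spacer_taxa, res$vcs)
    pro_taxa <- bundle$truth$prophages |>
      transmute_prophage_taxa()
    pro_links <- prophage_vc_links(
      res$vcs |>
        bind_rows(tibble(
          contig_id = bundle$truth$prophages$host_contig_id,
          vc_id = res$vcs$vc_id[match(bundle$truth$prophages$phage_id,
                                      res$vcs$contig_id)],
          singleton = NA
        )),
      pro_taxa
    )
    res$host_predictions <<- merge_host_predictions(sp_links, pro_links)
    write_tsv_file(res$host_predictions,
                   file.path(out_dir, "host_predictions.tsv"))
  })

  run_stage("lineage", function() {
    bundle <- res$bundle
    if (nrow(bundle$truth$subfamilies) == 0) {
      res$lineage <<- NULL
      return(invisible(NULL))
    }
    fam_ids <- bundle$truth$subfamilies$contig_id
    assign <- classify_family(
      bundle$proteins |> filter(contig_id %in% fam_ids),
      bundle$contigs |> filter(contig_id %in% fam_ids)
    )
    members <- assign$contig_id[assign$family_member]
    subf <- assign_subfamilies(members, res$pc_membership,
                               k = config$lineage$k %||% 3)
    res$lineage <<- list(family = assign, subfamilies = subf)
    write_tsv_file(assign |> select(contig_id, family_member),
                   file.path(out_dir, "lineage_assignments.tsv"))
    write_tsv_file(subf, file.path(out_dir, "subfamilies.tsv"))
  })

  run_stage("compare", function() {
    bundle <- res$bundle
    ab <- res$abundance
    comp <- prevalence_compare(
      ab$vc_relative |> rename(value = value),
      bundle$metadata
    )
    res$compare <<- comp
    write_tsv_file(comp, file.path(out_dir, "group_stats.tsv"))
  })

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- structure(
    list(
      config = config,
      files = tibble(
        file = basename(files),
        md5 = unname(tools::md5sum(files))
      ),
      timings = tibble(
        stage = names(timings),
        seconds = round(unlist(timings), 3)
      ),
      results = res
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(config = config,
         files = manifest$files,
         timings = manifest$timings),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  manifest
}

transmute_prophage_taxa <- function(prophages) {
  tibble(
    contig_id = prophages$host_contig_id,
    taxon = prophages$host_contig_id,
    rank = "genome",
    phylum = "synthetic_phylum"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  out_dir:", x$config$out_dir, "\n")
  cat("  stages run:", paste(x$timings$stage, collapse = ", "), "\n")
  cat("  files:", nrow(x$files), "\n")
  invisible(x)
}
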