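#' A marker gene set for lineage classification
#'
#' Bundles the marker proteins that define a phage lineage, the markers that
#' must all be hit for membership, the bit-score threshold, and the minimum
#' contig length.
#'
#' @param name Lineage name.
#' @param markers Named character vector of marker protein sequences.
#' @param required Names of the markers that must all be present (default:
#'   all of them).
#' @param min_bits Minimum bit score per marker hit (default 50).
#' @param min_contig_len Minimum contig length in bp (default 30,000).
#' @return A `marker_gene_set` list.
#' @export
marker_gene_set <- function(name, markers, required = names(markers),
                            min_bits = 50, min_contig_len = 30000) {
  vp_assert(length(markers) > 0, "empty marker set")
  vp_assert(!is.null(names(markers)) && all(nzchar(names(markers))),
            "`markers` must be named")
  vp_assert(all(required %in% names(markers)),
            "`required` must be a subset of marker names")
  structure(
    list(name = name, markers = markers, required = required,
         min_bits = min_bits, min_contig_len = min_contig_len),
    class = "marker_gene_set"
  )
}

read_fixture_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(
    system.file("extdata", file, package = "viromeprofiler",
                mustWork = TRUE)
  )
  setNames(as.character(x), vapply(strsplit(names(x), " "), `[`, "", 1))
}

#' The nine-marker gene set defining the candidate family
#'
#' Loads the package's synthetic seed proteins for the nine-gene core (four
#' structural genes: terminase large subunit, portal, Clp protease, major
#' capsid; three transcription-related: DNA polymerase I, SNF2-like
#' helicase, VRR-NUC nuclease; two of unknown function). The fixtures are
#' fixed random sequences standing in for the restricted-access cohort
#' genes; real marker sequences can be dropped in via [marker_gene_set()].
#'
#' @param relaxed When `TRUE`, only the four conserved structural genes are
#'   required (the validation-cohort mode that tolerates incomplete
#'   assemblies).
#' @param min_bits,min_contig_len Thresholds passed to [marker_gene_set()].
#' @return A `marker_gene_set`.
#' @export
heliusviridae_markers <- function(relaxed = FALSE, min_bits = 50,
                                  min_contig_len = 30000) {
  markers <- read_fixture_fasta("heliusviridae_marker_seeds_synthetic.faa")
  structural <- c("terminase_large_subunit", "portal_protein",
                  "clp_protease", "major_capsid_protein")
  marker_gene_set(
    name = "Heliusviridae",
    markers = markers,
    required = if (relaxed) structural else names(markers),
    min_bits = min_bits,
    min_contig_len = min_contig_len
  )
}

#' Crassvirales marker queries (terminase + polymerase)
#'
#' @return Named character vector with the two synthetic query proteins.
#' @export
crassvirales_queries <- function() {
  read_fixture_fasta("crassvirales_marker_queries_synthetic.faa")
}

# best bit score of each marker against a set of proteins (vectorized over
# the proteins); returns named numeric vector, -Inf when no alignment
best_marker_bits <- function(marker_seqs, protein_seqs, params) {
  if (length(protein_seqs) == 0) {
    return(setNames(rep(-Inf, length(marker_seqs)), names(marker_seqs)))
  }
  prots <- Biostrings::AAStringSet(protein_seqs)
  mat <- substitution_matrix(params)
  vapply(marker_seqs, function(mk) {
    raw <- Biostrings::pairwiseAlignment(
      prots, Biostrings::AAString(mk), type = "local",
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, scoreOnly = TRUE
    )
    max(bits_from_raw(raw, params))
  }, numeric(1))
}

#' Classify contigs into a marker-defined lineage
#'
#' A contig is a family member when its length clears
#' `markers$min_contig_len` and every required marker has a best hit of at
#' least `markers$min_bits` bits against the contig's proteins.
#' Classification is monotone: adding proteins can only add memberships,
#' and removing a required marker's homolog always removes membership.
#'
#' @param proteins A data frame `protein_id`, `contig_id`, `sequence`.
#' @param contigs A data frame `contig_id`, `length` (or `sequence`).
#' @param markers A [marker_gene_set()].
#' @param params [scoring_params()] used for the homology search.
#' @return A tibble `contig_id`, `family_member`, plus one `bits_<marker>`
#'   column per marker with the best bit score observed.
#' @export
classify_family <- function(proteins, contigs,
                            markers = heliusviridae_markers(),
                            params = scoring_params()) {
  vp_assert(inherits(markers, "marker_gene_set"),
            "`markers` must be a marker_gene_set")
  vp_assert_fields(proteins, c("protein_id", "contig_id", "sequence"),
                   "`proteins`")
  vp_assert_fields(contigs, "contig_id", "`contigs`")
  lens <- if ("length" %in% names(contigs)) contigs$length else
    nchar(contigs$sequence)
  lens <- setNames(lens, contigs$contig_id)
  prot_by_contig <- split(proteins$sequence, proteins$contig_id)
  rows <- lapply(contigs$contig_id, function(cid) {
    bits <- best_marker_bits(markers$markers,
                             prot_by_contig[[cid]] %||% character(0),
                             params)
    member <- lens[[cid]] >= markers$min_contig_len &&
      all(bits[markers$required] >= markers$min_bits)
    out <- tibble(contig_id = cid, family_member = member)
    for (mk in names(bits)) out[[paste0("bits_", mk)]] <- bits[[mk]]
    out
  })
  bind_rows(rows)
}

#' Delineate subfamilies among family members by shared-PC clustering
#'
#' Builds the pairwise shared-PC-fraction matrix over the member contigs,
#' takes Euclidean distances between its rows, clusters with
#' average-linkage hierarchical clustering, and cuts the dendrogram into
#' `k` groups. Labels are deterministic, assigned in decreasing cluster
#' size ("alpha", "beta", "gamma", then "subfamily_4", ... for larger k;
#' size ties broken by smallest member id).
#'
#' @param member_ids Contig ids of the family members.
#' @param pc_membership A data frame `contig_id`, `pc_id`.
#' @param k Number of subfamilies to cut (no automatic selection is
#'   attempted; k is the user's call).
#' @return A tibble `contig_id`, `subfamily`.
#' @export
assign_subfamilies <- function(member_ids, pc_membership, k = 3) {
  member_ids <- sort(unique(member_ids))
  vp_assert(length(member_ids) >= k,
            sprintf("need at least k = %d members, got %d", k,
                    length(member_ids)))
  m <- shared_pc_matrix(pc_membership, member_ids)
  if (k == 1) {
    return(tibble(contig_id = member_ids, subfamily = "alpha"))
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  cut <- cutree(hc, k = k)
  sizes <- table(cut)
  first_member <- tapply(names(cut), cut, min)
  ord <- order(-as.integer(sizes), first_member)
  greek <- c("alpha", "beta", "gamma")
  labels <- c(greek, paste0("subfamily_", seq_len(max(0, k - 3)) + 3))
  label_of <- setNames(labels[seq_len(k)], names(sizes)[ord])
  tibble(
    contig_id = names(cut),
    subfamily = unname(label_of[as.character(cut)])
  ) |> arrange(contig_id)
}

#' Classify contigs as Crassvirales by terminase + polymerase markers
#'
#' A contig is flagged when both marker queries hit its proteins at
#' `min_bits` bits or more with an alignment of at least `min_aln_len`
#' (in `unit`: alignment columns in residues by default, or "nt" to
#' interpret the threshold on the nucleotide scale, i.e. columns * 3), and
#' the contig is at least `min_contig_len` bp (default 70,000).
#'
#' @param proteins A data frame `protein_id`, `contig_id`, `sequence`.
#' @param contigs A data frame `contig_id` and `length` (or `sequence`).
#' @param queries Named character vector with elements `crass_terminase`
#'   and `crass_polymerase` (default: package fixtures).
#' @param min_bits Bit-score cutoff (default 50).
#' @param min_aln_len Minimum query alignment length (default 350).
#' @param unit `"residues"` or `"nt"` for the alignment-length threshold.
#' @param min_contig_len Minimum contig length in bp (default 70,000).
#' @param params [scoring_params()].
#' @return A tibble `contig_id`, `crassvirales` plus per-query best bits
#'   and alignment lengths.
#' @export
classify_crassvirales <- function(proteins, contigs,
                                  queries = crassvirales_queries(),
                                  min_bits = 50, min_aln_len = 350,
                                  unit = c("residues", "nt"),
                                  min_contig_len = 70000,
                                  params = scoring_params()) {
  unit <- match.arg(unit)
  vp_assert(length(queries) == 2 && !is.null(names(queries)),
            "`queries` must be two named protein sequences")
  vp_assert_fields(proteins, c("protein_id", "contig_id", "sequence"),
                   "`proteins`")
  lens <- if ("length" %in% names(contigs)) contigs$length else
    nchar(contigs$sequence)
  lens <- setNames(lens, contigs$contig_id)
  mat <- substitution_matrix(params)
  prot_by_contig <- split(proteins$sequence, proteins$contig_id)
  rows <- lapply(contigs$contig_id, function(cid) {
    seqs <- prot_by_contig[[cid]] %||% character(0)
    res <- lapply(queries, function(qr) {
      if (length(seqs) == 0) return(list(bits = -Inf, aln = 0L))
      alns <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(seqs), Biostrings::AAString(qr),
        type = "local", substitutionMatrix = mat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend
      )
      bits <- bits_from_raw(Biostrings::score(alns), params)
      best <- which.max(bits)
      list(bits = bits[best],
           aln = nchar(as.character(Biostrings::pattern(alns[best]))))
    })
    aln_lens <- vapply(res, function(r) as.numeric(r$aln), numeric(1))
    if (unit == "nt") aln_lens <- aln_lens * 3
    hit <- vapply(res, function(r) r$bits, numeric(1)) >= min_bits &
      aln_lens >= min_aln_len
    tibble(
      contig_id = cid,
      crassvirales = unname(lens[cid]) >= min_contig_len && all(hit),
      bits_terminase = res[[1]]$bits,
      bits_polymerase = res[[2]]$bits,
      aln_terminase = res[[1]]$aln,
      aln_polymerase = res[[2]]$aln
    )
  })
  bind_rows(rows)
}

#' A per-contig read-depth profile with host flanks
#'
#' @param contig_id Contig id.
#' @param depth A samples-by-positions numeric matrix of per-base depth
#'   (row names are sample ids); vector input is treated as one sample.
#' @param flanks A list with `left` and `right` 0-based half-open host
#'   flank intervals, e.g. `list(left = c(0, 10000), right = c(78665, L))`.
#' @param candidate Optional 0-based half-open candidate phage interval
#'   (default: the gap between the flanks).
#' @return A `depth_profile` object.
#' @export
depth_profile <- function(contig_id, depth, flanks, candidate = NULL) {
  if (is.vector(depth)) depth <- matrix(depth, nrow = 1)
  vp_assert(is.matrix(depth), "`depth` must be a matrix or vector")
  vp_assert(all(c("left", "right") %in% names(flanks)),
            "`flanks` needs `left` and `right` intervals")
  candidate <- candidate %||% c(flanks$left[2], flanks$right[1])
  vp_assert(candidate[1] < candidate[2],
            "empty candidate interval between flanks")
  structure(
    list(contig_id = contig_id, depth = depth, flanks = flanks,
         candidate = candidate),
    class = "depth_profile"
  )
}

#' Extract prophage boundaries from read-depth profiles
#'
#' In samples where the bacterial flanks of a prophage-carrying contig are
#' well covered but the integrated phage is absent, read depth drops across
#' the prophage. Informative samples are those with mean flank depth of at
#' least `host_min_depth` and mean candidate-region depth at most
#' `phage_max_ratio` times the flank mean. Per informative sample, the
#' depth is smoothed with a running median (window `window` bp) and the
#' boundaries are the outermost positions of the region where smoothed
#' depth falls below half the flank mean; the reported interval is the
#' per-sample median of these positions.
#'
#' @param profile A [depth_profile()].
#' @param host_min_depth Minimum mean flank depth for an informative sample
#'   (default 5).
#' @param phage_max_ratio Maximum candidate/flank mean-depth ratio for an
#'   informative sample (default 0.1).
#' @param window Running-median window in bp (odd; default 21).
#' @return A list `start`, `end` (0-based half-open), `length`,
#'   `n_informative`.
#' @export
extract_prophage_boundaries <- function(profile, host_min_depth = 5,
                                        phage_max_ratio = 0.1,
                                        window = 21) {
  vp_assert(inherits(profile, "depth_profile"),
            "`profile` must be a depth_profile")
  d <- profile$depth
  L <- ncol(d)
  fl <- profile$flanks
  flank_idx <- c(idx_of(fl$left, L), idx_of(fl$right, L))
  cand_idx <- idx_of(profile$candidate, L)
  starts <- ends <- numeric(0)
  for (s in seq_len(nrow(d))) {
    flank_mean <- mean(d[s, flank_idx])
    if (flank_mean < host_min_depth) next
    if (mean(d[s, cand_idx]) > phage_max_ratio * flank_mean) next
    sm <- runmed(d[s, ], k = window, endrule = "median")
    below <- sm < flank_mean / 2
    # the maximal below-half run overlapping the candidate region
    runs <- rle(below)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    cand_mid <- floor(mean(cand_idx))
    ok <- which(runs$values & run_start <= max(cand_idx) &
                  run_end >= min(cand_idx))
    if (length(ok) == 0) next
    # pick the run containing (or nearest to) the candidate midpoint
    dist_mid <- pmax(run_start[ok] - cand_mid, cand_mid - run_end[ok], 0)
    r <- ok[which.min(dist_mid)]
    starts <- c(starts, run_start[r] - 1L)   # to 0-based
    ends <- c(ends, run_end[r])              # half-open
  }
  vp_assert(length(starts) > 0, "no discriminating sample",
            class = "viromeprofiler_no_informative_sample")
  start <- median(starts)
  end <- median(ends)
  list(start = start, end = end, length = end - start,
       n_informative = length(starts))
}

idx_of <- function(interval, L) {
  s <- max(0, interval[1])
  e <- min(L, interval[2])
  seq.int(s + 1L, e)
}

#' Per-lineage per-group presence counts
#'
#' Presence of a lineage in a sample means any member unit (VC or contig)
#' has non-zero filtered abundance there. Counts are tallied per metadata
#' group, ready for prevalence testing with
#' [prevalence_compare()] / [fisher_exact()].
#'
#' @param assignments A data frame `unit_id`, `lineage` (e.g. subfamily
#'   labels, or one family-level row per unit).
#' @param layer Abundance layer tibble with a unit id column, `sample_id`,
#'   `value`.
#' @param metadata A data frame `sample_id`, `group`.
#' @return A tibble `lineage`, `group`, `n_present`, `n_samples`.
#' @export
lineage_prevalence <- function(assignments, layer, metadata) {
  vp_assert_fields(assignments, c("unit_id", "lineage"), "`assignments`")
  vp_assert_fields(metadata, c("sample_id", "group"), "`metadata`")
  unit_col <- intersect(c("vc_id", "unit_id", "contig_id"),
                        names(layer))[1]
  vp_assert(!is.na(unit_col), "`layer` needs a unit id column")
  present <- layer |>
    rename(unit_id = dplyr::all_of(unit_col)) |>
    dplyr::inner_join(assignments, by = "unit_id",
                      relationship = "many-to-many") |>
    group_by(lineage, sample_id) |>
    summarise(present = any(value > 0), .groups = "drop")
  grid <- tidyr::expand_grid(
    lineage = unique(assignments$lineage),
    sample_id = metadata$sample_id
  )
  grid |>
    left_join(present, by = c("lineage", "sample_id")) |>
    mutate(present = !is.na(present) & present) |>
    left_join(metadata |> select(sample_id, group), by = "sample_id") |>
    group_by(lineage, group) |>
    summarise(n_present = sum(present), n_samples = dplyr::n(),
              .groups = "drop")
}
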