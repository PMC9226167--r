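#' Detect circular contigs by identical terminal direct repeats
#'
#' Assemblies of circular genomes often carry an artifactual terminal direct
#' repeat: the first and last bases of the contig are identical. Contigs
#' inside the short-contig size window (`[min_len, max_len)`, default
#' 1,500-5,000 bp) that carry an exact terminal repeat of at least
#' `min_repeat` bp are flagged circular; longer contigs fall outside the
#' window because they are retained by the >5,000 bp length rule regardless
#' of circularity.
#'
#' @param contigs A data frame with columns `contig_id` and `sequence`.
#' @param min_len,max_len Size window in bp (half-open: `[min_len, max_len)`).
#' @param min_repeat Minimum exact terminal repeat length in bp.
#' @return The input tibble with logical `circular` and integer
#'   `terminal_repeat` (longest exact terminal repeat found, 0 if none)
#'   columns added.
#' @export
#' @examples
#' core <- strrep("ACGT", 700)
#' tb <- tibble::tibble(
#'   contig_id = "c1",
#'   sequence = paste0(substr(core, 1, 55), core, substr(core, 1, 55))
#' )
#' detect_circular(tb)
detect_circular <- function(contigs, min_len = 1500, max_len = 5000,
                            min_repeat = 20) {
  vp_assert_fields(contigs, c("contig_id", "sequence"), "`contigs`")
  vp_assert(min_len <= max_len, "`min_len` must be <= `max_len`")
  vp_assert(all(nzchar(contigs$sequence)),
            "empty sequence in `contigs`")
  reps <- vapply(contigs$sequence, terminal_repeat_length,
                 integer(1), min_repeat = min_repeat, USE.NAMES = FALSE)
  len <- nchar(contigs$sequence)
  contigs |>
    mutate(
      terminal_repeat = reps,
      circular = len >= min_len & len < max_len & reps >= min_repeat
    )
}

# longest k with prefix(k) == suffix(k); 0 when no repeat of >= min_repeat.
# scans k upward so a single mismatch inside the minimal repeat fails it.
terminal_repeat_length <- function(sequence, min_repeat = 20) {
  n <- nchar(sequence)
  kmax <- n %/% 2L
  if (kmax < min_repeat) return(0L)
  best <- 0L
  for (k in seq.int(min_repeat, kmax)) {
    if (substr(sequence, 1L, k) ==
        substr(sequence, n - k + 1L, n)) best <- k
  }
  best
}

#' Classify contigs as phage and/or bacterial from upstream triage evidence
#'
#' Applies the study's decision rule to per-contig evidence from upstream
#' virus-prediction tools. A contig is called phage when any of these hold:
#' (1) its sorter category is 1, 2, 4 or 5; (2) its finder score exceeds 0.9
#' with p < 0.05; or (3) its sorter category is 3 or 6, its finder score
#' exceeds 0.7 with p < 0.05, and its superkingdom annotation is "Viruses" or
#' "unclassified". Contigs annotated as eukaryotic viruses are then removed
#' from the phage set. A contig is called bacterial when annotated
#' "Bacteria" at superkingdom level and either not phage or in a prophage
#' category (4, 5 or 6) -- the prophage exception that leaves
#' prophage-carrying contigs in both datasets. Absent evidence fails its
#' clause rather than erroring, because real feature tables are sparse.
#'
#' @param features A data frame with columns `contig_id`, `sorter_category`
#'   (integer 1-6 or NA), `finder_score`, `finder_p`,
#'   `annotation_superkingdom` (character or NA) and
#'   `annotation_is_eukaryotic_virus` (logical).
#' @return A tibble with `contig_id`, logical `phage` and `bacterial`, and a
#'   `reasons` column tracing the decision path (";"-separated).
#' @export
classify_viral <- function(features) {
  vp_assert_fields(
    features,
    c("contig_id", "sorter_category", "finder_score", "finder_p",
      "annotation_superkingdom", "annotation_is_eukaryotic_virus"),
    "`features`"
  )
  cat_ok <- !is.na(features$sorter_category)
  vp_assert(all(features$sorter_category[cat_ok] %in% 1:6),
            "`sorter_category` must be in 1..6 when present")

  cat_ <- features$sorter_category
  score <- features$finder_score
  pval <- features$finder_p
  sk <- features$annotation_superkingdom
  euk <- isTRUE_vec(features$annotation_is_eukaryotic_virus)

  by_category <- !is.na(cat_) & cat_ %in% c(1, 2, 4, 5)
  by_finder <- !is.na(score) & !is.na(pval) & score > 0.9 & pval < 0.05
  by_joint <- !is.na(cat_) & cat_ %in% c(3, 6) &
    !is.na(score) & !is.na(pval) & score > 0.7 & pval < 0.05 &
    !is.na(sk) & sk %in% c("Viruses", "unclassified")

  phage <- (by_category | by_finder | by_joint) & !euk
  prophage_cat <- !is.na(cat_) & cat_ %in% c(4, 5, 6)
  bacterial <- !is.na(sk) & sk == "Bacteria" & (!phage | prophage_cat)

  reasons <- pmap(
    list(by_category, by_finder, by_joint, euk, phage, bacterial,
         prophage_cat),
    function(bc, bf, bj, ek, ph, ba, pc) {
      r <- character(0)
      if (bc) r <- c(r, "sorter_category_1_2_4_5")
      if (bf) r <- c(r, "finder_score_gt_0.9_p_lt_0.05")
      if (bj) r <- c(r, "category_3_6_finder_gt_0.7_viral_annotation")
      if (ek) r <- c(r, "excluded_eukaryotic_virus")
      if (ba && pc && ph) r <- c(r, "prophage_exception_kept_bacterial")
      if (ba && !ph) r <- c(r, "bacterial_superkingdom")
      if (length(r) == 0) r <- "no_evidence"
      paste(r, collapse = ";")
    }
  )

  tibble(
    contig_id = features$contig_id,
    phage = phage,
    bacterial = bacterial,
    reasons = unlist(reasons)
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Deduplicate contigs at a nucleotide-identity cutoff
#'
#' Reproduces duplicate-and-containment removal: a contig is removed when it
#' aligns to a strictly longer retained contig (ties broken by
#' lexicographically earlier id) at `min_identity` percent identity or more
#' over at least `min_coverage` percent of the shorter contig's length.
#' Candidate pairs are pre-screened by shared k-mers, then confirmed with
#' local alignment. The result is invariant to input order.
#'
#' @param contigs A data frame with columns `contig_id` and `sequence`.
#' @param min_identity Minimum percent identity (default 90).
#' @param min_coverage Minimum percent of the shorter contig's length that
#'   the alignment must span (default 95).
#' @return A list with `representatives` (tibble of retained contigs) and
#'   `duplicates` (tibble `contig_id`, `duplicate_of`).
#' @export
deduplicate <- function(contigs, min_identity = 90, min_coverage = 95) {
  vp_assert_fields(contigs, c("contig_id", "sequence"), "`contigs`")
  vp_assert(!anyDuplicated(contigs$contig_id),
            "duplicate `contig_id` values in `contigs`")
  vp_assert(min_identity > 0 && min_identity <= 100,
            "`min_identity` must be in (0, 100]")

  # canonical retention order: longest first, ties by id
  ord <- order(-nchar(contigs$sequence), contigs$contig_id)
  contigs <- contigs[ord, , drop = FALSE]
  n <- nrow(contigs)
  if (n <= 1) {
    return(list(representatives = as_tibble(contigs),
                duplicates = tibble(contig_id = character(0),
                                    duplicate_of = character(0))))
  }

  kmers <- lapply(contigs$sequence, contig_kmers, k = 14L)
  retained <- logical(n)
  dup_of <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- NA_character_
    for (j in seq_len(i - 1L)) {
      if (!retained[j]) next
      # j precedes i in (-length, id) order: strictly longer, or equal
      # length with the lexicographically earlier id (the tie rule)
      if (nchar(contigs$sequence[j]) < nchar(contigs$sequence[i])) next
      if (!any(kmers[[i]] %in% kmers[[j]])) next
      if (is_contained(contigs$sequence[i], contigs$sequence[j],
                       min_identity, min_coverage)) {
        hit <- contigs$contig_id[j]
        break
      }
    }
    if (is.na(hit)) retained[i] <- TRUE else dup_of[i] <- hit
  }

  list(
    representatives = as_tibble(contigs[retained, , drop = FALSE]),
    duplicates = tibble(contig_id = contigs$contig_id[!retained],
                        duplicate_of = dup_of[!retained])
  )
}

contig_kmers <- function(sequence, k = 14L) {
  n <- nchar(sequence)
  if (n < k) return(sequence)
  unique(substring(sequence, 1:(n - k + 1L), k:n))
}

# local alignment of the shorter against the longer; containment when
# identity and span-of-shorter both clear their cutoffs
is_contained <- function(short_seq, long_seq, min_identity, min_coverage) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(short_seq), Biostrings::DNAString(long_seq),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  pid <- Biostrings::pid(aln, type = "PID1")
  pat <- Biostrings::pattern(aln)
  aligned_short <- Biostrings::end(pat) - Biostrings::start(pat) + 1L
  span <- 100 * aligned_short / nchar(short_seq)
  pid >= min_identity && span >= min_coverage
}
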