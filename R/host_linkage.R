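# Phage-host linkage: three evidence routes (CRISPR protospacer, prophage
# taxonomy propagation, reference co-clustering) merged with provenance.

#' Detect CRISPR arrays in bacterial contigs (simplified)
#'
#' Finds arrays of at least `min_copies` near-identical direct repeats
#' (length `repeat_len_range`, at most one mismatch between a copy and the
#' array consensus) separated by mutually distinct spacers of length
#' `spacer_len_range`, and returns the spacers. Detection is seeded on exact
#' repeated 23-mers, so highly degenerate repeats are out of scope; the
#' downstream computation consumes spacer geometry only, not array quality
#' scores.
#'
#' @param contigs A data frame with `contig_id` and `sequence` columns.
#' @param repeat_len_range Repeat length bounds in bp (default 23-55).
#' @param spacer_len_range Spacer length bounds in bp (default 18-50).
#' @param min_copies Minimum repeat copies (default 3).
#' @return A tibble of spacer records: `host_contig_id`, `array_id`,
#'   `spacer_id`, `spacer_seq`, `repeat_seq`, `start`, `end` (0-based
#'   half-open spacer coordinates).
#' @export
detect_crispr_arrays <- function(contigs,
                                 repeat_len_range = c(23, 55),
                                 spacer_len_range = c(18, 50),
                                 min_copies = 3) {
  vp_assert_fields(contigs, c("contig_id", "sequence"), "`contigs`")
  out <- purrr::map2(contigs$contig_id, contigs$sequence, function(id, seq) {
    arrays <- find_arrays_one(seq, repeat_len_range, spacer_len_range,
                              min_copies)
    if (length(arrays) == 0) return(NULL)
    bind_rows(purrr::imap(arrays, function(ar, k) {
      tibble(
        host_contig_id = id,
        array_id = paste0(id, "_array", k),
        spacer_id = paste0(id, "_array", k, "_sp", seq_len(nrow(ar$spacers))),
        spacer_seq = ar$spacers$seq,
        repeat_seq = ar$repeat_seq,
        start = ar$spacers$start,
        end = ar$spacers$end
      )
    }))
  })
  out <- purrr::compact(out)
  if (length(out) == 0) {
    return(tibble(host_contig_id = character(0), array_id = character(0),
                  spacer_id = character(0), spacer_seq = character(0),
                  repeat_seq = character(0), start = integer(0),
                  end = integer(0)))
  }
  bind_rows(out)
}

# seed on exact 23-mers occurring >= min_copies times with plausible
# spacing, then extend to the full repeat and cut out the spacers
find_arrays_one <- function(seq, repeat_len_range, spacer_len_range,
                            min_copies) {
  k <- 23L
  n <- nchar(seq)
  if (n < min_copies * (k + spacer_len_range[1])) return(list())
  words <- substring(seq, 1:(n - k + 1L), k:n)
  tab <- table(words)
  seeds <- names(tab)[tab >= min_copies]
  if (length(seeds) == 0) return(list())
  arrays <- list()
  used_regions <- integer(0)
  for (w in seeds) {
    pos <- which(words == w)                 # 1-based start positions
    # keep runs whose consecutive spacing fits repeat + spacer geometry
    gaps <- diff(pos)
    lo <- k + spacer_len_range[1]
    hi <- repeat_len_range[2] + spacer_len_range[2]
    ok_run <- split_runs(pos, gaps >= lo & gaps <= hi)
    for (run in ok_run) {
      if (length(run) < min_copies) next
      if (any(run %in% used_regions)) next
      ar <- extend_array(seq, run, k, repeat_len_range, spacer_len_range,
                         min_copies)
      if (is.null(ar)) next
      arrays[[length(arrays) + 1L]] <- ar
      # mark the full extended repeat copies so seeds at other offsets
      # within the same repeat cannot re-report the array
      used_regions <- c(used_regions,
                        unlist(lapply(ar$repeat_starts, function(p) {
                          p:(p + nchar(ar$repeat_seq) - 1L)
                        })))
    }
  }
  arrays
}

split_runs <- function(pos, keep_gap) {
  if (length(pos) == 1) return(list(pos))
  breaks <- c(0, which(!keep_gap), length(pos))
  runs <- list()
  for (i in seq_len(length(breaks) - 1L)) {
    run <- pos[(breaks[i] + 1L):breaks[i + 1L]]
    runs[[i]] <- run
  }
  runs
}

extend_array <- function(seq, starts, k, repeat_len_range,
                         spacer_len_range, min_copies) {
  n <- nchar(seq)
  len <- k
  max_len <- repeat_len_range[2]
  # extend left while all copies agree (the seed may start mid-repeat)
  while (len < max_len && starts[1] > 1) {
    prev <- substring(seq, starts - 1L, starts - 1L)
    if (length(unique(prev)) == 1) {
      starts <- starts - 1L
      len <- len + 1L
    } else break
  }
  # extend right while all copies still agree with the first copy
  gap_min <- min(diff(starts))
  while (len < max_len && len < gap_min) {
    nxt <- substr(seq, starts[1], starts[1] + len)
    if (all(substring(seq, starts, starts + len) == nxt) &&
        starts[length(starts)] + len <= n) {
      len <- len + 1L
    } else break
  }
  if (len < repeat_len_range[1]) return(NULL)
  repeat_seq <- substr(seq, starts[1], starts[1] + len - 1L)
  # tolerate <= 1 mismatch of each copy against the consensus (first copy)
  copies <- substring(seq, starts, starts + len - 1L)
  mm <- vapply(copies, function(cp) hamming_dist(cp, repeat_seq),
               integer(1))
  keep <- mm <= 1
  starts <- starts[keep]
  if (length(starts) < min_copies) return(NULL)
  sp_start <- starts[-length(starts)] + len      # 1-based
  sp_end <- starts[-1] - 1L
  sp_len <- sp_end - sp_start + 1L
  ok <- sp_len >= spacer_len_range[1] & sp_len <= spacer_len_range[2]
  if (sum(ok) == 0) return(NULL)
  spacers <- tibble(
    seq = substring(seq, sp_start[ok], sp_end[ok]),
    start = sp_start[ok] - 1L,                   # to 0-based half-open
    end = sp_end[ok]
  )
  if (anyDuplicated(spacers$seq)) {
    spacers <- spacers[!duplicated(spacers$seq), , drop = FALSE]
  }
  if (nrow(spacers) == 0) return(NULL)
  list(repeat_seq = repeat_seq, spacers = spacers, repeat_starts = starts)
}

hamming_dist <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Match CRISPR spacers against phage contigs (protospacer search)
#'
#' Reports every position on either strand where a spacer matches a contig
#' with at most `max_mismatches` substitutions (Hamming distance; indels are
#' not considered, matching short protospacer practice). The default
#' tolerance of 1 reads the convention "hits with less than 2 mismatches are
#' valid" literally.
#'
#' @param spacers A data frame with `spacer_id`, `spacer_seq` columns.
#' @param contigs A data frame with `contig_id`, `sequence` columns.
#' @param max_mismatches Maximum substitutions (default 1).
#' @return A tibble `spacer_id`, `contig_id`, `start`, `end` (0-based
#'   half-open on the forward strand), `strand` ("+"/"-"), `mismatches`.
#' @export
match_protospacers <- function(spacers, contigs, max_mismatches = 1) {
  vp_assert_fields(spacers, c("spacer_id", "spacer_seq"), "`spacers`")
  vp_assert_fields(contigs, c("contig_id", "sequence"), "`contigs`")
  vp_assert(all(grepl("^[ACGT]+$", spacers$spacer_seq)),
            "spacers must be non-empty ACGT sequences")
  short <- nchar(spacers$spacer_seq) < 18
  if (any(short)) {
    rlang::warn(sprintf("%d spacer(s) shorter than 18 nt; still searched",
                        sum(short)))
  }
  subjects <- Biostrings::DNAStringSet(setNames(contigs$sequence,
                                                contigs$contig_id))
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$spacer_seq[i]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") Biostrings::DNAString(sp) else
        Biostrings::reverseComplement(Biostrings::DNAString(sp))
      hits <- Biostrings::vmatchPattern(pat, subjects,
                                        max.mismatch = max_mismatches,
                                        with.indels = FALSE)
      for (ci in seq_along(hits)) {
        h <- hits[[ci]]
        if (length(h) == 0) next
        s1 <- Biostrings::start(h)
        e1 <- Biostrings::end(h)
        keep <- s1 >= 1 & e1 <= nchar(contigs$sequence[ci])
        if (!any(keep)) next
        s1 <- s1[keep]; e1 <- e1[keep]
        mm <- vapply(seq_along(s1), function(j) {
          hamming_dist(substr(contigs$sequence[ci], s1[j], e1[j]),
                       as.character(pat))
        }, integer(1))
        out[[length(out) + 1L]] <- tibble(
          spacer_id = spacers$spacer_id[i],
          contig_id = contigs$contig_id[ci],
          start = s1 - 1L, end = e1,
          strand = strand, mismatches = mm
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(spacer_id = character(0), contig_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  bind_rows(out) |> arrange(spacer_id, contig_id, start, strand)
}

#' VC-host links from CRISPR protospacer hits
#'
#' Joins protospacer hits to the spacers' source taxa and the target
#' contigs' VCs, yielding one prediction per (VC, taxon) with
#' route = "spacer".
#'
#' @param hits Output of [match_protospacers()].
#' @param spacer_taxa A data frame `spacer_id`, `taxon`, `rank`, `phylum`.
#' @param vcs A data frame `contig_id`, `vc_id`.
#' @return A host-prediction tibble `vc_id`, `taxon`, `rank`, `phylum`,
#'   `route`, `evidence_ids`.
#' @export
spacer_vc_links <- function(hits, spacer_taxa, vcs) {
  vp_assert_fields(spacer_taxa, c("spacer_id", "taxon", "rank", "phylum"),
                   "`spacer_taxa`")
  hits |>
    left_join(spacer_taxa, by = "spacer_id") |>
    left_join(vcs |> select(contig_id, vc_id), by = "contig_id") |>
    filter(!is.na(vc_id), !is.na(taxon)) |>
    group_by(vc_id, taxon, rank, phylum) |>
    summarise(route = "spacer",
              evidence_ids = paste(sort(unique(spacer_id)), collapse = ","),
              .groups = "drop")
}

#' VC-host links from prophage-carrying bacterial contigs
#'
#' Every VC that contains a prophage-flagged contig inherits that contig's
#' bacterial taxon, with route = "prophage".
#'
#' @param vcs A data frame `contig_id`, `vc_id` over phage contigs.
#' @param prophage_taxa A data frame `contig_id`, `taxon`, `rank`, `phylum`
#'   for prophage contigs with a bacterial annotation.
#' @return A host-prediction tibble (same shape as [spacer_vc_links()]).
#' @export
prophage_vc_links <- function(vcs, prophage_taxa) {
  vp_assert_fields(prophage_taxa, c("contig_id", "taxon", "rank", "phylum"),
                   "`prophage_taxa`")
  prophage_taxa |>
    left_join(vcs |> select(contig_id, vc_id), by = "contig_id") |>
    filter(!is.na(vc_id)) |>
    group_by(vc_id, taxon, rank, phylum) |>
    summarise(route = "prophage",
              evidence_ids = paste(sort(unique(contig_id)), collapse = ","),
              .groups = "drop")
}

#' VC-host links from co-clustered reference phages
#'
#' A VC containing characterized reference phages is linked to a host
#' family only when all its references infect hosts within the same
#' bacterial family (unanimity rule); split references yield no link.
#' This route emits family-rank predictions only.
#'
#' @param vcs A data frame `contig_id`, `vc_id` covering reference genomes
#'   clustered together with cohort contigs.
#' @param reference_hosts A data frame `contig_id`, `host_family`, `phylum`
#'   for reference genomes with known hosts.
#' @return A host-prediction tibble (route = "reference").
#' @export
refseq_cocluster_links <- function(vcs, reference_hosts) {
  vp_assert_fields(reference_hosts, c("contig_id", "host_family", "phylum"),
                   "`reference_hosts`")
  joined <- reference_hosts |>
    left_join(vcs |> select(contig_id, vc_id), by = "contig_id") |>
    filter(!is.na(vc_id))
  joined |>
    group_by(vc_id) |>
    filter(dplyr::n_distinct(host_family) == 1) |>
    summarise(
      taxon = host_family[1], rank = "family", phylum = phylum[1],
      route = "reference",
      evidence_ids = paste(sort(unique(contig_id)), collapse = ","),
      .groups = "drop"
    )
}

#' Merge host predictions across evidence routes
#'
#' Takes the union of predictions, deduplicated by (VC, taxon, rank) with
#' routes concatenated, and flags VCs whose predictions span more than one
#' bacterial phylum.
#'
#' @param ... Host-prediction tibbles (from the three link routes), or a
#'   single list of them.
#' @return A tibble `vc_id`, `taxon`, `rank`, `phylum`, `route`,
#'   `evidence_ids`, `multi_phylum`.
#' @export
merge_host_predictions <- function(...) {
  preds <- list(...)
  if (length(preds) == 1 && is.list(preds[[1]]) &&
      !is.data.frame(preds[[1]])) {
    preds <- preds[[1]]
  }
  preds <- purrr::compact(preds)
  if (length(preds) == 0 || sum(vapply(preds, nrow, 1L)) == 0) {
    return(tibble(vc_id = character(0), taxon = character(0),
                  rank = character(0), phylum = character(0),
                  route = character(0), evidence_ids = character(0),
                  multi_phylum = logical(0)))
  }
  merged <- bind_rows(preds) |>
    group_by(vc_id, taxon, rank) |>
    summarise(
      phylum = phylum[1],
      route = paste(sort(unique(route)), collapse = ";"),
      evidence_ids = paste(sort(unique(unlist(
        strsplit(evidence_ids, ",", fixed = TRUE)))), collapse = ","),
      .groups = "drop"
    )
  merged |>
    group_by(vc_id) |>
    mutate(multi_phylum =
             dplyr::n_distinct(phylum[!is.na(phylum)]) > 1) |>
    ungroup() |>
    arrange(vc_id, taxon)
}
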