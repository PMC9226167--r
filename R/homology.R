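#' Protein homology scoring parameters
#'
#' Standard protein-search defaults: BLOSUM62 with gap open 11 / extend 1,
#' and ungapped Karlin-Altschul constants lambda = 0.267 nats per score unit
#' and K = 0.041 for converting raw Smith-Waterman scores to bit scores.
#' Exact bit scores from heuristic search engines are not reproduced; only
#' the >= `bit_threshold` decision on homologous versus unrelated pairs is
#' promised.
#'
#' @param matrix Substitution matrix name (only "BLOSUM62" is shipped).
#' @param gap_open,gap_extend Gap penalties in score units.
#' @param lambda,K Karlin-Altschul constants for the bit conversion.
#' @param bit_threshold Minimum bit score for a reported hit.
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041,
                           bit_threshold = 50) {
  vp_assert(lambda > 0, "`lambda` must be > 0")
  vp_assert(K > 0, "`K` must be > 0")
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, K = K, bit_threshold = bit_threshold),
    class = "scoring_params"
  )
}

#' Convert a raw alignment score to bits
#'
#' `bits = (lambda * raw - ln K) / ln 2`. The conversion is invertible; see
#' [raw_from_bits()].
#'
#' @param raw Raw score in score units.
#' @param params A [scoring_params()] object.
#' @return Bit score(s).
#' @export
bits_from_raw <- function(raw, params = scoring_params()) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' @rdname bits_from_raw
#' @param bits Bit score(s).
#' @export
raw_from_bits <- function(bits, params = scoring_params()) {
  (bits * log(2) + log(params$K)) / params$lambda
}

substitution_matrix <- function(params) {
  vp_assert(params$matrix == "BLOSUM62",
            "only the BLOSUM62 substitution matrix is shipped")
  get_blosum62()
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

validate_protein <- function(seq, what = "sequence") {
  vp_assert(nzchar(seq), sprintf("%s must be non-empty", what))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    rlang::abort(sprintf("invalid residue '%s' at position %d in %s",
                         chars[bad[1]], bad[1], what))
  }
  invisible(TRUE)
}

#' Score homology between two proteins
#'
#' Local (Smith-Waterman) alignment under [scoring_params()], with the raw
#' score converted to bits. A hit is returned only when the bit score clears
#' `params$bit_threshold`; otherwise `NULL`.
#'
#' @param query,subject Amino-acid sequence strings (20-letter alphabet).
#' @param params A [scoring_params()] object.
#' @param query_id,subject_id Optional ids carried into the hit.
#' @return A one-row tibble (`query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `alignment_length`) or `NULL` when below threshold.
#' @export
score_homology <- function(query, subject, params = scoring_params(),
                           query_id = "query", subject_id = "subject") {
  validate_protein(query, "`query`")
  validate_protein(subject, "`subject`")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  raw <- Biostrings::score(aln)
  bits <- bits_from_raw(raw, params)
  if (bits < params$bit_threshold) return(NULL)
  tibble(
    query_id = query_id, subject_id = subject_id,
    raw_score = raw, bit_score = bits,
    alignment_length = nchar(as.character(Biostrings::pattern(aln)))
  )
}

#' All-versus-all protein homology search
#'
#' Scores unordered pairs of proteins by local alignment and reports the
#' pairs whose bit score clears the threshold. With `prefilter = TRUE`
#' (the default) candidate pairs are first screened for at least one shared
#' amino-acid 5-mer -- a standard seeding heuristic that discards the vast
#' majority of unrelated pairs while retaining essentially all pairs capable
#' of reaching 50 bits; `prefilter = FALSE` aligns every pair exhaustively.
#' Scores are symmetric, so each pair is computed once and reported in both
#' orientations when `symmetric = TRUE`.
#'
#' @param proteins A data frame with columns `protein_id` and `sequence`.
#' @param params A [scoring_params()] object.
#' @param symmetric Report each passing pair in both orientations.
#' @param prefilter Screen candidate pairs by shared k-mers first.
#' @param prefilter_k K-mer size for the screen (default 5).
#' @return A tibble of hits: `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`.
#' @export
homology_search <- function(proteins, params = scoring_params(),
                            symmetric = TRUE, prefilter = TRUE,
                            prefilter_k = 5L) {
  vp_assert_fields(proteins, c("protein_id", "sequence"), "`proteins`")
  vp_assert(!anyDuplicated(proteins$protein_id),
            "duplicate `protein_id` values")
  n <- nrow(proteins)
  if (n < 2) {
    return(tibble(query_id = character(0), subject_id = character(0),
                  raw_score = numeric(0), bit_score = numeric(0)))
  }
  for (i in seq_len(n)) validate_protein(proteins$sequence[i],
                                         proteins$protein_id[i])
  seqs <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                           proteins$protein_id))
  mat <- substitution_matrix(params)
  cand <- if (prefilter) {
    kmer_candidate_pairs(proteins$sequence, prefilter_k)
  } else NULL
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    idx <- if (is.null(cand)) seq.int(i + 1L, n) else {
      j <- cand[[i]]
      j[j > i]
    }
    if (length(idx) == 0) next
    raw <- Biostrings::pairwiseAlignment(
      seqs[idx], seqs[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE
    )
    bits <- bits_from_raw(raw, params)
    pass <- bits >= params$bit_threshold
    if (any(pass)) {
      out[[i]] <- tibble(
        query_id = proteins$protein_id[i],
        subject_id = proteins$protein_id[idx[pass]],
        raw_score = raw[pass], bit_score = bits[pass]
      )
    }
  }
  hits <- bind_rows(out)
  if (symmetric && nrow(hits) > 0) {
    hits <- bind_rows(
      hits,
      hits |> rename(query_id = subject_id, subject_id = query_id)
    ) |> arrange(query_id, subject_id)
  }
  hits
}

# inverted 5-mer index -> list of candidate partner indices per protein
kmer_candidate_pairs <- function(seqs, k) {
  n <- length(seqs)
  nk <- nchar(seqs) - k + 1L
  kmers <- lapply(seq_len(n), function(i) {
    if (nk[i] < 1) return(character(0))
    unique(substring(seqs[i], 1:nk[i], k:(nk[i] + k - 1L)))
  })
  prot_idx <- rep.int(seq_len(n), lengths(kmers))
  by_kmer <- split(prot_idx, unlist(kmers))
  by_kmer <- by_kmer[lengths(by_kmer) > 1]
  partners <- vector("list", n)
  for (grp in by_kmer) {
    for (i in grp) partners[[i]] <- c(partners[[i]], grp)
  }
  lapply(seq_len(n), function(i) {
    p <- unique(partners[[i]])
    p[p != i]
  })
}

#' Form protein clusters (PCs) from thresholded homology hits
#'
#' PCs are the connected components of the hit graph at the bit-score
#' threshold. Every protein in `protein_ids` belongs to exactly one PC;
#' proteins without hits become singleton PCs. PC ids are deterministic:
#' each cluster is named after its lexicographically smallest member.
#'
#' @param hits A data frame of hits (`query_id`, `subject_id`), already
#'   thresholded.
#' @param protein_ids Character vector of all protein ids (the PC universe);
#'   defaults to the ids present in `hits`.
#' @return A tibble `protein_id`, `pc_id`.
#' @export
build_protein_clusters <- function(hits, protein_ids = NULL) {
  ids <- protein_ids %||% unique(c(hits$query_id, hits$subject_id))
  ids <- sort(unique(ids))
  if (length(ids) == 0) {
    return(tibble(protein_id = character(0), pc_id = character(0)))
  }
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(hits) > 0) {
    keep <- hits$query_id != hits$subject_id
    if (any(keep)) {
      a <- pmin(hits$query_id[keep], hits$subject_id[keep])
      b <- pmax(hits$query_id[keep], hits$subject_id[keep])
      pairs <- unique(paste(a, b, sep = "\r"))
      ab <- strsplit(pairs, "\r", fixed = TRUE)
      g <- igraph::add_edges(
        g, rbind(match(vapply(ab, `[`, "", 1), ids),
                 match(vapply(ab, `[`, "", 2), ids))
      )
    }
  }
  comp <- igraph::components(g)$membership
  smallest <- tapply(ids, comp, min)
  tibble(
    protein_id = ids,
    pc_id = paste0("PC_", smallest[as.character(comp[ids])])
  ) |> arrange(protein_id)
}
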