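#' Default scanning parameters
#'
#' Seed-and-extend settings for the hallmark homology scan: seed length `k`,
#' identity and length cut-offs for reported hits, and local-alignment
#' scores. The permissive identity default (60%) admits strongly diverged
#' hallmark copies (such as the SIDER1-beta class) while keeping the
#' empirical false-positive rate on i.i.d. sequence below 1e-4 per kb; the
#' cut-offs are exposed so users can tighten them.
#'
#' @param k seed length in nt (exact-match seeding; must be >= 6).
#' @param min_identity minimum percent identity (matches / aligned columns).
#' @param min_length minimum aligned length on the genome, nt.
#' @param match,mismatch,gap alignment scores (`match > 0 > mismatch, gap`).
#' @return a named list of parameters.
#' @export
scan_params <- function(k = 11L, min_identity = 60, min_length = 50L,
                        match = 1L, mismatch = -1L, gap = -2L) {
  if (k < 6L) abort("seed length k < 6 makes seeding degenerate")
  if (!(match > 0 && mismatch < 0 && gap < 0))
    abort("scores must satisfy match > 0 > mismatch, gap")
  list(k = as.integer(k), min_identity = min_identity,
       min_length = as.integer(min_length),
       match = as.integer(match), mismatch = as.integer(mismatch),
       gap = as.integer(gap))
}

empty_hits <- function() {
  tibble(contig = character(), start = integer(), end = integer(),
         strand = character(), identity = numeric(), score = integer(),
         query_id = character(), n_aligned = integer())
}

#' Scan a genome for hallmark-like signatures
#'
#' Seed-and-extend local alignment of a hallmark query (the 77-nt Pr77
#' consensus, or any 40-200 nt probe) against both strands of a genome.
#' Exact `k`-mer seed matches (IUPAC codes in the query match any contained
#' base; N in the genome matches nothing) are extended by Smith-Waterman
#' alignment in a window around each seed cluster; maximal local alignments
#' passing the identity and length cut-offs are reported. Overlapping
#' same-strand hits are merged keeping the higher score.
#'
#' @param genome genome sequences (named character vector, `DNAStringSet`,
#'   or FASTA path); see [as_genome()].
#' @param query a single query sequence (string, optionally named) or a
#'   named character vector of length 1; IUPAC ambiguity codes allowed.
#' @param params scanning parameters from [scan_params()].
#' @param query_id label recorded in the `query_id` column.
#' @return tibble of hits with columns `contig`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `identity` (percent), `score`,
#'   `query_id`, `n_aligned`, sorted by (contig, start).
#' @examples
#' g <- c(chr1 = paste(rep("ACGT", 30), collapse = ""))
#' scan_genome(g, "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
#'             scan_params(min_length = 40))
#' @export
scan_genome <- function(genome, query, params = scan_params(),
                        query_id = NULL) {
  genome <- as_genome(genome)
  if (is.null(query_id))
    query_id <- if (!is.null(names(query)) && nzchar(names(query)[[1]]))
      names(query)[[1]] else "query"
  query <- normalize_seq(unname(query[[1]]), "query")
  qlen <- nchar(query)
  if (params$k > qlen) abort("seed length k exceeds query length")
  hits <- list()
  for (contig in names(genome)) {
    subj <- genome[[contig]]
    smask <- iupac_mask(seq_chars(subj), subject = TRUE)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else revcomp(query)
      hs <- scan_one_strand(q, subj, smask, params)
      if (nrow(hs)) {
        hs$contig <- contig
        hs$strand <- strand
        hits[[length(hits) + 1L]] <- hs
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- dplyr::bind_rows(hits)
  out$query_id <- query_id
  out <- merge_overlapping_hits(out)
  dplyr::arrange(out, .data$contig, .data$start)[
    , c("contig", "start", "end", "strand", "identity", "score",
        "query_id", "n_aligned")]
}

# seed, window, extend on the forward coordinates of `subj` with query `q`
# (already reverse-complemented for minus-strand scans)
scan_one_strand <- function(q, subj, smask, params) {
  qlen <- nchar(q)
  slen <- nchar(subj)
  subj_x <- Biostrings::DNAString(subj)
  starts <- integer()
  for (pos in seq_len(qlen - params$k + 1L)) {
    kmer <- substr(q, pos, pos + params$k - 1L)
    if (grepl("N", kmer, fixed = TRUE)) next
    mt <- Biostrings::matchPattern(Biostrings::DNAString(kmer), subj_x,
                                   fixed = "subject")
    if (length(mt))
      starts <- c(starts, Biostrings::start(mt) - 1L - (pos - 1L))
  }
  if (!length(starts)) {
    return(tibble(start = integer(), end = integer(), identity = numeric(),
                  score = integer(), n_aligned = integer()))
  }
  margin <- 25L
  win <- IRanges::reduce(IRanges::IRanges(
    start = pmax(1L, starts + 1L - margin),
    end = pmin(slen, starts + qlen + margin)))
  qmask <- iupac_mask(seq_chars(q))
  res <- list()
  for (w in seq_along(win)) {
    w0 <- IRanges::start(win)[w] - 1L           # 0-based window offset
    wmask <- smask[IRanges::start(win)[w]:IRanges::end(win)[w]]
    for (iter in 1:8) {
      al <- sw_align(qmask, wmask, params$match, params$mismatch, params$gap)
      if (is.null(al)) break
      ok <- al$identity >= params$min_identity &&
        (al$s_end - al$s_start) >= params$min_length
      if (ok)
        res[[length(res) + 1L]] <- tibble(
          start = w0 + al$s_start, end = w0 + al$s_end,
          identity = al$identity, score = al$score, n_aligned = al$n_cols)
      # mask the aligned region and look for further (e.g. tandem) copies
      wmask[(al$s_start + 1L):al$s_end] <- 0L
      if (!ok) break
    }
  }
  dplyr::bind_rows(res)
}

# drop the lower-scoring hit of any same-contig same-strand overlapping pair
merge_overlapping_hits <- function(hits) {
  hits <- dplyr::arrange(hits, .data$contig, .data$strand,
                         dplyr::desc(.data$score), .data$start)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i == nrow(hits)) break
    for (j in (i + 1L):nrow(hits)) {
      if (!keep[j]) next
      if (hits$contig[j] != hits$contig[i] ||
          hits$strand[j] != hits$strand[i]) next
      if (hits$start[j] < hits$end[i] && hits$start[i] < hits$end[j])
        keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Iterative hallmark screen with hit-derived queries
#'
#' Re-screens the genome with the sequences of newly found hits as
#' additional queries, so that copies too diverged from the original
#' consensus are still recovered through intermediate homologues. Rounds
#' stop when no new hit (deduplicated by coordinates: same contig and
#' strand, reciprocal overlap >= 80%) appears or `max_rounds` is reached.
#'
#' @param genome see [scan_genome()].
#' @param queries named character vector of initial query sequences.
#' @param params scanning parameters from [scan_params()].
#' @param max_rounds maximum number of screening rounds (>= 1).
#' @return tibble of hits as in [scan_genome()]; a superset of the
#'   first-round hit set.
#' @export
iterative_scan <- function(genome, queries, params = scan_params(),
                           max_rounds = 5L) {
  if (max_rounds < 1L) abort("max_rounds must be >= 1")
  genome <- as_genome(genome)
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  acc <- empty_hits()
  new_queries <- queries
  seen_query_seqs <- character()
  for (round in seq_len(max_rounds)) {
    round_hits <- purrr::imap(as.list(new_queries), function(q, id) {
      scan_genome(genome, q, params, query_id = id)
    })
    round_hits <- dplyr::bind_rows(round_hits)
    fresh <- hit_setdiff(round_hits, acc)
    acc <- merge_overlapping_hits(dplyr::bind_rows(acc, fresh))
    if (!nrow(fresh) || round == max_rounds) break
    qs <- hit_sequences(genome, fresh)
    qs <- qs[!(unname(qs) %in% seen_query_seqs)]
    qs <- qs[!duplicated(unname(qs))]
    seen_query_seqs <- c(seen_query_seqs, unname(qs))
    if (!length(qs)) break
    new_queries <- qs
  }
  dplyr::arrange(acc, .data$contig, .data$start)
}

# hits in `x` that do not duplicate (reciprocal overlap >= 0.8, same contig
# and strand) any hit in `ref`
hit_setdiff <- function(x, ref, min_reciprocal = 0.8) {
  if (!nrow(x)) return(x)
  x <- merge_overlapping_hits(x)
  if (!nrow(ref)) return(x)
  keep <- vapply(seq_len(nrow(x)), function(i) {
    same <- ref$contig == x$contig[i] & ref$strand == x$strand[i]
    if (!any(same)) return(TRUE)
    ov <- pmin(ref$end[same], x$end[i]) - pmax(ref$start[same], x$start[i])
    len_x <- x$end[i] - x$start[i]
    len_r <- ref$end[same] - ref$start[same]
    !any(ov > 0 & ov / len_x >= min_reciprocal & ov / len_r >= min_reciprocal)
  }, logical(1))
  x[keep, , drop = FALSE]
}

# element-strand sequences of hits, used as next-round queries
hit_sequences <- function(genome, hits) {
  purrr::map_chr(seq_len(nrow(hits)), function(i) {
    s <- substr(genome[[hits$contig[i]]], hits$start[i] + 1L, hits$end[i])
    if (hits$strand[i] == "-") revcomp(s) else s
  }) |>
    setNames(sprintf("hit:%s:%d-%d(%s)", hits$contig, hits$start,
                     hits$end, hits$strand))
}
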