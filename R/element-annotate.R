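# Mobile-element context filters around hallmark hits — downstream poly-A
# tracks at the short (~0.6 kb) or long (5-6 kb) distance, 7-11 nt
# target-site duplications at the element boundaries — and classification
# of loci as SIDER1, SIDER2, DIRE-like LINE or NAR-like short elements.

#' Poly-A search configuration
#'
#' Distance windows are measured from the hallmark 3' end to the track
#' start, on the element strand. The short window (300-1000 nt) captures
#' short-element architectures with the poly-A roughly 0.6 kb downstream;
#' the long window (4500-6500 nt) captures full-length LINE/DIRE
#' architectures. A track is a maximal run of >= `min_run` nt with
#' A-fraction >= `purity`, flanked by non-A.
#'
#' @param short_window,long_window distance windows, nt.
#' @param min_run minimum track length, nt.
#' @param purity minimum A fraction of a track.
#' @return named list.
#' @export
polya_config <- function(short_window = c(300L, 1000L),
                         long_window = c(4500L, 6500L),
                         min_run = 10L, purity = 0.9) {
  stopifnot(short_window[1] < short_window[2],
            long_window[1] < long_window[2],
            min_run >= 2L, purity > 0.5, purity <= 1)
  list(short_window = short_window, long_window = long_window,
       min_run = as.integer(min_run), purity = purity)
}

#' TSD search configuration
#'
#' @param len_range TSD lengths to try, nt (searched longest first).
#' @param max_offset boundary slack allowed on each side, nt.
#' @param min_identity_pct minimum percent identity between the two copies.
#' @param min_matches minimum matching positions.
#' @return named list.
#' @export
tsd_config <- function(len_range = c(7L, 11L), max_offset = 5L,
                       min_identity_pct = 80, min_matches = 7L) {
  stopifnot(len_range[1] >= 4L, len_range[1] <= len_range[2],
            max_offset >= 0L)
  list(len_range = as.integer(len_range), max_offset = as.integer(max_offset),
       min_identity_pct = min_identity_pct, min_matches = as.integer(min_matches))
}

# maximal >=purity A-runs (or T-runs) in a character window; returns
# 0-based half-open offsets within the window
maximal_base_runs <- function(chars, base, min_run, purity) {
  is_b <- chars == base
  r <- rle(is_b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(runs)) return(tibble(start = integer(), end = integer(),
                                 a_fraction = numeric()))
  nb <- function(s, e) sum(is_b[s:e])
  # join neighbouring substantial runs (>= 3 nt each) across short
  # impurities while the combined fraction stays above the purity floor;
  # stray single bases are never absorbed, so a clean planted tail keeps
  # fraction 1
  repeat {
    if (nrow(runs) < 2L) break
    len <- runs$end - runs$start + 1L
    frac <- vapply(seq_len(nrow(runs) - 1L), function(i) {
      if (len[i] < 3L || len[i + 1L] < 3L) return(0)
      nb(runs$start[i], runs$end[i + 1L]) /
        (runs$end[i + 1L] - runs$start[i] + 1L)
    }, 1)
    i <- which.max(frac)
    if (frac[i] < purity) break
    runs$end[i] <- runs$end[i + 1L]
    runs <- runs[-(i + 1L), , drop = FALSE]
  }
  frac <- vapply(seq_len(nrow(runs)),
                 function(i) nb(runs$start[i], runs$end[i]) /
                   (runs$end[i] - runs$start[i] + 1L), 1)
  len <- runs$end - runs$start + 1L
  keep <- len >= min_run & frac >= purity
  tibble(start = runs$start[keep] - 1L, end = runs$end[keep],
         a_fraction = frac[keep])
}

#' Find downstream poly-A tracks for a hallmark hit
#'
#' Scans the strand-aware downstream windows for maximal poly-A runs. On
#' the minus strand the element's poly-A appears as a T-run upstream of
#' the hit in forward coordinates. Windows extending beyond the contig are
#' truncated with a warning.
#'
#' @param genome see [as_genome()].
#' @param hallmark one hit (list or single tibble row with `contig`,
#'   `start`, `end`, `strand`).
#' @param config from [polya_config()].
#' @return tibble with columns `start`, `end` (0-based half-open, forward
#'   strand), `a_fraction`, `window_class` (`SHORT`/`LONG`), `distance`
#'   (hallmark 3' end to track start, element strand).
#' @export
find_polyA <- function(genome, hallmark, config = polya_config()) {
  genome <- as_genome(genome)
  contig <- genome[[hallmark$contig]]
  if (is.null(contig)) abort("hallmark contig not in genome")
  L <- nchar(contig)
  if (hallmark$start < 0 || hallmark$end > L) abort("hallmark outside contig")
  reach <- config$long_window[2] + 50L
  if (hallmark$strand == "+") {
    he <- hallmark$end                      # 0-based hallmark 3' end
    lo <- he; hi <- min(L, he + reach)
    if (he + reach > L) warn("poly-A window truncated at contig end")
    runs <- maximal_base_runs(seq_chars(substr(contig, lo + 1L, hi)), "A",
                              config$min_run, config$purity)
    runs$start <- runs$start + lo; runs$end <- runs$end + lo
    runs$distance <- runs$start - he
  } else {
    hs <- hallmark$start
    lo <- max(0L, hs - reach); hi <- hs
    if (hs - reach < 0L) warn("poly-A window truncated at contig start")
    runs <- maximal_base_runs(seq_chars(substr(contig, lo + 1L, hi)), "T",
                              config$min_run, config$purity)
    runs$start <- runs$start + lo; runs$end <- runs$end + lo
    runs$distance <- hs - runs$end
  }
  wc <- dplyr::case_when(
    runs$distance >= config$short_window[1] &
      runs$distance <= config$short_window[2] ~ "SHORT",
    runs$distance >= config$long_window[1] &
      runs$distance <= config$long_window[2] ~ "LONG",
    TRUE ~ NA_character_)
  runs$window_class <- wc
  runs[!is.na(wc), c("start", "end", "a_fraction", "window_class", "distance")]
}

empty_tsd <- function() {
  tibble(length = integer(), left_start = integer(), right_start = integer(),
         left_seq = character(), right_seq = character(),
         identity = numeric(), off_left = integer(), off_right = integer())
}

#' Find a target-site duplication flanking an element span
#'
#' Compares the L-mer ending at the element 5' boundary with the L-mer
#' starting after the element 3' end (the poly-A end), for L from the top
#' of `len_range` down and boundary offsets up to `max_offset` on each
#' side. Accepts partial conservation (identity and match-count
#' thresholds); ties break to the longest L, then the highest identity,
#' then the smallest total offset.
#'
#' @param genome see [as_genome()].
#' @param element_span list or one-row tibble with `contig`, `start`,
#'   `end` (0-based half-open, forward strand).
#' @param config from [tsd_config()].
#' @return one-row tibble (`length`, `left_start`, `right_start`,
#'   `left_seq`, `right_seq`, `identity`, `off_left`, `off_right`) or a
#'   zero-row tibble when no acceptable duplication exists.
#' @export
find_TSD <- function(genome, element_span, config = tsd_config()) {
  genome <- as_genome(genome)
  contig <- genome[[element_span$contig]]
  s <- element_span$start; e <- element_span$end
  Lmax <- config$len_range[2]
  need <- Lmax + config$max_offset
  if (s < 15L || nchar(contig) - e < 15L) {
    warn("insufficient flank for TSD search")
    return(empty_tsd())
  }
  chars <- seq_chars(contig)
  best <- NULL
  for (L in rev(seq.int(config$len_range[1], config$len_range[2]))) {
    cands <- list()
    for (off_l in 0:config$max_offset) for (off_r in 0:config$max_offset) {
      ls <- s - off_l - L; rs <- e + off_r        # 0-based starts
      if (ls < 0L || rs + L > length(chars)) next
      lv <- chars[(ls + 1L):(ls + L)]; rv <- chars[(rs + 1L):(rs + L)]
      m <- sum(lv == rv & lv %in% c("A", "C", "G", "T"))
      idt <- 100 * m / L
      if (idt >= config$min_identity_pct && m >= config$min_matches)
        cands[[length(cands) + 1L]] <- tibble(
          length = L, left_start = ls, right_start = rs,
          left_seq = paste(lv, collapse = ""),
          right_seq = paste(rv, collapse = ""),
          identity = idt, off_left = off_l, off_right = off_r)
    }
    if (length(cands)) {
      cands <- dplyr::bind_rows(cands)
      cands <- cands[order(-cands$identity, cands$off_left + cands$off_right,
                           cands$off_left), ]
      best <- cands[1, ]
      break
    }
  }
  if (is.null(best)) empty_tsd() else best
}

#' Classify a hallmark locus as a mobile-element type
#'
#' Applies the annotation rules in order: (1) two tandem hallmarks
#' separated by at most `tandem_gap` are a SIDER2; (2) a span of at least
#' 4 kb from the first hallmark to the poly-A end is a DIRE-like LINE;
#' (3) a single hallmark with a short-window poly-A whose element ends
#' both align at >= 80% identity to a supplied full-length reference is a
#' NAR-like short element; (4) a single hallmark with a short-window
#' poly-A is a SIDER1; anything else is UNCLASSIFIED. A missing TSD
#' downgrades confidence to `no_tsd` without changing the class.
#'
#' @param hallmarks tibble of hits at one locus, sorted 5' to 3' on the
#'   element strand.
#' @param polya tibble of poly-A tracks ([find_polyA()]); the nearest
#'   track is used.
#' @param tsd result of [find_TSD()] (possibly zero rows).
#' @param long_ref optional reference long-element sequence for the
#'   NAR-like test.
#' @param genome required when `long_ref` is given, to extract element
#'   end regions.
#' @param tandem_gap maximum inter-hallmark gap for SIDER2, nt.
#' @return one-row tibble: `contig`, `start`, `end`, `strand`,
#'   `element_class`, `confidence`, `n_hallmarks`.
#' @export
classify_element <- function(hallmarks, polya, tsd, long_ref = NULL,
                             genome = NULL, tandem_gap = 200L) {
  if (!nrow(hallmarks)) abort("locus without hallmarks")
  strand <- hallmarks$strand[1]
  contig <- hallmarks$contig[1]
  polya <- dplyr::arrange(polya, .data$distance)
  pa <- if (nrow(polya)) polya[1, ] else NULL
  span_start <- min(hallmarks$start, if (!is.null(pa)) pa$start else Inf)
  span_end <- max(hallmarks$end, if (!is.null(pa)) pa$end else -Inf)
  confidence <- if (nrow(tsd)) "full" else "no_tsd"
  gaps <- if (nrow(hallmarks) > 1L)
    hallmarks$start[-1L] - hallmarks$end[-nrow(hallmarks)] else integer()
  cls <- if (nrow(hallmarks) == 2L && all(gaps <= tandem_gap)) {
    "SIDER2"
  } else if (!is.null(pa) && nrow(hallmarks) >= 1L &&
             (span_end - span_start) >= 4000L) {
    "LINE_DIRE"
  } else if (nrow(hallmarks) == 1L && !is.null(pa) &&
             pa$window_class == "SHORT" && !is.null(long_ref) &&
             ends_match_reference(genome, contig, strand,
                                  span_start, span_end, long_ref)) {
    "SIDE_NAR"
  } else if (nrow(hallmarks) == 1L && !is.null(pa) &&
             pa$window_class == "SHORT") {
    "SIDER1"
  } else {
    "UNCLASSIFIED"
  }
  tibble(contig = contig,
         start = as.integer(if (is.finite(span_start)) span_start
                            else min(hallmarks$start)),
         end = as.integer(if (is.finite(span_end)) span_end
                          else max(hallmarks$end)),
         strand = strand, element_class = cls, confidence = confidence,
         n_hallmarks = nrow(hallmarks))
}

# do both end regions of the element align to the reference ends at >= 80%?
ends_match_reference <- function(genome, contig, strand, start, end,
                                 long_ref, region = 150L) {
  if (is.null(genome)) return(FALSE)
  genome <- as_genome(genome)
  el <- substr(genome[[contig]], start + 1L, end)
  if (strand == "-") el <- revcomp(el)
  ref <- normalize_seq(long_ref, "long_ref")
  idt <- function(q, s) {
    al <- sw_align(iupac_mask(seq_chars(q)),
                   iupac_mask(seq_chars(s), subject = TRUE))
    if (is.null(al)) 0 else
      al$identity * min(1, (al$q_end - al$q_start) / (0.8 * nchar(q)))
  }
  head_ok <- idt(substr(el, 1L, region),
                 substr(ref, 1L, 2L * region)) >= 80
  tail_ok <- idt(substr(el, nchar(el) - region + 1L, nchar(el)),
                 substr(ref, nchar(ref) - 2L * region + 1L, nchar(ref))) >= 80
  head_ok && tail_ok
}

#' Annotation pipeline configuration
#'
#' Bundles the knobs of every annotation stage with a global RNG seed.
#'
#' @param scan [scan_params()].
#' @param descriptor [ribozyme_descriptor()].
#' @param polya [polya_config()].
#' @param tsd [tsd_config()].
#' @param tandem_gap maximum gap between tandem hallmarks, nt.
#' @param max_rounds iterative-scan rounds.
#' @param long_ref optional reference long-element sequence.
#' @param rng_seed global seed recorded in run manifests.
#' @return named list of class `annotate_config`.
#' @export
annotate_config <- function(scan = scan_params(),
                            descriptor = ribozyme_descriptor(),
                            polya = polya_config(), tsd = tsd_config(),
                            tandem_gap = 200L, max_rounds = 4L,
                            long_ref = NULL, rng_seed = 1L) {
  structure(list(scan = scan, descriptor = descriptor, polya = polya,
                 tsd = tsd, tandem_gap = as.integer(tandem_gap),
                 max_rounds = as.integer(max_rounds), long_ref = long_ref,
                 rng_seed = as.integer(rng_seed)),
            class = "annotate_config")
}

#' Annotate a genome for hallmark-bearing mobile elements
#'
#' Full screening pipeline: iterative hallmark scan, grouping of hits into
#' loci (same contig and strand, gap <= `tandem_gap`), poly-A and TSD
#' context detection, fold validation of each hallmark, and element
#' classification. A stage failure at one locus marks it UNCLASSIFIED
#' rather than aborting the run.
#'
#' @param genome see [as_genome()].
#' @param queries named character vector of hallmark query sequences.
#' @param config an [annotate_config()].
#' @return tibble with one row per locus: `locus_id`, `contig`, `start`,
#'   `end`, `strand`, `element_class`, `confidence`, `n_hallmarks`,
#'   `polya_start`, `polya_end`, `tsd_len`, `fold_passes`, plus
#'   list-columns `hallmarks`, `polya`, `tsd`, `folds`; ordered by
#'   (contig, start).
#' @export
annotate_genome <- function(genome, queries, config = annotate_config()) {
  genome <- as_genome(genome)
  if (!length(queries)) abort("at least one query is required")
  hits <- iterative_scan(genome, queries, config$scan, config$max_rounds)
  if (!nrow(hits)) return(empty_annotations())
  hits <- suppress_antisense_shadows(hits)
  # loci are built per strand: tandem signatures sit on one strand even
  # when an element on the other strand lies nearby
  hits <- dplyr::arrange(hits, .data$contig, .data$strand, .data$start)
  brk <- c(TRUE, hits$contig[-1] != hits$contig[-nrow(hits)] |
             hits$strand[-1] != hits$strand[-nrow(hits)] |
             (hits$start[-1] - hits$end[-nrow(hits)]) > config$tandem_gap)
  hits$locus <- cumsum(brk)
  loci <- split(hits, hits$locus)
  rows <- purrr::imap(loci, function(h, locus_id) {
    tryCatch(annotate_locus(genome, h, config, locus_id),
             error = function(e) unclassified_locus(h, locus_id))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$contig, .data$start)
}

# The hallmark is partially self-complementary (it is mostly helices), so
# a genuine hit often drags along a weaker antisense match over the same
# interval. Drop any hit that overlaps a strictly higher-scoring hit on
# the opposite strand by >= 50% of its own length.
suppress_antisense_shadows <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    other <- which(hits$contig == hits$contig[i] &
                     hits$strand != hits$strand[i] &
                     hits$score > hits$score[i])
    if (!length(other)) next
    ov <- pmin(hits$end[other], hits$end[i]) -
      pmax(hits$start[other], hits$start[i])
    if (any(ov >= 0.5 * (hits$end[i] - hits$start[i]))) keep[i] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

annotate_locus <- function(genome, h, config, locus_id) {
  strand <- h$strand[1]
  # hallmarks ordered 5' -> 3' on the element strand (signature I first)
  h <- if (strand == "+") dplyr::arrange(h, .data$start) else
    dplyr::arrange(h, dplyr::desc(.data$start))
  three_prime <- h[if (strand == "+") which.max(h$end) else
    which.min(h$start), ]
  polya <- find_polyA(genome, as.list(three_prime), config$polya)
  polya <- dplyr::arrange(polya, .data$distance)
  hm_fwd <- dplyr::arrange(h, .data$start)
  span_start <- min(hm_fwd$start, if (nrow(polya)) polya$start[1] else Inf)
  span_end <- max(hm_fwd$end, if (nrow(polya)) polya$end[1] else -Inf)
  tsd <- empty_tsd()
  if (nrow(polya)) {
    # the poly-A-derived boundary can overshoot the element by a few
    # background A/T residues; if the flush search fails, pull that
    # boundary in by a few nt before giving up
    for (shrink in 0:5) {
      span2 <- if (strand == "+")
        list(contig = h$contig[1], start = span_start,
             end = span_end - shrink)
      else
        list(contig = h$contig[1], start = span_start + shrink,
             end = span_end)
      tsd <- find_TSD(genome, span2, config$tsd)
      if (nrow(tsd)) break
    }
  }
  folds <- purrr::map(seq_len(nrow(h)), function(i) {
    seq <- hallmark_fold_seq(genome, h[i, ])
    tryCatch(validate_hallmark(seq, config$descriptor),
             error = function(e) list(passes = NA, violations = character(),
                                      fold = NULL))
  })
  cls <- classify_element(h, polya, tsd, long_ref = config$long_ref,
                          genome = genome, tandem_gap = config$tandem_gap)
  tibble(locus_id = sprintf("locus%03d", as.integer(locus_id)),
         contig = cls$contig, start = cls$start, end = cls$end,
         strand = cls$strand, element_class = cls$element_class,
         confidence = cls$confidence, n_hallmarks = cls$n_hallmarks,
         polya_start = if (nrow(polya)) polya$start[1] else NA_integer_,
         polya_end = if (nrow(polya)) polya$end[1] else NA_integer_,
         tsd_len = if (nrow(tsd)) tsd$length[1] else NA_integer_,
         fold_passes = sum(vapply(folds, function(f) isTRUE(f$passes),
                                  logical(1))),
         hallmarks = list(h), polya = list(polya), tsd = list(tsd),
         folds = list(folds))
}

unclassified_locus <- function(h, locus_id) {
  tibble(locus_id = sprintf("locus%03d", as.integer(locus_id)),
         contig = h$contig[1], start = min(h$start), end = max(h$end),
         strand = h$strand[1], element_class = "UNCLASSIFIED",
         confidence = "no_tsd", n_hallmarks = nrow(h),
         polya_start = NA_integer_, polya_end = NA_integer_,
         tsd_len = NA_integer_, fold_passes = 0L,
         hallmarks = list(h), polya = list(tibble()), tsd = list(empty_tsd()),
         folds = list(list()))
}

empty_annotations <- function() {
  tibble(locus_id = character(), contig = character(), start = integer(),
         end = integer(), strand = character(), element_class = character(),
         confidence = character(), n_hallmarks = integer(),
         polya_start = integer(), polya_end = integer(),
         tsd_len = integer(), fold_passes = integer(),
         hallmarks = list(), polya = list(), tsd = list(), folds = list())
}

# candidate sequence for fold validation: the hit on its own strand,
# extended 3' to at least 77 nt and clipped to the 60-140 nt bounds
hallmark_fold_seq <- function(genome, hit) {
  contig <- genome[[hit$contig]]
  len <- hit$end - hit$start
  want <- min(140L, max(len, 77L))
  if (hit$strand == "+") {
    e <- min(nchar(contig), hit$start + want)
    substr(contig, hit$start + 1L, e)
  } else {
    s <- max(0L, hit$end - want)
    revcomp(substr(contig, s + 1L, hit$end))
  }
}

#' Plot annotated elements along their contigs
#'
#' Simple ideogram-style overview: one horizontal track per contig,
#' elements drawn as segments coloured by class.
#'
#' @param annotations output of [annotate_genome()].
#' @return a ggplot object.
#' @export
plot_elements <- function(annotations) {
  ggplot2::ggplot(annotations,
                  ggplot2::aes(x = .data$start / 1e3, xend = .data$end / 1e3,
                               y = .data$contig, yend = .data$contig,
                               colour = .data$element_class)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::labs(x = "position (kb)", y = NULL, colour = "class")
}
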