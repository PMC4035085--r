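# Generators for every input the pipeline consumes: descriptor-satisfying
# (and deliberately broken) ribozyme sequences, planted genomes with truth
# annotations, and noisy cleavage time-courses. All generation is seeded
# and reproducible.

sample_int <- function(lo, hi) {
  if (hi < lo) abort("empty sampling range")
  if (lo == hi) return(lo)
  sample(lo:hi, 1L)
}

WC_PAIRS <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
GC_PAIRS <- list(c("G", "C"), c("C", "G"))

#' Sample a sequence satisfying the ribozyme descriptor
#'
#' Constructive inverse of the fold validator: helix placements are drawn
#' within the descriptor windows, paired strands are filled complementarily
#' (position 1 is set to C pairing G, extending into the required run of
#' consecutive G-C pairs in P1; P1.1 receives G-C pairs only), and
#' junctions are filled with random bases, rejection-sampled until
#' [validate_hallmark()] passes.
#'
#' @param descriptor a [ribozyme_descriptor()].
#' @param rng_seed integer seed; identical seeds give identical sequences.
#' @return list with `seq` (DNA string) and `truth` (the best, passing,
#'   `fold_assignment`).
#' @export
sample_ribozyme <- function(descriptor = ribozyme_descriptor(), rng_seed = 1L) {
  d <- descriptor
  if (d$p1_min_consecutive_gc > d$helices$P1$max_len)
    abort("unsatisfiable descriptor: p1_min_consecutive_gc exceeds P1 max_len")
  withr::with_seed(rng_seed, {
    for (outer in 1:60) {
      pl <- try(sample_placements(d), silent = TRUE)
      if (inherits(pl, "try-error")) next
      for (fill in 1:40) {
        seq <- fill_bases(pl, d)
        v <- validate_hallmark(seq, d)
        if (v$passes) return(list(seq = seq, truth = v$fold))
      }
    }
  })
  abort("could not satisfy descriptor; helix windows leave no room for a consistent placement")
}

sample_placements <- function(d) {
  h <- d$helices; jx <- d$junctions
  len1 <- sample_int(h$P1$min_len, h$P1$max_len)
  e1 <- sample_int(max(h$P1$window_3p[1] + len1 - 1L, 33L),
                   min(h$P1$window_3p[2], 42L))
  p1_3p_start <- e1 - len1 + 1L
  # P2 just 3' of the P1 5' strand, closing over P3
  len2 <- sample_int(h$P2$min_len, h$P2$max_len)
  s2_lo <- max(h$P2$window_5p[1], len1 + 1L + jx$j12[1])
  s2_hi <- min(h$P2$window_5p[2] - len2 + 1L, len1 + 1L + jx$j12[2])
  s2 <- sample_int(s2_lo, s2_hi)
  len3 <- sample_int(h$P3$min_len, h$P3$max_len)
  e2_lo <- max(h$P2$window_3p[1] + len2 - 1L,
               s2 + len2 + 2L * len3 + 5L + len2 - 1L)
  e2_hi <- min(h$P2$window_3p[2], p1_3p_start - 1L)
  e2 <- sample_int(e2_lo, e2_hi)
  s3_lo <- max(h$P3$window_5p[1], s2 + len2)
  e3_hi <- min(h$P3$window_3p[2], e2 - len2)
  s3 <- sample_int(s3_lo, min(s3_lo + 2L, e3_hi - 2L * len3 - 4L))
  e3 <- sample_int(s3 + 2L * len3 + 3L, e3_hi)
  # P1.1 5' partner inside the P3 loop
  a_lo <- max(h$"P1.1"$window_5p[1], s3 + len3)
  a_hi <- min(h$"P1.1"$window_5p[2] - 1L, e3 - len3 - 1L)
  a <- sample_int(a_lo, a_hi)
  # P1.1 3' strand just 3' of the P1 3' strand
  b_end <- e1 + 2L + sample_int(0L, 2L)
  if (b_end - 1L < h$"P1.1"$window_3p[1] || b_end > h$"P1.1"$window_3p[2])
    abort("P1.1 window infeasible")
  len4 <- sample_int(h$P4$min_len, min(h$P4$max_len, 8L))
  loop4 <- sample_int(jx$l4[1], min(jx$l4[2], 8L))
  s4 <- b_end + 1L + sample_int(jx$j42[1], min(jx$j42[2], 5L))
  if (s4 < h$P4$window_5p[1]) s4 <- h$P4$window_5p[1]
  e4 <- s4 + 2L * len4 + loop4 - 1L
  if (s4 + len4 - 1L > h$P4$window_5p[2] || e4 > h$P4$window_3p[2] ||
      e4 > 130L)
    abort("P4 window infeasible")
  list(P1 = list(s5 = 1L, e3 = e1, len = len1),
       P2 = list(s5 = s2, e3 = e2, len = len2),
       P3 = list(s5 = s3, e3 = e3, len = len3),
       "P1.1" = list(s5 = a, e3 = b_end, len = 2L),
       P4 = list(s5 = s4, e3 = e4, len = len4))
}

fill_bases <- function(pl, d) {
  L <- max(60L, pl$P4$e3 + sample_int(3L, 8L))
  chars <- rep(NA_character_, L)
  for (nm in names(pl)) {
    p <- pl[[nm]]
    for (t in 0:(p$len - 1L)) {
      i <- p$s5 + t; j <- p$e3 - t
      pair <- if (nm == "P1.1") {
        GC_PAIRS[[sample_int(1L, 2L)]]
      } else if (nm == "P1" && t == 0L) {
        c("C", "G")                      # the +1 C pairs a G
      } else if (nm == "P1" && t < d$p1_min_consecutive_gc) {
        GC_PAIRS[[sample_int(1L, 2L)]]
      } else {
        WC_PAIRS[[sample_int(1L, 4L)]]
      }
      chars[i] <- pair[1]; chars[j] <- pair[2]
    }
  }
  free <- which(is.na(chars))
  chars[free] <- sample(c("A", "C", "G", "T"), length(free), replace = TRUE)
  paste(chars, collapse = "")
}

# partner lookup and mutation helpers used by break_constraint ------------

# set every position of a helix's windows that no other helix occupies in
# the current best fold to A, so no placement of that helix survives
blank_helix_windows <- function(chars, fold, name, d) {
  h <- d$helices[[name]]
  occupied <- with(fold$pairs[fold$pairs$helix != name, ], c(i, j))
  win <- c(seq.int(h$window_5p[1], min(h$window_5p[2], length(chars))),
           seq.int(h$window_3p[1], min(h$window_3p[2], length(chars))))
  win <- setdiff(win[win >= 2L], occupied)
  chars[win] <- "A"
  chars
}

fold_helix <- function(fold, name) {
  p <- fold$pairs[fold$pairs$helix == name, , drop = FALSE]
  p[order(p$i), , drop = FALSE]
}

illegal_base_for <- function(partner_of, wobble, gc_only) {
  cand <- c("A", "C", "G", "T")
  bad <- vapply(cand, function(b)
    !legal_pair(partner_of, b, wobble, gc_only), logical(1))
  cand[bad]
}

#' Mutate a passing ribozyme so that a named violation is reported
#'
#' Applies targeted mutations (guided by the current best fold, iterating
#' until alternative placements are ruled out) so that
#' [validate_hallmark()] on the result fails with a violation list
#' containing `code`. Mirrors the structural defects seen in natural
#' hallmark copies: a C1-A mismatch at the +1 pair, a 3-bp P2 helix, an
#' unfoldable P1.1 pseudoknot, and so on.
#'
#' @param seq a sequence that passes validation.
#' @param truth its passing `fold_assignment` (from [sample_ribozyme()]).
#' @param code one of `r paste(VIOLATION_CODES, collapse = ", ")`.
#' @param rng_seed integer seed for the mutation choices.
#' @param descriptor the descriptor `seq` was generated under.
#' @return the mutated sequence.
#' @export
break_constraint <- function(seq, truth, code, rng_seed = 1L,
                             descriptor = ribozyme_descriptor()) {
  code <- match.arg(code, VIOLATION_CODES)
  d <- descriptor
  withr::with_seed(rng_seed, {
    for (attempt in 1:20) {
      out <- try(break_once(seq, truth, code, d), silent = TRUE)
      if (!inherits(out, "try-error")) {
        v <- validate_hallmark(out, d)
        if (!v$passes && code %in% v$violations) return(out)
      }
    }
  })
  abort(paste0("could not break constraint ", code, " for this sequence"))
}

break_once <- function(seq, truth, code, d) {
  chars <- seq_chars(seq)
  pick <- function(x) x[[sample_int(1L, length(x))]]
  if (code == "WINDOW_UNSATISFIABLE") {
    # empty both P1 strand windows of pairable bases
    w3 <- d$helices$P1$window_3p
    idx <- c(2:d$helices$P1$window_5p[2],
             w3[1]:min(w3[2], length(chars)))
    chars[idx] <- "A"
    chars[1] <- "C"
    return(paste(chars, collapse = ""))
  }
  # iterative knockout guided by the current best fold, so that rescuing
  # alternative placements are eliminated too
  for (iter in 1:15) {
    v <- validate_hallmark(paste(chars, collapse = ""), d)
    if (!v$passes && code %in% v$violations)
      return(paste(chars, collapse = ""))
    f <- v$fold
    if (code == "P1_GC_RUN_SHORT") {
      # convert every (min_gc)-th pair inside each G-C run to A-T: the
      # smallest change that caps all runs below the threshold
      p1 <- fold_helix(f, "P1")
      if (!nrow(p1)) abort("P1 unfolded before its G-C run could shrink")
      gc <- is_gc_pair(chars[p1$i], chars[p1$j])
      run_id <- cumsum(c(TRUE, diff(gc) != 0))
      for (rid in unique(run_id[gc])) {
        idx <- which(run_id == rid & gc)
        brk <- idx[seq_along(idx) %% d$p1_min_consecutive_gc == 0]
        at <- WC_PAIRS[[sample_int(1L, 2L)]]
        chars[p1$i[brk]] <- at[1]; chars[p1$j[brk]] <- at[2]
      }
    } else if (code == "P1_MISMATCH_AT_PLUS1") {
      p1 <- fold_helix(f, "P1")
      tgt <- p1$j[p1$i == 1L]
      if (!length(tgt)) abort("P1 no longer pairs the +1 nucleotide")
      chars[tgt] <- if (chars[1] == "C") "A" else
        pick(illegal_base_for(chars[1], d$helices$P1$wobble_allowed, FALSE))
      # the planted G-C run includes the +1 pair; rebuild it in the
      # surviving pairs so the mismatch, not a short register, is the
      # best assignment
      for (t in 2:(1 + d$p1_min_consecutive_gc)) {
        row <- which(p1$i == t)
        if (length(row)) {
          gc <- GC_PAIRS[[sample_int(1L, 2L)]]
          chars[p1$i[row]] <- gc[1]; chars[p1$j[row]] <- gc[2]
        }
      }
    } else if (code == "P1_TOO_SHORT") {
      p1 <- fold_helix(f, "P1")
      if (nrow(p1) < d$helices$P1$min_len) abort("P1 already short")
      k <- d$helices$P1$min_len
      tgt <- p1$j[k]
      chars[tgt] <- pick(illegal_base_for(chars[p1$i[k]],
                                          d$helices$P1$wobble_allowed, FALSE))
    } else if (code == "P2_TOO_SHORT") {
      p2 <- fold_helix(f, "P2")
      if (nrow(p2) >= 4L && iter <= 4L) {
        tgt <- p2$j[4L]
        chars[tgt] <- pick(illegal_base_for(chars[p2$i[4L]],
                                            d$helices$P2$wobble_allowed,
                                            FALSE))
      } else {
        # alternative registers keep reviving a long P2: empty its
        # windows instead (an unplaceable P2 carries the same code)
        chars <- blank_helix_windows(chars, f, "P2", d)
      }
    } else {
      nm <- switch(code, P3_UNFOLDED = "P3", P11_UNFOLDED = "P1.1",
                   P4_UNFOLDED = "P4")
      hp <- fold_helix(f, nm)
      if (nrow(hp) && iter <= 4L) {
        for (r in seq_len(nrow(hp))) {
          chars[hp$j[r]] <- pick(illegal_base_for(
            chars[hp$i[r]], d$helices[[nm]]$wobble_allowed,
            isTRUE(d$helices[[nm]]$gc_only)))
        }
      } else {
        chars <- blank_helix_windows(chars, f, nm, d)
      }
    }
  }
  paste(chars, collapse = "")
}

# element construction -----------------------------------------------------

ELEMENT_CLASSES <- c("SIDER1", "SIDER2", "LINE_DIRE", "SIDE_NAR")

diverge_seq <- function(seq, pct) {
  if (pct <= 0) return(seq)
  chars <- seq_chars(seq)
  n_mut <- round(length(chars) * pct / 100)
  if (n_mut == 0L) return(seq)
  pos <- sample(seq_along(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Assemble a synthetic mobile element
#'
#' Concatenates hallmark copies (two in tandem for SIDER2), a random body
#' of class-appropriate length, and a 3' poly-A tail, applying point
#' mutations to the hallmark copies at the requested divergence. Body
#' lengths place the poly-A in the short (~0.6 kb) window for SIDER1 /
#' SIDER2 / NAR-like elements and in the long (5-6 kb) window for
#' DIRE-like LINEs. A target-site duplication sequence is drawn for
#' [plant_genome()] to duplicate at both ends.
#'
#' @param element_class one of SIDER1, SIDER2, LINE_DIRE, SIDE_NAR.
#' @param rng_seed integer seed.
#' @param hallmark_seq the hallmark consensus to plant (default: a fresh
#'   [sample_ribozyme()] draw).
#' @param divergence_pct percent of hallmark positions to mutate.
#' @param tsd_len target-site duplication length, 7-11 nt.
#' @param polyA_len poly-A tail length, nt.
#' @param body_len body length between the last hallmark and the poly-A
#'   (default 550 nt for short classes, 5200 for LINE_DIRE).
#' @param tandem_gap nt between the two SIDER2 hallmarks.
#' @param long_ref optional DIRE-like reference element sequence whose 5'
#'   and 3' end regions are copied into a SIDE_NAR body.
#' @param descriptor descriptor used when `hallmark_seq` is sampled.
#' @return list with `seq`, `hallmark_spans` (tibble, 0-based half-open
#'   within the element), `polya_span`, `tsd_seq`, `element_class`.
#' @export
build_element <- function(element_class, rng_seed = 1L, hallmark_seq = NULL,
                          divergence_pct = 0, tsd_len = NULL,
                          polyA_len = 20L, body_len = NULL, tandem_gap = 10L,
                          long_ref = NULL,
                          descriptor = ribozyme_descriptor()) {
  if (!element_class %in% ELEMENT_CLASSES)
    abort(paste0("unknown element class '", element_class, "'"))
  if (is.null(hallmark_seq))
    hallmark_seq <- sample_ribozyme(descriptor, rng_seed)$seq
  withr::with_seed(rng_seed + 1L, {
    if (is.null(tsd_len)) tsd_len <- sample_int(7L, 11L)
    if (tsd_len < 7L || tsd_len > 11L) abort("tsd_len must be in [7, 11]")
    if (is.null(body_len))
      body_len <- if (element_class == "LINE_DIRE") 5200L else 550L
    h1 <- diverge_seq(hallmark_seq, divergence_pct)
    parts <- h1
    spans <- tibble(start = 0L, end = nchar(h1))
    if (element_class == "SIDER2") {
      h2 <- diverge_seq(hallmark_seq, divergence_pct)
      parts <- c(parts, random_dna(tandem_gap), h2)
      spans <- dplyr::bind_rows(spans, tibble(
        start = nchar(h1) + tandem_gap,
        end = nchar(h1) + tandem_gap + nchar(h2)))
    }
    body <- if (element_class == "SIDE_NAR" && !is.null(long_ref)) {
      end_len <- 200L
      mid <- body_len - 2L * end_len
      if (mid < 0L) abort("body_len too small for shared end regions")
      paste0(substr(long_ref, nchar(hallmark_seq) + 1L,
                    nchar(hallmark_seq) + end_len),
             random_dna(mid),
             substr(long_ref, nchar(long_ref) - end_len + 1L, nchar(long_ref)))
    } else {
      random_dna(body_len)
    }
    parts <- c(parts, body, strrep("A", polyA_len))
    seq <- paste(parts, collapse = "")
    list(seq = seq,
         hallmark_spans = spans,
         polya_span = c(nchar(seq) - polyA_len, nchar(seq)),
         tsd_seq = random_dna(tsd_len),
         element_class = element_class)
  })
}

#' Plant synthetic elements in a random background genome
#'
#' Generates i.i.d. background contigs and inserts each element with its
#' target-site duplication repeated flush at both ends (unless the element's row
#' disables it, producing a TSD-less decoy). Minus-strand elements are
#' inserted reverse-complemented; TSD copies remain direct repeats in
#' forward coordinates, as target-primed reverse transcription leaves them.
#'
#' @param n_contigs number of background contigs.
#' @param contig_len length of each contig before insertions, nt.
#' @param element_specs tibble (or data.frame) with one row per element:
#'   columns `class`, `divergence_pct`, `strand` ("+"/"-"), `with_tsd`
#'   (logical); optional `body_len`, `tsd_len`.
#' @param rng_seed integer seed controlling background, element bodies,
#'   TSDs and placements.
#' @param hallmark_seq hallmark consensus planted in every element
#'   (default: sampled from `descriptor` with this seed).
#' @param gc background GC fraction.
#' @param descriptor descriptor for hallmark sampling.
#' @return list with `genome` (named character vector), `truth` (tibble:
#'   `element_id`, `contig`, `start`, `end`, `strand`, `element_class`,
#'   `with_tsd`, `tsd_seq`, `polya_start`, `polya_end` and a `hallmarks`
#'   list-column of 0-based spans), `queries` (the hallmark consensus) and
#'   `manifest` (all seeds and parameters).
#' @export
plant_genome <- function(n_contigs = 1L, contig_len = 200000L,
                         element_specs, rng_seed = 42L, hallmark_seq = NULL,
                         gc = 0.5, descriptor = ribozyme_descriptor()) {
  specs <- as_tibble(element_specs)
  stopifnot(all(c("class", "divergence_pct", "strand", "with_tsd") %in%
                  names(specs)))
  if (is.null(hallmark_seq))
    hallmark_seq <- sample_ribozyme(descriptor, rng_seed)$seq
  n <- nrow(specs)
  withr::with_seed(rng_seed + 1L, {
    specs$contig <- rep(paste0("contig", seq_len(n_contigs)), length.out = n)
    genome <- character(n_contigs)
    names(genome) <- paste0("contig", seq_len(n_contigs))
    truth <- list()
    for (ci in seq_len(n_contigs)) {
      cname <- names(genome)[ci]
      bg <- random_dna(contig_len, gc)
      rows <- which(specs$contig == cname)
      if (!length(rows)) { genome[[ci]] <- bg; next }
      slot <- contig_len %/% (length(rows) + 1L)
      builds <- lapply(seq_along(rows), function(k) {
        r <- rows[k]
        build_element(specs$class[r],
                      rng_seed = rng_seed + 100L * ci + k,
                      hallmark_seq = hallmark_seq,
                      divergence_pct = specs$divergence_pct[r],
                      tsd_len = if ("tsd_len" %in% names(specs))
                        specs$tsd_len[r] else NULL,
                      body_len = if ("body_len" %in% names(specs) &&
                                     !is.na(specs$body_len[r]))
                        specs$body_len[r] else NULL,
                      descriptor = descriptor)
      })
      ins_len <- vapply(seq_along(rows), function(k) {
        nchar(builds[[k]]$seq) +
          if (specs$with_tsd[rows[k]]) 2L * nchar(builds[[k]]$tsd_seq) else 0L
      }, 1L)
      if (any(slot < ins_len + 2000L))
        abort("contig capacity overflow: elements do not fit with >= 1 kb spacing")
      # one insertion point per slot, away from slot edges
      pts <- vapply(seq_along(rows), function(k)
        as.integer((k - 1L) * slot + slot %/% 4L +
                     sample_int(0L, slot %/% 4L)), 1L)
      pieces <- character(); prev <- 0L; shift <- 0L
      for (k in seq_along(rows)) {
        r <- rows[k]; b <- builds[[k]]
        tsd <- if (specs$with_tsd[r]) b$tsd_seq else ""
        oriented <- if (specs$strand[r] == "+") b$seq else revcomp(b$seq)
        pieces <- c(pieces, substr(bg, prev + 1L, pts[k]),
                    tsd, oriented, tsd)
        ins_at <- pts[k] + shift            # 0-based, final coordinates
        el_start <- ins_at + nchar(tsd)
        el_end <- el_start + nchar(b$seq)
        hm <- b$hallmark_spans
        if (specs$strand[r] == "+") {
          hm_abs <- tibble(start = el_start + hm$start, end = el_start + hm$end)
          pa <- el_start + b$polya_span
        } else {
          hm_abs <- tibble(start = el_end - hm$end, end = el_end - hm$start)
          hm_abs <- hm_abs[order(hm_abs$start), ]
          pa <- c(el_end - b$polya_span[2], el_end - b$polya_span[1])
        }
        truth[[length(truth) + 1L]] <- tibble(
          element_id = sprintf("el%02d", r), contig = cname,
          start = el_start, end = el_end, strand = specs$strand[r],
          element_class = b$element_class, with_tsd = specs$with_tsd[r],
          tsd_seq = if (nzchar(tsd)) tsd else NA_character_,
          polya_start = pa[1], polya_end = pa[2],
          hallmarks = list(hm_abs))
        shift <- shift + nchar(tsd) * 2L + nchar(b$seq)
        prev <- pts[k]
      }
      pieces <- c(pieces, substr(bg, prev + 1L, contig_len))
      genome[[ci]] <- paste(pieces, collapse = "")
    }
  })
  truth <- dplyr::arrange(dplyr::bind_rows(truth), .data$contig, .data$start)
  list(genome = genome, truth = truth,
       queries = c(hallmark_consensus = hallmark_seq),
       manifest = list(rng_seed = rng_seed, n_contigs = n_contigs,
                       contig_len = contig_len, gc = gc,
                       element_specs = specs))
}

#' Canonical synthetic screening fixture
#'
#' The study genome used throughout the package's examples and checks: one
#' 200 kb contig with 12 planted elements — 4 SIDER1, 4 SIDER2, 2
#' DIRE-like LINEs and 2 TSD-less SIDER1 decoys — on mixed strands with
#' hallmark divergences between 0 and 10%.
#'
#' @param rng_seed integer seed.
#' @param contig_len background contig length, nt.
#' @return see [plant_genome()].
#' @export
synthetic_screen_fixture <- function(rng_seed = 42L, contig_len = 200000L) {
  specs <- tibble(
    class = c(rep("SIDER1", 4), rep("SIDER2", 4), rep("LINE_DIRE", 2),
              rep("SIDER1", 2)),
    divergence_pct = c(0, 5, 5, 10, 0, 2, 5, 10, 5, 5, 0, 5),
    strand = c("+", "-", "+", "-", "+", "+", "-", "-", "+", "-", "+", "-"),
    with_tsd = c(rep(TRUE, 10), FALSE, FALSE))
  plant_genome(n_contigs = 1L, contig_len = contig_len,
               element_specs = specs, rng_seed = rng_seed)
}

#' Two-phase decay model of the cleaved fraction
#'
#' Evaluates `fc(t) = A + B exp(-k1 t) + C exp(-k2 t)`, the double
#' exponential that describes HDV-like ribozyme cleavage: `A` is the
#' cleaved fraction (%) at infinite time, `-B` and `-C` the amplitudes of
#' the fast and slow observable phases, and `k1 >= k2 > 0` the observed
#' first-order rate constants (per minute).
#'
#' @param A plateau, percent.
#' @param B,C phase amplitudes, percent (non-positive for rising curves).
#' @param k1,k2 rate constants, 1/min; both must be positive.
#' @param t time(s), minutes; must be non-negative.
#' @return cleaved fraction(s), percent.
#' @export
two_phase_model <- function(A, B, C, k1, k2, t) {
  if (any(t < 0)) abort("negative time")
  if (k1 <= 0 || k2 <= 0) abort("rate constants must be positive")
  A + B * exp(-k1 * t) + C * exp(-k2 * t)
}

#' Simulate a noisy cleavage time-course
#'
#' Evaluates the two-phase decay model at the given times and adds
#' Gaussian noise, clipping to the 0-100% range.
#'
#' @inheritParams two_phase_model
#' @param times sampling times in minutes, strictly increasing from 0.
#' @param noise_sd Gaussian noise standard deviation, percentage points.
#' @param rng_seed integer seed.
#' @param mg_mM magnesium concentration label.
#' @param replicate_id replicate label.
#' @return tibble with columns `replicate_id`, `mg_mM`, `time_min`,
#'   `fc_pct`.
#' @export
simulate_timecourse <- function(A, B, C, k1, k2,
                                times = c(0, 1, 2, 5, 10, 20, 40, 80, 160),
                                noise_sd = 2, rng_seed = 1L,
                                mg_mM = 0.1, replicate_id = "sim") {
  stopifnot(k1 >= k2, k2 > 0)
  fc <- two_phase_model(A, B, C, k1, k2, times)
  if (noise_sd > 0)
    fc <- withr::with_seed(rng_seed, fc + rnorm(length(times), 0, noise_sd))
  tibble(replicate_id = replicate_id, mg_mM = mg_mM, time_min = times,
         fc_pct = pmin(100, pmax(0, fc)))
}
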