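# Descriptor-based validation of the HDV-like ribozyme architecture.
#
# The HDV-like fold is a nested double pseudoknot built from helices P1,
# P2, P4 and the pseudoknot pairings P1.1 and P3. Positions are 1-based
# within the candidate, position 1 being the +1 nucleotide; self-cleavage
# occurs at the bond 5' of position 1. A descriptor gives, per helix, a
# length range and windows for the 5' and 3' strands; an assignment places
# each helix concretely (or leaves it unfolded) and carries coded
# violations. Replaces manual folding with an exhaustive, testable search.

VIOLATION_CODES <- c("P1_MISMATCH_AT_PLUS1", "P1_GC_RUN_SHORT", "P1_TOO_SHORT",
                     "P2_TOO_SHORT", "P3_UNFOLDED", "P11_UNFOLDED",
                     "P4_UNFOLDED", "WINDOW_UNSATISFIABLE")

HELIX_ORDER <- c("P1", "P2", "P3", "P1.1", "P4")
HELIX_LAYER <- c(P1 = 1L, P2 = 1L, P4 = 1L, P3 = 2L, "P1.1" = 3L)
LAYER_BRACKETS <- list(c("(", ")"), c("[", "]"), c("{", "}"))
ABSENT_CODE <- c(P1 = "WINDOW_UNSATISFIABLE", P2 = "P2_TOO_SHORT",
                 P3 = "P3_UNFOLDED", "P1.1" = "P11_UNFOLDED",
                 P4 = "P4_UNFOLDED")

#' Default HDV-like ribozyme structural descriptor
#'
#' Encodes the fold requirements used to accept or reject hallmark
#' candidates: helix length ranges, per-strand position windows relative to
#' the +1 nucleotide (position 1), wobble permissions and the minimum run
#' of consecutive G-C pairs in P1. Defaults describe an ~80-nt hallmark:
#' P1 pairs positions 1..6-8 against a 3' strand in window 30-45 (so the
#' +1 partner sits near position 39), P2 (4-7 bp) closes over the P3
#' hairpin (3-6 bp), the two obligate G-C pairs of pseudoknot P1.1 join the
#' P3 loop to the region just 3' of the P1 3' strand, and P4 is a local
#' hairpin further downstream. Wobble G-U pairs are allowed everywhere
#' except P1.1. Every field is data, so species-specific geometries can be
#' described without code changes.
#'
#' @param p1_min_consecutive_gc minimum run of consecutive G-C pairs in P1
#'   (default 3; relax to 2 for hallmarks with only two G-C pairs).
#' @param max_violations violations tolerated before a candidate is
#'   rejected (default 0).
#' @param helices optional list overriding per-helix specs; entries are
#'   lists with `min_len`, `max_len`, `window_5p`, `window_3p`,
#'   `wobble_allowed`, `gc_only`.
#' @param junctions optional list overriding junction length ranges
#'   (`j12`, `j42`, `l4`), in nt.
#' @return an object of class `ribozyme_descriptor`.
#' @export
ribozyme_descriptor <- function(p1_min_consecutive_gc = 3L,
                                max_violations = 0L,
                                helices = list(), junctions = list()) {
  hx <- list(
    P1 = list(min_len = 6L, max_len = 8L, window_5p = c(1L, 8L),
              window_3p = c(30L, 45L), wobble_allowed = TRUE,
              gc_only = FALSE),
    P2 = list(min_len = 4L, max_len = 7L, window_5p = c(8L, 18L),
              window_3p = c(20L, 34L), wobble_allowed = TRUE,
              gc_only = FALSE),
    P3 = list(min_len = 3L, max_len = 6L, window_5p = c(12L, 24L),
              window_3p = c(18L, 33L), wobble_allowed = TRUE,
              gc_only = FALSE),
    "P1.1" = list(min_len = 2L, max_len = 2L, window_5p = c(15L, 28L),
                  window_3p = c(36L, 52L), wobble_allowed = FALSE,
                  gc_only = TRUE),
    P4 = list(min_len = 3L, max_len = 12L, window_5p = c(42L, 110L),
              window_3p = c(48L, 126L), wobble_allowed = TRUE,
              gc_only = FALSE))
  for (nm in names(helices)) hx[[nm]] <- modifyList(hx[[nm]], helices[[nm]])
  jx <- modifyList(list(j12 = c(0L, 6L), j42 = c(0L, 12L), l4 = c(3L, 12L)),
                   junctions)
  for (nm in names(hx)) {
    h <- hx[[nm]]
    if (h$min_len > h$max_len)
      abort(paste0(nm, ": min_len > max_len"))
    if (any(c(h$window_5p, h$window_3p) < 1) ||
        any(c(h$window_5p, h$window_3p) > 130))
      abort(paste0(nm, ": windows must lie within [1, 130]"))
  }
  if (p1_min_consecutive_gc > hx$P1$max_len)
    abort("p1_min_consecutive_gc exceeds P1 max_len")
  structure(list(helices = hx, junctions = jx,
                 p1_min_consecutive_gc = as.integer(p1_min_consecutive_gc),
                 p1_len_floor = 3L, p2_len_floor = 3L,
                 max_violations = as.integer(max_violations)),
            class = "ribozyme_descriptor")
}

#' @export
print.ribozyme_descriptor <- function(x, ...) {
  cat("HDV-like ribozyme descriptor\n")
  for (nm in HELIX_ORDER) {
    h <- x$helices[[nm]]
    cat(sprintf("  %-4s %d-%d bp  5' window [%d,%d]  3' window [%d,%d]%s%s\n",
                nm, h$min_len, h$max_len, h$window_5p[1], h$window_5p[2],
                h$window_3p[1], h$window_3p[2],
                if (h$wobble_allowed) "  wobble" else "",
                if (isTRUE(h$gc_only)) "  G-C only" else ""))
  }
  cat(sprintf("  P1 G-C run >= %d; max violations %d\n",
              x$p1_min_consecutive_gc, x$max_violations))
  invisible(x)
}

legal_pair <- function(x, y, wobble = TRUE, gc_only = FALSE) {
  if (gc_only) return((x == "G" & y == "C") | (x == "C" & y == "G"))
  wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  if (!wobble) return(wc)
  wc | (x == "G" & y == "T") | (x == "T" & y == "G")
}

is_gc_pair <- function(x, y) (x == "G" & y == "C") | (x == "C" & y == "G")

# enumerate concrete placements of one helix; each record carries its pair
# matrix, the occupied strand positions and per-placement violation codes
helix_placements <- function(chars, name, desc) {
  h <- desc$helices[[name]]
  L <- length(chars)
  len_lo <- switch(name, P1 = desc$p1_len_floor, P2 = desc$p2_len_floor,
                   h$min_len)
  seq_range <- function(lo, hi) if (hi < lo) integer() else lo:hi
  out <- vector("list", 64L); n_out <- 0L
  push <- function(rec) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- rec
  }
  for (len in len_lo:h$max_len) {
    s5s <- if (name == "P1") 1L else seq_range(h$window_5p[1],
                                               h$window_5p[2] - len + 1L)
    s5s <- s5s[s5s >= 1L & (s5s + len - 1L) <= min(h$window_5p[2], L)]
    e3s <- seq_range(h$window_3p[1] + len - 1L, min(h$window_3p[2], L))
    for (s5 in s5s) for (e3 in e3s) {
      loop <- (e3 - len + 1L) - (s5 + len - 1L) - 1L
      if (loop < 3L) next
      if (name == "P4" &&
          (loop < desc$junctions$l4[1] || loop > desc$junctions$l4[2])) next
      i <- s5 + 0:(len - 1L); j <- e3 - 0:(len - 1L)
      ok <- legal_pair(chars[i], chars[j], h$wobble_allowed, h$gc_only)
      viol <- character()
      pi <- i; pj <- j
      if (all(ok)) {
        if (len < h$min_len)
          viol <- paste0(sub("\\..*", "", name), "_TOO_SHORT")
      } else if (name == "P1" && len >= h$min_len &&
                 !ok[1] && all(ok[-1])) {
        # helix forms but the +1 nucleotide cannot pair (e.g. C1.A39)
        pi <- i[-1]; pj <- j[-1]
        viol <- "P1_MISMATCH_AT_PLUS1"
      } else next
      gc_run <- 0L
      if (name == "P1") {
        gc_run <- max_run(is_gc_pair(chars[pi], chars[pj]))
        if (gc_run < desc$p1_min_consecutive_gc)
          viol <- c(viol, "P1_GC_RUN_SHORT")
      }
      push(list(helix = name, s5 = s5, e3 = e3, len = len,
                pi = pi, pj = pj, pos = c(i, j), viol = viol,
                nviol = length(viol), npairs = length(pi), gc_run = gc_run,
                layer = HELIX_LAYER[[name]],
                key = sprintf("%s:%d:%d:%d", name, s5, e3, len)))
    }
  }
  out[seq_len(n_out)]
}

# fast data-frame constructor (validated inputs only)
quick_tbl <- function(...) {
  l <- list(...)
  structure(l, class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(length(l[[1]])))
}

arcs_cross <- function(a, b) {
  (a$s5 < b$s5 && b$s5 < a$e3 && a$e3 < b$e3) ||
    (b$s5 < a$s5 && a$s5 < b$e3 && b$e3 < a$e3)
}

# check placement `pl` against already-chosen placements (occupancy mask,
# base-layer non-crossing, junction length ranges)
placement_compatible <- function(pl, chosen, occ, desc) {
  if (any(occ[pl$pos])) return(FALSE)
  for (p in chosen) {
    if (pl$layer == 1L && p$layer == 1L && arcs_cross(pl, p)) return(FALSE)
    if (pl$helix == "P2" && p$helix == "P1") {
      gap <- pl$s5 - (p$s5 + p$len - 1L) - 1L
      if (gap < desc$junctions$j12[1] || gap > desc$junctions$j12[2])
        return(FALSE)
    }
    if (pl$helix == "P4" && p$helix == "P1.1") {
      gap <- pl$s5 - p$e3 - 1L
      if (gap < desc$junctions$j42[1] || gap > desc$junctions$j42[2])
        return(FALSE)
    }
  }
  TRUE
}

# materialise a full fold_assignment from chosen placements
fold_assignment <- function(seq, L, chosen, absent) {
  viol <- character()
  for (p in chosen) viol <- c(viol, p$viol)
  viol <- sort(unique(c(viol, unname(ABSENT_CODE[absent]))))
  pi <- integer(); pj <- integer(); ph <- character()
  db <- rep(".", L)
  hl <- setNames(integer(length(HELIX_ORDER)), HELIX_ORDER)
  p1_3p_start <- 999L; gc_run <- 0L
  for (p in chosen) {
    pi <- c(pi, p$pi); pj <- c(pj, p$pj)
    ph <- c(ph, rep(p$helix, length(p$pi)))
    db[p$pi] <- LAYER_BRACKETS[[p$layer]][1]
    db[p$pj] <- LAYER_BRACKETS[[p$layer]][2]
    hl[[p$helix]] <- p$len
    if (p$helix == "P1") {
      p1_3p_start <- p$e3 - p$len + 1L
      gc_run <- p$gc_run
    }
  }
  ord <- order(pi)
  structure(list(seq = seq,
                 pairs = quick_tbl(i = pi[ord], j = pj[ord],
                                   helix = ph[ord]),
                 dotbracket = paste(db, collapse = ""),
                 violations = viol, passes = length(viol) == 0L,
                 p1_gc_run = gc_run, helix_lengths = hl,
                 n_pairs = length(pi), p1_3p_start = p1_3p_start,
                 key = paste(vapply(chosen, `[[`, "", "key"),
                             collapse = ";")),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  cat("helices:",
      paste(sprintf("%s=%d", names(x$helix_lengths), x$helix_lengths),
            collapse = " "), "\n")
  cat(if (x$passes) "PASSES" else
    paste("violations:", paste(x$violations, collapse = ", ")), "\n")
  invisible(x)
}

# total order on assignments: fewest violations, most pairs, longest P1
# G-C run, leftmost P1 3' strand, then a deterministic key
fold_order <- function(folds) {
  order(vapply(folds, function(f) length(f$violations), 1L),
        -vapply(folds, `[[`, 1L, "n_pairs"),
        -vapply(folds, `[[`, 1L, "p1_gc_run"),
        vapply(folds, `[[`, 1L, "p1_3p_start"),
        vapply(folds, `[[`, "", "key"))
}

check_fold_input <- function(seq) {
  seq <- normalize_seq(seq, "candidate sequence")
  if (nchar(seq) < 60L || nchar(seq) > 140L)
    abort("candidate sequence must be 60-140 nt")
  if (!grepl("^[ACGTN]+$", seq)) abort("candidate has non-ACGTUN residues")
  seq
}

fold_candidates <- function(chars, descriptor) {
  lapply(setNames(HELIX_ORDER, HELIX_ORDER), function(nm)
    helix_placements(chars, nm, descriptor))
}

#' Enumerate all descriptor-consistent fold assignments
#'
#' Exhaustively places every helix within its descriptor windows (or leaves
#' it unfolded, which carries the corresponding violation code), keeping
#' only chemically legal, position-disjoint combinations whose base layer
#' (P1, P2, P4) is non-crossing; pseudoknot layers P3 and P1.1 may cross.
#' This is the reference search that [best_folding()] must agree with.
#'
#' @param seq candidate sequence, 60-140 nt; T and U are equivalent.
#' @param descriptor a [ribozyme_descriptor()].
#' @param materialize when `FALSE`, returned assignments omit the pair
#'   table and dot-bracket string (cheaper for bulk oracle comparisons);
#'   violations, pass flags, helix lengths and the ordering are identical.
#' @return list of `fold_assignment` objects, best first under the order
#'   described in [best_folding()].
#' @export
enumerate_foldings <- function(seq, descriptor = ribozyme_descriptor(),
                               materialize = TRUE) {
  seq <- check_fold_input(seq)
  chars <- seq_chars(seq)
  L <- length(chars)
  cand <- fold_candidates(chars, descriptor)
  out <- vector("list", 256L); n_out <- 0L
  recurse <- function(level, chosen, absent, occ) {
    if (level > length(HELIX_ORDER)) {
      n_out <<- n_out + 1L
      if (n_out > length(out)) length(out) <<- 2L * n_out
      out[[n_out]] <<- list(chosen = chosen, absent = absent)
      if (n_out > 500000L) abort("descriptor windows admit too many assignments")
      return(invisible())
    }
    nm <- HELIX_ORDER[[level]]
    placed <- FALSE
    for (pl in cand[[nm]]) {
      if (placement_compatible(pl, chosen, occ, descriptor)) {
        placed <- TRUE
        occ2 <- occ; occ2[pl$pos] <- TRUE
        recurse(level + 1L, c(chosen, list(pl)), absent, occ2)
      }
    }
    # a helix is left unfolded only when nothing can be placed, so that
    # its violation code means what it says
    if (!placed) recurse(level + 1L, chosen, c(absent, nm), occ)
  }
  recurse(1L, list(), character(), logical(L))
  out <- out[seq_len(n_out)]
  build <- if (materialize) fold_assignment else fold_assignment_light
  out <- lapply(out, function(r) build(seq, L, r$chosen, r$absent))
  out[fold_order(out)]
}

# as fold_assignment, but without the pair table and dot-bracket string
fold_assignment_light <- function(seq, L, chosen, absent) {
  viol <- character()
  hl <- setNames(integer(length(HELIX_ORDER)), HELIX_ORDER)
  p1_3p_start <- 999L; gc_run <- 0L; npairs <- 0L
  for (p in chosen) {
    viol <- c(viol, p$viol)
    hl[[p$helix]] <- p$len
    npairs <- npairs + p$npairs
    if (p$helix == "P1") {
      p1_3p_start <- p$e3 - p$len + 1L
      gc_run <- p$gc_run
    }
  }
  viol <- sort(unique(c(viol, unname(ABSENT_CODE[absent]))))
  structure(list(seq = seq, pairs = NULL, dotbracket = NA_character_,
                 violations = viol, passes = length(viol) == 0L,
                 p1_gc_run = gc_run, helix_lengths = hl, n_pairs = npairs,
                 p1_3p_start = p1_3p_start,
                 key = paste(vapply(chosen, `[[`, "", "key"),
                             collapse = ";")),
            class = "fold_assignment")
}

#' Best fold assignment under the descriptor
#'
#' Branch-and-bound search for the top assignment under the total order:
#' fewest violations, then most total base pairs, then longest run of
#' consecutive G-C pairs in P1, then leftmost P1 3' strand. Equals the
#' first element of [enumerate_foldings()] on any input.
#'
#' @inheritParams enumerate_foldings
#' @return a single `fold_assignment`.
#' @export
best_folding <- function(seq, descriptor = ribozyme_descriptor()) {
  seq <- check_fold_input(seq)
  chars <- seq_chars(seq)
  L <- length(chars)
  cand <- fold_candidates(chars, descriptor)
  max_pairs <- vapply(cand, function(pls)
    if (length(pls)) max(vapply(pls, `[[`, 1L, "npairs")) else 0L, 1L)
  rem_pairs <- rev(cumsum(rev(c(max_pairs, 0L))))  # index by level
  best <- NULL
  recurse <- function(level, chosen, absent, occ, nviol, npairs) {
    if (!is.null(best)) {
      bviol <- length(best$violations)
      opt_pairs <- npairs + rem_pairs[level]
      if (nviol > bviol ||
          (nviol == bviol && opt_pairs < best$n_pairs)) return(invisible())
    }
    if (level > length(HELIX_ORDER)) {
      f <- fold_assignment(seq, L, chosen, absent)
      if (is.null(best) || fold_order(list(f, best))[1] == 1L) best <<- f
      return(invisible())
    }
    nm <- HELIX_ORDER[[level]]
    placed <- FALSE
    for (pl in cand[[nm]]) {
      if (placement_compatible(pl, chosen, occ, descriptor)) {
        placed <- TRUE
        occ2 <- occ; occ2[pl$pos] <- TRUE
        recurse(level + 1L, c(chosen, list(pl)), absent, occ2,
                nviol + pl$nviol, npairs + pl$npairs)
      }
    }
    if (!placed)
      recurse(level + 1L, chosen, c(absent, nm), occ, nviol + 1L, npairs)
  }
  recurse(1L, list(), character(), logical(L), 0L, 0L)
  best
}

#' Validate a hallmark candidate against the ribozyme descriptor
#'
#' Thin wrapper over [best_folding()]: a candidate passes when its best
#' assignment carries no more than `descriptor$max_violations` violations
#' (default 0), mirroring the accept/reject decision of the screening
#' procedure.
#'
#' @inheritParams enumerate_foldings
#' @return list with elements `passes`, `violations` and `fold`.
#' @export
validate_hallmark <- function(seq, descriptor = ribozyme_descriptor()) {
  fold <- best_folding(seq, descriptor)
  list(passes = length(fold$violations) <= descriptor$max_violations,
       violations = fold$violations, fold = fold)
}

#' Predicted self-cleavage sites for hallmark hits
#'
#' The scissile bond lies 5' of the +1 nucleotide of each ribozyme, i.e.
#' immediately upstream of the hallmark hit on its own strand. On the plus
#' strand the +1 position is the hit start; on the minus strand it is the
#' forward-strand coordinate `end - 1`.
#'
#' @param hits hit tibble from [scan_genome()] (or any tibble with
#'   `contig`, `start`, `end`, `strand`).
#' @return tibble with one cleavage site per hit: `contig`, `position`
#'   (0-based coordinate of the +1 nucleotide), `strand`; the scissile
#'   bond joins `position - 1` and `position` on the plus strand and
#'   `position` and `position + 1` on the minus strand.
#' @export
predicted_cleavage_site <- function(hits) {
  stopifnot(all(c("contig", "start", "end", "strand") %in% names(hits)))
  tibble(contig = hits$contig,
         position = ifelse(hits$strand == "+", hits$start, hits$end - 1L),
         strand = hits$strand)
}
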