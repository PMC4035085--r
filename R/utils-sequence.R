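# Low-level sequence utilities shared by the scanner, the fold validator and
# the synthetic-data generator. Sequences are plain uppercase character
# strings over A/C/G/T/N (IUPAC codes allowed in queries); coordinates are
# 0-based half-open internally and only converted to 1-based inclusive in
# GFF3 output.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

BASE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# bitmask of concrete bases an IUPAC code stands for; N in a *subject*
# (genome) is coded 0 so it can never satisfy a match
iupac_mask <- function(chars, subject = FALSE) {
  out <- integer(length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (subject) {
      out[[i]] <- if (ch %in% names(BASE_BIT)) BASE_BIT[[ch]] else 0L
    } else {
      set <- IUPAC_SETS[[ch]]
      if (is.null(set)) abort(paste0("invalid residue '", ch, "'"))
      out[[i]] <- sum(BASE_BIT[set])
    }
  }
  out
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

normalize_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    abort(paste0(what, " must be a non-empty string"))
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Coerce genome input to a named character vector
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet], or a path
#' to a FASTA file. Residues are uppercased; U is converted to T.
#'
#' @param genome genome sequences in any of the accepted forms.
#' @return named character vector of uppercase DNA sequences.
#' @export
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && length(genome) == 1L &&
             !grepl("^[ACGTUNacgtun]+$", genome) && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (!is.character(genome) || length(genome) == 0L)
    abort("genome must be a named character vector, DNAStringSet or FASTA path")
  if (is.null(names(genome)) || any(names(genome) == ""))
    names(genome) <- paste0("contig", seq_along(genome))
  out <- vapply(genome, function(s) gsub("U", "T", toupper(s), fixed = TRUE), "")
  bad <- !grepl("^[ACGTN]*$", out)
  if (any(bad))
    abort(paste0("genome contig(s) contain non-ACGTN residues: ",
                 paste(names(out)[bad], collapse = ", ")))
  if (any(nchar(out) == 0L)) abort("empty genome contig")
  out
}

# Smith-Waterman local alignment of an IUPAC query against a concrete DNA
# subject with linear gap penalties.  Returns the single best local
# alignment with a traceback so identity can be computed as
# matches / aligned columns.  Vectorised per query row; the left-gap
# propagation uses the cummax identity
#   max_{l<=j}(T_l + g*(j-l)) = g*j + cummax(T_l - g*l).
sw_align <- function(qmask, smask, match = 1L, mismatch = -1L, gap = -2L) {
  n <- length(qmask)
  m <- length(smask)
  if (m == 0L || n == 0L) return(NULL)
  H <- matrix(0, n + 1L, m + 1L)
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    hit <- bitwAnd(qmask[[i]], smask) != 0L
    s <- ifelse(hit, match, mismatch)
    t <- pmax(0, H[i, jj] + s, H[i, jj + 1L] + gap)
    a <- t - gap * jj
    H[i + 1L, jj + 1L] <- cummax(c(a[1L], a))[-1L] + gap * jj
  }
  best <- which.max(H)
  sc <- H[[best]]
  if (sc <= 0) return(NULL)
  i <- (best - 1L) %% (n + 1L)
  j <- (best - 1L) %/% (n + 1L)
  matches <- 0L; cols <- 0L
  qi_end <- i; sj_end <- j
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    hit <- bitwAnd(qmask[[i]], smask[[j]]) != 0L
    s <- if (hit) match else mismatch
    h <- H[i + 1L, j + 1L]
    if (h == H[i, j] + s) {
      matches <- matches + as.integer(hit)
      cols <- cols + 1L
      i <- i - 1L; j <- j - 1L
    } else if (h == H[i, j + 1L] + gap) {
      cols <- cols + 1L
      i <- i - 1L
    } else {
      cols <- cols + 1L
      j <- j - 1L
    }
  }
  list(score = as.integer(sc),
       q_start = i, q_end = qi_end,       # 0-based half-open in query
       s_start = j, s_end = sj_end,       # 0-based half-open in subject
       n_match = matches, n_cols = cols,
       identity = 100 * matches / cols)
}

# longest run of TRUE values
max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
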