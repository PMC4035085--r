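# Independent oracles used across the test files.

# Exhaustive local alignment via Biostrings, with the same scoring scheme
# as the scanner (match +1, mismatch -1, linear gap -2). Returns the best
# local alignment interval (0-based half-open on the subject), its score
# and percent identity.
oracle_local_align <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  pat <- Biostrings::alignedPattern(al)
  sub <- Biostrings::alignedSubject(al)
  a <- strsplit(as.character(pat), "")[[1]]
  b <- strsplit(as.character(sub), "")[[1]]
  list(score = Biostrings::score(al),
       s_start = Biostrings::start(Biostrings::subject(al)) - 1L,
       s_end = Biostrings::end(Biostrings::subject(al)),
       identity = 100 * sum(a == b) / length(a))
}

# percent identity of two equal-length (ungapped) sequences
hamming_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  100 * sum(av == bv) / length(av)
}

# Brute-force two-phase fit: dense log-spaced (k1, k2) grid with an exact
# linear solve for the amplitudes at each grid point, followed by a
# Nelder-Mead polish on the rates. Independent of the package's
# multi-start + Levenberg-Marquardt route.
oracle_two_phase <- function(t, y) {
  sse_at <- function(k1, k2) {
    X <- cbind(1, exp(-k1 * t), exp(-k2 * t))
    beta <- tryCatch(qr.solve(X, y), error = function(e) c(mean(y), 0, 0))
    beta[1] <- min(100, max(0, beta[1]))
    beta[2:3] <- pmin(0, pmax(-100, beta[2:3]))
    list(sse = sum((y - X %*% beta)^2), beta = beta)
  }
  ks <- exp(seq(log(1e-3), log(10), length.out = 40))
  best <- NULL
  for (k1 in ks) for (k2 in ks) {
    if (k2 >= k1) next
    r <- sse_at(k1, k2)
    if (is.null(best) || r$sse < best$sse)
      best <- c(r, list(k1 = k1, k2 = k2))
  }
  pol <- optim(log(c(best$k1, best$k2)), function(p) {
    sse_at(exp(p[1]), exp(p[2]))$sse
  }, method = "Nelder-Mead", control = list(maxit = 500))
  fin <- sse_at(exp(pol$par[1]), exp(pol$par[2]))
  list(A = fin$beta[1], B = fin$beta[2], C = fin$beta[3],
       k1 = exp(pol$par[1]), k2 = exp(pol$par[2]), sse = fin$sse)
}

# plant a sequence inside a background string at a 0-based offset
plant_at <- function(background, insert, at) {
  paste0(substr(background, 1, at), insert,
         substr(background, at + 1, nchar(background)))
}

# mutate the given 1-based positions of a sequence to different bases,
# deterministically (A->C, C->A, G->T, T->G)
mutate_positions <- function(seq, pos) {
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- swap[ch[pos]]
  paste(ch, collapse = "")
}

fixture_background <- function(n, seed, gc = 0.5) {
  withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  })
}
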