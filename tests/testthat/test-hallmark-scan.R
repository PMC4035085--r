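test_that("an exact planted copy is found with full identity and coordinates", {
  q <- fixture_background(77, seed = 901)
  bg <- fixture_background(10000, seed = 42)
  g <- c(chr1 = plant_at(bg, q, 5000))
  hits <- scan_genome(g, c(pr77 = q))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 5000L)
  expect_equal(hits$end, 5077L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$identity, 100)
  expect_equal(hits$score, 77L)
})

test_that("a copy with 5 interior substitutions matches the exhaustive aligner", {
  q <- fixture_background(77, seed = 901)
  bg <- fixture_background(10000, seed = 42)
  mut <- mutate_positions(q, c(10, 20, 35, 50, 65))
  g <- c(chr1 = plant_at(bg, mut, 5000))
  hits <- scan_genome(g, c(pr77 = q))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 100 * 72 / 77, tolerance = 1e-9)
  orc <- oracle_local_align(q, g[[1]])
  expect_equal(hits$score, as.integer(orc$score))
  expect_equal(hits$start, orc$s_start)
  expect_equal(hits$end, orc$s_end)
})

test_that("a reverse-complemented copy is reported on the minus strand at forward coordinates", {
  q <- fixture_background(77, seed = 901)
  bg <- fixture_background(10000, seed = 42)
  g <- c(chr1 = plant_at(bg, siderscan:::revcomp(q), 5000))
  hits <- scan_genome(g, c(pr77 = q))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 5000L)
  expect_equal(hits$end, 5077L)
  expect_equal(hits$identity, 100)
})

test_that("scanning the reverse-complemented genome mirrors the hit set", {
  q <- fixture_background(77, seed = 77)
  bg <- fixture_background(8000, seed = 5)
  g <- plant_at(plant_at(bg, q, 2000),
                siderscan:::revcomp(mutate_positions(q, c(5, 40, 70))), 6000)
  fwd <- scan_genome(c(c1 = g), c(q = q))
  rev <- scan_genome(c(c1 = siderscan:::revcomp(g)), c(q = q))
  L <- nchar(g)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- tibble::tibble(start = L - rev$end, end = L - rev$start,
                             strand = ifelse(rev$strand == "+", "-", "+"),
                             score = rev$score)
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(fwd$start, mirrored$start)
  expect_equal(fwd$end, mirrored$end)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score)
})

test_that("identical inputs give byte-identical output and N never matches", {
  q <- fixture_background(77, seed = 31)
  bg <- fixture_background(4000, seed = 8)
  g <- c(chr = plant_at(bg, q, 1500))
  h1 <- scan_genome(g, c(q = q))
  h2 <- scan_genome(g, c(q = q))
  expect_identical(h1, h2)
  # blanking the copy with N leaves nothing to find
  gN <- g
  substr(gN[["chr"]], 1501, 1577) <- strrep("N", 77)
  expect_equal(nrow(scan_genome(gN, c(q = q))), 0L)
})

test_that("every planted copy clearly above the identity cut-off is recovered", {
  q <- fixture_background(77, seed = 13)
  params <- scan_params(min_identity = 85, min_length = 60)
  withr::with_seed(99, {
    bg <- fixture_background(120000, seed = 100)
    n <- 50L
    g <- bg
    starts <- integer(n)
    for (i in seq_len(n)) {
      pos <- (i - 1L) * 2300L + 500L
      mut <- mutate_positions(q, sample(5:72, 6))   # 71/77 = 92.2% identity
      g <- paste0(substr(g, 1, pos), mut,
                  substr(g, pos + 78, nchar(g)))
      starts[i] <- pos
    }
  })
  hits <- scan_genome(c(chr = g), c(q = q), params)
  found <- vapply(starts, function(s)
    any(hits$start <= s + 5 & hits$end >= s + 72), logical(1))
  expect_true(all(found))
})

test_that("scanner agrees with the exhaustive quadratic aligner on small genomes", {
  q <- fixture_background(77, seed = 55)
  for (seed in 1:5) {
    bg <- fixture_background(1800, seed = 200 + seed)
    mut <- mutate_positions(q, c(8, 33, 61))
    g <- plant_at(bg, mut, 700 + seed * 50)
    hits <- scan_genome(c(chr = g), c(q = q))
    orc <- oracle_local_align(q, g)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$score, as.integer(orc$score))
    expect_equal(c(hits$start, hits$end), c(orc$s_start, orc$s_end))
  }
})

test_that("parameter and input validation reject degenerate settings", {
  expect_error(scan_params(k = 5), "degenerate")
  expect_error(scan_params(match = -1), "scores")
  expect_error(scan_genome(c(chr = ""), "ACGT"), "empty")
  q <- fixture_background(40, seed = 1)
  expect_error(scan_genome(c(chr = fixture_background(100, seed = 2)), q,
                           scan_params(k = 50)),
               "exceeds query length")
})

test_that("IUPAC codes in the query match any contained base", {
  bg <- fixture_background(3000, seed = 21)
  target <- fixture_background(60, seed = 22)
  g <- c(chr = plant_at(bg, target, 1000))
  # degenerate query: R at a G position, Y at a C position
  ch <- strsplit(target, "")[[1]]
  gpos <- which(ch == "G")[1]; cpos <- which(ch == "C")[1]
  ch[gpos] <- "R"; ch[cpos] <- "Y"
  hits <- scan_genome(g, c(q = paste(ch, collapse = "")),
                      scan_params(min_length = 50))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 100)
})

test_that("tandem copies in one seed window are both reported", {
  q <- fixture_background(77, seed = 61)
  bg <- fixture_background(5000, seed = 62)
  g <- c(chr = plant_at(bg, paste0(q, strrep("T", 10), q), 2000))
  hits <- scan_genome(g, c(q = q))
  expect_equal(nrow(hits), 2L)
  expect_equal(sort(hits$start), c(2000L, 2087L))
})

test_that("iterative re-screening reaches diverged copies through intermediates", {
  withr::with_seed(303, {
    A <- fixture_background(77, seed = 71)
    posB <- sample(4:74, 9)          # interior so local alignments span fully
    B <- mutate_positions(A, posB)
    posC <- sample(setdiff(4:74, posB), 9)
    C <- mutate_positions(B, posC)
  })
  # direct-alignment identities: C is reachable from B but not from A
  expect_gte(hamming_identity(B, A), 85)
  expect_gte(hamming_identity(C, B), 85)
  expect_lt(hamming_identity(C, A), 85)
  bg <- fixture_background(30000, seed = 72)
  g <- c(chr = plant_at(plant_at(plant_at(bg, A, 2000), B, 12000), C, 22000))
  params <- scan_params(min_identity = 85, min_length = 60)
  r1 <- scan_genome(g, c(q = A), params)
  expect_equal(sort(r1$start), c(2000L, 12000L))
  full <- iterative_scan(g, c(q = A), params, max_rounds = 4)
  expect_equal(sort(full$start), c(2000L, 12000L, 22000L))
  # max_rounds = 1 equals the plain scan union
  r1b <- iterative_scan(g, c(q = A), params, max_rounds = 1)
  expect_equal(sort(r1b$start), sort(r1$start))
})

test_that("iterative scan is a fixed point when no diverged copies exist", {
  q <- fixture_background(77, seed = 81)
  bg <- fixture_background(10000, seed = 82)
  g <- c(chr = plant_at(bg, q, 4000))
  one <- scan_genome(g, c(q = q))
  it <- iterative_scan(g, c(q = q), max_rounds = 5)
  expect_equal(it$start, one$start)
  expect_equal(it$end, one$end)
  expect_error(iterative_scan(g, c(q = q), max_rounds = 0), "max_rounds")
})
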