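make_hit <- function(contig, start, end, strand = "+") {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), strand = strand, identity = 100,
                 score = end - start, query_id = "q",
                 n_aligned = end - start)
}

test_that("planted poly-A tracks are found in the right distance windows", {
  bg <- fixture_background(20000, seed = 11)
  hit <- list(contig = "c", start = 1000L, end = 1077L, strand = "+")
  # A x 20 at 600 nt downstream of the hallmark end (G guards keep the
  # planted run exactly 20 nt)
  g1 <- c(c = plant_at(bg, paste0("G", strrep("A", 20), "G"), 1077 + 599))
  tr1 <- find_polyA(g1, hit)
  expect_equal(nrow(tr1), 1L)
  expect_equal(tr1$window_class, "SHORT")
  expect_equal(tr1$a_fraction, 1.0)
  expect_equal(tr1$distance, 600L)
  # A x 15 at 5500 nt downstream
  g2 <- c(c = plant_at(bg, paste0("G", strrep("A", 15), "G"), 1077 + 5499))
  tr2 <- find_polyA(g2, hit)
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$window_class, "LONG")
})

test_that("random sequence contains no qualifying poly-A track", {
  g <- c(c = fixture_background(9000, seed = 3))
  # independent check on the same window: no >=10 nt run at >=90% purity
  win <- substr(g[["c"]], 1078, 8700)
  expect_equal(length(regmatches(win, gregexpr("A{10,}", win))[[1]]), 0L)
  tr <- find_polyA(g, list(contig = "c", start = 1000L, end = 1077L,
                           strand = "+"))
  expect_equal(nrow(tr), 0L)
})

test_that("minus-strand elements expose their poly-A as an upstream T run", {
  bg <- fixture_background(20000, seed = 12)
  hit <- list(contig = "c", start = 9000L, end = 9077L, strand = "-")
  g <- c(c = plant_at(bg, paste0("C", strrep("T", 18), "C"), 9000 - 600))
  tr <- find_polyA(g, hit)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$window_class, "SHORT")
  expect_equal(tr$distance, 9000L - tr$end)
})

test_that("impure but >=90% A runs merge into one maximal track", {
  bg <- fixture_background(5000, seed = 13)
  run <- paste0("CC", strrep("A", 9), "G", strrep("A", 10), "CC")  # 19/20 A
  g <- c(c = plant_at(bg, run, 1998))
  # the long window overruns this short contig: truncation is warned
  expect_warning(
    tr <- find_polyA(g, list(contig = "c", start = 1000L, end = 1500L,
                             strand = "+")),
    "truncated")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$end - tr$start, 20L)
  expect_equal(tr$a_fraction, 0.95)
})

test_that("flush identical TSD copies are recovered at full identity", {
  tsd <- "GATTACAGG"
  bg <- fixture_background(4000, seed = 21)
  elem <- fixture_background(600, seed = 22)
  g <- c(c = plant_at(bg, paste0(tsd, elem, tsd), 2000))
  span <- list(contig = "c", start = 2009L, end = 2609L)
  res <- find_TSD(g, span)
  expect_equal(nrow(res), 1L)
  expect_equal(res$length, 9L)
  expect_equal(res$identity, 100)
  expect_equal(res$left_seq, tsd)
  expect_equal(res$right_seq, tsd)
  expect_equal(res$left_start, 2000L)
  expect_equal(res$right_start, 2609L)
})

test_that("one mismatch in an 8-mer TSD is accepted at 87.5% identity", {
  left <- "GATTACAG"; right <- "GATTACAT"
  bg <- fixture_background(4000, seed = 23)
  elem <- fixture_background(500, seed = 24)
  g <- c(c = plant_at(bg, paste0(left, elem, right), 1500))
  res <- find_TSD(g, list(contig = "c", start = 1508L, end = 2008L))
  expect_equal(nrow(res), 1L)
  expect_equal(res$length, 8L)
  expect_equal(res$identity, 87.5)
})

test_that("random flanks yield no TSD, confirmed by exhaustive comparison", {
  g <- c(c = fixture_background(3000, seed = 25))
  span <- list(contig = "c", start = 1200L, end = 1800L)
  res <- find_TSD(g, span)
  # independent exhaustive check over all lengths and offsets
  ch <- strsplit(g[["c"]], "")[[1]]
  any_hit <- FALSE
  for (L in 7:11) for (ol in 0:5) for (or in 0:5) {
    lv <- ch[(1200 - ol - L + 1):(1200 - ol)]
    rv <- ch[(1800 + or + 1):(1800 + or + L)]
    m <- sum(lv == rv)
    if (m >= 7 && 100 * m / L >= 80) any_hit <- TRUE
  }
  expect_equal(nrow(res) > 0, any_hit)
})

test_that("TSD detection is symmetric under reverse complementation", {
  tsd <- "CCATGATTAC"
  bg <- fixture_background(5000, seed = 26)
  elem <- fixture_background(700, seed = 27)
  g <- plant_at(bg, paste0(tsd, elem, tsd), 2500)
  L <- nchar(g)
  span <- list(contig = "c", start = 2510L, end = 3210L)
  fwd <- find_TSD(c(c = g), span)
  rc <- find_TSD(c(c = siderscan:::revcomp(g)),
                 list(contig = "c", start = L - span$end,
                      end = L - span$start))
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$length, fwd$length)
  expect_equal(rc$identity, fwd$identity)
  expect_equal(rc$left_seq, siderscan:::revcomp(fwd$right_seq))
  expect_equal(rc$left_start, L - (fwd$right_start + fwd$length))
})

test_that("raising the TSD identity threshold never adds detections", {
  counts <- vapply(c(60, 75, 90, 100), function(thr) {
    n <- 0L
    for (seed in 1:15) {
      g <- c(c = fixture_background(2500, seed = 600 + seed))
      res <- find_TSD(g, list(contig = "c", start = 1000L, end = 1600L),
                      tsd_config(min_identity_pct = thr))
      n <- n + nrow(res)
    }
    n
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("widening the poly-A windows never removes tracks", {
  narrow <- polya_config(short_window = c(400L, 800L))
  wide <- polya_config(short_window = c(300L, 1000L))
  n_narrow <- 0L; n_wide <- 0L
  for (seed in 1:10) {
    bg <- fixture_background(10000, seed = 700 + seed)
    g <- c(c = plant_at(bg, strrep("A", 12), 1077 + 300 + seed * 60))
    hit <- list(contig = "c", start = 1000L, end = 1077L, strand = "+")
    n_narrow <- n_narrow + nrow(find_polyA(g, hit, narrow))
    n_wide <- n_wide + nrow(find_polyA(g, hit, wide))
  }
  expect_gte(n_wide, n_narrow)
})

test_that("classification rules follow the annotation order", {
  short_pa <- tibble::tibble(start = 1700L, end = 1720L, a_fraction = 1,
                             window_class = "SHORT", distance = 600L)
  long_pa <- tibble::tibble(start = 6400L, end = 6420L, a_fraction = 1,
                            window_class = "LONG", distance = 5300L)
  tsd_yes <- tibble::tibble(length = 9L, left_start = 1L, right_start = 2L,
                            left_seq = "x", right_seq = "x", identity = 100,
                            off_left = 0L, off_right = 0L)
  tsd_no <- tsd_yes[0, ]
  h2 <- make_hit("c", c(1000, 1090), c(1077, 1167))
  s2 <- classify_element(h2, short_pa, tsd_yes)
  expect_equal(s2$element_class, "SIDER2")
  expect_equal(s2$confidence, "full")
  h1 <- make_hit("c", 1000, 1077)
  expect_equal(classify_element(h1, long_pa, tsd_yes)$element_class,
               "LINE_DIRE")
  expect_equal(classify_element(h1, short_pa, tsd_no)$element_class, "SIDER1")
  expect_equal(classify_element(h1, short_pa, tsd_no)$confidence, "no_tsd")
  # no poly-A at all falls through to UNCLASSIFIED
  expect_equal(classify_element(h1, short_pa[0, ], tsd_no)$element_class,
               "UNCLASSIFIED")
  expect_error(classify_element(h1[0, ], short_pa, tsd_no), "hallmark")
})

test_that("annotation recovers planted elements with correct classes", {
  specs <- tibble::tibble(
    class = c("SIDER1", "SIDER2", "LINE_DIRE", "SIDER1"),
    divergence_pct = c(0, 5, 10, 5),
    strand = c("+", "-", "+", "-"),
    with_tsd = c(TRUE, TRUE, TRUE, FALSE))
  pg <- plant_genome(1, 60000, specs, rng_seed = 9)
  ann <- annotate_genome(pg$genome, pg$queries)
  expect_equal(nrow(ann), 4L)
  # match annotations to truth by overlap
  for (i in seq_len(nrow(pg$truth))) {
    tr <- pg$truth[i, ]
    j <- which(ann$start < tr$end & ann$end > tr$start)
    expect_length(j, 1L)
    expect_equal(ann$element_class[j], tr$element_class)
    expect_equal(ann$strand[j], tr$strand)
    expect_equal(ann$confidence[j], if (tr$with_tsd) "full" else "no_tsd")
  }
})

test_that("a hallmark without context stays unclassified and empty genomes give no loci", {
  q <- sample_ribozyme(rng_seed = 7)$seq
  bg <- fixture_background(8000, seed = 31)
  g <- c(c = plant_at(bg, q, 3000))
  # the poly-A window overruns the short contig; truncation is warned
  suppressWarnings(ann <- annotate_genome(g, c(q = q)))
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$element_class, "UNCLASSIFIED")
  none <- annotate_genome(c(c = fixture_background(5000, seed = 32)),
                          c(q = q))
  expect_equal(nrow(none), 0L)
})

test_that("a NAR-like element is recognised through its shared ends", {
  ref <- build_element("LINE_DIRE", rng_seed = 40, body_len = 5200L)
  nar <- build_element("SIDE_NAR", rng_seed = 41,
                       hallmark_seq = substr(ref$seq, 1,
                                             ref$hallmark_spans$end[1]),
                       long_ref = ref$seq, body_len = 550L)
  bg <- fixture_background(30000, seed = 42)
  tsd <- "GATTACAGG"
  g <- c(c = plant_at(plant_at(bg, paste0(tsd, ref$seq, tsd), 20000),
                      paste0(tsd, nar$seq, tsd), 4000))
  q <- substr(ref$seq, 1, ref$hallmark_spans$end[1])
  cfg <- annotate_config(long_ref = ref$seq)
  ann <- annotate_genome(g, c(q = q), cfg)
  expect_setequal(ann$element_class, c("SIDE_NAR", "LINE_DIRE"))
})
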