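test_that("information values hit their closed forms", {
  uniform <- matrix(0.25, nrow = 4, ncol = 1,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(information_vector(uniform), 0)
  onehot <- matrix(c(1, 0, 0, 0), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(information_vector(onehot), log(4))
  half <- matrix(c(0.5, 0.5, 0, 0), nrow = 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(information_vector(half), log(2))
})

test_that("core positions maximize summed information with leftmost ties", {
  info <- c(0.1, 0.9, 0.9, 0.9, 0.9, 0.9, 0.1)
  expect_equal(core_positions(info), 2:6)
  expect_equal(core_positions(rep(1, 6)), 1:5)  # tie -> leftmost
  expect_equal(core_positions(c(1, 1, 1)), 1:3)  # short matrix: all positions
})

test_that("consensus scores 1, worst-base site scores 0, and N sites error", {
  p <- toy_pwm_informative()
  sc <- match_scores(p, "ACT")
  expect_equal(unname(sc), c(1, 1))
  worst <- match_scores(p, "CAA")  # per-position minimum base
  expect_equal(unname(worst[["matrix_score"]]), 0)
  expect_error(match_scores(p, "ANT"), "N")
  expect_error(match_scores(p, "AC"), "length")
})

test_that("match scoring equals the brute-force oracle on every site of toy matrices", {
  set.seed(31)
  for (L in 2:4) {
    freq <- matrix(0, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in 1:L) {
      v <- -log(runif(4)); freq[, j] <- v / sum(v)
    }
    p <- pwm(paste0("T", L), freq = freq)
    for (site in all_words(L)) {
      sc <- match_scores(p, site)
      expect_equal(sc[["matrix_score"]], oracle_match_score(freq, site),
                   tolerance = 1e-12)
      expect_equal(sc[["core_score"]],
                   oracle_match_score(freq, site, p$core_idx),
                   tolerance = 1e-12)
      expect_gte(sc[["matrix_score"]], 0)
      expect_lte(sc[["matrix_score"]], 1)
    }
  }
})

test_that("mutating a site toward the consensus never decreases the score", {
  set.seed(33)
  p <- gen_pwm(8, 0.7, seed = 33, id = "MONO")
  cons <- strsplit(pwm_consensus(p), "")[[1]]
  for (rep in 1:20) {
    site <- strsplit(random_dna(8), "")[[1]]
    before <- match_scores(p, paste(site, collapse = ""))[["matrix_score"]]
    j <- sample.int(8, 1)
    site[j] <- cons[j]
    after <- match_scores(p, paste(site, collapse = ""))[["matrix_score"]]
    expect_gte(after, before - 1e-12)
  }
})

test_that("scanning finds planted consensus sites and respects strand symmetry", {
  set.seed(35)
  p <- gen_pwm(12, 0.95, seed = 36, id = "PLANT")
  cons <- pwm_consensus(p)
  at <- function(n) random_dna(n, probs = c(0.5, 0, 0, 0.5))
  # non-repetitive flank with no C/G keeps the informative matrix quiet
  seq <- paste0(at(60), cons, at(60))
  hits <- scan_pwms(c(s1 = seq), p, core_cut = 1.0, mss_cut = 0.9)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 60L)
  expect_equal(plus$matrix_score, 1.0)

  # strand symmetry: a + hit at s implies a - hit on the reverse complement
  rc_hits <- scan_pwms(c(s1 = reverse_complement(seq)), p,
                       core_cut = 1.0, mss_cut = 0.9)
  minus <- rc_hits[rc_hits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$start, nchar(seq) - 60L - 12L)

  # cutoffs (1,1) on a sequence lacking the consensus
  none <- scan_pwms(c(s1 = at(100)), p, core_cut = 1, mss_cut = 1)
  expect_equal(nrow(none), 0L)
})

test_that("cutoffs (0,0) return every window on both strands", {
  set.seed(37)
  seq <- random_dna(40)
  p <- toy_pwm_informative()
  hits <- scan_pwms(c(x = seq), p, core_cut = 0, mss_cut = 0)
  expect_equal(nrow(hits), (40 - 3 + 1) * 2)
})

test_that("box annotation finds a planted TATA and stays quiet in GC-poor windows", {
  set.seed(39)
  gcpoor <- function(n) random_dna(n, probs = c(0.5, 0, 0, 0.5))
  # TATAAAA planted so its first base sits at -30
  flank <- 3000
  chars <- strsplit(gcpoor(2 * flank + 1), "")[[1]]
  chars[(flank - 30 + 1):(flank - 30 + 7)] <- strsplit("TATAAAA", "")[[1]]
  r <- promoter_record("g", paste(chars, collapse = ""), flank)
  ann <- annotate_boxes(r, core_cut = 1.0, mss_cut = 0.85)
  tata <- ann[ann$box_type == "TATA", ]
  expect_gt(nrow(tata), 0L)
  expect_true((flank - 30) %in% tata$start)
  # no GC box can match in a C/G-free search window
  expect_equal(nrow(ann[ann$box_type == "GC", ]), 0L)
  # window outside the sequence errors
  expect_error(annotate_boxes(promoter_record("s", random_dna(50), 25),
                              windows = list(TATA = relative_window(-100, -1),
                                             CCAAT = relative_window(-200, -1),
                                             GC = relative_window(-200, -1))),
               "outside")
})
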