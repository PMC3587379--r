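test_that("occurrence counting is overlapping", {
  expect_equal(oracle_count("AA", "AAAA"), 3L)
  cnt <- promkit:::count_oligos("AAAA", 2L)
  expect_equal(unname(cnt[["AA"]]), 3)
})

test_that("k-mer rate profiles normalize per window and locate k-mers", {
  r <- promoter_record("g", strrep("A", 40), 20)
  prof <- kmer_rate_profile(list(r), k = 1, window = 20)
  expect_true(all(prof$rates["A", ] == 1))
  expect_true(all(prof$rates[c("C", "G", "T"), ] == 0))

  r2 <- promoter_record("g", strrep("ACGT", 10), 20)
  prof2 <- kmer_rate_profile(list(r2), k = 2, window = 4)
  # every 4-bp window holds 3 overlapping distinct dimers, each at rate 1/3
  expect_true(all(colSums(prof2$rates) - 1 < 1e-9))
  first <- prof2$rates[, 1]
  expect_equal(unname(first[c("AC", "CG", "GT")]), rep(1 / 3, 3))

  # per-window rates over all 4^k k-mers sum to 1
  set.seed(2)
  r3 <- promoter_record("g", random_dna(60), 30)
  for (k in 1:3) {
    p <- kmer_rate_profile(list(r3), k = k, window = 20)
    expect_equal(unname(colSums(p$rates)), rep(1, ncol(p$rates)),
                 tolerance = 1e-9)
  }
  expect_error(kmer_rate_profile(list(r3), k = 2, window = 1), ">= k")
})

test_that("profile clustering assigns anchors to themselves and recovers planted groups", {
  set.seed(5)
  npos <- 50
  anchor_a <- dnorm(seq(-3, 3, length.out = npos))
  anchor_g <- -anchor_a + 0.5
  # build synthetic rates: mononucleotide anchors exact, di/tri-mers = anchor + noise
  mk <- function(base, labels, noise = 0.02) {
    m <- t(vapply(seq_along(labels), function(i)
      base + rnorm(npos, sd = noise), numeric(npos)))
    rownames(m) <- labels
    m
  }
  k1 <- rbind(mk(anchor_a, c("A", "T")), mk(anchor_g, c("C", "G")))
  k1 <- k1[c("A", "C", "G", "T"), ]
  dimers <- all_words(2)
  truth2 <- ifelse(seq_along(dimers) %% 2 == 0, "A", "G")
  k2 <- rbind(mk(anchor_a, dimers[truth2 == "A"]), mk(anchor_g, dimers[truth2 == "G"]))
  trimers <- all_words(3)
  truth3 <- ifelse(seq_along(trimers) %% 2 == 0, "A", "G")
  k3 <- rbind(mk(anchor_a, trimers[truth3 == "A"]), mk(anchor_g, trimers[truth3 == "G"]))
  profs <- list(list(positions = 1:npos, rates = k1),
                list(positions = 1:npos, rates = k2),
                list(positions = 1:npos, rates = k3))
  cl <- cluster_profiles(profs)
  expect_true("A" %in% cl$group_A)
  expect_true("G" %in% cl$group_G)
  expect_length(c(cl$group_A, cl$group_G), 84L)
  truth <- c(A = "A", C = "G", G = "G", T = "A",
             setNames(truth2, dimers), setNames(truth3, trimers))
  assigned <- c(setNames(rep("A", length(cl$group_A)), cl$group_A),
                setNames(rep("G", length(cl$group_G)), cl$group_G))
  expect_gte(mean(assigned[names(truth)] == truth), 0.95)
})

test_that("hexamer z-scores match a brute-force recount", {
  set.seed(9)
  windows <- vapply(1:5, function(i) random_dna(200), "")
  bg <- background_model(base_freq = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  st <- hexamer_zscores(windows, bg)
  expect_equal(nrow(st), 4096L)
  N <- sum(nchar(windows) - 5)
  for (w in c("AAAAAA", "ACGTAC", st$oligo[which.max(st$z)])) {
    n <- sum(vapply(windows, function(s) oracle_count(w, s), numeric(1)))
    p <- prod(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)[strsplit(w, "")[[1]]])
    z <- (n - N * p) / sqrt(N * p * (1 - p))
    row <- st[st$oligo == w, ]
    expect_equal(row$n, n)
    expect_equal(row$z, z, tolerance = 1e-9)
  }
  # sign conventions
  absent <- st[st$n == 0 & st$p > 0, ]
  expect_true(all(absent$z < 0))
})

test_that("top_hexamers ranks by z with lexicographic ties and is order-stable", {
  st <- data.frame(oligo = c("TTTTTT", "AAAAAA", "CCCCCC", "GGGGGG"),
                   n = c(5, 5, 1, 9), p = 0.1, expected = 2,
                   z = c(2, 2, -1, 20), flagged = FALSE)
  expect_equal(top_hexamers(st, 3), c("GGGGGG", "AAAAAA", "TTTTTT"))
  expect_equal(top_hexamers(st[sample(4), ], 3),
               c("GGGGGG", "AAAAAA", "TTTTTT"))
  expect_equal(top_hexamers(st, 0), character(0))
  expect_error(top_hexamers(st, 10), "only")
})

test_that("overrep_oligos reports planted words and little else under the null", {
  set.seed(13)
  bg <- background_model(base_freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  # background-matched regions: essentially no hexamer above z = 5 when the
  # expected counts are large enough for the normal approximation
  null_regions <- vapply(1:10, function(i) random_dna(2000), "")
  res_null <- overrep_oligos(null_regions, bg, kmin = 6, kmax = 6)
  expect_lt(nrow(res_null), 5)

  # 50 tandem copies of a fixed 10-mer must be reported
  planted <- paste0(strrep("ACGGTTCAGA", 50))
  res <- overrep_oligos(c(null_regions, planted), bg, kmin = 6, kmax = 12)
  expect_true("ACGGTTCAGA" %in% res$oligo)
  expect_gt(res$z[res$oligo == "ACGGTTCAGA"], 5)

  expect_equal(nrow(overrep_oligos(null_regions, bg, zthresh = Inf)), 0L)
  expect_error(overrep_oligos(null_regions, bg, kmin = 8, kmax = 6), "kmin")
})

test_that("Markov background models reproduce generating probabilities", {
  set.seed(17)
  seqs <- vapply(1:5, function(i) random_dna(2000, probs = c(0.4, 0.1, 0.1, 0.4)), "")
  bg0 <- background_model(seqs = seqs, order = 0)
  expect_equal(unname(oligo_prob(bg0, "AT")), 0.16, tolerance = 0.03)
  bg1 <- background_model(seqs = seqs, order = 1)
  # i.i.d. data: order-1 estimate close to the i.i.d. product
  expect_equal(unname(oligo_prob(bg1, "ATA")), 0.4^3, tolerance = 0.02)
})
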