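# Independent brute-force oracles used to validate the fast implementations.
# These deliberately re-derive everything from first principles and share no
# code with the package internals.

# naive overlapping-occurrence count of `word` in `seq`
oracle_count <- function(word, seq) {
  k <- nchar(word)
  L <- nchar(seq)
  if (L < k) return(0L)
  sum(vapply(1:(L - k + 1L), function(i) substr(seq, i, i + k - 1L) == word,
             logical(1)))
}

# MATCH-style score of one site by direct formula evaluation
oracle_match_score <- function(freq, site, idx = seq_len(ncol(freq))) {
  info <- numeric(ncol(freq))
  for (j in seq_len(ncol(freq))) {
    f <- freq[, j]
    info[j] <- sum(ifelse(f > 0, f * log(4 * f), 0))
  }
  bases <- c(A = 1, C = 2, G = 3, T = 4)
  chars <- strsplit(site, "")[[1]]
  cur <- 0; mx <- 0; mn <- 0
  for (j in idx) {
    cur <- cur + info[j] * freq[bases[[chars[j]]], j]
    mx <- mx + info[j] * max(freq[, j])
    mn <- mn + info[j] * min(freq[, j])
  }
  if (mx - mn < 1e-15) return(1)
  unname((cur - mn) / (mx - mn))
}

# frequent itemsets by full powerset enumeration
oracle_itemsets <- function(transactions, min_support) {
  items <- sort(unique(unlist(transactions)))
  n <- length(transactions)
  out <- list()
  for (size in seq_along(items)) {
    for (s in utils::combn(items, size, simplify = FALSE)) {
      cnt <- sum(vapply(transactions, function(tx) all(s %in% tx), logical(1)))
      if (cnt / n >= min_support) {
        out[[paste(s, collapse = "/")]] <- cnt / n
      }
    }
  }
  out
}

# hypergeometric upper tail by exact integer arithmetic (exactly
# representable in doubles for K <= 50)
oracle_hypergeom <- function(K, T_, k, t) {
  if (t == 0) return(1)
  num <- 0
  for (i in t:min(T_, k)) num <- num + choose(T_, i) * choose(K - T_, k - i)
  num / choose(K, k)
}

# all DNA words of length k
all_words <- function(k) {
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1) for (i in 2:k) out <- as.vector(t(outer(out, bases, paste0)))
  sort(out)
}

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# small toy matrices reused across PWM tests
toy_pwm_informative <- function() {
  pwm("TOY1", freq = matrix(c(
    0.7, 0.1, 0.1, 0.1,
    0.1, 0.7, 0.1, 0.1,
    0.1, 0.1, 0.1, 0.7), nrow = 4,
    dimnames = list(c("A", "C", "G", "T"), NULL)))
}
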