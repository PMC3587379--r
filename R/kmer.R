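# Nucleotide composition profiling and over-represented oligonucleotides.
#
# Occurrence counting is always over overlapping positions (the count of
# "AA" in "AAAA" is 3). Over-representation is scored against a background
# model by the binomial normal approximation:
#   z = (n - N p) / sqrt(N p (1 - p))
# with n the pooled occurrence count, N the pooled number of scanned
# positions, and p the background probability of the oligo.

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  if (k == 1L) return(bases)
  out <- bases
  for (i in 2:k) out <- as.vector(t(outer(out, bases, paste0)))
  sort(out)
}

count_oligos <- function(seqs, k) {
  # overlapping occurrence counts of all 4^k oligos, pooled over seqs;
  # windows containing N contribute nothing
  set <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  colSums(counts)
}

scanned_positions <- function(seqs, k) {
  sum(pmax(0L, nchar(seqs) - k + 1L))
}

#' Positional k-mer occurrence-rate profile
#'
#' Slides a window (default 20 bp) along each record and computes, per
#' window, the occurrence rate of every k-mer (k = 1, 2 or 3): overlapping
#' occurrences divided by the `window - k + 1` scanned positions. Rates are
#' averaged across records per TSS-relative window start.
#'
#' @param records List of `promoter_record`s sharing the same TSS-relative
#'   extent.
#' @param k Word size, 1, 2 or 3.
#' @param window Window size in bp, default 20.
#' @param step Slide step in bp, default 1.
#' @return A list with `positions` (TSS-relative window starts) and `rates`
#'   (matrix, one row per k-mer, one column per window).
#' @export
kmer_rate_profile <- function(records, k, window = 20L, step = 1L) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  window <- as.integer(window)
  if (window < k) stop("window must be >= k")
  if (inherits(records, "promoter_record")) records <- list(records)
  L <- nchar(records[[1]]$seq)
  if (any(vapply(records, function(r) nchar(r$seq), 1L) != L)) {
    stop("all records must share the same length")
  }
  kmers <- all_kmers(k)
  nk <- length(kmers)
  starts <- seq.int(1L, L - window + 1L, by = step)
  denom <- window - k + 1L
  acc <- matrix(0, nrow = nk, ncol = length(starts),
                dimnames = list(kmers, NULL))
  for (r in records) {
    codes <- encode_bases(r$seq)
    # index of the k-mer starting at each position (NA where N intrudes)
    m <- codes[seq_len(L - k + 1L)]
    if (k >= 2L) for (j in 1:(k - 1L)) m <- m * 4L + codes[(1L + j):(L - k + 1L + j)]
    m <- m + 1L
    # cumulative count per k-mer index
    cum <- matrix(0L, nrow = L - k + 2L, ncol = nk)
    ok <- !is.na(m)
    ind <- matrix(0L, nrow = L - k + 1L, ncol = nk)
    ind[cbind(which(ok), m[ok])] <- 1L
    cum[-1L, ] <- apply(ind, 2L, cumsum)
    cnt <- cum[starts + denom, , drop = FALSE] - cum[starts, , drop = FALSE]
    acc <- acc + t(cnt) / denom
  }
  rates <- acc / length(records)
  pos0 <- starts - 1L
  positions <- index_to_rel_point(pos0, records[[1]]$tss_index)
  list(k = k, window = window, positions = positions, rates = rates)
}

#' Cluster positional k-mer profiles into the A-like and G-like groups
#'
#' The averaged positional distributions of all 84 mono-, di- and tri-mers
#' fall into two broad families around the TSS, anchored by the adenine and
#' guanine mononucleotide profiles. Each k-mer is assigned to the anchor its
#' profile correlates with more strongly (Pearson r); ties go to the A group
#' with a warning, and zero-variance profiles are assigned by the k-mer's
#' own GC content.
#'
#' @param profiles List of profiles from [kmer_rate_profile()] for k = 1, 2,
#'   3 on the same position grid.
#' @return List with `group_A`, `group_G` (k-mer labels) and `correlations`
#'   (matrix of r against the two anchors).
#' @export
cluster_profiles <- function(profiles) {
  mats <- lapply(profiles, `[[`, "rates")
  pos <- profiles[[1]]$positions
  for (p in profiles) {
    if (!identical(p$positions, pos)) stop("profiles must share a position grid")
  }
  rates <- do.call(rbind, mats)
  if (!all(c("A", "G") %in% rownames(rates))) {
    stop("profiles must include the mononucleotide (k = 1) profile")
  }
  anchor_a <- rates["A", ]
  anchor_g <- rates["G", ]
  labels <- rownames(rates)
  cors <- matrix(NA_real_, nrow = nrow(rates), ncol = 2,
                 dimnames = list(labels, c("A", "G")))
  group <- character(nrow(rates))
  for (i in seq_len(nrow(rates))) {
    v <- rates[i, ]
    if (stats::sd(v) == 0) {
      gc <- mean(strsplit(labels[i], "")[[1]] %in% c("G", "C"))
      group[i] <- if (gc >= 0.5) "G" else "A"
      message("constant profile for ", labels[i], ": assigned by GC content")
      next
    }
    ra <- stats::cor(v, anchor_a)
    rg <- stats::cor(v, anchor_g)
    cors[i, ] <- c(ra, rg)
    if (ra == rg) {
      warning("tie for ", labels[i], ": assigned to A group")
      group[i] <- "A"
    } else group[i] <- if (ra > rg) "A" else "G"
  }
  list(group_A = labels[group == "A"], group_G = labels[group == "G"],
       correlations = cors)
}

# ---------------------------------------------------------------------------
# Background models

#' Background oligonucleotide model
#'
#' Estimates background oligo probabilities either from explicit base
#' frequencies (order 0) or from a background FASTA/sequence set as a Markov
#' chain of order 0-2. The genome-wide background of a full annotation
#' pipeline is approximated by whatever sequence set the user supplies.
#'
#' @param seqs Character vector of background sequences (ignored when
#'   `base_freq` is given).
#' @param base_freq Optional named numeric `c(A=,C=,G=,T=)`; implies order 0.
#' @param order Markov order, 0, 1 or 2.
#' @return An object of class `background_model` with an `oligo_prob(w)`
#'   closure.
#' @export
background_model <- function(seqs = NULL, base_freq = NULL, order = 0L) {
  order <- as.integer(order)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  if (!is.null(base_freq)) {
    stopifnot(all(c("A", "C", "G", "T") %in% names(base_freq)))
    base_freq <- base_freq[c("A", "C", "G", "T")] / sum(base_freq)
    order <- 0L
    trans <- NULL
  } else {
    if (is.null(seqs)) stop("supply seqs or base_freq")
    cnt1 <- count_oligos(seqs, 1L)
    base_freq <- cnt1 / sum(cnt1)
    trans <- NULL
    if (order > 0L) {
      ck <- count_oligos(seqs, order)          # context counts
      ck1 <- count_oligos(seqs, order + 1L)    # context+next counts
      trans <- list(context = ck / sum(ck), joint = ck1)
    }
  }
  obj <- list(order = order, base_freq = base_freq, trans = trans)
  class(obj) <- "background_model"
  obj
}

#' Background probability of an oligonucleotide
#'
#' @param model A [background_model()].
#' @param oligos Character vector of oligos over A,C,G,T.
#' @return Numeric vector of probabilities.
#' @export
oligo_prob <- function(model, oligos) {
  stopifnot(inherits(model, "background_model"))
  vapply(oligos, function(w) .oligo_prob_one(model, w), numeric(1), USE.NAMES = FALSE)
}

.oligo_prob_one <- function(model, w) {
  chars <- strsplit(w, "")[[1]]
  if (model$order == 0L) return(prod(model$base_freq[chars]))
  m <- model$order
  k <- nchar(w)
  if (k <= m) {
    # short word: marginalize with the context distribution where possible
    if (k == m) return(unname(model$trans$context[w]))
    return(prod(model$base_freq[chars]))
  }
  ctx0 <- substr(w, 1, m)
  p <- model$trans$context[ctx0]
  if (is.na(p)) p <- prod(model$base_freq[strsplit(ctx0, "")[[1]]])
  for (i in seq_len(k - m)) {
    ctx <- substr(w, i, i + m - 1L)
    nxt <- substr(w, i, i + m)
    joint <- model$trans$joint[nxt]
    denom <- sum(model$trans$joint[paste0(ctx, c("A", "C", "G", "T"))])
    cond <- if (is.na(joint) || denom == 0) 0 else unname(joint) / denom
    p <- p * cond
  }
  unname(p)
}

# ---------------------------------------------------------------------------
# Z-scores

#' Over-representation z-scores for all oligos of one width
#'
#' Pools overlapping occurrence counts over all supplied windows and scores
#' each oligo against the background by the binomial normal approximation.
#' When the background probability is 0 but the oligo was observed, `z` is
#' `Inf` and flagged; when both are 0, `z = 0`.
#'
#' @param windows Character vector of promoter-window sequences.
#' @param background A [background_model()].
#' @param k Word size, default 6 (hexamers).
#' @return Data frame with columns `oligo`, `n` (observed count), `p`
#'   (background probability), `expected`, `z`, `flagged`.
#' @export
hexamer_zscores <- function(windows, background, k = 6L) {
  k <- as.integer(k)
  n <- count_oligos(windows, k)
  N <- scanned_positions(windows, k)
  oligos <- names(n)
  p <- oligo_prob(background, oligos)
  expected <- N * p
  denom <- sqrt(N * p * (1 - p))
  z <- ifelse(denom > 0, (n - expected) / denom, NA_real_)
  flagged <- p == 0 & n > 0
  z[flagged] <- Inf
  z[p == 0 & n == 0] <- 0
  z[p >= 1] <- 0
  data.frame(oligo = oligos, n = as.numeric(n), p = p,
             expected = expected, z = z, flagged = flagged,
             row.names = NULL)
}

#' Select the top over-represented hexamers
#'
#' @param stats Data frame from [hexamer_zscores()].
#' @param n Number of hexamers to return, default 100 (the SVM feature set).
#' @return Character vector of hexamers sorted by z descending, ties broken
#'   lexicographically.
#' @export
top_hexamers <- function(stats, n = 100L) {
  finite <- stats[is.finite(stats$z) | stats$flagged, , drop = FALSE]
  # flagged (p = 0, n > 0) oligos are maximally over-represented: rank first
  key <- ifelse(finite$flagged, Inf, finite$z)
  if (n > nrow(finite)) stop("asked for ", n, " hexamers but only ",
                             nrow(finite), " have defined z")
  if (n == 0L) return(character(0))
  ord <- order(-key, finite$oligo)
  finite$oligo[ord][seq_len(n)]
}

#' Over-represented oligonucleotides of width 6-12
#'
#' Scores every oligo width from `kmin` to `kmax` against the background and
#' reports those with z above the threshold (default 5). For widths above 8
#' only observed oligos are enumerated (absent oligos cannot exceed a
#' positive threshold).
#'
#' @param regions Character vector of promoter-region sequences.
#' @param background A [background_model()].
#' @param kmin,kmax Width range, defaults 6 and 12.
#' @param zthresh Z-score threshold, default 5.
#' @return Data frame as [hexamer_zscores()] plus a `k` column, sorted by z
#'   descending.
#' @export
overrep_oligos <- function(regions, background, kmin = 6L, kmax = 12L,
                           zthresh = 5) {
  if (kmin > kmax) stop("kmin must not exceed kmax")
  out <- list()
  for (k in kmin:kmax) {
    if (4^k <= 65536) {
      st <- hexamer_zscores(regions, background, k = k)
    } else {
      st <- .observed_zscores(regions, background, k)
    }
    st <- st[(st$z > zthresh) & !is.na(st$z), , drop = FALSE]
    if (nrow(st)) {
      st$k <- k
      out[[length(out) + 1L]] <- st
    }
  }
  if (!length(out)) {
    return(data.frame(oligo = character(0), n = numeric(0), p = numeric(0),
                      expected = numeric(0), z = numeric(0),
                      flagged = logical(0), k = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(-res$z, res$oligo), , drop = FALSE]
}

.observed_zscores <- function(regions, background, k) {
  # enumerate only oligos that actually occur (N-free)
  subs <- unlist(lapply(regions, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  }))
  subs <- subs[!grepl("N", subs, fixed = TRUE)]
  tab <- table(subs)
  N <- scanned_positions(regions, k)
  oligos <- names(tab)
  p <- oligo_prob(background, oligos)
  expected <- N * p
  denom <- sqrt(N * p * (1 - p))
  z <- ifelse(denom > 0, (as.numeric(tab) - expected) / denom, Inf)
  flagged <- p == 0
  data.frame(oligo = oligos, n = as.numeric(tab), p = p,
             expected = expected, z = z, flagged = flagged, row.names = NULL)
}
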