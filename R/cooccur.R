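# Co-occurrence mining of TFBSs in a gene group.
#
# Each promoter is a transaction whose items are the TF matrices with at
# least one binding-site hit. Frequent itemsets are mined levelwise
# (Apriori) and each combination of size >= 2 is scored against a
# background promoter set with the hypergeometric upper tail
#   P(t) = sum_{i=t}^{min(T,k)} C(T,i) C(K-T, k-i) / C(K,k)
# where K = background promoters, T = observed promoters, k = background
# promoters carrying the combination, t = observed promoters carrying it.

#' Map TFBS hits to per-promoter transactions
#'
#' @param hits Data frame with columns `seq_id` and `matrix_id` (e.g. from
#'   [scan_pwms()]).
#' @param promoter_ids Optional character vector of all promoter ids;
#'   promoters without hits are retained as empty transactions.
#' @return Named list of character vectors (sorted unique item sets), class
#'   `transactions`.
#' @export
build_transactions <- function(hits, promoter_ids = NULL) {
  if (is.null(promoter_ids)) promoter_ids <- unique(hits$seq_id)
  tx <- lapply(stats::setNames(promoter_ids, promoter_ids), function(id) {
    sort(unique(hits$matrix_id[hits$seq_id == id]))
  })
  class(tx) <- "transactions"
  tx
}

.norm_frac <- function(x, what) {
  # accept percent-style inputs (e.g. 90) and fractions (0.9)
  if (x > 1 && x <= 100) x <- x / 100
  if (x <= 0 || x > 1) stop(what, " must lie in (0, 1] (or 0-100 as percent)")
  x
}

support_of <- function(transactions, itemset) {
  mean(vapply(transactions, function(tx) all(itemset %in% tx), logical(1)))
}

#' Apriori frequent-itemset and association-rule mining
#'
#' Levelwise search with candidate pruning: a (k)-itemset is a candidate
#' only if every (k-1)-subset is frequent. Rules `A => B` are generated from
#' frequent itemsets with `confidence = support(A u B) / support(A)`.
#' Support and confidence accept percent (90) or fraction (0.9) inputs.
#'
#' @param transactions A [build_transactions()] result (or plain list of
#'   character vectors).
#' @param min_support Minimum itemset support, default 0.9.
#' @param min_confidence Minimum rule confidence, default 0.9.
#' @return List with `itemsets` (data frame: `itemset` (slash-joined),
#'   `size`, `support`, `count`, plus list column `items`) ordered by (size,
#'   support desc, lexical), and `rules` (data frame: `lhs`, `rhs`,
#'   `support`, `confidence`).
#' @export
apriori <- function(transactions, min_support = 0.9, min_confidence = 0.9) {
  min_support <- .norm_frac(min_support, "min_support")
  min_confidence <- .norm_frac(min_confidence, "min_confidence")
  n <- length(transactions)
  empty <- list(itemsets = data.frame(itemset = character(0), size = integer(0),
                                      support = numeric(0), count = integer(0)),
                rules = data.frame(lhs = character(0), rhs = character(0),
                                   support = numeric(0), confidence = numeric(0)))
  empty$itemsets$items <- list()
  if (n == 0L) return(empty)
  items <- sort(unique(unlist(transactions)))
  if (!length(items)) return(empty)
  # transaction-item incidence matrix
  inc <- vapply(items, function(it) {
    vapply(transactions, function(tx) it %in% tx, logical(1))
  }, logical(n))
  inc <- matrix(inc, nrow = n, dimnames = list(NULL, items))

  freq <- list()  # list of (items, count)
  # level 1
  cnt1 <- colSums(inc)
  lvl <- lapply(items[cnt1 / n >= min_support], function(it) list(items = it))
  add_level <- function(cand) {
    kept <- list()
    for (cs in cand) {
      cnt <- sum(rowSums(inc[, cs, drop = FALSE]) == length(cs))
      if (cnt / n >= min_support) {
        kept[[length(kept) + 1L]] <- list(items = cs, count = cnt)
      }
    }
    kept
  }
  level_sets <- add_level(lapply(lvl, `[[`, "items"))
  freq <- level_sets
  while (length(level_sets) > 1L) {
    prev <- lapply(level_sets, `[[`, "items")
    k <- length(prev[[1]]) + 1L
    # candidate join: pairs sharing the first k-2 items
    cand <- list()
    for (i in seq_along(prev)) for (j in seq_along(prev)) {
      if (j <= i) next
      a <- prev[[i]]; b <- prev[[j]]
      if (k == 2L || identical(a[-(k - 1L)], b[-(k - 1L)])) {
        u <- sort(unique(c(a, b)))
        if (length(u) == k) cand[[paste(u, collapse = "\r")]] <- u
      }
    }
    # prune: all (k-1)-subsets frequent
    prev_keys <- vapply(prev, paste, "", collapse = "\r")
    cand <- Filter(function(u) {
      all(vapply(seq_along(u), function(d)
        paste(u[-d], collapse = "\r") %in% prev_keys, logical(1)))
    }, cand)
    level_sets <- add_level(unname(cand))
    freq <- c(freq, level_sets)
    if (!length(level_sets)) break
  }
  if (!length(freq)) return(empty)
  sizes <- vapply(freq, function(f) length(f$items), 1L)
  counts <- vapply(freq, `[[`, 1, "count")
  labels <- vapply(freq, function(f) paste(f$items, collapse = "/"), "")
  itemsets <- data.frame(itemset = labels, size = sizes,
                         support = counts / n, count = as.integer(counts))
  itemsets$items <- lapply(freq, `[[`, "items")
  ord <- order(itemsets$size, -itemsets$support, itemsets$itemset)
  itemsets <- itemsets[ord, , drop = FALSE]
  rownames(itemsets) <- NULL

  # rules from frequent itemsets of size >= 2
  sup_lookup <- stats::setNames(itemsets$support,
                                vapply(itemsets$items, paste, "", collapse = "\r"))
  rules <- list()
  for (i in which(itemsets$size >= 2L)) {
    s <- itemsets$items[[i]]
    sup_s <- itemsets$support[i]
    for (m in 1:(length(s) - 1L)) {
      combs <- utils::combn(s, m, simplify = FALSE)
      for (a in combs) {
        key <- paste(a, collapse = "\r")
        sup_a <- sup_lookup[key]
        if (is.na(sup_a)) sup_a <- support_of(transactions, a)
        conf <- sup_s / sup_a
        if (conf >= min_confidence) {
          rules[[length(rules) + 1L]] <- data.frame(
            lhs = paste(a, collapse = "/"),
            rhs = paste(setdiff(s, a), collapse = "/"),
            support = sup_s, confidence = conf)
        }
      }
    }
  }
  rules <- if (length(rules)) do.call(rbind, rules) else empty$rules
  if (nrow(rules)) {
    rules <- rules[order(-rules$confidence, -rules$support, rules$lhs, rules$rhs), ]
    rownames(rules) <- NULL
  }
  list(itemsets = itemsets, rules = rules)
}

#' Hypergeometric upper-tail probability of a TFBS combination
#'
#' `P(t) = sum_{i=t}^{min(T,k)} C(T,i) C(K-T, k-i) / C(K,k)`: the chance of
#' seeing at least `t` combination-bearing promoters among `T` observed when
#' `k` of the `K` background promoters carry the combination. Computed in
#' log-space for numerical stability.
#'
#' @param K Background set size.
#' @param T_ Observed set size (`T` in the model).
#' @param k Combination-bearing promoters in the background.
#' @param t Combination-bearing promoters in the observed set.
#' @return The p-value in (0, 1].
#' @export
hypergeom_p <- function(K, T_, k, t) {
  if (any(c(K, T_, k, t) < 0) || t > T_ || T_ > K || k > K || t > k) {
    stop("need 0 <= t <= min(T, k), T <= K, k <= K")
  }
  if (t == 0) return(1)
  upper <- min(T_, k)
  i <- t:upper
  lg <- lchoose(T_, i) + lchoose(K - T_, k - i) - lchoose(K, k)
  m <- max(lg)
  min(1, exp(m + log(sum(exp(lg - m)))))
}

#' Score frequent combinations against a background promoter set
#'
#' For each frequent itemset of size >= `min_size`, counts the observed
#' (`t` of `T`) and background (`k` of `K`) promoters containing it and
#' computes the hypergeometric upper-tail p-value, optionally with
#' Benjamini-Hochberg adjustment across itemsets. Background transactions
#' must be built with the same scanning parameters as the observed ones.
#'
#' @param itemsets Itemset data frame from [apriori()] (or a list of
#'   character vectors).
#' @param observed_tx,background_tx Transaction lists.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param min_size Smallest combination size scored, default 2.
#' @return Data frame with `itemset`, `support`, `t`, `k`, `T`, `K`,
#'   `p_value` (and `q_value` when adjusted), sorted by p-value.
#' @export
evaluate_combinations <- function(itemsets, observed_tx, background_tx,
                                  adjust = c("none", "BH"), min_size = 2L) {
  adjust <- match.arg(adjust)
  T_ <- length(observed_tx)
  K <- length(background_tx)
  if (K < T_) stop("background set (K=", K, ") smaller than observed set (T=", T_, ")")
  if (is.data.frame(itemsets)) {
    sets <- itemsets$items[itemsets$size >= min_size]
  } else {
    sets <- Filter(function(s) length(s) >= min_size, itemsets)
  }
  if (!length(sets)) {
    return(data.frame(itemset = character(0), support = numeric(0),
                      t = integer(0), k = integer(0), T = integer(0),
                      K = integer(0), p_value = numeric(0)))
  }
  rows <- lapply(sets, function(s) {
    t <- sum(vapply(observed_tx, function(tx) all(s %in% tx), logical(1)))
    k <- sum(vapply(background_tx, function(tx) all(s %in% tx), logical(1)))
    # a combination seen in observed promoters absent from the background
    # set makes t > k; score against k := t (most conservative valid count)
    k_eff <- max(k, t)
    data.frame(itemset = paste(s, collapse = "/"), support = t / T_,
               t = t, k = k, T = T_, K = K,
               p_value = hypergeom_p(K, T_, k_eff, t))
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$itemset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full gene-group co-occurrence analysis
#'
#' Scans observed and background promoters with the same matrices and
#' cutoffs, mines frequent TF itemsets in the observed group, and scores
#' them against the background.
#'
#' @param observed,background Named character vectors of promoter sequences.
#' @param pwms List of [pwm()]s.
#' @param min_support,min_confidence Apriori thresholds, defaults 0.9
#'   (percent inputs accepted).
#' @param core_cut,mss_cut MATCH cutoffs, defaults 1.0 and 0.7.
#' @param adjust Multiple-testing adjustment, `"none"` or `"BH"`.
#' @return List with `transactions`, `apriori` (itemsets + rules) and
#'   `results` (scored combinations).
#' @export
gene_group_analysis <- function(observed, background, pwms,
                                min_support = 0.9, min_confidence = 0.9,
                                core_cut = 1.0, mss_cut = 0.7,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  obs_hits <- scan_pwms(observed, pwms, core_cut = core_cut, mss_cut = mss_cut)
  bg_hits <- scan_pwms(background, pwms, core_cut = core_cut, mss_cut = mss_cut)
  obs_tx <- build_transactions(obs_hits, promoter_ids = names(observed))
  bg_tx <- build_transactions(bg_hits, promoter_ids = names(background))
  ap <- apriori(obs_tx, min_support, min_confidence)
  res <- evaluate_combinations(ap$itemsets, obs_tx, bg_tx, adjust = adjust)
  list(transactions = obs_tx, apriori = ap, results = res)
}
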