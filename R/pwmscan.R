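# MATCH-style PWM scanning.
#
# Each matrix position i carries an information value
#   I(i) = sum_b f(i,b) * ln(4 f(i,b))
# (0 for a uniform column, ln 4 for a one-hot column). A site is scored by
# the information-weighted frequency sum Current = sum_i I(i) f(i, site_i),
# min-max normalized over the per-position worst/best bases:
#   score = (Current - Min) / (Max - Min) in [0,1].
# The matrix similarity score (MSS) uses all positions; the core score uses
# the 5 consecutive positions with maximal summed information (leftmost on
# ties). Both strands are scanned; windows containing N are skipped.

#' Construct a position weight matrix object
#'
#' @param id,name Identifier and display name.
#' @param freq 4 x L numeric matrix of per-position base frequencies, rows
#'   named A, C, G, T; columns must each sum to 1.
#' @param counts Optional raw count matrix of the same shape.
#' @return An object of class `pwm` with precomputed `info` (per-position
#'   information values) and `core_idx` (core positions).
#' @export
pwm <- function(id, name = id, freq, counts = NULL) {
  freq <- as.matrix(freq)
  if (nrow(freq) != 4L) stop("freq must be a 4 x L matrix (rows A,C,G,T)")
  if (is.null(rownames(freq))) rownames(freq) <- c("A", "C", "G", "T")
  freq <- freq[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(freq) == 0L) stop("zero-length matrix")
  sums <- colSums(freq)
  if (any(abs(sums - 1) > 1e-6)) stop("PWM columns must sum to 1")
  info <- information_vector(freq)
  structure(
    list(id = id, name = name, freq = freq, counts = counts,
         length = ncol(freq), info = info,
         core_idx = core_positions(info)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s): %d positions, core %d-%d\n", x$id, x$name,
              x$length, min(x$core_idx), max(x$core_idx)))
  invisible(x)
}

#' Per-position information values of a PWM
#'
#' `I(i) = sum_b f(i,b) ln(4 f(i,b))` with `0 ln 0 = 0`. Uniform columns
#' score 0; one-hot columns score `ln 4`.
#'
#' @param x A `pwm` or a 4 x L frequency matrix.
#' @return Numeric vector of length L.
#' @export
information_vector <- function(x) {
  freq <- if (inherits(x, "pwm")) x$freq else as.matrix(x)
  apply(freq, 2L, function(f) {
    nz <- f > 0
    sum(f[nz] * log(4 * f[nz]))
  })
}

#' Core positions: 5 consecutive positions of maximal summed information
#' @param info Numeric vector of per-position information values.
#' @return Integer vector of min(5, L) consecutive indices (leftmost on ties).
#' @export
core_positions <- function(info) {
  L <- length(info)
  w <- min(5L, L)
  sums <- vapply(1:(L - w + 1L), function(i) sum(info[i:(i + w - 1L)]), numeric(1))
  i0 <- which.max(sums)  # which.max takes the leftmost maximum
  i0:(i0 + w - 1L)
}

#' MATCH-style core and matrix similarity scores of one site
#'
#' @param pwm A [pwm()].
#' @param site DNA string of the matrix length over A,C,G,T.
#' @return Named numeric `c(core_score=, matrix_score=)`, both in `[0,1]`.
#' @export
match_scores <- function(pwm, site) {
  if (nchar(site) != pwm$length) stop("site length must equal matrix length")
  codes <- encode_bases(site)
  if (anyNA(codes)) stop("site contains N or invalid base")
  f_site <- pwm$freq[cbind(codes + 1L, seq_len(pwm$length))]
  c(core_score = .minmax_score(pwm, f_site, pwm$core_idx),
    matrix_score = .minmax_score(pwm, f_site, seq_len(pwm$length)))
}

.minmax_score <- function(pwm, f_site, idx) {
  I <- pwm$info[idx]
  cur <- sum(I * f_site[idx])
  mx <- sum(I * apply(pwm$freq[, idx, drop = FALSE], 2L, max))
  mn <- sum(I * apply(pwm$freq[, idx, drop = FALSE], 2L, min))
  if (mx - mn <= .Machine$double.eps) {
    warning("degenerate matrix region (max == min score): score set to 1")
    return(1)
  }
  (cur - mn) / (mx - mn)
}

# score every window of coded sequence against one index set of the pwm;
# returns normalized scores with NA where a window touches an N
.scan_scores <- function(codes, pwm, idx) {
  L <- pwm$length
  n_win <- length(codes) - L + 1L
  if (n_win < 1L) return(numeric(0))
  I <- pwm$info
  cur <- numeric(n_win)
  na_hit <- rep(FALSE, n_win)
  for (j in idx) {
    cj <- codes[j:(j + n_win - 1L)]
    na_hit <- na_hit | is.na(cj)
    w <- I[j] * pwm$freq[, j]
    contrib <- w[cj + 1L]
    contrib[is.na(contrib)] <- 0
    cur <- cur + contrib
  }
  mx <- sum(I[idx] * apply(pwm$freq[, idx, drop = FALSE], 2L, max))
  mn <- sum(I[idx] * apply(pwm$freq[, idx, drop = FALSE], 2L, min))
  if (mx - mn <= .Machine$double.eps) {
    s <- rep(1, n_win)
  } else s <- (cur - mn) / (mx - mn)
  s[na_hit] <- NA_real_
  s
}

#' Scan sequences for TFBS hits with core/matrix score cutoffs
#'
#' Scans both strands of every sequence with every matrix and reports
#' windows whose core score and matrix similarity score reach the cutoffs
#' (defaults 1.0 and 0.7). Reverse-strand hits are reported in forward
#' coordinates. Windows containing N are skipped.
#'
#' @param seqs Named character vector of sequences (or a single string).
#' @param pwms A [pwm()] or list of them.
#' @param core_cut,mss_cut Score cutoffs in `[0,1]`, defaults 1.0 and 0.7.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return Data frame with columns `seq_id`, `matrix_id`, `start` (0-based),
#'   `end`, `strand`, `core_score`, `matrix_score`, sorted by
#'   (seq_id, start, matrix_id).
#' @export
scan_pwms <- function(seqs, pwms, core_cut = 1.0, mss_cut = 0.7,
                      both_strands = TRUE) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (core_cut < 0 || core_cut > 1 || mss_cut < 0 || mss_cut > 1) {
    stop("cutoffs must lie in [0,1]")
  }
  rows <- list()
  tol <- 1e-9  # guard against float round-off at cutoff 1.0
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    codes_f <- encode_bases(s)
    strands <- if (both_strands) c("+", "-") else "+"
    codes_r <- if (both_strands) encode_bases(reverse_complement(s)) else NULL
    for (p in pwms) {
      L <- p$length
      if (nchar(s) < L) next
      for (st in strands) {
        codes <- if (st == "+") codes_f else codes_r
        mss <- .scan_scores(codes, p, seq_len(L))
        core <- .scan_scores(codes, p, p$core_idx)
        keep <- which(!is.na(mss) & core >= core_cut - tol & mss >= mss_cut - tol)
        if (!length(keep)) next
        start0 <- keep - 1L
        if (st == "-") start0 <- nchar(s) - start0 - L
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid, matrix_id = p$id, start = start0, end = start0 + L,
          strand = st, core_score = pmin(core[keep], 1),
          matrix_score = pmin(mss[keep], 1))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), matrix_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), core_score = numeric(0),
                      matrix_score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id, out$start, out$matrix_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# TATA / CCAAT / GC box annotation

#' Bundled consensus-derived box matrices
#'
#' Loads the TATA, CCAAT and GC box matrices bundled with the package.
#' These are synthetic consensus-derived profiles (TATAWAW, CCAAT, GGGCGG
#' with mild smoothing), not curated database matrices; supply your own
#' TRANSFAC-format matrices to override.
#'
#' @return Named list of three [pwm()]s: `TATA`, `CCAAT`, `GC`.
#' @export
default_box_pwms <- function() {
  path <- system.file("extdata", "box_matrices_synthetic.transfac",
                      package = "promkit")
  pwms <- parse_transfac_matrices(path)
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  pwms
}

#' Annotate TATA, CCAAT and GC boxes near a TSS
#'
#' Scans box matrices inside conventional TSS-relative search windows
#' (TATA: -100..-1; CCAAT and GC: -200..-1 by default).
#'
#' @param record A [promoter_record()] (the TSS defines the windows), or a
#'   plain string together with `tss_index`.
#' @param box_pwms Named list of box PWMs; default [default_box_pwms()].
#' @param windows Named list of [relative_window()]s per box type.
#' @param core_cut,mss_cut Score cutoffs, defaults 1.0 and 0.7.
#' @param tss_index 0-based TSS when `record` is a plain string.
#' @return Data frame with columns `box_type`, `start`, `end`, `strand`,
#'   `core_score`, `matrix_score` (start/end 0-based in the full sequence).
#' @export
annotate_boxes <- function(record, box_pwms = default_box_pwms(),
                           windows = list(TATA = relative_window(-100, -1),
                                          CCAAT = relative_window(-200, -1),
                                          GC = relative_window(-200, -1)),
                           core_cut = 1.0, mss_cut = 0.7, tss_index = NULL) {
  if (inherits(record, "promoter_record")) {
    seq <- record$seq
    tss_index <- record$tss_index
  } else {
    seq <- record
    if (is.null(tss_index)) stop("supply a promoter_record or tss_index")
  }
  rows <- list()
  for (bt in names(box_pwms)) {
    win <- windows[[bt]]
    if (is.null(win)) stop("no search window for box type ", bt)
    idx <- rel_to_index(win, tss_index, nchar(seq))
    sub <- substr(seq, idx[["start"]] + 1L, idx[["end"]])
    hits <- scan_pwms(stats::setNames(sub, bt), box_pwms[[bt]],
                      core_cut = core_cut, mss_cut = mss_cut)
    if (nrow(hits)) {
      hits$box_type <- bt
      hits$start <- hits$start + idx[["start"]]
      hits$end <- hits$end + idx[["start"]]
      rows[[length(rows) + 1L]] <-
        hits[, c("box_type", "start", "end", "strand",
                 "core_score", "matrix_score")]
    }
  }
  if (!length(rows)) {
    return(data.frame(box_type = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      core_score = numeric(0), matrix_score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
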