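# CpG island detection.
#
# Standard three-criterion definition: length >= 500 bp, GC fraction >= 0.5,
# observed/expected CpG ratio >= 0.6, with
#   obs/exp = (#CG dinucleotides * region length) / (#C * #G).
# Detection is a greedy seed-extend-merge: all min_length windows satisfying
# the criteria seed candidate regions; overlapping seeds are unioned; each
# candidate is verified as a whole and, if the union fails, greedily trimmed
# from the right until it passes. N counts as non-C/non-G and breaks CpG
# dinucleotides.

.cpg_counts <- function(seq) {
  codes <- encode_bases(toupper(seq))
  is_c <- !is.na(codes) & codes == 1L
  is_g <- !is.na(codes) & codes == 2L
  n <- length(codes)
  cg <- is_c[-n] & is_g[-1L]
  # cg[i+1] == number of CG steps at 0-based positions < i (length n)
  list(c = c(0L, cumsum(is_c)), g = c(0L, cumsum(is_g)),
       cg = c(0L, cumsum(cg)), n = n)
}

# criteria for region [start, end) (0-based), using cumulative counts
.region_ok <- function(cc, start, end, gc_min, oe_min) {
  len <- end - start
  nc <- cc$c[end + 1L] - cc$c[start + 1L]
  ng <- cc$g[end + 1L] - cc$g[start + 1L]
  # CG steps fully inside [start, end): steps at positions start..end-2
  ncg <- if (len >= 2L) cc$cg[end] - cc$cg[start + 1L] else 0L
  gc <- (nc + ng) / len
  oe <- if (nc * ng > 0) (ncg * len) / (nc * ng) else 0
  c(ok = gc >= gc_min && oe >= oe_min, gc = gc, oe = oe)
}

#' Detect CpG islands
#'
#' @param seq DNA string (case-insensitive; N allowed).
#' @param min_length Minimum island length, default 500 bp.
#' @param gc_min Minimum GC fraction, default 0.5.
#' @param oe_min Minimum observed/expected CpG ratio, default 0.6.
#' @return Data frame with columns `start`, `end` (0-based half-open), `gc`,
#'   `obs_exp`; islands are non-overlapping and sorted by start.
#' @export
find_cpg_islands <- function(seq, min_length = 500L, gc_min = 0.5,
                             oe_min = 0.6) {
  min_length <- as.integer(min_length)
  if (min_length < 2L) stop("min_length must be >= 2")
  L <- nchar(seq)
  if (L < min_length) {
    return(data.frame(start = integer(0), end = integer(0),
                      gc = numeric(0), obs_exp = numeric(0)))
  }
  cc <- .cpg_counts(seq)
  starts <- 0:(L - min_length)
  ends <- starts + min_length
  nc <- cc$c[ends + 1L] - cc$c[starts + 1L]
  ng <- cc$g[ends + 1L] - cc$g[starts + 1L]
  ncg <- cc$cg[ends] - cc$cg[starts + 1L]
  gc <- (nc + ng) / min_length
  oe <- ifelse(nc * ng > 0, (ncg * min_length) / (nc * ng), 0)
  seed_starts <- starts[gc >= gc_min & oe >= oe_min]
  if (!length(seed_starts)) {
    return(data.frame(start = integer(0), end = integer(0),
                      gc = numeric(0), obs_exp = numeric(0)))
  }
  # union runs of overlapping seed windows
  gaps <- which(diff(seed_starts) >= min_length)
  run_first <- seed_starts[c(1L, gaps + 1L)]
  run_last <- seed_starts[c(gaps, length(seed_starts))]
  out <- list()
  for (i in seq_along(run_first)) {
    s <- run_first[i]
    e <- run_last[i] + min_length
    # the union of passing windows need not pass as a whole; trim from the
    # right (each trim still contains the leftmost passing seed window)
    repeat {
      m <- .region_ok(cc, s, e, gc_min, oe_min)
      if (m[["ok"]] == 1) break
      e <- e - 1L
      if (e - s < min_length) { e <- s + min_length; m <- .region_ok(cc, s, e, gc_min, oe_min); break }
    }
    out[[length(out) + 1L]] <- data.frame(start = s, end = e,
                                          gc = m[["gc"]], obs_exp = m[["oe"]])
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Does a TSS-relative window overlap a CpG island?
#'
#' Used to route a sequence to the with-CpG or without-CpG promoter model
#' branch: returns `TRUE` iff any detected island overlaps the resolved
#' window by at least 1 bp.
#'
#' @param record A [promoter_record()].
#' @param window A [relative_window()].
#' @param ... Passed to [find_cpg_islands()].
#' @return Logical scalar.
#' @export
has_cpg_island <- function(record, window, ...) {
  idx <- rel_to_index(window, record$tss_index, nchar(record$seq))
  islands <- find_cpg_islands(record$seq, ...)
  if (nrow(islands) == 0L) return(FALSE)
  any(islands$start < idx[["end"]] & islands$end > idx[["start"]])
}
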