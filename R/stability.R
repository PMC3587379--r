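# DNA duplex stability from unified nearest-neighbor thermodynamics.
#
# Free energy of duplex formation is summed over overlapping dinucleotide
# steps using the unified nearest-neighbor dG°37 parameters (kcal/mol).
# A step and its reverse complement share one value, so the 16 dinucleotides
# collapse onto 10 canonical duplex steps. Less negative dG = less stable:
# promoters show a stability minimum (dG maximum) around the TATA region.

# unified NN dG°37, kcal/mol, for the 10 canonical steps
.NN_CANONICAL <- c(
  "AA/TT" = -1.00, "AT/TA" = -0.88, "TA/AT" = -0.58,
  "CA/GT" = -1.45, "GT/CA" = -1.44, "CT/GA" = -1.28,
  "GA/CT" = -1.30, "CG/GC" = -2.17, "GC/CG" = -2.24,
  "GG/CC" = -1.84
)

# initiation terms of the same parameter set (per duplex end)
.NN_INIT <- c(GC = 0.98, AT = 1.03)

#' Unified nearest-neighbor free-energy table
#'
#' Returns the unified nearest-neighbor standard free energies (dG°37,
#' kcal/mol) of the ten dinucleotide duplex steps, expanded by
#' reverse-complement symmetry to all sixteen dinucleotides.
#'
#' @return Named numeric vector of length 16 (names `AA`..`TT`), with the
#'   canonical ten-step table attached as attribute `"canonical"`.
#' @export
load_nn_table <- function() {
  canonical <- .NN_CANONICAL
  steps <- substr(names(canonical), 1, 2)
  full <- stats::setNames(canonical, steps)
  # reverse-complement closure: dG(XY) == dG(revcomp(XY))
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  all16 <- as.vector(outer(bases, bases, paste0))
  out <- stats::setNames(numeric(16), all16)
  for (d in all16) {
    rc <- paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
    if (d %in% names(full)) out[d] <- full[d]
    else out[d] <- full[rc]
  }
  attr(out, "canonical") <- canonical
  out
}

# integer encoding A=0 C=1 G=2 T=3; N and others -> NA
.base_codes <- local({
  m <- rep(NA_integer_, 256)
  m[utf8ToInt("A")] <- 0L; m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L; m[utf8ToInt("T")] <- 3L
  m
})

encode_bases <- function(seq) {
  .base_codes[utf8ToInt(seq)]
}

# dG lookup vector indexed by 4*first + second + 1
.step_dg_vector <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      full <- load_nn_table()
      bases <- c("A", "C", "G", "T")
      v <- numeric(16)
      for (i in 0:3) for (j in 0:3) {
        v[4 * i + j + 1] <- full[paste0(bases[i + 1], bases[j + 1])]
      }
      tab <<- v
    }
    tab
  }
})

#' Standard free energy of a DNA duplex from dinucleotide steps
#'
#' Sums the unified nearest-neighbor dG°37 values over the `length - 1`
#' overlapping dinucleotide steps of `seq`. By default no initiation terms
#' are added: the sliding-window profiles compare windows of identical
#' length, for which constant terms cancel. Set `initiation = TRUE` for a
#' standalone duplex estimate.
#'
#' @param seq DNA string over A,C,G,T, length >= 2.
#' @param initiation Add the two terminal initiation penalties.
#' @return Free energy in kcal/mol (negative = stable).
#' @export
duplex_delta_g <- function(seq, initiation = FALSE) {
  codes <- encode_bases(seq)
  if (length(codes) < 2L) stop("need at least 2 bases for a dinucleotide step")
  if (anyNA(codes)) stop("duplex_delta_g: sequence contains N or invalid base")
  steps <- 4L * codes[-length(codes)] + codes[-1L] + 1L
  dg <- sum(.step_dg_vector()[steps])
  if (initiation) {
    ends <- codes[c(1L, length(codes))]
    dg <- dg + sum(ifelse(ends %in% c(1L, 2L), .NN_INIT[["GC"]], .NN_INIT[["AT"]]))
  }
  dg
}

#' Sliding-window DNA stability profile
#'
#' Computes the nearest-neighbor free-energy sum in a window (default 15 nt)
#' sliding 1 nt at a time. Windows containing N yield `NA` and are excluded
#' from downstream averaging. When a TSS is supplied (directly or via a
#' `promoter_record`), window-start positions are reported TSS-relative
#' (TSS = +1, no position 0), else 0-based.
#'
#' @param x A `promoter_record` or a DNA string.
#' @param window Window size in nt (>= 2), default 15.
#' @param tss_index Optional 0-based TSS index (ignored when `x` is a
#'   `promoter_record`).
#' @return Data frame with columns `position` (window start) and `delta_g`
#'   (kcal/mol); attribute `"window"` records the window size.
#' @export
stability_profile <- function(x, window = 15L, tss_index = NULL) {
  if (inherits(x, "promoter_record")) {
    tss_index <- x$tss_index
    seq <- x$seq
  } else seq <- x
  window <- as.integer(window)
  if (window < 2L) stop("stability window must be >= 2")
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than window")
  codes <- encode_bases(seq)
  step_dg <- .step_dg_vector()[4L * codes[-L] + codes[-1L] + 1L]  # NA where N
  # rolling sum of (window - 1) consecutive step values
  k <- window - 1L
  cs <- cumsum(ifelse(is.na(step_dg), 0, step_dg))
  csn <- cumsum(is.na(step_dg))
  n_win <- L - window + 1L
  lo <- seq_len(n_win)
  vals <- cs[lo + k - 1L] - c(0, cs)[lo]
  nas <- csn[lo + k - 1L] - c(0, csn)[lo]
  vals[nas > 0L] <- NA_real_
  starts0 <- lo - 1L
  pos <- if (!is.null(tss_index)) index_to_rel_point(starts0, tss_index) else starts0
  out <- data.frame(position = pos, delta_g = vals)
  attr(out, "window") <- window
  out
}

#' Sliding-window GC-content profile
#'
#' @param seq DNA string; N counts as non-G/C.
#' @param window Window size in nt (>= 1), default 15.
#' @param tss_index Optional 0-based TSS index for TSS-relative positions.
#' @return Data frame with columns `position` and `gc` (fraction in `[0,1]`).
#' @export
gc_profile <- function(seq, window = 15L, tss_index = NULL) {
  window <- as.integer(window)
  if (window < 1L) stop("gc window must be >= 1")
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than window")
  codes <- encode_bases(seq)
  is_gc <- as.numeric(codes %in% c(1L, 2L))
  cs <- c(0, cumsum(is_gc))
  n_win <- L - window + 1L
  lo <- seq_len(n_win)
  gc <- (cs[lo + window] - cs[lo]) / window
  starts0 <- lo - 1L
  pos <- if (!is.null(tss_index)) index_to_rel_point(starts0, tss_index) else starts0
  out <- data.frame(position = pos, gc = gc)
  attr(out, "window") <- window
  out
}
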