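# Sequence I/O and the TSS-relative coordinate convention.
#
# Internally every coordinate is 0-based half-open. User-facing positions are
# TSS-relative with the TSS at +1 and no position 0 (the convention of
# promoter databases: "-200 to +100" spans 300 bp).

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Read a FASTA file of DNA sequences
#'
#' Reads a (multi-)FASTA file, uppercases the sequences, and validates that
#' every character is one of A, C, G, T, N. Degenerate IUPAC codes other than
#' N are rejected: downstream scoring assumes a 4-letter alphabet and treats
#' N as "unscorable".
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase sequences, one element per
#'   record; names are the full FASTA headers up to the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal character(s) outside {A,C,G,T,N} in record '",
         names(seqs)[bad][1L], "'")
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a promoter record
#'
#' A promoter record is one training unit: a sequence with a declared TSS and
#' a CpG-island class label.
#'
#' @param gene_id Identifier string.
#' @param seq Uppercase DNA string over A,C,G,T,N.
#' @param tss_index 0-based index of the TSS base within `seq`.
#' @param cpg_class One of `"WITH_CPG"`, `"WITHOUT_CPG"`, `"UNKNOWN"`.
#' @return An object of class `promoter_record`.
#' @export
promoter_record <- function(gene_id, seq, tss_index,
                            cpg_class = c("UNKNOWN", "WITH_CPG", "WITHOUT_CPG")) {
  cpg_class <- match.arg(cpg_class)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("record '", gene_id, "': illegal character outside {A,C,G,T,N}")
  }
  tss_index <- as.integer(tss_index)
  if (tss_index < 0L || tss_index >= nchar(seq)) {
    stop("record '", gene_id, "': tss_index out of bounds")
  }
  structure(
    list(gene_id = gene_id, seq = seq, tss_index = tss_index,
         cpg_class = cpg_class),
    class = "promoter_record"
  )
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("<promoter_record> %s: %d bp, TSS at index %d, class %s\n",
              x$gene_id, nchar(x$seq), x$tss_index, x$cpg_class))
  invisible(x)
}

#' Construct a TSS-relative window
#'
#' Positions are TSS-relative with the TSS at +1; position 0 does not exist.
#' The window is inclusive of both endpoints, so `relative_window(-200, 100)`
#' spans 300 bp.
#'
#' @param start_rel,end_rel Nonzero integers, `start_rel < end_rel`.
#' @return An object of class `relative_window`.
#' @export
relative_window <- function(start_rel, end_rel) {
  start_rel <- as.integer(start_rel)
  end_rel <- as.integer(end_rel)
  if (start_rel == 0L || end_rel == 0L) {
    stop("relative positions are nonzero: TSS is +1, there is no position 0")
  }
  if (start_rel > end_rel) stop("start_rel must not exceed end_rel")
  structure(list(start_rel = start_rel, end_rel = end_rel),
            class = "relative_window")
}

#' Map one TSS-relative position to a 0-based index
#' @keywords internal
rel_point_to_index <- function(rel, tss_index) {
  if (any(rel == 0L)) stop("there is no relative position 0")
  ifelse(rel > 0L, tss_index + rel - 1L, tss_index + rel)
}

#' Map one 0-based index to a TSS-relative position
#' @keywords internal
index_to_rel_point <- function(idx, tss_index) {
  ifelse(idx >= tss_index, idx - tss_index + 1L, idx - tss_index)
}

#' Resolve a TSS-relative window to 0-based half-open indices
#'
#' @param window A [relative_window()].
#' @param tss_index 0-based TSS index.
#' @param seq_length Optional sequence length; when given, out-of-bounds
#'   windows raise an error.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
rel_to_index <- function(window, tss_index, seq_length = NULL) {
  stopifnot(inherits(window, "relative_window"))
  start <- rel_point_to_index(window$start_rel, tss_index)
  end <- rel_point_to_index(window$end_rel, tss_index) + 1L
  if (!is.null(seq_length)) {
    if (start < 0L || end > seq_length) {
      stop(sprintf("window %+d..%+d resolves to [%d,%d), outside sequence of length %d",
                   window$start_rel, window$end_rel, start, end, seq_length))
    }
  }
  c(start = as.integer(start), end = as.integer(end))
}

#' Extract the subsequence covered by a TSS-relative window
#' @param record A [promoter_record()].
#' @param window A [relative_window()].
#' @return Character scalar.
#' @export
window_seq <- function(record, window) {
  idx <- rel_to_index(window, record$tss_index, nchar(record$seq))
  substr(record$seq, idx[["start"]] + 1L, idx[["end"]])
}

# ---------------------------------------------------------------------------
# TRANSFAC flat-file matrices

#' Parse a TRANSFAC flat-file matrix library
#'
#' Accepts the classic flat-file dialect: matrices delimited by `//`, an
#' optional `ID`/`NA` pair, a `P0  A  C  G  T` header and numbered count
#' rows. Count matrices (row sums > 1.5) and frequency matrices are both
#' accepted; counts are converted to frequencies with a small pseudocount of
#' `0.01 * (rowtotal + 1) / 4` per cell before renormalization, so that
#' information values never hit log(0).
#'
#' @param path Path to the matrix file.
#' @return A list of [pwm()] objects.
#' @export
parse_transfac_matrices <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pwms <- list()
  cur_id <- NULL; cur_name <- NULL; cur_rows <- list(); seen_p0 <- FALSE

  flush <- function() {
    if (!seen_p0 && length(cur_rows) == 0L) return(NULL)
    if (!seen_p0) stop("matrix block without P0 header line")
    if (length(cur_rows) == 0L) stop("zero-length matrix",
                                     if (!is.null(cur_id)) paste0(" '", cur_id, "'"))
    counts <- do.call(rbind, cur_rows)
    totals <- rowSums(counts)
    if (max(totals) > 1.5) {
      # count matrix: warn if row totals are wildly inconsistent
      if (max(totals) > 0 && (max(totals) - min(totals)) / max(totals) > 0.1) {
        warning("matrix '", cur_id %||% "?",
                "': row totals differ by more than 10%")
      }
    }
    freq <- counts + 0.01 * (totals + 1) / 4
    freq <- freq / rowSums(freq)
    pwm(id = cur_id %||% paste0("M", length(pwms) + 1L),
        name = cur_name %||% cur_id %||% "unnamed",
        freq = t(freq), counts = t(counts))
  }

  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "XX") || startsWith(ln, "CC")) next
    if (startsWith(ln, "//")) {
      p <- flush()
      if (!is.null(p)) pwms[[length(pwms) + 1L]] <- p
      cur_id <- NULL; cur_name <- NULL; cur_rows <- list(); seen_p0 <- FALSE
      next
    }
    if (grepl("^ID\\s", ln)) { cur_id <- trimws(sub("^ID\\s+", "", ln)); next }
    if (grepl("^NA\\s", ln)) { cur_name <- trimws(sub("^NA\\s+", "", ln)); next }
    if (grepl("^P0\\b", ln) || grepl("^PO\\b", ln)) { seen_p0 <- TRUE; next }
    if (grepl("^[0-9]+\\s", ln)) {
      if (!seen_p0) stop("matrix row before P0 header (missing P0 line?)")
      parts <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (any(is.na(vals))) stop("unparseable matrix row: ", ln)
      cur_rows[[length(cur_rows) + 1L]] <- vals
      next
    }
  }
  p <- flush()
  if (!is.null(p)) pwms[[length(pwms) + 1L]] <- p
  if (length(pwms) == 0L) stop("no matrices found in ", path)
  pwms
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# BED output

#' Write TFBS hits (or islands) as BED6
#'
#' The BED score column is the matrix similarity score scaled to an integer
#' in 0..1000.
#'
#' @param hits Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `name` (or `matrix_id`), `strand`, and a score column in
#'   `[0,1]` named `matrix_score` or `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (any(hits$end <= hits$start)) stop("BED intervals need end > start")
  score <- if ("matrix_score" %in% names(hits)) hits$matrix_score else hits$score
  name <- if ("matrix_id" %in% names(hits)) hits$matrix_id else hits$name
  strand <- if ("strand" %in% names(hits)) hits$strand else "+"
  bed <- data.frame(chrom = hits$seq_id,
                    start = as.integer(hits$start),
                    end = as.integer(hits$end),
                    name = name,
                    score = as.integer(pmax(0, pmin(1000, round(score * 1000)))),
                    strand = strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param seq Character scalar over A,C,G,T,N.
#' @return The reverse complement as a character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
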