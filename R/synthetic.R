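# Synthetic promoter-like data with planted regulatory structure.
#
# The generators emulate the kind of TSS-anchored training data promoter
# classifiers are built from: +/- 3000 bp flanks around a TSS, a TATA
# cassette upstream of the TSS, over-represented hexamers enriched in the
# proximal window, an AT-rich low-stability dip, and (for the with-CpG
# class) a GC/CpG-rich island over the TSS. Effect sizes default to clearly
# separable signals; `hard = TRUE` halves them for sensitivity analyses.
# All generators are deterministic given their seed.

.sample_bases <- function(n, probs) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate background (non-promoter) sequences
#'
#' i.i.d. bases with a target GC fraction split evenly between G and C.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param gc GC fraction in (0, 1), default 0.41 (mammalian-like).
#' @param seed Integer seed.
#' @return Named character vector (`bg1`, `bg2`, ...).
#' @export
gen_background <- function(n, length, gc = 0.41, seed = 1L) {
  if (length <= 0) stop("length must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly inside (0, 1)")
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i) .sample_bases(length, probs), "")
  stats::setNames(seqs, paste0("bg", seq_len(n)))
}

.default_planted_hexamers <- c("GGCTGG", "CCGCCC", "GCCAAT", "CTGTCC",
                               "GGGCGG", "TCCAGC")

#' Generate promoter records with planted regulatory structure
#'
#' Each record has background flanks around a TSS at the center, a TATA
#' consensus sampled base-by-base at `tata_strength` placed at
#' `tata_position`, planted hexamers overwritten at random positions within
#' -200..+100 (each with probability `hexamer_rate`), an optional AT-rich
#' stability dip at -40..-20, and for the `WITH_CPG` class a 600-bp GC-rich,
#' CpG-retaining island rewritten over -350..+250.
#'
#' @param n Number of records.
#' @param flank Flank length on each side of the TSS, default 3000 bp.
#' @param gc Background GC fraction, default 0.41.
#' @param cpg_class `"WITH_CPG"` or `"WITHOUT_CPG"`.
#' @param planted_hexamers Hexamers to enrich in the proximal window.
#' @param hexamer_rate Per-hexamer embedding probability, default 0.8.
#' @param tata_position TSS-relative start of the TATA cassette, default -31.
#' @param tata_strength Per-base consensus probability, default 0.9.
#' @param stability_dip Enrich -40..-20 for A/T, default `TRUE`.
#' @param hard Halve all effect sizes, default `FALSE`.
#' @param seed Integer seed.
#' @return List of [promoter_record()]s.
#' @export
gen_promoters <- function(n, flank = 3000L, gc = 0.41,
                          cpg_class = c("WITHOUT_CPG", "WITH_CPG"),
                          planted_hexamers = .default_planted_hexamers,
                          hexamer_rate = 0.8, tata_position = -31L,
                          tata_strength = 0.9, stability_dip = TRUE,
                          hard = FALSE, seed = 1L) {
  cpg_class <- match.arg(cpg_class)
  if (hard) {
    hexamer_rate <- hexamer_rate / 2
    tata_strength <- tata_strength / 2
  }
  set.seed(seed)
  L <- 2L * flank + 1L
  tss <- flank  # 0-based index of the TSS base
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  tata_consensus <- "TATAAAA"
  records <- vector("list", n)
  for (i in seq_len(n)) {
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs)
    if (cpg_class == "WITH_CPG") {
      # GC-rich i.i.d. segment: GC ~ 0.66 and CpG obs/exp ~ 1, comfortably
      # above the island detector's thresholds
      isl_idx <- rel_point_to_index(-350L, tss):rel_point_to_index(250L, tss)
      chars[isl_idx + 1L] <- sample(c("A", "C", "G", "T"), length(isl_idx),
                                    replace = TRUE,
                                    prob = c(0.17, 0.33, 0.33, 0.17))
    }
    if (stability_dip) {
      dip_idx <- rel_point_to_index(-40L, tss):rel_point_to_index(-20L, tss)
      chars[dip_idx + 1L] <- sample(c("A", "C", "G", "T"), length(dip_idx),
                                    replace = TRUE,
                                    prob = c(0.45, 0.05, 0.05, 0.45))
    }
    # TATA cassette, base-by-base at tata_strength
    t_idx <- rel_point_to_index(tata_position, tss)
    t_bases <- strsplit(tata_consensus, "")[[1]]
    keep <- stats::runif(length(t_bases)) < tata_strength
    rnd <- sample(c("A", "C", "G", "T"), length(t_bases), replace = TRUE)
    chars[t_idx + seq_along(t_bases)] <- ifelse(keep, t_bases, rnd)
    # planted hexamers within -200..+100, avoiding the TATA cassette
    occupied <- t_idx:(t_idx + length(t_bases) - 1L)
    win_lo <- rel_point_to_index(-200L, tss)
    win_hi <- rel_point_to_index(100L, tss) - 5L
    for (hx in planted_hexamers) {
      if (stats::runif(1) >= hexamer_rate) next
      placed <- FALSE
      for (attempt in 1:100) {
        s <- sample(win_lo:win_hi, 1L)
        span <- s:(s + 5L)
        if (!any(span %in% occupied)) {
          chars[span + 1L] <- strsplit(hx, "")[[1]]
          occupied <- c(occupied, span)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place hexamer ", hx,
                        " after 100 attempts (window too crowded)")
    }
    records[[i]] <- promoter_record(
      gene_id = sprintf("%s_%03d", tolower(cpg_class), i),
      seq = paste(chars, collapse = ""),
      tss_index = tss, cpg_class = cpg_class)
  }
  records
}

#' Generate a random PWM of controllable informativeness
#'
#' Per-position frequencies are Dirichlet(1,1,1,1) draws interpolated toward
#' a random one-hot consensus: `informativeness = 0` gives near-uniform
#' columns, `1` gives exact one-hot columns.
#'
#' @param length Matrix length (>= 4).
#' @param informativeness Interpolation weight in `[0, 1]`.
#' @param seed Integer seed.
#' @param id Matrix id, default `"SYN1"`.
#' @return A [pwm()].
#' @export
gen_pwm <- function(length, informativeness, seed = 1L, id = "SYN1") {
  if (length < 4L) stop("PWM length must be >= 4")
  if (informativeness < 0 || informativeness > 1) {
    stop("informativeness must lie in [0, 1]")
  }
  set.seed(seed)
  freq <- matrix(0, nrow = 4, ncol = length,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(length)) {
    dir <- -log(stats::runif(4)); dir <- dir / sum(dir)  # Dirichlet(1,1,1,1)
    onehot <- numeric(4); onehot[sample.int(4, 1)] <- 1
    col <- (1 - informativeness) * dir + informativeness * onehot
    freq[, j] <- col / sum(col)
  }
  pwm(id = id, name = id, freq = freq)
}

#' Consensus sequence of a PWM (per-position argmax base)
#' @param p A [pwm()].
#' @return Character scalar.
#' @export
pwm_consensus <- function(p) {
  paste(c("A", "C", "G", "T")[apply(p$freq, 2L, which.max)], collapse = "")
}

#' Generate an observed gene group and background set with planted TFBSs
#'
#' Each observed promoter embeds (jointly, with probability `embed_prob`)
#' one consensus site of every TF in `co_set`, plus decoy sites of the other
#' matrices; background promoters embed every TF independently at
#' `bg_rate`.
#'
#' @param pwms Named list of [pwm()]s.
#' @param co_set Character vector of co-occurring matrix ids (subset of
#'   `names(pwms)`).
#' @param n_genes Number of observed promoters (> 0).
#' @param embed_prob Joint embedding probability, default 0.9 (must be > 0).
#' @param background_n Number of background promoters, default 100.
#' @param bg_rate Per-TF background embedding rate, default 0.05.
#' @param decoy_rate Per-decoy-TF observed embedding rate, default 0.2.
#' @param promoter_length Promoter length in bp, default 500.
#' @param gc Background GC fraction, default 0.41.
#' @param seed Integer seed.
#' @return List with named character vectors `observed` and `background`.
#' @export
gen_gene_group <- function(pwms, co_set, n_genes, embed_prob = 0.9,
                           background_n = 100L, bg_rate = 0.05,
                           decoy_rate = 0.2, promoter_length = 500L,
                           gc = 0.41, seed = 1L) {
  if (n_genes <= 0L) stop("n_genes must be positive")
  if (embed_prob <= 0 || embed_prob > 1) stop("embed_prob must lie in (0, 1]")
  if (!all(co_set %in% names(pwms))) stop("co_set must be a subset of names(pwms)")
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  consensus <- vapply(pwms, pwm_consensus, "")

  embed <- function(chars, site) {
    # overwrite at a random position not colliding with prior insertions
    occ <- attr(chars, "occupied") %||% integer(0)
    for (attempt in 1:100) {
      s <- sample.int(length(chars) - nchar(site) + 1L, 1L)
      span <- s:(s + nchar(site) - 1L)
      if (!any(span %in% occ)) {
        chars[span] <- strsplit(site, "")[[1]]
        attr(chars, "occupied") <- c(occ, span)
        return(chars)
      }
    }
    stop("could not place site after 100 attempts")
  }

  make_promoter <- function(tf_ids) {
    chars <- sample(c("A", "C", "G", "T"), promoter_length,
                    replace = TRUE, prob = probs)
    for (id in tf_ids) chars <- embed(chars, consensus[[id]])
    paste(chars, collapse = "")
  }

  decoys <- setdiff(names(pwms), co_set)
  observed <- vapply(seq_len(n_genes), function(i) {
    tfs <- character(0)
    if (stats::runif(1) < embed_prob) tfs <- co_set
    tfs <- c(tfs, decoys[stats::runif(length(decoys)) < decoy_rate])
    make_promoter(tfs)
  }, "")
  names(observed) <- sprintf("gene%03d", seq_len(n_genes))
  background <- vapply(seq_len(background_n), function(i) {
    tfs <- names(pwms)[stats::runif(length(pwms)) < bg_rate]
    make_promoter(tfs)
  }, "")
  names(background) <- sprintf("bg%03d", seq_len(background_n))
  list(observed = observed, background = background)
}
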