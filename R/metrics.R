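#' Species-level methylation profile
#'
#' Aggregation is unweighted at every level: cytosine ratios are averaged
#' within fragments, fragment means within samples, sample means within
#' species. Fragment-level methylation bins (low < 0.2, mid \[0.2, 0.8\],
#' high > 0.8) are computed per sample on fragments with at least
#' `min_fragment_reads` total reads and averaged across samples. Non-CpG
#' methylation is reported per context.
#'
#' @param calls `mc_calls` covering one or more species.
#' @param meta data.frame with `sample_id` and `species` (and optionally
#'   more).
#' @param min_fragment_reads coverage filter for the bin fractions.
#' @return data.frame, one row per species: `mean_cpg_methylation`,
#'   `frac_low`, `frac_mid`, `frac_high`, `noncpg_*`, `n_samples`.
#' @export
aggregate_species <- function(calls, meta, min_fragment_reads = 10L) {
  stopifnot(all(c("sample_id", "species") %in% names(meta)))
  cpg <- calls[calls$context == "CpG" & !is.na(calls$context) &
                 calls$n_total >= 1L]
  frag <- cpg[, list(meth = mean(n_meth / n_total),
                     reads = sum(n_total)),
              by = c("sample_id", "fragment_id")]
  frag[, "species" := meta$species[match(frag$sample_id, meta$sample_id)]]

  samp <- frag[, list(
    sample_mean = mean(meth),
    frac_low = {
      el <- meth[reads >= min_fragment_reads]
      if (length(el)) mean(el < 0.2) else NA_real_
    },
    frac_mid = {
      el <- meth[reads >= min_fragment_reads]
      if (length(el)) mean(el >= 0.2 & el <= 0.8) else NA_real_
    },
    frac_high = {
      el <- meth[reads >= min_fragment_reads]
      if (length(el)) mean(el > 0.8) else NA_real_
    }
  ), by = c("species", "sample_id")]

  sp <- samp[, list(
    mean_cpg_methylation = mean(sample_mean),
    frac_low = mean(frac_low, na.rm = TRUE),
    frac_mid = mean(frac_mid, na.rm = TRUE),
    frac_high = mean(frac_high, na.rm = TRUE),
    n_samples = .N
  ), by = "species"]

  ncpg <- calls[!is.na(calls$context) & calls$context != "CpG" &
                  calls$n_total >= 1L]
  if (nrow(ncpg)) {
    ncpg[, "species" := meta$species[match(ncpg$sample_id, meta$sample_id)]]
    bysamp <- ncpg[, list(level = sum(n_meth) / sum(n_total)),
                   by = c("species", "sample_id", "context")]
    bysp <- bysamp[, list(level = mean(level)), by = c("species", "context")]
    wide <- dcast(bysp, species ~ context, value.var = "level")
    names(wide)[-1] <- paste0("noncpg_", names(wide)[-1])
    sp <- merge(sp, wide, by = "species", all.x = TRUE)
  }
  as.data.frame(sp)
}

#' Brain vs other-tissue non-CpG methylation log-ratio
#'
#' Per species, the natural log of the brain non-CpG methylation level over
#' the mean level of the other tissues, with a one-sided paired Wilcoxon
#' signed-rank test across species for elevation in brain.
#'
#' @param calls `mc_calls`.
#' @param meta data.frame with `sample_id`, `species`, `tissue`.
#' @param brain_tissue tissue label treated as brain.
#' @return list with `per_species` (species, brain, other, log_ratio) and
#'   `p_value`.
#' @export
noncpg_brain_logratio <- function(calls, meta, brain_tissue = "brain") {
  ncpg <- calls[!is.na(calls$context) & calls$context != "CpG" &
                  calls$n_total >= 1L]
  ncpg[, c("species", "tissue") := list(
    meta$species[match(ncpg$sample_id, meta$sample_id)],
    meta$tissue[match(ncpg$sample_id, meta$sample_id)])]
  bysamp <- ncpg[, list(level = sum(n_meth) / sum(n_total)),
                 by = c("species", "tissue", "sample_id")]
  per <- bysamp[, {
    br <- level[tissue == brain_tissue]
    ot <- level[tissue != brain_tissue]
    if (!length(br) || !length(ot)) {
      NULL
    } else {
      list(brain = mean(br), other = mean(ot))
    }
  }, by = "species"]
  zero <- per$other == 0 | per$brain == 0
  if (any(zero)) {
    warning("species with zero non-CpG level excluded: ",
            paste(per$species[zero], collapse = ", "))
    per <- per[!zero]
  }
  per[, "log_ratio" := log(per$brain / per$other)]
  p <- if (nrow(per) >= 2) {
    suppressWarnings(wilcox.test(per$brain, per$other, paired = TRUE,
                                 alternative = "greater")$p.value)
  } else {
    NA_real_
  }
  list(per_species = as.data.frame(per), p_value = p)
}

#' Classify a read's CpG states as concordant, discordant or invalid
#'
#' The first and last CpG on the read are dropped as unreliable; reads with
#' fewer than `min_valid_cpgs` valid (M/U) states among the rest are
#' invalid; otherwise all-M or all-U is concordant and any mixture
#' discordant.
#'
#' @param states character vector over `"M"`, `"U"`, `NA`, ordered along
#'   the read.
#' @param min_valid_cpgs minimum valid measurements.
#' @param drop_end_cpgs drop the first and last CpG position.
#' @return one of `"concordant"`, `"discordant"`, `"invalid"`.
#' @export
classify_read_concordance <- function(states, min_valid_cpgs = 4L,
                                      drop_end_cpgs = TRUE) {
  if (drop_end_cpgs && length(states) >= 2L) {
    states <- states[-c(1L, length(states))]
  } else if (drop_end_cpgs) {
    states <- states[0L]
  }
  v <- states[!is.na(states)]
  if (length(v) < min_valid_cpgs) return("invalid")
  if (all(v == "M") || all(v == "U")) "concordant" else "discordant"
}

#' Proportion of discordant reads (PDR)
#'
#' Each read with at least `min_valid_cpgs` valid CpG measurements (after
#' dropping the read-end CpGs) is classified concordant or discordant; the
#' PDR of a CpG is the fraction of discordant reads among valid reads
#' covering it, the sample PDR the unweighted mean over CpGs with at least
#' one valid read, and the species PDR the mean over samples.
#'
#' @param read_states data.table as stored by [call_methylation()]
#'   (`sample_id`, `fragment_id`, `read_idx`, `pos`, `state`), or an
#'   `mc_calls` object carrying it as an attribute.
#' @param meta optional data.frame with `sample_id`, `species`.
#' @param min_valid_cpgs minimum valid CpGs per read.
#' @param drop_end_cpgs drop first/last CpG per read.
#' @return list with `per_cpg`, `per_sample`, `per_species` data.frames.
#' @export
compute_pdr <- function(read_states, meta = NULL, min_valid_cpgs = 4L,
                        drop_end_cpgs = TRUE) {
  if (inherits(read_states, "mc_calls")) {
    read_states <- attr(read_states, "read_states")
  }
  rs <- as.data.table(read_states)
  setorderv(rs, c("sample_id", "fragment_id", "read_idx", "pos"))
  rs[, "ncpg" := .N, by = c("sample_id", "fragment_id", "read_idx")]
  rs[, "cpg_rank" := seq_len(.N),
     by = c("sample_id", "fragment_id", "read_idx")]
  if (drop_end_cpgs) {
    rs <- rs[rs$cpg_rank > 1L & rs$cpg_rank < rs$ncpg]
  }
  cls <- rs[!is.na(rs$state)][, list(
    n_valid = .N,
    discordant = length(unique(state)) > 1L,
    pos_list = list(pos)
  ), by = c("sample_id", "fragment_id", "read_idx")]
  cls <- cls[cls$n_valid >= min_valid_cpgs]
  if (!nrow(cls)) stop("no valid reads for PDR", call. = FALSE)
  valid <- merge(rs[!is.na(rs$state)], cls[, c("sample_id", "fragment_id",
                                               "read_idx", "discordant")],
                 by = c("sample_id", "fragment_id", "read_idx"))
  per_cpg <- valid[, list(n_valid_reads = .N, pdr = mean(discordant)),
                   by = c("sample_id", "fragment_id", "pos")]
  per_sample <- per_cpg[, list(pdr = mean(pdr)), by = "sample_id"]
  out <- list(per_cpg = as.data.frame(per_cpg),
              per_sample = as.data.frame(per_sample))
  if (!is.null(meta)) {
    ps <- merge(per_sample, as.data.table(meta)[, c("sample_id", "species")],
                by = "sample_id")
    out$per_species <- as.data.frame(
      ps[, list(pdr = mean(pdr)), by = "species"])
  }
  out
}

#' Expected PDR under independent per-CpG methylation
#'
#' With `n` CpGs per read each independently methylated with probability
#' `m`, a read is concordant only when all CpGs share one state, so the
#' expected PDR is `1 - m^n - (1 - m)^n`. The curve vanishes at m = 0 and
#' m = 1 and is symmetric about m = 0.5, where it attains its maximum.
#'
#' @param m_grid methylation levels to evaluate (step <= 0.001 recommended
#'   for locating the argmax).
#' @param n CpGs per read (>= 4).
#' @return object of class `mc_pdr_curve`: data.frame `curve` (m,
#'   expected_pdr) plus `argmax_m` and `n`.
#' @export
expected_pdr <- function(m_grid = seq(0, 1, by = 0.001), n = 4L) {
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  pdr <- 1 - m_grid^n - (1 - m_grid)^n
  structure(list(curve = data.frame(m = m_grid, expected_pdr = pdr),
                 argmax_m = m_grid[which.max(pdr)], n = n),
            class = "mc_pdr_curve")
}

#' @export
print.mc_pdr_curve <- function(x, ...) {
  cat("expected PDR curve (n =", x$n, "): maximum",
      round(max(x$curve$expected_pdr), 4), "at m =", x$argmax_m, "\n")
  invisible(x)
}
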