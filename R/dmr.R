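#' Tissue versus individual variance decomposition
#'
#' For each eligible species (at least two individuals, two tissues, and
#' one tissue shared between individuals), the variance explained by
#' tissue is the mean squared Pearson correlation of fragment-level
#' methylation between samples of the same tissue from different
#' individuals, and the variance explained by the individual the mean over
#' same-individual different-tissue pairs. A two-sided paired Wilcoxon
#' signed-rank test compares the two across species.
#'
#' @param calls `mc_calls`.
#' @param meta data.frame with sample_id, species, tissue, individual.
#' @param min_shared_fragments minimum fragments shared by a sample pair
#'   for its correlation to count.
#' @return list with `per_species` (species, r2_tissue, r2_individual,
#'   n_pairs_tissue, n_pairs_individual) and `p_value`.
#' @export
variance_decomposition <- function(calls, meta, min_shared_fragments = 100L) {
  cpg <- calls[calls$context == "CpG" & !is.na(calls$context) &
                 calls$n_total >= 1L]
  frag <- cpg[, list(meth = mean(n_meth / n_total)),
              by = c("sample_id", "fragment_id")]
  md <- as.data.table(meta)
  rows <- lapply(unique(md$species), function(sp) {
    ms <- md[md$species == sp]
    if (length(unique(ms$individual)) < 2L ||
        length(unique(ms$tissue)) < 2L) {
      return(NULL)
    }
    shared <- any(vapply(unique(ms$tissue), function(tt) {
      length(unique(ms$individual[ms$tissue == tt])) >= 2L
    }, TRUE))
    if (!shared) return(NULL)
    sids <- ms$sample_id
    prof <- frag[frag$sample_id %chin% sids]
    wide <- dcast(prof, fragment_id ~ sample_id, value.var = "meth")
    pair_r2 <- function(a, b) {
      va <- wide[[a]]; vb <- wide[[b]]
      ok <- !is.na(va) & !is.na(vb)
      if (sum(ok) < min_shared_fragments) return(NA_real_)
      cor(va[ok], vb[ok])^2
    }
    cmb <- combn(sids, 2L)
    t_r2 <- c(); i_r2 <- c()
    for (ci in seq_len(ncol(cmb))) {
      a <- cmb[1, ci]; b <- cmb[2, ci]
      ta <- ms$tissue[ms$sample_id == a]; tb <- ms$tissue[ms$sample_id == b]
      ia <- ms$individual[ms$sample_id == a]
      ib <- ms$individual[ms$sample_id == b]
      if (ta == tb && ia != ib) t_r2 <- c(t_r2, pair_r2(a, b))
      if (ta != tb && ia == ib) i_r2 <- c(i_r2, pair_r2(a, b))
    }
    data.frame(species = sp,
               r2_tissue = if (length(t_r2)) mean(t_r2, na.rm = TRUE) else NA_real_,
               r2_individual = if (length(i_r2)) mean(i_r2, na.rm = TRUE) else NA_real_,
               n_pairs_tissue = sum(!is.na(t_r2)),
               n_pairs_individual = sum(!is.na(i_r2)))
  })
  per <- do.call(rbind, rows)
  p <- NA_real_
  if (!is.null(per) && sum(complete.cases(
    per[, c("r2_tissue", "r2_individual")])) >= 2L) {
    cc <- per[complete.cases(per[, c("r2_tissue", "r2_individual")]), ]
    p <- suppressWarnings(wilcox.test(cc$r2_tissue, cc$r2_individual,
                                      paired = TRUE)$p.value)
  }
  list(per_species = per, p_value = p)
}

# Smyth-style moment fit of the scale / df of an inverse-chi-square prior
# on residual variances: returns list(d0, s0_sq)
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & df > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s0_sq = mean(s2[s2 > 0])))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  ebar <- mean(e)
  v <- mean((e - ebar)^2 * length(e) / (length(e) - 1)) -
    mean(trigamma(df[ok] / 2))
  if (is.na(v) || v <= 0) {
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  }
  rhs <- v
  f <- function(x) trigamma(x) - rhs
  lo <- 1e-6; hi <- 1e7
  d0_half <- tryCatch(uniroot(f, c(lo, hi))$root, error = function(e) Inf)
  d0 <- 2 * d0_half
  s0_sq <- exp(ebar + digamma(d0_half) - log(d0_half))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated per-CpG differential methylation test between two tissues
#'
#' Per CpG, a two-group t-test on methylation ratios with empirical-Bayes
#' variance shrinkage: the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` with the prior `(d0, s0)` fitted across
#' CpGs by moment matching on log variances; the moderated t has `d + d0`
#' degrees of freedom. P-values are Benjamini-Hochberg adjusted.
#'
#' @param calls `mc_calls`.
#' @param meta data.frame with sample_id, tissue.
#' @param tissues length-2 character; the difference is
#'   `tissues[1] - tissues[2]`.
#' @param min_samples minimum samples per tissue per CpG.
#' @return data.table per CpG: fragment_id, pos, means per tissue, diff,
#'   t, df, p, q, coverage means.
#' @export
cpg_differential_test <- function(calls, meta, tissues = c("heart", "liver"),
                                  min_samples = 2L) {
  md <- as.data.table(meta)
  cpg <- calls[calls$context == "CpG" & !is.na(calls$context) &
                 calls$n_total >= 1L]
  cpg[, "tissue" := md$tissue[match(cpg$sample_id, md$sample_id)]]
  cpg <- cpg[cpg$tissue %chin% tissues]
  cpg[, "ratio" := cpg$n_meth / cpg$n_total]
  st <- cpg[, list(
    n1 = sum(tissue == tissues[1]), n2 = sum(tissue == tissues[2]),
    m1 = mean(ratio[tissue == tissues[1]]),
    m2 = mean(ratio[tissue == tissues[2]]),
    v1 = var(ratio[tissue == tissues[1]]),
    v2 = var(ratio[tissue == tissues[2]]),
    cov1 = mean(n_total[tissue == tissues[1]]),
    cov2 = mean(n_total[tissue == tissues[2]])
  ), by = c("fragment_id", "pos")]
  st <- st[st$n1 >= min_samples & st$n2 >= min_samples]
  if (!nrow(st)) stop("no CpG with enough samples per tissue", call. = FALSE)
  df <- st$n1 + st$n2 - 2L
  s2 <- ((st$n1 - 1) * ifelse(is.na(st$v1), 0, st$v1) +
           (st$n2 - 1) * ifelse(is.na(st$v2), 0, st$v2)) / df
  if (all(s2 == 0)) {
    warning("zero variance everywhere; falling back to exact counts test")
    p <- vapply(seq_len(nrow(st)), function(i) {
      sub <- cpg[cpg$fragment_id == st$fragment_id[i] & cpg$pos == st$pos[i]]
      tab <- rbind(
        c(sum(sub$n_meth[sub$tissue == tissues[1]]),
          sum((sub$n_total - sub$n_meth)[sub$tissue == tissues[1]])),
        c(sum(sub$n_meth[sub$tissue == tissues[2]]),
          sum((sub$n_total - sub$n_meth)[sub$tissue == tissues[2]])))
      fisher.test(tab)$p.value
    }, 0)
    st[, c("t", "df", "p") := list(NA_real_, NA_real_, p)]
  } else {
    prior <- fit_variance_prior(s2, df)
    s2post <- if (is.finite(prior$d0)) {
      (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
    } else {
      rep(prior$s0_sq, length(s2))
    }
    se <- sqrt(s2post * (1 / st$n1 + 1 / st$n2))
    tstat <- (st$m1 - st$m2) / se
    dftot <- df + (if (is.finite(prior$d0)) prior$d0 else Inf)
    p <- 2 * pt(-abs(tstat), dftot)
    p[se == 0] <- 1
    st[, c("t", "df", "p") := list(tstat, dftot, p)]
  }
  st[, "q" := p.adjust(st$p, method = "BH")]
  st[, "diff" := st$m1 - st$m2]
  setnames(st, c("m1", "m2", "cov1", "cov2"),
           c(paste0("mean_", tissues), paste0("cov_", tissues)))
  st[]
}

#' Combine per-CpG p-values into fragment p-values
#'
#' Fisher's statistic `X = -2 sum(log p)` per fragment, referred by default
#' to a scaled chi-square whose moments are corrected for the average
#' correlation between CpGs within fragments (Brown's method with the
#' Kost-McDermott polynomial approximation of the log-p covariance);
#' `method = "fisher"` uses the plain chi-square with `2m` degrees of
#' freedom.
#'
#' @param p numeric p-values.
#' @param fragment_id fragment of each p-value.
#' @param method `"brown"` or `"fisher"`.
#' @param rho average within-fragment correlation of the per-CpG
#'   statistics; estimated with [estimate_cpg_correlation()] or supplied;
#'   `NULL` means 0 (independence).
#' @return data.table (fragment_id, n_cpgs, statistic, p).
#' @export
combine_fragment_p <- function(p, fragment_id, method = c("brown", "fisher"),
                               rho = NULL) {
  method <- match.arg(method)
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-values of 0 clipped to 1e-300")
    p[p == 0] <- 1e-300
  }
  if (is.null(rho) || method == "fisher") rho <- 0
  rho <- max(min(rho, 0.99), 0)
  dt <- data.table(fragment_id = fragment_id, p = p)[!is.na(p)]
  out <- dt[, {
    m <- .N
    X <- -2 * sum(log(p))
    if (m == 1L) {
      list(n_cpgs = m, statistic = X, p = p)
    } else {
      covt <- 3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3
      EX <- 2 * m
      VX <- 4 * m + 2 * choose(m, 2) * covt
      cscale <- VX / (2 * EX)
      fdf <- 2 * EX^2 / VX
      list(n_cpgs = m, statistic = X,
           p = pchisq(X / cscale, df = fdf, lower.tail = FALSE))
    }
  }, by = "fragment_id"]
  out[]
}

#' Average within-fragment correlation of per-CpG methylation ratios
#'
#' @param calls `mc_calls`.
#' @param max_fragments subsample for speed.
#' @return scalar mean pairwise Pearson correlation.
#' @export
estimate_cpg_correlation <- function(calls, max_fragments = 500L) {
  cpg <- calls[calls$context == "CpG" & !is.na(calls$context) &
                 calls$n_total >= 1L]
  cpg[, "ratio" := cpg$n_meth / cpg$n_total]
  frs <- unique(cpg$fragment_id)
  if (length(frs) > max_fragments) frs <- frs[seq_len(max_fragments)]
  cors <- c()
  for (fr in frs) {
    sub <- cpg[cpg$fragment_id == fr]
    w <- dcast(sub, sample_id ~ pos, value.var = "ratio")
    if (ncol(w) < 3L || nrow(w) < 3L) next
    cm <- suppressWarnings(cor(as.matrix(w[, -1]),
                               use = "pairwise.complete.obs"))
    v <- cm[upper.tri(cm)]
    cors <- c(cors, v[!is.na(v)])
  }
  if (!length(cors)) return(0)
  mean(cors)
}

#' Select top differentially methylated fragments by combined rank
#'
#' Fragments are ranked ascending by p-value, by negative absolute
#' relative difference, and by negative absolute difference; the combined
#' rank is the maximum of the three. Per direction, fragments passing
#' `p < p_threshold` and coverage >= `min_coverage` in both tissues are
#' selected in combined-rank order up to `top_k` (ties broken by fragment
#' id). The relative difference uses the mean of the two tissue means as
#' denominator.
#'
#' @param fragment_stats data.frame with fragment_id, p, and the per-tissue
#'   mean and coverage columns produced by aggregating
#'   [cpg_differential_test()] (see [fragment_dmr_stats()]).
#' @param tissues the two tissue names (direction `hypo-in-<tissue>` means
#'   that tissue is the less methylated one).
#' @param top_k selections per direction.
#' @param p_threshold,min_coverage eligibility filters.
#' @return data.table of class `mc_dmr` with ranks, direction and
#'   `selected`.
#' @export
rank_dmrs <- function(fragment_stats, tissues = c("heart", "liver"),
                      top_k = 500L, p_threshold = 0.05, min_coverage = 2) {
  fs <- as.data.table(fragment_stats)
  mcol <- paste0("mean_", tissues)
  ccol <- paste0("cov_", tissues)
  stopifnot(all(c("fragment_id", "p", mcol, ccol) %in% names(fs)))
  m1 <- fs[[mcol[1]]]; m2 <- fs[[mcol[2]]]
  fs[, "mean_diff" := m1 - m2]
  denom <- (m1 + m2) / 2
  fs[, "rel_diff" := ifelse(denom > 0, (m1 - m2) / denom, 0)]
  fs[, "rank_p" := rank(fs$p, ties.method = "min")]
  fs[, "rank_rel" := rank(-abs(fs$rel_diff), ties.method = "min")]
  fs[, "rank_abs" := rank(-abs(fs$mean_diff), ties.method = "min")]
  fs[, "combined_rank" := pmax(fs$rank_p, fs$rank_rel, fs$rank_abs)]
  fs[, "direction" := ifelse(fs$mean_diff < 0, paste0("hypo-in-", tissues[1]),
                             paste0("hypo-in-", tissues[2]))]
  eligible <- fs$p < p_threshold & fs[[ccol[1]]] >= min_coverage &
    fs[[ccol[2]]] >= min_coverage & fs$mean_diff != 0
  fs[, "selected" := FALSE]
  for (dr in unique(fs$direction)) {
    idx <- which(eligible & fs$direction == dr)
    idx <- idx[order(fs$combined_rank[idx], fs$fragment_id[idx])]
    fs$selected[head(idx, top_k)] <- TRUE
  }
  setattr(fs, "class", c("mc_dmr", class(fs)))
  fs[]
}

#' Fragment-level DMR statistics from per-CpG tests
#'
#' Aggregates per-CpG moderated tests to fragments: combined p-value (see
#' [combine_fragment_p()]) plus per-tissue fragment means and coverages.
#'
#' @param cpg_res result of [cpg_differential_test()].
#' @param method,rho passed to [combine_fragment_p()].
#' @param tissues the two tissue names.
#' @return data.frame ready for [rank_dmrs()].
#' @export
fragment_dmr_stats <- function(cpg_res, method = "brown", rho = NULL,
                               tissues = c("heart", "liver")) {
  comb <- combine_fragment_p(cpg_res$p, cpg_res$fragment_id,
                             method = method, rho = rho)
  mcol <- paste0("mean_", tissues)
  ccol <- paste0("cov_", tissues)
  agg <- cpg_res[, list(
    m1 = mean(get(mcol[1])), m2 = mean(get(mcol[2])),
    c1 = mean(get(ccol[1])), c2 = mean(get(ccol[2]))
  ), by = "fragment_id"]
  setnames(agg, c("m1", "m2", "c1", "c2"), c(mcol, ccol))
  as.data.frame(merge(comb, agg, by = "fragment_id"))
}
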