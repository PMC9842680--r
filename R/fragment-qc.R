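#' Coverage-based fragment flags (repeat / amplified / private)
#'
#' Per sample, a fragment is "reliably covered" if its read count exceeds
#' half the sample's average coverage and "highly covered" if it exceeds
#' four times the average (averages taken over fragments with nonzero
#' coverage in that sample; all thresholds strict). A fragment highly
#' covered in more than 80% of samples is flagged `repeat`; highly covered
#' in fewer than 20% (but at least one) is `amplified`; reliably covered in
#' more than 80% of one individual's samples and fewer than 20% of all
#' other individuals' samples is `private`. Flags are mutually exclusive
#' with precedence repeat > amplified > private. The private rule needs at
#' least four samples from at least two individuals.
#'
#' @param coverage numeric matrix, fragments x samples (read counts).
#' @param individuals named character vector mapping sample -> individual.
#' @param high_factor,reliable_factor multiples of the sample average
#'   defining "highly" / "reliably" covered.
#' @param high_frac,low_frac sample-fraction thresholds (strict).
#' @return list with `flags` (data.frame fragment, flag) and `per_sample`
#'   (data.frame of per-sample flag fractions among fragments covered in
#'   that sample).
#' @export
classify_fragments <- function(coverage, individuals,
                               high_factor = 4, reliable_factor = 0.5,
                               high_frac = 0.8, low_frac = 0.2) {
  stopifnot(is.matrix(coverage))
  if (is.null(rownames(coverage))) {
    rownames(coverage) <- sprintf("frag%06d", seq_len(nrow(coverage)))
  }
  if (is.null(colnames(coverage))) {
    colnames(coverage) <- sprintf("sample%03d", seq_len(ncol(coverage)))
  }
  empty <- colSums(coverage) == 0
  if (any(empty)) {
    warning("samples with all-zero coverage excluded: ",
            paste(colnames(coverage)[empty], collapse = ", "))
    coverage <- coverage[, !empty, drop = FALSE]
  }
  avg <- apply(coverage, 2, function(x) mean(x[x > 0]))
  high <- sweep(coverage, 2, high_factor * avg, ">")
  reliable <- sweep(coverage, 2, reliable_factor * avg, ">")

  ns <- ncol(coverage)
  high_frac_obs <- rowMeans(high)
  flag <- rep("none", nrow(coverage))
  flag[high_frac_obs > high_frac] <- "repeat"
  amp <- flag == "none" & high_frac_obs < low_frac & rowSums(high) >= 1L
  flag[amp] <- "amplified"

  inds <- individuals[colnames(coverage)]
  if (ns >= 4L && length(unique(inds)) >= 2L) {
    for (ind in unique(inds)) {
      own <- inds == ind
      if (!any(own) || all(own)) next
      own_frac <- rowMeans(reliable[, own, drop = FALSE])
      oth_frac <- rowMeans(reliable[, !own, drop = FALSE])
      priv <- flag == "none" & own_frac > high_frac & oth_frac < low_frac
      flag[priv] <- "private"
    }
  }
  flags <- data.frame(fragment = rownames(coverage), flag = flag,
                      stringsAsFactors = FALSE)
  per_sample <- do.call(rbind, lapply(seq_len(ns), function(si) {
    cov_here <- coverage[, si] > 0
    denom <- sum(cov_here)
    f <- flag[cov_here]
    data.frame(sample_id = colnames(coverage)[si],
               frac_repeat = if (denom) mean(f == "repeat") else NA_real_,
               frac_amplified = if (denom) mean(f == "amplified") else NA_real_,
               frac_private = if (denom) mean(f == "private") else NA_real_,
               frac_none = if (denom) mean(f == "none") else NA_real_)
  }))
  list(flags = flags, per_sample = per_sample)
}

#' Mean pairwise CpG overlap between samples of a species
#'
#' Pair overlap is `|A intersect B| / mean(|A|, |B|)` (denominator
#' configurable); the species value is the mean over all sample pairs, and
#' a species is dropped when it falls strictly below `drop_below`.
#'
#' @param covered_sets list of per-sample CpG identifier vectors.
#' @param denominator `"mean"`, `"min"` or `"jaccard"`.
#' @param drop_below keep/drop threshold (strict less-than).
#' @return list with `overlap` (mean), `pairwise` (data.frame) and `keep`
#'   (logical).
#' @export
cpg_overlap <- function(covered_sets, denominator = c("mean", "min", "jaccard"),
                        drop_below = 0.5) {
  denominator <- match.arg(denominator)
  if (length(covered_sets) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (is.null(names(covered_sets))) {
    names(covered_sets) <- sprintf("sample%03d", seq_along(covered_sets))
  }
  cmb <- combn(length(covered_sets), 2L)
  pw <- apply(cmb, 2, function(ij) {
    a <- unique(covered_sets[[ij[1]]])
    b <- unique(covered_sets[[ij[2]]])
    inter <- length(intersect(a, b))
    den <- switch(denominator,
                  mean = mean(c(length(a), length(b))),
                  min = min(length(a), length(b)),
                  jaccard = length(union(a, b)))
    if (den == 0) 0 else inter / den
  })
  pairwise <- data.frame(sample_a = names(covered_sets)[cmb[1, ]],
                         sample_b = names(covered_sets)[cmb[2, ]],
                         overlap = pw)
  ov <- mean(pw)
  list(overlap = ov, pairwise = pairwise, keep = !(ov < drop_below))
}

#' Fragment x sample coverage matrix from a call set
#'
#' Coverage of a fragment in a sample is the mean read total across its
#' cytosines.
#'
#' @param calls `mc_calls`.
#' @return numeric matrix fragments x samples.
#' @export
fragment_coverage_matrix <- function(calls) {
  agg <- calls[, list(cov = mean(n_total)),
               by = c("fragment_id", "sample_id")]
  frags <- sort(unique(agg$fragment_id))
  samps <- sort(unique(agg$sample_id))
  m <- matrix(0, length(frags), length(samps),
              dimnames = list(frags, samps))
  m[cbind(match(agg$fragment_id, frags), match(agg$sample_id, samps))] <-
    agg$cov
  m
}
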