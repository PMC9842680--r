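#' Construct a planted sequence-to-methylation rule
#'
#' The planted rule assigns each locus a base methylation probability
#' `plogis(intercept + sum(weights * 3-mer frequencies))`. Weights are
#' centred to mean zero (3-mer frequencies sum to one, so a common shift is
#' equivalent to moving the intercept). The default weight spread is chosen
#' so that loci of a few hundred bp receive strongly bimodal probabilities,
#' emulating the largely binary methylation landscape of vertebrate RRBS
#' fragments.
#'
#' @param kmer_weights optional named numeric over all 64 3-mers; drawn
#'   Gaussian when `NULL`.
#' @param intercept intercept on the logit scale.
#' @param weight_sd standard deviation of randomly drawn weights.
#' @param inverted flip the sign of all weights (an "inverted" species).
#' @param seed integer seed for random weights.
#' @return object of class `mc_code`.
#' @export
planted_code <- function(kmer_weights = NULL, intercept = 0,
                         weight_sd = 60, inverted = FALSE, seed = 1L) {
  kmers <- all_kmers(3L)
  if (is.null(kmer_weights)) {
    w <- with_seed(seed, rnorm(64, sd = weight_sd))
    names(w) <- kmers
  } else {
    if (!all(kmers %in% names(kmer_weights))) {
      stop("kmer_weights must be defined for all 64 3-mers", call. = FALSE)
    }
    w <- as.numeric(kmer_weights[kmers])
    names(w) <- kmers
  }
  w <- w - mean(w)
  if (inverted) w <- -w
  structure(list(kmers = kmers, weights = w, intercept = intercept,
                 link = "logistic", inverted = inverted),
            class = "mc_code")
}

#' Sign-flip a planted code (inverted species)
#' @param code `mc_code`.
#' @return `mc_code` with flipped weights and toggled `inverted` flag.
#' @export
invert_code <- function(code) {
  code$weights <- -code$weights
  code$inverted <- !code$inverted
  code
}

code_logit <- function(code, seqs) {
  f <- kmer_count_matrix(seqs, 3L, columns = code$kmers, freq = TRUE)
  as.vector(code$intercept + f %*% code$weights)
}

#' Assign a true methylome to loci under a planted code
#'
#' Computes per-fragment base methylation probabilities from the planted
#' code, then adds tissue and individual offsets (on the logit scale) for
#' randomly chosen effect fragments plus per-fragment-per-sample Gaussian
#' noise. Probabilities are the logistic transform, hence always in
#' \[0, 1\].
#'
#' @param fragments data.frame with columns `fragment_id` and `seq`.
#' @param code `mc_code` planted rule.
#' @param design data.frame of samples with columns `sample_id`, `tissue`,
#'   `individual` (plus optionally `species`, `library`).
#' @param tissue_effect_frac fraction of fragments given tissue-specific
#'   offsets.
#' @param individual_effect_frac fraction given individual-specific offsets.
#' @param tissue_sd,individual_sd offset standard deviations (logit scale).
#' @param noise_sd per fragment x sample Gaussian noise (logit scale).
#' @param cpg_jitter_sd per-CpG jitter applied on the probability scale when
#'   reads or calls are simulated.
#' @param noncpg_level baseline non-CpG methylation probability.
#' @param noncpg_brain_factor multiplier on `noncpg_level` for samples whose
#'   tissue is `"brain"` (non-CpG methylation is elevated in brain).
#' @param tissue_effects optional explicit list mapping fragment_id ->
#'   named numeric of per-tissue offsets; tissue names must occur in the
#'   design.
#' @param seed integer seed.
#' @return object of class `mc_methylome`: fragments, samples, `prob`
#'   (fragment x sample matrix), effect sets, and the noise parameters.
#' @export
assign_methylome <- function(fragments, code, design,
                             tissue_effect_frac = 0.1,
                             individual_effect_frac = 0.1,
                             tissue_sd = 2, individual_sd = 1,
                             noise_sd = 0.5, cpg_jitter_sd = 0.03,
                             noncpg_level = 0.01, noncpg_brain_factor = 2,
                             tissue_effects = NULL, seed = 1L) {
  stopifnot(all(c("fragment_id", "seq") %in% names(fragments)))
  need <- c("sample_id", "tissue", "individual")
  if (!all(need %in% names(design))) {
    stop("design needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  tissues <- unique(design$tissue)
  if (!is.null(tissue_effects)) {
    bad <- setdiff(unlist(lapply(tissue_effects, names)), tissues)
    if (length(bad)) {
      stop("unknown tissue label in effect set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  with_seed(seed, {
    nf <- nrow(fragments)
    ns <- nrow(design)
    base <- code_logit(code, fragments$seq)
    logit <- matrix(base, nf, ns,
                    dimnames = list(fragments$fragment_id, design$sample_id))

    t_set <- character()
    t_off <- list()
    if (!is.null(tissue_effects)) {
      t_set <- names(tissue_effects)
      t_off <- tissue_effects
    } else if (tissue_effect_frac > 0 && length(tissues) > 1) {
      t_set <- sample(fragments$fragment_id,
                      max(1L, round(tissue_effect_frac * nf)))
      t_off <- lapply(t_set, function(f) {
        setNames(rnorm(length(tissues), sd = tissue_sd), tissues)
      })
      names(t_off) <- t_set
    }
    inds <- unique(design$individual)
    i_set <- character()
    i_off <- list()
    if (individual_effect_frac > 0 && length(inds) > 1) {
      i_set <- sample(fragments$fragment_id,
                      max(1L, round(individual_effect_frac * nf)))
      i_off <- lapply(i_set, function(f) {
        setNames(rnorm(length(inds), sd = individual_sd), inds)
      })
      names(i_off) <- i_set
    }
    for (f in t_set) {
      logit[f, ] <- logit[f, ] + unname(t_off[[f]][design$tissue])
    }
    for (f in i_set) {
      logit[f, ] <- logit[f, ] + unname(i_off[[f]][design$individual])
    }
    if (noise_sd > 0) {
      logit <- logit + matrix(rnorm(nf * ns, sd = noise_sd), nf, ns)
    }
    structure(list(
      fragments = as.data.frame(fragments),
      samples = as.data.frame(design),
      prob = plogis(logit),
      base_logit = base,
      tissue_effect_set = t_set,
      individual_effect_set = i_set,
      tissue_offsets = t_off,
      individual_offsets = i_off,
      noise_sd = noise_sd,
      cpg_jitter_sd = cpg_jitter_sd,
      noncpg_level = noncpg_level,
      noncpg_brain_factor = noncpg_brain_factor
    ), class = "mc_methylome")
  })
}

#' @export
print.mc_methylome <- function(x, ...) {
  cat("mc_methylome:", nrow(x$fragments), "fragments x",
      nrow(x$samples), "samples;",
      length(x$tissue_effect_set), "tissue-effect fragments\n")
  invisible(x)
}

# per-sample non-CpG methylation probability implied by the methylome
noncpg_prob <- function(methylome, sample_row) {
  lev <- methylome$noncpg_level
  if (identical(sample_row$tissue, "brain")) lev <- lev * methylome$noncpg_brain_factor
  min(lev, 1)
}

#' Simulate a methylation call set directly from a true methylome
#'
#' Convenience generator that skips read simulation: per CpG, coverage is
#' Poisson and methylated counts are binomial around the planted per-CpG
#' probability (fragment probability plus per-CpG jitter). Useful for
#' testing downstream statistics at scale; the read-level simulator
#' ([simulate_rrbs_reads()]) exercises the same quantities end to end.
#'
#' @param methylome `mc_methylome`.
#' @param mean_coverage Poisson mean reads per CpG.
#' @param seed integer seed.
#' @return `mc_calls` data.table with columns `sample_id`, `fragment_id`,
#'   `pos`, `context`, `n_meth`, `n_total`.
#' @export
simulate_callset <- function(methylome, mean_coverage = 20, seed = 1L) {
  frag <- methylome$fragments
  cpg_pos <- lapply(frag$seq, function(s) {
    unlist(gregexpr("CG", s, fixed = TRUE))
  })
  cpg_pos <- lapply(cpg_pos, function(p) p[p > 0] - 1L) # 0-based C position
  with_seed(seed, {
    out <- vector("list", nrow(methylome$samples))
    ncpg <- lengths(cpg_pos)
    frag_idx <- rep(seq_len(nrow(frag)), ncpg)
    pos_all <- unlist(cpg_pos)
    for (si in seq_len(nrow(methylome$samples))) {
      p <- methylome$prob[frag_idx, si] +
        rnorm(length(frag_idx), sd = methylome$cpg_jitter_sd)
      p <- pmin(pmax(p, 0), 1)
      n_tot <- rpois(length(frag_idx), mean_coverage)
      n_meth <- rbinom(length(frag_idx), n_tot, p)
      out[[si]] <- data.table(
        sample_id = methylome$samples$sample_id[si],
        fragment_id = frag$fragment_id[frag_idx],
        pos = pos_all, context = "CpG",
        n_meth = n_meth, n_total = n_tot
      )
    }
    calls <- rbindlist(out)[n_total > 0]
    setattr(calls, "class", c("mc_calls", class(calls)))
    calls[]
  })
}
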