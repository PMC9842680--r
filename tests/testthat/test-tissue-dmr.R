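test_that("variance decomposition attributes variance to the planted factor", {
  # duplicated identical samples: both correlations are perfect
  sim <- make_tissue_calls(n_frag = 150, n_eff = 0, seed = 1)
  dup <- data.table::copy(sim$calls)
  per <- variance_decomposition(sim$calls, sim$design,
                                min_shared_fragments = 50)$per_species
  expect_true(all(per$r2_tissue <= 1 & per$r2_tissue >= 0))

  # exact duplicates across tissue and individual give r2 = 1
  calls_id <- data.table::copy(sim$calls)
  s2 <- calls_id[calls_id$sample_id == "s1"]
  ident <- data.table::rbindlist(list(
    s2, within(as.data.frame(s2), sample_id <- "s2x"),
    within(as.data.frame(s2), sample_id <- "s3x"),
    within(as.data.frame(s2), sample_id <- "s4x")))
  data.table::setattr(ident, "class", class(sim$calls))
  meta_id <- data.frame(sample_id = c("s1", "s2x", "s3x", "s4x"),
                        species = "spX",
                        tissue = c("heart", "heart", "liver", "liver"),
                        individual = c("i1", "i2", "i1", "i2"))
  per_id <- variance_decomposition(ident, meta_id,
                                   min_shared_fragments = 50)$per_species
  expect_equal(per_id$r2_tissue, 1)
  expect_equal(per_id$r2_individual, 1)

  # species with one individual is excluded
  meta_one <- meta_id
  meta_one$individual <- "i1"
  expect_null(variance_decomposition(ident, meta_one)$per_species)

  # planted tissue effects dominate over replicates
  wins <- 0L
  for (r in 1:8) {
    sim_t <- make_tissue_calls(n_frag = 200, n_eff = 40, eff = 2,
                               seed = 10 + r)
    per_t <- variance_decomposition(sim_t$calls, sim_t$design,
                                    min_shared_fragments = 50)$per_species
    wins <- wins + (per_t$r2_tissue > per_t$r2_individual)
  }
  expect_gte(wins, 7L)
})

test_that("moderated t matches the limma moments and controls type I error", {
  sim <- make_tissue_calls(n_frag = 300, n_eff = 0, seed = 3, noise_sd = 0.3)
  res <- cpg_differential_test(sim$calls, sim$design)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= res$p - 1e-12))

  # type I: null CpGs rejected at close to the nominal rate
  expect_gt(mean(res$p < 0.05), 0.01)
  expect_lt(mean(res$p < 0.05), 0.09)

  # planted strong difference is detected decisively
  simd <- make_tissue_calls(n_frag = 200, n_eff = 25, eff = 4, seed = 4,
                            noise_sd = 0.1)
  resd <- cpg_differential_test(simd$calls, simd$design)
  planted <- resd[resd$fragment_id %in% simd$eff_frags]
  expect_lt(median(planted$p), 1e-4)

  # identical values in both groups: maximal p
  flat <- data.table::data.table(
    sample_id = paste0("s", 1:8), fragment_id = "f1", pos = 0L,
    context = "CpG", n_meth = 10L, n_total = 20L)
  data.table::setattr(flat, "class", c("mc_calls", class(flat)))
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     tissue = rep(c("heart", "liver"), each = 4))
  expect_warning(r1 <- cpg_differential_test(flat, meta), "zero variance")
  expect_equal(r1$p, 1)

  skip_if_not_installed("limma")
  # cross-check the variance prior fit against limma::squeezeVar on data
  # drawn from a genuine scaled-inverse-chi-square prior
  set.seed(5)
  d0_true <- 8; s0_true <- 0.02; d <- 6
  varg <- s0_true * d0_true / rchisq(500, df = d0_true)
  s2 <- varg * rchisq(500, df = d) / d
  prior <- methcode:::fit_variance_prior(s2, rep(d, 500))
  sq <- limma::squeezeVar(s2, df = d)
  expect_lt(abs(prior$d0 - sq$df.prior) / sq$df.prior, 0.2)
  expect_lt(abs(prior$s0_sq - sq$var.prior) / sq$var.prior, 0.1)
  post <- (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
  expect_lt(max(abs(post - sq$var.post) / sq$var.post), 0.1)
})

test_that("fragment p-value combination follows Fisher / Brown", {
  # single CpG: fragment p equals the CpG p
  one <- combine_fragment_p(0.03, "f1")
  expect_equal(one$p, 0.03)

  # all p = 1: no evidence
  flat <- combine_fragment_p(rep(1, 5), rep("f1", 5))
  expect_equal(flat$p, 1, tolerance = 1e-12)

  # independent p = (0.05, 0.05), plain Fisher: X = 11.98, df 4
  fis <- combine_fragment_p(c(0.05, 0.05), c("f1", "f1"),
                            method = "fisher")
  expect_equal(fis$statistic, -2 * sum(log(c(0.05, 0.05))),
               tolerance = 1e-9)
  expect_equal(fis$p, pchisq(11.98293, df = 4, lower.tail = FALSE),
               tolerance = 1e-4)
  expect_equal(round(fis$p, 4), 0.0175)

  # Brown with rho = 0 reduces to Fisher
  br0 <- combine_fragment_p(c(0.05, 0.05), c("f1", "f1"),
                            method = "brown", rho = 0)
  expect_equal(br0$p, fis$p, tolerance = 1e-9)
  # positive correlation weakens the combination
  br5 <- combine_fragment_p(c(0.05, 0.05), c("f1", "f1"),
                            method = "brown", rho = 0.5)
  expect_gt(br5$p, br0$p)

  expect_warning(z <- combine_fragment_p(c(0, 0.5), rep("f1", 2)),
                 "clipped")
  expect_true(z$p > 0)
})

test_that("type I error of the fragment-level combination stays controlled", {
  sim <- make_tissue_calls(n_frag = 900, n_eff = 0, seed = 6, noise_sd = 0.3)
  res <- cpg_differential_test(sim$calls, sim$design)
  rho <- estimate_cpg_correlation(sim$calls)
  fs <- fragment_dmr_stats(res, rho = rho)
  expect_lte(mean(fs$p < 0.05), 0.07)
})

test_that("combined-rank DMR selection respects its filters and symmetry", {
  sim <- make_tissue_calls(n_frag = 300, n_eff = 25, eff = 3, seed = 7,
                           noise_sd = 0.2)
  res <- cpg_differential_test(sim$calls, sim$design)
  fs <- fragment_dmr_stats(res, rho = estimate_cpg_correlation(sim$calls))
  dmr <- rank_dmrs(fs, top_k = 30)
  expect_true(all(dmr$p[dmr$selected] < 0.05))
  expect_true(all(dmr$cov_heart[dmr$selected] >= 2))
  expect_true(all(dmr$cov_liver[dmr$selected] >= 2))
  expect_lte(sum(dmr$selected & dmr$direction == "hypo-in-heart"), 30L)
  # planted fragments (hypo in heart) occupy the top combined ranks
  sel <- dmr[dmr$selected & dmr$direction == "hypo-in-heart", ]
  best <- sel$fragment_id[order(sel$combined_rank)][1:10]
  expect_gte(mean(best %in% sim$eff_frags), 0.9)

  # fragments failing the p filter or the coverage filter are never chosen
  fs_bad <- fs
  fs_bad$p[1] <- 0.2
  fs_bad$cov_liver[2] <- 1
  dmr2 <- rank_dmrs(fs_bad, top_k = 1000)
  expect_false(dmr2$selected[dmr2$fragment_id == fs_bad$fragment_id[1]])
  expect_false(dmr2$selected[dmr2$fragment_id == fs_bad$fragment_id[2]])

  # swapping the tissue labels flips directions, keeps combined ranks
  fs_sw <- fs
  fs_sw[, c("mean_heart", "mean_liver")] <- fs[, c("mean_liver",
                                                   "mean_heart")]
  fs_sw[, c("cov_heart", "cov_liver")] <- fs[, c("cov_liver", "cov_heart")]
  dmr_sw <- rank_dmrs(fs_sw, top_k = 30)
  expect_equal(dmr_sw$combined_rank, dmr$combined_rank)
  flip <- c("hypo-in-heart" = "hypo-in-liver",
            "hypo-in-liver" = "hypo-in-heart")
  expect_equal(dmr_sw$direction, unname(flip[dmr$direction]))
  expect_equal(dmr_sw$selected, dmr$selected)
})

test_that("motif enrichment finds planted motifs with exact-null thresholds", {
  meme <- write_test_meme(c(M1 = "ACGTACGT", M0 = "TTAAGGCC"))
  pw <- read_meme(meme)
  expect_named(pw, c("M1", "M0"))
  expect_equal(dim(pw$M1$mat), c(8L, 4L))

  set.seed(8)
  fg <- rand_seqs(250, 100)
  bg <- rand_seqs(250, 100)
  idx <- sample(250, 200)
  fg[idx] <- paste0(substr(fg[idx], 1, 40), "ACGTACGT",
                    substr(fg[idx], 49, 100))
  enr <- dmr_motif_enrichment(fg, bg, pw)
  expect_true(all(enr$q >= enr$p - 1e-12))
  m1h <- enr[enr$motif == "M1" & enr$direction == "hyper", ]
  expect_true(m1h$significant)
  expect_lt(m1h$q, 1e-6)
  # the null motif is never significant
  expect_false(any(enr$significant[enr$motif == "M0"]))

  # foreground equal to background: nothing significant
  enr0 <- dmr_motif_enrichment(fg, fg, pw)
  expect_false(any(enr0$significant))
})

test_that("motif hit calling matches a brute-force empirical threshold scan", {
  meme <- write_test_meme(c(MX = "ACGTACGT"))
  pw <- read_meme(meme)
  set.seed(9)
  seqs <- rand_seqs(60, 120)
  bg <- rep(0.25, 4)
  pm <- (pw$MX$mat + 0.01) / rowSums(pw$MX$mat + 0.01)
  lod <- round(log2(sweep(pm, 2, bg, "/")) * 1000) / 1000
  thr <- methcode:::pwm_score_threshold(lod, bg, 1e-4)
  # brute force: the null exceedance of thr over all 4^8 words <= 1e-4,
  # and the next lower achievable score exceeds 1e-4
  words <- expand.grid(rep(list(1:4), 8))
  sc <- as.matrix(words)
  scores <- vapply(seq_len(nrow(sc)), function(i) {
    sum(lod[cbind(1:8, sc[i, ])])
  }, 0)
  expect_lte(mean(scores >= thr), 1e-4)
  lower <- max(scores[scores < thr])
  expect_gt(mean(scores >= lower), 1e-4)
  # sequence-level hits equal the brute-force window scan
  hits_pkg <- methcode:::pwm_max_scores(seqs, lod) >= thr
  brute <- vapply(seqs, function(s) {
    best <- -Inf
    for (str in c(s, revcomp(s))) {
      ch <- match(strsplit(str, "")[[1]], c("A", "C", "G", "T"))
      for (st in 1:(length(ch) - 7)) {
        best <- max(best, sum(lod[cbind(1:8, ch[st:(st + 7)])]))
      }
    }
    best >= thr
  }, TRUE, USE.NAMES = FALSE)
  expect_equal(unname(hits_pkg), brute)
})

test_that("TF activity rules combine preference, direction and expression", {
  enr <- data.frame(
    motif = c("m1", "m2", "m3", "m4"), name = c("TF1", "TF2", "TF3", "TF4"),
    n_fg = 500, fg_hits = 100, n_bg = 500, bg_hits = 5,
    odds_ratio = 20, p = 1e-10, q = 1e-9,
    significant = TRUE,
    direction = c("hypo", "hyper", "hyper", "hypo"))
  pref <- data.frame(tf = c("TF1", "TF2", "TF3", "TF4"),
                     preference = c("unmethylated", "methylated",
                                    "unmethylated", "unmethylated"))
  expr <- data.frame(tf = c("TF1", "TF2", "TF3", "TF4"),
                     heart = c(5, 5, 5, 0.5), liver = c(2, 2, 2, 0.9))
  tg <- data.frame(tf = c("TF1", "TF2"), target = c("GENE1", "GENE2"),
                   sign = c("activation", "repression"))
  res <- tf_activity_and_network(enr, pref, expr, tg, min_enrichments = 2)
  act <- setNames(res$calls$activity, res$calls$tf)
  expect_equal(unname(act["TF1"]), "liver")   # unmeth pref + liver hypo
  expect_equal(unname(act["TF2"]), "liver")   # meth pref + liver hyper
  expect_equal(unname(act["TF3"]), "heart")   # unmeth pref + liver hyper
  expect_equal(unname(act["TF4"]), "none")    # expression <= 1 everywhere
  expect_equal(sort(res$edges$target), c("GENE1", "GENE2"))

  # below the species-level enrichment minimum: no calls
  res2 <- tf_activity_and_network(enr, pref, expr, tg, min_enrichments = 10)
  expect_true(all(res2$calls$activity == "none"))
})
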