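test_that("crossmap places fragments, rejects high-mismatch and ambiguity", {
  set.seed(1)
  genome <- rand_seqs(1, 30000, gc = 0.45)
  starts <- seq(100, 25000, by = 500)[1:40]
  frags <- setNames(substring(genome, starts + 1, starts + 50),
                    sprintf("f%03d", seq_along(starts)))
  cm <- crossmap_fragments(frags, list(gA = c(chr1 = genome)))
  expect_equal(cm$best_genome, "gA")
  expect_equal(unname(cm$mapping_rates["gA"]), 1)
  mp <- cm$mappings
  expect_true(all(mp$n_mismatches == 0L))
  # every accepted mapping satisfies the mismatch-rate bound
  expect_true(all(mp$n_mismatches / 50 <= 0.2))
  expect_equal(sort(mp$start), sort(starts))

  # 11 substitutions in 50 bp (rate 0.22) exceeds the bound -> rejected
  mut <- orig <- frags[1]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  for (i in seq(1, 41, by = 4)) {
    substr(mut, i, i) <- nxt[substr(orig, i, i)]
  }
  n_mm <- sum(strsplit(orig, "")[[1]] != strsplit(mut, "")[[1]])
  expect_gte(n_mm, 11L)
  cm_mut <- crossmap_fragments(setNames(mut, "mut"),
                               list(gA = c(chr1 = genome)))
  expect_equal(nrow(cm_mut$mappings), 0L)

  # duplicated placement: ambiguous best hits stay unmapped
  dup_genome <- paste0(genome, substr(genome, 101, 150))
  cm_dup <- crossmap_fragments(frags["f001"],
                               list(gA = c(chr1 = dup_genome)))
  expect_equal(nrow(cm_dup$mappings), 0L)

  # genome containing the fragments verbatim dominates a random genome
  set.seed(2)
  cm2 <- crossmap_fragments(frags, list(
    gA = c(chr1 = genome), gB = c(chr1 = rand_seqs(1, 30000))))
  expect_equal(cm2$best_genome, "gA")

  # minus-strand placements are found
  rc <- setNames(revcomp(frags[2]), "rc")
  cm_rc <- crossmap_fragments(rc, list(gA = c(chr1 = genome)))
  expect_equal(cm_rc$mappings$strand, "-")
  expect_equal(cm_rc$mappings$start, starts[2])
})

test_that("gene profiles bin flanks and body, strand-aware", {
  genes <- data.frame(chrom = "chr1", start = c(20000L, 40000L),
                      end = c(23000L, 43000L), strand = c("+", "-"),
                      name = c("gp", "gm"))
  pos <- seq(0L, 60000L, by = 20L)
  # uniform field: every bin 0.8, dip 0
  calls_df <- data.frame(chrom = "chr1", pos = pos, ratio = 0.8)
  gp <- gene_profile(calls_df, genes)
  expect_true(all(abs(gp$meta - 0.8) < 1e-12))
  expect_equal(gp$dip_statistic, 0)

  # planted unmethylated promoters: meta-profile minimum in promoter bins
  ratio <- rep(0.8, length(pos))
  ratio[pos >= 18500 & pos < 20000] <- 0.05  # plus-strand promoter
  ratio[pos >= 43000 & pos < 44500] <- 0.05  # minus-strand promoter
  gp2 <- gene_profile(data.frame(chrom = "chr1", pos = pos, ratio = ratio),
                      genes)
  expect_true(which.min(gp2$meta) %in% gp2$promoter_bins)
  expect_gt(gp2$dip_statistic, 0.5)

  # strand symmetry: a minus-strand gene yields the mirrored profile of
  # the equivalent plus-strand construction
  g_minus <- genes[2, , drop = FALSE]
  g_plus <- data.frame(chrom = "chr1", start = 40000L, end = 43000L,
                       strand = "+", name = "gm_as_plus")
  r2 <- rep(0.8, length(pos))
  r2[pos >= 41000 & pos < 42000] <- 0.2
  d2 <- data.frame(chrom = "chr1", pos = pos, ratio = r2)
  pm_prof <- gene_profile(d2, g_minus)$per_gene[1, ]
  pp_prof <- gene_profile(d2, g_plus)$per_gene[1, ]
  expect_equal(unname(pm_prof), rev(unname(pp_prof)))
})

test_that("promoter matrix maps genes through ortholog dictionaries", {
  genes <- data.frame(chrom = "chr1", start = c(10000L, 20000L, 30000L),
                      end = c(12000L, 22000L, 32000L),
                      strand = "+", name = c("gA", "gB", "gC"))
  pos <- seq(0L, 40000L, by = 10L)
  calls_df <- data.frame(chrom = "chr1", pos = pos, ratio = 0.3)
  pv <- promoter_methylation(calls_df, genes)
  expect_equal(unname(pv), rep(0.3, 3), tolerance = 1e-12)

  g2n <- data.frame(gene_id = c("gA", "gB", "gC"),
                    ncbi_id = c("n1", "n2", "n3"))
  n2h <- data.frame(ncbi_id = c("n1", "n2"), human_id = c("HG1", "HG1"))
  m <- promoter_matrix(list(s1 = pv), g2n, n2h)
  # gC lacks an ortholog -> absent; gA and gB share HG1 -> averaged
  expect_equal(colnames(m), "HG1")
  expect_equal(unname(m["s1", "HG1"]), 0.3, tolerance = 1e-12)

  # duplicate dictionary rows are deduplicated with a warning
  g2n_dup <- rbind(g2n, data.frame(gene_id = "gA", ncbi_id = "n9"))
  expect_warning(promoter_matrix(list(s1 = pv), g2n_dup, n2h), "duplicate")
})

test_that("scrambling preserves the missingness mask exactly", {
  set.seed(3)
  m <- matrix(runif(200), 20, 10)
  m[sample(200, 60)] <- NA
  sc <- methcode:::scramble_matrix(m, seed = 4)
  expect_identical(is.na(sc), is.na(m))
  expect_equal(sort(sc[!is.na(sc)]), sort(m[!is.na(m)]))
  expect_false(identical(sc, m))
})

test_that("embedding recovers planted sample groups; scrambling destroys them", {
  set.seed(5)
  n1 <- 20L; n2 <- 20L; ng <- 80L
  base1 <- rbeta(ng, 2, 5); base2 <- rbeta(ng, 5, 2)
  mm <- rbind(t(replicate(n1, base1 + rnorm(ng, 0, 0.05))),
              t(replicate(n2, base2 + rnorm(ng, 0, 0.05))))
  rownames(mm) <- paste0("s", seq_len(n1 + n2))
  colnames(mm) <- paste0("g", seq_len(ng))
  mm[sample(length(mm), length(mm) * 0.1)] <- NA
  emb <- embed_and_cluster(mm, "samples", min_other = 5, min_own = 5,
                           n_neighbors = 8, resolution = 0.5, seed = 6)
  truth <- rep(1:2, c(n1, n2))[match(emb$embedding$id, rownames(mm))]
  tab <- table(emb$embedding$cluster, truth)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(length(unique(emb$embedding$cluster)), 2L)
  expect_gte(purity, 0.9)
  # scrambled control: clustering collapses or purity near chance
  struth <- rep(1:2, c(n1, n2))[match(emb$scrambled$id, rownames(mm))]
  stab <- table(emb$scrambled$cluster, struth)
  spurity <- sum(apply(stab, 1, max)) / sum(stab)
  expect_true(length(unique(emb$scrambled$cluster)) <= 1L ||
                spurity < 0.75)
})

test_that("held-out classification separates planted signal from scrambled", {
  set.seed(7)
  n_sp <- 30L; n_genes <- 60L
  species <- rep(sprintf("sp%02d", seq_len(n_sp)), each = 2)
  tissue <- rep(c("heart", "liver"), n_sp)
  samples <- paste0(species, "_", tissue)
  m <- matrix(rbeta(length(samples) * n_genes, 2, 2), length(samples),
              n_genes, dimnames = list(samples, paste0("HG", 1:n_genes)))
  m[tissue == "heart", 1:20] <- m[tissue == "heart", 1:20] * 0.3
  m[sample(length(m), length(m) * 0.2)] <- NA
  labels <- setNames(tissue, samples)
  spv <- setNames(species, samples)
  ho <- classify_held_out(m, labels, spv, n_train_species = 20,
                          n_reps = 8, n_trees = 15, seed = 8)
  expect_gte(ho$mean_auc, 0.85)
  expect_gte(ho$mean_auc - ho$scrambled_mean_auc, 0.2)
  expect_gt(ho$scrambled_mean_auc, 0.3)
  expect_lt(ho$scrambled_mean_auc, 0.7)
  # planted genes dominate the importances
  top <- names(ho$importance)[1:10]
  expect_gte(mean(top %in% paste0("HG", 1:20)), 0.7)

  # determinism under a fixed seed
  ho2 <- classify_held_out(m, labels, spv, n_train_species = 20,
                           n_reps = 8, n_trees = 15, seed = 8)
  expect_identical(ho$aucs, ho2$aucs)

  # labels independent of values: AUC near chance
  set.seed(9)
  null_lab <- setNames(sample(tissue), samples)
  ho0 <- classify_held_out(m, null_lab, spv, n_train_species = 20,
                           n_reps = 8, n_trees = 15, seed = 10,
                           scramble = FALSE)
  expect_lt(abs(ho0$mean_auc - 0.5), 0.2)
})
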