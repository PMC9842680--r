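test_that("simulate_tree yields valid, deterministic, ultrametric trees", {
  expect_error(simulate_tree(1), "n_species")

  t2 <- simulate_tree(2, seed = 1)
  expect_s3_class(t2, "mc_tree")
  expect_length(t2$phy$tip.label, 2L)
  expect_true(all(t2$phy$edge.length > 0))

  a <- simulate_tree(8, seed = 7)
  b <- simulate_tree(8, seed = 7)
  expect_identical(tree_newick(a), tree_newick(b))
  expect_false(identical(tree_newick(a), tree_newick(simulate_tree(8, seed = 8))))

  # ultrametric: equal root-to-leaf depth, checked by traversal
  depths <- ape::node.depth.edgelength(a$phy)[seq_len(8)]
  expect_lt(diff(range(depths)), 1e-9)

  expect_false(anyDuplicated(a$phy$tip.label) > 0)
  expect_true(all(a$phy$tip.label %in% names(a$groups)))
})

test_that("simulate_genome respects composition, islands and repeats", {
  g <- simulate_genome(10000, gc_content = 0.4, island_count = 0, seed = 3)
  gc <- sum(strsplit(g$seq, "")[[1]] %in% c("C", "G")) / nchar(g$seq)
  expect_lt(abs(gc - 0.4), 0.03)

  gi <- simulate_genome(10000, 0.4, island_count = 5, seed = 3)
  expect_equal(nrow(gi$islands), 5L)
  expect_true(all(gi$islands$end - gi$islands$start == 300L))

  gr <- simulate_genome(10000, 0.4, repeat_spec = list(motif = "ACGACGACG",
                                                       copies = 50), seed = 3)
  n_occ <- sum(gregexpr("ACGACGACG", gr$seq, fixed = TRUE)[[1]] > 0)
  expect_gte(n_occ, 50L)

  expect_error(simulate_genome(900), "length")
  expect_error(simulate_genome(1200, island_count = 5), "infeasible")
})

test_that("assign_methylome implements the logistic planted rule", {
  fs <- data.frame(fragment_id = c("a", "b", "c"),
                   seq = c("ACGTACGTAC", "GGGGCCCCGG", "ATATATATAT"))
  design <- data.frame(sample_id = "s1", species = "sp", tissue = "heart",
                       individual = "i1", library = "converted")
  zero <- planted_code(kmer_weights = setNames(rep(0, 64), all_kmers(3)))

  my <- assign_methylome(fs, zero, design, tissue_effect_frac = 0,
                         individual_effect_frac = 0, noise_sd = 0)
  expect_equal(unname(my$prob[, 1]), rep(0.5, 3))

  sat <- planted_code(kmer_weights = setNames(rep(0, 64), all_kmers(3)),
                      intercept = 10)
  my2 <- assign_methylome(fs, sat, design, tissue_effect_frac = 0,
                          individual_effect_frac = 0, noise_sd = 0)
  expect_true(all(my2$prob > 0.999))

  # sign-flipped weights give the mirror probability at intercept 0
  code <- planted_code(seed = 4)
  p1 <- assign_methylome(fs, code, design, tissue_effect_frac = 0,
                         individual_effect_frac = 0, noise_sd = 0)$prob
  p2 <- assign_methylome(fs, invert_code(code), design,
                         tissue_effect_frac = 0,
                         individual_effect_frac = 0, noise_sd = 0)$prob
  expect_equal(unname(p2[, 1]), 1 - unname(p1[, 1]), tolerance = 1e-12)

  expect_error(
    assign_methylome(fs, zero, design,
                     tissue_effects = list(a = c(kidney = 1))),
    "unknown tissue")
})

test_that("read simulation respects conversion chemistry and determinism", {
  set.seed(1)
  fs <- data.frame(fragment_id = sprintf("f%03d", 1:30),
                   seq = rand_seqs(30, 120))
  design <- data.frame(sample_id = "s1", species = "sp", tissue = "heart",
                       individual = "i1", library = "converted")
  full <- planted_code(kmer_weights = setNames(rep(0, 64), all_kmers(3)),
                       intercept = 30)
  none <- planted_code(kmer_weights = setNames(rep(0, 64), all_kmers(3)),
                       intercept = -30)
  cfg <- read_sim_config(mean_coverage = 5, conversion_rate = 1,
                         over_conversion = 0, seq_error_rate = 0,
                         spike_in_fraction = 0, seed = 2)

  # fully methylated: converted reads keep C at every genomic C
  my1 <- assign_methylome(fs, full, design, tissue_effect_frac = 0,
                          individual_effect_frac = 0, noise_sd = 0,
                          cpg_jitter_sd = 0, noncpg_level = 1)
  rd1 <- simulate_rrbs_reads(my1, cfg)
  s1 <- rd1$samples[["s1"]]
  tmpl <- setNames(rd1$templates$seq, rd1$templates$template_id)
  expect_identical(s1$reads, unname(tmpl[as.character(s1$truth$template_id)]))

  # fully unmethylated: every genomic C reads as T
  my0 <- assign_methylome(fs, none, design, tissue_effect_frac = 0,
                          individual_effect_frac = 0, noise_sd = 0,
                          cpg_jitter_sd = 0, noncpg_level = 0)
  rd0 <- simulate_rrbs_reads(my0, cfg)
  s0 <- rd0$samples[["s1"]]
  expect_identical(
    s0$reads,
    bs_collapse(unname(tmpl[as.character(s0$truth$template_id)])))

  # unconverted library equals the genomic templates exactly
  un <- rd0$samples[["sp_unconv"]]
  expect_identical(un$reads, unname(tmpl[as.character(un$truth$template_id)]))

  # byte-identical FASTQ under a fixed seed
  d1 <- tempfile(); d2 <- tempfile()
  simulate_rrbs_reads(my0, cfg, out_dir = d1)
  simulate_rrbs_reads(my0, cfg, out_dir = d2)
  f1 <- file.path(d1, "s1.fastq"); f2 <- file.path(d2, "s1.fastq")
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0L)
})

test_that("realized read-level methylation converges to planted values", {
  set.seed(5)
  fs <- data.frame(fragment_id = sprintf("f%03d", 1:20),
                   seq = rand_seqs(20, 100, gc = 0.5))
  design <- data.frame(sample_id = "s1", species = "sp", tissue = "heart",
                       individual = "i1", library = "converted")
  code <- planted_code(seed = 6)
  my <- assign_methylome(fs, code, design, tissue_effect_frac = 0,
                         individual_effect_frac = 0, noise_sd = 0,
                         cpg_jitter_sd = 0)
  cfg <- read_sim_config(mean_coverage = 100, conversion_rate = 1,
                         over_conversion = 0, seq_error_rate = 0,
                         spike_in_fraction = 0, seed = 7)
  rd <- simulate_rrbs_reads(my, cfg)
  s <- rd$samples[["s1"]]
  # realized per-CpG methylated fraction in plus-strand prefix reads
  tmpl <- rd$templates[rd$templates$end == 1 &
                         !is.na(match(rd$templates$fragment_id,
                                      fs$fragment_id)), ]
  bad <- 0L
  for (i in seq_len(nrow(tmpl))) {
    cpg <- gregexpr("CG", tmpl$seq[i], fixed = TRUE)[[1]]
    cpg <- cpg[cpg > 0]
    if (!length(cpg)) next
    rds <- s$reads[s$truth$template_id == tmpl$template_id[i]]
    if (length(rds) < 50) next
    p <- my$prob[tmpl$fragment_id[i], 1]
    for (cp in cpg) {
      obs <- mean(substr(rds, cp, cp) == "C")
      se <- sqrt(max(p * (1 - p), 1e-6) / length(rds))
      if (abs(obs - p) > 3 * se + 1e-9) bad <- bad + 1L
    }
  }
  n_checked <- sum(vapply(seq_len(nrow(tmpl)), function(i) {
    m <- gregexpr("CG", tmpl$seq[i], fixed = TRUE)[[1]]
    sum(m > 0)
  }, 0L))
  expect_lt(bad / max(n_checked, 1), 0.05)
})

test_that("spike-in reads appear at the configured fraction", {
  set.seed(8)
  fs <- data.frame(fragment_id = sprintf("f%03d", 1:50),
                   seq = rand_seqs(50, 100))
  design <- data.frame(sample_id = "s1", species = "sp", tissue = "heart",
                       individual = "i1", library = "converted")
  my <- assign_methylome(fs, planted_code(seed = 1), design, seed = 2)
  cfg <- read_sim_config(mean_coverage = 50, spike_in_fraction = 0.01,
                         seed = 3)
  rd <- simulate_rrbs_reads(my, cfg)
  spike_tmpl <- rd$templates$template_id[!is.na(rd$templates$fixed_p)]
  frac <- mean(rd$samples[["s1"]]$truth$template_id %in% spike_tmpl)
  expect_gt(frac, 0.003)
  expect_lt(frac, 0.03)
})
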