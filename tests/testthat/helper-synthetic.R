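# shared generators for the test suite (everything built in code)

rand_seqs <- function(n, len = 100L, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  }, "")
}

# a species' labeled fragment set under a planted code, via the direct
# callset generator (fast path used by the classifier tests)
make_labeled_species <- function(code, n_frag = 1000L, seed = 1L,
                                 len = 150L, coverage = 20,
                                 noise_sd = 0.3, species = "sp") {
  set.seed(seed)
  fs <- data.frame(fragment_id = sprintf("f%05d", seq_len(n_frag)),
                   seq = rand_seqs(n_frag, len))
  design <- data.frame(sample_id = paste0(species, "_s", 1:2),
                       species = species, tissue = c("heart", "liver"),
                       individual = c("i1", "i2"), library = "converted")
  my <- assign_methylome(fs, code, design, tissue_effect_frac = 0,
                         individual_effect_frac = 0, noise_sd = noise_sd,
                         seed = seed + 1L)
  calls <- simulate_callset(my, mean_coverage = coverage, seed = seed + 2L)
  discretize_fragments(calls, fs, species = species)
}

# small multi-tissue call set with optional planted tissue effects
make_tissue_calls <- function(n_frag = 400L, n_eff = 30L, eff = 2,
                              seed = 1L, noise_sd = 0.2, coverage = 20,
                              n_ind = 4L, individual_eff = FALSE) {
  set.seed(seed)
  fs <- data.frame(fragment_id = sprintf("f%04d", seq_len(n_frag)),
                   seq = rand_seqs(n_frag, 120L))
  design <- data.frame(sample_id = paste0("s", seq_len(2L * n_ind)),
                       species = "sp1",
                       tissue = rep(c("heart", "liver"), each = n_ind),
                       individual = rep(paste0("i", seq_len(n_ind)), 2L),
                       library = "converted")
  te <- NULL
  eff_frags <- character()
  if (n_eff > 0L) {
    eff_frags <- fs$fragment_id[seq_len(n_eff)]
    te <- lapply(eff_frags, function(f) c(heart = -eff, liver = eff))
    names(te) <- eff_frags
  }
  my <- assign_methylome(fs, planted_code(weight_sd = 10, seed = seed + 1L),
                         design, tissue_effects = te,
                         tissue_effect_frac = if (n_eff > 0) 0.1 else 0,
                         individual_effect_frac = if (individual_eff) 0.3 else 0,
                         individual_sd = if (individual_eff) 2 else 1,
                         noise_sd = noise_sd, seed = seed + 2L)
  calls <- simulate_callset(my, mean_coverage = coverage, seed = seed + 3L)
  list(calls = calls, design = design, fragments = fs,
       eff_frags = eff_frags, methylome = my)
}

# write a minimal MEME file of near-consensus motifs, return its path
write_test_meme <- function(patterns, path = tempfile(fileext = ".meme")) {
  block <- function(id, pat) {
    rows <- vapply(strsplit(pat, "")[[1]], function(b) {
      v <- rep(0.01, 4)
      v[match(b, c("A", "C", "G", "T"))] <- 0.97
      paste(sprintf("%.2f", v), collapse = " ")
    }, "")
    c(paste("MOTIF", id, id),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              nchar(pat)), rows, "")
  }
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  for (i in seq_along(patterns)) {
    lines <- c(lines, block(names(patterns)[i], patterns[[i]]))
  }
  writeLines(lines, path)
  path
}
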