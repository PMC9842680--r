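mk_calls2 <- function(df) {
  dt <- data.table::as.data.table(df)
  data.table::setattr(dt, "class", c("mc_calls", class(dt)))
  dt
}

test_that("discretize_fragments applies class rules and coverage filter", {
  seqs <- data.frame(fragment_id = c("f1", "f2", "f3"),
                     sequence = c("ACGTACGT", "CGCGCGCG", "ATATATAT"))
  calls <- mk_calls2(data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    fragment_id = rep(c("f1", "f2", "f3"), 2),
    pos = 0L, context = "CpG",
    n_meth = c(1L, 1L, 18L, 2L, 17L, 17L),
    n_total = 20L))
  lab <- discretize_fragments(calls, seqs)
  # f1: means {0.05, 0.10} in all samples below 0.2 -> low
  expect_equal(lab$label[lab$fragment_id == "f1"], "low")
  # f2: {0.05, 0.85} conflicts under the strict rule -> unlabeled
  expect_false("f2" %in% lab$fragment_id)
  # f3: {0.90, 0.85} -> high
  expect_equal(lab$label[lab$fragment_id == "f3"], "high")

  # lenient rule: any sample below threshold labels low
  lab2 <- discretize_fragments(calls, seqs, rule = "lenient")
  expect_equal(lab2$label[lab2$fragment_id == "f2"], "low")

  # mean coverage exactly at the threshold is excluded (strict >)
  calls10 <- mk_calls2(data.frame(
    sample_id = "s1", fragment_id = c("f1", "f3"), pos = 0L,
    context = "CpG", n_meth = c(0L, 10L), n_total = c(10L, 11L)))
  lab3 <- discretize_fragments(calls10, seqs)
  expect_false("f1" %in% lab3$fragment_id)
  expect_true("f3" %in% lab3$fragment_id)

  calls_none <- mk_calls2(data.frame(
    sample_id = "s1", fragment_id = "f1", pos = 0L, context = "CpG",
    n_meth = 10L, n_total = 20L))
  expect_error(discretize_fragments(calls_none, seqs), "lenient")
})

test_that("make_balanced_sets balances classes and keeps sets disjoint", {
  lab <- structure(data.frame(
    fragment_id = sprintf("f%05d", 1:5600),
    seq = "ACGT",
    label = rep(c("high", "low"), c(5000, 600))),
    class = c("mc_labeled", "data.frame"))
  # plenty of both classes: 2000 per set, 1000 per class
  big <- structure(within(as.data.frame(lab), label <-
                            rep(c("high", "low"), 2800)),
                   class = c("mc_labeled", "data.frame"))
  s1 <- make_balanced_sets(big, set_size = 2000, seed = 1)
  expect_equal(nrow(s1$train), 2000L)
  expect_equal(as.integer(table(s1$train$label)), c(1000L, 1000L))
  expect_length(intersect(s1$train$fragment_id, s1$test$fragment_id), 0L)

  # limiting class of 600: both classes reduced to 300 per set
  s2 <- make_balanced_sets(lab, set_size = 2000, seed = 1)
  expect_equal(nrow(s2$train), 600L)
  expect_equal(as.integer(table(s2$train$label)), c(300L, 300L))
  expect_equal(as.integer(table(s2$test$label)), c(300L, 300L))

  s3 <- make_balanced_sets(lab, set_size = 2000, seed = 1)
  expect_identical(s2$train$fragment_id, s3$train$fragment_id)
})

test_that("AUC follows the midrank convention", {
  test <- structure(data.frame(fragment_id = paste0("f", 1:6),
                               seq = "ACGT",
                               label = rep(c("high", "low"), each = 3)),
                    class = c("mc_labeled", "data.frame"))
  expect_equal(evaluate_auc(c(6, 5, 4, 3, 2, 1), test)$auc, 1)
  expect_equal(evaluate_auc(c(1, 2, 3, 4, 5, 6), test)$auc, 0)
  expect_equal(evaluate_auc(rep(1, 6), test)$auc, 0.5)
  one_class <- test
  one_class$label <- "high"
  expect_error(evaluate_auc(1:6, one_class), "both classes")

  # sign-flip complement: AUC(f) + AUC(-f) = 1 exactly
  set.seed(2)
  sc <- rnorm(6)
  expect_equal(evaluate_auc(sc, test)$auc + evaluate_auc(-sc, test)$auc, 1)

  skip_if_not_installed("pROC")
  set.seed(3)
  sc2 <- rnorm(200)
  lb <- sample(c("high", "low"), 200, replace = TRUE)
  t2 <- structure(data.frame(fragment_id = paste0("f", 1:200), seq = "A",
                             label = lb),
                  class = c("mc_labeled", "data.frame"))
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(lb == "high", sc2, quiet = TRUE,
                        levels = c(FALSE, TRUE), direction = "<"))))
  expect_equal(evaluate_auc(sc2, t2)$auc, ref, tolerance = 1e-12)
})

test_that("separable and shuffled training behave at the AUC extremes", {
  set.seed(4)
  n <- 300
  seqs <- rand_seqs(n, 80)
  # balanced, cleanly separable problem: high sequences carry a CGCG box
  # (plus whatever CpGs they had), low sequences are CpG-free
  seqs[1:150] <- paste0(substr(seqs[1:150], 1, 38), "CGCG",
                        substr(seqs[1:150], 43, 80))
  while (any(grepl("CG", seqs[151:300]))) {
    seqs[151:300] <- sub("CG", "AT", seqs[151:300])
  }
  lab <- structure(data.frame(fragment_id = paste0("f", 1:n), seq = seqs,
                              label = rep(c("high", "low"), each = 150)),
                   class = c("mc_labeled", "data.frame"))
  sets <- make_balanced_sets(lab, set_size = 150, seed = 5)
  m <- train_code_model(sets$train, k_grid = 2:4, folds = 5, seed = 6)
  expect_gte(m$cv_auc, 0.99)
  expect_gte(evaluate_auc(m, sets$test)$auc, 0.9)

  # permutation null: labels shuffled in train and test
  shuf <- sets$train
  set.seed(7)
  shuf$label <- sample(shuf$label)
  shte <- sets$test
  shte$label <- sample(shte$label)
  ms <- train_code_model(shuf, k_grid = 3, C_grid = 1, folds = 5, seed = 6)
  expect_lt(abs(evaluate_auc(ms, shte)$auc - 0.5), 0.1)
})

test_that("planted-code models transfer between species and invert correctly", {
  code <- planted_code(seed = 11)
  labA <- make_labeled_species(code, n_frag = 2400, seed = 1, species = "A")
  labB <- make_labeled_species(code, n_frag = 2400, seed = 2, species = "B")
  labI <- make_labeled_species(invert_code(code), n_frag = 2400, seed = 3,
                               species = "I")
  sets <- lapply(list(A = labA, B = labB, I = labI), make_balanced_sets,
                 set_size = 1000, seed = 4)
  models <- lapply(sets, function(s) {
    train_code_model(s$train, k_grid = 3, C_grid = 1, folds = 5, seed = 5)
  })
  tests <- lapply(sets, `[[`, "test")
  cm <- cross_species_matrix(models, tests)
  expect_equal(dim(cm$auc), c(3L, 3L))
  expect_true(all(!is.na(diag(cm$auc))))
  # within-species recovery
  expect_gte(cm$auc["A", "A"], 0.9)
  # shared code transfers: symmetric off-diagonal within 0.05
  expect_lt(abs(cm$auc["A", "B"] - cm$auc["B", "A"]), 0.05)
  expect_lt(abs(cm$auc["A", "B"] - cm$auc["A", "A"]), 0.05)
  # inverted species scores below chance in both directions
  expect_lt(cm$auc["I", "A"], 0.5)
  expect_lt(cm$auc["A", "I"], 0.5)
  inv <- detect_inverted(cm)
  expect_identical(inv, "I")
})

test_that("detect_inverted applies a strict threshold", {
  m <- matrix(0.8, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  m[, "s2"] <- 0.30; diag(m) <- 0.9
  expect_identical(detect_inverted(m), "s2")
  m[, "s2"] <- 0.45; diag(m) <- 0.9
  expect_length(detect_inverted(m), 0L)
  expect_error(detect_inverted(m[1:2, 1:2]), "3 species")
})

test_that("differential feature weights single out a flipped 3-mer", {
  mk_model <- function(w, sp) {
    structure(list(species = sp, k = 3, C = 1, weights = w, intercept = 0,
                   cv_auc = NA, grid = NULL), class = "mc_code_model")
  }
  set.seed(8)
  base <- setNames(rnorm(64), all_kmers(3))
  grp <- lapply(1:6, function(i) {
    mk_model(base + rnorm(64, sd = 0.05), paste0("g", i))
  })
  names(grp) <- paste0("g", 1:6)
  flipped <- base
  flipped["ACG"] <- -base["ACG"] - 5
  models <- c(grp, list(focal = mk_model(flipped, "focal")))
  res <- differential_feature_weights(models, "focal", paste0("g", 1:6))
  expect_lte(nrow(res$top), 10L)
  expect_true("ACG" %in% res$top$kmer[1:3])
  expect_true(all(res$logo$positive >= 0), all(res$logo$negative <= 0))

  # focal identical to the group: no strongly significant 3-mer
  same <- c(grp, list(focal = mk_model(base, "focal")))
  res2 <- differential_feature_weights(same, "focal", paste0("g", 1:6))
  # nothing survives multiple-testing adjustment across the 64 3-mers
  expect_gt(min(res2$top$p) * 64, 0.05)
})

test_that("9-mer repeat frequencies separate planted repeat species", {
  set.seed(9)
  mk_lab <- function(seqs_high, seqs_low) {
    structure(data.frame(
      fragment_id = sprintf("f%04d", seq_len(length(seqs_high) +
                                               length(seqs_low))),
      seq = c(seqs_high, seqs_low),
      label = rep(c("high", "low"), c(length(seqs_high),
                                      length(seqs_low)))),
      class = c("mc_labeled", "data.frame"))
  }
  plain <- mk_lab(rand_seqs(50, 90), rand_seqs(50, 90))
  rep_high <- vapply(rand_seqs(50, 90), function(s) {
    paste0(substr(s, 1, 40), "ACGACGACG", substr(s, 50, 90))
  }, "")
  planted <- mk_lab(unname(rep_high), rand_seqs(50, 90))
  res <- ninemer_repeat_analysis(list(plain = plain, planted = planted),
                                 "ACG")
  d <- setNames(res$per_species$diff, res$per_species$species)
  expect_gt(unname(d["planted"]), 0)
  expect_equal(unname(d["plain"]), 0, tolerance = 5e-4)

  # no occurrences anywhere: difference 0
  none <- ninemer_repeat_analysis(
    list(x = mk_lab(rep(strrep("AT", 45), 5), rep(strrep("TA", 45), 5))),
    "ACG")
  expect_equal(none$per_species$diff, 0)
})
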