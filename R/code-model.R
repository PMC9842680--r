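#' Discretize fragments into high / low methylation classes
#'
#' Under the strict rule a fragment is `low` when its mean CpG methylation
#' is below `low` in all samples and `high` when above `high` in all
#' samples; the lenient rule labels `low` when any sample is below the
#' threshold (high still requires all). Fragments must exceed
#' `min_mean_coverage` mean reads (strictly) averaged across samples;
#' fragments meeting neither class rule stay unlabeled and are dropped.
#'
#' @param calls `mc_calls`.
#' @param sequences data.frame/data.table with `fragment_id` and `sequence`
#'   (e.g. the `fragments` table of an `mc_consensus`), or a named
#'   character vector.
#' @param rule `"strict"` or `"lenient"`.
#' @param min_mean_coverage strict lower bound on mean fragment coverage.
#' @param low,high class thresholds on the methylation fraction.
#' @param species species id recorded on the set.
#' @return data.frame of class `mc_labeled`: fragment_id, seq, label.
#' @export
discretize_fragments <- function(calls, sequences, rule = c("strict", "lenient"),
                                 min_mean_coverage = 10, low = 0.2,
                                 high = 0.8, species = "species1") {
  rule <- match.arg(rule)
  if (is.character(sequences)) {
    sequences <- data.frame(fragment_id = names(sequences),
                            sequence = unname(sequences))
  }
  seq_col <- if ("sequence" %in% names(sequences)) "sequence" else "seq"
  cpg <- calls[calls$context == "CpG" & !is.na(calls$context) &
                 calls$n_total >= 1L]
  frag <- cpg[, list(meth = mean(n_meth / n_total), cov = mean(n_total)),
              by = c("fragment_id", "sample_id")]
  agg <- frag[, list(
    all_low = all(meth < low), any_low = any(meth < low),
    all_high = all(meth > high),
    mean_cov = mean(cov)
  ), by = "fragment_id"]
  agg <- agg[agg$mean_cov > min_mean_coverage]
  lab <- rep(NA_character_, nrow(agg))
  if (rule == "strict") {
    lab[agg$all_low] <- "low"
  } else {
    lab[agg$any_low & !agg$all_high] <- "low"
  }
  lab[agg$all_high] <- "high"
  keep <- !is.na(lab)
  if (!any(keep)) {
    stop("no fragments labeled; consider rule = \"lenient\"", call. = FALSE)
  }
  out <- data.frame(fragment_id = agg$fragment_id[keep], label = lab[keep],
                    stringsAsFactors = FALSE)
  out$seq <- sequences[[seq_col]][match(out$fragment_id,
                                        sequences$fragment_id)]
  out <- out[!is.na(out$seq), c("fragment_id", "seq", "label")]
  attr(out, "species") <- species
  class(out) <- c("mc_labeled", "data.frame")
  out
}

#' Class-balanced disjoint train and test sets
#'
#' Each set holds `set_size` sequences, half per class; when the limiting
#' class has fewer than `set_size` members both classes are reduced to keep
#' the balance (the limiting class is split evenly across train and test).
#'
#' @param labeled `mc_labeled`.
#' @param set_size sequences per set.
#' @param seed integer seed.
#' @return list with `train` and `test` (`mc_labeled` data.frames,
#'   disjoint).
#' @export
make_balanced_sets <- function(labeled, set_size = 2000L, seed = 1L) {
  n_high <- sum(labeled$label == "high")
  n_low <- sum(labeled$label == "low")
  if (min(n_high, n_low) < 2L) {
    stop("need at least 2 fragments per class", call. = FALSE)
  }
  per_class <- min(set_size %/% 2L, min(n_high, n_low) %/% 2L)
  with_seed(seed, {
    pick <- function(lab) {
      idx <- which(labeled$label == lab)
      idx <- sample(idx, 2L * per_class)
      list(train = idx[seq_len(per_class)],
           test = idx[per_class + seq_len(per_class)])
    }
    hi <- pick("high"); lo <- pick("low")
    train <- labeled[c(hi$train, lo$train), , drop = FALSE]
    test <- labeled[c(hi$test, lo$test), , drop = FALSE]
    attr(train, "species") <- attr(labeled, "species")
    attr(test, "species") <- attr(labeled, "species")
    list(train = train, test = test)
  })
}

# spectrum kernel machinery: sparse k-mer frequency features, unit-norm
# scaled (the cosine-normalised spectrum kernel), and their inner-product
# kernel
code_features <- function(seqs, k, columns = NULL) {
  m <- kmer_count_matrix(seqs, k, columns = columns, freq = TRUE)
  nrm <- sqrt(Matrix::rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

fit_spectrum_svm <- function(X, y, C) {
  K <- kernlab::as.kernelMatrix(as.matrix(Matrix::tcrossprod(X)))
  m <- kernlab::ksvm(K, y, type = "C-svc", C = C, kernel = "matrix",
                     scaled = FALSE)
  ai <- unlist(kernlab::alphaindex(m))
  co <- unlist(kernlab::coef(m))
  w <- as.vector(Matrix::t(X[ai, , drop = FALSE]) %*% co)
  names(w) <- colnames(X)
  b0 <- kernlab::b(m)
  f <- as.vector(X %*% w) - b0
  # orient so that positive score means the "high" class
  pr <- kernlab::predict(m, kernlab::as.kernelMatrix(
    as.matrix(Matrix::tcrossprod(X, X[ai, , drop = FALSE]))))
  if (mean((f > 0) == (pr == "high")) < 0.5) {
    w <- -w
    b0 <- -b0
  }
  list(weights = w, intercept = -b0)
}

score_with_weights <- function(seqs, k, weights, intercept) {
  X <- code_features(seqs, k) # normalise over the sequences' own k-mers
  common <- intersect(colnames(X), names(weights))
  as.vector(X[, common, drop = FALSE] %*% weights[common]) + intercept
}

#' Train a k-mer methylation-code classifier
#'
#' Linear support vector machine on normalized k-mer frequency vectors (the
#' primal form of a spectrum-kernel SVM). The regularization constant C and
#' word length k are chosen by grid search with stratified
#' cross-validation, maximizing mean held-out AUC; ties prefer smaller k,
#' then smaller C. The winning configuration is refit on the full training
#' set.
#'
#' @param train `mc_labeled` training set (balanced).
#' @param C_grid candidate regularization values.
#' @param k_grid candidate word lengths.
#' @param folds cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @return object of class `mc_code_model`: `species`, `k`, `C`, sparse
#'   named `weights`, `intercept`, `cv_auc`, and the full `grid` results.
#' @export
train_code_model <- function(train, C_grid = c(0.01, 0.1, 1, 10),
                             k_grid = 1:10, folds = 10L, seed = 1L) {
  y <- factor(train$label, levels = c("low", "high"))
  n <- nrow(train)
  with_seed(seed, {
    fold_id <- integer(n)
    for (lab in levels(y)) {
      idx <- sample(which(y == lab))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    grid <- data.frame()
    best <- NULL
    for (k in k_grid) {
      X <- code_features(train$seq, k)
      usable <- Matrix::rowSums(X) > 0
      K <- as.matrix(Matrix::tcrossprod(X))
      for (C in C_grid) {
        aucs <- vapply(seq_len(folds), function(fd) {
          tr <- which(fold_id != fd & usable)
          te <- which(fold_id == fd & usable)
          if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
            return(NA_real_)
          }
          m <- kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr]), y[tr],
                             type = "C-svc", C = C, kernel = "matrix",
                             scaled = FALSE)
          ai <- unlist(kernlab::alphaindex(m))
          co <- unlist(kernlab::coef(m))
          f <- as.vector(K[te, tr[ai], drop = FALSE] %*% co) - kernlab::b(m)
          pr <- kernlab::predict(m, kernlab::as.kernelMatrix(
            K[tr, tr[ai], drop = FALSE]))
          ftr <- as.vector(K[tr, tr[ai], drop = FALSE] %*% co) - kernlab::b(m)
          if (mean((ftr > 0) == (pr == "high")) < 0.5) f <- -f
          auc_rank(f, y[te] == "high")
        }, 0)
        grid <- rbind(grid, data.frame(k = k, C = C,
                                       cv_auc = mean(aucs, na.rm = TRUE)))
      }
    }
    # ties: smaller k, then smaller C (grid is ordered that way)
    win <- grid[which.max(grid$cv_auc), ]
    Xw <- code_features(train$seq, win$k)
    usable <- Matrix::rowSums(Xw) > 0
    sv <- fit_spectrum_svm(Xw[usable, , drop = FALSE], y[usable], win$C)
    structure(list(species = attr(train, "species"),
                   k = win$k, C = win$C,
                   weights = sv$weights, intercept = sv$intercept,
                   cv_auc = win$cv_auc, grid = grid),
              class = "mc_code_model")
  })
}

#' @export
print.mc_code_model <- function(x, ...) {
  cat("mc_code_model (", x$species, "): k =", x$k, ", C =", x$C,
      ", CV AUC =", round(x$cv_auc, 3), "\n")
  invisible(x)
}

#' Score sequences with a trained code model
#' @param model `mc_code_model`.
#' @param seqs character vector (or `mc_labeled`).
#' @return numeric scores; higher means predicted high methylation.
#' @export
predict_code <- function(model, seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  score_with_weights(seqs, model$k, model$weights, model$intercept)
}

#' ROC curve and AUC of a code model on a labeled test set
#'
#' AUC uses the rank (Mann-Whitney) statistic with midrank ties.
#'
#' @param model `mc_code_model` (or a numeric score vector).
#' @param test `mc_labeled` with both classes.
#' @return list with `auc` and the `roc` data.frame (fpr, tpr).
#' @export
evaluate_auc <- function(model, test) {
  scores <- if (is.numeric(model)) model else predict_code(model, test)
  labels <- test$label == "high"
  if (!any(labels) || all(labels)) {
    stop("test set must contain both classes", call. = FALSE)
  }
  auc <- auc_rank(scores, labels)
  o <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[o]) / sum(labels)
  fpr <- cumsum(!labels[o]) / sum(!labels)
  list(auc = auc, roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Cross-species AUC matrix
#'
#' Every model is evaluated on every species' test set (features recomputed
#' at the model's k); the diagonal is the within-species held-out AUC.
#'
#' @param models named list of `mc_code_model` per species.
#' @param test_sets named list of `mc_labeled` per species.
#' @param threshold inversion threshold on the mean off-diagonal test AUC.
#' @return list of class `mc_crossmatrix`: `auc` matrix
#'   (train x test), `mean_test_auc` (per test species, off-diagonal
#'   column mean), `inverted` logical.
#' @export
cross_species_matrix <- function(models, test_sets, threshold = 0.45) {
  sp_tr <- names(models)
  sp_te <- names(test_sets)
  m <- matrix(NA_real_, length(sp_tr), length(sp_te),
              dimnames = list(train = sp_tr, test = sp_te))
  for (a in sp_tr) {
    for (b in sp_te) {
      if (is.null(test_sets[[b]])) next
      m[a, b] <- evaluate_auc(models[[a]], test_sets[[b]])$auc
    }
  }
  mean_test <- vapply(sp_te, function(b) {
    mean(m[setdiff(sp_tr, b), b], na.rm = TRUE)
  }, 0)
  structure(list(auc = m, mean_test_auc = mean_test,
                 inverted = detect_inverted_vec(mean_test, threshold),
                 threshold = threshold),
            class = "mc_crossmatrix")
}

detect_inverted_vec <- function(mean_test, threshold) {
  !is.na(mean_test) & mean_test < threshold
}

#' Detect inverted species from a cross-species AUC matrix
#'
#' A species is inverted iff its mean off-diagonal AUC as test species is
#' strictly below the threshold: sequence motifs that predict low
#' methylation elsewhere predict high methylation there.
#'
#' @param x `mc_crossmatrix` (or a plain AUC matrix with dimnames).
#' @param threshold inversion threshold.
#' @return character vector of inverted species ids.
#' @export
detect_inverted <- function(x, threshold = 0.45) {
  if (inherits(x, "mc_crossmatrix")) {
    mt <- vapply(colnames(x$auc), function(b) {
      mean(x$auc[setdiff(rownames(x$auc), b), b], na.rm = TRUE)
    }, 0)
  } else {
    mt <- vapply(colnames(x), function(b) {
      mean(x[setdiff(rownames(x), b), b], na.rm = TRUE)
    }, 0)
  }
  if (length(mt) < 3L) stop("need >= 3 species", call. = FALSE)
  names(mt)[detect_inverted_vec(mt, threshold)]
}

#' Differential 3-mer feature weights of a focal species versus a group
#'
#' Requires models trained at k = 3. For each 3-mer, the focal weights are
#' compared with the group's by Wilcoxon test (rank-sum when the focal set
#' has several species, one-sample signed-rank of the group against the
#' focal value otherwise); the ten most significant 3-mers are reported,
#' together with the group's mean weights split by sign (for logo
#' rendering).
#'
#' @param models named list of `mc_code_model` (all k = 3).
#' @param focal character vector of focal species.
#' @param group character vector of comparison species (>= 3).
#' @param top_n differential k-mers to report.
#' @return list: `top` data.frame (kmer, p, focal_mean, group_mean),
#'   `logo` data.frame (kmer, positive, negative group mean weights).
#' @export
differential_feature_weights <- function(models, focal,
                                         group = setdiff(names(models), focal),
                                         top_n = 10L) {
  if (length(group) < 3L) stop("need >= 3 species in group", call. = FALSE)
  ks <- vapply(models, function(m) m$k, 0)
  if (any(ks[c(focal, group)] != 3)) {
    stop("all models must be trained at k = 3", call. = FALSE)
  }
  kmers <- all_kmers(3L)
  wmat <- vapply(models, function(m) {
    w <- setNames(numeric(64), kmers)
    w[names(m$weights)] <- m$weights
    w
  }, numeric(64))
  rows <- lapply(kmers, function(km) {
    wf <- wmat[km, focal]
    wg <- wmat[km, group]
    p <- if (length(focal) >= 2L) {
      suppressWarnings(wilcox.test(wf, wg)$p.value)
    } else {
      suppressWarnings(wilcox.test(wg, mu = wf)$p.value)
    }
    data.frame(kmer = km, p = p, focal_mean = mean(wf),
               group_mean = mean(wg), diff = mean(wf) - mean(wg))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p, -abs(tab$diff)), ]
  gm <- rowMeans(wmat[, group, drop = FALSE])
  logo <- data.frame(kmer = kmers,
                     positive = pmax(gm, 0),
                     negative = pmin(gm, 0))
  list(top = head(tab, top_n), logo = logo)
}

#' Tandem 9-mer repeat frequency difference between methylation classes
#'
#' For each species, the per-bp frequency of the tripled focal 3-mer (e.g.
#' `ACG` -> `ACGACGACG`) among high-methylation fragments minus the
#' frequency among low-methylation fragments; optionally correlated with a
#' per-species AUC vector (e.g. performance under an inverted-trained
#' model).
#'
#' @param labeled_by_species named list of `mc_labeled`.
#' @param focal_3mer the 3-mer whose 9-mer repeat is counted.
#' @param auc optional named numeric per species.
#' @return list: `per_species` data.frame (species, freq_high, freq_low,
#'   diff) and `cor` (Pearson r against `auc`, or `NA`).
#' @export
ninemer_repeat_analysis <- function(labeled_by_species, focal_3mer,
                                    auc = NULL) {
  ninemer <- strrep(focal_3mer, 3L)
  freq_in <- function(seqs) {
    if (!length(seqs)) return(NA_real_)
    hits <- sum(vapply(gregexpr(ninemer, seqs, fixed = TRUE),
                       function(m) sum(m > 0), 0L))
    wins <- sum(pmax(nchar(seqs) - nchar(ninemer) + 1L, 0L))
    if (wins > 0) hits / wins else NA_real_
  }
  rows <- lapply(names(labeled_by_species), function(sp) {
    lb <- labeled_by_species[[sp]]
    fh <- freq_in(lb$seq[lb$label == "high"])
    fl <- freq_in(lb$seq[lb$label == "low"])
    data.frame(species = sp, freq_high = fh, freq_low = fl,
               diff = fh - fl)
  })
  per <- do.call(rbind, rows)
  r <- NA_real_
  if (!is.null(auc)) {
    common <- intersect(per$species, names(auc))
    if (length(common) >= 3L) {
      r <- cor(per$diff[match(common, per$species)], auc[common])
    }
  }
  list(per_species = per, cor = r)
}
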