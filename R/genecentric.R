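#' Cross-map consensus fragments to candidate reference genomes
#'
#' Ungapped seed-and-extend alignment (11-mer seeds, both strands) of each
#' fragment against every candidate genome. A fragment maps to the location
#' with the fewest mismatches provided the mismatch rate is at most
#' `max_mismatch_rate`; ties between equally good locations leave the
#' fragment unmapped (ambiguous). The genome with the highest mapping rate
#' is the best fit.
#'
#' @param fragments named character vector of fragment sequences, or a
#'   data.frame with `fragment_id` and `seq`/`sequence`.
#' @param genomes named list; each element a named character vector of
#'   chromosome sequences (or a single unnamed sequence).
#' @param max_mismatch_rate maximum mismatches per aligned base.
#' @param seed_len seed length for the alignment index.
#' @return list of class `mc_crossmap`: `mappings` (per genome and
#'   fragment: chrom, 0-based start, end, strand, n_mismatches),
#'   `mapping_rates`, `best_genome`.
#' @export
crossmap_fragments <- function(fragments, genomes, max_mismatch_rate = 0.2,
                               seed_len = 11L) {
  if (is.data.frame(fragments)) {
    sq <- if ("seq" %in% names(fragments)) fragments$seq else
      fragments$sequence
    fragments <- setNames(sq, fragments$fragment_id)
  }
  if (!length(genomes)) stop("need >= 1 candidate genome", call. = FALSE)
  if (is.null(names(genomes))) {
    names(genomes) <- sprintf("genome%02d", seq_along(genomes))
  }
  lens <- nchar(fragments)
  all_maps <- list()
  rates <- setNames(numeric(length(genomes)), names(genomes))
  for (g in names(genomes)) {
    chroms <- genomes[[g]]
    if (is.null(names(chroms))) {
      names(chroms) <- sprintf("chr%d", seq_along(chroms))
    }
    hits_all <- list()
    for (L in unique(lens)) {
      qi <- which(lens == L)
      h <- align_ungapped(unname(fragments[qi]), chroms,
                          max_mismatch_rate = max_mismatch_rate,
                          seed_len = seed_len)
      if (nrow(h)) {
        h[, "fragment_id" := names(fragments)[qi][h$query]]
        h[, "len" := L]
        hits_all[[length(hits_all) + 1L]] <- h
      }
    }
    mapped <- data.table(fragment_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), n_mismatches = integer())
    if (length(hits_all)) {
      h <- rbindlist(hits_all)
      h <- unique(h, by = c("fragment_id", "subject", "start", "strand"))
      setorderv(h, c("fragment_id", "mismatches"))
      best <- h[, {
        if (.N >= 2L && mismatches[2] == mismatches[1]) {
          NULL # ambiguous best hit
        } else {
          list(chrom = subject[1], start = start[1],
               end = start[1] + len[1], strand = strand[1],
               n_mismatches = mismatches[1])
        }
      }, by = "fragment_id"]
      mapped <- best
    }
    mapped[, "genome" := g]
    all_maps[[g]] <- mapped
    rates[g] <- nrow(mapped) / length(fragments)
  }
  best_genome <- if (any(rates > 0)) names(which.max(rates)) else NA_character_
  structure(list(mappings = rbindlist(all_maps, fill = TRUE),
                 mapping_rates = rates, best_genome = best_genome),
            class = "mc_crossmap")
}

#' @export
print.mc_crossmap <- function(x, ...) {
  cat("mc_crossmap: best genome", x$best_genome, "( rates:",
      paste(sprintf("%s=%.2f", names(x$mapping_rates), x$mapping_rates),
            collapse = ", "), ")\n")
  invisible(x)
}

# mean methylation per bin given 0-based positions/ratios and bin edges
bin_means <- function(pos, ratio, start, width, n_bins) {
  b <- ((pos - start) %/% width) + 1L
  ok <- b >= 1L & b <= n_bins
  out <- rep(NA_real_, n_bins)
  if (any(ok)) {
    agg <- tapply(ratio[ok], b[ok], mean)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Methylation profile across genes (flanks, body, meta-gene)
#'
#' Averages methylation calls in 100 bp bins across 5000 bp upstream and
#' downstream flanks and in 200 bp bins within the gene body; for the
#' meta-gene average the variable number of body bins is rescaled onto
#' `n_body_meta` relative positions. Minus-strand genes are reversed so
#' bin 1 is always the 5' upstream end. The promoter dip statistic is the
#' mean profile level minus the minimum over the promoter bins (the
#' upstream bins within 2500 bp of the TSS).
#'
#' @param calls_df data.frame with `chrom`, `pos` (0-based) and `ratio`.
#' @param genes data.frame with chrom, start, end, strand, name.
#' @param flank,flank_bin,body_bin profile geometry in bp.
#' @param n_body_meta body bins in the meta-gene profile.
#' @return list of class `mc_gene_profile`: `per_gene` matrix (genes x
#'   bins), `meta` (mean profile), `bin_type`, `dip_statistic`.
#' @export
gene_profile <- function(calls_df, genes, flank = 5000L, flank_bin = 100L,
                         body_bin = 200L, n_body_meta = 20L) {
  stopifnot(all(c("chrom", "pos", "ratio") %in% names(calls_df)),
            all(c("chrom", "start", "end", "strand") %in% names(genes)))
  nfl <- flank %/% flank_bin
  nb <- n_body_meta
  total_bins <- 2L * nfl + nb
  prof <- matrix(NA_real_, nrow(genes), total_bins)
  rownames(prof) <- if ("name" %in% names(genes)) genes$name else
    sprintf("gene%04d", seq_len(nrow(genes)))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    sub <- calls_df[calls_df$chrom == g$chrom, ]
    up <- bin_means(sub$pos, sub$ratio, g$start - flank, flank_bin, nfl)
    dn <- bin_means(sub$pos, sub$ratio, g$end, flank_bin, nfl)
    glen <- g$end - g$start
    nbody <- max(1L, as.integer(ceiling(glen / body_bin)))
    body <- bin_means(sub$pos, sub$ratio, g$start, body_bin, nbody)
    # rescale body bins onto the fixed meta grid
    body_meta <- vapply(seq_len(nb), function(b) {
      lo <- ceiling((b - 1L) * nbody / nb) + 1L
      hi <- max(lo, ceiling(b * nbody / nb))
      v <- body[lo:hi]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
    row <- c(up, body_meta, dn)
    if (g$strand == "-") row <- rev(row)
    prof[gi, ] <- row
  }
  meta <- colMeans(prof, na.rm = TRUE)
  bin_type <- c(rep("upstream", nfl), rep("body", nb),
                rep("downstream", nfl))
  prom_bins <- (nfl - (2500L %/% flank_bin) + 1L):nfl
  dip <- mean(meta, na.rm = TRUE) - min(meta[prom_bins], na.rm = TRUE)
  structure(list(per_gene = prof, meta = meta, bin_type = bin_type,
                 promoter_bins = prom_bins, dip_statistic = dip),
            class = "mc_gene_profile")
}

#' Mean promoter methylation per gene
#'
#' The promoter is the 2500 bp upstream of the TSS (strand-aware), split
#' into 50 bins of 50 bp; the promoter value is the mean over bins with
#' data.
#'
#' @param calls_df data.frame with chrom, pos (0-based), ratio.
#' @param genes data.frame with chrom, start, end, strand, name.
#' @param upstream,n_bins promoter geometry.
#' @return named numeric per gene (NA when no bin has data).
#' @export
promoter_methylation <- function(calls_df, genes, upstream = 2500L,
                                 n_bins = 50L) {
  width <- upstream %/% n_bins
  vals <- vapply(seq_len(nrow(genes)), function(gi) {
    g <- genes[gi, ]
    sub <- calls_df[calls_df$chrom == g$chrom, ]
    if (g$strand == "-") {
      b <- bin_means(sub$pos, sub$ratio, g$end, width, n_bins)
    } else {
      b <- bin_means(sub$pos, sub$ratio, g$start - upstream, width, n_bins)
    }
    if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE)
  }, 0)
  names(vals) <- if ("name" %in% names(genes)) genes$name else
    sprintf("gene%04d", seq_len(nrow(genes)))
  vals
}

#' Assemble a sample x human-ortholog promoter methylation matrix
#'
#' Gene identifiers are mapped to NCBI ids and then to human orthologs via
#' two-column dictionaries; genes lacking an ortholog are dropped and
#' several source genes mapping to one ortholog are averaged. Missing
#' values stay explicit.
#'
#' @param promoter_values named list per sample of named numerics (gene ->
#'   promoter methylation), e.g. from [promoter_methylation()].
#' @param gene2ncbi data.frame (gene_id, ncbi_id).
#' @param ncbi2human data.frame (ncbi_id, human_id).
#' @return numeric matrix samples x human gene ids with NA for missing.
#' @export
promoter_matrix <- function(promoter_values, gene2ncbi, ncbi2human) {
  g2n <- unique(stats::na.omit(gene2ncbi[, 1:2]))
  n2h <- unique(stats::na.omit(ncbi2human[, 1:2]))
  if (anyDuplicated(g2n[[1]]) || anyDuplicated(n2h[[1]])) {
    warning("duplicate dictionary rows deduplicated (first kept)")
    g2n <- g2n[!duplicated(g2n[[1]]), ]
    n2h <- n2h[!duplicated(n2h[[1]]), ]
  }
  rows <- lapply(names(promoter_values), function(s) {
    v <- promoter_values[[s]]
    ncbi <- g2n[[2]][match(names(v), g2n[[1]])]
    hum <- n2h[[2]][match(ncbi, n2h[[1]])]
    ok <- !is.na(hum) & !is.na(v)
    if (!any(ok)) return(NULL)
    agg <- tapply(v[ok], hum[ok], mean)
    data.table(sample = s, gene = names(agg), value = as.numeric(agg))
  })
  long <- rbindlist(rows)
  if (!nrow(long)) stop("no gene with an ortholog mapping", call. = FALSE)
  genes <- sort(unique(long$gene))
  samples <- names(promoter_values)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(long$sample, samples), match(long$gene, genes))] <- long$value
  m
}

# permute non-missing values over non-missing positions (mask preserved)
scramble_matrix <- function(m, seed = 1L) {
  with_seed(seed, {
    idx <- which(!is.na(m))
    m[idx] <- m[sample(idx)]
    m
  })
}

#' Neighborhood-graph embedding and clustering of the ortholog matrix
#'
#' Rows (samples) or columns (genes) are filtered by coverage, correlated
#' on pairwise-complete observations (iteratively dropping the worst
#' row/column until no correlation is undefined), connected into a
#' k-nearest-neighbor graph by correlation, embedded in 2-D by
#' force-directed layout, and clustered by Leiden community detection.
#' A scrambled control (values permuted over the non-missing positions,
#' missingness preserved) is embedded the same way.
#'
#' @param m samples x genes matrix with NA for missing.
#' @param mode `"samples"` or `"genes"`; sets the coverage filters
#'   (samples: genes covered in > 100 samples and samples covering > 400
#'   genes; genes: > 400 / > 50) and the neighborhood size (20 / 15).
#' @param min_other,min_own filter overrides (counts; `NULL` = mode
#'   default).
#' @param n_neighbors neighborhood size override.
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed (layout and control).
#' @param scramble also embed the scrambled control.
#' @return list of class `mc_embedding`: `embedding` (data.frame id, x, y,
#'   cluster), `clusters`, and optionally `scrambled`.
#' @export
embed_and_cluster <- function(m, mode = c("samples", "genes"),
                              min_other = NULL, min_own = NULL,
                              n_neighbors = NULL, resolution = 0.06,
                              seed = 1L, scramble = TRUE) {
  mode <- match.arg(mode)
  defaults <- if (mode == "samples") {
    list(min_other = 100L, min_own = 400L, nn = 20L)
  } else {
    list(min_other = 400L, min_own = 50L, nn = 15L)
  }
  if (is.null(min_other)) min_other <- defaults$min_other
  if (is.null(min_own)) min_own <- defaults$min_own
  if (is.null(n_neighbors)) n_neighbors <- defaults$nn
  if (mode == "genes") m <- t(m)
  # column filter: kept if covered in > min_other rows; row filter: kept if
  # covering > min_own columns
  keep_col <- colSums(!is.na(m)) > min_other
  m <- m[, keep_col, drop = FALSE]
  keep_row <- rowSums(!is.na(m)) > min_own
  m <- m[keep_row, , drop = FALSE]
  if (nrow(m) < 10L) stop("filters leave fewer than 10 rows", call. = FALSE)
  run_once <- function(mm, sd_offset = 0L) {
    cc <- suppressWarnings(cor(t(mm), use = "pairwise.complete.obs"))
    while (anyNA(cc)) {
      worst <- which.max(rowSums(is.na(cc)))
      cc <- cc[-worst, -worst, drop = FALSE]
    }
    ids <- rownames(cc)
    k <- min(n_neighbors, nrow(cc) - 1L)
    edges <- list()
    for (i in seq_len(nrow(cc))) {
      ord <- order(cc[i, -i], decreasing = TRUE)
      nb <- setdiff(seq_len(nrow(cc)), i)[ord][seq_len(k)]
      edges[[i]] <- data.frame(a = i, b = nb, w = (cc[i, nb] + 1) / 2)
    }
    ed <- do.call(rbind, edges)
    key <- paste(pmin(ed$a, ed$b), pmax(ed$a, ed$b))
    ed <- ed[!duplicated(key), ]
    g <- igraph::graph_from_data_frame(
      data.frame(from = ids[ed$a], to = ids[ed$b], weight = ed$w),
      directed = FALSE, vertices = ids)
    with_seed(seed + sd_offset, {
      cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution,
                                   weights = igraph::E(g)$weight)
      xy <- igraph::layout_with_fr(g)
    })
    memb <- igraph::membership(cl)
    data.frame(id = ids, x = xy[, 1], y = xy[, 2],
               cluster = as.integer(memb[ids]))
  }
  emb <- run_once(m)
  out <- list(embedding = emb,
              clusters = setNames(emb$cluster, emb$id),
              mode = mode)
  if (scramble) {
    out$scrambled <- run_once(scramble_matrix(m, seed = seed + 1L),
                              sd_offset = 2L)
  }
  class(out) <- "mc_embedding"
  out
}

#' Species-held-out classification of sample properties
#'
#' Predicts a binary sample label (e.g. heart vs liver, mammal vs bird)
#' from promoter methylation with a bagged ensemble of rpart trees, which
#' route missing values through surrogate splits (no imputation). Train
#' and test sets never share a species; the procedure is repeated
#' `n_reps` times and compared against a scrambled-matrix control with
#' identical splits and missingness.
#'
#' @param m samples x genes matrix (NA allowed).
#' @param labels named factor/character per sample (2 levels).
#' @param species named character per sample.
#' @param n_train_species species drawn for training per repetition.
#' @param n_reps repetitions.
#' @param n_trees trees per ensemble.
#' @param min_gene_coverage,min_sample_coverage coverage filters (fraction
#'   of samples a gene must cover; fraction of genes a sample must cover).
#' @param seed integer seed.
#' @param scramble also run the scrambled control.
#' @return list of class `mc_heldout`: `mean_auc`, `aucs`, `importance`
#'   (mean rpart variable importance), `scrambled_mean_auc`,
#'   `scrambled_aucs`.
#' @export
classify_held_out <- function(m, labels, species, n_train_species = 80L,
                              n_reps = 100L, n_trees = 25L,
                              min_gene_coverage = 0.6,
                              min_sample_coverage = 0.12, seed = 1L,
                              scramble = TRUE) {
  keep_gene <- colMeans(!is.na(m)) >= min_gene_coverage
  m <- m[, keep_gene, drop = FALSE]
  keep_sample <- rowMeans(!is.na(m)) >= min_sample_coverage
  m <- m[keep_sample, , drop = FALSE]
  labels <- factor(labels[rownames(m)])
  stopifnot(nlevels(labels) == 2L)
  species <- species[rownames(m)]
  pos <- levels(labels)[2]
  colnames(m) <- make.names(colnames(m))

  run <- function(mm, seed_offset) {
    aucs <- numeric(0)
    imp <- setNames(numeric(ncol(mm)), colnames(mm))
    with_seed(seed + seed_offset, {
      rep_i <- 0L
      guard <- 0L
      while (rep_i < n_reps && guard < 10L * n_reps) {
        guard <- guard + 1L
        sp_all <- unique(species)
        tr_sp <- sample(sp_all, min(n_train_species, length(sp_all) - 1L))
        tr <- species %in% tr_sp
        te <- !tr
        stopifnot(!any(species[tr] %in% species[te]))
        if (length(unique(labels[te])) < 2L ||
            length(unique(labels[tr])) < 2L) {
          next # one-class split; redraw
        }
        d <- data.frame(.label = labels, mm, check.names = FALSE)
        votes <- numeric(sum(te))
        for (b in seq_len(n_trees)) {
          idx <- sample(which(tr), sum(tr), replace = TRUE)
          fit <- rpart::rpart(.label ~ ., data = d[idx, , drop = FALSE],
                              method = "class",
                              control = rpart::rpart.control(
                                cp = 0.01, maxsurrogate = 5,
                                usesurrogate = 2, xval = 0))
          pr <- predict(fit, d[te, , drop = FALSE])[, pos]
          votes <- votes + pr
          vi <- fit$variable.importance
          if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + vi
        }
        aucs <- c(aucs, auc_rank(votes / n_trees, labels[te] == pos))
        rep_i <- rep_i + 1L
      }
    })
    list(aucs = aucs, importance = imp / max(length(aucs), 1))
  }
  main <- run(m, 0L)
  out <- list(mean_auc = mean(main$aucs), aucs = main$aucs,
              importance = sort(main$importance, decreasing = TRUE))
  if (scramble) {
    sc <- run(scramble_matrix(m, seed = seed + 7L), 1000L)
    out$scrambled_mean_auc <- mean(sc$aucs)
    out$scrambled_aucs <- sc$aucs
  }
  class(out) <- "mc_heldout"
  out
}

#' @export
print.mc_heldout <- function(x, ...) {
  cat("species-held-out classification: mean AUC", round(x$mean_auc, 3))
  if (!is.null(x$scrambled_mean_auc)) {
    cat(" (scrambled control", round(x$scrambled_mean_auc, 3), ")")
  }
  cat("\n")
  invisible(x)
}
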