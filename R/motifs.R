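#' Read position weight matrices in MEME (minimal) format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#'
#' @param path MEME-format file.
#' @return named list of motifs; each a list with `id`, `name` and `mat`
#'   (w x 4 probability matrix, columns A, C, G, T).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "MOTIF")) {
      parts <- strsplit(ln, "\\s+")[[1]]
      id <- parts[2]
      name <- if (length(parts) >= 3) parts[3] else id
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("letter-probability matrix", lines[j])) {
        if (startsWith(trimws(lines[j]), "MOTIF")) break
        j <- j + 1L
      }
      if (j <= length(lines) &&
          grepl("letter-probability matrix", lines[j])) {
        w <- suppressWarnings(as.integer(
          sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
        rows <- list()
        j <- j + 1L
        while (j <= length(lines)) {
          v <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]),
                                                    "\\s+")[[1]]))
          if (length(v) != 4L || anyNA(v)) break
          rows[[length(rows) + 1L]] <- v
          j <- j + 1L
        }
        mat <- do.call(rbind, rows)
        if (is.null(mat) || !nrow(mat) ||
            any(colSums(mat) == 0) && all(rowSums(mat) == 0)) {
          stop("invalid motif file: motif ", id,
               " has an empty probability matrix", call. = FALSE)
        }
        if (any(rowSums(mat) <= 0)) {
          stop("invalid motif file: zero row in motif ", id, call. = FALSE)
        }
        colnames(mat) <- DNA_BASES
        out[[id]] <- list(id = id, name = name, mat = mat)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) stop("no motifs found in ", path, call. = FALSE)
  out
}

# exact single-window null distribution of a (discretised) log-odds score
# under a 0-order background, by dynamic programming over the score
# histogram; returns the smallest threshold with exceedance prob <= hit_p
pwm_score_threshold <- function(lod, bg, hit_p, precision = 1000L) {
  w <- nrow(lod)
  scaled <- round(lod * precision)
  offset <- -apply(scaled, 1, min)
  tot_off <- sum(offset)
  maxs <- sum(apply(scaled, 1, max) + offset)
  dist <- numeric(maxs + 1L)
  dist[1] <- 1
  for (i in seq_len(w)) {
    nd <- numeric(maxs + 1L)
    for (b in 1:4) {
      sh <- scaled[i, b] + offset[i]
      idx <- which(dist > 0)
      nd[idx + sh] <- nd[idx + sh] + dist[idx] * bg[b]
    }
    dist <- nd
  }
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= hit_p)
  if (!length(ok)) {
    return(Inf)
  }
  (min(ok) - 1L - tot_off) / precision
}

# maximum log-odds window score of each sequence (both strands)
pwm_max_scores <- function(seqs, lod) {
  w <- nrow(lod)
  score_one_strand <- function(ss) {
    vapply(ss, function(s) {
      n <- nchar(s)
      if (n < w) return(-Inf)
      ch <- match(strsplit(s, "")[[1]], DNA_BASES)
      best <- -Inf
      for (st in seq_len(n - w + 1L)) {
        b <- ch[st:(st + w - 1L)]
        if (anyNA(b)) next
        sc <- sum(lod[cbind(seq_len(w), b)])
        if (sc > best) best <- sc
      }
      best
    }, 0, USE.NAMES = FALSE)
  }
  pmax(score_one_strand(seqs), score_one_strand(revcomp(seqs)))
}

#' Motif enrichment between foreground and background sequence sets
#'
#' Each motif is turned into a log-odds matrix against the 0-order
#' background estimated from all input sequences; a sequence is a hit iff
#' some window (either strand) reaches the score threshold whose exact
#' null exceedance probability is at most `hit_p` (computed by dynamic
#' programming over the discretised score distribution). Enrichment of
#' foreground over background hits is tested one-sided by Fisher's exact
#' test and adjusted by Benjamini-Hochberg across motifs (and directions,
#' when called through [dmr_motif_enrichment()]).
#'
#' @param foreground,background character vectors of sequences.
#' @param pwms motif list from [read_meme()].
#' @param hit_p per-window null hit probability.
#' @param pseudocount added to the PWM probabilities before log-odds.
#' @return data.frame per motif: hit counts, odds ratio, p, q,
#'   significant.
#' @export
motif_enrichment <- function(foreground, background, pwms, hit_p = 1e-4,
                             pseudocount = 0.01) {
  stopifnot(length(foreground) > 0, length(background) > 0)
  allseq <- paste(c(foreground, background), collapse = "")
  counts <- vapply(DNA_BASES, function(b) {
    nchar(allseq) - nchar(gsub(b, "", allseq, fixed = TRUE))
  }, 0)
  bg <- counts / sum(counts)
  rows <- lapply(pwms, function(m) {
    pm <- (m$mat + pseudocount) / rowSums(m$mat + pseudocount)
    lod <- log2(sweep(pm, 2, bg, "/"))
    # fixed score resolution: the DP null distribution is then exact for
    # the same matrix used in scanning
    lod <- round(lod * 1000) / 1000
    thr <- pwm_score_threshold(lod, bg, hit_p)
    fg_hit <- sum(pwm_max_scores(foreground, lod) >= thr)
    bg_hit <- sum(pwm_max_scores(background, lod) >= thr)
    ft <- fisher.test(rbind(c(fg_hit, length(foreground) - fg_hit),
                            c(bg_hit, length(background) - bg_hit)),
                      alternative = "greater")
    data.frame(motif = m$id, name = m$name,
               n_fg = length(foreground), fg_hits = fg_hit,
               n_bg = length(background), bg_hits = bg_hit,
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.05
  out
}

#' Motif enrichment in both DMR directions
#'
#' Scores each motif among the hypermethylated fragments relative to the
#' hypomethylated ones and vice versa; BH adjustment spans both
#' directions.
#'
#' @param hyper_seqs,hypo_seqs sequences of the two selected DMR sets
#'   (e.g. top-500 per direction).
#' @param pwms motif list from [read_meme()].
#' @param hit_p per-window null hit probability.
#' @return data.frame with a `direction` column (`"hyper"` = enriched
#'   among hypermethylated fragments).
#' @export
dmr_motif_enrichment <- function(hyper_seqs, hypo_seqs, pwms, hit_p = 1e-4) {
  a <- motif_enrichment(hyper_seqs, hypo_seqs, pwms, hit_p)
  a$direction <- "hyper"
  b <- motif_enrichment(hypo_seqs, hyper_seqs, pwms, hit_p)
  b$direction <- "hypo"
  out <- rbind(a, b)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.05
  out
}

#' Transcription factor activity calls and regulatory network
#'
#' Combines motif enrichments (in liver-vs-heart DMR directions) with each
#' factor's methylation binding preference and tissue expression: a factor
#' preferring unmethylated sites whose motif is enriched among
#' liver-hypomethylated fragments is active in liver; one preferring
#' methylated sites enriched among liver-hypermethylated fragments is also
#' active in liver; the mirror combinations give heart activity. Factors
#' need normalized expression > 1 in heart or liver, and calls are only
#' made when the species has at least `min_enrichments` significant
#' enrichments.
#'
#' @param enrichments data.frame from [dmr_motif_enrichment()] with
#'   `direction` interpreted as liver-relative (`"hypo"` = hypomethylated
#'   in liver) and a `tf` column (defaults to `name`).
#' @param preference data.frame (tf, preference in
#'   methylated/unmethylated).
#' @param expression data.frame (tf, heart, liver) normalized expression.
#' @param targets data.frame (tf, target, sign) regulator -> target table.
#' @param min_enrichments minimum significant enrichments to call
#'   anything.
#' @param expression_threshold minimum expression in either tissue.
#' @return list with `calls` (tf, preference, expression_ok, activity) and
#'   `edges` (active TF -> target).
#' @export
tf_activity_and_network <- function(enrichments, preference, expression,
                                    targets = NULL, min_enrichments = 10L,
                                    expression_threshold = 1) {
  if (!"tf" %in% names(enrichments)) enrichments$tf <- enrichments$name
  sig <- enrichments[enrichments$significant, , drop = FALSE]
  if (nrow(sig) < min_enrichments) {
    message("fewer than ", min_enrichments,
            " significant enrichments; no activity calls")
    sig <- sig[0, , drop = FALSE]
  }
  tfs <- unique(enrichments$tf)
  calls <- do.call(rbind, lapply(tfs, function(tf) {
    pref <- preference$preference[match(tf, preference$tf)]
    ex <- expression[match(tf, expression$tf), , drop = FALSE]
    expression_ok <- !is.na(pref) && nrow(ex) == 1L &&
      !is.na(ex$heart) && !is.na(ex$liver) &&
      (ex$heart > expression_threshold | ex$liver > expression_threshold)
    dirs <- sig$direction[sig$tf == tf]
    activity <- "none"
    if (expression_ok && length(dirs)) {
      if (!is.na(pref) && pref == "unmethylated" && "hypo" %in% dirs) {
        activity <- "liver"
      } else if (!is.na(pref) && pref == "methylated" && "hyper" %in% dirs) {
        activity <- "liver"
      } else if (!is.na(pref) && pref == "unmethylated" && "hyper" %in% dirs) {
        activity <- "heart"
      } else if (!is.na(pref) && pref == "methylated" && "hypo" %in% dirs) {
        activity <- "heart"
      }
    }
    data.frame(tf = tf, preference = if (is.na(pref)) NA_character_ else pref,
               expression_ok = expression_ok, activity = activity)
  }))
  edges <- data.frame(tf = character(), target = character(),
                      sign = character(), activity = character())
  if (!is.null(targets)) {
    act <- calls[calls$activity != "none", , drop = FALSE]
    edges <- merge(targets, act[, c("tf", "activity")], by = "tf")
  }
  list(calls = calls, edges = edges)
}
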