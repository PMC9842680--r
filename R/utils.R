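#' @import data.table
#' @importFrom methods as is
#' @importFrom stats AIC aov coef cor cor.test fisher.test lm logLik median
#'   na.omit p.adjust pchisq plogis pnorm predict pt qlogis quantile rbinom
#'   rnorm rpois runif sd setNames step t.test terms uniroot var wilcox.test
#'   as.formula anova complete.cases
#' @importFrom utils head read.table write.table combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate all DNA k-mers in lexicographic order
#'
#' @param k word length (1 to 10).
#' @return character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 10)
  out <- DNA_BASES
  if (k > 1) {
    for (i in 2:k) out <- as.vector(t(outer(out, DNA_BASES, paste0)))
  }
  out
}

#' Reverse complement of DNA strings
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# bisulfite-collapse: every C read as T
bs_collapse <- function(x) chartr("C", "T", x)

check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains characters outside ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T", call. = FALSE)
  }
  invisible(TRUE)
}

# overlapping k-mer windows of all sequences as a long data.table
# (seq_idx, kmer); windows containing non-ACGT characters are dropped
kmer_windows <- function(seqs, k) {
  n <- nchar(seqs)
  keep <- which(n >= k)
  if (!length(keep)) {
    return(data.table(seq_idx = integer(), kmer = character()))
  }
  nw <- n[keep] - k + 1L
  idx <- rep(keep, nw)
  start <- unlist(lapply(nw, seq_len), use.names = FALSE)
  km <- substring(seqs[idx], start, start + k - 1L)
  ok <- !grepl("[^ACGT]", km)
  data.table(seq_idx = idx[ok], kmer = km[ok])
}

#' Per-sequence k-mer count matrix (sparse)
#'
#' Counts overlapping k-mers per sequence; windows containing non-ACGT
#' characters are skipped. Columns are restricted to k-mers observed in the
#' input (plus any requested via `columns`), which keeps large k tractable.
#'
#' @param seqs character vector of DNA sequences.
#' @param k word length.
#' @param columns optional character vector of k-mers to use as the column
#'   space (unobserved ones become all-zero columns).
#' @param freq divide each row by its total window count.
#' @return a `dgCMatrix` with one row per sequence.
#' @export
kmer_count_matrix <- function(seqs, k, columns = NULL, freq = FALSE) {
  dt <- kmer_windows(seqs, k)
  cols <- if (is.null(columns)) sort(unique(dt$kmer)) else columns
  if (!length(cols)) cols <- all_kmers(min(k, 1L))[0L]
  dt <- dt[dt$kmer %chin% cols]
  m <- Matrix::sparseMatrix(
    i = dt$seq_idx, j = match(dt$kmer, cols), x = 1,
    dims = c(length(seqs), length(cols)),
    dimnames = list(names(seqs), cols)
  )
  if (freq) {
    tot <- Matrix::rowSums(m)
    tot[tot == 0] <- 1
    m <- m / tot
  }
  m
}

#' Rank-based ROC AUC with midrank tie handling
#'
#' Equals the Mann-Whitney U statistic divided by `n1 * n0`.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or two-level factor/character; `TRUE` (or the
#'   `positive` level) marks the positive class.
#' @param positive label value treated as positive when `labels` is not
#'   logical.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels, positive = "high") {
  if (!is.logical(labels)) labels <- labels == positive
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes in the test set", call. = FALSE)
  }
  r <- rank(scores) # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# mismatch counts between equal-length string pairs, vectorised by position
string_mismatches <- function(a, b) {
  L <- nchar(a[1])
  mm <- integer(length(a))
  for (j in seq_len(L)) {
    mm <- mm + (substr(a, j, j) != substr(b, j, j))
  }
  mm
}

# Ungapped seed-and-extend alignment of short queries against subject
# sequences. Returns, per query, all candidate placements with mismatch
# counts at or below max_mm. Coordinates are 0-based.
# subjects: named character vector. Both strands of the subject are searched
# when both_strands is TRUE; hits on the minus strand are reported in plus
# coordinates with strand "-".
align_ungapped <- function(queries, subjects, max_mismatch_rate = 0.1,
                           seed_len = 11L, both_strands = TRUE) {
  qlen <- nchar(queries)
  stopifnot(length(unique(qlen)) <= 1L)
  if (!length(queries) || !length(subjects)) {
    return(data.table(query = integer(), subject = character(),
                      start = integer(), strand = character(),
                      mismatches = integer()))
  }
  L <- qlen[1]
  seed_len <- min(seed_len, L)
  subj_tab <- data.table(subject = names(subjects), seq = unname(subjects))
  if (both_strands) {
    subj_tab <- rbind(
      cbind(subj_tab, strand = "+"),
      data.table(subject = subj_tab$subject, seq = revcomp(subj_tab$seq),
                 strand = "-")
    )
  } else {
    subj_tab[, "strand" := "+"]
  }
  # index all subject seed_len-mers with their positions
  idx <- rbindlist(lapply(seq_len(nrow(subj_tab)), function(i) {
    s <- subj_tab$seq[i]
    n <- nchar(s) - seed_len + 1L
    if (n < 1L) return(NULL)
    km <- substring(s, seq_len(n), seq_len(n) + seed_len - 1L)
    ok <- !grepl("[^ACGT]", km)
    data.table(srow = i, seed = km[ok], spos = which(ok))
  }))
  qoff <- unique(c(seq(1L, L - seed_len + 1L, by = seed_len), L - seed_len + 1L))
  qseed <- data.table(
    query = rep(seq_along(queries), each = length(qoff)),
    qpos = rep(qoff, times = length(queries))
  )
  qseed[, "seed" := substring(queries[qseed$query], qseed$qpos,
                              qseed$qpos + seed_len - 1L)]
  cand <- merge(qseed, idx, by = "seed", allow.cartesian = TRUE)
  if (!nrow(cand)) {
    return(data.table(query = integer(), subject = character(),
                      start = integer(), strand = character(),
                      mismatches = integer()))
  }
  cand[, "astart" := cand$spos - cand$qpos + 1L] # 1-based on subject row
  cand <- unique(cand[, c("query", "srow", "astart")])
  slen <- nchar(subj_tab$seq)[cand$srow]
  cand <- cand[cand$astart >= 1L & cand$astart + L - 1L <= slen]
  if (!nrow(cand)) {
    return(data.table(query = integer(), subject = character(),
                      start = integer(), strand = character(),
                      mismatches = integer()))
  }
  sub_seq <- substring(subj_tab$seq[cand$srow], cand$astart,
                       cand$astart + L - 1L)
  cand[, "mismatches" := string_mismatches(queries[cand$query], sub_seq)]
  max_mm <- floor(max_mismatch_rate * L)
  cand <- cand[cand$mismatches <= max_mm]
  if (!nrow(cand)) {
    return(data.table(query = integer(), subject = character(),
                      start = integer(), strand = character(),
                      mismatches = integer()))
  }
  cand[, "subject" := subj_tab$subject[cand$srow]]
  cand[, "strand" := subj_tab$strand[cand$srow]]
  # convert minus-strand placements to plus-strand 0-based start
  full_len <- nchar(subj_tab$seq)[cand$srow]
  cand[, "start" := ifelse(cand$strand == "+", cand$astart - 1L,
                           full_len - (cand$astart - 1L) - L)]
  cand[, c("query", "subject", "start", "strand", "mismatches")]
}

# deterministic RNG scope helper: run expr with a local seed, restoring state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Read a sample metadata sheet
#'
#' Expects tab-separated columns `sample_id`, `species`, `tissue`,
#' `individual`, `library` (values `converted` or `unconverted`).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "tissue", "individual", "library")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x
}

#' Write / read BED6 interval files (0-based half-open)
#'
#' @param x data.frame with columns chrom, start, end and optionally name,
#'   score, strand.
#' @param path file path.
#' @return `read_bed` returns a data.frame with BED6 columns.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  out <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0L,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(x)[seq_len(min(6L, ncol(x)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(x)))]
  x
}
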