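#' Find restriction sites in a DNA sequence
#'
#' Reports the 0-based start position of every occurrence of each
#' recognition motif (default MspI `CCGG` and TaqI `TCGA`), overlapping
#' occurrences included. `N` bases never match.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param motifs character vector of recognition sequences.
#' @return named list (one element per motif) of sorted 0-based positions.
#' @export
find_restriction_sites <- function(seq, motifs = c("CCGG", "TCGA")) {
  if (!length(motifs)) stop("motifs must be non-empty", call. = FALSE)
  check_dna(seq, allow_n = TRUE)
  subj <- Biostrings::DNAString(seq)
  out <- lapply(motifs, function(m) {
    as.integer(Biostrings::start(Biostrings::matchPattern(m, subj))) - 1L
  })
  names(out) <- motifs
  out
}

#' In silico restriction digest with RRBS size selection
#'
#' Cuts after the first base of each recognition site (C^CGG, T^CGA),
#' partitions the sequence into fragments (terminal fragments included),
#' retains fragments with `min_len <= length <= max_len` (inclusive), and
#' registers the first and last `read_length` bp of each retained fragment
#' as simulated RRBS read intervals.
#'
#' @param seq DNA string (used only for its length when `sites` is given).
#' @param sites integer vector of 0-based site starts (e.g. pooled from
#'   [find_restriction_sites()]); must be sorted ascending.
#' @param min_len,max_len size-selection bounds in bp (inclusive).
#' @param read_length simulated read length in bp.
#' @param chrom chromosome name recorded on the fragments.
#' @return data.frame of class `mc_fragments` with 0-based half-open
#'   columns `start`, `end`, `length` and read intervals `r1_start`,
#'   `r1_end`, `r2_start`, `r2_end` (clipped to the fragment).
#' @export
digest_and_select <- function(seq, sites, min_len = 50L, max_len = 1000L,
                              read_length = 50L, chrom = "chr1") {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  if (is.list(sites)) sites <- unlist(sites, use.names = FALSE)
  sites <- sort(unique(as.integer(sites)))
  L <- nchar(seq)
  cuts <- sites + 1L # cut after the first base of the site
  cuts <- cuts[cuts > 0L & cuts < L]
  bounds <- unique(c(0L, cuts, L))
  start <- bounds[-length(bounds)]
  end <- bounds[-1L]
  len <- end - start
  keep <- len >= min_len & len <= max_len
  start <- start[keep]; end <- end[keep]; len <- len[keep]
  rl <- pmin(as.integer(read_length), len)
  out <- data.frame(
    chrom = chrom, start = start, end = end, length = len,
    r1_start = start, r1_end = start + rl,
    r2_start = end - rl, r2_end = end
  )
  class(out) <- c("mc_fragments", "data.frame")
  out
}

#' Concatenate scaffolds into pseudo-chromosomes
#'
#' Distributes scaffolds round-robin over at most `n_chrom`
#' pseudo-chromosomes, separating adjacent scaffolds by `spacer` Ns, and
#' returns a bidirectional coordinate map.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param n_chrom maximum number of pseudo-chromosomes.
#' @param spacer number of Ns between adjacent scaffolds.
#' @return object of class `mc_pseudo`: list with `seqs` (named character)
#'   and `map` (data.frame scaffold, chrom, offset, length).
#' @export
concat_scaffolds <- function(scaffolds, n_chrom = 20L, spacer = 100L) {
  stopifnot(length(scaffolds) >= 1L)
  if (is.null(names(scaffolds))) {
    names(scaffolds) <- sprintf("scaffold%05d", seq_along(scaffolds))
  }
  n_chrom <- min(n_chrom, length(scaffolds))
  assign_chrom <- rep(seq_len(n_chrom), length.out = length(scaffolds))
  map <- data.frame(scaffold = names(scaffolds),
                    chrom = sprintf("pchr%02d", assign_chrom),
                    offset = NA_integer_,
                    length = nchar(scaffolds),
                    stringsAsFactors = FALSE)
  seqs <- character(n_chrom)
  names(seqs) <- sprintf("pchr%02d", seq_len(n_chrom))
  pad <- strrep("N", spacer)
  for (ci in seq_len(n_chrom)) {
    idx <- which(assign_chrom == ci)
    off <- 0L
    parts <- character()
    for (i in idx) {
      if (length(parts)) off <- off + spacer
      map$offset[i] <- off
      parts <- c(parts, scaffolds[i])
      off <- off + nchar(scaffolds[i])
    }
    seqs[ci] <- paste(parts, collapse = pad)
  }
  structure(list(seqs = seqs, map = map), class = "mc_pseudo")
}

#' Map scaffold coordinates to pseudo-chromosome coordinates and back
#'
#' Positions are 0-based. `coord_to_original` returns NA scaffolds for
#' positions falling in spacer Ns.
#'
#' @param pseudo `mc_pseudo` from [concat_scaffolds()].
#' @param scaffold,pos scaffold names and 0-based positions.
#' @return data.frame with mapped coordinates.
#' @export
coord_to_pseudo <- function(pseudo, scaffold, pos) {
  m <- pseudo$map[match(scaffold, pseudo$map$scaffold), ]
  data.frame(chrom = m$chrom, pos = m$offset + pos)
}

#' @rdname coord_to_pseudo
#' @param chrom pseudo-chromosome names.
#' @export
coord_to_original <- function(pseudo, chrom, pos) {
  out <- data.frame(scaffold = NA_character_, pos = NA_integer_,
                    stringsAsFactors = FALSE)[rep(1L, length(pos)), ]
  rownames(out) <- NULL
  for (i in seq_along(pos)) {
    cand <- pseudo$map[pseudo$map$chrom == chrom[i] &
                         pseudo$map$offset <= pos[i] &
                         pos[i] < pseudo$map$offset + pseudo$map$length, ]
    if (nrow(cand) == 1L) {
      out$scaffold[i] <- cand$scaffold
      out$pos[i] <- pos[i] - cand$offset
    }
  }
  out
}

# promoter intervals (0-based half-open) from transcript intervals:
# upstream bp before the TSS and downstream bp after it, on the gene strand
promoter_intervals <- function(transcripts, upstream = 1000L,
                               downstream = 500L) {
  strand <- if ("strand" %in% names(transcripts)) transcripts$strand else "+"
  tss <- ifelse(strand == "-", transcripts$end - 1L, transcripts$start)
  start <- ifelse(strand == "-", tss - downstream + 1L, tss - upstream)
  end <- ifelse(strand == "-", tss + upstream + 1L, tss + downstream)
  data.frame(chrom = transcripts$chrom, start = pmax(start, 0L), end = end)
}

#' Expected RRBS CpG coverage of genomic element classes
#'
#' A CpG is covered iff it lies inside any simulated read interval of the
#' digest. Fractions are reported per element class and genome-wide; a class
#' with no CpGs (or absent) yields a missing fraction, not zero.
#'
#' @param cpg_positions 0-based positions of CpG cytosines.
#' @param fragments `mc_fragments` from [digest_and_select()].
#' @param elements named list of BED-like data.frames (`start`, `end`,
#'   optionally `strand`), e.g. `cpg_island`, `transcript`, `repeat`.
#'   Promoters are derived from the `transcript` element via
#'   `promoter_def` unless supplied explicitly.
#' @param promoter_def `c(upstream, downstream)` around the TSS in bp.
#' @return data.frame (element_class, n_total, n_covered, fraction).
#' @export
element_coverage <- function(cpg_positions, fragments, elements = list(),
                             promoter_def = c(1000L, 500L)) {
  cpg_positions <- sort(unique(as.integer(cpg_positions)))
  iv_start <- c(fragments$r1_start, fragments$r2_start)
  iv_end <- c(fragments$r1_end, fragments$r2_end)
  covered <- in_any_interval(cpg_positions, iv_start, iv_end)

  if (!is.null(elements$transcript) && is.null(elements$promoter)) {
    elements$promoter <- promoter_intervals(elements$transcript,
                                            promoter_def[1], promoter_def[2])
  }
  classes <- c("cpg_island", "transcript", "promoter", "repeat")
  rows <- lapply(classes, function(cl) {
    el <- elements[[cl]]
    if (is.null(el) || !nrow(el)) {
      return(data.frame(element_class = cl, n_total = NA_integer_,
                        n_covered = NA_integer_, fraction = NA_real_))
    }
    inside <- in_any_interval(cpg_positions, el$start, el$end)
    n_tot <- sum(inside)
    n_cov <- sum(inside & covered)
    data.frame(element_class = cl, n_total = n_tot, n_covered = n_cov,
               fraction = if (n_tot > 0) n_cov / n_tot else NA_real_)
  })
  gw <- data.frame(element_class = "genome_wide",
                   n_total = length(cpg_positions),
                   n_covered = sum(covered),
                   fraction = if (length(cpg_positions)) {
                     mean(covered)
                   } else NA_real_)
  rbind(do.call(rbind, rows), gw)
}

# membership of 0-based positions in any 0-based half-open interval
in_any_interval <- function(pos, start, end) {
  if (!length(start)) return(rep(FALSE, length(pos)))
  if (!length(pos)) return(logical())
  o <- order(start)
  start <- start[o]; end <- end[o]
  # sweep: for each pos, any interval with start <= pos < end
  hits <- rep(FALSE, length(pos))
  # merge intervals first (they may overlap)
  ms <- start[1]; me <- end[1]
  merged_s <- integer(); merged_e <- integer()
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
  idx <- findInterval(pos, merged_s)
  ok <- idx >= 1L
  hits[ok] <- pos[ok] < merged_e[idx[ok]]
  hits
}

#' Extract fragment sequences from a genome
#'
#' @param genome `mc_genome` or a plain character sequence.
#' @param fragments `mc_fragments`.
#' @param prefix fragment id prefix.
#' @return data.frame (fragment_id, seq, start, end) suitable for
#'   [assign_methylome()].
#' @export
fragment_sequences <- function(genome, fragments, prefix = "frag") {
  seq <- if (inherits(genome, "mc_genome")) genome$seq else genome
  data.frame(
    fragment_id = sprintf("%s%06d", prefix, seq_len(nrow(fragments))),
    seq = substring(seq, fragments$start + 1L, fragments$end),
    start = fragments$start, end = fragments$end,
    stringsAsFactors = FALSE
  )
}
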