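#' Pooled k-mer spectrum of consensus fragments
#'
#' Overlapping k-mers are counted across all fragments (positions pooled,
#' not per-fragment means); windows containing non-ACGT characters are
#' skipped and frequencies are normalised to sum to one over all `4^k`
#' k-mers. When given an `mc_consensus`, only fragments covered by the
#' unconverted library are used, since only those have fully recovered
#' genomic cytosines.
#'
#' @param x character vector of sequences, or an `mc_consensus`.
#' @param k word length (1 to 10).
#' @return list of class `mc_spectrum`: `k`, named `freq` vector of length
#'   `4^k`, `n_positions`.
#' @export
kmer_spectrum <- function(x, k) {
  stopifnot(k >= 1, k <= 10)
  seqs <- spectrum_input(x)
  if (!length(seqs)) stop("no qualifying fragments", call. = FALSE)
  dt <- kmer_windows(seqs, k)
  if (!nrow(dt)) stop("no countable k-mer windows", call. = FALSE)
  tab <- dt[, .N, by = "kmer"]
  kmers <- all_kmers(k)
  freq <- setNames(numeric(length(kmers)), kmers)
  freq[tab$kmer] <- tab$N
  n <- sum(freq)
  structure(list(k = k, freq = freq / n, n_positions = n),
            class = "mc_spectrum")
}

spectrum_input <- function(x) {
  if (inherits(x, "mc_consensus")) {
    x$fragments$sequence[x$fragments$covered_by_unconverted]
  } else {
    as.character(x)
  }
}

#' CG composition of a fragment set
#'
#' Counts are pooled across fragments. The observed/expected CpG ratio is
#' `(#CpG * N) / (#C * #G)` with `N` the total base count, missing when the
#' sequence has no C or no G.
#'
#' @param x character vector of sequences or an `mc_consensus`.
#' @return data.frame with freq_C, freq_G, freq_CpG, obs_exp_cpg, n_cpgs.
#' @export
cg_composition <- function(x) {
  seqs <- spectrum_input(x)
  stopifnot(length(seqs) > 0)
  n_c <- sum(nchar(seqs) - nchar(gsub("C", "", seqs, fixed = TRUE)))
  n_g <- sum(nchar(seqs) - nchar(gsub("G", "", seqs, fixed = TRUE)))
  N <- sum(nchar(seqs))
  cg <- count_cpgs(seqs)
  n_dinuc <- sum(pmax(nchar(seqs) - 1L, 0L))
  data.frame(
    freq_C = n_c / N, freq_G = n_g / N,
    freq_CpG = if (n_dinuc > 0) cg / n_dinuc else NA_real_,
    obs_exp_cpg = if (n_c > 0 && n_g > 0) cg * N / (n_c * n_g) else NA_real_,
    n_cpgs = cg
  )
}

count_cpgs <- function(seqs) {
  sum(vapply(gregexpr("CG", seqs, fixed = TRUE),
             function(m) sum(m > 0), 0L))
}

#' Fraction of fragments qualifying as CpG islands
#'
#' A fragment qualifies iff at least one 50 bp window (sliding by `step`)
#' passes both thresholds of the chosen criterion: GC content >= 0.50 and
#' CpG observed/expected >= 0.6 (Gardiner-Garden) or GC >= 0.55 and
#' obs/exp >= 0.65 (Takai-Jones). Fragments shorter than 50 bp count as
#' non-islands.
#'
#' @param x character vector of fragments or an `mc_consensus`.
#' @param criterion `"gardiner_garden"` or `"takai_jones"`.
#' @param step window step in bp.
#' @param window window width in bp.
#' @return list with `fraction` and the per-fragment logical `is_island`.
#' @export
island_fraction <- function(x, criterion = c("gardiner_garden", "takai_jones"),
                            step = 1L, window = 50L) {
  criterion <- match.arg(criterion)
  seqs <- spectrum_input(x)
  th <- if (criterion == "gardiner_garden") c(gc = 0.50, oe = 0.6) else
    c(gc = 0.55, oe = 0.65)
  is_island <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < window) return(FALSE)
    ch <- strsplit(s, "")[[1]]
    cc <- cumsum(ch == "C")
    cg_ <- cumsum(ch == "G")
    dinuc <- c(ch[-n] == "C" & ch[-1] == "G", FALSE)
    ccg <- cumsum(dinuc)
    starts <- seq(1L, n - window + 1L, by = step)
    ends <- starts + window - 1L
    wc <- cc[ends] - c(0, cc)[starts]
    wg <- cg_[ends] - c(0, cg_)[starts]
    # CpG dinucleotides fully inside the window
    wcg <- ccg[ends - 1L] - c(0, ccg)[starts]
    gc_ok <- (wc + wg) / window >= th["gc"]
    oe <- ifelse(wc > 0 & wg > 0, wcg * window / (wc * wg), NA_real_)
    any(gc_ok & !is.na(oe) & oe >= th["oe"])
  }, TRUE, USE.NAMES = FALSE)
  list(fraction = mean(is_island), is_island = is_island)
}

#' Species distances and clustering from k-mer spectra
#'
#' Euclidean distances between per-species k-mer frequency vectors,
#' followed by agglomerative hierarchical clustering. Species whose spectra
#' recapitulate their phylogeny cluster accordingly.
#'
#' @param spectra named list of `mc_spectrum` objects (or plain frequency
#'   vectors), one per species; all at the same k.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `dist` (matrix), `hclust`, and `newick` dendrogram
#'   string.
#' @export
species_kmer_clustering <- function(spectra, linkage = "complete") {
  if (length(spectra) < 2L) stop("need >= 2 species", call. = FALSE)
  vecs <- lapply(spectra, function(s) if (inherits(s, "mc_spectrum")) s$freq else s)
  bad <- vapply(vecs, function(v) any(is.na(v)) || !length(v), TRUE)
  if (any(bad)) {
    warning("species with missing spectra excluded: ",
            paste(names(vecs)[bad], collapse = ", "))
    vecs <- vecs[!bad]
  }
  m <- do.call(rbind, vecs)
  rownames(m) <- names(vecs)
  # deterministic order for reproducible tie-breaks
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- stats::dist(m)
  hc <- stats::hclust(d, method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(dist = as.matrix(d), hclust = hc, newick = nwk)
}

#' Species-level sequence feature table
#'
#' Convenience assembly of the feature groups used by the genome-wide
#' models: 1- to 3-mer frequencies, CG composition, and the two CpG-island
#' fractions, computed on the unconverted-covered consensus fragments of
#' each species.
#'
#' @param consensus_by_species named list of `mc_consensus` (or sequence
#'   vectors) per species.
#' @return data.frame, one row per species; 3-mer columns are prefixed
#'   `kmer_`.
#' @export
species_feature_table <- function(consensus_by_species) {
  rows <- lapply(names(consensus_by_species), function(sp) {
    x <- consensus_by_species[[sp]]
    sp3 <- kmer_spectrum(x, 3L)
    comp <- cg_composition(x)
    gg <- island_fraction(x, "gardiner_garden")$fraction
    tj <- island_fraction(x, "takai_jones")$fraction
    km <- as.data.frame(t(sp3$freq))
    names(km) <- paste0("kmer_", names(sp3$freq))
    cbind(data.frame(species = sp), km, comp,
          data.frame(island_gg = gg, island_tj = tj))
  })
  do.call(rbind, rows)
}
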