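#' Read-simulation configuration
#'
#' @param read_length read length in bp.
#' @param mean_coverage expected reads per fragment end (Poisson).
#' @param conversion_rate probability that an unmethylated C is read as T.
#' @param over_conversion probability that a methylated C is read as T.
#' @param seq_error_rate per-base substitution error rate.
#' @param spike_in_fraction fraction of reads drawn from the spike-in
#'   control sequences (half fully methylated, half fully unmethylated);
#'   the default matches the 0.1% concentration used for RRBS conversion
#'   controls.
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical output.
#' @return object of class `mc_readsim_config`.
#' @export
read_sim_config <- function(read_length = 50L, mean_coverage = 20,
                            conversion_rate = 0.99, over_conversion = 0.005,
                            seq_error_rate = 0.001,
                            spike_in_fraction = 0.001, seed = 1L) {
  rates <- c(conversion_rate, over_conversion, seq_error_rate,
             spike_in_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (read_length < 1) stop("read_length must be >= 1", call. = FALSE)
  structure(list(read_length = as.integer(read_length),
                 mean_coverage = mean_coverage,
                 conversion_rate = conversion_rate,
                 over_conversion = over_conversion,
                 seq_error_rate = seq_error_rate,
                 spike_in_fraction = spike_in_fraction,
                 seed = as.integer(seed)),
            class = "mc_readsim_config")
}

#' Spike-in control sequences
#'
#' Two fixed 200 bp control sequences shipped with the package: one treated
#' as fully methylated and one as fully unmethylated during read simulation
#' and usable to estimate bisulfite conversion efficiency.
#'
#' @return named character vector `c(spike_meth = ..., spike_unmeth = ...)`.
#' @export
spike_in_sequences <- function() {
  path <- system.file("extdata", "spikeins.fa", package = "methcode")
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Simulate RRBS reads (converted and unconverted libraries)
#'
#' Reads are the first `read_length` bases of each fragment end: the plus
#' strand prefix and the reverse complement of the suffix (single-end,
#' directional protocol). Converted libraries apply bisulfite chemistry per
#' cytosine: methylated cytosines stay C except with probability
#' `over_conversion`; unmethylated cytosines read T with probability
#' `conversion_rate`. CpG cytosines use the planted per-fragment probability
#' (plus per-CpG jitter); other cytosines use the methylome's non-CpG level.
#' Unconverted libraries (one per species, `library == "unconverted"` in the
#' design, auto-added when absent) apply no conversion. Spike-in control
#' reads are mixed in at `spike_in_fraction`.
#'
#' @param methylome `mc_methylome`; its fragments must carry sequences.
#' @param cfg `mc_readsim_config`.
#' @param out_dir optional directory; when given, one FASTQ per sample is
#'   written (constant Q30 qualities).
#' @return object of class `mc_reads`: per-sample read vectors with truth
#'   annotations, the template table, metadata, and the configuration.
#' @export
simulate_rrbs_reads <- function(methylome, cfg = read_sim_config(),
                                out_dir = NULL) {
  stopifnot(inherits(methylome, "mc_methylome"),
            inherits(cfg, "mc_readsim_config"))
  rl <- cfg$read_length
  frag <- methylome$fragments
  short <- nchar(frag$seq) < rl
  if (any(short)) {
    warning(sum(short), " fragments shorter than read_length dropped")
    frag <- frag[!short, , drop = FALSE]
  }
  if (!nrow(frag)) {
    warning("no fragments available after size filtering; empty output")
    return(structure(list(samples = list(), templates = NULL,
                          metadata = methylome$samples, config = cfg),
                     class = "mc_reads"))
  }

  design <- methylome$samples
  if (is.null(design$library)) design$library <- "converted"
  if (is.null(design$species)) design$species <- "species1"
  for (sp in unique(design$species)) {
    if (!any(design$species == sp & design$library == "unconverted")) {
      design <- rbind(design, data.frame(
        sample_id = paste0(sp, "_unconv"), species = sp,
        tissue = design$tissue[design$species == sp][1],
        individual = design$individual[design$species == sp][1],
        library = "unconverted",
        stringsAsFactors = FALSE
      )[, names(design)])
    }
  }

  spikes <- spike_in_sequences()
  nfr <- nrow(frag)
  templates <- data.table(
    template_id = seq_len(2L * nfr + 4L),
    fragment_id = c(rep(frag$fragment_id, 2L), rep(names(spikes), each = 2L)),
    end = c(rep(1:2, each = nfr), rep(1:2, 2L)),
    seq = c(substr(frag$seq, 1L, rl),
            revcomp(substr(frag$seq, nchar(frag$seq) - rl + 1L,
                           nchar(frag$seq))),
            substr(spikes[1], 1, rl),
            revcomp(substr(spikes[1], nchar(spikes[1]) - rl + 1,
                           nchar(spikes[1]))),
            substr(spikes[2], 1, rl),
            revcomp(substr(spikes[2], nchar(spikes[2]) - rl + 1,
                           nchar(spikes[2])))),
    fixed_p = c(rep(NA_real_, 2L * nfr), 1, 1, 0, 0)
  )
  nt <- nrow(templates)
  genomic <- which(is.na(templates$fixed_p))
  spike_rows <- which(!is.na(templates$fixed_p))

  # template character structure
  tchar <- matrix("", nt, rl)
  for (j in seq_len(rl)) tchar[, j] <- substr(templates$seq, j, j)
  is_c <- tchar == "C"
  is_cpg <- is_c
  is_cpg[, rl] <- FALSE
  for (j in seq_len(rl - 1L)) {
    is_cpg[, j] <- is_c[, j] & tchar[, j + 1L] == "G"
  }
  frag_row <- match(templates$fragment_id, rownames(methylome$prob))

  with_seed(cfg$seed, {
    jitter <- matrix(rnorm(nt * rl, sd = methylome$cpg_jitter_sd), nt, rl)
    other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
    out <- vector("list", nrow(design))
    names(out) <- design$sample_id
    for (si in seq_len(nrow(design))) {
      srow <- design[si, , drop = FALSE]
      conv <- srow$library == "converted"
      # auto-added unconverted samples have no methylome column; their
      # methylation draws are discarded anyway
      ci <- match(srow$sample_id, colnames(methylome$prob))
      if (is.na(ci)) ci <- 1L
      counts <- rpois(2L * nfr, cfg$mean_coverage)
      n_gen <- sum(counts)
      n_spk <- round(cfg$spike_in_fraction * n_gen)
      spk_counts <- integer(4L)
      if (n_spk > 0) {
        spk_counts <- as.integer(table(factor(
          sample.int(4L, n_spk, replace = TRUE), levels = 1:4)))
      }
      all_counts <- c(counts, spk_counts)
      rt <- rep(seq_len(nt), all_counts)
      reads <- templates$seq[rt]
      n <- length(reads)
      if (n) {
        pn <- noncpg_prob(methylome, srow)
        for (j in seq_len(rl)) {
          rows <- which(is_c[rt, j])
          if (!length(rows)) next
          tj <- rt[rows]
          p <- rep(pn, length(rows))
          fixed <- !is.na(templates$fixed_p[tj])
          p[fixed] <- templates$fixed_p[tj[fixed]]
          cpg_here <- !fixed & is_cpg[cbind(tj, rep(j, length(tj)))]
          if (any(cpg_here)) {
            tjj <- tj[cpg_here]
            p[cpg_here] <- pmin(pmax(
              methylome$prob[frag_row[tjj], ci] +
                jitter[cbind(tjj, rep(j, length(tjj)))], 0), 1)
          }
          meth <- runif(length(rows)) < p
          if (conv) {
            to_t <- ifelse(meth, runif(length(rows)) < cfg$over_conversion,
                           runif(length(rows)) < cfg$conversion_rate)
          } else {
            # draw and discard to keep the RNG stream aligned across
            # converted and unconverted libraries
            runif(length(rows))
            to_t <- rep(FALSE, length(rows))
          }
          if (any(to_t)) {
            idx <- rows[to_t]
            substr(reads[idx], j, j) <- "T"
          }
        }
        if (cfg$seq_error_rate > 0) {
          for (j in seq_len(rl)) {
            err <- which(runif(n) < cfg$seq_error_rate)
            if (!length(err)) next
            cur <- substr(reads[err], j, j)
            pick <- sample.int(3L, length(err), replace = TRUE)
            newc <- vapply(seq_along(err),
                           function(i) other[[cur[i]]][pick[i]], "")
            substr(reads[err], j, j) <- newc
          }
        }
      }
      out[[si]] <- list(
        sample_id = srow$sample_id,
        library = srow$library,
        reads = reads,
        truth = data.table(template_id = rt,
                           fragment_id = templates$fragment_id[rt],
                           end = templates$end[rt])
      )
    }
    res <- structure(list(samples = out, templates = as.data.frame(templates),
                          metadata = design, config = cfg),
                     class = "mc_reads")
    if (!is.null(out_dir)) write_reads_fastq(res, out_dir)
    res
  })
}

#' @export
print.mc_reads <- function(x, ...) {
  cat("mc_reads:", length(x$samples), "samples,",
      sum(vapply(x$samples, function(s) length(s$reads), 0L)), "reads\n")
  invisible(x)
}

#' Write simulated reads as FASTQ (constant Q30) plus a metadata sheet
#'
#' @param reads `mc_reads` object.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_reads_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (s in reads$samples) {
    p <- file.path(dir, paste0(s$sample_id, ".fastq"))
    if (length(s$reads)) {
      dss <- Biostrings::DNAStringSet(s$reads)
      names(dss) <- sprintf("%s_read%06d", s$sample_id, seq_along(s$reads))
      qual <- Biostrings::BStringSet(strrep("?", nchar(s$reads)))
      Biostrings::writeXStringSet(dss, p, format = "fastq", qualities = qual)
    } else {
      file.create(p)
    }
    paths <- c(paths, p)
  }
  meta <- file.path(dir, "samples.tsv")
  write.table(reads$metadata, meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, meta))
}

#' Read a FASTQ file into a plain character vector of sequences
#' @param path FASTQ file.
#' @return character vector.
#' @export
read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
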