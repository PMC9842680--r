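#' Filter contaminating reads against a decoy sequence set
#'
#' A read is removed iff it aligns to any decoy sequence (either strand,
#' ungapped) with a mismatch rate at or below `max_mismatch_rate`. Matching
#' is bisulfite-aware: both reads and decoys are C-to-T collapsed before
#' comparison, so a read T matches a decoy C.
#'
#' @param reads character vector of read sequences.
#' @param decoys named character vector of decoy sequences (may be empty).
#' @param max_mismatch_rate maximum mismatches per aligned base.
#' @return list with `kept`, `removed` (read vectors) and
#'   `contamination_rate` (removed / total; `NA` for an empty read set).
#' @export
filter_contamination <- function(reads, decoys = character(),
                                 max_mismatch_rate = 0.1) {
  if (!length(reads)) {
    return(list(kept = reads, removed = character(),
                contamination_rate = NA_real_))
  }
  if (!length(decoys)) {
    return(list(kept = reads, removed = character(),
                contamination_rate = 0))
  }
  if (is.null(names(decoys))) {
    names(decoys) <- sprintf("decoy%03d", seq_along(decoys))
  }
  L <- min(nchar(reads))
  q <- bs_collapse(substr(reads, 1L, L))
  subj <- bs_collapse(decoys)
  uq <- unique(q)
  hits <- align_ungapped(uq, subj, max_mismatch_rate = max_mismatch_rate)
  bad_keys <- uq[unique(hits$query)]
  removed <- q %chin% bad_keys
  list(kept = reads[!removed], removed = reads[removed],
       contamination_rate = mean(removed))
}

# candidate Hamming<=1 neighbour pairs among equal-length keys, found by
# exact match on either half (pigeonhole: one mismatch leaves one half
# intact)
hamming1_pairs <- function(keys) {
  L <- nchar(keys[1])
  half <- L %/% 2L
  h1 <- substr(keys, 1L, half)
  h2 <- substr(keys, half + 1L, L)
  pairs_from <- function(groups, other) {
    idx <- split(seq_along(keys), groups)
    idx <- idx[lengths(idx) > 1L]
    if (!length(idx)) {
      return(data.table(i = integer(), j = integer()))
    }
    res <- lapply(idx, function(v) {
      cmb <- combn(v, 2L)
      data.table(i = cmb[1, ], j = cmb[2, ])
    })
    res <- rbindlist(res)
    mm <- string_mismatches(other[res$i], other[res$j])
    res[mm <= 1L]
  }
  out <- rbind(pairs_from(h1, h2), pairs_from(h2, h1))
  unique(out)
}

#' Build consensus reference fragments from pooled RRBS reads
#'
#' Reads from all samples are grouped into stacks by their C-to-T collapsed
#' key (exact match, then a single merge pass joining keys within Hamming
#' distance `merge_distance`, the larger stack absorbing the smaller). The
#' stack key is the consensus backbone; at each backbone T, a genomic
#' cytosine is called iff unconverted members show C at frequency >=
#' `tau_unconv`, or converted members show C at frequency >= `tau_meth`
#' (a methylated cytosine visible through bisulfite conversion).
#'
#' @param converted_reads character vector, or list of per-sample vectors,
#'   of bisulfite-converted reads.
#' @param unconverted_reads optional character vector of unconverted-library
#'   reads.
#' @param merge_distance Hamming tolerance for stack merging.
#' @param min_stack_depth stacks with fewer total members are dropped.
#' @param tau_unconv minimum unconverted C frequency to call a cytosine.
#' @param tau_meth minimum converted C frequency to call a cytosine.
#' @return object of class `mc_consensus`: `fragments` (fragment_id,
#'   sequence, depth, n_conv, n_unconv, covered_by_unconverted),
#'   `cytosines` (fragment_id, 0-based `pos`, `context` among
#'   CpG/CpA/CpC/CpT), `key_map`, and `read_length`.
#' @export
build_consensus <- function(converted_reads, unconverted_reads = NULL,
                            merge_distance = 1L, min_stack_depth = 5L,
                            tau_unconv = 0.5, tau_meth = 0.1) {
  if (is.list(converted_reads)) {
    converted_reads <- unlist(converted_reads, use.names = FALSE)
  }
  if (is.null(unconverted_reads)) unconverted_reads <- character()
  all_reads <- c(converted_reads, unconverted_reads)
  if (!length(all_reads)) stop("no reads supplied", call. = FALSE)
  L <- min(nchar(all_reads))
  dt <- data.table(
    seq = substr(all_reads, 1L, L),
    conv = rep(c(TRUE, FALSE),
               c(length(converted_reads), length(unconverted_reads)))
  )
  uniq <- dt[, list(n_conv = sum(conv), n_unconv = sum(!conv)), by = "seq"]
  uniq[, "key" := bs_collapse(uniq$seq)]

  stacks <- uniq[, list(depth = sum(n_conv) + sum(n_unconv)), by = "key"]
  setorderv(stacks, c("depth", "key"), order = c(-1L, 1L))
  stacks[, "rep" := stacks$key]

  if (merge_distance > 0L && nrow(stacks) > 1L) {
    pr <- hamming1_pairs(stacks$key)
    if (nrow(pr)) {
      # stacks is sorted by depth desc, key asc: smaller row index means
      # higher priority; the lower-priority member of each pair is absorbed
      tgt <- seq_len(nrow(stacks))
      small <- pmax(pr$i, pr$j)
      big <- pmin(pr$i, pr$j)
      # each small stack points at its highest-priority neighbour
      best <- tapply(big, small, min)
      tgt[as.integer(names(best))] <- as.integer(best)
      # resolve chains
      repeat {
        nxt <- tgt[tgt]
        if (identical(nxt, tgt)) break
        tgt <- nxt
      }
      stacks[, "rep" := stacks$key[tgt]]
    }
  }
  uniq <- merge(uniq, stacks[, c("key", "rep")], by = "key", sort = FALSE)

  agg <- uniq[, list(depth = sum(n_conv) + sum(n_unconv),
                     n_conv = sum(n_conv), n_unconv = sum(n_unconv)),
              by = "rep"]
  agg <- agg[agg$depth >= min_stack_depth]
  if (!nrow(agg)) {
    warning("no read stack reaches min_stack_depth; empty consensus")
    return(structure(list(
      fragments = data.table(fragment_id = character(),
                             sequence = character(), depth = integer(),
                             n_conv = integer(), n_unconv = integer(),
                             covered_by_unconverted = logical()),
      cytosines = data.table(fragment_id = character(), pos = integer(),
                             context = character()),
      key_map = setnames(data.table(k = character(),
                                    fragment_id = character()), "k", "key"),
      read_length = L), class = "mc_consensus"))
  }
  setorderv(agg, c("depth", "rep"), order = c(-1L, 1L))
  agg[, "stack_idx" := seq_len(nrow(agg))]
  uniq <- uniq[uniq$rep %chin% agg$rep]
  uniq[, "stack_idx" := agg$stack_idx[match(uniq$rep, agg$rep)]]

  ns <- nrow(agg)
  n_conv_c <- matrix(0, ns, L)
  n_unconv_c <- matrix(0, ns, L)
  for (j in seq_len(L)) {
    w <- which(substr(uniq$seq, j, j) == "C")
    if (length(w)) {
      tc <- tapply(uniq$n_conv[w], uniq$stack_idx[w], sum)
      n_conv_c[as.integer(names(tc)), j] <- tc
      tu <- tapply(uniq$n_unconv[w], uniq$stack_idx[w], sum)
      n_unconv_c[as.integer(names(tu)), j] <- tu
    }
  }

  cons <- agg$rep
  for (j in seq_len(L)) {
    bt <- substr(cons, j, j) == "T"
    call_c <- bt & ((agg$n_unconv > 0 &
                       n_unconv_c[, j] / pmax(agg$n_unconv, 1) >= tau_unconv) |
                      (agg$n_conv > 0 &
                         n_conv_c[, j] / pmax(agg$n_conv, 1) >= tau_meth))
    if (any(call_c)) substr(cons[call_c], j, j) <- "C"
  }

  frag_id <- sprintf("frag%06d", seq_len(ns))
  fragments <- data.table(
    fragment_id = frag_id, sequence = cons, depth = agg$depth,
    n_conv = agg$n_conv, n_unconv = agg$n_unconv,
    covered_by_unconverted = agg$n_unconv > 0L
  )

  cyt <- rbindlist(lapply(seq_len(ns), function(i) {
    p <- which(strsplit(cons[i], "")[[1]] == "C")
    if (!length(p)) return(NULL)
    nxt <- ifelse(p < L, substring(cons[i], p + 1L, p + 1L), NA_character_)
    data.table(fragment_id = frag_id[i], pos = p - 1L,
               context = ifelse(is.na(nxt), NA_character_,
                                paste0("Cp", nxt)))
  }))
  if (is.null(cyt) || !nrow(cyt)) {
    cyt <- data.table(fragment_id = character(), pos = integer(),
                      context = character())
  }
  key_map <- unique(uniq[, c("key", "stack_idx")])
  key_map[, "fragment_id" := frag_id[key_map$stack_idx]]
  key_map[, "stack_idx" := NULL]

  structure(list(fragments = fragments, cytosines = cyt,
                 key_map = key_map, read_length = L),
            class = "mc_consensus")
}

#' @export
print.mc_consensus <- function(x, ...) {
  cat("mc_consensus:", nrow(x$fragments), "fragments (",
      sum(x$fragments$covered_by_unconverted), "covered by unconverted ),",
      nrow(x$cytosines), "cytosines\n")
  invisible(x)
}

#' Write consensus fragments as FASTA plus a cytosine sidecar TSV
#' @param consensus `mc_consensus`.
#' @param dir output directory.
#' @return invisibly, paths written.
#' @export
write_consensus <- function(consensus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "consensus.fa")
  s <- Biostrings::DNAStringSet(setNames(consensus$fragments$sequence,
                                         consensus$fragments$fragment_id))
  Biostrings::writeXStringSet(s, fa)
  tsv <- file.path(dir, "cytosines.tsv")
  write.table(consensus$cytosines, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fa, tsv))
}

# assign collapsed read keys to consensus fragments; exact key lookup first,
# then Hamming <= 1 rescue against representative keys
assign_reads <- function(keys, consensus) {
  fid <- consensus$key_map$fragment_id[match(keys, consensus$key_map$key)]
  un <- which(is.na(fid))
  if (length(un)) {
    uq <- unique(keys[un])
    reps <- unique(consensus$key_map$key)
    both <- c(uq, reps)
    pr <- hamming1_pairs(both)
    nu <- length(uq)
    pr <- pr[(pr$i <= nu) != (pr$j <= nu)]
    if (nrow(pr)) {
      qi <- ifelse(pr$i <= nu, pr$i, pr$j)
      ri <- ifelse(pr$i <= nu, pr$j, pr$i) - nu
      m <- data.table(q = qi, frag = consensus$key_map$fragment_id[
        match(reps[ri], consensus$key_map$key)])
      setorderv(m, c("q", "frag"))
      m <- m[!duplicated(m$q)]
      res <- m$frag[match(match(keys[un], uq), m$q)]
      fid[un] <- res
    }
  }
  fid
}

#' Call methylation for one sample against consensus fragments
#'
#' Reads are assigned to fragments by collapsed-key lookup (with Hamming-1
#' rescue). At each consensus cytosine, a read C counts as methylated, a
#' read T as unmethylated, any other base is ignored. Per-read CpG state
#' vectors are retained (as an attribute) for discordance analysis.
#'
#' @param reads character vector of this sample's converted reads.
#' @param consensus `mc_consensus`.
#' @param sample_id sample identifier recorded on the calls.
#' @return `mc_calls` data.table (sample_id, fragment_id, pos, context,
#'   n_meth, n_total) with attributes `read_states` (per-read CpG states)
#'   and `mapping_rates` (named numeric).
#' @export
call_methylation <- function(reads, consensus, sample_id = "sample1") {
  if (!nrow(consensus$fragments)) stop("consensus is empty", call. = FALSE)
  L <- consensus$read_length
  total <- length(reads)
  short <- nchar(reads) < L
  reads <- substr(reads[!short], 1L, L)
  fid <- assign_reads(bs_collapse(reads), consensus)
  ok <- !is.na(fid)
  rd <- data.table(read_idx = which(ok), fragment_id = fid[ok],
                   seq = reads[ok])
  mapping_rate <- if (total) nrow(rd) / total else NA_real_

  cyt <- consensus$cytosines
  states <- rbindlist(lapply(sort(unique(cyt$pos)), function(p) {
    frs <- cyt$fragment_id[cyt$pos == p]
    sub <- rd[rd$fragment_id %chin% frs]
    if (!nrow(sub)) return(NULL)
    data.table(read_idx = sub$read_idx, fragment_id = sub$fragment_id,
               pos = p, ch = substr(sub$seq, p + 1L, p + 1L))
  }))
  if (is.null(states) || !nrow(states)) {
    states <- data.table(read_idx = integer(), fragment_id = character(),
                         pos = integer(), ch = character())
  }
  calls <- states[, list(n_meth = sum(ch == "C"),
                         n_total = sum(ch %chin% c("C", "T"))),
                  by = c("fragment_id", "pos")]
  calls <- merge(cyt, calls, by = c("fragment_id", "pos"), all.x = TRUE)
  calls[is.na(calls$n_meth), c("n_meth", "n_total") := list(0L, 0L)]
  # only fragments this sample actually covers
  calls <- calls[calls$fragment_id %chin% unique(rd$fragment_id)]
  calls[, "sample_id" := sample_id]
  setcolorder(calls, c("sample_id", "fragment_id", "pos", "context",
                       "n_meth", "n_total"))

  cpg <- cyt[cyt$context == "CpG" & !is.na(cyt$context)]
  rs <- merge(states, cpg, by = c("fragment_id", "pos"))
  rs[, "state" := ifelse(rs$ch == "C", "M",
                         ifelse(rs$ch == "T", "U", NA_character_))]
  rs[, "sample_id" := sample_id]
  read_states <- rs[, c("sample_id", "fragment_id", "read_idx", "pos",
                        "state")]
  setorderv(read_states, c("fragment_id", "read_idx", "pos"))

  setattr(calls, "class", c("mc_calls", class(calls)))
  setattr(calls, "read_states", read_states)
  setattr(calls, "mapping_rates", setNames(mapping_rate, sample_id))
  setattr(calls, "n_short_reads", setNames(sum(short), sample_id))
  calls[]
}

#' Call methylation for all converted samples of a read set
#'
#' @param reads `mc_reads` from [simulate_rrbs_reads()], or a named list of
#'   read vectors.
#' @param consensus `mc_consensus`.
#' @return combined `mc_calls` with per-sample attributes merged.
#' @export
call_methylation_samples <- function(reads, consensus) {
  if (inherits(reads, "mc_reads")) {
    conv <- Filter(function(s) s$library == "converted", reads$samples)
    lst <- lapply(conv, function(s) s$reads)
    names(lst) <- vapply(conv, function(s) s$sample_id, "")
  } else {
    lst <- reads
  }
  parts <- lapply(names(lst), function(sid) {
    call_methylation(lst[[sid]], consensus, sample_id = sid)
  })
  calls <- rbindlist(parts)
  setattr(calls, "class", c("mc_calls", class(calls)))
  setattr(calls, "read_states",
          rbindlist(lapply(parts, attr, "read_states")))
  setattr(calls, "mapping_rates",
          do.call(c, lapply(parts, attr, "mapping_rates")))
  calls[]
}

#' Identify consensus fragments matching the spike-in controls
#'
#' @param consensus `mc_consensus`.
#' @param which `"meth"`, `"unmeth"` or both.
#' @param max_mismatch Hamming tolerance on collapsed sequences.
#' @return character vector of fragment ids.
#' @export
identify_spike_fragments <- function(consensus, which = c("meth", "unmeth"),
                                     max_mismatch = 2L) {
  which <- match.arg(which, several.ok = TRUE)
  spikes <- spike_in_sequences()
  keep <- spikes[paste0("spike_", which)]
  L <- consensus$read_length
  tmpl <- unlist(lapply(keep, function(s) {
    c(substr(s, 1, L), revcomp(substr(s, nchar(s) - L + 1, nchar(s))))
  }))
  tmpl <- bs_collapse(tmpl)
  cons_keys <- bs_collapse(consensus$fragments$sequence)
  hit <- vapply(cons_keys, function(k) {
    any(string_mismatches(rep(k, length(tmpl)), tmpl) <= max_mismatch)
  }, TRUE)
  consensus$fragments$fragment_id[hit]
}

#' Estimate bisulfite conversion rate from unmethylated spike-in calls
#'
#' @param calls `mc_calls` restricted to unmethylated spike-in fragments
#'   (see [identify_spike_fragments()]); all cytosine contexts are used.
#' @return named numeric, conversion rate per sample (fraction of cytosine
#'   observations read as T); `NA` with a warning for samples without
#'   spike observations.
#' @export
estimate_conversion_rate <- function(calls) {
  if (!nrow(calls) || sum(calls$n_total) == 0) {
    warning("no spike-in cytosine observations; conversion rate missing")
    return(setNames(NA_real_, unique(calls$sample_id)))
  }
  agg <- calls[, list(rate = 1 - sum(n_meth) / sum(n_total)),
               by = "sample_id"]
  setNames(agg$rate, agg$sample_id)
}

#' Per-sample summary metrics
#'
#' @param calls `mc_calls` (one or many samples).
#' @param contamination_rates,conversion_rates,pcr_cycles optional named
#'   vectors joined into the table.
#' @return data.frame, one row per sample: mapping_rate, n_covered_cpgs,
#'   mean CpG methylation, conversion/contamination rates, and a
#'   pre-fragmentation proxy (fraction of covered fragments below half the
#'   sample's mean fragment coverage).
#' @export
compute_sample_metrics <- function(calls, contamination_rates = NULL,
                                   conversion_rates = NULL,
                                   pcr_cycles = NULL) {
  mr <- attr(calls, "mapping_rates")
  cpg <- calls[calls$context == "CpG" & !is.na(calls$context)]
  per <- cpg[, list(
    n_covered_cpgs = sum(n_total >= 1L),
    mean_methylation = {
      r <- n_meth[n_total >= 1L] / n_total[n_total >= 1L]
      if (length(r)) mean(r) else NA_real_
    }
  ), by = "sample_id"]
  fragcov <- calls[, list(cov = mean(n_total)),
                   by = c("sample_id", "fragment_id")]
  prefrag <- fragcov[, list(
    prefragmentation_proxy = mean(cov < 0.5 * mean(cov))
  ), by = "sample_id"]
  out <- merge(as.data.frame(per), as.data.frame(prefrag), by = "sample_id",
               all = TRUE)
  out$mapping_rate <- if (!is.null(mr)) unname(mr[out$sample_id]) else NA_real_
  grab <- function(v) if (is.null(v)) NA_real_ else unname(v[out$sample_id])
  out$contamination_rate <- grab(contamination_rates)
  out$conversion_rate <- grab(conversion_rates)
  out$pcr_cycles <- grab(pcr_cycles)
  out
}
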