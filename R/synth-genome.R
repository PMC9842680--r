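#' Simulate an annotated genome sequence
#'
#' Generates a random genome with a target GC content, optional CpG-island
#' blocks (300 bp, CpG-enriched), optional planted tandem repeats of a 9-mer,
#' and non-overlapping gene intervals with strand. Islands and repeat runs
#' replace genome sequence and never overlap each other; genes are interval
#' annotations only.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc_content target GC fraction of the background sequence.
#' @param island_count number of 300 bp CpG-island blocks to plant.
#' @param repeat_spec optional `list(motif = <9-mer>, copies = <count>)`;
#'   copies are planted as tandem runs of up to 10 copies each.
#' @param gene_count number of gene intervals to annotate (default one per
#'   10 kb).
#' @param seed integer seed.
#' @return object of class `mc_genome`: list with `seq` (character),
#'   `genes`, `islands`, `repeats` (BED-like data.frames with 0-based
#'   half-open `start`/`end`), and `gc_content`.
#' @export
simulate_genome <- function(length, gc_content = 0.4, island_count = 0L,
                            repeat_spec = NULL,
                            gene_count = length %/% 10000L, seed = 1L) {
  if (length < 1000) stop("genome length must be >= 1000", call. = FALSE)
  if (island_count * 300 > length) {
    stop("infeasible composition: island_count * 300 exceeds genome length",
         call. = FALSE)
  }
  if (!is.null(repeat_spec)) {
    stopifnot(is.list(repeat_spec), nchar(repeat_spec$motif) == 9L,
              repeat_spec$copies >= 1)
    check_dna(repeat_spec$motif, allow_n = FALSE, what = "repeat motif")
  }
  with_seed(seed, {
    p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
           G = gc_content / 2, T = (1 - gc_content) / 2)
    chars <- sample(DNA_BASES, length, replace = TRUE, prob = p)

    occupied <- data.table(start = integer(), end = integer())
    place_block <- function(w) {
      # rejection-sample a non-overlapping placement (0-based half-open)
      for (try in 1:2000) {
        s <- sample.int(length - w + 1L, 1L) - 1L
        if (!nrow(occupied) ||
            all(s + w <= occupied$start | s >= occupied$end)) {
          occupied <<- rbind(occupied, data.table(start = s, end = s + w))
          return(s)
        }
      }
      stop("could not place feature without overlap; genome too crowded",
           call. = FALSE)
    }

    islands <- data.table(chrom = character(), start = integer(),
                          end = integer(), name = character())
    if (island_count > 0) {
      for (i in seq_len(island_count)) {
        s <- place_block(300L)
        # CpG-enriched block: tokens drawn so GC ~ 0.66 and obs/exp high
        tok <- sample(c("CG", "A", "C", "G", "T"), 300,
                      replace = TRUE, prob = c(0.25, 0.14, 0.16, 0.16, 0.14))
        isl <- substr(paste(tok, collapse = ""), 1, 300)
        chars[(s + 1):(s + 300)] <- strsplit(isl, "")[[1]]
        islands <- rbind(islands, data.table(
          chrom = "chr1", start = s, end = s + 300L,
          name = sprintf("island%03d", i)))
      }
    }

    repeats <- data.table(chrom = character(), start = integer(),
                          end = integer(), name = character())
    if (!is.null(repeat_spec)) {
      left <- as.integer(repeat_spec$copies)
      run_id <- 0L
      while (left > 0) {
        nc <- min(10L, left)
        w <- nc * 9L
        s <- place_block(w)
        chars[(s + 1):(s + w)] <-
          strsplit(strrep(repeat_spec$motif, nc), "")[[1]]
        run_id <- run_id + 1L
        repeats <- rbind(repeats, data.table(
          chrom = "chr1", start = s, end = s + w,
          name = sprintf("rep%03d", run_id)))
        left <- left - nc
      }
    }

    genes <- data.table(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        strand = character())
    if (gene_count > 0) {
      gene_len <- min(2000L, max(600L, length %/% (5L * max(gene_count, 1L))))
      slots <- seq(0L, length - gene_len, by = gene_len + 200L)
      take <- sort(sample(seq_along(slots), min(gene_count, length(slots))))
      for (i in seq_along(take)) {
        s <- slots[take[i]]
        genes <- rbind(genes, data.table(
          chrom = "chr1", start = s, end = s + gene_len,
          name = sprintf("gene%04d", i),
          strand = sample(c("+", "-"), 1L)))
      }
    }

    structure(list(
      seq = paste(chars, collapse = ""),
      genes = as.data.frame(genes),
      islands = as.data.frame(islands),
      repeats = as.data.frame(repeats),
      gc_content = gc_content
    ), class = "mc_genome")
  })
}

#' @export
print.mc_genome <- function(x, ...) {
  cat("mc_genome:", nchar(x$seq), "bp,", nrow(x$genes), "genes,",
      nrow(x$islands), "islands,", nrow(x$repeats), "repeat runs\n")
  invisible(x)
}

#' Write a simulated genome as FASTA plus BED annotation files
#'
#' @param genome `mc_genome` object.
#' @param dir output directory (created if absent).
#' @param name chromosome / file stem name.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, dir, name = "chr1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fa"))
  s <- Biostrings::DNAStringSet(setNames(genome$seq, name))
  Biostrings::writeXStringSet(s, fa)
  paths <- fa
  for (el in c("genes", "islands", "repeats")) {
    if (nrow(genome[[el]])) {
      p <- file.path(dir, paste0(name, ".", el, ".bed"))
      write_bed(genome[[el]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
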