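# Amplicon panel handling: BED parsing, near-duplicate merging, read
# assignment by maximum overlap, per-amplicon counting, count-table I/O.
#
# Coordinate convention: BED 0-based half-open throughout; SAM 1-based
# positions are converted on read.

#' Build an amplicon panel from parts
#'
#' Low-level constructor used by [parse_panel()] and the simulator. Sorts by
#' (chrom, start), computes lengths and assigns consecutive ids.
#'
#' @param chrom,start,end,gene,gc vectors of equal length describing each
#'   amplicon; `start`/`end` are 0-based half-open, `gc` a fraction in
#'   `[0, 1]`.
#' @return An `amplicon_panel`: a data.frame with columns `id`, `chrom`,
#'   `start`, `end`, `gene`, `gc`, `length`, sorted by genomic position.
#' @export
amplicon_panel <- function(chrom, start, end, gene, gc = NA_real_) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(gene) == length(chrom))
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("malformed coordinates (start >= end) for amplicon at line ", bad,
         ": ", chrom[bad], ":", start[bad], "-", end[bad])
  }
  gc <- rep_len(as.numeric(gc), length(chrom))
  if (any(!is.na(gc) & (gc < 0 | gc > 1)))
    stop("gc fractions must lie in [0, 1]")
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   gene = as.character(gene), gc = gc,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  df$length <- df$end - df$start
  df <- cbind(id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  class(df) <- c("amplicon_panel", "data.frame")
  df
}

#' Parse an amplicon panel from a BED file
#'
#' Reads a 4+-column BED (`chrom`, `start`, `end`, `name`, ...). The gene
#' symbol is the name field up to the first `_` (so `ERBB2_ex20` maps to
#' `ERBB2`). GC content must come from somewhere: either a numeric BED column
#' (`gc_column`, 1-based index) or a reference FASTA (`reference`) from which
#' per-amplicon GC fractions are computed with Biostrings.
#'
#' @param bed_path path to the panel BED file.
#' @param reference optional path to a reference FASTA (sequence names must
#'   match panel chromosomes).
#' @param gc_column optional 1-based column index holding the GC fraction.
#' @return An [amplicon_panel()].
#' @export
parse_panel <- function(bed_path, reference = NULL, gc_column = NULL) {
  bed <- read.table(bed_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    quote = "")
  if (ncol(bed) < 4)
    stop("panel BED needs at least 4 columns (chrom, start, end, name)")
  gene <- sub("_.*$", "", as.character(bed[[4]]))
  gc <- NULL
  if (!is.null(gc_column)) {
    if (gc_column > ncol(bed)) stop("gc_column ", gc_column, " not present")
    gc <- as.numeric(bed[[gc_column]])
  } else if (!is.null(reference)) {
    gc <- gc_from_fasta(reference, bed[[1]], bed[[2]], bed[[3]])
  } else {
    stop("no GC provenance: supply gc_column or a reference FASTA")
  }
  amplicon_panel(bed[[1]], bed[[2]], bed[[3]], gene, gc)
}

# GC fraction of each [start, end) interval, reference coordinates 0-based.
gc_from_fasta <- function(fasta_path, chrom, start, end) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to compute GC from a reference FASTA")
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  miss <- setdiff(unique(chrom), names(ref))
  if (length(miss))
    stop("reference FASTA lacks sequences: ", paste(miss, collapse = ", "))
  vapply(seq_along(chrom), function(i) {
    s <- Biostrings::subseq(ref[[chrom[i]]], start[i] + 1L, end[i])
    gc <- sum(Biostrings::letterFrequency(s, c("G", "C")))
    acgt <- sum(Biostrings::letterFrequency(s, c("A", "C", "G", "T")))
    if (acgt == 0) return(NA_real_)
    gc / acgt
  }, numeric(1))
}

#' Merge amplicons that reciprocally overlap
#'
#' Two amplicons are merged when their overlap exceeds `min_frac` of BOTH
#' lengths ("overlap each other"). Merging replaces the pair by the union
#' interval (gene symbols concatenated with `,` when they differ, each kept
#' once) and is applied transitively until a fixed point. GC of a merged
#' amplicon is the length-weighted mean of its parts. Ids are re-indexed.
#'
#' @param panel an [amplicon_panel()].
#' @param min_frac reciprocal-overlap fraction above which to merge
#'   (default 0.75).
#' @return A merged `amplicon_panel`.
#' @export
merge_overlapping <- function(panel, min_frac = 0.75) {
  stopifnot(inherits(panel, "amplicon_panel"))
  df <- as.data.frame(panel)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(df)) {
      j <- i + 1L
      # sorted panel: only neighbours can reciprocally overlap this much,
      # but scan forward while starts still precede end of i
      while (j <= nrow(df) && df$chrom[j] == df$chrom[i] &&
             df$start[j] < df$end[i]) {
        ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
        li <- df$end[i] - df$start[i]
        lj <- df$end[j] - df$start[j]
        if (ov > min_frac * li && ov > min_frac * lj) {
          genes <- unique(c(strsplit(df$gene[i], ",")[[1]],
                            strsplit(df$gene[j], ",")[[1]]))
          gc <- if (anyNA(c(df$gc[i], df$gc[j]))) NA_real_ else
            (df$gc[i] * li + df$gc[j] * lj) / (li + lj)
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df$gene[i] <- paste(genes, collapse = ",")
          df$gc[i] <- gc
          df <- df[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  amplicon_panel(df$chrom, df$start, df$end, df$gene, df$gc)
}

#' Gene ranges of a panel
#'
#' @param panel an [amplicon_panel()].
#' @return data.frame with one row per contiguous run of a gene: `gene`,
#'   `chrom`, `first_id`, `last_id`, `n`.
#' @export
gene_ranges <- function(panel) {
  r <- rle(paste(panel$gene, panel$chrom, sep = "\r"))
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.frame(gene = panel$gene[first], chrom = panel$chrom[first],
             first_id = panel$id[first], last_id = panel$id[last],
             n = r$lengths, stringsAsFactors = FALSE)
}

#' Assign one read alignment to an amplicon
#'
#' The read goes to the amplicon with which it shares the largest overlap in
#' bp; ties go to the amplicon with the smaller start (then smaller id).
#' Reads overlapping no amplicon return `NA`.
#'
#' @param chrom,start,end alignment span, 0-based half-open.
#' @param panel an [amplicon_panel()].
#' @return Amplicon id (integer) or `NA_integer_`.
#' @export
assign_read <- function(chrom, start, end, panel) {
  assign_reads(chrom, start, end, panel)
}

#' Vectorised maximum-overlap read assignment
#'
#' @inheritParams assign_read
#' @return Integer vector of amplicon ids (`NA` where no overlap).
#' @export
assign_reads <- function(chrom, start, end, panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  out <- rep(NA_integer_, length(start))
  for (ch in unique(chrom)) {
    pi <- which(panel$chrom == ch)
    ri <- which(chrom == ch)
    if (!length(pi) || !length(ri)) next
    out[ri] <- assign_reads_cpp(as.numeric(start[ri]), as.numeric(end[ri]),
                                as.numeric(panel$start[pi]),
                                as.numeric(panel$end[pi]),
                                as.integer(panel$id[pi]))
  }
  out
}

#' Count reads per amplicon for one sample
#'
#' Each read is assigned to exactly one amplicon (maximum overlap); duplicate
#' reads are deliberately kept, as amplicon libraries are single-ended and
#' ultra-deep. Reads overlapping no amplicon are dropped from counting and
#' tallied in the `n_unassigned` attribute.
#'
#' @param chrom,start,end alignment spans (0-based half-open), e.g. from
#'   [read_sam_alignments()].
#' @param panel an [amplicon_panel()].
#' @return Integer count vector (one entry per amplicon, panel order) with
#'   attributes `n_reads` (input alignments) and `n_unassigned`.
#' @export
count_reads <- function(chrom, start, end, panel) {
  if (length(start) == 0L)
    warning("empty alignment stream: all-zero count column")
  ids <- assign_reads(chrom, start, end, panel)
  counts <- tabulate(ids, nbins = nrow(panel))
  attr(counts, "n_reads") <- length(start)
  attr(counts, "n_unassigned") <- sum(is.na(ids))
  counts
}

#' Read alignment spans from a SAM/BAM file
#'
#' Uses Rsamtools. Unmapped, secondary and supplementary alignments are
#' excluded so each sequenced read is counted at most once; duplicates are
#' kept. Positions are converted to 0-based half-open spans covering the
#' aligned reference footprint.
#'
#' @param path SAM or BAM file.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_sam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM alignments")
  p <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    p <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "qwidth", "cigar"))
  b <- Rsamtools::scanBam(p, param = param)[[1]]
  width <- cigar_ref_width(b$cigar)
  keep <- !is.na(b$pos) & !is.na(width) & width > 0
  data.frame(chrom = as.character(b$rname)[keep],
             start = b$pos[keep] - 1L,
             end = b$pos[keep] - 1L + width[keep],
             stringsAsFactors = FALSE)
}

# reference-consuming width of each CIGAR (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    tok <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", tok))
    op <- sub("^[0-9]+", "", tok)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Assemble a count matrix
#'
#' @param panel an [amplicon_panel()].
#' @param counts matrix (amplicons x samples) of non-negative integers, or a
#'   list of count columns from [count_reads()].
#' @param total_reads per-sample total sequenced reads `N`; defaults to the
#'   column sums (i.e. every read assignable).
#' @return A `count_matrix`: list with `panel`, `counts`, `samples`,
#'   `total_reads`.
#' @export
count_matrix <- function(panel, counts, total_reads = NULL) {
  if (is.list(counts) && !is.matrix(counts))
    counts <- do.call(cbind, counts)
  counts <- as.matrix(counts)
  stopifnot(inherits(panel, "amplicon_panel"), nrow(counts) == nrow(panel))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (is.null(total_reads)) total_reads <- colSums(counts)
  stopifnot(length(total_reads) == ncol(counts),
            all(colSums(counts) <= total_reads + 1e-8))
  structure(list(panel = panel, counts = counts,
                 samples = colnames(counts),
                 total_reads = setNames(as.numeric(total_reads),
                                        colnames(counts)),
                 gender_corrected = FALSE),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "amplicons x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' Write a count table to TSV
#'
#' Columns: `chrom`, `start`, `end`, `gene`, `gc`, `length`, then one integer
#' column per sample. Integer counts round-trip losslessly through
#' [read_count_table()].
#'
#' @param cm a [count_matrix()].
#' @param path output TSV path.
#' @export
write_count_table <- function(cm, path) {
  df <- cbind(cm$panel[, c("chrom", "start", "end", "gene", "gc", "length")],
              as.data.frame(cm$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# total_reads: ",
                    paste(cm$samples, cm$total_reads, sep = "=",
                          collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' Also accepts externally produced tables without the `# total_reads` header
#' (totals then default to column sums).
#'
#' @param path TSV path.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1)
  totals <- NULL
  if (startsWith(first, "# total_reads:")) {
    kv <- strsplit(sub("^# total_reads:\\s*", "", first), "\t")[[1]]
    kv <- strsplit(kv, "=", fixed = TRUE)
    totals <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                       vapply(kv, `[`, "", 1))
  }
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("chrom", "start", "end", "gene", "gc", "length")
  if (!all(meta %in% names(df)))
    stop("count table lacks required columns: ",
         paste(setdiff(meta, names(df)), collapse = ", "))
  panel <- amplicon_panel(df$chrom, df$start, df$end, df$gene, df$gc)
  samp <- setdiff(names(df), meta)
  counts <- as.matrix(df[, samp, drop = FALSE])
  # restore panel sort order for the count rows
  ord <- order(df$chrom, df$start, df$end)
  counts <- counts[ord, , drop = FALSE]
  if (!is.null(totals)) totals <- totals[samp]
  count_matrix(panel, counts, totals)
}
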