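#' Read spliced alignments from SAM text
#'
#' Parses the mandatory SAM columns of a text-format alignment file into a
#' data frame of mapped reads. Header lines (`@`) are skipped. Unmapped
#' records (flag 0x4) are always dropped; secondary (0x100) and
#' supplementary (0x800) alignments are dropped by default because a
#' junction read counted twice through a secondary alignment would inflate
#' the transcript count.
#'
#' @param path Path to a SAM file, or a character vector of SAM lines.
#' @param keep_secondary Keep secondary/supplementary alignments
#'   (default `FALSE`).
#' @return A data frame with columns `read_id`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, one row per retained alignment.
#' @export
parse_sam <- function(path, keep_secondary = FALSE) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  empty <- data.frame(read_id = character(), flag = integer(),
                      chrom = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    stop("malformed SAM record at alignment line ", which(nf < 11)[1],
         ": fewer than 11 fields")
  }
  m <- vapply(fields, function(f) f[1:6], character(6))
  out <- data.frame(read_id = m[1, ],
                    flag = suppressWarnings(as.integer(m[2, ])),
                    chrom = m[3, ],
                    pos = suppressWarnings(as.integer(m[4, ])),
                    mapq = suppressWarnings(as.integer(m[5, ])),
                    cigar = m[6, ],
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$flag) | is.na(out$pos) | out$pos < 0 |
                 is.na(out$mapq))
  if (length(bad) > 0) {
    stop("malformed SAM record at alignment line ", bad[1],
         ": non-numeric flag/pos/mapq")
  }
  mapped <- bitwAnd(out$flag, 4L) == 0L
  out <- out[mapped, , drop = FALSE]
  if (!keep_secondary && nrow(out) > 0) {
    out <- out[bitwAnd(out$flag, 256L) == 0L &
                 bitwAnd(out$flag, 2048L) == 0L, , drop = FALSE]
  }
  if (nrow(out) > 0) {
    cig_bad <- which(out$cigar == "*" |
                       !grepl("^([0-9]+[MIDNSHP=X])+$", out$cigar))
    if (length(cig_bad) > 0) {
      stop("malformed CIGAR '", out$cigar[cig_bad[1]],
           "' for read '", out$read_id[cig_bad[1]], "'")
    }
  }
  rownames(out) <- NULL
  out
}

# Decode one CIGAR into per-op reference intervals.
# Returns data.frame(op, len, ref_start, ref_end); non-reference-consuming
# ops (I, S, H, P) get zero-width intervals at the current position.
cigar_ref_layout <- function(cigar, pos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  consumes <- ops %in% c("M", "D", "N", "=", "X")
  ref_start <- integer(length(ops))
  ref_end <- integer(length(ops))
  cur <- pos
  for (i in seq_along(ops)) {
    if (consumes[i]) {
      ref_start[i] <- cur
      ref_end[i] <- cur + lens[i] - 1L
      cur <- cur + lens[i]
    } else {
      ref_start[i] <- cur
      ref_end[i] <- cur - 1L
    }
  }
  data.frame(op = ops, len = lens, ref_start = ref_start,
             ref_end = ref_end, stringsAsFactors = FALSE)
}

# Length of the contiguous aligned (M/=/X) reference stretch adjacent to
# op index `i`, scanning in `dir` (-1 left, +1 right). Insertions and
# padding do not consume reference and do not break the stretch;
# deletions, clips and further skips end it.
flank_anchor <- function(layout, i, dir) {
  anchor <- 0L
  j <- i + dir
  while (j >= 1 && j <= nrow(layout)) {
    op <- layout$op[j]
    if (op %in% c("M", "=", "X")) {
      anchor <- anchor + layout$len[j]
    } else if (!(op %in% c("I", "P"))) {
      break
    }
    j <- j + dir
  }
  anchor
}

#' Does one spliced alignment span a junction signature?
#'
#' `TRUE` iff the alignment contains a splice (`N`) whose skipped
#' reference interval is exactly `[donor_end + 1, acceptor_start - 1]`
#' (optionally within `tolerance` bases of each boundary) and the aligned
#' reference coverage immediately flanking that skip is at least
#' `min_overhang` bases on both sides. Exact boundary matching is the
#' default because junction identity -- not mere overlap -- is what makes
#' the assay transcript-specific.
#'
#' @param read A single-row data frame as returned by [parse_sam()] (or a
#'   list with `chrom`, `pos`, `cigar`).
#' @param sig A single-row signature data frame (see [build_toy_ar_model()]).
#' @param min_overhang Minimum aligned bases required on each side of the
#'   splice (default 6).
#' @param tolerance Allowed slack, in bases, on each skip boundary
#'   (default 0 = exact).
#' @return Logical scalar.
#' @export
read_spans_junction <- function(read, sig, min_overhang = 6L,
                                tolerance = 0L) {
  stopifnot(min_overhang >= 1)
  if (read$chrom != sig$chrom) return(FALSE)
  layout <- cigar_ref_layout(read$cigar, read$pos)
  n_idx <- which(layout$op == "N")
  if (length(n_idx) == 0) return(FALSE)
  want_start <- sig$donor_end + 1L
  want_end <- sig$acceptor_start - 1L
  for (i in n_idx) {
    if (abs(layout$ref_start[i] - want_start) <= tolerance &&
        abs(layout$ref_end[i] - want_end) <= tolerance) {
      if (flank_anchor(layout, i, -1L) >= min_overhang &&
          flank_anchor(layout, i, +1L) >= min_overhang) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Count junction-spanning reads per transcript signature
#'
#' Screens every alignment against every signature in the model and
#' returns one row per transcript with the number of spanning reads and a
#' positivity call. Because signatures are unique (enforced before
#' counting), a read is assigned to at most one transcript.
#'
#' Positivity follows the presence/absence convention used for reporting
#' transcript-positive samples: a sample is positive when at least
#' `positivity_threshold` junction reads are observed (default 1).
#'
#' @param reads Data frame from [parse_sam()].
#' @param model An `ar_model`.
#' @param min_overhang Minimum anchor on each side of the splice
#'   (default 6).
#' @param positivity_threshold Spanning reads needed to call a transcript
#'   positive (default 1).
#' @param tolerance Boundary slack in bases (default 0).
#' @param min_mapq Drop alignments below this mapping quality (default 0,
#'   i.e. keep all).
#' @return A data frame with columns `transcript_id`, `spanning_reads`,
#'   `total_reads_screened`, `positive`.
#' @export
count_junction_reads <- function(reads, model, min_overhang = 6L,
                                 positivity_threshold = 1L,
                                 tolerance = 0L, min_mapq = 0L) {
  stopifnot(inherits(model, "ar_model"))
  stop_on_collision(model)
  sig <- model$signatures
  if (min_mapq > 0 && nrow(reads) > 0) {
    reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  }
  n_total <- nrow(reads)
  counts <- integer(nrow(sig))
  if (n_total > 0 && nrow(sig) > 0) {
    for (r in seq_len(n_total)) {
      read <- reads[r, ]
      for (s in seq_len(nrow(sig))) {
        if (read_spans_junction(read, sig[s, ], min_overhang, tolerance)) {
          counts[s] <- counts[s] + 1L
          break  # unique signatures: one read, at most one transcript
        }
      }
    }
  }
  data.frame(transcript_id = sig$transcript_id,
             spanning_reads = counts,
             total_reads_screened = n_total,
             positive = counts >= positivity_threshold,
             stringsAsFactors = FALSE)
}

#' Write junction counts as TSV and JSON
#'
#' @param counts Data frame from [count_junction_reads()].
#' @param tsv,json Output paths; either may be `NULL` to skip.
#' @return `counts`, invisibly.
#' @export
write_junction_counts <- function(counts, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(counts, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(counts, json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(counts)
}
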