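#' Transcript models for AR splice-variant junction detection
#'
#' An `ar_model` holds the exon structure of the androgen receptor (AR)
#' transcripts of interest and, for each transcript, the single exon-exon
#' junction whose splice uniquely discriminates it from all other isoforms:
#'
#' * **AR-FL** (full length): exon 7 spliced to exon 8;
#' * **AR-V7**: exon 3 spliced to cryptic exon 3 (CE3), a cryptic exon in
#'   intron 3 that carries a premature stop;
#' * **AR-v567es**: exon 4 spliced directly to exon 8 (exons 5-7 skipped).
#'
#' A junction signature is the pair (last base of donor exon, first base of
#' acceptor exon) in 1-based reference coordinates. A spliced read supports
#' a transcript only when its skip bridges exactly that pair; uniqueness of
#' the pairs across the model is what makes read assignment unambiguous.
#'
#' @name ar_model
#' @seealso [build_toy_ar_model()], [load_model()], [validate_signatures()]
NULL

.MODEL_COLS <- c("transcript_id", "donor_exon", "acceptor_exon",
                 "donor_end", "acceptor_start", "chrom", "strand")

new_ar_model <- function(exons, signatures) {
  stopifnot(is.data.frame(exons), is.data.frame(signatures))
  structure(list(exons = exons, signatures = signatures),
            class = "ar_model")
}

#' Build the shipped toy AR transcript model
#'
#' Returns a self-consistent model on a single synthetic contig
#' (`chrT_AR`, "+" strand) with exons E1-E8 and cryptic exon CE3 laid out
#' at documented toy coordinates (each exon 100 bp starting at 101, 301,
#' 501, ...; CE3 occupies 701-800 inside intron 3). The genomic
#' coordinates of the real AR locus are not part of the model; supply them
#' through [load_model()] with an hg38 junction table when analysing real
#' alignments.
#'
#' @return An `ar_model` with 9 exons and the three discriminating
#'   signatures: AR-FL E7->E8, AR-V7 E3->CE3, AR-v567es E4->E8.
#' @examples
#' model <- build_toy_ar_model()
#' model$signatures
#' @export
build_toy_ar_model <- function() {
  ids <- c("E1", "E2", "E3", "CE3", "E4", "E5", "E6", "E7", "E8")
  starts <- c(101, 301, 501, 701, 901, 1101, 1301, 1501, 1701)
  exons <- data.frame(
    exon_id = ids,
    chrom = "chrT_AR",
    start = starts,
    end = starts + 99,
    strand = "+",
    stringsAsFactors = FALSE
  )
  sig <- function(tx, donor, acceptor) {
    de <- exons[exons$exon_id == donor, ]
    ae <- exons[exons$exon_id == acceptor, ]
    data.frame(transcript_id = tx, donor_exon = donor,
               acceptor_exon = acceptor, donor_end = de$end,
               acceptor_start = ae$start, chrom = de$chrom,
               strand = de$strand, stringsAsFactors = FALSE)
  }
  signatures <- rbind(
    sig("AR-FL", "E7", "E8"),
    sig("AR-V7", "E3", "CE3"),
    sig("AR-v567es", "E4", "E8")
  )
  model <- new_ar_model(exons, signatures)
  stop_on_collision(model)
  model
}

#' Load a transcript model from a junction-definition table
#'
#' Reads a tab-separated table with one header line and columns
#' `transcript_id`, `donor_exon`, `acceptor_exon`, `donor_end`,
#' `acceptor_start`, `chrom`, `strand`. This is how real (e.g. hg38) AR
#' junction coordinates enter the pipeline. Exon records are synthesised
#' from the junction boundaries: only the boundary coordinates matter for
#' junction counting.
#'
#' Rows on the "-" strand with `donor_end > acceptor_start` are
#' normalised at load so the skipped interval is always expressed
#' left-to-right in reference coordinates; counting then works identically
#' on either strand.
#'
#' @param path Path to the junction-definition file.
#' @return An `ar_model`.
#' @export
load_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(.MODEL_COLS, names(tab))
  if (length(missing_cols) > 0) {
    stop("junction-definition file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    warning("junction-definition file '", path,
            "' defines no signatures")
    empty <- data.frame(transcript_id = character(), donor_exon = character(),
                        acceptor_exon = character(), donor_end = integer(),
                        acceptor_start = integer(), chrom = character(),
                        strand = character(), stringsAsFactors = FALSE)
    exon0 <- data.frame(exon_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    return(new_ar_model(exon0, empty))
  }
  de <- suppressWarnings(as.integer(tab$donor_end))
  as_ <- suppressWarnings(as.integer(tab$acceptor_start))
  bad <- which(is.na(de) | is.na(as_) | de < 1 | as_ < 1 |
                 !(tab$strand %in% c("+", "-")))
  if (length(bad) > 0) {
    stop("malformed junction-definition row at line ", bad[1] + 1L,
         " of '", path, "'")
  }
  tab$donor_end <- de
  tab$acceptor_start <- as_
  # normalise "-"-strand rows to the canonical left-to-right orientation
  flip <- tab$strand == "-" & tab$donor_end > tab$acceptor_start
  if (any(flip)) {
    tmp_e <- tab$donor_exon[flip]; tmp_c <- tab$donor_end[flip]
    tab$donor_exon[flip] <- tab$acceptor_exon[flip]
    tab$donor_end[flip] <- tab$acceptor_start[flip]
    tab$acceptor_exon[flip] <- tmp_e
    tab$acceptor_start[flip] <- tmp_c
  }
  if (any(tab$donor_end >= tab$acceptor_start)) {
    i <- which(tab$donor_end >= tab$acceptor_start)[1]
    stop("malformed junction-definition row at line ", i + 1L,
         ": donor_end must be < acceptor_start after orientation")
  }
  exon_ids <- unique(c(tab$donor_exon, tab$acceptor_exon))
  # exon stubs anchored at junction boundaries; widths are not used
  exons <- data.frame(exon_id = exon_ids, chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    d <- match(tab$donor_exon[i], exons$exon_id)
    a <- match(tab$acceptor_exon[i], exons$exon_id)
    exons$chrom[c(d, a)] <- tab$chrom[i]
    exons$strand[c(d, a)] <- tab$strand[i]
    exons$end[d] <- tab$donor_end[i]
    exons$start[a] <- tab$acceptor_start[i]
  }
  exons$start[is.na(exons$start)] <- 1L
  exons$end[is.na(exons$end)] <- pmax(exons$start[is.na(exons$end)], 1L)
  model <- new_ar_model(exons, tab[, .MODEL_COLS])
  stop_on_collision(model)
  model
}

#' Write a model's junction definitions to a tab-separated file
#'
#' @param model An `ar_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ar_model"))
  utils::write.table(model$signatures[, .MODEL_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that every junction signature is unique
#'
#' Two transcripts that share a junction (the AR-V7 / AR-V9 situation,
#' where both variants end in highly similar cryptic-exon sequence) cannot
#' be told apart by junction-spanning reads. This reports every pair of
#' signatures with identical `(chrom, donor_end, acceptor_start)`
#' coordinates; an empty report means every signature uniquely identifies
#' its transcript.
#'
#' @param model An `ar_model`.
#' @return A data frame with one row per colliding pair (columns
#'   `transcript_a`, `transcript_b`, `chrom`, `donor_end`,
#'   `acceptor_start`); zero rows when the model is collision-free.
#' @export
validate_signatures <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  sig <- model$signatures
  out <- data.frame(transcript_a = character(), transcript_b = character(),
                    chrom = character(), donor_end = integer(),
                    acceptor_start = integer(), stringsAsFactors = FALSE)
  if (nrow(sig) < 2) return(out)
  key <- paste(sig$chrom, sig$donor_end, sig$acceptor_start)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    pairs <- utils::combn(idx, 2)
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      out <- rbind(out, data.frame(
        transcript_a = sig$transcript_id[i1],
        transcript_b = sig$transcript_id[i2],
        chrom = sig$chrom[i1], donor_end = sig$donor_end[i1],
        acceptor_start = sig$acceptor_start[i1],
        stringsAsFactors = FALSE))
    }
  }
  out
}

stop_on_collision <- function(model) {
  rep <- validate_signatures(model)
  if (nrow(rep) > 0) {
    stop("signature collision: transcripts ",
         paste(unique(c(rep$transcript_a, rep$transcript_b)),
               collapse = ", "),
         " share junction coordinates and cannot be discriminated")
  }
  invisible(model)
}

#' @export
print.ar_model <- function(x, ...) {
  cat("AR transcript model:", nrow(x$exons), "exon(s),",
      nrow(x$signatures), "junction signature(s)\n")
  if (nrow(x$signatures) > 0) {
    print(x$signatures[, c("transcript_id", "donor_exon", "acceptor_exon",
                           "donor_end", "acceptor_start")],
          row.names = FALSE)
  }
  invisible(x)
}
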