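#' Cohort analytics for per-patient transcript quantifications
#'
#' A cohort is a long-format table with one row per (subject, transcript)
#' measurement and columns `subject_id`, `disease_group` (benign /
#' primary / mCRPC / NEPC), `unit` (bulk_CTC / CTC_pool / single_CTC),
#' `epcam_status` (pos / neg / NA) and `copies` (copies/sample;
#' nonnegative, `NA` when the measurement is missing). These tables are
#' produced either by the ddPCR quantification chain or by
#' [simulate_cohort()].
#'
#' @name cohort
NULL

.TRANSCRIPTS <- c("AR-FL", "AR-V7", "AR-v567es")

#' Read a cohort table
#'
#' Comma-separated, columns `subject_id`, `disease_group`, `unit`,
#' `epcam_status`, `transcript`, `copies`.
#'
#' @param path CSV path.
#' @return Data frame of records.
#' @export
read_cohort_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  need <- c("subject_id", "transcript", "copies")
  if (!all(need %in% names(d))) {
    stop("cohort table must have columns ", paste(need, collapse = ", "))
  }
  d$copies <- as.numeric(d$copies)
  if (any(d$copies < 0, na.rm = TRUE)) stop("copies must be nonnegative")
  d
}

#' Call a sample positive for a transcript
#'
#' Positive means detected signal above `threshold_copies` copies/sample.
#' The default threshold of 0 treats any detected signal as positive (the
#' presence/absence convention of a detection heatmap where white means
#' not detected). A missing measurement is never positive and is logged.
#'
#' @param copies Numeric vector of copies/sample (`NA` = missing).
#' @param threshold_copies Nonnegative detection threshold (default 0).
#' @return Logical vector.
#' @export
call_positive <- function(copies, threshold_copies = 0) {
  if (threshold_copies < 0) stop("threshold_copies must be >= 0")
  copies <- as.numeric(copies)
  if (anyNA(copies)) {
    message(sum(is.na(copies)),
            " missing measurement(s) treated as not detected")
  }
  !is.na(copies) & copies > threshold_copies
}

#' Per-transcript cohort summary (prevalence, central tendency, range)
#'
#' For each transcript: number and percentage of positive subjects, and
#' the median, mean and range of copies/sample computed over **all**
#' records including the zeros of negative subjects -- the convention of a
#' cohort table whose ranges start at 0. Missing measurements count in
#' the denominator and enter the summary statistics as 0 (not detected).
#' Prevalence is reported rounded to an integer percent but also returned
#' at full precision.
#'
#' @param records Cohort data frame (see [read_cohort_table()]).
#' @param threshold_copies Positivity threshold (default 0).
#' @return A data frame with one row per transcript: `transcript_id`,
#'   `n_positive`, `n_total`, `prevalence_percent` (integer-rounded),
#'   `prevalence_exact`, `median`, `mean`, `min`, `max`.
#' @export
summarize_cohort <- function(records, threshold_copies = 0) {
  if (nrow(records) == 0) stop("empty cohort")
  txs <- unique(records$transcript)
  rows <- lapply(txs, function(tx) {
    v <- records$copies[records$transcript == tx]
    pos <- suppressMessages(call_positive(v, threshold_copies))
    v0 <- ifelse(is.na(v), 0, v)
    prev <- 100 * sum(pos) / length(v)
    data.frame(transcript_id = tx, n_positive = sum(pos),
               n_total = length(v),
               prevalence_percent = round(prev),
               prevalence_exact = prev,
               median = stats::median(v0), mean = mean(v0),
               min = min(v0), max = max(v0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare transcript prevalence between EpCAM-positive and -negative
#' CTC fractions
#'
#' For each transcript, computes the positivity prevalence in the
#' EpCAM-positive and EpCAM-negative fractions and a two-tailed Fisher
#' exact p-value on the resulting 2x2 table. This quantifies whether
#' EpCAM-based CTC capture under-samples variant-expressing cells.
#'
#' @param records Cohort data frame with `epcam_status` in
#'   `{"pos", "neg"}`.
#' @param threshold_copies Positivity threshold (default 0).
#' @return Data frame with one row per transcript: positive counts and
#'   totals per fraction, prevalence percentages, and `fisher_p`.
#' @export
compare_epcam_fractions <- function(records, threshold_copies = 0) {
  pos_frac <- records[records$epcam_status %in% "pos", , drop = FALSE]
  neg_frac <- records[records$epcam_status %in% "neg", , drop = FALSE]
  if (nrow(pos_frac) == 0 || nrow(neg_frac) == 0) {
    stop("need records in both the EpCAM-positive and -negative fractions")
  }
  txs <- unique(records$transcript)
  rows <- lapply(txs, function(tx) {
    vp <- pos_frac$copies[pos_frac$transcript == tx]
    vn <- neg_frac$copies[neg_frac$transcript == tx]
    kp <- sum(suppressMessages(call_positive(vp, threshold_copies)))
    kn <- sum(suppressMessages(call_positive(vn, threshold_copies)))
    tab <- rbind(c(kp, length(vp) - kp), c(kn, length(vn) - kn))
    data.frame(transcript_id = tx,
               epcam_pos_positive = kp, epcam_pos_total = length(vp),
               epcam_pos_prevalence = 100 * kp / length(vp),
               epcam_neg_positive = kn, epcam_neg_total = length(vn),
               epcam_neg_prevalence = 100 * kn / length(vn),
               fisher_p = fisher_exact_two_tailed(tab)$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subjects-by-transcripts expression matrix
#'
#' Pivots a cohort table to a numeric matrix (rows: subjects sorted by
#' id; columns: transcripts) of copies/sample, with `NA` marking a
#' missing (never-measured) cell -- distinct from a true measured zero.
#' Suitable for heatmap rendering or export.
#'
#' @param records Cohort data frame.
#' @param transcripts Column order; defaults to the AR transcript trio
#'   when present, otherwise the transcripts observed.
#' @return Numeric matrix with subject ids as rownames.
#' @export
heatmap_matrix <- function(records,
                           transcripts = NULL) {
  if (nrow(records) == 0) stop("empty cohort")
  if (is.null(transcripts)) {
    seen <- unique(records$transcript)
    transcripts <- if (all(seen %in% .TRANSCRIPTS)) {
      .TRANSCRIPTS[.TRANSCRIPTS %in% seen]
    } else sort(seen)
  }
  subjects <- sort(unique(records$subject_id))
  m <- matrix(NA_real_, nrow = length(subjects),
              ncol = length(transcripts),
              dimnames = list(subjects, transcripts))
  for (i in seq_len(nrow(records))) {
    s <- records$subject_id[i]; tx <- records$transcript[i]
    if (tx %in% transcripts) m[s, tx] <- records$copies[i]
  }
  m
}

#' Export / import a heatmap matrix
#'
#' Tab-separated with the sentinel `ND` for not-detected/missing cells so
#' a round trip preserves the distinction from measured zeros.
#'
#' @param m Matrix from [heatmap_matrix()].
#' @param path Output (or input) path.
#' @return `path` invisibly; `read_heatmap_matrix` returns the matrix.
#' @export
write_heatmap_matrix <- function(m, path) {
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "ND")
  invisible(path)
}

#' @rdname write_heatmap_matrix
#' @export
read_heatmap_matrix <- function(path) {
  df <- utils::read.delim(path, na.strings = "ND", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  storage.mode(m) <- "double"
  m
}
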