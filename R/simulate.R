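#' Synthetic data generators
#'
#' Every analysis stage of the package can be exercised without external
#' data: droplet tables with known template labels, spliced SAM reads
#' over the toy AR model with known junction counts, and patient cohorts
#' with known per-transcript prevalence. All generators take an explicit
#' `seed` and are bit-reproducible under it.
#'
#' @name simulate
NULL

#' Simulate a well of ddPCR droplets
#'
#' Template molecules are loaded into droplets as Poisson(`lambda_true`);
#' droplets carrying at least one template fluoresce around `mu_pos`,
#' empty droplets around `mu_neg`, both with Gaussian noise `sigma`. An
#' optional `rain_fraction` of droplets is given an amplitude uniform
#' between the two modes, mimicking partial-amplification "rain" -- the
#' simplest adversarial case for a threshold, with no claim to match
#' instrument physics.
#'
#' @param lambda_true Mean template copies per droplet (>= 0).
#' @param n_droplets Number of droplets (default 15000, a typical
#'   accepted-droplet count).
#' @param mu_neg,mu_pos,sigma Amplitude distribution parameters (defaults
#'   1000 / 8000 / 300, arbitrary fluorescence units).
#' @param rain_fraction Fraction of droplets re-drawn as rain, in
#'   `[0, 0.2)` (default 0).
#' @param seed Integer seed (required).
#' @param well_id,channel Labels for the emitted droplet table.
#' @return A list: `droplets` (data frame `well_id`, `channel`,
#'   `amplitude`) and `truth` (data frame with per-droplet template
#'   `count`, `template` flag, `is_rain`).
#' @export
simulate_droplets <- function(lambda_true, n_droplets = 15000L,
                              mu_neg = 1000, mu_pos = 8000, sigma = 300,
                              rain_fraction = 0, seed,
                              well_id = "A01", channel = "FAM") {
  if (lambda_true < 0) stop("lambda_true must be >= 0")
  if (n_droplets < 1) stop("need at least one droplet")
  if (mu_neg >= mu_pos) stop("mu_neg must be below mu_pos")
  if (rain_fraction < 0 || rain_fraction >= 0.2) {
    stop("rain_fraction must be in [0, 0.2)")
  }
  set.seed(seed)
  count <- stats::rpois(n_droplets, lambda_true)
  template <- count >= 1
  amplitude <- ifelse(template,
                      stats::rnorm(n_droplets, mu_pos, sigma),
                      stats::rnorm(n_droplets, mu_neg, sigma))
  is_rain <- rep(FALSE, n_droplets)
  if (rain_fraction > 0) {
    n_rain <- round(rain_fraction * n_droplets)
    if (n_rain > 0) {
      idx <- sample.int(n_droplets, n_rain)
      is_rain[idx] <- TRUE
      amplitude[idx] <- stats::runif(n_rain, mu_neg, mu_pos)
    }
  }
  list(droplets = data.frame(well_id = well_id, channel = channel,
                             amplitude = amplitude,
                             stringsAsFactors = FALSE),
       truth = data.frame(count = count, template = template,
                          is_rain = is_rain))
}

#' Simulate spliced SAM reads over a transcript model
#'
#' For each requested junction read, emits a SAM record whose CIGAR is
#' `aMkNbM`: `a` and `b` aligned anchor bases drawn uniformly from
#' `anchor_range`, and `k` exactly the signature's skipped-intron length,
#' so the read bridges the junction precisely. Unspliced background reads
#' (`read_len` aligned bases at random positions) are added on top. Base
#' sequences are a fixed repeating pattern: junction counting never
#' inspects bases.
#'
#' @param model An `ar_model` (toy coordinates from
#'   [build_toy_ar_model()] unless loaded).
#' @param mixture Named integer vector: junction reads to emit per
#'   transcript (names must be transcript ids of the model). May be
#'   empty.
#' @param read_len Length of background reads (>= 2; default 60).
#' @param anchor_range Integer range `c(lo, hi)` for each junction-read
#'   anchor (default `c(6, 30)`).
#' @param n_background Number of unspliced background reads (default 0).
#' @param seed Integer seed (required).
#' @return A list: `sam` (character vector of SAM lines incl. header),
#'   `truth` (named integer vector of emitted junction reads per
#'   transcript).
#' @export
simulate_spliced_reads <- function(model, mixture = integer(),
                                   read_len = 60L,
                                   anchor_range = c(6L, 30L),
                                   n_background = 0L, seed) {
  stopifnot(inherits(model, "ar_model"))
  if (read_len < 2) stop("read_len must be >= 2")
  mixture <- mixture[mixture > 0]
  unknown <- setdiff(names(mixture), model$signatures$transcript_id)
  if (length(unknown) > 0) {
    stop("mixture names not in model: ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  chrom <- if (nrow(model$exons) > 0) model$exons$chrom[1] else "chrT_AR"
  contig_len <- max(c(model$exons$end, model$signatures$acceptor_start,
                      1000L)) + read_len + 100L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, contig_len))
  pattern <- function(len) {
    paste(rep_len(c("A", "C", "G", "T"), len), collapse = "")
  }
  records <- character()
  truth <- stats::setNames(integer(nrow(model$signatures)),
                           model$signatures$transcript_id)
  ri <- 0L
  for (tx in names(mixture)) {
    sig <- model$signatures[model$signatures$transcript_id == tx, ]
    k <- sig$acceptor_start - sig$donor_end - 1L
    for (j in seq_len(mixture[[tx]])) {
      a <- sample(anchor_range[1]:anchor_range[2], 1L)
      b <- sample(anchor_range[1]:anchor_range[2], 1L)
      pos <- sig$donor_end - a + 1L
      cigar <- sprintf("%dM%dN%dM", a, k, b)
      ri <- ri + 1L
      records <- c(records, paste(
        sprintf("jr%04d", ri), 0L, chrom, pos, 60L, cigar, "*", 0L, 0L,
        pattern(a + b), strrep("I", a + b), sep = "\t"))
      truth[tx] <- truth[tx] + 1L
    }
  }
  if (n_background > 0) {
    for (j in seq_len(n_background)) {
      pos <- sample.int(contig_len - read_len, 1L)
      ri <- ri + 1L
      records <- c(records, paste(
        sprintf("bg%04d", ri), 0L, chrom, pos, 60L,
        sprintf("%dM", read_len), "*", 0L, 0L,
        pattern(read_len), strrep("I", read_len), sep = "\t"))
    }
  }
  list(sam = c(header, records), truth = truth)
}

#' Simulate a patient cohort with known transcript prevalence
#'
#' Each subject is positive for each transcript independently with the
#' configured prevalence; positive subjects draw copies/sample from a
#' log-normal distribution (heavy-tailed, matching the orders-of-magnitude
#' spread seen in CTC transcript measurements), negatives are exactly 0.
#'
#' Default prevalences (90% / 66% / 52% for AR-FL / AR-V7 / AR-v567es
#' over 29 subjects) and expression scales reflect a metastatic
#' castration-resistant prostate cancer CTC cohort.
#'
#' @param n_subjects Number of subjects (default 29).
#' @param prevalence Named vector of per-transcript positivity
#'   probabilities in `[0, 1]`.
#' @param meanlog,sdlog Log-normal parameters for positive copies; scalar
#'   or named per transcript.
#' @param disease_group,unit,epcam_status Labels stamped on every record.
#' @param seed Integer seed (required).
#' @return A list: `records` (long cohort data frame) and `truth`
#'   (data frame of configured prevalence and realised positive counts
#'   per transcript).
#' @export
simulate_cohort <- function(n_subjects = 29L,
                            prevalence = c("AR-FL" = 0.90,
                                           "AR-V7" = 0.66,
                                           "AR-v567es" = 0.52),
                            meanlog = log(c("AR-FL" = 15,
                                            "AR-V7" = 2.5,
                                            "AR-v567es" = 0.4)),
                            sdlog = 1.2,
                            disease_group = "mCRPC", unit = "bulk_CTC",
                            epcam_status = NA_character_, seed) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalence values must be in [0, 1]")
  }
  set.seed(seed)
  txs <- names(prevalence)
  ml <- if (length(meanlog) == 1) stats::setNames(rep(meanlog, length(txs)), txs)
        else meanlog[txs]
  sl <- if (length(sdlog) == 1) stats::setNames(rep(sdlog, length(txs)), txs)
        else sdlog[txs]
  subj <- sprintf("S%03d", seq_len(n_subjects))
  rows <- list()
  realised <- stats::setNames(integer(length(txs)), txs)
  for (tx in txs) {
    pos <- stats::runif(n_subjects) < prevalence[[tx]]
    copies <- numeric(n_subjects)
    if (any(pos)) {
      copies[pos] <- stats::rlnorm(sum(pos), ml[[tx]], sl[[tx]])
    }
    realised[tx] <- sum(pos)
    rows[[tx]] <- data.frame(subject_id = subj,
                             disease_group = disease_group, unit = unit,
                             epcam_status = epcam_status, transcript = tx,
                             copies = copies, stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = data.frame(transcript_id = txs,
                          prevalence_true = unname(prevalence),
                          n_positive = unname(realised),
                          n_subjects = n_subjects,
                          stringsAsFactors = FALSE))
}
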