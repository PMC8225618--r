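#' Droplet digital PCR absolute quantification
#'
#' In droplet digital PCR (ddPCR) a reaction is partitioned into tens of
#' thousands of nanolitre droplets. Template molecules distribute across
#' droplets approximately Poisson, so after end-point PCR the fraction of
#' fluorescence-positive droplets determines the mean template occupancy
#' \eqn{\hat\lambda = -\ln(1 - n_{pos}/n_{total})} and hence the absolute
#' concentration of the target, with no standard curve.
#'
#' @name ddpcr
#' @seealso [classify_droplets()], [poisson_concentration()],
#'   [copies_per_sample()], [replicate_cv()], [apply_plate_controls()]
NULL

#' Split droplet amplitudes into positive and negative clusters
#'
#' With a numeric `threshold`, droplets with amplitude strictly above it
#' are positive. With `threshold = "auto"`, the amplitudes are split into
#' the two-class partition that minimises total within-class variance
#' (found exactly by scanning every split point of the sorted amplitudes)
#' and the threshold is placed at the midpoint of the two class means --
#' a deterministic stand-in for the instrument software's per-well
#' thresholding, which is not published.
#'
#' @param amplitudes Numeric vector of droplet fluorescence amplitudes.
#' @param threshold Numeric amplitude cutoff, or `"auto"`.
#' @return A list with `n_pos`, `n_neg`, `n_total` and the `threshold`
#'   used.
#' @examples
#' classify_droplets(c(100, 200, 5000, 6000), threshold = 1000)
#' @export
classify_droplets <- function(amplitudes, threshold = "auto") {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) == 0) stop("no droplets to classify")
  if (any(!is.finite(amplitudes))) stop("non-finite droplet amplitude")
  if (identical(threshold, "auto")) {
    threshold <- auto_threshold(amplitudes)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  n_pos <- sum(amplitudes > threshold)
  list(n_pos = n_pos, n_neg = length(amplitudes) - n_pos,
       n_total = length(amplitudes), threshold = threshold)
}

# Exact two-class 1-D split minimising within-class variance; the
# threshold is the midpoint of the two class means. Degenerate inputs
# (constant amplitudes) put every droplet in the negative class.
auto_threshold <- function(amplitudes) {
  x <- sort(amplitudes)
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(x[n])
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  # within-class sum of squares for split after position k
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  k_best <- which.min(ss_lo + ss_hi)
  mu_lo <- cs[k_best] / k_best
  mu_hi <- (cs[n] - cs[k_best]) / (n - k_best)
  (mu_lo + mu_hi) / 2
}

#' Poisson estimate of target concentration from droplet counts
#'
#' Converts positive/total droplet counts to mean copies per droplet,
#' \eqn{\hat\lambda = -\ln(1 - n_{pos}/n_{total})}, and to copies per
#' microlitre of reaction given the droplet volume. When every droplet is
#' positive the estimate diverges; the well is flagged `SATURATED` and
#' `lambda_hat` is `Inf`. Wells with fewer accepted droplets than
#' `min_droplets` are flagged `LOW_DROPLETS` but still estimated.
#'
#' @param n_pos,n_total Positive and total droplet counts.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85,
#'   the QX200 nominal partition volume).
#' @param min_droplets Accepted-droplet QC floor (default 10000).
#' @return A list with `lambda_hat`, `conc_per_ul` (copies/uL of
#'   reaction), and `flags` (character vector, possibly empty).
#' @examples
#' poisson_concentration(5000, 20000)
#' @export
poisson_concentration <- function(n_pos, n_total, droplet_volume_nl = 0.85,
                                  min_droplets = 10000L) {
  if (n_pos < 0 || n_total < 1 || n_pos > n_total) {
    stop("need 0 <= n_pos <= n_total with n_total >= 1")
  }
  if (droplet_volume_nl <= 0) stop("droplet volume must be positive")
  flags <- character()
  if (n_total < min_droplets) flags <- c(flags, "LOW_DROPLETS")
  if (n_pos == n_total) {
    return(list(lambda_hat = Inf, conc_per_ul = Inf,
                flags = c(flags, "SATURATED")))
  }
  lambda_hat <- -log(1 - n_pos / n_total)
  conc_per_ul <- lambda_hat * 1000 / droplet_volume_nl
  list(lambda_hat = lambda_hat, conc_per_ul = conc_per_ul, flags = flags)
}

#' Scale a concentration to copies per reaction and per sample
#'
#' `copies_per_reaction = conc_per_ul * reaction_volume_ul`;
#' `copies_per_sample = copies_per_reaction / sample_fraction_loaded`,
#' where `sample_fraction_loaded` is the fraction of the extracted sample
#' that entered the reaction (1 when the whole sample was loaded). The
#' default reaction volume of 22 uL matches a one-step RT-ddPCR set-up
#' loading 11 uL of sample RNA into a 22 uL reaction.
#'
#' @param conc_per_ul Copies per microlitre of reaction.
#' @param reaction_volume_ul Reaction volume in microlitres (default 22).
#' @param sample_fraction_loaded Fraction of the sample loaded, in (0, 1]
#'   (default 1).
#' @param normalizer Optional positive divisor applied to
#'   `copies_per_sample` (e.g. number of CTCs in a pool, or nanograms of
#'   input RNA) for per-cell or per-ng reporting. Default 1 (none).
#' @return A list with `copies_per_reaction` and `copies_per_sample`.
#' @export
copies_per_sample <- function(conc_per_ul, reaction_volume_ul = 22,
                              sample_fraction_loaded = 1,
                              normalizer = 1) {
  if (reaction_volume_ul <= 0) stop("reaction volume must be positive")
  if (sample_fraction_loaded <= 0 || sample_fraction_loaded > 1) {
    stop("sample_fraction_loaded must be in (0, 1]")
  }
  if (normalizer <= 0) stop("normalizer must be positive")
  per_reaction <- conc_per_ul * reaction_volume_ul
  list(copies_per_reaction = per_reaction,
       copies_per_sample = per_reaction / sample_fraction_loaded /
         normalizer)
}

#' Quantify every well of a droplet table
#'
#' Groups a droplet table (columns `well_id`, `channel`, `amplitude`) by
#' well, classifies droplets, and derives the full chain of estimates
#' per well.
#'
#' @param droplets Data frame with columns `well_id`, `channel`,
#'   `amplitude`.
#' @param threshold Amplitude cutoff or `"auto"` (per well).
#' @param droplet_volume_nl,reaction_volume_ul,sample_fraction_loaded
#'   See [poisson_concentration()] and [copies_per_sample()].
#' @param min_droplets Accepted-droplet QC floor per well.
#' @return A data frame with one row per (well, channel): counts,
#'   `lambda_hat`, `conc_per_ul`, `copies_per_reaction`,
#'   `copies_per_sample`, and a semicolon-joined `flags` column.
#' @export
quantify_wells <- function(droplets, threshold = "auto",
                           droplet_volume_nl = 0.85,
                           reaction_volume_ul = 22,
                           sample_fraction_loaded = 1,
                           min_droplets = 10000L) {
  need <- c("well_id", "channel", "amplitude")
  if (!all(need %in% names(droplets))) {
    stop("droplet table must have columns ",
         paste(need, collapse = ", "))
  }
  keys <- unique(droplets[, c("well_id", "channel")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- droplets$well_id == keys$well_id[i] &
      droplets$channel == keys$channel[i]
    cls <- classify_droplets(droplets$amplitude[sel], threshold)
    pc <- poisson_concentration(cls$n_pos, cls$n_total,
                                droplet_volume_nl, min_droplets)
    cps <- if (is.finite(pc$conc_per_ul)) {
      copies_per_sample(pc$conc_per_ul, reaction_volume_ul,
                        sample_fraction_loaded)
    } else {
      list(copies_per_reaction = Inf, copies_per_sample = Inf)
    }
    data.frame(well_id = keys$well_id[i], channel = keys$channel[i],
               n_total = cls$n_total, n_pos = cls$n_pos,
               threshold = cls$threshold, lambda_hat = pc$lambda_hat,
               conc_per_ul = pc$conc_per_ul,
               copies_per_reaction = cps$copies_per_reaction,
               copies_per_sample = cps$copies_per_sample,
               flags = paste(pc$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply plate controls to a quantified plate
#'
#' Checks the no-template control (NTC) and the per-transcript positive
#' controls (e.g. HEK293 cells transfected with AR-FL, AR-V7 or
#' AR-v567es) on a quantified plate. An NTC well with more positive
#' droplets than `ntc_tolerance` fails the plate; a positive-control well
#' with zero positive droplets fails its target. Sample wells on a failed
#' plate are marked unreliable but remain in the report.
#'
#' @param wells Data frame from [quantify_wells()].
#' @param control_map Data frame with columns `well_id` and `role`, where
#'   `role` is `"NTC"`, `"POS:<target>"` (e.g. `"POS:AR-V7"`), or
#'   `"sample"`. Every declared control well must exist in `wells`.
#' @param ntc_tolerance Positive droplets tolerated in an NTC well
#'   (default 2, a small rain allowance).
#' @return A list with `plate_pass` (logical), `failures` (data frame of
#'   failed control wells and reasons), and `wells` with an added
#'   `reliable` column.
#' @export
apply_plate_controls <- function(wells, control_map, ntc_tolerance = 2L) {
  if (!all(c("well_id", "role") %in% names(control_map))) {
    stop("control_map must have columns well_id, role")
  }
  ctrl <- control_map[control_map$role != "sample", , drop = FALSE]
  missing_wells <- setdiff(ctrl$well_id, wells$well_id)
  if (length(missing_wells) > 0) {
    stop("control well(s) missing from plate: ",
         paste(missing_wells, collapse = ", "))
  }
  failures <- data.frame(well_id = character(), role = character(),
                         reason = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ctrl))) {
    w <- wells[wells$well_id == ctrl$well_id[i], ][1, ]
    role <- ctrl$role[i]
    if (role == "NTC" && w$n_pos > ntc_tolerance) {
      failures <- rbind(failures, data.frame(
        well_id = w$well_id, role = role,
        reason = sprintf("NTC_FAIL: %d positive droplets (tolerance %d)",
                         w$n_pos, ntc_tolerance),
        stringsAsFactors = FALSE))
    } else if (startsWith(role, "POS:") && w$n_pos == 0) {
      failures <- rbind(failures, data.frame(
        well_id = w$well_id, role = role,
        reason = sprintf("CONTROL_FAIL: positive control for %s has no positive droplets",
                         sub("^POS:", "", role)),
        stringsAsFactors = FALSE))
    }
  }
  plate_pass <- nrow(failures) == 0
  wells$reliable <- plate_pass
  is_ctrl <- wells$well_id %in% ctrl$well_id
  wells$reliable[is_ctrl] <- NA
  list(plate_pass = plate_pass, failures = failures, wells = wells)
}

#' Repeatability / reproducibility of replicate measurements
#'
#' Coefficient of variation of replicate concentration measurements:
#' `cv_percent = 100 * sd / mean`, with the sample standard deviation
#' (n - 1 denominator). Used both for intra-assay (repeatability, same
#' run) and inter-assay (reproducibility, different days/operators)
#' replicate sets.
#'
#' @param values Numeric vector of at least two replicate measurements
#'   (e.g. copies/uL).
#' @param label `"intra"` or `"inter"` (stored, not interpreted).
#' @return A list with `label`, `values`, `n`, `mean`, `sd`,
#'   `cv_percent` (`NA` with an `UNDEFINED_CV` flag when the mean is 0).
#' @examples
#' replicate_cv(c(8, 10, 12))  # CV 20%
#' @export
replicate_cv <- function(values, label = "intra") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 replicate values")
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0) {
    return(list(label = label, values = values, n = length(values),
                mean = m, sd = s, cv_percent = NA_real_,
                flags = "UNDEFINED_CV"))
  }
  list(label = label, values = values, n = length(values), mean = m,
       sd = s, cv_percent = 100 * s / m, flags = character())
}

#' Read a droplet amplitude table
#'
#' Comma-separated export with columns `well_id`, `channel`, `amplitude`
#' (one row per droplet, QuantaSoft-style).
#'
#' @param path CSV path.
#' @return Data frame of droplets.
#' @export
read_droplet_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "channel", "amplitude")
  if (!all(need %in% names(d))) {
    stop("droplet table must have columns ", paste(need, collapse = ", "))
  }
  d$amplitude <- as.numeric(d$amplitude)
  d
}
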