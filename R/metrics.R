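#' Expression noise as coefficient of variation squared
#'
#' `CV^2 = variance / mean^2`, the standard cell-to-cell variability metric.
#' Undefined (NA) when the mean is not positive, as can happen after
#' background subtraction of a near-background sample.
#'
#' @param mean Mean expression (AU); vectorized.
#' @param variance Expression variance (AU^2); vectorized.
#' @return Numeric vector of CV^2 values, NA where `mean <= 0`.
#' @examples
#' compute_cv2(100, 1000) # 0.1
#' @export
compute_cv2 <- function(mean, variance) {
  ifelse(is.finite(mean) & mean > 0, variance / mean^2, NA_real_)
}

#' Summarize one cytometry sample: gate, fit, subtract background
#'
#' Runs the core analysis chain on one event table: density gate on scatter,
#' probability density of the gated fluorescence on log-spaced bins,
#' least-squares gamma fit, then background subtraction of the control
#' strain's mean. Noise is `CV^2 = variance / mean_bgsub^2` with the fitted
#' variance unadjusted; it is flagged undefined when the subtracted mean is
#' not positive.
#'
#' @param events An event table (see [simulate_flow_sample()]).
#' @param control_mean Mean fluorescence of the non-fluorescent control
#'   strain (AU), >= 0; see [control_mean_from_events()].
#' @param gate Optional precomputed [density_gate()] result for these
#'   events; computed with the settings below when NULL.
#' @param gate_fraction,gate_bins,gate_smooth Gate settings when `gate` is
#'   NULL.
#' @param n_bins Number of log-spaced density bins for the fit.
#' @param channel Fluorescence column to analyse.
#' @return A one-row `data.frame` of class `sample_summary` with columns
#'   `sample_id`, `condition_atc_nM`, `condition_iptg_uM`, `replicate`,
#'   `channel`, `n_gated`, `mean_raw`, `control_mean`, `mean_bgsub`,
#'   `variance`, `cv2`, `cv2_defined`, `fit_converged`.
#' @export
summarize_sample <- function(events, control_mean, gate = NULL,
                             gate_fraction = 1 / 3, gate_bins = 64L,
                             gate_smooth = 1, n_bins = 48L,
                             channel = "fl1_area") {
  stopifnot(is.data.frame(events), channel %in% names(events),
            is.numeric(control_mean), length(control_mean) == 1L,
            control_mean >= 0)
  if (is.null(gate)) {
    gate <- density_gate(events, target_fraction = gate_fraction,
                         bins = gate_bins, smooth_sigma = gate_smooth)
  } else {
    stopifnot(inherits(gate, "gate_result"),
              length(gate$retain) == nrow(events))
  }
  fit <- fit_sample_gamma(events[[channel]][gate$retain], n_bins = n_bins)
  mean_bgsub <- fit$mean - control_mean
  cv2 <- compute_cv2(mean_bgsub, fit$variance)
  out <- data.frame(sample_id = events$sample_id[1L],
                    condition_atc_nM = events$condition_atc_nM[1L],
                    condition_iptg_uM = events$condition_iptg_uM[1L],
                    replicate = events$replicate[1L],
                    channel = channel,
                    n_gated = gate$n_retained,
                    mean_raw = fit$mean,
                    control_mean = control_mean,
                    mean_bgsub = mean_bgsub,
                    variance = fit$variance,
                    cv2 = cv2,
                    cv2_defined = is.finite(cv2),
                    fit_converged = fit$converged)
  class(out) <- c("sample_summary", "data.frame")
  out
}

#' Background mean of a non-fluorescent control sample
#'
#' Estimates the autofluorescence background as the mean gated fluorescence
#' of a control strain that carries no fluorescent protein. Only the first
#' moment of the background is needed for subtraction, so the plain mean of
#' the density-gated events is used: a control distribution is narrow
#' (instrument noise around the autofluorescence level), and forcing a
#' gamma density fit across the decades-wide range opened up by stray
#' debris events would be ill-posed, while the gated mean is already robust
#' (the scatter gate removes the debris mode).
#'
#' @inheritParams summarize_sample
#' @return The mean (AU) of the gated control fluorescence.
#' @export
control_mean_from_events <- function(events, gate_fraction = 1 / 3,
                                     gate_bins = 64L, gate_smooth = 1,
                                     channel = "fl1_area") {
  gate <- density_gate(events, target_fraction = gate_fraction,
                       bins = gate_bins, smooth_sigma = gate_smooth)
  mean(events[[channel]][gate$retain])
}

#' Dose-response summary across inducer conditions
#'
#' Averages per-condition sample summaries over replicates and reports the
#' induction curve: (inducer, mean, CV^2) with replicate SEMs, the dynamic
#' range over nonzero-inducer conditions (the zero-inducer condition is
#' reported separately, since it sits off a log axis), and a monotonicity
#' flag for the mean over the full ordered ladder.
#'
#' @param summaries A `data.frame` of [summarize_sample()] rows.
#' @param inducer `"iptg"` or `"atc"`: which condition column is the dose.
#' @return An object of class `dose_response_summary`: `table` (one row per
#'   nonzero dose: `inducer`, `mean_bgsub`, `mean_sem`, `cv2`, `cv2_sem`,
#'   `n_replicates`), `zero_condition` (same columns, or NULL),
#'   `dynamic_range`, `monotone`, `inducer`.
#' @export
dose_response <- function(summaries, inducer = c("iptg", "atc")) {
  inducer <- match.arg(inducer)
  col <- if (inducer == "iptg") "condition_iptg_uM" else "condition_atc_nM"
  stopifnot(is.data.frame(summaries), col %in% names(summaries))
  dose <- summaries[[col]]
  if (nrow(summaries) < 1L) stop("no summaries given", call. = FALSE)
  if (anyNA(dose)) stop("missing ", inducer, " condition values",
                        call. = FALSE)
  key <- paste(dose, summaries$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, replicate) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else
    NA_real_
  agg <- do.call(rbind, lapply(split(summaries, dose), function(d) {
    data.frame(inducer = d[[col]][1L],
               mean_bgsub = mean(d$mean_bgsub),
               mean_sem = sem(d$mean_bgsub),
               cv2 = mean(d$cv2),
               cv2_sem = sem(d$cv2),
               n_replicates = nrow(d))
  }))
  agg <- agg[order(agg$inducer), , drop = FALSE]
  rownames(agg) <- NULL
  nz <- agg$inducer > 0
  dynamic_range <- if (sum(nz) >= 1L) {
    max(agg$mean_bgsub[nz]) / min(agg$mean_bgsub[nz])
  } else NA_real_
  structure(list(table = agg[nz, , drop = FALSE],
                 zero_condition = if (any(!nz)) agg[!nz, , drop = FALSE]
                 else NULL,
                 dynamic_range = dynamic_range,
                 monotone = !is.unsorted(agg$mean_bgsub),
                 inducer = inducer),
            class = "dose_response_summary")
}

#' @export
print.dose_response_summary <- function(x, ...) {
  cat("<dose_response_summary>", x$inducer, "ladder,",
      nrow(x$table), "nonzero conditions\n")
  cat("  dynamic range:", signif(x$dynamic_range, 4),
      " monotone mean:", x$monotone, "\n")
  print(x$table)
  invisible(x)
}

#' Percent drop in mean expression between two plasmid backbones
#'
#' Compares matched inducer conditions measured on a higher-copy and a
#' lower-copy backbone: per condition the replicate-averaged subtracted
#' means give `drop = 100 * (1 - mean_low / mean_high)` (percent), then the
#' per-condition drops are averaged with their SEM. Negative autoregulation
#' is expected to shrink this drop below the copy-number ratio itself
#' (dosage compensation).
#'
#' @param high,low `data.frame`s of [summarize_sample()] rows for the
#'   higher- and lower-copy backbone; conditions must match.
#' @return An object of class `backbone_comparison`: `drop_pct`, `sem`,
#'   `per_condition` table.
#' @export
compare_backbones <- function(high, low) {
  stopifnot(is.data.frame(high), nrow(high) > 0L,
            is.data.frame(low), nrow(low) > 0L)
  cond_key <- function(d) paste(d$condition_atc_nM, d$condition_iptg_uM)
  mean_by_cond <- function(d) {
    vapply(split(d$mean_bgsub, cond_key(d)), mean, numeric(1))
  }
  mh <- mean_by_cond(high)
  ml <- mean_by_cond(low)
  extra_h <- setdiff(names(mh), names(ml))
  extra_l <- setdiff(names(ml), names(mh))
  if (length(extra_h) || length(extra_l)) {
    stop("unmatched conditions: ",
         paste(c(extra_h, extra_l), collapse = "; "), call. = FALSE)
  }
  ml <- ml[names(mh)]
  drop <- 100 * (1 - ml / mh)
  sem <- if (length(drop) > 1L) stats::sd(drop) / sqrt(length(drop)) else
    NA_real_
  structure(list(drop_pct = mean(drop), sem = sem,
                 per_condition = data.frame(condition = names(mh),
                                            mean_high = unname(mh),
                                            mean_low = unname(ml),
                                            drop_pct = unname(drop),
                                            row.names = NULL)),
            class = "backbone_comparison")
}

#' @export
print.backbone_comparison <- function(x, ...) {
  cat(sprintf("<backbone_comparison> drop = %.1f%% (SEM %.2f) over %d conditions\n",
              x$drop_pct, x$sem, nrow(x$per_condition)))
  invisible(x)
}

#' Crosstalk between two independently induced channels
#'
#' Quantifies how much each channel's expression responds to the *other*
#' channel's inducer on a complete factorial (ATc x IPTG) grid. For a
#' channel whose own inducer is, say, ATc: at each ATc level the
#' replicate-averaged subtracted means across the IPTG levels give a spread
#' `(max - min)` relative to the mean at the lowest IPTG level (the
#' baseline for that row of the grid), so a doubling at high IPTG scores
#' exactly 1. The channel's crosstalk is the maximum spread over its
#' own-inducer levels. Channels are declared independent when both
#' crosstalk values fall at or below `tolerance`.
#'
#' @param summaries A `data.frame` of [summarize_sample()] rows covering a
#'   complete (ATc x IPTG) grid for each channel, with a `channel` column.
#' @param own_inducer Named character vector mapping each channel name to
#'   its own inducer (`"atc"` or `"iptg"`).
#' @param tolerance Independence threshold on the crosstalk metric.
#' @return An object of class `crosstalk_summary`: `per_channel`
#'   (`channel`, `own_inducer`, `crosstalk`), `independent`, `tolerance`.
#' @export
crosstalk <- function(summaries,
                      own_inducer = c(fl1_area = "atc", fl2_area = "iptg"),
                      tolerance = 0.05) {
  stopifnot(is.data.frame(summaries), "channel" %in% names(summaries))
  channels <- unique(summaries$channel)
  per <- lapply(channels, function(ch) {
    d <- summaries[summaries$channel == ch, , drop = FALSE]
    own <- own_inducer[[ch]]
    if (is.null(own)) stop("no own_inducer mapping for channel ", ch,
                           call. = FALSE)
    own_col <- if (own == "atc") "condition_atc_nM" else "condition_iptg_uM"
    oth_col <- if (own == "atc") "condition_iptg_uM" else "condition_atc_nM"
    own_lv <- sort(unique(d[[own_col]]))
    oth_lv <- sort(unique(d[[oth_col]]))
    if (length(own_lv) < 2L || length(oth_lv) < 2L) {
      stop("crosstalk needs >= 2 levels per inducer for channel ", ch,
           call. = FALSE)
    }
    grid <- expand.grid(own = own_lv, oth = oth_lv)
    have <- paste(d[[own_col]], d[[oth_col]])
    missing <- !(paste(grid$own, grid$oth) %in% have)
    if (any(missing)) {
      stop("incomplete grid for channel ", ch, "; missing cells: ",
           paste(paste0("(", own, "=", grid$own[missing], ", other=",
                        grid$oth[missing], ")"), collapse = " "),
           call. = FALSE)
    }
    spread <- vapply(own_lv, function(lv) {
      dl <- d[d[[own_col]] == lv, , drop = FALSE]
      oth <- dl[[oth_col]]
      m <- vapply(split(dl$mean_bgsub, oth), mean, numeric(1))
      m <- m[order(as.numeric(names(m)))]
      (max(m) - min(m)) / m[[1]]
    }, numeric(1))
    data.frame(channel = ch, own_inducer = own, crosstalk = max(spread))
  })
  per <- do.call(rbind, per)
  structure(list(per_channel = per,
                 independent = all(per$crosstalk <= tolerance),
                 tolerance = tolerance),
            class = "crosstalk_summary")
}

#' @export
print.crosstalk_summary <- function(x, ...) {
  cat("<crosstalk_summary> independent:", x$independent,
      sprintf("(tolerance %.3g)\n", x$tolerance))
  print(x$per_channel)
  invisible(x)
}
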