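#' Density-based scatter gate
#'
#' Reproduces the standard cytometry density gate: events are binned on a
#' 2D histogram of (log10 FSC area, log10 SSC height), the histogram is
#' smoothed with a Gaussian kernel, and the events whose bins are densest —
#' i.e. nearest the histogram mode — are retained until a fixed fraction of
#' all events is kept. Whole bins are retained in decreasing-density order;
#' inside the single boundary bin, events are retained in ascending row
#' order until the count equals `round(target_fraction * n_events)` exactly.
#'
#' Binning covers the central 99.9% range of each log-scatter channel with
#' `bins` equal-width bins; events outside the range are clamped into the
#' edge bins. Events with nonpositive scatter on either channel cannot be
#' log-binned: they are routed to an underflow class and never retained.
#'
#' @param events An event table (see [simulate_flow_sample()]) with columns
#'   `fsc_area` and `ssc_height`; at least 10 rows.
#' @param target_fraction Fraction of events to retain, in (0, 1].
#' @param bins Number of histogram bins per axis.
#' @param smooth_sigma SD of the Gaussian smoothing kernel, in bins
#'   (0 disables smoothing).
#' @return An object of class `gate_result`: list with `retain` (logical per
#'   event), `n_retained`, `retained_fraction`, the gate parameters, the
#'   smoothed `density_matrix`, per-event `bin_index` (NA for underflow),
#'   the `boundary_bin` index (NA if no bin was split) and a `degenerate`
#'   flag (all events in one bin, or fewer usable events than the target).
#' @examples
#' ev <- simulate_flow_sample(
#'   simulate_population(tetr_circuit(), 25, 2000, seed = 1),
#'   measurement_params(), n_events = 2000, seed = 2)
#' g <- density_gate(ev, target_fraction = 1/3)
#' g$n_retained
#' @export
density_gate <- function(events, target_fraction = 1 / 3, bins = 64L,
                         smooth_sigma = 1) {
  stopifnot(is.data.frame(events),
            all(c("fsc_area", "ssc_height") %in% names(events)))
  n <- nrow(events)
  if (n < 10L) stop("density_gate needs at least 10 events", call. = FALSE)
  if (!(target_fraction > 0 && target_fraction <= 1)) {
    stop("target_fraction must be in (0, 1]", call. = FALSE)
  }
  bins <- as.integer(bins)
  target <- as.integer(round(target_fraction * n))

  x <- events$fsc_area
  y <- events$ssc_height
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  res <- list(retain = rep.int(FALSE, n), target_fraction = target_fraction,
              bins = bins, smooth_sigma = smooth_sigma,
              bin_index = rep.int(NA_integer_, n), boundary_bin = NA_integer_,
              degenerate = FALSE)
  class(res) <- "gate_result"
  if (sum(ok) == 0L) {
    res$degenerate <- TRUE
    res$n_retained <- 0L
    res$retained_fraction <- 0
    res$density_matrix <- matrix(0, bins, bins)
    return(res)
  }

  lx <- log10(x[ok])
  ly <- log10(y[ok])
  rx <- stats::quantile(lx, c(5e-4, 1 - 5e-4), names = FALSE)
  ry <- stats::quantile(ly, c(5e-4, 1 - 5e-4), names = FALSE)
  degenerate_axis <- rx[1] >= rx[2] || ry[1] >= ry[2]

  if (!degenerate_axis) {
    bx <- seq(rx[1], rx[2], length.out = bins + 1L)
    by <- seq(ry[1], ry[2], length.out = bins + 1L)
    ix <- findInterval(lx, bx, all.inside = TRUE)
    ix[lx < bx[1]] <- 1L                       # clamp below-range events
    iy <- findInterval(ly, by, all.inside = TRUE)
    iy[ly < by[1]] <- 1L
    bin <- ix + (iy - 1L) * bins
  } else {
    bin <- rep.int(1L, sum(ok))
  }
  res$bin_index[ok] <- bin

  counts <- matrix(tabulate(bin, nbins = bins * bins), bins, bins)
  dens <- smooth_gaussian2d(counts, smooth_sigma)
  res$density_matrix <- dens

  occupied <- sort(unique(bin))
  if (length(occupied) == 1L || degenerate_axis) {
    # all usable events share one bin: keep the first `target` of them
    res$degenerate <- TRUE
    keep_rows <- which(ok)[seq_len(min(target, sum(ok)))]
    res$retain[keep_rows] <- TRUE
  } else {
    d_occ <- dens[occupied]
    ord <- occupied[order(-d_occ, occupied)]   # density desc, index asc
    cnt <- tabulate(bin, nbins = bins * bins)[ord]
    cum <- cumsum(cnt)
    full <- ord[cum <= target]
    taken <- if (length(full)) cum[length(full)] else 0L
    keep <- bin %in% full
    if (taken < target && length(full) < length(ord)) {
      boundary <- ord[length(full) + 1L]
      res$boundary_bin <- boundary
      in_b <- which(bin == boundary)           # ascending row order
      keep[in_b[seq_len(min(target - taken, length(in_b)))]] <- TRUE
    }
    res$retain[ok] <- keep
    if (sum(res$retain) < target) res$degenerate <- TRUE  # ran out of events
  }
  res$n_retained <- sum(res$retain)
  res$retained_fraction <- res$n_retained / n
  res
}

# Separable truncated-Gaussian smoothing with edge renormalization, so the
# smoothed histogram conserves total mass near the borders.
smooth_gaussian2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- as.integer(ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(mat) {
    nr <- nrow(mat)
    padded <- rbind(matrix(0, r, ncol(mat)), mat, matrix(0, r, ncol(mat)))
    out <- matrix(0, nr, ncol(mat))
    wt <- numeric(nr)
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[seq_len(nr) + (j - 1L), , drop = FALSE]
    }
    # renormalize rows whose kernel support leaves the matrix
    ones <- c(rep.int(0, r), rep.int(1, nr), rep.int(0, r))
    for (i in seq_len(nr)) wt[i] <- sum(k * ones[i:(i + 2L * r)])
    out / wt
  }
  t(smooth1(t(smooth1(m))))
}

#' @export
print.gate_result <- function(x, ...) {
  cat("<gate_result> retained", x$n_retained, "events",
      sprintf("(%.4f of total; target %.4f)%s\n", x$retained_fraction,
              x$target_fraction, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
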