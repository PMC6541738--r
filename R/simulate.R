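#' Fraction of repressor left active at a given inducer concentration
#'
#' The inducer binds and inactivates the repressor; the active fraction
#' follows a decreasing Hill curve \eqn{\rho(I) = 1 / (1 + (I/K_d)^{h})}.
#'
#' @param inducer Inducer concentration (same units as `Kd_I`), >= 0.
#' @param Kd_I Half-de-repression concentration.
#' @param hill_I Hill coefficient (>= 1).
#' @return Active repressor fraction in (0, 1].
#' @export
active_repressor_fraction <- function(inducer, Kd_I, hill_I) {
  1 / (1 + (inducer / Kd_I)^hill_I)
}

#' Per-copy promoter activity under repression
#'
#' @param R_active Active repressor level (protein units), >= 0.
#' @param basal Basal activity fraction.
#' @param K_R Half-repression point.
#' @param hill_R Hill coefficient of repression.
#' @return Activity fraction in `[basal, 1]`.
#' @export
per_copy_activity <- function(R_active, basal, K_R, hill_R) {
  basal + (1 - basal) / (1 + (R_active / K_R)^hill_R)
}

#' Deterministic steady-state reporter level
#'
#' Solves the deterministic backbone of the circuit model. In constitutive
#' mode the reporter is explicit,
#' \eqn{G = N \alpha\, a(R_0 \rho(I))}.
#' In autoregulated mode the reporter and the repressor share the bicistron,
#' so G solves the fixed-point equation
#' \eqn{G = N \alpha\, a(r\, G\, \rho(I))},
#' whose right-hand side is strictly decreasing in G: the fixed point is
#' unique and is bracketed by `[0, N * alpha]`. It is found with
#' [stats::uniroot()] at tolerance `1e-10 * N * alpha`.
#'
#' @param params A [circuit_params()] object.
#' @param inducer Inducer concentration (>= 0), scalar.
#' @param N Plasmid copy number(s); vectorized.
#' @return Numeric vector of deterministic reporter levels, same length as `N`.
#' @examples
#' p <- circuit_params(mode = "constitutive_repressor", alpha = 1000, R0 = 0)
#' steady_state_reporter(p, 0, N = c(1, 10)) # = N * alpha
#' @export
steady_state_reporter <- function(params, inducer, N) {
  validate_circuit_params(params)
  stopifnot(length(inducer) == 1L, is.finite(inducer), inducer >= 0)
  rho <- active_repressor_fraction(inducer, params$Kd_I, params$hill_I)
  if (params$mode == "constitutive_repressor") {
    a <- per_copy_activity(params$R0 * rho, params$basal, params$K_R,
                           params$hill_R)
    return(N * params$alpha * a)
  }
  vapply(N, function(n) solve_autoreg_fixed_point(params, rho, n),
         numeric(1))
}

# Unique root of f(G) = G - N*alpha*a(r*G*rho) on [0, N*alpha].
# f(0) <= 0 and f(N*alpha) >= 0, so the bracket always holds.
solve_autoreg_fixed_point <- function(params, rho, n) {
  upper <- n * params$alpha
  if (upper == 0) return(0)
  f <- function(g) {
    g - upper * per_copy_activity(params$r_ratio * g * rho, params$basal,
                                  params$K_R, params$hill_R)
  }
  if (rho == 0) return(upper)  # no active repressor: promoter fully on
  sol <- tryCatch(
    stats::uniroot(f, lower = 0, upper = upper,
                   tol = max(1e-10 * upper, 1e-14), maxiter = 2000L),
    error = function(e) {
      stop("autoregulation fixed point did not converge (N = ", n,
           ", rho = ", signif(rho, 4), "): ", conditionMessage(e),
           call. = FALSE)
    })
  sol$root
}

draw_copy_number <- function(n, N_mean, N_disp) {
  if (N_disp == 0) return(rep.int(max(1L, as.integer(round(N_mean))), n))
  N <- if (N_disp <= 1) {
    stats::rpois(n, lambda = N_mean)
  } else {
    stats::rnbinom(n, mu = N_mean, size = N_mean / (N_disp - 1))
  }
  pmax(N, 1L)
}

# Lognormal size factors with mean exactly 1 and CV^2 = size_cv2.
draw_size_factors <- function(n, size_cv2) {
  if (size_cv2 == 0) return(rep.int(1, n))
  sdlog <- sqrt(log1p(size_cv2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Gamma burst noise around a deterministic level; burst = 0 is exact.
draw_intrinsic <- function(G_det, burst) {
  if (burst == 0) return(G_det)
  out <- numeric(length(G_det))
  pos <- G_det > 0
  out[pos] <- stats::rgamma(sum(pos), shape = G_det[pos] / burst,
                            scale = burst)
  out
}

#' Simulate a single-cell population from the circuit model
#'
#' Draws per-cell plasmid copy numbers, solves the deterministic reporter
#' level per copy number, overlays gamma-distributed intrinsic burst noise
#' (`G ~ Gamma(shape = G_det/burst, scale = burst)`), and multiplies by a
#' lognormal cell-size factor (mean 1, CV^2 = `size_cv2`) shared by all
#' channels of a cell. An optional second, independently parameterized
#' channel (e.g. a compatible second plasmid) reuses the same size factors.
#'
#' All random draws flow from a single `set.seed(seed)` call in a fixed
#' order (copy numbers, intrinsic noise, sizes, then the second channel), so
#' identical arguments reproduce identical populations.
#'
#' @param params A [circuit_params()] object.
#' @param inducer Inducer concentration for channel 1 (>= 0).
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed.
#' @param params2 Optional [circuit_params()] for a second channel.
#' @param inducer2 Inducer concentration for the second channel.
#' @return An object of class `cell_population`: list with per-cell vectors
#'   `copy_number`, `repressor`, `reporter`, `size` (and `copy_number2`,
#'   `repressor2`, `reporter2` when `params2` is given) plus `provenance`.
#' @examples
#' pop <- simulate_population(tetr_circuit(), inducer = 25,
#'                            n_cells = 1000, seed = 1)
#' mean(pop$reporter)
#' @export
simulate_population <- function(params, inducer, n_cells, seed,
                                params2 = NULL, inducer2 = 0) {
  validate_circuit_params(params)
  stopifnot(n_cells >= 1, inducer >= 0, inducer2 >= 0)
  set.seed(as.integer(seed))
  ch1 <- simulate_channel(params, inducer, n_cells)
  s <- draw_size_factors(n_cells, params$size_cv2)
  pop <- list(copy_number = ch1$N,
              repressor = ch1$R,
              reporter = ch1$G * s,
              size = s)
  if (!is.null(params2)) {
    ch2 <- simulate_channel(params2, inducer2, n_cells)
    pop$copy_number2 <- ch2$N
    pop$repressor2 <- ch2$R
    pop$reporter2 <- ch2$G * s
  }
  pop$provenance <- list(params = params, inducer = inducer,
                         params2 = params2, inducer2 = inducer2,
                         n_cells = as.integer(n_cells),
                         seed = as.integer(seed))
  class(pop) <- "cell_population"
  pop
}

simulate_channel <- function(params, inducer, n_cells) {
  validate_circuit_params(params)
  N <- draw_copy_number(n_cells, params$N_mean, params$N_disp)
  uN <- sort(unique(N))
  G_det_u <- steady_state_reporter(params, inducer, uN)
  G_det <- G_det_u[match(N, uN)]
  G <- draw_intrinsic(G_det, params$burst)
  R <- if (params$mode == "autoregulated") params$r_ratio * G else
    rep.int(params$R0, n_cells)
  list(N = N, G = G, R = R)
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population> n =", length(x$reporter),
      if (!is.null(x$reporter2)) "(two channels)" else "", "\n")
  cat("  reporter mean:", signif(mean(x$reporter), 5),
      " copy number mean:", signif(mean(x$copy_number), 4), "\n")
  invisible(x)
}

#' Render a cell population as a cytometry event table
#'
#' Applies the measurement model of [measurement_params()] to a population:
#' cells are sampled (with replacement only if more events than cells are
#' requested), fluorescence areas are computed as
#' `(G * maturation + autofluorescence * s) * (1 + instrument noise)`, and
#' scatter channels are derived from cell size with channel-specific noise.
#' A `debris_fraction` of events is replaced by small, dim particles:
#' exponentially distributed fluorescence around `debris_scale` and scatter
#' drawn from a sub-cellular size mode.
#'
#' @param pop A [simulate_population()] result.
#' @param meas A [measurement_params()] object.
#' @param n_events Number of events; defaults to `meas$n_events`.
#' @param seed Integer seed.
#' @param sample_id,atc_nM,iptg_uM,replicate Sample metadata columns.
#' @return A `data.frame` with columns `sample_id`, `condition_atc_nM`,
#'   `condition_iptg_uM`, `replicate`, `is_control`, `fsc_area`,
#'   `ssc_height`, `fl1_area` (and `fl2_area` for two-channel populations),
#'   with a logical attribute `is_debris` marking debris rows.
#' @export
simulate_flow_sample <- function(pop, meas, n_events = meas$n_events, seed,
                                 sample_id = "sample", atc_nM = NA_real_,
                                 iptg_uM = NA_real_, replicate = 1L) {
  stopifnot(inherits(pop, "cell_population"))
  validate_measurement_params(meas)
  n_cells <- length(pop$reporter)
  if (n_cells < 1L) stop("empty population", call. = FALSE)
  if (n_events < 1L) stop("n_events must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sample.int(n_cells, n_events, replace = n_events > n_cells)
  G <- pop$reporter[idx]
  s <- pop$size[idx]

  fl1 <- (G * meas$maturation_fraction + meas$autofluorescence * s) *
    (1 + stats::rnorm(n_events) * meas$instrument_cv)
  fsc <- meas$fsc_gain * s * (1 + stats::rnorm(n_events) * meas$fsc_cv)
  ssc <- meas$ssc_gain * s * (1 + stats::rnorm(n_events) * meas$ssc_cv)
  fl2 <- if (!is.null(pop$reporter2)) {
    (pop$reporter2[idx] * meas$maturation_fraction2 +
       meas$autofluorescence * s) *
      (1 + stats::rnorm(n_events) * meas$instrument_cv)
  } else NULL

  is_debris <- rep.int(FALSE, n_events)
  if (meas$debris_fraction > 0) {
    is_debris <- stats::runif(n_events) < meas$debris_fraction
    nd <- sum(is_debris)
    if (nd > 0) {
      fl1[is_debris] <- stats::rexp(nd, rate = 1 / max(meas$debris_scale,
                                                       .Machine$double.eps))
      sd_deb <- 0.3 * exp(stats::rnorm(nd) * 0.6)  # sub-cellular size mode
      fsc[is_debris] <- meas$fsc_gain * sd_deb *
        (1 + stats::rnorm(nd) * meas$fsc_cv)
      ssc[is_debris] <- meas$ssc_gain * sd_deb *
        (1 + stats::rnorm(nd) * meas$ssc_cv)
      if (!is.null(fl2)) {
        fl2[is_debris] <- stats::rexp(nd, rate = 1 / max(meas$debris_scale,
                                                         .Machine$double.eps))
      }
    }
  }

  ev <- data.frame(sample_id = sample_id,
                   condition_atc_nM = atc_nM,
                   condition_iptg_uM = iptg_uM,
                   replicate = as.integer(replicate),
                   is_control = FALSE,
                   fsc_area = fsc,
                   ssc_height = ssc,
                   fl1_area = fl1)
  if (!is.null(fl2)) ev$fl2_area <- fl2
  attr(ev, "is_debris") <- is_debris
  ev
}

#' Simulate an autofluorescence-only control sample
#'
#' Emits the event table of a control strain that carries a similar plasmid
#' but no fluorescent protein: the reporter is forced to zero so `fl1_area`
#' contains only size-scaled autofluorescence, measurement noise and debris.
#' The fitted mean of such a sample is the background subtracted from every
#' expressing sample.
#'
#' @inheritParams simulate_flow_sample
#' @param size_cv2 Cell-size CV^2 of the control population.
#' @return An event table as in [simulate_flow_sample()] with
#'   `is_control = TRUE`.
#' @export
simulate_control_sample <- function(meas, n_events = meas$n_events, seed,
                                    size_cv2 = 0.05, sample_id = "control",
                                    atc_nM = NA_real_, iptg_uM = NA_real_,
                                    replicate = 1L) {
  blank <- circuit_params(mode = "constitutive_repressor", alpha = 0,
                          size_cv2 = size_cv2)
  pop <- simulate_population(blank, inducer = 0, n_cells = n_events,
                             seed = seed)
  ev <- simulate_flow_sample(pop, meas, n_events = n_events,
                             seed = as.integer(seed) + 1L,
                             sample_id = sample_id, atc_nM = atc_nM,
                             iptg_uM = iptg_uM, replicate = replicate)
  ev$is_control <- TRUE
  ev
}
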