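#' Boltzmann fit of the Q-V (activation) curve
#'
#' Least-squares fit of the gating-charge activation curve. With
#' `holding = NULL` (default) the model is the plain single Boltzmann
#' `Q(V) = q_max / (1 + exp(-(V - v_half)/k))`. When a holding potential is
#' supplied the holding-referenced form
#' `Q(V) = q_max * (s(V) - s(holding))` is fitted instead (with `s` the same
#' Boltzmann), which is the correct model for off-charge measured relative to
#' the gate's resting position at the holding potential; the pipeline uses
#' this form. Initial values come from the data (`v_half` from the voltage at
#' half-maximal charge, `k` from the 10-90% rise span divided by `2*log(9)`,
#' `q_max` from the plateau).
#'
#' @param points Data frame with columns `v` (prepulse, mV) and `q_off` (pC),
#'   e.g. from [build_iv()]; alternatively pass `v` and `q_off` vectors.
#' @param q_off Optional charge vector when `points` is a voltage vector.
#' @param holding Holding potential (mV) for the holding-referenced model, or
#'   `NULL` for the plain Boltzmann.
#' @param v_min Discard prepulses below this voltage before fitting. The
#'   pipeline uses -10 mV: below that the 10 ms pulse is too short for the
#'   (slow, hyperpolarized) gate to equilibrate, so those points carry no
#'   activation information.
#' @return An object of class `boltzmann_fit`: `q_max` (pC), `v_half` (mV),
#'   `k` (mV), `resid_norm`, `n_points`, `converged`, plus the data and a
#'   `predict` closure.
#' @export
fit_boltzmann <- function(points, q_off = NULL, holding = NULL, v_min = -Inf) {
  if (is.data.frame(points)) {
    v <- points$v
    q <- if ("q_off" %in% names(points)) points$q_off else points$q
  } else {
    v <- points
    q <- q_off
  }
  keep <- is.finite(v) & is.finite(q) & v >= v_min
  v <- v[keep]; q <- q[keep]
  if (length(v) < 3) stop("need at least 3 usable (v, q_off) points")
  if (length(v) < 5)
    warning("fewer than 5 points: Boltzmann fit may be poorly constrained")

  model <- function(v, q_max, v_half, k) {
    s <- 1 / (1 + exp(-(v - v_half) / k))
    if (is.null(holding)) q_max * s
    else q_max * (s - 1 / (1 + exp(-(holding - v_half) / k)))
  }

  # data-driven starting values
  ord <- order(v)
  vs <- v[ord]; qs <- q[ord]
  q_top <- max(qs)
  q_lo <- min(qs)
  v_half0 <- stats::approx(qs, vs, xout = q_lo + 0.5 * (q_top - q_lo),
                           ties = mean)$y
  if (!is.finite(v_half0)) v_half0 <- vs[which.min(abs(qs - q_top / 2))]
  v10 <- stats::approx(qs, vs, xout = q_lo + 0.1 * (q_top - q_lo), ties = mean)$y
  v90 <- stats::approx(qs, vs, xout = q_lo + 0.9 * (q_top - q_lo), ties = mean)$y
  k0 <- if (is.finite(v10) && is.finite(v90) && v90 > v10)
    (v90 - v10) / (2 * log(9)) else diff(range(vs)) / 8
  k0 <- max(k0, 1)
  start <- c(q_max = q_top, v_half = v_half0, k = k0)

  dat <- data.frame(v = v, q = q)
  fit <- tryCatch(
    minpack.lm::nlsLM(q ~ model(v, q_max, v_half, k), data = dat,
                      start = as.list(start),
                      lower = c(q_max = 0, v_half = min(v) - 200, k = 0.1),
                      upper = c(q_max = Inf, v_half = max(v) + 200, k = 500),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    converged <- TRUE
  } else {
    # fall back to direct SSE minimization from several starts
    obj <- function(par) sum((q - model(v, par[1], par[2], abs(par[3])))^2)
    best <- NULL
    for (ks in c(k0, 10, 25, 50)) {
      o <- stats::optim(unname(c(start[1], start[2], ks)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    cf <- c(q_max = unname(best$par[1]), v_half = unname(best$par[2]),
            k = abs(unname(best$par[3])))
    converged <- best$convergence == 0
  }

  pred <- model(v, cf[["q_max"]], cf[["v_half"]], cf[["k"]])
  structure(list(q_max = cf[["q_max"]], v_half = cf[["v_half"]], k = cf[["k"]],
                 resid_norm = sqrt(sum((q - pred)^2)), n_points = length(v),
                 converged = converged, holding = holding,
                 data = dat,
                 predict = function(vnew) model(vnew, cf[["q_max"]],
                                                cf[["v_half"]], cf[["k"]])),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit%s: q_max = %.4g pC, V0.5 = %.2f mV, k = %.2f mV (n = %d%s)\n",
    if (is.null(x$holding)) "" else sprintf(" (holding-referenced, %g mV)", x$holding),
    x$q_max, x$v_half, x$k, x$n_points,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Normalized Q-V curve
#'
#' Divides measured charges by the fitted `q_max`. Values may slightly exceed
#' 1 under noise; they are deliberately not clipped.
#'
#' @param fit A [fit_boltzmann()] result with `q_max > 0`.
#' @param points Data frame with `v` and `q_off` (defaults to the fitted
#'   data).
#' @return Data frame with columns `v` and `q_norm`.
#' @export
normalize_qv <- function(fit, points = NULL) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (fit$q_max <= 0) stop("fitted q_max must be positive")
  if (is.null(points)) points <- stats::setNames(fit$data, c("v", "q_off"))
  data.frame(v = points$v, q_norm = points$q_off / fit$q_max)
}

#' Q_off/current ratio (transport-efficiency statistic)
#'
#' Off-gating charge divided by the steady-state transport current at the
#' preceding (reference) voltage; an inverse measure of transport efficiency.
#' When the current is below `i_threshold` (loss-of-function cells at the
#' noise floor) the ratio is undefined and `NA` is returned with attribute
#' `defined = FALSE`.
#'
#' @param q_off_ref Off charge after the reference prepulse (pC).
#' @param i_ss_ref Steady-state current at the reference voltage (nA).
#' @param i_threshold Noise-floor current threshold (nA).
#' @return Ratio in pC/nA (`NA` if undefined), with attributes `defined` and
#'   `v_ref` when supplied via `...`.
#' @export
qoff_current_ratio <- function(q_off_ref, i_ss_ref, i_threshold = 0.05) {
  if (!is.finite(i_ss_ref) || abs(i_ss_ref) < i_threshold) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  out <- q_off_ref / i_ss_ref
  attr(out, "defined") <- TRUE
  out
}

#' Transport activity curve
#'
#' The study's derived statistic: normalized off charge at each prepulse
#' divided by the Q_off/current ratio, reporting voltage-dependent transport
#' efficacy independent of absolute expression. Prepulses with normalized
#' charge below `min_q_norm` are dropped (`NA`) to avoid noise-dominated
#' ratios.
#'
#' @param norm_qv Data frame with `v` and `q_norm` from [normalize_qv()].
#' @param rho Q_off/current ratio (pC/nA) from [qoff_current_ratio()].
#' @param min_q_norm Keep only prepulses with `q_norm` above this value.
#' @return Data frame with columns `v` and `ta` (nA/pC); all-`NA` `ta` (with
#'   attribute `defined = FALSE`) when `rho` is undefined.
#' @export
transport_activity <- function(norm_qv, rho, min_q_norm = 0.05) {
  defined <- is.finite(rho) && rho > 0
  ta <- if (defined) norm_qv$q_norm / rho else rep(NA_real_, nrow(norm_qv))
  ta[!is.na(ta) & norm_qv$q_norm <= min_q_norm] <- NA_real_
  out <- data.frame(v = norm_qv$v, ta = ta)
  attr(out, "defined") <- defined
  out
}

#' Expression-normalized current slope factor
#'
#' Ordinary least-squares line (free intercept) through per-cell
#' (fluorescence, steady-state current) points of one variant. The slope is
#' the expression-normalized macroscopic current amplitude; the intercept is
#' kept free because measured fluorescence contains a nonzero background, and
#' is reported for transparency.
#'
#' @param fluorescence Per-cell fluorescence (a.u.).
#' @param i_ss Per-cell steady-state current at the reference voltage (nA),
#'   conventionally +175 mV.
#' @return List with `slope` (nA per a.u.), `slope_se`, `intercept`,
#'   `intercept_se`, `r_squared`, `n`.
#' @export
fluorescence_slope <- function(fluorescence, i_ss) {
  keep <- is.finite(fluorescence) & is.finite(i_ss)
  f <- fluorescence[keep]; i <- i_ss[keep]
  if (length(f) < 3) stop("need at least 3 cells for a slope factor")
  if (stats::sd(f) == 0) stop("fluorescence values are degenerate (no spread)")
  fit <- stats::lm(i ~ f)
  # summary.lm warns on an exactly collinear (noise-free) fit; the slope and
  # intercept remain valid
  sm <- suppressWarnings(summary(fit))
  s <- sm$coefficients
  list(slope = s["f", "Estimate"], slope_se = s["f", "Std. Error"],
       intercept = s["(Intercept)", "Estimate"],
       intercept_se = s["(Intercept)", "Std. Error"],
       r_squared = sm$r.squared, n = length(f))
}

#' Full per-cell analysis
#'
#' Runs the complete trace pipeline on one recording: P/8 subtraction, I-V /
#' Q-V assembly, holding-referenced Boltzmann fit of the Q-V curve
#' (prepulses >= `v_min_fit`), Q_off/current ratio at the variant's reference
#' prepulse, and the transport-activity curve.
#'
#' A per-cell quality flag `qv_ok` marks recordings suitable for activation
#' analysis: the steady transport current at the reference prepulse must
#' reach `qv_i_min` (and the fit must have converged). Dim, low-expression
#' cells below this floor carry unresolvable gating charge and give
#' heavy-tailed midpoint estimates; excluding them mirrors routine
#' electrophysiology practice (the study likewise analyzes fewer cells for
#' V0.5 than it records). The criterion is an expression proxy measured
#' independently of the Q-V fit, so it does not select on fit noise.
#'
#' @param rec A `clc_recording`.
#' @param v_ref Reference prepulse (mV); defaults to the variant's `v_ref`.
#' @param v_min_fit Lower prepulse bound for the Boltzmann fit.
#' @param i_threshold Noise-floor current for ratio definition (nA).
#' @param qv_i_min Minimal steady current at the reference prepulse (nA)
#'   for a cell to enter activation (V0.5) statistics.
#' @return List with `iv`, `fit`, `norm_qv`, `ta`, and a one-row data frame
#'   `metrics` (cell_id, variant, fluorescence, i_ss at max voltage and at
#'   `v_ref`, q_off at `v_ref`, q_max, v_half, k, rho, qv_ok, converged).
#' @export
analyze_recording <- function(rec, v_ref = NULL, v_min_fit = -10,
                              i_threshold = 0.05, qv_i_min = 1) {
  stopifnot(inherits(rec, "clc_recording"))
  if (is.null(v_ref)) v_ref <- rec$variant$v_ref
  iv <- build_iv(rec)
  fit <- fit_boltzmann(iv, holding = rec$protocol$holding, v_min = v_min_fit)
  # degenerate (zero-charge) fits in loss-of-function cells: normalized
  # curve undefined, flagged downstream rather than an error
  nq <- if (fit$q_max > 0) normalize_qv(fit, iv)
        else data.frame(v = iv$v, q_norm = NA_real_)
  jr <- which.min(abs(iv$v - v_ref))
  rho <- qoff_current_ratio(iv$q_off[jr], iv$i_ss[jr], i_threshold)
  ta <- transport_activity(nq, as.numeric(rho))
  v_top <- iv$v[which.max(iv$v)]
  metrics <- data.frame(
    cell_id = rec$meta$cell_id, variant = rec$meta$variant,
    fluorescence = rec$fluorescence,
    i_ss_max = iv$i_ss[which.max(iv$v)], v_max = v_top,
    i_ss_ref = iv$i_ss[jr], q_off_ref = iv$q_off[jr], v_ref = iv$v[jr],
    q_max = fit$q_max, v_half = fit$v_half, k = fit$k,
    rho = as.numeric(rho), rho_defined = isTRUE(attr(rho, "defined")),
    qv_ok = fit$converged && is.finite(iv$i_ss[jr]) &&
      abs(iv$i_ss[jr]) >= qv_i_min,
    fit_converged = fit$converged, stringsAsFactors = FALSE)
  list(iv = iv, fit = fit, norm_qv = nq, ta = ta, metrics = metrics)
}

#' Analyze every cell of a cohort
#'
#' @param cohort A `clc_cohort` from [simulate_cohort()] (or assembled from
#'   imported recordings).
#' @param ... Passed to [analyze_recording()].
#' @return List with `cells` (per-cell analysis lists), `metrics` (per-cell
#'   tidy table) and `summary` (per-variant means, s.e.m. and n from
#'   [summarize_cohort()]).
#' @export
analyze_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "clc_cohort"))
  res <- lapply(cohort$cells, analyze_recording, ...)
  metrics <- do.call(rbind, lapply(res, `[[`, "metrics"))
  rownames(metrics) <- NULL
  list(cells = res, metrics = metrics, summary = summarize_cohort(metrics))
}

#' Per-variant summary of cell metrics
#'
#' Means, standard errors of the mean and cell counts per variant for the
#' headline metrics; per-variant slope factors from [fluorescence_slope()]
#' where at least 3 cells are available. Undefined (flagged) values are
#' excluded from the means but counted; activation (V0.5, k) statistics use
#' only quality-passing cells (`qv_ok`, see [analyze_recording()]), so
#' loss-of-function variants with unresolvable gating charge report `NA`
#' midpoints rather than noise.
#'
#' @param metrics Per-cell metrics table from [analyze_cohort()].
#' @return Data frame with one row per variant.
#' @export
summarize_cohort <- function(metrics) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (is.null(metrics$qv_ok)) metrics$qv_ok <- TRUE
  do.call(rbind, lapply(split(metrics, metrics$variant), function(d) {
    rho_ok <- d$rho[d$rho_defined & is.finite(d$rho)]
    qv <- d[d$qv_ok, , drop = FALSE]
    slope <- tryCatch(fluorescence_slope(d$fluorescence, d$i_ss_max),
                      error = function(e) list(slope = NA_real_,
                                               slope_se = NA_real_))
    data.frame(
      variant = d$variant[1], n = nrow(d), n_qv = nrow(qv),
      v_half_mean = if (nrow(qv)) mean(qv$v_half) else NA_real_,
      v_half_sem = if (nrow(qv) > 1) sem(qv$v_half) else NA_real_,
      k_mean = if (nrow(qv)) mean(qv$k) else NA_real_,
      i_ss_max_mean = mean(d$i_ss_max), i_ss_max_sem = sem(d$i_ss_max),
      rho_mean = if (length(rho_ok)) mean(rho_ok) else NA_real_,
      rho_sem = if (length(rho_ok) > 1) sem(rho_ok) else NA_real_,
      n_rho_defined = length(rho_ok),
      slope = slope$slope, slope_se = slope$slope_se,
      stringsAsFactors = FALSE)
  }))
}
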