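# Cardiac, respiratory and CO2 impulse-response bases and regressor-set
# construction by convolution on a fine time grid.

#' Canonical cardiac response function
#'
#' The impulse response of the BOLD signal to a unit heart-rate fluctuation:
#' an early positive gamma-shaped peak followed by a negative Gaussian
#' trough centred near 12 s,
#' \deqn{CRF(t) = 0.6 t^{2.7} e^{-t/1.6} - \frac{16}{\sqrt{18\pi}} e^{-(t-12)^2/18}.}
#' Zero for `t < 0` (causal).
#'
#' @param t_s time in seconds (vectorized).
#' @return CRF amplitude at each time.
#' @export
crf <- function(t_s) {
  out <- numeric(length(t_s))
  pos <- t_s >= 0
  t <- t_s[pos]
  out[pos] <- 0.6 * t^2.7 * exp(-t / 1.6) -
    16 / sqrt(18 * pi) * exp(-(t - 12)^2 / 18)
  out
}

#' Canonical respiratory response function
#'
#' The impulse response of the BOLD signal to a unit respiratory-variation
#' fluctuation: an early overshoot and a late undershoot,
#' \deqn{RRF(t) = 0.6 t^{2.1} e^{-t/1.6} - 0.0023 t^{3.54} e^{-t/4.25}.}
#' Zero for `t < 0`.
#'
#' @inheritParams crf
#' @return RRF amplitude at each time.
#' @export
rrf <- function(t_s) {
  out <- numeric(length(t_s))
  pos <- t_s >= 0
  t <- t_s[pos]
  out[pos] <- 0.6 * t^2.1 * exp(-t / 1.6) - 0.0023 * t^3.54 * exp(-t / 4.25)
  out
}

#' Default CO2 response-function parameters
#'
#' Amplitudes and gamma-variate shape parameters of the double-gamma
#' end-tidal CO2 response function. These are editable defaults: the peak
#' sits near 12 s with a shallow late undershoot, capturing the slower,
#' delayed BOLD response to CO2 relative to the cardiac response.
#'
#' @return named list with `A1`, `tau1`, `n1`, `A2`, `tau2`, `n2`.
#' @export
co2_rf_params <- function() {
  list(A1 = 1, tau1 = 3, n1 = 5, A2 = 0.3, tau2 = 6, n2 = 5)
}

#' Double-gamma end-tidal CO2 response function
#'
#' \deqn{CO2RF(t) = A_1 g(t; n_1, \tau_1) - A_2 g(t; n_2, \tau_2)}
#' where `g` is the gamma probability density with shape `n` and scale
#' `tau` (mode at `(n-1) tau`). Zero at the origin and for `t < 0`.
#'
#' @inheritParams crf
#' @param params named list as from [co2_rf_params()].
#' @return CO2 response amplitude at each time.
#' @export
co2_rf <- function(t_s, params = co2_rf_params()) {
  p <- utils::modifyList(co2_rf_params(), params)
  if (p$tau1 <= 0 || p$tau2 <= 0 || p$n1 <= 0 || p$n2 <= 0)
    cfg_error("CO2 response shape parameters must be positive")
  out <- numeric(length(t_s))
  pos <- t_s > 0
  t <- t_s[pos]
  out[pos] <- p$A1 * stats::dgamma(t, shape = p$n1, scale = p$tau1) -
    p$A2 * stats::dgamma(t, shape = p$n2, scale = p$tau2)
  out
}

#' Construct a response-function object
#'
#' @param name one of `"CRF"`, `"RRF"`, `"CO2RF"`.
#' @param params optional parameter list (CO2RF only).
#' @param support_s evaluation span in seconds.
#' @return object of class `response_function` with a `fun(t)` element.
#' @export
response_function <- function(name = c("CRF", "RRF", "CO2RF"), params = NULL,
                              support_s = 60) {
  name <- match.arg(name)
  fun <- switch(name,
    CRF = crf,
    RRF = rrf,
    CO2RF = function(t) co2_rf(t, if (is.null(params)) co2_rf_params() else params))
  structure(list(name = name, fun = fun, params = params, support_s = support_s),
            class = "response_function")
}

#' Temporal and dispersive derivative basis of a response function
#'
#' Returns evaluators for the primary response, its temporal derivative
#' (central finite difference, step 0.01 s) and its dispersive
#' derivative `[rf(t/w)/w - rf(t)]/(w - 1)` with `w = 1.1`, which captures
#' voxelwise differences in response width. The dispersive form preserves
#' area and vanishes wherever the primary response is zero and flat.
#'
#' @param rf a [response_function()].
#' @param w dispersion factor (> 1).
#' @param h finite-difference step for the temporal derivative (s).
#' @return named list of vectorized functions
#'   `list(primary, temporal, dispersive)`.
#' @export
derivative_basis <- function(rf, w = 1.1, h = 0.01) {
  stopifnot(inherits(rf, "response_function"))
  f <- rf$fun
  list(primary = f,
       temporal = function(t) (f(t + h) - f(t - h)) / (2 * h),
       dispersive = function(t) (f(t / w) / w - f(t)) / (w - 1))
}

# Convolve a fine-grid series with a kernel sampled on the same grid;
# causal, scaled by the grid step so the result approximates the integral.
conv_causal <- function(x, kernel, dt) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  out * dt
}

#' Build a TR-locked physiological design matrix
#'
#' Each physiological timecourse is linearly detrended and z-scored,
#' linearly upsampled to a fine grid (default 0.5 s), convolved with each
#' basis function of its response family, sampled back at the volume
#' acquisition times and z-scored again. Heart rate uses the CRF with
#' temporal and dispersive derivatives (3 columns); respiratory variation
#' uses the RRF likewise (3 columns); end-tidal CO2 uses the double-gamma
#' CO2 response and its temporal derivative (2 columns). Legendre
#' polynomial drift terms up to `drift_order` (including the intercept)
#' are appended.
#'
#' @param physio named list of [physio_timecourse()] objects; recognised
#'   names are `hr`, `rv`, `petco2`.
#' @param model_tag `"joint"`, `"cardiac"` or `"respiratory"`.
#' @param tr_s repetition time (s); defaults to the timecourses' TR.
#' @param n_vols number of volumes; defaults to the timecourses' length.
#' @param drift_order highest Legendre polynomial order.
#' @param dt_s convolution grid step (s).
#' @param co2_params optional CO2 response parameter list.
#' @return object of class `regressor_set`: design matrix `X` (n_vols x k),
#'   `labels`, `phys_idx`, `drift_idx`, `model_tag`, `tr_s`, `drift_order`.
#'   Zero-variance physiological columns are dropped with a warning.
#' @export
build_regressors <- function(physio,
                             model_tag = c("joint", "cardiac", "respiratory"),
                             tr_s = NULL, n_vols = NULL, drift_order = 4,
                             dt_s = 0.5, co2_params = NULL) {
  model_tag <- match.arg(model_tag)
  stopifnot(is.list(physio))
  tcs <- Filter(function(x) inherits(x, "physio_timecourse"), physio)
  if (!length(tcs)) cfg_error("no physiological timecourses supplied")
  if (is.null(tr_s)) tr_s <- tcs[[1]]$tr_s
  if (is.null(n_vols)) n_vols <- tcs[[1]]$n_vols
  for (tc in tcs)
    if (tc$n_vols != n_vols || abs(tc$tr_s - tr_s) > 1e-9)
      stop("physiological timecourses disagree in length or TR")

  want_cardiac <- model_tag %in% c("joint", "cardiac")
  want_resp <- model_tag %in% c("joint", "respiratory")
  tv <- vol_times(tr_s, n_vols)
  tfine <- seq(0, tv[n_vols], by = dt_s)

  one_series <- function(tc, rf_name, prefix, params = NULL) {
    basis <- derivative_basis(response_function(rf_name, params = params))
    if (rf_name == "CO2RF") basis <- basis[c("primary", "temporal")]
    x <- zscore(detrend_linear(tc$values))
    xf <- interp_to(tv, x, tfine)
    cols <- lapply(basis, function(bf) {
      k <- bf(seq(0, 60, by = dt_s))
      interp_to(tfine, conv_causal(xf, k, dt_s), tv)
    })
    M <- do.call(cbind, cols)
    colnames(M) <- paste0(prefix, "_", c("rf", "td", "dd")[seq_len(ncol(M))])
    M
  }

  blocks <- list()
  if (want_cardiac) {
    if (is.null(physio[["hr"]])) {
      warning("cardiac model requested but no 'hr' timecourse; skipping cardiac columns")
    } else blocks$hr <- one_series(physio[["hr"]], "CRF", "hr_crf")
  }
  if (want_resp) {
    if (!is.null(physio[["rv"]])) {
      blocks$rv <- one_series(physio[["rv"]], "RRF", "rv_rrf")
    } else if (!is.null(physio[["petco2"]])) {
      blocks$co2 <- one_series(physio[["petco2"]], "CO2RF", "co2", params = co2_params)
    } else {
      warning("respiratory model requested but no 'rv' or 'petco2' timecourse; skipping")
    }
  }
  if (!length(blocks)) stop("no physiological columns could be built")
  P <- do.call(cbind, blocks)

  keep <- apply(P, 2, stats::sd) > 1e-12
  if (!all(keep)) {
    warning(sprintf("dropping zero-variance regressor column(s): %s",
                    paste(colnames(P)[!keep], collapse = ", ")))
    P <- P[, keep, drop = FALSE]
  }
  if (!ncol(P)) stop("all physiological columns degenerate")
  P <- apply(P, 2, zscore)

  D <- legendre_basis(n_vols, drift_order)
  X <- cbind(P, D)
  structure(list(X = X, labels = colnames(X),
                 phys_idx = seq_len(ncol(P)),
                 drift_idx = ncol(P) + seq_len(ncol(D)),
                 model_tag = model_tag, tr_s = tr_s, drift_order = drift_order),
            class = "regressor_set")
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("<regressor_set> %s model: %d volumes x %d columns (%d physiological + %d drift)\n",
              x$model_tag, nrow(x$X), ncol(x$X),
              length(x$phys_idx), length(x$drift_idx)))
  cat(" columns:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Write a regressor set as TSV for audit
#'
#' @param rs a `regressor_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regressors <- function(rs, path) {
  stopifnot(inherits(rs, "regressor_set"))
  df <- as.data.frame(rs$X)
  names(df) <- rs$labels
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
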