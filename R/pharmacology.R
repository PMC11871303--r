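#' Fit a three-parameter sigmoidal dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + EC50 / x)`,
#' the three-parameter sigmoidal model with the Hill slope fixed at 1 --
#' the convention used for plate-based coregulator-recruitment and
#' reporter potency fitting. The fit is performed on `logEC50` with
#' self-starting values from the response quantiles, and `EC50` is bounded
#' within `[min(x)/100, 100*max(x)]`. Flat data return a non-converged
#' result with `bottom = top = mean(y)` instead of an error.
#'
#' @param table Data frame with columns `concentration_M` (> 0) and
#'   `response`; >= 4 distinct concentrations required.
#' @param direction_hint Optional `"increasing"`/`"decreasing"` used only
#'   to order the starting bottom/top; inferred from the data by default.
#' @param hill_slope Fixed Hill slope; 1 for the three-parameter model.
#'   A free slope is deliberately not fitted here.
#' @return One-row data frame of class `dose_response_fit`: `bottom`,
#'   `top`, `logEC50`, `EC50`, `efficacy_window`, `se_bottom`, `se_top`,
#'   `se_logEC50`, `rss`, `converged`.
#' @export
fit_dose_response <- function(table, direction_hint = NULL, hill_slope = 1) {
  x <- table$concentration_M; y <- table$response
  if (length(unique(x)) < 4L) stop_invalid("need >= 4 distinct concentrations")
  if (any(x <= 0)) stop_invalid("concentrations must be > 0")
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    out <- data.frame(bottom = mean(y), top = mean(y), logEC50 = NA_real_,
                      EC50 = NA_real_, efficacy_window = 0,
                      se_bottom = NA_real_, se_top = NA_real_,
                      se_logEC50 = NA_real_, rss = sum((y - mean(y))^2),
                      converged = FALSE)
    class(out) <- c("dose_response_fit", "data.frame")
    return(out)
  }
  increasing <- if (!is.null(direction_hint)) direction_hint == "increasing" else
    stats::cor(log10(x), y) >= 0
  qs <- stats::quantile(y, c(0.05, 0.95), names = FALSE)
  b0 <- if (increasing) qs[1] else qs[2]
  t0 <- if (increasing) qs[2] else qs[1]
  mid <- (qs[1] + qs[2]) / 2
  l0 <- log10(x[which.min(abs(y - mid))])
  lo <- log10(min(x) / 100); hi <- log10(100 * max(x))
  resid_fn <- function(p) {
    y - (p[1] + (p[2] - p[1]) / (1 + (10^p[3] / x)^hill_slope))
  }
  fit <- minpack.lm::nls.lm(
    par = c(bottom = b0, top = t0, logEC50 = min(max(l0, lo), hi)),
    fn = resid_fn, lower = c(-Inf, -Inf, lo), upper = c(Inf, Inf, hi),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  converged <- fit$info %in% 1:4
  cf <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  out <- data.frame(bottom = cf[["bottom"]], top = cf[["top"]],
                    logEC50 = cf[["logEC50"]], EC50 = 10^cf[["logEC50"]],
                    efficacy_window = cf[["top"]] - cf[["bottom"]],
                    se_bottom = se[[1]], se_top = se[[2]], se_logEC50 = se[[3]],
                    rss = fit$deviance, converged = converged)
  class(out) <- c("dose_response_fit", "data.frame")
  out
}

#' Evaluate a fitted dose-response model at a concentration
#'
#' @param fit A [fit_dose_response()] result.
#' @param concentration Molar concentration (may be `Inf` for the plateau).
#' @return Model response at that concentration.
#' @export
efficacy_at <- function(fit, concentration) {
  if (!fit$converged) stop_invalid("fit did not converge")
  if (is.infinite(concentration)) return(fit$top)
  fit$bottom + (fit$top - fit$bottom) / (1 + fit$EC50 / concentration)
}

#' Fit a one-site total-binding saturation curve with fixed Bmax
#'
#' Least-squares fit of `Y = Bmax * X / (Kd + X) + background` with `Kd`
#' and `background` free and `Bmax` fixed -- the convention for fitting
#' saturation-binding panels in which weak-affinity conditions do not
#' saturate at the highest titratable protein concentration, so Bmax
#' cannot be estimated per curve and is instead shared from the
#' high-affinity conditions (see [estimate_shared_bmax()]). The fit is
#' performed on `log(Kd)` to keep the affinity positive.
#'
#' @param table Data frame with columns `protein_M` (> 0) and `response`;
#'   >= 4 distinct concentrations.
#' @param Bmax_fixed Fixed specific-signal span (> 0).
#' @return One-row data frame of class `saturation_fit`: `Kd`, `pKd`,
#'   `Bmax`, `background`, `se_logKd`, `rss`, `converged`.
#' @export
fit_saturation <- function(table, Bmax_fixed) {
  x <- table$protein_M; y <- table$response
  if (length(unique(x)) < 4L) stop_invalid("need >= 4 distinct concentrations")
  if (Bmax_fixed <= 0) stop_invalid("`Bmax_fixed` must be > 0")
  if (all(y == 0)) {
    out <- data.frame(Kd = NA_real_, pKd = NA_real_, Bmax = Bmax_fixed,
                      background = 0, se_logKd = NA_real_, rss = 0,
                      converged = FALSE)
    class(out) <- c("saturation_fit", "data.frame")
    return(out)
  }
  bg0 <- min(y)
  half <- bg0 + Bmax_fixed / 2
  k0 <- log(x[which.min(abs(y - half))])
  resid_fn <- function(p) y - (Bmax_fixed * x / (exp(p[1]) + x) + p[2])
  fit <- minpack.lm::nls.lm(par = c(logKd = k0, background = bg0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- fit$par
  kd <- exp(cf[["logKd"]])
  se <- tryCatch(summary(fit)$coefficients["logKd", "Std. Error"],
                 error = function(e) NA_real_)
  out <- data.frame(Kd = kd, pKd = -log10(kd), Bmax = Bmax_fixed,
                    background = cf[["background"]], se_logKd = se,
                    rss = fit$deviance, converged = fit$info %in% 1:4)
  class(out) <- c("saturation_fit", "data.frame")
  out
}

#' Estimate a shared Bmax from high-affinity saturation curves
#'
#' Selects the curves that actually saturate -- maximum protein
#' concentration at least `saturation_factor` times the apparent Kd from a
#' free-Bmax per-curve fit -- and jointly refits them with a common Bmax
#' (per-curve Kd and background remain free). The returned Bmax is then
#' fixed for all curves in the analysis set, including the non-saturating
#' ones.
#'
#' @param tables List of saturation tables (`protein_M`, `response`).
#' @param saturation_factor Qualification threshold (default 5).
#' @return List: `Bmax`, `qualifying` (logical per table), `fits`
#'   (per-table free fits used for qualification).
#' @export
estimate_shared_bmax <- function(tables, saturation_factor = 5) {
  free_fit <- function(tab) {
    x <- tab$protein_M; y <- tab$response
    minpack.lm::nls.lm(
      par = c(B = diff(range(y)), logKd = log(stats::median(x)), bg = min(y)),
      fn = function(p) y - (p[1] * x / (exp(p[2]) + x) + p[3]),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  fits <- lapply(tables, free_fit)
  qualifying <- vapply(seq_along(tables), function(i) {
    if (!fits[[i]]$info %in% 1:4) return(FALSE)
    kd <- exp(fits[[i]]$par[["logKd"]])
    max(tables[[i]]$protein_M) >= saturation_factor * kd
  }, logical(1))
  if (!any(qualifying)) {
    stop_invalid("no saturating curve available to anchor Bmax; supply Bmax explicitly")
  }
  idx <- which(qualifying)
  # joint fit: shared Bmax, per-curve logKd and background
  dat <- do.call(rbind, lapply(seq_along(idx), function(k) {
    data.frame(curve = k, x = tables[[idx[k]]]$protein_M,
               y = tables[[idx[k]]]$response)
  }))
  nk <- length(idx)
  start <- c(B = mean(vapply(idx, function(i) fits[[i]]$par[["B"]], numeric(1))),
             stats::setNames(vapply(idx, function(i) fits[[i]]$par[["logKd"]], numeric(1)),
                             paste0("logKd", seq_len(nk))),
             stats::setNames(vapply(idx, function(i) fits[[i]]$par[["bg"]], numeric(1)),
                             paste0("bg", seq_len(nk))))
  resid_fn <- function(par) {
    B <- par[1]
    unlist(lapply(seq_len(nk), function(k) {
      sel <- dat$curve == k
      pred <- B * dat$x[sel] / (exp(par[1 + k]) + dat$x[sel]) + par[1 + nk + k]
      dat$y[sel] - pred
    }))
  }
  joint <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(maxiter = 500))
  list(Bmax = unname(joint$par[1]), qualifying = qualifying, fits = fits)
}

#' Coregulator bias factor
#'
#' The corepressor-vs-coactivator selectivity summary: the MED1
#' (coactivator) value subtracted from the NCoR1 (corepressor) value. For
#' TR-FRET the inputs are efficacies on the linear response scale; for FP
#' affinities the default scale is pKd (`-log10 Kd`), since differences of
#' raw dissociation constants are dominated by the weakest binder.
#'
#' @param ncor1,med1 Finite numeric values on a common scale.
#' @param scale `"linear"` (values used as given) or `"log_affinity"`
#'   (inputs are Kd in molar, converted to pKd before differencing).
#' @return One-row data frame `ncor1_value`, `med1_value`, `bias`, `scale`.
#' @examples
#' bias_factor(0.5, 0.2)$bias                        # 0.3
#' bias_factor(1e-6, 1e-5, "log_affinity")$bias      # +1
#' @export
bias_factor <- function(ncor1, med1, scale = c("linear", "log_affinity")) {
  scale <- match.arg(scale)
  if (!is.finite(ncor1) || !is.finite(med1)) stop_invalid("bias inputs must be finite")
  if (scale == "log_affinity") {
    ncor1 <- -log10(ncor1); med1 <- -log10(med1)
  }
  data.frame(ncor1_value = ncor1, med1_value = med1,
             bias = ncor1 - med1, scale = scale, stringsAsFactors = FALSE)
}

#' Relative expression by the comparative-Ct (ddCt) method
#'
#' Per condition: `dCt = Ct_target - Ct_housekeeping` (replicate means),
#' `ddCt = dCt_condition - dCt_calibrator`, `RQ = 2^(-ddCt)`. Replicate
#' spread is propagated as the sd of the per-replicate dCt values, and the
#' reported limits are `RQ` evaluated at `ddCt -/+ sd` (upper and lower
#' fold-change limits).
#'
#' @param ct Long data frame with columns `condition`, `gene`,
#'   `replicate`, `ct`.
#' @param target,housekeeping Gene labels present for every condition.
#' @param calibrator Condition used as the ddCt reference.
#' @return Data frame per condition: `condition`, `delta_ct`,
#'   `delta_delta_ct`, `rq`, `rq_lower`, `rq_upper`, `sd_delta_ct`.
#' @export
relative_expression <- function(ct, target, housekeeping, calibrator) {
  conds <- unique(ct$condition)
  if (!calibrator %in% conds) stop_invalid("calibrator condition not present")
  per_cond <- lapply(conds, function(cond) {
    tg <- ct[ct$condition == cond & ct$gene == target, ]
    hk <- ct[ct$condition == cond & ct$gene == housekeeping, ]
    if (nrow(tg) == 0L) stop_invalid("missing target gene Ct for condition ", cond)
    if (nrow(hk) == 0L) stop_invalid("missing housekeeping gene Ct for condition ", cond)
    # pair replicates where possible; otherwise difference of means
    if (nrow(tg) == nrow(hk)) {
      dct_rep <- tg$ct[order(tg$replicate)] - hk$ct[order(hk$replicate)]
    } else {
      dct_rep <- mean(tg$ct) - mean(hk$ct)
    }
    c(dct = mean(dct_rep), sd = if (length(dct_rep) > 1) stats::sd(dct_rep) else 0)
  })
  dct <- vapply(per_cond, `[[`, numeric(1), "dct")
  sds <- vapply(per_cond, `[[`, numeric(1), "sd")
  ddct <- dct - dct[match(calibrator, conds)]
  data.frame(condition = conds, delta_ct = dct, delta_delta_ct = ddct,
             rq = 2^(-ddct), rq_lower = 2^(-(ddct + sds)),
             rq_upper = 2^(-(ddct - sds)), sd_delta_ct = sds,
             stringsAsFactors = FALSE)
}
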