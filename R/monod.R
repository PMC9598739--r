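# Monod model with a zero-growth threshold:
#   r(Ca) = r_max (Ca - Ca_ZPG) / (Ca - Ca_ZPG + K_s)
# Ca_ZPG is the calcium concentration at which population growth is zero;
# K_s sets how quickly growth saturates towards r_max above the threshold.

#' Threshold Monod growth curve
#'
#' @param ca Calcium concentration(s) (mg Ca L^-1).
#' @param r_max Maximal population growth rate (day^-1).
#' @param ca_zpg Zero-population-growth threshold (mg Ca L^-1).
#' @param k_s Monod half-saturation constant (mg Ca L^-1).
#' @return Predicted growth rate(s) (day^-1).
#' @export
#' @examples
#' monod_threshold_model(0.57, r_max = 0.2, ca_zpg = 0.27, k_s = 0.3)  # 0.1
monod_threshold_model <- function(ca, r_max, ca_zpg, k_s) {
  denom <- ca - ca_zpg + k_s
  if (any(abs(denom) < .Machine$double.eps * 100))
    stop("monod_threshold_model: singular denominator (ca - ca_zpg + k_s = 0)")
  r_max * (ca - ca_zpg) / denom
}

#' Fit the threshold Monod model to growth-rate data
#'
#' Least-squares estimation of `(r_max, ca_zpg, k_s)` by the
#' Levenberg-Marquardt algorithm, with asymptotic standard errors from the
#' Jacobian at the optimum and t-based 95% confidence intervals on `n - 3`
#' degrees of freedom. The fit is refused (not an error) when every growth
#' rate is negative, since the zero-growth threshold is then outside the
#' observed gradient.
#'
#' @param points A `data.frame` with columns `ca` and `r`, optionally
#'   `weight` (inverse-variance weights; unweighted by default).
#' @param init Optional named starting values `c(r_max=, ca_zpg=, k_s=)`.
#'   When missing: `r_max = max(r)`, `ca_zpg` = largest Ca with `r <= 0`
#'   (or `min(ca)/2` if all rates are positive), `k_s = median(ca) - ca_zpg`
#'   floored at 0.01.
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `monod_fit`: estimates, `se`, `ci_ca_zpg`,
#'   `p_wald` (two-sided Wald t p-values), `rss`, `n_points`, `converged`,
#'   `refused`, `reason`.
#' @export
#' @examples
#' pts <- data.frame(ca = c(0.25, 0.41, 1.02, 1.74))
#' pts$r <- monod_threshold_model(pts$ca, 0.25, 0.27, 0.4)
#' fit_monod_threshold(pts)
fit_monod_threshold <- function(points, init = NULL, conf_level = 0.95) {
  stopifnot(all(c("ca", "r") %in% names(points)))
  points <- points[is.finite(points$ca) & is.finite(points$r), , drop = FALSE]
  n <- nrow(points)
  if (n < 4L)
    stop("fit_monod_threshold: need >= 4 (ca, r) points for 3 parameters")
  refusal <- function(reason) {
    out <- list(r_max = NA_real_, ca_zpg = NA_real_, k_s = NA_real_,
                se = c(r_max = NA_real_, ca_zpg = NA_real_, k_s = NA_real_),
                ci_ca_zpg = c(NA_real_, NA_real_), p_wald = NULL,
                rss = NA_real_, n_points = n, converged = FALSE,
                refused = TRUE, reason = reason)
    class(out) <- "monod_fit"
    out
  }
  if (all(points$r < 0))
    return(refusal("all growth rates negative; Ca_ZPG not estimable"))
  if (is.null(init)) {
    ca_zpg0 <- if (any(points$r <= 0)) max(points$ca[points$r <= 0])
    else min(points$ca) / 2
    init <- c(r_max = max(points$r), ca_zpg = ca_zpg0,
              k_s = max(0.01, stats::median(points$ca) - ca_zpg0))
  }
  w <- if ("weight" %in% names(points)) points$weight else rep(1, n)
  one_fit <- function(start) {
    try(minpack.lm::nlsLM(
      r ~ r_max * (ca - ca_zpg) / (ca - ca_zpg + k_s),
      data = points, start = as.list(start), weights = w,
      lower = c(r_max = -Inf, ca_zpg = -Inf, k_s = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
  }
  # a valid growth curve keeps ca - ca_zpg + k_s > 0 over the data range;
  # optima on the singular branch (denominator changing sign) are rejected
  valid <- function(f) {
    if (inherits(f, "try-error")) return(FALSE)
    p <- stats::coef(f)
    min(points$ca) - p[["ca_zpg"]] + p[["k_s"]] > 0
  }
  fit <- one_fit(init)
  if (!valid(fit)) {
    starts <- lapply(seq(min(points$ca) - 0.5, max(points$ca), length.out = 12),
                     function(z0) c(r_max = max(points$r), ca_zpg = z0,
                                    k_s = max(0.05, stats::median(points$ca) -
                                                z0 + 0.05)))
    cands <- Filter(valid, lapply(starts, one_fit))
    if (!length(cands))
      return(refusal("no valid optimum (denominator sign change)"))
    fit <- cands[[which.min(vapply(cands, function(f)
      sum(w * stats::residuals(f)^2), numeric(1)))]]
  }
  est <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 3L)
  p_wald <- 2 * stats::pt(abs(est / se), df = n - 3L, lower.tail = FALSE)
  out <- list(
    r_max = unname(est["r_max"]), ca_zpg = unname(est["ca_zpg"]),
    k_s = unname(est["k_s"]),
    se = se,
    ci_ca_zpg = unname(est["ca_zpg"] + c(-1, 1) * tq * se["ca_zpg"]),
    p_wald = p_wald,
    rss = sum(w * stats::residuals(fit)^2),
    n_points = n,
    converged = fit$convInfo$isConv %||% TRUE,
    refused = FALSE, reason = NULL,
    fit = fit)
  class(out) <- "monod_fit"
  out
}

#' @export
print.monod_fit <- function(x, ...) {
  if (x$refused) {
    cat("Threshold Monod fit refused:", x$reason, "\n")
  } else {
    cat(sprintf(
      "Threshold Monod fit (n = %d): r_max = %.4f (SE %.4f), Ca_ZPG = %.4f (SE %.4f), K_s = %.4f (SE %.4f)\n",
      x$n_points, x$r_max, x$se["r_max"], x$ca_zpg, x$se["ca_zpg"],
      x$k_s, x$se["k_s"]))
    cat(sprintf("  95%% CI for Ca_ZPG: %.4f - %.4f; RSS = %.3g\n",
                x$ci_ca_zpg[1], x$ci_ca_zpg[2], x$rss))
  }
  invisible(x)
}
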