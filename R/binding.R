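#' Fraction of labelled ligand bound in a 1:1 titration
#'
#' Closed-form ligand-depletion isotherm for a 1:1 complex at total protein
#' `P` and total labelled ligand `L`:
#' \deqn{f = \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4 P L}}{2L}}
#' evaluated in the numerically stable rationalized form
#' `f = 2P / (b + sqrt(b^2 - 4PL))` with `b = P + L + Kd`, which avoids the
#' catastrophic cancellation of the textbook form when `4PL << b^2`.
#'
#' @param P Total protein concentration(s), nM (>= 0; vectorized).
#' @param L Total labelled ligand concentration, nM (> 0).
#' @param Kd Dissociation constant, nM (>= 0).
#' @return Fraction bound in `[0, 1]`.
#' @export
fraction_bound <- function(P, L, Kd) {
  if (any(P < 0) || L <= 0 || Kd < 0) {
    abort("requires P >= 0, L > 0, Kd >= 0")
  }
  b <- P + L + Kd
  disc <- pmax(b^2 - 4 * P * L, 0)
  denom <- b + sqrt(disc)
  out <- ifelse(P == 0, 0, 2 * P / denom)
  pmin(pmax(out, 0), 1)
}

#' Fit a fluorescence-anisotropy titration
#'
#' Least-squares fit of
#' `A(P) = A_free + (A_bound - A_free) * fraction_bound(P, L, Kd)` over
#' `(Kd, A_free, A_bound)` by Levenberg-Marquardt, multi-started from a grid
#' of Kd values spanning one decade below to one decade above the titrated
#' concentration range; the best-SSR convergent start wins.  Standard errors
#' come from the Jacobian at the optimum.  A fit whose Kd falls below the
#' lowest non-zero concentration (binding already saturated at the first
#' point) is flagged non-identifiable rather than trusted.
#'
#' @param series Tibble with columns `protein_nM` and `anisotropy` (e.g.
#'   from [simulate_titration()]); replicate points are pooled.
#' @param L Labelled ligand concentration, nM (default 75).
#' @return A `binding_fit` object: list with `Kd`, `A_free`, `A_bound`,
#'   their standard errors, `residuals`, `converged`, `identifiable`, the
#'   underlying `nls` fit and the data.
#' @export
fit_titration <- function(series, L = 75) {
  stopifnot(is.data.frame(series),
            all(c("protein_nM", "anisotropy") %in% names(series)))
  df <- filter(series, complete.cases(.data$protein_nM, .data$anisotropy))
  if (length(unique(df$protein_nM)) < 5) {
    abort("at least 5 distinct concentrations are required for fitting")
  }
  if (diff(range(df$anisotropy)) == 0) {
    abort("no binding signal: anisotropy is constant across the titration")
  }
  assert_scalar_number(L, "L", positive = TRUE)
  pos <- sort(unique(df$protein_nM[df$protein_nM > 0]))
  kd_grid <- 10^seq(log10(min(pos)) - 1, log10(max(pos)) + 1, by = 0.5)
  a_lo <- min(df$anisotropy); a_hi <- max(df$anisotropy)
  best <- NULL
  for (kd0 in kd_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        anisotropy ~ A_free + (A_bound - A_free) * fraction_bound(protein_nM, L, Kd),
        data = df,
        start = list(Kd = kd0, A_free = a_lo, A_bound = a_hi),
        lower = c(Kd = 1e-9, A_free = -Inf, A_bound = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr - 1e-12) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, identifiable = FALSE,
                          data = df, L = L),
                     class = "binding_fit"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  identifiable <- cf[["Kd"]] >= min(pos)
  structure(list(
    Kd = unname(cf[["Kd"]]), A_free = unname(cf[["A_free"]]),
    A_bound = unname(cf[["A_bound"]]),
    se = c(Kd = unname(se[["Kd"]]), A_free = unname(se[["A_free"]]),
           A_bound = unname(se[["A_bound"]])),
    residuals = unname(stats::residuals(best$fit)),
    converged = TRUE, identifiable = identifiable,
    fit = best$fit, data = df, L = L
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<binding_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<binding_fit> Kd = %.4g nM (SE %.3g), A_free = %.4g, A_bound = %.4g%s\n",
              x$Kd, x$se[["Kd"]], x$A_free, x$A_bound,
              if (x$identifiable) "" else " [non-identifiable: Kd below sampled range]"))
  invisible(x)
}

#' @describeIn fit_titration One row per fitted parameter with estimate and
#'   standard error.
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @export
tidy.binding_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = character(0), estimate = numeric(0),
                  std.error = numeric(0)))
  }
  tibble(term = c("Kd", "A_free", "A_bound"),
         estimate = c(x$Kd, x$A_free, x$A_bound),
         std.error = unname(x$se[c("Kd", "A_free", "A_bound")]))
}

#' @describeIn fit_titration One-row fit summary (Kd, convergence,
#'   identifiability, residual standard deviation, number of points).
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(Kd = if (x$converged) x$Kd else NA_real_,
         converged = x$converged,
         identifiable = x$identifiable,
         sigma = if (x$converged) sqrt(mean(x$residuals^2)) else NA_real_,
         nobs = nrow(x$data))
}
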