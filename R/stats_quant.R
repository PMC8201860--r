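# Dose-response probit analysis (LC50 with Fieller confidence limits,
# resistance ratios, likelihood-ratio tests for equality of probit
# regressions) and delta-delta-Ct relative expression.

#' Fit a binomial probit dose-response model
#'
#' Maximum-likelihood probit regression of mortality on log10(dose) via
#' [stats::glm()]. The LC50 is `10^(-intercept/slope)`; its 95% confidence
#' interval uses Fieller's theorem on the ratio `-intercept/slope`, falling
#' back to the delta method (flagged) when the Fieller discriminant is
#' non-positive. Degenerate data (all dead or none dead at every dose) give
#' a flagged fit with no LC50.
#'
#' @param data data.frame with columns `dose` (> 0), `n` (treated) and
#'   `dead`; at least 3 distinct doses.
#' @param clone optional label carried through to outputs.
#' @return a `probit_fit` with components `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `lc50`, `lc50_ci` (95%), `ci_method`, `loglik`,
#'   `converged`, `flagged`, `model` (the glm), `data`, `clone`.
#' @examples
#' d <- simulate_dose_response(lc50 = 10, slope = 1.2,
#'                             doses = 10^seq(-1, 3, length.out = 7),
#'                             n = 50, seed = 1)
#' fit <- fit_probit(d)
#' fit$lc50
#' @export
fit_probit <- function(data, clone = NULL) {
  stopifnot(all(c("dose", "n", "dead") %in% names(data)))
  if (any(data$dose <= 0)) stop("doses must be positive")
  if (any(data$dead < 0 | data$dead > data$n)) {
    stop("dead must lie in [0, n]")
  }
  if (length(unique(data$dose)) < 3L) stop("need at least 3 distinct doses")
  out <- list(clone = clone, data = data)
  class(out) <- "probit_fit"
  if (all(data$dead == 0L) || all(data$dead == data$n)) {
    out$flagged <- TRUE
    out$flag_reason <- "degenerate mortality (all 0% or all 100%)"
    out$converged <- FALSE
    out$lc50 <- NA_real_
    return(out)
  }
  x <- log10(data$dose)
  fit <- stats::glm(cbind(dead, n - dead) ~ x,
                    family = stats::binomial(link = "probit"),
                    data = data)
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  slope <- unname(b[2]); inter <- unname(b[1])
  theta <- -inter / slope            # log10 LC50
  z <- stats::qnorm(0.975)
  # Fieller limits for -intercept/slope
  g <- z^2 * V[2, 2] / slope^2
  ci_method <- "fieller"
  if (is.finite(g) && g < 1) {
    centre <- (theta + g * V[1, 2] / V[2, 2]) / (1 - g)
    disc <- V[1, 1] + 2 * theta * V[1, 2] + theta^2 * V[2, 2] -
      g * (V[1, 1] - V[1, 2]^2 / V[2, 2])
    if (disc > 0) {
      half <- z / (abs(slope) * (1 - g)) * sqrt(disc)
      ci <- c(centre - half, centre + half)
    } else {
      ci_method <- "delta"
      se_theta <- sqrt((V[1, 1] + 2 * theta * V[1, 2] + theta^2 * V[2, 2])) /
        abs(slope)
      ci <- theta + c(-1, 1) * z * se_theta
    }
  } else {
    ci_method <- "delta"
    se_theta <- sqrt((V[1, 1] + 2 * theta * V[1, 2] + theta^2 * V[2, 2])) /
      abs(slope)
    ci <- theta + c(-1, 1) * z * se_theta
  }
  out$slope <- slope
  out$slope_se <- sqrt(V[2, 2])
  out$intercept <- inter
  out$intercept_se <- sqrt(V[1, 1])
  out$lc50 <- 10^theta
  out$lc50_ci <- 10^ci
  out$ci_method <- ci_method
  out$loglik <- as.numeric(stats::logLik(fit))
  out$converged <- fit$converged
  out$flagged <- !fit$converged || ci_method == "delta"
  out$model <- fit
  out
}

#' @export
print.probit_fit <- function(x, ...) {
  if (isTRUE(x$flagged) && is.na(x$lc50)) {
    cat("Probit fit flagged:", x$flag_reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("Probit dose-response%s: slope %.3f +/- %.3f (log10 dose)\n",
              if (!is.null(x$clone)) paste0(" [", x$clone, "]") else "",
              x$slope, x$slope_se))
  cat(sprintf("  LC50 %.4g (95%% CI %.4g - %.4g, %s)\n",
              x$lc50, x$lc50_ci[1], x$lc50_ci[2], x$ci_method))
  invisible(x)
}

#' @export
coef.probit_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted mortality at given doses
#'
#' @param object a `probit_fit`.
#' @param doses numeric doses.
#' @param ... unused.
#' @return predicted mortality fractions.
#' @export
predict.probit_fit <- function(object, doses, ...) {
  stats::pnorm(object$intercept + object$slope * log10(doses))
}

#' Resistance ratio
#'
#' Ratio of a test LC50 to a reference LC50, reported to 3 significant
#' figures.
#'
#' @param fit_or_lc50 a `probit_fit` or a numeric LC50.
#' @param reference_lc50 a `probit_fit` or numeric LC50 of the reference
#'   (susceptible) strain.
#' @return numeric resistance ratio (3 s.f.).
#' @examples
#' resistance_ratio(3.19, 1.07)   # 2.98
#' @export
resistance_ratio <- function(fit_or_lc50, reference_lc50) {
  lc <- function(x) if (inherits(x, "probit_fit")) x$lc50 else x
  a <- lc(fit_or_lc50); b <- lc(reference_lc50)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("resistance ratio requires positive LC50s")
  }
  signif(a / b, 3)
}

#' Likelihood-ratio test for equality of probit regressions
#'
#' Tests the null hypothesis that all groups share one slope and one
#' intercept: `chi2 = 2 * (sum of separate log-likelihoods - pooled
#' log-likelihood)` with `2*(k-1)` degrees of freedom for `k` groups.
#'
#' @param datasets list of dose-response data.frames (see [fit_probit()]).
#' @return list with `chi2`, `df`, `p`.
#' @export
lrt_equality <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least two datasets")
  fits <- lapply(datasets, fit_probit)
  if (any(vapply(fits, function(f) is.na(f$lc50), logical(1)))) {
    stop("a member fit failed; cannot test equality")
  }
  ll_sep <- sum(vapply(fits, `[[`, numeric(1), "loglik"))
  pooled <- do.call(rbind, lapply(datasets, function(d)
    d[, c("dose", "n", "dead")]))
  x <- log10(pooled$dose)
  pool_fit <- stats::glm(cbind(dead, n - dead) ~ x,
                         family = stats::binomial(link = "probit"),
                         data = pooled)
  chi2 <- 2 * (ll_sep - as.numeric(stats::logLik(pool_fit)))
  df <- 2L * (length(datasets) - 1L)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Simulate a dose-mortality experiment under a probit model
#'
#' @param lc50 true LC50.
#' @param slope true probit slope on log10 dose.
#' @param doses dose series.
#' @param n insects per dose.
#' @param seed integer seed.
#' @return data.frame with columns dose, n, dead.
#' @export
simulate_dose_response <- function(lc50, slope, doses, n, seed = 1) {
  stopifnot(lc50 > 0, all(doses > 0))
  p <- stats::pnorm(slope * (log10(doses) - log10(lc50)))
  with_seed(seed, data.frame(
    dose = doses, n = n, dead = stats::rbinom(length(doses), n, p)))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Normalises each target gene's Ct against the arithmetic mean of the
#' housekeeping genes' Cts (equivalent to the log of the geometric mean of
#' their linear quantities) and reports fold changes `2^-ddCt` relative to
#' the calibrator sample.
#'
#' @param ct_table data.frame with columns `sample`, `gene`, `ct`.
#' @param target_genes character vector of target gene names.
#' @param housekeeping_genes character vector (>= 1) of normaliser genes.
#' @param calibrator_sample sample against which fold changes are
#'   expressed.
#' @return data.frame: sample, gene, dct, ddct, fold_change.
#' @examples
#' ct <- expand.grid(sample = c("A", "B"), gene = c("tgt", "hk1", "hk2"),
#'                   stringsAsFactors = FALSE)
#' ct$ct <- c(20, 19, 25, 25, 25, 25)   # target 1 Ct lower in B
#' ddct_fold_change(ct, "tgt", c("hk1", "hk2"), "A")
#' @export
ddct_fold_change <- function(ct_table, target_genes, housekeeping_genes,
                             calibrator_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct_table)),
            length(housekeeping_genes) >= 1L)
  samples <- unique(ct_table$sample)
  if (!calibrator_sample %in% samples) stop("calibrator sample absent")
  get_ct <- function(s, g) {
    v <- ct_table$ct[ct_table$sample == s & ct_table$gene == g]
    if (length(v) != 1L || is.na(v)) {
      stop("missing Ct for sample ", s, ", gene ", g)
    }
    v
  }
  rows <- list()
  for (s in samples) {
    norm <- mean(vapply(housekeeping_genes, get_ct, numeric(1), s = s))
    for (g in target_genes) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = g, dct = get_ct(s, g) - norm,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  cal <- out[out$sample == calibrator_sample, ]
  out$ddct <- out$dct - cal$dct[match(out$gene, cal$gene)]
  out$fold_change <- 2^(-out$ddct)
  out
}

#' Build a dose-response summary table across clones
#'
#' One row per clone: LC50, 95% CI, slope +/- SE, resistance ratio against
#' the reference clone, and the likelihood-ratio equality test of each
#' clone against the reference.
#'
#' @param data data.frame with columns `clone`, `dose`, `n`, `dead`.
#' @param reference reference clone name.
#' @return data.frame, one row per clone.
#' @export
dose_response_table <- function(data, reference) {
  stopifnot(all(c("clone", "dose", "n", "dead") %in% names(data)))
  clones <- unique(data$clone)
  if (!reference %in% clones) stop("reference clone absent")
  fits <- lapply(clones, function(cl)
    fit_probit(data[data$clone == cl, ], clone = cl))
  names(fits) <- clones
  ref_fit <- fits[[reference]]
  rows <- lapply(clones, function(cl) {
    f <- fits[[cl]]
    rr <- if (cl == reference) NA_real_ else
      resistance_ratio(f, ref_fit)
    lrt <- if (cl == reference) list(chi2 = NA, df = NA, p = NA) else
      lrt_equality(list(data[data$clone == reference, ],
                        data[data$clone == cl, ]))
    data.frame(clone = cl, lc50 = f$lc50, ci_lo = f$lc50_ci[1],
               ci_hi = f$lc50_ci[2], slope = f$slope,
               slope_se = f$slope_se, rr = rr, chi2 = lrt$chi2,
               df = lrt$df, p = lrt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
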