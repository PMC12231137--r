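# Trait-environment models: simple linear regressions and penalized
# additive (smooth) models with the standard GAM summary surface (per-term
# edf / reference df / F / p, adjusted R-squared, % deviance explained, GCV).

#' Ordinary least-squares fit of y on x
#'
#' Two-sided t test on the slope; both plain and adjusted R-squared are
#' reported.
#'
#' @param x,y Numeric vectors; `NA` pairs dropped; `>= 3` complete pairs and
#'   non-constant `x` required.
#' @return List of class `linear_fit`: `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("linear_fit needs >= 3 complete pairs")
  if (stats::sd(x) == 0) stop("linear_fit: x has zero variance")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared,
                 p_value = s$coefficients[2L, 4L],
                 n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): slope %.4g, intercept %.4g\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("R-sq = %.3f (adj %.3f), slope p = %.3g\n",
              x$r_squared, x$adj_r_squared, x$p_value))
  invisible(x)
}

#' Penalized additive model with GCV smoothing selection
#'
#' Fits `response ~ s(term1) + s(term2) + ...` with thin-plate regression
#' splines (basis dimension `k` per smooth), smoothing parameters chosen by
#' generalized cross-validation, Gaussian family with identity link
#' (engine: `mgcv::gam`). The summary surface is the standard GAM one:
#' per-smooth edf, reference df, approximate F and p; intercept with SE;
#' adjusted R-squared; % deviance explained; GCV score; n.
#'
#' @param data `data.frame` of complete cases (rows with `NA` in used columns
#'   are dropped; `>= 30` must remain).
#' @param response Response column name.
#' @param smooth_terms Character vector of predictor column names (each gets
#'   one smooth); duplicates are an error.
#' @param k Basis dimension per smooth (default 10).
#' @return Object of class `additive_fit`: `summary` (per-term data.frame),
#'   `intercept`, `intercept_se`, `adj_r_squared`, `deviance_explained_pct`,
#'   `gcv`, `n`, `formula`, and the underlying `fit`.
#' @export
fit_additive_model <- function(data, response, smooth_terms, k = 10) {
  if (anyDuplicated(smooth_terms)) stop("duplicate smooth terms")
  miss <- setdiff(c(response, smooth_terms), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  use <- data[, c(response, smooth_terms), drop = FALSE]
  use <- use[stats::complete.cases(use), , drop = FALSE]
  if (nrow(use) < 30L) stop("fit_additive_model needs >= 30 complete cases, got ",
                            nrow(use))
  for (tm in smooth_terms)
    if (stats::sd(use[[tm]]) == 0) stop("constant predictor: ", tm)
  fml <- stats::as.formula(paste(
    sprintf("`%s`", response), "~",
    paste(sprintf("s(`%s`, k = %d)", smooth_terms, k), collapse = " + ")))
  fit <- mgcv::gam(fml, data = use, method = "GCV.Cp")
  if (!fit$converged)
    stop("smoothing parameter selection did not converge (",
         "n = ", nrow(use), ", k = ", k, ")")
  s <- summary(fit)
  st <- as.data.frame(s$s.table)
  names(st) <- c("edf", "ref_df", "F", "p_value")
  st$term <- gsub("`", "", rownames(st))
  st$stars <- significance_stars(st$p_value)
  rownames(st) <- NULL
  structure(list(
    summary = st[, c("term", "edf", "ref_df", "F", "p_value", "stars")],
    intercept = unname(s$p.table[1L, 1L]),
    intercept_se = unname(s$p.table[1L, 2L]),
    adj_r_squared = s$r.sq,
    deviance_explained_pct = 100 * s$dev.expl,
    gcv = unname(fit$gcv.ubre),
    scale_est = s$scale,
    n = nrow(use),
    response = response,
    formula = paste(response, "~",
                    paste(sprintf("s(%s)", smooth_terms), collapse = " + ")),
    fit = fit), class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat("Additive model:", x$formula, "\n")
  cat(sprintf("(Intercept) %.5g  (SE %.3g)\n", x$intercept, x$intercept_se))
  cat("Approximate significance of smooth terms:\n")
  out <- x$summary
  out$edf <- round(out$edf, 3); out$ref_df <- round(out$ref_df, 3)
  out$F <- round(out$F, 3); out$p_value <- signif(out$p_value, 3)
  print(out, row.names = FALSE)
  cat(sprintf("R-sq.(adj) = %.3f; deviance explained = %.1f%%\n",
              x$adj_r_squared, x$deviance_explained_pct))
  cat(sprintf("GCV = %.4g; n = %d\n", x$gcv, x$n))
  invisible(x)
}

#' Run the standard model battery on a merged trait/metadata table
#'
#' Fits the two headline additive models —
#' `pH ~ s(Organic_Matter_LOI) + s(ave.gs) + s(ave.rrna) + s(ave.gc)` and
#' `ave.snb ~ s(Organic_Matter_LOI) + s(pH) + s(ave.gs) + s(ave.rrna) +
#' s(ave.gc)` — plus the four simple regressions (pH ~ OM,
#' ave.gs ~ ave.rrna, simpson ~ pH, ave.snb ~ ave.gs), and emits one
#' machine-readable report. Within each additive model, term p-values are
#' additionally Benjamini-Hochberg adjusted and starred at 0.05/0.01/0.001.
#'
#' @param profiles Per-sample trait table from [weighted_sample_traits()]
#'   (needs `ave.gs`, `ave.rrna`, `ave.gc`, `ave.snb`, `simpson`).
#' @param meta Sample metadata (needs `pH`, `om_loi`).
#' @param k Basis dimension per smooth (default 10).
#' @return Object of class `model_battery`: `gam_ph`, `gam_snb`
#'   (`additive_fit`s), `linear` (list of `linear_fit`s), and `report`
#'   (one row per model term).
#' @export
model_battery <- function(profiles, meta, k = 10) {
  need_p <- c("sample_id", "ave.gs", "ave.rrna", "ave.gc", "ave.snb", "simpson")
  need_m <- c("sample_id", "pH", "om_loi")
  miss <- c(setdiff(need_p, names(profiles)), setdiff(need_m, names(meta)))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- merge(profiles[need_p], meta[need_m], by = "sample_id")
  df$Organic_Matter_LOI <- df$om_loi

  gam_ph <- fit_additive_model(df, "pH",
                               c("Organic_Matter_LOI", "ave.gs", "ave.rrna", "ave.gc"),
                               k = k)
  gam_snb <- fit_additive_model(df, "ave.snb",
                                c("Organic_Matter_LOI", "pH", "ave.gs",
                                  "ave.rrna", "ave.gc"), k = k)
  linear <- list(
    ph_om = linear_fit(df$om_loi, df$pH),
    gs_rrna = linear_fit(df$ave.rrna, df$ave.gs),
    simpson_ph = linear_fit(df$pH, df$simpson),
    snb_gs = linear_fit(df$ave.gs, df$ave.snb))

  gam_report <- function(fit, model) {
    out <- fit$summary
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$stars <- significance_stars(out$p_adjusted)
    data.frame(model = model, term = out$term, statistic = out$F,
               edf = out$edf, p_value = out$p_value,
               p_adjusted = out$p_adjusted, stars = out$stars,
               r_squared = fit$adj_r_squared, n = fit$n,
               stringsAsFactors = FALSE)
  }
  lin_report <- function(fit, model, term) {
    data.frame(model = model, term = term, statistic = fit$slope,
               edf = NA_real_, p_value = fit$p_value,
               p_adjusted = fit$p_value,
               stars = significance_stars(fit$p_value),
               r_squared = fit$r_squared, n = fit$n,
               stringsAsFactors = FALSE)
  }
  report <- rbind(
    gam_report(gam_ph, "gam_pH"),
    gam_report(gam_snb, "gam_ave.snb"),
    lin_report(linear$ph_om, "lm_pH_om", "om_loi"),
    lin_report(linear$gs_rrna, "lm_ave.gs_ave.rrna", "ave.rrna"),
    lin_report(linear$simpson_ph, "lm_simpson_pH", "pH"),
    lin_report(linear$snb_gs, "lm_ave.snb_ave.gs", "ave.gs"))
  structure(list(gam_ph = gam_ph, gam_snb = gam_snb, linear = linear,
                 report = report, n = nrow(df)),
            class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat("Model battery over", x$n, "samples\n\n")
  print(x$gam_ph); cat("\n"); print(x$gam_snb); cat("\n")
  cat("Simple regressions:\n")
  for (nm in names(x$linear)) {
    f <- x$linear[[nm]]
    cat(sprintf("  %-12s R-sq = %.3f (adj %.3f), p = %.3g, n = %d\n",
                nm, f$r_squared, f$adj_r_squared, f$p_value, f$n))
  }
  invisible(x)
}
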