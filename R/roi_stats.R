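# ROI-level statistics: group t tests with Benjamini-Hochberg FDR,
# multiple regression of DTI scalars on histology (DTI ~ AI + CD), and the
# chi projection chi = beta_AI * AI + beta_CD * CD used to display the
# fitted relationship.
#
# An ROI table holds one record per (animal, hemisphere, level, region)
# with columns: animal_id, group ("sham"/"mTBI"), hemisphere
# ("ipsilateral"/"contralateral"), level (mm from bregma: +1.08, -1.60,
# -3.60), region ("cc","ec","S1","ic","VPL"; ic and VPL only at -3.60),
# AI, CD (on the x 1e-2 cells/um^2 reporting scale), FA, AD (mm^2/s).

ROI_LEVELS <- c(1.08, -1.60, -3.60)
ROI_REGIONS <- list(`1.08` = c("cc", "ec", "S1"),
                    `-1.6` = c("cc", "ec", "S1"),
                    `-3.6` = c("cc", "ec", "S1", "ic", "VPL"))

#' Regions available at a bregma level
#' @param level Level in mm from bregma.
#' @return Character vector of region codes.
#' @export
regions_at_level <- function(level) {
  ROI_REGIONS[[as.character(round(level, 2))]] %||%
    stop("unknown bregma level: ", level)
}

#' Regression region families at a bregma level
#'
#' Single regions plus the pooled families used in the regression table:
#' cc + ec at every level, and additionally cc + ec + ic and S1 + VPL at
#' -3.60 mm.
#' @param level Level in mm from bregma.
#' @return List of character vectors.
#' @export
region_families <- function(level) {
  single <- as.list(regions_at_level(level))
  fams <- c(single, list(c("cc", "ec")))
  if (round(level, 2) == -3.60) {
    fams <- c(fams, list(c("cc", "ec", "ic"), c("S1", "VPL")))
  }
  fams
}

#' Unpaired two-sample t test
#'
#' Student's pooled-variance t by default (df = nA + nB - 2); Welch's
#' variant behind `var_equal = FALSE`. Degenerate zero-variance input is
#' handled by convention: equal means give t = 0, p = 1; unequal means
#' give t = +/-Inf, p = 0, with `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student's t (default TRUE).
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg q values
#'
#' Step-up FDR-adjusted p values: `q(i) = min_{j >= i} m p(j) / j` on the
#' sorted family, capped at 1 and mapped back to input order.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @return q values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Multiple regression of a DTI scalar on histology
#'
#' Ordinary least squares of `response ~ AI + CD` over all records of a
#' region family (both groups and both hemispheres enter, as the pooled
#' design intends). CD is used on the x 1e-2 cells/um^2 scale of the ROI
#' table, so coefficients are on the reporting scale.
#'
#' @param records ROI table (tibble/data.frame with at least `region`,
#'   `AI`, `CD` and the response column; `level` if `level` is given).
#' @param response `"FA"` or `"AD"`.
#' @param regions Character vector naming the region family.
#' @param level Optional bregma level filter.
#' @return A `regression_result` list: `response`, `family`, `n`,
#'   coefficients (`beta_AI`, `beta_CD`, `intercept`), `t_AI`, `t_CD`,
#'   `p_AI`, `p_CD`, `r2`, `r2_adj`, `F`, `p_model`, `df_model`,
#'   `df_resid` and per-record `chi` values.
#' @export
fit_dti_histology_regression <- function(records, response = c("FA", "AD"),
                                         regions, level = NULL) {
  response <- match.arg(response)
  d <- as.data.frame(records)
  if (!is.null(level)) d <- d[round(d$level, 2) == round(level, 2), , drop = FALSE]
  d <- d[d$region %in% regions, , drop = FALSE]
  fam <- paste(regions, collapse = " + ")
  if (nrow(d) < 4) stop("family '", fam, "': fewer than 4 records")
  if (stats::var(d$AI) == 0 || stats::var(d$CD) == 0 ||
      abs(stats::cor(d$AI, d$CD)) > 1 - 1e-10) {
    stop("family '", fam, "': AI and CD are collinear")
  }
  d$.y <- d[[response]]
  fit <- stats::lm(.y ~ AI + CD, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  p_model <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(
    response = response, family = fam, regions = regions, n = nrow(d),
    intercept = co["(Intercept)", "Estimate"],
    beta_AI = co["AI", "Estimate"], beta_CD = co["CD", "Estimate"],
    t_AI = co["AI", "t value"], t_CD = co["CD", "t value"],
    p_AI = co["AI", "Pr(>|t|)"], p_CD = co["CD", "Pr(>|t|)"],
    r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
    F = unname(fstat[1]), p_model = unname(p_model),
    df_model = unname(fstat[2]), df_resid = unname(fstat[3]),
    chi = chi_projection(list(beta_AI = co["AI", "Estimate"],
                              beta_CD = co["CD", "Estimate"]), d),
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s ~ AI + CD [%s]: R2adj = %.2f, F = %.1f, t(AI) = %.2f, t(CD) = %.2f, n = %d\n",
              x$response, x$family, x$r2_adj, x$F, x$t_AI, x$t_CD, x$n))
  invisible(x)
}

#' Chi projection of ROI records
#'
#' `chi = beta_AI * AI + beta_CD * CD` -- the fitted linear combination
#' without the intercept, used as the x axis of regression scatter plots.
#'
#' @param result A `regression_result` (or any list with `beta_AI`,
#'   `beta_CD`).
#' @param records ROI records with `AI` and `CD` columns.
#' @return Numeric vector of chi values.
#' @export
chi_projection <- function(result, records) {
  result$beta_AI * records$AI + result$beta_CD * records$CD
}

#' Cohort analysis: group-contrast and regression tables
#'
#' Reproduces the two reporting tables from an ROI table. The t-test table
#' has one row per (level, region, hemisphere, measure in AI/CD) with
#' group means +/- SD, the pooled t statistic and BH q values; the default
#' FDR family is one family per measure across all levels, regions and
#' hemispheres (`fdr_family = "per_measure"`), with a single pooled family
#' available. The regression table fits `FA ~ AI + CD` and `AD ~ AI + CD`
#' over the region families of [region_families()] per level, with one BH
#' family covering all regression p values (coefficients and model).
#'
#' @param records ROI table.
#' @param alpha Significance threshold on q (default 0.05).
#' @param fdr_family `"per_measure"` (default) or `"pooled"` for the
#'   t-test table.
#' @param var_equal Pooled-variance t test (default TRUE).
#' @return List of tibbles `t_table`, `regression_table`, `chi_table`.
#' @export
analyze_cohort <- function(records, alpha = 0.05,
                           fdr_family = c("per_measure", "pooled"),
                           var_equal = TRUE) {
  fdr_family <- match.arg(fdr_family)
  d <- as.data.frame(records)
  rows <- list()
  for (lv in ROI_LEVELS) {
    for (rg in regions_at_level(lv)) {
      for (hemi in c("ipsilateral", "contralateral")) {
        for (me in c("AI", "CD")) {
          sub <- d[round(d$level, 2) == round(lv, 2) & d$region == rg &
                     d$hemisphere == hemi, , drop = FALSE]
          a <- sub[[me]][sub$group == "sham"]
          b <- sub[[me]][sub$group == "mTBI"]
          if (length(a) < 2 || length(b) < 2) {
            warning("missing records for ", rg, " at ", lv, " (", hemi, ", ", me, ")")
            rows[[length(rows) + 1L]] <- tibble::tibble(
              level = lv, region = rg, hemisphere = hemi, measure = me,
              mean_sham = NA_real_, sd_sham = NA_real_,
              mean_mTBI = NA_real_, sd_mTBI = NA_real_,
              t = NA_real_, df = NA_real_, p = NA_real_)
            next
          }
          tt <- unpaired_t(a, b, var_equal = var_equal)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            level = lv, region = rg, hemisphere = hemi, measure = me,
            mean_sham = mean(a), sd_sham = stats::sd(a),
            mean_mTBI = mean(b), sd_mTBI = stats::sd(b),
            t = tt$t, df = tt$df, p = tt$p)
        }
      }
    }
  }
  t_table <- dplyr::bind_rows(rows)
  t_table$q <- NA_real_
  ok <- !is.na(t_table$p)
  if (fdr_family == "per_measure") {
    for (me in c("AI", "CD")) {
      i <- ok & t_table$measure == me
      t_table$q[i] <- bh_fdr(t_table$p[i])
    }
  } else {
    t_table$q[ok] <- bh_fdr(t_table$p[ok])
  }
  t_table$significant <- !is.na(t_table$q) & t_table$q < alpha

  reg_rows <- list(); chi_rows <- list()
  for (lv in ROI_LEVELS) {
    for (fam in region_families(lv)) {
      for (resp in c("FA", "AD")) {
        res <- tryCatch(
          fit_dti_histology_regression(d, resp, fam, level = lv),
          error = function(e) NULL)
        if (is.null(res)) {
          warning("regression skipped for ", paste(fam, collapse = "+"),
                  " at ", lv, " (", resp, ")")
          next
        }
        reg_rows[[length(reg_rows) + 1L]] <- tibble::tibble(
          level = lv, family = res$family, response = resp, n = res$n,
          beta_AI = res$beta_AI, beta_CD = res$beta_CD,
          intercept = res$intercept,
          t_AI = res$t_AI, t_CD = res$t_CD,
          p_AI = res$p_AI, p_CD = res$p_CD,
          r2_adj = res$r2_adj, F = res$F, p_model = res$p_model)
        sub <- d[round(d$level, 2) == round(lv, 2) & d$region %in% fam, , drop = FALSE]
        chi_rows[[length(chi_rows) + 1L]] <- tibble::tibble(
          level = lv, family = res$family, response = resp,
          animal_id = sub$animal_id, group = sub$group,
          hemisphere = sub$hemisphere, region = sub$region,
          chi = res$chi, value = sub[[resp]])
      }
    }
  }
  regression_table <- dplyr::bind_rows(reg_rows)
  if (nrow(regression_table) > 0) {
    # one family over all regression p values (coefficient + model)
    m <- nrow(regression_table)
    fam_p <- c(regression_table$p_AI, regression_table$p_CD,
               regression_table$p_model)
    fam_q <- bh_fdr(fam_p)
    regression_table$q_AI <- fam_q[seq_len(m)]
    regression_table$q_CD <- fam_q[m + seq_len(m)]
    regression_table$q_model <- fam_q[2 * m + seq_len(m)]
  }
  list(t_table = t_table,
       regression_table = regression_table,
       chi_table = dplyr::bind_rows(chi_rows))
}
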