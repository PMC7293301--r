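# The joint linear dosage model: OLS of carrier expression z-scores on the
# five SV covariates (exonic proportion, enhancer sum, promoter proportion,
# SV length in raw bp, within-TAD indicator), fitted separately for
# deletions and duplications. An intercept is included: carrier z-scores
# need not be mean zero and omitting it would bias the slopes (it can be
# switched off for the no-intercept parameterization).

DOSAGE_COVARIATES <- c("p_exon", "enh_sum", "p_prom", "sv_length", "within_tad")

#' Fit the joint dosage model for one CNV type
#'
#' @param features a [build_feature_table] output (or any data.frame with
#'   the five covariates); rows are joined to `effects` on
#'   `(sv_id, gene_id)` unless `effects` is `NULL` and `features` already
#'   carries a `z_score` column.
#' @param effects an [expression_effects] table, or `NULL`.
#' @param sv_type `"DEL"` or `"DUP"`; only rows of this type are fitted.
#' @param intercept include an intercept (default `TRUE`).
#' @param cohort optional label stored on the fit.
#' @return object of class `dosage_fit`: list with `sv_type`,
#'   `coefficients` (data.frame term/beta/se/t/p), `n`, `cohort`, `lm`.
#' @export
fit_dosage_model <- function(features, effects = NULL, sv_type = c("DEL", "DUP"),
                             intercept = TRUE, cohort = NA_character_) {
  sv_type <- match.arg(sv_type)
  df <- join_features_effects(features, effects)
  df <- df[df$sv_type == sv_type & !is.na(df$z_score), , drop = FALSE]
  if (nrow(df) < 10 * (length(DOSAGE_COVARIATES) + intercept))
    stop("too few rows (", nrow(df), ") to fit the ", sv_type, " dosage model")
  fml <- stats::as.formula(paste("z_score ~", paste(DOSAGE_COVARIATES, collapse = " + "),
                                 if (!intercept) "- 1" else ""))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  ct <- summary(fit)$coefficients
  out <- list(sv_type = sv_type,
              coefficients = data.frame(term = rownames(ct), beta = ct[, 1],
                                        se = ct[, 2], t = ct[, 3], p = ct[, 4],
                                        row.names = NULL, stringsAsFactors = FALSE),
              n = nrow(df), cohort = cohort, intercept = intercept, lm = fit)
  class(out) <- "dosage_fit"
  out
}

join_features_effects <- function(features, effects) {
  if (is.null(effects)) {
    stopifnot("z_score" %in% names(features))
    return(features)
  }
  f <- data.table::as.data.table(features)
  e <- data.table::as.data.table(
    effects[, c("sv_id", "gene_id", "z_score"), drop = FALSE])
  as.data.frame(merge(f, e, by = c("sv_id", "gene_id")))
}

#' @exportS3Method base::print
print.dosage_fit <- function(x, ...) {
  cat(sprintf("dosage_fit (%s%s): n = %d rows\n", x$sv_type,
              if (!is.na(x$cohort)) paste0(", ", x$cohort) else "", x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Predict expression z-scores from a fitted dosage model
#'
#' @param model a [fit_dosage_model] object.
#' @param features data.frame with the five covariates and `sv_type`.
#' @return numeric vector of linear predictions, one per feature row.
#' @export
predict_z <- function(model, features) {
  if (!all(features$sv_type == model$sv_type))
    stop("sv_type mismatch: model is for ", model$sv_type)
  beta <- setNames(model$coefficients$beta, model$coefficients$term)
  X <- as.matrix(features[, DOSAGE_COVARIATES, drop = FALSE])
  pred <- drop(X %*% beta[DOSAGE_COVARIATES])
  if ("(Intercept)" %in% names(beta)) pred <- pred + beta[["(Intercept)"]]
  unname(pred)
}

#' Cross-cohort prediction evaluation
#'
#' Fits the dosage model per cohort and CNV type on that cohort's carrier
#' z-scores, predicts on every cohort (including itself), and reports the
#' squared Pearson correlation between predicted and observed z.
#'
#' @param study a [simulate_study] object, or a list with `svs`,
#'   `features`, `cpm`, `adjusted`, `cohort_of`.
#' @param min_pairs cohorts contributing fewer usable pairs are skipped
#'   with a warning (default 100).
#' @return data.frame `train`, `test`, `sv_type`, `r2`, `n`.
#' @export
cross_cohort_eval <- function(study, min_pairs = 100) {
  cohorts <- unique(unname(study$cohort_of))
  eff <- lapply(cohorts, function(co)
    expression_effects(study$svs, study$features, study$cpm, study$adjusted,
                       samples = names(study$cohort_of)[study$cohort_of == co]))
  names(eff) <- cohorts
  out <- list()
  for (ty in CNV_TYPES) for (tr in cohorts) {
    dtr <- join_features_effects(study$features, eff[[tr]])
    dtr <- dtr[dtr$sv_type == ty & !is.na(dtr$z_score), , drop = FALSE]
    if (nrow(dtr) < min_pairs) {
      warning(sprintf("cohort %s has %d usable %s pairs (< %d); skipped",
                      tr, nrow(dtr), ty, min_pairs))
      next
    }
    fit <- fit_dosage_model(dtr, NULL, ty, cohort = tr)
    for (te in cohorts) {
      dte <- join_features_effects(study$features, eff[[te]])
      dte <- dte[dte$sv_type == ty & !is.na(dte$z_score), , drop = FALSE]
      if (nrow(dte) < min_pairs) next
      pred <- predict_z(fit, dte)
      r2 <- if (sd(pred) == 0 || sd(dte$z_score) == 0) NA_real_
            else cor(pred, dte$z_score)^2
      out[[length(out) + 1]] <- data.frame(train = tr, test = te, sv_type = ty,
                                           r2 = r2, n = nrow(dte),
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
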