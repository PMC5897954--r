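# Fixed-effects model comparison for localization accuracy.

default_accuracy_formulas <- function() {
  list(
    m0      = loc_accuracy ~ 1,
    m1      = loc_accuracy ~ period,
    m2      = loc_accuracy ~ dist,
    m3      = loc_accuracy ~ areamic,
    m4      = loc_accuracy ~ period + dist,
    m4.int  = loc_accuracy ~ period * dist,
    m5      = loc_accuracy ~ period + areamic,
    m5.int  = loc_accuracy ~ period * areamic,
    m6      = loc_accuracy ~ dist + areamic,
    m6.int  = loc_accuracy ~ dist * areamic,
    mc      = loc_accuracy ~ period + dist + areamic
  )
}

#' Compare linear accuracy models by AIC
#'
#' Fits ordinary least-squares models of localization accuracy on
#' combinations of the design covariates (`period`, `dist`, `areamic`,
#' singly, summed and with interactions — eleven models by default,
#' including the intercept-only null) and ranks them by AIC
#' (`2k - 2 lnL` with the Gaussian profile likelihood). Rank-deficient
#' designs are flagged but do not stop the comparison.
#'
#' @param records Evaluation records (see [evaluate_campaign()]).
#' @param formulas Named list of model formulas; default
#'   the eleven-model set above.
#' @return An object of class `accuracy_models`. [glance()] gives the AIC
#'   table (sorted, with `delta_aic`), [tidy()] the coefficient estimates
#'   with standard errors, and [autoplot()] an AIC dot plot.
#' @export
fit_models_aic <- function(records, formulas = default_accuracy_formulas()) {
  records <- records %>% filter(complete.cases(records[all.vars(formulas[[length(formulas)]])]))
  p_max <- max(purrr::map_int(formulas, function(f) {
    tryCatch(ncol(stats::model.matrix(stats::delete.response(stats::terms(f)),
                                      records)),
             error = function(e) 0L)
  }))
  if (nrow(records) < p_max + 2) {
    abort("too few records for the largest model")
  }
  fits <- purrr::imap(formulas, function(f, name) {
    fit <- tryCatch(lm(f, data = records), error = function(e) NULL)
    bad <- is.null(fit) ||
      fit$rank < length(stats::coef(fit)) ||
      anyNA(stats::coef(fit))
    list(
      name = name, fit = fit,
      comparison = tibble(
        model = name,
        fixed_effects = paste(deparse(f[[3]]), collapse = ""),
        k = if (is.null(fit)) NA_integer_ else length(stats::coef(fit)) + 1L,
        aic = if (is.null(fit)) NA_real_ else AIC(fit),
        rank_deficient = bad
      )
    )
  })
  comparison <- purrr::map(fits, "comparison") %>%
    bind_rows() %>%
    arrange(.data$aic) %>%
    mutate(delta_aic = .data$aic - min(.data$aic, na.rm = TRUE))
  structure(
    list(fits = purrr::map(fits, "fit"), comparison = comparison,
         n = nrow(records)),
    class = "accuracy_models"
  )
}

#' @export
print.accuracy_models <- function(x, ...) {
  cat(sprintf("<accuracy_models> %d OLS models on %d records\n",
              nrow(x$comparison), x$n))
  print(x$comparison)
  invisible(x)
}

#' @rdname fit_models_aic
#' @param x An `accuracy_models` object.
#' @param ... Unused.
#' @method glance accuracy_models
#' @export
glance.accuracy_models <- function(x, ...) {
  x$comparison
}

#' @rdname fit_models_aic
#' @method tidy accuracy_models
#' @export
tidy.accuracy_models <- function(x, ...) {
  purrr::imap(x$fits, function(fit, name) {
    if (is.null(fit)) return(NULL)
    s <- summary(fit)$coefficients
    tibble(
      model = name, term = rownames(s),
      estimate = s[, 1], std_error = s[, 2]
    )
  }) %>% bind_rows()
}

#' Best model of an AIC comparison
#'
#' @param x An `accuracy_models` object.
#' @return The name of the lowest-AIC model.
#' @export
best_model <- function(x) {
  stopifnot(inherits(x, "accuracy_models"))
  x$comparison$model[1]
}
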