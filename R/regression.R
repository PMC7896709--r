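#' Classification precision of a confusion matrix
#'
#' Overall precision in the accuracy sense: correct predictions over all
#' predictions, `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn Confusion-matrix cell counts.
#' @return Precision in `[0, 1]`.
#' @export
classification_precision <- function(tp, tn, fp, fn) {
  (tp + tn) / (tp + tn + fp + fn)
}

#' Logistic regression of pass status with subset selection
#'
#' Models a binary pass/fail response (e.g., metacommunity-level neutrality
#' status) as a logistic function of community/species characteristics,
#' selecting the covariate subset by AIC — exhaustively when there are at
#' most `max_exhaustive` candidates, else by bidirectional stepwise search.
#' Reports Wald tests for the selected coefficients and overall prediction
#' precision at the 0.5 probability cutoff.
#'
#' @param data Data frame containing the response and covariates.
#' @param response Name of the binary (0/1 or logical) response column.
#' @param covariates Candidate covariate names (default: all other numeric
#'   columns).
#' @param selection `"exhaustive"` or `"stepwise"` (AIC in both cases).
#' @param cutoff Probability cutoff for the confusion matrix.
#' @param max_exhaustive Largest candidate count for exhaustive search.
#' @return An object of class `logit_subset`: the selected `glm` in
#'   `model`, `selected` covariate names, `coefficients` table (estimate,
#'   SE, z, Wald p), `confusion` matrix, `precision`, and a `separation`
#'   flag when fitted probabilities are numerically 0/1.
#' @export
fit_logistic_subset <- function(data, response,
                                covariates = NULL,
                                selection = c("exhaustive", "stepwise"),
                                cutoff = 0.5, max_exhaustive = 12L) {
  selection <- match.arg(selection)
  if (!response %in% names(data)) stop("response column not found")
  y <- data[[response]]
  if (is.logical(y)) y <- as.integer(y)
  if (anyNA(y)) stop("missing values in response")
  if (length(unique(y)) < 2L)
    stop("response has a single class; logistic regression is undefined")
  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          response)
  }
  X <- data[covariates]
  if (any(!vapply(X, function(v) all(is.finite(v)), logical(1))))
    stop("covariates must be finite")
  if (nrow(data) < 10L * length(covariates))
    warning("fewer than 10 rows per candidate covariate")
  df <- data.frame(.y = y, X, check.names = FALSE)

  fit_formula <- function(vars) {
    f <- if (length(vars) == 0L) ".y ~ 1"
    else paste(".y ~", paste(sprintf("`%s`", vars), collapse = " + "))
    suppressWarnings(stats::glm(stats::as.formula(f), family = stats::binomial(),
                                data = df))
  }

  if (selection == "exhaustive" && length(covariates) <= max_exhaustive) {
    best <- NULL
    best_vars <- character()
    p <- length(covariates)
    for (mask in 0:(2^p - 1)) {
      vars <- covariates[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
      m <- fit_formula(vars)
      if (is.null(best) || stats::AIC(m) < stats::AIC(best)) {
        best <- m
        best_vars <- vars
      }
    }
    model <- best
    selected <- best_vars
  } else {
    full <- fit_formula(covariates)
    model <- suppressWarnings(
      stats::step(full, direction = "both", trace = 0,
                  scope = list(lower = stats::as.formula(".y ~ 1"))))
    selected <- setdiff(all.vars(stats::formula(model)), ".y")
  }

  prob <- stats::fitted(model)
  separation <- any(prob > 1 - 1e-8) || any(prob < 1e-8)
  if (separation)
    warning("possible complete separation: fitted probabilities at 0/1; ",
            "coefficients reported but unstable")
  pred <- as.integer(prob > cutoff)
  confusion <- table(factor(pred, levels = c(0, 1)),
                     factor(y, levels = c(0, 1)),
                     dnn = c("predicted", "observed"))
  precision <- mean(pred == y)
  cf <- summary(model)$coefficients
  colnames(cf) <- c("estimate", "se", "z", "p")
  structure(list(model = model, selected = selected, coefficients = cf,
                 confusion = confusion, precision = precision,
                 cutoff = cutoff, separation = separation,
                 selection = selection, response = response),
            class = "logit_subset")
}

#' @export
print.logit_subset <- function(x, ...) {
  cat("Logistic regression of", x$response, "with", x$selection,
      "subset selection\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("  overall precision at cutoff %.2g: %.1f%%\n",
              x$cutoff, 100 * x$precision))
  if (x$separation) cat("  WARNING: possible complete separation\n")
  invisible(x)
}

#' @export
summary.logit_subset <- function(object, ...) {
  list(coefficients = object$coefficients, confusion = object$confusion,
       precision = object$precision, aic = stats::AIC(object$model))
}

#' @export
coef.logit_subset <- function(object, ...) {
  stats::coef(object$model)
}

#' @export
predict.logit_subset <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$model))
  stats::predict(object$model, newdata = newdata, type = "response")
}

#' Assemble the regression dataset from pipeline results
#'
#' One row per metacommunity: dominance and diversity covariates plus the
#' model-derived covariates theta, M (posterior-median migration averaged
#' over sites), X (mean niche birth/death ratio), and Y (mean niche
#' immigration), together with the MSN/NNH pass flags.
#'
#' @param results A results data.frame from [run_msnnh()].
#' @return Data frame ready for [fit_logistic_subset()].
#' @export
regression_dataset <- function(results) {
  data.frame(meta_id = results$meta_id,
             community_dominance = results$community_dominance,
             species_dominance = results$species_dominance,
             hill0 = results$hill0, shannon = results$shannon,
             theta = results$theta, M = results$M,
             X = results$X, Y = results$Y,
             msn_meta_pass = as.integer(results$msn_meta_pass),
             msn_local_pass = as.integer(results$msn_local_pass),
             nnh_meta_pass = as.integer(results$nnh_meta_pass))
}
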