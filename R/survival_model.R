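#' Split a cohort into training and internal test sets
#'
#' Disjoint, exhaustive, seed-reproducible random split.
#'
#' @param data data.frame.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_cohort <- function(data, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(data)
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n) stop("n too small to populate both sets")
  set.seed(as.integer(seed))
  idx <- sample.int(n, n_train)
  list(train = data[idx, , drop = FALSE],
       test = data[-idx, , drop = FALSE])
}

#' LASSO-Cox covariate selection with forced PA-pattern terms
#'
#' Fits a penalized Cox model over the candidate covariates with the PA
#' pattern dummies forced in (penalty factor 0: the base learner must
#' always be able to predict under all four patterns), selecting the
#' penalty by k-fold cross-validated partial-likelihood deviance and
#' returning the covariates with any nonzero coefficient at the
#' deviance-minimizing lambda.
#'
#' @param data training data.frame with `time`, `event`, `pattern` and the
#'   candidate columns.
#' @param candidates character vector of candidate covariate names.
#' @param folds number of CV folds.
#' @param seed integer seed (controls fold assignment).
#' @param lambda_rule `"min"` (deviance-minimizing, default) or `"1se"`.
#' @param lambda_fixed optional fixed penalty value bypassing
#'   cross-validation (e.g. 0 for the unpenalized support, or a very large
#'   value leaving only the forced terms).
#' @return list of class `lasso_fit`: `lambda`, `cvm`, `lambda_chosen`,
#'   `selected` (covariate names, pattern excluded), `forced`, `seed`.
#' @export
select_covariates_lasso <- function(data, candidates, folds = 10L, seed = 1L,
                                    lambda_rule = c("min", "1se"),
                                    lambda_fixed = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (sum(data$event) < folds) stop("fewer events than folds")
  keep <- vapply(candidates, function(v) length(unique(data[[v]])) > 1L,
                 logical(1))
  if (any(!keep)) {
    warning("dropping constant candidate(s): ",
            paste(candidates[!keep], collapse = ", "))
    candidates <- candidates[keep]
  }
  fml <- stats::reformulate(c("pattern", candidates))
  mm <- stats::model.matrix(fml, data)[, -1, drop = FALSE]
  asgn <- attr(stats::model.matrix(fml, data), "assign")[-1]
  term_labels <- attr(stats::terms(fml), "term.labels")
  pf <- ifelse(term_labels[asgn] == "pattern", 0, 1)
  y <- survival::Surv(data$time, data$event)
  if (!is.null(lambda_fixed)) {
    fit <- glmnet::glmnet(mm, y, family = "cox", penalty.factor = pf,
                          standardize = TRUE,
                          lambda = sort(unique(c(lambda_fixed, 10^seq(2, -4))),
                                        decreasing = TRUE))
    b <- as.matrix(stats::coef(fit, s = lambda_fixed, exact = TRUE,
                               x = mm, y = y, penalty.factor = pf))[, 1]
    sel_terms <- unique(term_labels[asgn][abs(b) > 1e-8])
    return(structure(list(lambda = fit$lambda, cvm = NULL,
                          lambda_chosen = lambda_fixed,
                          selected = setdiff(sel_terms, "pattern"),
                          forced = "pattern", seed = as.integer(seed)),
                     class = "lasso_fit"))
  }
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(folds), nrow(data)))
  cv <- glmnet::cv.glmnet(mm, y, family = "cox", foldid = foldid,
                          penalty.factor = pf, standardize = TRUE)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  b <- as.matrix(stats::coef(cv, s = lam))[, 1]
  sel_terms <- unique(term_labels[asgn][b != 0])
  structure(list(lambda = cv$lambda, cvm = cv$cvm, lambda_chosen = lam,
                 selected = setdiff(sel_terms, "pattern"),
                 forced = "pattern", seed = as.integer(seed)),
            class = "lasso_fit")
}

#' Fit the interaction Cox base learner
#'
#' Fits a multivariable Cox model containing the PA-pattern dummies
#' (reference: `baseline`), the selected covariate main effects, and all
#' second-order pattern-by-covariate interactions (Efron ties by default),
#' together with the Breslow baseline cumulative hazard evaluated at zero
#' covariate values. This single model is the S-learner's base learner:
#' counterfactual survival under any pattern is obtained by toggling the
#' pattern input.
#'
#' @param data training data.frame with `time`, `event`, `pattern` and
#'   covariates.
#' @param covariates covariate names entering as main effects.
#' @param interactions covariates given pattern-by-covariate interactions
#'   (default: all of `covariates`).
#' @param ties ties method for [survival::coxph()].
#' @return object of class `cox_interaction_model`; see Details.
#' @details The returned object carries `formula` (character), `coef`,
#'   `vcov`, `basehaz` (Breslow cumulative hazard step function as a
#'   data.frame `time`/`hazard`), `xlevels`, `ranges` (training ranges of
#'   numeric covariates, used for out-of-support warnings), `ties`,
#'   `converged`, and the underlying `fit` (not serialized).
#' @export
fit_interaction_cox <- function(data, covariates,
                                interactions = covariates,
                                ties = "efron") {
  stopifnot(all(covariates %in% names(data)),
            all(interactions %in% covariates))
  rhs <- c("pattern", covariates,
           if (length(interactions)) paste0("pattern:", interactions))
  fml <- stats::reformulate(rhs, response = "survival::Surv(time, event)")
  n_terms <- length(rhs)
  if (sum(data$event) < n_terms) {
    stop("fewer events (", sum(data$event), ") than model terms (",
         n_terms, ")")
  }
  fit <- survival::coxph(fml, data = data, ties = ties, x = FALSE,
                         model = FALSE)
  if (any(is.na(stats::coef(fit)))) {
    stop("non-identified coefficients (complete separation in a pattern stratum?)")
  }
  # centered = FALSE: cumulative hazard at zero covariates, matching the
  # raw-dummy linear predictor used in predict_survival (the survfit
  # interaction warning does not apply to the zero-covariate curve)
  bh <- suppressWarnings(survival::basehaz(fit, centered = FALSE))
  num <- covariates[vapply(data[covariates], is.numeric, logical(1))]
  ranges <- lapply(data[num], range)
  structure(list(
    formula = paste(deparse(stats::formula(fit)), collapse = " "),
    coef = stats::coef(fit),
    vcov = stats::vcov(fit),
    basehaz = data.frame(time = bh$time, hazard = bh$hazard),
    xlevels = fit$xlevels,
    ranges = ranges,
    ties = ties,
    covariates = covariates,
    interactions = interactions,
    iterations = fit$iter,
    assign = fit$assign,
    fit = fit
  ), class = "cox_interaction_model")
}

#' @export
print.cox_interaction_model <- function(x, ...) {
  cat("Cox interaction model (", x$ties, " ties): ",
      length(x$coef), " coefficients\n", sep = "")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  pattern interactions:", paste(x$interactions, collapse = ", "), "\n")
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("  eliminated:", paste(x$trace$term, collapse = ", "), "\n")
  }
  invisible(x)
}

# Wald chi-square for each removable term of a fitted coxph
term_wald <- function(fit) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  out <- lapply(names(fit$assign), function(tm) {
    ix <- fit$assign[[tm]]
    bi <- b[ix]
    W <- tryCatch(drop(t(bi) %*% solve(V[ix, ix, drop = FALSE], bi)),
                  error = function(e) Inf)
    data.frame(term = tm, chisq = W, df = length(ix),
               p = stats::pchisq(W, length(ix), lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Backward elimination on the interaction Cox model
#'
#' Iteratively removes the weakest removable term until no removal improves
#' the criterion. Interaction terms are removable at any time; a covariate
#' main effect only once its pattern interaction is gone (model hierarchy);
#' the PA-pattern dummies are never removed. Term contribution is judged by
#' its Wald chi-square: under `criterion = "AIC"` a term is removable when
#' its chi-square is below twice its degrees of freedom (the AIC gain of
#' dropping it), under `criterion = "p"` when its Wald p-value exceeds
#' `alpha`. The weakest term is removed, the model refitted, and the step
#' recorded in an elimination trace.
#'
#' @param model a `cox_interaction_model`.
#' @param data the training data used to refit after each removal.
#' @param criterion `"AIC"` or `"p"`.
#' @param alpha removal threshold for `criterion = "p"`.
#' @return the refined `cox_interaction_model` with a `trace` data.frame
#'   (`term`, `chisq`, `df`, `p` at removal time).
#' @export
backward_eliminate <- function(model, data, criterion = c("AIC", "p"),
                               alpha = 0.05) {
  criterion <- match.arg(criterion)
  covariates <- model$covariates
  interactions <- model$interactions
  trace <- list()
  repeat {
    fit <- model$fit
    tw <- term_wald(fit)
    tw <- tw[tw$term != "pattern", , drop = FALSE]
    # hierarchy: a main effect is removable only without its interaction
    inter_terms <- paste0("pattern:", interactions)
    removable <- tw$term %in% inter_terms |
      (tw$term %in% covariates & !(tw$term %in% interactions))
    tw <- tw[removable, , drop = FALSE]
    drop_ok <- if (criterion == "AIC") tw$chisq < 2 * tw$df else tw$p > alpha
    if (!nrow(tw) || !any(drop_ok)) break
    cand <- tw[drop_ok, , drop = FALSE]
    worst <- cand[order(if (criterion == "AIC") cand$chisq - 2 * cand$df
                        else -cand$p)[1L], , drop = FALSE]
    trace[[length(trace) + 1L]] <- worst
    if (startsWith(worst$term, "pattern:")) {
      interactions <- setdiff(interactions, sub("^pattern:", "", worst$term))
    } else {
      covariates <- setdiff(covariates, worst$term)
    }
    model <- fit_interaction_cox(data, covariates, interactions,
                                 ties = model$ties)
  }
  model$trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(term = character(), chisq = numeric(), df = integer(),
               p = numeric())
  model
}

# right-continuous Breslow cumulative hazard H0(t), H0(0) = 0
eval_basehaz <- function(model, t) {
  bh <- model$basehaz
  f <- stats::stepfun(bh$time, c(0, bh$hazard))
  f(t)
}

# linear predictor for newdata under the model's coefficient parameterization
model_lp <- function(model, newdata) {
  fml <- stats::as.formula(model$formula)
  tt <- stats::delete.response(stats::terms(fml))
  newdata$pattern <- pa_pattern_factor(as.character(newdata$pattern))
  mf <- stats::model.frame(tt, newdata, xlev = model$xlevels,
                           na.action = stats::na.fail)
  mm <- stats::model.matrix(tt, mf)
  unname(drop(mm[, names(model$coef), drop = FALSE] %*% model$coef))
}

#' Predict survival probability from the interaction Cox model
#'
#' \eqn{S(t \mid x, k) = \exp\{-H_0(t) e^{lp(x,k)}\}} with the Breslow
#' baseline cumulative hazard \eqn{H_0} stored in the model. Returns 1 at
#' `t = 0`. Covariate values outside the training range raise a warning
#' (not a refusal), matching an open-input recommendation tool.
#'
#' @param model a `cox_interaction_model`.
#' @param newdata data.frame of covariates (must include `pattern` unless
#'   `pattern` is supplied).
#' @param pattern optional single pattern label (or vector) overriding
#'   `newdata$pattern`.
#' @param t horizon (years); scalar or vector (one prediction per
#'   row-horizon combination when scalar; if `t` is a vector it must be
#'   scalar-row or equal-length).
#' @return numeric vector of survival probabilities.
#' @export
predict_survival <- function(model, newdata, pattern = NULL, t = 10) {
  stopifnot(all(t >= 0))
  if (!is.null(pattern)) newdata$pattern <- pattern
  for (v in names(model$ranges)) {
    r <- model$ranges[[v]]
    if (v %in% names(newdata) &&
        any(newdata[[v]] < r[1] | newdata[[v]] > r[2], na.rm = TRUE)) {
      warning("covariate '", v, "' outside training support")
    }
  }
  lp <- model_lp(model, newdata)
  H <- eval_basehaz(model, t)
  exp(-H * exp(lp))
}

#' Serialize / restore the interaction Cox model
#'
#' Writes the coefficients, their covariance, the Breslow baseline hazard
#' step function, factor levels, training ranges and ties method to JSON,
#' sufficient to reproduce predictions without the fitting data.
#'
#' @param model a `cox_interaction_model`.
#' @param path file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `cox_interaction_model` (without the
#'   underlying `fit`; such a model predicts but cannot be re-eliminated).
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    formula = model$formula,
    coef = as.list(model$coef),
    vcov = model$vcov,
    basehaz = model$basehaz,
    xlevels = model$xlevels,
    ranges = model$ranges,
    ties = model$ties,
    covariates = model$covariates,
    interactions = model$interactions
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    formula = obj$formula,
    coef = unlist(obj$coef),
    vcov = as.matrix(obj$vcov),
    basehaz = as.data.frame(obj$basehaz),
    xlevels = lapply(obj$xlevels, as.character),
    ranges = lapply(obj$ranges, as.numeric),
    ties = obj$ties,
    covariates = obj$covariates,
    interactions = obj$interactions,
    fit = NULL
  )
  class(model) <- "cox_interaction_model"
  model
}
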