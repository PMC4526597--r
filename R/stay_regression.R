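#' Build the trial-lagged stay/switch design
#'
#' One row per training-phase choice whose same-game predecessor had an
#' observed response: `stay` is 1 when the current choice repeats the
#' previous choice made in the same game (not necessarily the previous
#' trial overall), and the reward/transition predictors come from that
#' previous same-game trial, coded +1 (rewarded / common) and -1
#' (unrewarded / rare). Missed trials are skipped both as lag sources and
#' as targets; the first usable trial of each game per subject emits no
#' row.
#'
#' @param trials trial records (any number of subjects).
#' @param include_stabilized include stabilized training trials (Exp 2's
#'   tail) in the design; default `FALSE`, matching the convention that
#'   only the drifting trials assess trial-by-trial learning.
#' @return Data frame with columns `subject`, `game`, `stay`,
#'   `prev_reward`, `prev_transition`.
#' @export
build_lagged_design <- function(trials, include_stabilized = FALSE) {
  tr <- trials[trials$phase == "training" & trials$action != "none", ]
  if (!include_stabilized && "stabilized" %in% names(tr))
    tr <- tr[!tr$stabilized, ]
  if (nrow(tr) == 0)
    return(data.frame(subject = integer(), game = character(),
                      stay = integer(), prev_reward = numeric(),
                      prev_transition = numeric()))
  tr <- tr[order(tr$subject, tr$game, tr$trial), ]
  grp <- paste(tr$subject, tr$game, sep = "\r")
  n <- nrow(tr)
  prev <- c(FALSE, grp[-1] == grp[-n])  # row above is the same subject x game
  idx <- which(prev)
  data.frame(
    subject = tr$subject[idx],
    game = tr$game[idx],
    stay = as.integer(tr$action[idx] == tr$action[idx - 1]),
    prev_reward = 2 * tr$reward[idx - 1] - 1,
    prev_transition = ifelse(tr$transition[idx - 1] == "common", 1, -1),
    stringsAsFactors = FALSE
  )
}

# canonical fixed-effect order (main effects, two-way, three-way)
term_names_full <- c("(Intercept)", "Reward", "Transition", "Devaluation",
                     "Reward:Transition", "Reward:Devaluation",
                     "Transition:Devaluation",
                     "Reward:Transition:Devaluation")

# merge a per-subject deval_z vector/df into a design
deval_z_lookup <- function(deval_z) {
  if (is.data.frame(deval_z)) {
    stopifnot(all(c("subject", "deval_z") %in% names(deval_z)))
    stats::setNames(deval_z$deval_z, deval_z$subject)
  } else if (!is.null(names(deval_z))) {
    deval_z
  } else stop("deval_z must be a named vector or a data frame with ",
              "columns subject, deval_z", call. = FALSE)
}

#' Mixed-effects stay model with a devaluation moderator
#'
#' Hierarchical logistic regression of stay on previous reward, previous
#' transition, and standardized between-subject devaluation sensitivity:
#' all fixed two- and three-way interactions, with per-subject random
#' intercept, reward, transition, and reward-by-transition effects
#' (`stay ~ reward * transition * deval_z + (1 + reward * transition |
#' subject)`).
#'
#' Two engines: `"glmer"` fits the model with [lme4::glmer()] (full
#' random-effect covariance, Laplace approximation, Wald tests);
#' `"twostage"` approximates it by per-subject Firth-penalized logistic
#' fits of `stay ~ reward * transition` followed by a random-effects
#' meta-regression of each within-subject coefficient on `deval_z`
#' ([metafor::rma()], DerSimonian-Laird), whose intercepts give the
#' within-subject main terms and whose slopes give the devaluation
#' interactions.
#'
#' @param design a [build_lagged_design()] data frame.
#' @param deval_z standardized devaluation sensitivity: named numeric
#'   vector (names = subject) or data frame with columns `subject`,
#'   `deval_z`.
#' @param engine `"glmer"` or `"twostage"`.
#' @return List of class `stay_fit`: `terms` (term, estimate, se, stat,
#'   p_value), `engine`, `n_subjects`, `diagnostics` (convergence
#'   messages), and the underlying model object(s).
#' @export
fit_mixed_stay_model <- function(design, deval_z,
                                 engine = c("twostage", "glmer")) {
  engine <- match.arg(engine)
  dz <- deval_z_lookup(deval_z)
  subjects <- unique(design$subject)
  if (length(subjects) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (abs(mean(dz[as.character(subjects)])) > 0.5 &&
      stats::sd(dz[as.character(subjects)]) > 0)
    warning("deval_z does not look standardized")
  if (engine == "glmer") {
    d <- design
    d$deval_z <- dz[as.character(d$subject)]
    msgs <- character()
    fit <- withCallingHandlers(
      lme4::glmer(
        stay ~ prev_reward * prev_transition * deval_z +
          (1 + prev_reward * prev_transition | subject),
        data = d, family = stats::binomial(),
        control = lme4::glmerControl(optimizer = "bobyqa",
                                     calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    cf <- summary(fit)$coefficients
    # map lme4's term order onto the canonical labels
    lbl <- c("(Intercept)" = "(Intercept)", "prev_reward" = "Reward",
             "prev_transition" = "Transition", "deval_z" = "Devaluation",
             "prev_reward:prev_transition" = "Reward:Transition",
             "prev_reward:deval_z" = "Reward:Devaluation",
             "prev_transition:deval_z" = "Transition:Devaluation",
             "prev_reward:prev_transition:deval_z" =
               "Reward:Transition:Devaluation")
    terms <- data.frame(term = unname(lbl[rownames(cf)]),
                        estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"], stat = cf[, "z value"],
                        p_value = cf[, "Pr(>|z|)"],
                        row.names = NULL, stringsAsFactors = FALSE)
    res <- list(terms = terms, engine = engine,
                n_subjects = length(subjects), diagnostics = msgs,
                model = fit)
  } else {
    per <- per_subject_indices(design, method = "independent",
                               keep_se = TRUE)
    z_s <- dz[as.character(per$subject)]
    within <- c("(Intercept)" = "intercept", "Reward" = "mf_index",
                "Transition" = "transition",
                "Reward:Transition" = "mb_index")
    inter <- c("(Intercept)" = "Devaluation",
               "Reward" = "Reward:Devaluation",
               "Transition" = "Transition:Devaluation",
               "Reward:Transition" = "Reward:Transition:Devaluation")
    rows <- list(); models <- list(); msgs <- character()
    for (k in names(within)) {
      yi <- per[[within[[k]]]]
      sei <- per[[paste0(within[[k]], "_se")]]
      m <- tryCatch(
        metafor::rma(yi = yi, sei = sei, mods = ~z_s, method = "DL"),
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          suppressWarnings(metafor::rma(yi = yi, sei = sei, mods = ~z_s,
                                        method = "DL"))
        })
      models[[k]] <- m
      rows[[k]] <- data.frame(
        term = c(k, inter[[k]]),
        estimate = as.numeric(m$beta), se = m$se, stat = m$zval,
        p_value = m$pval, stringsAsFactors = FALSE)
    }
    terms <- do.call(rbind, c(rows, make.row.names = FALSE))
    terms <- terms[match(term_names_full, terms$term), ]
    rownames(terms) <- NULL
    res <- list(terms = terms, engine = engine,
                n_subjects = length(subjects), diagnostics = msgs,
                per_subject = per, models = models)
  }
  class(res) <- "stay_fit"
  res
}

#' @export
print.stay_fit <- function(x, ...) {
  cat("Stay-probability model (", x$engine, " engine, ",
      x$n_subjects, " subjects)\n", sep = "")
  print(x$terms, digits = 3)
  if (length(x$diagnostics))
    cat("diagnostics:", paste(unique(x$diagnostics), collapse = "; "), "\n")
  invisible(x)
}

#' Per-subject model-based and model-free indices
#'
#' Per-subject coefficients of the basic stay model
#' `stay ~ reward * transition` (no between-subject predictor): the reward
#' beta is the model-free index and the reward-by-transition beta the
#' model-based index. `method = "ranef"` (default) takes subject-level
#' effects from the hierarchical [lme4::glmer()] fit of that model;
#' `method = "independent"` fits each subject separately with
#' Firth-penalized logistic regression, which keeps the indices finite
#' under perfect stay/switch patterns.
#'
#' @param design a [build_lagged_design()] data frame.
#' @param method `"ranef"` or `"independent"`.
#' @param keep_se also return per-subject standard errors (independent
#'   method only).
#' @return Data frame: `subject`, `intercept`, `mf_index`, `transition`,
#'   `mb_index` (and `*_se` columns when requested).
#' @export
per_subject_indices <- function(design, method = c("ranef", "independent"),
                                keep_se = FALSE) {
  method <- match.arg(method)
  subjects <- unique(design$subject)
  if (method == "ranef") {
    fit <- suppressWarnings(lme4::glmer(
      stay ~ prev_reward * prev_transition +
        (1 + prev_reward * prev_transition | subject),
      data = design, family = stats::binomial(),
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   calc.derivs = FALSE)))
    cf <- stats::coef(fit)$subject
    out <- data.frame(subject = rownames(cf),
                      intercept = cf[, "(Intercept)"],
                      mf_index = cf[, "prev_reward"],
                      transition = cf[, "prev_transition"],
                      mb_index = cf[, "prev_reward:prev_transition"],
                      stringsAsFactors = FALSE)
    if (is.numeric(design$subject)) out$subject <- as.numeric(out$subject)
    rownames(out) <- NULL
    return(out[order(out$subject), ])
  }
  rows <- lapply(subjects, function(s) {
    d <- design[design$subject == s, ]
    if (nrow(d) < 8) return(NULL)  # too few lagged trials to fit 4 terms
    x <- cbind(1, d$prev_reward, d$prev_transition,
               d$prev_reward * d$prev_transition)
    colnames(x) <- c("intercept", "mf_index", "transition", "mb_index")
    f <- firth_logistic(x, d$stay)
    r <- data.frame(subject = s, t(f$coefficients))
    if (keep_se) r <- cbind(r, stats::setNames(as.data.frame(t(f$se)),
                                               paste0(names(f$se), "_se")))
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-subject model: devaluation sensitivity on learning indices
#'
#' Ordinary linear model with devaluation sensitivity as the dependent
#' variable and the standardized model-free and model-based indices as
#' predictors, optionally with additional covariates (e.g. consumption
#' sensitivity, comprehension fail count) and their interactions with the
#' model-based index.
#'
#' @param indices a [per_subject_indices()] data frame.
#' @param deval_sensitivity per-subject devaluation sensitivity, aligned
#'   with `indices$subject` (named vector or data frame with columns
#'   `subject` and `deval_sensitivity`).
#' @param covariates optional data frame of extra per-subject predictors
#'   (plus a `subject` column).
#' @param covariate_interactions include `model_based:covariate`
#'   interaction terms (default `TRUE`, matching the covariate-adjusted
#'   analyses).
#' @return List of class `deval_lm`: `terms` (term, estimate, se, stat,
#'   p_value), the `lm` object, and `aliased` (names of any rank-deficient
#'   terms).
#' @export
predict_devaluation <- function(indices, deval_sensitivity,
                                covariates = NULL,
                                covariate_interactions = TRUE) {
  if (is.data.frame(deval_sensitivity)) {
    y <- deval_sensitivity$deval_sensitivity[
      match(indices$subject, deval_sensitivity$subject)]
  } else if (!is.null(names(deval_sensitivity))) {
    y <- deval_sensitivity[as.character(indices$subject)]
  } else {
    stopifnot(length(deval_sensitivity) == nrow(indices))
    y <- deval_sensitivity
  }
  d <- data.frame(deval = y,
                  model_free = zscore(indices$mf_index),
                  model_based = zscore(indices$mb_index))
  fml <- "deval ~ model_free + model_based"
  if (!is.null(covariates)) {
    cn <- setdiff(names(covariates), "subject")
    for (v in cn) {
      d[[v]] <- covariates[[v]][match(indices$subject, covariates$subject)]
      fml <- paste(fml, "+", v)
      if (covariate_interactions) fml <- paste0(fml, " + model_based:", v)
    }
  }
  fit <- stats::lm(stats::as.formula(fml), data = d)
  cf <- summary(fit)$coefficients
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased))
    warning("rank-deficient model; aliased terms: ",
            paste(aliased, collapse = ", "))
  structure(list(
    terms = data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                       stat = cf[, 3], p_value = cf[, 4],
                       row.names = NULL, stringsAsFactors = FALSE),
    model = fit, aliased = aliased), class = "deval_lm")
}

#' @export
print.deval_lm <- function(x, ...) {
  cat("Linear model: devaluation sensitivity ~ learning indices\n")
  print(x$terms, digits = 3)
  invisible(x)
}
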