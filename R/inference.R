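#' Small-sample-corrected Akaike information criterion
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (fixed coefficients plus
#'   variance/covariance components plus the residual variance).
#' @param n number of observations.
#' @return AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1).
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(n - k - 1 > 0)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# build an lme4 formula from a fixed-term set and random-structure switches
lmm_formula <- function(fixed_terms, random_slope = TRUE, nest_housing = TRUE) {
  # sorted terms give deterministic coefficient names (e.g. the habitat x
  # temperature column is always "habitaturban:t_nest_int")
  fx <- if (length(fixed_terms) == 0) "1"
        else paste(sort(fixed_terms), collapse = " + ")
  rnd <- if (random_slope) "(1 + t_nest_int | id)" else "(1 | id)"
  if (nest_housing) rnd <- paste(rnd, "+ (1 | housing_half:id)")
  stats::as.formula(paste("rmr_mass_specific ~", fx, "+", rnd))
}

#' Fit one candidate linear mixed model of mass-specific RMR
#'
#' Fits a Gaussian linear mixed model with the given fixed-term set and a
#' random structure of individual intercepts (and, by default, individual
#' nest-temperature slopes) with intercepts nested in the housing-period
#' half. Backed by `lmerTest::lmer`; the contract is the returned
#' log-likelihood, parameter count, AICc and coefficient table.
#'
#' @param records hourly RMR table (see [extract_hourly_rmr()] or
#'   [simulate_rmr_records()]); factors are set up internally with forest /
#'   day / run 1 / second-half as reference levels.
#' @param fixed_terms character vector of fixed terms, a subset of
#'   `c("t_nest_int", "habitat", "diel", "run", "housing_half",
#'   "habitat:t_nest_int", "habitat:run")`.
#' @param method `"ML"` (model comparison) or `"REML"` (reporting).
#' @param random_slope include the individual random temperature slope.
#' @param nest_housing nest random intercepts in housing-period half.
#' @return object of class `candidate_fit`: list with `terms`, `formula`,
#'   `fit`, `logLik`, `k`, `n`, `aicc`, `coefficients` (estimate, SE, df,
#'   CI), `varcomp`, `singular`.
#' @export
fit_lmm <- function(records, fixed_terms, method = c("ML", "REML"),
                    random_slope = TRUE, nest_housing = TRUE) {
  method <- match.arg(method)
  d <- records
  d$habitat <- stats::relevel(factor(d$habitat), "forest")
  d$diel <- stats::relevel(factor(d$diel), "day")
  d$run <- factor(d$run)
  if ("housing_half" %in% names(d)) {
    d$housing_half <- stats::relevel(factor(d$housing_half), "second")
  }
  form <- lmm_formula(fixed_terms, random_slope, nest_housing)
  ctl <- lme4::lmerControl(optimizer = "bobyqa",
                           check.conv.singular = "ignore")
  fit <- try(lmerTest::lmer(form, data = d, REML = (method == "REML"),
                            control = ctl), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("mixed-model fit failed for terms {",
         paste(fixed_terms, collapse = ", "), "}: ",
         attr(fit, "condition")$message, call. = FALSE)
  }
  conv_msgs <- fit@optinfo$conv$lme4$messages
  if (!is.null(conv_msgs)) {
    # retry once from a perturbed start before accepting the fit
    theta <- lme4::getME(fit, "theta")
    refit <- try(stats::update(fit, start = theta * 1.05 + 1e-4),
                 silent = TRUE)
    if (!inherits(refit, "try-error") &&
        is.null(refit@optinfo$conv$lme4$messages)) {
      fit <- refit
      conv_msgs <- NULL
    } else {
      warning("mixed model did not fully converge for terms {",
              paste(fixed_terms, collapse = ", "), "}: ",
              paste(conv_msgs, collapse = "; "), call. = FALSE)
    }
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  cs <- as.data.frame(coef(summary(fit)))
  names(cs) <- c("estimate", "se", "df", "t", "p")[seq_len(ncol(cs))]
  cs$ci_low <- cs$estimate - 1.96 * cs$se
  cs$ci_high <- cs$estimate + 1.96 * cs$se
  structure(list(terms = fixed_terms, formula = form, fit = fit,
                 logLik = as.numeric(ll), k = k, n = n,
                 aicc = aicc(as.numeric(ll), k, n),
                 coefficients = cs,
                 varcomp = as.data.frame(lme4::VarCorr(fit)),
                 singular = lme4::isSingular(fit),
                 converged = is.null(conv_msgs),
                 method = method),
            class = "candidate_fit")
}

#' @export
print.candidate_fit <- function(x, ...) {
  cat("Linear mixed model (", x$method, "): rmr_mass_specific ~ ",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "\n  logLik ", format(x$logLik), ", k = ", x$k, ", n = ", x$n,
      ", AICc = ", format(x$aicc),
      if (x$singular) "  [singular fit]" else "", "\n", sep = "")
  invisible(x)
}

#' Enumerate all candidate fixed-term subsets respecting marginality
#'
#' Generates every subset of the main terms, each augmented with every
#' admissible subset of the interaction terms (an interaction is admissible
#' only when both its parents are present). Order is deterministic: by
#' number of terms, then lexicographically.
#'
#' @param main_terms character vector of main fixed terms.
#' @param interactions character vector of two-way interactions written
#'   `"a:b"` with `a`, `b` in `main_terms`.
#' @return list of character vectors (term sets), including the empty
#'   (intercept-only) set.
#' @export
enumerate_candidates <- function(main_terms,
                                 interactions = character(0)) {
  stopifnot(!anyDuplicated(main_terms))
  for (ia in interactions) {
    parents <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (!all(parents %in% main_terms)) {
      stop("interaction ", ia, " has a parent outside main_terms", call. = FALSE)
    }
  }
  subsets <- function(x) {
    if (length(x) == 0) return(list(character(0)))
    rest <- subsets(x[-1])
    c(rest, lapply(rest, function(s) c(x[1], s)))
  }
  out <- list()
  for (ms in subsets(main_terms)) {
    admissible <- Filter(function(ia) {
      all(strsplit(ia, ":", fixed = TRUE)[[1]] %in% ms)
    }, interactions)
    for (is_ in subsets(admissible)) {
      out[[length(out) + 1]] <- c(sort(ms), sort(is_))
    }
  }
  ord <- order(vapply(out, length, integer(1)),
               vapply(out, function(s) paste(s, collapse = "|"), character(1)))
  out[ord]
}

#' Rank candidate fits by AICc and compute the Akaike-weight panel
#'
#' Computes, over a set of candidate fits to identical records:
#' Delta-AICc relative to the best model, Akaike weights
#' \eqn{W_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)}, evidence ratios
#' \eqn{ER_i = W_1/W_i = \exp(\Delta_i/2)}, membership in the smallest
#' top-ranked set with cumulative weight >= `conf_level`, and per-predictor
#' variable weights (sum of weights of models containing the predictor).
#'
#' @param fits list of `candidate_fit` objects (or plain lists with
#'   `terms`, `logLik`, `k`, `n`).
#' @param conf_level cumulative-weight level of the confidence set.
#' @return list of class `selection_table`: `table` (ranked data.frame with
#'   `model`, `terms`, `k`, `logLik`, `aicc`, `delta_aicc`, `weight`,
#'   `evidence_ratio`, `cum_weight`, `in_confidence_set`),
#'   `variable_weights` (named numeric) and `conf_level`.
#' @export
build_selection_table <- function(fits, conf_level = 0.95) {
  stopifnot(length(fits) >= 1, conf_level > 0, conf_level <= 1)
  n_obs <- unique(vapply(fits, function(f) f$n, numeric(1)))
  if (length(n_obs) != 1) {
    stop("candidate fits are on differing record sets (n = ",
         paste(n_obs, collapse = ", "), "); models are incomparable",
         call. = FALSE)
  }
  aiccs <- vapply(fits, function(f) aicc(f$logLik, f$k, f$n), numeric(1))
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(aiccs)
  tab <- data.frame(
    model = paste0("M", seq_along(ord)),
    terms = vapply(fits[ord], function(f) {
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept)"
    }, character(1)),
    k = vapply(fits[ord], function(f) f$k, numeric(1)),
    logLik = vapply(fits[ord], function(f) f$logLik, numeric(1)),
    aicc = aiccs[ord],
    delta_aicc = delta[ord],
    weight = w[ord],
    evidence_ratio = exp(delta[ord] / 2)
  )
  tab$cum_weight <- cumsum(tab$weight)
  cutoff <- which(tab$cum_weight >= conf_level)[1]
  if (is.na(cutoff)) cutoff <- nrow(tab)
  tab$in_confidence_set <- seq_len(nrow(tab)) <= cutoff
  all_terms <- sort(unique(unlist(lapply(fits, function(f) f$terms))))
  vw <- vapply(all_terms, function(tm) {
    sum(w[vapply(fits, function(f) tm %in% f$terms, logical(1))])
  }, numeric(1))
  structure(list(table = tab, variable_weights = vw,
                 conf_level = conf_level,
                 fits = fits[ord]),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  print(x$table[, setdiff(names(x$table), "logLik")], digits = 4)
  cat("\nVariable weights:\n")
  print(round(x$variable_weights, 3))
  invisible(x)
}

# marginal and conditional R2 (Nakagawa-style) for an lmer fit
r2_mixed <- function(fit) {
  var_fixed <- stats::var(as.vector(
    lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  # per-observation random-effect variance: mean diag(Z Sigma Z')
  z <- lme4::getME(fit, "Z")
  lam <- lme4::getME(fit, "Lambda")
  sig2 <- stats::sigma(fit)^2
  zl <- z %*% lam
  var_random <- sig2 * mean(Matrix::rowSums(zl^2))
  total <- var_fixed + var_random + sig2
  c(r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + var_random) / total)
}

# ICC: random-intercept variance share of all random + residual variance
icc_mixed <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  vars <- vc[is.na(vc$var2) & vc$grp != "Residual", ]
  v_int <- sum(vars$vcov[vars$var1 == "(Intercept)"])
  v_all <- sum(vars$vcov)
  sig2 <- stats::sigma(fit)^2
  v_int / (v_all + sig2)
}

# drop a predictor plus any interaction that contains it
drop_term <- function(terms, x) {
  keep <- vapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    !(x %in% parts) && tm != x
  }, logical(1))
  terms[keep]
}

#' Effect sizes, ICC and R2 panel for the top-ranked model
#'
#' Refits the top model with REML and computes, per predictor, a signed
#' local Cohen's f2 from the drop-one change in marginal R2,
#' \deqn{f^2(X) = (R^2_{m} - R^2_{m,-X}) / (1 - R^2_{m}),}
#' signed by the predictor's coefficient (for multi-level factors, by the
#' level with the largest absolute coefficient); plus the intraclass
#' correlation coefficient and marginal/conditional R2.
#'
#' @param records hourly RMR table.
#' @param top_terms fixed-term set of the top-ranked model.
#' @param random_slope,nest_housing random-structure switches (see
#'   [fit_lmm()]).
#' @return list of class `effect_size_panel`: `fit` (REML `candidate_fit`),
#'   `f2` (named numeric, NA when a reduced fit fails), `icc`,
#'   `r2_marginal`, `r2_conditional`.
#' @export
effect_sizes <- function(records, top_terms, random_slope = TRUE,
                         nest_housing = TRUE) {
  full <- fit_lmm(records, top_terms, method = "REML",
                  random_slope = random_slope, nest_housing = nest_housing)
  r2_full <- r2_mixed(full$fit)
  f2 <- stats::setNames(rep(NA_real_, length(top_terms)), top_terms)
  for (x in top_terms) {
    reduced_terms <- drop_term(top_terms, x)
    red <- try(fit_lmm(records, reduced_terms, method = "REML",
                       random_slope = random_slope,
                       nest_housing = nest_housing), silent = TRUE)
    if (inherits(red, "try-error")) next
    r2_red <- r2_mixed(red$fit)
    raw <- (r2_full["r2_marginal"] - r2_red["r2_marginal"]) /
      (1 - r2_full["r2_marginal"])
    cs <- full$coefficients
    rn <- rownames(cs)
    hit <- rn[vapply(rn, function(r) identical(term_of_coef(r, top_terms), x),
                     logical(1))]
    sgn <- if (length(hit)) sign(cs[hit[which.max(abs(cs[hit, "estimate"]))],
                                    "estimate"]) else 1
    f2[x] <- abs(raw) * if (sgn == 0) 1 else sgn
  }
  structure(list(fit = full, f2 = f2, icc = icc_mixed(full$fit),
                 r2_marginal = unname(r2_full["r2_marginal"]),
                 r2_conditional = unname(r2_full["r2_conditional"])),
            class = "effect_size_panel")
}

# map a coefficient row name (e.g. "habitaturban:t_nest_int", "run2") back
# to the fixed term that produced it
term_of_coef <- function(coef_name, terms) {
  if (coef_name == "(Intercept)") return("(Intercept)")
  for (tm in terms[order(-nchar(terms))]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    n_colon <- lengths(regmatches(coef_name, gregexpr(":", coef_name)))
    if (n_colon != length(parts) - 1) next
    cparts <- strsplit(coef_name, ":", fixed = TRUE)[[1]]
    if (length(cparts) == length(parts) &&
        all(mapply(function(cp, p) startsWith(cp, p), cparts, parts))) {
      return(tm)
    }
  }
  NA_character_
}

#' @export
print.effect_size_panel <- function(x, ...) {
  cat("Top model (REML):\n")
  print(round(x$fit$coefficients[, c("estimate", "se", "ci_low", "ci_high")], 4))
  cat("\nCohen's f2 (signed):\n")
  print(round(x$f2, 3))
  cat(sprintf("\nICC %.3f | marginal R2 %.3f | conditional R2 %.3f\n",
              x$icc, x$r2_marginal, x$r2_conditional))
  invisible(x)
}
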