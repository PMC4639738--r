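#' Model specification for the measure GLMM
#'
#' The full model regresses a network measure on age class, sex,
#' deprivation class and the sex-by-deprivation-class interaction as fixed
#' factors, with a group-level random intercept (normal response, identity
#' link). A specification must respect marginality: the interaction may
#' only appear together with both of its main effects.
#'
#' @param response name of the response column.
#' @param fixed_terms character vector drawn from
#'   `c("age_class", "sex", "deprivation_class", "sex:deprivation_class")`.
#' @param random name of the grouping column for the random intercept.
#' @return A `model_spec` object.
#' @export
model_spec <- function(response,
                       fixed_terms = c("age_class", "sex",
                                       "deprivation_class",
                                       "sex:deprivation_class"),
                       random = "group_id") {
  allowed <- c("age_class", "sex", "deprivation_class",
               "sex:deprivation_class")
  bad <- setdiff(fixed_terms, allowed)
  if (length(bad) > 0) {
    stop("unknown fixed term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_marginality(fixed_terms)
  structure(list(response = response, fixed_terms = fixed_terms,
                 random = random),
            class = "model_spec")
}

check_marginality <- function(fixed_terms) {
  for (tm in grep(":", fixed_terms, value = TRUE)) {
    mains <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(mains %in% fixed_terms)) {
      stop("marginality violation: interaction ", tm,
           " requires main effects ", paste(mains, collapse = " and "),
           call. = FALSE)
    }
  }
  invisible(fixed_terms)
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed_terms) == 0) "1" else
    paste(spec$fixed_terms, collapse = " + ")
  stats::as.formula(paste0(spec$response, " ~ ", rhs,
                           " + (1 | ", spec$random, ")"))
}

fit_lmer_raw <- function(f, data, contrasts, reml) {
  suppressMessages(withCallingHandlers(
    lme4::lmer(f, data = data, REML = reml,
               contrasts = if (length(contrasts) > 0) contrasts,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 check.conv.grad = "ignore", check.conv.hess = "ignore")),
    warning = function(w) invokeRestart("muffleWarning")
  ))
}

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\,logLik + 2k + 2k(k+1)/(n-k-1)}
#' where k counts all estimated parameters (fixed effects plus variance
#' components).
#'
#' @param loglik maximized log-likelihood (ML).
#' @param k parameter count.
#' @param n sample size; must exceed k + 1.
#' @return The AICc value.
#' @export
#' @examples
#' aicc_value(-10, k = 3, n = 20)  # 27.5
aicc_value <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc_value
#' @param fit a [fit_lmm()] result.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  aicc_value(fit$loglik, fit$k, fit$n)
}

#' Fit the measure GLMM
#'
#' Fits the normal, identity-link mixed model by maximum likelihood (ML,
#' not REML, so that AICc values of different fixed structures are
#' comparable), using sum-to-zero factor contrasts. Each fixed term gets a
#' marginal (type-III-style) Wald F test with denominator degrees of
#' freedom n - rank, the residual df. A singular random-effect fit (group
#' variance estimated at zero) is flagged, not raised.
#'
#' @param data a data frame (typically a [metrics_table()] subset) with the
#'   response, factor covariates and the grouping column; rows with missing
#'   response must be dropped by the caller.
#' @param spec a [model_spec()].
#' @return An `lmm_fit`: list with the lme4 `model`, `coefficients`,
#'   `terms` (tibble: term, F, df1, df2, p), `loglik`, `k`, `n`, `aicc`,
#'   `singular`, `sigma` and the `spec`.
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  if (!spec$response %in% names(data)) {
    stop("response column not found: ", spec$response, call. = FALSE)
  }
  if (anyNA(data[[spec$response]])) {
    stop("response contains missing values; drop undefined rows first",
         call. = FALSE)
  }
  if (!spec$random %in% names(data)) {
    stop("grouping column not found: ", spec$random, call. = FALSE)
  }
  if (length(unique(data[[spec$random]])) < 2) {
    stop("random intercept needs at least 2 groups", call. = FALSE)
  }
  vars <- unique(unlist(strsplit(spec$fixed_terms, ":", fixed = TRUE)))
  for (v in vars) data[[v]] <- droplevels(factor(data[[v]]))
  # terms whose factor collapses to one level carry no information here
  keep <- vapply(spec$fixed_terms, function(tm) {
    all(vapply(strsplit(tm, ":", fixed = TRUE)[[1]],
               function(v) nlevels(data[[v]]) > 1, logical(1)))
  }, logical(1))
  est_terms <- spec$fixed_terms[keep]
  contr <- lapply(stats::setNames(vars, vars), function(v) "contr.sum")
  contr <- contr[vapply(vars, function(v) nlevels(data[[v]]) > 1,
                        logical(1))]
  f <- spec_formula(list(response = spec$response, fixed_terms = est_terms,
                         random = spec$random))
  model <- fit_lmer_raw(f, data, contr, reml = FALSE)
  beta <- lme4::fixef(model)
  p_rank <- length(beta)
  n <- nrow(data)
  k <- p_rank + 2L  # + random-intercept variance + residual variance
  ll <- as.numeric(stats::logLik(model))
  # a fully degenerate fit (e.g. constant response) can leave vcov unusable;
  # term tests then report F = 0 on zero estimated effects
  vc <- tryCatch(suppressWarnings(as.matrix(stats::vcov(model))),
                 error = function(e) matrix(NA_real_, p_rank, p_rank))
  asgn <- attr(stats::model.matrix(model), "assign")
  labels <- attr(stats::terms(model), "term.labels")
  terms_tbl <- lapply(seq_along(labels), function(j) {
    idx <- which(asgn == j)
    q <- length(idx)
    if (q == 0) {
      # all of this term's columns were removed as rank deficient
      return(tibble::tibble(term = labels[j], F = NA_real_, df1 = 0L,
                            df2 = n - p_rank, p = NA_real_))
    }
    b <- beta[idx]
    degenerate <- all(abs(b) < 1e-8 * max(1, abs(beta[1])))
    fstat <- if (degenerate) 0 else tryCatch(
      as.numeric(crossprod(b, solve(vc[idx, idx, drop = FALSE], b))) / q,
      error = function(e) NA_real_)
    # a numerically non-positive-definite vcov can yield a negative
    # quadratic form; the Wald statistic is then indistinguishable from 0
    if (is.finite(fstat) && fstat < 0) fstat <- 0
    tibble::tibble(term = labels[j], F = fstat, df1 = q, df2 = n - p_rank,
                   p = stats::pf(fstat, q, n - p_rank, lower.tail = FALSE))
  })
  # spec terms with no estimable contrast are reported as carrying 0 df
  dropped <- setdiff(spec$fixed_terms, est_terms)
  if (length(dropped) > 0) {
    terms_tbl <- c(terms_tbl, list(tibble::tibble(
      term = dropped, F = NA_real_, df1 = 0L, df2 = n - p_rank,
      p = NA_real_)))
  }
  structure(
    list(spec = spec, model = model, formula = f, data = data,
         contrasts = contr, coefficients = beta,
         terms = dplyr::bind_rows(terms_tbl),
         loglik = ll, k = k, n = n,
         aicc = aicc_value(ll, k, n),
         singular = lme4::isSingular(model, tol = 1e-5),
         sigma = stats::sigma(model)),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s ~ %s + (1 | %s)\n", x$spec$response,
              if (length(x$spec$fixed_terms) == 0) "1" else
                paste(x$spec$fixed_terms, collapse = " + "),
              x$spec$random))
  cat(sprintf("  ML logLik %.3f, k = %d, n = %d, AICc = %.3f%s\n",
              x$loglik, x$k, x$n, x$aicc,
              if (x$singular) " (singular random effect)" else ""))
  print(x$terms)
  invisible(x)
}

droppable_terms <- function(fixed_terms) {
  # a term may be dropped only if no retained higher-order term contains it
  ok <- vapply(fixed_terms, function(tm) {
    parts <- strsplit(setdiff(fixed_terms, tm), ":", fixed = TRUE)
    !any(vapply(parts, function(p) tm %in% p, logical(1)))
  }, logical(1))
  fixed_terms[ok]
}

term_order <- function(terms) {
  # higher-order terms first, then alphabetical: the deterministic
  # tie-break order for candidate drops
  ord <- order(-lengths(strsplit(terms, ":", fixed = TRUE)), terms)
  terms[ord]
}

#' Backward stepwise model reduction by AICc
#'
#' Starting from the full model, repeatedly refits every candidate
#' one-term-smaller model (never dropping a main effect while its
#' interaction is retained) and removes the term whose removal lowers the
#' AICc most; stops when no removal lowers it. All candidate AICc values at
#' every step are recorded in a ledger. The selected model is refit by REML
#' for coefficient reporting (`best_reml`); AICc comparison always uses the
#' ML fits.
#'
#' @inheritParams fit_lmm
#' @param spec the full [model_spec()].
#' @return List with `best` (`lmm_fit`, ML), `best_reml` (lme4 model),
#'   and `ledger` (tibble: step, model, candidate_drop, aicc, chosen).
#' @export
backward_select <- function(data, spec) {
  current <- fit_lmm(data, spec)
  ledger <- list(tibble::tibble(
    step = 0L, model = format_terms(spec$fixed_terms),
    candidate_drop = NA_character_, aicc = current$aicc, chosen = TRUE))
  step <- 0L
  repeat {
    step <- step + 1L
    cands <- term_order(droppable_terms(current$spec$fixed_terms))
    if (length(cands) == 0) break
    fits <- lapply(cands, function(tm) {
      fit_lmm(data, model_spec(spec$response,
                               setdiff(current$spec$fixed_terms, tm),
                               spec$random))
    })
    aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
    best_i <- which.min(aiccs)  # ties resolved by candidate order
    improved <- aiccs[best_i] < current$aicc
    ledger <- c(ledger, list(tibble::tibble(
      step = step, model = vapply(fits, function(f)
        format_terms(f$spec$fixed_terms), character(1)),
      candidate_drop = cands,
      aicc = aiccs,
      chosen = improved & seq_along(cands) == best_i)))
    if (!improved) break
    current <- fits[[best_i]]
  }
  best_reml <- fit_lmer_raw(current$formula, current$data,
                            current$contrasts, reml = TRUE)
  list(best = current, best_reml = best_reml,
       ledger = dplyr::bind_rows(ledger))
}

format_terms <- function(terms) {
  if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test reporting U under the convention
#' \eqn{U = \min(U_a, U_b)}. The p value is computed by the exact null
#' distribution when \eqn{n_a n_b \le 400} and there are no ties, and
#' otherwise by the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b numeric samples (non-empty).
#' @return List with `U`, `p`, `n_a`, `n_b`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("mann_whitney_u: both samples must be non-empty", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u <- min(u_a, n_a * n_b - u_a)
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n_a * n_b <= 400) {
    # exact: two-sided p doubles the lower tail of the symmetric null
    p <- min(1, 2 * stats::pwilcox(u, n_a, n_b))
    method <- "exact"
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sd_u <- sqrt(n_a * n_b / 12 * ((n + 1) - tie_term))
    z <- u_a - mu
    z <- (z - sign(z) * 0.5) / sd_u   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_tie_corrected"
  }
  list(U = u, p = p, n_a = n_a, n_b = n_b, method = method)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the m raw p values ascending, multiplies the i-th smallest by
#' m - i + 1, enforces monotonicity and caps at 1; values are returned in
#' the original order.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
holm_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Post-hoc pairwise Mann-Whitney comparisons with Holm correction
#'
#' Runs the comparison families the retained model terms call for:
#' \enumerate{
#'   \item all pairs of eligible deprivation classes (always);
#'   \item female vs male, when `sex` was retained;
#'   \item within-sex deprivation-class pairs, when the
#'     sex-by-deprivation-class interaction was retained.
#' }
#' Classes (overall or within sex) with fewer than `min_class_n`
#' individuals are excluded, mirroring the exclusion of very small classes
#' from the study analysis. Holm correction is applied within each family.
#'
#' @param table a [metrics_table()] result (or compatible data frame).
#' @param measure `"strength_centrality"` or `"dy2"`; for `dy2`, undefined
#'   rows are excluded listwise.
#' @param behaviour,period subset selectors (`NULL` keeps all rows, for
#'   pre-subset tables).
#' @param retained_terms fixed terms of the selected model (drives families
#'   ii and iii).
#' @param alpha significance level for the `significant` flag.
#' @param min_class_n minimum class size for eligibility.
#' @return A `posthoc_table` tibble: measure, behaviour, period, family,
#'   grouping, level_a, level_b, n_a, n_b, U, p_raw, p_holm, significant.
#' @export
posthoc_pairwise <- function(table, measure = c("strength_centrality", "dy2"),
                             behaviour = NULL, period = NULL,
                             retained_terms = character(),
                             alpha = 0.05, min_class_n = 3) {
  measure <- match.arg(measure)
  df <- tibble::as_tibble(table)
  if (!is.null(behaviour)) df <- df[df$behaviour %in% behaviour, ]
  if (!is.null(period)) df <- df[df$period_id %in% period, ]
  if (measure == "dy2") df <- df[df$defined, ]
  df$value <- df[[measure]]
  beh <- if (!is.null(behaviour)) behaviour else
    paste(unique(df$behaviour), collapse = "+")
  per <- if (!is.null(period)) period else
    paste(unique(df$period_id), collapse = "+")
  empty <- tibble::tibble(
    measure = character(), behaviour = character(), period = character(),
    family = character(), grouping = character(),
    level_a = character(), level_b = character(),
    n_a = integer(), n_b = integer(), U = numeric(),
    p_raw = numeric(), p_holm = numeric(), significant = logical())
  run_family <- function(sub, family, grouping, pairs) {
    if (nrow(pairs) == 0) return(empty)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- sub$value[sub$level == pairs$a[i]]
      b <- sub$value[sub$level == pairs$b[i]]
      mw <- mann_whitney_u(a, b)
      tibble::tibble(
        measure = measure, behaviour = beh, period = per,
        family = family, grouping = grouping,
        level_a = pairs$a[i], level_b = pairs$b[i],
        n_a = mw$n_a, n_b = mw$n_b, U = mw$U, p_raw = mw$p)
    })
    dplyr::bind_rows(rows)
  }
  class_pairs <- function(sub) {
    sizes <- table(sub$level)
    eligible <- sort(names(sizes)[sizes >= min_class_n])
    if (length(eligible) < 2) {
      return(tibble::tibble(a = character(), b = character()))
    }
    cmb <- utils::combn(eligible, 2)
    tibble::tibble(a = cmb[1, ], b = cmb[2, ])
  }
  fams <- list()
  # (i) deprivation-class pairs
  sub <- df; sub$level <- sub$deprivation_class
  fams$class <- run_family(sub, "deprivation_class", "all", class_pairs(sub))
  if (nrow(fams$class) == 0) {
    message("posthoc: fewer than 2 eligible deprivation classes for ",
            measure, " (", beh, ", ", per, ")")
  }
  # (ii) sex, when retained
  if ("sex" %in% retained_terms) {
    sub <- df; sub$level <- sub$sex
    sizes <- table(sub$level)
    if (length(sizes) == 2) {
      fams$sex <- run_family(sub, "sex", "all",
                             tibble::tibble(a = "female", b = "male"))
    }
  }
  # (iii) within-sex class pairs, when the interaction is retained
  if ("sex:deprivation_class" %in% retained_terms) {
    rows <- lapply(sort(unique(df$sex)), function(sx) {
      sub <- df[df$sex == sx, ]; sub$level <- sub$deprivation_class
      run_family(sub, "sex_by_class", sx, class_pairs(sub))
    })
    fams$sexclass <- dplyr::bind_rows(rows)
  }
  out <- lapply(fams, function(fam) {
    if (nrow(fam) == 0) return(fam)
    fam$p_holm <- holm_adjust(fam$p_raw)
    fam$significant <- fam$p_holm < alpha
    fam
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) out <- empty
  class(out) <- c("posthoc_table", class(out))
  out
}
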