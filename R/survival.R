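#' Chemotherapy keyword list
#'
#' The drug-name search strings used to classify patients as receiving
#' DNA-damaging, antifolate, or antinucleotide chemotherapy: "platin",
#' "dox", "uracil", "rubicin", "mycin", "phosphamid", "citabine",
#' "cytoxan", "trexate", "ac", "capecetabine", "5-fu", "metotreksat",
#' "mitoxantrone", "cytoxen", "gemzar", "tc", "tch", "xeloda".
#'
#' @return Character vector of keywords (lower case).
#' @export
chemo_keywords <- function() {
  c("platin", "dox", "uracil", "rubicin", "mycin", "phosphamid",
    "citabine", "cytoxan", "trexate", "ac", "capecetabine", "5-fu",
    "metotreksat", "mitoxantrone", "cytoxen", "gemzar", "tc", "tch",
    "xeloda")
}

#' Classify treatments from free-text drug names
#'
#' A patient is classed `chemo` if any of their drug strings matches any
#' keyword after lower-casing and trimming. By default (`match =
#' "safe"`), keywords of at least 4 alphabetic characters match as
#' substrings while short codes ("ac", "tc", "tch", "5-fu") match only as
#' whole tokens, so "paclitaxel" is not swept up by the substring "ac";
#' `match = "substring"` replicates pure substring matching for all
#' keywords. Patients with no (or empty) drug strings are `non_chemo` and
#' flagged `untreated`.
#'
#' @param drugs Character vector (one free-text entry per patient; multiple
#'   drugs may share an entry) or a list of character vectors per patient.
#' @param keywords Keyword list; defaults to [chemo_keywords()].
#' @param match `"safe"` (token matching for short codes) or
#'   `"substring"`.
#' @return `data.frame`: `class` (`"chemo"`/`"non_chemo"`), `untreated`,
#'   `matched` (first matching keyword or `NA`).
#' @examples
#' classify_treatment(c("Oxaliplatin", "letrozole", "paclitaxel", ""))
#' @export
classify_treatment <- function(drugs, keywords = chemo_keywords(),
                               match = c("safe", "substring")) {
  match <- base::match.arg(match)
  if (!is.list(drugs)) drugs <- as.list(drugs)
  keywords <- tolower(trimws(keywords))
  token_kw <- if (match == "safe") {
    keywords[nchar(keywords) < 4 | grepl("[^a-z]", keywords)]
  } else character()
  sub_kw <- setdiff(keywords, token_kw)
  one <- function(dr) {
    dr <- tolower(trimws(as.character(dr)))
    dr <- dr[!is.na(dr) & nzchar(dr)]
    if (length(dr) == 0) {
      return(c(class = "non_chemo", untreated = TRUE, matched = NA_character_))
    }
    for (k in sub_kw) {
      if (any(grepl(k, dr, fixed = TRUE))) {
        return(c(class = "chemo", untreated = FALSE, matched = k))
      }
    }
    tokens <- unlist(strsplit(dr, "[^a-z0-9-]+"))
    hit <- token_kw[token_kw %in% tokens]
    if (length(hit)) {
      return(c(class = "chemo", untreated = FALSE, matched = hit[1]))
    }
    c(class = "non_chemo", untreated = FALSE, matched = NA_character_)
  }
  m <- t(vapply(drugs, one, character(3)))
  data.frame(class = m[, 1], untreated = as.logical(m[, 2]),
             matched = m[, 3], stringsAsFactors = FALSE, row.names = NULL)
}

#' Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit survival curve with right censoring and
#' Greenwood variance. If every observation is censored before the first
#' event the curve is identically 1 (with a warning).
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Object of class `"km_curve"`: `data.frame` of `time`, `n_risk`,
#'   `n_event`, `surv`, `var` (Greenwood), plus `n` and `events`
#'   attributes. Query with [km_at()].
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1) stop("need >= 1 subject")
  if (any(time <= 0)) stop("times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  if (sum(event) == 0) {
    warning("no events observed; survival curve is identically 1")
    tab <- data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), surv = numeric(), var = numeric())
  } else {
    et <- sort(unique(time[event == 1]))
    n_risk <- vapply(et, function(t) sum(time >= t), integer(1))
    n_event <- vapply(et, function(t) sum(time == t & event == 1), integer(1))
    surv <- cumprod(1 - n_event / n_risk)
    gw <- ifelse(n_risk > n_event,
                 n_event / (n_risk * (n_risk - n_event)), NA_real_)
    var <- surv^2 * cumsum(gw)
    tab <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                      surv = surv, var = var)
  }
  structure(tab, class = c("km_curve", "data.frame"),
            n = length(time), events = sum(event))
}

#' Survival probability at a horizon
#'
#' Evaluates a [km_curve()] at time `t` using the right-continuous step
#' convention: the estimate at the last event time at or before `t`
#' (1 before the first event).
#'
#' @param km A `"km_curve"` object.
#' @param t Numeric horizon(s).
#' @return Survival probabilities.
#' @export
km_at <- function(km, t) {
  vapply(t, function(tt) {
    below <- km$time <= tt
    if (!any(below)) 1 else km$surv[max(which(below))]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", attr(x, "n"),
      ", events =", attr(x, "events"), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Cox proportional hazards fit (single covariate, Efron ties)
#'
#' Maximises the Efron-tie partial likelihood by Newton-Raphson for a
#' single numeric or two-level covariate and reports the hazard ratio
#' `exp(coef)`, its standard error and the Wald p-value. With a binary
#' group, swapping the labels inverts the hazard ratio exactly. If one
#' group carries all the events (monotone likelihood) the fit is reported
#' as diverged with `hr = NA` rather than a spurious number.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level factor/character (second level is the exposed
#'   group) or a numeric covariate.
#' @param tol Convergence tolerance on the score (default 1e-9).
#' @param max_iter Newton-Raphson iteration cap.
#' @return Object of class `"cox_fit"`: list with `coef`, `hr`, `se`, `p`,
#'   `n`, `events`, `diverged`, `levels`.
#' @export
cox_hr <- function(time, event, group, tol = 1e-9, max_iter = 30) {
  if (sum(event) < 1) stop("need >= 1 event")
  levs <- NULL
  if (!is.numeric(group)) {
    levs <- if (is.factor(group)) levels(droplevels(factor(group))) else sort(unique(as.character(group)))
    if (length(levs) != 2) stop("group must have exactly two levels")
    x <- as.numeric(factor(as.character(group), levels = levs)) - 1
  } else {
    x <- group
  }
  if (stats::sd(x) == 0) stop("group covariate has zero variance")
  binary <- all(x %in% c(0, 1))
  if (binary) {
    ev_by <- tapply(event, x, sum)
    if (any(ev_by == 0) || length(ev_by) < 2) {
      warning("all events in one group: monotone partial likelihood, fit diverges")
      return(structure(list(coef = NA_real_, hr = NA_real_, se = NA_real_,
                            p = NA_real_, n = length(time),
                            events = sum(event), diverged = TRUE,
                            levels = levs), class = "cox_fit"))
    }
  }
  beta <- 0
  for (it in seq_len(max_iter)) {
    d <- efron_derivs(beta, time, event, x)
    if (abs(d$grad) < tol) break
    step <- d$grad / d$info
    if (!is.finite(step)) break
    # damp huge steps for stability
    if (abs(step) > 5) step <- sign(step) * 5
    beta <- beta + step
  }
  d <- efron_derivs(beta, time, event, x)
  se <- sqrt(1 / d$info)
  z <- beta / se
  structure(list(coef = beta, hr = exp(beta), se = se,
                 p = 2 * stats::pnorm(-abs(z)), n = length(time),
                 events = sum(event), diverged = FALSE, levels = levs),
            class = "cox_fit")
}

#' Efron partial log-likelihood
#'
#' Evaluates the Efron-tie partial log-likelihood at `beta` for a single
#' covariate. Exposed so estimates can be checked against brute-force
#' maximisation.
#'
#' @inheritParams cox_hr
#' @param beta Coefficient value(s) at which to evaluate.
#' @param x Numeric covariate vector.
#' @return Log partial likelihood value(s).
#' @export
efron_loglik <- function(beta, time, event, x) {
  vapply(beta, function(b) efron_derivs(b, time, event, x)$loglik, numeric(1))
}

efron_derivs <- function(beta, time, event, x) {
  r <- exp(beta * x)
  et <- sort(unique(time[event == 1]))
  ll <- 0; grad <- 0; info <- 0
  for (t in et) {
    R <- time >= t
    D <- time == t & event == 1
    d <- sum(D)
    s0R <- sum(r[R]); s1R <- sum(r[R] * x[R]); s2R <- sum(r[R] * x[R]^2)
    s0D <- sum(r[D]); s1D <- sum(r[D] * x[D]); s2D <- sum(r[D] * x[D]^2)
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      a0 <- s0R - (l / d) * s0D
      a1 <- s1R - (l / d) * s1D
      a2 <- s2R - (l / d) * s2D
      ll <- ll - log(a0)
      grad_t <- a1 / a0
      grad <- grad - grad_t
      info <- info + a2 / a0 - grad_t^2
    }
    grad <- grad + sum(x[D])
  }
  list(loglik = ll, grad = grad, info = info)
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$diverged) {
    cat("Cox fit: diverged (monotone likelihood);",
        x$events, "events in", x$n, "subjects\n")
  } else {
    cat(sprintf("Cox fit: HR = %.4g (coef %.4g, se %.4g), Wald p = %.3g, n = %d, events = %d\n",
                x$hr, x$coef, x$se, x$p, x$n, x$events))
    if (!is.null(x$levels)) {
      cat("  hazard of", x$levels[2], "relative to", x$levels[1], "\n")
    }
  }
  invisible(x)
}

#' Burden- and treatment-stratified survival analysis
#'
#' Reproduces the cohort-stratification design: patients are split by
#' treatment class (chemo vs non-chemo) and aneuploidy burden class
#' (net_gain vs net_loss); within each treatment class a two-group Cox
#' model estimates the hazard of net_loss relative to net_gain, and a
#' Kaplan-Meier curve with the survival probability at `horizon` years is
#' reported for each of the four strata. Follow-up is administratively
#' truncated at `horizon` before fitting.
#'
#' @param cohort `data.frame` with `time`, `event`, `treatment_class`
#'   (`"chemo"`/`"non_chemo"`), `burden_class` (`"net_gain"`/`"net_loss"`).
#' @param horizon Years of follow-up analysed (default 5).
#' @return A list: `km` (`data.frame` per stratum: `treatment_class`,
#'   `burden_class`, `n`, `events`, `surv_horizon`) and `cox`
#'   (`data.frame` per treatment class: `hr`, `coef`, `se`, `p`, `n`,
#'   `events`). Missing strata yield a partial table with a warning;
#'   a cohort with only one burden class is rejected.
#' @export
stratified_survival_analysis <- function(cohort, horizon = 5) {
  req <- c("time", "event", "treatment_class", "burden_class")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  if (length(unique(cohort$burden_class)) < 2) {
    stop("cohort must contain both net_gain and net_loss burden classes")
  }
  over <- cohort$time > horizon
  cohort$event[over] <- 0L
  cohort$time[over] <- horizon

  strata <- expand.grid(treatment_class = c("chemo", "non_chemo"),
                        burden_class = c("net_gain", "net_loss"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  km_rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- cohort$treatment_class == strata$treatment_class[i] &
      cohort$burden_class == strata$burden_class[i]
    if (!any(sel)) return(NULL)
    km <- suppressWarnings(km_curve(cohort$time[sel], cohort$event[sel]))
    data.frame(strata[i, ], n = sum(sel), events = sum(cohort$event[sel]),
               surv_horizon = km_at(km, horizon), stringsAsFactors = FALSE)
  })
  empty <- vapply(km_rows, is.null, logical(1))
  if (any(empty)) {
    warning("empty stratum(s): ",
            paste(paste(strata$treatment_class[empty],
                        strata$burden_class[empty]), collapse = ", "),
            "; partial table returned")
  }
  km_tab <- do.call(rbind, km_rows[!empty])

  cox_rows <- lapply(c("chemo", "non_chemo"), function(tc) {
    sel <- cohort$treatment_class == tc
    sub <- cohort[sel, , drop = FALSE]
    if (length(unique(sub$burden_class)) < 2 || sum(sub$event) == 0) return(NULL)
    fit <- cox_hr(sub$time, sub$event,
                  factor(sub$burden_class, levels = c("net_gain", "net_loss")))
    data.frame(treatment_class = tc, hr = fit$hr, coef = fit$coef,
               se = fit$se, p = fit$p, n = fit$n, events = fit$events,
               diverged = fit$diverged, stringsAsFactors = FALSE)
  })
  cox_tab <- do.call(rbind, cox_rows)
  list(km = km_tab, cox = cox_tab)
}
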