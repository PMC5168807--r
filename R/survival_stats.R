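# two-group log-rank core: returns c(chisq, oe) where oe = observed minus
# expected deaths in the g == TRUE group. Inputs must be NA-free.
# Variance uses the standard hypergeometric form, matching survival::survdiff.
.logrank_core <- function(time, event, g) {
  o <- order(time)
  time <- time[o]; event <- event[o]; g <- g[o]
  n <- length(time)
  first <- which(!duplicated(time))          # row of first occurrence per distinct time
  atrisk <- n - first + 1
  suff_g <- rev(cumsum(rev(as.numeric(g))))  # patients in group at risk from row i on
  atrisk1 <- suff_g[first]
  d <- rowsum(as.numeric(event), time)[, 1]
  d1 <- rowsum(as.numeric(event & g), time)[, 1]
  keep <- d > 0
  d <- d[keep]; d1 <- d1[keep]
  nk <- atrisk[keep]; n1 <- atrisk1[keep]
  oe <- sum(d1 - d * n1 / nk)
  denom <- ifelse(nk > 1, nk - 1, 1)
  v <- sum(d * (n1 / nk) * (1 - n1 / nk) * (nk - d) / denom)
  if (v <= 0) return(c(0, 0))
  c(oe^2 / v, oe)
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank chi-square statistic (1 df) over the pooled
#' distinct event times, with the p-value from the chi-square upper tail.
#' If no event is observed in either group the test is degenerate: the
#' statistic is 0 and p = 1, with a warning.
#'
#' @param time follow-up times in days (death or last follow-up).
#' @param event logical, death observed.
#' @param group logical (or two-level) group indicator.
#' @return one-row tibble: `statistic`, `p_value`, `n_a`, `n_b`
#'   (group sizes for `group == TRUE` / `FALSE`).
#' @examples
#' logrank_test(c(1, 2, 3, 4, 5, 6), rep(TRUE, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
logrank_test <- function(time, event, group) {
  if (!is.logical(group)) {
    lv <- unique(group)
    if (length(lv) > 2) stop("log-rank test is two-group; got ", length(lv), " levels",
                             call. = FALSE)
    group <- group == sort(lv)[length(lv)]
  }
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- as.logical(event[ok]); group <- group[ok]
  if (sum(group) == 0 || sum(!group) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (!any(event)) {
    warning("no events in either group; log-rank test degenerate", call. = FALSE)
    return(tibble::tibble(statistic = 0, p_value = 1,
                          n_a = sum(group), n_b = sum(!group)))
  }
  st <- .logrank_core(time, event, group)
  tibble::tibble(statistic = st[1],
                 p_value = stats::pchisq(st[1], df = 1, lower.tail = FALSE),
                 n_a = sum(group), n_b = sum(!group))
}

# vectorized Welch t across matrix rows: x, y are features x samples value
# matrices (same rows). Returns tibble(t, df, p, n_x, n_y); rows with fewer
# than 2 values on either side get NA (caller skips them).
.welch_rows <- function(x, y) {
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- (rowSums(x^2, na.rm = TRUE) - nx * mx^2) / pmax(nx - 1, 1)
  vy <- (rowSums(y^2, na.rm = TRUE) - ny * my^2) / pmax(ny - 1, 1)
  vx <- pmax(vx, 0); vy <- pmax(vy, 0)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  bad <- nx < 2 | ny < 2 | !is.finite(t)
  t[bad] <- NA_real_; df[bad] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, n_x = nx, n_y = ny)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with the Welch-Satterthwaite degrees of
#' freedom. Missing values are dropped; fewer than two values on either side
#' is an error (feature-level callers skip such features instead).
#'
#' @param x,y numeric vectors.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `n_x`, `n_y`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t_test needs at least 2 non-missing values per group", call. = FALSE)
  }
  w <- .welch_rows(matrix(x, 1), matrix(y, 1))
  tibble::tibble(statistic = w$t, df = w$df, p_value = w$p,
                 n_x = w$n_x, n_y = w$n_y)
}

#' Fit a Cox proportional-hazards model
#'
#' Wraps [survival::coxph()] with the Efron approximation for tied event
#' times. Patients missing any requested covariate are dropped (complete-case
#' fit). Non-convergence or monotone-likelihood (perfect separation) fits are
#' returned flagged rather than failing, so exhaustive model searches can
#' skip them with a logged reason.
#'
#' @param data tibble with columns `time_days`, `event` (logical) and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @return a `surv_model` object: coefficients, maximized log partial
#'   likelihood, `AIC = -2 loglik + 2 k`, number of patients/events used,
#'   convergence flag.
#' @export
fit_cox <- function(data, covariates) {
  stopifnot(length(covariates) >= 1)
  miss <- setdiff(c("time_days", "event", covariates), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[c("time_days", "event", covariates)]
  cc <- stats::complete.cases(d)
  d <- d[cc, ]
  if (nrow(d) < length(covariates) + 2) {
    stop(sprintf("too few complete cases (%d) for %d covariate(s)", nrow(d),
                 length(covariates)), call. = FALSE)
  }
  if (!any(d$event)) stop("no events among complete cases", call. = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time_days, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  flag <- NULL
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = d, ties = "efron"),
             error = function(e) e),
    warning = function(w) {
      flag <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    return(structure(list(covariates = covariates, coef = NULL, loglik = NA_real_,
                          aic = NA_real_, n = nrow(d), n_event = sum(d$event),
                          converged = FALSE, flag = conditionMessage(fit), fit = NULL),
                     class = "surv_model"))
  }
  beta <- stats::coef(fit)
  names(beta) <- covariates
  ll <- fit$loglik[length(fit$loglik)]
  converged <- is.null(flag) && all(is.finite(beta))
  structure(list(covariates = covariates, coef = beta, loglik = ll,
                 aic = -2 * ll + 2 * length(beta), n = nrow(d),
                 n_event = sum(d$event), converged = converged, flag = flag,
                 fit = fit),
            class = "surv_model")
}

#' @export
print.surv_model <- function(x, ...) {
  cat(sprintf("<surv_model> %d covariate(s), n = %d (%d events), loglik = %.3f, AIC = %.3f%s\n",
              length(x$covariates), x$n, x$n_event, x$loglik, x$aic,
              if (!x$converged) paste0(" [flagged: ", x$flag, "]") else ""))
  if (!is.null(x$coef)) print(round(x$coef, 4))
  invisible(x)
}

#' Tidy a fitted survival model
#'
#' @param x a `surv_model`.
#' @param ... unused.
#' @return tibble with one row per coefficient: `term`, `estimate` (log
#'   hazard ratio), `std.error`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.surv_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = character(), estimate = double(),
                          std.error = double(), statistic = double(),
                          p.value = double()))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = x$covariates, estimate = unname(x$coef),
                 std.error = unname(s[, "se(coef)"]),
                 statistic = unname(s[, "z"]), p.value = unname(s[, "Pr(>|z|)"]))
}

#' @rdname tidy.surv_model
#' @exportS3Method generics::glance
glance.surv_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik, AIC = x$aic,
                 df = length(x$covariates), converged = x$converged)
}

#' Risk score (linear predictor) of a fitted model
#'
#' Plain `X %*% beta` on the model's covariates; patients missing any
#' covariate get `NA`. Unlike `coxph`'s centered linear predictor this is not
#' shifted, but concordance is invariant to shifts.
#'
#' @param model a `surv_model`.
#' @param data tibble containing the model's covariate columns.
#' @return named numeric vector (names from `data$patient_id` if present).
#' @export
risk_score <- function(model, data) {
  X <- as.matrix(data[model$covariates])
  lp <- drop(X %*% model$coef)
  if ("patient_id" %in% names(data)) names(lp) <- data$patient_id
  lp
}

#' Harrell's concordance index
#'
#' Comparable pairs are (i, j) with an observed event for i and
#' `time_i < time_j`; a pair is concordant when the higher-risk patient dies
#' first (`risk_i > risk_j`), and tied risks count 1/2. Pairs censored at
#' equal times are not comparable. C = (concordant + 0.5 tied) / comparable.
#'
#' @param risk per-patient risk scores (higher = worse prognosis).
#' @param time follow-up times.
#' @param event logical event indicator.
#' @return one-row tibble: `c_index`, `concordant`, `discordant`, `tied_risk`,
#'   `comparable_pairs`.
#' @examples
#' concordance_index(risk = c(4, 3, 2, 1), time = 1:4,
#'                   event = c(TRUE, FALSE, TRUE, FALSE))
#' @export
concordance_index <- function(risk, time, event) {
  ok <- !is.na(risk) & !is.na(time) & !is.na(event)
  risk <- risk[ok]; time <- time[ok]; event <- as.logical(event[ok])
  st <- .cindex_core(risk, time, event)
  if (st[["comparable"]] == 0) stop("no comparable pairs", call. = FALSE)
  tibble::tibble(c_index = (st[["concordant"]] + 0.5 * st[["tied"]]) / st[["comparable"]],
                 concordant = st[["concordant"]], discordant = st[["discordant"]],
                 tied_risk = st[["tied"]], comparable_pairs = st[["comparable"]])
}

# O(n^2) vectorized pair counting; n <= ~1000 in this package's workloads
.cindex_core <- function(risk, time, event) {
  cmp <- outer(time, time, "<") & event        # row i comparable to col j
  dr <- outer(risk, risk, "-")
  concordant <- sum(cmp & dr > 0)
  tied <- sum(cmp & dr == 0)
  comparable <- sum(cmp)
  c(concordant = concordant, discordant = comparable - concordant - tied,
    tied = tied, comparable = comparable)
}

# scalar C-index for hot loops
.cindex <- function(risk, time, event) {
  st <- .cindex_core(risk, time, event)
  if (st[["comparable"]] == 0) return(NA_real_)
  (st[["concordant"]] + 0.5 * st[["tied"]]) / st[["comparable"]]
}

#' Serialize / read model coefficients
#'
#' @param model a `surv_model`.
#' @param path TSV path of (covariate, coefficient) rows.
#' @export
write_model <- function(model, path) {
  readr::write_tsv(tibble::tibble(covariate = model$covariates,
                                  coefficient = .fmt_num(unname(model$coef))),
                   path, progress = FALSE)
  invisible(path)
}
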