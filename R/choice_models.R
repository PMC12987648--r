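#' Inclusion mask for analysis trials
#'
#' Trials enter analyses when not artifact-rejected and RT is at or below
#' 600 ms (responses beyond the longest deadline are omitted).
#'
#' @param trials a trial table.
#' @return logical vector.
#' @export
included_trials <- function(trials) {
  ok <- !isTRUE_vec(trials$excluded) & !is.na(trials$rt_ms) & trials$rt_ms <= 600
  ok & !is.na(trials$choice)
}

#' Build a regression design matrix for choice models
#'
#' Binary coding follows the study convention: upper-field targets and
#' choices, correct responses and the 600 ms deadline are coded 1 (their
#' alternatives 0). Continuous predictors are z-scored over the included
#' trials; RT enters in seconds. With quadratic RT interactions each predictor
#' contributes three regressors (main effect, x RT, x RT^2), so 16 predictors
#' yield 48 columns.
#'
#' @param trials a trial table.
#' @param covariates numeric matrix (trials x signals) of continuous
#'   predictors, e.g. the C1 plus extracted choice signals; may be NULL.
#' @param rt_interactions `"quadratic"` or `"none"`.
#' @param include which trial-table predictors to add: any of `"target"`,
#'   `"prev_choice"`.
#' @param z_score z-score continuous predictors (default TRUE).
#' @return list with `X` (matrix, named columns), `y` (0/1 upper choice),
#'   `rt_s`, `rows` (indices of trials used), `groups` (participant ids or
#'   NULL).
#' @export
build_design <- function(trials, covariates = NULL,
                         rt_interactions = c("quadratic", "none"),
                         include = c("target", "prev_choice"),
                         z_score = TRUE) {
  rt_interactions <- match.arg(rt_interactions)
  keep <- included_trials(trials)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  if ("prev_choice" %in% include) keep <- keep & !is.na(trials$prev_choice)
  if (!any(keep)) .fail("no trials remain after exclusions/missingness")
  rows <- which(keep)
  preds <- list()
  if ("target" %in% include)
    preds$target <- as.numeric(trials$target[rows] == "upper")
  if ("prev_choice" %in% include)
    preds$prev_choice <- as.numeric(trials$prev_choice[rows] == "upper")
  if (!is.null(covariates)) {
    cv <- covariates[rows, , drop = FALSE]
    for (nm in colnames(cv)) {
      v <- cv[, nm]
      if (z_score) {
        s <- stats::sd(v)
        v <- if (s > 0) (v - mean(v)) / s else v
      }
      preds[[nm]] <- v
    }
  }
  const <- vapply(preds, function(v) stats::sd(v) == 0, logical(1L))
  if (any(const)) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(names(preds)[const], collapse = ", ")))
    preds <- preds[!const]
  }
  if (length(preds) == 0L) .fail("no usable predictors")
  rt_s <- trials$rt_ms[rows] / 1000
  cols <- list()
  for (nm in names(preds)) {
    cols[[nm]] <- preds[[nm]]
    if (rt_interactions == "quadratic") {
      cols[[paste0(nm, ":rt")]]  <- preds[[nm]] * rt_s
      cols[[paste0(nm, ":rt2")]] <- preds[[nm]] * rt_s^2
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = as.numeric(trials$choice[rows] == "upper"), rt_s = rt_s,
       rows = rows, groups = trials$participant[rows])
}

# quick logistic fit on a plain design matrix (intercept added); returns NULL
# on rank deficiency, otherwise term table + convergence flag. Fisher scoring
# (IRLS) through the normal equations -- fast for the small designs used in
# the sliding-window analyses; cross-checked against stats::glm in the tests.
.logistic_fit <- function(X, y, df_t = TRUE, maxit = 30L, tol = 1e-10,
                          beta_init = NULL, rank_check = TRUE) {
  Xd <- cbind(`(Intercept)` = 1, X)
  if (rank_check && qr(Xd)$rank < ncol(Xd)) return(NULL)
  beta <- if (is.null(beta_init) || length(beta_init) != ncol(Xd) ||
              anyNA(beta_init)) numeric(ncol(Xd)) else beta_init
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w[w < 1e-12] <- 1e-12
    z <- eta + (y - mu) / w
    XtW <- Xd * w
    ch <- tryCatch(chol(crossprod(Xd, XtW)), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- drop(backsolve(ch, forwardsolve(t(ch), crossprod(XtW, z))))
    eta2 <- drop(Xd %*% beta)
    dev <- 2 * sum(log1p(exp(-abs(eta2))) + pmax(eta2, 0) - y * eta2)
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE; break
    }
    dev_old <- dev
  }
  eta <- drop(Xd %*% beta)
  sep <- any(abs(eta) > 25)   # fitted probabilities numerically 0/1
  mu <- 1 / (1 + exp(-eta))
  w <- mu * (1 - mu)
  w[w < 1e-12] <- 1e-12
  cov <- tryCatch(chol2inv(chol(crossprod(Xd, Xd * w))), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  se <- sqrt(diag(cov))
  tval <- beta / se
  df <- length(y) - ncol(Xd)
  p <- if (df_t) 2 * stats::pt(-abs(tval), df) else 2 * stats::pnorm(-abs(tval))
  list(table = data.frame(term = colnames(Xd), beta = beta, se = se,
                          t = tval, p = p, row.names = NULL),
       n = length(y), converged = converged && !sep, separation = sep)
}

#' Fit a (mixed-effects) logistic regression
#'
#' Maximum-likelihood logistic regression of a binary response on a design
#' matrix, optionally with per-group random intercepts (Laplace approximation
#' via `lme4::glmer`). Wald t statistics use residual degrees of freedom.
#' Perfect separation is flagged as non-convergence with a warning, and
#' coefficients are still reported.
#'
#' @param X design matrix (no intercept column; one is added).
#' @param y 0/1 response.
#' @param random_intercepts logical.
#' @param groups grouping factor (participant ids), required when
#'   `random_intercepts = TRUE`.
#' @return object of class `model_fit`: list with `table` (term, beta, se, t,
#'   p), `n`, `converged`.
#' @export
fit_logistic <- function(X, y, random_intercepts = FALSE, groups = NULL) {
  if (length(unique(y)) < 2L) .fail("response is constant")
  if (!random_intercepts) {
    res <- .logistic_fit(as.matrix(X), y)
    if (is.null(res)) .fail("design matrix is rank deficient")
    if (res$separation)
      warning("possible perfect separation; coefficients reported but flagged non-converged")
    res$family <- "binomial"
    class(res) <- "model_fit"
    return(res)
  }
  if (is.null(groups)) .fail("groups required for random intercepts")
  dat <- data.frame(.y = y, .g = factor(groups), X, check.names = FALSE)
  xn <- colnames(X)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", xn), collapse = " + "),
                                 "+ (1 | .g)"))
  fit <- lme4::glmer(fml, data = dat, family = stats::binomial(), nAGQ = 1L,
                     control = lme4::glmerControl(calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  df <- length(y) - nrow(sm)
  res <- list(table = data.frame(term = rownames(sm), beta = sm[, 1L],
                                 se = sm[, 2L], t = sm[, 3L],
                                 p = 2 * stats::pt(-abs(sm[, 3L]), df),
                                 row.names = NULL),
              n = length(y),
              converged = length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L,
              family = "binomial", random_intercepts = TRUE)
  class(res) <- "model_fit"
  res
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s, n = %d%s\n", x$family %||% "gaussian", x$n,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  tb <- x$table
  tb$beta <- signif(tb$beta, 4); tb$se <- signif(tb$se, 3)
  tb$t <- signif(tb$t, 3); tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Vertex of a quadratic RT coefficient function
#'
#' For a predictor with main, linear-RT and quadratic-RT coefficients, the RT
#' at which its effect is extremal: `-beta_lin / (2 beta_quad)`, converted
#' from seconds to ms. Invariant to rescaling all three betas by a common
#' positive factor.
#'
#' @param beta_main,beta_lin,beta_quad coefficients (RT in seconds).
#' @return list with `rt_ms` and `extremum` ("minimum" if `beta_quad > 0`,
#'   else "maximum").
#' @export
quadratic_vertex <- function(beta_main, beta_lin, beta_quad) {
  if (beta_quad == 0) .fail("beta_quad is 0: vertex undefined")
  list(rt_ms = 1000 * (-beta_lin / (2 * beta_quad)),
       extremum = if (beta_quad > 0) "minimum" else "maximum")
}

#' Sliding RT-percentile-window choice models
#'
#' Fits the full covariate choice model (no RT interaction terms, no random
#' intercepts) within sliding windows of the pooled RT distribution: windows
#' span `width` percentile points and are centred at each unit percentile of
#' `centers` (default 10..90, giving 81 windows).
#'
#' @param trials a trial table.
#' @param covariates as [build_design()] (C1 first column by convention).
#' @param centers window centres in percentile points.
#' @param width window width in percentile points (default 20).
#' @param include trial-level predictors, as [build_design()].
#' @param percentile_scope `"pooled"` (default; percentiles of the pooled
#'   included-trial RT distribution) or `"participant"`.
#' @param alpha two-sided significance level for per-window flags.
#' @param flip_c1 name of the covariate whose reported coefficient is
#'   sign-flipped so positive = choice-congruent (default `"c1"`; set NULL to
#'   disable).
#' @return object of class `window_series`: data.frame with one row per
#'   window x term (`center_pct`, `center_ms`, `term`, `beta`, `se`, `t`,
#'   `p`, `sig`, `beta_report`, `valid`), with attributes `alpha`, `width`.
#' @export
sliding_rt_models <- function(trials, covariates = NULL, centers = 10:90,
                              width = 20, include = c("target", "prev_choice"),
                              percentile_scope = c("pooled", "participant"),
                              alpha = 0.05, flip_c1 = "c1") {
  percentile_scope <- match.arg(percentile_scope)
  d <- build_design(trials, covariates, rt_interactions = "none",
                    include = include)
  rt <- d$rt_s * 1000
  pr <- if (percentile_scope == "pooled") {
    stats::ecdf(rt)(rt) * 100
  } else {
    g <- d$groups %||% rep(1L, length(rt))
    out <- numeric(length(rt))
    for (p in unique(g)) {
      i <- g == p
      out[i] <- stats::ecdf(rt[i])(rt[i]) * 100
    }
    out
  }
  half <- width / 2
  ord <- order(pr)                 # windows slide over the percentile order
  pr_s <- pr[ord]; rt_s_ms <- rt[ord]
  Xs <- d$X[ord, , drop = FALSE]; ys <- d$y[ord]
  terms <- colnames(d$X); k <- length(terms)
  nw <- length(centers)
  beta_m <- se_m <- t_m <- p_m <- matrix(NA_real_, nw, k)
  cms <- numeric(nw); valid <- logical(nw)
  warm <- NULL
  for (wi in seq_len(nw)) {
    cc <- centers[wi]
    i0 <- findInterval(cc - half - 1e-9, pr_s) + 1L   # first index >= cc - half
    i1 <- findInterval(cc + half + 1e-9, pr_s)        # last index <= cc + half
    cm <- stats::median(rt_s_ms[pr_s >= cc - 0.5 & pr_s <= cc + 0.5])
    if (!is.finite(cm)) cm <- stats::quantile(rt, cc / 100, names = FALSE)
    cms[wi] <- cm
    if (i1 - i0 + 1L <= k + 2L) next
    yw <- ys[i0:i1]
    if (all(yw == yw[1L])) next
    fit <- .logistic_fit(Xs[i0:i1, , drop = FALSE], yw,
                         beta_init = warm, rank_check = is.null(warm))
    if (is.null(fit)) { warm <- NULL; next }
    warm <- fit$table$beta
    bi <- fit$table$beta[-1L]; si <- fit$table$se[-1L]
    beta_m[wi, ] <- bi; se_m[wi, ] <- si
    t_m[wi, ] <- fit$table$t[-1L]; p_m[wi, ] <- fit$table$p[-1L]
    valid[wi] <- TRUE
  }
  flip <- if (is.null(flip_c1)) rep(FALSE, k) else terms %in% flip_c1
  out <- data.frame(
    center_pct = rep(centers, each = k), center_ms = rep(cms, each = k),
    term = rep(terms, nw), beta = as.vector(t(beta_m)),
    se = as.vector(t(se_m)), t = as.vector(t(t_m)), p = as.vector(t(p_m)),
    sig = as.vector(t(p_m)) < alpha & rep(valid, each = k),
    beta_report = as.vector(t(beta_m)) * ifelse(rep(flip, nw), -1, 1),
    valid = rep(valid, each = k), stringsAsFactors = FALSE)
  out$sig[is.na(out$sig)] <- FALSE
  attr(out, "alpha") <- alpha
  attr(out, "width") <- width
  class(out) <- c("window_series", "data.frame")
  out
}

#' Extract one term's significance sequence from a window series
#'
#' @param ws a [sliding_rt_models()] result.
#' @param term term name.
#' @return list with `sig` (logical), `beta` (reported, i.e. possibly
#'   sign-flipped), `center_pct`, `center_ms`.
#' @export
window_term <- function(ws, term) {
  z <- ws[ws$term == term, ]
  if (nrow(z) == 0L) .fail("term '%s' not in window series", term)
  z <- z[order(z$center_pct), ]
  list(sig = z$sig & z$valid, beta = z$beta_report,
       center_pct = z$center_pct, center_ms = z$center_ms)
}

#' Greedy collinearity pruning
#'
#' Removes regressors until all pairwise correlation magnitudes are at or
#' below `max_abs_r`, removing as few columns as possible (greedily: the
#' column implicated in most violations first; ties broken by larger maximal
#' correlation, then column order). Protected columns are never removed; if a
#' violating pair is entirely protected, an error names the blocking pair.
#'
#' @param X design matrix.
#' @param max_abs_r threshold (default 0.5).
#' @param protect column names never removed (default: the C1 terms).
#' @return list with `X` (reduced), `dropped` (names).
#' @export
collinearity_prune <- function(X, max_abs_r = 0.5,
                               protect = grep("^c1", colnames(X), value = TRUE)) {
  if (ncol(X) < 2L) .fail("need >= 2 regressors")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  keep <- colnames(X)
  dropped <- character(0)
  repeat {
    R <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    if (max(R, na.rm = TRUE) <= max_abs_r) break
    viol <- R > max_abs_r
    cand <- keep[!(keep %in% protect)]
    if (length(cand) == 0L || all(!viol[cand, , drop = FALSE])) {
      ij <- which(R == max(R), arr.ind = TRUE)[1L, ]
      .fail("cannot reach |r| <= %g without removing protected columns (blocking pair: %s, %s)",
            max_abs_r, keep[ij[1L]], keep[ij[2L]])
    }
    counts <- rowSums(viol)[cand]
    worst <- apply(R[cand, , drop = FALSE], 1L, max)
    pick <- cand[order(-counts, -worst)][1L]
    dropped <- c(dropped, pick)
    keep <- setdiff(keep, pick)
  }
  list(X = X[, keep, drop = FALSE], dropped = dropped)
}

#' Linear model of C1 amplitude on choices, history and covariates
#'
#' The choice-probability model with the roles of C1 and choice swapped: C1 is
#' the dependent variable and current choice, previous choice, target location
#' and the covariate signals are predictors, each with quadratic RT
#' interactions. Optionally refits with current-choice terms omitted (the
#' choice-history bias should be essentially unchanged).
#'
#' @param trials a trial table.
#' @param covariates continuous covariate matrix (excluding the C1).
#' @param c1 per-trial C1 values (µV).
#' @param drop_current_choice omit the current-choice terms.
#' @param random_intercepts use participant random intercepts (`lme4::lmer`).
#' @return a `model_fit`.
#' @export
fit_c1_dv_model <- function(trials, covariates = NULL, c1,
                            drop_current_choice = FALSE,
                            random_intercepts = FALSE) {
  keep <- included_trials(trials) & !is.na(c1) & !is.na(trials$prev_choice)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  rows <- which(keep)
  rt_s <- trials$rt_ms[rows] / 1000
  preds <- list(target = as.numeric(trials$target[rows] == "upper"),
                prev_choice = as.numeric(trials$prev_choice[rows] == "upper"))
  if (!drop_current_choice)
    preds <- c(list(choice = as.numeric(trials$choice[rows] == "upper")), preds)
  if (!is.null(covariates)) {
    cv <- covariates[rows, , drop = FALSE]
    for (nm in colnames(cv)) {
      v <- cv[, nm]; s <- stats::sd(v)
      preds[[nm]] <- if (s > 0) (v - mean(v)) / s else v
    }
  }
  cols <- list()
  for (nm in names(preds)) {
    cols[[nm]] <- preds[[nm]]
    cols[[paste0(nm, ":rt")]]  <- preds[[nm]] * rt_s
    cols[[paste0(nm, ":rt2")]] <- preds[[nm]] * rt_s^2
  }
  X <- do.call(cbind, cols); colnames(X) <- names(cols)
  yv <- c1[rows]
  if (!random_intercepts) {
    fit <- stats::lm(yv ~ X)
    sm <- summary(fit)$coefficients
    rownames(sm) <- c("(Intercept)", colnames(X))
    res <- list(table = data.frame(term = rownames(sm), beta = sm[, 1L],
                                   se = sm[, 2L], t = sm[, 3L], p = sm[, 4L],
                                   row.names = NULL),
                n = length(yv), converged = TRUE, family = "gaussian")
    class(res) <- "model_fit"
    return(res)
  }
  dat <- data.frame(.y = yv, .g = factor(trials$participant[rows]), X,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                               collapse = " + "), "+ (1 | .g)"))
  fit <- lme4::lmer(fml, data = dat, REML = FALSE)
  sm <- summary(fit)$coefficients
  df <- length(yv) - nrow(sm)
  res <- list(table = data.frame(term = rownames(sm), beta = sm[, 1L],
                                 se = sm[, 2L], t = sm[, 3L],
                                 p = 2 * stats::pt(-abs(sm[, 3L]), df),
                                 row.names = NULL),
              n = length(yv), converged = TRUE, family = "gaussian",
              random_intercepts = TRUE)
  class(res) <- "model_fit"
  res
}

#' Standard behavioural regression set
#'
#' Fits the study's behavioural models on a trial table: (i) accuracy against
#' block and session trends; (ii) accuracy against deadline plus a quadratic
#' function of RT; (iii) choice against previous choice with quadratic RT
#' interactions (the switching bias and its fast-RT dominance); (iv) RT
#' against deadline and against correctness; and a paired contrast of
#' per-participant RT variability between deadlines.
#'
#' @param trials a trial table (columns used where present: `block`,
#'   `session`, `deadline_ms`, `participant`).
#' @return named list of `model_fit` objects plus `rt_variability` (paired
#'   t-test results or NULL).
#' @export
fit_behavioural_models <- function(trials) {
  keep <- included_trials(trials)
  tt <- trials[keep, ]
  rt_s <- tt$rt_ms / 1000
  out <- list()
  if (!is.null(tt$block)) {
    Xb <- cbind(block = tt$block,
                session = if (!is.null(tt$session)) tt$session else NULL)
    out$performance_trend <- fit_logistic(Xb, tt$correct)
  }
  Xa <- cbind(deadline = as.numeric(tt$deadline_ms == 600), rt = rt_s, rt2 = rt_s^2)
  out$accuracy_rt <- fit_logistic(Xa, tt$correct)
  hs <- !is.na(tt$prev_choice)
  pc <- as.numeric(tt$prev_choice[hs] == "upper")
  Xh <- cbind(prev_choice = pc, `prev_choice:rt` = pc * rt_s[hs],
              `prev_choice:rt2` = pc * rt_s[hs]^2)
  out$history <- fit_logistic(Xh, as.numeric(tt$choice[hs] == "upper"))
  lmfit <- function(X, y) {
    f <- stats::lm(y ~ X)
    sm <- summary(f)$coefficients
    rownames(sm) <- c("(Intercept)", colnames(X))
    structure(list(table = data.frame(term = rownames(sm), beta = sm[, 1L],
                                      se = sm[, 2L], t = sm[, 3L], p = sm[, 4L],
                                      row.names = NULL),
                   n = length(y), converged = TRUE, family = "gaussian"),
              class = "model_fit")
  }
  out$rt_deadline <- lmfit(cbind(deadline = as.numeric(tt$deadline_ms == 600)), tt$rt_ms)
  out$rt_correct  <- lmfit(cbind(correct = tt$correct), tt$rt_ms)
  out$rt_variability <- NULL
  if (!is.null(tt$participant) && length(unique(tt$deadline_ms)) == 2L) {
    sds <- stats::aggregate(rt_ms ~ participant + deadline_ms, tt, stats::sd)
    wide <- stats::reshape(sds, idvar = "participant", timevar = "deadline_ms",
                           direction = "wide")
    both <- stats::complete.cases(wide)
    if (sum(both) >= 2L) {
      tst <- stats::t.test(wide[both, 3L], wide[both, 2L], paired = TRUE)
      out$rt_variability <- list(t = unname(tst$statistic), p = tst$p.value,
                                 df = unname(tst$parameter),
                                 mean_diff = unname(tst$estimate))
    }
  }
  out
}
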