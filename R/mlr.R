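# OLS model fitting and the validation battery: LOO/LMO cross-validation,
# external predictivity, Y-randomization, QUIK rule, applicability domain.

# Fast OLS core shared by the GA fitness and the validation statistics.
# Returns NULL on rank deficiency.
.ols_core <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) return(NULL)
  coef <- qr.coef(qx, y)
  fitted <- drop(Xd %*% coef)
  e <- y - fitted
  Q <- qr.Q(qx)
  h <- rowSums(Q^2)
  list(coef = coef, fitted = fitted, resid = e, hat = h, qr = qx,
       n = length(y), p = ncol(X))
}

#' Lin's concordance correlation coefficient
#'
#' 2*cov(a,b) / (var(a) + var(b) + (mean(a) - mean(b))^2) with
#' n-denominator moments; penalises both scatter and location/scale shift.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return concordance in \[-1, 1\].
#' @export
ccc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  ma <- mean(a); mb <- mean(b)
  va <- sum((a - ma)^2) / n
  vb <- sum((b - mb)^2) / n
  cab <- sum((a - ma) * (b - mb)) / n
  den <- va + vb + (ma - mb)^2
  if (den == 0) stop("concordance undefined: zero total variance")
  2 * cab / den
}

#' Fit an ordinary-least-squares QSAR model
#'
#' @param X numeric matrix (training compounds x descriptors), full column
#'   rank, with column names.
#' @param y numeric response (e.g. pEC50).
#' @return an `mlr_model`: coefficients with standard errors, and training
#'   fit statistics R2, R2adj, F, s (standard error of estimate),
#'   RMSE_tr (= sqrt(RSS/n)), MAE_tr, RSS_tr, CCC_tr.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 training compounds")
  core <- .ols_core(X, y)
  if (is.null(core)) {
    qx <- qr(cbind(1, X), LAPACK = FALSE)
    dropped <- qx$pivot[seq.int(qx$rank + 1L, ncol(X) + 1L)]
    bad <- colnames(X)[dropped[dropped > 1L] - 1L]
    stop("singular design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  rss <- sum(core$resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  df_res <- n - p - 1
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(core$qr))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- names(core$coef)
  f_stat <- if (rss == 0) Inf else ((tss - rss) / p) / sigma2
  structure(
    list(
      coefficients = core$coef, se = se, descriptors = colnames(X),
      n = n, p = p, fitted = core$fitted, residuals = core$resid,
      hat = core$hat, y = y, y_mean = mean(y),
      stats = list(
        R2 = r2, R2adj = 1 - (1 - r2) * (n - 1) / df_res,
        F = f_stat, s = sqrt(sigma2),
        RMSE_tr = sqrt(rss / n), MAE_tr = mean(abs(core$resid)),
        RSS_tr = rss, CCC_tr = ccc(y, core$fitted)
      ),
      XtXinv = XtXinv
    ),
    class = "mlr_model"
  )
}

#' Predict from an `mlr_model`
#' @param object an `mlr_model`.
#' @param newdata matrix with the model's descriptor columns.
#' @param ... unused.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$descriptors, colnames(newdata))
  if (length(miss))
    stop("newdata lacks model descriptor(s): ", paste(miss, collapse = ", "))
  X <- newdata[, object$descriptors, drop = FALSE]
  drop(cbind(1, X) %*% object$coefficients)
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(format_model_equation(x), "\n")
  s <- x$stats
  cat(sprintf("n = %d, R2 = %.3f, R2adj = %.3f, F = %.2f, s = %.3f\n",
              x$n, s$R2, s$R2adj, s$F, s$s))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Computed from the hat-matrix deletion identity (each deleted residual is
#' e_i / (1 - h_ii)), so no refitting is needed.
#'
#' @param X training descriptor matrix.
#' @param y training response.
#' @return list with `Q2_LOO`, `PRESS`, `RMSE_cv`, `MAE_cv`, `CCC_cv` and
#'   the vector of LOO predictions.
#' @export
q2_loo <- function(X, y) {
  core <- .ols_core(as.matrix(X), y)
  if (is.null(core)) stop("singular design matrix in LOO")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("undefined statistic: response has zero variance")
  d <- 1 - core$hat
  if (any(d < 1e-10)) stop("leverage 1 encountered: LOO prediction undefined")
  del <- core$resid / d
  press <- sum(del^2)
  pred <- y - del
  list(Q2_LOO = 1 - press / tss, PRESS = press,
       RMSE_cv = sqrt(press / core$n), MAE_cv = mean(abs(del)),
       CCC_cv = ccc(y, pred), pred = pred)
}

# GA fitness: Q2_LOO or -Inf for rank-deficient / degenerate subsets.
.q2_loo_fitness <- function(X, y, idx, tss) {
  Xd <- cbind(1, X[, idx, drop = FALSE])
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) return(-Inf)
  e <- qr.resid(qx, y)
  h <- rowSums(qr.Q(qx)^2)
  d <- 1 - h
  if (any(d < 1e-10)) return(-Inf)
  1 - sum((e / d)^2) / tss
}

#' Leave-many-out cross-validation
#'
#' Repeatedly deletes a random group of compounds, refits, and predicts the
#' held-out group. Reports the mean over iterations of
#' 1 - PRESS_g / TSS_g, with TSS_g taken about the mean of the retained
#' (fitting) compounds.
#'
#' @param X,y training data.
#' @param leave_fraction share of compounds deleted per iteration.
#' @param n_iter number of random deletion groups.
#' @param seed RNG seed.
#' @return list with `Q2_LMO`, per-iteration values, and the settings.
#' @export
q2_lmo <- function(X, y, leave_fraction = 0.3, n_iter = 1000, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  g <- max(1L, round(leave_fraction * n))
  if (n - g < p + 2) stop("infeasible group size: too few compounds retained")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  vals <- vapply(seq_len(n_iter), function(i) {
    out <- sample.int(n, g)
    core <- .ols_core(X[-out, , drop = FALSE], y[-out])
    if (is.null(core)) return(NA_real_)
    pred <- drop(cbind(1, X[out, , drop = FALSE]) %*% core$coef)
    press <- sum((y[out] - pred)^2)
    tss <- sum((y[out] - mean(y[-out]))^2)
    if (tss == 0) return(NA_real_)
    1 - press / tss
  }, 0)
  list(Q2_LMO = mean(vals, na.rm = TRUE), values = vals,
       leave_fraction = leave_fraction, n_iter = n_iter, seed = seed)
}

# Roy r2m helper: squared correlation r2 and through-origin r2_0 for
# observed (obs) against predicted (pred).
.roy_r2m <- function(obs, pred) {
  r2 <- stats::cor(obs, pred)^2
  k <- sum(obs * pred) / sum(pred^2)        # slope of obs ~ k * pred
  r2_0 <- 1 - sum((obs - k * pred)^2) / sum((obs - mean(obs))^2)
  rm2 <- r2 * (1 - sqrt(max(0, r2 - r2_0)))
  list(r2 = r2, r2_0 = r2_0, k = k, rm2 = rm2)
}

#' External validation statistics
#'
#' Computes the external predictivity battery on a prediction set:
#' R2_ext (squared correlation), Q2_F1 (deviations scaled by the external
#' TSS about the training mean), Q2_F2 (about the external mean),
#' Q2_F3 (mean squared error ratio against training variance), CCC_ex,
#' Roy's rm2 metrics (both regression directions, average and absolute
#' difference), and the Golbraikh-Tropsha checks.
#'
#' @param model fitted `mlr_model`.
#' @param Xext,yext prediction-set descriptors and observed response.
#' @param q2_loo_value training Q2_LOO (used by the Golbraikh-Tropsha
#'   verdict); optional.
#' @return list of external statistics and `golbraikh_tropsha` verdicts.
#' @export
external_validation <- function(model, Xext, yext, q2_loo_value = NULL) {
  if (length(yext) < 3) stop("need at least 3 external compounds")
  pred <- predict(model, Xext)
  rss_ext <- sum((pred - yext)^2)
  tss_tr_mean <- sum((yext - model$y_mean)^2)
  tss_ext <- sum((yext - mean(yext))^2)
  if (tss_ext == 0 || tss_tr_mean == 0)
    stop("undefined statistic: degenerate external variance")
  tss_tr <- sum((model$y - model$y_mean)^2)
  q2f1 <- 1 - rss_ext / tss_tr_mean
  q2f2 <- 1 - rss_ext / tss_ext
  q2f3 <- 1 - (rss_ext / length(yext)) / (tss_tr / model$n)
  r2_ext <- stats::cor(yext, pred)^2
  fwd <- .roy_r2m(yext, pred)   # observed ~ predicted
  rev <- .roy_r2m(pred, yext)   # predicted ~ observed
  rm2_avg <- (fwd$rm2 + rev$rm2) / 2
  rm2_delta <- abs(fwd$rm2 - rev$rm2)
  gt <- list(
    q2_loo_gt_0.5 = if (is.null(q2_loo_value)) NA else q2_loo_value > 0.5,
    r2_ext_gt_0.6 = r2_ext > 0.6,
    r2_r20_ratio_lt_0.1 =
      (fwd$r2 - fwd$r2_0) / fwd$r2 < 0.1 ||
      (rev$r2 - rev$r2_0) / rev$r2 < 0.1,
    slope_in_0.85_1.15 =
      (fwd$k >= 0.85 && fwd$k <= 1.15) || (rev$k >= 0.85 && rev$k <= 1.15)
  )
  gt$pass <- all(unlist(gt)[!is.na(unlist(gt))])
  list(R2_ext = r2_ext, Q2_F1 = q2f1, Q2_F2 = q2f2, Q2_F3 = q2f3,
       CCC_ex = ccc(yext, pred), RMSE_ext = sqrt(rss_ext / length(yext)),
       rm2_fwd = fwd$rm2, rm2_rev = rev$rm2,
       rm2_avg = rm2_avg, rm2_delta = rm2_delta,
       golbraikh_tropsha = gt, pred = pred)
}

#' Y-randomization (response scrambling)
#'
#' Refits the model on the same descriptors after permuting the response,
#' recording R2 and Q2_LOO for each permutation. Low scrambled values
#' indicate the original model is not a chance correlation.
#'
#' @param X,y training data.
#' @param n_iter number of permutations (0 returns an empty record with a
#'   `no_op` flag).
#' @param seed RNG seed.
#' @param perms optional list of explicit permutations (overrides random
#'   draws; used for auditing).
#' @return list with the scrambled `R2` and `Q2_LOO` vectors and summary
#'   statistics (mean and max of each).
#' @export
y_randomization <- function(X, y, n_iter = 2000, seed = 1L, perms = NULL) {
  X <- as.matrix(X)
  if (is.null(perms) && n_iter == 0)
    return(list(R2 = numeric(), Q2_LOO = numeric(), no_op = TRUE))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (is.null(perms))
    perms <- replicate(n_iter, sample.int(length(y)), simplify = FALSE)
  tssy <- sum((y - mean(y))^2)
  r2 <- q2 <- numeric(length(perms))
  for (i in seq_along(perms)) {
    ys <- y[perms[[i]]]
    core <- .ols_core(X, ys)
    if (is.null(core)) { r2[i] <- q2[i] <- NA; next }
    r2[i] <- 1 - sum(core$resid^2) / tssy
    d <- 1 - core$hat
    q2[i] <- 1 - sum((core$resid / d)^2) / tssy
  }
  list(R2 = r2, Q2_LOO = q2, no_op = FALSE,
       mean_R2 = mean(r2, na.rm = TRUE), max_R2 = max(r2, na.rm = TRUE),
       mean_Q2 = mean(q2, na.rm = TRUE), max_Q2 = max(q2, na.rm = TRUE))
}

# Todeschini multivariate K correlation index of a column block.
.k_index <- function(M) {
  if (any(apply(M, 2, stats::sd) == 0))
    stop("undefined correlation: constant column in K-index block")
  lambda <- eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  m <- ncol(M)
  sum(abs(lambda / sum(lambda) - 1 / m)) / (2 * (m - 1) / m)
}

#' QUIK rule check
#'
#' Compares the Todeschini multivariate correlation index of the descriptor
#' block (K_xx) with that of the block augmented by the response (K_xxy).
#' The model passes when K_xxy exceeds K_xx by at least `delta`: the
#' response must add correlation structure beyond what the descriptors
#' share among themselves.
#'
#' @param X training descriptor matrix with at least 2 columns.
#' @param y training response.
#' @param delta required margin K_xxy - K_xx (conventionally 0.05).
#' @return list with `K_xx`, `K_xxy`, `delta`, `pass`.
#' @export
quik_check <- function(X, y, delta = 0.05) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("QUIK rule needs at least 2 descriptors")
  kxx <- .k_index(X)
  kxxy <- .k_index(cbind(X, y))
  list(K_xx = kxx, K_xxy = kxxy, delta = delta, pass = kxxy - kxx >= delta)
}

#' Applicability domain (Williams plot data)
#'
#' Leverages h_i = x_i (X'X)^-1 x_i' (intercept included), warning
#' threshold h* = 3(p+1)/n, and standardized residuals e_i / s. Labels:
#' `X_outlier` when h > h*, `Y_outlier` when |standardized residual|
#' exceeds `resid_cutoff` (a compound exceeding both carries both flags,
#' reported as `XY_outlier`), and `model_outlier` for compounds inside both
#' margins whose deletion (leave-one-out) residual still exceeds
#' 3 * RMSE_cv — anomalies visible only against the cross-validated model.
#'
#' @param model fitted `mlr_model`.
#' @param Xq,yq optional query (e.g. prediction-set) descriptors and
#'   observed response; query rows get leverages always, residual-based
#'   labels only when `yq` is given.
#' @param resid_cutoff standardized-residual cutoff (default 3).
#' @return list with `table` (data frame: id, set, leverage, std_residual,
#'   label), `h_star` and `resid_cutoff`.
#' @export
applicability_domain <- function(model, Xq = NULL, yq = NULL,
                                 resid_cutoff = 3) {
  h_star <- 3 * (model$p + 1) / model$n
  s <- model$stats$s
  std_res <- model$residuals / s
  d <- 1 - model$hat
  del_res <- model$residuals / d
  rmse_cv <- sqrt(sum(del_res^2) / model$n)
  lab <- function(h, r, dr) {
    x_out <- h > h_star
    y_out <- !is.na(r) & abs(r) > resid_cutoff
    if (x_out && y_out) return("XY_outlier")
    if (x_out) return("X_outlier")
    if (y_out) return("Y_outlier")
    if (!is.na(dr) && abs(dr) > 3 * rmse_cv) return("model_outlier")
    "inside"
  }
  ids <- rownames(model$hat)
  tab <- data.frame(
    id = if (!is.null(names(model$y))) names(model$y) else
      sprintf("tr%03d", seq_len(model$n)),
    set = "train", leverage = model$hat, std_residual = std_res,
    label = mapply(lab, model$hat, std_res, del_res),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(Xq)) {
    Xq <- as.matrix(Xq)
    miss <- setdiff(model$descriptors, colnames(Xq))
    if (length(miss))
      stop("query descriptors do not match the model: missing ",
           paste(miss, collapse = ", "))
    Xqd <- cbind(1, Xq[, model$descriptors, drop = FALSE])
    hq <- rowSums((Xqd %*% model$XtXinv) * Xqd)
    rq <- if (!is.null(yq)) (yq - predict(model, Xq)) / s else
      rep(NA_real_, nrow(Xq))
    tabq <- data.frame(
      id = if (!is.null(rownames(Xq))) rownames(Xq) else
        sprintf("q%03d", seq_len(nrow(Xq))),
      set = "test", leverage = hq, std_residual = rq,
      label = mapply(lab, hq, rq, rep(NA_real_, length(hq))),
      stringsAsFactors = FALSE, row.names = NULL
    )
    tab <- rbind(tab, tabq)
  }
  list(table = tab, h_star = h_star, resid_cutoff = resid_cutoff,
       rmse_cv = rmse_cv)
}

#' Run the full validation battery
#'
#' Convenience wrapper assembling internal cross-validation, external
#' validation, Y-randomization, the QUIK rule and the applicability domain
#' into one report.
#'
#' @param Xtr,ytr training data (descriptor subset already chosen).
#' @param Xext,yext optional prediction set.
#' @param lmo_fraction,lmo_iter leave-many-out settings.
#' @param yrand_iter Y-randomization permutation count.
#' @param quik_delta QUIK margin.
#' @param resid_cutoff applicability-domain residual cutoff.
#' @param seed RNG seed for LMO and Y-randomization.
#' @return a `qsar_validation` report list with elements `model`,
#'   `internal`, `external`, `randomization`, `quik`, `domain`.
#' @export
validate_model <- function(Xtr, ytr, Xext = NULL, yext = NULL,
                           lmo_fraction = 0.3, lmo_iter = 1000,
                           yrand_iter = 2000, quik_delta = 0.05,
                           resid_cutoff = 3, seed = 1L) {
  Xtr <- as.matrix(Xtr)
  model <- fit_ols(Xtr, ytr)
  loo <- q2_loo(Xtr, ytr)
  lmo <- q2_lmo(Xtr, ytr, lmo_fraction, lmo_iter, seed = seed)
  internal <- list(Q2_LOO = loo$Q2_LOO, Q2_LMO = lmo$Q2_LMO,
                   PRESS_cv = loo$PRESS, RMSE_cv = loo$RMSE_cv,
                   MAE_cv = loo$MAE_cv, CCC_cv = loo$CCC_cv)
  external <- NULL
  if (!is.null(Xext)) {
    external <- external_validation(model, Xext, yext,
                                    q2_loo_value = loo$Q2_LOO)
  }
  rand <- y_randomization(Xtr, ytr, n_iter = yrand_iter, seed = seed)
  quik <- if (ncol(Xtr) >= 2) quik_check(Xtr, ytr, quik_delta) else NULL
  domain <- applicability_domain(model, Xq = Xext, yq = yext,
                                 resid_cutoff = resid_cutoff)
  structure(
    list(model = model, internal = internal, external = external,
         randomization = rand[c("mean_R2", "max_R2", "mean_Q2", "max_Q2")],
         quik = quik, domain = domain, seed = seed),
    class = "qsar_validation"
  )
}

#' @export
print.qsar_validation <- function(x, ...) {
  s <- x$model$stats
  cat("QSAR validation report\n")
  cat(sprintf("  fit:      R2 = %.3f  R2adj = %.3f  F = %.2f  RMSE_tr = %.3f  CCC_tr = %.3f\n",
              s$R2, s$R2adj, s$F, s$RMSE_tr, s$CCC_tr))
  cat(sprintf("  internal: Q2_LOO = %.3f  Q2_LMO = %.3f  RMSE_cv = %.3f  CCC_cv = %.3f\n",
              x$internal$Q2_LOO, x$internal$Q2_LMO, x$internal$RMSE_cv,
              x$internal$CCC_cv))
  if (!is.null(x$external))
    cat(sprintf("  external: R2_ext = %.3f  Q2_F1 = %.3f  Q2_F2 = %.3f  Q2_F3 = %.3f  CCC_ex = %.3f\n",
                x$external$R2_ext, x$external$Q2_F1, x$external$Q2_F2,
                x$external$Q2_F3, x$external$CCC_ex))
  if (!is.null(x$randomization$mean_R2))
    cat(sprintf("  y-scrambling: mean R2 = %.3f  max R2 = %.3f\n",
                x$randomization$mean_R2, x$randomization$max_R2))
  if (!is.null(x$quik))
    cat(sprintf("  QUIK: K_xx = %.3f  K_xxy = %.3f  pass = %s\n",
                x$quik$K_xx, x$quik$K_xxy, x$quik$pass))
  out <- x$domain$table$label != "inside"
  if (any(out))
    cat("  outliers:", paste(sprintf("%s (%s)", x$domain$table$id[out],
                                     x$domain$table$label[out]),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a validation report
#'
#' Writes the report as JSON plus a flat CSV of per-compound leverage and
#' standardized residuals (Williams plot data).
#'
#' @param report a `qsar_validation`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- report$model
  json <- list(
    equation = format_model_equation(m),
    coefficients = as.list(m$coefficients),
    standard_errors = as.list(m$se),
    fit = m$stats, internal = report$internal, external =
      if (!is.null(report$external))
        report$external[setdiff(names(report$external), "pred")],
    randomization = report$randomization, quik = report$quik,
    domain = list(h_star = report$domain$h_star,
                  resid_cutoff = report$domain$resid_cutoff)
  )
  jsonlite::write_json(json, file.path(dir, "validation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(report$domain$table, file.path(dir, "williams.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Format a fitted model as an equation with standard errors
#'
#' @param model an `mlr_model`.
#' @param response response name used on the left-hand side.
#' @return single string, e.g.
#'   `"pEC50 = 1.234 (+-0.1) + 0.5 (+-0.02) desc1 - ..."`.
#' @export
format_model_equation <- function(model, response = "pEC50") {
  co <- model$coefficients
  se <- model$se
  terms <- sprintf("%.4g (±%.4g)", abs(co[1]), se[1])
  for (i in seq_along(model$descriptors)) {
    terms <- paste0(terms, if (co[i + 1] >= 0) " + " else " - ",
                    sprintf("%.4g (±%.4g) %s", abs(co[i + 1]),
                            se[i + 1], model$descriptors[i]))
  }
  paste0(response, " = ", if (co[1] >= 0) "" else "-", terms)
}

#' Parse a formatted model equation back to its coefficients
#'
#' Inverse of [format_model_equation()] at printed precision; used to check
#' that emitted model equations round-trip.
#'
#' @param text equation string.
#' @return list with `intercept`, `coefficients` (named), `response`.
#' @export
parse_model_equation <- function(text) {
  parts <- strsplit(text, " = ", fixed = TRUE)[[1]]
  rhs <- parts[2]
  toks <- regmatches(rhs, gregexpr(
    "[+-]? ?[0-9.eE+-]+ \\(±[0-9.eE+-]+\\)( [A-Za-z_][A-Za-z0-9_]*)?",
    rhs))[[1]]
  coefs <- numeric(); nms <- character(); intercept <- NA_real_
  for (tk in toks) {
    num <- as.numeric(sub("^([+-]?) ?([0-9.eE+-]+) .*$", "\\1\\2", tk))
    name <- sub("^.*\\) ?", "", tk)
    if (!nzchar(name)) intercept <- num
    else { coefs <- c(coefs, num); nms <- c(nms, name) }
  }
  names(coefs) <- nms
  list(response = parts[1], intercept = intercept, coefficients = coefs)
}
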