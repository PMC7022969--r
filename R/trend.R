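## Mixed-model trend analysis of herd-year traits.
##
## Model: for herd h in year t,
##   y_ht = x_ht' beta + b_h + e_ht
## with b_h ~ N(0, sigma2_between) a herd random intercept and e_ht a
## stationary AR(1) process with marginal variance sigma2_within and
## correlation rho^|dt| between years dt apart (gaps in follow-up years
## decay the correlation by the elapsed time). MAST and LAM are analyzed
## on the log scale (a lognormal response model); the other traits on the
## natural scale. Estimation is by restricted maximum likelihood with the
## common scale profiled out and a quasi-Newton search over the variance
## ratio and the AR(1) correlation.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the fixed-effect design for a trait trend model
#'
#' Assembles the model frame and full-rank treatment-coded design matrix
#' for one trait: categorical nuisance factors (agroecological zone,
#' predominant breed, herd-size class, calendar period) plus adoption
#' level, follow-up year and, optionally, their interaction. For the
#' lognormal traits the response is log-transformed after adding
#' `log_offset` when zero values are present. Rows are grouped by herd and
#' ordered by follow-up year for the serial correlation structure.
#'
#' @param traits herd-year trait table (see [derive_traits()]).
#' @param herds data frame with `herd_id`, adoption `level`, and (when the
#'   zone/breed factors are requested) `zone` and `breed_group`.
#' @param trait which trait to model, one of [TRAITS].
#' @param factors nuisance factors to adjust for, a subset of
#'   `c("zone", "breed", "herd_size", "period")`.
#' @param interaction include the adoption-level x follow-up-year
#'   interaction (default TRUE).
#' @param family `"NORMAL"` or `"LOGNORMAL"`; defaults to lognormal for
#'   MAST/LAM and normal otherwise.
#' @param log_offset positive value added to a lognormal response before
#'   the log transform when zeros are present (default 0.5 percentage
#'   points).
#' @param drop_single with the default `FALSE`, a factor with a single
#'   observed level is an error naming the factor; with `TRUE` such
#'   factors (including adoption level, e.g. for health traits recorded
#'   by one level only) are silently dropped and listed in the returned
#'   `dropped_factors`.
#' @return A list with the response `y`, design matrix `X`, `herd` ids,
#'   `time` (follow-up years), term metadata and the model frame.
#' @export
build_design <- function(traits, herds, trait,
                         factors = c("zone", "breed", "herd_size", "period"),
                         interaction = TRUE, family = NULL,
                         log_offset = 0.5, drop_single = FALSE) {
  stopifnot(trait %in% TRAITS)
  if (is.null(family)) {
    family <- if (trait %in% LOGNORMAL_TRAITS) "LOGNORMAL" else "NORMAL"
  }
  family <- match.arg(family, c("NORMAL", "LOGNORMAL"))
  d <- traits[traits$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for trait ", trait)
  idx <- match(d$herd_id, herds$herd_id)
  if (anyNA(idx)) stop("trait table contains herds absent from `herds`")

  mf <- data.frame(herd_id = d$herd_id, stringsAsFactors = FALSE)
  mf$adoption <- factor(herds$level[idx], levels = c("LOW", "MEDIUM", "HIGH"))
  mf$adoption <- droplevels(mf$adoption)
  mf$followup <- factor(d$followup_year, levels = sort(unique(d$followup_year)))
  if ("zone" %in% factors) {
    if (is.null(herds$zone)) stop("`herds` lacks a zone column")
    mf$zone <- droplevels(factor(herds$zone[idx], levels = ZONES))
  }
  if ("breed" %in% factors) {
    if (is.null(herds$breed_group)) stop("`herds` lacks a breed_group column")
    mf$breed <- droplevels(factor(herds$breed_group[idx],
                                  levels = BREED_GROUPS))
  }
  if ("herd_size" %in% factors) {
    mf$herd_size <- droplevels(factor(d$herd_size_class, levels = 1:5))
  }
  if ("period" %in% factors) {
    mf$period <- droplevels(factor(d$calendar_period,
                                   levels = CALENDAR_PERIODS))
  }
  fterms <- c(intersect(c("zone", "breed", "herd_size", "period"), factors),
              "adoption", "followup",
              if (interaction) "adoption:followup")
  dropped_factors <- character(0)
  for (f in setdiff(fterms, "adoption:followup")) {
    if (nlevels(mf[[f]]) < 2L) {
      if (!drop_single) stop("factor '", f, "' has a single observed level")
      dropped_factors <- c(dropped_factors, f)
    }
  }
  if (length(dropped_factors) > 0L) {
    fterms <- setdiff(fterms, dropped_factors)
    if ("adoption" %in% dropped_factors) {
      fterms <- setdiff(fterms, "adoption:followup")
    }
    if (length(setdiff(fterms, "adoption:followup")) == 0L) {
      stop("no usable factors left for trait ", trait)
    }
  }

  offset_used <- 0
  y <- d$value
  if (family == "LOGNORMAL") {
    if (any(y < 0)) stop("negative values under a lognormal response")
    if (any(y == 0)) {
      if (log_offset <= 0) stop("log_offset must be positive")
      offset_used <- log_offset
      y <- y + log_offset
    }
    y <- log(y)
  }
  mf$.y <- y
  mf$.time <- d$followup_year

  ord <- order(mf$herd_id, mf$.time)
  mf <- mf[ord, , drop = FALSE]
  dup <- duplicated(paste(mf$herd_id, mf$.time, sep = "\r"))
  if (any(dup)) stop("duplicate herd-year rows for trait ", trait)

  fml <- stats::as.formula(paste("~", paste(fterms, collapse = " + ")))
  X <- stats::model.matrix(fml, mf)
  asg <- attr(X, "assign")
  dropped <- character(0)
  ## drop aliased columns so the design has full column rank
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- sort(q$pivot[seq_len(q$rank)])
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
    asg <- asg[keep]
  }
  xlevels <- lapply(mf[, setdiff(fterms, "adoption:followup"),
                       drop = FALSE], levels)
  list(y = mf$.y, X = X, assign = asg, dropped = dropped,
       dropped_factors = dropped_factors,
       herd = mf$herd_id, time = mf$.time,
       frame = mf, formula = fml, family = family, trait = trait,
       log_offset_used = offset_used, xlevels = xlevels,
       factors = fterms, interaction = interaction)
}

## ---- REML machinery ---------------------------------------------------

## Precompute per-pattern cross-products so each REML evaluation is a small
## weighted sum: herds sharing the same follow-up-year pattern contribute
## through X_j'X_k, X_j'y_k, y_j'y_k summed over herds, where j,k index
## positions within the pattern.
precompute_blocks <- function(X, y, herd, time) {
  ord_ids <- unique(herd)
  row_by_herd <- split(seq_along(herd), factor(herd, levels = ord_ids))
  sig <- vapply(row_by_herd, function(r) paste(time[r], collapse = ","),
                character(1))
  patterns <- list()
  for (s in unique(sig)) {
    hsel <- which(sig == s)
    rows <- row_by_herd[hsel]
    t_pat <- time[rows[[1]]]
    Tn <- length(t_pat)
    m <- length(rows)
    rows_mat <- matrix(unlist(rows), nrow = Tn)  # Tn x m row indices
    Xs <- lapply(seq_len(Tn), function(j) X[rows_mat[j, ], , drop = FALSE])
    ys <- lapply(seq_len(Tn), function(j) y[rows_mat[j, ]])
    Cxx <- vector("list", Tn * Tn)
    Cxy <- vector("list", Tn * Tn)
    Cyy <- matrix(0, Tn, Tn)
    for (j in seq_len(Tn)) {
      for (k in seq_len(Tn)) {
        Cxx[[(j - 1L) * Tn + k]] <- crossprod(Xs[[j]], Xs[[k]])
        Cxy[[(j - 1L) * Tn + k]] <- crossprod(Xs[[j]], ys[[k]])
        Cyy[j, k] <- sum(ys[[j]] * ys[[k]])
      }
    }
    patterns[[length(patterns) + 1L]] <- list(
      t = t_pat, m = m, Cxx = Cxx, Cxy = Cxy, Cyy = Cyy,
      lag = abs(outer(t_pat, t_pat, "-")), J = matrix(1, Tn, Tn))
  }
  patterns
}

## Generalized-least-squares pieces for covariance Sigma_pat = f(pattern).
## Returns A = X'WX, b = X'Wy, yy = y'Wy, ldet = sum log|Sigma_i|.
gls_pieces <- function(patterns, sigma_fun) {
  p <- nrow(patterns[[1]]$Cxx[[1]])
  A <- matrix(0, p, p)
  b <- numeric(p)
  yy <- 0
  ldet <- 0
  for (pat in patterns) {
    S <- sigma_fun(pat)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    W <- chol2inv(ch)
    ldet <- ldet + pat$m * 2 * sum(log(diag(ch)))
    Tn <- length(pat$t)
    for (j in seq_len(Tn)) {
      for (k in seq_len(Tn)) {
        w <- W[j, k]
        if (w == 0) next
        A <- A + w * pat$Cxx[[(j - 1L) * Tn + k]]
        b <- b + w * pat$Cxy[[(j - 1L) * Tn + k]]
        yy <- yy + w * pat$Cyy[j, k]
      }
    }
  }
  list(A = A, b = b, yy = yy, ldet = ldet)
}

## Profiled REML deviance (up to a constant) over
## theta = (log gamma, atanh rho), gamma = sigma2_between / sigma2_within.
reml_profiled <- function(theta, patterns, n, p, ar1) {
  gamma <- exp(theta[1])
  rho <- if (ar1) tanh(theta[2]) else 0
  g <- gls_pieces(patterns, function(pat) gamma * pat$J + rho^pat$lag)
  if (is.null(g)) return(1e10)
  Ainv_b <- tryCatch(solve(g$A, g$b), error = function(e) NULL)
  if (is.null(Ainv_b)) return(1e10)
  rss <- g$yy - sum(g$b * Ainv_b)
  if (rss <= 0) return(1e10)
  ldetA <- determinant(g$A, logarithm = TRUE)$modulus
  as.numeric((n - p) * log(rss) + g$ldet + ldetA)
}

## Unprofiled REML deviance (-2 logREML without the 2*pi constant) as a
## function of (sigma2_between, sigma2_within, rho); used for the Wald
## covariance of the variance components.
reml_full_dev <- function(s2b, s2w, rho, patterns, n, p) {
  if (s2b < 0 || s2w <= 0 || abs(rho) >= 1) return(NA_real_)
  g <- gls_pieces(patterns, function(pat) s2b * pat$J + s2w * rho^pat$lag)
  if (is.null(g)) return(NA_real_)
  Ainv_b <- tryCatch(solve(g$A, g$b), error = function(e) NULL)
  if (is.null(Ainv_b)) return(NA_real_)
  rss <- g$yy - sum(g$b * Ainv_b)
  ldetA <- determinant(g$A, logarithm = TRUE)$modulus
  as.numeric(g$ldet + ldetA + rss)
}

central_hessian <- function(f, x, h = pmax(1e-4, 1e-3 * abs(x))) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit the herd trend mixed model for one trait
#'
#' Fits, by restricted maximum likelihood, a linear mixed model for one
#' herd-year performance trait with categorical fixed effects (nuisance
#' adjustment factors plus adoption level, follow-up year and their
#' interaction), a between-herd random intercept, and within-herd AR(1)
#' serial correlation of the yearly deviations. MAST/LAM are modelled on
#' the log scale, so their fitted cell means back-transform to geometric
#' means.
#'
#' @inheritParams build_design
#' @param ar1 estimate the AR(1) correlation (default TRUE); with
#'   `ar1 = FALSE` the model reduces to a standard random-intercept fit.
#' @param control list of optimizer settings passed to [stats::nlminb()].
#' @return An object of class `"herd_trend"`: coefficient estimates and
#'   their covariance, variance components `sigma2_between` and
#'   `sigma2_within` with the AR(1) correlation `rho`, Wald chi-square
#'   tests per fixed-effect term, Wald Z tests for the random components,
#'   the REML log-likelihood and a convergence flag.
#' @seealso [marginal_means()], [effect_table()]
#' @export
herd_trend <- function(traits, herds, trait,
                       factors = c("zone", "breed", "herd_size", "period"),
                       interaction = TRUE, family = NULL, log_offset = 0.5,
                       ar1 = TRUE, drop_single = FALSE, control = list()) {
  design <- build_design(traits, herds, trait, factors = factors,
                         interaction = interaction, family = family,
                         log_offset = log_offset, drop_single = drop_single)
  fit <- fit_lmm(design, ar1 = ar1, control = control)
  fit$call <- match.call()
  fit
}

#' @rdname herd_trend
#' @param design a design structure from [build_design()].
#' @export
fit_lmm <- function(design, ar1 = TRUE, control = list()) {
  X <- design$X
  y <- design$y
  n <- length(y)
  p <- ncol(X)
  if (length(unique(design$herd)) < 2L) stop("need at least 2 herds")
  patterns <- precompute_blocks(X, y, design$herd, design$time)

  start <- if (ar1) c(0, atanh(0.3)) else 0
  obj <- function(th) {
    theta <- if (ar1) th else c(th, 0)
    reml_profiled(theta, patterns, n, p, ar1 = ar1)
  }
  ctl <- utils::modifyList(list(rel.tol = 1e-10, eval.max = 500,
                                iter.max = 300), control)
  opt <- stats::nlminb(start, obj, control = ctl)
  if (opt$convergence != 0) {
    ## one restart from the stopping point; flat-ridge stops ("false
    ## convergence") at an unchanged optimum are accepted
    opt2 <- stats::nlminb(opt$par, obj, control = ctl)
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  converged <- opt$convergence == 0 ||
    grepl("false convergence|singular convergence", opt$message %||% "")
  gamma <- exp(opt$par[1])
  rho <- if (ar1) tanh(opt$par[2]) else 0

  g <- gls_pieces(patterns, function(pat) gamma * pat$J + rho^pat$lag)
  beta <- drop(solve(g$A, g$b))
  rss <- g$yy - sum(g$b * beta)
  sigma2_w <- rss / (n - p)
  sigma2_b <- gamma * sigma2_w
  vcov_beta <- sigma2_w * solve(g$A)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  loglik <- -0.5 * ((n - p) * (log(2 * pi) + 1 + log(sigma2_w)) +
                      g$ldet +
                      determinant(g$A, logarithm = TRUE)$modulus)
  loglik <- as.numeric(loglik)

  ## Wald Z for the variance components from the unprofiled REML surface;
  ## parameters are reflected at their boundaries so the numerical Hessian
  ## stays evaluable when a component sits near zero
  theta3 <- c(sigma2_b, sigma2_w, rho)
  dev3 <- function(t3) {
    reml_full_dev(abs(t3[1]), abs(t3[2]),
                  max(-0.999, min(0.999, t3[3])), patterns, n, p)
  }
  vc_se <- rep(NA_real_, 3)
  H <- tryCatch(central_hessian(dev3, theta3), error = function(e) NULL)
  if (!is.null(H) && !anyNA(H)) {
    cv <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) > 0)) vc_se <- sqrt(diag(cv))
  }
  z <- theta3 / vc_se
  random_tests <- data.frame(
    component = c("sigma2_between", "sigma2_within", "rho"),
    estimate = theta3, se = vc_se, z = z,
    p_value = c(stats::pnorm(z[1], lower.tail = FALSE),
                stats::pnorm(z[2], lower.tail = FALSE),
                2 * stats::pnorm(-abs(z[3]))),
    stringsAsFactors = FALSE
  )

  ## joint Wald chi-square per fixed-effect term
  asg <- design$assign
  labels <- c("(Intercept)", attr(stats::terms(design$formula), "term.labels"))
  wald <- lapply(seq_along(labels)[-1], function(ti) {
    cols <- which(asg == ti - 1L)
    if (length(cols) == 0L) return(NULL)
    bsub <- beta[cols]
    vsub <- vcov_beta[cols, cols, drop = FALSE]
    stat <- tryCatch(as.numeric(crossprod(bsub, solve(vsub, bsub))),
                     error = function(e) NA_real_)
    data.frame(term = labels[ti], chisq = stat, df = length(cols),
               p_value = stats::pchisq(stat, length(cols),
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  wald <- do.call(rbind, wald)
  rownames(wald) <- NULL

  structure(list(
    coefficients = beta, vcov = vcov_beta,
    sigma2_between = sigma2_b, sigma2_within = sigma2_w,
    sigma2_residual = 0, rho = if (ar1) rho else 0,
    ar1 = ar1, loglik = loglik, converged = converged,
    opt = opt, wald_fixed = wald, wald_random = random_tests,
    design = design, n = n, p = p,
    n_herds = length(unique(design$herd)),
    trait = design$trait, family = design$family,
    log_offset_used = design$log_offset_used
  ), class = "herd_trend")
}

## ---- methods -----------------------------------------------------------

#' @export
print.herd_trend <- function(x, ...) {
  cat(sprintf("Herd trend mixed model: %s (%s response)\n", x$trait,
              tolower(x$family)))
  cat(sprintf("  %d herd-years, %d herds; REML logLik %.2f%s\n", x$n,
              x$n_herds, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  sigma2_between %.4g, sigma2_within %.4g, AR(1) rho %.3f\n",
              x$sigma2_between, x$sigma2_within, x$rho))
  cat("  Fixed-effect Wald tests:\n")
  print(x$wald_fixed, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.herd_trend <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  coefs <- data.frame(estimate = object$coefficients, se = se,
                      z = object$coefficients / se,
                      p_value = 2 * stats::pnorm(-abs(object$coefficients / se)))
  out <- list(fit = object, coefficients = coefs,
              wald_fixed = object$wald_fixed,
              wald_random = object$wald_random)
  class(out) <- "summary.herd_trend"
  out
}

#' @export
print.summary.herd_trend <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 4))
  cat("\nRandom components (Wald Z):\n")
  print(x$wald_random, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.herd_trend <- function(object, ...) object$coefficients

#' @export
vcov.herd_trend <- function(object, ...) object$vcov

#' @export
logLik.herd_trend <- function(object, ...) {
  structure(object$loglik, df = object$p + if (object$ar1) 3 else 2,
            class = "logLik")
}

#' @export
fitted.herd_trend <- function(object, ...) {
  as.numeric(object$design$X %*% object$coefficients)
}

#' @export
residuals.herd_trend <- function(object,
                                 type = c("marginal", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$design$y - fitted(object)
  if (type == "pearson") {
    r <- r / sqrt(object$sigma2_between + object$sigma2_within)
  }
  r
}

#' Predict from a herd trend model
#'
#' Linear predictor for new factor combinations; for lognormal fits
#' `type = "response"` back-transforms by exponentiation (a geometric
#' mean), subtracting any log offset that was applied.
#'
#' @param object a fitted `"herd_trend"` model.
#' @param newdata data frame with the model's factor columns; defaults to
#'   the fitted frame.
#' @param type `"link"` (model scale) or `"response"`.
#' @param ... unused.
#' @export
predict.herd_trend <- function(object, newdata = NULL,
                               type = c("link", "response"), ...) {
  type <- match.arg(type)
  des <- object$design
  if (is.null(newdata)) {
    eta <- fitted(object)
  } else {
    for (f in names(des$xlevels)) {
      newdata[[f]] <- factor(newdata[[f]], levels = des$xlevels[[f]])
    }
    Xn <- stats::model.matrix(des$formula, newdata)
    Xn <- Xn[, colnames(des$X), drop = FALSE]
    eta <- as.numeric(Xn %*% object$coefficients)
  }
  if (type == "response" && object$family == "LOGNORMAL") {
    exp(eta) - object$log_offset_used
  } else {
    eta
  }
}

#' Simulate responses from a fitted herd trend model
#'
#' Draws new herd-year response vectors from the fitted marginal
#' distribution (fixed effects plus herd intercept plus AR(1) deviations),
#' on the model scale.
#'
#' @param object a fitted `"herd_trend"` model.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, rows aligned with the fitted
#'   model frame.
#' @export
simulate.herd_trend <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  mu <- fitted(object)
  herds <- unique(des$herd)
  out <- matrix(0, length(mu), nsim)
  for (h in herds) {
    rows <- which(des$herd == h)
    t_h <- des$time[rows]
    S <- object$sigma2_between +
      object$sigma2_within * object$rho^abs(outer(t_h, t_h, "-"))
    L <- chol(S)
    z <- matrix(stats::rnorm(length(rows) * nsim), length(rows), nsim)
    out[rows, ] <- mu[rows] + crossprod(L, z)
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.herd_trend <- function(x, ...) {
  mm <- marginal_means(x)
  plot(mm, main = sprintf("%s marginal means by adoption level", x$trait),
       ...)
  invisible(x)
}

#' Marginal (least-squares) means by adoption level and follow-up year
#'
#' Averages the linear predictor over the levels of the nuisance factors
#' with equal weights (the classical least-squares-means convention) for
#' every adoption-level x follow-up-year cell, then back-transforms
#' lognormal fits by exponentiation so their cells are geometric means.
#'
#' @param fit a fitted `"herd_trend"` model.
#' @param by factors defining the cells (default adoption level and
#'   follow-up year).
#' @return A data frame of class `"herd_trend_means"` with columns
#'   `adoption_level`, `followup_year` (or the requested `by` columns),
#'   `mean`, `se` (response scale) and `scale`
#'   (`"arithmetic"`/`"geometric"`).
#' @export
marginal_means <- function(fit, by = c("adoption", "followup")) {
  if (!fit$converged) stop("model did not converge; no marginal means")
  des <- fit$design
  by <- intersect(by, names(des$xlevels))
  if (length(by) == 0L) stop("no `by` factors present in the model")
  grid <- expand.grid(des$xlevels, stringsAsFactors = FALSE)
  for (f in names(des$xlevels)) {
    grid[[f]] <- factor(grid[[f]], levels = des$xlevels[[f]])
  }
  Xg <- stats::model.matrix(des$formula, grid)
  Xg <- Xg[, colnames(des$X), drop = FALSE]
  key <- do.call(paste, c(grid[by], list(sep = "\r")))
  L <- rowsum(Xg, key)                       # rows sorted by key
  counts <- as.vector(table(key))            # same sorted order
  L <- L / counts
  est <- as.numeric(L %*% fit$coefficients)
  se <- sqrt(rowSums((L %*% fit$vcov) * L))
  cells <- unique(grid[by])
  ckey <- do.call(paste, c(cells, list(sep = "\r")))
  cells <- cells[match(rownames(L), ckey), , drop = FALSE]
  out <- data.frame(cells, row.names = NULL)
  names(out) <- ifelse(names(out) == "adoption", "adoption_level",
                       ifelse(names(out) == "followup", "followup_year",
                              names(out)))
  if (fit$family == "LOGNORMAL") {
    out$mean <- exp(est) - fit$log_offset_used
    out$se <- exp(est) * se
    out$scale <- "geometric"
  } else {
    out$mean <- est
    out$se <- se
    out$scale <- "arithmetic"
  }
  out$mean_link <- est
  out$se_link <- se
  class(out) <- c("herd_trend_means", "data.frame")
  out
}

#' @export
plot.herd_trend_means <- function(x, ...) {
  if (!all(c("adoption_level", "followup_year") %in% names(x))) {
    stop("plot method needs adoption_level and followup_year cells")
  }
  fy <- as.integer(as.character(x$followup_year))
  lv <- as.character(x$adoption_level)
  levels_present <- unique(lv)
  yrs <- sort(unique(fy))
  mat <- sapply(levels_present, function(l) {
    x$mean[lv == l][order(fy[lv == l])]
  })
  graphics::matplot(yrs, mat, type = "b", pch = 19, lty = 1,
                    xlab = "Follow-up year", ylab = "Marginal mean", ...)
  graphics::legend("topright", legend = levels_present, col = seq_along(
    levels_present), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Significance summary across traits
#'
#' Assembles the per-effect Wald p-values of several fitted trait models
#' into one effects-by-traits matrix, with the random between-herd and
#' within-herd components (Wald Z tests) as the final rows.
#'
#' @param fits named list of `"herd_trend"` fits (names are traits).
#' @return A data frame with one row per model effect and one column per
#'   trait.
#' @export
effect_table <- function(fits) {
  stopifnot(length(fits) > 0)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$trait, character(1))
  }
  terms_all <- unique(unlist(lapply(fits, function(f) f$wald_fixed$term)))
  rows <- c(terms_all, "between_herd_variance", "within_herd_variance")
  out <- data.frame(effect = rows, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    pv <- rep(NA_real_, length(rows))
    pv[match(f$wald_fixed$term, rows)] <- f$wald_fixed$p_value
    pv[match("between_herd_variance", rows)] <-
      f$wald_random$p_value[f$wald_random$component == "sigma2_between"]
    pv[match("within_herd_variance", rows)] <-
      f$wald_random$p_value[f$wald_random$component == "sigma2_within"]
    out[[nm]] <- pv
  }
  out
}
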