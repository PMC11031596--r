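#' Generalized estimating equations for MNP outcomes
#'
#' Linear marginal model (identity link, Gaussian working variance) with an
#' exchangeable working correlation clustered by subject and robust
#' (sandwich) standard errors - the standard analysis for a continuous
#' outcome measured repeatedly within subjects. `hemisphere`, `day` and
#' `block_order` are treated as factors (first level is the reference);
#' logical covariates enter as 0/1; `age_years` is continuous.
#'
#' @param table a cohort table: one row per block x measure x window with
#'   columns `subject_id`, the outcome, and the covariates (see
#'   [cohort_table_from_mnp()]).
#' @param outcome name of the outcome column (default `"mnp"`).
#' @param terms character vector of covariate names to include (univariate:
#'   one term; multivariable: several).
#' @param measure,window optional filters applied to the table before
#'   fitting, selecting one analysis cell.
#' @param max_iter,tol convergence controls of the working-correlation
#'   iteration.
#' @return A `gee_fit`: `coefficients` data.frame (`term`, `estimate`,
#'   `se`, `ci_lo`, `ci_hi`, `z`, `p`), working correlation `rho`,
#'   dispersion `phi`, `n_clusters`, `n_obs`.
#' @export
fit_gee <- function(table, outcome = "mnp", terms, measure = NULL,
                    window = NULL, max_iter = 50, tol = 1e-8) {
  stopifnot(is.data.frame(table), length(terms) >= 1)
  if (!is.null(measure)) table <- table[table$measure == measure, , drop = FALSE]
  if (!is.null(window)) table <- table[table$window == window, , drop = FALSE]
  miss <- setdiff(c("subject_id", outcome, terms), names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  table <- table[stats::complete.cases(table[, c("subject_id", outcome, terms)]), ,
                 drop = FALSE]
  if (length(unique(table$subject_id)) < 2) {
    stop("GEE needs at least 2 subject clusters")
  }

  df <- table
  factor_like <- c("hemisphere", "day", "block_order")
  for (tm in terms) {
    v <- df[[tm]]
    if (is.character(v) || tm %in% factor_like) df[[tm]] <- factor(v)
    if (is.logical(v)) df[[tm]] <- as.numeric(v)
  }
  for (tm in terms) {
    if (length(unique(df[[tm]])) < 2) {
      stop("singular design: term '", tm, "' is constant in this table")
    }
  }
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(form, df)
  y <- as.numeric(df[[outcome]])
  if (qr(X)$rank < ncol(X)) {
    stop("singular design for terms: ", paste(terms, collapse = ", "))
  }
  cl <- split(seq_len(nrow(X)), df$subject_id, drop = TRUE)
  p <- ncol(X)
  n_obs <- nrow(X)

  beta <- qr.coef(qr(X), y)              # OLS start
  rho <- 0
  for (it in seq_len(max_iter)) {
    e <- y - drop(X %*% beta)
    phi <- sum(e^2) / (n_obs - p)
    num <- 0; npair <- 0
    for (idx in cl) {
      ei <- e[idx]; ni <- length(ei)
      if (ni >= 2) {
        num <- num + (sum(ei)^2 - sum(ei^2)) / 2
        npair <- npair + ni * (ni - 1) / 2
      }
    }
    rho_new <- if (npair > p) num / (phi * (npair - p)) else 0
    rho_new <- min(max(rho_new, 0), 0.99)
    A <- matrix(0, p, p); b <- numeric(p)
    for (idx in cl) {
      Xi <- X[idx, , drop = FALSE]; yi <- y[idx]; ni <- length(idx)
      # R^{-1} of exchangeable correlation, closed form
      a1 <- 1 / (1 - rho_new)
      a2 <- -rho_new / ((1 - rho_new) * (1 + (ni - 1) * rho_new))
      WX <- a1 * Xi + a2 * matrix(colSums(Xi), ni, p, byrow = TRUE)
      A <- A + crossprod(Xi, WX)
      b <- b + crossprod(WX, yi)
    }
    beta_new <- solve(A, b)
    done <- max(abs(beta_new - beta)) < tol && abs(rho_new - rho) < tol
    beta <- beta_new; rho <- rho_new
    if (done) break
  }

  e <- y - drop(X %*% beta)
  phi <- sum(e^2) / (n_obs - p)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (idx in cl) {
    Xi <- X[idx, , drop = FALSE]; ei <- e[idx]; ni <- length(idx)
    a1 <- 1 / (1 - rho)
    a2 <- -rho / ((1 - rho) * (1 + (ni - 1) * rho))
    WX <- a1 * Xi + a2 * matrix(colSums(Xi), ni, p, byrow = TRUE)
    B <- B + crossprod(Xi, WX)
    u <- crossprod(WX, ei)
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  se <- sqrt(diag(V))
  est <- drop(beta)
  z <- est / se
  coef <- data.frame(
    term = colnames(X), estimate = est, se = se,
    ci_lo = est - stats::qnorm(0.975) * se,
    ci_hi = est + stats::qnorm(0.975) * se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coef, rho = rho, phi = phi,
                 n_clusters = length(cl), n_obs = n_obs,
                 outcome = outcome, terms = terms,
                 measure = measure, window = window),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "<gee_fit> %s ~ %s  (%d obs, %d clusters, exchangeable rho = %.3f)\n",
    x$outcome, paste(x$terms, collapse = " + "), x$n_obs, x$n_clusters, x$rho))
  co <- x$coefficients
  co$ci <- sprintf("(%.1f, %.1f)", co$ci_lo, co$ci_hi)
  print(data.frame(term = co$term, estimate = round(co$estimate, 2),
                   CI = co$ci, Z = round(co$z, 2), p = signif(co$p, 3)),
        row.names = FALSE)
  invisible(x)
}
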