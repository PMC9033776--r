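GROUP_LEVELS <- c("CTRL_VEH", "SZ_VEH", "CTRL_JQ", "SZ_JQ")

#' Cell-means design matrix and standard contrasts
#'
#' Collapses diagnosis (CTRL/SZ) and treatment (VEH/JQ1) into one four-level
#' group factor and builds a no-intercept indicator design plus the four
#' standard contrast vectors: `SZ_vs_CTRL`, `JQ_vs_CTRL`, `SZJQ_vs_CTRL`
#' and the interaction `SYNERGY = SZ_JQ - SZ_VEH - CTRL_JQ + CTRL_VEH`.
#'
#' @param samples data.frame with columns `diagnosis` (CTRL/SZ) and
#'   `treatment` (VEH/JQ1); a `group` column is recomputed from these.
#' @return list with `design` (samples x groups indicator matrix),
#'   `contrasts` (groups x contrasts numeric matrix) and `group` (factor).
#' @export
build_design <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("diagnosis", "treatment") %in% names(samples)))
  if (!all(samples$diagnosis %in% c("CTRL", "SZ")))
    stop("diagnosis must be CTRL or SZ")
  if (!all(samples$treatment %in% c("VEH", "JQ1", "JQ")))
    stop("treatment must be VEH or JQ1")
  group <- paste0(samples$diagnosis, "_",
                  ifelse(samples$treatment == "VEH", "VEH", "JQ"))
  present <- GROUP_LEVELS[GROUP_LEVELS %in% group]
  group <- factor(group, levels = present)
  design <- stats::model.matrix(~ 0 + group)
  colnames(design) <- present
  rownames(design) <- if (!is.null(samples$sample_id)) samples$sample_id
                      else rownames(samples)

  cdef <- list(
    SZ_vs_CTRL   = c(CTRL_VEH = -1, SZ_VEH = 1, CTRL_JQ = 0, SZ_JQ = 0),
    JQ_vs_CTRL   = c(CTRL_VEH = -1, SZ_VEH = 0, CTRL_JQ = 1, SZ_JQ = 0),
    SZJQ_vs_CTRL = c(CTRL_VEH = -1, SZ_VEH = 0, CTRL_JQ = 0, SZ_JQ = 1),
    SYNERGY      = c(CTRL_VEH = 1, SZ_VEH = -1, CTRL_JQ = -1, SZ_JQ = 1),
    ADDITIVE     = c(CTRL_VEH = -2, SZ_VEH = 1, CTRL_JQ = 1, SZ_JQ = 0)
  )
  keep <- vapply(cdef, function(co) all(names(co)[co != 0] %in% present),
                 logical(1L))
  if (!any(keep)) stop("no standard contrast is estimable for these groups")
  contrasts <- vapply(cdef[keep], function(co) co[present], numeric(length(present)))
  rownames(contrasts) <- present
  list(design = design, contrasts = contrasts, group = group)
}

#' Voom-type mean-variance precision weights
#'
#' Fits each gene by unweighted least squares, smooths the square-root
#' residual standard deviations against average log2-CPM with `lowess`,
#' and maps every fitted value through the trend by piecewise-linear
#' interpolation (clamped at both ends). The precision weight is the
#' interpolated trend value to the power -4.
#'
#' @param logexpr log2-CPM matrix, genes x samples.
#' @param design design matrix from [build_design()].
#' @param span lowess span.
#' @param lib_size optional per-sample (effective) library sizes; when
#'   supplied, the trend is indexed on the log2-count scale so each
#'   observation's predicted log-count reflects its sample's depth.
#' @return list with `weights` (positive matrix, genes x samples) and
#'   `trend` (list of `x`, `y` lowess coordinates).
#' @export
mean_variance_weights <- function(logexpr, design, span = 0.5,
                                  lib_size = NULL) {
  stopifnot(is.matrix(logexpr), nrow(design) == ncol(logexpr))
  n <- ncol(logexpr); p <- ncol(design)
  if (n <= p) stop("no residual degrees of freedom")
  qrX <- qr(design)
  beta <- t(qr.coef(qrX, t(logexpr)))
  fitted <- beta %*% t(design)
  res <- logexpr - fitted
  sigma <- sqrt(rowSums(res^2) / (n - p))
  if (is.null(lib_size)) {
    sx <- rowMeans(logexpr)
    pred <- fitted
  } else {
    stopifnot(length(lib_size) == n)
    shift <- log2(lib_size + 1) - log2(1e6)
    sx <- rowMeans(logexpr) + mean(shift)
    pred <- sweep(fitted, 2L, shift, "+")
  }
  sy <- sqrt(sigma)                       # quarter-root variance scale
  lo <- stats::lowess(sx, sy, f = span)
  l <- stats::approx(lo$x, lo$y, xout = as.vector(pred), rule = 2)$y
  l <- pmax(l, 1e-6)
  w <- matrix(l^-4, nrow(logexpr), n, dimnames = dimnames(logexpr))
  list(weights = w, trend = list(x = lo$x, y = lo$y))
}

#' Per-gene weighted least-squares contrast fits
#'
#' Fits `y_g = X beta_g` by WLS for every gene and evaluates the requested
#' contrasts: coefficient `beta = c' beta_g`, unscaled standard error
#' `u = sqrt(c' (X'WX)^-1 c)`, residual standard deviation `s_g` and
#' residual degrees of freedom `d_g = n - p`.
#'
#' @param logexpr log2-CPM matrix, genes x samples.
#' @param weights positive precision weights (matrix conformable with
#'   `logexpr`, a per-sample vector, or `NULL` for unweighted).
#' @param design full-rank design matrix.
#' @param contrasts groups x contrasts numeric matrix.
#' @return object of class `contrast_fit`: `coefficients` and
#'   `stdev_unscaled` (genes x contrasts), `group_coefficients` (genes x
#'   design columns), `sigma`, `df_residual`, `cov_unscaled` (p x p x genes
#'   array), plus the design, weights and contrast matrix.
#' @export
fit_contrasts <- function(logexpr, weights = NULL, design, contrasts) {
  stopifnot(is.matrix(logexpr), is.matrix(design),
            nrow(design) == ncol(logexpr))
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  G <- nrow(logexpr); n <- ncol(logexpr); p <- ncol(design)
  if (is.null(weights)) weights <- matrix(1, G, n)
  if (is.vector(weights)) weights <- matrix(weights, G, n, byrow = TRUE)
  stopifnot(all(weights > 0), all(is.finite(weights)))
  contrasts <- as.matrix(contrasts)
  stopifnot(nrow(contrasts) == p)
  K <- ncol(contrasts)

  beta_grp <- matrix(NA_real_, G, p, dimnames = list(rownames(logexpr),
                                                     colnames(design)))
  sigma <- numeric(G)
  covu <- array(NA_real_, c(p, p, G))
  for (g in seq_len(G)) {
    w <- weights[g, ]
    xw <- design * sqrt(w)
    yw <- logexpr[g, ] * sqrt(w)
    xtx <- crossprod(xw)
    V <- tryCatch(chol2inv(chol(xtx)),
                  error = function(e) stop("singular weighted normal equations"))
    b <- V %*% crossprod(xw, yw)
    r <- yw - xw %*% b
    beta_grp[g, ] <- b
    sigma[g] <- sqrt(sum(r^2) / (n - p))
    covu[, , g] <- V
  }
  coefs <- beta_grp %*% contrasts
  stdev_u <- matrix(NA_real_, G, K, dimnames = list(rownames(logexpr),
                                                    colnames(contrasts)))
  for (k in seq_len(K)) {
    co <- contrasts[, k]
    stdev_u[, k] <- sqrt(apply(covu, 3L, function(V) drop(t(co) %*% V %*% co)))
  }
  structure(list(
    coefficients = coefs, stdev_unscaled = stdev_u,
    group_coefficients = beta_grp, sigma = sigma,
    df_residual = rep(n - p, G), cov_unscaled = covu,
    design = design, contrasts = contrasts, weights = weights
  ), class = "contrast_fit")
}

trigamma_inverse <- function(x) {
  # Newton iteration on the log scale; trigamma is convex decreasing.
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2`
#' by moment matching of the log sample variances to a scaled-F model
#' (closed form via digamma/trigamma inversion), then forms posterior
#' variances `s2_post = (d0 s0^2 + d s^2) / (d0 + d)`, moderated t
#' statistics `t = beta / (u * sqrt(s2_post))`, two-sided p-values on
#' `d0 + d` degrees of freedom and BH-adjusted q-values.
#'
#' @param fit a `contrast_fit` from [fit_contrasts()].
#' @param prior_df optional forced `d0`: `0` reproduces the ordinary t
#'   statistic, `Inf` shrinks every variance to the common prior.
#' @return the fit augmented with `d0`, `s0_2`, `s2_post`, `t`, `p`, `q`.
#' @export
moderate_statistics <- function(fit, prior_df = NULL) {
  stopifnot(inherits(fit, "contrast_fit"))
  s2 <- fit$sigma^2
  df <- fit$df_residual
  ok <- df > 0 & is.finite(s2)
  if (sum(ok) < 10L && is.null(prior_df))
    stop("need at least 10 genes with positive residual df")
  if (all(s2[ok] == 0)) stop("all residual variances are zero")

  if (is.null(prior_df)) {
    z <- log(pmax(s2[ok], 1e-300))
    e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1L) - mean(trigamma(df[ok] / 2))
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(emean)
    }
  } else {
    d0 <- prior_df
    s0_2 <- if (is.finite(d0) && d0 == 0) NA_real_ else mean(s2[ok])
  }

  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0_2 + df * s2) / (d0 + df)
  df_total <- df + d0
  tt <- fit$coefficients / (fit$stdev_unscaled * sqrt(s2_post))
  pp <- 2 * stats::pt(-abs(tt), df = df_total)
  qq <- apply(pp, 2L, adjust_fdr)
  fit$d0 <- d0; fit$s0_2 <- s0_2; fit$s2_post <- s2_post
  fit$df_total <- df_total
  fit$t <- tt; fit$p <- pp; fit$q <- matrix(qq, nrow(pp), ncol(pp),
                                            dimnames = dimnames(pp))
  fit$moderated <- TRUE
  fit
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1
#' (delegates to `stats::p.adjust`).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
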