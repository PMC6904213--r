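#' Repeated-measures ANOVA with sphericity handling
#'
#' One- or two-factor fully within-subject ANOVA on a complete balanced
#' design. Each effect is tested against its own subject-by-effect error
#' stratum via orthonormal effect contrasts; Mauchly's sphericity test and
#' the Greenhouse-Geisser epsilon are computed from the covariance of the
#' contrast scores, and the corrected degrees of freedom and p-value are
#' applied whenever Mauchly's p falls below `gg_alpha` (and reported
#' regardless). Linear and quadratic polynomial contrasts are reported for
#' ordered factors with at least 3 levels.
#'
#' @param data long-format data frame with a `subject` column, a `value`
#'   column, and the factor columns named in `factors`.
#' @param factors character vector of 1 or 2 within-subject factor column
#'   names.
#' @param gg_alpha sphericity-violation threshold on Mauchly's p.
#' @return tibble of class `rm_anova`: one row per effect with `F`, `df1`,
#'   `df2`, `p`, `mauchly_W`, `mauchly_p`, `gg_epsilon`, `df1_gg`,
#'   `df2_gg`, `p_gg`, `sphericity_violated`, and (attribute `contrasts`)
#'   the polynomial contrast t-tests.
#' @export
rm_anova <- function(data, factors, gg_alpha = 0.05) {
  stopifnot(length(factors) %in% 1:2,
            all(c("subject", "value", factors) %in% names(data)))
  data <- as.data.frame(data)
  for (f in factors) data[[f]] <- factor(data[[f]])
  data$subject <- factor(data$subject)
  levs <- lapply(factors, function(f) levels(data[[f]]))
  n_lev <- vapply(levs, length, integer(1))

  # per-subject cell means, cells ordered by expand.grid over the factors
  cells <- do.call(expand.grid, c(stats::setNames(levs, factors),
                                  list(stringsAsFactors = FALSE)))
  key <- interaction(data[factors], drop = FALSE, lex.order = FALSE)
  cell_key <- interaction(cells, drop = FALSE, lex.order = FALSE)
  agg <- stats::aggregate(value ~ subject + key,
                          data = cbind(data, key = key), FUN = mean)
  Y <- matrix(NA_real_, nlevels(data$subject), nrow(cells))
  Y[cbind(as.integer(agg$subject), match(agg$key, cell_key))] <- agg$value
  if (anyNA(Y)) stop("incomplete design: every subject needs every cell")
  n <- nrow(Y)

  orth <- function(p) {
    # orthonormal basis of the contrast space (columns)
    C <- stats::contr.helmert(p)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
  }
  unitv <- function(p) matrix(1 / sqrt(p), p, 1)

  effects <- if (length(factors) == 1) {
    stats::setNames(list(list(orth(n_lev[1]))), factors)
  } else {
    # expand.grid varies the FIRST factor fastest; kronecker's right factor
    # varies fastest, so factor 1's matrix goes on the right
    stats::setNames(
      list(list(orth(n_lev[1]), unitv(n_lev[2])),
           list(unitv(n_lev[1]), orth(n_lev[2])),
           list(orth(n_lev[1]), orth(n_lev[2]))),
      c(factors, paste(factors, collapse = ":")))
  }

  rows <- lapply(names(effects), function(eff) {
    mats <- effects[[eff]]
    U <- if (length(mats) == 1) mats[[1]] else kronecker(mats[[2]], mats[[1]])
    Z <- Y %*% U
    df1 <- ncol(Z)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    R <- sweep(Z, 2, zbar)
    ss_err <- sum(R^2)
    df2 <- (n - 1) * df1
    Fv <- (ss_eff / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    S <- crossprod(R) / (n - 1)
    if (df1 > 1) {
      eps <- sum(diag(S))^2 / (df1 * sum(S^2))
      W <- det(S) / (sum(diag(S)) / df1)^df1
      fm <- (2 * df1^2 + df1 + 2) / (6 * df1)
      chi <- -(n - 1 - fm) * log(max(W, .Machine$double.xmin))
      mdf <- df1 * (df1 + 1) / 2 - 1
      mp <- stats::pchisq(chi, mdf, lower.tail = FALSE)
    } else {
      eps <- 1; W <- 1; mp <- NA_real_
    }
    violated <- !is.na(mp) && mp < gg_alpha
    tibble::tibble(
      effect = eff, F = Fv, df1 = df1, df2 = df2, p = p,
      mauchly_W = W, mauchly_p = mp, gg_epsilon = eps,
      df1_gg = eps * df1, df2_gg = eps * df2,
      p_gg = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
      sphericity_violated = violated,
      p_reported = if (violated) stats::pf(Fv, eps * df1, eps * df2,
                                           lower.tail = FALSE) else p)
  })
  res <- dplyr::bind_rows(rows)

  # polynomial contrasts for ordered main effects
  contr <- list()
  for (j in seq_along(factors)) {
    p <- n_lev[j]
    if (p < 3) next
    cp <- stats::contr.poly(p)
    # per-subject marginal means of this factor (averaged over the other)
    agg2 <- stats::aggregate(
      value ~ subject + fac,
      data = data.frame(value = data$value, subject = data$subject,
                        fac = data[[factors[j]]]), FUN = mean)
    marg <- matrix(NA_real_, n, p)
    marg[cbind(as.integer(agg2$subject), as.integer(agg2$fac))] <- agg2$value
    for (cn in c("linear", "quadratic")) {
      cc <- cp[, if (cn == "linear") 1 else 2]
      sc <- as.numeric(marg %*% cc)
      tt <- stats::t.test(sc, mu = 0)
      contr[[paste(factors[j], cn)]] <-
        list(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
    }
  }
  attr(res, "contrasts") <- contr
  class(res) <- c("rm_anova", class(res))
  res
}

#' One-sample / paired t-tests with Bonferroni-corrected alpha
#'
#' Runs a family of one-sample (or paired, by supplying the partner
#' values) t-tests and reports the Bonferroni-corrected critical alpha
#' `0.05 / family_size` alongside each comparison. Zero-variance inputs
#' yield an undefined p and are flagged rather than erroring.
#'
#' @param values numeric vector, or list of numeric vectors (one per
#'   comparison).
#' @param mu0 null value for one-sample tests.
#' @param partner optional vector/list matching `values` for paired tests.
#' @param family_size number of comparisons in the family (defaults to the
#'   number supplied).
#' @param labels comparison labels.
#' @param alpha family-wise alpha.
#' @return tibble: `comparison`, `t`, `df`, `p`, `corrected_alpha`,
#'   `significant`, `degenerate`.
#' @export
t_test_suite <- function(values, mu0 = 0, partner = NULL,
                         family_size = NULL, labels = NULL, alpha = 0.05) {
  if (!is.list(values)) values <- list(values)
  if (!is.null(partner) && !is.list(partner)) partner <- list(partner)
  m <- length(values)
  if (is.null(family_size)) family_size <- m
  if (is.null(labels)) labels <- paste0("comparison_", seq_len(m))
  corrected <- alpha / family_size
  rows <- lapply(seq_len(m), function(i) {
    x <- values[[i]]
    if (!is.null(partner)) x <- x - partner[[i]]
    if (length(x) < 2) stop("need n >= 2 for a t-test")
    if (stats::sd(x) == 0) {
      return(tibble::tibble(comparison = labels[i], t = NA_real_,
                            df = length(x) - 1, p = NA_real_,
                            corrected_alpha = corrected,
                            significant = NA, degenerate = TRUE))
    }
    tt <- stats::t.test(x, mu = mu0)
    tibble::tibble(comparison = labels[i], t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   corrected_alpha = corrected,
                   significant = tt$p.value < corrected, degenerate = FALSE)
  })
  dplyr::bind_rows(rows)
}
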