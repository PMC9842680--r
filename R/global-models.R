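#' Ordinary least squares fit with Wherry-adjusted R-squared
#'
#' @param y numeric response (species-level methylation).
#' @param X data.frame or matrix of predictors.
#' @return list of class `mc_modelfit`: coefficients, `r2`,
#'   `r2_wherry_adjusted` (1 - (1 - R2)(n - 1)/(n - p - 1)), `aic`,
#'   `loglik`, `n`, `p`, and the underlying `lm`.
#' @export
fit_linear <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  d <- cbind(data.frame(.y = y), X)
  fit <- lm(.y ~ ., data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("singular design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r2 <- summary(fit)$r.squared
  structure(list(
    coefficients = coef(fit),
    r2 = r2,
    r2_wherry_adjusted = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    aic = AIC(fit),
    loglik = as.numeric(logLik(fit)),
    n = n, p = p, fit = fit
  ), class = "mc_modelfit")
}

#' @export
print.mc_modelfit <- function(x, ...) {
  cat("linear fit: n =", x$n, ", p =", x$p,
      ", R2 =", round(x$r2, 4),
      ", Wherry-adjusted R2 =", round(x$r2_wherry_adjusted, 4),
      ", AIC =", round(x$aic, 2), "\n")
  invisible(x)
}

tree_phylo <- function(tree) {
  phy <- if (inherits(tree, "mc_tree")) tree$phy else tree
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  phy
}

#' Phylogenetic generalized least squares (Brownian covariance)
#'
#' Fits `y ~ X` by GLS with residual covariance proportional to shared
#' branch length under Brownian motion on the given tree. On a star tree
#' (no shared internal branches) the estimates reduce to ordinary least
#' squares.
#'
#' @param y named numeric (names = species, all present as tree tips).
#' @param X data.frame/matrix of predictors (rows in the order of `y`), or
#'   `NULL` for an intercept-only model.
#' @param tree `mc_tree` or `phylo`; trees without branch lengths get unit
#'   lengths.
#' @return list of class `mc_pglsfit`: `coefficients` (data.frame with
#'   estimate, se, t, p), `loglik`, `aic`, the pruned tree and the `gls`
#'   fit.
#' @export
fit_pgls <- function(y, X = NULL, tree) {
  phy <- tree_phylo(tree)
  sp <- names(y)
  if (is.null(sp)) stop("y must be named by species", call. = FALSE)
  missing_sp <- setdiff(sp, phy$tip.label)
  if (length(missing_sp)) {
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  phy <- ape::keep.tip(phy, sp)
  d <- data.frame(.y = unname(y), .species = sp)
  form <- .y ~ 1
  if (!is.null(X)) {
    X <- as.data.frame(X)
    d <- cbind(d, X)
    form <- as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
  }
  corr <- ape::corBrownian(1, phy = phy, form = ~.species)
  fit <- nlme::gls(form, data = d, correlation = corr, method = "ML")
  tt <- summary(fit)$tTable
  coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                      se = tt[, "Std.Error"], t = tt[, "t-value"],
                      p = tt[, "p-value"], row.names = NULL)
  structure(list(coefficients = coefs,
                 loglik = as.numeric(logLik(fit)),
                 aic = AIC(fit), tree = phy, fit = fit),
            class = "mc_pglsfit")
}

#' @export
print.mc_pglsfit <- function(x, ...) {
  cat("phylogenetic GLS (Brownian):\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Stepwise AIC feature selection with bootstrap stability
#'
#' Bidirectional greedy AIC search starting from the intercept-only model,
#' then repeated on bootstrap resamples of the species; each feature's
#' stability is the percentage of bootstrap runs selecting it.
#'
#' @param y numeric response.
#' @param X data.frame of candidate features (e.g. the 64 3-mer
#'   frequencies).
#' @param n_bootstrap bootstrap iterations.
#' @param seed integer seed.
#' @return list of class `mc_stability`: `selected` (features in the final
#'   model on the full data), `final_fit` (`mc_modelfit`), and `stability`
#'   data.frame (feature, stability percent, n_bootstrap).
#' @export
stepwise_select <- function(y, X, n_bootstrap = 100L, seed = 1L) {
  X <- as.data.frame(X)
  if (length(y) < 20L) stop("need n >= 20 species", call. = FALSE)
  d <- cbind(data.frame(.y = y), X)
  upper <- as.formula(paste("~", paste(names(X), collapse = " + ")))
  run_step <- function(dat) {
    base <- lm(.y ~ 1, data = dat)
    fit <- step(base, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0)
    attr(terms(fit), "term.labels")
  }
  selected <- run_step(d)
  final <- if (length(selected) && length(y) > length(selected) + 1L) {
    fit_linear(y, X[, selected, drop = FALSE])
  } else {
    NULL
  }
  hits <- setNames(numeric(ncol(X)), names(X))
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(nrow(d), replace = TRUE)
      sel_b <- tryCatch(run_step(d[idx, , drop = FALSE]),
                        error = function(e) character())
      hits[sel_b] <- hits[sel_b] + 1
    }
  })
  stability <- data.frame(feature = names(X),
                          stability = 100 * hits / n_bootstrap,
                          n_bootstrap = n_bootstrap, row.names = NULL)
  structure(list(selected = selected, final_fit = final,
                 stability = stability),
            class = "mc_stability")
}

#' Per-feature association tests with and without phylogeny
#'
#' Each feature is tested alone against the response, once by ordinary
#' linear regression and once by Brownian-motion PGLS; p-values are
#' Bonferroni-adjusted across features (capped at 1).
#'
#' @param y named numeric (species).
#' @param X data.frame of features (e.g. 64 3-mer frequencies).
#' @param tree `mc_tree` or `phylo`.
#' @return data.frame per feature: `p_lm`, `p_pgls`, adjusted versions and
#'   their -log10 values.
#' @export
per_feature_phylo_test <- function(y, X, tree) {
  X <- as.data.frame(X)
  m <- ncol(X)
  rows <- lapply(names(X), function(f) {
    xv <- X[[f]]
    pl <- summary(lm(y ~ xv))$coefficients
    p_lm <- if (nrow(pl) >= 2) pl[2, 4] else NA_real_
    pg <- fit_pgls(y, data.frame(x = xv), tree)$coefficients
    p_pgls <- pg$p[pg$term == "x"]
    data.frame(feature = f, p_lm = p_lm, p_pgls = p_pgls)
  })
  out <- do.call(rbind, rows)
  out$p_lm_adj <- pmin(out$p_lm * m, 1)
  out$p_pgls_adj <- pmin(out$p_pgls * m, 1)
  out$neglog10_p_lm <- -log10(out$p_lm)
  out$neglog10_p_pgls <- -log10(out$p_pgls)
  out$significant <- out$p_pgls_adj < 0.05
  out
}

#' Association of a species metric with a covariate, phylogeny-corrected
#'
#' Pearson correlation on complete pairs plus a phylogeny-corrected p-value
#' from a Brownian PGLS of `metric ~ covariate`.
#'
#' @param metric,covariate named numerics over species.
#' @param tree `mc_tree` or `phylo`.
#' @param group optional group label to restrict to.
#' @param groups named character vector species -> group (defaults to the
#'   `mc_tree` groups).
#' @return list: `r`, `p_naive`, `p_phylo`, `n`.
#' @export
covariate_association <- function(metric, covariate, tree, group = NULL,
                                  groups = NULL) {
  if (is.null(groups) && inherits(tree, "mc_tree")) groups <- tree$groups
  sp <- intersect(names(metric), names(covariate))
  if (!is.null(group)) sp <- sp[groups[sp] == group]
  ok <- sp[!is.na(metric[sp]) & !is.na(covariate[sp])]
  if (length(ok) < 4L) {
    warning("fewer than 4 species with both values; association missing")
    return(list(r = NA_real_, p_naive = NA_real_, p_phylo = NA_real_,
                n = length(ok)))
  }
  ct <- cor.test(metric[ok], covariate[ok])
  p_phylo <- tryCatch({
    pg <- fit_pgls(metric[ok], data.frame(cov = unname(covariate[ok])), tree)
    pg$coefficients$p[pg$coefficients$term == "cov"]
  }, error = function(e) {
    # degenerate fits (e.g. exactly collinear input) have no finite test
    NA_real_
  })
  list(r = unname(ct$estimate), p_naive = ct$p.value, p_phylo = p_phylo,
       n = length(ok))
}
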