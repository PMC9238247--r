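#' Likelihood-ratio test of features against pseudotime
#'
#' For every feature, compares a Gaussian fit of the (optionally
#' log1p-transformed) values on a degree-4 B-spline basis of pseudotime
#' (the alternative) against a constant-mean fit (the null), and reports the
#' likelihood-ratio statistic with a chi-squared p-value. The spline basis
#' uses no interior knots, so the alternative has 4 extra parameters
#' (`df = 4`). Gene expression should be tested on `log1p` counts; motif
#' deviation scores are continuous already and can be tested as-is
#' (`logTransform = FALSE`).
#'
#' @param X cells x features matrix of values.
#' @param t pseudotime per cell (finite, non-constant).
#' @param logTransform apply `log1p` to `X` before fitting (default `TRUE`).
#' @param degree spline degree (default 4).
#' @return data.frame with `feature`, `loglik_alt`, `loglik_null`,
#'   `lr_stat`, `df`, `p_value` and a Benjamini-Hochberg `fdr` column
#'   (informational; selection uses raw p-values).
#' @export
lrtPseudotime <- function(X, t, logTransform = TRUE, degree = 4) {
    X <- .as_dense(X)
    .assert(length(t) == nrow(X), "length(t) must equal nrow(X)")
    .assert(all(is.finite(t)), "pseudotime must be finite")
    if (stats::var(t) == 0)
        stop("pseudotime is constant; the spline basis is degenerate",
             call. = FALSE)
    Y <- if (logTransform) log1p(X) else X
    n <- nrow(Y)
    basis <- splines::bs(t, degree = degree)
    design <- cbind(1, basis)
    qr_alt <- qr(design)
    rss_alt <- colSums(qr.resid(qr_alt, Y)^2)
    rss_null <- colSums(sweep(Y, 2, colMeans(Y))^2)
    df <- ncol(design) - 1L
    loglik <- function(rss) -n / 2 * (log(2 * pi) + log(pmax(rss, 1e-300) / n) + 1)
    ll_alt <- loglik(rss_alt)
    ll_null <- loglik(rss_null)
    lr <- pmax(2 * (ll_alt - ll_null), 0)
    p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
    constant <- rss_null < 1e-12
    lr[constant] <- 0
    p[constant] <- 1
    feats <- colnames(Y)
    if (is.null(feats)) feats <- paste0("feature", seq_len(ncol(Y)))
    data.frame(feature = feats, loglik_alt = ll_alt, loglik_null = ll_null,
               lr_stat = lr, df = df, p_value = p,
               fdr = stats::p.adjust(p, "BH"), row.names = NULL)
}

#' Select significant features by p-value and count cut-off
#'
#' Sorts ascending by p-value (ties broken by feature id), keeps features
#' with `p < alpha`, and truncates to the first `topN`. The conventional
#' cut-offs are 100 for genes and 50 for motifs.
#'
#' @param results data.frame from [lrtPseudotime()].
#' @param alpha significance level (strict inequality; default 0.05).
#' @param topN maximum number of features to keep.
#' @return The selected rows, sorted by p-value.
#' @export
selectSignificant <- function(results, alpha = 0.05, topN = 100) {
    ord <- order(results$p_value, results$feature)
    res <- results[ord, , drop = FALSE]
    res <- res[res$p_value < alpha, , drop = FALSE]
    utils::head(res, topN)
}
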