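# Internal numeric helpers shared across modules.

# Pairwise Euclidean distance matrix between rows of x (and optionally y).
# Clamps tiny negative values arising from the expansion trick.
.pdist <- function(x, y = NULL) {
    x <- as.matrix(x)
    if (is.null(y)) {
        sq <- rowSums(x^2)
        d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
        diag(d2) <- 0
    } else {
        y <- as.matrix(y)
        d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    }
    d2[d2 < 0] <- 0
    sqrt(d2)
}

# Squared pairwise distances (no sqrt); same clamping.
.pdist2 <- function(x, y = NULL) {
    x <- as.matrix(x)
    if (is.null(y)) {
        sq <- rowSums(x^2)
        d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
        diag(d2) <- 0
    } else {
        y <- as.matrix(y)
        d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    }
    d2[d2 < 0] <- 0
    d2
}

.assert <- function(cond, ...) if (!cond) stop(sprintf(...), call. = FALSE)

# Run expr with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards so library code does not perturb user-level randomness.
# `seed` is forced first: evaluating it may itself draw from the caller's
# stream (e.g. seed = sample.int(...)).
.with_seed <- function(seed, expr) {
    force(seed)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

.as_dense <- function(x) {
    if (inherits(x, "Matrix")) as.matrix(x) else x
}

# Fast column-wise scale/shift (avoids sweep()'s aperm copies).
.cmul <- function(x, v) x * rep(v, each = nrow(x))
.cdiv <- function(x, v) x * rep(1 / v, each = nrow(x))
.cadd <- function(x, v) x + rep(v, each = nrow(x))
.csub <- function(x, v) x - rep(v, each = nrow(x))
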