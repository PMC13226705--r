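# Internal numeric helpers shared across modules.

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sign() with the convention sign(0) = 0, i.e. pixels with an exactly zero
# gradient receive no update.
#' @keywords internal
sign0 <- function(x) sign(x)

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax of a matrix, numerically stable.
#' @keywords internal
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations in the package route through this so that
# results are pure functions of their configuration.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Mean silhouette width (Euclidean) of a labelled point set; used as the
# quantitative stand-in for "class clusters collapse" statements about
# attacked feature spaces.
#' @export
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2L) stop("silhouette_score() needs >= 2 classes")
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    same[i] <- FALSE
    if (!any(same)) { s[i] <- 0; next }
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Stable short hash of an R object, via its canonical JSON serialisation.
#' @keywords internal
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
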