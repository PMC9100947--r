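## Internal numeric and plumbing helpers.

#' @importFrom stats median rbinom rnbinom runif rlnorm optimize prcomp
#'   kmeans dist setNames dbinom
#' @importFrom utils write.table read.table packageVersion
NULL

## x * log(p) with the convention 0 * log(0) = 0 (binomial log-likelihood
## must stay finite when the corresponding count is zero).
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

## Row-wise log-sum-exp of a matrix, guarded against all -Inf rows.
rowLogSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

## Deterministic per-stage seed derived from the run seed: one user-facing
## seed reproduces every stochastic stage.  Kept strictly below 2^31.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 977 + h) %% 2147483629)
}

## TSV helpers: plain, loss-free, diffable.
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "",
             colClasses = NA, na.strings = "NA")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

## Integer storage for count matrices read back from MatrixMarket (doubles).
asIntegerMatrix <- function(m) {
  storage.mode(m) <- "integer"
  m
}
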