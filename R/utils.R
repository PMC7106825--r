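# shared small helpers

.BASES <- c("A", "C", "G", "T")

#' Reverse-complement character vector of DNA strings
#' @param x character vector of A/C/G/T/N strings
#' @return character vector
#' @keywords internal
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes
#' @param n number of trials
#' @param conf confidence level (default 0.95)
#' @return matrix with columns low, high (one row per element)
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- ifelse(n > 0, k / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

# write a data.frame as deterministic TSV ('.' decimal, no quoting)
.writeTSV <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

.readTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
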