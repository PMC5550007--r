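#' Construct a physiological / internal-model temporal filter
#'
#' Four causal filters over TR lags, each normalized to unit weight sum so
#' that steady-state gain is 1. They serve both as the physiological response
#' `h` linking neural activity to the measured signal and as the learner's
#' internal model `m` (its hypothesis about that response):
#'
#' * `impulse`: one TR, no delay -- weights `[1]`.
#' * `delay`: a pure 3-TR (6 s) lag -- weights `[0, 0, 0, 1]`.
#' * `blur`: a 10-s moving average over the current and previous 4 TRs --
#'   weights `[0.2, 0.2, 0.2, 0.2, 0.2]`.
#' * `hrf`: the canonical double-gamma BOLD response over the current and
#'   previous 14 TRs -- response gamma of shape 6 and scale 0.9 s (the
#'   Glover-style parameterization, time-to-peak just under 5 s), undershoot
#'   gamma of shape 16 and scale 1 with ratio 1/6 -- sampled on the TR grid
#'   `t = 0, 2, ..., 28 s`. The lag-0 weight is exactly zero (the response
#'   carries no information within the first TR) and the peak weight falls in
#'   the 4-6 s bins; the small negative undershoot lobe is retained and the
#'   signed weights are normalized to unit sum.
#'
#' @param kind One of `"impulse"`, `"hrf"`, `"delay"`, `"blur"`.
#' @param tr_seconds Sampling interval (TR) in seconds.
#' @return An object of class `nf_filter` with fields `kind`, `tr_seconds`,
#'   `weights` (over lags `0..L`) and `L`.
#' @examples
#' make_filter("blur")$weights[1]  # 0.2: 20% of the information within one TR
#' @export
make_filter <- function(kind = c("impulse", "hrf", "delay", "blur"),
                        tr_seconds = 2) {
  kind <- match.arg(kind)
  w <- switch(kind,
    impulse = 1,
    delay = c(0, 0, 0, 1),
    blur = rep(0.2, 5),
    hrf = {
      t <- (seq_len(15) - 1) * tr_seconds
      h <- dgamma(t, shape = 6, scale = 0.9) -
        dgamma(t, shape = 16, scale = 1) / 6
      h / sum(h)
    })
  structure(list(kind = kind, tr_seconds = tr_seconds, weights = w,
                 L = length(w) - 1L), class = "nf_filter")
}

#' @export
print.nf_filter <- function(x, ...) {
  cat("<nf_filter> ", x$kind, " (TR = ", x$tr_seconds, " s, lags 0..", x$L,
      ")\n  weights: ", paste(signif(x$weights, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

as_nf_filter <- function(x, tr_seconds = 2) {
  if (inherits(x, "nf_filter")) x else make_filter(x, tr_seconds)
}

#' Apply a temporal filter to a TR-indexed series
#'
#' Causal convolution `y[n] = sum_j w[j] * x[n - j]`, applied independently to
#' each column when `x` is a matrix with time along rows. History before the
#' first TR is treated as zeros (sessions start from rest).
#'
#' @param x Numeric vector, or matrix with TRs in rows (e.g. voxels in
#'   columns).
#' @param filter An `nf_filter` (or a kind string).
#' @param tr_seconds If supplied, checked against the filter's TR.
#' @return Filtered series with the same shape as `x`.
#' @export
apply_filter <- function(x, filter, tr_seconds = NULL) {
  filter <- as_nf_filter(filter)
  if (!is.null(tr_seconds) && !isTRUE(all.equal(tr_seconds, filter$tr_seconds)))
    stop("series TR (", tr_seconds, " s) does not match filter TR (",
         filter$tr_seconds, " s)")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x) else x
  L <- filter$L
  padded <- rbind(matrix(0, L, ncol(xm)), xm)
  y <- stats::filter(padded, filter$weights, method = "convolution", sides = 1)
  y <- matrix(as.numeric(y), nrow(padded))[seq_len(nrow(xm)) + L, , drop = FALSE]
  if (vec) drop(y) else { dimnames(y) <- dimnames(xm); y }
}

#' Write / read filter weights as CSV
#'
#' Plain-text round trip of a filter's `(lag_TR, weight)` table, for exact
#' regression tests and external use.
#'
#' @param filter An `nf_filter`.
#' @param path File path.
#' @return `write_filter_csv()` returns `path` invisibly; `read_filter_csv()`
#'   returns an `nf_filter`.
#' @export
write_filter_csv <- function(filter, path) {
  stopifnot(inherits(filter, "nf_filter"))
  df <- data.frame(lag_TR = seq_along(filter$weights) - 1L, weight = filter$weights)
  attr <- sprintf("# kind=%s tr_seconds=%s", filter$kind, filter$tr_seconds)
  writeLines(c(attr, "lag_TR,weight",
               sprintf("%d,%.17g", df$lag_TR, df$weight)), path)
  invisible(path)
}

#' @rdname write_filter_csv
#' @export
read_filter_csv <- function(path) {
  header <- readLines(path, n = 1)
  kv <- strsplit(sub("^# ", "", header), " ")[[1]]
  kv <- strsplit(kv, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- read.csv(path, skip = 1)
  structure(list(kind = unname(meta["kind"]),
                 tr_seconds = as.numeric(meta["tr_seconds"]),
                 weights = df$weight, L = nrow(df) - 1L),
            class = "nf_filter")
}
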