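# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a message naming the offending argument
#' @noRd
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample from a lognormal restricted to one side of a cut point
#'
#' Draws from the lognormal(meanlog, sdlog) conditional on being below
#' (side = "below") or above (side = "above") `cut`, by inverse-CDF
#' sampling. Used to plant an exact crossing probability for the
#' recording-interval signature.
#' @noRd
rlnorm_trunc <- function(n, meanlog, sdlog, cut, side = c("below", "above")) {
  side <- match.arg(side)
  if (n == 0L) return(numeric(0))
  p_cut <- plnorm(cut, meanlog, sdlog)
  u <- if (side == "below") {
    runif(n, 0, p_cut)
  } else {
    runif(n, p_cut, 1)
  }
  qlnorm(u, meanlog, sdlog)
}

#' Mixture draw: own-mode side with probability 1 - leak, other side with
#' probability leak. Guarantees P(value < cut) exactly 1 - leak (below mode)
#' or leak (above mode).
#' @noRd
rgap <- function(n, meanlog, sdlog, cut, main_side, leak) {
  if (n == 0L) return(numeric(0))
  other <- if (main_side == "below") "above" else "below"
  # record times are quantized to whole seconds downstream, which can
  # shrink a gap by up to 1 s; draws on the long side of the cut are
  # therefore truncated at cut + 1 so the planted signature survives
  # quantization
  bound <- function(side) if (side == "above") cut + 1 else cut
  flip <- runif(n) < leak
  out <- numeric(n)
  out[!flip] <- rlnorm_trunc(sum(!flip), meanlog, sdlog, bound(main_side),
                             main_side)
  out[flip] <- rlnorm_trunc(sum(flip), meanlog, sdlog, bound(other), other)
  out
}

#' Split an integer count across bins proportionally to weights,
#' preserving the total exactly (cumulative rounding, ties half-to-even).
#' @noRd
apportion_count <- function(count, weights) {
  if (length(weights) == 1L) return(count)
  w <- weights / sum(weights)
  cum <- round(cumsum(w) * count)
  diff(c(0, cum))
}

#' md5 of an R object via its serialized bytes (written to a temp file so
#' tools::md5sum can be used).
#' @noRd
object_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Deterministic child seed derived from a parent seed and a stream label.
#' Kept below 2^31 - 1.
#' @noRd
child_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.numeric(seed) * 48271 + s) %% 2147483647
}
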