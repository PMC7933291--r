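# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  code
}

#' Derive a stage-specific child seed from a global seed
#'
#' A single pipeline seed fans out deterministically to per-stage seeds so that
#' any stage can be re-run in isolation with the same stream. The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u)) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 1103) %% 2147483647)
}

# Equal-count (quantile) bin assignment. Duplicate quantile edges are merged,
# so the effective number of bins can be smaller than requested.
quantile_bins <- function(x, n_bins, warn = TRUE) {
  n_bins <- as.integer(n_bins)
  if (n_bins <= 1L || length(x) == 0L) return(rep(1L, length(x)))
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) return(rep(1L, length(x)))
  if (warn && length(edges) - 1L < n_bins) {
    warning("fewer distinct values than requested bins; bins merged",
            call. = FALSE)
  }
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

stop_if_not_scalar_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 0 || x > 1 || (open_left && x == 0) || (open_right && x == 1)) {
    stop(sprintf("`%s` must be a single value in %s0, 1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}
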