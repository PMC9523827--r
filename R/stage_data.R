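#' Two-arm trial data with staged accrual
#'
#' Container for accumulating observations of a parallel two-arm trial
#' monitored at up to `K` analyses. Each observation carries the arm it was
#' randomised to and the first analysis (stage) at which it is available;
#' analysis `k` uses the cumulative data of all observations with stage of
#' arrival `<= k`.
#'
#' @param arm integer vector of arm labels, each 1 or 2.
#' @param value numeric vector of responses (ordinal endpoints coded as
#'   numbers; any order-preserving coding is equivalent since all methods are
#'   rank-based).
#' @param stage integer vector, the first analysis at which each observation
#'   is available (1-based).
#' @param K total number of planned analyses; defaults to `max(stage)`.
#'
#' @return An object of class `two_arm_stage_data`.
#' @examples
#' d <- two_arm_stage_data(arm = c(1, 1, 2, 2), value = c(3, 1, 4, 2),
#'                         stage = c(1, 1, 1, 1))
#' stage_counts(d)
#' @export
two_arm_stage_data <- function(arm, value, stage = rep(1L, length(arm)),
                               K = max(stage)) {
  n <- length(value)
  if (n == 0L) stop_invalid_input("no observations supplied")
  if (length(arm) != n || length(stage) != n)
    stop_invalid_input("'arm', 'value' and 'stage' must have equal length")
  if (!all(arm %in% c(1L, 2L)))
    stop_invalid_input("'arm' must only contain 1 and 2")
  if (!is.numeric(value) || anyNA(value))
    stop_invalid_input("'value' must be numeric without missing values")
  stage <- as.integer(stage)
  if (anyNA(stage) || any(stage < 1L))
    stop_invalid_input("'stage' must contain positive integers")
  K <- as.integer(K)
  if (K < max(stage))
    stop_invalid_input("'K' is smaller than the largest stage of arrival")
  structure(
    list(arm = as.integer(arm), value = as.numeric(value), stage = stage,
         K = K),
    class = "two_arm_stage_data"
  )
}

#' Cumulative observations of one arm at an analysis
#'
#' @param data a [two_arm_stage_data] object.
#' @param stage analysis index `k`.
#' @param arm arm label, 1 or 2.
#' @return Numeric vector of the responses available at analysis `k`.
#' @export
stage_values <- function(data, stage, arm) {
  stopifnot(inherits(data, "two_arm_stage_data"))
  if (stage < 1L || stage > data$K)
    stop_invalid_input(sprintf("stage %d outside 1..%d", stage, data$K))
  data$value[data$arm == arm & data$stage <= stage]
}

#' Cumulative group sizes per analysis
#'
#' @param data a [two_arm_stage_data] object.
#' @return Integer matrix with `K` rows and columns `n1`, `n2`, `N`; row `k`
#'   holds the cumulative counts at analysis `k` (nondecreasing in `k`).
#' @export
stage_counts <- function(data) {
  stopifnot(inherits(data, "two_arm_stage_data"))
  K <- data$K
  n1 <- vapply(seq_len(K), function(k) sum(data$arm == 1L & data$stage <= k),
               integer(1))
  n2 <- vapply(seq_len(K), function(k) sum(data$arm == 2L & data$stage <= k),
               integer(1))
  cbind(n1 = n1, n2 = n2, N = n1 + n2)
}

#' @export
print.two_arm_stage_data <- function(x, ...) {
  cnt <- stage_counts(x)
  cat(sprintf("Two-arm staged data: %d observations, %d analyses\n",
              length(x$value), x$K))
  for (k in seq_len(x$K))
    cat(sprintf("  stage %d: n1 = %d, n2 = %d (N = %d)\n",
                k, cnt[k, 1], cnt[k, 2], cnt[k, 3]))
  invisible(x)
}
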