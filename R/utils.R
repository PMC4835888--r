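#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-down: ties at .5 go to the LOWER integer (conservative toward
# deletion; the confirmation worklist catches the ambiguous calls)
round_half_down <- function(x) ceiling(x - 0.5)

stop_c4 <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x == round(x)

check_prob_vector <- function(p, name, tol = 1e-9) {
  if (any(p < 0)) stop_c4("'%s' has negative entries", name)
  if (abs(sum(p) - 1) > tol) stop_c4("'%s' must sum to 1 (got %.12f)", name, sum(p))
  invisible(p)
}

# canonical probe names used throughout
C4_PROBES <- c("C4A", "C4B", "C4-ex30", "EP300", "CREBBP")
C4_TEST_PROBES <- c("C4A", "C4B", "C4-ex30")
C4_CONTROL_PROBES <- c("EP300", "CREBBP")

C4_LOCI <- c("C4A", "C4B", "totalC4")

# default modal-class anchors and allowed integer ranges per locus
default_anchors <- function() c(C4A = 2L, C4B = 2L, totalC4 = 4L)
default_cn_ranges <- function() list(C4A = c(0L, 5L), C4B = c(0L, 4L), totalC4 = c(0L, 9L))

#' Bonferroni correction for a fixed number of tests
#'
#' Multiplies a p-value by the number of independent tests and caps at 1.
#' The pipeline's headline analyses use `m = 3` (three copy-number loci:
#' C4A, C4B, total C4).
#'
#' @param p p-value(s) in (0, 1].
#' @param m number of tests, `m >= 1`.
#' @return corrected p-value(s), `min(1, m * p)`.
#' @examples
#' bonferroni_correct(4.4e-5, 3)
#' @export
bonferroni_correct <- function(p, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop_c4("'m' must be a single integer >= 1")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_c4("'p' must lie in (0, 1]")
  pmin(1, m * p)
}
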