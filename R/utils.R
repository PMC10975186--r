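#' @keywords internal
"_PACKAGE"

# Shared input checks. All user-facing errors go through stop(call. = FALSE)
# so messages read as contract violations, not tracebacks.

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

check_times <- function(times) {
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times)))
    stop("`times` must be finite numeric hours", call. = FALSE)
  if (any(times < 0))
    stop("negative times are outside the model domain (hours since first dose)",
         call. = FALSE)
  invisible(as.numeric(times))
}

#' Molar amounts and molar dose ratios
#'
#' Helpers for expressing co-administered doses on the molar scale, e.g. the
#' piperacillin/tazobactam combination where a 16 g + 2 g daily dose
#' corresponds to 30.98 mmol + 6.66 mmol and a tazobactam:piperacillin molar
#' ratio of 0.2150.
#'
#' @param mg dose in milligrams.
#' @param mw molecular weight in g/mol.
#' @param mmol_num,mmol_den molar amounts (mmol) of the numerator and
#'   denominator drug.
#' @return `mg_to_mmol()` returns millimoles; `molar_ratio()` the
#'   dimensionless ratio `mmol_num / mmol_den`.
#' @examples
#' molar_ratio(6.66, 30.98)   # tazobactam : piperacillin
#' @export
molar_ratio <- function(mmol_num, mmol_den) {
  check_scalar(mmol_num, "mmol_num", nonneg = TRUE)
  check_scalar(mmol_den, "mmol_den", positive = TRUE)
  mmol_num / mmol_den
}

#' @rdname molar_ratio
#' @export
mg_to_mmol <- function(mg, mw) {
  check_scalar(mw, "mw", positive = TRUE)
  mg / mw
}

# Halton low-discrepancy sequence in [0,1)^d, used for the initial
# adaptive-grid candidate set. A seeded uniform shift (mod 1) randomizes the
# sequence while preserving its space-filling behaviour.
halton <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (dim > length(primes)) stop("halton: dimension too large", call. = FALSE)
  vandercorput <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  out <- matrix(0, n, dim)
  for (d in seq_len(dim))
    out[, d] <- vapply(seq_len(n), vandercorput, 0, base = primes[d])
  out
}
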