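## Canalization measures of Boolean functions: sensitivity and effective
## connectivity (prime-implicant input redundancy).

as_bool_fn <- function(f) {
  if (is.character(f)) return(boolean_function(f))
  if (is.list(f) && !is.null(f$tt)) {
    return(list(inputs = f$inputs %||% paste0("x", seq_len(log2(length(f$tt)))),
                tt = as.integer(f$tt)))
  }
  stop("expected an expression string or a list(inputs, tt)")
}

#' Average sensitivity of a Boolean function
#'
#' The mean number of single-input flips that change the function's output,
#' averaged over all input states:
#' `(1/2^k) * sum_x #\{i : f(x) != f(x with bit i flipped)\}`.
#'
#' @param f Expression string (e.g. `"A | B & C"`) or `list(inputs, tt)`.
#' @return Numeric scalar in `[0, k]`.
#' @export
sensitivity <- function(f) {
  f <- as_bool_fn(f)
  k <- length(f$inputs)
  if (k > 16L) stop("sensitivity limited to 16 inputs")
  if (k == 0L) return(0)
  idx <- 0:(2L^k - 1L)
  s <- 0
  for (j in seq_len(k)) {
    flipped <- bitwXor(idx, 2L^(j - 1L))
    s <- s + mean(f$tt != f$tt[flipped + 1L])
  }
  s
}

## prime implicants of a set of minterms over k inputs (Quine-McCluskey):
## returns a data frame with columns `bits` (values on specified positions)
## and `mask` (bit set = wildcard '#')
qm_primes <- function(minterms, k) {
  if (length(minterms) == 0L) {
    return(data.frame(bits = integer(0), mask = integer(0)))
  }
  cur <- unique(data.frame(bits = as.integer(minterms), mask = 0L))
  primes <- list()
  while (nrow(cur) > 0L) {
    combined <- rep(FALSE, nrow(cur))
    nxt <- list()
    for (i in seq_len(nrow(cur))) {
      for (j in seq_len(nrow(cur))) {
        if (i >= j) next
        if (cur$mask[i] != cur$mask[j]) next
        d <- bitwXor(cur$bits[i], cur$bits[j])
        if (d != 0L && bitwAnd(d, d - 1L) == 0L) {  # differ in exactly one bit
          combined[i] <- TRUE; combined[j] <- TRUE
          nxt[[length(nxt) + 1L]] <- c(bitwAnd(cur$bits[i], bitwNot(d)),
                                       bitwOr(cur$mask[i], d))
        }
      }
    }
    primes[[length(primes) + 1L]] <- cur[!combined, , drop = FALSE]
    if (length(nxt) == 0L) break
    m <- unique(do.call(rbind, nxt))
    cur <- data.frame(bits = m[, 1L], mask = m[, 2L])
  }
  out <- unique(do.call(rbind, primes))
  rownames(out) <- NULL
  out
}

popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Effective connectivity of a Boolean function
#'
#' The in-degree `k` minus the mean input redundancy: for each input state
#' `x`, the redundancy `k_r(x)` is the average number of wildcard positions
#' over all prime implicants (of the function's ON-set if `f(x) = 1`, of the
#' OFF-set otherwise) that cover `x`; effective connectivity is
#' `k - mean(k_r)`. A value well below `k` indicates canalization: few inputs
#' typically suffice to determine the output.
#'
#' @param f Expression string or `list(inputs, tt)`.
#' @return Numeric scalar in `[0, k]`.
#' @export
effective_connectivity <- function(f) {
  f <- as_bool_fn(f)
  k <- length(f$inputs)
  if (k > 12L) stop("effective connectivity limited to 12 inputs")
  if (k == 0L) return(0)
  on <- which(f$tt == 1L) - 1L
  off <- which(f$tt == 0L) - 1L
  p_on <- qm_primes(on, k)
  p_off <- qm_primes(off, k)
  wc_on <- popcount(p_on$mask)
  wc_off <- popcount(p_off$mask)
  kr <- vapply(0:(2L^k - 1L), function(x) {
    if (f$tt[x + 1L] == 1L) {
      cov <- bitwAnd(x, bitwNot(p_on$mask)) == p_on$bits
      mean(wc_on[cov])
    } else {
      cov <- bitwAnd(x, bitwNot(p_off$mask)) == p_off$bits
      mean(wc_off[cov])
    }
  }, numeric(1))
  k - mean(kr)
}

#' Ensemble canalization of random k-input Boolean functions
#'
#' Mean sensitivity and mean effective connectivity of truth tables whose
#' `2^k` entries are i.i.d. Bernoulli(`p`). In `"exact"` mode all `2^(2^k)`
#' truth tables are enumerated and weighted by `p^ones * (1-p)^zeros`
#' (limited to `k <= 4`); in `"sample"` mode `n` tables are drawn and means
#' with standard errors are reported. At the critical bias, `2*k*p*(1-p) = 1`,
#' the exact mean sensitivity equals 1.
#'
#' @param k Number of inputs.
#' @param p Bias (probability of output 1); defaults to [critical_p()] of
#'   `k`.
#' @param mode `"exact"` or `"sample"`.
#' @param n Sample size for `"sample"` mode.
#' @param seed Optional RNG seed for `"sample"` mode.
#' @param essential_only Condition on all `k` inputs being essential.
#' @return List with `mean_sensitivity`, `mean_effective_connectivity`, and
#'   in sample mode their standard errors.
#' @export
ensemble_canalization <- function(k, p = critical_p(k),
                                  mode = c("exact", "sample"),
                                  n = 10000L, seed = NULL,
                                  essential_only = FALSE) {
  mode <- match.arg(mode)
  nbits <- 2L^k
  if (mode == "exact") {
    if (k > 4L) stop("exact mode limited to k <= 4")
    ncodes <- 2L^nbits
    wts <- numeric(ncodes)
    sens <- numeric(ncodes)
    ec <- numeric(ncodes)
    for (code in 0:(ncodes - 1L)) {
      tt <- bitwAnd(bitwShiftR(code, 0:(nbits - 1L)), 1L)
      if (essential_only && !all(tt_essential(tt, k))) {
        wts[code + 1L] <- 0
        next
      }
      ones <- sum(tt)
      wts[code + 1L] <- p^ones * (1 - p)^(nbits - ones)
      fn <- list(inputs = paste0("x", seq_len(k)), tt = tt)
      sens[code + 1L] <- sensitivity(fn)
      ec[code + 1L] <- effective_connectivity(fn)
    }
    wts <- wts / sum(wts)
    list(mean_sensitivity = sum(wts * sens),
         mean_effective_connectivity = sum(wts * ec))
  } else {
    if (!is.null(seed)) set.seed(seed)
    sens <- numeric(n); ec <- numeric(n)
    i <- 0L
    while (i < n) {
      tt <- stats::rbinom(nbits, 1L, p)
      if (essential_only && !all(tt_essential(tt, k))) next
      i <- i + 1L
      fn <- list(inputs = paste0("x", seq_len(k)), tt = tt)
      sens[i] <- sensitivity(fn)
      ec[i] <- effective_connectivity(fn)
    }
    list(mean_sensitivity = mean(sens),
         mean_effective_connectivity = mean(ec),
         se_sensitivity = stats::sd(sens) / sqrt(n),
         se_effective_connectivity = stats::sd(ec) / sqrt(n))
  }
}
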