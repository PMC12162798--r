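## Critical N-K random Boolean network ensembles, fixture network families,
## and the package's large-scale experiments at desk scale.

#' Critical bias of a K-input random Boolean function ensemble
#'
#' The order-to-chaos transition of N-K random Boolean networks occurs at
#' `2*K*p*(1-p) = 1`. For `K >= 2` the equation has two roots
#' `(1 +/- sqrt(1 - 2/K)) / 2`; the smaller one is returned by default (the
#' two are statistically equivalent by output negation symmetry). `K = 1`
#' admits no real root and conventionally uses `p = 0.5` (maximizing
#' `2*p*(1-p)`).
#'
#' @param K In-degree, `K >= 1`.
#' @param root `"lower"` (default), `"upper"` or `"both"`.
#' @return Numeric scalar (or length-2 vector for `"both"`).
#' @export
critical_p <- function(K, root = c("lower", "upper", "both")) {
  root <- match.arg(root)
  stopifnot(K >= 1)
  if (K < 2) {
    p <- c(0.5, 0.5)
  } else {
    s <- sqrt(1 - 2 / K)
    p <- c((1 - s) / 2, (1 + s) / 2)
  }
  switch(root, lower = p[1], upper = p[2], both = p)
}

#' Configuration of an ensemble experiment
#'
#' @param N Number of variables.
#' @param K Number of (distinct) regulators drawn per variable.
#' @param p Truth-table bias; defaults to the critical bias of `K`.
#' @param seed RNG seed; every experiment result is bit-identical under a
#'   fixed seed and configuration.
#' @param samples Number of networks to draw (fixed-sample stop rule).
#' @param maa_target Alternative stop rule: sample until this many networks
#'   with at least one MAA have been found.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(N, K, p = critical_p(K), seed = 1L,
                            samples = NULL, maa_target = NULL) {
  stopifnot(K >= 1, K <= N, p > 0, p < 1)
  structure(list(N = as.integer(N), K = as.integer(K), p = p,
                 seed = as.integer(seed), samples = samples,
                 maa_target = maa_target),
            class = "ensemble_config")
}

#' Generate one critical N-K random Boolean network
#'
#' Each node receives `K` regulators drawn uniformly without replacement
#' from all `N` nodes (self-regulation allowed); the `2^K` truth-table
#' entries are i.i.d. Bernoulli(`p`). Normalization prunes non-essential
#' inputs; the attribute `"pruned"` records how many were dropped.
#'
#' @param N,K,p Ensemble parameters (see [ensemble_config()]).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so that experiments are reproducible from a single seed).
#' @return A `boolean_network`.
#' @export
generate_critical_rbn <- function(N, K, p = critical_p(K), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vars <- paste0("x", seq_len(N))
  fns <- vector("list", N)
  names(fns) <- vars
  for (i in seq_len(N)) {
    regs <- sort(sample.int(N, K))
    fns[[i]] <- list(inputs = vars[regs],
                     tt = stats::rbinom(2L^K, 1L, p))
  }
  raw_inputs <- N * K
  net <- normalize_network(
    structure(list(variables = vars, functions = fns),
              class = "boolean_network"))
  attr(net, "pruned") <- raw_inputs -
    sum(vapply(net$functions, function(f) length(f$inputs), integer(1)))
  net
}

#' The star-shaped MAA family
#'
#' The canonical realization on `N >= 2` variables has
#' `f_i(x) = 1` iff the Hamming weight of `x` is 0 or `N` (every update
#' function is the consensus indicator of the all-zeros or all-ones state;
#' at `N = 2` this is XNOR). Every network
#' in the family has a point attractor at the all-ones state, a
#' motif-avoidant attractor consisting of the zero state plus all `N`
#' weight-1 states (`N + 1` states in a star shape), and a complete
#' interaction graph with `N^2` edges. `N = 2` is the unique two-variable
#' MAA network (both functions XNOR). The minimal number of delays that
#' eliminates the MAA is `floor(N^2 / 4)`.
#'
#' @param N Number of variables, between 2 and 26.
#' @return A `boolean_network` with variables `A`, `B`, ...
#' @export
star_network <- function(N) {
  if (N < 2L) stop("star family requires N >= 2")
  if (N > 26L) stop("star family limited to 26 variables")
  vars <- LETTERS[seq_len(N)]
  weights <- popcount(0:(2L^N - 1L))
  tt <- as.integer(weights == 0L | weights == N)
  fns <- lapply(stats::setNames(vars, vars), function(v) {
    list(inputs = vars, tt = tt)
  })
  boolean_network(vars, fns)
}

#' Wilson score confidence interval
#'
#' The 95% interval with center `(m + 2) / (n + 4)` and half-width
#' `(2 / (n + 4)) * sqrt(1 + n * var)`, clipped to `[0, 1]`. For `n = 230`,
#' `m = 0`, `var = 0` the upper endpoint is about 1.7%.
#'
#' @param n Sample count.
#' @param m Positive count.
#' @param var Sample variance of the indicator (defaults to the binomial
#'   plug-in `phat * (1 - phat)`).
#' @return Named numeric vector `c(low = , high = )`.
#' @export
wilson_interval <- function(n, m, var = (m / n) * (1 - m / n)) {
  if (n < 1 || m < 0 || m > n || var < 0) stop("invalid counts")
  center <- (m + 2) / (n + 4)
  half <- (2 / (n + 4)) * sqrt(1 + n * var)
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Enumerate all two-variable networks and their MAA equivalence classes
#'
#' All 256 two-variable Boolean networks are enumerated, grouped by the
#' action of variable permutation combined with per-variable negation (state
#' conjugation, which preserves asynchronous dynamics up to relabeling), and
#' each network is tested for an asynchronous MAA.
#'
#' @return List with `n_networks` (256), `n_maa_networks`,
#'   `n_maa_classes`, `representatives` (one `boolean_network` per flagged
#'   class) and `maa_flags` (per-network logical, in enumeration order).
#' @export
enumerate_2var_classes <- function() {
  vars <- c("A", "B")
  tts <- function(code) bitwAnd(bitwShiftR(code, 0:3), 1L)
  net_of <- function(a, b) {
    boolean_network(vars, list(A = list(inputs = vars, tt = tts(a)),
                               B = list(inputs = vars, tt = tts(b))))
  }
  ## transform raw truth-table pair under permutation `perm` (of 1:2) and
  ## negation mask `cneg` (length 2, in {0,1}): state conjugation
  transform_pair <- function(a, b, perm, cneg) {
    raw <- list(tts(a), tts(b))
    newtt <- function(j) {
      vapply(0:3, function(y) {
        ybits <- bitwAnd(bitwShiftR(y, 0:1), 1L)
        ## x = phi^{-1}(y): x_{perm[i]} = y_i xor cneg_i
        xbits <- integer(2)
        xbits[perm] <- bitwXor(ybits, cneg)
        x <- xbits[1] + 2L * xbits[2]
        bitwXor(raw[[perm[j]]][x + 1L], cneg[j])
      }, integer(1))
    }
    c(sum(newtt(1) * 2L^(0:3)), sum(newtt(2) * 2L^(0:3)))
  }
  perms <- list(1:2, 2:1)
  negs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  maa_flag <- logical(256)
  canon <- integer(256)
  for (a in 0:15) {
    for (b in 0:15) {
      i <- a * 16L + b + 1L
      maa_flag[i] <- length(find_maas(net_of(a, b))) > 0L
      keys <- integer(0)
      for (pm in perms) {
        for (cn in negs) {
          tp <- transform_pair(a, b, pm, cn)
          keys <- c(keys, tp[1] * 16L + tp[2])
        }
      }
      canon[i] <- min(keys)
    }
  }
  ## sanity: the MAA flag is a class invariant
  for (key in unique(canon)) {
    flags <- maa_flag[canon == key]
    if (length(unique(flags)) != 1L) stop("MAA flag not class-invariant")
  }
  flagged <- unique(canon[maa_flag])
  reps <- lapply(flagged, function(key) {
    net_of(key %/% 16L, key %% 16L)
  })
  list(n_networks = 256L,
       n_maa_networks = sum(maa_flag),
       n_maa_classes = length(flagged),
       class_keys = sort(flagged),
       representatives = reps,
       maa_flags = maa_flag,
       canon = canon)
}

## ---- experiments -----------------------------------------------------------

new_experiment_result <- function(samples, positives, skipped, records,
                                  extra = list()) {
  denom <- samples - skipped
  freq <- if (denom > 0) positives / denom else NA_real_
  res <- c(list(samples = samples, positives = positives, skipped = skipped,
                frequency = freq,
                wilson = if (denom > 0) {
                  wilson_interval(denom, positives)
                } else c(low = NA_real_, high = NA_real_),
                records = records),
           extra)
  structure(res, class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Ensemble experiment:", x$samples, "samples,",
      x$positives, "MAA-positive,", x$skipped, "skipped\n")
  cat(sprintf("  frequency %.5f  (Wilson 95%%: [%.5f, %.5f])\n",
              x$frequency, x$wilson["low"], x$wilson["high"]))
  for (nm in setdiff(names(x), c("samples", "positives", "skipped",
                                 "frequency", "wilson", "records"))) {
    if (is.numeric(x[[nm]]) && length(x[[nm]]) == 1L) {
      cat(sprintf("  %s: %.4f\n", nm, x[[nm]]))
    }
  }
  invisible(x)
}

#' MAA frequency in a critical RBN ensemble
#'
#' Samples networks from the configured ensemble and reports the fraction
#' that contain at least one motif-avoidant attractor, with its Wilson 95%
#' interval. Networks exceeding the explicit-STG size guard are counted as
#' skipped and excluded from the denominator.
#'
#' @param cfg An [ensemble_config()] with a `samples` stop rule.
#' @return An `experiment_result`.
#' @export
maa_frequency_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "ensemble_config"), !is.null(cfg$samples))
  set.seed(cfg$seed)
  positive <- logical(cfg$samples)
  skipped <- logical(cfg$samples)
  for (i in seq_len(cfg$samples)) {
    net <- generate_critical_rbn(cfg$N, cfg$K, cfg$p)
    if (n_vars(net) > MAX_STG_VARS) {
      skipped[i] <- TRUE
      next
    }
    positive[i] <- length(find_maas(net)) > 0L
  }
  new_experiment_result(cfg$samples, sum(positive), sum(skipped),
                        data.frame(sample = seq_len(cfg$samples),
                                   positive = positive, skipped = skipped))
}

#' MAA frequency and size statistics of maximally reduced critical RBNs
#'
#' Each sampled network is maximally reduced by node deletion; the reduced
#' network is tested for MAAs. Reports the reduced-network MAA frequency,
#' the mean reduced size (empty networks count as size 0 and as MAA-free)
#' with its standard error, and the mean number of interactions per variable
#' among non-empty reduced networks.
#'
#' @param cfg An [ensemble_config()] with a `samples` stop rule.
#' @return An `experiment_result` with extra fields `mean_reduced_size`,
#'   `se_reduced_size`, `mean_interactions_per_variable`.
#' @export
reduction_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "ensemble_config"), !is.null(cfg$samples))
  set.seed(cfg$seed)
  size <- integer(cfg$samples)
  ipv <- rep(NA_real_, cfg$samples)
  positive <- logical(cfg$samples)
  skipped <- logical(cfg$samples)
  for (i in seq_len(cfg$samples)) {
    net <- generate_critical_rbn(cfg$N, cfg$K, cfg$p)
    tr <- reduce_max(net)
    if (tr$skipped || n_vars(tr$final) > MAX_STG_VARS) {
      skipped[i] <- TRUE
      next
    }
    red <- tr$final
    size[i] <- n_vars(red)
    if (size[i] > 0L) {
      ig <- interaction_graph(red)
      ipv[i] <- nrow(ig$edges) / size[i]
      positive[i] <- length(find_maas(red)) > 0L
    }
  }
  ok <- !skipped
  new_experiment_result(
    cfg$samples, sum(positive), sum(skipped),
    data.frame(sample = seq_len(cfg$samples), reduced_size = size,
               interactions_per_variable = ipv, positive = positive,
               skipped = skipped),
    extra = list(
      mean_reduced_size = mean(size[ok]),
      se_reduced_size = stats::sd(size[ok]) / sqrt(sum(ok)),
      mean_interactions_per_variable = mean(ipv[ok], na.rm = TRUE)))
}

#' Single-delay fragility of MAAs in a critical RBN ensemble
#'
#' Samples networks until `maa_target` MAA-containing networks are found;
#' for every MAA, runs [single_delay_survey()] and records how many
#' single-edge delay extensions eliminate motif avoidance, whether the MAA
#' resists every single delay, and whether the two-variable MAA pattern is
#' embedded in it.
#'
#' @param cfg An [ensemble_config()].
#' @param maa_target Number of MAA-containing networks to collect.
#' @param max_samples Hard cap on the number of sampled networks.
#' @return An `experiment_result` with extra fields `resistant_fraction`
#'   and `success_histogram`; `records` has one row per MAA.
#' @export
fragility_experiment <- function(cfg, maa_target = 100L,
                                 max_samples = 1e6) {
  stopifnot(inherits(cfg, "ensemble_config"))
  set.seed(cfg$seed)
  samples <- 0L
  found <- 0L
  skipped <- 0L
  recs <- list()
  while (found < maa_target && samples < max_samples) {
    samples <- samples + 1L
    net <- generate_critical_rbn(cfg$N, cfg$K, cfg$p)
    if (n_vars(net) > MAX_STG_VARS) {
      skipped <- skipped + 1L
      next
    }
    reports <- find_maas(net)
    if (length(reports) == 0L) next
    found <- found + 1L
    for (rep_i in seq_along(reports)) {
      rp <- reports[[rep_i]]
      survey <- tryCatch(single_delay_survey(net, rp), error = function(e) NULL)
      if (is.null(survey)) next
      recs[[length(recs) + 1L]] <- data.frame(
        sample = samples, maa = rep_i,
        n_edges_surveyed = nrow(survey),
        n_success = attr(survey, "n_success"),
        resistant = attr(survey, "n_success") == 0L,
        embedded_2var = detect_embedded_2var(net, rp))
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(sample = integer(0), maa = integer(0),
               n_edges_surveyed = integer(0), n_success = integer(0),
               resistant = logical(0), embedded_2var = logical(0))
  new_experiment_result(
    samples, found, skipped, records,
    extra = list(
      maa_networks = found,
      resistant_fraction = if (nrow(records) > 0) mean(records$resistant)
                           else NA_real_,
      success_histogram = if (nrow(records) > 0) table(records$n_success)
                          else table(integer(0))))
}

#' Detect an embedded two-variable MAA pattern
#'
#' Tests whether the four-state plane sub-graph of the prototypical
#' two-variable MAA (a hub with mutual transitions to two one-bit
#' neighbours) can be embedded in the given MAA: two oscillating variables
#' `u`, `v` and an attractor state `h` such that `h`, `h` with `u` flipped
#' and `h` with `v` flipped all belong to the attractor and are connected by
#' the transitions `h <-> h^u` and `h <-> h^v` (negation of `u`, `v` is
#' absorbed by the choice of hub corner).
#'
#' @param net A `boolean_network`.
#' @param report An `maa_report` with `is_motif_avoidant = TRUE`.
#' @return Logical scalar.
#' @export
detect_embedded_2var <- function(net, report) {
  if (!inherits(report, "maa_report") || !report$is_motif_avoidant) {
    stop("report is not a motif-avoidant attractor")
  }
  A <- report$attractor$states
  osc <- match(report$attractor$oscillating, net$variables)
  if (length(osc) < 2L) return(FALSE)
  ## transitions inside the attractor
  has_edge <- function(s, t) {
    i <- which(bitwXor(s, t) == 2L^(seq_len(n_vars(net)) - 1L))
    eval_var_assignment(net, net$variables[i],
                        state_bit(s, seq_len(n_vars(net)))) == state_bit(t, i)
  }
  for (h in A) {
    for (ui in seq_along(osc)) {
      a <- bitwXor(h, 2L^(osc[ui] - 1L))
      if (!(a %in% A) || !has_edge(h, a) || !has_edge(a, h)) next
      for (vi in seq_along(osc)) {
        if (vi == ui) next
        b <- bitwXor(h, 2L^(osc[vi] - 1L))
        if ((b %in% A) && has_edge(h, b) && has_edge(b, h)) return(TRUE)
      }
    }
  }
  FALSE
}
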