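# Statistical significance, covariation power, and the four-way
# structure-evidence classification.
#
# E-values are empirical: the expected number of column pairs per null
# alignment scoring at least as high as the observed pair.  Empirical
# counts alone cannot resolve E below 1/M, so scores beyond the largest
# pooled null score are extrapolated with an exponential tail anchored at
# the pooled maximum (where E = 1/M by construction, keeping the two
# regimes continuous); the decay rate is a least-squares fit to the
# log-survival of the top 1% of pooled scores.  A mean-excess MLE on a
# wider tail slice is badly biased here: the null G-test tail is lighter
# than exponential until far out, and the bulk near the threshold drags
# the fitted rate down ~1.6x.

#' Build a null score distribution for an alignment
#'
#' Generates a null ensemble, scores every null with the same statistic and
#' APC treatment as the input, and pools all column-pair scores.
#'
#' @param aln source `rna_alignment`.
#' @param tree rooted tree (default [build_tree()]).
#' @param n_nulls number of null alignments.
#' @param seed master seed.
#' @param stat `"gtest"` or `"mi"`.  RAF is refused: it mixes covariation
#'   with conservation, which the conservation-destroying nulls turn into
#'   artifactual significance.
#' @param use_apc score with the average product correction (default).
#' @param gap_preserving passed to the null generator.
#' @return list of class `null_distribution`: sorted `pooled` scores, `M`
#'   (number of nulls), `P` (pairs per alignment), `stat`, `use_apc`, and
#'   the exponential tail fit (`tail_thr`, `tail_rate`, `tail_k`).
#' @export
null_distribution <- function(aln, tree = NULL, n_nulls = 20L, seed = NULL,
                              stat = c("gtest", "mi"), use_apc = TRUE,
                              gap_preserving = TRUE) {
  stat <- match.arg(stat)
  if (is.null(tree)) tree <- build_tree(aln)
  ens <- null_ensemble(aln, tree, n_nulls = n_nulls, seed = seed,
                       gap_preserving = gap_preserving)
  pooled <- unlist(lapply(ens, function(nl) {
    sm <- score_matrix(nl, stat = stat)
    v <- if (use_apc) sm$apc else sm$raw
    v[upper.tri(v)]
  }))
  pooled <- sort(pooled[is.finite(pooled)])
  P <- n_col(aln) * (n_col(aln) - 1L) / 2L
  # tail decay: LS fit of log-survival over the top 1% of pooled scores
  k <- max(20L, ceiling(0.01 * length(pooled)))
  k <- min(k, length(pooled))
  tail_scores <- pooled[(length(pooled) - k + 1L):length(pooled)]
  rate <- Inf
  if (length(unique(tail_scores)) >= 3L) {
    logsurv <- log(seq(length(tail_scores), 1L))
    fit <- stats::lm.fit(cbind(1, tail_scores), logsurv)
    slope <- fit$coefficients[2]
    if (is.finite(slope) && slope < 0) rate <- -slope
  }
  out <- list(pooled = pooled, M = n_nulls, P = P, stat = stat,
              use_apc = use_apc, gap_preserving = gap_preserving,
              tail_rate = unname(rate), tail_k = k,
              pooled_max = pooled[length(pooled)])
  class(out) <- "null_distribution"
  out
}

#' Empirical E-value of covariation scores
#'
#' `E = (# pooled null scores >= score) / M`.  Scores exceeding every
#' pooled null score use the fitted exponential tail, anchored so that
#' `E = 1/M` at the pooled maximum.  A score below the null minimum
#' returns `P`, the number of pairs per alignment.
#'
#' @param score numeric vector of scores (same statistic and APC treatment
#'   as the null distribution).
#' @param nd a `null_distribution`.
#' @param stat statistic the scores were computed with; must match `nd`.
#' @return numeric vector of E-values (`>= 0`).
#' @export
evalue <- function(score, nd, stat = nd$stat) {
  if (!identical(stat, nd$stat))
    stop("statistic mismatch: scores are ", stat, ", null is ", nd$stat)
  pooled <- nd$pooled
  n <- length(pooled)
  # count of pooled >= s  =  n - (# pooled < s)
  cnt <- n - findInterval(score, pooled, left.open = TRUE)
  E <- cnt / nd$M
  beyond <- cnt == 0L
  if (any(beyond)) {
    rate <- if (is.finite(nd$tail_rate)) nd$tail_rate else 0
    E[beyond] <- (1 / nd$M) *
      exp(-(score[beyond] - nd$pooled_max) * rate)
  }
  E
}

#' Score, test and annotate every column pair of an alignment
#'
#' Computes APC-corrected scores, empirical E-values against the null
#' distribution, per-pair substitution counts from a Fitch sample of the
#' input, and covariation power.
#'
#' @param aln an `rna_alignment`.
#' @param nd a `null_distribution` for this alignment (built if `NULL`).
#' @param tree rooted tree (built if `NULL`).
#' @param stat `"gtest"` or `"mi"`.
#' @param threshold significance cutoff on the E-value (default 0.05).
#' @param seed master seed (nulls and the Fitch sample).
#' @param power_curves list with elements `single`, `double`
#'   ([power_curve] objects; default: the shipped calibration).
#' @param ... passed to [null_distribution()] when `nd` is `NULL`.
#' @return data frame of class `pair_evidence`, one row per column pair
#'   `i < j`, sorted by E-value then `(i, j)`: `raw`, `score`
#'   (APC-corrected), `evalue`, `significant`, `subs_single`,
#'   `subs_double`, `power_single`, `power_double`, `adjacent`
#'   (`j - i <= 3`; excluded from structure-evidence summaries, reported
#'   for within-codon diagnostics), `in_structure`.
#' @export
significant_pairs <- function(aln, nd = NULL, tree = NULL,
                              stat = c("gtest", "mi"), threshold = 0.05,
                              seed = NULL, power_curves = NULL, ...) {
  stat <- match.arg(stat)
  if (is.null(tree)) tree <- build_tree(aln)
  if (is.null(nd))
    nd <- null_distribution(aln, tree, seed = seed, stat = stat, ...)
  sm <- score_matrix(aln, stat = stat)
  v <- if (nd$use_apc) sm$apc else sm$raw
  L <- n_col(aln)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  scores <- v[ut]
  ev <- evalue(scores, nd, stat = stat)
  smp <- fitch_sample(aln, tree,
                      seed = if (is.null(seed)) NULL else seed + 1L)
  map <- count_substitutions(smp)
  dbl <- crossprod(map$incidence * 1)    # branches with events at both cols
  if (is.null(power_curves))
    power_curves <- list(single = default_power_curve("single"),
                         double = default_power_curve("double"))
  subs_s <- map$s_col_res[ut[, 1]] + map$s_col_res[ut[, 2]]
  subs_d <- dbl[ut]
  out <- data.frame(
    i = ut[, 1], j = ut[, 2],
    raw = sm$raw[ut], score = scores, evalue = ev,
    significant = ev < threshold,
    subs_single = subs_s, subs_double = subs_d,
    power_single = power_value(power_curves$single, subs_s),
    power_double = power_value(power_curves$double, subs_d),
    adjacent = (ut[, 2] - ut[, 1]) <= 3L)
  out$in_structure <- FALSE
  if (!is.null(aln$structure) && nrow(aln$structure))
    out$in_structure <- paste(out$i, out$j) %in%
      paste(aln$structure$i, aln$structure$j)
  out <- out[order(out$evalue, out$i, out$j), ]
  rownames(out) <- NULL
  attr(out, "stat") <- stat
  attr(out, "threshold") <- threshold
  attr(out, "submap") <- map
  class(out) <- c("pair_evidence", class(out))
  out
}

# ---- covariation power -----------------------------------------------------

#' Fit a covariation power curve
#'
#' Isotonic (monotone non-decreasing) regression of significance outcome on
#' substitution count, with the value at 0 substitutions forced to 0: a
#' pair with no substitutions carries no information, whatever the training
#' data says.
#'
#' @param subs substitution counts of training base pairs.
#' @param significant logical (or 0/1): was the pair significantly
#'   covarying.
#' @param mode `"single"` or `"double"` substitution counting.
#' @return object of class `power_curve`: `x` (substitution levels), `y`
#'   (power, non-decreasing in `[0, 1]`), `mode`.
#' @export
fit_power_curve <- function(subs, significant, mode = c("single", "double")) {
  mode <- match.arg(mode)
  stopifnot(length(subs) == length(significant))
  if (length(unique(subs)) < 2L)
    stop("degenerate training set: a single substitution level")
  ord <- order(subs)
  iso <- stats::isoreg(subs[ord], as.numeric(significant)[ord])
  fit <- data.frame(x = subs[ord], y = iso$yf)
  agg <- stats::aggregate(y ~ x, data = fit, FUN = max)
  x <- agg$x; y <- pmin(pmax(agg$y, 0), 1)
  if (x[1] != 0) { x <- c(0, x); y <- c(0, y) }
  y[1] <- 0
  y <- cummax(y)
  out <- list(x = x, y = y, mode = mode)
  class(out) <- "power_curve"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a power curve at substitution counts
#'
#' Linear interpolation between fitted levels; flat beyond the largest
#' training level; 0 at 0 substitutions.
#'
#' @param curve a `power_curve`.
#' @param n substitution counts.
#' @return power values in `[0, 1]`.
#' @export
power_value <- function(curve, n) {
  stats::approx(curve$x, curve$y, xout = n, rule = 2)$y
}

# shipped default calibration, read once per session
.power_env <- new.env(parent = emptyenv())

#' Shipped default power curve
#'
#' Calibrated on the package's own structure-constrained simulations
#' (see `scripts/calibrate_power.R`); users analysing a trusted structural
#' collection should refit with [fit_power_curve()].
#'
#' @param mode `"single"` or `"double"`.
#' @return a `power_curve`.
#' @export
default_power_curve <- function(mode = c("single", "double")) {
  mode <- match.arg(mode)
  key <- paste0("curve_", mode)
  if (is.null(.power_env[[key]])) {
    path <- system.file("extdata", "power_default.tsv", package = "rnacov")
    if (!nzchar(path)) stop("shipped power calibration not found")
    tab <- utils::read.delim(path)
    tab <- tab[tab$mode == mode, ]
    out <- list(x = tab$subs, y = tab$power, mode = mode)
    class(out) <- "power_curve"
    .power_env[[key]] <- out
  }
  .power_env[[key]]
}

#' Expected number of covarying pairs under a proposed structure
#'
#' Sum over the proposed base pairs of the power at that pair's observed
#' substitution count.
#'
#' @param pairs data frame with columns `i`, `j` (the proposed structure).
#' @param map a `substitution_map` for the alignment.
#' @param curve a `power_curve`.
#' @return expected count (numeric scalar).
#' @export
expected_covarying <- function(pairs, map, curve) {
  if (!nrow(pairs)) return(0)
  counts <- vapply(seq_len(nrow(pairs)), function(k) {
    pc <- pair_substitution_counts(map, pairs$i[k], pairs$j[k])
    unname(pc[curve$mode])
  }, numeric(1))
  sum(power_value(curve, counts))
}

# ---- classification --------------------------------------------------------

#' Four-way structure-evidence classification
#'
#' `STRUCTURAL` requires at least 3 significantly covarying base pairs.
#' Otherwise: `CANNOT_TELL` when the expected covarying count (single-subs
#' power) is at most 5; `NEGATIVE` when the double-subs expectation is at
#' least 8; `INCONSISTENT_POWER` when single-subs power is high
#' (expected `>= 8`) but double-subs power is low (expected `<= 5`),
#' indicating an alignment that does not support the proposed structure;
#' `INCONCLUSIVE` otherwise.
#'
#' @param observed number of significantly covarying proposed pairs.
#' @param expected_single expected covarying count under single-subs power.
#' @param expected_double expected covarying count under double-subs power.
#' @return list of class `structure_call` with `call` plus the inputs.
#' @export
classify <- function(observed, expected_single, expected_double) {
  stopifnot(observed >= 0)
  call <- if (observed >= 3) "STRUCTURAL"
  else if (expected_single <= 5) "CANNOT_TELL"
  else if (expected_double >= 8) "NEGATIVE"
  else if (expected_single >= 8 && expected_double <= 5) "INCONSISTENT_POWER"
  else "INCONCLUSIVE"
  out <- list(call = call, observed = observed,
              expected_single = expected_single,
              expected_double = expected_double)
  class(out) <- "structure_call"
  out
}

#' @export
print.structure_call <- function(x, ...) {
  cat(sprintf("%s (observed %d covarying pairs; expected %.1f single-subs / %.1f double-subs)\n",
              x$call, x$observed, x$expected_single, x$expected_double))
  invisible(x)
}

# ---- top-level pipeline ----------------------------------------------------

#' Full covariation-evidence analysis of an alignment
#'
#' Builds (or accepts) a tree, synthesizes null alignments, scores all
#' column pairs, assigns E-values and power, and classifies the alignment.
#' Adjacent pairs (`j - i <= 3`) are excluded from the structure-evidence
#' summary but kept in the pair table for within-codon diagnostics.
#'
#' @param aln an `rna_alignment` (consensus structure used if present).
#' @param n_nulls number of null alignments (default 20; raised adaptively
#'   until the pooled null has at least 10x more scores than alignment
#'   pairs -- always satisfied at the default since every null contributes
#'   all pairs).
#' @param stat `"gtest"` (default) or `"mi"`.
#' @param evalue_cutoff significance threshold (default 0.05).
#' @param gap_preserving null mode (default `TRUE`).
#' @param seed master seed.
#' @param tree optional user tree (overrides the built tree).
#' @param power_curves optional list(single=, double=) of `power_curve`s.
#' @return list of class `rnacov_analysis`: `pairs` (the
#'   [significant_pairs()] table), `call` (a `structure_call`, or `NULL`
#'   when the alignment has no consensus structure), `n_significant`
#'   (non-adjacent significant pairs), `nd`, `tree`.
#' @export
analyze <- function(aln, n_nulls = 20L, stat = c("gtest", "mi"),
                    evalue_cutoff = 0.05, gap_preserving = TRUE,
                    seed = NULL, tree = NULL, power_curves = NULL) {
  stat <- match.arg(stat)
  if (is.null(tree)) tree <- build_tree(aln)
  nd <- null_distribution(aln, tree, n_nulls = n_nulls, seed = seed,
                          stat = stat, gap_preserving = gap_preserving)
  pairs <- significant_pairs(aln, nd = nd, tree = tree, stat = stat,
                             threshold = evalue_cutoff, seed = seed,
                             power_curves = power_curves)
  n_sig <- sum(pairs$significant & !pairs$adjacent)
  call <- NULL
  if (!is.null(aln$structure) && nrow(aln$structure)) {
    struct <- aln$structure[!aln$structure$short_range, , drop = FALSE]
    map <- attr(pairs, "submap")
    if (is.null(power_curves))
      power_curves <- list(single = default_power_curve("single"),
                           double = default_power_curve("double"))
    obs <- sum(pairs$significant & pairs$in_structure & !pairs$adjacent)
    exp_s <- expected_covarying(struct, map, power_curves$single)
    exp_d <- expected_covarying(struct, map, power_curves$double)
    call <- classify(obs, exp_s, exp_d)
  }
  out <- list(pairs = pairs, call = call, n_significant = n_sig,
              nd = nd, tree = tree, stat = stat,
              evalue_cutoff = evalue_cutoff)
  class(out) <- "rnacov_analysis"
  out
}

#' @export
print.rnacov_analysis <- function(x, ...) {
  cat(sprintf("rnacov analysis (%s, E < %g, %d nulls)\n", x$stat,
              x$evalue_cutoff, x$nd$M))
  cat(sprintf("  %d significant non-adjacent pair(s)\n", x$n_significant))
  if (!is.null(x$call)) print(x$call)
  invisible(x)
}

#' Write the per-pair table and alignment-level call to files
#'
#' @param analysis an `rnacov_analysis`.
#' @param tsv path for the per-pair TSV (1-based columns).
#' @param json optional path for the alignment-level JSON summary.
#' @return invisibly, the analysis.
#' @export
write_analysis <- function(analysis, tsv, json = NULL) {
  utils::write.table(analysis$pairs, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json)) {
    summ <- list(stat = analysis$stat,
                 evalue_cutoff = analysis$evalue_cutoff,
                 n_significant = analysis$n_significant)
    if (!is.null(analysis$call))
      summ <- c(summ, analysis$call[c("call", "observed",
                                      "expected_single", "expected_double")])
    jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(analysis)
}
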