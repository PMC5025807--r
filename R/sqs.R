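#' Good's u coverage of a bin's occurrence sample
#'
#' Coverage is the proportion of the underlying taxon frequency
#' distribution represented in the sample, estimated as
#' `u = 1 - n1 / N` where `N` is the number of occurrences and `n1` the
#' number of singleton genera. In `by_occurrence` mode a singleton is a
#' genus with exactly one occurrence in the bin; in `by_reference` mode,
#' a genus known from exactly one publication in the bin.
#'
#' @param occs Occurrence rows of one bin (an `occurrence_table` subset).
#' @param singleton_mode `"by_occurrence"` (default) or `"by_reference"`.
#' @return List with `N`, `n1` and `u` (`u` is `NA` when `N = 0`).
#' @examples
#' # tallies A:3 B:2 C:1 -> N = 6, n1 = 1, u = 5/6
#' @export
estimate_coverage <- function(occs,
                              singleton_mode = c("by_occurrence",
                                                 "by_reference")) {
  singleton_mode <- match.arg(singleton_mode)
  N <- nrow(occs)
  if (is.null(N) || N == 0L) {
    return(list(N = 0L, n1 = 0L, u = NA_real_))
  }
  if (singleton_mode == "by_occurrence") {
    n1 <- sum(table(occs$genus) == 1L)
  } else {
    refs_per_genus <- tapply(occs$reference_id, occs$genus,
                             function(r) length(unique(r)))
    n1 <- sum(refs_per_genus == 1L)
  }
  list(N = N, n1 = as.integer(n1), u = 1 - n1 / N)
}

#' SQS configuration
#'
#' @param quorum Target coverage level in (0, 1]; baseline 0.4.
#' @param trials Subsampling trials per bin (default 1000).
#' @param seed Integer seed; all SQS randomness derives from it.
#' @param pubs_cap Collections drawn per newly encountered publication
#'   (default 3): whenever a collection from a new publication is sampled,
#'   further collections from that publication are drawn until `pubs_cap`
#'   have been selected or the publication is exhausted.
#' @param singleton_mode Passed to [estimate_coverage()].
#' @param exclude_dominant If `TRUE`, the single most frequent genus is
#'   dropped from coverage accumulation and 1 is added to the returned
#'   richness (off by default).
#' @param deflate_by_u If `TRUE` (default), the stopping target is
#'   `quorum / u`: the full bin's summed raw shares equal 1 while its true
#'   coverage is about `u`, so bins with `u < quorum` are automatically
#'   reported `NA`.
#' @return An `sqs_config` list.
#' @export
sqs_config <- function(quorum = 0.4, trials = 1000L, seed = 1L,
                       pubs_cap = 3L,
                       singleton_mode = c("by_occurrence", "by_reference"),
                       exclude_dominant = FALSE, deflate_by_u = TRUE) {
  singleton_mode <- match.arg(singleton_mode)
  stopifnot(is.numeric(quorum), length(quorum) == 1L,
            quorum > 0, quorum <= 1,
            trials >= 1L, pubs_cap >= 1L)
  out <- list(quorum = quorum, trials = as.integer(trials),
              seed = as.integer(seed), pubs_cap = as.integer(pubs_cap),
              singleton_mode = singleton_mode,
              exclude_dominant = isTRUE(exclude_dominant),
              deflate_by_u = isTRUE(deflate_by_u))
  class(out) <- "sqs_config"
  out
}

# Precompute per-bin draw structures: integer-coded genera per collection,
# genus shares, collection -> publication map.
.sqs_bin_data <- function(occs) {
  genus <- factor(occs$genus)
  coll <- factor(occs$collection_id)
  counts <- tabulate(genus, nbins = nlevels(genus))
  N <- nrow(occs)
  share <- counts / N
  coll_idx <- as.integer(coll)
  coll_pub <- integer(nlevels(coll))
  pub <- factor(occs$reference_id)
  coll_pub[coll_idx] <- as.integer(pub)   # last write wins; pub constant per coll
  coll_genera <- split(as.integer(genus), coll_idx)
  coll_genera <- lapply(coll_genera, unique)
  list(
    n_coll = nlevels(coll),
    n_gen = nlevels(genus),
    n_pub = nlevels(pub),
    share = share,
    dominant = which.max(counts),
    coll_pub = coll_pub,
    coll_genera = coll_genera
  )
}

# Deterministic trial given a collection ordering. Returns richness
# (integer) or NA_integer_ on quorum failure.
.sqs_run_order <- function(bd, ord, target, pubs_cap, exclude_dominant) {
  n <- bd$n_coll
  used <- logical(n)
  seen <- logical(bd$n_gen)
  pub_new <- !logical(bd$n_pub)
  C <- 0
  dom <- if (exclude_dominant) bd$dominant else 0L
  process <- function(ci) {
    used[ci] <<- TRUE
    for (g in bd$coll_genera[[ci]]) {
      if (!seen[g]) {
        seen[g] <<- TRUE
        if (g != dom) C <<- C + bd$share[g]
      }
    }
  }
  done <- FALSE
  i <- 1L
  while (i <= n && !done) {
    ci <- ord[i]
    if (!used[ci]) {
      process(ci)
      if (C >= target - 1e-12) done <- TRUE
      p <- bd$coll_pub[ci]
      if (!done && pub_new[p]) {
        pub_new[p] <- FALSE
        extra <- pubs_cap - 1L
        j <- i + 1L
        while (extra > 0L && j <= n && !done) {
          cj <- ord[j]
          if (!used[cj] && bd$coll_pub[cj] == p) {
            process(cj)
            extra <- extra - 1L
            if (C >= target - 1e-12) done <- TRUE
          }
          j <- j + 1L
        }
      } else if (pub_new[p]) {
        pub_new[p] <- FALSE
      }
    }
    i <- i + 1L
  }
  if (!done) return(NA_integer_)
  rich <- sum(seen)
  if (exclude_dominant) {
    # dominant is excluded from accumulation but assumed present
    rich <- sum(seen & seq_along(seen) != dom) + 1L
  }
  as.integer(rich)
}

.sqs_target <- function(config, u) {
  if (config$deflate_by_u) {
    if (is.na(u) || u <= 0) return(Inf)
    config$quorum / u
  } else {
    config$quorum
  }
}

#' One SQS subsampling trial
#'
#' Draws collections in random order subject to the publication rule; each
#' newly encountered genus adds its share (bin-wide relative occurrence
#' frequency) to accumulated coverage, and the trial stops once coverage
#' reaches the quorum target. Returns the number of distinct genera drawn,
#' or `NA` if the quorum is unreachable (e.g. `quorum / u > 1` under
#' coverage deflation).
#'
#' @param occs Occurrence rows of one bin.
#' @param config An [sqs_config()].
#' @param u Precomputed Good's u for the bin (computed if `NULL`).
#' @param order Optional explicit collection ordering (indices into the
#'   bin's sorted unique collection ids); random when `NULL`.
#' @return Integer subsampled richness, or `NA_integer_` on failure.
#' @export
sqs_single_trial <- function(occs, config = sqs_config(), u = NULL,
                             order = NULL) {
  if (nrow(occs) == 0L) return(NA_integer_)
  if (is.null(u)) u <- estimate_coverage(occs, config$singleton_mode)$u
  target <- .sqs_target(config, u)
  if (target > 1 + 1e-12) return(NA_integer_)
  bd <- .sqs_bin_data(occs)
  if (is.null(order)) order <- sample.int(bd$n_coll)
  .sqs_run_order(bd, order, target, config$pubs_cap, config$exclude_dominant)
}

.bin_seed <- function(seed, bin, salt = 0L) {
  as.integer((as.double(seed) + 1009 * bin + 9973 * salt) %% 2147483629)
}

# Core per-bin estimate on a prepared occurrence subset.
.sqs_one_bin <- function(occs, config, bin_index, salt = 0L) {
  N <- nrow(occs)
  cov <- estimate_coverage(occs, config$singleton_mode)
  out <- list(n_occ = N, raw_richness = if (N) length(unique(occs$genus)) else NA_integer_,
              u = cov$u, mean = NA_real_, sd = NA_real_, n_trials_ok = 0L)
  if (N == 0L) return(out)
  target <- .sqs_target(config, cov$u)
  if (target > 1 + 1e-12) return(out)
  bd <- .sqs_bin_data(occs)
  set.seed(.bin_seed(config$seed, bin_index, salt))
  res <- integer(config$trials)
  for (t in seq_len(config$trials)) {
    res[t] <- .sqs_run_order(bd, sample.int(bd$n_coll), target,
                             config$pubs_cap, config$exclude_dominant)
  }
  ok <- !is.na(res)
  out$n_trials_ok <- sum(ok)
  if (any(ok)) {
    out$mean <- mean(res[ok])
    out$sd <- stats::sd(res[ok])
  }
  out
}

#' Coverage-standardized (SQS) diversity curve
#'
#' Per bin: mean and SD of subsampled genus richness over successful
#' trials. Bins where the quorum is unreachable (no occurrences, or
#' `u < quorum` under coverage deflation) are reported `NA`.
#' Deterministic under a fixed seed; per-bin substreams are derived from
#' the seed so results do not depend on evaluation order.
#'
#' @param binned A `binned_occurrences`.
#' @param config An [sqs_config()].
#' @param label Curve label.
#' @return An `sqs_estimate` data frame: `bin`, `name`, `base_ma`,
#'   `top_ma`, `n_occ`, `raw_richness`, `u`, `mean`, `sd`, `n_trials_ok`.
#' @export
sqs_estimate <- function(binned, config = sqs_config(), label = "SQS") {
  stopifnot(inherits(binned, "binned_occurrences"))
  sc <- binned$scheme
  occ <- .assigned(binned)
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    sub <- occ[occ$bin == i, , drop = FALSE]
    .sqs_one_bin(sub, config, i)
  })
  out <- data.frame(
    bin = seq_len(nrow(sc)), name = sc$name,
    base_ma = sc$base_ma, top_ma = sc$top_ma,
    n_occ = vapply(rows, `[[`, integer(1), "n_occ"),
    raw_richness = vapply(rows, function(r) as.integer(r$raw_richness %||% NA),
                          integer(1)),
    u = vapply(rows, `[[`, numeric(1), "u"),
    mean = vapply(rows, `[[`, numeric(1), "mean"),
    sd = vapply(rows, `[[`, numeric(1), "sd"),
    n_trials_ok = vapply(rows, `[[`, integer(1), "n_trials_ok"),
    stringsAsFactors = FALSE
  )
  attr(out, "label") <- label
  attr(out, "config") <- config
  class(out) <- c("sqs_estimate", "data.frame")
  out
}

#' Bootstrap confidence intervals for SQS diversity
#'
#' For each bin, collections are resampled with replacement to the
#' original collection count, the SQS estimate is recomputed on each
#' resample (coverage re-estimated per resample), and a percentile
#' interval of the resample means is reported.
#'
#' @param binned A `binned_occurrences`.
#' @param config An [sqs_config()].
#' @param reps Bootstrap resamples per bin (>= 2).
#' @param level Interval level (default 0.95).
#' @return The [sqs_estimate()] frame plus `ci_lo`, `ci_hi`, `n_reps_ok`.
#' @export
bootstrap_sqs <- function(binned, config = sqs_config(), reps = 100L,
                          level = 0.95) {
  stopifnot(reps >= 2L, level > 0, level < 1)
  est <- sqs_estimate(binned, config)
  occ <- .assigned(binned)
  ci_lo <- ci_hi <- rep(NA_real_, nrow(est))
  n_ok <- integer(nrow(est))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  for (i in seq_len(nrow(est))) {
    sub <- occ[occ$bin == i, , drop = FALSE]
    if (nrow(sub) == 0L) next
    colls <- unique(sub$collection_id)
    by_coll <- split(seq_len(nrow(sub)), sub$collection_id)
    means <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      set.seed(.bin_seed(config$seed, i, salt = r))
      draw <- sample(colls, length(colls), replace = TRUE)
      idx <- unlist(by_coll[draw], use.names = FALSE)
      boot <- sub[idx, , drop = FALSE]
      # duplicated collections become distinct drawable copies
      copy <- rep(seq_along(draw), vapply(by_coll[draw], length, integer(1)))
      boot$collection_id <- paste0(boot$collection_id, "#", copy)
      res <- .sqs_one_bin(boot, config, i, salt = 1000L + r)
      means[r] <- res$mean
    }
    ok <- !is.na(means)
    n_ok[i] <- sum(ok)
    if (any(ok)) {
      q <- stats::quantile(means[ok], probs = probs, names = FALSE)
      ci_lo[i] <- q[1]
      ci_hi[i] <- q[2]
    }
  }
  est$ci_lo <- ci_lo
  est$ci_hi <- ci_hi
  est$n_reps_ok <- n_ok
  attr(est, "ci_level") <- level
  est
}
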