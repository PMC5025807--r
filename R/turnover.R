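#' Compile per-genus stratigraphic ranges
#'
#' For each genus among assigned occurrences: first- and last-appearance
#' bin indices, the set of bins with sampled occurrences, and the
#' range-through presence (all bins between first and last inclusive,
#' filling internal gaps).
#'
#' @param binned A `binned_occurrences`.
#' @return A `taxon_ranges` list: `genus`, `first`, `last`, `sampled`
#'   (genus x bin logical matrix) and `scheme`.
#' @export
compile_taxon_ranges <- function(binned) {
  stopifnot(inherits(binned, "binned_occurrences"))
  occ <- .assigned(binned)
  if (nrow(occ) == 0L) {
    stop("no assigned occurrences to compile ranges from", call. = FALSE)
  }
  n_bins <- nrow(binned$scheme)
  genus <- factor(occ$genus)
  sampled <- matrix(FALSE, nlevels(genus), n_bins,
                    dimnames = list(levels(genus), binned$scheme$name))
  sampled[cbind(as.integer(genus), occ$bin)] <- TRUE
  first <- apply(sampled, 1L, function(z) which(z)[1L])
  last <- apply(sampled, 1L, function(z) max(which(z)))
  out <- list(genus = levels(genus), first = unname(first),
              last = unname(last), sampled = sampled,
              scheme = binned$scheme)
  class(out) <- "taxon_ranges"
  out
}

#' Boundary-crosser (Foote) tallies per bin
#'
#' Range-through categories for bin *i*: `Nbt` cross both boundaries,
#' `NbL` cross the bottom and last appear within, `NFt` first appear
#' within and cross the top, `NFL` are confined singletons. Their sum is
#' the range-through richness of the bin.
#'
#' @param ranges A `taxon_ranges`.
#' @return Data frame: `bin`, `name`, `Nbt`, `NbL`, `NFt`, `NFL`.
#' @export
foote_counts <- function(ranges) {
  stopifnot(inherits(ranges, "taxon_ranges"))
  n_bins <- nrow(ranges$scheme)
  f <- ranges$first
  l <- ranges$last
  tally <- function(cond) vapply(seq_len(n_bins), cond, integer(1))
  data.frame(
    bin = seq_len(n_bins), name = ranges$scheme$name,
    Nbt = tally(function(i) sum(f < i & l > i)),
    NbL = tally(function(i) sum(f < i & l == i)),
    NFt = tally(function(i) sum(f == i & l > i)),
    NFL = tally(function(i) sum(f == i & l == i)),
    stringsAsFactors = FALSE
  )
}

#' Foote boundary-crosser extinction and origination rates
#'
#' Per-capita rates from boundary-crosser tallies:
#' `q_i = -ln(Nbt_i / (Nbt_i + NbL_i))` and
#' `p_i = -ln(Nbt_i / (Nbt_i + NFt_i))`, `NA` where `Nbt_i = 0`.
#' Rates are per bin by default; `per_myr = TRUE` divides by bin duration.
#' Singletons (`NFL`) are tallied but never enter either rate.
#'
#' @param ranges A `taxon_ranges`.
#' @param per_myr Normalize by bin duration (Myr)?
#' @return A `rates_curve` data frame with tallies and columns `p`
#'   (origination) and `q` (extinction), method `"foote"`.
#' @export
foote_rates <- function(ranges, per_myr = FALSE) {
  fc <- foote_counts(ranges)
  q <- ifelse(fc$Nbt > 0, -log(fc$Nbt / (fc$Nbt + fc$NbL)), NA_real_)
  p <- ifelse(fc$Nbt > 0, -log(fc$Nbt / (fc$Nbt + fc$NFt)), NA_real_)
  if (per_myr) {
    q <- q / ranges$scheme$duration_myr
    p <- p / ranges$scheme$duration_myr
  }
  fc$duration_myr <- ranges$scheme$duration_myr
  fc$p <- p
  fc$q <- q
  attr(fc, "method") <- "foote"
  attr(fc, "per_myr") <- per_myr
  class(fc) <- c("rates_curve", "data.frame")
  fc
}

#' Three-timer tallies per bin
#'
#' From sampled bins only (no range-through): `two_t_bottom` genera
#' sampled in bins i-1 and i; `two_t_top` in i and i+1; `three_t` in all
#' of i-1, i, i+1; `part_t` in i-1 and i+1 but not i. The implied per-bin
#' sampling probability is `Ps = three_t / (three_t + part_t)`, replaced
#' by the pooled value over all bins where a bin's denominator is zero.
#'
#' @param ranges A `taxon_ranges`.
#' @return Data frame: `bin`, `name`, `two_t_bottom`, `two_t_top`,
#'   `three_t`, `part_t`, `Ps` (with attribute `"pooled_Ps"`).
#' @export
three_timer_counts <- function(ranges) {
  stopifnot(inherits(ranges, "taxon_ranges"))
  s <- ranges$sampled
  n_bins <- ncol(s)
  ttb <- tta <- tt3 <- pt <- rep(NA_integer_, n_bins)
  for (i in seq_len(n_bins)) {
    if (i > 1L) ttb[i] <- sum(s[, i - 1L] & s[, i])
    if (i < n_bins) tta[i] <- sum(s[, i] & s[, i + 1L])
    if (i > 1L && i < n_bins) {
      tt3[i] <- sum(s[, i - 1L] & s[, i] & s[, i + 1L])
      pt[i] <- sum(s[, i - 1L] & !s[, i] & s[, i + 1L])
    }
  }
  denom <- tt3 + pt
  pooled <- if (sum(denom, na.rm = TRUE) > 0) {
    sum(tt3, na.rm = TRUE) / sum(denom, na.rm = TRUE)
  } else {
    NA_real_
  }
  Ps <- ifelse(!is.na(denom) & denom > 0, tt3 / denom, pooled)
  out <- data.frame(
    bin = seq_len(n_bins), name = ranges$scheme$name,
    two_t_bottom = ttb, two_t_top = tta, three_t = tt3, part_t = pt,
    Ps = Ps, stringsAsFactors = FALSE
  )
  attr(out, "pooled_Ps") <- pooled
  out
}

#' Three-timer extinction and origination rates
#'
#' Sampling-corrected per-capita rates:
#' `mu_i = ln(2tb_i / 3t_i) + ln(Ps_{i+1})` and
#' `lambda_i = ln(2ta_i / 3t_i) + ln(Ps_{i-1})`, `NA` where a required
#' tally is zero or the neighbouring correction bin is missing (so the end
#' bins of the scheme are always `NA`).
#'
#' @param ranges A `taxon_ranges`.
#' @return A `rates_curve` data frame with tallies and columns `p`
#'   (origination, lambda) and `q` (extinction, mu), method `"threetimer"`.
#' @export
three_timer_rates <- function(ranges) {
  tc <- three_timer_counts(ranges)
  n_bins <- nrow(tc)
  mu <- lam <- rep(NA_real_, n_bins)
  for (i in seq_len(n_bins)) {
    if (!is.na(tc$two_t_bottom[i]) && !is.na(tc$three_t[i]) &&
        tc$two_t_bottom[i] > 0L && tc$three_t[i] > 0L &&
        i + 1L <= n_bins && !is.na(tc$Ps[i + 1L]) && tc$Ps[i + 1L] > 0) {
      mu[i] <- log(tc$two_t_bottom[i] / tc$three_t[i]) + log(tc$Ps[i + 1L])
    }
    if (!is.na(tc$two_t_top[i]) && !is.na(tc$three_t[i]) &&
        tc$two_t_top[i] > 0L && tc$three_t[i] > 0L &&
        i - 1L >= 1L && !is.na(tc$Ps[i - 1L]) && tc$Ps[i - 1L] > 0) {
      lam[i] <- log(tc$two_t_top[i] / tc$three_t[i]) + log(tc$Ps[i - 1L])
    }
  }
  tc$p <- lam
  tc$q <- mu
  attr(tc, "method") <- "threetimer"
  class(tc) <- c("rates_curve", "data.frame")
  tc
}
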