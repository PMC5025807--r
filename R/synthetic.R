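#' Simulate a true diversity history (discrete birth--death)
#'
#' Discrete-time birth--death over `n_bins` bins. Each taxon alive in bin
#' *i* survives into bin *i+1* with probability `1 - mu[i]`; new taxa
#' originating in bin *i+1* are Poisson with mean `lambda[i] * R_i` where
#' `R_i` is the richness of bin *i*. `mu` is a per-bin extinction
#' *probability*: with `lambda = 0, mu = 0.5` expected richness halves
#' each bin, and the matching per-capita rate is `-ln(1 - mu)`.
#'
#' @param n_bins Number of bins.
#' @param initial_richness Taxa alive in the first bin (>= 1).
#' @param lambda Per-capita origination probability per bin (scalar or
#'   length `n_bins`).
#' @param mu Per-capita extinction probability per bin (scalar or length
#'   `n_bins`).
#' @param seed Integer seed.
#' @return A `synthetic_world` list: `taxa` (data frame `taxon_id`,
#'   `orig_bin`, `ext_bin`), `true_richness`, `n_bins`, `lambda`, `mu`,
#'   `seed`.
#' @export
simulate_true_world <- function(n_bins, initial_richness, lambda = 0,
                                mu = 0, seed = 1L) {
  stopifnot(n_bins >= 1L, initial_richness >= 1L,
            all(lambda >= 0), all(mu >= 0), all(mu <= 1))
  lambda <- rep_len(lambda, n_bins)
  mu <- rep_len(mu, n_bins)
  set.seed(as.integer(seed))
  orig <- rep(1L, initial_richness)
  ext <- rep(NA_integer_, initial_richness)
  alive <- seq_len(initial_richness)
  richness <- integer(n_bins)
  richness[1L] <- length(alive)
  for (i in seq_len(n_bins)) {
    if (i == n_bins) {
      ext[alive] <- n_bins
      break
    }
    if (length(alive)) {
      dies <- stats::runif(length(alive)) < mu[i]
      ext[alive[dies]] <- i
      alive <- alive[!dies]
    }
    n_new <- if (richness[i] > 0) stats::rpois(1L, lambda[i] * richness[i]) else 0L
    if (n_new > 0L) {
      new_ids <- length(orig) + seq_len(n_new)
      orig <- c(orig, rep(i + 1L, n_new))
      ext <- c(ext, rep(NA_integer_, n_new))
      alive <- c(alive, new_ids)
    }
    richness[i + 1L] <- length(alive)
  }
  ext[is.na(ext)] <- n_bins
  out <- list(
    taxa = data.frame(taxon_id = sprintf("t%05d", seq_along(orig)),
                      orig_bin = orig, ext_bin = ext,
                      stringsAsFactors = FALSE),
    true_richness = richness, n_bins = as.integer(n_bins),
    lambda = lambda, mu = mu, seed = as.integer(seed)
  )
  class(out) <- "synthetic_world"
  out
}

#' Realized per-bin per-capita rates of a synthetic world
#'
#' Extinction: `q_i = -ln(survivors into i+1 / alive in i)`; origination:
#' `p_i = -ln((alive in i - newly originated in i) / alive in i)`.
#' `NA` where undefined (no taxa alive, nothing surviving, or end bins).
#'
#' @param world A `synthetic_world`.
#' @return Data frame: `bin`, `alive`, `true_p`, `true_q`.
#' @export
true_rates <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  tx <- world$taxa
  n <- world$n_bins
  alive_n <- surv <- new_n <- integer(n)
  for (i in seq_len(n)) {
    alive <- tx$orig_bin <= i & tx$ext_bin >= i
    alive_n[i] <- sum(alive)
    surv[i] <- sum(alive & tx$ext_bin > i)
    new_n[i] <- sum(tx$orig_bin == i)
  }
  q <- ifelse(alive_n > 0L & surv > 0L & seq_len(n) < n,
              -log(surv / alive_n), NA_real_)
  held <- alive_n - new_n
  p <- ifelse(alive_n > 0L & held > 0L & seq_len(n) > 1L,
              -log(held / alive_n), NA_real_)
  data.frame(bin = seq_len(n), alive = alive_n, true_p = p, true_q = q)
}

#' Sampling regime for the synthetic fossil record
#'
#' @param collections_per_bin Collections drawn per bin (scalar or per
#'   bin).
#' @param occ_per_collection Expected occurrences per collection (Poisson
#'   mean).
#' @param sampling_multiplier Per-bin multiplier on expected occurrences
#'   per collection (scalar or per bin). `Inf` means complete sampling:
#'   every living taxon yields one occurrence in every bin it lives in.
#' @param abundance `"geometric"` (rank-abundance, share of rank *r*
#'   proportional to `(1 - k)^(r-1)`; singleton-heavy for small samples)
#'   or `"lognormal"`.
#' @param abundance_param Geometric `k` (default 0.5) or lognormal
#'   `sdlog`.
#' @param pubs_mean Mean of the heavy-tailed publications-per-bin draw
#'   (`1 + NegBin(size = 1, mu = pubs_mean - 1)`), exercising the
#'   publication cap rule.
#' @return A `sampling_regime` list.
#' @export
sampling_regime <- function(collections_per_bin = 20L,
                            occ_per_collection = 3,
                            sampling_multiplier = 1,
                            abundance = c("geometric", "lognormal"),
                            abundance_param = 0.5,
                            pubs_mean = 3) {
  abundance <- match.arg(abundance)
  stopifnot(all(collections_per_bin >= 0),
            occ_per_collection > 0,
            all(sampling_multiplier > 0),
            abundance_param > 0, pubs_mean >= 1)
  out <- list(collections_per_bin = collections_per_bin,
              occ_per_collection = occ_per_collection,
              sampling_multiplier = sampling_multiplier,
              abundance = abundance, abundance_param = abundance_param,
              pubs_mean = pubs_mean)
  class(out) <- "sampling_regime"
  out
}

.abundance_shares <- function(n_taxa, regime) {
  if (regime$abundance == "geometric") {
    w <- (1 - regime$abundance_param)^(seq_len(n_taxa) - 1L)
  } else {
    w <- sort(stats::rlnorm(n_taxa, sdlog = regime$abundance_param),
              decreasing = TRUE)
  }
  w / sum(w)
}

#' Simulate a fossil occurrence record from a synthetic world
#'
#' Per bin: publications and collections are drawn (collection counts per
#' publication are skewed so some publications contribute many
#' collections), occurrences are drawn from the living taxa under the
#' regime's rank-abundance distribution, and each occurrence gets an age
#' range strictly inside its bin so strict-containment binning recovers
#' the generating bin without loss.
#'
#' @param world A `synthetic_world`.
#' @param regime A [sampling_regime()].
#' @param scheme Optional `bin_scheme` with `world$n_bins` bins; a uniform
#'   5-Myr scheme ending at 66 Ma is built when `NULL`.
#' @param seed Integer seed.
#' @param realm,region,group Labels stamped on every occurrence.
#' @return An `occurrence_table` with attribute `"scheme"`.
#' @export
simulate_fossil_record <- function(world, regime = sampling_regime(),
                                   scheme = NULL, seed = 1L,
                                   realm = "nonmarine", region = "Other",
                                   group = "Synthetica") {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(regime, "sampling_regime"))
  n_bins <- world$n_bins
  if (is.null(scheme)) {
    scheme <- make_uniform_bins(66 + 5 * n_bins, 66, n_bins,
                                prefix = "synth")
  }
  stopifnot(nrow(scheme) == n_bins)
  set.seed(as.integer(seed))
  n_coll_bin <- rep_len(regime$collections_per_bin, n_bins)
  mult <- rep_len(regime$sampling_multiplier, n_bins)
  tx <- world$taxa
  rows <- vector("list", n_bins)
  for (i in seq_len(n_bins)) {
    living <- which(tx$orig_bin <= i & tx$ext_bin >= i)
    n_coll <- n_coll_bin[i]
    if (!length(living) || n_coll < 1L) next
    if (is.infinite(mult[i])) {
      # complete sampling: one occurrence per living taxon
      genus_idx <- living
      coll_of <- rep_len(seq_len(n_coll), length(genus_idx))
    } else {
      shares <- .abundance_shares(length(living), regime)
      living <- sample(living)   # random rank order
      n_occ <- stats::rpois(n_coll, regime$occ_per_collection * mult[i])
      total <- sum(n_occ)
      if (total == 0L) next
      genus_idx <- living[sample.int(length(living), total, replace = TRUE,
                                     prob = shares)]
      coll_of <- rep(seq_len(n_coll), n_occ)
    }
    n_pub <- max(1L, min(n_coll,
                         1L + stats::rnbinom(1L, size = 1,
                                             mu = regime$pubs_mean - 1)))
    pub_of_coll <- sample.int(n_pub, n_coll, replace = TRUE,
                              prob = 1 / seq_len(n_pub))
    n_form <- max(1L, ceiling(n_coll / 3))
    form_of_coll <- sample.int(n_form, n_coll, replace = TRUE)
    base <- scheme$base_ma[i]
    top <- scheme$top_ma[i]
    dt <- base - top
    mid <- stats::runif(length(genus_idx), top + 0.15 * dt,
                        base - 0.15 * dt)
    half <- stats::runif(length(genus_idx), 0, 0.1 * dt)
    rows[[i]] <- data.frame(
      occurrence_id = NA_character_,
      genus = tx$taxon_id[genus_idx],
      collection_id = sprintf("c%03d_%04d", i, coll_of),
      reference_id = sprintf("r%03d_%03d", i, pub_of_coll[coll_of]),
      formation_id = sprintf("f%03d_%03d", i, form_of_coll[coll_of]),
      max_ma = mid + half, min_ma = mid - half,
      realm = realm, region = region, group = group,
      stringsAsFactors = FALSE
    )
  }
  occs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(occs)) {
    occs <- data.frame(occurrence_id = character(0), genus = character(0),
                       collection_id = character(0),
                       reference_id = character(0),
                       formation_id = character(0),
                       max_ma = numeric(0), min_ma = numeric(0),
                       realm = character(0), region = character(0),
                       group = character(0), stringsAsFactors = FALSE)
  } else {
    occs$occurrence_id <- sprintf("o%06d", seq_len(nrow(occs)))
  }
  rownames(occs) <- NULL
  class(occs) <- c("occurrence_table", "data.frame")
  attr(occs, "scheme") <- scheme
  occs
}

#' Simulate a driver series with known influence on true richness
#'
#' Constructs a driver such that `true_richness = a * driver + eps` where
#' `eps` is AR(1) noise with autocorrelation `phi` and marginal standard
#' deviation `noise_sd`, plus `n_decoys` independent AR(1) decoy series
#' scaled to the driver's spread. With `noise_sd = 0` the response is
#' perfectly collinear with the driver.
#'
#' @param world A `synthetic_world`.
#' @param a True linear coefficient (non-zero).
#' @param noise_sd Marginal SD of the AR(1) noise.
#' @param phi AR(1) autocorrelation of noise and decoys (|phi| < 1).
#' @param n_decoys Number of decoy series.
#' @param seed Integer seed.
#' @return Data frame: `bin`, `driver`, `decoy1`..`decoyK`, with
#'   attributes `"true_driver" = "driver"` and `"a"`.
#' @export
simulate_driver_series <- function(world, a = 1, noise_sd = 1, phi = 0.5,
                                   n_decoys = 4L, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"), a != 0, noise_sd >= 0,
            abs(phi) < 1)
  n <- world$n_bins
  set.seed(as.integer(seed))
  ar1 <- function(n, sd_marg) {
    if (sd_marg == 0) return(numeric(n))
    as.numeric(stats::arima.sim(list(ar = phi), n,
                                sd = sd_marg * sqrt(1 - phi^2)))
  }
  eps <- ar1(n, noise_sd)
  driver <- (world$true_richness - eps) / a
  out <- data.frame(bin = seq_len(n), driver = driver)
  if (n_decoys > 0L) {
    sd_d <- max(stats::sd(driver), 1e-8)
    for (d in seq_len(n_decoys)) {
      out[[paste0("decoy", d)]] <- mean(driver) + ar1(n, sd_d)
    }
  }
  attr(out, "true_driver") <- "driver"
  attr(out, "a") <- a
  out
}
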