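# In-code fixtures and independent oracles shared across test files.

# Quick occurrence-table constructor with recycling.
occ_df <- function(genus, collection = seq_along(genus),
                   reference = collection, formation = NA_character_,
                   max_ma = 150, min_ma = 148, realm = "nonmarine",
                   region = "Other", group = NA_character_) {
  n <- length(genus)
  out <- data.frame(
    occurrence_id = sprintf("o%04d", seq_len(n)),
    genus = as.character(genus),
    collection_id = as.character(rep_len(collection, n)),
    reference_id = as.character(rep_len(reference, n)),
    formation_id = as.character(rep_len(formation, n)),
    max_ma = rep_len(max_ma, n),
    min_ma = rep_len(min_ma, n),
    realm = rep_len(realm, n),
    region = rep_len(region, n),
    group = as.character(rep_len(group, n)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("occurrence_table", "data.frame")
  out
}

# Write a CSV in the PaleoDB-classic dialect for read_occurrence_table().
write_paleodb_csv <- function(df, path) {
  out <- data.frame(
    occurrence_no = df$occurrence_id, genus = df$genus,
    collection_no = df$collection_id, reference_no = df$reference_id,
    formation = df$formation_id, max_ma = df$max_ma, min_ma = df$min_ma,
    realm = df$realm, region = df$region, group = df$group,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  path
}

# Hand-rolled taxon_ranges from first/last bin vectors (continuous ranges).
make_ranges <- function(first, last, n_bins, sampled = NULL) {
  stopifnot(length(first) == length(last), all(first <= last))
  sc <- make_uniform_bins(100, 100 - 2 * n_bins, n_bins, prefix = "b")
  if (is.null(sampled)) {
    sampled <- matrix(FALSE, length(first), n_bins)
    for (g in seq_along(first)) sampled[g, first[g]:last[g]] <- TRUE
  }
  rownames(sampled) <- sprintf("g%03d", seq_len(nrow(sampled)))
  out <- list(genus = rownames(sampled), first = first, last = last,
              sampled = sampled, scheme = sc)
  class(out) <- "taxon_ranges"
  out
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Independent SQS oracle: given one bin's occurrences and an explicit
# ordering of its (sorted unique) collection ids, play out the draw rule
# from its verbal definition and return the richness at stopping (NA on
# quorum failure). Written separately from the package's engine.
oracle_sqs_trial <- function(occs, quorum, pubs_cap = 3,
                             deflate = TRUE, ord = NULL) {
  N <- nrow(occs)
  cnt <- table(occs$genus)
  share <- cnt / N
  u <- 1 - sum(cnt == 1) / N
  target <- if (deflate) quorum / u else quorum
  if (target > 1 + 1e-12) return(NA_integer_)
  colls <- sort(unique(occs$collection_id))
  if (is.null(ord)) ord <- sample(seq_along(colls))
  queue <- colls[ord]
  pub_of <- function(cc) occs$reference_id[occs$collection_id == cc][1]
  seen <- character(0)
  pubs_done <- character(0)
  C <- 0
  sample_coll <- function(cc) {
    gs <- unique(occs$genus[occs$collection_id == cc])
    new <- setdiff(gs, seen)
    seen <<- union(seen, gs)
    C <<- C + sum(share[new])
  }
  while (length(queue)) {
    cc <- queue[1]
    queue <- queue[-1]
    sample_coll(cc)
    if (C >= target - 1e-12) return(length(seen))
    p <- pub_of(cc)
    if (!(p %in% pubs_done)) {
      pubs_done <- c(pubs_done, p)
      same <- queue[vapply(queue, function(x) pub_of(x) == p, logical(1))]
      take <- utils::head(same, pubs_cap - 1L)
      for (cc2 in take) {
        queue <- queue[queue != cc2]
        sample_coll(cc2)
        if (C >= target - 1e-12) return(length(seen))
      }
    }
  }
  NA_integer_
}

# Exact expected SQS richness by enumerating every collection ordering.
oracle_sqs_expected <- function(occs, quorum, pubs_cap = 3,
                                deflate = TRUE) {
  n <- length(unique(occs$collection_id))
  stopifnot(n <= 6)
  perms <- all_perms(n)
  vals <- apply(perms, 1L, function(ord) {
    oracle_sqs_trial(occs, quorum, pubs_cap, deflate, ord = ord)
  })
  mean(vals)   # NA if any ordering fails, which the tests avoid
}

# A small multi-bin synthetic record binned against its own scheme.
small_binned_record <- function(seed = 42, n_bins = 8, richness = 40,
                                collections = 15, occ_rate = 3) {
  world <- simulate_true_world(n_bins, richness, lambda = 0.1, mu = 0.1,
                               seed = seed)
  rec <- simulate_fossil_record(
    world, sampling_regime(collections_per_bin = collections,
                           occ_per_collection = occ_rate),
    seed = seed + 1L)
  assign_to_bins(rec, attr(rec, "scheme"))
}
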