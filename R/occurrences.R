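#' Default occurrence-table column map (PaleoDB-classic dialect)
#'
#' Maps the internal occurrence fields to the column names of a
#' PaleoDB-style CSV export. Override individual entries to read other
#' dialects. `formation_id`, `realm`, `region` and `group` are optional:
#' if the mapped column is absent the field is filled with its default
#' (no formation, non-marine, region "Other", group `NA`).
#'
#' @return Named list of column names.
#' @export
default_column_map <- function() {
  list(
    occurrence_id = "occurrence_no",
    genus = "genus",
    collection_id = "collection_no",
    reference_id = "reference_no",
    formation_id = "formation",
    max_ma = "max_ma",
    min_ma = "min_ma",
    realm = "realm",
    region = "region",
    group = "group"
  )
}

.mandatory_fields <- c("occurrence_id", "genus", "collection_id",
                       "reference_id", "max_ma", "min_ma")
.region_levels <- c("Africa", "Asia", "Europe", "SouthAmerica",
                    "NorthAmerica", "Other")
.realm_levels <- c("marine", "nonmarine")

#' Canonicalize genus names
#'
#' Strips open-nomenclature qualifiers ("aff.", "cf.", "?"), removes
#' parenthetical subgenus designations, collapses whitespace and
#' case-folds to initial-capital form, so that qualified occurrences
#' count under their genus.
#'
#' @param x Character vector of genus names as published.
#' @return Character vector of canonical names ("" where nothing remains).
#' @examples
#' canonicalize_genus(c("cf. Allosaurus", "?Stegosaurus",
#'                      "Allosaurus (Antrodemus)"))
#' @export
canonicalize_genus <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- gsub("\\([^)]*\\)", " ", x)            # subgenus in parentheses
  x <- gsub("\\?", " ", x, fixed = FALSE)     # "?" qualifier anywhere
  x <- gsub("(?i)\\b(aff|cf)\\.?(\\s+|$)", " ", x, perl = TRUE)
  x <- trimws(gsub("\\s+", " ", x))
  n <- nchar(x)
  out <- ifelse(n > 0L,
                paste0(toupper(substr(x, 1L, 1L)),
                       tolower(substr(x, 2L, n))),
                "")
  out
}

.normalize_realm <- function(x) {
  x <- tolower(trimws(as.character(x)))
  # only fully pelagic records are marine; semi-aquatic/coastal -> nonmarine
  ifelse(x %in% c("marine", "pelagic"), "marine", "nonmarine")
}

.normalize_region <- function(x) {
  x <- gsub("\\s+", "", as.character(x))
  x[is.na(x) | x == ""] <- "Other"
  ifelse(x %in% .region_levels, x, "Other")
}

#' Read and validate a genus-level occurrence table
#'
#' Reads a CSV of fossil occurrences, canonicalizes genus names, parses
#' ages, and drops invalid rows (empty genus, non-numeric ages, inverted
#' ranges `min_ma > max_ma`, non-positive ages) with a warning that counts
#' the drops. The drop tally is attached as attribute `"drop_log"`.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param column_map Named list mapping internal fields to file columns;
#'   see [default_column_map()].
#' @return An `occurrence_table` data frame with columns `occurrence_id`,
#'   `genus`, `collection_id`, `reference_id`, `formation_id`, `max_ma`,
#'   `min_ma`, `realm`, `region`, `group`.
#' @export
read_occurrence_table <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = character(0))
  cm <- utils::modifyList(default_column_map(), as.list(column_map))
  missing_cols <- vapply(.mandatory_fields, function(f) {
    !(cm[[f]] %in% names(raw))
  }, logical(1))
  if (any(missing_cols)) {
    stop("format error: missing mandatory column(s): ",
         paste(unlist(cm[.mandatory_fields][missing_cols]), collapse = ", "),
         call. = FALSE)
  }
  grab <- function(field, default) {
    col <- cm[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  occs <- data.frame(
    occurrence_id = as.character(raw[[cm$occurrence_id]]),
    genus = canonicalize_genus(raw[[cm$genus]]),
    collection_id = as.character(raw[[cm$collection_id]]),
    reference_id = as.character(raw[[cm$reference_id]]),
    formation_id = as.character(grab("formation_id", NA_character_)),
    max_ma = suppressWarnings(as.numeric(raw[[cm$max_ma]])),
    min_ma = suppressWarnings(as.numeric(raw[[cm$min_ma]])),
    realm = .normalize_realm(grab("realm", "nonmarine")),
    region = .normalize_region(grab("region", "Other")),
    group = as.character(grab("group", NA_character_)),
    stringsAsFactors = FALSE
  )
  for (opt in c("formation_id", "group")) {
    blank <- !is.na(occs[[opt]]) & trimws(occs[[opt]]) == ""
    occs[[opt]][blank] <- NA_character_
  }

  bad_genus <- occs$genus == ""
  bad_age <- !bad_genus & (is.na(occs$max_ma) | is.na(occs$min_ma))
  inverted <- !bad_genus & !bad_age & occs$min_ma > occs$max_ma
  nonpos <- !bad_genus & !bad_age & !inverted & occs$min_ma <= 0
  drop <- bad_genus | bad_age | inverted | nonpos
  drop_log <- c(empty_genus = sum(bad_genus), non_numeric_age = sum(bad_age),
                inverted_age = sum(inverted), nonpositive_age = sum(nonpos))
  if (any(drop)) {
    warning(sprintf(
      "dropped %d invalid occurrence row(s): %s",
      sum(drop),
      paste(sprintf("%s=%d", names(drop_log), drop_log), collapse = ", ")
    ), call. = FALSE)
  }
  occs <- occs[!drop, , drop = FALSE]
  rownames(occs) <- NULL
  if (anyDuplicated(occs$occurrence_id)) {
    stop("integrity error: duplicate occurrence_id in table", call. = FALSE)
  }
  attr(occs, "drop_log") <- drop_log
  class(occs) <- c("occurrence_table", "data.frame")
  occs
}

#' Write an occurrence table to CSV
#'
#' Round-trips all fields through [read_occurrence_table()] with an
#' identity column map.
#'
#' @param occs An `occurrence_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(occs, path) {
  utils::write.csv(as.data.frame(occs), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Identity column map for tables written by [write_occurrence_table()]
#' @return Named list of column names.
#' @export
identity_column_map <- function() {
  f <- names(default_column_map())
  stats::setNames(as.list(f), f)
}

.as_occurrence_table <- function(occs) {
  stopifnot(is.data.frame(occs))
  need <- names(default_column_map())
  if (!all(need %in% names(occs))) {
    stop("not an occurrence table: missing field(s) ",
         paste(setdiff(need, names(occs)), collapse = ", "), call. = FALSE)
  }
  if (!inherits(occs, "occurrence_table")) {
    class(occs) <- c("occurrence_table", class(occs))
  }
  occs
}

#' Assign occurrences to time bins (strict single-bin containment)
#'
#' An occurrence is assigned to bin *b* iff its whole age range lies inside
#' *b*: `max_ma <= b$base_ma` and `min_ma >= b$top_ma` (closed intervals).
#' Ranges spanning a bin boundary stay unassigned, which avoids counting
#' one occurrence in several bins. A range that is exactly the point shared
#' by two bins goes to the older bin.
#'
#' @param occs An `occurrence_table`.
#' @param scheme A `bin_scheme`.
#' @return A `binned_occurrences` object: list with `occurrences` (the
#'   table plus integer `bin` index, `NA` = unassigned, and `bin_name`)
#'   and `scheme`.
#' @export
assign_to_bins <- function(occs, scheme) {
  occs <- .as_occurrence_table(occs)
  if (!inherits(scheme, "bin_scheme") || nrow(scheme) == 0L) {
    stop("configuration error: scheme must be a non-empty bin_scheme",
         call. = FALSE)
  }
  tol <- 1e-9
  idx <- rep(NA_integer_, nrow(occs))
  for (i in seq_len(nrow(scheme))) {   # oldest first => boundary tie -> older bin
    hit <- is.na(idx) &
      occs$max_ma <= scheme$base_ma[i] + tol &
      occs$min_ma >= scheme$top_ma[i] - tol
    idx[hit] <- i
  }
  occs$bin <- idx
  occs$bin_name <- scheme$name[idx]
  out <- list(occurrences = occs, scheme = scheme)
  class(out) <- "binned_occurrences"
  out
}

#' @export
print.binned_occurrences <- function(x, ...) {
  n <- nrow(x$occurrences)
  na <- sum(is.na(x$occurrences$bin))
  cat(sprintf(
    "<binned_occurrences: %d occurrences, %d assigned to %d bins, %d unassigned>\n",
    n, n - na, nrow(x$scheme), na))
  invisible(x)
}

.assigned <- function(binned) {
  binned$occurrences[!is.na(binned$occurrences$bin), , drop = FALSE]
}

#' Subset occurrences by realm, region or group
#'
#' Partitions by one key; partitions over the levels of a key are disjoint
#' and exhaustive. Unknown realm or region levels are configuration
#' errors; any group label is accepted (an absent group yields an empty
#' table).
#'
#' @param occs An `occurrence_table` or `binned_occurrences`.
#' @param by One of `"realm"`, `"region"`, `"group"`.
#' @param value Level to keep.
#' @return Object of the same class as `occs`, subset to the level.
#' @export
partition_occurrences <- function(occs, by = c("realm", "region", "group"),
                                  value) {
  by <- match.arg(by)
  if (by == "realm" && !value %in% .realm_levels) {
    stop("configuration error: unknown realm level: ", value, call. = FALSE)
  }
  if (by == "region" && !value %in% .region_levels) {
    stop("configuration error: unknown region level: ", value, call. = FALSE)
  }
  if (inherits(occs, "binned_occurrences")) {
    keep <- !is.na(occs$occurrences[[by]]) & occs$occurrences[[by]] == value
    occs$occurrences <- occs$occurrences[keep, , drop = FALSE]
    return(occs)
  }
  occs <- .as_occurrence_table(occs)
  keep <- !is.na(occs[[by]]) & occs[[by]] == value
  out <- occs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Raw (uncorrected) taxonomic diversity
#'
#' Per-bin count of distinct genera among assigned occurrences (the TDE of
#' the literature). Bins with no occurrences carry `NA` — a gap in the
#' sampled record, not zero diversity.
#'
#' @param binned A `binned_occurrences`.
#' @param label Curve label.
#' @return A `diversity_curve` data frame: `bin`, `name`, `base_ma`,
#'   `top_ma`, `value`, `n_occurrences`.
#' @export
raw_taxonomic_diversity <- function(binned, label = "TDE") {
  stopifnot(inherits(binned, "binned_occurrences"))
  sc <- binned$scheme
  occ <- .assigned(binned)
  value <- rep(NA_integer_, nrow(sc))
  n_occ <- integer(nrow(sc))
  if (nrow(occ)) {
    tab <- split(occ$genus, factor(occ$bin, levels = seq_len(nrow(sc))))
    n_occ <- vapply(tab, length, integer(1))
    value <- ifelse(n_occ > 0L,
                    vapply(tab, function(g) length(unique(g)), integer(1)),
                    NA_integer_)
  }
  out <- data.frame(
    bin = seq_len(nrow(sc)), name = sc$name,
    base_ma = sc$base_ma, top_ma = sc$top_ma,
    value = as.integer(value), n_occurrences = as.integer(n_occ),
    stringsAsFactors = FALSE
  )
  attr(out, "label") <- label
  class(out) <- c("diversity_curve", "data.frame")
  out
}

#' Per-bin sampling-proxy counts
#'
#' Counts of distinct fossil-bearing formations and collections per bin,
#' split by realm: `TBF`/`TBC` (non-marine) and `MBF`/`MBC` (marine). A
#' formation (or collection) containing any non-marine occurrence counts
#' toward the non-marine tally even if it also holds marine material, and
#' vice versa — each realm tally counts opportunities to sample that
#' realm. Empty bins give 0 (proxies are counts, not diversity signals).
#'
#' @param binned A `binned_occurrences`.
#' @return Data frame: `bin`, `name`, `TBF`, `TBC`, `MBF`, `MBC`.
#' @export
sampling_proxies <- function(binned) {
  stopifnot(inherits(binned, "binned_occurrences"))
  sc <- binned$scheme
  occ <- .assigned(binned)
  count_units <- function(ids, bins) {
    # distinct non-NA ids per bin
    keep <- !is.na(ids)
    ids <- ids[keep]; bins <- bins[keep]
    if (!length(ids)) return(integer(nrow(sc)))
    u <- !duplicated(paste(bins, ids, sep = "\r"))
    tabulate(bins[u], nbins = nrow(sc))
  }
  nm <- occ[occ$realm == "nonmarine", , drop = FALSE]
  ma <- occ[occ$realm == "marine", , drop = FALSE]
  data.frame(
    bin = seq_len(nrow(sc)), name = sc$name,
    TBF = count_units(nm$formation_id, nm$bin),
    TBC = count_units(nm$collection_id, nm$bin),
    MBF = count_units(ma$formation_id, ma$bin),
    MBC = count_units(ma$collection_id, ma$bin),
    stringsAsFactors = FALSE
  )
}

#' Write a per-bin curve to CSV
#'
#' Serializes `NA` as an empty field, keeping "no signal" distinct from 0.
#'
#' @param curve A `diversity_curve` or any per-bin data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, na = "")
  invisible(path)
}
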